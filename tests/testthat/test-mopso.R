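test_that("map_index is the worked-anchor-pinned equal-cell partition", {
  expect_equal(map_index(0.75, 18), 14L)  # the 9-NN anchor
  expect_equal(map_index(0.60, 9), 6L)
  expect_equal(map_index(0, 18), 1L)
  expect_equal(map_index(1, 18), 18L)
  # exhaustive grid: surjective, monotone, equal cells
  for (n in c(1, 2, 9, 18)) {
    x <- seq(0, 1, by = 1e-3)
    idx <- map_index(x, n)
    expect_setequal(idx, seq_len(n))
    expect_true(all(diff(idx) >= 0))
    expect_equal(idx, pmin(n, floor(x * n) + 1))
  }
  expect_error(map_index(1.2, 9), "domain error")
  expect_error(map_index(-0.1, 9), "domain error")
})

test_that("decode_position maps components through the variable-typed pools", {
  sch <- var_schema(c("d1", "c1", "y"),
                    c("discrete", "continuous", "discrete"),
                    c("independent", "independent", "dependent"))
  a <- decode_position(c(0, 0), c("d1", "c1"), sch)
  expect_equal(a$index, c(1L, 1L))
  b <- decode_position(c(0.75, 0.60), c("d1", "c1"), sch)
  expect_equal(b$index, c(14L, 6L))
  expect_equal(b$label[1], "9-NN")
  expect_equal(b$vtype, c("discrete", "continuous"))
})

test_that("swarm initialization is uniform, sized, and seed-deterministic", {
  cfg <- swarm_config(seed = 9)
  sw <- init_swarm(cfg, 3)
  expect_equal(dim(sw$position), c(100L, 3L))
  expect_true(all(sw$velocity == 0))
  expect_identical(sw$position, init_swarm(cfg, 3)$position)
  big <- init_swarm(swarm_config(n_particles = 2500, seed = 4), 4)
  expect_true(abs(mean(big$position) - 0.5) < 0.03)  # 1e4 components
  expect_true(all(big$position >= 0 & big$position <= 1))
})

test_that("velocity update attracts toward bests and clamps symmetrically", {
  cfg <- swarm_config(seed = 1)
  x <- c(0.5, 0.5)
  # pbest = leader = x -> v unchanged (then clamped)
  v <- update_velocity(c(0.1, -0.2), x, x, x, cfg, vmax = 1)
  expect_equal(v, c(0.1, -0.2))
  # upper clamp: forced pre-clamp value 1.4 -> 0.5
  v2 <- update_velocity(0.9, 0.5, 1, 0.75, cfg, vmax = 0.5,
                        r1 = 0.25, r2 = 0.25)
  expect_equal(v2, 0.5)
  # symmetric negative clamp
  v3 <- update_velocity(-0.8, 0.5, 0.5, 0.5, cfg, vmax = 0.5)
  expect_equal(v3, -0.5)
})

test_that("the velocity-clamp fraction decays geometrically from 1", {
  cfg <- swarm_config()
  expect_equal(vmax_schedule(0, cfg), 1)
  expect_equal(vmax_schedule(1, cfg), 0.9)
  expect_equal(vmax_schedule(2, cfg), 0.81)
  gens <- 0:30
  v <- vapply(gens, vmax_schedule, numeric(1), cfg = cfg)
  expect_true(all(diff(v) < 0))
  b <- cbind(c(0, -1), c(1, 1))
  expect_equal(vmax_schedule(1, cfg, bounds = b), c(0.9, 1.8))
})

test_that("archive updates keep exactly the non-dominated set", {
  a <- archive_update(new_archive(), c(0.5), c(0.2, 0.3))
  a2 <- archive_update(a, c(0.6), c(0.1, 0.1))
  expect_equal(nrow(a2), 1L)  # strict domination replaces
  expect_equal(a2$d_sensitivity, 0.1)
  a3 <- archive_update(archive_update(new_archive(), c(0.1), c(0.1, 0.4)),
                       c(0.9), c(0.4, 0.1))
  expect_equal(nrow(a3), 2L)  # mutual non-domination keeps both
  # dominated candidate is rejected
  a4 <- archive_update(a2, c(0.2), c(0.5, 0.5))
  expect_identical(a4, a2)
})

test_that("a 200-candidate stream matches the brute-force non-dominated filter", {
  withr::with_seed(31, {
    objs <- matrix(runif(400), ncol = 2)
  })
  arch <- new_archive()
  for (i in 1:200) {
    arch <- archive_update(arch, c(i / 200), objs[i, ], capacity = Inf)
  }
  # O(n^2) oracle over the whole stream
  nondom <- vapply(1:200, function(i) {
    !any(vapply(1:200, function(j) {
      all(objs[j, ] <= objs[i, ]) && any(objs[j, ] < objs[i, ])
    }, logical(1)))
  }, logical(1))
  oracle <- objs[nondom, , drop = FALSE]
  got <- cbind(arch$d_sensitivity, arch$d_specificity)
  expect_equal(nrow(got), nrow(oracle))
  expect_equal(got[order(got[, 1]), ], oracle[order(oracle[, 1]), ],
               ignore_attr = TRUE)
})

test_that("capacity overflow is pruned by crowding distance, extremes kept", {
  arch <- new_archive()
  # a clean front of 6 points; capacity 4 must keep both extremes
  front <- cbind(seq(0, 1, length.out = 6), seq(1, 0, length.out = 6))
  for (i in 1:6) arch <- archive_update(arch, c(i), front[i, ], capacity = 4)
  expect_equal(nrow(arch), 4L)
  expect_true(0 %in% arch$d_sensitivity)
  expect_true(0 %in% arch$d_specificity)
})

test_that("termination triggers on swarm collapse or the generation cap", {
  cfg <- swarm_config(rnorm_threshold = 0.01, max_generations = 50)
  pos <- matrix(0.4, nrow = 5, ncol = 2)
  t1 <- check_termination(pos, c(0.4, 0.4), diameter0 = 1, cfg, generation = 3)
  expect_true(t1$stop)
  expect_equal(t1$rmax, 0)
  spread <- rbind(c(0, 0), c(1, 1), c(0.5, 0.2), c(0.1, 0.9), c(0.3, 0.3))
  t2 <- check_termination(spread, c(0.5, 0.5), diameter0 = sqrt(2), cfg, 3)
  expect_false(t2$stop)
  # brute-force rmax: max distance of the 5 particles to the leader
  oracle <- max(sqrt(rowSums(sweep(spread, 2, c(0.5, 0.5))^2)))
  expect_equal(t2$rmax, oracle)
  expect_equal(t2$rnorm, oracle / sqrt(2))
  t3 <- check_termination(spread, c(0.5, 0.5), sqrt(2), cfg, generation = 50)
  expect_true(t3$stop)
  expect_warning(t4 <- check_termination(spread, c(0.5, 0.5), 0, cfg, 0),
                 "zero")
  expect_true(t4$stop)
})

test_that("final selection takes the accuracy argmax with a fair random tie-break", {
  sch <- var_schema(c("d1", "y"), c("discrete", "discrete"),
                    c("independent", "dependent"))
  arch <- new_archive()
  arch <- archive_update(arch, 0.05, c(0.3, 0.1))   # index 1
  arch <- archive_update(arch, 0.45, c(0.2, 0.2))   # index 9
  arch <- archive_update(arch, 0.95, c(0.1, 0.3))   # index 18
  accs <- c(`1` = 70.0, `9` = 72.5, `18` = 71.0)
  score <- function(asg) unname(accs[as.character(asg$index[1])])
  sel <- final_select(arch, score, "d1", sch, seed = 1)
  expect_equal(sel$assignment$index, 9L)

  # singleton archive
  single <- archive_update(new_archive(), 0.5, c(0.1, 0.1))
  expect_equal(final_select(single, function(a) 50, "d1", sch)$assignment$index,
               10L)

  # exact tie: binomial check over 1000 seeded draws
  accs_tie <- c(`1` = 72.5, `9` = 72.5, `18` = 60)
  score_tie <- function(asg) unname(accs_tie[as.character(asg$index[1])])
  picks <- vapply(1:1000, function(s) {
    final_select(arch, score_tie, "d1", sch, seed = s)$assignment$index
  }, integer(1))
  expect_true(abs(sum(picks == 1L) - 500) <= 60)
  expect_error(final_select(new_archive(), score, "d1", sch),
               "optimization failure")
})

test_that("swarm dynamics respect bounds and clamps at every step", {
  # a 20-generation synthetic run driven by a cheap deterministic objective
  cfg <- swarm_config(n_particles = 12, max_generations = 20,
                      rnorm_threshold = 0, seed = 21)
  sw <- init_swarm(cfg, 3)
  pos <- sw$position; vel <- sw$velocity
  pbest <- pos
  obj <- function(x) c(sum((x - 0.3)^2), sum((x - 0.7)^2))
  pfit <- t(apply(pos, 1, obj))
  arch <- new_archive()
  for (i in seq_len(nrow(pos))) arch <- archive_update(arch, pos[i, ], pfit[i, ])
  withr::with_seed(99, {
    for (g in 1:20) {
      vmax <- vmax_schedule(g, cfg)
      for (i in seq_len(nrow(pos))) {
        leader <- arch$position[[sample.int(nrow(arch), 1)]]
        vel[i, ] <- update_velocity(vel[i, ], pos[i, ], pbest[i, ], leader,
                                    cfg, vmax)
        pos[i, ] <- pmin(pmax(pos[i, ] + vel[i, ], 0), 1)
        f <- obj(pos[i, ])
        if (all(f <= pfit[i, ]) && any(f < pfit[i, ])) {
          pfit[i, ] <- f; pbest[i, ] <- pos[i, ]
        }
        arch <- archive_update(arch, pos[i, ], f)
      }
      expect_true(all(abs(vel) <= vmax + 1e-12), label = paste("gen", g))
      expect_true(all(pos >= 0 & pos <= 1), label = paste("gen", g))
      # archive invariant: mutually non-dominated
      om <- cbind(arch$d_sensitivity, arch$d_specificity)
      for (i in seq_len(nrow(om))) {
        expect_false(any(vapply(seq_len(nrow(om))[-i], function(j) {
          all(om[j, ] <= om[i, ]) && any(om[j, ] < om[i, ])
        }, logical(1))))
      }
    }
  })
})
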