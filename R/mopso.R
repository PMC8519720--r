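# Multiobjective particle swarm search over chain assignments.
# Particles live in [0,1]^n (n = chain length); each component maps to an
# algorithm index in its variable's pool; the two minimized objectives are
# the fitness pair (|delta sensitivity|, |delta specificity|).

#' Map a unit-interval coordinate to a pool index
#'
#' Deterministic transformation of a particle coordinate in `[0, 1]` onto the
#' discrete index range `1..n` of an algorithm pool: `min(n, floor(x * n) + 1)`.
#' The map partitions `[0, 1]` into `n` equal cells, is surjective onto
#' `1..n`, and is non-decreasing in `x`.
#'
#' @param x Numeric in `[0, 1]` (vectorized).
#' @param n Pool size (positive integer).
#' @return Integer vector in `1..n`.
#' @examples
#' map_index(0.75, 18)  # 14: the 9-NN row of the discrete pool
#' @export
map_index <- function(x, n) {
  stopifnot(n >= 1)
  if (any(x < 0 | x > 1)) {
    stop("domain error: coordinate outside [0, 1] reached map_index(); ",
         "positions must be clamped before mapping", call. = FALSE)
  }
  pmin.int(as.integer(n), as.integer(floor(x * n)) + 1L)
}

#' Decode a particle position into a chain assignment
#'
#' Component `j` maps through [map_index()] with pool size 18 when chain
#' variable `j` is discrete and 9 when continuous, and is paired with the
#' corresponding registry row.
#'
#' @param position Numeric vector in `[0, 1]^n`.
#' @param order Character vector of chain variables (see [chain_order()]).
#' @param schema The dataset's schema.
#' @return A [chain_assignment()].
#' @export
decode_position <- function(position, order, schema) {
  stopifnot(length(position) == length(order))
  vtypes <- schema$type[match(order, schema$name)]
  idx <- purrr::map2_int(position, vtypes,
                         function(x, vt) map_index(x, pool_size(vt)))
  chain_assignment(order, idx, schema = schema)
}

#' Swarm configuration
#'
#' @param n_particles Swarm size (default 100).
#' @param c1,c2 Cognitive and social acceleration coefficients (default 2).
#' @param inertia Velocity carry-over multiplier (default 1: the update rule
#'   carries the previous velocity unchanged).
#' @param delta0 Initial velocity-clamp fraction (default 1).
#' @param delta_decay Per-generation geometric decay of the clamp fraction
#'   (default 0.9, i.e. `delta(i) = 0.9^i`).
#' @param max_generations Generation cap (default 50).
#' @param rnorm_threshold Normalized swarm-radius termination tolerance
#'   (default 0.01).
#' @param archive_capacity Pareto-archive cap; overflow pruned by crowding
#'   distance (default 100).
#' @param seed Integer seed for swarm initialization and stochastic updates.
#' @return A list of class `"swarm_config"`.
#' @export
swarm_config <- function(n_particles = 100L, c1 = 2, c2 = 2, inertia = 1,
                         delta0 = 1, delta_decay = 0.9,
                         max_generations = 50L, rnorm_threshold = 0.01,
                         archive_capacity = 100L, seed = 1L) {
  stopifnot(n_particles >= 2, c1 > 0, c2 > 0,
            delta_decay > 0, delta_decay < 1)
  structure(list(n_particles = as.integer(n_particles), c1 = c1, c2 = c2,
                 inertia = inertia, delta0 = delta0,
                 delta_decay = delta_decay,
                 max_generations = as.integer(max_generations),
                 rnorm_threshold = rnorm_threshold,
                 archive_capacity = as.integer(archive_capacity),
                 seed = as.integer(seed)),
            class = "swarm_config")
}

#' Initialize the swarm
#'
#' Positions i.i.d. uniform on `[0, 1]` per component; velocities zero;
#' deterministic under the configured seed.
#'
#' @param cfg A [swarm_config()].
#' @param n_dims Number of chain variables.
#' @return List with matrices `position` and `velocity`
#'   (`n_particles x n_dims`).
#' @export
init_swarm <- function(cfg, n_dims) {
  stopifnot(n_dims >= 1)
  pos <- withr::with_seed(cfg$seed, {
    matrix(stats::runif(cfg$n_particles * n_dims),
           nrow = cfg$n_particles, ncol = n_dims)
  })
  list(position = pos,
       velocity = matrix(0, nrow = cfg$n_particles, ncol = n_dims))
}

#' Velocity-clamp schedule
#'
#' The per-dimension speed limit is a fraction `delta` of the dimension's
#' range; `delta` starts at 1 and decays geometrically each generation
#' (`delta(i) = decay^i`), shifting the swarm from exploration to
#' exploitation.
#'
#' @param generation Generation index (0-based).
#' @param cfg A [swarm_config()].
#' @param bounds Two-column matrix of per-dimension `(min, max)`; defaults to
#'   the unit box.
#' @return Numeric vector of per-dimension `vmax`.
#' @export
vmax_schedule <- function(generation, cfg, bounds = NULL) {
  stopifnot(generation >= 0)
  delta <- cfg$delta0 * cfg$delta_decay^generation
  if (is.null(bounds)) return(delta)
  delta * (bounds[, 2] - bounds[, 1])
}

#' One velocity update
#'
#' `v' = inertia * v + c1 r1 (pbest - x) + c2 r2 (leader - x)`, with `r1`,
#' `r2` uniform per component, then `|v'|` clamped symmetrically to `vmax`.
#'
#' @param velocity,position,pbest,leader Numeric vectors of equal length.
#' @param cfg A [swarm_config()].
#' @param vmax Positive clamp (scalar or per-dimension vector).
#' @param r1,r2 Optional fixed random factors (for deterministic checks);
#'   drawn uniform when `NULL`.
#' @return The clamped new velocity vector.
#' @export
update_velocity <- function(velocity, position, pbest, leader, cfg, vmax,
                            r1 = NULL, r2 = NULL) {
  stopifnot(all(vmax > 0))
  d <- length(velocity)
  if (is.null(r1)) r1 <- stats::runif(d)
  if (is.null(r2)) r2 <- stats::runif(d)
  v <- cfg$inertia * velocity +
    cfg$c1 * r1 * (pbest - position) +
    cfg$c2 * r2 * (leader - position)
  pmin(pmax(v, -vmax), vmax)
}

# --- Pareto archive ----------------------------------------------------------

# strict dominance for minimized objective pairs
dominates <- function(a, b) {
  all(a <= b) && any(a < b)
}

#' Update a Pareto archive with a candidate
#'
#' The archive holds mutually non-dominated (position, objective-pair)
#' entries for the two minimized objectives. A candidate enters iff no member
#' dominates it; members it dominates are removed; when the archive exceeds
#' `capacity` the most crowded entries (smallest crowding distance on the
#' objective plane) are pruned.
#'
#' @param archive A tibble with list-column `position` and numeric columns
#'   `d_sensitivity`, `d_specificity` (use [new_archive()] for an empty one).
#' @param position Numeric position vector of the candidate.
#' @param objectives Numeric pair `(d_sensitivity, d_specificity)`.
#' @param capacity Maximum archive size (`Inf` for unbounded).
#' @return The updated archive tibble.
#' @export
archive_update <- function(archive, position, objectives, capacity = Inf) {
  stopifnot(all(is.finite(objectives)), length(objectives) == 2)
  obj_mat <- cbind(archive$d_sensitivity, archive$d_specificity)
  if (nrow(archive)) {
    dominated_by_member <- any(apply(obj_mat, 1, function(m)
      dominates(m, objectives)))
    if (dominated_by_member) return(archive)
    keep <- !apply(obj_mat, 1, function(m) dominates(objectives, m))
    archive <- archive[keep, , drop = FALSE]
  }
  archive <- dplyr::bind_rows(
    archive,
    tibble::tibble(position = list(as.numeric(position)),
                   d_sensitivity = objectives[1],
                   d_specificity = objectives[2]))
  if (nrow(archive) > capacity) {
    cd <- crowding_distance(cbind(archive$d_sensitivity,
                                  archive$d_specificity))
    archive <- archive[order(cd, decreasing = TRUE)[seq_len(capacity)], ]
  }
  archive
}

#' Empty Pareto archive
#' @return A zero-row archive tibble.
#' @export
new_archive <- function() {
  tibble::tibble(position = list(), d_sensitivity = numeric(),
                 d_specificity = numeric())
}

# NSGA-II crowding distance on a two-objective matrix
crowding_distance <- function(obj) {
  n <- nrow(obj)
  if (n <= 2) return(rep(Inf, n))
  cd <- numeric(n)
  for (j in 1:2) {
    ord <- order(obj[, j])
    rng <- obj[ord[n], j] - obj[ord[1], j]
    cd[ord[c(1, n)]] <- Inf
    if (rng > 0) {
      for (i in 2:(n - 1)) {
        cd[ord[i]] <- cd[ord[i]] + (obj[ord[i + 1], j] - obj[ord[i - 1], j]) / rng
      }
    }
  }
  cd
}

# --- termination -------------------------------------------------------------

#' Swarm-radius termination check
#'
#' The search stops when the swarm has collapsed: the maximum Euclidean
#' distance from any particle to the leader (`rmax`), normalized by the
#' initial swarm diameter, falls below the threshold — or the generation cap
#' is reached.
#'
#' @param positions Matrix of current particle positions.
#' @param leader Leader position (termination reference).
#' @param diameter0 Maximum pairwise distance of the initial swarm.
#' @param cfg A [swarm_config()].
#' @param generation Current generation index.
#' @return A list: `stop` (logical), `rmax`, `rnorm`.
#' @export
check_termination <- function(positions, leader, diameter0, cfg, generation) {
  if (diameter0 == 0) {
    warning("initial swarm diameter is zero; terminating immediately",
            call. = FALSE)
    return(list(stop = TRUE, rmax = 0, rnorm = 0))
  }
  d <- sqrt(rowSums(sweep(positions, 2, leader)^2))
  rmax <- max(d)
  rnorm <- rmax / diameter0
  list(stop = rnorm < cfg$rnorm_threshold ||
         generation >= cfg$max_generations,
       rmax = rmax, rnorm = rnorm)
}

swarm_diameter <- function(positions) {
  max(stats::dist(positions))
}

# single deterministic leader used for the termination radius: the archive
# member with the smallest objective sum
termination_leader <- function(archive) {
  i <- which.min(archive$d_sensitivity + archive$d_specificity)
  archive$position[[i]]
}

# --- final selection ---------------------------------------------------------

#' Select the final assignment from the Pareto archive
#'
#' Every archive member's decoded assignment is re-scored for downstream
#' classification accuracy (a fresh seeded amputation/imputation/evaluation
#' pass, one per distinct assignment) and the highest-accuracy assignment is
#' returned; exact ties are broken uniformly at random under the seed.
#'
#' @param archive A non-empty Pareto archive.
#' @param score_fn `function(assignment) -> accuracy` on the percent scale.
#' @param order,schema Chain order and schema for decoding.
#' @param seed Integer seed for the tie-break.
#' @return A list: `assignment` (the winner), `scores` (tibble of distinct
#'   assignments with their accuracies).
#' @export
final_select <- function(archive, score_fn, order, schema, seed = 1L) {
  if (!nrow(archive)) {
    stop("optimization failure: empty Pareto archive", call. = FALSE)
  }
  assignments <- purrr::map(archive$position, decode_position,
                            order = order, schema = schema)
  key <- purrr::map_chr(assignments, ~ paste(.x$index, collapse = "-"))
  first <- !duplicated(key)
  assignments <- assignments[first]
  key <- key[first]
  acc <- purrr::map_dbl(assignments, score_fn)
  best <- which(acc == max(acc))
  pick <- if (length(best) == 1L) best else {
    withr::with_seed(seed, sample(best, 1L))
  }
  list(assignment = assignments[[pick]],
       scores = tibble::tibble(key = key, accuracy = acc,
                               selected = seq_along(acc) == pick))
}

# --- main search -------------------------------------------------------------

#' Search for the best imputation-algorithm assignment
#'
#' Runs the multiobjective particle swarm over the space of chain
#' assignments. Each particle is a point in `[0, 1]^n` (`n` = number of
#' incomplete variables); decoding maps each coordinate to an algorithm in
#' the variable's pool; the two minimized objectives are the mean absolute
#' sensitivity and specificity changes under simulated missingness
#' ([fitness()]). The Pareto archive collects non-dominated assignments;
#' each particle's velocity leader is a uniformly drawn archive member.
#' Positions decoding to an already-scored index vector reuse the cached
#' fitness (the objective is deterministic given the fitness seed).
#'
#' @param observational A fully observed [mds()] block.
#' @param profile A `"missingness_profile"` for the simulated missingness.
#' @param order Chain order; default [chain_order()] cannot be derived from a
#'   complete block, so pass the order measured on the real incomplete data.
#' @param cfg A [swarm_config()].
#' @param classifier Downstream classifier spec (default logistic
#'   regression).
#' @param n_repeats Amputation/imputation cycles per fitness evaluation.
#' @param fitness_seed Seed shared by all fitness evaluations (so particles
#'   are compared on identical simulated-missingness draws).
#' @param folds,positive Passed to [fitness()].
#' @param select_repeats Accuracy-scoring cycles inside the final selection.
#' @return An object of class `"mopso_result"`: list with `assignment` (the
#'   selected [chain_assignment()]), `archive`, `selection` (accuracy
#'   table), `trace` (per-generation tibble), `config`, `order`,
#'   `n_evaluations` (distinct assignments scored).
#' @export
mopso_select <- function(observational, profile, order,
                         cfg = swarm_config(),
                         classifier = registry_spec("discrete", 17L),
                         n_repeats = 100L, fitness_seed = NULL,
                         folds = 5L, positive = NULL,
                         select_repeats = 3L) {
  stopifnot(length(order) >= 1)
  if (is.null(fitness_seed)) fitness_seed <- cfg$seed + 10000L
  n_dims <- length(order)
  schema <- observational$schema
  cache <- new.env(parent = emptyenv())
  eval_position <- function(x) {
    idx <- purrr::map2_int(x, schema$type[match(order, schema$name)],
                           function(xi, vt) map_index(xi, pool_size(vt)))
    key <- paste(idx, collapse = "-")
    if (!is.null(cache[[key]])) return(cache[[key]])
    asg <- chain_assignment(order, idx, schema = schema)
    fit <- fitness(asg, observational, profile, classifier = classifier,
                   n_repeats = n_repeats, seed = fitness_seed, folds = folds,
                   positive = positive)
    out <- c(fit$d_sensitivity, fit$d_specificity)
    cache[[key]] <- out
    out
  }

  swarm <- init_swarm(cfg, n_dims)
  pos <- swarm$position
  vel <- swarm$velocity
  diameter0 <- swarm_diameter(pos)
  fit <- t(apply(pos, 1, eval_position))
  pbest_pos <- pos
  pbest_fit <- fit
  archive <- new_archive()
  for (i in seq_len(nrow(pos))) {
    archive <- archive_update(archive, pos[i, ], fit[i, ],
                              capacity = cfg$archive_capacity)
  }
  trace <- tibble::tibble(generation = 0L,
                          best_d_sensitivity = min(fit[, 1]),
                          best_d_specificity = min(fit[, 2]),
                          rnorm = NA_real_,
                          archive_size = nrow(archive))
  generation <- 0L
  withr::with_seed(cfg$seed + 1L, {
    repeat {
      leader_term <- termination_leader(archive)
      term <- check_termination(pos, leader_term, diameter0, cfg, generation)
      trace$rnorm[nrow(trace)] <- term$rnorm
      if (term$stop) break
      generation <- generation + 1L
      vmax <- vmax_schedule(generation, cfg)
      for (i in seq_len(nrow(pos))) {
        leader <- archive$position[[sample.int(nrow(archive), 1L)]]
        vel[i, ] <- update_velocity(vel[i, ], pos[i, ], pbest_pos[i, ],
                                    leader, cfg, vmax)
        pos[i, ] <- pmin(pmax(pos[i, ] + vel[i, ], 0), 1)
        f <- eval_position(pos[i, ])
        fit[i, ] <- f
        if (dominates(f, pbest_fit[i, ])) {
          pbest_fit[i, ] <- f
          pbest_pos[i, ] <- pos[i, ]
        }
        archive <- archive_update(archive, pos[i, ], f,
                                  capacity = cfg$archive_capacity)
      }
      trace <- dplyr::bind_rows(trace, tibble::tibble(
        generation = generation,
        best_d_sensitivity = min(fit[, 1]),
        best_d_specificity = min(fit[, 2]),
        rnorm = NA_real_,
        archive_size = nrow(archive)))
    }
  })

  score_fn <- function(asg) {
    s <- fitness_seed + 70001L
    accs <- purrr::map_dbl(seq_len(select_repeats), function(r) {
      amputed <- ampute(observational, profile, seed = s + r)
      completed <- impute_chain(amputed, asg, seed = s + r)
      cv_panel(completed, classifier, folds = folds, seed = s + r,
               positive = positive)$accuracy
    })
    mean(accs)
  }
  sel <- final_select(archive, score_fn, order, schema,
                      seed = cfg$seed + 2L)
  structure(list(assignment = sel$assignment, archive = archive,
                 selection = sel$scores, trace = trace, config = cfg,
                 order = order,
                 n_evaluations = length(ls(cache))),
            class = "mopso_result")
}

#' @export
print.mopso_result <- function(x, ...) {
  cat("<mopso_result> ", nrow(x$trace) - 1L, " generations, ",
      x$n_evaluations, " distinct assignments scored, archive size ",
      nrow(x$archive), "\n", sep = "")
  cat("selected assignment:\n")
  print(tibble::as_tibble(x$assignment))
  invisible(x)
}

#' @export
tidy.mopso_result <- function(x, ...) {
  tibble::tibble(
    member = seq_len(nrow(x$archive)),
    position = x$archive$position,
    d_sensitivity = x$archive$d_sensitivity,
    d_specificity = x$archive$d_specificity
  )
}

#' @export
glance.mopso_result <- function(x, ...) {
  tibble::tibble(
    generations = nrow(x$trace) - 1L,
    n_evaluations = x$n_evaluations,
    archive_size = nrow(x$archive),
    best_d_sensitivity = min(x$archive$d_sensitivity),
    best_d_specificity = min(x$archive$d_specificity),
    final_rnorm = x$trace$rnorm[nrow(x$trace)]
  )
}

#' Pareto front of a finished search
#'
#' Archive members on the objective plane (mean |delta sensitivity| vs mean
#' |delta specificity|, percent points), with the selected assignment's
#' objectives highlighted.
#'
#' @param object A `"mopso_result"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mopso_result <- function(object, ...) {
  front <- tidy(object)
  ggplot2::ggplot(front, ggplot2::aes(x = .data$d_sensitivity,
                                      y = .data$d_specificity)) +
    ggplot2::geom_step(direction = "vh", colour = "grey60",
                       data = front[order(front$d_sensitivity), ]) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "mean |Δ sensitivity| (pp)",
                  y = "mean |Δ specificity| (pp)",
                  title = "Pareto archive of imputation-algorithm assignments") +
    ggplot2::theme_minimal()
}
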