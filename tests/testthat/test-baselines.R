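test_that("listwise deletion keeps exactly the complete records", {
  df <- tibble::tibble(x1 = c(1, NA, 3, 4, NA, 6, 7, 8, 9, 10),
                       x2 = c(1, 2, NA, 4:10),
                       y = factor(rep(c("u", "v"), 5)))
  ds <- make_ds(df, c("continuous", "continuous", "discrete"))
  out <- impute_deletion(ds)
  expect_equal(nrow(out$data), sum(complete.cases(df)))
  expect_true(all(!is.na(out$data)))
  complete <- make_ds(df[6:10, ], c("continuous", "continuous", "discrete"))
  expect_identical(impute_deletion(complete)$data, complete$data)
  allholes <- make_ds(tibble::tibble(x1 = c(NA, NA), x2 = c(1, NA),
                                     y = factor(c("u", "v"))),
                      c("continuous", "continuous", "discrete"))
  expect_error(impute_deletion(allholes), "degenerate")

  # brute-force surviving count on a profile fixture
  fx <- generate_fixture("gastric", seed = 6)
  kept <- drop_high_missing(fx$amputed, 0.5)
  expect_equal(nrow(impute_deletion(kept)$data),
               sum(rowSums(is.na(kept$data)) == 0))
})

test_that("mean/mode imputation fills the hand-computed values", {
  df <- tibble::tibble(
    x1 = c(1, 2, 3, NA, 10, 20),
    x2 = c(NA, 4, 4, 8, NA, 8),
    g = factor(c("A", "A", "B", NA, "B", NA)),
    y = factor(rep(c("u", "v"), 3)))
  ds <- make_ds(df, c("continuous", "continuous", "discrete", "discrete"))
  out <- impute_mean(ds)
  expect_equal(out$data$x1[4], mean(c(1, 2, 3, 10, 20)))
  expect_equal(out$data$x2[c(1, 5)], c(6, 6))
  expect_equal(as.character(out$data$g[c(4, 6)]), c("A", "A"))  # tie -> first level
  expect_true(all(!is.na(out$data)))

  bad <- make_ds(tibble::tibble(x1 = c(NA_real_, NA_real_), x2 = c(1, 2),
                                y = factor(c("u", "v"))),
                 c("continuous", "continuous", "discrete"))
  expect_error(impute_mean(bad), "fully missing")
})

test_that("EM imputation exploits correlation that mean imputation ignores", {
  withr::with_seed(17, {
    x <- rnorm(200)
    ycol <- 0.9 * x + sqrt(1 - 0.81) * rnorm(200)
    df <- tibble::tibble(x1 = x, x2 = ycol,
                         y = factor(rep(c("u", "v"), 100)))
  })
  ds <- make_ds(df, c("continuous", "continuous", "discrete"))
  holes <- withr::with_seed(18, sample(200, 40))
  truth <- ds$data$x2[holes]
  ds$data$x2[holes] <- NA
  em <- impute_em(ds)
  mn <- impute_mean(ds)
  rmse <- function(v) sqrt(mean((v[holes] - truth)^2))
  expect_lt(rmse(em$data$x2), rmse(mn$data$x2))
  expect_true(all(!is.na(em$data)))

  # zero missing -> identity
  full <- make_ds(df, c("continuous", "continuous", "discrete"))
  expect_identical(impute_em(full)$data, full$data)

  # single continuous column: conditional = marginal mean
  one <- make_ds(tibble::tibble(x1 = c(1, 2, NA, 5), g = factor(c("A","B","A","B")),
                                y = factor(c("u", "v", "u", "v"))),
                 c("continuous", "discrete", "discrete"))
  expect_equal(impute_em(one)$data$x1[3], mean(c(1, 2, 5)))
})

test_that("chained-equations imputation is seeded, complete, and linearity-aware", {
  sim <- withr::with_seed(21, {
    x <- rnorm(60)
    tibble::tibble(x1 = x, x2 = 2 * x + rnorm(60, sd = 0.5),
                   y = factor(rep(c("u", "v"), 30)))
  })
  ds <- make_ds(sim, c("continuous", "continuous", "discrete"))
  expect_identical(impute_mice(ds, seed = 1)$data, ds$data)  # identity

  wins <- 0L
  for (s in 1:50) {
    holed <- ds
    holes <- withr::with_seed(200 + s, sample(60, 18))
    truth <- holed$data$x2[holes]
    holed$data$x2[holes] <- NA
    a <- impute_mice(holed, seed = s)
    b <- impute_mice(holed, seed = s)
    expect_identical(a$data, b$data)
    mn <- impute_mean(holed)
    rmse <- function(d) sqrt(mean((d$data$x2[holes] - truth)^2))
    if (rmse(a) < rmse(mn)) wins <- wins + 1L
  }
  expect_gte(wins / 50, 0.9)
})

test_that("random-forest imputation handles nonlinearity better than linear chains", {
  sim <- withr::with_seed(31, {
    x <- runif(80, -2, 2)
    tibble::tibble(x1 = x, x2 = x^2 + rnorm(80, sd = 0.2),
                   y = factor(rep(c("u", "v"), 40)))
  })
  ds <- make_ds(sim, c("continuous", "continuous", "discrete"))
  out0 <- impute_missforest(ds, seed = 1)
  expect_identical(out0$data, ds$data)
  expect_equal(attr(out0, "iterations"), 0L)

  wins <- 0L
  n_rep <- 50L
  for (s in seq_len(n_rep)) {
    holed <- ds
    holes <- withr::with_seed(300 + s, sample(80, 24))
    truth <- holed$data$x2[holes]
    holed$data$x2[holes] <- NA
    mf <- impute_missforest(holed, seed = s, num_trees = 50)
    mi <- impute_mice(holed, seed = s)
    rmse <- function(d) sqrt(mean((d$data$x2[holes] - truth)^2))
    if (rmse(mf) < rmse(mi)) wins <- wins + 1L
    expect_true(all(!is.na(mf$data)))
    expect_lte(attr(mf, "iterations"), 10L)
  }
  expect_gte(wins / n_rep, 0.7)
})

test_that("all imputers are completions that never alter observed cells", {
  fx <- generate_fixture("atll", seed = 9)
  ds <- drop_high_missing(fx$amputed, 0.5)
  obs <- !is.na(ds$data)
  for (f in list(impute_mean, impute_em,
                 function(d) impute_mice(d, seed = 2),
                 function(d) impute_missforest(d, seed = 2, num_trees = 30))) {
    out <- f(ds)
    expect_equal(sum(is.na(out$data)), 0L)
    for (v in names(ds$data)) {
      expect_identical(out$data[[v]][obs[, v]], ds$data[[v]][obs[, v]])
    }
  }
})

test_that("the benchmark report has one row per method with the six-metric panel", {
  sim <- simulate_clinical(60, 3, 1, correlation = 0.5,
                           missing_profile = c(x1 = 0.2, x2 = 0.15),
                           mechanism = "MCAR", seed = 12)
  rep <- benchmark_imputers(sim$amputed,
                            methods = c("deletion", "mean", "em", "mice",
                                        "missforest"),
                            protocol = "tenfold", n_runs = 3, seed = 4)
  expect_equal(nrow(rep), 5L)
  expect_true(all(c("sensitivity", "specificity", "accuracy", "ppv_pos",
                    "ppv_neg", "f_measure") %in% names(rep)))
  expect_true(all(rep$evaluable))
  expect_true(all(rep$accuracy >= 0 & rep$accuracy <= 100, na.rm = TRUE))

  one <- benchmark_imputers(sim$amputed, methods = "mean",
                            protocol = "split_70_30", n_runs = 3, seed = 4)
  expect_equal(nrow(one), 1L)
  expect_equal(attr(one, "protocol"), "split_70_30")

  long <- tidy(rep)
  expect_equal(nrow(long), 5L * 6L)
})

test_that("deletion leaving too few records is marked not evaluable, others proceed", {
  # heavy missingness: deletion leaves almost nothing for tenfold
  sim <- simulate_clinical(30, 3, 0, correlation = 0.3,
                           missing_profile = c(x1 = 0.5, x2 = 0.5, x3 = 0.5),
                           mechanism = "MCAR", seed = 3)
  rep <- benchmark_imputers(sim$amputed, methods = c("deletion", "mean"),
                            protocol = "tenfold", n_runs = 2, seed = 5)
  expect_false(rep$evaluable[rep$method == "deletion"])
  expect_true(rep$evaluable[rep$method == "mean"])
})
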