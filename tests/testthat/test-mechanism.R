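test_that("Little statistic matches a brute-force pattern-sum on a hand instance", {
  # 5 records x 3 continuous variables, two missingness patterns, with known
  # mean/covariance injected so the oracle is direct arithmetic
  X <- rbind(c(1, 2, 3),
             c(2, 1, 2),
             c(0, 3, 4),
             c(1.5, NA, NA),
             c(0.5, NA, NA))
  mu <- c(1, 2, 3)
  sigma <- diag(c(1, 2, 1.5))
  res <- little_mcar_test(X, mu = mu, sigma = sigma)

  # oracle: direct evaluation of sum_j k_j (ybar_j - mu_j)' S_j^-1 (ybar_j - mu_j)
  d_full <- colMeans(X[1:3, ]) - mu
  d_part <- mean(X[4:5, 1]) - mu[1]
  oracle <- 3 * drop(t(d_full) %*% solve(sigma) %*% d_full) +
    2 * d_part^2 / sigma[1, 1]
  expect_equal(res$statistic, oracle, tolerance = 1e-12)
  expect_equal(res$df, (3 + 1) - 3)
  expect_equal(res$n_patterns, 2L)
  expect_equal(res$p_value, pchisq(oracle, 1, lower.tail = FALSE))
})

test_that("Little test is vacuous on a single missingness pattern", {
  ds <- make_ds(tibble::tibble(a = rnorm(10), b = rnorm(10),
                               y = rep(c("u", "v"), 5)),
                c("continuous", "continuous", "discrete"))
  res <- little_mcar_test(ds)
  expect_false(res$applicable)
  expect_true(is.na(res$p_value))
  expect_error(little_mcar_test(make_ds(
    tibble::tibble(a = rnorm(5), y = rep(c("u", "v"), length.out = 5)),
    c("continuous", "discrete"))), "2 continuous")
})

test_that("mechanism resolution follows the test / declaration / MNAR policy", {
  ds <- generate_fixture("atll", seed = 1)$amputed
  fake <- function(p) structure(list(statistic = 1, df = 1, p_value = p,
                                     n_patterns = 3, applicable = TRUE),
                                class = "little_test")
  expect_equal(resolve_mechanism(ds, test = fake(0.6))$mechanism, "MCAR")
  expect_equal(resolve_mechanism(ds, test = fake(0.01), declared = "mar",
                                 mar_driver = c(x1 = "x20"))$mechanism, "MAR")
  expect_equal(resolve_mechanism(ds, test = fake(0.01))$mechanism, "MNAR")
  expect_error(resolve_mechanism(ds, test = fake(0.01), declared = "mar"),
               "mar_driver")
  prof <- resolve_mechanism(ds, test = fake(0.6))
  expect_equal(sum(prof$patterns$count), nrow(ds$data))
  expect_true(all(prof$per_var_fraction > 0))
})

test_that("amputation hits requested counts exactly under every mechanism", {
  base <- withr::with_seed(7, tibble::tibble(
    x1 = rnorm(50), x2 = rnorm(50),
    y = factor(rep(c("u", "v"), 25))))
  ds <- make_ds(base, c("continuous", "continuous", "discrete"))
  for (mech in c("MCAR", "MAR", "MNAR")) {
    prof <- missingness_profile(
      c(x1 = 0.30), mechanism = mech,
      mar_driver = if (mech == "MAR") c(x1 = "x2"))
    out <- ampute(ds, prof, seed = 3)
    expect_equal(sum(is.na(out$data$x1)), 15L)
    expect_equal(sum(is.na(out$data$x2)), 0L)
    expect_equal(sum(is.na(out$data$y)), 0L)
    # deterministic under the seed
    out2 <- ampute(ds, prof, seed = 3)
    expect_identical(out$data, out2$data)
  }
  # zero fraction is the identity
  none <- ampute(ds, missingness_profile(c(x1 = 0)), seed = 1)
  expect_identical(none$data, ds$data)
})

test_that("MNAR amputation deletes exactly the requested tail", {
  ds <- make_ds(tibble::tibble(x1 = as.numeric(1:100),
                               y = factor(rep(c("u", "v"), 50))),
                c("continuous", "discrete"))
  up <- ampute(ds, missingness_profile(c(x1 = 0.2), "MNAR"), seed = 1)
  expect_equal(which(is.na(up$data$x1)), 81:100)
  lo <- ampute(ds, missingness_profile(c(x1 = 0.2), "MNAR",
                                       mnar_tail = "lower"), seed = 1)
  expect_equal(which(is.na(lo$data$x1)), 1:20)
  both <- ampute(ds, missingness_profile(c(x1 = 0.2), "MNAR",
                                         mnar_tail = "both"), seed = 1)
  expect_equal(which(is.na(both$data$x1)), c(1:10, 91:100))
})

test_that("amputation guards its preconditions", {
  ds <- make_ds(tibble::tibble(x1 = rnorm(10), x2 = rnorm(10),
                               y = factor(rep(c("u", "v"), 5))),
                c("continuous", "continuous", "discrete"))
  expect_error(ampute(ds, missingness_profile(c(y = 0.2))), "dependent")
  expect_error(ampute(ds, missingness_profile(c(x1 = 1.5))), "fraction")
  holed <- ds; holed$data$x1[1] <- NA
  expect_error(ampute(holed, missingness_profile(c(x2 = 0.2))),
               "fully observed")
  expect_error(ampute(ds, missingness_profile(c(x1 = 0.2), "MAR",
                                              mar_driver = c(x1 = "x2")),
                      seed = 1), NA)
})

test_that("MAR amputation concentrates missingness where the driver is high", {
  base <- tibble::tibble(x1 = rnorm(400), x2 = seq(-3, 3, length.out = 400),
                         y = factor(rep(c("u", "v"), 200)))
  ds <- make_ds(base, c("continuous", "continuous", "discrete"))
  prof <- missingness_profile(c(x1 = 0.4), "MAR", mar_driver = c(x1 = "x2"))
  hit_high <- mean(vapply(1:20, function(s) {
    out <- ampute(ds, prof, seed = s)
    mean(ds$data$x2[is.na(out$data$x1)] > 0)
  }, numeric(1)))
  expect_gt(hit_high, 0.55)  # upper-driver rows are preferentially deleted
})

test_that("mice_bootstrap promotes exactly enough records, fewest-missing first", {
  withr::with_seed(11, {
    df <- tibble::tibble(x1 = rnorm(100), x2 = rnorm(100), x3 = rnorm(100),
                         y = factor(rep(c("u", "v"), 50)))
    # 37 complete; 33 records missing one cell; 30 missing two
    df$x1[38:70] <- NA
    df$x1[71:100] <- NA
    df$x2[71:100] <- NA
  })
  ds <- make_ds(df, c(rep("continuous", 3), "discrete"))
  expect_equal(sum(complete.cases(ds$data)), 37L)
  out <- mice_bootstrap(ds, target_fraction = 0.5, seed = 2)
  expect_equal(sum(complete.cases(out$data)), 50L)
  # the 13 promoted records are among those missing a single cell
  promoted <- which(complete.cases(out$data) & !complete.cases(ds$data))
  expect_length(promoted, 13L)
  expect_true(all(promoted %in% 38:70))
  # untouched records keep their holes
  expect_true(all(is.na(out$data$x1[84:100])))

  # no-op above target
  ok <- make_ds(tibble::tibble(x1 = c(rnorm(60), rep(NA, 40)),
                               x2 = rnorm(100),
                               y = factor(rep(c("u", "v"), 50))),
                c("continuous", "continuous", "discrete"))
  expect_identical(mice_bootstrap(ok, 0.5, seed = 1)$data, ok$data)

  # zero complete records of 10 -> 5 promoted (ceil(0.5 * 10) - 0)
  allmiss <- withr::with_seed(4, tibble::tibble(
    x1 = c(rep(NA_real_, 5), rnorm(5)),
    x2 = c(rnorm(5), rep(NA_real_, 5)),
    y = factor(rep(c("u", "v"), 5))))
  allmiss <- make_ds(allmiss, c("continuous", "continuous", "discrete"))
  expect_equal(sum(complete.cases(allmiss$data)), 0L)
  out2 <- mice_bootstrap(allmiss, 0.5, seed = 3)
  expect_equal(sum(complete.cases(out2$data)), 5L)
})
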