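# Small programmatic fixtures shared across the suite.

# mds from a data frame with type/role vectors in column order
make_ds <- function(df, types, roles = NULL) {
  if (is.null(roles)) {
    roles <- c(rep("independent", ncol(df) - 1L), "dependent")
  }
  suppressWarnings(mds(df, var_schema(names(df), types, roles)))
}

# a fully observed mixed table with a binary outcome
toy_complete <- function(n = 20, seed = 42) {
  withr::with_seed(seed, {
    tibble::tibble(
      a = rnorm(n),
      b = rnorm(n),
      g = factor(sample(c("u", "v"), n, replace = TRUE)),
      outcome = factor(sample(c("neg", "pos"), n, replace = TRUE))
    )
  })
}

toy_types <- c("continuous", "continuous", "discrete", "discrete")

# dataset whose outcome is strongly driven by x1, with x1 linear in x2:
# the substrate for selection-recovery checks
linear_target_ds <- function(n = 60, noise = 0.3, seed = 1) {
  withr::with_seed(seed, {
    x2 <- rnorm(n)
    x1 <- 2 * x2 + rnorm(n, sd = noise)
    outcome <- factor(ifelse(runif(n) < plogis(2 * x1), "pos", "neg"),
                      levels = c("neg", "pos"))
    tibble::tibble(x1 = x1, x2 = x2, outcome = outcome)
  })
}

# gastric-shaped amputed fixture (Table-3-like missingness profile)
gastric_fixture <- function(seed = 1) generate_fixture("gastric", seed = seed)
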