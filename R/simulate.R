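# Seeded generator of mixed-type clinical fixtures with known generative
# structure and mechanism-controlled missingness.

#' Simulate a mixed-type clinical dataset with controlled missingness
#'
#' Generates records from an equicorrelated latent Gaussian: continuous
#' variables are the latent scores; discrete variables are quantile-
#' thresholded latent scores with 2–4 levels; the binary outcome is drawn
#' from a logistic link on the latent scores. Missing cells are then created
#' by mechanism-faithful amputation ([ampute()]) so that every deleted
#' cell's true value is known.
#'
#' Variables are named `x1..xp` (the first `n_continuous` are continuous,
#' the rest discrete); the dependent variable is `outcome` with levels
#' `"neg"`/`"pos"`.
#'
#' @param n_records Number of records.
#' @param n_continuous,n_discrete Counts of continuous and discrete
#'   independent variables.
#' @param correlation Latent pairwise (equi)correlation in `[0, 1)`.
#' @param outcome_coefficients Logistic-link coefficients on the latent
#'   scores; default: the first half of the variables get 1, the rest 0, so
#'   feature relevance is known.
#' @param missing_profile Named numeric vector variable -> missing fraction;
#'   default: no missingness.
#' @param mechanism `"MCAR"`, `"MAR"` or `"MNAR"`.
#' @param mar_driver Named character map (amputed variable -> driver).
#' @param mnar_tail `"upper"`, `"lower"` or `"both"`.
#' @param seed Integer seed; the full triple is deterministic given it.
#' @return A list: `complete` (fully observed [mds()]), `amputed` ([mds()]
#'   with the requested missingness), `ground_truth` (tibble `row`,
#'   `variable`, `value` for every deleted cell), `profile` (the
#'   missingness profile used).
#' @export
simulate_clinical <- function(n_records, n_continuous, n_discrete,
                              correlation = 0.3,
                              outcome_coefficients = NULL,
                              missing_profile = NULL,
                              mechanism = "MCAR", mar_driver = NULL,
                              mnar_tail = "upper", seed = 1L) {
  p <- n_continuous + n_discrete
  stopifnot(p >= 1, n_records >= 1, correlation >= 0, correlation < 1)
  if (is.null(outcome_coefficients)) {
    outcome_coefficients <- rep(c(1, 0), c(ceiling(p / 2), floor(p / 2)))
  }
  stopifnot(length(outcome_coefficients) == p)
  vars <- paste0("x", seq_len(p))
  types <- rep(c("continuous", "discrete"), c(n_continuous, n_discrete))
  latent <- withr::with_seed(seed, {
    g <- stats::rnorm(n_records)
    sqrt(correlation) * matrix(g, n_records, p) +
      sqrt(1 - correlation) * matrix(stats::rnorm(n_records * p),
                                     n_records, p)
  })
  colnames(latent) <- vars
  df <- tibble::as_tibble(latent)
  withr::with_seed(seed + 1L, {
    n_levels_cycle <- rep_len(2:4, max(1, n_discrete))
    for (j in seq_len(n_discrete)) {
      v <- vars[n_continuous + j]
      L <- n_levels_cycle[j]
      cuts <- stats::quantile(df[[v]], probs = seq(0, 1, length.out = L + 1))
      cuts[1] <- -Inf; cuts[L + 1] <- Inf
      df[[v]] <- factor(paste0("l", as.integer(cut(df[[v]], cuts))),
                        levels = paste0("l", seq_len(L)))
    }
    eta <- drop(scale(latent) %*% outcome_coefficients)
    df$outcome <- factor(ifelse(stats::runif(n_records) < stats::plogis(eta),
                                "pos", "neg"), levels = c("neg", "pos"))
  })
  schema <- var_schema(c(vars, "outcome"), c(types, "discrete"),
                       c(rep("independent", p), "dependent"))
  complete <- mds(df, schema)
  if (is.null(missing_profile) || !length(missing_profile)) {
    return(list(complete = complete, amputed = complete,
                ground_truth = tibble::tibble(row = integer(),
                                              variable = character(),
                                              value = character()),
                profile = NULL))
  }
  bad <- setdiff(names(missing_profile), vars)
  if (length(bad)) stop("missing_profile names unknown: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  profile <- missingness_profile(missing_profile, mechanism = mechanism,
                                 mar_driver = mar_driver,
                                 mnar_tail = mnar_tail)
  amputed <- ampute(complete, profile, seed = seed + 2L)
  holes <- which(is.na(amputed$data) & !is.na(complete$data), arr.ind = TRUE)
  ground_truth <- tibble::tibble(
    row = unname(holes[, 1]),
    variable = names(complete$data)[holes[, 2]],
    value = purrr::map2_chr(holes[, 1], holes[, 2],
                            ~ as.character(complete$data[[.y]][.x]))
  )
  list(complete = complete, amputed = amputed, ground_truth = ground_truth,
       profile = profile)
}

#' Case-study-shaped fixture presets
#'
#' Two presets emulating the shapes and missingness profiles of the package's
#' motivating case studies (only shapes, types and missing fractions — not
#' clinical marginal distributions):
#' \describe{
#'   \item{`"gastric"`}{80 records, 15 independent variables (3 continuous,
#'     12 discrete), 8 variables with missingness from 1.25% to 88.75%
#'     (354 of 1200 cells, 29.5% overall).}
#'   \item{`"atll"`}{25 records, 35 independent variables (30 continuous,
#'     5 discrete), 12 variables with missingness from 4% to 48%.}
#' }
#'
#' @param preset `"gastric"` or `"atll"`.
#' @param seed Integer seed.
#' @param mechanism Amputation mechanism for the preset (default MCAR).
#' @return The argument list for [simulate_clinical()]; pass through
#'   [generate_fixture()] to materialize it.
#' @export
fixture_preset <- function(preset = c("gastric", "atll"), seed = 1L,
                           mechanism = "MCAR") {
  preset <- match.arg(preset)
  if (preset == "gastric") {
    list(n_records = 80L, n_continuous = 3L, n_discrete = 12L,
         correlation = 0.3,
         missing_profile = c(x1 = 0.725, x2 = 0.05, x3 = 0.0125,
                             x4 = 0.8875, x5 = 0.80, x6 = 0.80,
                             x7 = 0.7125, x8 = 0.4375),
         mechanism = mechanism, seed = seed)
  } else {
    list(n_records = 25L, n_continuous = 30L, n_discrete = 5L,
         correlation = 0.3,
         missing_profile = c(x1 = 0.48, x2 = 0.32, x3 = 0.32, x4 = 0.32,
                             x5 = 0.32, x6 = 0.20, x7 = 0.20, x8 = 0.20,
                             x9 = 0.04, x10 = 0.04, x11 = 0.04, x12 = 0.04),
         mechanism = mechanism, seed = seed)
  }
}

#' Materialize a fixture preset
#'
#' @param preset `"gastric"`, `"atll"`, or an argument list from
#'   [fixture_preset()].
#' @param ... Overrides merged over the preset's arguments.
#' @return See [simulate_clinical()].
#' @export
generate_fixture <- function(preset, ...) {
  args <- if (is.character(preset)) fixture_preset(preset) else preset
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulate_clinical, args)
}
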