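#' Binary classification metric panel
#'
#' Sensitivity, specificity, accuracy, positive/negative predictive values
#' and the F-measure (harmonic mean of sensitivity and PPV+), all on the
#' percent scale. Ratios with a zero denominator are reported as 0 and the
#' panel is flagged degenerate.
#'
#' @param truth Vector of true class labels (exactly two distinct labels).
#' @param predicted Vector of predicted labels, same length.
#' @param positive The label counted as positive; default: the
#'   lexicographically last observed label.
#' @return A one-row tibble: `sensitivity`, `specificity`, `accuracy`,
#'   `ppv_pos`, `ppv_neg`, `f_measure` (percent), `degenerate` (logical).
#' @examples
#' metric_panel(c(1, 1, 0, 0), c(1, 0, 0, 0), positive = "1")
#' @export
metric_panel <- function(truth, predicted, positive = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted), length(truth) >= 1)
  labs <- sort(unique(truth))
  if (length(labs) > 2L) {
    stop("unsupported target: metric panel requires a binary label space, got ",
         length(labs), " labels", call. = FALSE)
  }
  if (is.null(positive)) positive <- labs[length(labs)]
  pos_t <- truth == positive
  pos_p <- predicted == positive
  tp <- sum(pos_t & pos_p)
  fn <- sum(pos_t & !pos_p)
  tn <- sum(!pos_t & !pos_p)
  fp <- sum(!pos_t & pos_p)
  degenerate <- FALSE
  ratio <- function(num, den) {
    if (den == 0) {
      degenerate <<- TRUE
      0
    } else 100 * num / den
  }
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  acc <- ratio(tp + tn, tp + fn + tn + fp)
  ppvp <- ratio(tp, tp + fp)
  ppvn <- ratio(tn, tn + fn)
  fm <- if (sens + ppvp == 0) {
    degenerate <- TRUE
    0
  } else 2 * sens * ppvp / (sens + ppvp)
  tibble::tibble(sensitivity = sens, specificity = spec, accuracy = acc,
                 ppv_pos = ppvp, ppv_neg = ppvn, f_measure = fm,
                 degenerate = degenerate)
}

# stratified k-fold ids (per class, cyclic assignment after a shuffle)
stratified_folds <- function(y, folds, seed) {
  ids <- integer(length(y))
  withr::with_seed(seed, {
    for (lev in unique(y)) {
      idx <- which(y == lev)
      idx <- idx[sample.int(length(idx))]
      ids[idx] <- rep_len(sample.int(folds), length(idx))
    }
  })
  ids
}

# cross-validated panel on a complete dataset: confusion counts pooled over
# folds into a single panel
cv_panel <- function(ds, classifier, folds = 5L, seed = 1L, positive = NULL) {
  dep <- dependent_var(ds)
  y <- droplevels(ds$data[[dep]])
  X <- ds$data[independent_vars(ds)]
  if (nlevels(y) < 2L) {
    stop("optimization-setup error: dependent variable has a single observed ",
         "class; classification metrics undefined", call. = FALSE)
  }
  folds <- min(folds, min(table(y)))
  folds <- max(folds, 2L)
  ids <- stratified_folds(y, folds, seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in sort(unique(ids))) {
    test <- ids == f
    p <- fit_predict(classifier, X[!test, , drop = FALSE], y[!test],
                     X[test, , drop = FALSE], seed = seed + f)
    pred[test] <- factor(as.character(p), levels = levels(y))
  }
  metric_panel(y, pred, positive = positive)
}

#' Two-objective fitness of a chain assignment
#'
#' Scores how well an assignment of imputation algorithms preserves the
#' downstream classifier: `n_repeats` times, missing cells are simulated in
#' the observational block under the resolved mechanism profile and imputed
#' along the chain with the candidate assignment; the cross-validated metric
#' panel of the imputed block is compared against the panel of the intact
#' block evaluated on the *same* fold draw (a paired comparison — identical
#' data yields an exactly zero difference). The fitness is the pair of mean
#' absolute differences (|delta sensitivity|, |delta specificity|), in
#' percent points — lower is better on both.
#'
#' @param assignment A [chain_assignment()].
#' @param observational A fully observed [mds()] block.
#' @param profile A `"missingness_profile"` describing the simulated
#'   missingness.
#' @param classifier A discrete registry spec used as the downstream
#'   classifier; default logistic regression (discrete pool index 17).
#' @param n_repeats Number of amputation/imputation cycles (default 100).
#' @param seed Integer seed; repeat `r` uses `seed + r` for its amputation
#'   draw and its cross-validation folds.
#' @param folds Cross-validation folds (default 5, stratified).
#' @param positive Positive class label (default: lexicographically last).
#' @param imputer Optional override: a `function(amputed_mds, seed)` that
#'   returns a completed [mds()], replacing the chain executor. Used to
#'   score reference imputations (e.g. ground-truth restoration or pure
#'   noise) on the same objectives.
#' @return An object of class `"dyn_fitness"`: list with `d_sensitivity`,
#'   `d_specificity`, `n_repeats`, `per_repeat` (tibble of per-cycle pairs)
#'   and `baseline` (the intact panel).
#' @export
fitness <- function(assignment, observational, profile,
                    classifier = registry_spec("discrete", 17L),
                    n_repeats = 100L, seed = 1L, folds = 5L,
                    positive = NULL, imputer = NULL) {
  stopifnot(n_repeats >= 1)
  if (anyNA(observational$data)) {
    stop("fitness() expects a fully observed observational block",
         call. = FALSE)
  }
  baseline <- cv_panel(observational, classifier, folds = folds, seed = seed,
                       positive = positive)
  base_cache <- new.env(parent = emptyenv())
  per <- purrr::map_dfr(seq_len(n_repeats), function(r) {
    s <- seed + r
    amputed <- ampute(observational, profile, seed = s)
    completed <- if (is.null(imputer)) {
      impute_chain(amputed, assignment, seed = s)
    } else {
      imputer(amputed, s)
    }
    panel <- cv_panel(completed, classifier, folds = folds, seed = s,
                      positive = positive)
    # intact-block panel under the same fold draw: the paired reference
    key <- as.character(s)
    if (is.null(base_cache[[key]])) {
      base_cache[[key]] <- cv_panel(observational, classifier, folds = folds,
                                    seed = s, positive = positive)
    }
    base <- base_cache[[key]]
    tibble::tibble(repeat_id = r,
                   d_sensitivity = abs(panel$sensitivity - base$sensitivity),
                   d_specificity = abs(panel$specificity - base$specificity),
                   accuracy = panel$accuracy)
  })
  structure(list(d_sensitivity = mean(per$d_sensitivity),
                 d_specificity = mean(per$d_specificity),
                 n_repeats = n_repeats, per_repeat = per,
                 baseline = baseline),
            class = "dyn_fitness")
}

#' @export
print.dyn_fitness <- function(x, ...) {
  cat(sprintf("<dyn_fitness> d_sensitivity = %.3f, d_specificity = %.3f (%d repeats)\n",
              x$d_sensitivity, x$d_specificity, x$n_repeats))
  invisible(x)
}

#' @export
tidy.dyn_fitness <- function(x, ...) x$per_repeat

#' @export
glance.dyn_fitness <- function(x, ...) {
  tibble::tibble(d_sensitivity = x$d_sensitivity,
                 d_specificity = x$d_specificity,
                 n_repeats = x$n_repeats,
                 baseline_sensitivity = x$baseline$sensitivity,
                 baseline_specificity = x$baseline$specificity)
}
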