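#' @importFrom rlang .data
#' @importFrom stats pchisq complete.cases predict sd var
NULL

# --- multivariate-normal EM with missing data --------------------------------

# EM estimates of mean and covariance of a numeric matrix with NAs.
# Rows are grouped by missingness pattern; the E-step fills conditional
# expectations E[y_mis | y_obs] and adds the conditional covariance to the
# second-moment accumulator. Convergence on observed-data log-likelihood.
em_norm <- function(X, tol = 1e-6, max_iter = 500, ridge = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p == 1L) {
    mu <- mean(X, na.rm = TRUE)
    s2 <- stats::var(as.numeric(X[!is.na(X)])) * (sum(!is.na(X)) - 1) /
      max(1, sum(!is.na(X)))
    return(list(mu = mu, sigma = matrix(max(s2, ridge), 1, 1),
                iterations = 0L, converged = TRUE))
  }
  mu <- colMeans(X, na.rm = TRUE)
  sig <- diag(apply(X, 2, function(c) {
    v <- stats::var(c, na.rm = TRUE)
    if (!is.finite(v) || v <= 0) 1 else v
  }), p)
  pat_key <- apply(is.na(X), 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pat_key)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    T1 <- numeric(p)
    T2 <- matrix(0, p, p)
    ll <- 0
    for (rows in groups) {
      mis <- is.na(X[rows[1], ])
      obs <- !mis
      Yo <- X[rows, obs, drop = FALSE]
      k <- length(rows)
      if (!any(obs)) {
        Yfull <- matrix(mu, k, p, byrow = TRUE)
        T1 <- T1 + colSums(Yfull)
        T2 <- T2 + crossprod(Yfull) + k * sig
        next
      }
      Soo <- sig[obs, obs, drop = FALSE]
      Soo_inv <- solve(Soo + diag(ridge, sum(obs)))
      dev <- sweep(Yo, 2, mu[obs])
      # observed-data log-likelihood contribution
      ld <- determinant(Soo, logarithm = TRUE)$modulus
      quad <- rowSums((dev %*% Soo_inv) * dev)
      ll <- ll + sum(-0.5 * (sum(obs) * log(2 * pi) + ld + quad))
      Yfull <- matrix(0, k, p)
      Yfull[, obs] <- Yo
      if (any(mis)) {
        Smo <- sig[mis, obs, drop = FALSE]
        B <- Smo %*% Soo_inv
        Yfull[, mis] <- matrix(mu[mis], k, sum(mis), byrow = TRUE) +
          dev %*% t(B)
        Cmm <- sig[mis, mis, drop = FALSE] - B %*% t(Smo)
        T2[mis, mis] <- T2[mis, mis] + k * Cmm
      }
      T1 <- T1 + colSums(Yfull)
      T2 <- T2 + crossprod(Yfull)
    }
    mu <- T1 / n
    sig <- T2 / n - tcrossprod(mu)
    sig <- (sig + t(sig)) / 2
    diag(sig) <- diag(sig) + ridge
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(mu = mu, sigma = sig, iterations = iter, converged = converged)
}

# --- Little's MCAR test ------------------------------------------------------

#' Little's MCAR test
#'
#' Chi-square test of the missing-completely-at-random hypothesis: for each
#' distinct missingness pattern j with k_j records, the pattern's observed-
#' variable means are compared against EM estimates of the grand mean and
#' covariance, d2 = sum_j k_j (ybar_j - mu_j)' Sigma_j^-1 (ybar_j - mu_j),
#' with degrees of freedom (sum_j p_j) - p. Under MCAR the pattern means all
#' estimate the same mean and d2 is asymptotically chi-square; a small
#' p-value argues against MCAR.
#'
#' The test operates on the continuous variables only (its multivariate-normal
#' EM estimates are undefined for nominal data); discrete variables are
#' ignored here but still amputed and imputed elsewhere.
#'
#' @param ds An [mds()] object (or a numeric data frame / matrix).
#' @param tol,max_iter,ridge EM convergence controls.
#' @param mu,sigma Optional known mean vector and covariance matrix; when
#'   supplied the EM step is skipped (used for hand-checkable instances).
#' @return An object of class `"little_test"`: list with `statistic`, `df`,
#'   `p_value`, `n_patterns`, `applicable`. When fewer than two distinct
#'   missingness patterns exist, the test is vacuous: `applicable = FALSE`
#'   and `p_value = NA` (treated as consistent with MCAR downstream).
#' @export
little_mcar_test <- function(ds, tol = 1e-6, max_iter = 500, ridge = 1e-8,
                             mu = NULL, sigma = NULL) {
  X <- if (inherits(ds, "mds")) {
    cont <- ds$schema$name[ds$schema$type == "continuous"]
    if (length(cont) < 2L) {
      stop("Little's test needs at least 2 continuous variables", call. = FALSE)
    }
    as.matrix(ds$data[cont])
  } else as.matrix(ds)
  storage.mode(X) <- "double"
  pat_key <- apply(is.na(X), 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(nrow(X)), pat_key)
  # rows with no observed continuous value contribute nothing
  groups <- Filter(function(rows) any(!is.na(X[rows[1], ])), groups)
  n_patterns <- length(groups)
  if (n_patterns < 2L) {
    return(structure(list(statistic = 0, df = 0L, p_value = NA_real_,
                          n_patterns = n_patterns, applicable = FALSE),
                     class = "little_test"))
  }
  if (is.null(mu) || is.null(sigma)) {
    est <- em_norm(X, tol = tol, max_iter = max_iter, ridge = ridge)
    mu <- est$mu
    sigma <- est$sigma
  }
  p <- ncol(X)
  d2 <- 0
  sum_pj <- 0L
  for (rows in groups) {
    obs <- !is.na(X[rows[1], ])
    ybar <- colMeans(X[rows, obs, drop = FALSE])
    Soo <- sigma[obs, obs, drop = FALSE]
    Soo_inv <- tryCatch(solve(Soo), error = function(e) {
      stop("numerical error: restricted covariance is singular for a ",
           "missingness pattern; consider dropping collinear columns",
           call. = FALSE)
    })
    diff <- ybar - mu[obs]
    d2 <- d2 + length(rows) * drop(t(diff) %*% Soo_inv %*% diff)
    sum_pj <- sum_pj + sum(obs)
  }
  df <- sum_pj - p
  structure(list(statistic = d2, df = df,
                 p_value = stats::pchisq(d2, df, lower.tail = FALSE),
                 n_patterns = n_patterns, applicable = TRUE),
            class = "little_test")
}

#' @export
print.little_test <- function(x, ...) {
  cat("Little's MCAR test\n")
  if (!x$applicable) {
    cat("  not applicable: ", x$n_patterns,
        " missingness pattern(s); treated as consistent with MCAR\n", sep = "")
  } else {
    cat(sprintf("  chi-square = %.4f, df = %d, p = %.4g (%d patterns)\n",
                x$statistic, x$df, x$p_value, x$n_patterns))
  }
  invisible(x)
}

#' @export
tidy.little_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
                 n.patterns = x$n_patterns, applicable = x$applicable)
}

# --- mechanism resolution ----------------------------------------------------

#' Resolve the operating missingness mechanism
#'
#' Decision policy: if Little's test fails to reject MCAR at `alpha` (or is
#' vacuous), the mechanism is MCAR. Otherwise, a user-declared mechanism —
#' domain knowledge about why cells are missing — takes precedence; with no
#' declaration the conservative default is MNAR.
#'
#' @param ds An [mds()] object.
#' @param test A [little_mcar_test()] result; computed from `ds` when omitted
#'   (and `NULL` when `ds` lacks two continuous variables, in which case the
#'   declared mechanism or MNAR is used directly).
#' @param declared Optional declared mechanism: `"mcar"`, `"mar"` or `"mnar"`.
#' @param mar_driver Named character vector mapping each incomplete variable
#'   to the observed covariate that drives its missingness; required when
#'   `declared = "mar"`.
#' @param alpha Significance level, default 0.05.
#' @param mnar_tail Which tail of the variable's own distribution is deleted
#'   under MNAR amputation: `"upper"` (default), `"lower"`, or `"both"`.
#' @return A `"missingness_profile"` object: list with `per_var_fraction`
#'   (named vector over incomplete independent variables), `patterns` (tibble
#'   of distinct indicator rows with counts), `mechanism`, `mar_driver`,
#'   `mnar_tail`, `test`.
#' @export
resolve_mechanism <- function(ds, test = NULL, declared = NULL,
                              mar_driver = NULL, alpha = 0.05,
                              mnar_tail = c("upper", "lower", "both")) {
  stopifnot(alpha > 0, alpha < 1)
  mnar_tail <- match.arg(mnar_tail)
  if (!is.null(declared)) {
    declared <- match.arg(tolower(declared), c("mcar", "mar", "mnar"))
    if (declared == "mar" && is.null(mar_driver)) {
      stop("configuration error: declared = 'mar' requires a mar_driver map",
           call. = FALSE)
    }
  }
  if (is.null(test)) {
    n_cont <- sum(ds$schema$type == "continuous")
    test <- if (n_cont >= 2L) little_mcar_test(ds) else NULL
  }
  rejected <- !is.null(test) && isTRUE(test$applicable) &&
    !is.na(test$p_value) && test$p_value < alpha
  mechanism <- if (!rejected && !is.null(test)) {
    "MCAR"
  } else if (!is.null(declared)) {
    toupper(declared)
  } else {
    "MNAR"
  }
  if (mechanism != "MAR") mar_driver <- NULL
  frac <- missing_fraction(ds)
  frac <- frac[frac$variable %in% independent_vars(ds) & frac$n_missing > 0, ]
  per_var <- stats::setNames(frac$fraction, frac$variable)
  R <- is.na(ds$data)
  key <- apply(R, 1, function(r) paste(as.integer(r), collapse = ""))
  patterns <- tibble::as_tibble(as.data.frame(table(key),
                                              stringsAsFactors = FALSE))
  names(patterns) <- c("pattern", "count")
  structure(list(per_var_fraction = per_var, patterns = patterns,
                 mechanism = mechanism, mar_driver = mar_driver,
                 mnar_tail = mnar_tail, test = test),
            class = "missingness_profile")
}

#' Build a missingness profile directly from target fractions
#'
#' Used to prescribe simulated missingness (amputation) without measuring it
#' from an incomplete dataset.
#'
#' @param fractions Named numeric vector: variable -> missing fraction.
#' @param mechanism `"MCAR"`, `"MAR"` or `"MNAR"`.
#' @param mar_driver Named character vector (incomplete variable -> driver).
#' @param mnar_tail `"upper"`, `"lower"` or `"both"`.
#' @return A `"missingness_profile"` object.
#' @export
missingness_profile <- function(fractions,
                                mechanism = c("MCAR", "MAR", "MNAR"),
                                mar_driver = NULL,
                                mnar_tail = c("upper", "lower", "both")) {
  mechanism <- match.arg(toupper(mechanism[1]), c("MCAR", "MAR", "MNAR"))
  mnar_tail <- match.arg(mnar_tail)
  stopifnot(is.numeric(fractions), all(fractions >= 0), all(fractions <= 1),
            !is.null(names(fractions)))
  if (mechanism == "MAR" && is.null(mar_driver)) {
    stop("configuration error: MAR requires a mar_driver map", call. = FALSE)
  }
  structure(list(per_var_fraction = fractions,
                 patterns = NULL, mechanism = mechanism,
                 mar_driver = mar_driver, mnar_tail = mnar_tail, test = NULL),
            class = "missingness_profile")
}

#' @export
print.missingness_profile <- function(x, ...) {
  cat("<missingness_profile> mechanism:", x$mechanism, "\n")
  cat("per-variable fractions:\n")
  print(round(x$per_var_fraction, 4))
  invisible(x)
}

# --- amputation --------------------------------------------------------------

#' Delete cells from complete data under a missingness mechanism
#'
#' Simulates missingness in a fully observed (observational) block so that
#' imputation quality can be scored against known truth. For every profiled
#' variable exactly `round(fraction * n)` cells are deleted:
#' \describe{
#'   \item{MCAR}{cells chosen uniformly at random;}
#'   \item{MAR}{sampling probability proportional to a logistic weight
#'     `plogis(z)` on the driver covariate's standardized value (weighted
#'     sampling without replacement);}
#'   \item{MNAR}{the cells with the most extreme values of the variable
#'     itself — upper tail by default, configurable to lower/both. Discrete
#'     variables order by level code; ties break by row position.}
#' }
#' The dependent variable is never amputed.
#'
#' @param ds A fully observed [mds()] object.
#' @param profile A `"missingness_profile"` with target fractions.
#' @param seed Integer seed; the result is deterministic given it.
#' @return An [mds()] with the requested cells set to missing.
#' @export
ampute <- function(ds, profile, seed = 1L) {
  if (any(is.na(ds$data))) {
    stop("ampute() expects a fully observed dataset", call. = FALSE)
  }
  frac <- profile$per_var_fraction
  if (any(frac > 1)) stop("configuration error: fraction > 1", call. = FALSE)
  dep <- dependent_var(ds)
  if (dep %in% names(frac)) {
    stop("configuration error: the dependent variable cannot be amputed",
         call. = FALSE)
  }
  n <- nrow(ds$data)
  data <- ds$data
  withr::with_seed(seed, {
    for (v in names(frac)) {
      m <- round(frac[[v]] * n)
      if (m == 0L) next
      col <- data[[v]]
      num <- if (is.factor(col)) as.numeric(col) else as.numeric(col)
      idx <- switch(profile$mechanism,
        MCAR = sample.int(n, m),
        MAR = {
          drv <- profile$mar_driver[[v]]
          if (is.null(drv) || is.na(drv)) {
            stop("configuration error: MAR amputation of '", v,
                 "' has no driver", call. = FALSE)
          }
          if (anyNA(data[[drv]])) {
            stop("configuration error: MAR driver '", drv,
                 "' has missing values", call. = FALSE)
          }
          z <- data[[drv]]
          z <- if (is.factor(z)) as.numeric(z) else as.numeric(z)
          s <- stats::sd(z)
          z <- if (is.finite(s) && s > 0) (z - mean(z)) / s else z * 0
          w <- stats::plogis(z)
          sample.int(n, m, prob = w)
        },
        MNAR = {
          tail <- profile$mnar_tail %||% "upper"
          ord_up <- order(num, seq_len(n), decreasing = TRUE)
          ord_lo <- order(num, seq_len(n))
          switch(tail,
                 upper = ord_up[seq_len(m)],
                 lower = ord_lo[seq_len(m)],
                 both = {
                   m_lo <- m %/% 2
                   c(ord_lo[seq_len(m_lo)], ord_up[seq_len(m - m_lo)])
                 })
        },
        stop("unknown mechanism: ", profile$mechanism, call. = FALSE)
      )
      data[[v]][idx] <- NA
    }
  })
  structure(list(data = data, schema = ds$schema), class = "mds")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- MICE bootstrap of the observational block -------------------------------

#' Grow the observational block to a minimum fraction via chained equations
#'
#' The framework needs at least half the records fully observed to train and
#' simulate on. When fewer are complete, just enough incomplete records —
#' fewest missing cells first, so the least invented information enters the
#' observational block — are completed by the package's chained-equations
#' imputer ([impute_mice()]) and promoted; the remaining records are left
#' untouched.
#'
#' @param ds An [mds()] object.
#' @param target_fraction Minimum complete-record fraction, default 0.5.
#' @param seed Integer seed.
#' @param n_iterations Chained-equation sweeps, passed to [impute_mice()].
#' @return An [mds()] in which at least `target_fraction` of records are
#'   complete. A no-op when the target is already met.
#' @export
mice_bootstrap <- function(ds, target_fraction = 0.5, seed = 1L,
                           n_iterations = 10L) {
  n <- nrow(ds$data)
  complete <- stats::complete.cases(ds$data)
  need <- ceiling(target_fraction * n) - sum(complete)
  if (need <= 0L) return(ds)
  miss_counts <- rowSums(is.na(ds$data))
  candidates <- which(!complete)
  promote <- candidates[order(miss_counts[candidates], candidates)][seq_len(need)]
  filled <- tryCatch(
    impute_mice(ds, n_iterations = n_iterations, seed = seed),
    error = function(e) {
      message("chained equations failed (", conditionMessage(e),
              "); falling back to mean/mode completion for promoted records")
      impute_mean(ds)
    })
  data <- ds$data
  data[promote, ] <- filled$data[promote, ]
  structure(list(data = data, schema = ds$schema), class = "mds")
}
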