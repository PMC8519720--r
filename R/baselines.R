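# The five comparison imputers and the benchmarking harness.

#' Listwise deletion
#'
#' Removes every record containing at least one missing independent cell.
#'
#' @param ds An [mds()] object.
#' @return An [mds()] with only complete records.
#' @export
impute_deletion <- function(ds) {
  keep <- stats::complete.cases(ds$data[independent_vars(ds)])
  if (!any(keep)) {
    stop("degenerate output: listwise deletion removed every record",
         call. = FALSE)
  }
  structure(list(data = ds$data[keep, , drop = FALSE], schema = ds$schema),
            class = "mds")
}

#' Mean / mode imputation
#'
#' Continuous missing cells get the column mean of the observed values;
#' discrete cells the column mode (ties broken by level order).
#'
#' @param ds An [mds()] object.
#' @return A completed [mds()].
#' @export
impute_mean <- function(ds) {
  data <- ds$data
  for (v in names(data)) {
    miss <- is.na(data[[v]])
    if (!any(miss)) next
    if (all(miss)) {
      stop("configuration error: column '", v, "' is fully missing ",
           "(should have been dropped upstream)", call. = FALSE)
    }
    data[[v]][miss] <- mode_or_mean(data[[v]])
  }
  structure(list(data = data, schema = ds$schema), class = "mds")
}

#' Expectation-maximization imputation
#'
#' Completes the continuous block under a multivariate normal model: EM
#' estimates the joint mean and covariance from the incomplete block, then
#' each record's missing continuous cells are replaced by their conditional
#' expectation given the record's observed continuous cells. Discrete cells
#' are completed by the column mode. Deterministic.
#'
#' @param ds An [mds()] object with at least one continuous variable.
#' @param tol EM log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap; non-convergence returns the last
#'   iterate with a warning.
#' @return A completed [mds()] with attribute `em_converged`.
#' @export
impute_em <- function(ds, tol = 1e-6, max_iter = 500) {
  cont <- ds$schema$name[ds$schema$type == "continuous"]
  if (!length(cont)) {
    stop("EM imputation needs at least one continuous variable", call. = FALSE)
  }
  data <- ds$data
  X <- as.matrix(data[cont])
  converged <- TRUE
  if (anyNA(X)) {
    est <- em_norm(X, tol = tol, max_iter = max_iter)
    converged <- est$converged
    if (!converged) {
      warning("EM did not converge within ", max_iter,
              " iterations; using the last iterate", call. = FALSE)
    }
    for (i in which(!stats::complete.cases(X))) {
      mis <- is.na(X[i, ])
      obs <- !mis
      if (any(obs)) {
        Soo <- est$sigma[obs, obs, drop = FALSE]
        B <- est$sigma[mis, obs, drop = FALSE] %*%
          solve(Soo + diag(1e-8, sum(obs)))
        X[i, mis] <- est$mu[mis] + B %*% (X[i, obs] - est$mu[obs])
      } else {
        X[i, mis] <- est$mu[mis]
      }
    }
    data[cont] <- tibble::as_tibble(X)
  }
  out <- structure(list(data = data, schema = ds$schema), class = "mds")
  out <- impute_mean(out)   # discrete leftovers by mode
  attr(out, "em_converged") <- converged
  out
}

#' Chained-equations imputation
#'
#' Single-imputation multivariate chained equations: after a mean/mode
#' initialization, each incomplete variable in turn is regressed on all
#' other variables over its originally observed rows (linear model for
#' continuous targets, logistic/multinomial for discrete) and its missing
#' cells are re-drawn from the fitted predictive distribution; the sweep is
#' repeated `n_iterations` times. Singular fits fall back to a
#' ridge-stabilized solve (continuous) or an observed-frequency draw
#' (discrete), with a message.
#'
#' @param ds An [mds()] object with at least 2 variables.
#' @param n_iterations Number of sweeps (default 10).
#' @param seed Integer seed; completions are deterministic given it.
#' @return A completed [mds()].
#' @export
impute_mice <- function(ds, n_iterations = 10L, seed = 1L) {
  data <- ds$data
  miss_idx <- purrr::map(data, ~ which(is.na(.x)))
  targets <- names(miss_idx)[lengths(miss_idx) > 0]
  if (!length(targets)) return(ds)
  # ascending missingness sweep order
  targets <- targets[order(lengths(miss_idx[targets]),
                           match(targets, names(data)))]
  filled <- impute_mean(structure(list(data = data, schema = ds$schema),
                                  class = "mds"))$data
  withr::with_seed(seed, {
    for (it in seq_len(n_iterations)) {
      for (v in targets) {
        rows <- miss_idx[[v]]
        others <- setdiff(names(data), v)
        X <- encode_matrix(filled[others])
        obs <- setdiff(seq_len(nrow(data)), rows)
        if (var_type(ds, v) == "continuous") {
          filled[[v]][rows] <- mice_draw_continuous(
            X[obs, , drop = FALSE], filled[[v]][obs],
            X[rows, , drop = FALSE])
        } else {
          filled[[v]][rows] <- mice_draw_discrete(
            X[obs, , drop = FALSE], filled[[v]][obs],
            X[rows, , drop = FALSE], levels(data[[v]]))
        }
      }
    }
  })
  structure(list(data = filled, schema = ds$schema), class = "mds")
}

# normal predictive draw from a least-squares fit; ridge fallback on
# singular designs
mice_draw_continuous <- function(Xo, yo, Xq) {
  Xo1 <- cbind(1, Xo)
  Xq1 <- cbind(1, Xq)
  beta <- tryCatch(qr.solve(Xo1, yo), error = function(e) NULL)
  if (is.null(beta) || anyNA(beta)) {
    message("chained equations: singular design; ridge fallback")
    lambda <- 1e-4 * nrow(Xo1)
    beta <- solve(crossprod(Xo1) + diag(lambda, ncol(Xo1)), crossprod(Xo1, yo))
  }
  res <- yo - drop(Xo1 %*% beta)
  sigma <- sqrt(sum(res^2) / max(1, length(yo) - ncol(Xo1)))
  if (!is.finite(sigma)) sigma <- 0
  drop(Xq1 %*% beta) + stats::rnorm(nrow(Xq1), 0, sigma)
}

# class draw from fitted logistic/multinomial probabilities; empirical
# frequency fallback when the fit degenerates
mice_draw_discrete <- function(Xo, yo, Xq, lev) {
  yo <- droplevels(factor(yo, levels = lev))
  draw_fallback <- function() {
    p <- tabulate(yo, nbins = nlevels(yo))
    factor(levels(yo)[sample.int(nlevels(yo), nrow(Xq), replace = TRUE,
                                 prob = p / sum(p))], levels = lev)
  }
  if (nlevels(yo) < 2L) {
    return(factor(rep(levels(yo)[1], nrow(Xq)), levels = lev))
  }
  pr <- tryCatch({
    if (nlevels(yo) == 2L) {
      df <- data.frame(.y = yo, Xo, check.names = FALSE)
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                         family = stats::binomial()))
      p2 <- suppressWarnings(predict(fit, as.data.frame(Xq),
                                     type = "response"))
      cbind(1 - p2, p2)
    } else {
      df <- data.frame(.y = yo, Xo, check.names = FALSE)
      fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE)
      p <- predict(fit, as.data.frame(Xq), type = "probs")
      if (is.null(dim(p))) p <- matrix(p, nrow = nrow(Xq))
      p
    }
  }, error = function(e) NULL)
  if (is.null(pr) || anyNA(pr)) {
    message("chained equations: degenerate classifier; frequency fallback")
    return(draw_fallback())
  }
  picks <- vapply(seq_len(nrow(pr)), function(i) {
    sample.int(nlevels(yo), 1L, prob = pmax(pr[i, ], 1e-12))
  }, integer(1))
  factor(levels(yo)[picks], levels = lev)
}

#' Iterative random-forest imputation
#'
#' missForest-style completion: after a mean/mode initialization, variables
#' are revisited in ascending-missingness order, each fitted by a random
#' forest on all other (currently completed) variables and its missing cells
#' replaced by forest predictions. Iteration stops the first time the
#' difference criterion between successive completions increases (the
#' previous completion is returned) or at `max_iter`. The criterion is the
#' normalized squared change over continuous cells plus the disagreement
#' proportion over discrete cells.
#'
#' @param ds An [mds()] object with at least 2 variables.
#' @param max_iter Iteration cap (default 10).
#' @param seed Integer seed (forest growth).
#' @param num_trees Trees per forest (default 100).
#' @return A completed [mds()] with attribute `iterations` (accepted
#'   iterations).
#' @export
impute_missforest <- function(ds, max_iter = 10L, seed = 1L,
                              num_trees = 100L) {
  data <- ds$data
  miss_idx <- purrr::map(data, ~ which(is.na(.x)))
  targets <- names(miss_idx)[lengths(miss_idx) > 0]
  if (!length(targets)) {
    out <- ds
    attr(out, "iterations") <- 0L
    return(out)
  }
  targets <- targets[order(lengths(miss_idx[targets]),
                           match(targets, names(data)))]
  filled <- impute_mean(structure(list(data = data, schema = ds$schema),
                                  class = "mds"))$data
  prev <- filled
  prev_crit <- Inf
  accepted <- 0L
  for (it in seq_len(max_iter)) {
    for (v in targets) {
      rows <- miss_idx[[v]]
      others <- setdiff(names(data), v)
      df <- as.data.frame(encode_matrix(filled[others]))
      y <- filled[[v]]
      train <- setdiff(seq_len(nrow(data)), rows)
      ytr <- if (is.factor(y)) droplevels(y[train]) else y[train]
      if (is.factor(y) && nlevels(ytr) < 2L) next
      fit <- ranger::ranger(x = df[train, , drop = FALSE], y = ytr,
                            num.trees = num_trees, seed = seed + it,
                            num.threads = 1)
      pred <- predict(fit, df[rows, , drop = FALSE],
                      num.threads = 1)$predictions
      if (is.factor(y)) {
        filled[[v]][rows] <- factor(as.character(pred), levels = levels(y))
      } else {
        filled[[v]][rows] <- as.numeric(pred)
      }
    }
    crit <- missforest_criterion(filled, prev, ds$schema, miss_idx)
    if (crit > prev_crit) {
      filled <- prev     # revert: the previous completion was better
      break
    }
    accepted <- it
    prev <- filled
    prev_crit <- crit
  }
  out <- structure(list(data = filled, schema = ds$schema), class = "mds")
  attr(out, "iterations") <- accepted
  out
}

missforest_criterion <- function(new, old, schema, miss_idx) {
  crit <- 0
  cont_num <- 0; cont_den <- 0
  disc_dis <- 0; disc_n <- 0
  for (v in names(miss_idx)) {
    rows <- miss_idx[[v]]
    if (!length(rows)) next
    if (schema$type[match(v, schema$name)] == "continuous") {
      cont_num <- cont_num + sum((new[[v]][rows] - old[[v]][rows])^2)
      cont_den <- cont_den + sum(new[[v]][rows]^2)
    } else {
      disc_dis <- disc_dis + sum(new[[v]][rows] != old[[v]][rows])
      disc_n <- disc_n + length(rows)
    }
  }
  if (cont_den > 0) crit <- crit + cont_num / cont_den
  if (disc_n > 0) crit <- crit + disc_dis / disc_n
  crit
}

# --- benchmarking harness ----------------------------------------------------

method_registry <- function() {
  list(
    deletion = function(ds, seed) impute_deletion(ds),
    mean = function(ds, seed) impute_mean(ds),
    em = function(ds, seed) impute_em(ds),
    mice = function(ds, seed) impute_mice(ds, seed = seed),
    missforest = function(ds, seed) impute_missforest(ds, seed = seed)
  )
}

#' Benchmark imputation methods by downstream classification
#'
#' For each requested method the incomplete dataset is imputed once, then the
#' downstream classifier is evaluated `n_runs` times under the chosen
#' protocol — ten-fold cross-validation (each record tested exactly once per
#' run, confusion counts pooled) or repeated stratified 70/30 train/test
#' splits — and the metric panels are averaged over runs. The
#' `"proposed"` method runs the full swarm-selection pipeline
#' ([run_impute()]) to obtain its completion. Deletion that leaves too few
#' records for the protocol is marked not evaluable; other methods proceed.
#'
#' @param ds An [mds()] object with missing data.
#' @param methods Character vector from `c("deletion", "mean", "em", "mice",
#'   "missforest", "proposed")`.
#' @param protocol `"tenfold"` or `"split_70_30"`.
#' @param n_runs Evaluation repetitions per method (default 100).
#' @param classifier Downstream classifier spec (default logistic
#'   regression).
#' @param seed Integer seed.
#' @param train_fraction Training share of the split protocol (default 0.7).
#' @param positive Positive class label.
#' @param mopso_args List of arguments forwarded to [run_impute()] for the
#'   proposed method (e.g. `cfg`, `n_repeats`).
#' @return An object of class `"imputation_benchmark"`: tibble with one row
#'   per method and the six panel metrics (percent, averaged over runs),
#'   plus `evaluable`; attributes `protocol`, `n_runs`.
#' @export
benchmark_imputers <- function(ds,
                               methods = c("deletion", "mean", "em", "mice",
                                           "missforest", "proposed"),
                               protocol = c("tenfold", "split_70_30"),
                               n_runs = 100L,
                               classifier = registry_spec("discrete", 17L),
                               seed = 1L, train_fraction = 0.7,
                               positive = NULL, mopso_args = list()) {
  protocol <- match.arg(protocol)
  stopifnot(length(methods) >= 1)
  reg <- method_registry()
  rows <- purrr::map(methods, function(m) {
    completed <- tryCatch({
      if (m == "proposed") {
        do.call(run_impute, c(list(ds = ds, seed = seed), mopso_args))$imputed
      } else if (m %in% names(reg)) {
        reg[[m]](ds, seed)
      } else {
        stop("unknown method: ", m, call. = FALSE)
      }
    }, error = function(e) e)
    if (inherits(completed, "error")) {
      return(panel_row(m, NULL, conditionMessage(completed)))
    }
    folds_needed <- if (protocol == "tenfold") 10L else 2L
    min_class <- min(table(droplevels(completed$data[[dependent_var(completed)]])))
    if (nrow(completed$data) < 2L * folds_needed || min_class < 2L) {
      return(panel_row(m, NULL, "too few records for the protocol"))
    }
    panels <- purrr::map_dfr(seq_len(n_runs), function(r) {
      s <- seed + 1000L * match(m, methods) + r
      if (protocol == "tenfold") {
        cv_panel(completed, classifier, folds = 10L, seed = s,
                 positive = positive)
      } else {
        split_panel(completed, classifier, train_fraction, seed = s,
                    positive = positive)
      }
    })
    panel_row(m, dplyr::summarise(panels, dplyr::across(
      c("sensitivity", "specificity", "accuracy", "ppv_pos", "ppv_neg",
        "f_measure"), mean)), NA_character_)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "protocol") <- protocol
  attr(out, "n_runs") <- as.integer(n_runs)
  class(out) <- c("imputation_benchmark", class(tibble::tibble()))
  out
}

panel_row <- function(method, panel, note) {
  if (is.null(panel)) {
    panel <- tibble::tibble(sensitivity = NA_real_, specificity = NA_real_,
                            accuracy = NA_real_, ppv_pos = NA_real_,
                            ppv_neg = NA_real_, f_measure = NA_real_)
  }
  dplyr::bind_cols(tibble::tibble(method = method), panel,
                   tibble::tibble(evaluable = is.na(note), note = note))
}

# one stratified train/test split evaluation
split_panel <- function(ds, classifier, train_fraction, seed, positive) {
  dep <- dependent_var(ds)
  y <- droplevels(ds$data[[dep]])
  X <- ds$data[independent_vars(ds)]
  test <- withr::with_seed(seed, {
    idx <- logical(length(y))
    for (lev in levels(y)) {
      members <- which(y == lev)
      n_test <- max(1L, round((1 - train_fraction) * length(members)))
      idx[sample(members, n_test)] <- TRUE
    }
    idx
  })
  p <- fit_predict(classifier, X[!test, , drop = FALSE], y[!test],
                   X[test, , drop = FALSE], seed = seed)
  metric_panel(y[test], p, positive = positive)
}

#' @export
print.imputation_benchmark <- function(x, ...) {
  cat("Imputation benchmark (", attr(x, "protocol"), ", ",
      attr(x, "n_runs"), " runs)\n\n", sep = "")
  print(format_benchmark(x))
  invisible(x)
}

format_benchmark <- function(x) {
  df <- as.data.frame(x)
  num <- c("sensitivity", "specificity", "accuracy", "ppv_pos", "ppv_neg",
           "f_measure")
  for (v in num) df[[v]] <- sprintf("%6.2f", df[[v]])
  names(df) <- c("Method", "Sensitivity (%)", "Specificity (%)",
                 "Accuracy (%)", "PPV+ (%)", "PPV- (%)", "F-measure (%)",
                 "Evaluable", "Note")
  df
}

#' @export
tidy.imputation_benchmark <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(c("sensitivity", "specificity", "accuracy",
                          "ppv_pos", "ppv_neg", "f_measure"),
                        names_to = "metric", values_to = "percent")
}

#' @export
glance.imputation_benchmark <- function(x, ...) {
  tibble::tibble(protocol = attr(x, "protocol"),
                 n_runs = attr(x, "n_runs"),
                 n_methods = nrow(x),
                 best_accuracy_method = x$method[which.max(x$accuracy)])
}

#' Benchmark panel chart
#'
#' One bar per method and metric, percent scale.
#'
#' @param object An `"imputation_benchmark"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.imputation_benchmark <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$percent,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "percent", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
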