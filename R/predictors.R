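# Fixed algorithm pools. Selection chooses among these variants; nothing is
# tuned inside them.

discrete_pool <- function() {
  tibble::tibble(
    index = 1:18,
    family = c("svm_linear", "svm_quadratic", "svm_polynomial",
               rep("svm_rbf", 6),
               rep("knn", 5),
               "tree_c45", "ann", "logistic", "naive_bayes"),
    label = c("Support vector machine (linear)",
              "Support vector machine (quadratic)",
              "Support vector machine (polynomial)",
              paste0("Support vector machine (RBF = ",
                     c(5, 2, 1, 0.5, 0.2, 0.1), ")"),
              paste0(c(1, 3, 5, 7, 9), "-NN"),
              "Decision tree (C4.5-style, entropy split)",
              "Feed-forward neural network",
              "Logistic regression",
              "Naive Bayes"),
    param = c(NA, 2, 3, 5, 2, 1, 0.5, 0.2, 0.1, 1, 3, 5, 7, 9, NA, NA, NA, NA)
  )
}

continuous_pool <- function() {
  tibble::tibble(
    index = 1:9,
    family = c("svr", rep("knn", 5), "cart", "ann", "mreg"),
    label = c("Support vector regression (SVR)",
              paste0(c(1, 3, 5, 7, 9), "-NN"),
              "Regression tree (CART)",
              "Feed-forward neural network",
              "Multiple regression"),
    param = c(NA, 1, 3, 5, 7, 9, NA, NA, NA)
  )
}

#' The prediction-algorithm registry
#'
#' The fixed pools the optimizer selects from: 18 classification algorithms
#' for discrete targets and 9 regression algorithms for continuous targets.
#' All hyperparameters are fixed (the six RBF widths, the five k-NN sizes,
#' the polynomial degrees); the optimizer's job is selection among variants,
#' not tuning within them.
#'
#' @param vtype `"discrete"` or `"continuous"`.
#' @return A tibble with columns `index`, `family`, `label`, `param`
#'   (the single fixed hyperparameter where the family has one: RBF width
#'   gamma, k of k-NN, polynomial degree; `NA` otherwise).
#' @examples
#' predictor_registry("discrete")[14, ]  # 9-NN
#' @export
predictor_registry <- function(vtype = c("discrete", "continuous")) {
  vtype <- match.arg(vtype)
  if (vtype == "discrete") discrete_pool() else continuous_pool()
}

pool_size <- function(vtype) if (vtype == "discrete") 18L else 9L

registry_spec <- function(vtype, index) {
  reg <- predictor_registry(vtype)
  if (index < 1L || index > nrow(reg)) {
    stop("algorithm index ", index, " outside 1..", nrow(reg),
         " for ", vtype, " pool", call. = FALSE)
  }
  c(as.list(reg[index, ]), vtype = vtype)
}

# --- numeric encoding --------------------------------------------------------

# Learners receive predictors as a numeric matrix: continuous columns as-is,
# discrete columns as integer level codes (levels are fixed on the full
# column when the mds is built, so train and query codes always agree).
encode_matrix <- function(df) {
  if (!ncol(df)) return(matrix(numeric(0), nrow = nrow(df), ncol = 0))
  m <- vapply(df, function(col) {
    if (is.factor(col)) as.numeric(col) else as.numeric(col)
  }, numeric(nrow(df)))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(df))
  colnames(m) <- names(df)
  m
}

standardize_pair <- function(train, query) {
  mu <- colMeans(train)
  s <- apply(train, 2, stats::sd)
  s[!is.finite(s) | s == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, s, "/"),
       query = sweep(sweep(query, 2, mu), 2, s, "/"))
}

# --- train/predict contract --------------------------------------------------

#' Fit a pool algorithm and predict a query block
#'
#' One uniform train/predict surface over the whole registry. Discrete
#' predictions are drawn only from the levels observed in training; k-NN
#' reduces k to `n_train - 1` (with a message) when training is smaller than
#' k; a degenerate training target (single class, zero variance) falls back
#' to a constant predictor. Stochastic learners (the neural networks) are
#' seeded, so results are deterministic given `seed`.
#'
#' Input standardization: SVM/SVR, k-NN, neural-network, logistic and
#' multiple-regression families z-score the predictors on the training rows;
#' tree and naive-Bayes families use the raw encoding.
#'
#' @param spec One row of [predictor_registry()] (or a list with `family`,
#'   `param`, `vtype`).
#' @param train_x Data frame of predictors (no missing cells).
#' @param train_y Target column: factor for discrete specs, numeric for
#'   continuous.
#' @param query_x Data frame of predictors for the rows to predict.
#' @param seed Integer seed for stochastic learners.
#' @return A vector of `nrow(query_x)` predictions (factor or numeric).
#' @export
fit_predict <- function(spec, train_x, train_y, query_x, seed = 1L) {
  spec <- as.list(spec)
  fam <- spec$family
  vtype <- spec$vtype %||% if (is.factor(train_y) || is.character(train_y))
    "discrete" else "continuous"
  if (anyNA(train_x) || anyNA(train_y) || anyNA(query_x)) {
    stop("fit_predict inputs must be fully observed", call. = FALSE)
  }
  n_tr <- nrow(train_x)
  if (vtype == "discrete") {
    y <- droplevels(as.factor(train_y))
    if (nlevels(y) < 2L || n_tr < 2L) {
      lev <- if (nlevels(y)) levels(y)[which.max(tabulate(y))] else NA
      return(factor(rep(lev, nrow(query_x)), levels = levels(y)))
    }
  } else {
    y <- as.numeric(train_y)
    if (n_tr < 2L || stats::sd(y) == 0) {
      return(rep(if (n_tr) mean(y) else NA_real_, nrow(query_x)))
    }
  }
  Xtr <- encode_matrix(train_x)
  Xq <- encode_matrix(query_x)
  scaled_fams <- c("svm_linear", "svm_quadratic", "svm_polynomial", "svm_rbf",
                   "svr", "knn", "ann", "logistic", "mreg")
  if (fam %in% scaled_fams && ncol(Xtr)) {
    sp <- standardize_pair(Xtr, Xq)
    Xtr <- sp$train
    Xq <- sp$query
  }
  if (!ncol(Xtr)) {
    # empty predictor set: constant (mode / mean) prediction
    return(if (vtype == "discrete") {
      factor(rep(levels(y)[which.max(tabulate(y))], nrow(query_x)),
             levels = levels(y))
    } else rep(mean(y), nrow(query_x)))
  }
  pred <- switch(fam,
    svm_linear = svm_predict(Xtr, y, Xq, kernel = "linear"),
    svm_quadratic = svm_predict(Xtr, y, Xq, kernel = "polynomial",
                                degree = 2),
    svm_polynomial = svm_predict(Xtr, y, Xq, kernel = "polynomial",
                                 degree = spec$param %||% 3),
    svm_rbf = svm_predict(Xtr, y, Xq, kernel = "radial", gamma = spec$param),
    svr = svm_predict(Xtr, y, Xq, kernel = "radial", regression = TRUE),
    knn = knn_predict(Xtr, y, Xq, k = spec$param, vtype = vtype),
    tree_c45 = tree_predict(Xtr, y, Xq, method = "class",
                            split = "information"),
    cart = tree_predict(Xtr, y, Xq, method = "anova"),
    ann = ann_predict(Xtr, y, Xq, vtype = vtype, seed = seed),
    logistic = logistic_predict(Xtr, y, Xq),
    naive_bayes = nb_predict(Xtr, y, Xq),
    mreg = mreg_predict(Xtr, y, Xq),
    stop("unknown algorithm family: ", fam, call. = FALSE)
  )
  pred
}

svm_predict <- function(Xtr, y, Xq, kernel, degree = 3, gamma = NULL,
                        regression = FALSE) {
  args <- list(x = Xtr, y = y, kernel = kernel, scale = FALSE)
  if (kernel == "polynomial") args$degree <- degree
  if (!is.null(gamma)) args$gamma <- gamma
  if (regression) args$type <- "eps-regression"
  fit <- tryCatch(do.call(e1071::svm, args), error = function(e) NULL)
  if (is.null(fit)) return(constant_pred(y, nrow(Xq)))
  out <- tryCatch(predict(fit, Xq), error = function(e) NULL)
  if (is.null(out)) return(constant_pred(y, nrow(Xq)))
  unname(out)
}

knn_predict <- function(Xtr, y, Xq, k, vtype) {
  if (k >= nrow(Xtr)) {
    k_new <- max(1L, nrow(Xtr) - 1L)
    message("k-NN: k reduced from ", k, " to ", k_new,
            " (only ", nrow(Xtr), " training rows)")
    k <- k_new
  }
  if (vtype == "discrete") {
    class::knn(train = Xtr, test = Xq, cl = y, k = k)
  } else {
    fit <- caret::knnreg(Xtr, y, k = k)
    unname(predict(fit, Xq))
  }
}

tree_predict <- function(Xtr, y, Xq, method, split = "information") {
  df <- data.frame(.y = y, Xtr, check.names = FALSE)
  ctrl <- rpart::rpart.control(minsplit = 5, minbucket = 2, cp = 0.01,
                               xval = 0)
  fit <- if (method == "class") {
    rpart::rpart(.y ~ ., data = df, method = method, control = ctrl,
                 parms = list(split = split))
  } else {
    rpart::rpart(.y ~ ., data = df, method = method, control = ctrl)
  }
  newd <- as.data.frame(Xq)
  if (method == "class") {
    predict(fit, newd, type = "class")
  } else {
    unname(predict(fit, newd))
  }
}

ann_predict <- function(Xtr, y, Xq, vtype, seed) {
  n_out <- if (vtype == "discrete") nlevels(y) else 1L
  size <- max(1L, ceiling((ncol(Xtr) + n_out) / 2))
  withr::with_seed(seed, {
    if (vtype == "discrete") {
      fit <- nnet::nnet(Xtr, nnet::class.ind(y), size = size, maxit = 500,
                        softmax = nlevels(y) > 2, entropy = nlevels(y) == 2,
                        trace = FALSE)
      pr <- predict(fit, Xq)
      if (nlevels(y) == 2) {
        factor(levels(y)[1 + (pr[, 1] > 0.5)], levels = levels(y))
      } else {
        factor(levels(y)[max.col(pr)], levels = levels(y))
      }
    } else {
      mu <- mean(y); s <- stats::sd(y)
      fit <- nnet::nnet(Xtr, (y - mu) / s, size = size, maxit = 500,
                        linout = TRUE, trace = FALSE)
      unname(predict(fit, Xq)[, 1] * s + mu)
    }
  })
}

logistic_predict <- function(Xtr, y, Xq) {
  if (nlevels(y) == 2L) {
    df <- data.frame(.y = y, Xtr, check.names = FALSE)
    fit <- suppressWarnings(
      stats::glm(.y ~ ., data = df, family = stats::binomial()))
    pr <- suppressWarnings(predict(fit, as.data.frame(Xq), type = "response"))
    factor(levels(y)[1 + (pr > 0.5)], levels = levels(y))
  } else {
    df <- data.frame(.y = y, Xtr, check.names = FALSE)
    fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE)
    factor(as.character(predict(fit, as.data.frame(Xq))), levels = levels(y))
  }
}

nb_predict <- function(Xtr, y, Xq) {
  fit <- e1071::naiveBayes(as.data.frame(Xtr), y)
  predict(fit, as.data.frame(Xq))
}

mreg_predict <- function(Xtr, y, Xq) {
  df <- data.frame(.y = y, Xtr, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  unname(suppressWarnings(predict(fit, as.data.frame(Xq))))
}

constant_pred <- function(y, n) {
  if (is.factor(y)) {
    factor(rep(levels(y)[which.max(tabulate(y))], n), levels = levels(y))
  } else rep(mean(y), n)
}

# --- chain assignment and executor -------------------------------------------

#' Build a chain assignment from algorithm indices
#'
#' Pairs each incomplete variable (in chain order) with one algorithm from
#' its pool.
#'
#' @param ds An [mds()] object (supplies the chain order and types), or a
#'   character vector of ordered variable names together with `schema`.
#' @param indices Integer vector of registry indices, one per chain variable.
#' @param schema Required when `ds` is a character vector.
#' @return A tibble with columns `variable`, `vtype`, `index`, `family`,
#'   `label`; class `"chain_assignment"`.
#' @export
chain_assignment <- function(ds, indices, schema = NULL) {
  if (inherits(ds, "mds")) {
    order_vars <- chain_order(ds)
    schema <- ds$schema
  } else {
    order_vars <- ds
    if (is.null(schema)) stop("schema required", call. = FALSE)
  }
  if (length(indices) != length(order_vars)) {
    stop("need one algorithm index per chain variable (",
         length(order_vars), "), got ", length(indices), call. = FALSE)
  }
  vtypes <- schema$type[match(order_vars, schema$name)]
  rows <- purrr::map2(vtypes, indices, function(vt, ix) {
    reg <- predictor_registry(vt)
    if (ix < 1 || ix > nrow(reg)) {
      stop("index ", ix, " outside the ", vt, " pool (1..", nrow(reg), ")",
           call. = FALSE)
    }
    reg[ix, ]
  })
  out <- dplyr::bind_rows(rows)
  out <- tibble::tibble(variable = order_vars, vtype = vtypes,
                        index = out$index, family = out$family,
                        label = out$label, param = out$param)
  class(out) <- c("chain_assignment", class(tibble::tibble()))
  out
}

#' Impute missing cells along the chain
#'
#' Executes the chained prediction scheme: the first chain variable is
#' predicted from its partner (the second chain variable, or the
#' best-observed other independent variable when the chain has length one),
#' trained on the rows where both are observed; every later variable `x_i`
#' is predicted from the already-completed variables `x_1 .. x_(i-1)`.
#' Observed cells are never overwritten; the output has no missing cells in
#' chain variables.
#'
#' @param ds An [mds()] object with missing cells in independent variables.
#' @param assignment A [chain_assignment()] covering the chain variables.
#' @param seed Integer seed for stochastic learners.
#' @return A completed [mds()] object.
#' @export
impute_chain <- function(ds, assignment, seed = 1L) {
  data <- ds$data
  vars <- assignment$variable
  if (!length(vars)) return(ds)
  if (anyNA(data[[dependent_var(ds)]])) {
    stop("dependent variable must be fully observed before chain imputation",
         call. = FALSE)
  }
  for (i in seq_along(vars)) {
    v <- vars[i]
    target_missing <- is.na(data[[v]])
    if (!any(target_missing)) next
    if (i == 1L) {
      partner <- if (length(vars) >= 2L) {
        vars[2]
      } else {
        frac <- missing_fraction(structure(list(data = data,
                                                schema = ds$schema),
                                           class = "mds"))
        cand <- setdiff(independent_vars(ds), v)
        cand <- cand[order(frac$fraction[match(cand, frac$variable)],
                           match(cand, ds$schema$name))]
        if (length(cand)) cand[1] else character(0)
      }
      preds <- partner
    } else {
      preds <- vars[seq_len(i - 1L)]
    }
    spec <- c(as.list(assignment[i, c("family", "param", "index")]),
              vtype = assignment$vtype[i])
    train_rows <- !target_missing &
      stats::complete.cases(data[preds %||% character(0)])
    if (!length(preds) || sum(train_rows) < 2L) {
      message("chain variable '", v,
              "': empty/degenerate predictor set; mean/mode fallback")
      data[[v]][target_missing] <- mode_or_mean(data[[v]])
      next
    }
    query <- data[target_missing, preds, drop = FALSE]
    # partner cells may be missing on query rows at step 1; fill provisionally
    for (p in preds) {
      if (anyNA(query[[p]])) {
        query[[p]][is.na(query[[p]])] <-
          mode_or_mean(data[[p]][train_rows])
      }
    }
    pred <- fit_predict(spec,
                        train_x = data[train_rows, preds, drop = FALSE],
                        train_y = data[[v]][train_rows],
                        query_x = query,
                        seed = seed + i)
    if (is.factor(data[[v]])) {
      data[[v]][target_missing] <- factor(as.character(pred),
                                          levels = levels(data[[v]]))
    } else {
      data[[v]][target_missing] <- as.numeric(pred)
    }
  }
  structure(list(data = data, schema = ds$schema), class = "mds")
}

# observed-value mode (factors; ties -> first level) or mean (numeric)
mode_or_mean <- function(col) {
  obs <- col[!is.na(col)]
  if (is.factor(col)) {
    tab <- tabulate(obs, nbins = nlevels(col))
    factor(levels(col)[which.max(tab)], levels = levels(col))
  } else {
    mean(obs)
  }
}
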