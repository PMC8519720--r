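# End-to-end orchestration: read -> drop -> split -> (bootstrap) ->
# mechanism -> swarm selection -> chain imputation -> outputs.

#' Impute a dataset by swarm-selected chained prediction
#'
#' The full pipeline: (1) variables above the missingness threshold are
#' dropped; (2) records are split into the observational (complete) block
#' and the incomplete rest, and if fewer than half the records are complete
#' the block is grown by [mice_bootstrap()]; (3) the missingness mechanism
#' is resolved (Little's MCAR test, declared knowledge, MNAR default);
#' (4) the particle swarm selects one imputation algorithm per incomplete
#' variable by minimizing the (|delta sensitivity|, |delta specificity|)
#' objectives on simulated missingness; (5) the selected chain is executed
#' on the real missing cells.
#'
#' @param ds An [mds()] object, or a CSV path (then `schema` is required).
#' @param schema Schema (or schema file path) when `ds` is a path.
#' @param drop_threshold Missingness fraction above which independent
#'   variables are dropped (default 0.5).
#' @param declared,mar_driver,alpha,mnar_tail Mechanism declaration,
#'   passed to [resolve_mechanism()].
#' @param cfg A [swarm_config()]; its seed is overridden by `seed`.
#' @param classifier Downstream classifier spec (default logistic
#'   regression).
#' @param n_repeats Amputation/imputation cycles per fitness evaluation
#'   (default 100).
#' @param folds,positive Passed to [fitness()].
#' @param seed Integer master seed; every stochastic stage derives from it.
#' @param out_dir Optional output directory: writes `imputed.csv`, the
#'   imputation-mask report, `assignment.json` and `trace.jsonl`.
#' @return An object of class `"dyn_impute_run"`: list with `imputed`
#'   (completed [mds()]), `assignment`, `mopso` (the `"mopso_result"`, or
#'   `NULL` when nothing was missing), `profile`, `dropped` (variables
#'   removed by the threshold), `input` (the post-drop dataset).
#' @export
run_impute <- function(ds, schema = NULL, drop_threshold = 0.5,
                       declared = NULL, mar_driver = NULL, alpha = 0.05,
                       mnar_tail = "upper",
                       cfg = swarm_config(),
                       classifier = registry_spec("discrete", 17L),
                       n_repeats = 100L, folds = 5L, positive = NULL,
                       seed = 1L, out_dir = NULL) {
  if (is.character(ds)) {
    if (is.null(schema)) stop("schema required when ds is a path",
                              call. = FALSE)
    ds <- read_table(ds, schema)
  }
  before <- names(ds$data)
  ds <- drop_high_missing(ds, threshold = drop_threshold)
  dropped <- setdiff(before, names(ds$data))
  cfg$seed <- as.integer(seed)
  order <- withCallingHandlers(chain_order(ds),
                               message = function(m) invokeRestart("muffleMessage"))
  if (!length(order)) {
    res <- structure(list(imputed = ds, assignment = NULL, mopso = NULL,
                          profile = NULL, dropped = dropped, input = ds),
                     class = "dyn_impute_run")
    return(res)
  }
  parts <- split_observational(ds)
  if (observational_fraction(ds) < 0.5) {
    boot <- mice_bootstrap(ds, target_fraction = 0.5, seed = seed + 1L)
    parts <- split_observational(boot)
  }
  obs <- parts$observational
  test <- tryCatch(little_mcar_test(ds), error = function(e) NULL)
  profile <- resolve_mechanism(ds, test = test, declared = declared,
                               mar_driver = mar_driver, alpha = alpha,
                               mnar_tail = mnar_tail)
  mopso <- mopso_select(obs, profile, order, cfg = cfg,
                        classifier = classifier, n_repeats = n_repeats,
                        fitness_seed = seed + 10000L,
                        folds = folds, positive = positive)
  imputed <- impute_chain(ds, mopso$assignment, seed = seed + 2L)
  res <- structure(list(imputed = imputed, assignment = mopso$assignment,
                        mopso = mopso, profile = profile, dropped = dropped,
                        input = ds),
                   class = "dyn_impute_run")
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_table(res$imputed, file.path(out_dir, "imputed.csv"),
              original = res$input)
  if (!is.null(res$assignment)) {
    jsonlite::write_json(
      as.list(tibble::as_tibble(res$assignment)),
      file.path(out_dir, "assignment.json"), auto_unbox = FALSE, digits = NA)
  }
  if (!is.null(res$mopso)) {
    con <- file(file.path(out_dir, "trace.jsonl"), "w")
    on.exit(close(con))
    for (i in seq_len(nrow(res$mopso$trace))) {
      writeLines(jsonlite::toJSON(as.list(res$mopso$trace[i, ]),
                                  auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(out_dir)
}

#' @export
print.dyn_impute_run <- function(x, ...) {
  cat("<dyn_impute_run>\n")
  if (length(x$dropped)) {
    cat("dropped (> threshold missing):", paste(x$dropped, collapse = ", "),
        "\n")
  }
  if (is.null(x$assignment)) {
    cat("no missing data; imputation was a no-op\n")
  } else {
    cat("mechanism:", x$profile$mechanism, "\n")
    print(tibble::as_tibble(x$assignment))
  }
  invisible(x)
}

#' Benchmark entry point of the pipeline
#'
#' Thin wrapper over [benchmark_imputers()] mirroring [run_impute()]'s
#' input handling, with optional JSON/text report output.
#'
#' @param ds An [mds()] or CSV path.
#' @param schema Schema when `ds` is a path.
#' @param out_dir Optional directory for `benchmark.json` and
#'   `benchmark.txt`.
#' @param ... Passed to [benchmark_imputers()].
#' @return An `"imputation_benchmark"`.
#' @export
run_benchmark <- function(ds, schema = NULL, out_dir = NULL, ...) {
  if (is.character(ds)) {
    if (is.null(schema)) stop("schema required when ds is a path",
                              call. = FALSE)
    ds <- read_table(ds, schema)
  }
  report <- benchmark_imputers(ds, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(as.list(tibble::as_tibble(report)),
                         file.path(out_dir, "benchmark.json"),
                         auto_unbox = FALSE, digits = NA)
    utils::write.table(format_benchmark(report),
                       file.path(out_dir, "benchmark.txt"),
                       quote = FALSE, sep = "\t", row.names = FALSE)
  }
  report
}
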