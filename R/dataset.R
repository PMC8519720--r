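#' Construct a variable schema
#'
#' A schema declares, for every column of a clinical table, whether it is
#' discrete (nominal/ordinal) or continuous, and whether it is an independent
#' predictor or the dependent class variable. Exactly one variable must be the
#' dependent variable, and it must be discrete: the selection objectives
#' (sensitivity and specificity) are only defined for a classification target.
#'
#' @param name Character vector of unique column names.
#' @param type Character vector, each `"discrete"` or `"continuous"`.
#' @param role Character vector, each `"independent"` or `"dependent"`.
#' @return A tibble with columns `name`, `type`, `role` and class
#'   `"dyn_schema"`.
#' @examples
#' var_schema(c("age", "stage", "outcome"),
#'            c("continuous", "discrete", "discrete"),
#'            c("independent", "independent", "dependent"))
#' @export
var_schema <- function(name, type, role) {
  sch <- tibble::tibble(
    name = as.character(name),
    type = as.character(type),
    role = as.character(role)
  )
  validate_schema(sch)
}

validate_schema <- function(sch) {
  if (!all(c("name", "type", "role") %in% names(sch))) {
    stop("schema must have columns name, type, role", call. = FALSE)
  }
  sch <- tibble::as_tibble(sch[c("name", "type", "role")])
  if (anyDuplicated(sch$name)) {
    stop("schema error: duplicated variable names: ",
         paste(unique(sch$name[duplicated(sch$name)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(sch$type, c("discrete", "continuous"))
  if (length(bad)) stop("schema error: unknown type(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(sch$role, c("independent", "dependent"))
  if (length(bad)) stop("schema error: unknown role(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  ndep <- sum(sch$role == "dependent")
  if (ndep != 1L) {
    stop("schema error: exactly one dependent variable required, found ", ndep,
         call. = FALSE)
  }
  if (sch$type[sch$role == "dependent"] != "discrete") {
    stop("schema error: the dependent variable must be discrete ",
         "(sensitivity/specificity scoring requires a class variable)",
         call. = FALSE)
  }
  class(sch) <- c("dyn_schema", class(tibble::tibble()))
  sch
}

#' Read a schema from a YAML or JSON file
#'
#' The file holds a list of `{name, type, role}` records (YAML sequence or a
#' JSON array of objects).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` schema file.
#' @return A [var_schema()] tibble.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    yaml::yaml.load_file(path)
  }
  if (is.data.frame(raw)) {
    sch <- tibble::as_tibble(raw)
  } else {
    sch <- purrr::map_dfr(raw, ~ tibble::tibble(
      name = .x$name, type = .x$type, role = .x$role))
  }
  validate_schema(sch)
}

#' Bundle a data table and its schema into a missing-data set
#'
#' The central container of the package: a tibble of cell values (missing
#' cells are `NA`; the missingness-indicator matrix is `is.na()` of the data)
#' together with its variable schema. Discrete columns are stored as factors
#' whose levels are taken from the observed data only.
#'
#' Records in which the dependent variable itself is missing are excluded with
#' a warning: the class label cannot be imputed by this framework (it is the
#' quantity the objectives are computed against).
#'
#' @param data A data frame; column names must match the schema.
#' @param schema A [var_schema()] tibble (or data frame coercible to one).
#' @return An object of class `"mds"`: a list with elements `data` (tibble)
#'   and `schema`.
#' @export
mds <- function(data, schema) {
  schema <- validate_schema(schema)
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(schema$name, names(data))
  if (length(missing_cols)) {
    stop("schema error: columns absent from data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- data[schema$name]
  if (nrow(data) < 1L || ncol(data) < 2L) {
    stop("degenerate input: need at least 1 record and 2 variables",
         call. = FALSE)
  }
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    col <- data[[nm]]
    if (schema$type[i] == "continuous") {
      if (is.factor(col)) col <- as.character(col)
      suppressWarnings(num <- as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad)) {
        stop("parse error: column '", nm, "', row ", bad[1] + 1L,
             " (counting the header): '", col[bad[1]],
             "' is not numeric but the variable is declared continuous",
             call. = FALSE)
      }
      data[[nm]] <- num
    } else {
      chr <- as.character(col)
      lev <- sort(unique(chr[!is.na(chr)]))
      data[[nm]] <- factor(chr, levels = lev)
    }
  }
  dep <- schema$name[schema$role == "dependent"]
  dep_missing <- is.na(data[[dep]])
  if (any(dep_missing)) {
    warning(sum(dep_missing), " record(s) with a missing dependent variable ('",
            dep, "') were excluded", call. = FALSE)
    data <- data[!dep_missing, , drop = FALSE]
    if (nrow(data) < 1L) {
      stop("degenerate input: no records with an observed dependent variable",
           call. = FALSE)
    }
  }
  if (nlevels(droplevels(data[[dep]])) < 2L) {
    warning("dependent variable '", dep, "' has fewer than 2 observed levels; ",
            "classification metrics will be degenerate", call. = FALSE)
  }
  structure(list(data = data, schema = schema), class = "mds")
}

#' @export
print.mds <- function(x, ...) {
  n_miss <- sum(is.na(x$data))
  cat("<mds> ", nrow(x$data), " records x ", ncol(x$data), " variables; ",
      n_miss, " missing cells (",
      sprintf("%.1f%%", 100 * n_miss / prod(dim(x$data))), ")\n", sep = "")
  cat("dependent: ", dependent_var(x), "\n", sep = "")
  print(x$data, ...)
  invisible(x)
}

#' @export
dim.mds <- function(x) dim(x$data)

n_records <- function(ds) nrow(ds$data)

#' Name of the dependent (class) variable
#' @param ds An [mds()] object.
#' @return A single character string.
#' @export
dependent_var <- function(ds) ds$schema$name[ds$schema$role == "dependent"]

#' Names of the independent variables
#' @param ds An [mds()] object.
#' @return Character vector.
#' @export
independent_vars <- function(ds) ds$schema$name[ds$schema$role == "independent"]

var_type <- function(ds, var) {
  i <- match(var, ds$schema$name)
  if (is.na(i)) stop("unknown variable: ", var, call. = FALSE)
  ds$schema$type[i]
}

#' Read a CSV table against a declared schema
#'
#' Empty cells and a configurable set of sentinel strings become missing
#' cells; every other cell must parse according to its declared type.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema A [var_schema()] tibble, or a path to a YAML/JSON schema file.
#' @param na Character vector of sentinel strings treated as missing.
#' @return An [mds()] object.
#' @export
read_table <- function(path, schema, na = c("", "NA", "NaN", "?")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(schema) && length(schema) == 1L) schema <- read_schema(schema)
  schema <- validate_schema(schema)
  raw <- readr::read_csv(path, na = na, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  extra <- setdiff(schema$name, names(raw))
  if (length(extra)) {
    stop("schema error: header is missing column(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  mds(raw[schema$name], schema)
}

#' Write an imputed table and its imputation-mask report
#'
#' Writes the data as CSV (identical column order to the schema) and, when
#' `mask_report` is given, a JSON report listing which cells were imputed
#' relative to the original dataset.
#'
#' @param ds An [mds()] object (typically a completed one).
#' @param path Output CSV path.
#' @param original The pre-imputation [mds()]; when supplied, a JSON report of
#'   imputed cells is written next to `path`.
#' @param mask_path Path of the JSON mask report (default: `path` with a
#'   `.mask.json` suffix).
#' @return `path`, invisibly.
#' @export
write_table <- function(ds, path, original = NULL,
                        mask_path = sub("\\.csv$", "", path)) {
  out <- ds$data
  readr::write_csv(out, path, na = "")
  if (!is.null(original)) {
    imputed <- which(is.na(original$data) & !is.na(ds$data), arr.ind = TRUE)
    report <- list(
      n_records = nrow(ds$data),
      n_imputed_cells = nrow(imputed),
      cells = if (nrow(imputed)) {
        tibble::tibble(row = unname(imputed[, 1]),
                       variable = names(ds$data)[imputed[, 2]])
      } else tibble::tibble(row = integer(), variable = character())
    )
    jsonlite::write_json(report, paste0(mask_path, ".mask.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Per-variable missing-data fractions
#'
#' @param ds An [mds()] object.
#' @param var Optional variable name; when given, the fraction for that single
#'   variable is returned as a bare number.
#' @return With `var`: a proportion in `[0, 1]`. Without: a tibble with one
#'   row per variable (`variable`, `n_missing`, `fraction`), in schema order.
#' @examples
#' ds <- mds(data.frame(x = c(1, NA, 3), y = c("a", "b", "a")),
#'           var_schema(c("x", "y"), c("continuous", "discrete"),
#'                      c("independent", "dependent")))
#' missing_fraction(ds, "x")
#' @export
missing_fraction <- function(ds, var = NULL) {
  tab <- tibble::tibble(
    variable = names(ds$data),
    n_missing = unname(purrr::map_int(ds$data, ~ sum(is.na(.x)))),
    fraction = .data$n_missing / nrow(ds$data)
  )
  if (is.null(var)) return(tab)
  i <- match(var, tab$variable)
  if (is.na(i)) stop("unknown variable: ", var, call. = FALSE)
  tab$fraction[i]
}

#' Drop independent variables exceeding a missingness threshold
#'
#' Variables with more than `threshold` missing data carry too little signal
#' to train a per-variable predictor; they are removed from the table and the
#' schema. The dependent variable is never removed.
#'
#' @param ds An [mds()] object.
#' @param threshold Proportion in `(0, 1]`; default 0.5.
#' @return An [mds()] with the offending columns removed.
#' @export
drop_high_missing <- function(ds, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  frac <- missing_fraction(ds)
  drop <- frac$variable[frac$fraction > threshold &
                          frac$variable %in% independent_vars(ds)]
  keep <- setdiff(names(ds$data), drop)
  if (length(setdiff(keep, dependent_var(ds))) == 0L) {
    stop("degenerate input: dropping variables above ",
         threshold * 100, "% missingness would leave no independent variables",
         call. = FALSE)
  }
  if (!length(drop)) return(ds)
  structure(list(data = ds$data[keep],
                 schema = validate_schema(ds$schema[ds$schema$name %in% keep, ])),
            class = "mds")
}

#' Imputation chain order
#'
#' The imputation chain visits the incomplete independent variables in
#' ascending order of missing fraction, so the best-observed variables are
#' completed first and feed the predictors of later, worse-observed ones.
#' Ties are broken by schema column position.
#'
#' @param ds An [mds()] object.
#' @return Character vector of variable names in imputation order; length 0
#'   (with a message) when nothing is missing.
#' @export
chain_order <- function(ds) {
  frac <- missing_fraction(ds)
  frac <- frac[frac$variable %in% independent_vars(ds) & frac$n_missing > 0, ]
  if (!nrow(frac)) {
    message("no independent variable has missing data; the chain is empty")
    return(character(0))
  }
  pos <- match(frac$variable, ds$schema$name)
  frac$variable[order(frac$fraction, pos)]
}

#' Split records into observational (complete) and incomplete parts
#'
#' The observational block — records with every cell observed — is the
#' training and simulation substrate of the whole framework; records with at
#' least one missing cell form the second part. Record order is preserved and
#' the two parts partition the input.
#'
#' @param ds An [mds()] object.
#' @return A list with elements `observational` and `incomplete`, both
#'   [mds()]-shaped (the incomplete part may have 0 rows).
#' @export
split_observational <- function(ds) {
  complete <- stats::complete.cases(ds$data)
  list(
    observational = structure(list(data = ds$data[complete, , drop = FALSE],
                                   schema = ds$schema), class = "mds"),
    incomplete = structure(list(data = ds$data[!complete, , drop = FALSE],
                                schema = ds$schema), class = "mds")
  )
}

#' Fraction of records that are fully observed
#' @param ds An [mds()] object.
#' @return Proportion in `[0, 1]`.
#' @export
observational_fraction <- function(ds) {
  mean(stats::complete.cases(ds$data))
}

#' Missingness pattern heat map
#'
#' One tile per cell, shaded by observed/missing status, variables ordered by
#' missing fraction. A quick visual check of the missingness profile before
#' imputation.
#'
#' @param ds An [mds()] object.
#' @return A ggplot object.
#' @export
plot_missingness <- function(ds) {
  ord <- missing_fraction(ds)
  ord <- ord$variable[order(ord$fraction)]
  long <- ds$data |>
    dplyr::mutate(.record = dplyr::row_number(),
                  dplyr::across(-".record", ~ is.na(.x))) |>
    tidyr::pivot_longer(-".record", names_to = "variable",
                        values_to = "missing") |>
    dplyr::mutate(variable = factor(.data$variable, levels = ord))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$variable, y = .data$.record,
                                     fill = .data$missing)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey85", `TRUE` = "grey20"),
                               labels = c(`FALSE` = "observed", `TRUE` = "missing"),
                               name = NULL) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "record") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
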