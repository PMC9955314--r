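#' Reference schema for the Pima Indians diabetes benchmark
#'
#' The eight clinical features of the classic Pima Indians diabetes table,
#' together with the declared lower/upper bounds printed in its header
#' (e.g. glucose 0--199, serum insulin 0--846). These bounds drive min--max
#' normalization in `bounds_mode = "declared"` and the denominators of the
#' ReliefF difference function.
#'
#' @return A tibble with columns `feature`, `xmin`, `xmax`.
#' @examples
#' pima_bounds()
#' @export
pima_bounds <- function() {
  tibble::tibble(
    feature = c("pregnancies", "glucose", "blood_pressure", "skin_thickness",
                "insulin", "bmi", "pedigree", "age"),
    xmin = c(0, 0, 0, 0, 0, 0, 0.078, 21),
    xmax = c(17, 199, 122, 99, 846, 67.1, 2.42, 81)
  )
}

#' Construct a validated feature table
#'
#' A feature table is a tibble of numeric feature columns plus a binary
#' outcome column, carrying optional per-feature bounds as metadata. It is
#' the entry point of the numeric-to-image pipeline: rows are subjects,
#' columns are clinical measurements, and the outcome encodes case status
#' (0 = negative, 1 = positive).
#'
#' @param data A data frame containing the feature columns and the label
#'   column. All feature columns must be numeric with no missing values
#'   (records with missing measurements are rejected, not imputed).
#' @param label_col Name of the binary outcome column. Default `"outcome"`.
#' @param bounds Optional tibble with columns `feature`, `xmin`, `xmax`
#'   declaring the admissible range of each feature. `xmin < xmax` is
#'   required. When `NULL`, only `bounds_mode = "observed"` normalization is
#'   available downstream.
#' @return A `feature_table`: a tibble of the feature columns plus the label
#'   column, with attributes `label_col` and `bounds`.
#' @examples
#' ft <- feature_table(
#'   data.frame(glucose = c(89, 197), age = c(21, 53), outcome = c(0, 1)),
#'   bounds = tibble::tibble(feature = c("glucose", "age"),
#'                           xmin = c(0, 21), xmax = c(199, 81))
#' )
#' feature_names(ft)
#' @export
feature_table <- function(data, label_col = "outcome", bounds = NULL) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    abort("`data` must be a non-empty data frame.")
  }
  if (!label_col %in% names(data)) {
    abort(sprintf("Label column '%s' not found in the table.", label_col))
  }
  feats <- setdiff(names(data), label_col)
  if (length(feats) == 0) {
    abort("No features: the table contains only the label column.")
  }
  for (f in feats) {
    col <- data[[f]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))))[1]
      abort(sprintf("Non-numeric value in column '%s' (first at row %s).",
                    f, bad %||% "?"))
    }
    if (anyNA(col)) {
      abort(sprintf("Missing value in column '%s' at row %d; missing values are rejected, not imputed.",
                    f, which(is.na(col))[1]))
    }
  }
  lab <- data[[label_col]]
  if (anyNA(lab) || !all(lab %in% c(0, 1))) {
    abort(sprintf("Label column '%s' must contain only 0 and 1.", label_col))
  }
  if (nrow(data) < 2) abort("At least two rows are required.")
  if (!is.null(bounds)) {
    bounds <- as_tibble(bounds)
    stopifnot(all(c("feature", "xmin", "xmax") %in% names(bounds)))
    missing_b <- setdiff(feats, bounds$feature)
    if (length(missing_b) > 0) {
      abort(paste0("Bounds missing for feature(s): ",
                   paste(missing_b, collapse = ", ")))
    }
    bounds <- bounds[match(feats, bounds$feature), ]
    if (any(bounds$xmin >= bounds$xmax)) {
      bad <- bounds$feature[bounds$xmin >= bounds$xmax][1]
      abort(sprintf("Degenerate bounds for feature '%s': xmin must be < xmax.", bad))
    }
  }
  out <- as_tibble(data)[, c(feats, label_col)]
  attr(out, "label_col") <- label_col
  attr(out, "bounds") <- bounds
  class(out) <- c("feature_table", class(out))
  out
}

#' Read a feature table from CSV
#'
#' Reads a headered CSV, validates it, and splits out the binary outcome
#' column. Row order is preserved.
#'
#' @inheritParams feature_table
#' @param path Path to a CSV file with a header row.
#' @param feature_names Optional expected feature names; when given, the file
#'   header must contain exactly these features (plus the label column).
#'   When `NULL` the schema is inferred from the header.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, label_col = "outcome",
                               feature_names = NULL, bounds = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) abort("Empty table: the CSV contains no data rows.")
  if (!is.null(feature_names)) {
    expected <- c(feature_names, label_col)
    if (!setequal(names(raw), expected)) {
      abort(paste0("Header mismatch. Expected columns: ",
                   paste(expected, collapse = ", "),
                   "; found: ", paste(names(raw), collapse = ", ")))
    }
    raw <- raw[, expected]
  }
  feats <- setdiff(names(raw), label_col)
  for (f in feats) {
    col <- raw[[f]]
    if (is.character(col) || is.factor(col)) {
      conv <- suppressWarnings(as.numeric(as.character(col)))
      if (anyNA(conv)) {
        abort(sprintf("Non-numeric cell in column '%s', row %d.",
                      f, which(is.na(conv))[1]))
      }
      raw[[f]] <- conv
    }
  }
  feature_table(raw, label_col = label_col, bounds = bounds)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d rows x %d features (label: '%s'%s)\n",
              nrow(x), length(feature_names(x)), attr(x, "label_col"),
              if (is.null(attr(x, "bounds"))) "" else ", declared bounds"))
  NextMethod()
}

#' Feature names, labels and values of a feature table
#'
#' @param x A `feature_table` or `normalized_table`.
#' @return `feature_names()`: character vector of feature column names;
#'   `table_labels()`: integer vector of 0/1 outcomes; `feature_matrix()`:
#'   the numeric n x p matrix of feature values.
#' @export
feature_names <- function(x) {
  setdiff(names(x), attr(x, "label_col") %||% "outcome")
}

#' @rdname feature_names
#' @export
table_labels <- function(x) {
  as.integer(x[[attr(x, "label_col") %||% "outcome"]])
}

#' @rdname feature_names
#' @export
feature_matrix <- function(x) {
  as.matrix(x[, feature_names(x)])
}

resolve_bounds <- function(x, bounds_mode) {
  feats <- feature_names(x)
  if (bounds_mode == "declared") {
    b <- attr(x, "bounds")
    if (is.null(b)) {
      abort("bounds_mode = \"declared\" requires declared bounds on the table (see `feature_table(bounds = )`).")
    }
    b
  } else {
    vals <- feature_matrix(x)
    b <- tibble::tibble(
      feature = feats,
      xmin = apply(vals, 2, min),
      xmax = apply(vals, 2, max)
    )
    const <- b$feature[b$xmin == b$xmax]
    if (length(const) > 0) {
      abort(sprintf("Constant feature '%s': xmax equals xmin, min-max normalization is undefined.",
                    const[1]))
    }
    b
  }
}

#' Min--max normalization of a feature table
#'
#' Rescales each feature to the unit interval via
#' \eqn{\hat x = (x - x_{min}) / (x_{max} - x_{min})}. With
#' `bounds_mode = "declared"` the table's declared per-feature ranges are
#' used and out-of-range inputs are clipped to \[0, 1\] after the transform
#' (this keeps the 0--255 rasterization contract intact); with `"observed"`
#' the per-feature minimum and maximum of the data are used, so every column
#' attains both 0 and 1 exactly.
#'
#' @param table A [feature_table()].
#' @param bounds_mode `"declared"` (default) or `"observed"`.
#' @return A `normalized_table`: a tibble like `table` but with all feature
#'   values in \[0, 1\], carrying the bounds actually used in attribute
#'   `bounds` and the source table in attribute `source`.
#' @examples
#' ft <- simulate_table(sim_spec(n_per_class = c(5, 5), seed = 1))
#' nt <- minmax_normalize(ft)
#' range(feature_matrix(nt))
#' @export
minmax_normalize <- function(table, bounds_mode = c("declared", "observed")) {
  bounds_mode <- match.arg(bounds_mode)
  stopifnot(inherits(table, "feature_table"))
  b <- resolve_bounds(table, bounds_mode)
  feats <- feature_names(table)
  out <- table
  for (i in seq_along(feats)) {
    x <- table[[feats[i]]]
    xh <- (x - b$xmin[i]) / (b$xmax[i] - b$xmin[i])
    out[[feats[i]]] <- pmin(1, pmax(0, xh))
  }
  attr(out, "bounds") <- b
  attr(out, "bounds_mode") <- bounds_mode
  attr(out, "source") <- table
  class(out) <- unique(c("normalized_table", class(out)))
  out
}

#' @export
print.normalized_table <- function(x, ...) {
  cat(sprintf("<normalized_table> %d rows x %d features in [0,1] (%s bounds)\n",
              nrow(x), length(feature_names(x)), attr(x, "bounds_mode")))
  NextMethod()
}
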