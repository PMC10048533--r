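#' Construct a clustering data container
#'
#' Bundles an N x M numeric matrix (samples as rows, features as columns)
#' with an optional integer ground-truth label vector used only for external
#' evaluation, never during fitting.
#'
#' @param x Numeric matrix or data frame coercible to one; all entries must
#'   be finite. Rows are samples, columns are features.
#' @param labels Optional vector of length `nrow(x)` giving ground-truth
#'   class labels (any atomic type; stored as integer codes).
#' @return An object of class `fwec_data`: a list with elements `values`
#'   (numeric matrix) and `labels` (integer vector or `NULL`).
#' @examples
#' d <- fwec_data(matrix(rnorm(20), 10, 2), labels = rep(1:2, each = 5))
#' dim(d$values)
#' @export
fwec_data <- function(x, labels = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("`x` must be a numeric matrix (or a data frame of numerics)")
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("`x` must have at least one row and one column")
  if (!all(is.finite(x)))
    stop("all entries of `x` must be finite (no NA/NaN/Inf)")
  storage.mode(x) <- "double"
  if (!is.null(labels)) {
    if (length(labels) != nrow(x))
      stop("`labels` must have length nrow(x)")
    if (anyNA(labels))
      stop("`labels` must not contain missing values")
    labels <- as.integer(factor(labels))
  }
  structure(list(values = x, labels = labels), class = "fwec_data")
}

#' @export
print.fwec_data <- function(x, ...) {
  cat(sprintf("<fwec_data> %d samples x %d features%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$labels)) ""
              else sprintf(", %d label classes", length(unique(x$labels)))))
  invisible(x)
}

# Accept either an fwec_data or a bare matrix everywhere user-facing.
as_fwec_data <- function(x) {
  if (inherits(x, "fwec_data")) x else fwec_data(x)
}

#' Read a delimited numeric matrix, optionally with a label column
#'
#' @param path Path to a CSV/TSV file of numbers; a header row is detected
#'   automatically unless `header` is given.
#' @param label_col Column name or index holding ground-truth labels; it is
#'   removed from the feature matrix and stored as `labels`. `NULL` for none.
#' @param sep Field separator; `","` by default, use `"\t"` for TSV.
#' @param header Logical; `NA` (default) auto-detects by trying to parse the
#'   first row as numbers.
#' @return An `fwec_data` object.
#' @export
read_data_csv <- function(path, label_col = NULL, sep = ",", header = NA) {
  if (is.na(header)) {
    first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
    header <- anyNA(suppressWarnings(as.numeric(first)))
  }
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, check.names = FALSE)
  labels <- NULL
  if (!is.null(label_col)) {
    idx <- if (is.character(label_col)) match(label_col, names(df)) else as.integer(label_col)
    if (is.na(idx) || idx < 1L || idx > ncol(df))
      stop("`label_col` does not identify a column of the file")
    labels <- df[[idx]]
    df <- df[, -idx, drop = FALSE]
  }
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("all non-label columns must be numeric; missing values are not accepted")
  fwec_data(as.matrix(df), labels = labels)
}

#' Write hard labels and optional model matrices alongside a JSON run summary
#'
#' @param fit An `fwec_fit` (or baseline) result.
#' @param out_prefix Path prefix; writes `<prefix>_labels.csv` and
#'   `<prefix>_summary.json`, plus `_U.csv`, `_W.csv`, `_C.csv` when present
#'   and `matrices = TRUE`.
#' @param matrices Logical; also write the membership/weight/center matrices.
#' @return Invisibly, the vector of file paths written.
#' @export
write_fit_result <- function(fit, out_prefix, matrices = FALSE) {
  paths <- character(0)
  p <- paste0(out_prefix, "_labels.csv")
  utils::write.csv(data.frame(label = fit$hard_labels), p, row.names = FALSE)
  paths <- c(paths, p)
  if (matrices) {
    for (nm in c("U", "W", "C")) {
      m <- fit$model[[nm]]
      if (!is.null(m)) {
        p <- paste0(out_prefix, "_", nm, ".csv")
        utils::write.csv(m, p, row.names = FALSE)
        paths <- c(paths, p)
      }
    }
  }
  summary <- list(
    best_objective = fit$best_objective,
    n_iter = fit$model$n_iter,
    converged = fit$model$converged,
    per_restart_objectives = fit$per_restart_objectives,
    config = fit$config[setdiff(names(fit$config), "call")]
  )
  p <- paste0(out_prefix, "_summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA, null = "null")
  paths <- c(paths, p)
  invisible(paths)
}
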