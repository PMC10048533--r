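#' Per-feature precision parameters for the bounded kernel distance
#'
#' Computes, for each feature l, the population mean, the population variance
#' (divisor N) and the precision delta_l = 1/var_l that scales the
#' exponential-kernel distance. delta_l makes the kernel scale-free per
#' feature: rescaling a column by s multiplies var_l by s^2 and delta_l by
#' 1/s^2, leaving every pointwise distance unchanged.
#'
#' Features whose variance is numerically zero (var_l <= 1e-12 * max(1,
#' mean_l^2)) carry no clustering information; their delta is set to 0 so
#' that their distance contribution 1 - exp(0) is identically zero, and a
#' message is emitted.
#'
#' @param data An `fwec_data` object or numeric matrix.
#' @return An object of class `fwec_precision`: list with numeric vectors
#'   `delta`, `mean`, `var` (length M) and an integer vector `degenerate`
#'   of zero-variance feature indices.
#' @examples
#' feature_precision(matrix(c(0, 2, 1, 1), 2, 2))$delta
#' @export
feature_precision <- function(data) {
  x <- as_fwec_data(data)$values
  n <- nrow(x)
  mu <- colMeans(x)
  v <- colMeans(x^2) - mu^2          # population variance, divisor N
  v <- pmax(v, 0)                    # guard tiny negative rounding
  degenerate <- which(v <= 1e-12 * pmax(1, mu^2))
  delta <- ifelse(seq_along(v) %in% degenerate, 0, 1 / v)
  if (length(degenerate))
    message("feature_precision: ", length(degenerate),
            " zero-variance feature(s) excluded from the distance: ",
            paste(degenerate, collapse = ", "))
  structure(list(delta = delta, mean = mu, var = v, degenerate = degenerate),
            class = "fwec_precision")
}

#' @export
print.fwec_precision <- function(x, ...) {
  cat(sprintf("<fwec_precision> %d features, %d degenerate\n",
              length(x$delta), length(x$degenerate)))
  invisible(x)
}
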