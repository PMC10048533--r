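#' Pointwise dissimilarity between a value and a center on one feature
#'
#' In `"non_euclidean"` mode this is the bounded kernel distance
#' `1 - exp(-delta_l * (x - c)^2)`, which is 0 at the center and saturates
#' at 1 as |x - c| grows, limiting the influence of outliers. In
#' `"euclidean"` mode it is the plain squared difference `(x - c)^2`.
#' Vectorized over all arguments.
#'
#' @param x,c Numeric values (recycled as usual).
#' @param delta_l Non-negative finite precision(s); ignored in euclidean mode.
#' @param mode `"non_euclidean"` (default) or `"euclidean"`.
#' @return Numeric vector of dissimilarities.
#' @examples
#' dist_pointwise(1, 0, 1)          # 1 - exp(-1)
#' dist_pointwise(1, 0, 1, "euclidean")
#' @export
dist_pointwise <- function(x, c, delta_l, mode = c("non_euclidean", "euclidean")) {
  mode <- match.arg(mode)
  if (any(delta_l < 0) || any(!is.finite(delta_l)))
    stop("`delta_l` must be non-negative and finite")
  if (mode == "euclidean") (x - c)^2 else 1 - exp(-delta_l * (x - c)^2)
}

# N x M matrix of per-feature dissimilarities of all samples to one center.
# X: N x M, center: length-M, delta: length-M.
.dist_to_center <- function(X, center, delta, mode) {
  d2 <- sweep(X, 2L, center, `-`)^2
  if (mode == "euclidean") d2 else 1 - exp(-sweep(d2, 2L, delta, `*`))
}

#' Sample-to-cluster dispersion matrix
#'
#' Entry (i, j) is the feature-weight-averaged dissimilarity of sample i to
#' the center of cluster j: `D_ij = sum_l w_jl * d(x_il, c_jl)`. In
#' non-Euclidean mode each entry lies in [0, 1) as a convex combination of
#' bounded terms. This is the quantity the membership softmax acts on.
#'
#' @param data `fwec_data` or matrix (N x M).
#' @param C Center matrix (K x M).
#' @param W Feature-weight matrix (K x M), rows summing to 1.
#' @param delta Length-M precision vector (see [feature_precision()]).
#' @param mode Distance mode.
#' @return N x K numeric matrix.
#' @export
dispersion_matrix <- function(data, C, W, delta,
                              mode = c("non_euclidean", "euclidean")) {
  mode <- match.arg(mode)
  X <- as_fwec_data(data)$values
  K <- nrow(C)
  if (!is.matrix(C) || !is.matrix(W) || any(dim(W) != dim(C)) ||
      ncol(C) != ncol(X) || length(delta) != ncol(X))
    stop("shape mismatch among data, C, W, delta")
  D <- matrix(0, nrow(X), K)
  for (j in seq_len(K))
    D[, j] <- .dist_to_center(X, C[j, ], delta, mode) %*% W[j, ]
  D
}

# K x M matrix of per-(cluster, feature) dispersions
# D'_jl = sum_i u_ij * d(x_il, c_jl); the quantity the weight softmax acts on.
.weight_dispersion <- function(X, U, C, delta, mode) {
  K <- nrow(C)
  Dp <- matrix(0, K, ncol(X))
  for (j in seq_len(K))
    Dp[j, ] <- crossprod(U[, j], .dist_to_center(X, C[j, ], delta, mode))
  Dp
}
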