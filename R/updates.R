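# Closed-form block updates of the alternating minimization, plus the
# objective. Each softmax is computed with the per-row minimum subtracted
# before exponentiation -- algebraically identical, but mandatory for small
# lambda/gamma where exp(-D/lambda) underflows.

.row_softmax_neg <- function(D, temp) {
  E <- exp(-(D - apply(D, 1L, min)) / temp)
  E / rowSums(E)
}

#' Membership update (entropy-regularized softmax over clusters)
#'
#' Given the sample-to-cluster dispersions `D` (see [dispersion_matrix()]),
#' the minimizing membership matrix has rows
#' `u_ij = exp(-D_ij / lambda) / sum_t exp(-D_it / lambda)`:
#' a Gibbs distribution over clusters with temperature `lambda`. Rows sum to
#' 1 and all entries are strictly positive; large `lambda` drives every row
#' toward the uniform 1/K.
#'
#' @param dispersion N x K dispersion matrix.
#' @param lam Positive membership-entropy weight (lambda).
#' @return N x K membership matrix.
#' @export
update_memberships <- function(dispersion, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || lam <= 0)
    stop("`lam` must be a single positive number")
  .row_softmax_neg(as.matrix(dispersion), lam)
}

#' Feature-weight update (entropy-regularized softmax over features)
#'
#' For each cluster j the per-feature dispersion
#' `D'_jl = sum_i u_ij * d(x_il, c_jl)` measures how badly feature l fits
#' that cluster; the minimizing weights are
#' `w_jl = exp(-D'_jl / gamma) / sum_t exp(-D'_jt / gamma)`. Features that
#' are compact within a cluster receive larger weight there; large `gamma`
#' drives all weights toward 1/M.
#'
#' @param data `fwec_data` or matrix.
#' @param U N x K membership matrix (row-stochastic).
#' @param C K x M center matrix.
#' @param precision `fwec_precision` (or bare delta vector).
#' @param gam Positive weight-entropy parameter (gamma).
#' @param mode Distance mode.
#' @return K x M weight matrix, rows summing to 1.
#' @export
update_weights <- function(data, U, C, precision, gam,
                           mode = c("non_euclidean", "euclidean")) {
  mode <- match.arg(mode)
  if (!is.numeric(gam) || length(gam) != 1L || gam <= 0)
    stop("`gam` must be a single positive number")
  X <- as_fwec_data(data)$values
  delta <- if (inherits(precision, "fwec_precision")) precision$delta else precision
  Dp <- .weight_dispersion(X, U, C, delta, mode)
  .row_softmax_neg(Dp, gam)
}

#' Center update (one kernel-reweighted mean step)
#'
#' The stationarity condition for a center coordinate is implicit: the
#' kernel weights depend on the center itself. One fixed-point step is
#' taken per sweep, with the kernel evaluated at the previous center:
#' `c_jl = sum_i u_ij k_il x_il / sum_i u_ij k_il` where
#' `k_il = exp(-delta_l (x_il - c_prev_jl)^2)` (the constant factors
#' `w_jl * delta_l` cancel). Because `1 - exp(-delta t)` is concave in
#' `t = (x - c)^2`, this is a majorize-minimize step and never increases
#' the objective. In euclidean mode the center is the exact
#' membership-weighted mean. If for some (j, l) all kernel mass vanishes
#' (denominator below 1e-300) the previous coordinate is kept and a
#' warning is issued.
#'
#' @param data `fwec_data` or matrix.
#' @param U N x K membership matrix.
#' @param W K x M weight matrix (unused by the update itself -- the weights
#'   cancel -- but kept in the signature for the block-update contract).
#' @param precision `fwec_precision` or delta vector.
#' @param C_prev Previous K x M center matrix.
#' @param mode Distance mode.
#' @return New K x M center matrix; each coordinate lies within the data
#'   range of its feature.
#' @export
update_centers <- function(data, U, W, precision, C_prev,
                           mode = c("non_euclidean", "euclidean")) {
  mode <- match.arg(mode)
  X <- as_fwec_data(data)$values
  delta <- if (inherits(precision, "fwec_precision")) precision$delta else precision
  K <- ncol(U)
  C <- C_prev
  dead <- 0L
  for (j in seq_len(K)) {
    if (mode == "euclidean") {
      s <- sum(U[, j])
      C[j, ] <- crossprod(U[, j], X) / s
    } else {
      Km <- exp(-sweep(sweep(X, 2L, C_prev[j, ], `-`)^2, 2L, delta, `*`))
      num <- crossprod(U[, j], Km * X)
      den <- crossprod(U[, j], Km)
      ok <- den > 1e-300
      C[j, ok] <- num[ok] / den[ok]
      dead <- dead + sum(!ok)
    }
  }
  if (dead > 0L)
    warning(sprintf("update_centers: %d center coordinate(s) kept from the previous iterate (kernel mass vanished)", dead))
  C
}

#' Objective function of the entropy-weighted fuzzy clustering model
#'
#' `F(U, C, W) = sum_ijl u_ij w_jl d(x_il, c_jl) +
#'  lambda * sum_ij u_ij log u_ij + gamma * sum_jl w_jl log w_jl`
#' with natural logarithms and the convention 0 log 0 = 0 (a guard only:
#' both matrices are strictly positive by construction). Both entropy terms
#' are non-positive, so the objective may be negative.
#'
#' @param data `fwec_data` or matrix.
#' @param U,W,C Model matrices.
#' @param precision `fwec_precision` or delta vector.
#' @param lam,gam Positive entropy weights.
#' @param mode Distance mode.
#' @return Scalar objective value.
#' @export
fwec_objective <- function(data, U, W, C, precision, lam, gam,
                           mode = c("non_euclidean", "euclidean")) {
  mode <- match.arg(mode)
  X <- as_fwec_data(data)$values
  delta <- if (inherits(precision, "fwec_precision")) precision$delta else precision
  D <- dispersion_matrix(X, C, W, delta, mode)
  sum(U * D) + lam * sum(.xlogx(U)) + gam * sum(.xlogx(W))
}

.xlogx <- function(p) ifelse(p > 0, p * log(p), 0)
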