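# Classical comparison algorithms sharing the core data model and the
# random-row initialization protocol: K-means (hard, unweighted), WK-means
# (hard, one global weight per feature with exponent beta), and fuzzy
# c-means (soft memberships with fuzzifier m, plain squared distance).

#' Configuration for a baseline clustering algorithm
#'
#' @param K Number of clusters.
#' @param variant `"kmeans"`, `"wkmeans"` or `"fcm"`.
#' @param beta WK-means weight exponent; its stated domain is beta > 1 or
#'   beta <= 0 (default 2).
#' @param m FCM fuzzifier (> 1; default 2). m -> 1 recovers hard clustering.
#' @param tol,max_iter,restarts,seed As in [fwec_config()].
#' @return An object of class `baseline_config`.
#' @export
baseline_config <- function(K, variant = c("kmeans", "wkmeans", "fcm"),
                            beta = 2, m = 2, tol = 1e-5, max_iter = 100L,
                            restarts = 100L, seed = 1L) {
  variant <- match.arg(variant)
  K <- as.integer(K); max_iter <- as.integer(max_iter)
  restarts <- as.integer(restarts); seed <- as.integer(seed)
  stopifnot(
    "`K` must be a positive integer" = length(K) == 1L && !is.na(K) && K >= 1L,
    "`tol` must be > 0" = tol > 0, "`max_iter` must be >= 1" = max_iter >= 1L,
    "`restarts` must be >= 1" = restarts >= 1L
  )
  if (variant == "wkmeans" && !(beta > 1 || beta <= 0))
    stop("wkmeans requires beta > 1 or beta <= 0")
  if (variant == "fcm" && m <= 1)
    stop("fcm requires fuzzifier m > 1")
  structure(list(K = K, variant = variant, beta = beta, m = m, tol = tol,
                 max_iter = max_iter, restarts = restarts, seed = seed),
            class = "baseline_config")
}

# squared Euclidean distances of all rows of X to all rows of C, optionally
# feature-weighted: entry (i, j) = sum_l wf_l (x_il - c_jl)^2
.sqdist_all <- function(X, C, wf = NULL) {
  K <- nrow(C)
  D <- matrix(0, nrow(X), K)
  for (j in seq_len(K)) {
    d2 <- sweep(X, 2L, C[j, ], `-`)^2
    D[, j] <- if (is.null(wf)) rowSums(d2) else as.numeric(d2 %*% wf)
  }
  D
}

# nearest-center one-hot assignment (ties -> lowest index), with the
# empty-cluster rule: a cluster left empty is re-seeded from the point
# farthest from its own assigned center.
.assign_hard <- function(D) {
  assign <- max.col(-D, ties.method = "first")
  K <- ncol(D)
  empty <- setdiff(seq_len(K), unique(assign))
  if (length(empty)) {
    for (j in empty) {
      far <- which.max(D[cbind(seq_len(nrow(D)), assign)])
      assign[far] <- j
      D[far, ] <- -Inf  # don't reuse the same point for another empty cluster
    }
    message("baseline: re-seeded ", length(empty), " empty cluster(s) from farthest points")
  }
  assign
}

.centers_from_assign <- function(X, assign, K) {
  C <- matrix(0, K, ncol(X))
  for (j in seq_len(K)) {
    rows <- assign == j
    C[j, ] <- if (any(rows)) colMeans(X[rows, , drop = FALSE]) else NA_real_
  }
  C
}

.kmeans_once <- function(X, K, max_iter, seed, beta = NULL, weighted = FALSE) {
  N <- nrow(X); M <- ncol(X)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  C <- X[sample.int(N, K), , drop = FALSE]
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  wf <- if (weighted) rep(1 / M, M) else NULL
  assign_prev <- rep(0L, N)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    D <- .sqdist_all(X, C, if (weighted) wf^beta else NULL)
    assign <- .assign_hard(D)
    C <- .centers_from_assign(X, assign, K)
    if (weighted) wf <- .wkmeans_weights(X, assign, C, beta)
    D <- .sqdist_all(X, C, if (weighted) wf^beta else NULL)
    trace <- c(trace, sum(D[cbind(seq_len(N), assign)]))
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
  }
  U <- matrix(0, N, K); U[cbind(seq_len(N), assign)] <- 1
  list(hard_assign = U, assign = assign, centers = C, global_weights = wf,
       objective_trace = trace)
}

# global feature weights from per-feature within-cluster dispersions D_j,
# w_j proportional to 1 / sum_t (D_j / D_t)^(1/(beta-1)). Features with zero
# dispersion take the whole weight, split equally among them.
.wkmeans_weights <- function(X, assign, C, beta) {
  M <- ncol(X)
  Dj <- numeric(M)
  for (j in seq_len(nrow(C))) {
    rows <- assign == j
    if (any(rows))
      Dj <- Dj + colSums(sweep(X[rows, , drop = FALSE], 2L, C[j, ], `-`)^2)
  }
  Dj <- unname(Dj)
  zero <- Dj <= .Machine$double.eps * max(1, max(Dj))
  if (any(zero)) {
    message("wkmeans: ", sum(zero), " zero-dispersion feature(s) absorb all weight")
    w <- numeric(M); w[zero] <- 1 / sum(zero)
    return(w)
  }
  r <- exp(-log(Dj) / (beta - 1))      # Dj^(-1/(beta-1)), stable for spread Dj
  r / sum(r)
}

.fcm_once <- function(X, K, m, tol, max_iter, seed) {
  N <- nrow(X)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  C <- X[sample.int(N, K), , drop = FALSE]
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  expo <- 2 / (m - 1)
  trace <- numeric(0)
  F_prev <- Inf
  U <- NULL
  for (it in seq_len(max_iter)) {
    D <- .sqdist_all(X, C)
    U <- .fcm_memberships(D, expo)
    Um <- U^m
    C <- sweep(crossprod(Um, X), 1L, colSums(Um), `/`)
    D <- .sqdist_all(X, C)
    F_cur <- sum(U^m * D)
    trace <- c(trace, F_cur)
    if (is.finite(F_prev) && abs(F_prev - F_cur) <= tol) break
    F_prev <- F_cur
  }
  list(fuzzy_U = U, assign = hard_labels(U), centers = C, objective_trace = trace)
}

# u_ij = 1 / sum_t (d_ij / d_it)^(1/(m-1)) on squared distances; a point
# coinciding with a center gets membership 1 there (singularity rule).
.fcm_memberships <- function(D, expo) {
  N <- nrow(D); K <- ncol(D)
  U <- matrix(0, N, K)
  inv <- D^(-expo / 2)                 # d^(-2/(m-1)) on squared distances
  sing <- !is.finite(rowSums(inv)) | apply(D, 1L, min) == 0
  if (any(sing)) {
    for (i in which(sing)) U[i, which.min(D[i, ])] <- 1
  }
  reg <- !sing
  if (any(reg)) U[reg, ] <- inv[reg, , drop = FALSE] / rowSums(inv[reg, , drop = FALSE])
  U
}

#' Fit a baseline clustering algorithm with multiple restarts
#'
#' Shares the core model's protocol: centers are initialized from K distinct
#' data rows per restart, sub-seeds are spawned deterministically from
#' `config$seed`, and the lowest-objective restart is kept.
#'
#' @param data `fwec_data` or numeric matrix.
#' @param config A [baseline_config()].
#' @return An object of class `baseline_fit`: list with `model` (fields
#'   `hard_assign` or `fuzzy_U`, `centers`, `global_weights`,
#'   `objective_trace`), `hard_labels`, `best_objective`,
#'   `per_restart_objectives`, `config`.
#' @export
baseline_fit <- function(data, config) {
  stopifnot(inherits(config, "baseline_config"))
  X <- as_fwec_data(data)$values
  if (config$K > nrow(X)) stop("K must not exceed the number of samples N")
  seeds <- .spawn_seeds(config$seed, config$restarts)
  objs <- rep(NA_real_, config$restarts)
  best <- NULL
  for (r in seq_len(config$restarts)) {
    m <- switch(config$variant,
      kmeans  = .kmeans_once(X, config$K, config$max_iter, seeds[r]),
      wkmeans = .kmeans_once(X, config$K, config$max_iter, seeds[r],
                             beta = config$beta, weighted = TRUE),
      fcm     = .fcm_once(X, config$K, config$m, config$tol, config$max_iter, seeds[r]))
    objs[r] <- m$objective_trace[length(m$objective_trace)]
    if (is.null(best) || objs[r] < best$obj) best <- list(model = m, obj = objs[r])
  }
  structure(list(model = best$model, hard_labels = best$model$assign,
                 best_objective = best$obj, per_restart_objectives = objs,
                 config = config),
            class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("<baseline_fit> %s, K = %d, best objective %.6g over %d restart(s)\n",
              x$config$variant, x$config$K, x$best_objective, x$config$restarts))
  invisible(x)
}
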