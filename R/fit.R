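#' Configuration for the entropy-weighted fuzzy clustering fit
#'
#' Defaults mirror the reference experimental protocol: `lam = 0.3`,
#' `gam = 1.4`, objective-change tolerance `1e-5`, at most 100 sweeps,
#' 100 random restarts.
#'
#' @param K Number of clusters (1 <= K <= N at fit time).
#' @param lam Membership-entropy weight lambda (> 0). Larger values soften
#'   memberships toward uniform 1/K.
#' @param gam Feature-weight-entropy weight gamma (> 0). Larger values
#'   flatten feature weights toward uniform 1/M.
#' @param tol Stop when the absolute objective change per sweep is <= tol.
#' @param max_iter Maximum number of sweeps per restart.
#' @param restarts Number of independent random restarts; the lowest-objective
#'   run is kept.
#' @param seed Integer seed; deterministically spawns one sub-seed per
#'   restart, so runs are bit-reproducible.
#' @param distance `"non_euclidean"` (bounded kernel, default) or
#'   `"euclidean"` (plain squared distance).
#' @param standardize Logical; z-score each feature (population sd) before
#'   fitting. Default `FALSE`: the kernel distance is already scale-free via
#'   `delta_l`, so this mainly matters for euclidean mode. Centers are
#'   reported on the standardized scale when enabled.
#' @return An object of class `fwec_config` (a validated list).
#' @export
fwec_config <- function(K, lam = 0.3, gam = 1.4, tol = 1e-5, max_iter = 100L,
                        restarts = 100L, seed = 1L,
                        distance = c("non_euclidean", "euclidean"),
                        standardize = FALSE) {
  distance <- match.arg(distance)
  K <- as.integer(K); max_iter <- as.integer(max_iter)
  restarts <- as.integer(restarts); seed <- as.integer(seed)
  stopifnot(
    "`K` must be a positive integer" = length(K) == 1L && !is.na(K) && K >= 1L,
    "`lam` must be > 0" = is.numeric(lam) && length(lam) == 1L && lam > 0,
    "`gam` must be > 0" = is.numeric(gam) && length(gam) == 1L && gam > 0,
    "`tol` must be > 0" = is.numeric(tol) && length(tol) == 1L && tol > 0,
    "`max_iter` must be >= 1" = max_iter >= 1L,
    "`restarts` must be >= 1" = restarts >= 1L,
    "`seed` must be an integer" = !is.na(seed),
    "`standardize` must be TRUE or FALSE" =
      is.logical(standardize) && length(standardize) == 1L && !is.na(standardize)
  )
  structure(list(K = K, lam = lam, gam = gam, tol = tol, max_iter = max_iter,
                 restarts = restarts, seed = seed, distance = distance,
                 standardize = standardize),
            class = "fwec_config")
}

# Derive per-restart sub-seeds from one user seed, reproducibly and
# independently of the caller's RNG state. Kept below 2^31.
.spawn_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' Run one restart of the alternating-minimization loop
#'
#' Initializes the centers from K distinct data rows sampled without
#' replacement and the feature weights uniformly at 1/M, then sweeps
#' dispersion -> memberships U -> weights W -> centers C, recomputing the
#' objective after each full sweep, until the absolute objective change is
#' at most `config$tol` or `config$max_iter` sweeps have run. The objective
#' trace is monotone non-increasing (each block update is a minimizer or a
#' majorize-minimize step).
#'
#' @param data `fwec_data` or numeric matrix.
#' @param config An [fwec_config()].
#' @param seed Integer seed for this restart's initialization.
#' @return An object of class `fwec_model`: list with `U` (N x K), `W`
#'   (K x M), `C` (K x M), `precision`, `objective_trace`, `n_iter`,
#'   `converged`, and `diagnostics` (per-iteration worst-case constraint
#'   deviations).
#' @export
fwec_fit_once <- function(data, config, seed = config$seed) {
  d <- as_fwec_data(data)
  X <- d$values
  N <- nrow(X); M <- ncol(X); K <- config$K
  if (K > N) stop("K must not exceed the number of samples N")
  if (isTRUE(config$standardize)) {
    mu <- colMeans(X)
    s <- sqrt(pmax(colMeans(X^2) - mu^2, 0))   # population sd
    s[s <= 1e-12 * pmax(1, abs(mu))] <- 1      # leave constant columns alone
    X <- sweep(sweep(X, 2L, mu, `-`), 2L, s, `/`)
  }
  prec <- feature_precision(X)
  delta <- prec$delta
  mode <- config$distance

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  C <- X[sample.int(N, K), , drop = FALSE]
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  W <- matrix(1 / M, K, M)
  U <- NULL

  trace <- numeric(0)
  F_prev <- Inf
  converged <- FALSE
  diag <- list(u_rowsum_dev = 0, w_rowsum_dev = 0, u_min = Inf, w_min = Inf,
               trace_increase = -Inf)
  it <- 0L
  while (it < config$max_iter) {
    it <- it + 1L
    D <- dispersion_matrix(X, C, W, delta, mode)
    U <- update_memberships(D, config$lam)
    W <- update_weights(X, U, C, delta, config$gam, mode)
    C <- update_centers(X, U, W, delta, C, mode)
    F_cur <- fwec_objective(X, U, W, C, delta, config$lam, config$gam, mode)
    if (!is.finite(F_cur))
      stop(sprintf("non-finite objective at iteration %d", it))
    trace <- c(trace, F_cur)
    diag$u_rowsum_dev <- max(diag$u_rowsum_dev, max(abs(rowSums(U) - 1)))
    diag$w_rowsum_dev <- max(diag$w_rowsum_dev, max(abs(rowSums(W) - 1)))
    diag$u_min <- min(diag$u_min, min(U))
    diag$w_min <- min(diag$w_min, min(W))
    if (is.finite(F_prev)) diag$trace_increase <- max(diag$trace_increase, F_cur - F_prev)
    if (is.finite(F_prev) && abs(F_prev - F_cur) <= config$tol) {
      converged <- TRUE
      break
    }
    F_prev <- F_cur
  }
  structure(list(U = U, W = W, C = C, precision = prec,
                 objective_trace = trace, n_iter = it, converged = converged,
                 diagnostics = diag, seed = seed),
            class = "fwec_model")
}

#' Fit the entropy-weighted fuzzy clustering model with multiple restarts
#'
#' Runs [fwec_fit_once()] `config$restarts` times from independent seeded
#' initializations and keeps the model with the lowest final objective (an
#' unsupervised criterion: ground-truth labels are never consulted). Hard
#' labels are the row-wise argmax of the membership matrix, ties broken by
#' the lowest cluster index.
#'
#' @param data `fwec_data` or numeric matrix.
#' @param config An [fwec_config()].
#' @param keep_models Logical; keep every restart's model (memory permitting)
#'   rather than only the best. Default `FALSE`.
#' @return An object of class `fwec_fit`: list with `model` (best
#'   `fwec_model`), `hard_labels`, `best_objective`,
#'   `per_restart_objectives`, `restart_seeds`, `config`, and optionally
#'   `models`.
#' @examples
#' d <- make_blobs(blob_spec(n_per_cluster = c(20, 20), m_informative = 2,
#'                           separation = 8, seed = 7))
#' fit <- fwec(d, fwec_config(K = 2, restarts = 5, seed = 1))
#' table(fit$hard_labels, d$labels)
#' @export
fwec <- function(data, config, keep_models = FALSE) {
  stopifnot(inherits(config, "fwec_config"))
  d <- as_fwec_data(data)
  seeds <- .spawn_seeds(config$seed, config$restarts)
  objs <- rep(NA_real_, config$restarts)
  best <- NULL
  models <- if (keep_models) vector("list", config$restarts) else NULL
  errors <- character(0)
  for (r in seq_len(config$restarts)) {
    m <- tryCatch(fwec_fit_once(d, config, seed = seeds[r]),
                  error = function(e) e)
    if (inherits(m, "error")) {
      errors <- c(errors, sprintf("restart %d: %s", r, conditionMessage(m)))
      next
    }
    objs[r] <- m$objective_trace[length(m$objective_trace)]
    if (keep_models) models[[r]] <- m
    if (is.null(best) || objs[r] < best$obj) best <- list(model = m, obj = objs[r])
  }
  if (is.null(best))
    stop("all restarts failed: ", paste(errors, collapse = "; "))
  res <- structure(list(
    model = best$model,
    hard_labels = hard_labels(best$model$U),
    best_objective = best$obj,
    per_restart_objectives = objs,
    restart_seeds = seeds,
    config = config
  ), class = "fwec_fit")
  if (keep_models) res$models <- models
  res
}

#' Hard cluster assignment from a membership matrix
#'
#' Row-wise argmax; ties are broken by the lowest cluster index (the usual
#' fuzzy-c-means defuzzification convention).
#'
#' @param U N x K membership matrix.
#' @return Integer vector of cluster indices in 1..K.
#' @export
hard_labels <- function(U) max.col(U, ties.method = "first")

#' @export
print.fwec_fit <- function(x, ...) {
  cat(sprintf("<fwec_fit> K = %d, %s distance\n", x$config$K, x$config$distance))
  cat(sprintf("  best objective %.6g over %d restart(s); best run: %d sweep(s), %s\n",
              x$best_objective, x$config$restarts, x$model$n_iter,
              if (x$model$converged) "converged" else "hit max_iter"))
  cat("  cluster sizes:", paste(tabulate(x$hard_labels, x$config$K), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.fwec_model <- function(x, ...) {
  cat(sprintf("<fwec_model> %d x %d memberships, %d sweeps, %s\n",
              nrow(x$U), ncol(x$U), x$n_iter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
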