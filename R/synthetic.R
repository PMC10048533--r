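# Seeded generators for Gaussian-blob benchmarks with optional uniform
# noise features: the structure the noise-robustness experiments assume.

#' Specification for a synthetic Gaussian-blob dataset
#'
#' Informative features are spherical Gaussians around per-cluster centers;
#' noise features are i.i.d. uniform(noise_low, noise_high) columns carrying
#' no cluster signal. When `centers` is not supplied they are auto-placed at
#' the vertices of a regular simplex scaled so that all pairwise center
#' distances equal `separation * sigma` (separation measured in units of
#' the component standard deviation).
#'
#' @param n_per_cluster Integer vector, samples per cluster (length K).
#' @param m_informative Number of informative (signal) features.
#' @param m_noise Number of appended uniform noise features (default 0).
#' @param centers Optional K x m_informative center matrix; overrides
#'   `separation`.
#' @param separation Pairwise center distance in sigma units (default 6,
#'   well-separated).
#' @param sigma Component standard deviation (> 0, default 1).
#' @param noise_low,noise_high Uniform noise support (defaults 0 and 1).
#' @param seed Integer seed; the same spec and seed give bit-identical data.
#' @return An object of class `blob_spec`.
#' @export
blob_spec <- function(n_per_cluster, m_informative, m_noise = 0L,
                      centers = NULL, separation = 6, sigma = 1,
                      noise_low = 0, noise_high = 1, seed = 1L) {
  n_per_cluster <- as.integer(n_per_cluster)
  K <- length(n_per_cluster)
  stopifnot(
    "need at least one cluster with at least one sample" =
      K >= 1L && all(n_per_cluster >= 1L),
    "`m_informative` must be >= 1" = m_informative >= 1L,
    "`m_noise` must be >= 0" = m_noise >= 0L,
    "`sigma` must be > 0" = sigma > 0,
    "`separation` must be > 0" = separation > 0
  )
  if (noise_high <= noise_low) stop("`noise_high` must exceed `noise_low`")
  if (is.null(centers)) {
    centers <- simplex_centers(K, m_informative) * separation * sigma
  } else {
    centers <- as.matrix(centers)
    if (nrow(centers) != K || ncol(centers) != m_informative)
      stop("`centers` must be K x m_informative")
  }
  structure(list(n_per_cluster = n_per_cluster, m_informative = as.integer(m_informative),
                 m_noise = as.integer(m_noise), centers = centers,
                 sigma = sigma, noise_low = noise_low, noise_high = noise_high,
                 seed = as.integer(seed)),
            class = "blob_spec")
}

#' Vertices of a regular unit simplex, embedded in d dimensions
#'
#' Returns K points in d dimensions, centered at the origin, with all
#' pairwise distances equal to 1. Requires d >= K - 1.
#'
#' @param K Number of vertices.
#' @param d Embedding dimension.
#' @return K x d matrix.
#' @export
simplex_centers <- function(K, d) {
  if (d < K - 1L) stop("embedding dimension must be at least K - 1")
  if (K == 1L) return(matrix(0, 1L, d))
  H <- diag(K) - 1 / K                  # centered standard-basis vertices in R^K
  Q <- svd(H)$u[, seq_len(K - 1L), drop = FALSE]
  V <- H %*% Q / sqrt(2)                # pairwise distance 1
  cbind(V, matrix(0, K, d - K + 1L))
}

#' Generate a Gaussian-blob dataset from a specification
#'
#' @param spec A [blob_spec()].
#' @return An `fwec_data` with `sum(n_per_cluster)` rows,
#'   `m_informative + m_noise` columns (noise columns last) and integer
#'   labels. Deterministic given the spec (including its seed).
#' @examples
#' d <- make_blobs(blob_spec(c(10, 10, 10), m_informative = 2, m_noise = 1,
#'                           seed = 42))
#' dim(d$values)
#' @export
make_blobs <- function(spec) {
  stopifnot(inherits(spec, "blob_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  K <- length(spec$n_per_cluster)
  labels <- rep(seq_len(K), spec$n_per_cluster)
  N <- length(labels)
  X <- spec$centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(N * spec$m_informative, sd = spec$sigma),
           N, spec$m_informative)
  d <- fwec_data(X, labels = labels)
  if (spec$m_noise > 0L)
    d <- add_noise_features(d, spec$m_noise, spec$noise_low, spec$noise_high)
  d
}

#' Append uniform noise features to a dataset
#'
#' Adds `m_noise` i.i.d. uniform(low, high) columns to the right of the
#' feature matrix; existing columns and labels are untouched. These columns
#' mimic irrelevant measurements that an informative clustering should
#' down-weight.
#'
#' @param data `fwec_data` or numeric matrix.
#' @param m_noise Number of noise columns (>= 0; 0 is the identity).
#' @param low,high Uniform support bounds, `high > low`.
#' @param seed Optional integer seed; `NULL` (default) draws from the
#'   current RNG stream.
#' @return An `fwec_data` with the noise columns appended.
#' @export
add_noise_features <- function(data, m_noise, low = 0, high = 1, seed = NULL) {
  d <- as_fwec_data(data)
  m_noise <- as.integer(m_noise)
  if (m_noise < 0L) stop("`m_noise` must be >= 0")
  if (high <= low) stop("`high` must exceed `low`")
  if (m_noise == 0L) return(d)
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(d$values)
  noise <- matrix(stats::runif(N * m_noise, low, high), N, m_noise)
  fwec_data(cbind(d$values, noise), labels = d$labels)
}

#' Displace a fraction of samples to emulate heavy-tailed outliers
#'
#' Moves a random `fraction` of rows by `shift` (in sigma units) along a
#' random direction of the informative subspace, producing the gross
#' outliers that a bounded distance should resist.
#'
#' @param data An `fwec_data` (labels kept).
#' @param fraction Fraction of rows to displace (default 0.05).
#' @param shift Displacement magnitude in `sigma` units (default 20).
#' @param sigma Scale unit (default 1).
#' @param seed Optional integer seed.
#' @return The contaminated `fwec_data`.
#' @export
contaminate_outliers <- function(data, fraction = 0.05, shift = 20, sigma = 1,
                                 seed = NULL) {
  d <- as_fwec_data(data)
  if (fraction < 0 || fraction > 1) stop("`fraction` must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(d$values); M <- ncol(d$values)
  n_out <- round(fraction * N)
  if (n_out == 0L) return(d)
  rows <- sample.int(N, n_out)
  dir <- matrix(stats::rnorm(n_out * M), n_out, M)
  dir <- dir / sqrt(rowSums(dir^2))
  d$values[rows, ] <- d$values[rows, ] + shift * sigma * dir
  d
}
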