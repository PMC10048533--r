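# Independent brute-force oracles and instance generators. Everything here
# is deliberately scalar-loop / enumeration code: slow, obviously correct,
# and never shares a code path with the implementation it checks.

# triple-loop sample-to-cluster dispersion D_ij = sum_l w_jl d(x_il, c_jl)
oracle_dispersion <- function(X, C, W, delta, mode = "non_euclidean") {
  N <- nrow(X); K <- nrow(C); M <- ncol(X)
  D <- matrix(0, N, K)
  for (i in seq_len(N)) for (j in seq_len(K)) {
    s <- 0
    for (l in seq_len(M)) {
      d2 <- (X[i, l] - C[j, l])^2
      s <- s + W[j, l] * if (mode == "euclidean") d2 else 1 - exp(-delta[l] * d2)
    }
    D[i, j] <- s
  }
  D
}

# scalar-loop objective
oracle_objective <- function(X, U, W, C, delta, lam, gam, mode = "non_euclidean") {
  N <- nrow(X); K <- nrow(C); M <- ncol(X)
  f <- 0
  for (i in seq_len(N)) for (j in seq_len(K)) for (l in seq_len(M)) {
    d2 <- (X[i, l] - C[j, l])^2
    d <- if (mode == "euclidean") d2 else 1 - exp(-delta[l] * d2)
    f <- f + U[i, j] * W[j, l] * d
  }
  for (i in seq_len(N)) for (j in seq_len(K)) f <- f + lam * U[i, j] * log(U[i, j])
  for (j in seq_len(K)) for (l in seq_len(M)) f <- f + gam * W[j, l] * log(W[j, l])
  f
}

# scalar-loop per-(cluster, feature) dispersion D'_jl = sum_i u_ij d_il
oracle_weight_dispersion <- function(X, U, C, delta) {
  K <- nrow(C); M <- ncol(X)
  Dp <- matrix(0, K, M)
  for (j in seq_len(K)) for (l in seq_len(M)) {
    s <- 0
    for (i in seq_len(nrow(X)))
      s <- s + U[i, j] * (1 - exp(-delta[l] * (X[i, l] - C[j, l])^2))
    Dp[j, l] <- s
  }
  Dp
}

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms(n - 1L)) for (pos in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  }
  out
}

# exhaustive-matching clustering accuracy: try every injective mapping of
# the smaller label set into the larger one
oracle_accuracy <- function(pred, true) {
  tab <- table(pred, true)
  nr <- nrow(tab); nc <- ncol(tab)
  n <- max(nr, nc)
  pad <- matrix(0, n, n)
  pad[seq_len(nr), seq_len(nc)] <- tab
  best <- 0
  for (p in perms(n)) best <- max(best, sum(pad[cbind(seq_len(n), p)]))
  best / length(pred)
}

# O(N^2) pair-enumeration Rand index
oracle_rand <- function(pred, true) {
  n <- length(pred)
  agree <- 0; total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    total <- total + 1
    same_p <- pred[i] == pred[j]; same_t <- true[i] == true[j]
    if (same_p == same_t) agree <- agree + 1
  }
  agree / total
}

# direct plug-in NMI from scalar loops over label values
oracle_nmi <- function(pred, true) {
  n <- length(pred)
  up <- unique(pred); ut <- unique(true)
  hp <- 0; ht <- 0; mi <- 0
  for (a in up) { p <- sum(pred == a) / n; hp <- hp - p * log(p) }
  for (b in ut) { p <- sum(true == b) / n; ht <- ht - p * log(p) }
  if (hp == 0 && ht == 0) return(1)
  if (hp == 0 || ht == 0) return(0)
  for (a in up) for (b in ut) {
    pab <- sum(pred == a & true == b) / n
    if (pab > 0)
      mi <- mi + pab * log(pab / ((sum(pred == a) / n) * (sum(true == b) / n)))
  }
  mi / sqrt(hp * ht)
}

# exhaustive K = 2 k-means optimum for 1-D data: try every 2-partition
oracle_kmeans2_1d <- function(x) {
  n <- length(x)
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    g <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    ss <- sum((x[g] - mean(x[g]))^2) + sum((x[!g] - mean(x[!g]))^2)
    best <- min(best, ss)
  }
  best
}

# random row-stochastic matrix with strictly positive entries (Dirichlet)
rand_stochastic <- function(nr, nc) {
  m <- matrix(stats::rgamma(nr * nc, shape = 1), nr, nc)
  m / rowSums(m)
}

# random small test instance: data, a valid (U, W, C) state, and precision
rand_instance <- function(N, K, M, seed) {
  set.seed(seed)
  X <- matrix(stats::rnorm(N * M, sd = runif(1, 0.5, 3)), N, M)
  delta <- feature_precision(X)$delta
  list(X = X, delta = delta,
       U = rand_stochastic(N, K),
       W = rand_stochastic(K, M),
       C = X[sample.int(N, K), , drop = FALSE] +
         matrix(stats::rnorm(K * M, sd = 0.1), K, M))
}

# random label pair for metric tests
rand_labels <- function(n, kmax, seed) {
  set.seed(seed)
  list(pred = sample.int(sample.int(kmax, 1), n, replace = TRUE),
       true = sample.int(sample.int(kmax, 1), n, replace = TRUE))
}
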