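# External cluster-validity indices: accuracy under an optimal one-to-one
# cluster-to-class matching, the Rand index, and normalized mutual
# information. All three are invariant to any permutation of predicted
# cluster IDs and lie in [0, 1].

.check_pair <- function(pred, true) {
  if (length(pred) != length(true))
    stop("`pred` and `true` must have equal length")
  if (length(pred) < 1L) stop("need at least one sample")
  if (anyNA(pred) || anyNA(true)) stop("labels must not contain NA")
}

#' Contingency table of two labelings
#'
#' @param pred,true Label vectors of equal length.
#' @return Integer matrix, predicted clusters as rows, true classes as columns.
#' @export
contingency_table <- function(pred, true) {
  .check_pair(pred, true)
  unclass(table(pred = pred, true = true))
}

# Maximum-weight one-to-one assignment on a (possibly rectangular)
# non-negative profit matrix; returns the total profit and the column
# matched to each row (NA for unmatched rows). Jonker-Volgenant style
# shortest-augmenting-path solver on the square zero-padded cost matrix,
# O(n^3). clue/lpSolve are not available in the target environment.
.lap_max <- function(profit) {
  nr <- nrow(profit); nc <- ncol(profit)
  n <- max(nr, nc)
  cost <- matrix(0, n, n)
  cost[seq_len(nr), seq_len(nc)] <- max(profit) - profit
  # dual potentials and matching (1-indexed; 0 = unmatched)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)          # p[j]: row matched to column j (col n+1 = virtual)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  match_col <- rep(NA_integer_, nr)
  for (j in seq_len(n)) if (p[j] >= 1L && p[j] <= nr && j <= nc) match_col[p[j]] <- j
  total <- sum(profit[cbind(which(!is.na(match_col)), match_col[!is.na(match_col)])])
  list(total = total, match = match_col)
}

#' Clustering accuracy under cluster-to-class matching
#'
#' ACC = (number of samples correctly classified) / N, where "correct" is
#' induced by a mapping of predicted clusters to true classes. The default
#' `"optimal"` mapping is the one-to-one assignment maximizing the total
#' match count (maximum-weight bipartite matching on the contingency
#' table); when the cluster and class counts differ, unmatched clusters
#' contribute no correct samples. The `"majority"` mapping assigns each
#' cluster independently to its modal class (not one-to-one; provided for
#' comparison, not used as default).
#'
#' @param pred,true Label vectors of equal length.
#' @param mapping `"optimal"` (default) or `"majority"`.
#' @return Accuracy in (0, 1].
#' @examples
#' clustering_accuracy(c(1, 2, 2, 2), c(1, 1, 2, 2))  # 0.75
#' @export
clustering_accuracy <- function(pred, true, mapping = c("optimal", "majority")) {
  mapping <- match.arg(mapping)
  tab <- contingency_table(pred, true)
  n <- sum(tab)
  if (mapping == "majority") return(sum(apply(tab, 1L, max)) / n)
  .lap_max(tab)$total / n
}

#' Rand index of two partitions
#'
#' The fraction of the N(N-1)/2 unordered sample pairs on which the two
#' partitions agree: either together in both or apart in both. Computed
#' from the contingency table in closed form.
#'
#' @param pred,true Label vectors of equal length >= 2.
#' @return Rand index in [0, 1].
#' @export
rand_index <- function(pred, true) {
  .check_pair(pred, true)
  if (length(pred) < 2L) stop("the Rand index needs at least 2 samples")
  tab <- contingency_table(pred, true)
  n <- sum(tab)
  ch2 <- function(x) x * (x - 1) / 2
  total <- ch2(n)
  s <- sum(ch2(tab))                       # pairs together in both
  sr <- sum(ch2(rowSums(tab)))             # together in pred
  sc <- sum(ch2(colSums(tab)))             # together in true
  (total + 2 * s - sr - sc) / total
}

#' Normalized mutual information of two partitions
#'
#' Plug-in mutual information of the contingency distribution (natural
#' logarithms) normalized by the geometric mean sqrt(H(pred) * H(true)) of
#' the two partition entropies, so the value lies in [0, 1]. If both
#' partitions are the trivial single cluster the value is 1; if exactly one
#' has zero entropy it is 0.
#'
#' @param pred,true Label vectors of equal length.
#' @return NMI in [0, 1].
#' @export
nmi <- function(pred, true) {
  tab <- contingency_table(pred, true)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  h <- function(p) -sum(.xlogx(p))
  ha <- h(pi_); hb <- h(pj_)
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  min(max(mi / sqrt(ha * hb), 0), 1)
}

#' All three validity indices for one (predicted, true) pair
#'
#' @param pred,true Label vectors of equal length.
#' @return An object of class `partition_metrics`: list with `acc`, `ri`,
#'   `nmi`, the `contingency` table and the optimal cluster-to-class
#'   `mapping` used for ACC (NA for unmatched clusters).
#' @export
partition_metrics <- function(pred, true) {
  tab <- contingency_table(pred, true)
  lap <- .lap_max(tab)
  structure(list(
    acc = lap$total / sum(tab),
    ri = rand_index(pred, true),
    nmi = nmi(pred, true),
    contingency = tab,
    mapping = stats::setNames(colnames(tab)[lap$match], rownames(tab))
  ), class = "partition_metrics")
}

#' @export
print.partition_metrics <- function(x, ...) {
  cat(sprintf("<partition_metrics> ACC %.4f | RI %.4f | NMI %.4f\n",
              x$acc, x$ri, x$nmi))
  invisible(x)
}
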