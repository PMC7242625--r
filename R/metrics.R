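#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement computed from the contingency table of the
#' two partitions under the generalized hypergeometric model of randomness.
#' Binomial coefficients C(n, 2) are 0 for n <= 1, so singleton classes
#' contribute nothing. If the adjustment denominator is exactly 0 (both
#' partitions degenerate), the index is 1 when the partitions induce the
#' same grouping and 0 otherwise. The raw value is returned untruncated
#' (it can be negative for partitions agreeing less than chance).
#'
#' @param u,v partition label vectors of equal length (any atomic type).
#' @return a single numeric value.
#' @export
adjusted_rand_index <- function(u, v) {
  if (length(u) != length(v)) stop("partitions have different lengths")
  n <- length(u)
  tab <- table(u, v)
  sum_cells <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  expected <- if (total > 0) a * b / total else 0
  maximum <- (a + b) / 2
  denom <- maximum - expected
  if (denom == 0) {
    same <- identical(unname(as.integer(factor(u, levels = unique(u)))),
                      unname(as.integer(factor(v, levels = unique(v)))))
    return(if (same) 1 else 0)
  }
  (sum_cells - expected) / denom
}

#' Within-cluster homogeneity omega
#'
#' Over all unordered pairs of distinct examinees assigned to the same
#' cluster, one minus the average per-attribute disagreement of their true
#' attribute profiles:
#' \deqn{\omega = 1 - \frac{\sum_{i < i'} \sum_k |\alpha_{ik} -
#'   \alpha_{i'k}| \, 1[c_i = c_{i'}]}{K \sum_{i < i'} 1[c_i = c_{i'}]}.}
#' Equals 1 when every cluster contains a single true profile; defined as 1
#' (vacuously homogeneous) when no two examinees share a cluster.
#'
#' @param assignment cluster label vector, length I.
#' @param profiles I x K matrix of true attribute profiles.
#' @return a value in `[0, 1]`.
#' @export
omega <- function(assignment, profiles) {
  profiles <- as.matrix(profiles)
  if (length(assignment) != nrow(profiles))
    stop("assignment and profile counts differ")
  K <- ncol(profiles)
  total_pairs <- 0
  disagreements <- 0
  for (cl in unique(assignment)) {
    rows <- profiles[assignment == cl, , drop = FALSE]
    n <- nrow(rows)
    if (n < 2L) next
    total_pairs <- total_pairs + n * (n - 1) / 2
    s <- colSums(rows) # per attribute: s*(n-s) discordant binary pairs
    disagreements <- disagreements + sum(s * (n - s))
  }
  if (total_pairs == 0) return(1)
  1 - disagreements / (K * total_pairs)
}

#' Root mean squared within-cluster residual of sum-scores
#'
#' For cluster m: \eqn{MSR(m) = \sqrt{\sum_{i \in m} \lVert W_i - \bar
#' W(m) \rVert^2 / I_m}}. Smaller values indicate more homogeneous
#' clusters; a singleton cluster has MSR 0.
#'
#' @param W I x K sum-score matrix (see [sum_scores()]).
#' @param assignment cluster label vector, length I.
#' @return named numeric vector of MSR values, one per cluster label.
#' @export
msr <- function(W, assignment) {
  W <- as.matrix(W)
  if (length(assignment) != nrow(W)) stop("assignment and W lengths differ")
  labels <- sort(unique(assignment))
  out <- vapply(labels, function(cl) {
    rows <- W[assignment == cl, , drop = FALSE]
    centered <- sweep(rows, 2L, colMeans(rows))
    sqrt(sum(centered^2) / nrow(rows))
  }, numeric(1L))
  names(out) <- labels
  out
}

#' Per-cluster summary table ordered by mean sum-score
#'
#' For each cluster: size, mean attribute sum-score vector (columns
#' `W_1..W_K`), MSR, and mean total score. Rows are ordered by ascending
#' mean total sum-score — the heuristic used to infer attribute profiles
#' from unlabeled clusters, since mastering more attributes tends to yield
#' a higher total score.
#'
#' @param X I x J response matrix.
#' @param Q J x K Q-matrix.
#' @param assignment cluster label vector, length I.
#' @return a data.frame with one row per cluster.
#' @export
cluster_report <- function(X, Q, assignment) {
  W <- sum_scores(X, Q)
  total <- rowSums(unclass(X))
  labels <- sort(unique(assignment))
  meanW <- t(vapply(labels, function(cl)
    colMeans(W[assignment == cl, , drop = FALSE]), numeric(ncol(W))))
  colnames(meanW) <- paste0("W_", seq_len(ncol(W)))
  rep_df <- data.frame(
    cluster = labels,
    size = vapply(labels, function(cl) sum(assignment == cl), numeric(1L)),
    meanW,
    MSR = unname(msr(W, assignment)),
    mean_sum_score = vapply(labels, function(cl)
      mean(total[assignment == cl]), numeric(1L)))
  rep_df[order(rep_df$mean_sum_score), , drop = FALSE]
}
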