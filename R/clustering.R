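#' Attribute sum-score matrix W = XQ
#'
#' \eqn{W_{ik} = \sum_j X_{ij} q_{jk}}: the number of correctly answered
#' items among those requiring attribute k, for each examinee.
#'
#' @param X an I x J [response_matrix()].
#' @param Q a J x K [qmatrix()].
#' @return an I x K integer matrix.
#' @export
sum_scores <- function(X, Q) {
  if (ncol(X) != nrow(Q))
    stop("response matrix has ", ncol(X), " items but Q-matrix has ", nrow(Q))
  W <- unclass(X) %*% unclass(Q)
  storage.mode(W) <- "integer"
  W
}

#' "Best" K-means starting centroids from the expected response matrix
#'
#' \eqn{W_{M \times K} = P_{M \times J} Q_{J \times K}}, where row m of P is
#' the probability of each correct response under the m-th canonical
#' attribute profile. Only available in simulation, where the generating
#' item parameters are known.
#'
#' @param P M x J expected response matrix, rows in canonical profile order.
#' @param Q a J x K [qmatrix()].
#' @return an M x K numeric centroid matrix.
#' @export
best_starting_centroids <- function(P, Q) {
  if (ncol(P) != nrow(Q)) stop("P and Q dimensions do not conform")
  P %*% unclass(Q)
}

#' Ward's minimum-variance agglomerative clustering
#'
#' Starts from singletons and repeatedly merges the pair of clusters p, q
#' minimizing the within-cluster variance increase
#' \eqn{I_p I_q / (I_p + I_q) \, \lVert \bar Y_p - \bar Y_q \rVert^2},
#' until `M` clusters remain. Ties are broken toward the lowest (p, q)
#' cluster-id pair, where a merged cluster keeps the smaller id.
#'
#' @param data I x d numeric matrix.
#' @param M target number of clusters, `1 <= M <= I`.
#' @return a `cluster_solution` (see [kmeans_cdm()]), with `converged = TRUE`
#'   and `n_iterations` the number of merges.
#' @export
ward_clusters <- function(data, M) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  I <- nrow(data)
  if (M > I) stop("cannot form ", M, " clusters from ", I, " points")
  assignment <- .ward_agglomerate_cpp(data, as.integer(M))
  cluster_solution(assignment, data, n_iterations = I - M, converged = TRUE)
}

# assemble a cluster_solution: centroids are cluster means of `data`
cluster_solution <- function(assignment, data, n_iterations, converged,
                             centroids = NULL) {
  M <- max(assignment)
  d <- ncol(data)
  if (is.null(centroids)) {
    centroids <- matrix(NA_real_, M, d)
    for (m in seq_len(M)) {
      rows <- assignment == m
      if (any(rows))
        centroids[m, ] <- colMeans(data[rows, , drop = FALSE])
    }
  }
  sse <- numeric(M)
  for (m in seq_len(M)) {
    rows <- assignment == m
    if (any(rows))
      sse[m] <- sum(sweep(data[rows, , drop = FALSE], 2L, centroids[m, ])^2)
  }
  structure(list(assignment = as.integer(assignment), centroids = centroids,
                 n_iterations = n_iterations, converged = converged,
                 within_cluster_sse = sse),
            class = "cluster_solution")
}

#' K-means (Lloyd's algorithm) with best / Ward / random starting values
#'
#' Points are assigned to the nearest centroid in squared Euclidean
#' distance (ties toward the lowest cluster index), centroids are updated
#' to cluster means, and iteration stops when no centroid moves more than
#' `tol` or `max_iter` is reached. A cluster emptied during iteration is
#' reseeded with the point farthest from its current centroid.
#'
#' Starting values: `init = "best"` takes `centroids` as given (in
#' simulation, from [best_starting_centroids()]); `init = "ward"` seeds
#' with the cluster means of [ward_clusters()]; `init = "random"` samples M
#' distinct data rows (duplicated rows are jittered by 1e-6 seeded noise
#' when fewer than M distinct rows exist).
#'
#' @param data I x d numeric matrix.
#' @param M number of clusters.
#' @param init `"ward"`, `"random"` or `"best"`.
#' @param centroids M x d matrix of starting centroids (required for
#'   `init = "best"`).
#' @param max_iter maximum number of Lloyd iterations (default 300).
#' @param tol convergence threshold on the maximum centroid displacement
#'   (default 1e-8).
#' @return a `cluster_solution`: list with `assignment` (1..M),
#'   `centroids`, `n_iterations`, `converged`, `within_cluster_sse`, and
#'   `sse_trace` (total within-cluster SSE after each assignment step).
#' @export
kmeans_cdm <- function(data, M, init = c("ward", "random", "best"),
                       centroids = NULL, max_iter = 300L, tol = 1e-8) {
  init <- match.arg(init)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  I <- nrow(data)
  if (M > I) stop("cannot form ", M, " clusters from ", I, " points")

  C <- switch(init,
    best = {
      if (is.null(centroids)) stop("init = \"best\" requires starting centroids")
      as.matrix(centroids)
    },
    ward = ward_clusters(data, M)$centroids,
    random = {
      distinct <- unique(data)
      if (nrow(distinct) >= M) {
        distinct[sample.int(nrow(distinct), M), , drop = FALSE]
      } else {
        picked <- data[sample.int(I, M), , drop = FALSE]
        picked + matrix(stats::runif(length(picked), -1e-6, 1e-6),
                        M, ncol(data))
      }
    })
  if (nrow(C) != M) stop("starting centroid count does not equal M")

  x2 <- rowSums(data^2)
  assignment <- integer(I)
  sse_trace <- numeric(0L)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    d2 <- outer(x2, rowSums(C^2), "+") - 2 * data %*% t(C)
    assignment <- max.col(-d2, ties.method = "first")
    sse_trace <- c(sse_trace, sum(pmax(d2[cbind(seq_len(I), assignment)], 0)))
    newC <- C
    for (m in seq_len(M)) {
      rows <- assignment == m
      if (any(rows)) {
        newC[m, ] <- colMeans(data[rows, , drop = FALSE])
      } else { # reseed an emptied cluster with the worst-fitting point
        far <- which.max(d2[cbind(seq_len(I), assignment)])
        newC[m, ] <- data[far, ]
        assignment[far] <- m
      }
    }
    if (max(abs(newC - C)) <= tol) {
      C <- newC
      converged <- TRUE
      break
    }
    C <- newC
  }
  sol <- cluster_solution(assignment, data, n_iterations = iter,
                          converged = converged, centroids = C)
  sol$sse_trace <- sse_trace
  sol
}

#' Gaussian-kernel similarity matrix of binary response vectors
#'
#' \eqn{S_{ii'} = \exp(-\lVert X_i - X_{i'} \rVert^2 / 2\sigma^2)}. For
#' binary rows the squared Euclidean distance equals the Hamming distance.
#' The diagonal is 1 (every examinee is maximally similar to themselves).
#'
#' @param X I x J binary response matrix.
#' @param sigma2 kernel bandwidth \eqn{\sigma^2 > 0} (default 1).
#' @return a symmetric I x I similarity matrix with entries in (0, 1].
#' @export
spectral_similarity <- function(X, sigma2 = 1) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  X <- unclass(as.matrix(X))
  storage.mode(X) <- "double"
  g <- tcrossprod(X)
  sq <- diag(g)
  h <- outer(sq, sq, "+") - 2 * g # squared Euclidean distances
  h[h < 0] <- 0
  S <- exp(-h / (2 * sigma2))
  (S + t(S)) / 2
}

#' Degree matrix and normalized graph Laplacian
#'
#' \eqn{D_{ii} = \sum_{i'} S_{ii'}} (self-similarity included) and
#' \eqn{L = I - D^{-1/2} S D^{-1/2}}.
#'
#' @param S symmetric similarity matrix with positive row sums.
#' @return list with `D` (vector of degrees) and `L` (symmetric Laplacian).
#' @export
normalized_laplacian <- function(S) {
  deg <- rowSums(S)
  if (any(deg <= 0)) stop("zero or negative degree: similarity rows must have positive sums")
  inv_sqrt <- 1 / sqrt(deg)
  L <- -S * tcrossprod(inv_sqrt)
  diag(L) <- diag(L) + 1
  L <- (L + t(L)) / 2
  list(D = deg, L = L)
}

#' Spectral embedding from the normalized Laplacian
#'
#' Computes the eigenvectors of the M smallest eigenvalues of L (ascending
#' order), stacks them as columns of U, and normalizes each row of U to
#' unit Euclidean norm. A degenerate row with norm below 1e-12 is left at
#' zero with a warning.
#'
#' @param L normalized Laplacian from [normalized_laplacian()].
#' @param M embedding dimension (number of clusters), `M <= nrow(L)`.
#' @return an I x M matrix `Z` whose rows are the embedded points.
#' @export
spectral_embed <- function(L, M) {
  I <- nrow(L)
  if (M > I) stop("M cannot exceed the number of examinees")
  U <- .eig_smallest_cpp(L, as.integer(M))$vectors
  norms <- sqrt(rowSums(U^2))
  degenerate <- norms < 1e-12
  if (any(degenerate)) {
    warning(sum(degenerate), " embedding row(s) with near-zero norm left at zero")
    norms[degenerate] <- 1
  }
  U / norms
}

#' Spectral clustering of examinees from binary responses
#'
#' The full pipeline: Gaussian-kernel similarity, normalized Laplacian,
#' M-dimensional spectral embedding with row normalization, then K-means on
#' the embedded points with Ward or random starting values. Examinee i is
#' assigned the cluster of its embedded point \eqn{Z_i}.
#'
#' @param X I x J binary response matrix.
#' @param M number of clusters (for K attributes, \eqn{M = 2^K}).
#' @param init `"ward"` or `"random"` starting values for the final K-means.
#' @param sigma2 kernel bandwidth (default 1).
#' @param ... passed to [kmeans_cdm()].
#' @return a `cluster_solution` over the original examinees; the `embedding`
#'   element holds Z.
#' @export
spectral_cluster <- function(X, M, init = c("ward", "random"), sigma2 = 1, ...) {
  init <- match.arg(init)
  if (M > nrow(X)) stop("cannot form ", M, " clusters from ", nrow(X), " examinees")
  S <- spectral_similarity(X, sigma2)
  L <- normalized_laplacian(S)$L
  Z <- spectral_embed(L, M)
  sol <- kmeans_cdm(Z, M, init = init, ...)
  sol$embedding <- Z
  sol
}
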