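# Independent brute-force oracles used across test files. These stay
# deliberately naive (loops, exhaustive search) so they cannot share a bug
# with the vectorized / compiled implementations they check.

oracle_sum_scores <- function(X, Q) {
  W <- matrix(0L, nrow(X), ncol(Q))
  for (i in seq_len(nrow(X)))
    for (k in seq_len(ncol(Q)))
      for (j in seq_len(ncol(X)))
        W[i, k] <- W[i, k] + X[i, j] * Q[j, k]
  W
}

oracle_similarity <- function(X, sigma2 = 1) {
  I <- nrow(X)
  S <- matrix(0, I, I)
  for (i in seq_len(I))
    for (ip in seq_len(I))
      S[i, ip] <- exp(-sum((X[i, ] - X[ip, ])^2) / (2 * sigma2))
  S
}

oracle_laplacian <- function(S) {
  I <- nrow(S)
  D <- diag(rowSums(S))
  diag(I) - solve(sqrt(D)) %*% S %*% solve(sqrt(D))
}

# pair-counting Adjusted Rand Index over all C(I,2) pairs
oracle_ari <- function(u, v) {
  n <- length(u)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    su <- u[i] == u[j]
    sv <- v[i] == v[j]
    if (su && sv) n11 <- n11 + 1
    else if (su && !sv) n10 <- n10 + 1
    else if (!su && sv) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  total <- n11 + n10 + n01 + n00
  expected <- (n11 + n10) * (n11 + n01) / total
  maximum <- ((n11 + n10) + (n11 + n01)) / 2
  if (maximum == expected)
    return(if (n10 + n01 == 0) 1 else 0)
  (n11 - expected) / (maximum - expected)
}

# omega by direct summation over strict pairs
oracle_omega <- function(assignment, profiles) {
  I <- nrow(profiles)
  K <- ncol(profiles)
  num <- den <- 0
  for (i in 2:I) for (ip in 1:(i - 1)) {
    if (assignment[i] != assignment[ip]) next
    num <- num + sum(abs(profiles[i, ] - profiles[ip, ]))
    den <- den + K
  }
  if (den == 0) return(1)
  1 - num / den
}

# exhaustive-search Ward agglomeration: recompute every pair cost each step
oracle_ward <- function(data, M) {
  n <- nrow(data)
  members <- as.list(seq_len(n))
  while (length(members) > M) {
    best <- Inf
    bi <- bj <- NA
    for (a in seq_along(members)) for (b in seq_along(members)) {
      if (a >= b) next
      ma <- colMeans(data[members[[a]], , drop = FALSE])
      mb <- colMeans(data[members[[b]], , drop = FALSE])
      na <- length(members[[a]]); nb <- length(members[[b]])
      cost <- na * nb / (na + nb) * sum((ma - mb)^2)
      if (cost < best) { best <- cost; bi <- a; bj <- b }
    }
    members[[bi]] <- c(members[[bi]], members[[bj]])
    members[[bj]] <- NULL
  }
  out <- integer(n)
  ord <- order(vapply(members, min, numeric(1L)))
  for (m in seq_along(ord)) out[members[[ord[m]]]] <- m
  out
}

# small simulated dataset shared by several test files
make_sim_data <- function(I = 200, K = 3, J = 10, model = "DINA",
                          quality = "high", seed = 42) {
  set.seed(seed)
  Q <- generate_qmatrix(J, K)
  profiles <- simulate_attributes(I, K)
  params <- generate_item_parameters(Q, model, item_quality(quality))
  X <- simulate_responses(params, profiles)
  list(Q = Q, profiles = profiles, params = params, X = X)
}
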