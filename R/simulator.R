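#' Item-quality specification
#'
#' Item quality is governed by the two endpoint success probabilities of an
#' item: P(0), the probability of a correct response for examinees
#' mastering none of the required attributes (the baseline/guessing level),
#' and P(1), the probability for examinees mastering all of them.  High
#' quality draws the baseline P(0) and the slip 1 - P(1) from U(0.05, 0.15)
#' (so P(1) in (0.85, 0.95)); low quality draws both from U(0.25, 0.35).
#'
#' @param label `"high"` or `"low"`.
#' @return a list with `label`, `p0_range` and `slip_range`.
#' @export
item_quality <- function(label = c("high", "low")) {
  label <- match.arg(label)
  rng <- if (label == "high") c(0.05, 0.15) else c(0.25, 0.35)
  list(label = label, p0_range = rng, slip_range = rng)
}

#' Simulate true attribute profiles
#'
#' Latent abilities are drawn from a multivariate normal
#' \eqn{\theta_i \sim MVN(0, \Sigma)} with unit variances and common
#' correlation `rho`, and dichotomized attribute-wise:
#' \eqn{\alpha_{ik} = 1} iff \eqn{\theta_{ik} \ge \Phi^{-1}(k / (K + 1))},
#' so the marginal mastery probability of attribute k is 1 - k/(K+1).
#'
#' @param I number of examinees.
#' @param K number of attributes.
#' @param rho common latent correlation in `[0, 1)` (default 0.5).
#' @return an I x K integer matrix of attribute profiles.
#' @export
simulate_attributes <- function(I, K, rho = 0.5) {
  stopifnot(I >= 1, K >= 1)
  if (rho < 0 || rho >= 1)
    stop("rho must be in [0, 1) for a positive definite correlation matrix")
  sigma <- matrix(rho, K, K)
  diag(sigma) <- 1
  cf <- tryCatch(chol(sigma), error = function(e)
    stop("correlation matrix is not positive definite"))
  theta <- matrix(stats::rnorm(I * K), I, K) %*% cf
  thresholds <- stats::qnorm(seq_len(K) / (K + 1))
  alpha <- matrix(0L, I, K)
  for (k in seq_len(K)) alpha[, k] <- as.integer(theta[, k] >= thresholds[k])
  alpha
}

#' Generate item parameters under an identity-link CDM
#'
#' For each item the two endpoints are drawn from the quality ranges:
#' P(0) ~ U(p0_range) and P(1) = 1 - slip with slip ~ U(slip_range).  The
#' success probabilities of the \eqn{2^{K_j^*}} reduced attribute classes
#' (profiles restricted to the item's required attributes, canonical
#' order) are then filled in model-specifically:
#' \describe{
#'   \item{DINA}{baseline P(0) everywhere except the full-mastery class,
#'     which gets P(1) (conjunctive).}
#'   \item{DINO}{P(0) for the zero class, P(1) for every class mastering at
#'     least one required attribute (disjunctive).}
#'   \item{A-CDM}{equal main effects: P(0) plus
#'     (number mastered) x (P(1) - P(0)) / K_j* (additive).}
#'   \item{G-DINA}{endpoints pinned at P(0)/P(1); each intermediate class
#'     drawn uniformly between the maximum of its immediate sub-classes and
#'     P(1), in increasing order of mastered attributes, which guarantees
#'     weak monotonicity in the subset partial order in a single pass.}
#' }
#'
#' Uses the current R random number stream.
#'
#' @param Q a [qmatrix()].
#' @param model one of `"G-DINA"`, `"DINA"`, `"DINO"`, `"A-CDM"`.
#' @param quality an [item_quality()] specification (or its label).
#' @return an object of class `item_parameters`: list with `model`, `Q`,
#'   and `items`, a per-item list of `req` (required attribute indices) and
#'   `probs` (success probability per reduced class, canonical order).
#' @export
generate_item_parameters <- function(Q, model = c("G-DINA", "DINA", "DINO", "A-CDM"),
                                     quality = item_quality("high")) {
  model <- match.arg(model)
  if (is.character(quality)) quality <- item_quality(quality)
  J <- nrow(Q)
  p0 <- stats::runif(J, quality$p0_range[1L], quality$p0_range[2L])
  p1 <- 1 - stats::runif(J, quality$slip_range[1L], quality$slip_range[2L])
  items <- vector("list", J)
  for (j in seq_len(J)) {
    req <- which(Q[j, ] == 1L)
    items[[j]] <- list(req = req,
                       probs = reduced_class_probs(model, length(req), p0[j], p1[j]))
  }
  structure(list(model = model, Q = Q, items = items, p0 = p0, p1 = p1),
            class = "item_parameters")
}

# success probabilities for the 2^kstar reduced classes, canonical order
reduced_class_probs <- function(model, kstar, p0, p1) {
  space <- enumerate_profiles(kstar)
  n_mastered <- rowSums(space$profiles)
  L <- space$M
  probs <- switch(model,
    "DINA"  = ifelse(n_mastered == kstar, p1, p0),
    "DINO"  = ifelse(n_mastered >= 1L, p1, p0),
    "A-CDM" = p0 + n_mastered * (p1 - p0) / kstar,
    "G-DINA" = {
      pr <- numeric(L)
      pr[1L] <- p0
      pr[L] <- p1
      if (L > 2L) {
        ord <- order(n_mastered, seq_len(L))
        for (l in ord) {
          if (l == 1L || l == L) next
          prof <- space$profiles[l, ]
          parents <- which(prof == 1L)
          lo <- p0
          for (k in parents) { # immediate sub-classes: drop one mastered attribute
            sub <- prof
            sub[k] <- 0L
            lo <- max(lo, pr[space$index(sub)])
          }
          pr[l] <- stats::runif(1L, lo, p1)
        }
      }
      pr
    })
  probs
}

#' Item response function: success probability for an attribute profile
#'
#' Collapses a full attribute profile to the item's reduced class (the
#' profile restricted to the attributes the item requires) and returns that
#' class's success probability; profiles identical on the required
#' attributes receive identical probabilities.
#'
#' @param params an [generate_item_parameters()] object (or a fitted
#'   parameter set with the same shape).
#' @param j item index.
#' @param profile full attribute profile, length K (or matrix of profiles).
#' @return success probability (vector if `profile` is a matrix).
#' @export
irf <- function(params, j, profile) {
  it <- params$items[[j]]
  p <- if (is.matrix(profile)) profile else matrix(profile, nrow = 1L)
  if (ncol(p) != ncol(params$Q))
    stop("profile length does not match the Q-matrix attribute count")
  red <- p[, it$req, drop = FALSE]
  kstar <- length(it$req)
  pow <- 2L^((kstar - 1L):0L)
  it$probs[as.integer(red %*% pow) + 1L]
}

# I x J matrix of success probabilities for a set of profiles
response_prob_matrix <- function(params, profiles) {
  J <- length(params$items)
  P <- matrix(0, nrow(profiles), J)
  for (j in seq_len(J)) P[, j] <- irf(params, j, profiles)
  P
}

#' Expected response matrix over the full latent-class space
#'
#' Row m gives, for every item, the probability that an examinee with the
#' m-th canonical attribute profile answers correctly. Used to build the
#' "best" K-means starting centroids.
#'
#' @param params an [generate_item_parameters()] object.
#' @return an M x J matrix, rows in canonical profile order.
#' @export
expected_response_matrix <- function(params) {
  space <- enumerate_profiles(ncol(params$Q))
  response_prob_matrix(params, space$profiles)
}

#' Simulate binary responses
#'
#' \eqn{X_{ij} \sim Bernoulli(P_j(\alpha_i))} independently given the
#' profiles. Uses the current R random number stream.
#'
#' @param params an [generate_item_parameters()] object.
#' @param profiles I x K attribute profile matrix.
#' @return an I x J [response_matrix()].
#' @export
simulate_responses <- function(params, profiles) {
  if (ncol(profiles) != ncol(params$Q))
    stop("profile and Q-matrix attribute counts differ")
  P <- response_prob_matrix(params, profiles)
  X <- matrix(as.integer(stats::runif(length(P)) < P), nrow(P), ncol(P))
  response_matrix(X)
}
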