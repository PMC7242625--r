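PROB_CLAMP <- c(1e-4, 1 - 1e-4)

clamp01 <- function(p) pmin(pmax(p, PROB_CLAMP[1L]), PROB_CLAMP[2L])

# J x M matrix of success probabilities from per-item reduced-class probs;
# rc_map[[j]] maps each full latent class to the item's reduced class index
full_class_probs <- function(items, rc_map, M) {
  J <- length(items)
  P <- matrix(0, J, M)
  for (j in seq_len(J)) P[j, ] <- items[[j]]$probs[rc_map[[j]]]
  P
}

# reduced-class index of every full canonical class, for one item
reduced_class_map <- function(space, req) {
  kstar <- length(req)
  pow <- 2L^((kstar - 1L):0L)
  as.integer(space$profiles[, req, drop = FALSE] %*% pow) + 1L
}

# marginal log-likelihood and posterior responsibilities given class probs
e_step <- function(X, Xc, P, log_pi) {
  ll <- X %*% log(P) + Xc %*% log1p(-P) # I x M
  a <- sweep(ll, 2L, log_pi, "+")
  mx <- apply(a, 1L, max)
  r <- exp(a - mx)
  rs <- rowSums(r)
  list(loglik = sum(log(rs) + mx), posterior = r / rs)
}

#' Number of free parameters of an identity-link CDM
#'
#' Item parameters — G-DINA: \eqn{\sum_j 2^{K_j^*}}; DINA and DINO: 2 per
#' item; A-CDM: \eqn{1 + K_j^*} per item — plus \eqn{2^K - 1} free latent
#' class proportions.
#'
#' @param model `"G-DINA"`, `"DINA"`, `"DINO"` or `"A-CDM"`.
#' @param Q a [qmatrix()].
#' @return integer parameter count.
#' @export
count_parameters <- function(model = c("G-DINA", "DINA", "DINO", "A-CDM"), Q) {
  model <- match.arg(model)
  kj <- rowSums(unclass(Q))
  item_pars <- switch(model,
                      "G-DINA" = sum(2^kj),
                      "DINA"   = 2L * nrow(Q),
                      "DINO"   = 2L * nrow(Q),
                      "A-CDM"  = sum(1 + kj))
  as.integer(item_pars + 2^ncol(Q) - 1)
}

#' Fit a cognitive diagnosis model by marginal maximum likelihood (EM)
#'
#' EM over the \eqn{2^K} latent attribute classes. The E-step computes
#' class responsibilities from the Bernoulli likelihood of each response
#' vector; the M-step updates item parameters model-specifically — G-DINA:
#' each reduced-class probability is the responsibility-weighted proportion
#' correct (closed form); DINA/DINO: the two-group closed form (baseline
#' group vs full/any-mastery group); A-CDM: bounded quasi-Newton
#' maximization of the weighted Bernoulli log-likelihood in the intercept
#' and main effects — and the class proportions as mean responsibilities.
#' All probabilities are clamped to `[1e-4, 1 - 1e-4]`. Iteration stops
#' when the marginal log-likelihood improves by less than `tol`, which is
#' non-decreasing across iterations.
#'
#' Initialization: uniform class proportions; item endpoint probabilities
#' P(0) = 0.2, P(1) = 0.8 with intermediate classes linear in the number of
#' mastered required attributes.
#'
#' @param X I x J binary [response_matrix()].
#' @param Q J x K [qmatrix()].
#' @param model `"G-DINA"`, `"DINA"`, `"DINO"` or `"A-CDM"`.
#' @param max_iter maximum EM iterations (default 1000).
#' @param tol absolute log-likelihood convergence threshold (default 1e-6).
#' @return an object of class `cdm_fit`: list with `model`, `items`
#'   (per-item `req` + reduced-class `probs`; for A-CDM also `gamma`),
#'   `class_proportions`, `log_likelihood`, `ll_trace`, `n_parameters`,
#'   `AIC`, `BIC`, `posterior` (I x M), `map_profiles`, `converged`,
#'   `n_iterations`, and the latent-class `space`.
#' @export
fit_cdm <- function(X, Q, model = c("G-DINA", "DINA", "DINO", "A-CDM"),
                    max_iter = 1000L, tol = 1e-6) {
  model <- match.arg(model)
  X <- unclass(as.matrix(X))
  if (nrow(X) < 2L) stop("at least two examinees are required")
  if (ncol(X) != nrow(Q)) stop("response and Q-matrix item counts differ")
  I <- nrow(X); J <- ncol(X); K <- ncol(Q)
  space <- enumerate_profiles(K)
  M <- space$M
  storage.mode(X) <- "double"
  Xc <- 1 - X

  constant <- apply(X, 2L, function(col) all(col == col[1L]))
  if (any(constant))
    warning("item(s) ", paste(which(constant), collapse = ", "),
            " have constant responses; estimates clamped")

  rc_map <- vector("list", J)
  items <- vector("list", J)
  for (j in seq_len(J)) {
    req <- which(unclass(Q)[j, ] == 1L)
    kstar <- length(req)
    rc_map[[j]] <- reduced_class_map(space, req)
    n_mast <- rowSums(enumerate_profiles(kstar)$profiles)
    it <- list(req = req, probs = clamp01(0.2 + 0.6 * n_mast / kstar))
    if (model == "A-CDM") it$gamma <- c(0.2, rep(0.6 / kstar, kstar))
    items[[j]] <- it
  }
  pi_m <- rep(1 / M, M)

  ll_trace <- numeric(0L)
  prev <- -Inf
  converged <- FALSE
  iter <- 0L
  post <- NULL
  for (iter in seq_len(max_iter)) {
    P <- clamp01(full_class_probs(items, rc_map, M))
    es <- e_step(X, Xc, P, log(pi_m))
    post <- es$posterior
    ll_trace <- c(ll_trace, es$loglik)
    if (abs(es$loglik - prev) < tol) {
      converged <- TRUE
      break
    }
    prev <- es$loglik
    n_m <- colSums(post)                 # expected class counts
    Rx <- crossprod(X, post)             # J x M expected corrects
    for (j in seq_len(J)) {
      rc <- rc_map[[j]]
      L <- 2L^length(items[[j]]$req)
      Nl <- vapply(seq_len(L), function(l) sum(n_m[rc == l]), numeric(1L))
      Rl <- vapply(seq_len(L), function(l) sum(Rx[j, rc == l]), numeric(1L))
      items[[j]] <- m_step_item(model, items[[j]], Nl, Rl)
    }
    pi_m <- n_m / I
  }

  p <- count_parameters(model, Q)
  final_ll <- ll_trace[length(ll_trace)]
  map_idx <- max.col(post, ties.method = "first")
  fit <- list(model = model, items = items, Q = Q,
              class_proportions = pi_m,
              log_likelihood = final_ll, ll_trace = ll_trace,
              n_parameters = p,
              AIC = -2 * final_ll + 2 * p,
              BIC = -2 * final_ll + p * log(I),
              posterior = post,
              map_classes = map_idx,
              map_profiles = space$profiles[map_idx, , drop = FALSE],
              converged = converged, n_iterations = iter,
              space = space)
  class(fit) <- "cdm_fit"
  fit
}

# one item's M-step given expected class counts Nl and corrects Rl
m_step_item <- function(model, item, Nl, Rl) {
  L <- length(Nl)
  kstar <- length(item$req)
  red <- enumerate_profiles(kstar)
  n_mast <- rowSums(red$profiles)
  safe_ratio <- function(r, n, fallback) if (n > 0) r / n else fallback
  if (model == "G-DINA") {
    item$probs <- clamp01(vapply(seq_len(L), function(l)
      safe_ratio(Rl[l], Nl[l], item$probs[l]), numeric(1L)))
  } else if (model == "DINA") {
    full <- n_mast == kstar
    p1 <- safe_ratio(sum(Rl[full]), sum(Nl[full]), item$probs[L])
    p0 <- safe_ratio(sum(Rl[!full]), sum(Nl[!full]), item$probs[1L])
    item$probs <- clamp01(ifelse(full, p1, p0))
  } else if (model == "DINO") {
    any_m <- n_mast >= 1L
    p1 <- safe_ratio(sum(Rl[any_m]), sum(Nl[any_m]), item$probs[L])
    p0 <- safe_ratio(sum(Rl[!any_m]), sum(Nl[!any_m]), item$probs[1L])
    item$probs <- clamp01(ifelse(any_m, p1, p0))
  } else { # A-CDM: weighted Bernoulli likelihood in (gamma0, gamma_k)
    design <- cbind(1, red$profiles)
    negll <- function(g) {
      pl <- clamp01(as.vector(design %*% g))
      -sum(Rl * log(pl) + (Nl - Rl) * log1p(-pl))
    }
    opt <- tryCatch(
      stats::optim(item$gamma, negll, method = "L-BFGS-B",
                   lower = c(PROB_CLAMP[1L], rep(-1, kstar)),
                   upper = c(PROB_CLAMP[2L], rep(1, kstar)),
                   control = list(maxit = 25L)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value) && opt$value <= negll(item$gamma)) {
      item$gamma <- opt$par
    }
    item$probs <- clamp01(as.vector(design %*% item$gamma))
  }
  item
}

#' Information criteria of a fitted CDM
#'
#' AIC = -2 log L + 2p and BIC = -2 log L + p log I, where p counts item
#' parameters plus free class proportions. The model with the smaller
#' value is preferred; BIC penalizes parameters more heavily for I > 7.
#'
#' @param fit a [fit_cdm()] result.
#' @return named numeric vector `c(AIC =, BIC =)`.
#' @export
information_criteria <- function(fit) {
  c(AIC = fit$AIC, BIC = fit$BIC)
}

#' Maximum a posteriori attribute classification
#'
#' Assigns every examinee the attribute profile with the largest posterior
#' responsibility; ties go to the lowest canonical class index.
#'
#' @param fit a [fit_cdm()] result.
#' @return an I x K integer matrix of MAP attribute profiles.
#' @export
map_classify <- function(fit) {
  idx <- max.col(fit$posterior, ties.method = "first")
  fit$space$profiles[idx, , drop = FALSE]
}

# marginal log-likelihood of data under fixed item parameters and class
# proportions (no estimation); used for nested-model checks
marginal_loglik <- function(X, params, pi_m) {
  X <- unclass(as.matrix(X))
  storage.mode(X) <- "double"
  space <- enumerate_profiles(ncol(params$Q))
  P <- clamp01(t(response_prob_matrix(params, space$profiles)))
  e_step(X, 1 - X, P, log(pi_m))$loglik
}
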