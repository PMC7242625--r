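CLUSTER_METHODS <- c("SCA-W", "SCA-R", "Kmeans-W", "Kmeans-R", "Kmeans-B")
FIT_METHODS <- c("G-DINA", "DINA", "DINO", "A-CDM")
ALL_METHODS <- c(CLUSTER_METHODS, FIT_METHODS)

#' Define one cell of a factorial simulation study
#'
#' @param I examinees (the study grid uses 100 and 500).
#' @param K attributes (3, 4 or 5); clustering uses \eqn{M = 2^K} clusters.
#' @param J items (5, 10 or 20); must satisfy `J >= K`.
#' @param quality `"high"` or `"low"` item quality.
#' @param model generating CDM.
#' @param rho common latent attribute correlation (default 0.5).
#' @return a `sim_condition` list.
#' @export
sim_condition <- function(I, K, J, quality = c("high", "low"),
                          model = c("G-DINA", "DINA", "DINO", "A-CDM"),
                          rho = 0.5) {
  quality <- match.arg(quality)
  model <- match.arg(model)
  if (J < K) stop("condition has J < K: test too short to anchor every attribute")
  structure(list(I = I, K = K, J = J, quality = quality, model = model,
                 rho = rho),
            class = "sim_condition")
}

# deterministic per-replication seed; every term bounded so the arithmetic
# stays exact in doubles and the result below 2^31
replication_seed <- function(base_seed, cond, rep_index) {
  model_id <- match(cond$model, FIT_METHODS)
  quality_id <- match(cond$quality, c("high", "low"))
  cond_id <- cond$I * 1e6 + cond$K * 1e5 + cond$J * 1e3 +
    quality_id * 500 + model_id
  bs <- base_seed %% 32749
  as.integer((bs * 1048573 + cond_id * 31 + rep_index * 131071) %% 2147483587)
}

#' Run one simulation replication
#'
#' Draws a Q-matrix, true attribute profiles, item parameters and
#' responses for the condition, runs the requested classification methods,
#' and scores each against the partition induced by the true profiles
#' (examinees grouped by identical true attribute vectors). Fitted CDMs
#' are scored through their MAP latent-class partition.
#'
#' @param cond a [sim_condition()].
#' @param rep_index replication number (1-based).
#' @param base_seed integer; the replication seed is derived
#'   deterministically from `(base_seed, condition, rep_index)`.
#' @param methods subset of
#'   `c("SCA-W", "SCA-R", "Kmeans-W", "Kmeans-R", "Kmeans-B",`
#'   `"G-DINA", "DINA", "DINO", "A-CDM")`.
#' @return data.frame with columns `method`, `ari`, `omega`.
#' @export
run_replication <- function(cond, rep_index, base_seed = 1L,
                            methods = ALL_METHODS) {
  methods <- match.arg(methods, ALL_METHODS, several.ok = TRUE)
  set.seed(replication_seed(base_seed, cond, rep_index))
  Q <- generate_qmatrix(cond$J, cond$K)
  profiles <- simulate_attributes(cond$I, cond$K, cond$rho)
  params <- generate_item_parameters(Q, cond$model, item_quality(cond$quality))
  X <- simulate_responses(params, profiles)
  W <- sum_scores(X, Q)
  space <- enumerate_profiles(cond$K)
  truth <- space$index(profiles)
  M <- space$M

  assign_for <- function(method) {
    switch(method,
      "SCA-W"    = spectral_cluster(X, M, init = "ward")$assignment,
      "SCA-R"    = spectral_cluster(X, M, init = "random")$assignment,
      "Kmeans-W" = kmeans_cdm(W, M, init = "ward")$assignment,
      "Kmeans-R" = kmeans_cdm(W, M, init = "random")$assignment,
      "Kmeans-B" = kmeans_cdm(W, M, init = "best",
                              centroids = best_starting_centroids(
                                expected_response_matrix(params), Q))$assignment,
      fit_cdm(X, Q, model = method)$map_classes)
  }
  res <- lapply(methods, function(m) {
    a <- assign_for(m)
    data.frame(method = m, ari = adjusted_rand_index(truth, a),
               omega = omega(a, profiles))
  })
  do.call(rbind, res)
}

#' Run a factorial Monte-Carlo study
#'
#' Maps [run_replication()] over every condition and replication and
#' aggregates to per-condition, per-method means and standard deviations
#' of ARI and omega. Fully deterministic given `base_seed`. A failing
#' replication is logged and skipped rather than aborting the study.
#'
#' @param conditions list of [sim_condition()] objects.
#' @param replications replications per condition (the reference design
#'   uses 100).
#' @param base_seed integer seed for the whole study.
#' @param methods methods to run (see [run_replication()]).
#' @param verbose print per-condition progress?
#' @return list with `report` (one row per condition x method: mean/SD of
#'   ARI and omega, `n_reps`) and `raw` (per-replication values).
#' @export
run_study <- function(conditions, replications = 100L, base_seed = 1L,
                      methods = ALL_METHODS, verbose = FALSE) {
  if (replications < 1L) stop("replications must be >= 1")
  if (inherits(conditions, "sim_condition")) conditions <- list(conditions)
  raw <- vector("list", length(conditions))
  for (ci in seq_along(conditions)) {
    cond <- conditions[[ci]]
    if (verbose)
      message(sprintf("condition %d/%d: I=%d K=%d J=%d %s %s", ci,
                      length(conditions), cond$I, cond$K, cond$J,
                      cond$quality, cond$model))
    reps <- lapply(seq_len(replications), function(r) {
      out <- tryCatch(run_replication(cond, r, base_seed, methods),
                      error = function(e) {
                        warning(sprintf("replication %d of condition %d failed: %s",
                                        r, ci, conditionMessage(e)))
                        NULL
                      })
      if (!is.null(out)) out$rep <- r
      out
    })
    cr <- do.call(rbind, reps)
    cr$condition <- ci
    cr$I <- cond$I; cr$K <- cond$K; cr$J <- cond$J
    cr$quality <- cond$quality; cr$model <- cond$model
    raw[[ci]] <- cr
  }
  raw <- do.call(rbind, raw)
  agg <- do.call(rbind, lapply(split(raw, list(raw$condition, raw$method),
                                     drop = TRUE), function(d)
    data.frame(condition = d$condition[1L], I = d$I[1L], K = d$K[1L],
               J = d$J[1L], quality = d$quality[1L], model = d$model[1L],
               method = d$method[1L],
               mean_ari = mean(d$ari), sd_ari = stats::sd(d$ari),
               mean_omega = mean(d$omega), sd_omega = stats::sd(d$omega),
               n_reps = nrow(d))))
  agg <- agg[order(agg$condition, match(agg$method, ALL_METHODS)), ]
  rownames(agg) <- NULL
  list(report = agg, raw = raw)
}

#' Real-data classification workflow
#'
#' Fits all four CDMs to the response matrix (AIC/BIC comparison table),
#' reports the MAP classification of the BIC-best model per attribute
#' profile, runs spectral clustering and sum-score K-means (both
#' Ward-initialized, \eqn{M = 2^K} clusters) with cluster reports ordered
#' by mean sum-score, and tabulates the pairwise ARI between the three
#' partitions.
#'
#' @param X I x J binary [response_matrix()]; items must match the
#'   Q-matrix row order.
#' @param Q a [qmatrix()]; defaults to the embedded 11 x 3 mixed-number
#'   fraction subtraction Q-matrix.
#' @param seed seed for the clustering runs (Ward initialization is
#'   deterministic; the seed fixes any residual randomness).
#' @return list with `information_criteria` (data.frame, 4 models),
#'   `best_model`, `map_report`, `sca_report`, `kmeans_report` and
#'   `pairwise_ari` (3 x 3 symmetric matrix).
#' @export
run_real_data <- function(X, Q = fraction_subtraction_qmatrix(), seed = 1L) {
  if (ncol(X) != nrow(Q))
    stop("response matrix has ", ncol(X), " items but the Q-matrix defines ",
         nrow(Q), " (for the fraction subtraction test: 11 items in order ",
         "1,2,3,4,5,6,8,9,10,11,13)")
  K <- ncol(Q)
  M <- 2L^K
  set.seed(seed)

  fits <- lapply(FIT_METHODS, function(m) fit_cdm(X, Q, model = m))
  names(fits) <- FIT_METHODS
  ic <- data.frame(model = FIT_METHODS,
                   log_likelihood = vapply(fits, `[[`, numeric(1L), "log_likelihood"),
                   n_parameters = vapply(fits, `[[`, integer(1L), "n_parameters"),
                   AIC = vapply(fits, `[[`, numeric(1L), "AIC"),
                   BIC = vapply(fits, `[[`, numeric(1L), "BIC"))
  rownames(ic) <- NULL
  best <- ic$model[which.min(ic$BIC)]
  best_fit <- fits[[best]]

  map_rep <- cluster_report(X, Q, best_fit$map_classes)
  profs <- best_fit$space$profiles
  map_rep$profile <- apply(profs[map_rep$cluster, , drop = FALSE], 1L,
                           paste, collapse = "")

  sca <- spectral_cluster(X, M, init = "ward")
  km <- kmeans_cdm(sum_scores(X, Q), M, init = "ward")
  partitions <- list("A-CDM-MAP" = best_fit$map_classes,
                     "SCA-W" = sca$assignment, "Kmeans-W" = km$assignment)
  names(partitions)[1L] <- paste0(best, "-MAP")
  pw <- matrix(NA_real_, 3L, 3L, dimnames = list(names(partitions),
                                                 names(partitions)))
  for (a in 1:2) for (b in (a + 1):3)
    pw[a, b] <- pw[b, a] <- adjusted_rand_index(partitions[[a]],
                                                partitions[[b]])
  list(information_criteria = ic, best_model = best, map_report = map_rep,
       sca_report = cluster_report(X, Q, sca$assignment),
       kmeans_report = cluster_report(X, Q, km$assignment),
       pairwise_ari = pw)
}
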