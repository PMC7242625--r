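test_that("simulate_attributes matches the analytic mastery marginals", {
  # P(alpha_k = 1) = 1 - k/(K+1); large-sample frequency check
  set.seed(11)
  K <- 3
  alpha <- simulate_attributes(100000, K, rho = 0.5)
  expect_equal(colMeans(alpha), c(0.75, 0.5, 0.25), tolerance = 0.015)

  # rho = 0: attributes independent
  alpha0 <- simulate_attributes(50000, 3, rho = 0)
  cors <- cor(alpha0)[upper.tri(diag(3))]
  expect_true(all(abs(cors) < 0.02))

  # rho > 0 induces positive attribute association
  a5 <- simulate_attributes(50000, 3, rho = 0.5)
  expect_true(all(cor(a5)[upper.tri(diag(3))] > 0.15))

  expect_error(simulate_attributes(10, 3, rho = 1))
  expect_error(simulate_attributes(10, 3, rho = -0.1))
})

test_that("reduced-model item parameters follow the closed forms", {
  set.seed(2)
  Q <- qmatrix(matrix(c(1, 1, 0), 1, 3))
  # force known endpoints by stubbing the quality draw through a degenerate range
  deg <- list(label = "fixed", p0_range = c(0.1, 0.1), slip_range = c(0.1, 0.1))
  for (case in list(list(model = "DINA",  probs = c(0.1, 0.1, 0.1, 0.9)),
                    list(model = "DINO",  probs = c(0.1, 0.9, 0.9, 0.9)),
                    list(model = "A-CDM", probs = c(0.1, 0.5, 0.5, 0.9)))) {
    params <- generate_item_parameters(Q, case$model, deg)
    expect_equal(params$items[[1]]$probs, case$probs, tolerance = 1e-12)
  }
  # G-DINA pins the endpoints and keeps intermediates inside them
  params <- generate_item_parameters(Q, "G-DINA", deg)
  pr <- params$items[[1]]$probs
  expect_equal(pr[c(1, 4)], c(0.1, 0.9))
  expect_true(all(pr[2:3] >= 0.1 & pr[2:3] <= 0.9))
})

test_that("item quality ranges place the endpoints where expected", {
  set.seed(5)
  Q <- generate_qmatrix(20, 3)
  hi <- generate_item_parameters(Q, "G-DINA", item_quality("high"))
  expect_true(all(hi$p0 > 0.05 & hi$p0 < 0.15))
  expect_true(all(hi$p1 > 0.85 & hi$p1 < 0.95))
  lo <- generate_item_parameters(Q, "G-DINA", item_quality("low"))
  expect_true(all(lo$p0 > 0.25 & lo$p0 < 0.35))
  expect_true(all(lo$p1 > 0.65 & lo$p1 < 0.75))
})

test_that("every generated parameter set is weakly monotone in the subset order", {
  set.seed(9)
  for (trial in 1:20) {
    K <- sample(3:5, 1)
    Q <- generate_qmatrix(K + 5, K)
    model <- sample(c("G-DINA", "DINA", "DINO", "A-CDM"), 1)
    params <- generate_item_parameters(Q, model,
                                       item_quality(sample(c("high", "low"), 1)))
    for (j in seq_len(nrow(Q))) {
      kstar <- length(params$items[[j]]$req)
      red <- enumerate_profiles(kstar)$profiles
      pr <- params$items[[j]]$probs
      for (a in seq_len(nrow(red))) for (b in seq_len(nrow(red))) {
        if (all(red[a, ] <= red[b, ]))  # a subset of b
          expect_gte(pr[b], pr[a])
      }
    }
  }
})

test_that("irf collapses profiles to the reduced class of required attributes", {
  set.seed(4)
  Q <- qmatrix(matrix(c(1, 1, 0, 0), 1, 4))
  deg <- list(label = "fixed", p0_range = c(0.2, 0.2), slip_range = c(0.2, 0.2))
  params <- generate_item_parameters(Q, "DINA", deg)
  # lacking one required attribute: baseline
  expect_equal(irf(params, 1, c(1, 0, 1, 1)), 0.2)
  expect_equal(irf(params, 1, c(1, 1, 0, 0)), 0.8)
  # profiles identical on required attributes agree regardless of the rest
  gd <- generate_item_parameters(Q, "G-DINA", item_quality("high"))
  expect_equal(irf(gd, 1, c(1, 0, 1, 0)), irf(gd, 1, c(1, 0, 0, 1)))
  expect_equal(irf(gd, 1, c(1, 1, 1, 1)), gd$p1[1])
  expect_error(irf(params, 1, c(1, 0)), "profile length")
})

test_that("simulate_responses draws Bernoulli at the item response probabilities", {
  Q <- qmatrix(diag(1L, 2))
  profiles <- matrix(c(1L, 1L), 1, 2)
  base <- list(model = "DINA", Q = Q,
               items = list(list(req = 1L, probs = c(1, 1)),
                            list(req = 2L, probs = c(1, 1))))
  class(base) <- "item_parameters"
  expect_true(all(simulate_responses(base, profiles) == 1L))
  base$items <- lapply(base$items, function(it) { it$probs <- c(0, 0); it })
  expect_true(all(simulate_responses(base, profiles) == 0L))

  # frequency check against the generating probability
  set.seed(21)
  Q1 <- qmatrix(matrix(1L, 1, 1))
  deg <- list(label = "fixed", p0_range = c(0.1, 0.1), slip_range = c(0.1, 0.1))
  params <- generate_item_parameters(Q1, "DINA", deg)
  full <- matrix(1L, 20000, 1)
  X <- simulate_responses(params, full)
  expect_equal(mean(X), 0.9, tolerance = 0.01)
})

test_that("simulator operations are bit-identical under the same seed", {
  run <- function() {
    set.seed(99)
    Q <- generate_qmatrix(12, 4)
    profiles <- simulate_attributes(50, 4)
    params <- generate_item_parameters(Q, "G-DINA", item_quality("low"))
    X <- simulate_responses(params, profiles)
    list(Q = Q, profiles = profiles, params = params, X = X)
  }
  expect_identical(run(), run())
})
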