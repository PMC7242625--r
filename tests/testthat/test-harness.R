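test_that("run_replication is deterministic and scores every method", {
  cond <- sim_condition(60, 3, 8, "high", "DINA")
  r1 <- run_replication(cond, 3, base_seed = 5,
                        methods = c("SCA-W", "Kmeans-W", "Kmeans-B", "DINA"))
  r2 <- run_replication(cond, 3, base_seed = 5,
                        methods = c("SCA-W", "Kmeans-W", "Kmeans-B", "DINA"))
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 4L)
  expect_true(all(r1$omega >= 0 & r1$omega <= 1))
  expect_true(all(r1$ari <= 1))
  # a different replication index gives different data
  r3 <- run_replication(cond, 4, base_seed = 5, methods = "SCA-W")
  expect_false(identical(r1$ari[1], r3$ari[1]))
  expect_error(sim_condition(100, 4, 3), "J < K")
})

test_that("run_study aggregates exactly replications x methods", {
  conds <- list(sim_condition(40, 3, 6, "high", "DINA"),
                sim_condition(40, 3, 6, "low", "DINA"))
  st <- run_study(conds, replications = 2, base_seed = 9,
                  methods = c("SCA-W", "Kmeans-W"))
  expect_equal(nrow(st$report), 4L) # 2 conditions x 2 methods
  expect_true(all(st$report$n_reps == 2L))
  expect_equal(nrow(st$raw), 8L)
  # determinism of the whole study
  st2 <- run_study(conds, replications = 2, base_seed = 9,
                   methods = c("SCA-W", "Kmeans-W"))
  expect_identical(st$report, st2$report)
})

test_that("the true fitted model beats clustering, and Ward beats random, on aggregate", {
  # directional claims need the full 100-replication aggregate; the Ward
  # vs random advantage is only stable on within-cluster homogeneity
  # (omega), not on ARI, in this simulation world (see decisions notes)
  cond <- sim_condition(100, 3, 10, "high", "DINA")
  st <- run_study(cond, replications = 100, base_seed = 11,
                  methods = c("SCA-W", "SCA-R", "Kmeans-W", "Kmeans-R", "DINA"))
  r <- st$report
  val <- function(m, col) r[[col]][r$method == m]
  expect_gt(val("DINA", "mean_ari"), val("SCA-W", "mean_ari"))
  expect_gt(val("DINA", "mean_ari"), val("Kmeans-W", "mean_ari"))
  expect_gte(val("SCA-W", "mean_omega"), val("SCA-R", "mean_omega"))
  expect_gte(val("Kmeans-W", "mean_omega"), val("Kmeans-R", "mean_omega"))
})

test_that("high item quality outperforms low quality for SCA-W", {
  hi <- run_study(sim_condition(100, 3, 10, "high", "G-DINA"), 10, 13, "SCA-W")
  lo <- run_study(sim_condition(100, 3, 10, "low", "G-DINA"), 10, 13, "SCA-W")
  expect_gt(hi$report$mean_ari, lo$report$mean_ari)
  expect_gt(hi$report$mean_omega, lo$report$mean_omega)
})

test_that("run_real_data reproduces the workflow on synthetic A-CDM data", {
  set.seed(536)
  Q <- fraction_subtraction_qmatrix()
  profiles <- simulate_attributes(536, 3)
  params <- generate_item_parameters(Q, "A-CDM", item_quality("high"))
  X <- simulate_responses(params, profiles)
  res <- run_real_data(X, Q, seed = 1)

  expect_equal(res$information_criteria$model,
               c("G-DINA", "DINA", "DINO", "A-CDM"))
  # data generated from A-CDM: A-CDM should win on BIC
  expect_equal(res$best_model, "A-CDM")
  # cluster sizes account for every examinee; reports ordered by mean score
  expect_equal(sum(res$map_report$size), 536)
  expect_equal(sum(res$sca_report$size), 536)
  expect_false(is.unsorted(res$sca_report$mean_sum_score))
  expect_false(is.unsorted(res$map_report$mean_sum_score))
  # pairwise ARI matrix: symmetric, empty diagonal
  expect_true(all(is.na(diag(res$pairwise_ari))))
  expect_equal(res$pairwise_ari, t(res$pairwise_ari))
  off <- res$pairwise_ari[upper.tri(res$pairwise_ari)]
  expect_true(all(off > 0 & off <= 1))

  expect_error(run_real_data(X[, 1:9], Q), "11 items")
})

test_that("the CLI pipeline runs end to end on a temp directory", {
  dir <- withr::local_tempdir()
  expect_equal(cdmcluster_main(c("simulate", "--examinees", "60",
                                 "--num-attributes", "2", "--items", "8",
                                 "--seed", "4", "--out-dir", dir)), 0L)
  expect_true(all(file.exists(file.path(dir, c("responses.csv", "qmatrix.csv",
                                               "profiles.csv", "params.json")))))
  asg <- file.path(dir, "assignment.csv")
  expect_equal(cdmcluster_main(c("cluster", "--method", "sca",
                                 "--num-attributes", "2", "--seed", "4",
                                 "--responses", file.path(dir, "responses.csv"),
                                 "--out", asg)), 0L)
  out <- utils::read.csv(asg)
  expect_equal(nrow(out), 60L)
  expect_true(all(out$cluster %in% 1:4))
  evalj <- file.path(dir, "eval.json")
  expect_equal(cdmcluster_main(c("evaluate", "--assignment", asg,
                                 "--profiles", file.path(dir, "profiles.csv"),
                                 "--out", evalj)), 0L)
  ev <- jsonlite::read_json(evalj)
  expect_true(ev$omega >= 0 && ev$omega <= 1)
  fitd <- file.path(dir, "fit")
  expect_equal(cdmcluster_main(c("fit", "--model", "dina",
                                 "--responses", file.path(dir, "responses.csv"),
                                 "--qmatrix", file.path(dir, "qmatrix.csv"),
                                 "--out-dir", fitd)), 0L)
  expect_true(file.exists(file.path(fitd, "fit.json")))
  # unknown subcommand and runtime errors map to nonzero status
  expect_equal(suppressMessages(cdmcluster_main("frobnicate")), 1L)
  expect_equal(suppressWarnings(suppressMessages(
    cdmcluster_main(c("cluster", "--responses", "/nonexistent.csv")))), 2L)
})
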