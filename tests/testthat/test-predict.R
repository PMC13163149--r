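sim_matrix <- function(n = 60, p = 35, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- as.vector(outer(rv_parameters(), rv_metrics(),
                                   paste, sep = "_"))
    rownames(X) <- sprintf("pat_%03d", seq_len(n))
    X
  })
}

test_that("build_matrix selects labeled patients deterministically", {
  coh <- simulate_cohort(cohort_spec(n_patients = 15, n_controls = 12),
                         seed = 1, render = FALSE)
  feats <- cohort_features(coh)
  subj <- cohort_subjects(coh)
  mat <- build_matrix(feats, subj, "crsr")
  expect_equal(dim(mat$X), c(15, 35))
  expect_identical(rownames(mat$X), sort(subj$subject_id[subj$group == "patient"]))
  expect_true(all(mat$y >= 0 & mat$y <= 23))
  mat2 <- build_matrix(feats, subj, "outcome")
  expect_true(all(mat2$y %in% 0:1))
  subj_ctl <- subj[subj$group == "control", ]
  expect_error(build_matrix(feats, subj_ctl, "crsr"), "insufficient")
})

test_that("fold-wise standardization centres training data only", {
  X <- sim_matrix(40, seed = 3)
  sc <- respvar:::scale_fit(X[1:30, ])
  Xs <- respvar:::scale_apply(X[1:30, ], sc)
  expect_equal(unname(colMeans(Xs)), rep(0, 35), tolerance = 1e-12)
  expect_equal(unname(apply(Xs, 2, sd)), rep(1, 35), tolerance = 1e-12)
  # held-out rows transformed with training statistics, not their own
  Xv <- respvar:::scale_apply(X[31:40, ], sc)
  expect_false(isTRUE(all.equal(unname(colMeans(Xv)), rep(0, 35))))
})

test_that("elastic net recovers an exact linear signal", {
  X <- sim_matrix(60, seed = 4)
  y <- drop(X[, c(1, 5, 9)] %*% c(2, -1.5, 1))
  rep_ <- train_crsr_models(X, y, config = list(models = "elastic_net",
                                                n_iter = 15), seed = 2)
  expect_gt(rep_$metrics$r2, 0.99)
})

test_that("report identities hold and reports are reproducible", {
  coh <- simulate_cohort(cohort_spec(n_patients = 24, n_controls = 2),
                         seed = 5, render = FALSE)
  mat <- build_matrix(cohort_features(coh), cohort_subjects(coh), "crsr")
  cfg <- list(models = c("random_forest", "elastic_net"), n_iter = 4)
  # rf warns about the small number of distinct CRS-R values at this n
  r1 <- suppressWarnings(train_crsr_models(mat$X, mat$y, cfg, seed = 11))
  expect_equal(r1$metrics$rmse^2, r1$metrics$mse, tolerance = 1e-9)
  expect_true(all(r1$metrics$r2 <= 1))
  r2 <- suppressWarnings(train_crsr_models(mat$X, mat$y, cfg, seed = 11))
  expect_identical(r1$metrics, r2$metrics)
  expect_error(train_crsr_models(mat$X, rep(5, nrow(mat$X)), cfg, seed = 1),
               "constant")
})

test_that("outcome pipelines report coherent validation metrics", {
  X <- sim_matrix(80, seed = 6)
  y <- withr::with_seed(7, as.integer(X[, "ti_sd"] + 0.3 * rnorm(80) > 0))
  cfg <- list(n_iter = 3)
  rep_ <- train_outcome_models(X, y, cfg, seed = 3)
  m <- rep_$metrics
  expect_true(all(m$auc >= 0 & m$auc <= 1))
  expect_true(all(m$accuracy >= 0 & m$accuracy <= 1, na.rm = TRUE))
  # f1 consistent with precision/recall on the separable pipeline
  expect_gt(m$auc[m$pipeline == "rf_direct"], 0.7)
  r2 <- train_outcome_models(X, y, cfg, seed = 3)
  expect_identical(rep_$metrics, r2$metrics)
  expect_error(train_outcome_models(X, rep(1L, 80), cfg, seed = 1),
               "stratification")
})

test_that("a strongly separable outcome yields high rf AUC", {
  X <- sim_matrix(200, seed = 8)
  y <- as.integer(X[, "rate_sd"] > median(X[, "rate_sd"]))
  rep_ <- train_outcome_models(X, y, config = list(n_iter = 3,
                                                   pipelines = "rf_direct"),
                               seed = 4)
  expect_gt(rep_$metrics$auc, 0.9)
})

test_that("permutation importance ranks the informative feature first", {
  hits <- vapply(1:10, function(s) {
    X <- sim_matrix(80, seed = 100 + s)
    y <- drop(X[, "te_rmssd"] * 3) + withr::with_seed(s, rnorm(80, 0, 0.5))
    rf <- withr::with_seed(s, randomForest::randomForest(X, y, ntree = 300,
                                                         importance = TRUE))
    top <- importance_top_k(rf, 20)
    top$feature[1] == "te_rmssd"
  }, TRUE)
  expect_gte(mean(hits), 0.95)
  X <- sim_matrix(40, seed = 9)
  y <- withr::with_seed(9, rnorm(40))
  rf <- withr::with_seed(9, randomForest::randomForest(X, y, ntree = 100,
                                                       importance = TRUE))
  expect_equal(nrow(importance_top_k(rf, 100)), 35) # k capped at n features
})

test_that("single-subject prediction respects training ranges and errors", {
  coh <- simulate_cohort(cohort_spec(n_patients = 25, n_controls = 2),
                         seed = 10, render = FALSE)
  mat <- build_matrix(cohort_features(coh), cohort_subjects(coh), "crsr")
  rep_ <- train_crsr_models(mat$X, mat$y,
                            config = list(models = "random_forest",
                                          n_iter = 3), seed = 6)
  b <- rep_$bundles$random_forest
  pred <- predict_single(b, mat$X[1, ])
  expect_true(is.finite(pred))
  expect_gte(pred, min(mat$y)) # rf cannot extrapolate past leaf means
  expect_lte(pred, max(mat$y))
  expect_identical(pred, predict_single(b, mat$X[1, ]))
  expect_error(predict_single(b, mat$X[1, -1]), "rate_sd")

  maty <- build_matrix(cohort_features(coh), cohort_subjects(coh), "outcome")
  rep2 <- train_outcome_models(maty$X, maty$y,
                               config = list(n_iter = 2,
                                             pipelines = "rf_direct"),
                               seed = 6)
  pr <- predict_single(rep2$bundles$rf_direct, maty$X[2, ])
  expect_gte(pr, 0)
  expect_lte(pr, 1)
})

test_that("validation-only information cannot leak into training folds", {
  coh <- simulate_cohort(cohort_spec(n_patients = 30, n_controls = 2),
                         seed = 12, render = FALSE)
  mat <- build_matrix(cohort_features(coh), cohort_subjects(coh), "outcome")
  cfg <- list(n_iter = 3, pipelines = "rf_select_logistic")
  base <- train_outcome_models(mat$X, mat$y, cfg, seed = 7)
  # canary: replace one feature by the label on validation rows only
  Xc <- mat$X
  va <- base$split$validation
  Xc[va, "amplitude_cv"] <- mat$y[match(va, rownames(mat$X))] * 10
  canary <- train_outcome_models(Xc, mat$y, cfg, seed = 7)
  expect_identical(canary$split$validation, base$split$validation)
  expect_false("amplitude_cv" %in% canary$selected$rf_select_logistic)
})
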