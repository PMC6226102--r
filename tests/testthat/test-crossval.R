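test_that("38 cells partition into 25 training and 13 testing with all regions trained", {
  d <- build_survey_design(38, seed = 4)
  part <- partition_folds(d$cells, d$regions, seed = 10)
  expect_length(part$folds, 5)
  for (fold in part$folds) {
    expect_length(fold$train, 25)
    expect_length(fold$test, 13)
    expect_length(intersect(fold$train, fold$test), 0)
    expect_setequal(c(fold$train, fold$test), d$cells)
    train_regions <- d$regions[match(fold$train, d$cells)]
    expect_setequal(as.character(unique(train_regions)), DEFAULT_REGIONS)
  }
})

test_that("a region's only cell is always in training", {
  cells <- paste0("c", 1:12)
  regions <- c("A", rep(c("B", "C"), c(6, 5)))
  part <- partition_folds(cells, regions, n_partitions = 5, seed = 2)
  for (fold in part$folds) expect_true("c1" %in% fold$train)
})

test_that("partitions are deterministic under a seed", {
  d <- build_survey_design(38, seed = 4)
  p1 <- partition_folds(d$cells, d$regions, seed = 31)
  p2 <- partition_folds(d$cells, d$regions, seed = 31)
  expect_identical(p1, p2)
})

test_that("empty regions make the constraint infeasible", {
  expect_error(partition_folds(character(0), character(0)), "infeasible|at least")
  expect_error(partition_folds(paste0("c", 1:4), rep(c("A", "B"), 2),
                               train_fraction = 0.2),
               "infeasible")
})

test_that("AUC golden cases: perfect separation and all-tied scores", {
  expect_equal(auc(c(0.9, 0.1), c(1, 0)), 1.0)
  expect_equal(auc(c(0.5, 0.5, 0.5, 0.5), c(1, 0, 1, 0)), 0.5)
  expect_error(auc(c(0.2, 0.4), c(1, 1)), "single class")
})

test_that("rank-based AUC equals all-pairs concordance on random instances", {
  set.seed(15)
  for (rep in seq_len(200)) {
    n <- 50
    scores <- round(runif(n), sample(c(1, 2, 7), 1))  # coarse rounding forces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(auc(scores, labels), pairwise_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(16)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.4)
  base <- auc(scores, labels)
  expect_equal(auc(exp(scores), labels), base, tolerance = 1e-12)
  expect_equal(auc(qlogis(plogis(scores)) * 3 + 5, labels), base,
               tolerance = 1e-12)
})

test_that("rank-based AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.5)
  want <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                         direction = "<")))
  expect_equal(auc(scores, labels), want, tolerance = 1e-12)
})

test_that("cross-validated AUC is high when occupancy is covariate-driven and detection easy", {
  sim <- simulate_occu_dataset(
    n_cells = 200, seed = 61,
    beta = c(`(Intercept)` = 0, Forest = 4),
    alpha = c(`(Intercept)` = 2.5), gamma = 0.02, epsilon = 0.02)
  part <- partition_folds(sim$covariates$cell_id, sim$covariates$region,
                          n_partitions = 3, seed = 62)
  cv <- kfold_auc(sim$detections, sim$covariates, "Forest", character(),
                  part, config = fast_config(seed = 63, n_burnin = 200,
                                             n_sampling = 400))
  expect_gt(cv$mean_auc, 0.9)
})

test_that("shuffled labels give cross-validated AUC near one half", {
  set.seed(70)
  scores <- runif(2000)
  labels <- rbinom(2000, 1, 0.5)
  expect_lt(abs(auc(scores, labels) - 0.5), 0.05)
})

test_that("kfold_auc is reproducible with fixed partitions and seed", {
  sim <- tiny_dataset(n_cells = 30, seed = 80)
  part <- partition_folds(sim$covariates$cell_id, sim$covariates$region,
                          n_partitions = 2, seed = 81)
  cfg <- fast_config(seed = 82, n_burnin = 100, n_sampling = 200)
  cv1 <- kfold_auc(sim$detections, sim$covariates, "Forest", character(),
                   part, cfg)
  cv2 <- kfold_auc(sim$detections, sim$covariates, "Forest", character(),
                   part, cfg)
  expect_identical(cv1$fold_auc, cv2$fold_auc)
})
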