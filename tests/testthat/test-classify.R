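# z-score calibration, metrics, training/CV, one-class validation, prediction.

test_that("z-score calibration matches the closed form on both branches", {
  # continuity at P = 0.5 for a range of alpha
  for (a in c(0.5, 1, 2, 4))
    expect_equal(as.numeric(calibrate_zscore(0.5, a)), 0.5, tolerance = 1e-12)
  expect_equal(as.numeric(calibrate_zscore(1, 2)), 1)
  # high branch: t = P^a / (P^a + (1-P)^a)
  expect_equal(as.numeric(calibrate_zscore(0.8, 2)), 0.64 / 0.68,
               tolerance = 1e-9)
  # low branch: t + a (0.5 - t)
  t <- 0.2^2 / (0.2^2 + 0.8^2)
  expect_equal(as.numeric(calibrate_zscore(0.2, 2)), t + 2 * (0.5 - t),
               tolerance = 1e-9)
  # alpha = 2 mirror identity z(P) = z(1 - P) on a grid
  grid <- seq(0.01, 0.99, length.out = 99)
  z <- as.numeric(calibrate_zscore(grid, 2))
  expect_equal(z, rev(z), tolerance = 1e-9)
  # high branch strictly increasing on (0.5, 1]
  hi <- seq(0.5001, 1, length.out = 200)
  expect_true(all(diff(as.numeric(calibrate_zscore(hi, 3))) > 0))
  # clamping: alpha = 4, P = 0.3 exceeds 1 raw but is clamped
  z4 <- calibrate_zscore(0.3, 4)
  expect_lte(as.numeric(z4), 1)
  expect_gt(attr(z4, "raw"), 1)
  expect_error(calibrate_zscore(1.2, 2), "0, 1")
  expect_error(calibrate_zscore(0.5, 0), "alpha")
})

test_that("metrics match their definitions and a brute-force AUC", {
  # perfect predictions
  m <- evaluate_metrics(c("a", "b", "a"), c("a", "b", "a"),
                        matrix(c(1, 0, 1, 0, 1, 0), 3, 2,
                               dimnames = list(NULL, c("a", "b"))))
  expect_equal(m$accuracy, 1); expect_equal(m$kappa, 1)
  expect_equal(m$macro_auc, 1)
  expect_equal(sum(diag(m$confusion)), 3)
  # majority-class predictor on two equal classes: accuracy .5, kappa 0
  truth <- rep(c("a", "b"), each = 10)
  m2 <- evaluate_metrics(truth, rep("a", 20))
  expect_equal(m2$accuracy, 0.5); expect_equal(m2$kappa, 0)
  # two-class macro AUC is the mean of the two OvR AUCs, which coincide
  set.seed(6)
  p <- runif(30)
  prob <- cbind(a = p, b = 1 - p)
  t2 <- sample(c("a", "b"), 30, TRUE)
  m3 <- evaluate_metrics(t2, ifelse(p > .5, "a", "b"), prob)
  expect_equal(m3$macro_auc, auc_bruteforce(p, t2 == "a"), tolerance = 1e-9)
  # rank AUC equals the all-pairs count on random ties-heavy data
  for (i in 1:20) {
    sc <- sample(seq(0, 1, .1), 25, TRUE)
    lab <- sample(c(TRUE, FALSE), 25, TRUE)
    if (!any(lab) || all(lab)) next
    prob2 <- cbind(x = sc, y = 1 - sc)
    truth2 <- ifelse(lab, "x", "y")
    got <- evaluate_metrics(truth2, truth2, prob2)$macro_auc
    oracle <- mean(c(auc_bruteforce(sc, lab), auc_bruteforce(1 - sc, !lab)))
    expect_equal(got, oracle, tolerance = 1e-9)
  }
  # confusion rows = per-breed test counts
  m4 <- evaluate_metrics(c("a", "a", "b"), c("b", "b", "b"))
  expect_equal(as.integer(rowSums(m4$confusion)), c(2L, 1L))
  # random probabilities: macro AUC near 1/2
  set.seed(8)
  n <- 4000
  pr <- matrix(rgamma(3 * n, 1), n, 3); pr <- pr / rowSums(pr)
  colnames(pr) <- c("a", "b", "c")
  tt <- sample(colnames(pr), n, TRUE)
  m5 <- evaluate_metrics(tt, colnames(pr)[max.col(pr)], pr)
  expect_lt(abs(m5$macro_auc - 0.5), 0.05)
})

test_that("stratified folds partition individuals with balanced breed counts", {
  labels <- rep(c("a", "b", "c"), c(11, 7, 5))
  fold <- stratified_folds(labels, 4, seed = 2)
  expect_equal(length(fold), 23)
  expect_true(all(fold %in% 1:4))
  for (b in unique(labels)) {
    cnt <- table(factor(fold[labels == b], levels = 1:4))
    expect_lte(diff(range(cnt)), 1)
  }
  expect_error(stratified_folds(c("a", "a", "b"), 2), "single individual")
})

test_that("classifiers reach perfect CV on cleanly separable breeds", {
  sim <- simulate_breeds(sim_config(n_breeds = 3, n_per_breed = 12,
                                    n_snps = 300, fst = 0.35, seed = 70))
  sc <- suppressWarnings(
    snp_association_scores(sim$genotypes, sim$breeds, "chi2"))
  panel <- select_top(sc, count = 100)
  res <- train_classifier(sim$genotypes, sim$breeds, panel, "rf",
                          cv = "kfold:5", seed = 1)
  expect_equal(res$cv$accuracy, 1)
  expect_equal(res$cv$kappa, 1)
  expect_equal(res$cv$macro_auc, 1)
  expect_equal(as.integer(rowSums(res$cv$confusion)), rep(12L, 3))
  # determinism end to end
  res2 <- train_classifier(sim$genotypes, sim$breeds, panel, "rf",
                           cv = "kfold:5", seed = 1)
  expect_identical(res$cv$confusion, res2$cv$confusion)
  expect_identical(res$cv$accuracy, res2$cv$accuracy)
})

test_that("all four algorithms train, predict probabilities, and agree on easy data", {
  sim <- simulate_breeds(sim_config(n_breeds = 2, n_per_breed = 10,
                                    n_snps = 200, fst = 0.35, seed = 71))
  sc <- suppressWarnings(
    snp_association_scores(sim$genotypes, sim$breeds, "chi2"))
  panel <- select_top(sc, count = 50)
  for (algo in c("knn", "rf", "svm", "xgb")) {
    res <- train_classifier(sim$genotypes, sim$breeds, panel, algo,
                            cv = "kfold:2", seed = 3,
                            hyperparams = list(rf_trees = 100, xgb_rounds = 30))
    expect_gte(res$cv$accuracy, 0.9)
    preds <- predict_new(res$model, sim$genotypes)
    expect_equal(preds$breed, sim$breeds$breed)
    probs <- as.matrix(preds[, grep("^prob\\.", names(preds))])
    expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-6)
  }
})

test_that("cv scheme variants run and loo is refused at scale", {
  sim <- simulate_breeds(sim_config(n_breeds = 2, n_per_breed = 6,
                                    n_snps = 100, fst = 0.35, seed = 72))
  sc <- suppressWarnings(
    snp_association_scores(sim$genotypes, sim$breeds, "chi2"))
  panel <- select_top(sc, count = 30)
  rep_res <- train_classifier(sim$genotypes, sim$breeds, panel, "knn",
                              cv = "repeated_kfold:3x2", seed = 5)
  expect_length(rep_res$cv$fold_accuracy, 6)    # 3 folds x 2 repeats
  loo <- train_classifier(sim$genotypes, sim$breeds, panel, "knn",
                          cv = "loo", seed = 5)
  expect_length(loo$cv$fold_accuracy, 12)
  # a breed with one individual cannot be stratified
  b1 <- sim$breeds; b1$breed[1] <- "Singleton"
  expect_error(train_classifier(sim$genotypes, b1, panel, "knn",
                                cv = "kfold:2"), "single individual")
  expect_error(breedkit:::parse_cv_scheme("bogus:3"), "unknown")
})

test_that("one-class screen accepts own-breed training rows and rejects noise", {
  sim <- simulate_breeds(sim_config(n_breeds = 3, n_per_breed = 15,
                                    n_snps = 400, fst = 0.3, seed = 90))
  sc <- suppressWarnings(
    snp_association_scores(sim$genotypes, sim$breeds, "chi2"))
  panel <- select_top(sc, count = 200)
  res <- train_classifier(sim$genotypes, sim$breeds, panel, "rf",
                          cv = "kfold:3", seed = 2)
  # >= 99% of training rows pass their own breed threshold by construction
  train_pred <- predict_new(res$model, sim$genotypes)
  expect_gte(mean(train_pred$one_class_pass), 0.99)
  # uniform-random genotypes are flagged
  rnd <- random_genotypes(30, sim$genotypes$snps, seed = 4)
  rnd_pred <- predict_new(res$model, rnd)
  expect_gte(mean(!rnd_pred$one_class_pass), 0.95)
  expect_true(all(rnd_pred$one_class_reason[!rnd_pred$one_class_pass] ==
                  "unlike-training-breed"))
  # an all-missing row fails as low-quality
  chk <- one_class_check(res$model, rep(NA_real_, 200), "Breed01")
  expect_false(chk$pass)
  expect_equal(chk$reason, "low-quality")
})

test_that("prediction joins geography on the predicted breed", {
  sim <- simulate_breeds(sim_config(n_breeds = 2, n_per_breed = 8,
                                    n_snps = 150, fst = 0.35, seed = 91))
  sc <- suppressWarnings(
    snp_association_scores(sim$genotypes, sim$breeds, "chi2"))
  panel <- select_top(sc, count = 40)
  res <- train_classifier(sim$genotypes, sim$breeds, panel, "knn",
                          cv = "kfold:2", seed = 1)
  preds <- predict_new(res$model, sim$genotypes, geo = sim$geo)
  idx <- match(preds$breed, sim$geo$breed)
  expect_equal(preds$Latitude, sim$geo$Latitude[idx])
  expect_equal(preds$Location, sim$geo$Location[idx])
  # querying with a panel that shares no SNPs errors
  alien <- toy_G(matrix(1L, 2, 3), snp_ids = c("zz1", "zz2", "zz3"))
  expect_error(predict_new(res$model, alien), "no panel SNPs")
})
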