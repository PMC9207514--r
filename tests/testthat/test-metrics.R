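# Screening metrics, AUC, cross-validation folds and method ranking

test_that("confusion metrics match hand arithmetic", {
  # tp = 9, fn = 1, fp = 2, tn = 8
  y <- c(rep(1, 10), rep(0, 10))
  s <- c(rep(0.9, 9), 0.1, rep(0.9, 2), rep(0.1, 8))
  m <- classification_metrics(y, s, threshold = 0.5)
  expect_identical(c(m$tp, m$fn, m$fp, m$tn), c(9L, 1L, 2L, 8L))
  expect_equal(m$tpr, 0.9, tolerance = 1e-12)
  expect_equal(m$fpr, 0.2, tolerance = 1e-12)
  expect_equal(m$precision, 9 / 11, tolerance = 1e-12)
  expect_equal(m$specificity, 0.8, tolerance = 1e-12)
  expect_equal(m$f1, 2 * (9 / 11) * 0.9 / ((9 / 11) + 0.9),
               tolerance = 1e-12)
  expect_length(m$zero_division, 0)
})

test_that("degenerate predictions use the zero-division convention", {
  m <- classification_metrics(c(1, 1, 0, 0), c(0.1, 0.2, 0.1, 0.3))
  expect_identical(m$tpr, 0)          # nothing called positive
  expect_identical(m$specificity, 1)
  expect_true("precision" %in% m$zero_division)

  perfect <- classification_metrics(c(1, 0), c(0.9, 0.1))
  expect_identical(c(perfect$tpr, perfect$fpr, perfect$f1), c(1, 0, 1))
  expect_error(classification_metrics(numeric(0), numeric(0)), "empty")
})

test_that("metric identities hold on random inputs", {
  set.seed(21)
  for (i in 1:25) {
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- runif(40)
    m <- classification_metrics(y, s)
    expect_equal(m$specificity, 1 - m$fpr, tolerance = 1e-12)
    if (m$precision + m$tpr > 0)
      expect_equal(m$f1,
                   2 * m$precision * m$tpr / (m$precision + m$tpr),
                   tolerance = 1e-12)
  }
})

test_that("rank-based AUC matches pair enumeration, trapezoid and pROC", {
  expect_identical(auc_score(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_identical(auc_score(c(1, 0, 1, 0), rep(0.4, 4)), 0.5)
  expect_equal(auc_score(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)), 0.75,
               tolerance = 1e-12)
  set.seed(14)
  for (i in 1:30) {
    y <- c(rep(1, 12), rep(0, 18))
    s <- round(runif(30), 2)  # forces some ties
    expect_equal(auc_score(y, s), oracle_auc_pairs(y, s),
                 tolerance = 1e-12)
  }
  # tie-free scores: rank AUC equals trapezoidal ROC integration
  for (i in 1:10) {
    y <- c(rep(1, 10), rep(0, 10))
    s <- sample(seq(0.01, 1, length.out = 20))
    expect_equal(auc_score(y, s), oracle_auc_trapezoid(y, s),
                 tolerance = 1e-12)
  }
  # independent reference implementation
  y <- c(rep(1, 15), rep(0, 25))
  s <- runif(40)
  expect_equal(auc_score(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
  expect_error(auc_score(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("stratified folds partition the data with balanced classes", {
  set.seed(2)
  y <- c(rep(1, 23), rep(0, 41))
  f <- stratified_folds(y, k = 5)
  expect_setequal(unique(f), 1:5)
  expect_identical(length(f), length(y))
  for (k in 1:5) {
    expect_lte(abs(sum(y[f == k] == 1) - 23 / 5), 1)
    expect_lte(abs(sum(y[f == k] == 0) - 41 / 5), 1)
  }
  set.seed(9); f1 <- stratified_folds(y, 5)
  set.seed(9); f2 <- stratified_folds(y, 5)
  expect_identical(f1, f2)
  expect_error(stratified_folds(c(1, 0, 0, 0), k = 3), "smaller k")
})

test_that("average ranking applies the mid-rank rule", {
  tab <- rbind(A = c(0.9, 0.8), B = c(0.5, 0.8), C = c(0.4, 0.1))
  r <- rank_methods(tab)
  expect_identical(r[["A"]], 1.25)  # rank 1, then tied 1.5
  expect_identical(r[["B"]], 1.75)  # rank 2, then tied 1.5
  expect_identical(r[["C"]], 3)

  best <- rbind(A = c(1, 1, 1), B = c(0.5, 0.2, 0.9))
  expect_identical(rank_methods(best)[["A"]], 1)
  # column permutation leaves averaged ranks unchanged
  expect_identical(rank_methods(tab[, c(2, 1)]), r)
  # lower-is-better flips the ordering
  expect_identical(rank_methods(tab, higher_is_better = FALSE)[["C"]], 1)
  expect_error(rank_methods(rbind(c(1, NA))), "missing")
})

small_ctrl <- function() {
  fnt_control(pop_size = 4, gp_generations = 1, ssa_screen_pop = 4,
              ssa_screen_iter = 3, ssa_final_pop = 4, ssa_final_iter = 5)
}

test_that("cross-validation is stratified, complete and reproducible", {
  b <- sim_blobs(n_pos = 15, n_neg = 15, d = 3, seed = 11)
  cv1 <- fnt_cv(b$x, b$y, k = 3, control = small_ctrl(), seed = 5)
  cv2 <- fnt_cv(b$x, b$y, k = 3, control = small_ctrl(), seed = 5)
  expect_identical(cv1$per_fold, cv2$per_fold)
  expect_identical(sort(unique(cv1$folds)), 1:3)
  expect_identical(nrow(cv1$per_fold), 3L)
  expect_true(all(cv1$per_fold$auc >= 0 & cv1$per_fold$auc <= 1))
  expect_identical(cv1$mean[["auc"]], mean(cv1$per_fold$auc))
})

test_that("ratio experiment runs per ratio and survives pool exhaustion", {
  pos <- sim_fingerprints(n_pos = 12, n_neg = 0, n_bits = 32, seed = 3)$fps
  pool <- sim_decoy_pool(pos, pool_size = 40, seed = 4)
  tab <- ratio_experiment(pos, pool, ratios = c(1, 2, 10), k = 2,
                          control = small_ctrl(), seed = 6)
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$n_neg[1:2], c(12L, 24L))
  expect_true(all(is.na(tab$error[1:2])))
  # ratio 10 needs 120 decoys from a pool of 40
  expect_match(tab$error[3], "too small")
  expect_true(is.na(tab$auc_mean[3]))
})
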