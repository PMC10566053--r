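test_that("the three cohort-comparison chi-square p-values reproduce", {
  # family history, previous negative biopsy, abnormal DRE
  # (training yes/no vs validation yes/no), uncorrected Pearson
  expect_equal(round(pearsonChi2(matrix(c(53, 539, 19, 299), 2))$p, 4),
               0.1126)
  expect_equal(round(pearsonChi2(matrix(c(115, 424, 66, 213), 2))$p, 4),
               0.4486)
  expect_equal(round(pearsonChi2(matrix(c(236, 356, 86, 233), 2))$p, 4),
               0.0001)
  # equal proportions: statistic 0, p 1
  eq <- pearsonChi2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  expect_error(pearsonChi2(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("Mann-Whitney U follows its conventions and the exact law", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.3)
  same <- mannWhitneyU(x, x)
  expect_equal(same$p, 1)
  # disjoint supports: U = n1 * n2
  expect_equal(mannWhitneyU(c(10, 11, 12), c(1, 2, 3))$U, 9)
  expect_equal(mannWhitneyU(c(1, 2, 3), c(10, 11, 12))$U, 0)
  # normal approximation close to exact enumeration at n1 = n2 = 5
  set.seed(51)
  for (rep in 1:5) {
    a <- rnorm(5); b <- rnorm(5, mean = 0.8)
    expect_lt(abs(mannWhitneyU(a, b)$p - mwuExactP(a, b)), 0.02)
  }
})

test_that("rocAuc equals exhaustive pair counting, ties at one half", {
  set.seed(52)
  for (rep in 1:50) {
    n <- sample(6:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(1:8, n, TRUE)   # coarse grid forces ties
    expect_equal(auc(rocAuc(scores, labels)), aucPairCount(scores, labels))
  }
  expect_equal(auc(rocAuc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))), 1)
  expect_equal(auc(rocAuc(rep(1, 10), rep(c(0, 1), 5))), 0.5)
  expect_equal(auc(rocAuc(c(3, 5, 1, 4), c(1, 1, 0, 0))), 0.75)
  expect_error(rocAuc(1:5, rep(1, 5)), "both")
})

test_that("ROC curves are monotone and AUC matches the concordance", {
  set.seed(53)
  sc <- rnorm(60); lb <- rbinom(60, 1, 0.4)
  cv <- rocAuc(sc, lb)
  expect_true(all(diff(cv@sensitivity) >= 0))  # thresholds decreasing
  expect_true(all(diff(cv@specificity) <= 0))
  expect_true(auc(cv) >= 0 && auc(cv) <= 1)
})

test_that("DeLong self-comparison, symmetry and agreement with pROC", {
  set.seed(54)
  sc <- rnorm(40); lb <- rbinom(40, 1, 0.5); lb[1:2] <- c(0, 1)
  expect_equal(delongCompare(sc, sc, lb)$p, 1)
  sc2 <- sc + rnorm(40, sd = 0.5)
  d <- delongCompare(sc, sc2, lb)
  dInv <- delongCompare(sc, sc2, 1 - lb)
  # label inversion flips AUCs around 0.5, hence the difference's sign
  expect_equal(dInv$delta, -d$delta, tolerance = 1e-12)
  for (rep in 1:10) {
    scoresA <- rnorm(50); labels <- rbinom(50, 1, 0.5)
    labels[1:2] <- c(0, 1)
    scoresB <- 0.5 * scoresA + rnorm(50)
    ours <- delongCompare(scoresA, scoresB, labels)
    ref <- pROC::roc.test(
      pROC::roc(labels, scoresA, quiet = TRUE, levels = c(0, 1),
                direction = "<"),
      pROC::roc(labels, scoresB, quiet = TRUE, levels = c(0, 1),
                direction = "<"), method = "delong")
    expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
  }
  # single-curve DeLong variance agrees with pROC too
  v <- rocAuc(sc, lb)@var
  expect_equal(v, pROC::var(pROC::roc(lb, sc, quiet = TRUE,
                                      levels = c(0, 1), direction = "<"),
                            method = "delong"), tolerance = 1e-10)
})

test_that("Youden threshold equals brute-force maximization", {
  set.seed(55)
  for (rep in 1:20) {
    sc <- round(rnorm(30), 1); lb <- rbinom(30, 1, 0.5)
    lb[1:2] <- c(0, 1)
    cv <- rocAuc(sc, lb)
    op <- youdenThreshold(cv, sc, lb)
    bf <- youdenBruteForce(sc, lb)
    expect_equal(op$threshold, bf$t)
    expect_equal(op$sensitivity + op$specificity - 1, bf$j)
  }
  # perfect separation: J = 1; all-equal scores: J = 0
  cv1 <- rocAuc(c(2, 2, 1, 1), c(1, 1, 0, 0))
  op1 <- youdenThreshold(cv1, c(2, 2, 1, 1), c(1, 1, 0, 0))
  expect_equal(op1$sensitivity + op1$specificity - 1, 1)
  cv0 <- rocAuc(rep(3, 8), rep(c(0, 1), 4))
  op0 <- youdenThreshold(cv0, rep(3, 8), rep(c(0, 1), 4))
  expect_equal(op0$sensitivity + op0$specificity - 1, 0)
})

test_that("fixed-sensitivity operating points maximize specificity", {
  sc <- c(0.9, 0.8, 0.3, 0.1, 0.2, 0.7)
  lb <- c(1, 1, 1, 0, 0, 0)
  cv <- rocAuc(sc, lb)
  op <- operatingPointAtSensitivity(cv, sc, lb, 0.90)
  expect_equal(op$threshold, 0.3)
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 2 / 3)
  # target 1.0: threshold at or below the smallest positive score
  op1 <- operatingPointAtSensitivity(cv, sc, lb, 1.0)
  expect_lte(op1$threshold, 0.3)
  expect_error(operatingPointAtSensitivity(cv, sc, lb, 1.5), "sensitivity")
  # brute-force equality on random instances
  set.seed(56)
  for (rep in 1:20) {
    sc <- round(rnorm(40), 1); lb <- rbinom(40, 1, 0.5); lb[1:2] <- c(0, 1)
    cv <- rocAuc(sc, lb)
    op <- operatingPointAtSensitivity(cv, sc, lb, 0.9)
    bf <- sensTargetBruteForce(sc, lb, 0.9)
    expect_equal(op$threshold, bf$t)
    expect_equal(op$specificity, bf$spec)
  }
})

test_that("operating-point rates satisfy the contingency identities", {
  set.seed(57)
  sc <- rnorm(80); lb <- rbinom(80, 1, 0.4); lb[1:2] <- c(0, 1)
  cv <- rocAuc(sc, lb)
  for (t in sample(sc, 10)) {
    op <- operatingPointAtSensitivity(cv, sc, lb,
                                      target = max(1e-6, mean(sc[lb == 1] >= t)))
    tp <- sum(sc >= op$threshold & lb == 1)
    fp <- sum(sc >= op$threshold & lb == 0)
    tn <- sum(sc < op$threshold & lb == 0)
    fn <- sum(sc < op$threshold & lb == 1)
    expect_equal(op$sensitivity, tp / (tp + fn))
    expect_equal(op$specificity, tn / (tn + fp))
    expect_equal(op$accuracy, (tp + tn) / 80)
    if (tp + fp > 0) expect_equal(op$ppv, tp / (tp + fp))
    if (tn + fn > 0) expect_equal(op$npv, tn / (tn + fn))
  }
})

test_that("biopsy avoidance is the reweighted true-negative share", {
  # pure benign stratum at specificity 0.92 with weight 0.520 -> 47.84%
  lb <- rep(0, 100); sc <- c(rep(0, 92), rep(1, 8))
  expect_equal(biopsiesAvoided(lb, sc, 0.5, rep("benign", 100)), 47.84)
  # threshold below every score avoids nothing
  expect_equal(biopsiesAvoided(lb, sc, -1, rep("benign", 100)), 0)
  # all mass on one stratum: avoided = its negative x test-negative share
  w <- c(benign = 0, "VLR/LR" = 0, FIR = 0, UIR = 0, "HR/VHR" = 1, mPC = 0)
  lb2 <- c(rep(0, 10), rep(1, 10)); sc2 <- c(rep(0.1, 5), rep(0.9, 15))
  strat2 <- rep("HR/VHR", 20)
  expect_equal(biopsiesAvoided(lb2, sc2, 0.5, strat2, w), 100 * 5 / 20)
  expect_error(biopsiesAvoided(lb, sc, 0.5, rep("unknown", 100)), "stratum")
})

test_that("biopsy avoidance is monotone in threshold and bounded", {
  set.seed(58)
  n <- 120
  strat <- sample(riskStrata(), n, TRUE)
  lb <- as.integer(strat != "benign")
  sc <- plogis(rnorm(n) + lb)
  w <- cohortWeights()
  thr <- sort(runif(10))
  av <- vapply(thr, function(t) biopsiesAvoided(lb, sc, t, strat, w),
               numeric(1))
  expect_true(all(diff(av) >= 0))
  expect_lte(max(av), 100 * w[["benign"]] + 1e-9)
})

test_that("cohort weights validate composition", {
  expect_equal(sum(cohortWeights()), 1)
  expect_error(cohortWeights(c(benign = 0.6, "VLR/LR" = 0.1, FIR = 0.1,
                               UIR = 0.1, "HR/VHR" = 0.1, mPC = 0.1)),
               "sum to 1")
})
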