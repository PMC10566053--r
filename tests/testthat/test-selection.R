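test_that("univariate screen keeps signal, drops constants, honours alpha", {
  set.seed(41)
  n <- 300
  x <- cbind(sig = rnorm(n), const = rep(1, n), noise = rnorm(n))
  y <- rbinom(n, 1, plogis(1.5 * x[, "sig"]))
  expect_message(scr <- univariateScreen(x, y, 0.1), "constant")
  expect_true("sig" %in% scr$keep)
  expect_true(is.na(scr$p["const"]))
  # alpha = 1 keeps every non-constant feature
  scr1 <- suppressMessages(univariateScreen(x, y, alpha = 0.999999))
  expect_setequal(scr1$keep, c("sig", "noise"))
})

test_that("null features are retained at about the alpha rate", {
  set.seed(42)
  n <- 500; nf <- 1000
  x <- matrix(rnorm(n * nf), n, nf, dimnames = list(NULL, paste0("f", 1:nf)))
  y <- rbinom(n, 1, 0.5)
  scr <- suppressMessages(univariateScreen(x, y, 0.1))
  expect_lt(abs(length(scr$keep) / nf - 0.1), 0.03)
})

test_that("AIC backward elimination matches the stepwise glm oracle", {
  set.seed(43)
  for (rep in 1:5) {
    n <- 200
    X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("v", 1:5)))
    y <- rbinom(n, 1, plogis(1.2 * X[, 1] - 0.8 * X[, 3]))
    ours <- aicBackwardEliminate(X, y, colnames(X))
    df <- data.frame(y = y, X)
    oracle <- stats::step(glm(y ~ ., data = df, family = binomial),
                          direction = "backward", trace = 0)
    kept <- setdiff(names(coef(oracle)), "(Intercept)")
    expect_setequal(ours, kept)
  }
})

test_that("backward elimination keeps signal and can reach intercept-only", {
  set.seed(44)
  n <- 1000
  X <- cbind(signal = rnorm(n), noise = rnorm(n))
  y <- rbinom(n, 1, plogis(2 * X[, "signal"]))
  expect_identical(aicBackwardEliminate(X, y, colnames(X)), "signal")
  # a single pure-noise feature is eliminated entirely
  Xn <- matrix(rnorm(500), ncol = 1, dimnames = list(NULL, "noise"))
  yn <- rbinom(500, 1, 0.5)
  res <- aicBackwardEliminate(Xn, yn, "noise")
  f1 <- aic(fitLogistic(Xn, yn)); f0 <- aic(fitLogistic(NULL, yn))
  expect_identical(res, if (f0 < f1) character(0) else "noise")
})

test_that("multivariable pruning is a fixed point at compliant sets", {
  set.seed(45)
  n <- 400
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(n, 1, plogis(X[, 1] + X[, 2]))
  expect_setequal(multivariablePrune(X, y, c("a", "b"), 0.1), c("a", "b"))
  # planted signal survives pruning against correlated noise
  hits <- vapply(1:10, function(s) {
    set.seed(100 + s)
    n <- 600
    sig <- rnorm(n)
    Xc <- cbind(sig = sig,
                n1 = sig * 0.5 + rnorm(n), n2 = sig * 0.5 + rnorm(n),
                n3 = sig * 0.5 + rnorm(n))
    yc <- rbinom(n, 1, plogis(1.5 * sig))
    "sig" %in% multivariablePrune(Xc, yc, colnames(Xc), 0.1)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the ensemble produces rounds x folds models partitioning the cohort", {
  set.seed(46)
  n <- 80
  x <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:6)))
  y <- rbinom(n, 1, plogis(2 * x[, 1]))
  cfg <- selectionConfig(kFolds = 2, rounds = 1, seed = 9)
  models <- suppressMessages(runSelectionEnsemble(x, y, cfg))
  expect_length(models, 2)
  expect_setequal(unlist(lapply(models, `[[`, "test_ids")), rownames(x))
  # cardinality = rounds x folds; determinism for a fixed seed
  cfg2 <- selectionConfig(kFolds = 3, rounds = 4, seed = 9)
  m1 <- suppressMessages(runSelectionEnsemble(x, y, cfg2))
  m2 <- suppressMessages(runSelectionEnsemble(x, y, cfg2))
  expect_length(m1, 12)
  expect_identical(m1, m2)
  # each round is a partition: every sample tested exactly once
  for (r in 1:4) {
    ids <- unlist(lapply(m1[vapply(m1, `[[`, 1, "round") == r],
                         `[[`, "test_ids"))
    expect_identical(sort(ids), sort(rownames(x)))
  }
})

test_that("the leakage guard rejects forbidden sample ids", {
  x <- matrix(rnorm(40 * 3), 40, 3,
              dimnames = list(sprintf("v%02d", 1:40), paste0("f", 1:3)))
  y <- rep(c(0, 1), 20)
  expect_error(
    runSelectionEnsemble(x, y, selectionConfig(kFolds = 2, rounds = 1),
                         forbiddenIds = "v05"),
    "leaked")
})

test_that("recurrence ranking counts, cuts and tie-breaks as documented", {
  mk <- function(feats, auc) list(round = 1, fold = 1, features = feats,
                                  auc = auc, aic = 0, test_ids = "s")
  models <- list(mk(c("A", "B"), 0.9), mk(c("A", "C"), 0.8), mk("A", 0.7))
  cfg <- selectionConfig(topModelFraction = 1, topNRecurring = 10)
  rk <- rankByRecurrence(models, cfg,
                         univariateP = c(A = 0.01, B = 0.05, C = 0.02))
  expect_identical(rk$feature[1], "A")
  expect_equal(rk$count[1], 3)
  # B and C tie on count; C wins on smaller mean univariate p
  expect_identical(rk$feature[2:3], c("C", "B"))
  # with equal p the tie falls back to the feature id
  rk2 <- rankByRecurrence(models, cfg,
                          univariateP = c(A = 0.01, B = 0.05, C = 0.05))
  expect_identical(rk2$feature[2:3], c("B", "C"))
  # fraction 0.75 of 100 models uses exactly the 75 best by AUC
  models100 <- c(lapply(1:75, function(i) mk("GOOD", 0.9 - i * 1e-4)),
                 lapply(1:25, function(i) mk("BAD", 0.5 - i * 1e-4)))
  rk3 <- rankByRecurrence(models100, selectionConfig(topNRecurring = 10))
  expect_identical(rk3$feature, "GOOD")
  expect_equal(rk3$count, 75)
})

test_that("panel size sits at the AIC nadir (ties to the smaller panel)", {
  set.seed(47)
  n <- 400
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("v", 1:6)))
  y <- rbinom(n, 1, plogis(1.5 * X[, 1] + 1.0 * X[, 2] + 0.7 * X[, 3]))
  panel <- selectPanelSizeAicNadir(X, y, paste0("v", 1:6), maxPanel = 6)
  expect_equal(panelSize(panel), which.min(aicSequence(panel)))
  expect_length(aicSequence(panel), 6)
  # strictly informative nested features: AIC decreasing -> size = maxPanel
  panel3 <- selectPanelSizeAicNadir(X, y, paste0("v", 1:3), maxPanel = 3)
  expect_equal(panelSize(panel3), 3)
  expect_identical(panelFeatures(panel3), paste0("v", 1:3))
})

test_that("an end-to-end selection recovers strongly planted markers", {
  set.seed(48)
  n <- 300
  nf <- 40
  X <- matrix(rnorm(n * nf), n, nf, dimnames = list(NULL, paste0("f", 1:nf)))
  beta <- c(1.5, -1.2, 1.0)
  y <- rbinom(n, 1, plogis(X[, 1:3] %*% beta))
  sel <- suppressMessages(selectMarkerPanel(
    X, y, selectionConfig(kFolds = 5, rounds = 2, topNRecurring = 10,
                          seed = 3)))
  expect_length(sel$models, 10)
  expect_true(all(paste0("f", 1:3) %in% panelFeatures(sel$panel)))
})
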