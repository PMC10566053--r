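test_that("default cohort reproduces the published stratum composition", {
  co <- defaultCohort(seed = 1)
  tab <- table(riskStratum(co), cohortLabel(co))
  expect_equal(unname(tab[, "training"]), c(110, 74, 74, 105, 202, 38))
  expect_equal(unname(tab[, "validation"]), c(158, 26, 25, 34, 66, 16))
  expect_equal(sum(tab[, "training"]), 603)
  expect_equal(sum(tab[, "validation"]), 325)
  expect_equal(nrow(co), 1941)
})

test_that("generation is deterministic for a fixed seed", {
  a <- generateCohort(smallCohortConfig(seed = 7))
  b <- generateCohort(smallCohortConfig(seed = 7))
  expect_identical(peakValues(a), peakValues(b))
  expect_identical(subjectData(a), subjectData(b))
  expect_identical(urineCreatinine(a), urineCreatinine(b))
  c2 <- generateCohort(smallCohortConfig(seed = 8))
  expect_false(identical(peakValues(a), peakValues(c2)))
})

test_that("subject table honours its invariants", {
  sd <- subjectData(defaultCohort(seed = 1))
  expect_true(all(sd$psa_ng_ml > 0))
  expect_true(all(sd$age >= 20))
  benign <- sd$risk_group == "benign"
  expect_true(all(is.na(sd$gleason_sum[benign])))
  expect_true(all(sd$gleason_sum[!benign] %in% 6:10))
  # PSA location rises with severity (generator design)
  med <- tapply(sd$psa_ng_ml, riskStratum(sd$risk_group), median)
  expect_true(med[["mPC"]] > med[["benign"]])
})

test_that("invalid configurations name the offending field", {
  expect_error(cohortConfig(nFeatures = 0), "nFeatures")
  expect_error(cohortConfig(nInformative = 5, nFeatures = 3), "nInformative")
  expect_error(cohortConfig(missingRateBase = 1), "missingRateBase")
  expect_error(cohortConfig(nPerGroupTraining = c(benign = -1, "VLR/LR" = 1,
                                                  FIR = 1, UIR = 1,
                                                  "HR/VHR" = 1, mPC = 1)),
               "nPerGroupTraining")
  expect_error(
    cohortConfig(nInformative = 2, effectSizes = matrix(0, 3, 6)),
    "effectSizes")
})

test_that("a null configuration plants no group structure", {
  co <- generateCohort(cohortConfig(seed = 3, nFeatures = 300,
                                    nInformative = 0))
  lv <- log(peakValues(co))
  benign <- riskStratum(co) == "benign"
  cancer <- riskStratum(co) == "mPC"
  p <- apply(lv, 1, function(v) {
    a <- v[benign][!is.na(v[benign])]; b <- v[cancer][!is.na(v[cancer])]
    if (length(a) < 3 || length(b) < 3) return(NA_real_)
    t.test(a, b)$p.value
  })
  expect_lt(mean(p < 0.001, na.rm = TRUE), 0.01)
})

test_that("plantMarkerEffects shifts only the named cells, additively in log", {
  co <- generateCohort(smallCohortConfig(seed = 2, nFeatures = 50))
  eff <- matrix(0, 1, 6, dimnames = list("M0010", riskStrata()))
  eff["M0010", "mPC"] <- 1.0
  out <- plantMarkerEffects(co, eff)
  mpc <- riskStratum(co) == "mPC"
  lv0 <- log(peakValues(co)); lv1 <- log(peakValues(out))
  expect_equal(lv1["M0010", mpc], lv0["M0010", mpc] + 1.0)
  expect_identical(lv1["M0010", !mpc], lv0["M0010", !mpc])
  expect_identical(lv1[rownames(co) != "M0010", ], lv0[rownames(co) != "M0010", ])
  # empty effect list is the identity
  none <- plantMarkerEffects(co, matrix(0, 0, 6,
                                        dimnames = list(NULL, riskStrata())))
  expect_identical(peakValues(none), peakValues(co))
  expect_error(plantMarkerEffects(co, matrix(0, 1, 6,
    dimnames = list("NOPE", riskStrata()))), "NOPE")
})

test_that("a planted cancer-wide shift is recoverable by the univariate screen", {
  # shift -0.8 SD in all cancer strata; screen on a training cohort of
  # ~600 retains the marker in well over 90% of seeds
  eff <- matrix(rep(c(0, -0.8, -0.8, -0.8, -0.8, -0.8), each = 1), 1, 6,
                dimnames = list(NULL, riskStrata()))
  hits <- vapply(1:20, function(s) {
    cfg <- cohortConfig(nFeatures = 60, nInformative = 1,
                        effectSizes = eff, seed = s)
    co <- generateCohort(cfg)
    co <- co[, cohortLabel(co) == "training"]
    pp <- preprocessCohort(co)
    target <- metadata(co)$informative_features
    if (!target %in% rownames(pp)) return(FALSE)
    y <- buildEndpointLabels(pp, "I")
    scr <- suppressMessages(univariateScreen(analysisMatrix(pp), y, 0.1))
    target %in% scr$keep
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("CSV round trip preserves every cell and the missing mask", {
  co <- generateCohort(fixtureConfig())
  dir <- withr::local_tempdir()
  writeCohortCSV(co, dir)
  back <- readCohortCSV(dir)
  expect_equal(peakValues(back), peakValues(co))
  expect_identical(is.na(peakValues(back)), is.na(peakValues(co)))
  expect_equal(subjectData(back), subjectData(co))
  expect_equal(urineCreatinine(back), urineCreatinine(co))
  # missing cells serialize as empty fields, not zeros
  lines <- readLines(file.path(dir, "peaks.csv"))
  expect_true(any(grepl(",,", lines)))
  expect_false(any(grepl(",0,", lines, fixed = TRUE)))
})

test_that("the shipped fixture regenerates from its seed", {
  dir <- system.file("extdata", "synthetic_cohort10", package = "uroMetPanel")
  expect_true(nzchar(dir))
  shipped <- readCohortCSV(dir)
  regen <- generateCohort(fixtureConfig())
  expect_equal(peakValues(shipped), peakValues(regen))
  expect_equal(subjectData(shipped), subjectData(regen))
})
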