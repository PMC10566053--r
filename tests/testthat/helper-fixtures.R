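# Shared fixtures, all built in code.

# A tiny hand-specified cohort: explicit peak matrix (features x
# samples), risk groups, and unit defaults for the clinical fields.
makeTinyCohort <- function(peaks, risk_group,
                           cohort = rep("training", ncol(peaks)),
                           creatinine = rep(2, ncol(peaks)),
                           psa = rep(10, ncol(peaks)),
                           gleason = NULL) {
  n <- ncol(peaks)
  if (is.null(colnames(peaks))) colnames(peaks) <- sprintf("s%02d", 1:n)
  if (is.null(rownames(peaks))) rownames(peaks) <- sprintf("F%02d", 1:nrow(peaks))
  if (is.null(gleason))
    gleason <- ifelse(risk_group == "benign", NA_integer_, 7L)
  subjects <- data.frame(
    id = colnames(peaks), age = 65, psa_ng_ml = psa,
    family_history = 0L, prior_negative_biopsy = 0L, abnormal_dre = 0L,
    risk_group = risk_group, gleason_sum = as.integer(gleason),
    cohort = cohort)
  MetaboCohort(peaks, subjects, stats::setNames(creatinine, colnames(peaks)))
}

# Reduced-size generator config used where full scale is not the point
smallCohortConfig <- function(seed = 1, nFeatures = 200, nInformative = 0,
                              effectSizes = NULL, ...) {
  cohortConfig(
    nPerGroupTraining = c(benign = 30, "VLR/LR" = 10, FIR = 10,
                          UIR = 15, "HR/VHR" = 25, mPC = 10),
    nPerGroupValidation = c(benign = 20, "VLR/LR" = 4, FIR = 4,
                            UIR = 5, "HR/VHR" = 8, mPC = 3),
    nFeatures = nFeatures, nInformative = nInformative,
    effectSizes = effectSizes, seed = seed, ...)
}

# The published-composition default cohort is expensive; build it once
# per test run and memoize.
.fixtureEnv <- new.env(parent = emptyenv())
defaultCohort <- function(seed = 1) {
  key <- paste0("cohort", seed)
  if (is.null(.fixtureEnv[[key]]))
    .fixtureEnv[[key]] <- generateCohort(cohortConfig(seed = seed))
  .fixtureEnv[[key]]
}

# Config regenerating the shipped 10-subject CSV fixture (seed 42)
fixtureConfig <- function() {
  cohortConfig(
    nPerGroupTraining = c(benign = 2, "VLR/LR" = 1, FIR = 1,
                          UIR = 1, "HR/VHR" = 2, mPC = 1),
    nPerGroupValidation = c(benign = 1, "VLR/LR" = 0, FIR = 0,
                            UIR = 0, "HR/VHR" = 1, mPC = 0),
    nFeatures = 25, nInformative = 2, seed = 42)
}
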