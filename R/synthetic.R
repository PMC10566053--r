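#' Default per-marker effect profiles
#'
#' Builds standardized log-intensity shift profiles across the six
#' severity strata for planted marker metabolites. Odd-indexed markers
#' emulate metabolites depressed in all cancer strata (monopalmitin-like
#' behaviour); even-indexed markers rise monotonically with disease
#' severity (1-stearoyl-rac-glycerol-like behaviour). Shifts are in
#' units of the feature's log-scale standard deviation.
#'
#' @param n number of informative markers
#' @param magnitude absolute shift (in SD units) at the most severe
#'   stratum; default 1.0
#' @return n x 6 matrix of shifts, columns \code{riskStrata()}
#' @export
markerEffectProfiles <- function(n, magnitude = 1.0) {
  if (n == 0L)
    return(matrix(0, 0, 6, dimnames = list(NULL, .STRATA)))
  cancerDown <- -c(0, 1, 1, 1, 1, 1) * magnitude
  severityUp <- c(0, 0, 0.35, 0.7, 1, 1) * magnitude
  prof <- t(vapply(seq_len(n),
                   function(i) if (i %% 2 == 1) cancerDown else severityUp,
                   numeric(6)))
  colnames(prof) <- .STRATA
  rownames(prof) <- NULL
  prof
}

#' Synthetic cohort configuration
#'
#' Defaults reproduce the study's cohort structure: 603 training and
#' 325 validation subjects with the published stratum composition, a
#' 1,941-feature GC-MS peak table whose detection-limited missingness
#' is tuned so that roughly 170 features pass the 60\% presence filter,
#' PSA log-normal with location increasing in severity, and a small set
#' of planted differentially abundant markers.
#'
#' @param nPerGroupTraining,nPerGroupValidation named counts per merged
#'   stratum (benign, VLR/LR, FIR, UIR, HR/VHR, mPC)
#' @param nFeatures number of raw metabolite features
#' @param nInformative number of planted markers (<= nFeatures)
#' @param effectSizes nInformative x 6 matrix of standardized shifts per
#'   stratum; default [markerEffectProfiles()]
#' @param missingRateBase central probability that a feature is absent
#'   in a sample (detection limit); per-feature rates spread around it
#' @param presenceSdLogit spread (logit scale) of per-feature presence
#' @param psaParams list of \code{meanlog}, \code{sdlog} vectors per stratum
#' @param clinicalRates list of per-stratum prevalences of
#'   family history, previous negative biopsy, abnormal DRE
#' @param ageMean,ageSd age distribution (years)
#' @param creatinineMeanlog,creatinineSdlog urine creatinine (mg/dL),
#'   log-normal; uncalibrated plausible values
#' @param featureMeanlogLocation,featureMeanlogSd distribution of
#'   per-feature log-mean peak areas
#' @param featureSdlog within-feature log-scale SD (multiplicative noise)
#' @param intensityMissingSlope logit-slope linking a cell's standardized
#'   log intensity to its detection probability (lower peaks drop out
#'   more often)
#' @param seed integer seed driving all generation streams
#' @return a validated list of class \code{CohortConfig}
#' @export
cohortConfig <- function(
    nPerGroupTraining = c(benign = 110, "VLR/LR" = 74, FIR = 74,
                          UIR = 105, "HR/VHR" = 202, mPC = 38),
    nPerGroupValidation = c(benign = 158, "VLR/LR" = 26, FIR = 25,
                            UIR = 34, "HR/VHR" = 66, mPC = 16),
    nFeatures = 1941L,
    nInformative = 10L,
    effectSizes = NULL,
    missingRateBase = 0.87,
    presenceSdLogit = 1.5,
    psaParams = list(meanlog = log(c(6.5, 7, 9, 11, 16, 35)),
                     sdlog = c(0.55, 0.45, 0.5, 0.55, 0.6, 0.7)),
    clinicalRates = list(
      family_history        = c(0.08, 0.10, 0.09, 0.09, 0.09, 0.08),
      prior_negative_biopsy = c(0.30, 0.25, 0.20, 0.18, 0.15, 0.12),
      abnormal_dre          = c(0.20, 0.22, 0.30, 0.42, 0.60, 0.80)),
    ageMean = 69, ageSd = 8,
    creatinineMeanlog = log(100), creatinineSdlog = 0.5,
    featureMeanlogLocation = log(5e4), featureMeanlogSd = 1.0,
    featureSdlog = 0.7,
    intensityMissingSlope = 0.8,
    seed = 1L) {

  cfg <- list(nPerGroupTraining = nPerGroupTraining,
              nPerGroupValidation = nPerGroupValidation,
              nFeatures = as.integer(nFeatures),
              nInformative = as.integer(nInformative),
              effectSizes = effectSizes,
              missingRateBase = missingRateBase,
              presenceSdLogit = presenceSdLogit,
              psaParams = psaParams, clinicalRates = clinicalRates,
              ageMean = ageMean, ageSd = ageSd,
              creatinineMeanlog = creatinineMeanlog,
              creatinineSdlog = creatinineSdlog,
              featureMeanlogLocation = featureMeanlogLocation,
              featureMeanlogSd = featureMeanlogSd,
              featureSdlog = featureSdlog,
              intensityMissingSlope = intensityMissingSlope,
              seed = as.integer(seed))
  if (is.null(cfg$effectSizes))
    cfg$effectSizes <- markerEffectProfiles(cfg$nInformative)
  .validateCohortConfig(cfg)
  class(cfg) <- "CohortConfig"
  cfg
}

.validateCohortConfig <- function(cfg) {
  chkCounts <- function(x, field) {
    if (length(x) != 6 || !identical(names(x), .STRATA))
      stop("'", field, "' must be named counts for strata: ",
           paste(.STRATA, collapse = ", "))
    if (any(x < 0) || any(x != round(x)))
      stop("'", field, "' must be non-negative integer counts")
  }
  chkCounts(cfg$nPerGroupTraining, "nPerGroupTraining")
  chkCounts(cfg$nPerGroupValidation, "nPerGroupValidation")
  if (cfg$nFeatures < 1) stop("'nFeatures' must be >= 1")
  if (cfg$nInformative < 0 || cfg$nInformative > cfg$nFeatures)
    stop("'nInformative' must be in [0, nFeatures]")
  if (cfg$missingRateBase < 0 || cfg$missingRateBase >= 1)
    stop("'missingRateBase' must be in [0, 1)")
  if (!is.matrix(cfg$effectSizes) ||
      nrow(cfg$effectSizes) != cfg$nInformative ||
      ncol(cfg$effectSizes) != 6)
    stop("'effectSizes' must be an nInformative x 6 matrix")
  lapply(c("family_history", "prior_negative_biopsy", "abnormal_dre"),
         function(f) {
           r <- cfg$clinicalRates[[f]]
           if (length(r) != 6 || any(r < 0) || any(r > 1))
             stop("'clinicalRates$", f, "' must be 6 rates in [0,1]")
         })
  invisible(TRUE)
}

## one global seed -> stable per-purpose sub-seeds, so regenerating one
## layer (e.g. subjects) does not disturb the others
.subSeeds <- function(seed, n = 4L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

.sampleStratumLabel <- function(stratum, n) {
  # split merged strata into concrete NCCN groups at fixed proportions
  switch(stratum,
         "VLR/LR" = sample(c("VLR", "LR"), n, TRUE, prob = c(0.35, 0.65)),
         "HR/VHR" = sample(c("HR", "VHR"), n, TRUE, prob = c(0.6, 0.4)),
         rep(stratum, n))
}

.sampleGleason <- function(stratum, n) {
  switch(stratum,
         benign = rep(NA_integer_, n),
         "VLR/LR" = rep(6L, n),
         FIR = sample(c(6L, 7L), n, TRUE, prob = c(0.3, 0.7)),
         UIR = sample(c(7L, 8L), n, TRUE, prob = c(0.8, 0.2)),
         "HR/VHR" = sample(c(8L, 9L, 10L), n, TRUE,
                           prob = c(0.5, 0.4, 0.1)),
         mPC = sample(c(7L, 8L, 9L, 10L), n, TRUE,
                      prob = c(0.2, 0.3, 0.35, 0.15)))
}

#' Generate a synthetic cohort
#'
#' Draws a subject table and a detection-limited GC-MS peak table with
#' the statistical structure the downstream analysis assumes: exact
#' stratum counts, severity-correlated PSA, log-normal peak areas with
#' intensity-dependent missingness, and planted marker effects that are
#' monotone in severity. Deterministic for a fixed seed.
#'
#' @param config a [cohortConfig()]
#' @return a \linkS4class{MetaboCohort}; planted marker ids are recorded
#'   in \code{metadata(x)$informative_features}
#' @export
generateCohort <- function(config = cohortConfig()) {
  if (!inherits(config, "CohortConfig")) .validateCohortConfig(config)
  seeds <- .subSeeds(config$seed, 4L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))

  ## ---- subjects ----
  set.seed(seeds[1])
  plan <- rbind(
    data.frame(cohort = "training", stratum = .STRATA,
               n = as.integer(config$nPerGroupTraining)),
    data.frame(cohort = "validation", stratum = .STRATA,
               n = as.integer(config$nPerGroupValidation)))
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    n <- plan$n[i]; g <- plan$stratum[i]
    if (n == 0) return(NULL)
    gi <- match(g, .STRATA)
    data.frame(
      age = pmin(95, pmax(45, round(stats::rnorm(n, config$ageMean,
                                                 config$ageSd)))),
      psa_ng_ml = round(stats::rlnorm(n, config$psaParams$meanlog[gi],
                                      config$psaParams$sdlog[gi]), 2),
      family_history =
        stats::rbinom(n, 1, config$clinicalRates$family_history[gi]),
      prior_negative_biopsy =
        stats::rbinom(n, 1, config$clinicalRates$prior_negative_biopsy[gi]),
      abnormal_dre =
        stats::rbinom(n, 1, config$clinicalRates$abnormal_dre[gi]),
      risk_group = .sampleStratumLabel(g, n),
      gleason_sum = .sampleGleason(g, n),
      cohort = plan$cohort[i])
  })
  subjects <- do.call(rbind, rows)
  subjects <- data.frame(id = sprintf("S%04d", seq_len(nrow(subjects))),
                         subjects)
  creatinine <- stats::setNames(
    round(stats::rlnorm(nrow(subjects), config$creatinineMeanlog,
                        config$creatinineSdlog), 1), subjects$id)

  ## ---- feature parameters ----
  set.seed(seeds[2])
  nf <- config$nFeatures
  featIds <- sprintf("M%04d", seq_len(nf))
  muF <- stats::rnorm(nf, config$featureMeanlogLocation,
                      config$featureMeanlogSd)
  presenceLogit <- stats::qlogis(1 - config$missingRateBase) +
    stats::rnorm(nf, 0, config$presenceSdLogit)
  informative <- if (config$nInformative > 0)
    sort(sample.int(nf, config$nInformative)) else integer()
  # planted markers are well-detected metabolites
  presenceLogit[informative] <- pmax(presenceLogit[informative],
                                     stats::qlogis(0.95))

  ## ---- latent intensities ----
  set.seed(seeds[3])
  ns <- nrow(subjects)
  z <- matrix(stats::rnorm(nf * ns), nf, ns)
  strat <- as.integer(riskStratum(subjects$risk_group))
  if (length(informative)) {
    shift <- matrix(0, nf, ns)
    shift[informative, ] <- config$effectSizes[, strat, drop = FALSE]
    z <- z + shift
  }
  latent <- muF + config$featureSdlog * z

  ## ---- detection-limited missingness ----
  set.seed(seeds[4])
  pPresent <- stats::plogis(presenceLogit + config$intensityMissingSlope * z)
  present <- matrix(stats::runif(nf * ns), nf, ns) < pPresent
  peaks <- exp(latent)
  peaks[!present] <- NA_real_
  # a sample must have at least one observed peak for total-area scaling
  emptyCols <- which(colSums(present) == 0)
  for (j in emptyCols) {
    k <- which.max(pPresent[, j])
    peaks[k, j] <- exp(latent[k, j])
  }
  dimnames(peaks) <- list(featIds, subjects$id)

  cohort <- MetaboCohort(peaks, subjects, creatinine)
  metadata(cohort)$informative_features <- featIds[informative]
  metadata(cohort)$effect_sizes <- config$effectSizes
  metadata(cohort)$seed <- config$seed
  cohort
}

#' Plant additive log-intensity effects on named features
#'
#' Shifts the observed (non-missing) values of the named features by a
#' per-stratum amount on the natural-log scale, leaving every other
#' cell untouched. Used to emulate directional marker findings (e.g. a
#' metabolite depressed in all cancer strata, or elevated only in
#' clinically significant disease).
#'
#' @param cohort a \linkS4class{MetaboCohort}
#' @param effects matrix of log shifts with rownames = feature ids and
#'   one column per merged stratum (see \code{riskStrata()})
#' @return the modified cohort
#' @export
plantMarkerEffects <- function(cohort, effects) {
  if (is.null(dim(effects)))
    stop("'effects' must be a matrix with feature ids as rownames")
  if (nrow(effects) == 0L) return(cohort)
  if (is.null(rownames(effects)))
    stop("'effects' must be a matrix with feature ids as rownames")
  if (!identical(colnames(effects), .STRATA))
    stop("'effects' columns must be the strata: ",
         paste(.STRATA, collapse = ", "))
  bad <- setdiff(rownames(effects), rownames(cohort))
  if (length(bad))
    stop("unknown feature(s): ", paste(bad, collapse = ", "))
  v <- assay(cohort, "peaks")
  strat <- as.integer(riskStratum(cohort))
  for (f in rownames(effects)) {
    shift <- effects[f, strat]
    v[f, ] <- v[f, ] * exp(shift)   # additive on log scale
  }
  assay(cohort, "peaks") <- v
  cohort
}

#' Write a cohort to CSV files
#'
#' Emits \code{subjects.csv}, \code{peaks.csv} (samples in rows, one
#' column per feature; empty cell = peak not detected) and
#' \code{creatinine.csv} into \code{dir}. Round-trips exactly through
#' [readCohortCSV()].
#'
#' @param cohort a \linkS4class{MetaboCohort}
#' @param dir output directory (created if needed)
#' @return invisibly, the three file paths
#' @export
writeCohortCSV <- function(cohort, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", dir)
  subj <- subjectData(cohort)
  paths <- file.path(dir, c("subjects.csv", "peaks.csv", "creatinine.csv"))
  utils::write.csv(subj, paths[1], row.names = FALSE, na = "")
  pk <- t(peakValues(cohort))
  pkDf <- data.frame(id = rownames(pk), pk, check.names = FALSE)
  utils::write.csv(pkDf, paths[2], row.names = FALSE, na = "")
  cr <- data.frame(id = colnames(cohort),
                   urine_creatinine = unname(urineCreatinine(cohort)))
  utils::write.csv(cr, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Read a cohort from CSV files
#'
#' @param dir directory containing \code{subjects.csv},
#'   \code{peaks.csv}, \code{creatinine.csv} as written by
#'   [writeCohortCSV()], or explicit paths via the named arguments.
#' @param subjects,peaks,creatinine optional explicit file paths
#' @return a \linkS4class{MetaboCohort}
#' @export
readCohortCSV <- function(dir = NULL,
                          subjects = file.path(dir, "subjects.csv"),
                          peaks = file.path(dir, "peaks.csv"),
                          creatinine = file.path(dir, "creatinine.csv")) {
  for (f in c(subjects, peaks, creatinine))
    if (!file.exists(f)) stop("input file not found: ", f)
  subj <- utils::read.csv(subjects, colClasses = c(id = "character"))
  subj$risk_group <- as.character(subj$risk_group)
  subj$cohort <- as.character(subj$cohort)
  if (!"gleason_sum" %in% names(subj)) subj$gleason_sum <- NA_integer_
  subj$gleason_sum <- suppressWarnings(as.integer(subj$gleason_sum))
  pk <- utils::read.csv(peaks, check.names = FALSE,
                        colClasses = c(id = "character"))
  ids <- pk$id
  m <- as.matrix(pk[setdiff(colnames(pk), "id")])
  if (!is.numeric(m))
    stop("malformed numeric value in peaks file")
  rownames(m) <- ids
  cr <- utils::read.csv(creatinine, colClasses = c(id = "character"))
  orphans <- c(setdiff(subj$id, ids), setdiff(ids, subj$id))
  if (length(orphans))
    stop("subject/peak id mismatch; orphans: ",
         paste(unique(orphans), collapse = ", "))
  if (!setequal(cr$id, ids))
    stop("creatinine ids do not match the peak table")
  MetaboCohort(t(m), subj,
               stats::setNames(cr$urine_creatinine, cr$id))
}
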