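#' Preprocessing configuration
#'
#' @param presenceThreshold fraction of samples within a risk stratum in
#'   which a feature must be observed (strictly more than) to be kept;
#'   default 0.60
#' @param normalizationMode \code{"sequential"} (divide by total peak
#'   area, then by urine creatinine; default), \code{"creatinine"}, or
#'   \code{"total_area"}
#' @param imputeMode \code{"half_min"} (default) replaces missing cells
#'   by half the feature's minimum observed normalized value;
#'   \code{"none"} leaves them missing
#' @param logTransform apply natural log after imputation (default TRUE)
#' @return a list of class \code{PreprocessConfig}
#' @export
preprocessConfig <- function(presenceThreshold = 0.60,
                             normalizationMode = c("sequential",
                                                   "creatinine",
                                                   "total_area"),
                             imputeMode = c("half_min", "none"),
                             logTransform = TRUE) {
  if (presenceThreshold <= 0 || presenceThreshold > 1)
    stop("'presenceThreshold' must be in (0, 1]")
  cfg <- list(presenceThreshold = presenceThreshold,
              normalizationMode = match.arg(normalizationMode),
              imputeMode = match.arg(imputeMode),
              logTransform = isTRUE(logTransform))
  class(cfg) <- "PreprocessConfig"
  cfg
}

#' Presence filter by risk stratum
#'
#' A feature is retained iff it was observed (detected) in strictly
#' more than \code{threshold} of the samples of at least one risk
#' stratum. Strata are the pooled cohort's merged risk groups; the
#' filter is a data-acquisition quality screen and is applied before
#' the training/validation split.
#'
#' @param cohort a \linkS4class{MetaboCohort}
#' @param threshold presence fraction; strict inequality (default 0.60)
#' @return character vector of retained feature ids
#' @export
presenceFilter <- function(cohort, threshold = 0.60) {
  strat <- riskStratum(cohort)
  if (anyNA(strat)) stop("every sample needs a risk group")
  strat <- droplevels(strat)
  if (nlevels(strat) == 0L) stop("no risk strata present")
  obs <- !is.na(peakValues(cohort))
  frac <- vapply(levels(strat), function(g) {
    rowMeans(obs[, strat == g, drop = FALSE])
  }, numeric(nrow(obs)))
  frac <- matrix(frac, nrow = nrow(obs))   # guard the 1-feature case
  keep <- apply(frac > threshold, 1L, any)
  rownames(cohort)[keep]
}

#' Normalize peak areas
#'
#' \code{"creatinine"}: value / urine creatinine.
#' \code{"total_area"}: value / total observed peak area of the sample.
#' \code{"sequential"} (default): value / total peak area, then divided
#' by creatinine — applying both dilution corrections.
#' Missing cells stay missing.
#'
#' @param cohort a \linkS4class{MetaboCohort}
#' @param mode normalization mode
#' @param totalArea per-sample total peak areas; defaults to the sums
#'   over the cohort's current features. Pass the raw (pre-filter)
#'   totals when normalizing an already feature-filtered cohort, since
#'   dilution correction refers to the whole acquisition.
#' @return the cohort with a \code{"normalized"} assay added
#' @export
normalizePeaks <- function(cohort, mode = c("sequential", "creatinine",
                                            "total_area"),
                           totalArea = totalPeakArea(cohort)) {
  mode <- match.arg(mode)
  v <- peakValues(cohort)
  cr <- urineCreatinine(cohort)
  ta <- totalArea
  if (mode %in% c("creatinine", "sequential") && any(cr <= 0))
    stop("non-positive creatinine for sample(s): ",
         paste(colnames(cohort)[cr <= 0], collapse = ", "))
  if (mode %in% c("total_area", "sequential") && any(ta <= 0))
    stop("non-positive total peak area for sample(s): ",
         paste(colnames(cohort)[ta <= 0], collapse = ", "))
  div <- switch(mode,
                creatinine = cr,
                total_area = ta,
                sequential = ta * cr)
  norm <- sweep(v, 2L, div, "/")
  assay(cohort, "normalized") <- norm
  meta <- metadata(cohort)$preprocess
  meta$steps <- c(meta$steps, paste0("normalize[", mode, "]"))
  metadata(cohort)$preprocess <- meta
  cohort
}

#' Impute missing values and log-transform
#'
#' Half-minimum imputation replaces each missing cell by half the
#' minimum observed normalized value of that feature (a standard
#' detection-limit surrogate in metabolomics), after which the natural
#' log is applied. Requires the \code{"normalized"} assay; features
#' must already have passed the presence filter so every feature has at
#' least one observed value.
#'
#' @param cohort a normalized \linkS4class{MetaboCohort}
#' @param imputeMode \code{"half_min"} or \code{"none"}
#' @param logTransform apply natural log (default TRUE)
#' @return the cohort with an \code{"analysis"} assay added
#' @export
imputeAndTransform <- function(cohort, imputeMode = c("half_min", "none"),
                               logTransform = TRUE) {
  imputeMode <- match.arg(imputeMode)
  if (!"normalized" %in% assayNames(cohort))
    stop("run normalizePeaks() first")
  m <- assay(cohort, "normalized")
  if (imputeMode == "half_min") {
    nObs <- rowSums(!is.na(m))
    if (any(nObs == 0))
      stop("internal inconsistency: feature(s) with no observed values ",
           "after the presence filter: ",
           paste(rownames(m)[nObs == 0], collapse = ", "))
    halfMin <- apply(m, 1L, min, na.rm = TRUE) / 2
    idx <- which(is.na(m), arr.ind = TRUE)
    if (nrow(idx)) m[idx] <- halfMin[idx[, 1L]]
  }
  if (isTRUE(logTransform)) m <- log(m)
  if (imputeMode == "half_min" && any(!is.finite(m)))
    stop("internal inconsistency: non-finite analysis values")
  assay(cohort, "analysis") <- m
  meta <- metadata(cohort)$preprocess
  meta$steps <- c(meta$steps,
                  paste0("impute[", imputeMode, "]"),
                  if (logTransform) "log")
  metadata(cohort)$preprocess <- meta
  cohort
}

#' Run the full preprocessing pipeline
#'
#' Fixed order: presence filter (on the pooled cohort's risk strata)
#' -> normalization -> imputation -> log transform. The provenance
#' record in \code{metadata(x)$preprocess} lists the steps, parameters
#' and feature counts in/out.
#'
#' @param cohort a raw \linkS4class{MetaboCohort}
#' @param config a [preprocessConfig()]
#' @return the preprocessed cohort, subset to retained features, with
#'   an \code{"analysis"} assay (use [analysisMatrix()])
#' @export
preprocessCohort <- function(cohort, config = preprocessConfig()) {
  nIn <- nrow(cohort)
  rawTotal <- totalPeakArea(cohort)   # acquisition-level, pre-filter
  keep <- presenceFilter(cohort, config$presenceThreshold)
  cohort <- cohort[keep, ]
  metadata(cohort)$preprocess <- list(
    steps = sprintf("presence_filter[>%g]", config$presenceThreshold),
    presence_threshold = config$presenceThreshold,
    normalization_mode = config$normalizationMode,
    impute_mode = config$imputeMode,
    log_transform = config$logTransform,
    features_in = nIn, features_retained = length(keep))
  cohort <- normalizePeaks(cohort, config$normalizationMode,
                           totalArea = rawTotal)
  imputeAndTransform(cohort, config$imputeMode, config$logTransform)
}
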