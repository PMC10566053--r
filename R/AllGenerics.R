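#' Accessors for MetaboCohort and model objects
#'
#' @param x object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("peakValues", function(x) standardGeneric("peakValues"))
#' @rdname accessors
#' @export
setMethod("peakValues", "MetaboCohort", function(x) assay(x, "peaks"))

#' @rdname accessors
#' @export
setGeneric("urineCreatinine", function(x) standardGeneric("urineCreatinine"))
#' @rdname accessors
#' @export
setMethod("urineCreatinine", "MetaboCohort", function(x) {
  stats::setNames(colData(x)$urine_creatinine, colnames(x))
})

#' @rdname accessors
#' @export
setGeneric("totalPeakArea", function(x) standardGeneric("totalPeakArea"))
#' Total observed peak area per sample (recomputed from the raw table)
#' @rdname accessors
#' @export
setMethod("totalPeakArea", "MetaboCohort", function(x) {
  colSums(assay(x, "peaks"), na.rm = TRUE)
})

#' @rdname accessors
#' @export
setGeneric("subjectData", function(x) standardGeneric("subjectData"))
#' Subject table as a plain data.frame (one row per sample)
#' @rdname accessors
#' @export
setMethod("subjectData", "MetaboCohort", function(x) {
  cd <- as.data.frame(colData(x))
  data.frame(id = rownames(cd),
             cd[setdiff(colnames(cd), "urine_creatinine")],
             row.names = NULL)
})

#' @rdname accessors
#' @export
setGeneric("riskGroup", function(x) standardGeneric("riskGroup"))
#' @rdname accessors
#' @export
setMethod("riskGroup", "MetaboCohort", function(x) {
  stats::setNames(as.character(colData(x)$risk_group), colnames(x))
})

#' Merged risk stratum (benign, VLR/LR, FIR, UIR, HR/VHR, mPC)
#'
#' Maps the eight NCCN risk groups onto the six merged strata used for
#' presence filtering, planted effects and enrollment reweighting.
#' @param x a MetaboCohort or a character vector of risk groups
#' @return factor with levels \code{riskStrata()}
#' @export
setGeneric("riskStratum", function(x) standardGeneric("riskStratum"))
#' @rdname riskStratum
#' @export
setMethod("riskStratum", "MetaboCohort", function(x) {
  riskStratum(as.character(colData(x)$risk_group))
})
#' @rdname riskStratum
#' @export
setMethod("riskStratum", "character", function(x) {
  map <- c(benign = "benign", VLR = "VLR/LR", LR = "VLR/LR", FIR = "FIR",
           UIR = "UIR", HR = "HR/VHR", VHR = "HR/VHR", mPC = "mPC")
  bad <- setdiff(unique(x), names(map))
  if (length(bad)) stop("unknown risk group(s): ", paste(bad, collapse = ", "))
  factor(unname(map[x]), levels = .STRATA)
})

#' The six merged risk stratum labels, in severity order
#' @export
riskStrata <- function() .STRATA

#' @importFrom S4Vectors metadata
#' @export
S4Vectors::metadata

#' @importFrom SummarizedExperiment assay
#' @export
SummarizedExperiment::assay

#' @rdname accessors
#' @export
setGeneric("cohortLabel", function(x) standardGeneric("cohortLabel"))
#' @rdname accessors
#' @export
setMethod("cohortLabel", "MetaboCohort", function(x) {
  stats::setNames(as.character(colData(x)$cohort), colnames(x))
})

#' Analysis-ready matrix (samples x features) after preprocessing
#' @param x a preprocessed MetaboCohort (see [preprocessCohort()])
#' @return numeric matrix, samples in rows
#' @export
setGeneric("analysisMatrix", function(x) standardGeneric("analysisMatrix"))
#' @rdname analysisMatrix
#' @export
setMethod("analysisMatrix", "MetaboCohort", function(x) {
  if (!"analysis" %in% assayNames(x))
    stop("cohort has no 'analysis' assay; run preprocessCohort() first")
  t(assay(x, "analysis"))
})

#' @rdname accessors
#' @export
setGeneric("waldTable", function(x) standardGeneric("waldTable"))
#' Coefficients, standard errors, z and two-sided Wald p-values
#' @rdname accessors
#' @export
setMethod("waldTable", "LogisticFit", function(x) {
  se <- sqrt(diag(x@vcov))
  z <- x@coefficients / se
  cbind(estimate = x@coefficients, se = se, z = z,
        p = 2 * stats::pnorm(-abs(z)))
})

#' @rdname accessors
#' @export
setMethod("coef", "LogisticFit", function(object) object@coefficients)
#' @rdname accessors
#' @export
setMethod("logLik", "LogisticFit", function(object) object@logLik)

#' @rdname accessors
#' @export
setGeneric("aic", function(x) standardGeneric("aic"))
#' @rdname accessors
#' @export
setMethod("aic", "LogisticFit", function(x) x@aic)

#' @rdname accessors
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))
#' @rdname accessors
#' @export
setMethod("auc", "RocCurve", function(x) x@auc)

#' @rdname accessors
#' @export
setGeneric("panelFeatures", function(x) standardGeneric("panelFeatures"))
#' The chosen marker panel (top features up to the AIC nadir)
#' @rdname accessors
#' @export
setMethod("panelFeatures", "RankedPanel", function(x) {
  as.character(x@ranking$feature[seq_len(x@panelSize)])
})
#' @rdname accessors
#' @export
setGeneric("panelSize", function(x) standardGeneric("panelSize"))
#' @rdname accessors
#' @export
setMethod("panelSize", "RankedPanel", function(x) x@panelSize)
#' @rdname accessors
#' @export
setGeneric("aicSequence", function(x) standardGeneric("aicSequence"))
#' @rdname accessors
#' @export
setMethod("aicSequence", "RankedPanel", function(x) x@aicSequence)
#' @rdname accessors
#' @export
setGeneric("markerRanking", function(x) standardGeneric("markerRanking"))
#' @rdname accessors
#' @export
setMethod("markerRanking", "RankedPanel", function(x) x@ranking)

#' @rdname accessors
#' @export
setGeneric("reportResults", function(x) standardGeneric("reportResults"))
#' @rdname accessors
#' @export
setMethod("reportResults", "UtilityReport", function(x) x@results)
#' @rdname accessors
#' @export
setGeneric("reportMetadata", function(x) standardGeneric("reportMetadata"))
#' @rdname accessors
#' @export
setMethod("reportMetadata", "UtilityReport", function(x) x@metadata)
#' @rdname accessors
#' @export
setGeneric("reportSelection", function(x) standardGeneric("reportSelection"))
#' @rdname accessors
#' @export
setMethod("reportSelection", "UtilityReport", function(x) x@selection)
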