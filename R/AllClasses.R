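#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays assayNames colData
#' @importFrom stats coef logLik
NULL

## Ordered NCCN-derived risk strata as used throughout: the two
## low-risk groups (VLR, LR) and the two high-risk groups (HR, VHR)
## are merged, mirroring how cohort composition tables report them.
.STRATA <- c("benign", "VLR/LR", "FIR", "UIR", "HR/VHR", "mPC")
.RISK_GROUPS <- c("benign", "VLR", "LR", "FIR", "UIR", "HR", "VHR", "mPC")

.SUBJECT_COLS <- c("id", "age", "psa_ng_ml", "family_history",
                   "prior_negative_biopsy", "abnormal_dre", "risk_group",
                   "gleason_sum", "cohort")

#' MetaboCohort: a urine metabolomics cohort
#'
#' Container for one study cohort: a metabolite peak table (features x
#' samples, explicit \code{NA} for peaks not detected in a sample),
#' per-sample urine creatinine, and the clinical subject table (age,
#' serum PSA, family history, previous negative biopsy, abnormal DRE,
#' NCCN risk group, Gleason sum, training/validation assignment).
#' Extends \linkS4class{SummarizedExperiment}; subject fields live in
#' \code{colData} and preprocessing provenance in \code{metadata}.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}
#' @export
setClass("MetaboCohort", contains = "SummarizedExperiment")

.validMetaboCohort <- function(object) {
  msg <- character()
  cd <- colData(object)
  need <- setdiff(.SUBJECT_COLS, "id")
  miss <- setdiff(c(need, "urine_creatinine"), colnames(cd))
  if (length(miss))
    return(paste("missing colData columns:", paste(miss, collapse = ", ")))
  v <- assay(object, "peaks")
  if (any(v[!is.na(v)] <= 0))
    msg <- c(msg, "observed peak areas must be positive")
  if (any(is.na(cd$urine_creatinine)) || any(cd$urine_creatinine <= 0))
    msg <- c(msg, "urine_creatinine must be positive")
  if (any(is.na(cd$psa_ng_ml)) || any(cd$psa_ng_ml <= 0))
    msg <- c(msg, "psa_ng_ml must be positive")
  if (any(is.na(cd$age)) || any(cd$age < 20))
    msg <- c(msg, "age must be >= 20 years")
  if (!all(cd$risk_group %in% .RISK_GROUPS))
    msg <- c(msg, "risk_group outside the NCCN-derived set")
  if (!all(cd$cohort %in% c("training", "validation")))
    msg <- c(msg, "cohort must be 'training' or 'validation'")
  benign <- cd$risk_group == "benign"
  gs <- cd$gleason_sum
  if (any(!is.na(gs[benign])))
    msg <- c(msg, "gleason_sum must be absent for benign subjects")
  if (any(is.na(gs[!benign])) ||
      (any(!benign) && any(gs[!benign] < 6 | gs[!benign] > 10)))
    msg <- c(msg, "gleason_sum must be present and in [6,10] for cancers")
  if (length(msg)) msg else TRUE
}
setValidity("MetaboCohort", .validMetaboCohort)

#' Construct a MetaboCohort
#'
#' @param peaks numeric matrix, features x samples; \code{NA} marks a
#'   peak not detected in that sample; observed values must be > 0.
#' @param subjects data.frame with columns \code{id}, \code{age},
#'   \code{psa_ng_ml}, \code{family_history},
#'   \code{prior_negative_biopsy}, \code{abnormal_dre} (0/1),
#'   \code{risk_group}, \code{gleason_sum} (\code{NA} for benign),
#'   \code{cohort} ("training"/"validation"); one row per sample
#'   column of \code{peaks}, matched by \code{id}.
#' @param creatinine positive numeric, urine creatinine per sample
#'   (mg/dL), named by or ordered as the samples.
#' @return a \linkS4class{MetaboCohort}
#' @export
MetaboCohort <- function(peaks, subjects, creatinine) {
  stopifnot(is.matrix(peaks), is.data.frame(subjects))
  if (is.null(colnames(peaks))) colnames(peaks) <- subjects$id
  if (!identical(sort(colnames(peaks)), sort(as.character(subjects$id))))
    stop("sample ids of 'peaks' and 'subjects' do not match")
  subjects <- subjects[match(colnames(peaks), subjects$id), , drop = FALSE]
  if (!is.null(names(creatinine)))
    creatinine <- creatinine[colnames(peaks)]
  cd <- DataFrame(subjects[setdiff(colnames(subjects), "id")],
                  urine_creatinine = unname(creatinine),
                  row.names = subjects$id)
  se <- SummarizedExperiment(assays = list(peaks = peaks), colData = cd)
  new("MetaboCohort", se)
}

setMethod("show", "MetaboCohort", function(object) {
  cd <- colData(object)
  cat("MetaboCohort:", nrow(object), "features x", ncol(object), "samples\n")
  cat("  cohorts:",
      paste(sprintf("%s=%d", names(table(cd$cohort)), table(cd$cohort)),
            collapse = ", "), "\n")
  st <- table(factor(riskStratum(object), levels = .STRATA))
  cat("  strata: ", paste(sprintf("%s=%d", names(st), st), collapse = ", "),
      "\n", sep = "")
  obs <- mean(!is.na(assay(object, "peaks")))
  cat(sprintf("  observed cells: %.1f%%", 100 * obs), "\n")
  if (!is.null(metadata(object)$preprocess))
    cat("  preprocessed:",
        paste(metadata(object)$preprocess$steps, collapse = " -> "), "\n")
})

#' LogisticFit: a fitted binary logistic regression
#'
#' Maximum-likelihood fit via iteratively reweighted least squares,
#' with a small ridge penalty on slopes as fallback under separation
#' or non-convergence.
#'
#' @slot coefficients named numeric, intercept first (log-odds scale)
#' @slot vcov inverse observed information at the optimum
#' @slot logLik unpenalized binomial log-likelihood at the estimate
#' @slot aic 2k - 2 logLik, k counting all estimated coefficients
#' @slot converged TRUE iff the unpenalized fit converged
#' @slot penalty ridge penalty actually used (0 or the fallback value)
#' @slot n number of observations
#' @slot predictors predictor ids (excluding intercept)
#' @export
setClass("LogisticFit", representation(
  coefficients = "numeric", vcov = "matrix", logLik = "numeric",
  aic = "numeric", converged = "logical", penalty = "numeric",
  n = "integer", predictors = "character"))

setMethod("show", "LogisticFit", function(object) {
  cat(sprintf("LogisticFit: %d predictor(s), n = %d\n",
              length(object@predictors), object@n))
  cat(sprintf("  logLik = %.4f, AIC = %.4f%s\n", object@logLik, object@aic,
              if (object@penalty > 0)
                sprintf(" (ridge %g fallback)", object@penalty) else ""))
  print(round(waldTable(object), 4))
})

#' RocCurve: an empirical ROC curve
#'
#' @slot thresholds observed score values, decreasing; positivity is
#'   score >= threshold
#' @slot sensitivity,specificity rates at each threshold
#' @slot auc tie-corrected concordance probability
#' @slot var DeLong variance of the AUC
#' @slot nPos,nNeg class counts
#' @export
setClass("RocCurve", representation(
  thresholds = "numeric", sensitivity = "numeric", specificity = "numeric",
  auc = "numeric", var = "numeric", nPos = "integer", nNeg = "integer"))

setMethod("show", "RocCurve", function(object) {
  ci <- aucCI(object)
  cat(sprintf("RocCurve: AUC = %.4f (95%% CI %.4f-%.4f), %d pos / %d neg\n",
              object@auc, ci[1], ci[2], object@nPos, object@nNeg))
})

#' RankedPanel: recurrence-ranked markers with AIC-nadir size
#'
#' @slot ranking data.frame (feature, count, mean_univariate_p) ordered
#'   by recurrence among the top candidate models
#' @slot aicSequence AIC of nested models over the top-1..top-m markers
#' @slot panelSize argmin of the AIC sequence (ties -> smaller)
#' @export
setClass("RankedPanel", representation(
  ranking = "data.frame", aicSequence = "numeric", panelSize = "integer"))

setMethod("show", "RankedPanel", function(object) {
  cat(sprintf("RankedPanel: %d ranked markers, AIC-nadir panel size %d\n",
              nrow(object@ranking), object@panelSize))
  cat("  panel:", paste(panelFeatures(object), collapse = ", "), "\n")
})

#' UtilityReport: full evaluation of the fitted endpoint models
#'
#' Per endpoint x cohort x predictor set (clinical-only, marker panel,
#' panel + PSA, combined): AUC with DeLong CI and p versus chance,
#' paired AUC comparisons, operating points (Youden and fixed
#' sensitivities) with reweighted biopsy avoidance, and decision
#' curves.
#'
#' @slot results one entry per endpoint
#' @slot selection per-endpoint selection ensembles and rankings
#' @slot metadata seeds, configuration echo, feature counts
#' @export
setClass("UtilityReport", representation(
  results = "list", selection = "list", metadata = "list"))

setMethod("show", "UtilityReport", function(object) {
  cat("UtilityReport:", length(object@results), "endpoint model(s)\n")
  for (ep in names(object@results)) {
    res <- object@results[[ep]]
    cat(sprintf("  Model %s (panel size %d):\n", ep,
                length(res$panel$features)))
    for (ch in names(res$cohorts)) {
      aucs <- vapply(res$cohorts[[ch]]$sets,
                     function(s) s$auc, numeric(1))
      cat(sprintf("    %-10s %s\n", ch,
                  paste(sprintf("%s=%.3f", names(aucs), aucs),
                        collapse = "  ")))
    }
  }
})
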