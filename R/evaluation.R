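## ROC / AUC machinery with DeLong variance, operating points,
## reweighted biopsy avoidance, and the cohort-comparison tests.
## Score orientation throughout: higher score = more likely positive;
## a subject is test-positive iff score >= threshold.

.aucRank <- function(scores, labels) {
  r <- rank(scores)          # midranks: ties count 1/2
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## DeLong placement components: V10 per positive, V01 per negative
.delongPlacements <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  rAll <- rank(c(pos, neg))
  v10 <- (rAll[seq_len(m)] - rank(pos)) / n
  v01 <- 1 - (rAll[m + seq_len(n)] - rank(neg)) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Empirical ROC curve with tie-corrected AUC and DeLong variance
#'
#' AUC is the Mann-Whitney concordance probability (tied pairs count
#' one half). Curve thresholds are the observed score values; at each
#' threshold positivity is score >= threshold.
#'
#' @param scores numeric risk scores (higher = more likely positive)
#' @param labels binary 0/1 outcome
#' @return a \linkS4class{RocCurve}
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (length(unique(labels)) < 2L)
    stop("both outcome classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  pl <- .delongPlacements(scores, labels)
  v <- if (length(pos) > 1L && length(neg) > 1L)
    stats::var(pl$v10) / length(pos) + stats::var(pl$v01) / length(neg)
  else NA_real_
  new("RocCurve", thresholds = thr, sensitivity = sens,
      specificity = spec, auc = pl$auc, var = v,
      nPos = length(pos), nNeg = length(neg))
}

#' DeLong confidence interval for an AUC
#' @param curve a \linkS4class{RocCurve}
#' @param level confidence level (default 0.95)
#' @return length-2 numeric (lower, upper), clipped to [0, 1]
#' @export
aucCI <- function(curve, level = 0.95) {
  se <- sqrt(curve@var)
  z <- stats::qnorm(1 - (1 - level) / 2)
  pmin(1, pmax(0, curve@auc + c(-1, 1) * z * se))
}

#' DeLong p-value against chance (AUC = 0.5)
#' @param curve a \linkS4class{RocCurve}
#' @return two-sided p-value
#' @export
aucPValue <- function(curve) {
  se <- sqrt(curve@var)
  if (!is.finite(se) || se == 0)
    return(if (curve@auc == 0.5) 1 else 0)
  2 * stats::pnorm(-abs((curve@auc - 0.5) / se))
}

#' DeLong paired comparison of two AUCs
#'
#' Both score vectors must be defined on the same subjects in the same
#' order. The variance of the AUC difference comes from the covariance
#' of the per-subject placement components.
#'
#' @param scoresA,scoresB paired risk scores
#' @param labels binary outcome
#' @return list: \code{aucA}, \code{aucB}, \code{delta}, \code{se},
#'   \code{z}, \code{p} (two-sided), \code{degenerate} flag
#' @export
delongCompare <- function(scoresA, scoresB, labels) {
  labels <- as.integer(labels)
  if (length(scoresA) != length(scoresB) ||
      length(scoresA) != length(labels))
    stop("scores and labels must be paired (equal length)")
  a <- .delongPlacements(scoresA, labels)
  b <- .delongPlacements(scoresB, labels)
  m <- length(a$v10); n <- length(a$v01)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  varDelta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- a$auc - b$auc
  if (!is.finite(varDelta) || varDelta <= 0) {
    return(list(aucA = a$auc, aucB = b$auc, delta = delta,
                se = 0, z = NA_real_,
                p = if (abs(delta) < 1e-12) 1 else 0,
                degenerate = TRUE))
  }
  z <- delta / sqrt(varDelta)
  list(aucA = a$auc, aucB = b$auc, delta = delta, se = sqrt(varDelta),
       z = z, p = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

## all contingency-derived rates at one threshold (positivity: >= thr)
.operatingPoint <- function(scores, labels, threshold, strata = NULL,
                            weights = NULL) {
  testPos <- scores >= threshold
  tp <- sum(testPos & labels == 1); fn <- sum(!testPos & labels == 1)
  fp <- sum(testPos & labels == 0); tn <- sum(!testPos & labels == 0)
  bx <- if (!is.null(strata) && !is.null(weights))
    biopsiesAvoided(labels, scores, threshold, strata, weights)
  else NA_real_
  data.frame(threshold = threshold,
             sensitivity = tp / (tp + fn),
             specificity = tn / (tn + fp),
             npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
             ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
             accuracy = (tp + tn) / length(labels),
             biopsies_avoided_pct = bx)
}

#' Operating point at the Youden index
#'
#' Picks the observed threshold maximizing J = sensitivity +
#' specificity - 1; ties go to the higher-specificity (larger)
#' threshold.
#'
#' @param curve a \linkS4class{RocCurve}
#' @param scores,labels the scores/labels the curve was built from
#'   (needed for the contingency rates)
#' @param strata,weights optional: per-subject risk strata and
#'   enrollment weights to fill \code{biopsies_avoided_pct}
#' @return one-row data.frame (threshold, sensitivity, specificity,
#'   npv, ppv, accuracy, biopsies_avoided_pct)
#' @export
youdenThreshold <- function(curve, scores, labels, strata = NULL,
                            weights = NULL) {
  j <- curve@sensitivity + curve@specificity - 1
  # thresholds are stored in decreasing order, so the first maximum is
  # the largest threshold = highest specificity among ties
  best <- which.max(j)
  .operatingPoint(scores, labels, curve@thresholds[best], strata, weights)
}

#' Operating point at a fixed target sensitivity
#'
#' Chooses the highest observed threshold whose sensitivity is at
#' least \code{target}, i.e. maximizes specificity subject to the
#' sensitivity constraint (the published tables fix 90\% and 95\%
#' sensitivity for clinical relevance).
#'
#' @inheritParams youdenThreshold
#' @param target sensitivity in (0, 1]
#' @return one-row data.frame as in [youdenThreshold()]
#' @export
operatingPointAtSensitivity <- function(curve, scores, labels, target,
                                        strata = NULL, weights = NULL) {
  if (target <= 0 || target > 1)
    stop("'target' sensitivity must be in (0, 1]")
  ok <- which(curve@sensitivity >= target - 1e-12)
  if (!length(ok))
    stop("target sensitivity unattainable at any observed threshold")
  best <- ok[1L]   # thresholds decreasing; first qualifying = highest
  .operatingPoint(scores, labels, curve@thresholds[best], strata, weights)
}

#' Enrollment-composition weights per risk stratum
#'
#' The at-risk population composition during the enrollment period:
#' benign, VLR/LR, FIR, UIR, HR/VHR and mPC fractions. Used to
#' renormalize biopsy-avoidance figures from the (enriched) analysis
#' cohorts back to the population actually presenting at clinic.
#'
#' @param weights named non-negative fractions over
#'   \code{riskStrata()}, summing to 1
#' @return validated named numeric vector
#' @export
cohortWeights <- function(weights = c(benign = 0.520, "VLR/LR" = 0.087,
                                      FIR = 0.074, UIR = 0.110,
                                      "HR/VHR" = 0.183, mPC = 0.026)) {
  if (!identical(names(weights), .STRATA))
    stop("'weights' must be named over the strata: ",
         paste(.STRATA, collapse = ", "))
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  weights
}

#' Reweighted biopsy-avoidance percentage
#'
#' The share of the at-risk population (under the enrollment
#' composition weights) that is endpoint-negative and test-negative at
#' the given threshold — i.e. the biopsies that could be skipped
#' without missing disease. Each stratum contributes
#' \code{w_g * P(endpoint-negative & score < threshold | stratum g)},
#' so for a stratum that is entirely endpoint-negative this is
#' \code{w_g x} its specificity, and strata mixing both endpoint
#' classes (Model GS) have their weight allocated by the observed
#' negative-class share.
#'
#' @param labels binary endpoint labels
#' @param scores risk scores
#' @param threshold positivity threshold (test-positive iff >=)
#' @param strata per-subject risk stratum (factor over
#'   \code{riskStrata()} or coercible)
#' @param weights [cohortWeights()]
#' @return percentage in [0, 100]
#' @export
biopsiesAvoided <- function(labels, scores, threshold, strata,
                            weights = cohortWeights()) {
  strata <- as.character(strata)
  present <- unique(strata)
  missing <- setdiff(present, names(weights))
  if (length(missing))
    stop("stratum absent from weights: ", paste(missing, collapse = ", "))
  avoided <- 0
  for (g in present) {
    inG <- strata == g
    avoided <- avoided +
      weights[[g]] * mean(labels[inG] == 0 & scores[inG] < threshold)
  }
  100 * avoided
}

#' Uncorrected Pearson chi-square test on a 2x2 table
#'
#' No continuity correction (matching how the cohort-comparison
#' p-values are computed); 1 degree of freedom.
#'
#' @param table 2x2 matrix of counts
#' @return list: \code{statistic}, \code{p}
#' @export
pearsonChi2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("need a 2x2 table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in the 2x2 table")
  ht <- stats::chisq.test(table, correct = FALSE)
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' Mann-Whitney U test (normal approximation)
#'
#' Two-sided, tie-corrected, with continuity correction. U counts the
#' pairs where an \code{x} value exceeds a \code{y} value (ties count
#' one half), so U = n1*n2 when x stochastically dominates y with
#' disjoint supports.
#'
#' @param x,y numeric samples
#' @return list: \code{U}, \code{p}
#' @export
mannWhitneyU <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  list(U = unname(ht$statistic), p = unname(ht$p.value))
}
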