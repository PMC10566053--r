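## Binary logistic regression engine: IRLS with step halving, Wald
## covariance from the final observed information, and a small ridge
## penalty on slopes (never the intercept) as fallback when the
## unpenalized likelihood has no finite maximizer (separation) or IRLS
## fails to converge.

.RIDGE_FALLBACK <- 1e-4

.irls <- function(X, y, penalty = 0, maxIter = 100L, tol = 1e-8) {
  p <- ncol(X)
  beta <- numeric(p)
  beta[1] <- stats::qlogis(mean(y))
  penVec <- c(0, rep(penalty, p - 1L))   # never penalize the intercept
  penLL <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta))) - sum(penVec * b^2) / 2
  }
  llCur <- penLL(beta)
  converged <- FALSE
  H <- NULL
  for (it in seq_len(maxIter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X, y - mu)) - penVec * beta
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X)
    diag(H) <- diag(H) + penVec
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    # step halving keeps the penalized likelihood non-decreasing
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      llNew <- penLL(cand)
      if (is.finite(llNew) && llNew >= llCur - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) { cand <- beta; llNew <- llCur; break }
    }
    beta <- cand; llCur <- llNew
    if (max(abs(beta)) > 1e3) break   # diverging: separation
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  H <- crossprod(X * w, X)
  diag(H) <- diag(H) + penVec
  list(beta = beta, H = H, converged = converged,
       logLik = sum(stats::dbinom(y, 1, mu, log = TRUE)))
}

#' Fit a binary logistic regression
#'
#' Maximum likelihood via iteratively reweighted least squares (run to
#' a gradient max-norm below \code{1e-8} or 100 iterations). If the
#' unpenalized fit does not converge — typically under complete or
#' quasi-complete separation — the model is refit with a ridge penalty
#' of \code{1e-4} on the slopes (never the intercept) and flagged
#' \code{converged = FALSE} with the penalty recorded. Wald standard
#' errors come from the final information matrix.
#'
#' @param x numeric predictor matrix (n x p; p may be 0 for an
#'   intercept-only model), columns named
#' @param y binary outcome (0/1), both classes present
#' @return a \linkS4class{LogisticFit}
#' @export
fitLogistic <- function(x, y) {
  if (is.null(x)) x <- matrix(numeric(0), length(y), 0)
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("'y' must be binary 0/1")
  if (length(unique(y)) < 2L) stop("degenerate outcome: only one class")
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  if (ncol(x) > 0 && is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  X <- cbind("(Intercept)" = 1, x)
  fit <- .irls(X, y)
  penalty <- 0
  # Under (quasi-)complete separation the score also vanishes as the
  # slopes diverge, so "gradient small" alone is not enough: flag any
  # slope moving the logit by > 10 per predictor SD as separation
  # (finite MLEs in this domain sit far below that).
  separated <- FALSE
  if (ncol(x) > 0) {
    sdx <- apply(x, 2L, stats::sd)
    separated <- any(abs(fit$beta[-1]) * sdx > 10, na.rm = TRUE)
  }
  if (!fit$converged || separated) {
    fit <- .irls(X, y, penalty = .RIDGE_FALLBACK)
    fit$converged <- FALSE
    penalty <- .RIDGE_FALLBACK
  }
  vc <- tryCatch(solve(fit$H), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  dimnames(vc) <- list(colnames(X), colnames(X))
  k <- ncol(X)
  new("LogisticFit",
      coefficients = stats::setNames(fit$beta, colnames(X)),
      vcov = vc, logLik = fit$logLik, aic = 2 * k - 2 * fit$logLik,
      converged = fit$converged && penalty == 0,
      penalty = penalty, n = length(y),
      predictors = colnames(x) %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predicted probabilities and logits
#'
#' @param fit a \linkS4class{LogisticFit}
#' @param x predictor matrix whose columns cover the fit's predictors
#'   (matched by name)
#' @return list with \code{logit} and \code{probability} vectors
#' @export
predictProbability <- function(fit, x) {
  preds <- fit@predictors
  if (length(preds) == 0L) {
    logit <- rep(fit@coefficients[["(Intercept)"]],
                 if (is.null(x)) 1L else nrow(as.matrix(x)))
  } else {
    x <- as.matrix(x)
    missing <- setdiff(preds, colnames(x))
    if (length(missing))
      stop("predictor(s) absent from 'x': ",
           paste(missing, collapse = ", "))
    logit <- drop(cbind(1, x[, preds, drop = FALSE]) %*% fit@coefficients)
  }
  list(logit = unname(logit), probability = unname(stats::plogis(logit)))
}

#' Endpoint specifications (Models I, II, III, GS)
#'
#' Dichotomizations of the NCCN risk strata:
#' \describe{
#'   \item{I}{benign (0) vs any prostate cancer (1)}
#'   \item{II}{benign + VLR/LR (0) vs FIR through mPC (1) — significant
#'     cancer for men with a long life expectancy}
#'   \item{III}{benign + VLR/LR + FIR (0) vs UIR through mPC (1) —
#'     significant cancer for men with a shorter life expectancy}
#'   \item{GS}{benign or Gleason sum < 7 (0) vs Gleason sum >= 7 (1)}
#' }
#'
#' @param model one of \code{"I"}, \code{"II"}, \code{"III"}, \code{"GS"}
#' @return a list of class \code{EndpointSpec} with the id and mapping
#' @export
endpointSpec <- function(model = c("I", "II", "III", "GS")) {
  model <- match.arg(model)
  posStrata <- switch(model,
                      I = .STRATA[-1],
                      II = c("FIR", "UIR", "HR/VHR", "mPC"),
                      III = c("UIR", "HR/VHR", "mPC"),
                      GS = NULL)
  spec <- list(id = model, positive_strata = posStrata)
  class(spec) <- "EndpointSpec"
  spec
}

#' Binary endpoint labels for a cohort
#'
#' @param subjects a \linkS4class{MetaboCohort} or a subject data.frame
#'   with \code{risk_group} (and \code{gleason_sum} for Model GS)
#' @param spec an [endpointSpec()] or model id string
#' @return named integer vector of 0/1 labels
#' @export
buildEndpointLabels <- function(subjects, spec) {
  if (is.character(spec)) spec <- endpointSpec(spec)
  if (is(subjects, "MetaboCohort")) subjects <- subjectData(subjects)
  strat <- riskStratum(as.character(subjects$risk_group))
  if (anyNA(strat)) stop("unmapped risk group")
  if (spec$id == "GS") {
    gs <- subjects$gleason_sum
    cancer <- strat != "benign"
    if (any(cancer & is.na(gs)))
      stop("gleason_sum required for all cancers under Model GS")
    y <- as.integer(!is.na(gs) & gs >= 7)
  } else {
    y <- as.integer(strat %in% spec$positive_strata)
  }
  names(y) <- if (!is.null(subjects$id)) subjects$id else rownames(subjects)
  y
}

#' Clinical risk factor design matrix
#'
#' The five clinical factors used alongside the marker panels: age,
#' serum PSA (ng/mL, untransformed by default), family history of PC,
#' previous negative biopsy, abnormal DRE.
#'
#' @param subjects a \linkS4class{MetaboCohort} or subject data.frame
#' @param logPsa use log(PSA) instead of PSA
#' @return numeric matrix with one row per subject
#' @export
clinicalMatrix <- function(subjects, logPsa = FALSE) {
  if (is(subjects, "MetaboCohort")) subjects <- subjectData(subjects)
  psa <- if (logPsa) log(subjects$psa_ng_ml) else subjects$psa_ng_ml
  m <- cbind(age = subjects$age,
             psa = psa,
             family_history = subjects$family_history,
             prior_negative_biopsy = subjects$prior_negative_biopsy,
             abnormal_dre = subjects$abnormal_dre)
  rownames(m) <- if (!is.null(subjects$id)) subjects$id else NULL
  m
}
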