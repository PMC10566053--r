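#' Marker-selection configuration
#'
#' Defaults follow the published procedure: 5-fold cross-validation
#' repeated for 20 rounds (100 candidate models), univariate and
#' multivariable screening at p > 0.1 exclusion, recurrence ranking
#' over the top 75\% of models, top 30 recurring metabolites, and an
#' AIC-nadir search over nested panels.
#'
#' @param kFolds folds per round (>= 2)
#' @param rounds resampling rounds (>= 1)
#' @param univariateAlpha keep a feature iff its univariate Wald p <= this
#' @param multivariableAlpha joint-model pruning threshold
#' @param topModelFraction fraction of candidate models (ranked by
#'   held-out AUC) whose retained sets feed the recurrence count
#' @param topNRecurring number of top recurring features ranked
#' @param maxPanel largest panel size scanned in the AIC-nadir search
#' @param rankModelsBy \code{"auc"} (held-out AUC, default) or
#'   \code{"aic"} (training AIC, ascending) for the top-model cut
#' @param seed RNG seed for fold assignment
#' @return list of class \code{SelectionConfig}
#' @export
selectionConfig <- function(kFolds = 5L, rounds = 20L,
                            univariateAlpha = 0.1,
                            multivariableAlpha = 0.1,
                            topModelFraction = 0.75,
                            topNRecurring = 30L,
                            maxPanel = topNRecurring,
                            rankModelsBy = c("auc", "aic"),
                            seed = 1L) {
  if (kFolds < 2L) stop("'kFolds' must be >= 2")
  if (rounds < 1L) stop("'rounds' must be >= 1")
  for (a in c(univariateAlpha, multivariableAlpha))
    if (a <= 0 || a >= 1) stop("alphas must be in (0, 1)")
  if (topModelFraction <= 0 || topModelFraction > 1)
    stop("'topModelFraction' must be in (0, 1]")
  cfg <- list(kFolds = as.integer(kFolds), rounds = as.integer(rounds),
              univariateAlpha = univariateAlpha,
              multivariableAlpha = multivariableAlpha,
              topModelFraction = topModelFraction,
              topNRecurring = as.integer(topNRecurring),
              maxPanel = as.integer(maxPanel),
              rankModelsBy = match.arg(rankModelsBy),
              seed = as.integer(seed))
  class(cfg) <- "SelectionConfig"
  cfg
}

#' Univariate logistic screen
#'
#' Fits one single-feature logistic model per feature and keeps the
#' feature iff the two-sided Wald p-value of its slope is at most
#' \code{alpha} (the published rule excludes p > 0.1). Constant
#' features are excluded with a note (their slope is undefined).
#' For separation-flagged fits the Wald statistic is degenerate
#' (Hauck-Donner effect: the penalized slope is huge but so is its
#' standard error), so the likelihood-ratio p-value of the ridge
#' fallback fit is used instead — a perfectly separating feature is
#' therefore kept, as it should be.
#'
#' @param x samples x features matrix
#' @param y binary labels
#' @param alpha p-value threshold (default 0.1)
#' @return list: \code{keep} (feature ids) and \code{p} (named
#'   p-values, \code{NA} for constant features)
#' @export
univariateScreen <- function(x, y, alpha = 0.1) {
  x <- as.matrix(x)
  feats <- colnames(x)
  p <- stats::setNames(rep(NA_real_, length(feats)), feats)
  n <- length(y)
  pbar <- mean(y)
  llNull <- n * (pbar * log(pbar) + (1 - pbar) * log(1 - pbar))
  for (f in feats) {
    v <- x[, f]
    if (length(unique(v)) < 2L) next     # constant: slope undefined
    fit <- fitLogistic(x[, f, drop = FALSE], y)
    p[f] <- if (fit@converged) {
      waldTable(fit)[f, "p"]
    } else {
      stats::pchisq(2 * (logLik(fit) - llNull), 1L, lower.tail = FALSE)
    }
  }
  nConst <- sum(is.na(p))
  if (nConst)
    message("univariateScreen: ", nConst, " constant feature(s) excluded")
  list(keep = feats[!is.na(p) & p <= alpha], p = p)
}

#' AIC backward elimination
#'
#' Greedy stepwise removal: at each step the single feature whose
#' removal lowers AIC the most is dropped; the search stops when no
#' removal lowers AIC. The returned set's AIC is no worse than that of
#' any set reachable by one further removal.
#'
#' @param x samples x features matrix
#' @param y binary labels
#' @param features starting feature ids (non-empty)
#' @return retained feature ids (possibly empty: intercept-only is
#'   preferred)
#' @export
aicBackwardEliminate <- function(x, y, features) {
  if (length(features) == 0L) stop("'features' must be non-empty")
  x <- as.matrix(x)
  cur <- features
  curAic <- aic(fitLogistic(x[, cur, drop = FALSE], y))
  repeat {
    if (length(cur) == 0L) break
    cand <- vapply(cur, function(f) {
      rest <- setdiff(cur, f)
      aic(fitLogistic(x[, rest, drop = FALSE], y))
    }, numeric(1))
    best <- which.min(cand)
    if (cand[best] < curAic - 1e-10) {
      cur <- setdiff(cur, cur[best])
      curAic <- cand[best]
    } else break
  }
  cur
}

#' Multivariable p-value pruning
#'
#' Iteratively refits the joint logistic model and drops the single
#' worst feature with Wald p > \code{alpha}, until every remaining
#' feature satisfies p <= \code{alpha} (possibly none).
#'
#' @inheritParams aicBackwardEliminate
#' @param alpha threshold (default 0.1)
#' @return retained feature ids
#' @export
multivariablePrune <- function(x, y, features, alpha = 0.1) {
  x <- as.matrix(x)
  cur <- features
  while (length(cur)) {
    fit <- fitLogistic(x[, cur, drop = FALSE], y)
    p <- waldTable(fit)[cur, "p"]
    worst <- which.max(p)
    if (p[worst] > alpha) cur <- setdiff(cur, cur[worst]) else break
  }
  cur
}

.stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Run the resampling selection ensemble
#'
#' For each of \code{rounds} x \code{kFolds} outcome-stratified fold
#' assignments (reshuffled each round), runs the three screening
#' stages — univariate screen, AIC backward elimination, multivariable
#' pruning — on the fold-training portion, fits the retained set, and
#' evaluates AUC on the held-out fold. When the univariate screen
#' keeps more features than a tenth of the fold-training sample size,
#' the list is pre-truncated to the best n/10 by univariate p so the
#' joint fits stay well-posed (noted via \code{message}).
#'
#' @param x samples x features matrix (rownames = sample ids)
#' @param y binary labels
#' @param config a [selectionConfig()]
#' @param forbiddenIds sample ids that must not appear in any fold
#'   (leakage guard: the caller passes the validation ids)
#' @return list of candidate models, each with \code{round},
#'   \code{fold}, \code{features}, \code{auc} (held-out),
#'   \code{aic} (fold-training), \code{test_ids}
#' @export
runSelectionEnsemble <- function(x, y, config = selectionConfig(),
                                 forbiddenIds = NULL) {
  x <- as.matrix(x)
  if (min(table(y)) < config$kFolds)
    stop("each class needs at least kFolds members for stratification")
  if (!is.null(forbiddenIds) && !is.null(rownames(x))) {
    leaked <- intersect(rownames(x), forbiddenIds)
    if (length(leaked))
      stop("internal error: validation sample(s) leaked into selection: ",
           paste(utils::head(leaked, 5L), collapse = ", "))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  models <- vector("list", config$rounds * config$kFolds)
  m <- 0L
  truncated <- FALSE
  for (r in seq_len(config$rounds)) {
    fold <- .stratifiedFolds(y, config$kFolds)
    for (f in seq_len(config$kFolds)) {
      tr <- fold != f
      stopifnot(length(unique(y[tr])) == 2L, length(unique(y[!tr])) == 2L)
      scr <- suppressMessages(
        univariateScreen(x[tr, , drop = FALSE], y[tr],
                         config$univariateAlpha))
      keep <- scr$keep
      cap <- floor(sum(tr) / 10)
      if (length(keep) > cap) {
        keep <- keep[order(scr$p[keep])][seq_len(cap)]
        truncated <- TRUE
      }
      feats <- character()
      if (length(keep)) {
        feats <- aicBackwardEliminate(x[tr, , drop = FALSE], y[tr], keep)
        if (length(feats))
          feats <- multivariablePrune(x[tr, , drop = FALSE], y[tr],
                                      feats, config$multivariableAlpha)
      }
      fit <- fitLogistic(x[tr, feats, drop = FALSE], y[tr])
      pr <- predictProbability(fit, x[!tr, feats, drop = FALSE])
      testAuc <- if (length(feats))
        .aucRank(pr$probability, y[!tr]) else 0.5
      m <- m + 1L
      models[[m]] <- list(round = r, fold = f, features = feats,
                          auc = testAuc, aic = aic(fit),
                          test_ids = ids[!tr])
    }
  }
  if (truncated)
    message("runSelectionEnsemble: univariate screen pre-truncated to ",
            "n/10 features in at least one fold")
  models
}

#' Rank features by recurrence among the top candidate models
#'
#' Keeps the \code{ceiling(topModelFraction * M)} candidate models with
#' the highest held-out AUC (or lowest training AIC, per config),
#' counts each feature's appearances among their retained sets, and
#' returns the top \code{topNRecurring} features by count. Ties are
#' broken by mean univariate p (ascending), then feature id.
#'
#' @param models output of [runSelectionEnsemble()]
#' @param config a [selectionConfig()]
#' @param univariateP optional named vector of univariate p-values
#'   (computed on the full training cohort) used for tie-breaking
#' @return data.frame (feature, count, mean_univariate_p), ordered
#' @export
rankByRecurrence <- function(models, config = selectionConfig(),
                             univariateP = NULL) {
  if (length(models) == 0L) stop("need at least one candidate model")
  nTop <- ceiling(config$topModelFraction * length(models))
  score <- vapply(models, `[[`, numeric(1),
                  if (config$rankModelsBy == "auc") "auc" else "aic")
  ord <- order(if (config$rankModelsBy == "auc") -score else score)
  top <- models[ord[seq_len(nTop)]]
  feats <- unlist(lapply(top, `[[`, "features"), use.names = FALSE)
  if (length(feats) == 0L)
    return(data.frame(feature = character(), count = integer(),
                      mean_univariate_p = numeric()))
  cnt <- table(feats)
  df <- data.frame(feature = names(cnt), count = as.integer(cnt))
  df$mean_univariate_p <- if (is.null(univariateP))
    NA_real_ else unname(univariateP[df$feature])
  df <- df[order(-df$count, df$mean_univariate_p, df$feature), ]
  rownames(df) <- NULL
  if (nrow(df) < config$topNRecurring)
    message("rankByRecurrence: only ", nrow(df),
            " distinct features recurred (< topNRecurring)")
  utils::head(df, config$topNRecurring)
}

#' Choose panel size at the cumulative AIC nadir
#'
#' Fits nested joint logistic models on the full training cohort with
#' the top-1, top-2, ..., top-\code{maxPanel} ranked features and picks
#' the panel size minimizing AIC (ties go to the smaller panel),
#' balancing fit and complexity.
#'
#' @param x samples x features matrix (full training cohort)
#' @param y binary labels
#' @param ranking ordered ranking data.frame from [rankByRecurrence()]
#'   (or a character vector of ordered feature ids)
#' @param maxPanel largest size scanned (capped by the ranking length)
#' @return a \linkS4class{RankedPanel}
#' @export
selectPanelSizeAicNadir <- function(x, y, ranking, maxPanel = 30L) {
  if (is.character(ranking))
    ranking <- data.frame(feature = ranking,
                          count = NA_integer_,
                          mean_univariate_p = NA_real_)
  if (nrow(ranking) == 0L) stop("'ranking' must be non-empty")
  x <- as.matrix(x)
  m <- min(maxPanel, nrow(ranking))
  aicSeq <- vapply(seq_len(m), function(s) {
    aic(fitLogistic(x[, ranking$feature[seq_len(s)], drop = FALSE], y))
  }, numeric(1))
  new("RankedPanel", ranking = ranking[seq_len(m), , drop = FALSE],
      aicSequence = aicSeq, panelSize = which.min(aicSeq))
}

#' End-to-end marker panel selection
#'
#' Convenience wrapper: resampling ensemble -> recurrence ranking
#' (tie-broken by full-cohort univariate p) -> AIC-nadir panel sizing.
#'
#' @inheritParams runSelectionEnsemble
#' @return list: \code{panel} (\linkS4class{RankedPanel}),
#'   \code{models} (candidate models), \code{univariate_p}
#' @export
selectMarkerPanel <- function(x, y, config = selectionConfig(),
                              forbiddenIds = NULL) {
  models <- runSelectionEnsemble(x, y, config, forbiddenIds)
  pFull <- suppressMessages(univariateScreen(x, y, alpha = 1))$p
  ranking <- rankByRecurrence(models, config, pFull)
  if (nrow(ranking) == 0L)
    stop("no feature survived the ensemble screens; cannot size a panel")
  panel <- selectPanelSizeAicNadir(x, y, ranking, config$maxPanel)
  list(panel = panel, models = models, univariate_p = pFull)
}
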