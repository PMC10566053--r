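#' Pipeline configuration
#'
#' Exactly one input source: a synthetic [cohortConfig()] (default) or
#' a list of CSV \code{paths} (\code{subjects}, \code{peaks},
#' \code{creatinine}) as written by [writeCohortCSV()].
#'
#' @param cohort a [cohortConfig()] for synthetic input, or NULL
#' @param paths named list of CSV paths, or NULL
#' @param preprocess a [preprocessConfig()]
#' @param selection a [selectionConfig()]; its seed is re-derived per
#'   endpoint from \code{seed}
#' @param endpoints endpoint model ids to run (default all four)
#' @param sensitivityTargets fixed-sensitivity operating points
#' @param weights enrollment-composition [cohortWeights()]
#' @param dcaGrid threshold-probability grid for decision curves
#' @param logPsa enter PSA as log(PSA) in clinical models
#' @param seed master seed (drives generation and fold assignment)
#' @return list of class \code{PipelineConfig}
#' @export
pipelineConfig <- function(cohort = cohortConfig(), paths = NULL,
                           preprocess = preprocessConfig(),
                           selection = selectionConfig(),
                           endpoints = c("I", "II", "III", "GS"),
                           sensitivityTargets = c(0.90, 0.95),
                           weights = cohortWeights(),
                           dcaGrid = seq(0.01, 0.50, by = 0.01),
                           logPsa = FALSE,
                           seed = 1L) {
  if (is.null(cohort) == is.null(paths))
    stop("exactly one input source: 'cohort' (synthetic) or 'paths'")
  if (!length(endpoints)) stop("'endpoints' must be non-empty")
  endpoints <- match.arg(endpoints, c("I", "II", "III", "GS"),
                         several.ok = TRUE)
  cfg <- list(cohort = cohort, paths = paths, preprocess = preprocess,
              selection = selection, endpoints = endpoints,
              sensitivityTargets = sensitivityTargets,
              weights = cohortWeights(weights), dcaGrid = dcaGrid,
              logPsa = isTRUE(logPsa), seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Load cohort inputs from CSV files
#'
#' Validates the files against the CSV contracts (matching ids between
#' subjects, peaks and creatinine; empty peak cells parsed as missing,
#' never zero) and reports row counts.
#'
#' @param paths named list with \code{subjects}, \code{peaks},
#'   \code{creatinine} paths (or a single directory under \code{dir})
#' @param dir directory containing the three standard CSV files
#' @return a \linkS4class{MetaboCohort}
#' @export
loadInputs <- function(paths = NULL, dir = NULL) {
  cohort <- if (!is.null(dir)) readCohortCSV(dir)
  else readCohortCSV(subjects = paths$subjects, peaks = paths$peaks,
                     creatinine = paths$creatinine)
  message("loadInputs: ", ncol(cohort), " subjects, ", nrow(cohort),
          " features")
  cohort
}

.predictorSets <- function(M, panel, clin) {
  list(clinical = clin,
       panel = M[, panel, drop = FALSE],
       panel_psa = cbind(M[, panel, drop = FALSE],
                         psa = clin[, "psa"]),
       combined = cbind(M[, panel, drop = FALSE], clin))
}

.evaluateCohort <- function(fits, sets, y, strata, config) {
  scores <- lapply(names(sets), function(s) {
    predictProbability(fits[[s]], sets[[s]])$probability
  })
  names(scores) <- names(sets)
  out <- list(sets = list(), comparisons = list())
  for (s in names(sets)) {
    curve <- rocAuc(scores[[s]], y)
    ops <- rbind(
      cbind(point = "youden",
            youdenThreshold(curve, scores[[s]], y, strata,
                            config$weights)),
      do.call(rbind, lapply(config$sensitivityTargets, function(t) {
        cbind(point = sprintf("sens%.0f", 100 * t),
              operatingPointAtSensitivity(curve, scores[[s]], y, t,
                                          strata, config$weights))
      })))
    out$sets[[s]] <- list(
      auc = auc(curve), auc_ci = aucCI(curve),
      auc_p_vs_chance = aucPValue(curve),
      delong_var = curve@var,
      operating_points = ops,
      dca = dcaCurves(scores[[s]], y, config$dcaGrid))
  }
  cmp <- list(c("panel", "clinical"), c("panel_psa", "panel"),
              c("combined", "panel"))
  for (pair in cmp) {
    d <- delongCompare(scores[[pair[1]]], scores[[pair[2]]], y)
    out$comparisons[[paste(pair, collapse = "_vs_")]] <-
      d[c("aucA", "aucB", "delta", "z", "p")]
  }
  out
}

#' Run the end-to-end analysis pipeline
#'
#' Preprocesses the cohort, then per endpoint: marker selection on the
#' training cohort only (validation subjects can never enter a
#' selection fold — guarded), joint refits of the four predictor sets
#' (clinical-only, marker panel, panel + PSA, combined) on training,
#' and evaluation (ROC/AUC with DeLong machinery, Youden and
#' fixed-sensitivity operating points with reweighted biopsy
#' avoidance, decision curves) on both cohorts.
#'
#' @param config a [pipelineConfig()]
#' @return a \linkS4class{UtilityReport}
#' @export
runPipeline <- function(config = pipelineConfig()) {
  cohort <- if (!is.null(config$cohort)) generateCohort(config$cohort)
  else loadInputs(config$paths)
  message("pipeline: cohort of ", ncol(cohort), " subjects, ",
          nrow(cohort), " raw features")
  pp <- preprocessCohort(cohort, config$preprocess)
  message("pipeline: ", nrow(pp), " features retained by the ",
          "presence filter")
  M <- analysisMatrix(pp)
  subj <- subjectData(pp)
  strata <- riskStratum(pp)
  train <- subj$cohort == "training"
  validIds <- subj$id[!train]
  clin <- clinicalMatrix(subj, config$logPsa)
  rownames(M) <- rownames(clin) <- subj$id

  results <- list(); selection <- list()
  for (i in seq_along(config$endpoints)) {
    ep <- config$endpoints[i]
    message("pipeline: endpoint Model ", ep)
    y <- buildEndpointLabels(subj, ep)
    selCfg <- config$selection
    selCfg$seed <- (config$seed + 1000L * i) %% .Machine$integer.max
    sel <- selectMarkerPanel(M[train, , drop = FALSE], y[train],
                             selCfg, forbiddenIds = validIds)
    # belt-and-braces leakage check on the recorded folds
    foldIds <- unique(unlist(lapply(sel$models, `[[`, "test_ids")))
    if (length(intersect(foldIds, validIds)))
      stop("internal error: validation ids found in selection folds")
    panel <- panelFeatures(sel$panel)
    message("pipeline: Model ", ep, " panel size ", length(panel),
            " from ", length(sel$models), " candidate models")
    sets <- .predictorSets(M, panel, clin)
    fits <- lapply(sets, function(Xs) {
      fitLogistic(Xs[train, , drop = FALSE], y[train])
    })
    cohorts <- list(
      training = .evaluateCohort(
        fits, lapply(sets, function(Xs) Xs[train, , drop = FALSE]),
        y[train], strata[train], config),
      validation = .evaluateCohort(
        fits, lapply(sets, function(Xs) Xs[!train, , drop = FALSE]),
        y[!train], strata[!train], config))
    results[[ep]] <- list(
      panel = list(features = panel, size = length(panel),
                   aic_sequence = aicSequence(sel$panel),
                   ranking = markerRanking(sel$panel)),
      fits = lapply(fits, function(f) as.list(coef(f))),
      cohorts = cohorts)
    selection[[ep]] <- list(
      models = lapply(sel$models, function(m)
        m[c("round", "fold", "features", "auc", "aic")]),
      ranking = markerRanking(sel$panel),
      aic_sequence = aicSequence(sel$panel),
      panel = panel)
  }
  new("UtilityReport", results = results, selection = selection,
      metadata = list(
        seed = config$seed,
        endpoints = config$endpoints,
        n_training = sum(train), n_validation = sum(!train),
        features_raw = nrow(cohort), features_retained = nrow(pp),
        sensitivity_targets = config$sensitivityTargets,
        weights = as.list(config$weights),
        preprocess = metadata(pp)$preprocess,
        selection_config = unclass(config$selection),
        package_version = as.character(utils::packageVersion("uroMetPanel"))))
}

.reportAsList <- function(report) {
  list(metadata = report@metadata,
       results = lapply(report@results, function(res) {
         res$cohorts <- lapply(res$cohorts, function(ch) {
           ch$sets <- lapply(ch$sets, function(s) {
             s$operating_points <- as.list(s$operating_points)
             s$dca <- as.list(s$dca)
             s
           })
           ch
         })
         res$panel$ranking <- as.list(res$panel$ranking)
         res
       }))
}

#' Write a UtilityReport to disk
#'
#' Emits \code{report.json}, \code{metrics.csv} (one AUC row plus one
#' row per operating point per endpoint x cohort x predictor set),
#' \code{dca_<model>_<cohort>.csv}, \code{selection_report.json} and
#' \code{provenance.json}.
#'
#' @param report a \linkS4class{UtilityReport}
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
writeReport <- function(report, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  paths <- character()
  j <- file.path(dir, "report.json")
  jsonlite::write_json(.reportAsList(report), j, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, na = "null")
  paths <- c(paths, j)

  rows <- list()
  for (ep in names(report@results)) {
    for (ch in names(report@results[[ep]]$cohorts)) {
      setsL <- report@results[[ep]]$cohorts[[ch]]$sets
      for (s in names(setsL)) {
        x <- setsL[[s]]
        rows[[length(rows) + 1L]] <- data.frame(
          endpoint = ep, cohort = ch, predictor_set = s, point = "auc",
          threshold = NA, sensitivity = NA, specificity = NA, npv = NA,
          ppv = NA, accuracy = NA, biopsies_avoided_pct = NA,
          auc = x$auc, auc_ci_lo = x$auc_ci[1], auc_ci_hi = x$auc_ci[2],
          auc_p = x$auc_p_vs_chance)
        op <- x$operating_points
        rows[[length(rows) + 1L]] <- data.frame(
          endpoint = ep, cohort = ch, predictor_set = s,
          point = op$point, threshold = op$threshold,
          sensitivity = op$sensitivity, specificity = op$specificity,
          npv = op$npv, ppv = op$ppv, accuracy = op$accuracy,
          biopsies_avoided_pct = op$biopsies_avoided_pct,
          auc = NA, auc_ci_lo = NA, auc_ci_hi = NA, auc_p = NA)
        f <- file.path(dir, sprintf("dca_Model%s_%s_%s.csv", ep, ch, s))
        utils::write.csv(x$dca, f, row.names = FALSE)
        paths <- c(paths, f)
      }
    }
  }
  mf <- file.path(dir, "metrics.csv")
  utils::write.csv(do.call(rbind, rows), mf, row.names = FALSE)
  paths <- c(paths, mf)

  sf <- file.path(dir, "selection_report.json")
  jsonlite::write_json(report@selection, sf, auto_unbox = TRUE,
                       digits = 10, na = "null")
  pf <- file.path(dir, "provenance.json")
  jsonlite::write_json(report@metadata, pf, auto_unbox = TRUE,
                       digits = 10, na = "null")
  invisible(c(paths, sf, pf))
}

#' Read back a written report
#'
#' @param dir directory written by [writeReport()]
#' @return the parsed \code{report.json} as a list
#' @export
readReport <- function(dir) {
  jsonlite::fromJSON(file.path(dir, "report.json"),
                     simplifyVector = TRUE)
}
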