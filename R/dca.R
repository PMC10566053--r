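#' Net benefit at a threshold probability
#'
#' Standard decision-curve net benefit: subjects with predicted
#' probability >= \code{pt} are classified positive (biopsied), and
#' \code{NB = TP/n - (FP/n) * pt/(1 - pt)} weighs false positives by
#' the odds of the threshold probability.
#'
#' @param probabilities predicted probabilities in [0, 1]
#' @param labels binary outcome
#' @param pt threshold probability in (0, 1)
#' @return net benefit (scalar)
#' @export
netBenefit <- function(probabilities, labels, pt) {
  if (any(pt <= 0 | pt >= 1)) stop("'pt' must be in (0, 1)")
  if (any(probabilities < 0 | probabilities > 1))
    stop("probabilities must be in [0, 1]")
  n <- length(labels)
  vapply(pt, function(t) {
    pos <- probabilities >= t
    tp <- sum(pos & labels == 1)
    fp <- sum(pos & labels == 0)
    tp / n - (fp / n) * t / (1 - t)
  }, numeric(1))
}

#' Decision curves for a model and the reference strategies
#'
#' Evaluates the model's net benefit together with biopsy-for-all
#' (everyone positive) and biopsy-for-none (NB = 0) over a grid of
#' threshold probabilities, and the biopsies potentially avoided per
#' 1,000 at-risk subjects relative to biopsy-for-all.
#'
#' @inheritParams netBenefit
#' @param grid strictly increasing threshold probabilities within
#'   (0, 1); default 0.01 to 0.50 by 0.01
#' @return data.frame: \code{p_t}, \code{nb_model}, \code{nb_all},
#'   \code{nb_none}, \code{avoided_per_1000}
#' @export
dcaCurves <- function(probabilities, labels,
                      grid = seq(0.01, 0.50, by = 0.01)) {
  if (any(grid <= 0 | grid >= 1)) stop("'grid' must lie within (0, 1)")
  if (is.unsorted(grid, strictly = TRUE))
    stop("'grid' must be strictly increasing")
  prev <- mean(labels == 1)
  nbModel <- netBenefit(probabilities, labels, grid)
  nbAll <- prev - (1 - prev) * grid / (1 - grid)
  data.frame(p_t = grid, nb_model = nbModel, nb_all = nbAll,
             nb_none = 0,
             avoided_per_1000 =
               interventionsAvoided(nbModel, nbAll, grid))
}

#' Biopsies avoided per 1,000 at-risk subjects
#'
#' \code{1000 * (nbModel - nbAll) * (1 - pt) / pt}: the net reduction
#' in interventions relative to biopsy-for-all, at equal net benefit.
#'
#' @param nbModel,nbAll net benefits of the model and of biopsy-for-all
#' @param pt threshold probability in (0, 1)
#' @return interventions avoided per 1,000
#' @export
interventionsAvoided <- function(nbModel, nbAll, pt) {
  if (any(pt <= 0 | pt >= 1)) stop("'pt' must be in (0, 1)")
  1000 * (nbModel - nbAll) * (1 - pt) / pt
}
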