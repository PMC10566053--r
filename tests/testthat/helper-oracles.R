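# Independent oracles, deliberately naive.

# AUC by exhaustive concordant-pair counting (ties count 1/2)
aucPairCount <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Brute-force best Youden threshold over all observed score values;
# ties resolved toward the larger threshold (higher specificity)
youdenBruteForce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  thr <- sort(unique(scores), decreasing = TRUE)
  best <- NULL
  for (t in thr) {
    j <- mean(pos >= t) + mean(neg < t) - 1
    if (is.null(best) || j > best$j + 1e-12) best <- list(t = t, j = j)
  }
  best
}

# Brute-force highest threshold with sensitivity >= target
sensTargetBruteForce <- function(scores, labels, target) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  thr <- sort(unique(scores), decreasing = TRUE)
  for (t in thr) if (mean(pos >= t) >= target - 1e-12)
    return(list(t = t, sens = mean(pos >= t), spec = mean(neg < t)))
  NULL
}

# Exact two-sided Mann-Whitney p by enumerating all label assignments
mwuExactP <- function(x, y) {
  ustat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  n1 <- length(x); pool <- c(x, y)
  mid <- n1 * length(y) / 2
  obs <- abs(ustat(x, y) - mid)
  sets <- utils::combn(length(pool), n1)
  hits <- 0
  for (i in seq_len(ncol(sets))) {
    a <- pool[sets[, i]]; b <- pool[-sets[, i]]
    if (abs(ustat(a, b) - mid) >= obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(sets)
}

# Stratified paired-bootstrap p-value for an AUC difference: the
# bootstrap distribution of delta* yields an independent standard
# error for the observed difference, tested against a normal null.
# delta* for a resample with multiplicity weights wPos, wNeg is
# wPos' D wNeg / (m*n) where D[i,j] = (concordance of model A for pair
# i,j) - (same for model B); so all B resamples reduce to matrix ops.
delongBootstrapP <- function(scoresA, scoresB, labels, B = 1e5, seed = 1) {
  set.seed(seed)
  pos <- which(labels == 1); neg <- which(labels == 0)
  m <- length(pos); n <- length(neg)
  conc <- function(s) outer(s[pos], s[neg], ">") +
    0.5 * outer(s[pos], s[neg], "==")
  D <- conc(scoresA) - conc(scoresB)
  wPos <- t(stats::rmultinom(B, m, rep(1, m)))
  wNeg <- t(stats::rmultinom(B, n, rep(1, n)))
  delta <- rowSums((wPos %*% D) * wNeg) / (m * n)
  2 * stats::pnorm(-abs(mean(D) / stats::sd(delta)))
}
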