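## Single-sample per-GU statistics: mean methylation level (MML),
## normalized methylation entropy (NME), and the level / entropy
## classification schemes.

#' Mean methylation level of a genomic unit
#'
#' E[L] can be computed either as the mean of the level PMF or as the
#' average of the per-site marginals (1/K) sum `Pr(X_k = 1)`; the two routes
#' agree to numerical precision.
#'
#' @param x a [LevelPMF-class], or a numeric vector of per-site marginal
#'   methylation probabilities.
#' @return MML in `[0, 1]`.
#' @export
computeMML <- function(x) {
  if (is(x, "LevelPMF")) sum(pmfLevels(x) * pmfProbs(x)) else mean(x)
}

#' Normalized methylation entropy of a genomic unit
#'
#' h = -(1/log2(N + 1)) * sum_l P_L(l) log2 P_L(l), with 0 log 0 = 0.
#' Normalization by the maximal entropy log2(N + 1) makes the value
#' comparable across GUs with different CpG counts: a uniform level PMF
#' yields h = 1 for every N, a degenerate PMF yields h = 0.
#'
#' @param pmf a [LevelPMF-class] or probability vector over N + 1 levels.
#' @param N CpG count; defaults to `length(pmf) - 1`.
#' @return NME in `[0, 1]`.
#' @export
computeNME <- function(pmf, N = NULL) {
  p <- if (is(pmf, "LevelPMF")) pmfProbs(pmf) else as.numeric(pmf)
  if (is.null(N)) N <- length(p) - 1L
  if (N < 1L) stop("N must be >= 1")
  nz <- p > 0
  h <- -sum(p[nz] * log2(p[nz])) / log2(N + 1)
  min(max(h, 0), 1)
}

#' Default thresholds for the level classification scheme
#'
#' Cut points of the seven-way methylation-level classification, driven by
#' p_low = `Pr(L <= 0.25)`, p_mid = `Pr(0.25 < L < 0.75)` and
#' p_high = `Pr(L >= 0.75)`.
#' @export
levelThresholds <- function() {
  list(low = 0.25, high = 0.75, highly = 0.9, partially = 0.75,
       bistable = 0.4, highlyMixed = 0.9, mixed = 0.75)
}

#' Classify a genomic unit by the shape of its level PMF
#'
#' Seven classes: highly/partially unmethylated or methylated (mass
#' concentrated below 0.25 / above 0.75), bistable (substantial mass at
#' both extremes -- the maximal-variance shape linked to imprinting),
#' highly mixed and mixed (mass concentrated at intermediate levels), with
#' the nearest class by largest mass as fallback.  Ties break in the order
#' listed below.
#'
#' @param pmf a [LevelPMF-class].
#' @param thresholds see [levelThresholds()].
#' @return character class label.
#' @export
classifyLevel <- function(pmf, thresholds = levelThresholds()) {
  lev <- pmfLevels(pmf); p <- pmfProbs(pmf)
  t <- thresholds
  pLow <- sum(p[lev <= t$low])
  pHigh <- sum(p[lev >= t$high])
  pMid <- sum(p[lev > t$low & lev < t$high])
  if (pLow >= t$highly) return("highly_unmethylated")
  if (pHigh >= t$highly) return("highly_methylated")
  if (pLow >= t$partially) return("partially_unmethylated")
  if (pHigh >= t$partially) return("partially_methylated")
  if (min(pLow, pHigh) >= t$bistable) return("bistable")
  if (pMid >= t$highlyMixed) return("highly_mixed")
  if (pMid >= t$mixed) return("mixed")
  # fallback: nearest class by largest mass
  masses <- c(highly_unmethylated = pLow, highly_methylated = pHigh,
              highly_mixed = pMid,
              bistable = min(pLow, pHigh))
  names(masses)[which.max(masses)]
}

#' Default entropy bins
#'
#' Five ordered NME bins, symmetric about 0.5.
#' @export
entropyThresholds <- function() c(0.28, 0.44, 0.56, 0.72)

#' Classify a genomic unit by its NME
#'
#' Thresholding into five ordered categories from highly ordered
#' (low entropy, homogeneous methylation level across cells) to highly
#' disordered (entropy near the maximum).
#'
#' @param nme NME value in `[0, 1]`.
#' @param thresholds four increasing cut points, see [entropyThresholds()].
#' @return character class label.
#' @export
classifyEntropy <- function(nme, thresholds = entropyThresholds()) {
  stopifnot(all(nme >= 0 & nme <= 1))
  classes <- c("highly_ordered", "moderately_ordered",
               "weakly_ordered_disordered", "moderately_disordered",
               "highly_disordered")
  classes[findInterval(nme, thresholds, left.open = TRUE) + 1L]
}

#' Per-GU statistics of one sample
#'
#' For every GU of the partition that lies in a fitted region and contains
#' at least one CpG site, computes the level PMF, MML, NME and the level
#' and entropy classes.  GUs with no CpG or in unmodeled regions emit no
#' row (track gap).
#'
#' @param layout a [CpGLayout-class].
#' @param partition a [RegionPartition-class].
#' @param fits list of `FitResult`s indexed by region (as returned by
#'   [estimateRegionParams()]; unmodeled regions `NULL` or skipped).
#' @return data.frame with one row per modeled GU: `gu`, `chrom`, `start`,
#'   `end`, `K`, `mml`, `nme`, `levelClass`, `entropyClass`, and the level
#'   PMFs as a list column `pmf`.
#' @export
guStatistics <- function(layout, partition, fits) {
  rows <- vector("list", nGUs(partition))
  for (g in seq_len(nGUs(partition))) {
    first <- partition@guFirstSite[g]
    if (is.na(first)) next
    reg <- partition@guRegion[g]
    fit <- if (reg <= length(fits)) fits[[reg]] else NULL
    if (is.null(fit) || is.null(fit$model) || fit$status != "fitted") next
    regFirst <- partition@regionFirstSite[reg]
    guIdx <- (first:partition@guLastSite[g]) - regFirst + 1L
    pmf <- levelPMF(fit$model, guIdx)
    nme <- computeNME(pmf)
    rows[[g]] <- data.frame(
      gu = g, chrom = layout@chrom,
      start = partition@guStart[g], end = partition@guEnd[g],
      K = pmf@K, mml = computeMML(pmf), nme = nme,
      levelClass = classifyLevel(pmf), entropyClass = classifyEntropy(nme))
    rows[[g]]$pmf <- list(pmf)
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
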