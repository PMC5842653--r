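## Two-sample per-GU statistics: differential level PMF, dMML, dNME,
## Jensen-Shannon distance, and the differential classification schemes.

# Exact rational embedding of a level PMF: numerators over denominator K.
.pmfFraction <- function(pmf) {
  if (is(pmf, "LevelPMF")) list(num = 0:pmf@K, den = pmf@K, p = pmf@p)
  else list(num = seq_along(pmf) - 1L, den = length(pmf) - 1L,
            p = as.numeric(pmf))
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' PMF of the differential methylation level D_L = L_t - L_r
#'
#' Cross-convolution of the two level PMFs assuming the test and reference
#' levels are statistically independent.  Support values are handled as
#' exact rationals (numerators over the common denominator K_t * K_r), so
#' masses at identical differences merge exactly.
#'
#' @param pmfT,pmfR [LevelPMF-class] objects (CpG counts may differ).
#' @return list with `support` (sorted differences in `[-1, 1]`) and `p`.
#' @export
diffLevelPMF <- function(pmfT, pmfR) {
  ft <- .pmfFraction(pmfT); fr <- .pmfFraction(pmfR)
  den <- ft$den * fr$den
  num <- outer(ft$num * fr$den, fr$num * ft$den, `-`)
  mass <- outer(ft$p, fr$p)
  agg <- tapply(as.vector(mass), as.vector(num), sum)
  nums <- as.integer(names(agg))
  o <- order(nums)
  list(support = nums[o] / den, p = as.numeric(agg)[o])
}

#' Kullback-Leibler divergence in bits
#'
#' D(P || Q) = sum P log2(P/Q) over an aligned support, with 0 log(0/q) = 0
#' and +Inf where P > 0 but Q = 0.
#'
#' @param p,q probability vectors over the same support.
#' @export
klDivergence <- function(p, q) {
  stopifnot(length(p) == length(q))
  nz <- p > 0
  if (any(q[nz] == 0)) return(Inf)
  sum(p[nz] * (log2(p[nz]) - log2(q[nz])))
}

# Align two level PMFs on the union of their exact rational level values.
.alignLevels <- function(pmf1, pmf2) {
  f1 <- .pmfFraction(pmf1); f2 <- .pmfFraction(pmf2)
  g <- .gcd(f1$den, f2$den)
  L <- f1$den / g * f2$den # lcm
  n1 <- f1$num * (L / f1$den)
  n2 <- f2$num * (L / f2$den)
  grid <- sort(unique(c(n1, n2)))
  p1 <- numeric(length(grid)); p1[match(n1, grid)] <- f1$p
  p2 <- numeric(length(grid)); p2[match(n2, grid)] <- f2$p
  list(levels = grid / L, p1 = p1, p2 = p2)
}

#' Jensen-Shannon distance between two level PMFs
#'
#' d = sqrt((D(P1, M) + D(P2, M)) / 2) with M the midpoint PMF and D the
#' Kullback-Leibler divergence in bits.  When the CpG counts differ, the
#' PMFs are embedded on the union of their exact rational level values
#' (levels are equal only when k1/K1 = k2/K2), which preserves the
#' property that disjoint supports give d = 1.  The JSD is a normalized
#' metric on `[0, 1]`: 0 iff the PMFs are equal, 1 iff their supports are
#' disjoint.
#'
#' @param pmf1,pmf2 [LevelPMF-class] objects or probability vectors over
#'   levels `{0, 1/K, ..., 1}`.
#' @export
jsDistance <- function(pmf1, pmf2) {
  al <- .alignLevels(pmf1, pmf2)
  m <- (al$p1 + al$p2) / 2
  d2 <- (klDivergence(al$p1, m) + klDivergence(al$p2, m)) / 2
  sqrt(min(max(d2, 0), 1))
}

#' Default differential-level classification thresholds
#' @export
diffLevelThresholds <- function() {
  list(tStrong = 0.5, tModWeak = 0.25, strongly = 0.9, moderately = 0.75,
       weakly = 0.5)
}

#' Classify a GU by the PMF of its differential methylation level
#'
#' Seven ordered classes from strongly hypomethylated to strongly
#' hypermethylated, driven by the tail masses `Pr(D_L <= -t)` and
#' `Pr(D_L >= +t)`: strongly if the mass beyond 0.5 is at least 0.9,
#' moderately if the mass beyond 0.25 is at least 0.75, weakly if it is at
#' least 0.5; isomethylated otherwise.
#'
#' @param dlPmf output of [diffLevelPMF()].
#' @param thresholds see [diffLevelThresholds()].
#' @export
classifyDiffLevel <- function(dlPmf, thresholds = diffLevelThresholds()) {
  t <- thresholds
  lo <- function(cut) sum(dlPmf$p[dlPmf$support <= -cut])
  hi <- function(cut) sum(dlPmf$p[dlPmf$support >= cut])
  if (lo(t$tStrong) >= t$strongly) return("strongly_hypomethylated")
  if (hi(t$tStrong) >= t$strongly) return("strongly_hypermethylated")
  if (lo(t$tModWeak) >= t$moderately) return("moderately_hypomethylated")
  if (hi(t$tModWeak) >= t$moderately) return("moderately_hypermethylated")
  if (lo(t$tModWeak) >= t$weakly) return("weakly_hypomethylated")
  if (hi(t$tModWeak) >= t$weakly) return("weakly_hypermethylated")
  "isomethylated"
}

#' Default differential-entropy bins
#' @export
diffEntropyThresholds <- function() c(0.05, 0.25, 0.55)

#' Classify a GU by its differential NME
#'
#' Seven ordered bins symmetric about zero: |dNME| <= 0.05 isoentropic,
#' then weakly / moderately / strongly hypo- or hyperentropic at the 0.25
#' and 0.55 cut points.
#'
#' @param dnme differential NME in `[-1, 1]`.
#' @param thresholds three increasing positive cut points.
#' @export
classifyDiffEntropy <- function(dnme, thresholds = diffEntropyThresholds()) {
  stopifnot(all(dnme >= -1 & dnme <= 1))
  t <- thresholds
  cuts <- c(-1 - 1e-9, -t[3], -t[2], -t[1], t[1], t[2], t[3], 1 + 1e-9)
  classes <- c("strongly_hypoentropic", "moderately_hypoentropic",
               "weakly_hypoentropic", "isoentropic",
               "weakly_hyperentropic", "moderately_hyperentropic",
               "strongly_hyperentropic")
  classes[findInterval(dnme, cuts, left.open = TRUE,
                       rightmost.closed = TRUE)]
}

#' Differential per-GU statistics of a test/reference pair
#'
#' Joins the per-GU tables of two samples (from [guStatistics()]) on GU
#' index and computes dMML, dNME, JSD, and the differential level and
#' entropy classes for every GU modeled in both samples.
#'
#' @param statsT,statsR per-GU tables of the test and reference sample.
#' @param classify also compute the 7-way classifications (slower).
#' @return data.frame with per-GU `dmml`, `dnme`, `jsd` (and classes).
#' @export
differentialStatistics <- function(statsT, statsR, classify = FALSE) {
  common <- intersect(statsT$gu, statsR$gu)
  it <- match(common, statsT$gu); ir <- match(common, statsR$gu)
  n <- length(common)
  jsd <- numeric(n)
  dmlClass <- character(n); dnmeClass <- character(n)
  dmml <- statsT$mml[it] - statsR$mml[ir]
  dnme <- statsT$nme[it] - statsR$nme[ir]
  for (i in seq_len(n)) {
    pt <- statsT$pmf[[it[i]]]; pr <- statsR$pmf[[ir[i]]]
    jsd[i] <- jsDistance(pt, pr)
    if (classify) {
      dmlClass[i] <- classifyDiffLevel(diffLevelPMF(pt, pr))
      dnmeClass[i] <- classifyDiffEntropy(dnme[i])
    }
  }
  out <- data.frame(gu = common, chrom = statsT$chrom[it],
                    start = statsT$start[it], end = statsT$end[it],
                    dmml = dmml, dnme = dnme, jsd = jsd)
  if (classify) {
    out$dmlClass <- dmlClass
    out$dnmeClass <- dnmeClass
  }
  out
}
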