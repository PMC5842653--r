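## DMR detection from per-GU JSD values: kernel smoothing, null modeling
## (empirical replicate null or logit-normal mixture), BY-FDR, SQS scoring
## and morphological closing.

#' Standard deviation of the smoothing kernel implied by a bandwidth
#'
#' The Gaussian kernel is scaled so that its quartiles sit at
#' +/- 0.25 * bandwidth (the `stats::ksmooth` convention), i.e.
#' sigma = 0.25 * bandwidth / qnorm(0.75).  A 50-kb bandwidth therefore
#' corresponds to a kernel standard deviation of about 18.5 kb.
#'
#' @param bandwidth kernel bandwidth in bp.
#' @export
kernelSigma <- function(bandwidth) 0.25 * bandwidth / qnorm(0.75)

#' Smooth per-GU JSD values along the chromosome
#'
#' Nadaraya-Watson kernel regression with a Gaussian kernel, evaluated at
#' the GU centers themselves.  Smoothing never crosses chromosomes: call
#' once per chromosome.  Each smoothed value is a convex combination of
#' observed values, so it lies within their local range.
#'
#' @param guCenters sorted bp coordinates of the modeled GU centers.
#' @param jsd raw per-GU JSD values.
#' @param bandwidth kernel bandwidth in bp (the DMR scale parameter;
#'   genome-scale default 50000).
#' @return numeric vector of smoothed values (sJSD), parallel to input.
#' @export
smoothJSD <- function(guCenters, jsd, bandwidth = 50000) {
  stopifnot(length(guCenters) == length(jsd))
  if (is.unsorted(guCenters)) stop("guCenters must be sorted")
  if (length(jsd) == 0L) return(numeric())
  if (length(jsd) == 1L) return(jsd)
  ks <- ksmooth(guCenters, jsd, kernel = "normal", bandwidth = bandwidth,
                x.points = guCenters)
  out <- ks$y
  # points beyond kernel reach of any observation: keep the raw value
  out[is.na(out)] <- jsd[is.na(out)]
  out
}

#' Empirical null model from replicate-pair sJSD values
#'
#' Pools the sJSD (or JSD) values observed between pairs of replicate
#' reference samples into a genome-wide empirical null distribution.
#'
#' @param nullValues numeric vector of null statistic values.
#' @return a `NullModel` list (`kind = "empirical"`).
#' @export
empiricalNull <- function(nullValues) {
  nullValues <- nullValues[is.finite(nullValues)]
  if (length(nullValues) == 0L) stop("empty null set")
  list(kind = "empirical", values = sort(nullValues))
}

#' Logit-normal mixture null fitted to the observed sJSD values
#'
#' For studies without replicate reference samples: the sJSD values are
#' logit-transformed (values at 0/1 clipped to `[eps, 1 - eps]`) and a
#' two-component Gaussian mixture with unequal variances is fitted by EM.
#' The component with the smaller mean, mu = min(mu1, mu2), models GUs
#' whose dissimilarity reflects only biological, statistical and technical
#' variability and is used as the null; the other component captures
#' distinct epigenetic behavior.
#'
#' @param sjsd observed sJSD values in `[0, 1]`.
#' @param seed seed for the EM initialization.
#' @param eps clipping bound before the logit transform.
#' @return a `NullModel` list (`kind = "logit_normal"`) with the null
#'   `mu`, `sigma` and the full `mixture`.
#' @export
fitLogitNormalNull <- function(sjsd, seed = 1L, eps = 1e-6) {
  x <- pmin(pmax(sjsd, eps), 1 - eps)
  y <- log(x / (1 - x))
  mclustBIC <- mclust::mclustBIC # Mclust resolves this in the caller frame
  fit <- .withSeed(seed, {
    tryCatch(
      mclust::Mclust(y, G = 2, modelNames = "V", verbose = FALSE),
      error = function(e) NULL)
  })
  if (is.null(fit) || any(!is.finite(sqrt(fit$parameters$variance$sigmasq))) ||
      any(sqrt(fit$parameters$variance$sigmasq) <= 0))
    stop("mixture fit degenerate: could not estimate the logit-normal null")
  mu <- as.numeric(fit$parameters$mean)
  sigma <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sigma) == 1L) sigma <- rep(sigma, 2L)
  w <- as.numeric(fit$parameters$pro)
  k <- which.min(mu)
  list(kind = "logit_normal", mu = mu[k], sigma = sigma[k],
       mixture = list(mu1 = mu[1], mu2 = mu[2], sigma1 = sigma[1],
                      sigma2 = sigma[2], w1 = w[1], w2 = w[2]))
}

#' Density of the fitted logit-normal null on (0, 1)
#'
#' @param x values in (0, 1).
#' @param null a `NullModel` of kind `logit_normal`.
#' @export
logitNormalDensity <- function(x, null) {
  stopifnot(null$kind == "logit_normal")
  lg <- log(x / (1 - x))
  dnorm(lg, null$mu, null$sigma) / (x * (1 - x))
}

#' One-sided p-values against a null model
#'
#' Exceedance probability that the null statistic is at least as large as
#' the observed value.  Empirical null: the plus-one rank formula
#' p = (1 + #(null >= obs)) / (1 + #null), which guarantees p > 0.
#' Logit-normal null: the upper tail of the fitted logit-normal.
#'
#' @param null a `NullModel` from [empiricalNull()] or
#'   [fitLogitNormalNull()].
#' @param observed observed statistic values.
#' @export
nullPValues <- function(null, observed) {
  if (null$kind == "empirical") {
    n <- length(null$values)
    nGE <- n - findInterval(observed, null$values, left.open = TRUE)
    (1 + nGE) / (1 + n)
  } else {
    x <- pmin(pmax(observed, 1e-6), 1 - 1e-6)
    pnorm(log(x / (1 - x)), null$mu, null$sigma, lower.tail = FALSE)
  }
}

#' Benjamini-Yekutieli testing of all modeled GUs
#'
#' Adjusts the genome-wide family of per-GU p-values by the BY step-up
#' procedure (valid under dependence), converts q-values to statistical
#' quality scores SQS = -10 log10(q) (capped), and flags GUs with
#' q <= `fdrLevel`.
#'
#' @param p per-GU p-values (the full genome-wide family).
#' @param fdrLevel FDR control level.
#' @param sqsCap cap applied to SQS when q underflows.
#' @return data.frame with `p`, `q`, `sqs`, `isDM`.
#' @export
testGUs <- function(p, fdrLevel = 0.01, sqsCap = 300) {
  q <- p.adjust(p, method = "BY")
  sqs <- pmin(-10 * log10(pmax(q, .Machine$double.xmin)), sqsCap)
  data.frame(p = p, q = q, sqs = sqs, isDM = q <= fdrLevel)
}

#' Merge significant GUs into DMRs by morphological closing
#'
#' Gaps between neighboring significant GUs that are smaller than
#' `closingSize` bp (default: the smoothing bandwidth) are filled by a
#' binary morphological closing; each resulting connected run is emitted
#' as a DMR scored by the sum of the SQS values of its significant GUs,
#' and DMRs are ranked by score, descending.
#'
#' @param guStart,guEnd 1-based closed GU intervals, sorted, one
#'   chromosome.
#' @param isDM per-GU significance flags.
#' @param sqs per-GU statistical quality scores.
#' @param closingSize structuring-element size in bp.
#' @return data.frame of DMR calls: `start`, `end`, `score`, `nGUs`,
#'   `rank` (empty when nothing is significant).
#' @export
closeAndScore <- function(guStart, guEnd, isDM, sqs, closingSize = 50000) {
  stopifnot(length(guStart) == length(guEnd), length(isDM) == length(guStart))
  keep <- which(isDM)
  if (length(keep) == 0L)
    return(data.frame(start = integer(), end = integer(), score = numeric(),
                      nGUs = integer(), rank = integer()))
  s <- guStart[keep]; e <- guEnd[keep]; w <- sqs[keep]
  starts <- s[1]; ends <- e[1]; scores <- w[1]; ns <- 1L
  j <- 1L
  if (length(keep) > 1L) {
    for (i in 2L:length(keep)) {
      gap <- s[i] - ends[j] - 1L
      if (gap < closingSize) {
        ends[j] <- max(ends[j], e[i])
        scores[j] <- scores[j] + w[i]
        ns[j] <- ns[j] + 1L
      } else {
        j <- j + 1L
        starts[j] <- s[i]; ends[j] <- e[i]; scores[j] <- w[i]; ns[j] <- 1L
      }
    }
  }
  out <- data.frame(start = starts, end = ends, score = scores, nGUs = ns)
  out$rank <- rank(-out$score, ties.method = "first")
  out[order(out$rank), , drop = FALSE]
}

#' JSD-based DMR detection on one chromosome
#'
#' Ties the stages together: smooth the per-GU JSD signal, compute
#' one-sided p-values against the chosen null, apply BY-FDR, and merge
#' significant GUs into scored DMRs by morphological closing.
#'
#' @param diffStats per-GU differential table from
#'   [differentialStatistics()] (needs `start`, `end`, `jsd`).
#' @param null a `NullModel`; when `NULL`, a logit-normal mixture null is
#'   fitted to the sJSD values themselves.
#' @param bandwidth smoothing bandwidth in bp.
#' @param fdrLevel BY FDR level.
#' @param closingSize gap-filling size in bp; defaults to `bandwidth`.
#' @param seed seed for the mixture fit (no-replicate path).
#' @return list with per-GU table `gus` (sjsd, p, q, sqs, isDM) and the
#'   DMR table `dmrs`.
#' @export
detectDMRs <- function(diffStats, null = NULL, bandwidth = 50000,
                       fdrLevel = 0.01, closingSize = bandwidth,
                       seed = 1L) {
  centers <- (diffStats$start + diffStats$end) / 2
  sjsd <- smoothJSD(centers, diffStats$jsd, bandwidth)
  if (is.null(null)) null <- fitLogitNormalNull(sjsd, seed = seed)
  p <- nullPValues(null, sjsd)
  tt <- testGUs(p, fdrLevel = fdrLevel)
  gus <- cbind(diffStats[c("gu", "chrom", "start", "end", "jsd")],
               sjsd = sjsd, tt)
  dmrs <- closeAndScore(diffStats$start, diffStats$end, tt$isDM, tt$sqs,
                        closingSize)
  if (nrow(dmrs)) dmrs$chrom <- diffStats$chrom[1]
  list(gus = gus, dmrs = dmrs, null = null)
}
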