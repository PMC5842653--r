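## Ranking promoters/genes by epigenetic discordance: average JSD in the
## no-replicate setting, empirical-null p-values combined by Fisher's
## method with replicates, and rank products across comparisons.

#' Promoter windows around transcription start sites
#'
#' Centers a 4-kb window at each TSS (strand-agnostic) and attaches the
#' modeled GUs that intersect it by at least 1 bp.  Windows running off
#' the chromosome start are truncated.
#'
#' @param tss data.frame with columns `gene`, `transcript`, `tss`
#'   (1-based coordinate) and optionally `strand` (unused for centering).
#' @param guTable per-GU table with `gu`, `start`, `end` (modeled GUs).
#' @param windowSize total window width in bp.
#' @return data.frame with one row per transcript: `gene`, `transcript`,
#'   `start`, `end`, and list column `gus` of intersecting GU ids.
#' @export
promoterWindows <- function(tss, guTable, windowSize = 4000) {
  half <- windowSize / 2
  start <- pmax(tss$tss - half, 0) # half-open bp window [start, end)
  end <- tss$tss + half
  gus <- vector("list", nrow(tss))
  for (i in seq_len(nrow(tss))) {
    # GU [s, e] (1-based closed) intersects [start, end) by >= 1 bp
    hit <- guTable$end >= start[i] + 1 & guTable$start <= end[i]
    gus[[i]] <- guTable$gu[hit]
  }
  out <- data.frame(gene = tss$gene, transcript = tss$transcript,
                    start = start, end = end)
  out$gus <- gus
  out
}

#' Score a promoter window by average JSD
#'
#' Arithmetic mean of the JSD values of the modeled GUs intersecting the
#' window (missing GUs are ignored); higher scores indicate stronger
#' epigenetic discordance.  Windows with no modeled GU are unscored (`NA`).
#'
#' @param windows output of [promoterWindows()].
#' @param guTable per-GU table with `gu` and `jsd`.
#' @return numeric score per window.
#' @export
scoreAvgJSD <- function(windows, guTable) {
  vapply(windows$gus, function(g) {
    v <- guTable$jsd[match(g, guTable$gu)]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
}

#' Per-GU empirical p-values from replicate-pair JSD values
#'
#' Plus-one exceedance p-values of the raw (unsmoothed) per-GU JSD against
#' the pooled empirical distribution of JSD values between replicate
#' reference pairs.
#'
#' @param jsd observed per-GU JSD values.
#' @param replicateJsd pooled replicate-pair JSD values.
#' @export
guEmpiricalPvalues <- function(jsd, replicateJsd) {
  nullPValues(empiricalNull(replicateJsd), jsd)
}

#' Fisher's combination of p-values
#'
#' X = -2 sum log p_i referred to a chi-squared distribution with 2m
#' degrees of freedom.  The combined value is exact only under mutual
#' independence of the GUs and is used here as a ranking score.
#'
#' @param pvalues p-values in (0, 1]; zeros are clipped to 1e-300.
#' @export
fisherCombine <- function(pvalues) {
  if (length(pvalues) == 0L) stop("need at least one p-value")
  pvalues <- pmax(pvalues, 1e-300)
  x <- -2 * sum(log(pvalues))
  pchisq(x, df = 2 * length(pvalues), lower.tail = FALSE)
}

#' Rank promoters/genes in one comparison
#'
#' Without replicates, promoters are scored by average JSD (higher is more
#' discordant); with replicates, per-GU empirical p-values are combined by
#' Fisher's method (lower is more discordant).  Per gene only the best
#' ranking promoter is kept.
#'
#' @param windows output of [promoterWindows()].
#' @param guTable per-GU table with `gu` and `jsd`.
#' @param replicateJsd optional pooled replicate-pair JSD values; when
#'   given, the Fisher route is used.
#' @return data.frame `gene`, `transcript`, `score`, `rank`, `method`,
#'   sorted by rank; genes with no modeled GU are omitted.
#' @export
rankGenes <- function(windows, guTable, replicateJsd = NULL) {
  if (is.null(replicateJsd)) {
    score <- scoreAvgJSD(windows, guTable)
    method <- "avg_jsd"
    ord <- order(-score)
  } else {
    pv <- guEmpiricalPvalues(guTable$jsd, replicateJsd)
    score <- vapply(windows$gus, function(g) {
      p <- pv[match(g, guTable$gu)]
      p <- p[!is.na(p)]
      if (length(p)) fisherCombine(p) else NA_real_
    }, numeric(1))
    method <- "fisher"
    ord <- order(score)
  }
  df <- data.frame(gene = windows$gene, transcript = windows$transcript,
                   score = score, method = method)
  df <- df[!is.na(df$score), , drop = FALSE]
  df <- df[if (method == "avg_jsd") order(-df$score) else order(df$score), ,
           drop = FALSE]
  # keep the best-ranked promoter per gene
  df <- df[!duplicated(df$gene), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Combine per-comparison gene rankings by rank products
#'
#' RP(g) = (prod_i r_i(g))^(1/k) over k comparisons; genes absent from a
#' list receive rank (list length + 1).  The final order is ascending RP,
#' ties broken by mean rank and then by gene id.
#'
#' @param rankLists list of data.frames with columns `gene` and `rank`.
#' @return data.frame `gene`, `rp`, `rank`.
#' @export
rankProduct <- function(rankLists) {
  if (length(rankLists) == 0L) stop("need at least one ranked list")
  genes <- unique(unlist(lapply(rankLists, function(d) d$gene)))
  rmat <- sapply(rankLists, function(d) {
    r <- d$rank[match(genes, d$gene)]
    r[is.na(r)] <- nrow(d) + 1L
    r
  })
  rmat <- matrix(rmat, nrow = length(genes))
  rp <- exp(rowMeans(log(rmat)))
  meanRank <- rowMeans(rmat)
  ord <- order(rp, meanRank, genes)
  data.frame(gene = genes[ord], rp = rp[ord], rank = seq_along(genes))
}
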