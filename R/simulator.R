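## WGBS read simulator with ground truth: isolated CpG islands with
## uniformly spaced CpG sites, Ising-distributed methylation states (one
## latent molecule per read), and randomly placed fixed-length reads.

#' Configuration of the synthetic CpG-island study
#'
#' The synthetic genome consists of `nIslands` isolated CpG islands of
#' `islandLen` bp, each containing `cpgsPerIsland` uniformly spaced CpG
#' sites, separated by CpG-free gaps of `gap` bp.  Reads of `readLen` bp
#' are placed uniformly at random along the genome at `coverage` x mean
#' coverage.  With the defaults, CpG spacing is 15 bp and a read inside an
#' island covers 20 CpG sites.  The island count defaults to a desk-scale
#' 50 (the full-scale design uses 5000).
#'
#' @param nIslands number of CpG islands.
#' @param islandLen island length in bp.
#' @param cpgsPerIsland CpG sites per island (uniform spacing).
#' @param gap CpG-free gap between islands in bp.
#' @param readLen read length in bp.
#' @param coverage mean genome-wide coverage.
#' @export
simulationConfig <- function(nIslands = 50L, islandLen = 3000L,
                             cpgsPerIsland = 200L, gap = 100000L,
                             readLen = 300L, coverage = 15) {
  spacing <- islandLen / cpgsPerIsland
  stopifnot(spacing >= 2, coverage > 0, nIslands >= 1)
  list(nIslands = as.integer(nIslands), islandLen = as.integer(islandLen),
       cpgsPerIsland = as.integer(cpgsPerIsland), gap = as.integer(gap),
       readLen = as.integer(readLen), coverage = coverage,
       spacing = as.integer(spacing))
}

#' Synthetic genome layout of isolated CpG islands
#'
#' Islands sit at deterministic coordinates: island i occupies
#' `[(i-1)(islandLen+gap)+1, (i-1)(islandLen+gap)+islandLen]` with CpG
#' sites every `spacing` bp starting at the island start.
#'
#' @param config a [simulationConfig()].
#' @param regionSize,guSize passed to [partitionGenome()].
#' @return list with `layout` ([CpGLayout-class]), `partition`
#'   ([RegionPartition-class]), `islands` (data.frame `start`, `end`) and
#'   `genomeLength`.
#' @export
simulateLayout <- function(config, regionSize = 3000, guSize = 150) {
  stride <- config$islandLen + config$gap
  islandStart <- (seq_len(config$nIslands) - 1L) * stride + 1L
  islandEnd <- islandStart + config$islandLen - 1L
  genomeLength <- islandEnd[config$nIslands] + config$gap
  offsets <- (seq_len(config$cpgsPerIsland) - 1L) * config$spacing
  positions <- as.integer(outer(offsets, islandStart, `+`))
  layout <- buildCpGLayout("sim", positions = positions,
                           chromLength = genomeLength)
  partition <- partitionGenome(genomeLength, layout, regionSize, guSize)
  list(layout = layout, partition = partition,
       islands = data.frame(island = seq_len(config$nIslands),
                            start = islandStart, end = islandEnd),
       genomeLength = genomeLength)
}

#' Simulate WGBS reads over the synthetic genome
#'
#' Read starts are uniform over the genome; the read count is
#' `ceiling(coverage * genomeLength / readLen)`.  Each read overlapping an
#' island draws its own latent full-island methylation state from that
#' island's Ising model (a read is one cell's molecule, which is what
#' makes within-read correlation carry signal) and reports the exact
#' states of the CpG sites it covers; there are no bisulfite-conversion or
#' sequencing errors.  Reads falling entirely in CpG-free gaps are
#' retained but contribute no records.
#'
#' @param sim output of [simulateLayout()].
#' @param config the [simulationConfig()].
#' @param a,c Ising field and coupling; scalars or per-island vectors.
#' @param seed integer seed (the output is fully deterministic given it).
#' @return data.frame in the observation dialect: `chrom`, `read_id`,
#'   `cpg_pos`, `state`.
#' @export
simulateReads <- function(sim, config, a, c, seed) {
  positions <- cpgPositions(sim$layout)
  genomeLength <- sim$genomeLength
  nReadsTotal <- as.integer(ceiling(config$coverage * genomeLength /
                                    config$readLen))
  a <- rep_len(a, config$nIslands)
  c <- rep_len(c, config$nIslands)
  .withSeed(seed, {
    starts <- sample.int(genomeLength - config$readLen + 1L, nReadsTotal,
                         replace = TRUE)
    lo <- findInterval(starts - 0.5, positions) + 1L
    hi <- findInterval(starts + config$readLen - 1L + 0.5, positions)
    covered <- which(hi >= lo)
    island <- (lo[covered] - 1L) %/% config$cpgsPerIsland + 1L
    recs <- vector("list", config$nIslands)
    for (isl in seq_len(config$nIslands)) {
      rd <- covered[island == isl]
      if (length(rd) == 0L) next
      model <- regionModel(a = a[isl], c = c[isl],
                           R = config$cpgsPerIsland)
      states <- cpp_ising_sample(model@a, .modelC(model), length(rd))
      base <- (isl - 1L) * config$cpgsPerIsland
      lens <- hi[rd] - lo[rd] + 1L
      glob <- sequence(lens, from = lo[rd])
      row <- rep(seq_along(rd), lens)
      recs[[isl]] <- data.frame(read_id = rep(rd, lens),
                                cpg_pos = positions[glob],
                                state = states[cbind(row, glob - base)])
    }
    recs <- recs[!vapply(recs, is.null, logical(1))]
    out <- if (length(recs)) do.call(rbind, recs) else
      data.frame(read_id = integer(), cpg_pos = integer(), state = integer())
    out <- out[order(out$read_id, out$cpg_pos), , drop = FALSE]
    rownames(out) <- NULL
    cbind(chrom = "sim", out)
  })
}

#' Ground-truth differential labels of the islands
#'
#' An island is labeled differential iff the test and reference coupling
#' differ there.  With a = 0 in both samples, every CpG site has a true
#' marginal methylation probability of exactly 0.5 in both samples, so
#' all differences are invisible to marginal statistics.
#'
#' @param config the [simulationConfig()].
#' @param cTest,cRef per-island couplings of the two samples (recycled).
#' @return data.frame `island`, `label` (`"differential"` or `"null"`).
#' @export
labelTruth <- function(config, cTest, cRef) {
  cTest <- rep_len(cTest, config$nIslands)
  cRef <- rep_len(cRef, config$nIslands)
  data.frame(island = seq_len(config$nIslands),
             label = ifelse(cTest != cRef, "differential", "null"))
}
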