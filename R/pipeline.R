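## Pipeline stages tying the modules together: per-sample model fitting
## and GU statistics, test/reference comparison, DMR detection, and the
## end-to-end synthetic differential study.

#' Fit all eligible regions of one sample
#'
#' Applies the three eligibility filters to every estimation region and
#' fits the five Ising parameters by maximum marginal likelihood where
#' they pass.  Skipped regions carry their filter reason.
#'
#' @param layout a [CpGLayout-class].
#' @param partition a [RegionPartition-class].
#' @param obsList per-region [ObservationMatrix-class] list (from
#'   [observationsByRegion()]).
#' @param config an [optimizerConfig()].
#' @param seed master seed; each region is fitted with a seed derived from
#'   it, so the whole sample fit is deterministic.
#' @param minCpGs,minObsFraction,minDepth eligibility thresholds.
#' @return list of per-region `FitResult`s (`NULL` slots never occur;
#'   ineligible regions have `status = "skipped(<reason>)"`).
#' @export
fitSample <- function(layout, partition, obsList,
                      config = optimizerConfig(), seed = 1L,
                      minCpGs = 10, minObsFraction = 2 / 3,
                      minDepth = 2.5) {
  fits <- vector("list", nRegions(partition))
  for (rg in seq_len(nRegions(partition))) {
    slice <- regionSlice(layout, partition, rg)
    nS <- if (is.null(slice)) 0L else length(slice$sites)
    obs <- obsList[[rg]]
    elig <- regionEligible(nS, obs, minCpGs, minObsFraction, minDepth)
    if (!elig$pass) {
      fits[[rg]] <- list(theta = NULL, loglik = NA_real_, nParams = 5L,
                         model = NULL,
                         status = paste0("skipped(", elig$reason, ")"))
      next
    }
    fits[[rg]] <- estimateRegionParams(slice, obs, config,
                                       seed = (seed + rg) %% .Machine$integer.max)
  }
  fits
}

#' Per-sample analysis: fits plus GU statistics
#'
#' @inheritParams fitSample
#' @return list with `fits` and the per-GU table `gus` (see
#'   [guStatistics()]).
#' @export
analyzeSample <- function(layout, partition, obsList,
                          config = optimizerConfig(), seed = 1L, ...) {
  fits <- fitSample(layout, partition, obsList, config, seed, ...)
  list(fits = fits, gus = guStatistics(layout, partition, fits))
}

#' Skip log of a fitted sample
#'
#' @param partition a [RegionPartition-class].
#' @param fits per-region fit list.
#' @return data.frame `region`, `start`, `end`, `reason` for every region
#'   that was not fitted.
#' @export
skipLog <- function(partition, fits) {
  status <- vapply(fits, function(f) f$status, character(1))
  skipped <- which(status != "fitted")
  data.frame(region = skipped,
             start = partition@regionStart[skipped],
             end = partition@regionEnd[skipped],
             reason = sub("^skipped\\((.*)\\)$", "\\1", status[skipped]))
}

#' End-to-end synthetic differential study at one coupling difference
#'
#' Reproduces the synthetic CpG-island design at one value of the coupling
#' difference delta, with the matched-pairs structure of the original
#' study: three test samples (a = 0, c = 0) and three matched reference
#' samples (a = 0, c = delta), plus one held-out reference.  The empirical
#' sJSD null pools all three pairwise comparisons among the matched
#' reference samples, so its granularity reflects every available
#' replicate pair.  Sensitivity is assessed on the three matched
#' test/reference comparisons, specificity on the three comparisons of
#' the held-out reference against each matched reference; all six run the
#' identical DMR pipeline (smoothing, shared empirical null, BY-FDR,
#' morphological closing).
#'
#' Sensitivity is the fraction of modeled island GUs falling inside a
#' detected DMR, averaged over the test/reference comparisons;
#' specificity is the fraction of modeled GUs not falling inside any
#' detected DMR, averaged over the reference/reference comparisons.
#'
#' @param delta coupling difference between reference and test.
#' @param config a [simulationConfig()].
#' @param seed master seed.
#' @param bandwidth smoothing bandwidth in bp (the genome-scale default of
#'   50 kb targets large DMRs; for 3-kb features use 1 kb).
#' @param fdrLevel BY FDR level.
#' @param optConfig an [optimizerConfig()].
#' @return list with `sensitivity`, `specificity` (averages),
#'   `perComparison` (per-comparison rates), `nIslandGUs`, `nNullGUs`,
#'   the `detectDMRs()` results (`sens`, `spec`, lists of 3) and the
#'   island table.
#' @export
runSimulationStudy <- function(delta, config = simulationConfig(),
                               seed = 1L, bandwidth = 1000,
                               fdrLevel = 0.01,
                               optConfig = optimizerConfig()) {
  sim <- simulateLayout(config)
  sampleGUs <- function(c_value, subseed) {
    reads <- simulateReads(sim, config, a = 0, c = c_value, seed = subseed)
    obsList <- observationsByRegion(reads, sim$layout, sim$partition)
    analyzeSample(sim$layout, sim$partition, obsList, optConfig,
                  seed = subseed)$gus
  }
  base <- as.integer(seed) %% 100000L
  tests <- lapply(1:3, function(i) sampleGUs(0, base * 10L + i))
  refs <- lapply(4:7, function(i) sampleGUs(delta, base * 10L + i))

  sjsdOf <- function(g1, g2) {
    d <- differentialStatistics(g1, g2)
    smoothJSD((d$start + d$end) / 2, d$jsd, bandwidth)
  }
  # pooled null: all pairs among the three matched reference samples
  nullValues <- c(sjsdOf(refs[[1]], refs[[2]]),
                  sjsdOf(refs[[1]], refs[[3]]),
                  sjsdOf(refs[[2]], refs[[3]]))
  null <- empiricalNull(nullValues)

  sens <- lapply(1:3, function(i)
    detectDMRs(differentialStatistics(tests[[i]], refs[[i]]), null = null,
               bandwidth = bandwidth, fdrLevel = fdrLevel))
  spec <- lapply(1:3, function(i)
    detectDMRs(differentialStatistics(refs[[4]], refs[[i]]), null = null,
               bandwidth = bandwidth, fdrLevel = fdrLevel))

  inDMR <- function(gus, dmrs) {
    if (nrow(dmrs) == 0L) return(rep(FALSE, nrow(gus)))
    hit <- rep(FALSE, nrow(gus))
    for (i in seq_len(nrow(dmrs)))
      hit <- hit | (gus$start >= dmrs$start[i] & gus$end <= dmrs$end[i])
    hit
  }
  inIsland <- function(gus) {
    hit <- rep(FALSE, nrow(gus))
    for (i in seq_len(nrow(sim$islands)))
      hit <- hit | (gus$end >= sim$islands$start[i] &
                    gus$start <= sim$islands$end[i])
    hit
  }
  sensRates <- vapply(sens, function(s) {
    island <- inIsland(s$gus)
    mean(inDMR(s$gus, s$dmrs)[island])
  }, numeric(1))
  specRates <- vapply(spec, function(s)
    mean(!inDMR(s$gus, s$dmrs)), numeric(1))

  list(sensitivity = mean(sensRates), specificity = mean(specRates),
       perComparison = list(sensitivity = sensRates,
                            specificity = specRates),
       nIslandGUs = sum(vapply(sens, function(s)
         sum(inIsland(s$gus)), numeric(1))),
       nNullGUs = sum(vapply(spec, function(s) nrow(s$gus), numeric(1))),
       sens = sens, spec = spec, islands = sim$islands)
}
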