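#' @useDynLib methylIsing, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats optim pnorm qnorm dnorm p.adjust pchisq runif ksmooth
#'   setNames complete.cases
#' @importFrom utils read.table write.table
NULL

#' CpGLayout: CpG coordinates and local context of one chromosome
#'
#' Holds the 1-based coordinates of the cytosines of all CpG dinucleotides
#' on a chromosome, together with the per-site CpG density \eqn{\rho_n}
#' (number of CpG sites within +/- 500 bp of site n, divided by 1000) and
#' the distance \eqn{d_n} (bp) of each site from its predecessor.
#'
#' @slot chrom chromosome name.
#' @slot chromLength chromosome length in bp.
#' @slot positions strictly increasing integer coordinates (1-based) of the
#'   C of each CpG.
#' @slot rho per-site CpG density, in (0, 1].
#' @slot dist per-site distance in bp from the previous CpG; `NA` for the
#'   first site.
#' @export
setClass("CpGLayout",
  representation(
    chrom = "character",
    chromLength = "integer",
    positions = "integer",
    rho = "numeric",
    dist = "numeric"
  )
)

setValidity("CpGLayout", function(object) {
  p <- object@positions
  msgs <- character()
  if (length(object@chrom) != 1L) msgs <- c(msgs, "chrom must be a scalar")
  if (length(p) > 1L && any(diff(p) <= 0L))
    msgs <- c(msgs, "positions must be strictly increasing")
  if (length(p) > 1L && any(diff(p) < 2L))
    msgs <- c(msgs, "CpG sites cannot overlap (spacing >= 2 bp)")
  if (length(object@rho) != length(p) || (length(p) && any(object@rho <= 0)))
    msgs <- c(msgs, "rho must be positive and one value per site")
  if (length(object@dist) != length(p))
    msgs <- c(msgs, "dist must have one value per site")
  if (length(msgs)) msgs else TRUE
})

#' RegionPartition: tiling of a chromosome into estimation regions and GUs
#'
#' Regions (default 3 kb) are the units of Ising parameter estimation;
#' each region is subdivided into genomic units (GUs, default 150 bp), the
#' resolution at which all methylation statistics are reported.  Tiling is
#' anchored at coordinate 1; the trailing partial region is kept.
#'
#' @slot regionSize region length in bp.
#' @slot guSize GU length in bp.
#' @slot regionStart,regionEnd 1-based closed region intervals.
#' @slot regionFirstSite,regionLastSite indices (into the layout) of the
#'   first/last CpG site in each region; `NA` when the region has none.
#' @slot guStart,guEnd 1-based closed GU intervals.
#' @slot guRegion index of the region containing each GU.
#' @slot guFirstSite,guLastSite CpG site index range of each GU (`NA` if
#'   CpG-free).
#' @export
setClass("RegionPartition",
  representation(
    regionSize = "integer",
    guSize = "integer",
    regionStart = "integer",
    regionEnd = "integer",
    regionFirstSite = "integer",
    regionLastSite = "integer",
    guStart = "integer",
    guEnd = "integer",
    guRegion = "integer",
    guFirstSite = "integer",
    guLastSite = "integer"
  )
)

#' RegionModel: the Ising distribution of one estimation region
#'
#' The five region parameters theta = (alpha', alpha, alpha'', beta, gamma)
#' determine the per-site external fields a_n and the nearest-neighbour
#' couplings c_n: a_1 = alpha' + beta*rho_1 and a_R = alpha'' + beta*rho_R
#' at the region boundaries, a_n = alpha + beta*rho_n in the interior, and
#' c_n = gamma / d_n for n >= 2.
#'
#' @slot theta named numeric vector (alpha_p, alpha, alpha_pp, beta, gamma).
#' @slot a per-site external field.
#' @slot c per-pair coupling; `NA` in position 1.
#' @export
setClass("RegionModel",
  representation(theta = "numeric", a = "numeric", c = "numeric")
)

setValidity("RegionModel", function(object) {
  msgs <- character()
  R <- length(object@a)
  if (R < 1L) msgs <- c(msgs, "region must contain at least one CpG site")
  if (length(object@c) != R) msgs <- c(msgs, "a and c must have equal length")
  if (!all(is.finite(object@a))) msgs <- c(msgs, "fields a must be finite")
  if (R > 1L && !all(is.finite(object@c[-1L])))
    msgs <- c(msgs, "couplings c must be finite")
  if (length(msgs)) msgs else TRUE
})

#' LevelPMF: distribution of the methylation level of a genomic unit
#'
#' The methylation level of a GU with K CpG sites is L = (1/K) sum X_k,
#' supported on {0, 1/K, ..., 1}.
#'
#' @slot K number of CpG sites.
#' @slot p probabilities over the K + 1 levels.
#' @export
setClass("LevelPMF", representation(K = "integer", p = "numeric"))

setValidity("LevelPMF", function(object) {
  msgs <- character()
  if (length(object@p) != object@K + 1L)
    msgs <- c(msgs, "p must have K + 1 entries")
  if (any(object@p < -1e-12)) msgs <- c(msgs, "probabilities must be >= 0")
  if (abs(sum(object@p) - 1) > 1e-9) msgs <- c(msgs, "p must sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' ObservationMatrix: partial methylation observations of one region
#'
#' Stores M reads in compressed sparse row layout: read m observes entries
#' `ptr[m]+1 .. ptr[m+1]` of `sites` (1-based CpG index within the region,
#' ascending within a read) and `states` (0 = unmethylated, 1 = methylated).
#'
#' @slot ptr integer vector of length M + 1 with 0-based read offsets.
#' @slot sites CpG site indices within the region.
#' @slot states observed binary states.
#' @export
setClass("ObservationMatrix",
  representation(ptr = "integer", sites = "integer", states = "integer")
)

setValidity("ObservationMatrix", function(object) {
  msgs <- character()
  M <- length(object@ptr) - 1L
  if (M < 0L) msgs <- c(msgs, "ptr must have at least one entry")
  if (length(object@sites) != length(object@states))
    msgs <- c(msgs, "sites and states must have equal length")
  if (length(object@ptr) && object@ptr[length(object@ptr)] != length(object@sites))
    msgs <- c(msgs, "ptr must end at the number of records")
  if (M > 0L && any(diff(object@ptr) < 1L))
    msgs <- c(msgs, "each read must observe at least one site")
  if (length(object@states) && !all(object@states %in% c(0L, 1L)))
    msgs <- c(msgs, "states must be 0/1")
  # duplicate (read, site) pairs forbidden; sites ascending within read
  if (M > 0L) {
    for (m in seq_len(M)) {
      idx <- (object@ptr[m] + 1L):object@ptr[m + 1L]
      if (length(idx) > 1L && any(diff(object@sites[idx]) <= 0L)) {
        msgs <- c(msgs, "sites must be strictly ascending within each read")
        break
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

## ---- accessors & show ------------------------------------------------------

#' @describeIn CpGLayout-class number of CpG sites
#' @param x,object a `CpGLayout`
#' @export
nSites <- function(x) length(x@positions)

#' @describeIn CpGLayout-class CpG coordinates
#' @export
cpgPositions <- function(x) x@positions

#' @describeIn CpGLayout-class per-site density rho
#' @export
cpgDensity <- function(x) x@rho

#' @describeIn CpGLayout-class per-site distance d
#' @export
cpgDistances <- function(x) x@dist

#' Number of reads in an ObservationMatrix
#' @param x an `ObservationMatrix`
#' @export
nReads <- function(x) length(x@ptr) - 1L

#' Number of regions / GUs in a partition
#' @param x a `RegionPartition`
#' @export
nRegions <- function(x) length(x@regionStart)

#' @rdname nRegions
#' @export
nGUs <- function(x) length(x@guStart)

#' Levels of a LevelPMF (k/K)
#' @param x a `LevelPMF`
#' @export
pmfLevels <- function(x) seq(0L, x@K) / x@K

#' Probabilities of a LevelPMF
#' @param x a `LevelPMF`
#' @export
pmfProbs <- function(x) x@p

setMethod("show", "CpGLayout", function(object) {
  cat("CpGLayout on", object@chrom, "(", object@chromLength, "bp ):",
      length(object@positions), "CpG sites\n")
})

setMethod("show", "RegionPartition", function(object) {
  cat("RegionPartition:", length(object@regionStart), "regions of",
      object@regionSize, "bp;", length(object@guStart), "GUs of",
      object@guSize, "bp\n")
})

setMethod("show", "RegionModel", function(object) {
  cat("RegionModel with", length(object@a), "CpG sites\n")
  cat("  theta:", paste(sprintf("%s=%.4g", names(object@theta), object@theta),
                        collapse = ", "), "\n")
})

setMethod("show", "ObservationMatrix", function(object) {
  cat("ObservationMatrix:", nReads(object), "reads,",
      length(object@sites), "site observations\n")
})

setMethod("show", "LevelPMF", function(object) {
  cat("LevelPMF over", object@K + 1L, "levels; mean =",
      format(sum(pmfLevels(object) * object@p), digits = 6), "\n")
})
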