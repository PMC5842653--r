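## Genome layout: CpG coordinates, density, distances and the region/GU
## partition.  Coordinates are 1-based closed internally; emitted tracks use
## the 0-based half-open bedGraph convention (see io.R).

#' Locate CpG sites in a nucleotide sequence
#'
#' Scans a sequence for CG dinucleotides (case-insensitive) and returns the
#' 1-based coordinate of the C of each. N bases never form CpGs, and no
#' strand handling is needed: a CpG is palindromic, so one site per CG
#' dinucleotide with the C-coordinate convention covers both strands.
#'
#' @param sequence a character string or [Biostrings::DNAString] over
#'   `{A,C,G,T,N}` (case-insensitive).
#' @return integer vector of CpG positions (possibly empty).
#' @export
scanCpGSites <- function(sequence) {
  if (is.character(sequence)) {
    if (length(sequence) != 1L) stop("sequence must be a single string")
    if (nchar(sequence) == 0L) return(integer())
    sequence <- Biostrings::DNAString(toupper(sequence))
  }
  if (length(sequence) < 2L) return(integer())
  m <- Biostrings::matchPattern("CG", sequence)
  as.integer(BiocGenerics::start(m))
}

#' Per-site CpG density
#'
#' The density of CpG site n is the number of CpG sites within
#' `windowHalfwidth` bp downstream and upstream of it (the site itself
#' included), divided by 1000.  Self-inclusion keeps the density strictly
#' positive, so the density term of the field parameterization is always
#' well defined.
#'
#' @param positions sorted CpG coordinates.
#' @param windowHalfwidth half-width of the counting window in bp.
#' @return numeric vector of densities in (0, 1].
#' @export
computeCpGDensity <- function(positions, windowHalfwidth = 500) {
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  n <- length(positions)
  if (n == 0L) return(numeric())
  lo <- findInterval(positions - windowHalfwidth - 0.5, positions) + 1L
  hi <- findInterval(positions + windowHalfwidth + 0.5 - 1e-9, positions)
  (hi - lo + 1L) / 1000
}

#' Per-site CpG distances
#'
#' Distance d_n (bp) between the cytosines of CpG sites n and n - 1;
#' `NA` for the first site.
#'
#' @param positions sorted CpG coordinates (length >= 1).
#' @export
computeCpGDistances <- function(positions) {
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  if (length(positions) == 0L) return(numeric())
  c(NA_real_, diff(positions))
}

#' Build a CpGLayout from a sequence or precomputed positions
#'
#' @param chrom chromosome name.
#' @param sequence nucleotide sequence (string or `DNAString`); ignored when
#'   `positions` is given.
#' @param positions optional precomputed CpG coordinates.
#' @param chromLength chromosome length; defaults to the sequence length or
#'   the last CpG coordinate + 1.
#' @param windowHalfwidth density window half-width in bp.
#' @return a [CpGLayout-class] object.
#' @export
buildCpGLayout <- function(chrom, sequence = NULL, positions = NULL,
                           chromLength = NULL, windowHalfwidth = 500) {
  if (is.null(positions)) {
    if (is.null(sequence)) stop("supply either sequence or positions")
    positions <- scanCpGSites(sequence)
    if (is.null(chromLength)) {
      chromLength <- if (is.character(sequence)) nchar(sequence)
                     else length(sequence)
    }
  }
  positions <- as.integer(positions)
  if (is.null(chromLength)) {
    chromLength <- if (length(positions)) max(positions) + 1L else 0L
  }
  new("CpGLayout",
      chrom = as.character(chrom),
      chromLength = as.integer(chromLength),
      positions = positions,
      rho = computeCpGDensity(positions, windowHalfwidth),
      dist = computeCpGDistances(positions))
}

#' Read a multi-record FASTA into CpGLayouts
#'
#' @param path FASTA file (gzip allowed).
#' @return named list of [CpGLayout-class] objects, one per record.
#' @export
layoutFromFasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  out <- lapply(seq_along(seqs), function(i)
    buildCpGLayout(nm[i], sequence = seqs[[i]]))
  names(out) <- nm
  out
}

#' Partition a chromosome into estimation regions and genomic units
#'
#' Tiles `[1, chromLength]` with non-overlapping regions of `regionSize` bp
#' anchored at coordinate 1, each subdivided into GUs of `guSize` bp.  A CpG
#' at a tile's right boundary belongs to that tile (closed intervals); the
#' trailing partial region is kept.
#'
#' @param chromLength chromosome length in bp.
#' @param layout a [CpGLayout-class].
#' @param regionSize,guSize tile sizes in bp; `regionSize` must be divisible
#'   by `guSize`.
#' @return a [RegionPartition-class].
#' @export
partitionGenome <- function(chromLength, layout, regionSize = 3000,
                            guSize = 150) {
  regionSize <- as.integer(regionSize); guSize <- as.integer(guSize)
  if (regionSize %% guSize != 0L)
    stop("regionSize must be divisible by guSize")
  chromLength <- as.integer(chromLength)
  if (chromLength < 1L) stop("chromLength must be positive")
  nReg <- as.integer(ceiling(chromLength / regionSize))
  regStart <- (seq_len(nReg) - 1L) * regionSize + 1L
  regEnd <- pmin(seq_len(nReg) * regionSize, chromLength)
  nGU <- as.integer(ceiling(chromLength / guSize))
  guStart <- (seq_len(nGU) - 1L) * guSize + 1L
  guEnd <- pmin(seq_len(nGU) * guSize, chromLength)
  guRegion <- ((guStart - 1L) %/% regionSize) + 1L

  pos <- cpgPositions(layout)
  siteRange <- function(starts, ends) {
    # first/last CpG index within each closed interval
    first <- findInterval(starts - 0.5, pos) + 1L
    last <- findInterval(ends + 0.5 - 1e-9, pos)
    empty <- first > last
    first[empty] <- NA_integer_; last[empty] <- NA_integer_
    list(first = as.integer(first), last = as.integer(last))
  }
  rs <- siteRange(regStart, regEnd)
  gs <- siteRange(guStart, guEnd)

  new("RegionPartition",
      regionSize = regionSize, guSize = guSize,
      regionStart = regStart, regionEnd = regEnd,
      regionFirstSite = rs$first, regionLastSite = rs$last,
      guStart = guStart, guEnd = guEnd, guRegion = guRegion,
      guFirstSite = gs$first, guLastSite = gs$last)
}

#' Layout slice of one region
#'
#' Extracts the per-site density and distance vectors of the CpG sites of
#' one estimation region.  The distance of the region's first site refers
#' to a CpG outside the region and is reset to `NA`: couplings are only
#' defined within a region (regions are modeled independently).
#'
#' @param layout a [CpGLayout-class].
#' @param partition a [RegionPartition-class].
#' @param region region index.
#' @return list with `sites`, `positions`, `rho`, `dist` or `NULL` when the
#'   region holds no CpG.
#' @export
regionSlice <- function(layout, partition, region) {
  first <- partition@regionFirstSite[region]
  if (is.na(first)) return(NULL)
  last <- partition@regionLastSite[region]
  idx <- first:last
  d <- layout@dist[idx]
  d[1L] <- NA_real_
  list(sites = idx, positions = layout@positions[idx],
       rho = layout@rho[idx], dist = d)
}

#' Persist / load a layout as TSV (chrom, pos, rho, dist)
#' @param layout a [CpGLayout-class]
#' @param path file path
#' @export
writeLayoutTSV <- function(layout, path) {
  df <- data.frame(chrom = layout@chrom, pos = layout@positions,
                   rho = layout@rho, dist = layout@dist)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLayoutTSV
#' @param chromLength chromosome length (TSV stores only sites)
#' @export
readLayoutTSV <- function(path, chromLength = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE)
  stopifnot(all(c("chrom", "pos", "rho", "dist") %in% names(df)))
  if (is.null(chromLength)) chromLength <- max(df$pos) + 1L
  new("CpGLayout", chrom = as.character(df$chrom[1L]),
      chromLength = as.integer(chromLength),
      positions = as.integer(df$pos), rho = df$rho, dist = df$dist)
}
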