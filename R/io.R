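## File formats: the observation TSV dialect, bedGraph/BED track output,
## and model parameter tables.  GU intervals are 1-based closed internally
## and emitted as 0-based half-open records (bedGraph/BED standard), so GU
## [1, 150] becomes "chrom 0 150".

#' Group observation records into per-region ObservationMatrix objects
#'
#' Maps each record's CpG coordinate to the layout (unknown positions are
#' an error), assigns it to an estimation region, and groups records by
#' (read, region).  Reads overlapping two regions are split at the region
#' boundary, each fragment contributing to its own region, consistent with
#' regions being modeled independently.
#'
#' @param records data.frame with columns `read_id`, `cpg_pos`, `state`.
#' @param layout a [CpGLayout-class].
#' @param partition a [RegionPartition-class].
#' @return list of [ObservationMatrix-class], one entry per region (empty
#'   observation for regions without records).
#' @export
observationsByRegion <- function(records, layout, partition) {
  pos <- cpgPositions(layout)
  gsite <- match(records$cpg_pos, pos)
  if (anyNA(gsite)) {
    bad <- which(is.na(gsite))[1L]
    stop("record ", bad, ": position ", records$cpg_pos[bad],
         " is not a CpG site of the layout")
  }
  if (!all(records$state %in% c(0L, 1L))) {
    bad <- which(!(records$state %in% c(0L, 1L)))[1L]
    stop("record ", bad, ": state must be 0 or 1, got ",
         records$state[bad])
  }
  region <- findInterval(pos[gsite], partition@regionStart)
  local <- gsite - partition@regionFirstSite[region] + 1L
  key <- region * (max(records$read_id) + 1) + records$read_id
  if (anyDuplicated(as.numeric(records$read_id) * (length(pos) + 1) + gsite))
    stop("duplicate (read, site) observation")
  ord <- order(region, records$read_id, local)
  region <- region[ord]; local <- local[ord]
  state <- as.integer(records$state)[ord]
  key <- key[ord]
  readBreaks <- c(TRUE, diff(key) != 0)
  readLens <- diff(c(which(readBreaks), length(key) + 1L))
  readRegion <- region[readBreaks]
  out <- vector("list", nRegions(partition))
  regReadCounts <- tabulate(readRegion, nRegions(partition))
  regRecCounts <- tabulate(region, nRegions(partition))
  recOff <- cumsum(c(0L, regRecCounts))
  readOff <- cumsum(c(0L, regReadCounts))
  for (rg in seq_len(nRegions(partition))) {
    if (regRecCounts[rg] == 0L) {
      out[[rg]] <- new("ObservationMatrix", ptr = 0L, sites = integer(),
                       states = integer())
      next
    }
    ridx <- (recOff[rg] + 1L):recOff[rg + 1L]
    lens <- readLens[(readOff[rg] + 1L):readOff[rg + 1L]]
    out[[rg]] <- new("ObservationMatrix",
                     ptr = as.integer(c(0L, cumsum(lens))),
                     sites = local[ridx], states = state[ridx])
  }
  out
}

#' Read the observation TSV dialect
#'
#' Columns: `chrom`, `read_id`, `cpg_pos`, `state` (0/1).  Malformed
#' states and positions not present in the layout are hard errors with the
#' offending record reported.
#'
#' @param path TSV path.
#' @param layout a [CpGLayout-class] (single chromosome).
#' @param partition a [RegionPartition-class].
#' @return list of per-region [ObservationMatrix-class] objects.
#' @export
readObservations <- function(path, layout, partition) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "integer", "integer",
                                  "integer"))
  stopifnot(all(c("chrom", "read_id", "cpg_pos", "state") %in% names(df)))
  df <- df[df$chrom == layout@chrom, , drop = FALSE]
  observationsByRegion(df, layout, partition)
}

#' @rdname readObservations
#' @param records observation data.frame to persist.
#' @export
writeObservations <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a bedGraph track
#'
#' One line per record: `chrom  start0  end  value` with values printed to
#' 6 decimals.  Input intervals are 1-based closed and must be sorted and
#' non-overlapping.
#'
#' @param chrom chromosome name (scalar or vector).
#' @param start,end 1-based closed intervals.
#' @param value numeric track values.
#' @param path output file.
#' @param trackName optional bedGraph track header name.
#' @export
writeBedGraph <- function(chrom, start, end, value, path,
                          trackName = NULL) {
  if (is.unsorted(start)) stop("records must be sorted")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(trackName))
    writeLines(sprintf("track type=bedGraph name=\"%s\"", trackName), con)
  if (length(start))
    writeLines(sprintf("%s\t%d\t%d\t%.6f", chrom, as.integer(start) - 1L,
                       as.integer(end), value), con)
  invisible(path)
}

#' Read a bedGraph track written by [writeBedGraph()]
#' @param path bedGraph file.
#' @return data.frame `chrom`, `start` (1-based), `end`, `value`.
#' @export
readBedGraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track")]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  df <- read.table(text = lines, sep = "\t",
                   col.names = c("chrom", "start", "end", "value"))
  df$start <- df$start + 1L
  df
}

#' Write intervals as BED
#'
#' BED6 with `name` and `score`; BED scores are capped at 1000, with the
#' uncapped score carried in column 7.
#'
#' @param chrom,start,end 1-based closed intervals.
#' @param name feature names (e.g. DMR rank or class label).
#' @param score numeric scores (optional).
#' @param path output file.
#' @export
writeBed <- function(chrom, start, end, name, score = NULL, path) {
  if (is.unsorted(start)) stop("records must be sorted")
  con <- file(path, "w")
  on.exit(close(con))
  if (length(start)) {
    if (is.null(score)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", chrom, as.integer(start) - 1L,
                         as.integer(end), name), con)
    } else {
      writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.\t%.3f", chrom,
                         as.integer(start) - 1L, as.integer(end), name,
                         as.integer(pmin(round(score), 1000)), score), con)
    }
  }
  invisible(path)
}

#' Persist fitted region parameters as TSV
#'
#' Columns: chrom, region_start, region_end, alpha_p, alpha, alpha_pp,
#' beta, gamma, loglik, status.
#'
#' @param layout a [CpGLayout-class].
#' @param partition a [RegionPartition-class].
#' @param fits per-region fit list.
#' @param path output TSV.
#' @export
writeModelsTSV <- function(layout, partition, fits, path) {
  rows <- lapply(seq_along(fits), function(rg) {
    f <- fits[[rg]]
    if (is.null(f)) return(NULL)
    th <- if (!is.null(f$theta) && length(f$theta) == 5L) f$theta else
      rep(NA_real_, 5L)
    data.frame(chrom = layout@chrom,
               region_start = partition@regionStart[rg],
               region_end = partition@regionEnd[rg],
               alpha_p = th[1L], alpha = th[2L], alpha_pp = th[3L],
               beta = th[4L], gamma = th[5L],
               loglik = f$loglik, status = f$status)
  })
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rebuild per-region fits from a model TSV
#'
#' Inverse of [writeModelsTSV()]: reconstructs each fitted region's
#' [RegionModel-class] from its stored parameters and the layout.
#'
#' @param path model TSV.
#' @param layout a [CpGLayout-class].
#' @param partition the matching [RegionPartition-class].
#' @return per-region fit list usable by [guStatistics()].
#' @export
readModelsTSV <- function(path, layout, partition) {
  df <- read.table(path, sep = "\t", header = TRUE)
  fits <- vector("list", nRegions(partition))
  for (i in seq_len(nrow(df))) {
    rg <- match(df$region_start[i], partition@regionStart)
    if (is.na(rg)) stop("model row ", i, " does not match the partition")
    if (df$status[i] != "fitted") {
      fits[[rg]] <- list(theta = NULL, loglik = df$loglik[i],
                         nParams = 5L, model = NULL, status = df$status[i])
      next
    }
    slice <- regionSlice(layout, partition, rg)
    theta <- c(df$alpha_p[i], df$alpha[i], df$alpha_pp[i], df$beta[i],
               df$gamma[i])
    fits[[rg]] <- list(theta = theta, loglik = df$loglik[i], nParams = 5L,
                       model = buildPotentials(theta, slice$rho,
                                               slice$dist),
                       status = "fitted")
  }
  for (rg in seq_len(nRegions(partition))) {
    if (is.null(fits[[rg]]))
      fits[[rg]] <- list(theta = NULL, loglik = NA_real_, nParams = 5L,
                         model = NULL, status = "skipped(absent)")
  }
  fits
}
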