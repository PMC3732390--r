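#' Construct a peak set
#'
#' A `peak_set` is the atomic container of the package: a data frame of
#' TF-bound regions (TFBRs) for one transcription factor in one species and
#' one experimental condition.  Coordinates are 0-based half-open (BED
#' convention); the summit is an absolute base position with
#' `start <= summit < end`; the intensity is a non-negative ChIP enrichment
#' score in arbitrary units (untransformed at I/O time -- all log transforms
#' happen downstream).
#'
#' @param records data.frame with columns `chrom`, `start`, `end`, `summit`,
#'   `intensity` and optionally `locus_id` (filled with `NA` if absent).
#' @param species species identifier, e.g. `"C57BL6J"`.
#' @param tf transcription factor identifier, one of
#'   `"CEBPA"`, `"HNF4A"`, `"FOXA1"`, `"CTCF"`.
#' @param condition experimental condition, e.g. `"WT"`, `"replicate1"`,
#'   `"replicate2"`, `"pooled"`, `"Inter-pool"`, `"KO_CEBPA"`, `"KO_HNF4A"`.
#' @return A data.frame of class `peak_set` with attributes `species`, `tf`
#'   and `condition`.
#' @export
peak_set <- function(records, species, tf, condition = "pooled") {
  if (is.null(records) || nrow(records) == 0L) {
    records <- data.frame(chrom = character(), start = integer(),
                          end = integer(), summit = integer(),
                          intensity = numeric(), locus_id = character(),
                          stringsAsFactors = FALSE)
  }
  needed <- c("chrom", "start", "end", "summit", "intensity")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("peak_set records lack column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"locus_id" %in% names(records))
    records$locus_id <- rep(NA_character_, nrow(records))
  records <- records[, c("chrom", "start", "end", "summit", "intensity",
                         "locus_id")]
  records$chrom <- as.character(records$chrom)
  records$start <- as.integer(records$start)
  records$end <- as.integer(records$end)
  records$summit <- as.integer(records$summit)
  records$intensity <- as.numeric(records$intensity)
  records$locus_id <- as.character(records$locus_id)
  if (nrow(records)) {
    if (any(!nzchar(records$chrom)))
      stop("empty chromosome name in peak records")
    if (any(records$start < 0L) || any(records$start >= records$end))
      stop("invalid interval: require 0 <= start < end")
    bad <- records$summit < records$start | records$summit >= records$end
    if (any(bad))
      stop("summit outside interval for ", sum(bad), " record(s)")
    if (any(records$intensity < 0))
      stop("negative intensity")
    key <- paste(records$chrom, records$start, records$end)
    if (anyDuplicated(key))
      stop("duplicate (chrom,start,end) records in peak set")
  }
  rownames(records) <- NULL
  structure(records,
            species = as.character(species),
            tf = as.character(tf),
            condition = as.character(condition),
            class = c("peak_set", "data.frame"))
}

#' @export
as.data.frame.peak_set <- function(x, ...) {
  attr(x, "species") <- attr(x, "tf") <- attr(x, "condition") <- NULL
  class(x) <- "data.frame"
  x
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %d record(s) | species=%s tf=%s condition=%s\n",
              nrow(x), attr(x, "species"), attr(x, "tf"),
              attr(x, "condition")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

ps_species   <- function(x) attr(x, "species")
ps_tf        <- function(x) attr(x, "tf")
ps_condition <- function(x) attr(x, "condition")

#' Convert a peak set to a GRanges
#'
#' Internal coordinates are 0-based half-open; GRanges is 1-based closed, so
#' `start` is shifted by one.
#' @param x a `peak_set` or plain data.frame with `chrom`/`start`/`end`.
#' @return a `GRanges` with one range per record.
#' @keywords internal
peaks_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
}

# findOverlaps without the seqlevel-mismatch chatter (disjoint chromosome
# sets between query and subject are an expected, answerable situation)
find_overlaps <- function(...) {
  suppressWarnings(GenomicRanges::findOverlaps(...))
}

#' Read a peak file
#'
#' Supports ENCODE narrowPeak (BED6+4, 10 tab-separated columns) and BED6.
#' For narrowPeak the summit is `start + peak offset` (column 10); if the
#' offset is -1, or for BED6, the interval midpoint is used.  Intensity is
#' the signalValue column (narrowPeak) or the score column (BED6).
#'
#' @param path file path.
#' @param dialect `"narrowPeak"` or `"bed6"`.
#' @param species,tf,condition metadata attached to the returned set.
#' @return a [peak_set].
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "bed6"),
                       species = "unknown", tf = "unknown",
                       condition = "pooled") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(peak_set(NULL, species, tf, condition))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_expect <- if (dialect == "narrowPeak") 10L else 6L
  nf <- lengths(fields)
  if (any(nf != ncol_expect)) {
    i <- which(nf != ncol_expect)[1L]
    stop(sprintf("%s line %d: expected %d tab-separated columns, found %d",
                 path, i, ncol_expect, nf[i]))
  }
  m <- matrix(unlist(fields), ncol = ncol_expect, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("%s line %d: non-integer coordinates", path, bad[1L]))
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("%s line %d: start >= end", path, bad[1L]))
  name <- m[, 4L]
  name[name == "."] <- NA_character_
  if (dialect == "narrowPeak") {
    intensity <- suppressWarnings(as.numeric(m[, 7L]))
    offset <- suppressWarnings(as.integer(m[, 10L]))
    bad <- which(is.na(intensity) | is.na(offset))
    if (length(bad))
      stop(sprintf("%s line %d: non-numeric signalValue or peak offset",
                   path, bad[1L]))
    summit <- ifelse(offset >= 0L, start + offset,
                     start + (end - start) %/% 2L)
  } else {
    intensity <- suppressWarnings(as.numeric(m[, 5L]))
    bad <- which(is.na(intensity))
    if (length(bad))
      stop(sprintf("%s line %d: non-numeric score", path, bad[1L]))
    summit <- start + (end - start) %/% 2L
  }
  peak_set(data.frame(chrom = m[, 1L], start = start, end = end,
                      summit = as.integer(summit), intensity = intensity,
                      locus_id = name, stringsAsFactors = FALSE),
           species, tf, condition)
}

#' Write a peak set
#'
#' Writes the canonical form read back unchanged by [read_peaks]:
#' narrowPeak with score 0, strand ".", pValue/qValue -1, and summit encoded
#' as the peak-offset column; or BED6 with the intensity in the score column.
#' Numeric intensities are printed with `%g`.
#'
#' @param x a [peak_set].
#' @param path output path.
#' @param dialect `"narrowPeak"` or `"bed6"`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(x, path, dialect = c("narrowPeak", "bed6")) {
  dialect <- match.arg(dialect)
  name <- ifelse(is.na(x$locus_id), ".", x$locus_id)
  if (dialect == "narrowPeak") {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t.\t%g\t-1\t-1\t%d",
                     x$chrom, x$start, x$end, name, x$intensity,
                     x$summit - x$start)
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s\t%g\t.",
                     x$chrom, x$start, x$end, name, x$intensity)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Define TF-bound regions (TFBRs) from replicates and a pooled sample
#'
#' A TFBR is a pooled-sample peak supported by both biological replicates:
#' the returned set contains exactly those pooled records overlapped by at
#' least `min_overlap_bp` bases by at least one record in `rep1` AND at
#' least one in `rep2`.  Coordinates, summit and intensity are taken from
#' the pooled record.  This reproducible-peak filter removes the lowest
#' intensity and sporadic binding sites.
#'
#' @param rep1,rep2 replicate [peak_set]s.
#' @param pooled pooled-sample [peak_set].
#' @param min_overlap_bp minimum overlap in bases (default 1).
#' @return a [peak_set] with condition `"Inter-pool"`.
#' @export
define_tfbrs <- function(rep1, rep2, pooled, min_overlap_bp = 1L) {
  if (min_overlap_bp < 1L) stop("min_overlap_bp must be >= 1")
  for (r in list(rep1, rep2)) {
    if (!identical(ps_species(r), ps_species(pooled)) ||
        !identical(ps_tf(r), ps_tf(pooled)))
      stop("replicate and pooled peak sets must share species and tf")
  }
  if (nrow(pooled) == 0L)
    return(peak_set(NULL, ps_species(pooled), ps_tf(pooled), "Inter-pool"))
  gp <- peaks_granges(pooled)
  hit <- function(rep) {
    if (nrow(rep) == 0L) return(logical(nrow(pooled)))
    ov <- find_overlaps(gp, peaks_granges(rep),
                                      minoverlap = min_overlap_bp)
    seq_len(nrow(pooled)) %in% S4Vectors::queryHits(ov)
  }
  keep <- hit(rep1) & hit(rep2)
  peak_set(as.data.frame(pooled)[keep, , drop = FALSE],
           ps_species(pooled), ps_tf(pooled), "Inter-pool")
}
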