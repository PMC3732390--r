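#' Construct an orthology map
#'
#' Colinear coordinate blocks between two genomes, the carrier of all
#' cross-species projection.  Each block maps a source interval onto a
#' target interval of identical length, either preserving (`+`) or
#' reversing (`-`) orientation.  Blocks must be non-overlapping on both
#' genomes, which makes block-wise projection invertible.
#'
#' @param blocks data.frame with columns `src_chrom`, `src_start`,
#'   `src_end`, `tgt_chrom`, `tgt_start`, `tgt_end`, `strand` (`+`/`-`).
#'   Coordinates 0-based half-open.
#' @param source_species,target_species species identifiers.
#' @return a data.frame of class `orthology_map`.
#' @export
orthology_map <- function(blocks, source_species, target_species) {
  needed <- c("src_chrom", "src_start", "src_end",
              "tgt_chrom", "tgt_start", "tgt_end", "strand")
  if (length(setdiff(needed, names(blocks))))
    stop("orthology blocks lack column(s): ",
         paste(setdiff(needed, names(blocks)), collapse = ", "))
  blocks <- blocks[, needed]
  for (col in c("src_start", "src_end", "tgt_start", "tgt_end"))
    blocks[[col]] <- as.integer(blocks[[col]])
  blocks$src_chrom <- as.character(blocks$src_chrom)
  blocks$tgt_chrom <- as.character(blocks$tgt_chrom)
  blocks$strand <- as.character(blocks$strand)
  if (nrow(blocks)) {
    if (any(!blocks$strand %in% c("+", "-")))
      stop("block strand must be '+' or '-'")
    src_len <- blocks$src_end - blocks$src_start
    tgt_len <- blocks$tgt_end - blocks$tgt_start
    if (any(src_len <= 0L) || any(tgt_len <= 0L))
      stop("blocks must have positive length")
    if (any(src_len != tgt_len))
      stop("source and target block lengths differ")
    overlapping <- function(chrom, start, end) {
      gr <- GenomicRanges::GRanges(chrom,
                                   IRanges::IRanges(start + 1L, end))
      any(S4Vectors::queryHits(find_overlaps(gr)) !=
          S4Vectors::subjectHits(find_overlaps(gr)))
    }
    if (overlapping(blocks$src_chrom, blocks$src_start, blocks$src_end))
      stop("blocks overlap on the source genome")
    if (overlapping(blocks$tgt_chrom, blocks$tgt_start, blocks$tgt_end))
      stop("blocks overlap on the target genome")
  }
  rownames(blocks) <- NULL
  structure(blocks,
            source_species = as.character(source_species),
            target_species = as.character(target_species),
            class = c("orthology_map", "data.frame"))
}

om_source <- function(map) attr(map, "source_species")
om_target <- function(map) attr(map, "target_species")

#' @export
as.data.frame.orthology_map <- function(x, ...) {
  attr(x, "source_species") <- attr(x, "target_species") <- NULL
  class(x) <- "data.frame"
  x
}

#' @export
print.orthology_map <- function(x, ...) {
  cat(sprintf("orthology_map: %d block(s) | %s -> %s\n", nrow(x),
              om_source(x), om_target(x)))
  if (nrow(x)) print(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Read / write an orthology map TSV
#'
#' The supported dialect is a TSV with header
#' `src_chrom src_start src_end tgt_chrom tgt_start tgt_end strand`.
#'
#' @param path file path.
#' @param source_species,target_species species identifiers.
#' @return [read_orthology_map]: an `orthology_map`.
#' @export
read_orthology_map <- function(path, source_species = "unknown",
                               target_species = "unknown") {
  if (!file.exists(path)) stop("orthology map not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "character", "integer", "integer",
                                         "character"))
  orthology_map(df, source_species, target_species)
}

#' @param map an `orthology_map`.
#' @rdname read_orthology_map
#' @export
write_orthology_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Invert an orthology map
#'
#' Swaps source and target; block-wise projection through the inverted map
#' undoes projection through the original.
#' @param map an `orthology_map`.
#' @return the inverted `orthology_map`.
#' @export
invert_orthology_map <- function(map) {
  df <- as.data.frame(map)
  inv <- data.frame(src_chrom = df$tgt_chrom, src_start = df$tgt_start,
                    src_end = df$tgt_end, tgt_chrom = df$src_chrom,
                    tgt_start = df$src_start, tgt_end = df$src_end,
                    strand = df$strand, stringsAsFactors = FALSE)
  orthology_map(inv, om_target(map), om_source(map))
}

#' Project intervals onto an orthologous genome
#'
#' Each interval is matched against the map's blocks; the portion lying in
#' the block with the largest intersection is projected (a deterministic,
#' conservative policy for split alignments).  Orientation `-` reverses
#' coordinates within the block.  Intervals touching no block are
#' unalignable.
#'
#' @param map an `orthology_map`.
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `summit` (0-based half-open, source genome).
#' @return data.frame with one row per input interval: `chrom`, `start`,
#'   `end`, `summit` (projected; `NA` when unalignable), `alignable`
#'   (logical) and `block` (row index of the block used).
#' @export
project_intervals <- function(map, intervals) {
  n <- nrow(intervals)
  out <- data.frame(chrom = rep(NA_character_, n),
                    start = rep(NA_integer_, n),
                    end = rep(NA_integer_, n),
                    summit = rep(NA_integer_, n),
                    alignable = rep(FALSE, n),
                    block = rep(NA_integer_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L || nrow(map) == 0L) return(out)
  giv <- GenomicRanges::GRanges(intervals$chrom,
                                IRanges::IRanges(intervals$start + 1L,
                                                 intervals$end))
  gbl <- GenomicRanges::GRanges(map$src_chrom,
                                IRanges::IRanges(map$src_start + 1L,
                                                 map$src_end))
  ov <- find_overlaps(giv, gbl)
  if (!length(ov)) return(out)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  width <- pmin(intervals$end[q], map$src_end[s]) -
           pmax(intervals$start[q], map$src_start[s])
  # largest intersection wins; ties broken by lowest block index
  ord <- order(q, -width, s)
  q <- q[ord]; s <- s[ord]
  first <- !duplicated(q)
  q <- q[first]; s <- s[first]

  a <- pmax(intervals$start[q], map$src_start[s])   # clipped source portion
  b <- pmin(intervals$end[q], map$src_end[s])
  plus <- map$strand[s] == "+"
  out$chrom[q] <- map$tgt_chrom[s]
  out$start[q] <- ifelse(plus,
                         map$tgt_start[s] + (a - map$src_start[s]),
                         map$tgt_end[s] - (b - map$src_start[s]))
  out$end[q] <- ifelse(plus,
                       map$tgt_start[s] + (b - map$src_start[s]),
                       map$tgt_end[s] - (a - map$src_start[s]))
  if (!is.null(intervals$summit)) {
    sm <- pmin(pmax(intervals$summit[q], a), b - 1L)  # clamp into portion
    out$summit[q] <- ifelse(plus,
                            map$tgt_start[s] + (sm - map$src_start[s]),
                            map$tgt_end[s] - 1L - (sm - map$src_start[s]))
  }
  out$alignable[q] <- TRUE
  out$block[q] <- s
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  out$summit <- as.integer(out$summit)
  out
}

#' @describeIn project_intervals single-interval convenience wrapper;
#'   returns `NULL` when the interval intersects no block.
#' @param chrom,start,end a single source-genome interval.
#' @export
project_interval <- function(map, chrom, start, end) {
  p <- project_intervals(map, data.frame(chrom = chrom, start = start,
                                         end = end))
  if (!p$alignable[1L]) return(NULL)
  list(chrom = p$chrom[1L], start = p$start[1L], end = p$end[1L])
}

#' Call cross-species sharing of bound regions
#'
#' Each anchor TFBR is projected onto the partner genome and categorized:
#' `unalignable` when projection fails, `shared` when the projected interval
#' overlaps a partner record of the same TF by at least `min_overlap_bp`
#' bases (ties broken by largest overlap, then leftmost partner), else
#' `unshared`.
#'
#' @param anchor [peak_set] on the map's source species.
#' @param other [peak_set] on the map's target species.
#' @param map an `orthology_map` from anchor to other.
#' @param min_overlap_bp minimum overlap in bases (default 1).
#' @return data.frame of class `sharing_calls` with one row per anchor
#'   record: anchor coordinates and `locus_id`, `status`, partner
#'   coordinates/intensity/locus (`NA` unless shared), `overlap_bp`.
#' @export
call_shared <- function(anchor, other, map, min_overlap_bp = 1L) {
  if (!identical(ps_species(anchor), om_source(map)))
    stop("anchor species (", ps_species(anchor),
         ") does not match map source (", om_source(map), ")")
  if (!identical(ps_species(other), om_target(map)))
    stop("partner species (", ps_species(other),
         ") does not match map target (", om_target(map), ")")
  n <- nrow(anchor)
  proj <- project_intervals(map, as.data.frame(anchor))
  out <- data.frame(locus_id = anchor$locus_id, chrom = anchor$chrom,
                    start = anchor$start, end = anchor$end,
                    summit = anchor$summit, tf = rep(ps_tf(anchor), n),
                    species = rep(ps_species(anchor), n),
                    intensity = anchor$intensity,
                    status = ifelse(proj$alignable, "unshared",
                                    "unalignable"),
                    partner_chrom = rep(NA_character_, n),
                    partner_start = rep(NA_integer_, n),
                    partner_end = rep(NA_integer_, n),
                    partner_intensity = rep(NA_real_, n),
                    partner_locus_id = rep(NA_character_, n),
                    overlap_bp = rep(0L, n),
                    stringsAsFactors = FALSE)
  ali <- which(proj$alignable)
  if (length(ali) && nrow(other)) {
    gproj <- GenomicRanges::GRanges(proj$chrom[ali],
                                    IRanges::IRanges(proj$start[ali] + 1L,
                                                     proj$end[ali]))
    ov <- find_overlaps(gproj, peaks_granges(other),
                                      minoverlap = min_overlap_bp)
    if (length(ov)) {
      q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
      width <- pmin(proj$end[ali][q], other$end[s]) -
               pmax(proj$start[ali][q], other$start[s])
      ord <- order(q, -width, other$start[s], s)
      q <- q[ord]; s <- s[ord]; width <- width[ord]
      first <- !duplicated(q)
      q <- q[first]; s <- s[first]; width <- width[first]
      i <- ali[q]
      out$status[i] <- "shared"
      out$partner_chrom[i] <- other$chrom[s]
      out$partner_start[i] <- other$start[s]
      out$partner_end[i] <- other$end[s]
      out$partner_intensity[i] <- other$intensity[s]
      out$partner_locus_id[i] <- other$locus_id[s]
      out$overlap_bp[i] <- as.integer(width)
    }
  }
  structure(out,
            anchor_species = ps_species(anchor),
            partner_species = ps_species(other),
            tf = ps_tf(anchor),
            class = c("sharing_calls", "data.frame"))
}

#' Write sharing calls as TSV
#'
#' Columns: `locus_id chrom start end summit tf species status
#' partner_chrom partner_start partner_end`.
#' @param calls a `sharing_calls` data.frame from [call_shared].
#' @param path output path.
#' @export
write_sharing_calls <- function(calls, path) {
  cols <- c("locus_id", "chrom", "start", "end", "summit", "tf", "species",
            "status", "partner_chrom", "partner_start", "partner_end")
  utils::write.table(as.data.frame(calls)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = ".")
  invisible(path)
}
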