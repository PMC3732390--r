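#' Categorize combinatorial binding clusters
#'
#' Pools the bound regions of the three factors within one species and
#' partitions them into single-linkage components of the relation "summit
#' distance <= window" (300 bp by default).  Components are classed `1TF`
#' (singleton), `2TF` / `3TF` (two / three members, all factors distinct)
#' or `MULTI` (any factor repeated).  On a single coordinate axis, single
#' linkage reduces to chaining sorted summits whose successive gaps are
#' within the window.
#'
#' @param peaksets named list of [peak_set]s, one per TF, same species.
#' @param window linkage window in bp (default 300).
#' @return list of class `cluster_calls`: `clusters` (data.frame:
#'   `cluster_id`, `class`, `chrom`, `win_start`, `win_end`, `n_members`,
#'   `member_tfs`) and `members` (data.frame: one row per bound region
#'   with `cluster_id`, `class`, `tf`, `locus_id`, coordinates,
#'   `intensity`).
#' @export
categorize_clusters <- function(peaksets, window = 300L) {
  if (window <= 0) stop("window must be positive")
  sp <- unique(vapply(peaksets, ps_species, ""))
  if (length(sp) != 1L)
    stop("all peak sets must belong to the same species")
  members <- do.call(rbind, lapply(peaksets, function(x) {
    d <- as.data.frame(x)
    d$tf <- rep(ps_tf(x), nrow(d))
    d
  }))
  rownames(members) <- NULL
  if (!nrow(members))
    return(structure(list(clusters = data.frame(), members = members,
                          species = sp), class = "cluster_calls"))
  ord <- order(members$chrom, members$summit, members$tf)
  members <- members[ord, ]
  new_comp <- c(TRUE, members$chrom[-1L] != members$chrom[-nrow(members)] |
                  diff(members$summit) > window)
  comp <- cumsum(new_comp)
  members$cluster_id <- sprintf("c%06d", comp)

  cl_class <- function(tfs) {
    if (anyDuplicated(tfs)) "MULTI"
    else c("1TF", "2TF", "3TF")[length(tfs)]
  }
  agg <- split(seq_len(nrow(members)), comp)
  clusters <- data.frame(
    cluster_id = sprintf("c%06d", as.integer(names(agg))),
    class = vapply(agg, function(i) cl_class(members$tf[i]), ""),
    chrom = vapply(agg, function(i) members$chrom[i][1L], ""),
    win_start = vapply(agg, function(i) min(members$summit[i]), 0),
    win_end = vapply(agg, function(i) max(members$summit[i]), 0),
    n_members = lengths(agg),
    member_tfs = vapply(agg, function(i)
      paste(sort(members$tf[i]), collapse = ","), ""),
    stringsAsFactors = FALSE, row.names = NULL)
  members$class <- clusters$class[match(members$cluster_id,
                                        clusters$cluster_id)]
  structure(list(clusters = clusters, members = members, species = sp),
            class = "cluster_calls")
}

#' @export
print.cluster_calls <- function(x, ...) {
  tab <- table(factor(x$clusters$class,
                      c("1TF", "2TF", "3TF", "MULTI")))
  cat(sprintf("cluster_calls: %d clusters / %d bound regions (%s)\n",
              nrow(x$clusters), nrow(x$members), x$species))
  print(tab)
  invisible(x)
}

#' Per-class fraction of bound regions
#'
#' Fractions are counted per bound region (member), matching composition
#' statements of the form "1TF singletons represented 49\% of the regions
#' bound in the genome".
#' @param calls a `cluster_calls` object.
#' @return named numeric vector over `1TF`, `2TF`, `3TF`, `MULTI`.
#' @export
cluster_composition <- function(calls) {
  tab <- table(factor(calls$members$class,
                      c("1TF", "2TF", "3TF", "MULTI")))
  stats::setNames(as.vector(tab) / sum(tab), names(tab))
}

#' Cross-species fate of binding clusters
#'
#' Every member of every cluster is share-called against the partner
#' species (same machinery as the pairwise divergence analysis).  From the
#' viewpoint of an anchor TF, a cluster is `shared` when the anchor TF and
#' all co-bound members are shared, `part_shared` when the anchor is
#' shared but a co-bound member is missing, `part_unshared` when co-bound
#' members persist but the anchor TF is absent, and `totally_unshared`
#' when no member TF is bound at the orthologous location.
#'
#' @param calls `cluster_calls` for the anchor species.
#' @param anchor_tf the TF whose viewpoint is taken.
#' @param partner_peaks named list of partner-species [peak_set]s per TF.
#' @param map `orthology_map` anchor -> partner.
#' @param min_overlap_bp minimum overlap in bases.
#' @return data.frame: `cluster_id`, `class`, `status` for every cluster
#'   containing `anchor_tf`.
#' @export
cluster_fate <- function(calls, anchor_tf, partner_peaks, map,
                         min_overlap_bp = 1L) {
  members <- calls$members
  shared <- member_sharing(calls, partner_peaks, map, min_overlap_bp)
  id <- members$cluster_id
  is_anchor <- members$tf == anchor_tf
  agg <- function(x) tapply(x, id, any)
  has_anchor <- agg(is_anchor)
  anchor_shared <- agg(shared & is_anchor)
  co_shared <- agg(shared & !is_anchor)
  co_unshared <- agg(!shared & !is_anchor)
  ids <- names(has_anchor)[has_anchor]
  a <- anchor_shared[ids]; cs <- co_shared[ids]; cu <- co_unshared[ids]
  status <- ifelse(a & !cu, "shared",
            ifelse(a, "part_shared",
            ifelse(cs, "part_unshared", "totally_unshared")))
  data.frame(cluster_id = ids,
             class = members$class[match(ids, members$cluster_id)],
             status = unname(status), stringsAsFactors = FALSE,
             row.names = NULL)
}

# share-call every member against the partner's same-TF peaks; returns a
# logical vector aligned with calls$members rows
member_sharing <- function(calls, partner_peaks, map, min_overlap_bp = 1L) {
  members <- calls$members
  shared <- logical(nrow(members))
  for (tf in unique(members$tf)) {
    sel <- members$tf == tf
    anchor <- peak_set(members[sel, c("chrom", "start", "end", "summit",
                                      "intensity", "locus_id")],
                       calls$species, tf, "pooled")
    if (is.null(partner_peaks[[tf]])) next
    cs <- call_shared(anchor, partner_peaks[[tf]], map, min_overlap_bp)
    shared[sel] <- cs$status == "shared"
  }
  shared
}

#' Coevolution of co-bound binding-intensity changes
#'
#' Within 2TF and 3TF clusters, pairs of factors both shared with the
#' partner species are collected; for each member the intensity change
#' `delta = log2(partner) - log2(anchor)` is computed after per-species
#' median normalization of log2 intensities, and the Pearson correlation
#' of the two factors' deltas is reported per TF pair.  Pairs with any
#' unshared member are excluded.
#'
#' @inheritParams cluster_fate
#' @param min_pairs minimum number of co-bound shared pairs per TF pair
#'   (default 3).
#' @return data.frame of class `coevolution_result`: `tf_a`, `tf_b`, `n`,
#'   `r`, `r_squared`.
#' @export
coevolution <- function(calls, partner_peaks, map, min_overlap_bp = 1L,
                        min_pairs = 3L) {
  members <- calls$members
  use <- members$class %in% c("2TF", "3TF")
  delta <- rep(NA_real_, nrow(members))
  for (tf in unique(members$tf)) {
    sel <- which(members$tf == tf & use)
    if (!length(sel) || is.null(partner_peaks[[tf]])) next
    anchor <- peak_set(members[sel, c("chrom", "start", "end", "summit",
                                      "intensity", "locus_id")],
                       calls$species, tf, "pooled")
    cs <- call_shared(anchor, partner_peaks[[tf]], map, min_overlap_bp)
    la <- log2(anchor$intensity) -
      stats::median(log2(anchor$intensity))
    lp_all <- log2(partner_peaks[[tf]]$intensity)
    lp_med <- stats::median(lp_all)
    ok <- cs$status == "shared"
    delta[sel[ok]] <- (log2(cs$partner_intensity[ok]) - lp_med) - la[ok]
  }
  pairs <- t(utils::combn(sort(unique(members$tf)), 2L))
  out <- lapply(seq_len(nrow(pairs)), function(k) {
    ta <- pairs[k, 1L]; tb <- pairs[k, 2L]
    ids <- intersect(members$cluster_id[members$tf == ta & use &
                                          !is.na(delta)],
                     members$cluster_id[members$tf == tb & use &
                                          !is.na(delta)])
    da <- delta[match(paste(ids, ta), paste(members$cluster_id,
                                            members$tf))]
    db <- delta[match(paste(ids, tb), paste(members$cluster_id,
                                            members$tf))]
    if (length(ids) < min_pairs)
      stop("fewer than ", min_pairs, " co-bound shared pairs for ",
           ta, "-", tb)
    r <- stats::cor(da, db)
    data.frame(tf_a = ta, tf_b = tb, n = length(ids), r = r,
               r_squared = r^2, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out),
            class = c("coevolution_result", "data.frame"))
}

#' Write cluster calls as TSV
#' (`cluster_id chrom win_start win_end class member_tfs member_locus_ids`)
#' @param calls a `cluster_calls` object.
#' @param path output path.
#' @export
write_cluster_calls <- function(calls, path) {
  ids <- vapply(split(calls$members$locus_id, calls$members$cluster_id),
                paste, "", collapse = ",")
  df <- calls$clusters
  df$member_locus_ids <- ids[df$cluster_id]
  utils::write.table(
    df[, c("cluster_id", "chrom", "win_start", "win_end", "class",
           "member_tfs", "member_locus_ids")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  invisible(path)
}
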