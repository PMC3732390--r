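tf_initial <- c(CEBPA = "C", FOXA1 = "F", HNF4A = "H", CTCF = "T")

# class code of a cluster from its member TFs, e.g. "CH", "CHF", "CC"
cluster_class_code <- function(member_tfs) {
  vapply(strsplit(member_tfs, ",", fixed = TRUE),
         function(tfs) paste(sort(tf_initial[tfs]), collapse = ""), "")
}

member_retained <- function(members, ko_set, min_overlap_bp = 1L) {
  if (is.null(ko_set) || nrow(ko_set) == 0L)
    return(logical(nrow(members)))
  gm <- GenomicRanges::GRanges(members$chrom,
                               IRanges::IRanges(members$start + 1L,
                                                members$end))
  ov <- find_overlaps(gm, peaks_granges(ko_set),
                                    minoverlap = min_overlap_bp)
  seq_len(nrow(members)) %in% S4Vectors::queryHits(ov)
}

#' Retention of co-bound peaks after a TF knockout, by cluster class
#'
#' For every non-deleted member TF of every wild-type cluster class, the
#' fraction of WT peaks with an overlapping KO-condition peak of the same
#' TF (same genome, at least `min_overlap_bp` bases).  Knockout
#' completeness is verified first: if more than 20\% of the deleted TF's
#' own WT peaks persist in its KO ChIP, the report is flagged
#' `knockout_incomplete` with a warning.  An optional conservation mask
#' restricts the analysis to deeply shared clusters.
#'
#' @param calls wild-type `cluster_calls` (see [categorize_clusters]).
#' @param ko named list of KO-condition [peak_set]s per TF (may include
#'   `CTCF`).
#' @param deleted_tf the genetically deleted factor.
#' @param min_overlap_bp minimum overlap in bases.
#' @param mask optional character vector of cluster ids to keep (e.g.
#'   clusters bound in all five species).
#' @param ctcf optional pair `list(wt = , ko = )` of CTCF [peak_set]s
#'   used as an unperturbed control row.
#' @return list of class `retention_report`: `per_member` (rows `class`,
#'   `tf`, `contains_deleted`, `n`, `n_retained`, `fraction`),
#'   `per_cluster` (cluster counted retained when all its non-deleted
#'   members are), `contrasts` (per assayed TF: containing vs lacking
#'   classes, odds ratio and exact p), `self_retention`,
#'   `knockout_incomplete`, `deleted_tf`.
#' @export
retention_by_class <- function(calls, ko, deleted_tf,
                               min_overlap_bp = 1L, mask = NULL,
                               ctcf = NULL) {
  members <- calls$members
  clusters <- calls$clusters
  if (!is.null(mask)) {
    members <- members[members$cluster_id %in% mask, , drop = FALSE]
    clusters <- clusters[clusters$cluster_id %in% mask, , drop = FALSE]
  }
  code <- cluster_class_code(clusters$member_tfs)
  names(code) <- clusters$cluster_id
  members$class_code <- code[members$cluster_id]
  members$contains_deleted <-
    grepl(tf_initial[[deleted_tf]], members$class_code, fixed = TRUE)

  self <- members[members$tf == deleted_tf, , drop = FALSE]
  self_ret <- if (nrow(self))
    mean(member_retained(self, ko[[deleted_tf]], min_overlap_bp))
  else NA_real_
  incomplete <- isTRUE(self_ret > 0.2)
  if (incomplete)
    warning(sprintf("knockout incomplete: %.1f%% of %s peaks persist in its own KO ChIP",
                    100 * self_ret, deleted_tf))

  assay <- members[members$tf != deleted_tf, , drop = FALSE]
  assay$retained <- FALSE
  for (tf in unique(assay$tf)) {
    i <- assay$tf == tf
    assay$retained[i] <- member_retained(assay[i, , drop = FALSE],
                                         ko[[tf]], min_overlap_bp)
  }
  per_member <- do.call(rbind, lapply(
    split(assay, list(assay$class_code, assay$tf), drop = TRUE),
    function(d) data.frame(class = d$class_code[1L], tf = d$tf[1L],
                           contains_deleted = d$contains_deleted[1L],
                           n = nrow(d), n_retained = sum(d$retained),
                           fraction = mean(d$retained),
                           stringsAsFactors = FALSE)))
  rownames(per_member) <- NULL
  per_member <- per_member[order(per_member$class, per_member$tf), ]

  cl_ret <- tapply(assay$retained, assay$cluster_id, all)
  cl_df <- data.frame(cluster_id = names(cl_ret),
                      retained = as.logical(cl_ret),
                      stringsAsFactors = FALSE)
  cl_df$class <- code[cl_df$cluster_id]
  cl_df$contains_deleted <- grepl(tf_initial[[deleted_tf]], cl_df$class,
                                  fixed = TRUE)
  per_cluster <- do.call(rbind, lapply(split(cl_df, cl_df$class),
    function(d) data.frame(class = d$class[1L],
                           contains_deleted = d$contains_deleted[1L],
                           n = nrow(d), n_retained = sum(d$retained),
                           fraction = mean(d$retained),
                           stringsAsFactors = FALSE)))
  rownames(per_cluster) <- NULL

  contrasts <- do.call(rbind, lapply(unique(assay$tf), function(tf) {
    d <- assay[assay$tf == tf, ]
    has <- d$contains_deleted
    if (!any(has) || all(has)) return(NULL)
    degenerate <- all(d$retained) || !any(d$retained)
    ft <- if (degenerate) NULL
          else retention_test(sum(d$retained[has]), sum(has),
                              sum(d$retained[!has]), sum(!has))
    data.frame(tf = tf, n_containing = sum(has),
               n_lacking = sum(!has),
               fraction_containing = mean(d$retained[has]),
               fraction_lacking = mean(d$retained[!has]),
               odds_ratio = if (degenerate) NA_real_ else ft$odds_ratio,
               p_value = if (degenerate) NA_real_ else ft$p_value,
               log_p = if (degenerate) NA_real_ else ft$log_p,
               stringsAsFactors = FALSE)
  }))

  ctcf_row <- NULL
  if (!is.null(ctcf)) {
    ctcf_members <- as.data.frame(ctcf$wt)
    ret <- member_retained(ctcf_members, ctcf$ko, min_overlap_bp)
    ctcf_row <- data.frame(class = "CTCF", tf = "CTCF",
                           contains_deleted = FALSE,
                           n = nrow(ctcf_members),
                           n_retained = sum(ret), fraction = mean(ret),
                           stringsAsFactors = FALSE)
    per_member <- rbind(per_member, ctcf_row)
  }
  structure(list(per_member = per_member, per_cluster = per_cluster,
                 contrasts = contrasts, self_retention = self_ret,
                 knockout_incomplete = incomplete,
                 deleted_tf = deleted_tf),
            class = "retention_report")
}

#' @export
print.retention_report <- function(x, ...) {
  cat(sprintf("retention_report: %s knockout (self-retention %.3f%s)\n",
              x$deleted_tf, x$self_retention,
              if (x$knockout_incomplete) ", INCOMPLETE" else ""))
  print(x$per_member, row.names = FALSE)
  if (!is.null(x$contrasts)) {
    cat("containing vs lacking contrasts:\n")
    print(x$contrasts, row.names = FALSE)
  }
  invisible(x)
}

#' Exact test of containing-class vs lacking-class retention
#'
#' Two-sided Fisher's exact test of the 2x2 table
#' retained/lost x contains/lacks the deleted TF, computed by the same
#' log-space hypergeometric machinery as [snv_contingency] (p-values far
#' below 1e-15 are reported via `log_p`).
#'
#' @param retained_containing,n_containing retained and total counts in
#'   classes containing the deleted factor.
#' @param retained_lacking,n_lacking same for classes lacking it.
#' @return an `exact_test` (see [snv_contingency]).
#' @export
retention_test <- function(retained_containing, n_containing,
                           retained_lacking, n_lacking) {
  snv_contingency(matrix(c(retained_containing,
                           n_containing - retained_containing,
                           retained_lacking,
                           n_lacking - retained_lacking),
                         2L, 2L, byrow = TRUE,
                         dimnames = list(c("containing", "lacking"),
                                         c("retained", "lost"))))
}

#' Retention stratified by wild-type binding intensity
#'
#' Bins the non-deleted members of each cluster class into
#' `n_bins` quantile bins of WT log2 intensity and reports retention per
#' bin, plus a trend statistic: the difference between top- and
#' bottom-bin retention with a bootstrap confidence interval.
#'
#' @inheritParams retention_by_class
#' @param n_bins number of intensity bins (>= 2; default 10 for
#'   deciles).
#' @param n_boot bootstrap replicates for the trend CI.
#' @param conf confidence level.
#' @param seed seed for the bootstrap.
#' @return list: `bins` (data.frame `class`, `bin`, `n`, `fraction`),
#'   `trend` (data.frame `class`, `difference`, `ci_lo`, `ci_hi`).
#' @export
intensity_stratified_retention <- function(calls, ko, deleted_tf,
                                           n_bins = 10L, n_boot = 200L,
                                           conf = 0.95, seed = 1L) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  members <- calls$members
  code <- cluster_class_code(calls$clusters$member_tfs)
  names(code) <- calls$clusters$cluster_id
  members$class_code <- code[members$cluster_id]
  assay <- members[members$tf != deleted_tf, , drop = FALSE]
  assay$retained <- FALSE
  for (tf in unique(assay$tf)) {
    i <- assay$tf == tf
    assay$retained[i] <- member_retained(assay[i, , drop = FALSE],
                                         ko[[tf]])
  }
  set.seed(seed)
  bins_out <- list(); trend_out <- list()
  for (cl in unique(assay$class_code)) {
    d <- assay[assay$class_code == cl, ]
    if (nrow(d) < n_bins) {
      warning("class ", cl, " has fewer members than bins; skipped")
      next
    }
    q <- stats::quantile(log2(d$intensity),
                         probs = seq(0, 1, length.out = n_bins + 1L))
    bin <- cut(log2(d$intensity), unique(q), include.lowest = TRUE,
               labels = FALSE)
    frac <- tapply(d$retained, bin, mean)
    bins_out[[cl]] <- data.frame(class = cl,
                                 bin = as.integer(names(frac)),
                                 n = as.vector(table(bin)),
                                 fraction = as.vector(frac),
                                 stringsAsFactors = FALSE)
    top <- d$retained[bin == max(bin)]
    bot <- d$retained[bin == min(bin)]
    diffs <- vapply(seq_len(n_boot), function(b)
      mean(sample(top, replace = TRUE)) -
        mean(sample(bot, replace = TRUE)), 0)
    alpha <- (1 - conf) / 2
    trend_out[[cl]] <- data.frame(
      class = cl, difference = mean(top) - mean(bot),
      ci_lo = unname(stats::quantile(diffs, alpha)),
      ci_hi = unname(stats::quantile(diffs, 1 - alpha)),
      stringsAsFactors = FALSE)
  }
  list(bins = do.call(rbind, c(bins_out, list(make.row.names = FALSE))),
       trend = do.call(rbind, c(trend_out,
                                list(make.row.names = FALSE))))
}

#' Concordance of evolutionary and knockout sensitivity
#'
#' For 3TF clusters totally lost in a second species whose sequence
#' change is attributable to exactly one TF's motif, compares knockout
#' retention of the remaining members between the matched knockout (the
#' deleted TF is the motif-attributed one) and mismatched knockouts.
#' Clusters with SNVs in more than one motif must be excluded upstream.
#'
#' @param attribution data.frame with one row per cluster: `cluster_id`,
#'   `snv_tf` (the single motif-bearing TF).
#' @param ko_outcomes data.frame: `cluster_id`, `deleted_tf`, `retained`
#'   (logical: the cluster's remaining members persisted in that KO).
#' @return list of class `concordance_report`: `per_category`
#'   (`snv_tf`, `deleted_tf`, `matched`, `n`, `fraction`), `contrast`
#'   (`exact_test` of matched vs mismatched retention, `NULL` when a
#'   side is empty).
#' @export
evo_ko_concordance <- function(attribution, ko_outcomes) {
  if (anyDuplicated(attribution$cluster_id))
    stop("attribution must contain each cluster once ",
         "(exactly one motif-bearing TF)")
  d <- merge(ko_outcomes, attribution, by = "cluster_id")
  if (!nrow(d)) stop("no overlap between attribution and KO outcomes")
  d$matched <- d$deleted_tf == d$snv_tf
  per <- do.call(rbind, lapply(
    split(d, list(d$snv_tf, d$deleted_tf), drop = TRUE),
    function(g) data.frame(snv_tf = g$snv_tf[1L],
                           deleted_tf = g$deleted_tf[1L],
                           matched = g$matched[1L], n = nrow(g),
                           fraction = mean(g$retained),
                           stringsAsFactors = FALSE)))
  rownames(per) <- NULL
  contrast <- NULL
  if (any(d$matched) && any(!d$matched)) {
    contrast <- retention_test(sum(d$retained[d$matched]),
                               sum(d$matched),
                               sum(d$retained[!d$matched]),
                               sum(!d$matched))
  }
  structure(list(per_category = per, contrast = contrast),
            class = "concordance_report")
}
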