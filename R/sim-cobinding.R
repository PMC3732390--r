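# Cluster geometry: cluster centers every 2 kb (so clusters are >= 1.7 kb
# apart, far above the 400-bp separation needed for unambiguous
# categorization); member summits 120 bp apart around the center, so all
# members of a cluster fall pairwise within the 300-bp linkage window.

CLUSTER_SPACING <- 2000L
CLUSTERS_PER_CHROM <- 5000L
MEMBER_SPACING <- 120L

#' Simulate combinatorial co-binding clusters with coupled turnover
#'
#' Generates bound regions for CEBPA, HNF4A and FOXA1 grouped into 1TF
#' singletons, 2TF and 3TF clusters (distinct factors) and MULTI clusters
#' (the same factor repeated), in proportions given by
#' `cluster_composition` counted per bound region.  For each partner
#' species, member losses are coupled: with probability `coloss_coupling`
#' one loss draw decides the whole cluster, otherwise members draw
#' independently (the marginal per-member loss probability is
#' `1 - exp(-lambda t)` either way).  Between-species log2-intensity
#' changes of co-bound members share a cluster-level factor giving pairwise
#' correlation `delta_intensity_corr`.
#'
#' @param cfg a [sim_config]; `n_loci` is interpreted as the total number
#'   of bound regions.
#' @param partner_species species to project turnover and intensity change
#'   onto.
#' @return list with `peaks` (`peaks[[species]][[tf]]` is a [peak_set]),
#'   `maps` (anchor-to-partner orthology maps), `clusters` (data.frame:
#'   `cluster_id`, `class`, `chrom`, `center`) and `members` (data.frame:
#'   one row per bound region with true cluster assignment, log2
#'   intensity, and per-partner `present_*` / `delta_*` columns).
#' @export
simulate_cobinding <- function(cfg = sim_config(),
                               partner_species = "SPRET") {
  sim_seed(cfg$seed, 3L)
  comp <- cfg$cluster_composition
  sizes <- c(`1TF` = 1L, `2TF` = 2L, `3TF` = 3L, MULTI = cfg$multi_size)
  n_clusters <- round(cfg$n_loci * comp / sizes)
  cls <- rep(names(n_clusters), n_clusters)
  cls <- sample(cls)                       # interleave classes
  nc <- length(cls)
  i <- seq_len(nc) - 1L
  clusters <- data.frame(
    cluster_id = sprintf("CL%06d", i + 1L), class = cls,
    chrom = paste0("chr", i %/% CLUSTERS_PER_CHROM + 1L),
    center = (i %% CLUSTERS_PER_CHROM) * CLUSTER_SPACING + 1000L,
    stringsAsFactors = FALSE)

  m <- sizes[cls]
  rows <- rep.int(seq_len(nc), m)
  midx <- sequence(m)
  offs <- as.integer(round((midx - (m[rows] + 1L) / 2) * MEMBER_SPACING))
  tf_of <- function(cl, size) {
    switch(cl,
           `1TF` = sample(STUDY_TFS, 1L),
           `2TF` = sample(STUDY_TFS, 2L),
           `3TF` = sample(STUDY_TFS, 3L),
           MULTI = rep(sample(STUDY_TFS, 1L), size))
  }
  tfs <- unlist(lapply(seq_len(nc), function(k) tf_of(cls[k], m[k])),
                use.names = FALSE)
  cbase <- stats::rnorm(nc, cfg$base_mean, cfg$base_sd)
  members <- data.frame(
    cluster_id = clusters$cluster_id[rows], class = cls[rows],
    tf = tfs,
    locus_id = sprintf("%s_m%d", clusters$cluster_id[rows], midx),
    chrom = clusters$chrom[rows],
    summit = clusters$center[rows] + offs,
    log2 = cbase[rows] + stats::rnorm(length(rows), 0, 0.3),
    stringsAsFactors = FALSE)
  members$start <- members$summit - PEAK_HALFWIDTH
  members$end <- members$summit + PEAK_HALFWIDTH

  rho <- cfg$delta_intensity_corr
  if (rho < 0) stop("delta_intensity_corr must be non-negative here")
  coupled <- stats::runif(nc) < cfg$coloss_coupling
  for (sp in partner_species) {
    t_sp <- cfg$divergence_times[[sp]]
    p_keep <- exp(-cfg$loss_rate * t_sp)
    u_cluster <- stats::runif(nc)
    u_member <- stats::runif(length(rows))
    u <- ifelse(coupled[rows], u_cluster[rows], u_member)
    members[[paste0("present_", sp)]] <- u < p_keep
    g <- stats::rnorm(nc)
    e <- stats::rnorm(length(rows))
    members[[paste0("delta_", sp)]] <-
      cfg$delta_sd * (sqrt(rho) * g[rows] + sqrt(1 - rho) * e)
  }

  chroms <- unique(clusters$chrom)
  len <- CLUSTERS_PER_CHROM * CLUSTER_SPACING
  maps <- lapply(partner_species, function(sp) {
    off <- species_offset(sp)
    orthology_map(data.frame(src_chrom = chroms, src_start = 0L,
                             src_end = len, tgt_chrom = chroms,
                             tgt_start = off, tgt_end = off + len,
                             strand = "+", stringsAsFactors = FALSE),
                  "C57BL6J", sp)
  })
  names(maps) <- partner_species

  mk_sets <- function(sp) {
    off <- if (sp == "C57BL6J") 0L else species_offset(sp)
    pres <- if (sp == "C57BL6J") rep(TRUE, nrow(members))
            else members[[paste0("present_", sp)]]
    dlt <- if (sp == "C57BL6J") 0 else members[[paste0("delta_", sp)]]
    sets <- lapply(STUDY_TFS, function(tf) {
      sel <- pres & members$tf == tf
      d <- members[sel, c("locus_id", "chrom", "start", "end", "summit")]
      d$start <- d$start + off; d$end <- d$end + off
      d$summit <- d$summit + off
      d$intensity <- 2^(members$log2[sel] + if (length(dlt) > 1)
        dlt[sel] else 0)
      peak_set(d, sp, tf, "pooled")
    })
    names(sets) <- STUDY_TFS
    sets
  }
  peaks <- lapply(c("C57BL6J", partner_species), mk_sets)
  names(peaks) <- c("C57BL6J", partner_species)
  list(peaks = peaks, maps = maps, clusters = clusters, members = members)
}
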