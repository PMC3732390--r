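# Synthetic genome layout: loci on 1-Mb-spaced synthetic chromosomes,
# 1 kb apart, 200-bp peaks with central summits.  Partner genomes are the
# anchor genome shifted by a species-specific offset, which makes every
# orthology map a single identity-plus-offset block per chromosome.

LOCI_PER_CHROM <- 10000L
LOCUS_SPACING  <- 1000L
PEAK_HALFWIDTH <- 100L

locus_layout <- function(n_loci) {
  i <- seq_len(n_loci) - 1L
  chrom <- paste0("chr", i %/% LOCI_PER_CHROM + 1L)
  summit <- (i %% LOCI_PER_CHROM) * LOCUS_SPACING + 500L
  data.frame(locus_id = sprintf("L%06d", i + 1L), chrom = chrom,
             start = summit - PEAK_HALFWIDTH,
             end = summit + PEAK_HALFWIDTH,
             summit = summit, stringsAsFactors = FALSE)
}

species_offset <- function(species) {
  match(species, STUDY_SPECIES) * 1000000L
}

identity_offset_map <- function(chroms, anchor, species) {
  off <- species_offset(species)
  len <- LOCI_PER_CHROM * LOCUS_SPACING
  orthology_map(data.frame(src_chrom = chroms, src_start = 0L,
                           src_end = len, tgt_chrom = chroms,
                           tgt_start = off, tgt_end = off + len,
                           strand = "+", stringsAsFactors = FALSE),
                anchor, species)
}

#' Simulate presence/absence turnover of bound regions along the phylogeny
#'
#' Every locus is present in the anchor species (C57BL/6J).  A locus is
#' present in a species that split `t` MY ago with independent probability
#' `exp(-lambda * t)` (anchored-loss parameterization, matching the fitted
#' axis of the exponential sharing decay).  Gains are off by default; with
#' `gain_rate > 0` a stationary gain process adds partner-only loci at rate
#' `gain_rate * t` per anchor locus, which depresses anchored sharing below
#' `exp(-lambda * t)` when those loci are used as anchors in the reverse
#' direction.
#'
#' @param cfg a [sim_config]; uses `n_loci`, `loss_rate`,
#'   `divergence_times`, `base_mean`, `base_sd`, `seed`.
#' @param species partner species to simulate (default: all five study
#'   partners of the anchor).
#' @param tf transcription factor label for the emitted peak sets.
#' @param gain_rate per-MY rate of partner-only gains (default 0).
#' @param mode `"anchored"` (default): sharing decays as
#'   `exp(-lambda t)` with `t` the time since the split, matching the
#'   fitted axis of the observed decay; `"lineage"`: the rate applies
#'   per lineage, so anchored sharing decays as `exp(-2 lambda t)`.
#' @return list with elements `peaks` (named list of [peak_set], anchor
#'   first), `maps` (named list of anchor-to-partner `orthology_map`s) and
#'   `truth` (data.frame: locus layout, `base_log2`, and one logical
#'   presence column `present_<species>` per species).
#' @export
simulate_turnover <- function(cfg = sim_config(),
                              species = c("AJ", "CAST", "SPRET", "CAROLI",
                                          "RAT"),
                              tf = "CEBPA", gain_rate = 0,
                              mode = c("anchored", "lineage")) {
  mode <- match.arg(mode)
  lambda <- cfg$loss_rate * if (mode == "lineage") 2 else 1
  if (lambda < 0) stop("loss rate must be non-negative")
  t <- cfg$divergence_times[species]
  if (any(is.na(t)) || any(t < 0))
    stop("missing or negative divergence time for requested species")
  sim_seed(cfg$seed, 1L)
  anchor <- "C57BL6J"
  truth <- locus_layout(cfg$n_loci)
  truth$base_log2 <- stats::rnorm(cfg$n_loci, cfg$base_mean, cfg$base_sd)
  truth$present_C57BL6J <- TRUE
  for (sp in species)
    truth[[paste0("present_", sp)]] <-
      stats::runif(cfg$n_loci) < exp(-lambda * t[[sp]])

  chroms <- unique(truth$chrom)
  maps <- lapply(species, function(sp)
    identity_offset_map(chroms, anchor, sp))
  names(maps) <- species

  mk_set <- function(sp) {
    pres <- truth[[paste0("present_", sp)]]
    df <- truth[pres, c("locus_id", "chrom", "start", "end", "summit",
                        "base_log2")]
    off <- if (sp == anchor) 0L else species_offset(sp)
    df$start <- df$start + off
    df$end <- df$end + off
    df$summit <- df$summit + off
    df$intensity <- 2^df$base_log2
    df$base_log2 <- NULL
    if (sp != anchor && gain_rate > 0) {
      n_gain <- stats::rpois(1L, gain_rate * t[[sp]] * cfg$n_loci)
      if (n_gain > 0) {
        # gained loci sit midway between anchor loci, so they never overlap
        # a projected anchor peak
        g <- sample.int(cfg$n_loci, min(n_gain, cfg$n_loci))
        gd <- truth[g, c("chrom", "summit")]
        gd$summit <- gd$summit + LOCUS_SPACING %/% 2L + off
        df <- rbind(df, data.frame(
          locus_id = sprintf("G%06d_%s", g, sp), chrom = gd$chrom,
          start = gd$summit - PEAK_HALFWIDTH,
          end = gd$summit + PEAK_HALFWIDTH, summit = gd$summit,
          intensity = 2^stats::rnorm(length(g), cfg$base_mean,
                                     cfg$base_sd)))
      }
    }
    peak_set(df, sp, tf, "pooled")
  }
  peaks <- lapply(c(anchor, species), mk_set)
  names(peaks) <- c(anchor, species)
  list(peaks = peaks, maps = maps, truth = truth)
}
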