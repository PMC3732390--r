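#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator.  Defaults are
#' calibrated to the summary statistics of the reference study design:
#' anchored loss rate 0.12/MY, replicate log2-intensity noise chosen so
#' replicate R^2 falls in 0.76-0.83, cluster composition 49/23/18/9%
#' (1TF/2TF/3TF/multiplicity), between-species intensity-change correlation
#' sqrt(0.4) so co-evolution R^2 recovers 0.4, motif-SNV probability 14.1%
#' for shared loci (vs 31.2% unshared), and knockout retention 66%
#' (cluster contains the deleted factor) vs 96% (cluster lacks it) with
#' CTCF unperturbed.
#'
#' @param n_loci number of simulated loci (bound regions).
#' @param loss_rate anchored per-million-year loss rate lambda (1/MY): a
#'   locus present in the anchor is present in a species separated by `t`
#'   MY with probability `exp(-lambda * t)`.
#' @param divergence_times named vector, split age (MY) per species.
#' @param regime_mix probabilities of the intensity-evolution regimes
#'   `(conserved, progressive, random)`, summing to 1.
#' @param sigma_conserved,sigma_random log2-intensity dispersions of the
#'   conserved and random regimes.
#' @param progressive_total range (log2 units) of the total monotone change
#'   of the progressive regime across the mouse clade.
#' @param replicate_noise log2 sd of independent replicate noise.
#' @param replicate_dropout probability a pooled peak is missing from one
#'   replicate's call set.
#' @param base_mean,base_sd log2 mean and sd of per-locus baseline
#'   intensity.
#' @param cluster_composition probabilities that a bound region belongs to
#'   a `1TF`, `2TF`, `3TF` or `MULTI` (same TF repeated) cluster; sums
#'   to 1.
#' @param coloss_coupling probability in `[0,1]` that loss draws of a
#'   cluster's members are fully coupled (one draw for the whole cluster)
#'   rather than independent.
#' @param delta_intensity_corr correlation rho of between-species
#'   log2-intensity changes of co-bound members.
#' @param delta_sd log2 sd of the between-species intensity change.
#' @param snv_prob_shared,snv_prob_unshared probability that the partner
#'   species carries an SNV inside the bound motif, for loci shared /
#'   unshared with the partner.
#' @param background_snv_rate per-base substitution probability outside the
#'   motif.
#' @param ko_retention named list: retention probability of a co-bound peak
#'   after knockout when its cluster `contains_deleted` / `lacks_deleted`
#'   the deleted factor, for `CTCF` peaks, and optionally `sensitized`
#'   (clusters whose stability is attributed to the deleted TF's motif;
#'   `NA` disables the coupling).
#' @param multi_size number of same-TF peaks in a MULTI cluster.
#' @param seed integer seed; all generator randomness derives from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 10000L,
                       loss_rate = 0.12,
                       divergence_times = STUDY_DIVERGENCE_MY,
                       regime_mix = c(conserved = 0.50,
                                      progressive = 0.05,
                                      random = 0.45),
                       sigma_conserved = 0.12,
                       sigma_random = 1.8,
                       progressive_total = c(2, 4),
                       replicate_noise = 0.69,
                       replicate_dropout = 0.02,
                       base_mean = 8,
                       base_sd = 1.5,
                       cluster_composition = c(`1TF` = 0.49, `2TF` = 0.23,
                                               `3TF` = 0.18,
                                               MULTI = 0.09) / 0.99,
                       coloss_coupling = 0.5,
                       delta_intensity_corr = sqrt(0.4),
                       delta_sd = 1.0,
                       snv_prob_shared = 0.141,
                       snv_prob_unshared = 0.312,
                       background_snv_rate = 0.005,
                       ko_retention = list(contains_deleted = 0.66,
                                           lacks_deleted = 0.96,
                                           CTCF = 1.0,
                                           sensitized = NA_real_),
                       multi_size = 2L,
                       seed = 1L) {
  stopifnot(n_loci >= 1, loss_rate >= 0)
  chk01 <- function(x, what) {
    if (any(x < 0 | x > 1, na.rm = TRUE))
      stop(what, " must lie in [0, 1]")
  }
  if (abs(sum(regime_mix) - 1) > 1e-9)
    stop("regime_mix must sum to 1")
  if (abs(sum(cluster_composition) - 1) > 1e-9)
    stop("cluster_composition must sum to 1")
  chk01(regime_mix, "regime_mix")
  chk01(cluster_composition, "cluster_composition")
  chk01(coloss_coupling, "coloss_coupling")
  chk01(c(snv_prob_shared, snv_prob_unshared, background_snv_rate,
          replicate_dropout), "probabilities")
  chk01(unlist(ko_retention), "ko_retention")
  if (delta_intensity_corr < -1 || delta_intensity_corr > 1)
    stop("delta_intensity_corr must lie in [-1, 1]")
  if (sigma_conserved < 0 || sigma_random < 0 || replicate_noise < 0)
    stop("dispersions must be non-negative")
  structure(list(n_loci = as.integer(n_loci), loss_rate = loss_rate,
                 divergence_times = divergence_times,
                 regime_mix = regime_mix,
                 sigma_conserved = sigma_conserved,
                 sigma_random = sigma_random,
                 progressive_total = progressive_total,
                 replicate_noise = replicate_noise,
                 replicate_dropout = replicate_dropout,
                 base_mean = base_mean, base_sd = base_sd,
                 cluster_composition = cluster_composition,
                 coloss_coupling = coloss_coupling,
                 delta_intensity_corr = delta_intensity_corr,
                 delta_sd = delta_sd,
                 snv_prob_shared = snv_prob_shared,
                 snv_prob_unshared = snv_prob_unshared,
                 background_snv_rate = background_snv_rate,
                 ko_retention = ko_retention,
                 multi_size = as.integer(multi_size),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Stream-splitting: every generator stage re-seeds R's RNG from the single
# configured seed and a fixed per-stage stream index, so stages are
# individually reproducible and jointly deterministic.
sim_seed <- function(seed, stream) {
  set.seed((as.integer(seed) %% 1000000L) * 1009L + 7L * stream)
  invisible(NULL)
}
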