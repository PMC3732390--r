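# Shared fixtures, built in code.

example_pwm <- function() {
  read_pfm(system.file("extdata", "cebpa_synthetic.pfm",
                       package = "tfbindevo"))
}

# a small peak set on one chromosome; summits centred
toy_peaks <- function(starts, width = 200L, species = "C57BL6J",
                      tf = "CEBPA", condition = "pooled",
                      intensity = NULL, chrom = "chr1",
                      locus_id = NULL) {
  n <- length(starts)
  peak_set(data.frame(
    chrom = chrom, start = starts, end = starts + width,
    summit = starts + width %/% 2L,
    intensity = if (is.null(intensity)) rep(10, n) else intensity,
    locus_id = if (is.null(locus_id)) sprintf("p%03d", seq_len(n))
               else locus_id,
    stringsAsFactors = FALSE), species, tf, condition)
}

# identity orthology map covering chr1/chr2 up to 10 Mb
toy_identity_map <- function(source = "C57BL6J", target = "CAST",
                             chroms = c("chr1", "chr2"),
                             offset = 0L, len = 10000000L) {
  orthology_map(data.frame(
    src_chrom = chroms, src_start = 0L, src_end = len,
    tgt_chrom = chroms, tgt_start = offset, tgt_end = offset + len,
    strand = "+", stringsAsFactors = FALSE), source, target)
}

# independent enumeration oracle for the two-sided Fisher p of a 2x2
# table: sums point probabilities computed from binomial coefficients
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1])
  n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  lp <- lchoose(c1, support) + lchoose(n - c1, r1 - support) -
    lchoose(n, r1)
  p_obs <- lp[support == a]
  sum(exp(lp[lp <= p_obs + 1e-7]))
}
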