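test_that("sim_config validates probabilities and mixture sums", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(regime_mix = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(sim_config(cluster_composition = c(0.5, 0.5, 0.2, 0.1)),
               "sum to 1")
  expect_error(sim_config(loss_rate = -1))
  expect_error(sim_config(snv_prob_shared = 1.5), "\\[0, 1\\]")
})

test_that("turnover with zero loss keeps every locus in every species", {
  cfg <- sim_config(n_loci = 500L, loss_rate = 0, seed = 2)
  tv <- simulate_turnover(cfg)
  for (sp in names(tv$peaks))
    expect_equal(nrow(tv$peaks[[sp]]), 500L)
  fr <- sharing_fraction(tv$peaks$C57BL6J, tv$peaks$CAROLI,
                         tv$maps$CAROLI)
  expect_equal(fr$fraction, 1)
})

test_that("anchored sharing matches the binomial closed form at 6 MY", {
  cfg <- sim_config(n_loci = 10000L, loss_rate = 0.12, seed = 11)
  tv <- simulate_turnover(cfg, species = "CAROLI")
  p <- exp(-0.12 * 6)
  obs <- nrow(tv$peaks$CAROLI) / 10000
  expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / 10000))
  # lineage-rate mode halves the survival exponent's time scale
  tv2 <- simulate_turnover(sim_config(n_loci = 10000L, seed = 11),
                           species = "CAROLI", mode = "lineage")
  p2 <- exp(-2 * 0.12 * 6)
  obs2 <- nrow(tv2$peaks$CAROLI) / 10000
  expect_lt(abs(obs2 - p2), 3 * sqrt(p2 * (1 - p2) / 10000))
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_loci = 300L, seed = 77)
  a <- simulate_turnover(cfg); b <- simulate_turnover(cfg)
  expect_identical(a$truth, b$truth)
  ia <- simulate_intensities(a, cfg); ib <- simulate_intensities(b, cfg)
  expect_identical(ia$log2, ib$log2)
  expect_identical(ia$rep1, ib$rep1)
  ca <- simulate_cobinding(cfg); cb <- simulate_cobinding(cfg)
  expect_identical(ca$members, cb$members)
})

test_that("emitted peak counts equal truth presence sums and files re-parse", {
  cfg <- sim_config(n_loci = 400L, seed = 5)
  tv <- simulate_turnover(cfg)
  for (sp in c("CAST", "CAROLI")) {
    expect_equal(nrow(tv$peaks[[sp]]),
                 sum(tv$truth[[paste0("present_", sp)]]))
    f <- withr::local_tempfile(fileext = ".narrowPeak")
    write_peaks(tv$peaks[[sp]], f)
    back <- read_peaks(f, "narrowPeak", species = sp, tf = "CEBPA")
    expect_equal(nrow(back), nrow(tv$peaks[[sp]]))
    expect_equal(back$summit, tv$peaks[[sp]]$summit)
  }
})

test_that("replicate noise reproduces the interindividual R^2 band", {
  cfg <- sim_config(n_loci = 10000L, seed = 13)
  tv <- simulate_turnover(cfg)
  it <- simulate_intensities(tv, cfg)
  for (sp in c("C57BL6J", "SPRET")) {
    r2 <- stats::cor(it$rep1[, sp], it$rep2[, sp])^2
    expect_gte(r2, 0.76)
    expect_lte(r2, 0.83)
  }
})

test_that("zero dispersions give identical intensities for conserved loci", {
  cfg <- sim_config(n_loci = 300L, seed = 3, sigma_conserved = 0,
                    regime_mix = c(1, 0, 0), replicate_noise = 0)
  tv <- simulate_turnover(cfg)
  it <- simulate_intensities(tv, cfg)
  expect_true(all(apply(it$log2, 1L, function(x) diff(range(x))) == 0))
  expect_identical(it$rep1, it$log2)
})

test_that("uncoupled co-loss factorizes over 2TF cluster members", {
  cfg <- sim_config(n_loci = 30000L, seed = 21, coloss_coupling = 0,
                    cluster_composition = c(0, 1, 0, 0))
  cob <- simulate_cobinding(cfg, partner_species = "CAROLI")
  p_loss <- 1 - exp(-0.12 * 6)
  lost <- !cob$members$present_CAROLI
  both <- tapply(lost, cob$members$cluster_id, all)
  n <- length(both)
  expect_lt(abs(mean(both) - p_loss^2),
            3 * sqrt(p_loss^2 * (1 - p_loss^2) / n))
  # fully coupled co-loss: both-lost probability is the marginal
  cfg2 <- sim_config(n_loci = 30000L, seed = 22, coloss_coupling = 1,
                     cluster_composition = c(0, 1, 0, 0))
  cob2 <- simulate_cobinding(cfg2, partner_species = "CAROLI")
  both2 <- tapply(!cob2$members$present_CAROLI,
                  cob2$members$cluster_id, all)
  expect_lt(abs(mean(both2) - p_loss),
            3 * sqrt(p_loss * (1 - p_loss) / length(both2)))
})

test_that("motif simulation respects SNV probabilities and degenerate settings", {
  pwm <- example_pwm()
  cfg0 <- sim_config(n_loci = 200L, seed = 4, snv_prob_shared = 0,
                     snv_prob_unshared = 0, background_snv_rate = 0)
  status <- data.frame(locus_id = sprintf("m%03d", 1:200),
                       shared = rep(c(TRUE, FALSE), 100))
  ms <- simulate_motifs(status, pwm, cfg0)
  expect_identical(ms$anchor, ms$partner)

  cfg1 <- sim_config(n_loci = 6000L, seed = 4, snv_prob_shared = 0.141,
                     snv_prob_unshared = 0.312)
  status1 <- data.frame(locus_id = sprintf("m%04d", 1:6000),
                        shared = rep(c(TRUE, FALSE), 3000))
  ms1 <- simulate_motifs(status1, pwm, cfg1)
  for (sh in c(TRUE, FALSE)) {
    p <- if (sh) 0.141 else 0.312
    obs <- mean(ms1$truth$snv_in_motif[status1$shared == sh])
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / 3000))
  }
})

test_that("knockout simulation removes the deleted factor and applies retention", {
  cfg <- sim_config(n_loci = 2000L, seed = 6,
                    ko_retention = list(contains_deleted = 1,
                                        lacks_deleted = 1, CTCF = 1,
                                        sensitized = NA_real_))
  cob <- simulate_cobinding(cfg)
  ko <- simulate_knockout(cob$peaks$C57BL6J, cob$members, "HNF4A", cfg)
  expect_equal(nrow(ko$HNF4A), 0L)
  expect_equal(as.data.frame(ko$CEBPA),
               as.data.frame(cob$peaks$C57BL6J$CEBPA),
               ignore_attr = TRUE)
  expect_equal(as.data.frame(ko$FOXA1),
               as.data.frame(cob$peaks$C57BL6J$FOXA1),
               ignore_attr = TRUE)
  expect_error(simulate_knockout(cob$peaks$C57BL6J, cob$members,
                                 "FOXA1", cfg), "CEBPA or HNF4A")
})
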