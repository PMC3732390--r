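three_tf_sets <- function(summits_by_tf, species = "C57BL6J") {
  out <- lapply(names(summits_by_tf), function(tf) {
    s <- summits_by_tf[[tf]]
    if (!length(s)) return(peak_set(NULL, species, tf, "pooled"))
    toy_peaks(s - 100L, species = species, tf = tf,
              locus_id = sprintf("%s_%d", tf, seq_along(s)))
  })
  names(out) <- names(summits_by_tf)
  out
}

test_that("cluster categorization covers the canonical cases", {
  sets <- three_tf_sets(list(CEBPA = c(1000, 10000, 10100),
                             HNF4A = c(1100, 5000),
                             FOXA1 = c(1200)))
  cc <- categorize_clusters(sets, window = 300L)
  cl <- cc$clusters[order(cc$clusters$win_start), ]
  expect_equal(cl$class, c("3TF", "1TF", "MULTI"))
  # the 3TF cluster holds one summit per factor at 1000/1100/1200
  expect_equal(cl$member_tfs[1], "CEBPA,FOXA1,HNF4A")
  # two CEBPA summits 100 bp apart form a multiplicity cluster
  expect_equal(cl$member_tfs[3], "CEBPA,CEBPA")
  # partition: every input region appears exactly once
  expect_equal(nrow(cc$members), 6L)
  expect_setequal(cc$members$locus_id,
                  c("CEBPA_1", "CEBPA_2", "CEBPA_3", "HNF4A_1",
                    "HNF4A_2", "FOXA1_1"))
  expect_error(categorize_clusters(sets, window = 0), "positive")
})

test_that("single-linkage components match the transitive-closure oracle", {
  set.seed(61)
  for (rep in 1:4) {
    n <- 500L
    summits <- sort(sample.int(120000L, n))
    tfs <- sample(STUDY_TFS, n, replace = TRUE)
    sets <- lapply(STUDY_TFS, function(tf) {
      s <- summits[tfs == tf]
      toy_peaks(s - 50L, width = 100L, tf = tf,
                locus_id = paste0(tf, "_", s))
    })
    names(sets) <- STUDY_TFS
    cc <- categorize_clusters(sets, window = 300L)
    # quadratic oracle: transitive closure of |summit_i - summit_j| <= 300
    adj <- abs(outer(summits, summits, "-")) <= 300L
    reach <- adj
    repeat {
      nxt <- (reach %*% reach) > 0
      if (identical(nxt, reach)) break
      reach <- nxt
    }
    comp_oracle <- match(apply(reach, 1L, function(r) min(which(r))),
                         unique(apply(reach, 1L, function(r)
                           min(which(r)))))
    got <- cc$members[match(paste0(tfs, "_", summits),
                            cc$members$locus_id), "cluster_id"]
    expect_equal(length(unique(got)), length(unique(comp_oracle)))
    # same partition: cluster ids agree up to relabeling
    expect_true(all(tapply(comp_oracle, got, function(x)
      length(unique(x))) == 1))
    expect_true(all(tapply(got, comp_oracle, function(x)
      length(unique(x))) == 1))
  }
})

test_that("generator composition is recovered per bound region", {
  cfg <- sim_config(n_loci = 20000L, seed = 29)
  cob <- simulate_cobinding(cfg)
  cc <- categorize_clusters(cob$peaks$C57BL6J)
  comp <- cluster_composition(cc)
  target <- c(0.49, 0.23, 0.18, 0.09) / 0.99
  expect_true(all(abs(comp - target) < 0.015))
})

test_that("cluster fates distinguish shared, partial and total loss", {
  sets <- three_tf_sets(list(CEBPA = c(1000, 20000),
                             HNF4A = c(1100, 20100),
                             FOXA1 = numeric()))
  cc <- categorize_clusters(sets)
  map <- toy_identity_map()
  partner_all <- three_tf_sets(list(CEBPA = c(1000, 20000),
                                    HNF4A = c(1100, 20100),
                                    FOXA1 = numeric()), species = "CAST")
  fate <- cluster_fate(cc, "CEBPA", partner_all, map)
  expect_true(all(fate$status == "shared"))

  # co-bound HNF4A lost at the first cluster, anchor lost at the second
  partner_mix <- three_tf_sets(list(CEBPA = c(1000),
                                    HNF4A = c(20100),
                                    FOXA1 = numeric()), species = "CAST")
  fate2 <- cluster_fate(cc, "CEBPA", partner_mix, map)
  expect_equal(fate2$status[order(fate2$cluster_id)],
               c("part_shared", "part_unshared"))

  partner_none <- three_tf_sets(list(CEBPA = numeric(),
                                     HNF4A = numeric(),
                                     FOXA1 = numeric()), species = "CAST")
  fate3 <- cluster_fate(cc, "CEBPA", partner_none, map)
  expect_true(all(fate3$status == "totally_unshared"))

  # no cluster contains FOXA1 here: nothing to evaluate
  expect_equal(nrow(cluster_fate(cc, "FOXA1", partner_all, map)), 0L)
})

test_that("total loss becomes rarer with cluster size under partial coupling", {
  cfg <- sim_config(n_loci = 30000L, seed = 37, coloss_coupling = 0.5)
  cob <- simulate_cobinding(cfg, partner_species = "CAROLI")
  cc <- categorize_clusters(cob$peaks$C57BL6J)
  fate <- cluster_fate(cc, "CEBPA", cob$peaks$CAROLI, cob$maps$CAROLI)
  p_total <- tapply(fate$status == "totally_unshared", fate$class, mean)
  expect_gt(p_total[["1TF"]], p_total[["2TF"]])
  expect_gt(p_total[["2TF"]], p_total[["3TF"]])
})

test_that("coevolution recovers injected correlation and degenerate cases", {
  cfg <- sim_config(n_loci = 12000L, seed = 43)
  cob <- simulate_cobinding(cfg)
  cc <- categorize_clusters(cob$peaks$C57BL6J)
  cv <- coevolution(cc, cob$peaks$SPRET, cob$maps$SPRET)
  expect_true(all(cv$r_squared > 0.3 & cv$r_squared < 0.5))
  expect_true(all(cv$n >= 3))
  # result is symmetric in the factor pair by construction (sorted names)
  expect_true(all(cv$tf_a < cv$tf_b))

  # independent deltas: R^2 near zero
  cfg0 <- sim_config(n_loci = 12000L, seed = 44,
                     delta_intensity_corr = 0)
  cob0 <- simulate_cobinding(cfg0)
  cc0 <- categorize_clusters(cob0$peaks$C57BL6J)
  cv0 <- coevolution(cc0, cob0$peaks$SPRET, cob0$maps$SPRET)
  expect_true(all(cv0$r_squared < 0.01))

  # fewer than three co-bound shared pairs is an error
  tiny <- simulate_cobinding(sim_config(n_loci = 12L, seed = 45,
                                        cluster_composition = c(1, 0, 0, 0)))
  tc <- categorize_clusters(tiny$peaks$C57BL6J)
  expect_error(coevolution(tc, tiny$peaks$SPRET, tiny$maps$SPRET),
               "pairs")
})

test_that("identical delta vectors give a perfect coevolution fit", {
  # two TFs at the same loci whose partner intensities shift identically
  n <- 20L
  starts <- seq_len(n) * 2000L
  ints <- 2^stats::rnorm(n, 8, 1)
  ce <- toy_peaks(starts, tf = "CEBPA", intensity = ints,
                  locus_id = sprintf("c%02d", 1:n))
  hn <- toy_peaks(starts + 120L, tf = "HNF4A", intensity = ints,
                  locus_id = sprintf("h%02d", 1:n))
  cc <- categorize_clusters(list(CEBPA = ce, HNF4A = hn,
                                 FOXA1 = peak_set(NULL, "C57BL6J",
                                                  "FOXA1", "pooled")))
  shift <- 2^stats::rnorm(n, 0, 1)
  partner <- list(
    CEBPA = peak_set(transform(as.data.frame(ce),
                               intensity = intensity * shift),
                     "CAST", "CEBPA", "pooled"),
    HNF4A = peak_set(transform(as.data.frame(hn),
                               intensity = intensity * shift),
                     "CAST", "HNF4A", "pooled"))
  cv <- coevolution(cc, partner, toy_identity_map())
  expect_equal(cv$r_squared[cv$tf_a == "CEBPA" & cv$tf_b == "HNF4A"], 1)
})
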