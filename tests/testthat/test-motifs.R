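test_that("PWM construction and PFM parsing obey the probability invariants", {
  pwm <- example_pwm()
  expect_equal(ncol(pwm$mat), 10L)
  expect_true(all(abs(colSums(pwm$mat) - 1) < 1e-9))
  expect_true(all(pwm$mat > 0))

  # MEME minimal format parses to the same motif
  meme <- c("MEME version 4", "", "ALPHABET= ACGT", "",
            "MOTIF test_motif",
            "letter-probability matrix: alength= 4 w= 2 nsites= 20",
            " 0.7 0.1 0.1 0.1", " 0.1 0.1 0.1 0.7")
  f <- withr::local_tempfile(fileext = ".meme")
  writeLines(meme, f)
  m <- read_pfm(f)
  expect_equal(ncol(m$mat), 2L)
  expect_equal(pwm_consensus(m), "AT")

  expect_error(pwm(matrix(1, 3, 4)), "4 rows")
  expect_error(pwm(matrix(-1, 4, 2)), "non-negative")
})

test_that("consensus attains the closed-form maximal score", {
  pwm <- example_pwm()
  # independent closed form: sum over columns of the best base's log odds
  expected_max <- sum(apply(pwm$mat, 2L, function(col)
    log2(max(col) / 0.25)))
  expect_equal(pwm_max_score(pwm), expected_max)
  hits <- scan_pwm(paste0("ACGT", pwm_consensus(pwm), "ACGT"), pwm)
  expect_equal(max(hits$score), expected_max)
  expect_equal(hits$start[1], 4L)
  # no other 10-mer scores higher over random probes
  set.seed(41)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
               collapse = "")
    hs <- scan_pwm(s, pwm, min_score = -Inf)
    expect_lte(max(hs$score), expected_max + 1e-12)
  }
})

test_that("scanning is strand-symmetric and neutral on uniform PWMs", {
  pwm <- example_pwm()
  set.seed(43)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
    h1 <- scan_pwm(s, pwm, min_score = -Inf)
    h2 <- scan_pwm(rc(s), pwm, min_score = -Inf)
    expect_equal(sort(h1$score), sort(h2$score), tolerance = 1e-12)
    best1 <- h1[1, ]; best2 <- h2[1, ]
    expect_equal(best1$score, best2$score)
    expect_false(best1$strand == best2$strand &&
                 best1$start + best1$end != nchar(s))
  }
  flat <- pwm(matrix(0.25, 4, 6), pseudocount = 0)
  hs <- scan_pwm("ACGTACGTACGT", flat, min_score = -Inf)
  expect_true(all(abs(hs$score) < 1e-12))
  # N-containing windows are skipped
  hn <- scan_pwm("NNNNNNNNNNNNNNN", pwm, min_score = -Inf)
  expect_equal(nrow(hn), 0L)
})

test_that("summit-nearest motif and SNV annotation follow the contract", {
  pwm <- example_pwm()
  cons <- pwm_consensus(pwm)
  flank <- function(n) strrep("C", n)
  anchor <- paste0(flank(20), cons, flank(21))  # 51 bp, motif at 20..30
  expect_equal(nchar(anchor), 51L)

  r0 <- summit_motif_snv(anchor, anchor, pwm)
  expect_equal(r0$hit$start, 20L)
  expect_equal(nrow(r0$snvs), 0L)

  # one substitution inside the motif (position 4, G -> A)
  other <- anchor
  substr(other, 24, 24) <- "A"
  r1 <- summit_motif_snv(anchor, other, pwm)
  expect_equal(nrow(r1$snvs), 1L)
  expect_equal(r1$snvs$pos, 3L)
  expect_equal(r1$snvs$base_anchor, "G")
  expect_equal(r1$snvs$base_other, "A")
  expect_lt(r1$snvs$delta_bits, 0)  # away from consensus

  # substitution in the flank only: empty SNV list
  other2 <- anchor
  substr(other2, 5, 5) <- "T"
  r2 <- summit_motif_snv(anchor, other2, pwm)
  expect_equal(nrow(r2$snvs), 0L)

  expect_error(summit_motif_snv(anchor, paste0(anchor, "A"), pwm),
               "length")
})

test_that("the hit nearest the summit wins over a stronger distal hit", {
  pwm <- example_pwm()
  cons <- pwm_consensus(pwm)
  near <- cons
  substr(near, 3, 3) <- "C"   # weakened copy near the center
  s <- paste0(cons, substr(strrep("ACGT", 4), 1, 15), near,
              substr(strrep("TGCA", 4), 1, 16))
  # window length 51, central base offset 25; near copy spans 25..35
  r <- summit_motif_snv(s, s, pwm)
  expect_equal(r$hit$start, 25L)
  expect_lt(r$hit$score, pwm_max_score(pwm))
})

test_that("delta motif score is additive over SNVs", {
  pwm <- example_pwm()
  cons <- pwm_consensus(pwm)
  expect_equal(delta_motif_score(pwm, cons, cons)$delta_bits, 0)
  # single SNV toward the consensus raises the score
  weak <- cons
  substr(weak, 5, 5) <- "A"
  up <- delta_motif_score(pwm, weak, cons)
  expect_gt(up$delta_bits, 0)
  # multi-SNV delta equals full rescoring difference
  set.seed(47)
  bases <- c("A", "C", "G", "T")
  score_fwd <- function(s) {
    b <- strsplit(s, "")[[1]]
    sum(log2(pwm$mat[cbind(match(b, bases), seq_along(b))] / 0.25))
  }
  for (i in 1:20) {
    a <- paste(sample(bases, 10, replace = TRUE), collapse = "")
    b <- paste(sample(bases, 10, replace = TRUE), collapse = "")
    d <- delta_motif_score(pwm, a, b)
    expect_equal(d$delta_bits, score_fwd(b) - score_fwd(a),
                 tolerance = 1e-12)
    expect_equal(sum(d$per_snv$delta_bits), d$delta_bits)
  }
  expect_error(delta_motif_score(pwm, "ACGT", "ACGT"), "length")
})

test_that("the exact contingency test matches enumeration and fisher.test", {
  flat <- snv_contingency(matrix(10, 2, 2))
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p_value, 1)

  t1 <- matrix(c(12, 2, 3, 13), 2, byrow = TRUE)
  expect_equal(snv_contingency(t1)$p_value, fisher_enum_p(t1))

  # unit margins: two equiprobable tables, two-sided p = 1
  t2 <- matrix(c(1, 0, 0, 1), 2)
  expect_equal(snv_contingency(t2)$p_value, 1)
  expect_true(snv_contingency(t2)$continuity_corrected)

  expect_error(snv_contingency(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")

  set.seed(53)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8) + 1, 2)
    mine <- snv_contingency(tab)
    expect_equal(mine$p_value, stats::fisher.test(tab)$p.value,
                 tolerance = 1e-9)
    expect_equal(mine$p_value, fisher_enum_p(tab), tolerance = 1e-12)
  }
})

test_that("large-table p-values survive in log space", {
  tab <- matrix(c(1980, 1020, 2880, 120), 2, byrow = TRUE)
  res <- snv_contingency(tab)
  expect_lt(res$log_p, log(1e-15))
  expect_true(is.finite(res$log_p))
})

test_that("contingency power rises with the SNV probability gap", {
  pwm <- example_pwm()
  cfg <- sim_config(n_loci = 4000L, seed = 19, snv_prob_shared = 0.141,
                    snv_prob_unshared = 0.312)
  status <- data.frame(locus_id = sprintf("x%04d", 1:4000),
                       shared = rep(c(TRUE, FALSE), 2000))
  ms <- simulate_motifs(status, pwm, cfg)
  tab <- table(shared = factor(status$shared, c(FALSE, TRUE)),
               snv = factor(ms$truth$snv_in_motif, c(TRUE, FALSE)))
  res <- snv_contingency(unclass(tab))
  expect_gt(res$odds_ratio, 1)   # unshared (row 1) carry more SNVs
  expect_lt(res$p_value, 1e-10)
})
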