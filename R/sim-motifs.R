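#' Simulate bound sequences with motif-placed SNVs
#'
#' For each locus, a window of `2 * window + 1` bases centred on the
#' summit is generated: uniform random flanks with one copy of the PWM's
#' consensus motif centred on the summit (so every anchor locus carries a
#' top-scoring, recoverable motif; set `sample_motif = TRUE` to draw
#' motif bases from the PWM's column probabilities instead).  The
#' partner species copy receives an SNV inside the motif with
#' probability `snv_prob_shared` (loci shared with the partner) or
#' `snv_prob_unshared` (unshared loci), at a uniformly chosen motif
#' position, substituting a uniformly chosen different base; every flank
#' base mutates independently at `background_snv_rate`.
#'
#' @param status data.frame with columns `locus_id` and logical `shared`.
#' @param pwm a [pwm] object.
#' @param cfg a [sim_config].
#' @param window half-width of the sequence window around the summit (bp).
#' @param sample_motif draw motif bases from the PWM columns instead of
#'   embedding the consensus.
#' @return list with `anchor` and `partner` (named character vectors of
#'   sequences) and `truth` (data.frame: `locus_id`, `shared`,
#'   `snv_in_motif`, `motif_start` 0-based window offset of the motif,
#'   `snv_pos` 0-based position within the motif, `ref_base`,
#'   `alt_base`).
#' @export
simulate_motifs <- function(status, pwm, cfg = sim_config(),
                            window = 150L, sample_motif = FALSE) {
  sim_seed(cfg$seed, 4L)
  bases <- c("A", "C", "G", "T")
  L <- ncol(pwm$mat)
  n <- nrow(status)
  wlen <- 2L * window + 1L
  if (L > wlen) stop("motif longer than the sequence window")
  motif_start <- window - L %/% 2L        # 0-based; motif spans the summit

  seq_mat <- matrix(sample(bases, n * wlen, replace = TRUE), n, wlen)
  cons <- strsplit(pwm_consensus(pwm), "")[[1L]]
  for (j in seq_len(L))
    seq_mat[, motif_start + j] <- if (sample_motif)
      sample(bases, n, replace = TRUE, prob = pwm$mat[, j])
    else cons[j]
  anchor <- apply(seq_mat, 1L, paste, collapse = "")

  p_snv <- ifelse(status$shared, cfg$snv_prob_shared,
                  cfg$snv_prob_unshared)
  has_snv <- stats::runif(n) < p_snv
  snv_pos <- ifelse(has_snv, sample.int(L, n, replace = TRUE) - 1L,
                    NA_integer_)
  other_mat <- seq_mat
  # background substitutions in the flanks only
  flank <- setdiff(seq_len(wlen), motif_start + seq_len(L))
  bg <- matrix(stats::runif(n * length(flank)) < cfg$background_snv_rate,
               n, length(flank))
  if (any(bg)) {
    idx <- which(bg, arr.ind = TRUE)
    cols <- flank[idx[, 2L]]
    cur <- other_mat[cbind(idx[, 1L], cols)]
    new <- vapply(cur, function(b) sample(setdiff(bases, b), 1L), "")
    other_mat[cbind(idx[, 1L], cols)] <- new
  }
  ref_base <- rep(NA_character_, n)
  alt_base <- rep(NA_character_, n)
  if (any(has_snv)) {
    i <- which(has_snv)
    cols <- motif_start + snv_pos[i] + 1L
    ref_base[i] <- other_mat[cbind(i, cols)]
    alt_base[i] <- vapply(ref_base[i],
                          function(b) sample(setdiff(bases, b), 1L), "")
    other_mat[cbind(i, cols)] <- alt_base[i]
  }
  partner <- apply(other_mat, 1L, paste, collapse = "")
  names(anchor) <- names(partner) <- status$locus_id
  list(anchor = anchor, partner = partner,
       truth = data.frame(locus_id = status$locus_id,
                          shared = status$shared,
                          snv_in_motif = has_snv,
                          motif_start = motif_start,
                          snv_pos = snv_pos, ref_base = ref_base,
                          alt_base = alt_base, stringsAsFactors = FALSE))
}

#' Simulate a transcription-factor knockout condition
#'
#' Removes every peak of the deleted factor and retains each remaining
#' peak with a probability set by its cluster's relation to the deleted
#' factor: `ko_retention$contains_deleted` when the cluster contains the
#' deleted TF, `ko_retention$lacks_deleted` otherwise, and
#' `ko_retention$CTCF` for CTCF peaks (default 1: CTCF binding is
#' unperturbed).  When `ko_retention$sensitized` is set and `members`
#' carries a `sensitized_tf` column, peaks in clusters attributed to the
#' deleted TF's motif are retained at that (lower) rate instead.
#'
#' @param wt named list of wild-type [peak_set]s, one per TF (may include
#'   `CTCF`).
#' @param members data.frame linking peaks to clusters: columns
#'   `locus_id`, `cluster_id`, `tf` (and optionally `sensitized_tf`), as
#'   produced by [simulate_cobinding].
#' @param deleted_tf `"CEBPA"` or `"HNF4A"`.
#' @param cfg a [sim_config].
#' @return named list of KO-condition [peak_set]s (the deleted TF's set is
#'   empty), plus attribute `kept` (data.frame of per-peak survival
#'   flags).
#' @export
simulate_knockout <- function(wt, members, deleted_tf,
                              cfg = sim_config()) {
  if (!deleted_tf %in% c("CEBPA", "HNF4A"))
    stop("deleted_tf must be CEBPA or HNF4A")
  sim_seed(cfg$seed, 5L)
  contains <- tapply(members$tf == deleted_tf, members$cluster_id, any)
  ret <- cfg$ko_retention
  cond <- paste0("KO_", deleted_tf)
  kept_all <- list()
  out <- lapply(names(wt), function(tf) {
    x <- wt[[tf]]
    if (tf == deleted_tf)
      return(peak_set(NULL, ps_species(x), tf, cond))
    if (tf == "CTCF") {
      p <- rep(ret$CTCF, nrow(x))
    } else {
      idx <- match(x$locus_id, members$locus_id)
      if (anyNA(idx))
        stop("peak locus_id absent from cluster membership table")
      cl <- members$cluster_id[idx]
      p <- ifelse(contains[cl], ret$contains_deleted, ret$lacks_deleted)
      if (!is.null(members$sensitized_tf) && !is.na(ret$sensitized)) {
        sens <- members$sensitized_tf[idx] == deleted_tf
        sens[is.na(sens)] <- FALSE
        p[sens] <- ret$sensitized
      }
    }
    keep <- stats::runif(nrow(x)) < p
    kept_all[[tf]] <<- data.frame(tf = tf, locus_id = x$locus_id,
                                  kept = keep, stringsAsFactors = FALSE)
    peak_set(as.data.frame(x)[keep, , drop = FALSE], ps_species(x), tf,
             cond)
  })
  names(out) <- names(wt)
  attr(out, "kept") <- do.call(rbind, kept_all)
  out
}
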