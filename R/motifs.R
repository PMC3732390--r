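#' Position weight matrix
#'
#' Builds a PWM from a count (PFM) or probability matrix.  A pseudocount
#' is added to every cell of a count matrix before normalization;
#' probability columns must already sum to 1.  Scores are log2 odds
#' against the background base frequencies, in bits.
#'
#' @param mat 4 x L numeric matrix, rows A, C, G, T.
#' @param pseudocount added to each cell of a count matrix (default
#'   0.01).
#' @param background background base frequencies (default uniform 0.25).
#' @return list of class `pwm`: `mat` (probability matrix), `bg`,
#'   `pseudocount`, `name`.
#' @param name optional motif name.
#' @export
pwm <- function(mat, pseudocount = 0.01, background = rep(0.25, 4),
                name = NA_character_) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("PWM matrix must have 4 rows (A, C, G, T)")
  rownames(mat) <- c("A", "C", "G", "T")
  if (any(mat < 0)) stop("PWM entries must be non-negative")
  cs <- colSums(mat)
  if (any(cs <= 0)) stop("PWM columns must have positive sums")
  prob <- sweep(mat + pseudocount, 2L, cs + 4 * pseudocount, "/")
  if (any(prob <= 0)) stop("PWM probabilities must be positive")
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-6)
    stop("background must be 4 frequencies summing to 1")
  structure(list(mat = prob, bg = stats::setNames(background,
                                                  c("A", "C", "G", "T")),
                 pseudocount = pseudocount, name = name),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm: %s, length %d\n",
              ifelse(is.na(x$name), "<unnamed>", x$name), ncol(x$mat)))
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Read a motif matrix file
#'
#' Supports JASPAR-style PFM text (`>name` header, four rows
#' `A [ counts ]` ... `T [ counts ]`) and MEME minimal format
#' (`letter-probability matrix` block, one row per position).
#'
#' @param path file path.
#' @inheritParams pwm
#' @return a [pwm].
#' @export
read_pfm <- function(path, pseudocount = 0.01,
                     background = rep(0.25, 4)) {
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- readLines(path)
  if (any(grepl("letter-probability matrix", lines))) {
    i <- grep("letter-probability matrix", lines)[1L]
    name <- sub("^MOTIF\\s+", "", grep("^MOTIF", lines, value = TRUE)[1L])
    rows <- list()
    for (ln in lines[-seq_len(i)]) {
      if (!grepl("^\\s*[0-9.eE+-]", ln)) break
      rows[[length(rows) + 1L]] <-
        as.numeric(strsplit(trimws(ln), "\\s+")[[1L]])
    }
    m <- t(do.call(rbind, rows))
    return(pwm(m, pseudocount, background,
               name = if (length(name)) name else NA_character_))
  }
  hdr <- grep("^>", lines)
  name <- if (length(hdr)) sub("^>\\s*", "", lines[hdr[1L]])
          else NA_character_
  rows <- lapply(c("A", "C", "G", "T"), function(b) {
    ln <- grep(paste0("^", b, "\\b"), lines, value = TRUE)[1L]
    if (is.na(ln)) stop("PFM row for base ", b, " not found in ", path)
    v <- suppressWarnings(as.numeric(
      strsplit(gsub("[^0-9.eE+ -]", " ", sub(paste0("^", b), "", ln)),
               "\\s+")[[1L]]))
    v[!is.na(v)]
  })
  if (length(unique(lengths(rows))) != 1L)
    stop("PFM rows have unequal lengths in ", path)
  pwm(do.call(rbind, rows), pseudocount, background, name = name)
}

#' Write a PWM's probability matrix as JASPAR-style PFM text
#' @param x a [pwm].
#' @param path output path.
#' @export
write_pfm <- function(x, path) {
  lines <- c(paste0(">", ifelse(is.na(x$name), "motif", x$name)),
             vapply(c("A", "C", "G", "T"), function(b)
               sprintf("%s  [ %s ]", b,
                       paste(sprintf("%.6f", x$mat[b, ]),
                             collapse = " ")), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @describeIn pwm consensus sequence (column-wise most probable base).
#' @param x a `pwm`.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$mat)[apply(x$mat, 2L, which.max)], collapse = "")
}

#' @describeIn pwm maximal attainable log2-odds score (bits): the sum over
#'   positions of the best base's log odds.
#' @export
pwm_max_score <- function(x) {
  sum(apply(log2(x$mat / x$bg), 2L, max))
}

# score matrix in bits: rows A,C,G,T (+ N = NA), columns positions
pwm_score_matrix <- function(x) {
  m <- log2(x$mat / x$bg)
  rbind(m, N = NA_real_)
}

pwm_revcomp <- function(x) {
  m <- x$mat[c("T", "G", "C", "A"), rev(seq_len(ncol(x$mat))), drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  p <- x
  p$mat <- m
  p
}

seq_codes <- function(seq) {
  match(strsplit(toupper(seq), "")[[1L]], c("A", "C", "G", "T", "N"))
}

scan_strand <- function(codes, smat) {
  L <- ncol(smat)
  n <- length(codes)
  if (n < L) return(numeric(0))
  offs <- seq_len(n - L + 1L)
  idx <- outer(offs, seq_len(L) - 1L, "+")        # positions per window
  vals <- matrix(smat[cbind(as.vector(codes[idx]),
                            rep(seq_len(L), each = length(offs)))],
                 nrow = length(offs))
  rowSums(vals)                                   # NA when window has N
}

#' Scan a sequence with a PWM on both strands
#'
#' Log2-odds scores `sum(log2(p[pos, base] / bg[base]))` at every offset on
#' both strands; windows containing `N` are skipped.  Hits with score at
#' least `min_score` are returned sorted by decreasing score.  The default
#' threshold is 60\% of the maximal attainable score.
#'
#' @param seq nucleotide string over A/C/G/T/N.
#' @param x a [pwm].
#' @param min_score score threshold in bits (default
#'   `0.6 * pwm_max_score(x)`).
#' @param summit_offset 0-based offset of the peak summit within `seq`
#'   (default: the central base); hit-to-summit distances are measured
#'   from the hit midpoint.
#' @return data.frame of hits: `start` (0-based), `end`, `strand`,
#'   `score` (bits), `distance` (hit midpoint minus summit, bp).
#' @export
scan_pwm <- function(seq, x, min_score = NULL, summit_offset = NULL) {
  if (grepl("[^ACGTNacgtn]", seq)) stop("sequence contains non-ACGTN characters")
  if (is.null(min_score)) min_score <- 0.6 * pwm_max_score(x)
  L <- ncol(x$mat)
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (nchar(seq) < L) {
    warning("sequence shorter than the motif; no hits")
    return(empty)
  }
  if (is.null(summit_offset)) summit_offset <- (nchar(seq) - 1L) / 2
  codes <- seq_codes(seq)
  fwd <- scan_strand(codes, pwm_score_matrix(x))
  rev <- scan_strand(codes, pwm_score_matrix(pwm_revcomp(x)))
  hits <- data.frame(start = c(seq_along(fwd), seq_along(rev)) - 1L,
                     strand = rep(c("+", "-"),
                                  c(length(fwd), length(rev))),
                     score = c(fwd, rev), stringsAsFactors = FALSE)
  hits <- hits[!is.na(hits$score) & hits$score >= min_score, ]
  if (!nrow(hits)) return(empty)
  hits$end <- hits$start + L
  hits$distance <- (hits$start + (L - 1) / 2) - summit_offset
  hits <- hits[order(-hits$score, abs(hits$distance),
                     hits$strand != "+"), ]
  rownames(hits) <- NULL
  hits[, c("start", "end", "strand", "score", "distance")]
}

#' Nearest motif to the summit and its cross-species SNVs
#'
#' In the anchor-species window, the above-threshold motif hit nearest to
#' the summit is selected (ties: higher score, then `+` strand).  The
#' aligned partner-species window is compared base-by-base over the hit's
#' footprint (judged on the anchor-species hit, in motif orientation);
#' each mismatch yields an SNV record with its per-position log2-odds
#' score change.  Indels are out of scope: sequences must be equal-length
#' gapless alignments.
#'
#' @param seq_anchor,seq_other equal-length sequences centred on the
#'   summit.
#' @param x a [pwm].
#' @param min_score threshold in bits (default 60 percent of the maximum).
#' @return list: `hit` (one-row data.frame or `NULL` when no hit) and
#'   `snvs` (data.frame: `pos` 0-based within the motif, `base_anchor`,
#'   `base_other`, `delta_bits`).
#' @export
summit_motif_snv <- function(seq_anchor, seq_other, x, min_score = NULL) {
  if (nchar(seq_anchor) != nchar(seq_other))
    stop("anchor and partner sequences differ in length")
  hits <- scan_pwm(seq_anchor, x, min_score)
  empty_snv <- data.frame(pos = integer(), base_anchor = character(),
                          base_other = character(),
                          delta_bits = numeric(),
                          stringsAsFactors = FALSE)
  if (!nrow(hits)) return(list(hit = NULL, snvs = empty_snv))
  hits <- hits[order(abs(hits$distance), -hits$score,
                     hits$strand != "+"), ]
  hit <- hits[1L, ]
  L <- ncol(x$mat)
  sub_a <- substr(seq_anchor, hit$start + 1L, hit$start + L)
  sub_o <- substr(seq_other, hit$start + 1L, hit$start + L)
  if (hit$strand == "-") {
    rc <- function(s) as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    sub_a <- rc(sub_a); sub_o <- rc(sub_o)
  }
  a <- strsplit(sub_a, "")[[1L]]; o <- strsplit(sub_o, "")[[1L]]
  diffs <- which(a != o)
  if (!length(diffs)) return(list(hit = hit, snvs = empty_snv))
  sm <- log2(x$mat / x$bg)
  delta <- sm[cbind(match(o[diffs], rownames(sm)), diffs)] -
           sm[cbind(match(a[diffs], rownames(sm)), diffs)]
  list(hit = hit,
       snvs = data.frame(pos = diffs - 1L, base_anchor = a[diffs],
                         base_other = o[diffs], delta_bits = delta,
                         stringsAsFactors = FALSE))
}

#' Motif score change between two species' bound sequences
#'
#' `delta = score(other) - score(anchor)` in bits, additive over SNVs:
#' each substitution contributes `log2(p[pos, new] / p[pos, old])`
#' (background cancels position-wise).
#'
#' @param x a [pwm].
#' @param motif_anchor,motif_other motif-length sequences in motif
#'   orientation.
#' @return list: `delta_bits` and `per_snv` decomposition data.frame.
#' @export
delta_motif_score <- function(x, motif_anchor, motif_other) {
  L <- ncol(x$mat)
  if (nchar(motif_anchor) != L || nchar(motif_other) != L)
    stop("motif sequences must have the PWM's length")
  a <- strsplit(toupper(motif_anchor), "")[[1L]]
  o <- strsplit(toupper(motif_other), "")[[1L]]
  if (any(!c(a, o) %in% c("A", "C", "G", "T")))
    stop("motif sequences must be over A/C/G/T")
  diffs <- which(a != o)
  per <- data.frame(pos = diffs - 1L, base_anchor = a[diffs],
                    base_other = o[diffs],
                    delta_bits = log2(
                      x$mat[cbind(match(o[diffs], rownames(x$mat)),
                                  diffs)] /
                      x$mat[cbind(match(a[diffs], rownames(x$mat)),
                                  diffs)]),
                    stringsAsFactors = FALSE)
  list(delta_bits = sum(per$delta_bits), per_snv = per)
}

#' Two-sided exact test of a 2x2 contingency table
#'
#' Fisher's exact test by the point-probability method: the two-sided p
#' sums hypergeometric point probabilities not exceeding the observed
#' table's.  Probabilities are accumulated in log space, so p-values far
#' below 1e-15 (large-table knockout contrasts) do not underflow.  The
#' odds ratio is the sample `(ad)/(bc)`, with a 0.5 continuity correction
#' (flagged) when any cell is zero.
#'
#' @param counts 2x2 matrix of non-negative integers, e.g. rows
#'   shared/unshared, columns SNV/no-SNV.
#' @return list of class `exact_test`: `table`, `odds_ratio`,
#'   `p_value`, `log_p` (natural log, exact even when `p_value`
#'   underflows), `continuity_corrected`.
#' @export
snv_contingency <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("counts must be a 2x2 matrix")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate table: a zero margin")
  a <- counts[1L, 1L]
  r1 <- sum(counts[1L, ]); c1 <- sum(counts[, 1L]); n <- sum(counts)
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  lp <- stats::dhyper(support, c1, n - c1, r1, log = TRUE)
  lp_obs <- stats::dhyper(a, c1, n - c1, r1, log = TRUE)
  keep <- lp <= lp_obs + 1e-7
  mx <- max(lp[keep])
  log_p <- mx + log(sum(exp(lp[keep] - mx)))
  log_p <- min(log_p, 0)
  zero <- any(counts == 0)
  cc <- if (zero) 0.5 else 0
  or <- ((counts[1L, 1L] + cc) * (counts[2L, 2L] + cc)) /
        ((counts[1L, 2L] + cc) * (counts[2L, 1L] + cc))
  structure(list(table = counts, odds_ratio = or,
                 p_value = exp(log_p), log_p = log_p,
                 continuity_corrected = zero),
            class = "exact_test")
}

#' @export
print.exact_test <- function(x, ...) {
  cat(sprintf("exact_test: OR = %.3f, p = %.3g%s\n", x$odds_ratio,
              x$p_value,
              if (x$continuity_corrected) " (continuity-corrected OR)"
              else ""))
  invisible(x)
}
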