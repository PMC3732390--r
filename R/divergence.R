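#' Anchored sharing fraction between two species
#'
#' Fraction of the anchor's TFBRs whose orthologous location in the
#' partner species carries a TFBR of the same factor.  Unalignable anchor
#' peaks (no orthology block) are excluded from the denominator and
#' reported separately.
#'
#' @inheritParams call_shared
#' @param divergence_my divergence time in MY attached to the result
#'   (optional, `NA` by default).
#' @return one-row data.frame: `anchor_species`, `partner_species`, `tf`,
#'   `divergence_my`, `n_shared`, `n_alignable`, `n_unalignable`,
#'   `fraction`.
#' @export
sharing_fraction <- function(anchor, other, map, min_overlap_bp = 1L,
                             divergence_my = NA_real_) {
  calls <- call_shared(anchor, other, map, min_overlap_bp)
  n_ali <- sum(calls$status != "unalignable")
  if (n_ali == 0L)
    stop("sharing fraction undefined: no alignable anchor peaks")
  n_sh <- sum(calls$status == "shared")
  data.frame(anchor_species = ps_species(anchor),
             partner_species = ps_species(other), tf = ps_tf(anchor),
             divergence_my = divergence_my, n_shared = n_sh,
             n_alignable = n_ali,
             n_unalignable = nrow(calls) - n_ali,
             fraction = n_sh / n_ali, stringsAsFactors = FALSE)
}

#' Fit an exponential decay of sharing with divergence time
#'
#' Ordinary least squares of `ln(fraction)` on divergence time `t`; the
#' decay constant is minus the slope, so a fit of
#' `fraction = exp(intercept) * exp(-lambda t)` with free intercept
#' (replicate overlap is below 1 even at t = 0).  An option constrains the
#' intercept to the log of a replicate-overlap baseline.
#'
#' @param points data.frame with columns `t` (MY, >= 0) and `fraction`
#'   (> 0); at least two points.
#' @param intercept `"free"` (default) or a numeric baseline fraction at
#'   t = 0 to constrain the intercept to `log(baseline)`.
#' @return list of class `decay_fit`: `lambda` (1/MY), `intercept`
#'   (log-fraction at t = 0), `se_lambda`, `se_intercept`, `r_squared`,
#'   `n`.
#' @export
fit_decay <- function(points, intercept = "free") {
  if (nrow(points) < 2L) stop("need at least 2 points to fit a decay")
  if (any(points$fraction <= 0))
    stop("fractions must be positive for a log-linear fit")
  if (any(points$t < 0)) stop("divergence times must be non-negative")
  y <- log(points$fraction)
  if (identical(intercept, "free")) {
    fit <- stats::lm(y ~ t, data = data.frame(t = points$t, y = y))
    sm <- suppressWarnings(summary(fit))  # exact fits are fine
    co <- sm$coefficients
    out <- list(lambda = -unname(co["t", "Estimate"]),
                intercept = unname(co["(Intercept)", "Estimate"]),
                se_lambda = unname(co["t", "Std. Error"]),
                se_intercept = unname(co["(Intercept)", "Std. Error"]),
                r_squared = sm$r.squared, n = nrow(points))
  } else {
    if (!is.numeric(intercept) || intercept <= 0)
      stop("intercept must be \"free\" or a positive baseline fraction")
    b0 <- log(intercept)
    fit <- stats::lm(y0 ~ t - 1,
                     data = data.frame(t = points$t, y0 = y - b0))
    co <- suppressWarnings(summary(fit))$coefficients
    ss_res <- sum(stats::residuals(fit)^2)
    ss_tot <- sum((y - mean(y))^2)
    out <- list(lambda = -unname(co["t", "Estimate"]), intercept = b0,
                se_lambda = unname(co["t", "Std. Error"]),
                se_intercept = 0,
                r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                n = nrow(points))
  }
  structure(out, class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "decay_fit: lambda = %.4f /MY (se %.4f), intercept = %.4f, R^2 = %.3f, n = %d\n",
    x$lambda, x$se_lambda, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Cross-species correlation of binding intensities at shared loci
#'
#' Pearson correlation of log2 intensities after per-set median
#' normalization (each set's log2 median is subtracted, removing global
#' enrichment-scale differences between experiments).
#'
#' @param intensity_a,intensity_b positive intensities of the two members
#'   of each shared pair (equal length, n >= 3).
#' @return list: `n`, `r`, `r_squared`, `transform`.
#' @export
intensity_correlation <- function(intensity_a, intensity_b) {
  if (length(intensity_a) != length(intensity_b))
    stop("intensity vectors differ in length")
  if (length(intensity_a) < 3L) stop("need at least 3 pairs")
  if (any(intensity_a <= 0) || any(intensity_b <= 0))
    stop("intensities must be positive")
  a <- log2(intensity_a); a <- a - stats::median(a)
  b <- log2(intensity_b); b <- b - stats::median(b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined: zero variance")
  r <- stats::cor(a, b)
  list(n = length(a), r = r, r_squared = r^2,
       transform = "log2, median-normalized")
}

#' Sensitivity of sharing to the peak-calling threshold (shadow regions)
#'
#' Shadow regions are orthologous locations unbound in the anchor species
#' under the standard peak-calling threshold.  For each threshold in the
#' grid, partner loci whose anchor-side candidate (sub-threshold) peak
#' score reaches the threshold are re-classified as bound, and the sharing
#' fraction is recomputed.  The curve is monotone non-decreasing as the
#' threshold relaxes.
#'
#' @param calls `sharing_calls` from [call_shared] (the baseline).
#' @param candidate_scores numeric vector, one per anchor call: the best
#'   sub-threshold candidate-peak score at the partner's orthologous
#'   position for `unshared` calls (`NA` when no candidate exists).
#'   Ignored for calls already `shared`.
#' @param grid descending numeric vector of score thresholds.
#' @return data.frame with columns `threshold`, `n_shared`, `fraction`.
#' @export
shadow_sensitivity <- function(calls, candidate_scores, grid) {
  if (!length(grid)) stop("threshold grid is empty")
  if (is.unsorted(rev(grid)))
    stop("threshold grid must be descending")
  if (length(candidate_scores) != nrow(calls))
    stop("one candidate score per sharing call required")
  ali <- calls$status != "unalignable"
  n_ali <- sum(ali)
  base_shared <- calls$status == "shared"
  out <- lapply(grid, function(th) {
    rescued <- !base_shared & ali & !is.na(candidate_scores) &
      candidate_scores >= th
    n_sh <- sum(base_shared) + sum(rescued)
    data.frame(threshold = th, n_shared = n_sh,
               fraction = n_sh / n_ali)
  })
  do.call(rbind, out)
}
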