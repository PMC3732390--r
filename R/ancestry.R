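#' Continuous Wagner (L1) parsimony over many loci
#'
#' Farris interval algorithm on a rooted binary tree, vectorized over
#' loci.  Downpass: a leaf's interval is its value; an internal node's
#' interval is the intersection of its children's intervals when
#' non-empty (no cost), otherwise the closed gap between them, adding the
#' gap width to the cost.  The total cost is the exact minimum of
#' `sum |parent - child|` over all assignments of internal values
#' (branch lengths are ignored: unweighted Wagner parsimony).
#'
#' Point estimates are tip-proximal: each internal node's estimate is the
#' point of its Farris interval closest to the downpass midpoint of its
#' smaller (more recently diverged) child subtree; when the two child
#' subtrees are the same size (the root of a cherry, balanced nodes) the
#' interval midpoint is used.  On a pectinate species tree this keeps
#' successive ancestral estimates from inheriting each other's values,
#' which a parent-snapping uppass enforces by construction and which
#' would make non-directional intensity trajectories unrecognizable
#' (see the methods vignette).  `est_lo` / `est_hi` replace the
#' midpoint convention at tie nodes by the interval endpoints, tracing
#' how far the convention can move the reconstruction.
#'
#' @param tree rooted binary [ape::phylo]; tip labels must match
#'   `colnames(X)`.
#' @param X numeric matrix, loci x leaves.
#' @return list: `est` (loci x nodes point estimates), `est_lo`/`est_hi`
#'   (endpoint variants at tie nodes), `lo`/`hi` (Farris intervals),
#'   `cost` (per-locus L1 cost), `node_names` (tip labels followed by
#'   internal-node labels), `tree`.
#' @export
wagner_batch <- function(tree, X) {
  X <- as.matrix(X)
  if (!all(tree$tip.label %in% colnames(X)))
    stop("X must have one column per tree leaf")
  if (anyNA(X[, tree$tip.label]))
    stop("missing leaf values; drop incomplete loci or use ",
         "wagner_parsimony(drop_missing = TRUE) per locus")
  tree <- stats::reorder(tree, "postorder")
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  n <- nrow(X)
  lo <- hi <- est <- matrix(NA_real_, n, nt + nn)
  lo[, seq_len(nt)] <- hi[, seq_len(nt)] <- X[, tree$tip.label]
  cost <- numeric(n)
  parents <- unique(tree$edge[, 1L])        # postorder over internal nodes
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  for (nd in parents) {
    ch <- kids[[as.character(nd)]]
    if (length(ch) != 2L) stop("tree must be strictly binary")
    a <- pmax(lo[, ch[1L]], lo[, ch[2L]])
    b <- pmin(hi[, ch[1L]], hi[, ch[2L]])
    cost <- cost + pmax(a - b, 0)
    lo[, nd] <- pmin(a, b)
    hi[, nd] <- pmax(a, b)
  }
  # subtree sizes (number of leaves below each node)
  size <- c(rep(1L, nt), rep(0L, nn))
  for (nd in parents) {
    ch <- kids[[as.character(nd)]]
    size[nd] <- size[ch[1L]] + size[ch[2L]]
  }
  est <- est_lo <- est_hi <- matrix(NA_real_, n, nt + nn)
  est[, seq_len(nt)] <- est_lo[, seq_len(nt)] <- est_hi[, seq_len(nt)] <-
    X[, tree$tip.label]
  midp <- (lo + hi) / 2
  for (nd in parents) {
    ch <- kids[[as.character(nd)]]
    if (size[ch[1L]] == size[ch[2L]]) {          # tie: midpoint convention
      est[, nd] <- midp[, nd]
      est_lo[, nd] <- lo[, nd]
      est_hi[, nd] <- hi[, nd]
    } else {
      small <- ch[which.min(size[ch])]
      v <- pmin(pmax(midp[, small], lo[, nd]), hi[, nd])
      est[, nd] <- est_lo[, nd] <- est_hi[, nd] <- v
    }
  }
  node_names <- c(tree$tip.label,
                  if (!is.null(tree$node.label)) tree$node.label
                  else paste0("node", seq_len(nn)))
  colnames(lo) <- colnames(hi) <- colnames(est) <- node_names
  colnames(est_lo) <- colnames(est_hi) <- node_names
  list(est = est, est_lo = est_lo, est_hi = est_hi, lo = lo, hi = hi,
       cost = cost, node_names = node_names, tree = tree)
}

#' Wagner parsimony for a single locus
#'
#' @param tree rooted binary [ape::phylo].
#' @param leaf_values named numeric vector, one value per leaf.
#' @param drop_missing drop leaves with `NA` and reconstruct on the
#'   induced tree (flagged in the result); default errors on `NA`.
#' @return list of class `intensity_profile`: `nodes` (data.frame with
#'   `node`, `lo`, `hi`, `estimate`), `cost`, `dropped_leaves`.
#' @export
wagner_parsimony <- function(tree, leaf_values, drop_missing = FALSE) {
  vals <- leaf_values[tree$tip.label]
  dropped <- character()
  if (anyNA(vals)) {
    if (!drop_missing)
      stop("missing value for leaf ",
           paste(tree$tip.label[is.na(vals)], collapse = ", "))
    dropped <- tree$tip.label[is.na(vals)]
    tree <- ape::drop.tip(tree, dropped)
    if (length(tree$tip.label) < 2L)
      stop("fewer than 2 leaves left after dropping missing values")
    vals <- leaf_values[tree$tip.label]
  }
  w <- wagner_batch(tree, matrix(vals, 1L,
                                 dimnames = list(NULL, tree$tip.label)))
  structure(list(nodes = data.frame(node = w$node_names,
                                    lo = w$lo[1L, ], hi = w$hi[1L, ],
                                    estimate = w$est[1L, ],
                                    row.names = NULL,
                                    stringsAsFactors = FALSE),
                 cost = w$cost[1L], dropped_leaves = dropped),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("intensity_profile: L1 parsimony cost %.4f\n", x$cost))
  print(x$nodes)
  invisible(x)
}

# class of a matrix of four ancestral values, columns in root-to-recent
# order (A4, A3, A2, A1)
trajectory_class_points <- function(anc, tau) {
  cols <- lapply(seq_len(ncol(anc)), function(j) anc[, j])
  spread <- do.call(pmax, cols) - do.call(pmin, cols)
  up <- down <- TRUE
  for (j in seq_len(ncol(anc) - 1L)) {
    d <- anc[, j + 1L] - anc[, j]
    up <- up & d >= 0
    down <- down & d <= 0
  }
  total <- abs(anc[, ncol(anc)] - anc[, 1L])
  ifelse(spread <= tau, "conserved",
         ifelse((up | down) & total > tau, "progressive", "random"))
}

is_conserved_points <- function(anc, tau) {
  cols <- lapply(seq_len(ncol(anc)), function(j) anc[, j])
  do.call(pmax, cols) - do.call(pmin, cols) <= tau
}

#' Classify ancestral binding-intensity trajectories
#'
#' Given the four reconstructed mouse ancestors ordered root-to-recent
#' (A4, A3, A2, A1), a locus is `conserved` when the ancestral spread
#' (max - min) is at most `tau`; `progressive` when the sequence is
#' monotone (non-strict) and the net change `|A1 - A4|` exceeds `tau`
#' (so conserved and progressive are mutually exclusive); `random`
#' otherwise.  Parsimony reconstructions are not unique: when moving the
#' midpoint-convention estimates to their interval endpoints
#' (`wagner_batch()$est_lo` / `$est_hi`) flips the similarity decision
#' (conserved versus not), the locus is `undetermined` -- its ancestral
#' spread genuinely straddles the tolerance within the reconstruction's
#' freedom.  Directional differences between alternative reconstructions
#' are not flagged: they reflect the estimator's freedom, not the data,
#' and resolve to `random` through the "neither" rule.
#'
#' @param est matrix (loci x 4) of ancestral point estimates, columns
#'   ordered A4, A3, A2, A1.
#' @param est_lo,est_hi optional endpoint-variant estimates; enable the
#'   `undetermined` call.
#' @param tau similarity tolerance in log2 units (default 0.585, i.e.
#'   1.5-fold).
#' @return character vector of classes.
#' @export
classify_trajectory <- function(est, est_lo = NULL, est_hi = NULL,
                                tau = 0.585) {
  if (tau <= 0) stop("tau must be positive")
  est <- as.matrix(est)
  if (ncol(est) != 4L) stop("expected four ancestral nodes")
  cls <- trajectory_class_points(est, tau)
  if (!is.null(est_lo) && !is.null(est_hi)) {
    cons <- is_conserved_points(est, tau)
    flip <- is_conserved_points(as.matrix(est_lo), tau) != cons |
            is_conserved_points(as.matrix(est_hi), tau) != cons
    cls[flip] <- "undetermined"
  }
  cls
}

# order the mouse-ancestor columns A4..A1 out of a wagner_batch result
ancestor_columns <- function(w) {
  want <- c("A4", "A3", "A2", "A1")
  if (!all(want %in% w$node_names))
    stop("tree does not carry ancestor labels A1..A4")
  want
}

#' Ancestral profiles and trajectory classes for an intensity matrix
#'
#' Runs Wagner parsimony on every locus of a (log2, per-species
#' median-normalized) intensity matrix over the five mouse leaves and
#' classifies each trajectory.
#'
#' @param X loci x species matrix of log2 intensities; column names must
#'   cover the tree's leaves.
#' @param tree the mouse clade tree ([build_study_phylogeny] +
#'   [mouse_clade]); internal nodes labelled A1..A4.
#' @param tau classification tolerance (log2 units).
#' @return data.frame: `locus_id`, ancestor estimates `A4..A1`, `cost`,
#'   `class`.
#' @export
ancestral_profiles <- function(X, tree, tau = 0.585) {
  w <- wagner_batch(tree, X)
  anc <- ancestor_columns(w)
  cls <- classify_trajectory(w$est[, anc, drop = FALSE],
                             w$est_lo[, anc, drop = FALSE],
                             w$est_hi[, anc, drop = FALSE], tau)
  out <- data.frame(locus_id = if (!is.null(rownames(X))) rownames(X)
                    else sprintf("L%06d", seq_len(nrow(X))),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(w$est[, anc, drop = FALSE]))
  out$cost <- w$cost
  out$class <- cls
  out
}

#' Permutation null for trajectory-class fractions
#'
#' Reassigns intensities randomly within each species across loci (each
#' species column permuted independently), re-runs parsimony and
#' classification, and compares observed class fractions with the
#' permutation distribution: enrichment p for `conserved`
#' (`(1 + #{perm >= obs}) / (n_perm + 1)`), depletion p for
#' `progressive` and `random`.
#'
#' @inheritParams ancestral_profiles
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return list of class `null_distribution`: `observed` (class
#'   fractions), `perm` (n_perm x class matrix), `p` (named p-values),
#'   `n_perm`.
#' @export
randomization_null <- function(X, tree, tau = 0.585, n_perm = 999L,
                               seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (nrow(X) < 2L) stop("need at least 2 loci to permute")
  lev <- c("conserved", "progressive", "random", "undetermined")
  frac <- function(M) {
    w <- wagner_batch(tree, M)
    anc <- ancestor_columns(w)
    cls <- classify_trajectory(w$est[, anc], w$est_lo[, anc],
                               w$est_hi[, anc], tau)
    tab <- table(factor(cls, lev))
    as.vector(tab) / nrow(M)
  }
  observed <- stats::setNames(frac(X), lev)
  set.seed(seed)
  perm <- matrix(NA_real_, n_perm, length(lev),
                 dimnames = list(NULL, lev))
  for (i in seq_len(n_perm)) {
    Xp <- apply(X, 2L, sample)
    colnames(Xp) <- colnames(X)
    perm[i, ] <- frac(Xp)
  }
  p <- c(conserved = (1 + sum(perm[, "conserved"] >=
                                observed["conserved"])) / (n_perm + 1),
         progressive = (1 + sum(perm[, "progressive"] <=
                                  observed["progressive"])) /
           (n_perm + 1),
         random = (1 + sum(perm[, "random"] <= observed["random"])) /
           (n_perm + 1))
  structure(list(observed = observed, perm = perm, p = p,
                 n_perm = n_perm), class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution: %d permutations\n", x$n_perm))
  cat("observed fractions:\n"); print(round(x$observed, 4))
  cat("p-values (conserved enrichment; progressive/random depletion):\n")
  print(signif(x$p, 3))
  invisible(x)
}

#' Summaries by depth of conservation
#'
#' Bins loci by the number of species in which they are bound (1-5) and
#' summarizes, per depth bin: locus count, mean log2 intensity, fraction
#' of loci inside 2TF/3TF clusters, and fraction of shared loci whose
#' motif carries an SNV.
#'
#' @param presence logical matrix, loci x species.
#' @param log2_intensity numeric vector (anchor-species log2 intensity).
#' @param in_cluster optional logical vector: locus belongs to a 2TF or
#'   3TF cluster.
#' @param has_snv optional logical vector: motif carries an SNV (NA =
#'   not assessed).
#' @return data.frame: `depth`, `n`, `mean_log2`, `frac_cluster`,
#'   `frac_snv`.
#' @export
depth_of_conservation <- function(presence, log2_intensity,
                                  in_cluster = NULL, has_snv = NULL) {
  depth <- rowSums(presence)
  bins <- sort(unique(depth))
  out <- lapply(bins, function(d) {
    i <- depth == d
    data.frame(depth = d, n = sum(i),
               mean_log2 = mean(log2_intensity[i]),
               frac_cluster = if (is.null(in_cluster)) NA_real_
                              else mean(in_cluster[i]),
               frac_snv = if (is.null(has_snv)) NA_real_
                          else mean(has_snv[i], na.rm = TRUE))
  })
  do.call(rbind, out)
}

#' Median-normalize a matrix of intensities on the log2 scale
#' @param intensity positive matrix, loci x species.
#' @return log2 matrix with each column's median subtracted.
#' @export
normalize_log2 <- function(intensity) {
  l <- log2(intensity)
  sweep(l, 2L, apply(l, 2L, stats::median), "-")
}
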