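study_mouse_tree <- function() mouse_clade(build_study_phylogeny())

# exhaustive oracle: the L1 minimum is attained with internal nodes
# assigned leaf values, so enumerate all such assignments
brute_wagner_cost <- function(tree, vals) {
  tree <- stats::reorder(tree, "postorder")
  v <- vals[tree$tip.label]
  grid <- as.matrix(expand.grid(rep(list(v), tree$Nnode)))
  min(apply(grid, 1L, function(g) {
    a <- c(v, g)
    sum(abs(a[tree$edge[, 1L]] - a[tree$edge[, 2L]]))
  }))
}

test_that("constant leaves reconstruct as constant with zero cost", {
  tree <- study_mouse_tree()
  vals <- stats::setNames(rep(5, 5), tree$tip.label)
  w <- wagner_parsimony(tree, vals)
  expect_equal(w$cost, 0)
  expect_true(all(w$nodes$estimate == 5))
  expect_true(all(w$nodes$lo == 5 & w$nodes$hi == 5))
})

test_that("a two-leaf cherry yields the Farris interval and cost |a-b|", {
  cherry <- ape::read.tree(text = "(a:1,b:1)r;")
  w <- wagner_parsimony(cherry, c(a = 1, b = 3))
  expect_equal(w$cost, 2)
  anc <- w$nodes[w$nodes$node == "r", ]
  expect_equal(c(anc$lo, anc$hi), c(1, 3))
  expect_equal(anc$estimate, 2)  # midpoint convention at balanced nodes
})

test_that("interval-algorithm cost equals the exhaustive minimum", {
  tree <- study_mouse_tree()
  set.seed(71)
  for (i in 1:300) {
    vals <- stats::setNames(stats::runif(5, 0, 10), tree$tip.label)
    expect_equal(wagner_parsimony(tree, vals)$cost,
                 brute_wagner_cost(tree, vals), tolerance = 1e-9)
  }
})

test_that("cost is translation- and scale-equivariant; estimates stay in intervals", {
  tree <- study_mouse_tree()
  set.seed(73)
  X <- matrix(stats::rnorm(200 * 5, 8, 2), 200,
              dimnames = list(NULL, tree$tip.label))
  w <- wagner_batch(tree, X)
  expect_true(all(w$est >= w$lo - 1e-12 & w$est <= w$hi + 1e-12))
  expect_true(all(w$cost >= 0))
  expect_equal(wagner_batch(tree, 3 * X + 7)$cost, 3 * w$cost)
  expect_equal(wagner_batch(tree, -X)$cost, w$cost)
  # zero cost iff all leaves equal
  expect_equal(sum(w$cost == 0), 0L)
  Xc <- matrix(4, 3, 5, dimnames = list(NULL, tree$tip.label))
  expect_equal(wagner_batch(tree, Xc)$cost, rep(0, 3))
})

test_that("missing leaves error unless dropped onto the induced tree", {
  tree <- study_mouse_tree()
  vals <- c(C57BL6J = 1, AJ = 2, CAST = NA, SPRET = 4, CAROLI = 5)
  expect_error(wagner_parsimony(tree, vals), "CAST")
  w <- wagner_parsimony(tree, vals, drop_missing = TRUE)
  expect_equal(w$dropped_leaves, "CAST")
  expect_equal(w$cost, brute_wagner_cost(ape::drop.tip(tree, "CAST"),
                                         vals[!is.na(vals)]))
})

test_that("trajectory classes follow the spread/monotonicity rule", {
  tau <- 0.585
  expect_equal(classify_trajectory(rbind(c(5, 5, 5, 5)), tau = tau),
               "conserved")
  expect_equal(classify_trajectory(rbind(c(1, 2, 3, 4)), tau = tau),
               "progressive")
  expect_equal(classify_trajectory(rbind(c(4, 3, 2, 1)), tau = tau),
               "progressive")
  expect_equal(classify_trajectory(rbind(c(1, 4, 2, 5)), tau = tau),
               "random")
  # monotone but small net change is conserved, not progressive
  expect_equal(classify_trajectory(rbind(c(1, 1.1, 1.2, 1.3)),
                                   tau = tau), "conserved")
  expect_error(classify_trajectory(rbind(c(1, 2, 3, 4)), tau = 0),
               "positive")
})

test_that("regime labels are recovered from generator defaults", {
  tree <- study_mouse_tree()
  cfg <- sim_config(n_loci = 5000L, seed = 83)
  tv <- simulate_turnover(cfg)
  it <- simulate_intensities(tv, cfg)
  X <- normalize_log2(2^it$log2[, MOUSE_SPECIES])
  prof <- ancestral_profiles(X, tree)
  for (rg in c("conserved", "progressive", "random")) {
    rec <- mean(prof$class[it$regime == rg] == rg)
    expect_gte(rec, 0.9)
  }
  expect_lt(mean(prof$class == "undetermined"), 0.05)
})

test_that("the permutation null is deterministic and bounded below", {
  tree <- study_mouse_tree()
  set.seed(89)
  X <- matrix(stats::rnorm(300 * 5), 300,
              dimnames = list(NULL, tree$tip.label))
  n1 <- randomization_null(X, tree, n_perm = 49L, seed = 7)
  n2 <- randomization_null(X, tree, n_perm = 49L, seed = 7)
  expect_identical(n1$perm, n2$perm)
  expect_identical(n1$p, n2$p)
  expect_true(all(n1$p >= 1 / 50))
  expect_equal(rowSums(n1$perm), rep(1, 49L))
  expect_error(randomization_null(X, tree, n_perm = 0L), "n_perm")
})

test_that("conserved enrichment reaches the permutation floor when forced", {
  tree <- study_mouse_tree()
  cfg <- sim_config(n_loci = 1500L, seed = 97,
                    regime_mix = c(0.5, 0.05, 0.45))
  tv <- simulate_turnover(cfg)
  it <- simulate_intensities(tv, cfg)
  X <- normalize_log2(2^it$log2[, MOUSE_SPECIES])
  null <- randomization_null(X, tree, n_perm = 99L, seed = 3)
  expect_equal(unname(null$p["conserved"]), 1 / 100)
  # shuffling destroys half the conserved fraction or more
  expect_gt(null$observed[["conserved"]],
            max(null$perm[, "conserved"]))
})

test_that("fully random data sit inside the null's central region", {
  tree <- study_mouse_tree()
  cfg <- sim_config(n_loci = 800L, seed = 101,
                    regime_mix = c(0, 0, 1))
  tv <- simulate_turnover(cfg)
  it <- simulate_intensities(tv, cfg)
  X <- normalize_log2(2^it$log2[, MOUSE_SPECIES])
  null <- randomization_null(X, tree, n_perm = 99L, seed = 5)
  ci <- stats::quantile(null$perm[, "conserved"], c(0.025, 0.975))
  expect_gte(null$observed[["conserved"]], ci[[1]])
  expect_lte(null$observed[["conserved"]], ci[[2]])
})

test_that("depth-of-conservation summaries bin and summarize correctly", {
  set.seed(103)
  n <- 600L
  presence <- cbind(TRUE,
                    matrix(stats::runif(n * 4) < 0.7, n, 4))
  depth <- rowSums(presence)
  # deep loci get a +1 log2 boost per depth unit
  li <- stats::rnorm(n, 8, 0.2) + depth
  d <- depth_of_conservation(presence, li,
                             in_cluster = depth >= 3,
                             has_snv = stats::runif(n) < 0.2)
  expect_equal(d$depth, sort(unique(depth)))
  expect_equal(sum(d$n), n)
  expect_true(all(diff(d$mean_log2) > 0))
  # all species identical: a single depth-5 bin
  d5 <- depth_of_conservation(matrix(TRUE, 10, 5), rep(1, 10))
  expect_equal(d5$depth, 5)
  expect_equal(d5$n, 10)
})
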