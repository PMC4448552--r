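test_that("pruning matches a two-tip closed form and brute-force summation", {
  m <- subst_model("WAG")
  t2 <- read_newick(text = "(A:0.3,B:0.3);")
  aln <- new_msa(c("A", "B"), c("A", "A"))
  P <- oracle_prob_matrix(m, 0.3)
  hand <- log(sum(m$freq * P[, "A"]^2))
  expect_equal(tree_loglik(t2, aln, m), hand, tolerance = 1e-10)

  # 5-tip unrooted tree, 2 sites (one with missing data), exhaustive
  # summation over internal states
  t5 <- read_newick(text = "((A:0.12,B:0.3):0.08,(C:0.2,D:0.05):0.15,E:0.4);")
  aln5 <- new_msa(c("A", "B", "C", "D", "E"),
                  c("AW", "CW", "AD", "AX", "E-"))
  ll <- tree_loglik(t5, aln5, m)
  brute <- 0
  for (site in 1:2) {
    states <- setNames(substr(aln5$seqs, site, site), aln5$ids)
    states[states %in% c("X", "-")] <- NA
    brute <- brute + log(unname(oracle_site_lik(t5, states, m)))
  }
  expect_equal(ll, brute, tolerance = 1e-10)
})

test_that("likelihood limits behave: saturation and degenerate gamma", {
  m <- subst_model("WAG")
  t2 <- read_newick(text = "(A:50,B:50);")
  aln <- new_msa(c("A", "B"), c("AR", "CW"))
  ll <- tree_loglik(t2, aln, m)
  sat <- sum(log(m$freq[c("A", "R")])) + sum(log(m$freq[c("C", "W")]))
  expect_equal(ll, sat, tolerance = 1e-5)

  t4 <- read_newick(text = "((A:0.2,B:0.15):0.1,(C:0.3,D:0.1):0.05);")
  aln4 <- sim_alignment(t4, 40, m, seed = 2)
  mg <- subst_model("WAG", gamma_shape = 1e6)
  expect_equal(tree_loglik(t4, aln4, mg), tree_loglik(t4, aln4, m),
               tolerance = 1e-6)
})

test_that("likelihood is invariant under re-rooting", {
  m <- subst_model("WAG", gamma_shape = 0.7)
  t5 <- read_newick(text = "((A:0.1,B:0.2):0.1,(C:0.3,D:0.1):0.2,E:0.15);")
  aln <- sim_alignment(t5, 30, m, seed = 4)
  base <- tree_loglik(t5, aln, m)
  for (og in c("A", "C", "E")) {
    rooted <- ape::root(t5, outgroup = og, resolve.root = TRUE)
    expect_equal(tree_loglik(rooted, aln, m), base, tolerance = 1e-9)
  }
})

test_that("neighbor joining recovers additive trees exactly", {
  # path distances of ((A:1,B:2):1,(C:3,D:1))
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- 3; D["A", "C"] <- 5; D["A", "D"] <- 3
  D["B", "C"] <- 6; D["B", "D"] <- 4; D["C", "D"] <- 4
  D <- D + t(D)
  tr <- nj_tree(D)
  expect_setequal(tree_splits(tr), "C|D")  # the AB|CD split, keyed by the non-reference side
  # recovered path lengths equal the inputs
  pd <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(unname(pd), unname(D), tolerance = 1e-9)

  # three taxa: three-point formulas
  D3 <- matrix(c(0, 2, 3, 2, 0, 4.5, 3, 4.5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(D3)
  pd3 <- ape::cophenetic.phylo(t3)[rownames(D3), colnames(D3)]
  expect_equal(unname(pd3), unname(D3), tolerance = 1e-9)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("branch-length optimisation never decreases the likelihood", {
  m <- subst_model("WAG", gamma_shape = 1)
  t4 <- read_newick(text = "((A:0.4,B:0.02):0.2,(C:0.05,D:0.3):0.1);")
  aln <- sim_alignment(t4, 120, m, seed = 12)
  start <- t4
  start$edge.length <- rep(0.25, nrow(start$edge))
  l0 <- tree_loglik(start, aln, m)
  o <- optimize_branch_lengths(start, aln, m)
  expect_gte(o$loglik, l0 - 1e-9)
  expect_true(all(o$tree$edge.length >= 0))
})

test_that("simulated branch lengths are recovered, zero branches shrink", {
  m <- subst_model("WAG", gamma_shape = 1)
  true_tree <- read_newick(
    text = "((A:0.3,B:0.25):0.15,(C:0.2,D:0.1):0.0):0;")
  true_tree <- ape::unroot(true_tree)
  aln <- sim_alignment(true_tree, 1000, m, seed = 31,
                       gamma_cats = discrete_gamma_rates(1, 4))
  start <- true_tree
  start$edge.length <- rep(0.2, nrow(start$edge))
  o <- optimize_branch_lengths(start, aln, m)
  truth <- true_tree$edge.length
  est <- o$tree$edge.length
  big <- truth >= 0.05
  expect_true(all(abs(est[big] - truth[big]) / truth[big] < 0.25))
  expect_true(all(est[truth == 0] <= 0.01))
})

test_that("NNI search finds the exhaustive optimum on four taxa", {
  m <- subst_model("WAG", gamma_shape = 1)
  true_tree <- ape::unroot(read_newick(
    text = "((A:0.2,B:0.2):0.3,(C:0.2,D:0.2):0.0):0;"))
  aln <- sim_alignment(true_tree, 300, m, seed = 9)
  s <- nni_search(aln, m)
  topos <- c("((A,B),(C,D));", "((A,C),(B,D));", "((A,D),(B,C));")
  lls <- vapply(topos, function(tt) {
    optimize_branch_lengths(ape::unroot(read_newick(text = tt)), aln, m)$loglik
  }, 0)
  expect_equal(s$loglik, max(lls), tolerance = 1e-2)
  # starting at the true topology never moves to a worse neighbour
  s2 <- nni_search(aln, m, start = true_tree)
  expect_setequal(tree_splits(s2$tree), tree_splits(true_tree))
})

test_that("six-taxon topologies are recovered from clean simulated data", {
  m <- subst_model("WAG", gamma_shape = 1)
  true_tree <- ape::unroot(read_newick(text = paste0(
    "(((A:0.1,B:0.1):0.15,(C:0.1,D:0.1):0.15):0.1,E:0.3,F:0.35);")))
  wins <- 0
  for (r in 1:5) {
    aln <- sim_alignment(true_tree, 700, m, seed = 100 + r)
    s <- nni_search(aln, m)
    if (setequal(tree_splits(s$tree), tree_splits(true_tree))) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("model selection ranks by AIC and recovers the matrix family", {
  m <- subst_model("WAG", gamma_shape = 0.8)
  tree <- ape::unroot(read_newick(
    text = "((A:0.25,B:0.2):0.15,(C:0.2,D:0.25):0.1,(E:0.3,F:0.2):0.1);"))
  wins <- 0
  for (r in 1:3) {
    aln <- sim_alignment(tree, 600, m, seed = 200 + r,
                         gamma_cats = discrete_gamma_rates(0.8, 4))
    cand <- list(subst_model("WAG", gamma_shape = 1),
                 subst_model("JTT", gamma_shape = 1),
                 subst_model("WAG"), subst_model("JTT"))
    fit <- select_model(aln, cand)
    expect_equal(fit$AIC, -2 * fit$loglik + 2 * fit$k)
    expect_equal(fit$dAIC[1], 0)
    best_wag <- min(fit$AIC[grepl("WAG", fit$model)])
    best_jtt <- min(fit$AIC[grepl("JTT", fit$model)])
    if (best_wag < best_jtt) wins <- wins + 1
    # adding gamma never lowers the maximised likelihood
    expect_gte(fit$loglik[fit$model == "WAG+G"],
               fit$loglik[fit$model == "WAG"] - 1e-6)
  }
  expect_gte(wins, 3)
})

test_that("bootstrap supports are deterministic, bounded and informative", {
  m <- subst_model("WAG", gamma_shape = 1)
  true_tree <- ape::unroot(read_newick(text = paste0(
    "(((A:0.1,B:0.1):0.15,(C:0.1,D:0.1):0.15):0.1,E:0.3,F:0.35);")))
  aln <- sim_alignment(true_tree, 900, m, seed = 55)
  best <- nj_tree(msa_distances(aln))
  b1 <- bootstrap_support(aln, best, 40, seed = 3)
  b2 <- bootstrap_support(aln, best, 40, seed = 3)
  expect_identical(b1$supports, b2$supports)
  expect_true(all(b1$supports >= 0 & b1$supports <= 100))
  # clean data: the true splits get strong support
  for (k in tree_splits(true_tree)) {
    expect_gte(unname(b1$supports[k]), 90)
  }
})
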