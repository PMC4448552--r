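test_that("Yule trees are ultrametric, reproducible and sized correctly", {
  expect_error(simulate_species_tree(1, 1, 1), "n_taxa")
  t2 <- simulate_species_tree(2, 1, 5)
  d <- ape::node.depth.edgelength(t2)
  expect_equal(d[1], d[2], tolerance = 1e-12)

  a <- simulate_species_tree(50, 1, 9)
  b <- simulate_species_tree(50, 1, 9)
  expect_identical(write_newick(a), write_newick(b))
  depths <- ape::node.depth.edgelength(a)[1:50]
  expect_lt(max(depths) - min(depths), 1e-9)
})

test_that("Yule lineage accumulation grows at the birth rate", {
  # regression of log(lineage count) on time across replicates; the pure
  # birth process gives slope ~ birth_rate
  # split times scale as t_k ~ ln(k)/lambda; regress t on log-lineages
  # (the noise sits in the times) and invert the slope
  xs <- c(); ys <- c()
  for (r in 1:100) {
    tr <- simulate_species_tree(30, 1, r)
    bt <- sort(max(ape::branching.times(tr)) - ape::branching.times(tr))
    k <- 2:(length(bt) + 1)
    xs <- c(xs, bt); ys <- c(ys, log(k))
  }
  rate_hat <- 1 / coef(lm(xs ~ ys))[2]
  expect_gt(rate_hat, 0.8)
  expect_lt(rate_hat, 1.2)
})

test_that("zero branch lengths leave sequences identical to the root", {
  tree <- read_newick(text = "(A:0,B:0)root;")
  specs <- list(F1 = architecture_spec(c("signal_peptide", "lox")))
  out <- evolve_repertoire(tree, specs, list(seed = 3))
  expect_equal(out$records$sequence[1], out$records$sequence[2])
})

test_that("a root duplication doubles every tip repertoire", {
  tree <- read_newick(text = "((A:0.1,B:0.1)n1:0.1,C:0.2)root;")
  specs <- list(F1 = architecture_spec(c("signal_peptide", "lox")))
  ev <- data.frame(branch = "n1", type = "duplication", family = "F1",
                   new_family = "F2")
  out <- evolve_repertoire(tree, specs, list(seed = 3, events = ev))
  counts <- table(out$truth$taxon)
  expect_equal(as.vector(counts[c("A", "B")]), c(2L, 2L))
  expect_equal(as.vector(counts["C"]), 1L)
})

test_that("substitution proportions match the matrix-exponential expectation", {
  # one branch of length d, uniform rates: expected proportion of differing
  # sites is 1 - sum_a pi_a P_aa(d); observed within 3 SE over 200 sites
  m <- subst_model("WAG")
  d <- 0.3
  set.seed(41)
  aa <- rownames(m$Q)
  root <- sample(aa, 200, TRUE, prob = m$freq)
  tip <- loxevo:::evolve_chars(root, d, m, rep(1, 200), rep(FALSE, 200))
  P <- oracle_prob_matrix(m, d)
  p_exp <- 1 - sum(m$freq * diag(P))
  p_obs <- mean(root != tip)
  se <- sqrt(p_exp * (1 - p_exp) / 200)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("fixed seed gives bit-identical simulation bundles", {
  a <- preset("eumetazoa_duplication", 77)
  b <- preset("eumetazoa_duplication", 77)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  expect_identical(a$events, b$events)
})

test_that("presets plant exactly the advertised scenarios", {
  expect_error(preset("nonsense", 1), "valid.*vertebrate_repertoire")

  cp <- preset("catalytic_panel", 12)
  expect_equal(nrow(cp$records), 5)
  expect_equal(cp$truth$competent, c(TRUE, TRUE, FALSE, FALSE, FALSE))

  hg <- preset("prokaryote_hgt", 12)
  expect_equal(sum(hg$events$type == "hgt"), 2)

  vr <- preset("vertebrate_repertoire", 12)
  expect_equal(length(unique(vr$truth$architecture)), 5)
  expect_equal(length(unique(vr$truth$family)), 7)

  pf <- preset("porifera_families", 12)
  expect_equal(sum(pf$events$type == "duplication"), 3)
})

test_that("knockouts change only the scheduled residues", {
  cp <- preset("catalytic_panel", 5)
  s <- setNames(cp$records$sequence, cp$records$id)
  ref <- strsplit(s[["P_ref_LOX"]], "")[[1]]
  geo <- loxevo:::LOX_SEED_GEOMETRY
  h1 <- strsplit(s[["P_h1_LOX"]], "")[[1]]
  diff1 <- which(ref != h1)
  expect_equal(diff1, geo$motif_start + geo$h_offsets[1] - 1L)
  expect_equal(h1[diff1], "A")
  core <- strsplit(s[["P_core_LOX"]], "")[[1]]
  expect_equal(which(ref != core), geo$motif_start + geo$h_offsets[2:4] - 1L)
  expect_equal(which(ref != strsplit(s[["P_K_LOX"]], "")[[1]]), geo$k_pos)
  expect_equal(which(ref != strsplit(s[["P_Y_LOX"]], "")[[1]]), geo$y_pos)
})

test_that("replaying the event log reproduces tip gene counts", {
  for (nm in c("eumetazoa_duplication", "porifera_families", "prokaryote_hgt")) {
    b <- preset(nm, 31)
    tree <- ape::reorder.phylo(b$tree, "cladewise")
    nt <- length(tree$tip.label)
    root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
    root_fams <- unique(b$events$family[0])
    # recover root families: those present before any event that creates them
    created <- c(b$events$new_family[b$events$type == "duplication"])
    all_fams <- unique(b$truth$family)
    root_fams <- if (nm == "prokaryote_hgt") c("LOXA", "LOXB") else
      setdiff(all_fams, created)
    state <- list(); state[[root]] <- root_fams
    lab <- function(node) if (node <= nt) tree$tip.label[node] else
      tree$node.label[node - nt]
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
      fams <- state[[par]]
      evs <- b$events[b$events$branch == lab(chd), , drop = FALSE]
      if (nrow(evs)) for (i in seq_len(nrow(evs))) {
        if (evs$type[i] == "duplication") fams <- c(fams, evs$new_family[i])
        if (evs$type[i] == "gene_loss") fams <- setdiff(fams, evs$family[i])
        if (evs$type[i] == "hgt") fams <- union(fams, evs$family[i])
      }
      state[[chd]] <- fams
    }
    for (tip in seq_len(nt)) {
      got <- sort(b$truth$family[b$truth$taxon == tree$tip.label[tip]])
      expect_equal(got, sort(state[[tip]]), label = paste(nm, tree$tip.label[tip]))
    }
  }
})
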