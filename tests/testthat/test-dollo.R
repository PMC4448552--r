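euk_tree <- function() {
  read_newick(
    text = "(((Bilateria:1,Cnidaria:1)nEumet:1,Porifera:1)nMet:1,Outgroup:1)root;")
}

test_that("Dollo gains sit at the MRCA and losses are minimal", {
  tr <- euk_tree()
  all1 <- setNames(rep("1", 4), tr$tip.label)
  r <- dollo_reconstruct(tr, all1)
  expect_equal(r$gain, "root")
  expect_equal(r$n_losses, 0)

  # presence only in Bilateria, gain constrained to the eumetazoan stem:
  # exactly one loss, on the cnidarian branch
  st <- c(Bilateria = "1", Cnidaria = "0", Porifera = "0", Outgroup = "0")
  r2 <- dollo_reconstruct(tr, st, constrained_gain = "nEumet")
  expect_equal(r2$gain, "nEumet")
  expect_equal(r2$losses, "Cnidaria")

  expect_error(dollo_reconstruct(tr, setNames(rep("0", 4), tr$tip.label)),
               "no tip with state 1")
  expect_error(dollo_reconstruct(tr, st, constrained_gain = "Porifera"),
               "not ancestral")
})

test_that("missing data constrains neither presences nor losses", {
  tr <- euk_tree()
  st <- c(Bilateria = "1", Cnidaria = "?", Porifera = "1", Outgroup = "0")
  r <- dollo_reconstruct(tr, st)
  expect_equal(r$gain, "nMet")
  expect_equal(r$n_losses, 0)  # the ? tip needs no loss
})

test_that("loss counts equal the exhaustive minimum on random trees", {
  set.seed(44)
  for (rep in 1:20) {
    tr <- ape::rtree(6, tip.label = paste0("t", 1:6))
    tr$node.label <- paste0("n", seq_len(tr$Nnode))
    st <- setNames(sample(c("0", "1"), 6, TRUE), tr$tip.label)
    if (!any(st == "1")) st[sample(6, 1)] <- "1"
    r <- dollo_reconstruct(tr, st)
    brute <- oracle_dollo_min_losses(tr, st, r$gain)
    expect_equal(r$n_losses, brute)
    # every presence tip is below the gain and below no loss branch
    below <- tr$tip.label[loxevo:::tips_below(tr, loxevo:::node_by_label(tr, r$gain))]
    expect_true(all(names(st)[st == "1"] %in% below))
  }
})

test_that("gene-tree reconciliation anchors paralog families at the duplication", {
  b <- preset("eumetazoa_duplication", 25)
  # gene tree from the true domain subsequences
  dom <- b$domains[b$domains$kind == "lox", ]
  idx <- match(dom$id, b$records$id)
  seqs <- setNames(substr(b$records$sequence[idx], dom$start, dom$end), dom$id)
  gt <- nj_tree(msa_distances(progressive_align(seqs)))
  # the sponge gene predates the duplication: it roots the gene tree and
  # belongs to neither eumetazoan superfamily
  gt <- ape::root(gt, outgroup = "Pori1_LOXA", resolve.root = TRUE)
  fam <- setNames(b$truth$family, b$truth$id)
  fam["Pori1_LOXA"] <- NA
  sp <- setNames(b$truth$taxon, b$truth$id)
  gains <- reconcile_gain_nodes(gt, b$tree, fam, sp)
  expect_equal(unname(gains["LOXA"]), "nEumet")
  expect_equal(unname(gains["LOXB"]), "nEumet")

  # a single-species family whose gene-tree sister is not a clean family
  # clade sits on its own terminal branch
  gt1 <- read_newick(text = "((g1:1,g2:1):1,g3:2);")
  fam1 <- c(g1 = "F1", g2 = "F3", g3 = "F2")
  sp1 <- c(g1 = "Bilateria", g2 = "Cnidaria", g3 = "Porifera")
  g <- reconcile_gain_nodes(gt1, euk_tree(), fam1, sp1)
  expect_equal(unname(g["F2"]), "Porifera")
  # whereas a clean sister family pulls the gain down to the duplication
  fam1b <- c(g1 = "F1", g2 = "F1", g3 = "F2")
  g2 <- reconcile_gain_nodes(gt1, euk_tree(), fam1b, sp1)
  expect_equal(unname(g2["F2"]), "nMet")

  # non-monophyletic family errors with the intruder named
  fam2 <- c(g1 = "F1", g2 = "F2", g3 = "F1")
  expect_error(reconcile_gain_nodes(gt1, euk_tree(), fam2, sp1),
               "not monophyletic.*g2")
})

test_that("event reports conserve totals across characters", {
  tr <- euk_tree()
  mat <- data.frame(
    famA = c("1", "1", "1", "0"),
    famB = c("1", "0", "0", "0"),
    famC = c("1", "0", "1", "?"),
    row.names = tr$tip.label)
  rep <- event_report(tr, mat)
  expect_equal(sum(rep$events$type == "gain"), 3)
  expect_equal(sum(rep$per_branch$gains), 3)
  agg_losses <- sum(rep$per_branch$losses)
  expect_equal(agg_losses, sum(rep$events$type == "loss"))
})
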