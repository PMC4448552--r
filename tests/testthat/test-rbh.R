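test_that("Smith-Waterman scores follow BLOSUM62 and never go negative", {
  sw <- smith_waterman("MKWVE", "MKWVE")
  expect_equal(sw$score, 5 + 5 + 11 + 4 + 5)
  expect_equal(c(sw$a_start, sw$a_end), c(1, 5))

  sw2 <- smith_waterman(strrep("A", 12), strrep("D", 12))
  expect_equal(sw2$score, 0)  # S(A,D) = -2, empty alignment wins
  expect_equal(sw2$a_aln, "")

  set.seed(23)
  for (r in 1:20) {
    a <- paste(sample(loxevo:::AA20, sample(8:30, 1), TRUE), collapse = "")
    b <- paste(sample(loxevo:::AA20, sample(8:30, 1), TRUE), collapse = "")
    expect_equal(smith_waterman(a, b)$score, smith_waterman(b, a)$score)
  }
})

test_that("Smith-Waterman matches a quadratic DP oracle", {
  S <- blosum62()
  set.seed(29)
  for (r in 1:12) {
    a <- paste(sample(loxevo:::AA20, sample(10:25, 1), TRUE), collapse = "")
    b <- paste(sample(loxevo:::AA20, sample(10:25, 1), TRUE), collapse = "")
    expect_equal(smith_waterman(a, b)$score,
                 oracle_sw_score(a, b, S, 10, 0.5))
  }
})

test_that("Karlin-Altschul statistics scale as designed", {
  # bits = 30 at m = n = 1000: E = 1e6 * 2^-30
  s30 <- (30 * log(2) + log(0.041)) / 0.267
  ka <- evalue_ka(s30, 1000, 1000)
  expect_equal(ka$bits, 30, tolerance = 1e-9)
  expect_equal(ka$evalue, 1e6 * 2^-30, tolerance = 1e-9)

  expect_equal(evalue_ka(50, 2000, 1000)$evalue,
               2 * evalue_ka(50, 1000, 1000)$evalue)
  es <- vapply(c(10, 50, 100, 200), function(s) evalue_ka(s, 300, 300)$evalue, 0)
  expect_true(all(diff(es) < 0))
  expect_error(evalue_ka(10, 100, 100, lambda = 0), "lambda")
})

test_that("reciprocal networks connect homologs and respect thresholds", {
  set.seed(33)
  s1 <- paste(sample(loxevo:::AA20, 200, TRUE), collapse = "")
  s2 <- paste(sample(loxevo:::AA20, 200, TRUE), collapse = "")
  rec <- protein_records(c("a1", "a2", "b1"), c("t1", "t2", "t3"),
                         c("CladeA", "CladeA", "CladeB"),
                         c(s1, s1, s2))
  g <- reciprocal_network(rec, 1e-10)
  expect_equal(igraph::ecount(g), 1)
  ends <- igraph::ends(g, igraph::E(g))
  expect_setequal(as.vector(ends), c("a1", "a2"))

  comps <- components_and_clusters(g)
  expect_equal(nrow(comps), 2)
  expect_false(any(comps$mixed))  # unrelated clades never mix without HGT

  # edgeless graph: one component per node
  rec2 <- protein_records(c("x", "y"), c("t", "t"), c("c", "c"),
                          c(strrep("A", 50), strrep("D", 50)))
  g2 <- reciprocal_network(rec2, 1e-10)
  expect_equal(igraph::ecount(g2), 0)
  expect_equal(nrow(components_and_clusters(g2)), 2)
})

test_that("the HGT preset yields archaea connected to their bacterial donors", {
  b <- preset("prokaryote_hgt", 3)
  g <- reciprocal_network(b$records, 1e-10)
  clade <- setNames(b$records$clade, b$records$id)
  for (arch_gene in b$records$id[b$records$clade == "Archaea"]) {
    nb <- igraph::neighbors(g, arch_gene)$name
    expect_true(any(clade[nb] == "Bacteria"), label = arch_gene)
  }
  comps <- components_and_clusters(g)
  expect_equal(sum(comps$mixed), 2)

  # graph invariant under input order
  perm <- sample(nrow(b$records))
  g2 <- reciprocal_network(b$records[perm, ], 1e-10)
  e1 <- apply(igraph::ends(g, igraph::E(g)), 1, function(x) paste(sort(x), collapse = "~"))
  e2 <- apply(igraph::ends(g2, igraph::E(g2)), 1, function(x) paste(sort(x), collapse = "~"))
  expect_setequal(e1, e2)
})

test_that("GraphML export round-trips node and edge attributes", {
  rec <- protein_records(c("a", "b"), c("t1", "t2"), c("X", "Y"),
                         c(strrep("MKWVE", 30), strrep("MKWVE", 30)))
  g <- reciprocal_network(rec, 1e-5)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, f)
  back <- igraph::read_graph(f, format = "graphml")
  expect_equal(sort(igraph::V(back)$name), c("a", "b"))
  expect_equal(igraph::ecount(back), igraph::ecount(g))
})
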