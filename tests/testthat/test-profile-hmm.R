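toy_profile <- function(rows, pc = 1, id = "toy") {
  build_profile(new_msa(paste0("s", seq_along(rows)), rows), pc, id)
}

test_that("profile construction follows the pseudocount arithmetic", {
  # three identical ungapped rows
  p <- toy_profile(c("ACD", "ACD", "ACD"))
  expect_equal(p$L, 3)
  expect_equal(names(which.max(p$em[1, ])), "A")
  expect_true(all(abs(rowSums(p$em) - 1) < 1e-9))

  # two-row seed {AC, AD}: equal Henikoff weights, so C carries observed
  # frequency w = 1/2 in column 2; mixing in pc units of background mass
  # gives e = (w + pc * 1/20) / (1 + pc)
  p2 <- toy_profile(c("AC", "AD"), pc = 1)
  hand <- (0.5 + 1 * (1 / 20)) / (1 + 1)
  expect_equal(unname(p2$em[2, "C"]), hand, tolerance = 1e-12)
  expect_equal(unname(p2$em[2, "D"]), hand, tolerance = 1e-12)

  # a 60%-gap column is excluded from the match columns
  p3 <- toy_profile(c("A-D", "A-D", "A-D", "AC-", "ACD"))
  expect_equal(p3$L, 2)
  expect_equal(p3$match_cols, c(1L, 3L))

  expect_error(toy_profile(c("--", "--", "A-")), "no match columns")
})

test_that("profile transition distributions are normalised", {
  p <- toy_profile(c("ACDE", "AC-E", "ACDE", "AWDE"))
  for (j in seq_len(p$L - 1)) {
    expect_equal(p$tMM[j] + p$tMI[j] + p$tMD[j] + p$tME[j], 1, tolerance = 1e-9)
    expect_equal(p$tIM[j] + p$tII[j], 1, tolerance = 1e-9)
    expect_equal(p$tDM[j] + p$tDD[j], 1, tolerance = 1e-9)
  }
  expect_equal(p$tME[p$L], 1)
})

test_that("Viterbi and forward match exhaustive path enumeration", {
  set.seed(8)
  aa <- c("A", "C", "D", "E", "F", "G", "W")
  for (case in 1:6) {
    L <- sample(2:3, 1)
    rows <- replicate(3, paste(sample(aa, L, TRUE), collapse = ""))
    p <- toy_profile(rows, pc = runif(1, 0.5, 2))
    s <- paste(sample(c(aa, "X"), sample(2:5, 1), TRUE), collapse = "")
    oracle <- oracle_profile_paths(p, s)
    expect_equal(forward_score(p, s), oracle$forward_bits, tolerance = 1e-12)
    hit <- viterbi_scan(p, s)
    vit <- if (is.null(hit)) NA_real_ else hit$bits
    if (oracle$viterbi_bits > 0) {
      expect_equal(vit, oracle$viterbi_bits, tolerance = 1e-12)
    } else {
      expect_true(is.na(vit))
    }
  }
})

test_that("forward dominates Viterbi and the consensus scores best", {
  p <- load_domain_profiles("srcr")[[1]]
  set.seed(2)
  for (r in 1:5) {
    s <- paste(sample(loxevo:::AA20, 80, TRUE), collapse = "")
    f <- forward_score(p, s)
    h <- viterbi_scan(p, s)
    if (!is.null(h)) expect_gte(f, h$bits - 1e-9)
  }
  cons <- p$consensus
  base <- viterbi_scan(p, cons)
  expect_equal(base$start, 1)
  expect_equal(base$end, nchar(cons))
  # every single-point mutant of the consensus scores no better
  set.seed(3)
  for (r in 1:10) {
    pos <- sample(nchar(cons), 1)
    mut <- loxevo:::seq_chars(cons)
    mut[pos] <- sample(setdiff(loxevo:::AA20, mut[pos]), 1)
    hm <- viterbi_scan(p, paste(mut, collapse = ""))
    expect_lte(hm$bits, base$bits + 1e-9)
  }
  # all-X sequence: nothing above 0 bits
  expect_null(viterbi_scan(p, strrep("X", 60)))
})

test_that("a tandem duplication raises the forward score", {
  p <- load_domain_profiles("srcr")[[1]]
  single <- forward_score(p, p$consensus)
  double <- forward_score(p, strrep(p$consensus, 2))
  expect_gt(double, single)
})

test_that("E-values behave like a calibrated Gumbel tail", {
  p <- load_domain_profiles("srcr")[[1]]
  fit <- loxevo:::gumbel_null_fit(p, 200, seed = 4, null_length = 120)
  gam <- 0.5772156649015329
  mean_null <- fit$mu + gam * fit$beta
  # the method of moments pins the fitted mean to the sample mean, so the
  # exceedance there equals the Gumbel value 1 - exp(-exp(-gamma))
  e1 <- estimate_evalue(p, mean_null, database_size = 1, seed = 4,
                        null_length = 120)
  expect_equal(e1, 1 - exp(-exp(-gam)), tolerance = 1e-9)
  # database-size linearity is exact
  e10 <- estimate_evalue(p, mean_null, database_size = 10, seed = 4,
                         null_length = 120)
  expect_equal(e10, 10 * e1, tolerance = 1e-12)
  # monotone decreasing in score, vanishing for large scores
  es <- sapply(c(0, 20, 60, 200), function(s)
    estimate_evalue(p, s, 1, seed = 4, null_length = 120))
  expect_true(all(diff(es) < 0))
  expect_lt(es[4], 1e-12)
  expect_error(estimate_evalue(p, 10, 1, null_sample_size = 10),
               "null_sample_size")
})

test_that("proteome scanning decomposes multi-domain architectures", {
  vr <- preset("vertebrate_repertoire", 20)
  prot <- vr$records[vr$records$id == "Hsap_LOXL2", , drop = FALSE]
  profiles <- load_domain_profiles(c("lox", "srcr"))
  hits <- scan_proteome(profiles, prot, seed = 20)
  expect_equal(hits$profile, c("srcr", "srcr", "srcr", "srcr", "lox"))
  expect_true(all(diff(hits$start) > 0))
  truth <- vr$domains[vr$domains$id == "Hsap_LOXL2" &
                        vr$domains$kind %in% c("srcr", "lox"), ]
  for (i in seq_len(nrow(hits))) {
    ov <- pmin(hits$end[i], truth$end) - pmax(hits$start[i], truth$start) + 1
    frac <- max(ov / (truth$end - truth$start + 1))
    expect_gt(frac, 0.5)
  }
})

test_that("overlapping hits from different profiles keep only the best", {
  # scan a pure LOX domain with both the lox profile and a decoy profile
  # built from the same seed (hits the same region with a lower score)
  lox_seed <- load_seed_alignment("lox")
  sub_rows <- vapply(lox_seed$seqs, function(s) substr(s, 10, 90), "")
  decoy <- build_profile(new_msa(lox_seed$ids, sub_rows), id = "decoy")
  profiles <- list(lox = load_domain_profiles("lox")[[1]], decoy = decoy)
  prot <- protein_records("p1", "t", "c", loxevo:::degap(lox_seed$seqs[[2]]))
  hits <- scan_proteome(profiles, prot, seed = 6)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$profile, "lox")
})

test_that("random background proteins yield no hits at stringent E-values", {
  profiles <- load_domain_profiles(c("lox", "srcr"))
  set.seed(14)
  n_hit <- 0
  for (r in 1:20) {
    s <- paste(sample(loxevo:::AA20, 250, TRUE), collapse = "")
    prot <- protein_records(paste0("bg", r), "t", "c", s)
    h <- scan_proteome(profiles, prot, inclusion_evalue = 1e-5, seed = 14)
    n_hit <- n_hit + (nrow(h) > 0)
  }
  expect_lte(n_hit, 1)  # >= 95% clean
})
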