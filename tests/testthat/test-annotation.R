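test_that("Kyte-Doolittle window arithmetic matches hand computation", {
  # 19-mer of 18 Ile + 1 Asp: mean = (18*4.5 - 3.5)/19
  s <- "IIIIIIIIIIIDIIIIIII"
  means <- loxevo:::kd_window_means(loxevo:::seq_chars(s), 19)
  expect_equal(means, (18 * 4.5 - 3.5) / 19, tolerance = 1e-12)
  expect_gt(means, 1.6)
})

test_that("transmembrane helices are called from hydropathy runs", {
  s <- paste0(strrep("D", 30), strrep("I", 25), strrep("D", 30))
  tm <- detect_tm_helices(s)
  expect_equal(nrow(tm), 1)
  expect_equal(tm$kind, "tm_region")
  # the called region covers the Ile block (window slack allowed)
  expect_lte(tm$start, 31)
  expect_gte(tm$end, 54)

  expect_equal(nrow(detect_tm_helices(strrep("D", 80))), 0)
})

test_that("signal peptides require both hydrophobic core and cleavage motif", {
  sp <- detect_signal_peptide(paste0("MKKLLLLLLLLAAASA", strrep("DQERN", 20)))
  expect_false(is.null(sp))
  expect_equal(sp$start, 1)
  expect_equal(sp$end, 15)  # first [AGSV]-x-[AGS] motif ends at the S of AAS

  # poly-Asp N-terminus: no hydrophobic window
  expect_null(detect_signal_peptide(paste0(strrep("D", 30), strrep("L", 20),
                                           strrep("D", 30))))
  # hydrophobic stretch starting too late violates the window rule
  expect_null(detect_signal_peptide(paste0(strrep("D", 19), "LLLLLLLLAAASA",
                                           strrep("D", 30))))
})

test_that("proline-rich windows obey the 0.25 threshold exactly", {
  mk <- function(npro) {
    chars <- rep("G", 25)
    chars[seq_len(npro)] <- "P"
    paste(c(chars, rep("G", 10)), collapse = "")
  }
  expect_equal(nrow(detect_proline_rich(mk(7))), 1)   # 7/25 = 0.28
  expect_equal(nrow(detect_proline_rich(mk(6))), 0)   # 6/25 = 0.24

  # alternating P/A stretch merges into a single region
  s <- paste0(strrep("G", 20), strrep("PA", 15), strrep("G", 20))
  pr <- detect_proline_rich(s)
  expect_equal(nrow(pr), 1)
})

test_that("architecture strings collapse repeats and label propeptides", {
  hits <- data.frame(profile = c("srcr", "srcr", "srcr", "srcr", "lox"),
                     start = c(25, 90, 150, 215, 300),
                     end = c(80, 145, 205, 270, 500))
  feats <- data.frame(kind = "signal_peptide", start = 1, end = 18, score = 3)
  a <- assemble_architecture("p", strrep("G", 520), hits, feats)
  expect_equal(a$architecture, "SP+4xSRCR+LOX")

  b <- assemble_architecture("p", strrep("G", 520),
                             data.frame(profile = "lox", start = 1, end = 100),
                             NULL)
  expect_equal(b$architecture, "LOX")

  # SP, a 60-residue unannotated stretch, then LOX -> propeptide
  cc <- assemble_architecture("p", strrep("G", 200),
                              data.frame(profile = "lox", start = 79, end = 178),
                              data.frame(kind = "signal_peptide", start = 1,
                                         end = 18, score = 3))
  expect_equal(cc$architecture, "SP+PROPEP+LOX")

  # equal token lists give equal canonical strings and vice versa
  expect_identical(a$tokens, c("SP", rep("SRCR", 4), "LOX"))
})

test_that("annotation recovers the planted vertebrate architectures", {
  vr <- preset("vertebrate_repertoire", 33)
  profiles <- load_domain_profiles(c("lox", "srcr"))
  hits <- scan_proteome(profiles, vr$records, seed = 33)
  ann <- annotate_proteins(vr$records, hits)
  m <- merge(ann$architectures, vr$truth[, c("id", "architecture")],
             by.x = "protein", by.y = "id")
  expect_equal(mean(m$architecture.x == m$architecture.y), 1)
  expect_equal(length(unique(ann$architectures$architecture)),
               length(unique(vr$truth$architecture)))

  # LOXL1-type proteins carry exactly one proline-rich region overlapping
  # the planted one by >= 80%
  l1 <- vr$records$id[vr$truth$family == "LOXL1"][1]
  pr <- ann$features[ann$features$protein == l1 &
                       ann$features$kind == "proline_rich", ]
  expect_equal(nrow(pr), 1)
  tr <- vr$domains[vr$domains$id == l1 & vr$domains$kind == "proline_rich", ]
  ov <- min(pr$end, tr$end) - max(pr$start, tr$start) + 1
  expect_gte(ov / (tr$end - tr$start + 1), 0.8)
})

test_that("detectors are pure functions of their input", {
  s <- paste0("MKKLLLLLLLLAAASA", strrep("PG", 20), strrep("E", 40))
  expect_identical(detect_signal_peptide(s), detect_signal_peptide(s))
  expect_identical(detect_proline_rich(s), detect_proline_rich(s))
  expect_identical(detect_tm_helices(s), detect_tm_helices(s))
})
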