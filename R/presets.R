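# Named simulation presets.  Each preset fixes a species tree, a root
# repertoire and an event schedule that plant a known evolutionary
# scenario; the ground truth tables let every downstream stage be checked
# against the planted answer.

PRESET_NAMES <- c("vertebrate_repertoire", "eumetazoa_duplication",
                  "prokaryote_hgt", "porifera_families", "catalytic_panel")

#' Simulate a preset scenario
#'
#' * `vertebrate_repertoire`: seven vertebrate LOX family types (canonical
#'   LOX, LOXL1, LOXL5, LOXL2/L3/L4 and a membrane-associated SRCR
#'   variant) realizing exactly five distinct domain architectures.
#' * `eumetazoa_duplication`: one duplication on the eumetazoan stem
#'   creating two superfamilies, with loss of one paralog in cnidarians.
#' * `prokaryote_hgt`: two anciently diverged bacterial LOX subfamilies
#'   and two independent bacteria-to-archaea transfers (one per archaeal
#'   group), the archaea having no native copy.
#' * `porifera_families`: three family-founding duplications on the
#'   sponge stem (the first family retained only by calcareous sponges).
#' * `catalytic_panel`: one catalytically competent LOX domain plus four
#'   knockouts - first motif histidine, the three core histidines, the
#'   LTQ lysine, the LTQ tyrosine - with competence flags 1,1,0,0,0.
#'
#' @param name preset name.
#' @param seed master seed (mandatory; every random choice derives from it).
#' @return simulation bundle as returned by [evolve_repertoire()], plus
#'   `name`, `clades` and `config`.
#' @export
preset <- function(name, seed) {
  if (!name %in% PRESET_NAMES) {
    stop("unknown preset '", name, "'; valid: ", paste(PRESET_NAMES, collapse = ", "))
  }
  if (missing(seed)) stop("seed is mandatory")
  builder <- switch(name,
    vertebrate_repertoire = preset_vertebrate,
    eumetazoa_duplication = preset_eumetazoa,
    prokaryote_hgt = preset_prokaryote_hgt,
    porifera_families = preset_porifera,
    catalytic_panel = preset_catalytic_panel)
  out <- builder(seed)
  out$name <- name
  out$seed <- seed
  out
}

preset_tree <- function(text) {
  tree <- read_newick(text = text)
  ape::reorder.phylo(tree, "cladewise")
}

preset_vertebrate <- function(seed) {
  tree <- preset_tree(paste0(
    "(((((Hsap:0.06,Mmus:0.06)n1:0.05,Ggal:0.11)n2:0.05,Drer:0.16)n3:0.06,",
    "Pmar:0.22)n4:0.08,Bflo:0.3)root;"))
  clades <- c(Hsap = "Vertebrata", Mmus = "Vertebrata", Ggal = "Vertebrata",
              Drer = "Vertebrata", Pmar = "Vertebrata", Bflo = "Cephalochordata")
  specs <- list(
    LOX   = architecture_spec(c("signal_peptide", "propeptide", "lox")),
    LOXL1 = architecture_spec(c("signal_peptide", "proline_rich", "lox")),
    LOXL5 = architecture_spec(c("signal_peptide", "proline_rich", "propeptide", "lox")),
    LOXL2 = architecture_spec(c("signal_peptide", "srcr", "srcr", "srcr", "srcr", "lox")),
    LOXL3 = architecture_spec(c("signal_peptide", "srcr", "srcr", "srcr", "srcr", "lox")),
    LOXL4 = architecture_spec(c("signal_peptide", "srcr", "srcr", "srcr", "srcr", "lox")),
    LOXM  = architecture_spec(c("srcr", "srcr", "srcr", "srcr", "lox", "tm_region")))
  config <- list(seed = derive_seed(seed, "vertebrate_repertoire"),
                 gamma_shape = 0.8, clades = clades)
  out <- evolve_repertoire(tree, specs, config)
  out$clades <- clades
  out$config <- config
  out
}

preset_eumetazoa <- function(seed) {
  tree <- preset_tree(
    "(((Bila1:0.15,Bila2:0.15)nBila:0.15,Cnid1:0.3)nEumet:0.15,Pori1:0.45)root;")
  clades <- c(Bila1 = "Bilateria", Bila2 = "Bilateria",
              Cnid1 = "Cnidaria", Pori1 = "Porifera")
  specs <- list(LOXA = architecture_spec(c("signal_peptide", "lox")))
  events <- data.frame(
    branch = c("nEumet", "Cnid1"),
    type = c("duplication", "gene_loss"),
    family = c("LOXA", "LOXB"),
    new_family = c("LOXB", NA),
    stringsAsFactors = FALSE)
  config <- list(seed = derive_seed(seed, "eumetazoa_duplication"),
                 gamma_shape = 0.8, clades = clades, events = events)
  out <- evolve_repertoire(tree, specs, config)
  out$clades <- clades
  out$config <- config
  out
}

preset_prokaryote_hgt <- function(seed) {
  tree <- preset_tree(paste0(
    "((Bac1:0.15,(Bac2:0.1,Bac3:0.1)nB23:0.05)nBact:0.35,",
    "((Thau1:0.05,Thau2:0.05)nThau:0.2,(Eury1:0.05,Eury2:0.05)nEury:0.2)",
    "nArch:0.25)root;"))
  clades <- c(Bac1 = "Bacteria", Bac2 = "Bacteria", Bac3 = "Bacteria",
              Thau1 = "Archaea", Thau2 = "Archaea",
              Eury1 = "Archaea", Eury2 = "Archaea")
  cfg_seed <- derive_seed(seed, "prokaryote_hgt")
  # two anciently diverged bacterial subfamilies: LOXB is LOXA evolved a
  # long distance (6 substitutions/site, uniform rates so no site escapes),
  # leaving only the invariant catalytic residues shared between them
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg_seed, "root_repertoire"))
  ga <- realize_architecture("LOXA", architecture_spec("lox"))
  ga$site_cat <- sample(discrete_gamma_rates(0.8, 4L), length(ga$chars), TRUE)
  model <- subst_model("WAG", gamma_shape = 0.8)
  gb <- ga
  gb$family <- "LOXB"
  gb$chars <- evolve_chars(gb$chars, 6, model, rep(1, length(gb$chars)), gb$inv)
  events <- data.frame(
    branch = c("nArch", "nArch", "nThau", "nEury"),
    type = c("gene_loss", "gene_loss", "hgt", "hgt"),
    family = c("LOXA", "LOXB", "LOXA", "LOXB"),
    donor = c(NA, NA, "nBact", "nBact"),
    stringsAsFactors = FALSE)
  config <- list(seed = cfg_seed, gamma_shape = 0.8, model = model,
                 clades = clades, events = events)
  out <- evolve_repertoire(tree, list(ga, gb), config)
  out$clades <- clades
  out$config <- config
  out
}

preset_porifera <- function(seed) {
  tree <- preset_tree(paste0(
    "(((Sycon:0.1,Leuco:0.1)nCalc:0.15,(Amph:0.15,Osca:0.15)nNonCalc:0.1)",
    "nPori:0.2,Outg1:0.45)root;"))
  clades <- c(Sycon = "Porifera", Leuco = "Porifera", Amph = "Porifera",
              Osca = "Porifera", Outg1 = "Outgroup")
  specs <- list(LOXANC = architecture_spec("lox"))
  events <- data.frame(
    branch = c("nPori", "nPori", "nPori",
               "nPori", "nPori", "nPori", "nPori",
               "nPori", "nNonCalc"),
    type = c("duplication", "duplication", "duplication",
             "domain_gain", "domain_gain", "domain_gain", "domain_gain",
             "gene_loss", "gene_loss"),
    family = c("LOXANC", "LOXANC", "LOXANC",
               "LOXP1", "LOXP1", "LOXP2", "LOXP3",
               "LOXANC", "LOXP1"),
    new_family = c("LOXP1", "LOXP2", "LOXP3", rep(NA, 6)),
    feature = c(NA, NA, NA, "mam", "srcr", "srcr", "tm_region", NA, NA),
    position = c(NA, NA, NA, "N", "N", "N", "C", NA, NA),
    stringsAsFactors = FALSE)
  config <- list(seed = derive_seed(seed, "porifera_families"),
                 gamma_shape = 0.8, clades = clades, events = events)
  out <- evolve_repertoire(tree, specs, config)
  out$clades <- clades
  out$config <- config
  out
}

preset_catalytic_panel <- function(seed) {
  tree <- preset_tree(
    "(P_ref:0,P_h1:0,P_core:0,P_K:0,P_Y:0)root;")
  clades <- setNames(rep("Panel", 5), tree$tip.label)
  specs <- list(LOX = architecture_spec("lox"))
  events <- data.frame(
    branch = c("P_h1", "P_core", "P_K", "P_Y"),
    type = "catalytic_knockout",
    family = "LOX",
    residue_class = c("h1", "core", "ltq_k", "ltq_y"),
    stringsAsFactors = FALSE)
  config <- list(seed = derive_seed(seed, "catalytic_panel"),
                 gamma_shape = 0.8, clades = clades, events = events)
  out <- evolve_repertoire(tree, specs, config)
  # panel order: reference, h1, core, K, Y
  ord <- match(paste0("P_", c("ref", "h1", "core", "K", "Y"), "_LOX"), out$records$id)
  out$records <- out$records[ord, ]
  out$truth <- out$truth[match(out$records$id, out$truth$id), ]
  out$clades <- clades
  out$config <- config
  out
}
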