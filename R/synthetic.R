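# Synthetic proteome generator: multi-domain proteins (signal peptide,
# SRCR repeats, accessory domains, one LOX domain) evolving along a known
# species tree, with planted duplications, losses, domain gains/losses,
# horizontal transfers and catalytic knockouts, and a machine-readable
# ground-truth log.

# Geometry of the bundled LOX seed: the copper-talon motif and the LTQ
# lysine/tyrosine sit at fixed positions of the 100-residue domain.
LOX_SEED_GEOMETRY <- list(
  length = 100L, motif_start = 35L, motif = "WEWHSCHQHYHSMD",
  h_offsets = c(4L, 7L, 9L, 11L), k_pos = 70L, y_pos = 85L
)

# Positions inside a LOX domain kept invariant during simulated evolution
# (strong purifying selection on the catalytic machinery): the four
# copper-talon histidines and the LTQ K/Y.
lox_invariant_positions <- function() {
  g <- LOX_SEED_GEOMETRY
  c(g$motif_start + g$h_offsets - 1L, g$k_pos, g$y_pos)
}

DOMAIN_KINDS <- c("lox", "srcr", "pkd", "kringle", "plat", "mam", "sushi")

#' Load a bundled toy domain seed alignment
#'
#' @param kind one of `r paste(DOMAIN_KINDS, collapse=", ")`.
#' @return a `lox_msa`.
#' @export
load_seed_alignment <- function(kind) {
  f <- system.file("extdata", "seeds", paste0(kind, ".fasta"), package = "loxevo")
  if (!nzchar(f)) stop("no bundled seed alignment for kind: ", kind)
  read_alignment(f, format = "fasta")
}

#' Load the bundled domain profiles
#'
#' Builds one profile HMM per bundled seed alignment (cached per session).
#'
#' @param kinds domain kinds to load.
#' @return named list of `lox_profile` objects.
#' @export
load_domain_profiles <- function(kinds = DOMAIN_KINDS) {
  key <- paste(kinds, collapse = ",")
  if (!is.null(.profile_store[[key]])) return(.profile_store[[key]])
  out <- setNames(lapply(kinds, function(k) {
    build_profile(load_seed_alignment(k), id = k)
  }), kinds)
  .profile_store[[key]] <- out
  out
}
.profile_store <- new.env(parent = emptyenv())

#' Architecture specification
#'
#' An ordered N-to-C list of features.  Exactly one `lox` feature is
#' required; feature lengths are fixed by kind (domains take the length of
#' their seed alignment).
#'
#' @param kinds character vector of feature kinds in N-to-C order, from
#'   signal_peptide, proline_rich, propeptide, tm_region and the domain
#'   kinds (lox, srcr, pkd, kringle, plat, mam, sushi).
#' @return character vector of class `lox_archspec`.
#' @export
architecture_spec <- function(kinds) {
  ok <- c("signal_peptide", "proline_rich", "propeptide", "tm_region",
          DOMAIN_KINDS)
  bad <- setdiff(kinds, ok)
  if (length(bad)) stop("unknown feature kind: ", bad[1])
  if (sum(kinds == "lox") != 1) stop("an architecture needs exactly one lox feature")
  structure(kinds, class = "lox_archspec")
}

# canonical truth string for an architecture token list
arch_truth_string <- function(kinds) {
  tok <- vapply(kinds, arch_token, "")
  r <- rle(tok)
  paste(ifelse(r$lengths > 1, paste0(r$lengths, "x", r$values), r$values),
        collapse = "+")
}

# Sample one realisation of a single feature; returns list(chars, invariant)
realize_feature <- function(kind, linker_len = 12L) {
  soft <- c("A", "D", "E", "G", "H", "K", "N", "Q", "R", "S", "T")
  switch(kind,
    signal_peptide = {
      chars <- c("M", "K", "K", sample(c("L", "I", "V", "F", "A"), 10, TRUE),
                 "A", "S", "A")
      list(chars = chars, inv = rep(TRUE, length(chars)))
    },
    proline_rich = {
      other <- sample(soft, 15, TRUE)
      chars <- as.vector(rbind(rep("P", 15), other))
      inv <- as.vector(rbind(rep(TRUE, 15), rep(FALSE, 15)))
      list(chars = chars, inv = inv)
    },
    propeptide = {
      chars <- sample(setdiff(AA20, c("P", "I", "L", "V", "F")), 60, TRUE)
      list(chars = chars, inv = rep(FALSE, 60))
    },
    tm_region = {
      chars <- sample(c("I", "L", "V"), 25, TRUE)
      list(chars = chars, inv = rep(TRUE, 25))
    },
    {
      seed <- load_seed_alignment(kind)
      row <- seq_chars(degap(seed$seqs[[sample(length(seed$ids), 1)]]))
      inv <- rep(FALSE, length(row))
      if (kind == "lox") inv[lox_invariant_positions()] <- TRUE
      list(chars = row, inv = inv)
    }
  )
}

# Build a gene (sequence + true feature coordinates) from a spec.
realize_architecture <- function(family, spec, linker_len = 12L) {
  soft <- c("A", "D", "E", "G", "H", "K", "N", "Q", "R", "S", "T")
  chars <- character(0); inv <- logical(0)
  feats <- data.frame(kind = character(0), start = integer(0), end = integer(0))
  first <- TRUE
  for (kind in spec) {
    if (!first) {
      link <- sample(soft, linker_len, TRUE)
      chars <- c(chars, link); inv <- c(inv, rep(FALSE, linker_len))
    }
    f <- realize_feature(kind, linker_len)
    feats <- rbind(feats, data.frame(kind = kind,
                                     start = length(chars) + 1L,
                                     end = length(chars) + length(f$chars)))
    chars <- c(chars, f$chars); inv <- c(inv, f$inv)
    first <- FALSE
  }
  list(family = family, spec = as.character(spec), chars = chars, inv = inv,
       features = feats, knockouts = character(0))
}

# Evolve a residue vector for branch length t under model with per-site
# gamma category rates; invariant positions do not change.
evolve_chars <- function(chars, t, model, site_rates, inv) {
  if (t <= 0) return(chars)
  out <- chars
  for (r in unique(site_rates)) {
    sel <- which(site_rates == r & !inv & chars %in% AA20)
    if (!length(sel)) next
    P <- prob_matrix(model, t, rate = r)
    for (a in unique(chars[sel])) {
      idx <- sel[chars[sel] == a]
      out[idx] <- sample(AA20, length(idx), replace = TRUE, prob = P[a, ])
    }
  }
  out
}

#' Simulate a Yule (pure-birth) species tree
#'
#' Lineages split at rate `birth_rate` each; the process starts at the
#' root split and stops when `n_taxa` lineages exist, after which all
#' lineages are extended by one final exponential waiting time, giving an
#' ultrametric tree.  Fully reproducible for a fixed seed.
#'
#' @param n_taxa number of tips (>= 2).
#' @param birth_rate per-lineage speciation rate (> 0).
#' @param seed RNG seed.
#' @return an ultrametric [ape::phylo] tree with tips `t1..tn`.
#' @export
simulate_species_tree <- function(n_taxa, birth_rate = 1, seed = 1) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # active lineages: parent node id and birth time
  next_id <- n_taxa + 1L  # internal ids start after tips
  parent <- c(next_id, next_id); btime <- c(0, 0)
  node_time <- c()
  node_ids <- next_id
  next_id <- next_id + 1L
  t_now <- 0
  edges <- list()
  while (length(parent) < n_taxa) {
    k <- length(parent)
    t_now <- t_now + rexp(1, k * birth_rate)
    i <- sample.int(k, 1)
    new_node <- next_id; next_id <- next_id + 1L
    edges[[length(edges) + 1]] <- c(parent[i], new_node, t_now - btime[i])
    parent <- c(parent[-i], new_node, new_node)
    btime <- c(btime[-i], t_now, t_now)
  }
  t_end <- t_now + rexp(1, n_taxa * birth_rate)
  for (i in seq_along(parent)) {
    edges[[length(edges) + 1]] <- c(parent[i], i, t_end - btime[i])
  }
  em <- do.call(rbind, edges)
  tree <- list(edge = em[, 1:2, drop = FALSE] |> apply(2, as.integer),
               edge.length = em[, 3],
               Nnode = n_taxa - 1L,
               tip.label = paste0("t", seq_len(n_taxa)))
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree$node.label <- paste0("n", seq_len(tree$Nnode))
  tree
}

# node label lookup: tips by tip.label, internals by node.label
node_by_label <- function(tree, label) {
  i <- match(label, tree$tip.label)
  if (!is.na(i)) return(i)
  j <- match(label, tree$node.label)
  if (!is.na(j)) return(length(tree$tip.label) + j)
  NA_integer_
}

node_label <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) tree$tip.label[node] else tree$node.label[node - nt]
}

#' Evolve a gene repertoire along a species tree
#'
#' Genes evolve site-wise under the chosen substitution model with
#' discrete-gamma rate variation (categories assigned per site at the
#' root and inherited).  Scheduled events fire at the start of the branch
#' leading into the named node: duplications copy a gene under a new
#' family name, losses remove it, domain gains/losses edit the
#' architecture, horizontal transfers copy the donor node's current gene
#' into the recipient (replacing any same-family gene), and catalytic
#' knockouts substitute the scheduled catalytic residues with alanine.
#' Catalytic residues (the four copper-talon histidines and the LTQ K/Y)
#' are otherwise invariant, emulating strong purifying selection.
#'
#' @param tree a rooted [ape::phylo] with unique tip labels and (for event
#'   scheduling) internal node labels.
#' @param root_genes list of genes from `realize_architecture()` (built
#'   inside the same seeded context), or a named list of `lox_archspec`
#'   objects (names = family names) to be realized here.
#' @param config list with elements `model` (a `lox_model`; default
#'   WAG+G), `gamma_shape` (default 0.8), `seed` (mandatory), `clades`
#'   (named character vector by tip label), and `events` (data.frame with
#'   columns branch, type, family and optional new_family, donor, feature,
#'   position, residue_class).
#' @return list with `records` (tip proteins, `lox_records`), `truth`
#'   (gene table: id, taxon, clade, family, architecture, competent),
#'   `domains` (true feature coordinates per gene), `events` (the
#'   validated event log) and `tree`.
#' @export
evolve_repertoire <- function(tree, root_genes, config) {
  if (is.null(config$seed)) stop("config$seed is mandatory")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  model <- config$model %||% subst_model("WAG", gamma_shape = config$gamma_shape %||% 0.8)
  alpha <- config$gamma_shape %||% 0.8
  rates <- discrete_gamma_rates(alpha, 4L)
  clades <- config$clades %||% setNames(rep("", length(tree$tip.label)), tree$tip.label)
  events <- config$events %||% data.frame()
  if (nrow(events)) {
    for (col in c("new_family", "donor", "feature", "position", "residue_class")) {
      if (is.null(events[[col]])) events[[col]] <- NA_character_
    }
    bad <- vapply(events$branch, function(b) is.na(node_by_label(tree, b)), TRUE)
    if (any(bad)) stop("event on unknown branch: ", events$branch[bad][1])
    if (any(events$type == "hgt" & (is.na(events$donor) | events$donor == events$branch))) {
      stop("hgt events need a donor different from the recipient")
    }
  }

  if (!is.null(names(root_genes)) && inherits(root_genes[[1]], "lox_archspec")) {
    root_genes <- lapply(names(root_genes), function(fam) {
      realize_architecture(fam, root_genes[[fam]])
    })
  }
  # per-gene site categories at the root
  root_state <- lapply(root_genes, function(g) {
    if (is.null(g$site_cat)) {
      g$site_cat <- sample(rates, length(g$chars), replace = TRUE)
    }
    g
  })
  names(root_state) <- vapply(root_state, `[[`, "", "family")

  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  nt <- length(tree$tip.label)
  root <- tree_root(tree)
  states <- vector("list", nt + tree$Nnode)
  states[[root]] <- root_state
  log_rows <- list()
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
    blen <- tree$edge.length[e]
    st <- states[[par]]
    lab <- node_label(tree, chd)
    if (nrow(events)) {
      for (ev in which(events$branch == lab)) {
        type <- events$type[ev]; fam <- events$family[ev]
        if (type == "duplication") {
          if (is.null(st[[fam]])) stop("duplication of absent gene '", fam, "' on branch ", lab)
          g <- st[[fam]]; g$family <- events$new_family[ev]
          st[[g$family]] <- g
        } else if (type == "gene_loss") {
          if (is.null(st[[fam]])) stop("loss of absent gene '", fam, "' on branch ", lab)
          st[[fam]] <- NULL
        } else if (type == "hgt") {
          don <- states[[node_by_label(tree, events$donor[ev])]]
          if (is.null(don)) stop("hgt donor '", events$donor[ev], "' not yet evolved (reorder subtrees)")
          if (is.null(don[[fam]])) stop("hgt of absent gene '", fam, "' from donor ", events$donor[ev])
          g <- don[[fam]]
          newfam <- if (!is.na(events$new_family[ev])) events$new_family[ev] else fam
          g$family <- newfam
          st[[newfam]] <- g
        } else if (type == "domain_gain") {
          if (is.null(st[[fam]])) stop("domain gain on absent gene '", fam, "' on branch ", lab)
          st[[fam]] <- gene_gain_feature(st[[fam]], events$feature[ev],
                                         events$position[ev] %||% "N", rates)
        } else if (type == "domain_loss") {
          if (is.null(st[[fam]])) stop("domain loss on absent gene '", fam, "' on branch ", lab)
          st[[fam]] <- gene_lose_feature(st[[fam]], events$feature[ev])
        } else if (type == "catalytic_knockout") {
          if (is.null(st[[fam]])) stop("knockout on absent gene '", fam, "' on branch ", lab)
          st[[fam]] <- gene_knockout(st[[fam]], events$residue_class[ev])
        } else stop("unknown event type: ", type)
        log_rows[[length(log_rows) + 1]] <- cbind(events[ev, , drop = FALSE])
      }
    }
    st <- lapply(st, function(g) {
      g$chars <- evolve_chars(g$chars, blen, model, g$site_cat, g$inv)
      g
    })
    states[[chd]] <- st
  }

  recs <- list(); truth <- list(); doms <- list()
  for (tip in seq_len(nt)) {
    taxon <- tree$tip.label[tip]
    for (g in states[[tip]]) {
      gid <- paste0(taxon, "_", g$family)
      recs[[length(recs) + 1]] <- data.frame(
        id = gid, taxon = taxon, clade = unname(clades[taxon]),
        sequence = paste(g$chars, collapse = ""), stringsAsFactors = FALSE)
      truth[[length(truth) + 1]] <- data.frame(
        id = gid, taxon = taxon, clade = unname(clades[taxon]),
        family = g$family, architecture = arch_truth_string(g$features$kind),
        competent = gene_is_competent(g), stringsAsFactors = FALSE)
      doms[[length(doms) + 1]] <- cbind(id = gid, g$features)
    }
  }
  records <- if (length(recs)) {
    r <- do.call(rbind, recs)
    protein_records(r$id, r$taxon, r$clade, r$sequence)
  } else protein_records(character(0), character(0), character(0), character(0))
  list(records = records,
       truth = if (length(truth)) do.call(rbind, truth) else NULL,
       domains = if (length(doms)) do.call(rbind, doms) else NULL,
       events = if (length(log_rows)) do.call(rbind, log_rows) else events,
       tree = tree)
}

# A gene is competent iff its LOX catalytic residues are intact.
gene_is_competent <- function(g) {
  lox <- g$features[g$features$kind == "lox", ]
  if (nrow(lox) != 1) return(FALSE)
  geo <- LOX_SEED_GEOMETRY
  off <- lox$start - 1L
  h <- g$chars[off + geo$motif_start + geo$h_offsets[2:4] - 1L] == "H"
  K <- g$chars[off + geo$k_pos] == "K"
  Y <- g$chars[off + geo$y_pos] == "Y"
  all(h) && K && Y
}

gene_knockout <- function(g, residue_class) {
  lox <- g$features[g$features$kind == "lox", ]
  if (nrow(lox) != 1) stop("knockout on a gene without a lox domain")
  geo <- LOX_SEED_GEOMETRY
  off <- lox$start - 1L
  pos <- switch(residue_class,
    h1 = off + geo$motif_start + geo$h_offsets[1] - 1L,
    core = off + geo$motif_start + geo$h_offsets[2:4] - 1L,
    ltq_k = off + geo$k_pos,
    ltq_y = off + geo$y_pos,
    stop("unknown residue class: ", residue_class))
  g$chars[pos] <- "A"
  g$knockouts <- c(g$knockouts, residue_class)
  g
}

gene_gain_feature <- function(g, kind, position, rates, linker_len = 12L) {
  f <- realize_feature(kind)
  soft <- c("A", "D", "E", "G", "H", "K", "N", "Q", "R", "S", "T")
  link <- sample(soft, linker_len, TRUE)
  cat_new <- sample(rates, length(f$chars) + linker_len, replace = TRUE)
  if (identical(position, "C")) {
    g$features <- rbind(g$features, data.frame(
      kind = kind, start = length(g$chars) + linker_len + 1L,
      end = length(g$chars) + linker_len + length(f$chars)))
    g$chars <- c(g$chars, link, f$chars)
    g$inv <- c(g$inv, rep(FALSE, linker_len), f$inv)
    g$site_cat <- c(g$site_cat, cat_new)
  } else {
    shift <- length(f$chars) + linker_len
    g$features$start <- g$features$start + shift
    g$features$end <- g$features$end + shift
    g$features <- rbind(data.frame(kind = kind, start = 1L,
                                   end = length(f$chars)), g$features)
    g$chars <- c(f$chars, link, g$chars)
    g$inv <- c(f$inv, rep(FALSE, linker_len), g$inv)
    g$site_cat <- c(cat_new, g$site_cat)
  }
  g
}

gene_lose_feature <- function(g, kind) {
  hit <- which(g$features$kind == kind)
  if (!length(hit)) stop("domain loss of absent feature '", kind, "'")
  hit <- hit[1]
  a <- g$features$start[hit]; b <- g$features$end[hit]
  keep <- setdiff(seq_along(g$chars), a:b)
  g$chars <- g$chars[keep]; g$inv <- g$inv[keep]; g$site_cat <- g$site_cat[keep]
  g$features <- g$features[-hit, , drop = FALSE]
  after <- g$features$start > b
  g$features$start[after] <- g$features$start[after] - (b - a + 1L)
  g$features$end[after] <- g$features$end[after] - (b - a + 1L)
  g
}
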