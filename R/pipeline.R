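# End-to-end orchestration: simulate (or ingest) -> scan -> annotate ->
# extract domains -> align -> tree -> catalytic -> reciprocal-hit network
# -> gain/loss events -> summary.  Every stage's randomness derives from
# one master seed via labelled counters, so inserting a stage never
# changes another stage's results.

#' Count species-consistent gene lineages (paralog clades)
#'
#' Decomposes a gene tree into the minimal set of clades in which no
#' species contributes more than one gene, restricted to the genes of the
#' given taxa.  After one duplication on the stem of a taxon set, its
#' genes decompose into exactly two such clades; with no duplication the
#' count is one.  The tree is rooted on an outgroup gene (one from a
#' taxon outside `taxa`) when available.
#'
#' @param gene_tree [ape::phylo]; tip labels are gene ids.
#' @param species_of named character vector gene id -> taxon.
#' @param taxa taxa whose gene lineages are counted.
#' @return integer number of lineages.
#' @export
count_paralog_clades <- function(gene_tree, species_of, taxa) {
  genes_in <- gene_tree$tip.label[species_of[gene_tree$tip.label] %in% taxa]
  if (!length(genes_in)) return(0L)
  out_genes <- setdiff(gene_tree$tip.label, genes_in)
  tr <- gene_tree
  if (length(out_genes)) {
    tr <- tryCatch(ape::root(gene_tree, outgroup = out_genes, resolve.root = TRUE),
                   error = function(e) gene_tree)
  }
  nt <- length(tr$tip.label)
  children <- tree_children(tr)
  count <- function(node) {
    tips <- tr$tip.label[tips_below(tr, node)]
    mine <- intersect(tips, genes_in)
    if (!length(mine)) return(0L)
    sp <- species_of[mine]
    if (!anyDuplicated(sp)) return(1L)
    sum(vapply(children[[node]], count, 0L))
  }
  count(tree_root(tr))
}

#' Extract the LOX-domain subsequences from accepted hits
#'
#' @param proteins a `lox_records` data.frame.
#' @param hits hit table from [scan_proteome()].
#' @param profile_id which profile's hits to extract.
#' @return `lox_records` of domain subsequences (ids inherited).
#' @export
extract_domains <- function(proteins, hits, profile_id = "lox") {
  h <- hits[hits$profile == profile_id, , drop = FALSE]
  h <- h[!duplicated(h$protein), , drop = FALSE]  # best (first) per protein
  idx <- match(h$protein, proteins$id)
  protein_records(h$protein, proteins$taxon[idx], proteins$clade[idx],
                  substr(proteins$sequence[idx], h$start, h$end))
}

#' Run the full analysis pipeline on a preset or on user inputs
#'
#' Stages: simulate/ingest, profile-HMM proteome scan, feature annotation
#' and architectures, LOX-domain extraction and alignment, gene tree
#' (NJ + optional NNI) with bootstrap, catalytic assessment (against the
#' bundled competent LOX reference), reciprocal-hit network and clade
#' components, and a summary.  With `out_dir` set, every table is written
#' as TSV/FASTA/Newick/GraphML.
#'
#' @param config list (or path to a YAML file) with elements:
#'   `preset` (name) or `fasta` (+ optional `species_tree`) for real input;
#'   `seed` (master seed, mandatory); optional `inclusion_evalue` (1e-5),
#'   `rbh_evalue` (1e-10), `bootstrap` (0 = skip), `nni` (FALSE),
#'   `out_dir`.
#' @return list of class `lox_run` with elements `records`, `hits`,
#'   `annotation`, `domains`, `alignment`, `gene_tree`, `bootstrap`,
#'   `catalytic`, `network`, `components`, `summary` (+ `truth`, `events`
#'   for presets).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML run configuration requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) stop("config$seed is mandatory")
  seed <- config$seed
  stage <- function(label) derive_seed(seed, label)

  if (!is.null(config$preset)) {
    sim <- preset(config$preset, seed)
    records <- sim$records
  } else if (!is.null(config$fasta)) {
    sim <- NULL
    records <- read_fasta(config$fasta)
  } else stop("config needs either 'preset' or 'fasta'")

  profiles <- load_domain_profiles()
  hits <- scan_proteome(profiles, records,
                        inclusion_evalue = config$inclusion_evalue %||% 1e-5,
                        seed = stage("scan"))
  ann <- annotate_proteins(records, hits)

  domains <- extract_domains(records, hits, "lox")
  reference <- lox_reference_record()
  dom_with_ref <- rbind(as.data.frame(domains), as.data.frame(reference))
  alignment <- if (nrow(domains) >= 2) {
    progressive_align(setNames(dom_with_ref$sequence, dom_with_ref$id))
  } else NULL

  gene_tree <- NULL; boot <- NULL
  if (!is.null(alignment) && length(alignment$ids) >= 3) {
    drop_ref <- setdiff(alignment$ids, reference$id)
    aln_genes <- subset_msa(alignment, drop_ref)
    gene_tree <- nj_tree(msa_distances(aln_genes))
    if (!is.null(config$nni) && isTRUE(config$nni) && length(aln_genes$ids) >= 4) {
      model <- subst_model(config$model %||% "WAG", gamma_shape = 0.8)
      gene_tree <- nni_search(aln_genes, model, start = gene_tree,
                              seed = stage("nni"))$tree
    }
    nb <- config$bootstrap %||% 0
    if (nb > 0 && length(aln_genes$ids) >= 4) {
      boot <- bootstrap_support(aln_genes, gene_tree, nb, seed = stage("bootstrap"))
      gene_tree <- boot$tree
    }
  }

  catalytic <- if (!is.null(alignment)) {
    rule <- lox_reference_rule(alignment)
    tab <- assess_alignment(alignment, rule)
    tab[tab$protein != reference$id, , drop = FALSE]
  } else NULL

  network <- if (nrow(records) >= 2) {
    reciprocal_network(records, config$rbh_evalue %||% 1e-10)
  } else NULL
  comps <- if (!is.null(network)) components_and_clusters(network) else NULL

  summary <- data.frame(
    n_proteins = nrow(records),
    n_lox_hits = sum(hits$profile == "lox"),
    n_architectures = length(unique(ann$architectures$architecture)),
    n_mixed_components = if (!is.null(comps)) sum(comps$mixed) else NA_integer_,
    n_competent = if (!is.null(catalytic)) sum(catalytic$verdict == "competent") else NA_integer_,
    n_non_competent = if (!is.null(catalytic)) sum(catalytic$verdict == "non_competent") else NA_integer_
  )

  out <- list(records = records, hits = hits, annotation = ann,
              domains = domains, alignment = alignment,
              gene_tree = gene_tree, bootstrap = boot, catalytic = catalytic,
              network = network, components = comps, summary = summary,
              config = config)
  if (!is.null(sim)) {
    out$truth <- sim$truth
    out$events <- sim$events
    out$species_tree <- sim$tree
    out$clades <- sim$clades
  }
  class(out) <- "lox_run"
  if (!is.null(config$out_dir)) write_run_bundle(out, config$out_dir)
  out
}

#' @export
print.lox_run <- function(x, ...) {
  cat("loxevo pipeline run\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# The bundled competent reference: consensus-free first row of the LOX
# seed, used as alignment reference for catalytic assessment.
lox_reference_record <- function() {
  seed <- load_seed_alignment("lox")
  protein_records("LOX_REFERENCE", "reference", "Reference",
                  degap(seed$seqs[[1]]))
}

lox_reference_rule <- function(alignment) {
  geo <- LOX_SEED_GEOMETRY
  catalytic_rule(k_pos = geo$k_pos, y_pos = geo$y_pos,
                 reference_id = "LOX_REFERENCE")
}

# restrict an alignment to a subset of rows, dropping all-gap columns
subset_msa <- function(msa, ids) {
  mat <- msa_matrix(msa)[ids, , drop = FALSE]
  keep <- colSums(mat != "-") > 0
  new_msa(ids, apply(mat[, keep, drop = FALSE], 1, paste, collapse = ""))
}

# convert lox_records to a plain data.frame (for rbind)
#' @export
as.data.frame.lox_records <- function(x, ...) {
  class(x) <- "data.frame"
  x
}

write_run_bundle <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, f) {
    if (!is.null(d)) utils::write.table(d, file.path(dir, f), sep = "\t",
                                        quote = FALSE, row.names = FALSE)
  }
  write_fasta(run$records, file.path(dir, "proteins.fasta"))
  hits <- run$hits
  hits$map <- NULL
  tsv(hits, "hits.tsv")
  tsv(run$annotation$features, "features.tsv")
  tsv(run$annotation$architectures, "architectures.tsv")
  if (!is.null(run$alignment)) {
    write_alignment(run$alignment, file.path(dir, "lox_domains.aln.fasta"))
  }
  if (!is.null(run$gene_tree)) {
    write_newick(run$gene_tree, file.path(dir, "gene_tree.nwk"))
  }
  tsv(run$catalytic, "catalytic.tsv")
  if (!is.null(run$network)) {
    write_graphml(run$network, file.path(dir, "network.graphml"))
  }
  tsv(run$components, "components.tsv")
  tsv(run$summary, "summary.tsv")
  if (!is.null(run$truth)) tsv(run$truth, "truth.tsv")
  if (!is.null(run$events)) tsv(run$events, "events.tsv")
  if (!is.null(run$species_tree)) {
    write_newick(run$species_tree, file.path(dir, "species_tree.nwk"))
  }
  invisible(dir)
}
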