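# Reciprocal-hit similarity network for horizontal gene transfer
# assessment: Smith-Waterman local alignment, Karlin-Altschul bit scores
# and E-values, and the reciprocal-hit graph with clade-composition
# analysis of its connected components.

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' A gap of length L costs `gap_open + L * gap_extend`; the raw score is
#' never negative (the empty alignment scores 0).  Traceback starts at the
#' highest-scoring cell (then the leftmost: smallest end position in `a`,
#' then in `b`).
#'
#' @param a,b protein sequences.
#' @param submat substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend affine gap penalties.
#' @return list: `score` (raw), `a_start`, `a_end`, `b_start`, `b_end`
#'   (1-based inclusive; 0s when the best alignment is empty), `a_aln`,
#'   `b_aln`.
#' @export
smith_waterman <- function(a, b, submat = blosum62(), gap_open = 10,
                           gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence in local alignment")
  ac <- seq_chars(toupper(a)); bc <- seq_chars(toupper(b))
  S <- residue_scores(ac, bc, submat)
  dp <- affine_dp(S, gap_open, gap_extend, "local")
  M <- dp$M
  best <- max(M, 0)
  if (best <= 0) {
    return(list(score = 0, a_start = 0L, a_end = 0L, b_start = 0L, b_end = 0L,
                a_aln = "", b_aln = ""))
  }
  hit <- which(M == best, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
  i <- hit[1] - 1L; j <- hit[2] - 1L
  path <- affine_traceback(dp, S, gap_open, gap_extend, i, j, "M", local = TRUE)
  sel <- path[, 1] > 0
  list(score = best,
       a_start = min(path[sel, 1]), a_end = max(path[sel, 1]),
       b_start = min(path[path[, 2] > 0, 2]), b_end = max(path[path[, 2] > 0, 2]),
       a_aln = paste(ifelse(path[, 1] > 0, ac[pmax(path[, 1], 1)], "-"), collapse = ""),
       b_aln = paste(ifelse(path[, 2] > 0, bc[pmax(path[, 2], 1)], "-"), collapse = ""))
}

#' Karlin-Altschul bit score and E-value
#'
#' `bits = (lambda * S - ln K) / ln 2`; `E = m * n * 2^-bits`.  Defaults
#' are the conventional gapped BLOSUM62 (open 11, extend 1) parameters.
#'
#' @param score raw alignment score.
#' @param m,n effective sequence/database lengths.
#' @param lambda,K Karlin-Altschul parameters (> 0).
#' @return list with `bits` and `evalue`.
#' @export
evalue_ka <- function(score, m, n, lambda = 0.267, K = 0.041) {
  if (lambda <= 0 || K <= 0) stop("lambda and K must be > 0")
  bits <- (lambda * score - log(K)) / log(2)
  list(bits = bits, evalue = m * n * 2^(-bits))
}

#' Reciprocal-hit network
#'
#' All-versus-all local alignments; two proteins are connected iff each
#' finds the other with `E <= evalue_threshold` (any-hit reciprocity; with
#' `best_hit = TRUE` each must additionally be the other's best-scoring
#' hit).  The edge attribute `E` is the larger of the two directional
#' E-values.
#'
#' @param proteins a `lox_records` data.frame (>= 2 rows).
#' @param evalue_threshold inclusion threshold (> 0).
#' @param best_hit logical: require reciprocal BEST hits.
#' @param submat,gap_open,gap_extend alignment scoring.
#' @return an [igraph] graph with vertex attributes `name`, `taxon`,
#'   `clade` and edge attribute `E`.
#' @export
reciprocal_network <- function(proteins, evalue_threshold = 1e-10,
                               best_hit = FALSE, submat = blosum62(),
                               gap_open = 10, gap_extend = 0.5) {
  n <- nrow(proteins)
  if (n < 2) stop("need at least 2 proteins")
  if (evalue_threshold <= 0) stop("evalue_threshold must be > 0")
  ids <- proteins$id
  len <- nchar(proteins$sequence)
  Ebits <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  Eval <- matrix(Inf, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sw <- smith_waterman(proteins$sequence[i], proteins$sequence[j],
                           submat, gap_open, gap_extend)
      ka <- evalue_ka(sw$score, len[i], len[j])
      Ebits[i, j] <- Ebits[j, i] <- ka$bits
      Eval[i, j] <- Eval[j, i] <- ka$evalue
    }
  }
  edges <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pass <- Eval[i, j] <= evalue_threshold
      if (pass && best_hit) {
        pass <- (Eval[i, j] <= min(Eval[i, -i])) && (Eval[i, j] <= min(Eval[j, -j]))
      }
      if (pass) edges[[length(edges) + 1]] <- data.frame(
        from = ids[i], to = ids[j], E = Eval[i, j])
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, n, name = ids, taxon = proteins$taxon,
                            clade = proteins$clade)
  if (length(edges)) {
    ed <- do.call(rbind, edges)
    g <- igraph::add_edges(g, as.vector(rbind(match(ed$from, ids),
                                              match(ed$to, ids))),
                           E = ed$E)
  }
  g
}

#' Connected components and their clade composition
#'
#' @param graph a reciprocal-hit graph from [reciprocal_network()].
#' @return data.frame with one row per component: `component`, `n_nodes`,
#'   `clades` (comma-separated `clade:count`), `n_clades` and `mixed`
#'   (TRUE when more than one top-level clade is present, the horizontal
#'   transfer signal).
#' @export
components_and_clusters <- function(graph) {
  comp <- igraph::components(graph)
  clade <- igraph::vertex_attr(graph, "clade")
  rows <- lapply(seq_len(comp$no), function(c) {
    members <- which(comp$membership == c)
    tab <- sort(table(clade[members]), decreasing = TRUE)
    data.frame(component = c, n_nodes = length(members),
               clades = paste(paste0(names(tab), ":", as.integer(tab)),
                              collapse = ","),
               n_clades = length(tab), mixed = length(tab) > 1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export a hit graph to GraphML
#'
#' @param graph an igraph graph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
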