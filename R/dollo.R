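# Dollo parsimony reconstruction of gains and losses of families and
# domain features on a fixed species tree: each character is gained
# exactly once (at the MRCA of the taxa carrying it, unless constrained
# deeper by gene-tree evidence) and lost on the minimal set of branches
# covering the absences.

# children lookup for a rooted ape tree
tree_children <- function(tree) {
  split(tree$edge[, 2], factor(tree$edge[, 1],
                               levels = seq_len(length(tree$tip.label) + tree$Nnode)))
}

# tip indices below each node
tips_below <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) return(node)
  unlist(phangorn::Descendants(tree, node, "tips"))
}

#' Dollo reconstruction of one presence/absence character
#'
#' The gain is placed on the branch above the MRCA of the tips with
#' state 1 (or above `constrained_gain` when given, which must be
#' ancestral to all of them); losses are the roots of the maximal
#' subtrees inside the gain clade whose known tips are all 0.  `?` states
#' are treated as unsampled and constrain neither side.  The loss set is
#' the unique minimal one given the gain node.
#'
#' @param tree rooted [ape::phylo] with (for reporting) node labels.
#' @param states named vector over tips with values 0, 1 or `?`.
#' @param constrained_gain optional node label forcing a deeper gain.
#' @return list: `gain` (label of the node whose parent branch carries the
#'   gain), `losses` (labels of loss-branch child nodes), `n_losses`.
#' @export
dollo_reconstruct <- function(tree, states, constrained_gain = NULL) {
  nt <- length(tree$tip.label)
  st <- as.character(states[tree$tip.label])
  names(st) <- tree$tip.label
  ones <- which(st == "1")
  if (!length(ones)) stop("character has no tip with state 1")
  gain_node <- if (length(ones) == 1) ones else ape::getMRCA(tree, tree$tip.label[ones])
  if (!is.null(constrained_gain)) {
    cg <- node_by_label(tree, constrained_gain)
    if (is.na(cg)) stop("unknown constrained gain node: ", constrained_gain)
    below <- tips_below(tree, cg)
    if (!all(ones %in% below)) {
      stop("constrained gain node '", constrained_gain,
           "' is not ancestral to all presence tips")
    }
    gain_node <- cg
  }
  children <- tree_children(tree)
  # postorder flags: does a subtree contain any known-1 / known-0 tip?
  has1 <- has0 <- rep(FALSE, nt + tree$Nnode)
  post <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(post$edge))) {
    chd <- post$edge[e, 2]
    if (chd <= nt) {
      has1[chd] <- st[chd] == "1"
      has0[chd] <- st[chd] == "0"
    }
    par <- post$edge[e, 1]
    has1[par] <- has1[par] || has1[chd]
    has0[par] <- has0[par] || has0[chd]
  }
  # losses: maximal subtrees under the gain node with no 1 and >= 1 known 0
  losses <- integer(0)
  walk <- function(node) {
    kids <- children[[node]]
    for (k in kids) {
      if (!has1[k]) {
        if (has0[k]) losses <<- c(losses, k)
      } else if (k > nt) {
        walk(k)
      }
    }
  }
  if (gain_node > nt) walk(gain_node)
  list(gain = node_label(tree, gain_node),
       losses = vapply(losses, function(n) node_label(tree, n), ""),
       n_losses = length(losses))
}

#' Duplication-aware gain constraints from a gene tree
#'
#' For each designated family (a set of gene-tree tips), checks that the
#' family is monophyletic in the gene tree and places its gain at the
#' species-tree LCA of the species in the family clade united with the
#' species of its sister family clade: paralog families born of one
#' duplication are thereby both anchored on the branch where the
#' duplication happened, not on their individual (possibly later) MRCAs.
#'
#' @param gene_tree [ape::phylo] of genes.
#' @param species_tree rooted [ape::phylo] with node labels.
#' @param family_of named character vector: gene id -> family.
#' @param species_of named character vector: gene id -> species (tip label
#'   of the species tree).
#' @return named character vector: family -> species-tree node label.
#' @export
reconcile_gain_nodes <- function(gene_tree, species_tree, family_of, species_of) {
  fams <- unique(family_of[gene_tree$tip.label])
  fams <- fams[!is.na(fams)]
  out <- character(0)
  for (fam in fams) {
    members <- names(family_of)[family_of == fam]
    members <- intersect(members, gene_tree$tip.label)
    if (length(members) > 1) {
      mrca <- ape::getMRCA(gene_tree, members)
      below <- gene_tree$tip.label[tips_below(gene_tree, mrca)]
      intruders <- setdiff(below, members)
      if (length(intruders)) {
        stop("family '", fam, "' is not monophyletic in the gene tree; intruders: ",
             paste(head(intruders, 3), collapse = ", "))
      }
    }
    own_species <- unique(species_of[members])
    # sister clade in the gene tree
    sister_species <- character(0)
    if (length(members) >= 1 && length(gene_tree$tip.label) > length(members)) {
      node <- if (length(members) > 1) ape::getMRCA(gene_tree, members) else
        match(members, gene_tree$tip.label)
      par <- gene_tree$edge[gene_tree$edge[, 2] == node, 1]
      if (length(par)) {
        sibs <- setdiff(gene_tree$edge[gene_tree$edge[, 1] == par, 2], node)
        sib_tips <- unlist(lapply(sibs, function(s) {
          gene_tree$tip.label[tips_below(gene_tree, s)]
        }))
        sib_fams <- unique(family_of[sib_tips])
        # only a clean sister *family* clade counts as duplication context
        if (length(sib_fams) == 1 && !is.na(sib_fams) && sib_fams != fam) {
          sister_species <- unique(species_of[sib_tips])
        }
      }
    }
    span <- unique(c(own_species, sister_species))
    span <- intersect(span, species_tree$tip.label)
    node <- if (length(span) > 1) ape::getMRCA(species_tree, span) else
      match(span, species_tree$tip.label)
    out[fam] <- node_label(species_tree, node)
  }
  out
}

#' Gain/loss report for a character matrix
#'
#' Runs [dollo_reconstruct()] on every character and aggregates events
#' per branch.
#'
#' @param tree rooted species tree with node labels.
#' @param matrix data.frame/matrix of characters: rows = taxa (rownames),
#'   columns = characters; entries 0, 1 or `?`.
#' @param constrained_gains optional named vector: character -> node label.
#' @return list: `events` (data.frame character, branch, type), `per_branch`
#'   (data.frame branch, gains, losses), `per_character` (list of
#'   reconstructions).
#' @export
event_report <- function(tree, matrix, constrained_gains = NULL) {
  chars <- colnames(matrix)
  ev <- list(); recs <- list()
  for (ch in chars) {
    states <- setNames(as.character(matrix[, ch]), rownames(matrix))
    cg <- if (!is.null(constrained_gains) && ch %in% names(constrained_gains))
      constrained_gains[[ch]] else NULL
    r <- dollo_reconstruct(tree, states, cg)
    recs[[ch]] <- r
    ev[[length(ev) + 1]] <- data.frame(character = ch, branch = r$gain,
                                       type = "gain", stringsAsFactors = FALSE)
    for (l in r$losses) {
      ev[[length(ev) + 1]] <- data.frame(character = ch, branch = l,
                                         type = "loss", stringsAsFactors = FALSE)
    }
  }
  events <- do.call(rbind, ev)
  agg <- stats::aggregate(cbind(gains = events$type == "gain",
                                losses = events$type == "loss"),
                          by = list(branch = events$branch), FUN = sum)
  list(events = events, per_branch = agg, per_character = recs)
}
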