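# Bipartition bookkeeping across tree samples: split frequencies,
# majority-rule consensus, and the bpcomp-style maxdiff convergence scan
# used to decide when two tree samples agree.

# Canonical key of the bipartition induced by the edge above `node`:
# the side NOT containing the reference tip (lexicographically smallest
# label), sorted and joined.  NULL for trivial splits.
split_key <- function(tips_below, all_tips) {
  ref <- min(all_tips)
  side <- sort(tips_below)
  if (ref %in% side) side <- sort(setdiff(all_tips, side))
  if (length(side) < 2 || length(side) > length(all_tips) - 2) return(NULL)
  paste(side, collapse = "|")
}

split_key_for_node <- function(tree, node) {
  nt <- length(tree$tip.label)
  tips <- tree$tip.label[intersect(unlist(phangorn::Descendants(tree, node, "tips")), seq_len(nt))]
  split_key(tips, tree$tip.label)
}

#' Non-trivial bipartitions of a tree
#'
#' @param tree [ape::phylo].
#' @return character vector of canonical split keys (side not containing
#'   the reference tip, labels joined by `|`).
#' @export
tree_splits <- function(tree) {
  nt <- length(tree$tip.label)
  keys <- character(0)
  for (node in (nt + 1L):(nt + tree$Nnode)) {
    k <- split_key_for_node(tree, node)
    if (!is.null(k)) keys <- c(keys, k)
  }
  unique(keys)
}

# Apply burn-in fraction and stride to a tree list.
retain_trees <- function(trees, burn_in = 0, stride = 1) {
  n <- length(trees)
  from <- floor(burn_in * n) + 1L
  if (from > n) stop("burn-in removes every tree in the sample")
  idx <- seq(from, n, by = stride)
  trees[idx]
}

#' Bipartition frequencies across a tree sample
#'
#' @param trees list of trees (`multiPhylo`) on the same tip set.
#' @param burn_in fraction of initial trees discarded.
#' @param stride keep every `stride`-th tree after burn-in.
#' @return named numeric vector: split key -> fraction of retained trees
#'   containing the split.
#' @export
bipartition_frequencies <- function(trees, burn_in = 0, stride = 1) {
  kept <- retain_trees(trees, burn_in, stride)
  tipsets <- lapply(kept, function(t) sort(t$tip.label))
  if (length(unique(vapply(tipsets, paste, "", collapse = "|"))) > 1) {
    stop("trees have mismatched tip sets")
  }
  tab <- table(unlist(lapply(kept, tree_splits)))
  setNames(as.numeric(tab) / length(kept), names(tab))
}

#' Maximum bipartition-frequency difference between two tree samples
#'
#' The bpcomp statistic: the maximum over the union of observed splits of
#' the absolute difference between the two samples' frequencies.
#'
#' @param a,b tree samples on the same tip set.
#' @param burn_in,stride as in [bipartition_frequencies()].
#' @return maxdiff in `[0, 1]`.
#' @export
maxdiff <- function(a, b, burn_in = 0, stride = 1) {
  fa <- bipartition_frequencies(a, burn_in, stride)
  fb <- bipartition_frequencies(b, burn_in, stride)
  keys <- union(names(fa), names(fb))
  if (!length(keys)) return(0)
  va <- ifelse(keys %in% names(fa), fa[keys], 0)
  vb <- ifelse(keys %in% names(fb), fb[keys], 0)
  max(abs(va - vb))
}

#' Burn-in scan of the maxdiff statistic
#'
#' Evaluates maxdiff between two samples for burn-in fractions 1%..50%
#' (union-of-splits convention) and reports the minimising burn-in
#' (smallest on ties) and whether it clears the convergence threshold.
#'
#' @param a,b tree samples (>= 20 trees each).
#' @param threshold convergence threshold on maxdiff.
#' @param stride subsampling stride.
#' @param grid burn-in fractions scanned.
#' @return list of class `lox_convergence`: `table` (burn_in, maxdiff),
#'   `burn_in`, `maxdiff`, `converged`, `threshold`, `stride`, `n_trees`.
#' @export
convergence_scan <- function(a, b, threshold = 0.1, stride = 10,
                             grid = seq(0.01, 0.5, by = 0.01)) {
  if (length(a) < 20 || length(b) < 20) stop("need at least 20 trees per sample")
  md <- vapply(grid, function(bi) maxdiff(a, b, bi, stride), 0)
  tab <- data.frame(burn_in = grid, maxdiff = md)
  i <- which.min(md)  # smallest index wins ties
  structure(list(table = tab, burn_in = grid[i], maxdiff = md[i],
                 converged = md[i] <= threshold, threshold = threshold,
                 stride = stride, n_trees = c(length(a), length(b))),
            class = "lox_convergence")
}

#' @export
print.lox_convergence <- function(x, ...) {
  cat("maxdiff convergence scan (split union convention)\n")
  cat(sprintf("  samples: %d / %d trees, stride %d\n", x$n_trees[1],
              x$n_trees[2], x$stride))
  cat(sprintf("  best burn-in: %.0f%%  maxdiff: %.4f  (threshold %.2f) -> %s\n",
              100 * x$burn_in, x$maxdiff, x$threshold,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Majority-rule consensus of a tree sample
#'
#' Includes splits with frequency > 0.5; internal node labels carry
#' supports equal to 100 x the split frequency.
#'
#' @param trees tree sample.
#' @param burn_in,stride as in [bipartition_frequencies()].
#' @return [ape::phylo] (possibly multifurcating) with support labels.
#' @export
majority_consensus <- function(trees, burn_in = 0, stride = 1) {
  kept <- retain_trees(trees, burn_in, stride)
  class(kept) <- "multiPhylo"
  freqs <- bipartition_frequencies(kept)
  cons <- ape::consensus(kept, p = 0.5, rooted = FALSE)
  nt <- length(cons$tip.label)
  labs <- rep("", cons$Nnode)
  for (n in seq_len(cons$Nnode)) {
    key <- split_key_for_node(cons, nt + n)
    if (!is.null(key) && !is.na(freqs[key])) {
      labs[n] <- as.character(round(100 * freqs[key]))
    }
  }
  cons$node.label <- labs
  cons
}
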