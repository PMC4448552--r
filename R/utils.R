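# Shared constants and small helpers.

# The 20 standard amino acids, PAML/phylogenetics column order.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Accepted residue alphabet for unaligned input (X = unknown/missing).
AA_ALPHABET_X <- c(AA20, "X")

#' Derive a reproducible child seed from a master seed
#'
#' Stage-labelled, counter-based seed derivation: the seed of one stage does
#' not depend on how many draws another stage consumed, so inserting a stage
#' never shifts the randomness of the others.  Result is always a positive
#' 32-bit integer.
#'
#' @param master integer master seed.
#' @param label character stage label.
#' @param counter optional integer sub-counter (e.g. replicate number).
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, label, counter = 0L) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  x <- (as.double(master) %% 2147483647) * 48271 + h * 8191 + counter * 131071
  as.integer(x %% 2147483562 + 1)
}

# log2-sum-exp of a numeric vector (base 2), -Inf-safe.
log2sumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log2(sum(2^(x - m)))
}

# Elementwise log2-sum-exp of several equal-length vectors.
plog2sumexp <- function(...) {
  xs <- list(...)
  m <- do.call(pmax, xs)
  s <- 0
  for (x in xs) s <- s + ifelse(is.finite(m), 2^(x - m), 0)
  ifelse(is.finite(m), m + log2(s), m)
}

# Split a protein string into a character vector of residues.
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Validate a sequence against the residue alphabet; returns the position of
# the first offending character or 0L if clean.
first_bad_residue <- function(s, allow_gap = FALSE) {
  pat <- if (allow_gap) "[^ACDEFGHIKLMNPQRSTVWYX-]" else "[^ACDEFGHIKLMNPQRSTVWYX]"
  m <- regexpr(pat, s)
  if (m[1] == -1) 0L else as.integer(m[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Root node id of a (possibly re-rooted) ape tree: the node that is never
# a child.  ape convention is ntip+1, but trees emitted by other tools may
# differ.
tree_root <- function(tree) {
  setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
}
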