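# Catalytic-competence assessment of LOX domains: the copper-binding
# histidine core ("copper talon", InterPro conserved-site style motif) and
# the LTQ cofactor lysine/tyrosine pair.
#
# In human LOX the motif reads WEWHSCHQHYHSMD; its four histidines sit at
# offsets 4, 7, 9 and 11 (1-based within the motif).  Experimental
# mutagenesis showed that replacing the first histidine does not abolish
# copper binding, so only the last three are treated as the essential
# core; catalytic competence additionally requires the LTQ lysine and
# tyrosine (K320/Y355 in the human reference numbering).

#' Catalytic classification rule
#'
#' @param motif_pattern regular expression locating the copper-talon motif
#'   in the de-gapped reference sequence.
#' @param h_offsets 1-based offsets of the four histidine slots within the
#'   motif match; the first is dispensable, the remaining three are core.
#' @param k_pos,y_pos 1-based positions of the LTQ lysine and tyrosine in
#'   the de-gapped reference sequence.
#' @param reference_id id of the reference row.
#' @return a list of class `lox_catalytic_rule`.
#' @export
catalytic_rule <- function(motif_pattern = "W.WH..H.H.H",
                           h_offsets = c(4L, 7L, 9L, 11L),
                           k_pos, y_pos, reference_id) {
  stopifnot(length(h_offsets) == 4)
  structure(list(motif_pattern = motif_pattern, h_offsets = h_offsets,
                 core = 2:4, min_core = 3L, k_pos = as.integer(k_pos),
                 y_pos = as.integer(y_pos), reference_id = reference_id),
            class = "lox_catalytic_rule")
}

# Map a position in the de-gapped reference row to its alignment column.
ungapped_to_column <- function(row_chars, pos) {
  which(row_chars != "-")[pos]
}

#' Locate the copper-talon histidine columns in an alignment
#'
#' Finds the motif in the de-gapped reference row and maps the four
#' histidine offsets (and the LTQ K/Y positions) through the gap structure
#' to alignment columns.
#'
#' @param msa a `lox_msa` containing the reference row.
#' @param rule a `lox_catalytic_rule`.
#' @return list with `h_cols` (4 columns), `k_col`, `y_col` (1-based
#'   alignment columns).
#' @export
locate_copper_talon <- function(msa, rule) {
  ref_id <- rule$reference_id
  if (!ref_id %in% msa$ids) stop("reference '", ref_id, "' not in alignment")
  row <- msa$seqs[[ref_id]]
  chars <- seq_chars(row)
  ung <- degap(row)
  m <- regexpr(rule$motif_pattern, ung)
  if (m[1] == -1) {
    stop("reference '", ref_id, "' lacks the copper-talon motif (pattern ",
         rule$motif_pattern, ")")
  }
  h_pos <- m[1] + rule$h_offsets - 1L
  h_cols <- vapply(h_pos, function(p) ungapped_to_column(chars, p), 0L)
  if (any(substr(ung, h_pos, h_pos) != "H")) {
    stop("motif match in reference '", ref_id, "' has non-histidine at a histidine slot")
  }
  k_col <- if (rule$k_pos <= nchar(ung)) ungapped_to_column(chars, rule$k_pos) else NA_integer_
  y_col <- if (rule$y_pos <= nchar(ung)) ungapped_to_column(chars, rule$y_pos) else NA_integer_
  if (is.na(k_col) || substr(ung, rule$k_pos, rule$k_pos) != "K") {
    stop("reference '", ref_id, "' lacks lysine at LTQ position ", rule$k_pos)
  }
  if (is.na(y_col) || substr(ung, rule$y_pos, rule$y_pos) != "Y") {
    stop("reference '", ref_id, "' lacks tyrosine at LTQ position ", rule$y_pos)
  }
  list(h_cols = h_cols, k_col = k_col, y_col = y_col)
}

#' Assess one alignment row for catalytic competence
#'
#' A row is competent iff it keeps the three core histidines and both LTQ
#' residues; a gap at a located column counts as residue-absent
#' (conservative).  The first histidine is reported but not required.
#'
#' @param row gapped sequence string (one alignment row).
#' @param cols column set from [locate_copper_talon()].
#' @param protein_id id recorded in the result.
#' @return one-row data.frame: protein, h1..h4, K, Y, verdict, reasons.
#' @export
assess_sequence <- function(row, cols, protein_id = "query") {
  chars <- seq_chars(row)
  h <- chars[cols$h_cols] == "H"
  K <- chars[cols$k_col] == "K"
  Y <- chars[cols$y_col] == "Y"
  reasons <- character(0)
  if (!all(h[2:4])) reasons <- c(reasons, "lacks the histidine core")
  if (!K) reasons <- c(reasons, "lacks the LTQ lysine")
  if (!Y) reasons <- c(reasons, "lacks the LTQ tyrosine")
  if (!h[1] && all(h[2:4])) {
    reasons <- c(reasons, "first (dispensable) histidine absent")
  }
  verdict <- if (all(h[2:4]) && K && Y) "competent" else "non_competent"
  data.frame(protein = protein_id, h1 = h[1], h2 = h[2], h3 = h[3], h4 = h[4],
             K = K, Y = Y, verdict = verdict,
             reasons = paste(reasons, collapse = "; "),
             stringsAsFactors = FALSE)
}

#' Assess every row of a LOX-domain alignment
#'
#' @param msa a `lox_msa` containing the reference row.
#' @param rule a `lox_catalytic_rule`.
#' @return data.frame with one row per sequence plus a `summary` attribute
#'   of verdict counts.
#' @export
assess_alignment <- function(msa, rule) {
  cols <- locate_copper_talon(msa, rule)
  out <- do.call(rbind, lapply(msa$ids, function(id) {
    assess_sequence(msa$seqs[[id]], cols, id)
  }))
  attr(out, "summary") <- table(factor(out$verdict,
                                       levels = c("competent", "non_competent")))
  out
}
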