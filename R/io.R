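# Readers and writers for FASTA, aligned FASTA, Stockholm and Newick, plus
# record validation.  Coordinates are 0-based half-open internally and
# 1-based inclusive in every user-facing table.

#' Protein record sets
#'
#' A protein record set is a `data.frame` with columns `id`, `taxon`,
#' `clade` and `sequence`.  Ids are unique and non-empty; sequences are
#' upper-case strings over the 20 amino-acid letters plus `X` (unknown,
#' treated as missing data throughout the pipeline).
#'
#' @param id,taxon,clade,sequence character vectors of equal length.
#' @return a validated `data.frame` of class `lox_records`.
#' @export
protein_records <- function(id, taxon = "", clade = "", sequence) {
  n <- length(id)
  rec <- data.frame(
    id = as.character(id),
    taxon = rep_len(as.character(taxon), n),
    clade = rep_len(as.character(clade), n),
    sequence = toupper(as.character(sequence)),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(rec$id))) stop("protein record with empty id")
  dup <- rec$id[duplicated(rec$id)]
  if (length(dup)) stop("duplicate protein id: ", dup[1])
  if (any(!nzchar(rec$sequence))) {
    stop("empty sequence for id ", rec$id[which(!nzchar(rec$sequence))[1]])
  }
  for (i in seq_len(n)) {
    p <- first_bad_residue(rec$sequence[i])
    if (p > 0L) {
      stop("illegal character '", substr(rec$sequence[i], p, p),
           "' at position ", p, " in sequence ", rec$id[i])
    }
  }
  class(rec) <- c("lox_records", "data.frame")
  rec
}

#' Read protein sequences from a FASTA file
#'
#' Headers may follow the dialect `id|taxon|clade`; a plain id leaves taxon
#' and clade empty.  Sequences are upper-cased and validated against the
#' alphabet `ACDEFGHIKLMNPQRSTVWYX`; gap characters are rejected because
#' plain FASTA input is unaligned.
#'
#' @param path path to a FASTA file.
#' @return a `lox_records` data.frame, records in file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no records in FASTA file: ", path)
  heads <- names(set)
  parts <- strsplit(heads, "|", fixed = TRUE)
  id <- vapply(parts, function(p) trimws(p[1]), "")
  taxon <- vapply(parts, function(p) if (length(p) >= 2) trimws(p[2]) else "", "")
  clade <- vapply(parts, function(p) if (length(p) >= 3) trimws(p[3]) else "", "")
  protein_records(id, taxon, clade, as.character(set))
}

#' Write protein records to FASTA
#'
#' @param records a `lox_records` data.frame.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  hdr <- ifelse(nzchar(records$taxon) | nzchar(records$clade),
                paste(records$id, records$taxon, records$clade, sep = "|"),
                records$id)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", hdr[i]), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Multiple alignment container
#'
#' Rows are gapped sequences of equal length; `-` is the gap character.
#' Columns are indexed 0-based internally and reported 1-based in outputs.
#'
#' @param ids character vector of unique row ids.
#' @param seqs character vector of equal-length gapped sequences.
#' @return an object of class `lox_msa` with elements `ids`, `seqs`
#'   (named by id) and `ncol`.
#' @export
new_msa <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) stop("ids and seqs differ in length")
  if (anyDuplicated(ids)) stop("duplicate row id: ", ids[duplicated(ids)][1])
  len <- nchar(seqs)
  if (length(unique(len)) > 1) {
    bad <- ids[which(len != len[1])[1]]
    stop("ragged alignment: row '", bad, "' has different length")
  }
  for (i in seq_along(seqs)) {
    p <- first_bad_residue(seqs[i], allow_gap = TRUE)
    if (p > 0L) stop("illegal character at position ", p, " in row ", ids[i])
  }
  structure(list(ids = ids, seqs = setNames(seqs, ids), ncol = len[1]),
            class = "lox_msa")
}

#' @export
print.lox_msa <- function(x, ...) {
  cat("Multiple alignment:", length(x$ids), "sequences x", x$ncol, "columns\n")
  invisible(x)
}

# Alignment as a character matrix (rows = sequences).
msa_matrix <- function(msa) {
  do.call(rbind, lapply(msa$seqs, seq_chars))
}

#' Read a multiple alignment
#'
#' Supports aligned FASTA and Stockholm.  In Stockholm files, `#=..`
#' annotation lines and the `//` terminator are ignored; sequence lines may
#' be split over several blocks.  `.` gap characters are normalised to `-`.
#'
#' @param path input path.
#' @param format `"fasta"` or `"stockholm"`; the default guesses from the
#'   first non-blank line.
#' @return a `lox_msa` object.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (length(first) && startsWith(first, "# STOCKHOLM")) "stockholm" else "fasta"
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0) stop("no records in alignment file: ", path)
    return(new_msa(names(set), chartr(".", "-", as.character(set))))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  keep <- !startsWith(lines, "#") & !startsWith(lines, "//")
  acc <- list()
  order <- character(0)
  for (ln in lines[keep]) {
    f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(f) != 2) stop("malformed Stockholm sequence line: ", ln)
    if (!f[1] %in% order) order <- c(order, f[1])
    acc[[f[1]]] <- paste0(acc[[f[1]]] %||% "", f[2])
  }
  if (!length(order)) stop("no records in Stockholm file: ", path)
  new_msa(order, chartr(".", "-", unlist(acc[order])))
}

#' Write a multiple alignment
#'
#' @param msa a `lox_msa` object.
#' @param path output path.
#' @param format `"fasta"` or `"stockholm"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(msa, path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "fasta") {
    for (i in seq_along(msa$ids)) {
      writeLines(c(paste0(">", msa$ids[i]), msa$seqs[[i]]), con)
    }
  } else {
    writeLines("# STOCKHOLM 1.0", con)
    w <- max(nchar(msa$ids)) + 2L
    for (i in seq_along(msa$ids)) {
      writeLines(sprintf("%-*s%s", w, msa$ids[i], msa$seqs[[i]]), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

# De-gap one alignment row.
degap <- function(s) gsub("-", "", s, fixed = TRUE)

check_newick_balance <- function(s) {
  depth <- 0L
  chars <- seq_chars(s)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced parenthesis at character ", i, " of Newick string")
    }
  }
  if (depth != 0L) {
    stop("unbalanced parentheses in Newick string (", depth,
         " unclosed at end, length ", nchar(s), ")")
  }
  invisible(TRUE)
}

#' Read and write Newick trees
#'
#' Thin validating wrappers around [ape::read.tree()] /
#' [ape::write.tree()].  Reading checks parenthesis balance (reporting the
#' character offset on failure), tip-label uniqueness and non-negative
#' branch lengths; the round trip `read_newick(write_newick(t))` preserves
#' topology, labels and branch lengths to 10 significant digits.
#'
#' @param path path to a Newick file, or `text` a Newick string.
#' @param text optional Newick string instead of a file.
#' @return `read_newick`: an [ape::phylo] tree. `write_newick`: a Newick
#'   string (and the file written, when `path` is given).
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "")
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick input")
  check_newick_balance(text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("failed to parse Newick string")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip label: ", tree$tip.label[duplicated(tree$tip.label)][1])
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch length in tree")
  }
  tree
}

#' @rdname read_newick
#' @param tree an [ape::phylo] object.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree, digits = 10)
  if (!is.null(path)) writeLines(s, path)
  invisible(s)
}

#' Read several trees from a multi-line Newick file
#'
#' One tree per line, the format used for tree samples (bootstrap sets,
#' MCMC chains).
#'
#' @param path input path.
#' @return a list of [ape::phylo] trees (class `multiPhylo`).
#' @export
read_tree_sample <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no trees in file: ", path)
  trees <- lapply(lines, function(l) read_newick(text = l))
  class(trees) <- "multiPhylo"
  trees
}
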