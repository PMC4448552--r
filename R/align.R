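# Pairwise and progressive multiple alignment.  One vectorised affine-gap
# dynamic-programming kernel serves Needleman-Wunsch (global, on sequences
# or profiles) and Smith-Waterman (local).  A gap of length L costs
# open + L * extend.

.align_cache <- new.env(parent = emptyenv())

#' BLOSUM62 scoring matrix over the pipeline alphabet
#'
#' The standard BLOSUM62 substitution scores for the 20 amino acids, with
#' `X` (unknown) scoring 0 against everything, the convention used by all
#' alignment steps here.
#'
#' @return a 21x21 numeric matrix (rows/cols `ACDEFGHIKLMNPQRSTVWYX` order
#'   as in `AA20` plus `X`).
#' @export
blosum62 <- function() {
  if (!is.null(.align_cache$blosum62)) return(.align_cache$blosum62)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- matrix(0, 21, 21, dimnames = list(c(AA20, "X"), c(AA20, "X")))
  S[AA20, AA20] <- BLOSUM62[AA20, AA20]
  .align_cache$blosum62 <- S
  S
}

# Core affine-gap DP on a precomputed cell score matrix S (n x m).
# Returns the three DP matrices ((n+1) x (m+1)) for traceback.
# mode "global": NW; mode "local": SW (fresh starts, scores clamped).
affine_dp <- function(S, gap_open, gap_extend, mode = "global") {
  n <- nrow(S); m <- ncol(S)
  NEG <- -Inf
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  js <- seq_len(m)
  if (mode == "global") {
    M[1, 1] <- 0
    X[-1, 1] <- -gap_open - gap_extend * seq_len(n)
    Y[1, -1] <- -gap_open - gap_extend * js
  }
  open1 <- gap_open + gap_extend
  for (i in seq_len(n)) {
    diagM <- M[i, js]; diagX <- X[i, js]; diagY <- Y[i, js]
    best_diag <- pmax(diagM, diagX, diagY)
    if (mode == "local") best_diag <- pmax(best_diag, 0)
    Mrow <- S[i, ] + best_diag
    Xrow <- pmax(pmax(M[i, -1], Y[i, -1]) - open1, X[i, -1] - gap_extend)
    # Y within-row recurrence via running-max trick:
    # Y[i,j] = max_{k<j} (H[i,k] + k*ext) - open - ext*j  with H = max(M, X)
    H0 <- if (mode == "global") max(M[i + 1, 1], X[i + 1, 1]) else NEG
    Hrow <- c(H0, pmax(Mrow, Xrow))
    run <- cummax(Hrow + gap_extend * (0:m))
    Yrow <- run[js] - gap_open - gap_extend * js
    M[i + 1, -1] <- Mrow
    X[i + 1, -1] <- Xrow
    Y[i + 1, -1] <- Yrow
  }
  list(M = M, X = X, Y = Y)
}

# Traceback helper shared by global and local modes.  Returns a two-column
# matrix of (a index, b index), 0 marking a gap, ordered left to right.
# Tie preference: match > delete (gap in b) > insert (gap in a); in local
# mode a zero-valued diagonal predecessor ends the alignment.
affine_traceback <- function(dp, S, gap_open, gap_extend, i, j, state,
                             local = FALSE) {
  M <- dp$M; X <- dp$X; Y <- dp$Y
  open1 <- gap_open + gap_extend
  eps <- 1e-9
  path <- list()
  repeat {
    if (state == "M") {
      if (i == 0 || j == 0) break
      path[[length(path) + 1]] <- c(i, j)
      prev <- M[i + 1, j + 1] - S[i, j]
      i <- i - 1; j <- j - 1
      if (local && prev < eps) break
      if (abs(M[i + 1, j + 1] - prev) < eps) state <- "M"
      else if (abs(X[i + 1, j + 1] - prev) < eps) state <- "X"
      else if (abs(Y[i + 1, j + 1] - prev) < eps) state <- "Y"
      else if (i == 0 && j == 0) break
      else stop("traceback failure (M)")
      if (i == 0 && j == 0) break
    } else if (state == "X") {
      path[[length(path) + 1]] <- c(i, 0L)
      v <- X[i + 1, j + 1]
      i <- i - 1
      if (i == 0 && j == 0) break
      if (abs(M[i + 1, j + 1] - open1 - v) < eps) state <- "M"
      else if (abs(X[i + 1, j + 1] - gap_extend - v) < eps) state <- "X"
      else if (abs(Y[i + 1, j + 1] - open1 - v) < eps) state <- "Y"
      else stop("traceback failure (X)")
    } else {
      path[[length(path) + 1]] <- c(0L, j)
      v <- Y[i + 1, j + 1]
      j <- j - 1
      if (i == 0 && j == 0) break
      if (abs(M[i + 1, j + 1] - open1 - v) < eps) state <- "M"
      else if (abs(X[i + 1, j + 1] - open1 - v) < eps) state <- "X"
      else if (abs(Y[i + 1, j + 1] - gap_extend - v) < eps) state <- "Y"
      else stop("traceback failure (Y)")
    }
  }
  if (!length(path)) return(matrix(integer(0), 0, 2))
  do.call(rbind, rev(path))
}

# Cell scores between two residue vectors under a substitution matrix;
# unknown letters are mapped to X.
residue_scores <- function(a_chars, b_chars, submat) {
  a_chars[!a_chars %in% rownames(submat)] <- "X"
  b_chars[!b_chars %in% rownames(submat)] <- "X"
  submat[a_chars, b_chars, drop = FALSE]
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' A gap of length L costs `gap_open + L * gap_extend`.  Traceback is
#' deterministic, preferring match over deletion over insertion on ties.
#'
#' @param a,b protein sequences (strings).
#' @param submat substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend gap penalties (positive numbers).
#' @return list with `a_aln`, `b_aln` (gapped strings) and `score`.
#' @export
pairwise_global <- function(a, b, submat = blosum62(), gap_open = 10,
                            gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence in pairwise alignment")
  ac <- seq_chars(toupper(a)); bc <- seq_chars(toupper(b))
  S <- residue_scores(ac, bc, submat)
  dp <- affine_dp(S, gap_open, gap_extend, "global")
  n <- length(ac); m <- length(bc)
  fin <- c(M = dp$M[n + 1, m + 1], X = dp$X[n + 1, m + 1], Y = dp$Y[n + 1, m + 1])
  state <- names(fin)[which.max(fin)]  # which.max keeps M > X > Y on ties
  path <- affine_traceback(dp, S, gap_open, gap_extend, n, m, state)
  list(
    a_aln = paste(ifelse(path[, 1] > 0, ac[pmax(path[, 1], 1)], "-"), collapse = ""),
    b_aln = paste(ifelse(path[, 2] > 0, bc[pmax(path[, 2], 1)], "-"), collapse = ""),
    score = unname(max(fin))
  )
}

# Column frequency profile of a character matrix of alignment rows
# (21 symbols + gap row; gaps kept separate and scored 0).
profile_freqs <- function(rows) {
  syms <- c(AA20, "X", "-")
  ftab <- apply(rows, 2, function(col) {
    col[!col %in% syms] <- "X"
    tabulate(factor(col, levels = syms), nbins = 22)
  })
  ftab / nrow(rows)
}

# Profile-profile global alignment; returns the merged row matrix.
merge_profiles <- function(rowsA, rowsB, submat, gap_open, gap_extend) {
  S22 <- rbind(cbind(submat, `-` = 0), `-` = 0)
  fA <- profile_freqs(rowsA); fB <- profile_freqs(rowsB)
  S <- t(fA) %*% S22 %*% fB
  dp <- affine_dp(S, gap_open, gap_extend, "global")
  n <- ncol(rowsA); m <- ncol(rowsB)
  fin <- c(M = dp$M[n + 1, m + 1], X = dp$X[n + 1, m + 1], Y = dp$Y[n + 1, m + 1])
  state <- names(fin)[which.max(fin)]
  path <- affine_traceback(dp, S, gap_open, gap_extend, n, m, state)
  outA <- matrix("-", nrow(rowsA), nrow(path), dimnames = list(rownames(rowsA)))
  outB <- matrix("-", nrow(rowsB), nrow(path), dimnames = list(rownames(rowsB)))
  selA <- path[, 1] > 0; selB <- path[, 2] > 0
  outA[, selA] <- rowsA[, path[selA, 1], drop = FALSE]
  outB[, selB] <- rowsB[, path[selB, 2], drop = FALSE]
  rbind(outA, outB)
}

# Kimura-corrected distance from a fraction of differing sites.
kimura_distance <- function(p, cap = 0.85) {
  p <- pmin(p, cap)
  -log(1 - p - p^2 / 5)
}

#' Progressive multiple alignment
#'
#' A documented simplified stand-in for consistency-based aligners such as
#' MAFFT L-INS-i: pairwise global alignments give Kimura-corrected
#' distances, a UPGMA guide tree orders profile-profile merges under the
#' same affine-gap scoring, and an optional leave-one-out refinement round
#' re-aligns each sequence against the profile of the rest, keeping the
#' result when the mean pairwise identity improves.  Input order is
#' canonicalised (rows sorted by id) before the guide tree is built, so
#' the result does not depend on input order.
#'
#' @param records a `lox_records` data.frame (or named character vector of
#'   sequences).
#' @param submat substitution matrix.
#' @param gap_open,gap_extend affine gap penalties.
#' @param refine logical; run one refinement round.
#' @return a `lox_msa` alignment whose rows de-gap to the input sequences.
#' @export
progressive_align <- function(records, submat = blosum62(), gap_open = 10,
                              gap_extend = 0.5, refine = FALSE) {
  if (is.data.frame(records)) {
    seqs <- setNames(records$sequence, records$id)
  } else {
    seqs <- records
  }
  if (length(seqs) < 2) stop("need at least 2 sequences to align")
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence id: ", names(seqs)[duplicated(names(seqs))][1])
  }
  seqs <- seqs[order(names(seqs))]
  n <- length(seqs)
  # pairwise distances
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      al <- pairwise_global(seqs[[i]], seqs[[j]], submat, gap_open, gap_extend)
      ac <- seq_chars(al$a_aln); bc <- seq_chars(al$b_aln)
      comp <- ac != "-" & bc != "-"
      p <- if (any(comp)) mean(ac[comp] != bc[comp]) else 1
      D[i, j] <- D[j, i] <- kimura_distance(p)
    }
  }
  guide <- phangorn::upgma(stats::as.dist(D))
  msa <- align_on_guide(guide, seqs, submat, gap_open, gap_extend)
  if (refine) msa <- refine_once(msa, submat, gap_open, gap_extend)
  msa
}

align_on_guide <- function(guide, seqs, submat, gap_open, gap_extend) {
  nt <- length(guide$tip.label)
  children <- split(guide$edge[, 2], guide$edge[, 1])
  build <- function(node) {
    if (node <= nt) {
      id <- guide$tip.label[node]
      m <- matrix(seq_chars(seqs[[id]]), 1)
      rownames(m) <- id
      return(m)
    }
    kids <- children[[as.character(node)]]
    sub <- lapply(kids, build)
    out <- sub[[1]]
    for (k in seq_along(sub)[-1]) {
      out <- merge_profiles(out, sub[[k]], submat, gap_open, gap_extend)
    }
    out
  }
  rows <- build(nt + 1L)
  new_msa(rownames(rows), apply(rows, 1, paste, collapse = ""))
}

refine_once <- function(msa, submat, gap_open, gap_extend) {
  best <- msa
  best_id <- alignment_stats(msa)$mean_identity
  for (id in msa$ids) {
    rest <- msa_matrix(best)[setdiff(best$ids, id), , drop = FALSE]
    keep <- colSums(rest != "-") > 0
    rest <- rest[, keep, drop = FALSE]
    one <- matrix(seq_chars(degap(best$seqs[[id]])), 1, dimnames = list(id))
    rows <- merge_profiles(rest, one, submat, gap_open, gap_extend)
    cand <- new_msa(rownames(rows), apply(rows, 1, paste, collapse = ""))
    cand_id <- alignment_stats(cand)$mean_identity
    if (cand_id > best_id + 1e-12) {
      ord <- order(match(cand$ids, best$ids))
      best <- new_msa(cand$ids[ord], cand$seqs[ord])
      best_id <- cand_id
    }
  }
  best
}

#' Basic alignment statistics
#'
#' @param msa a `lox_msa`.
#' @return list with `n_sequences`, `n_columns` and `mean_identity`
#'   (pairwise identity over columns where both rows have residues;
#'   gap-gap and residue-gap pairs are ignored).
#' @export
alignment_stats <- function(msa) {
  mat <- msa_matrix(msa)
  n <- nrow(mat)
  ids <- numeric(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        comp <- mat[i, ] != "-" & mat[j, ] != "-"
        if (any(comp)) ids <- c(ids, mean(mat[i, comp] == mat[j, comp]))
      }
    }
  }
  list(n_sequences = n, n_columns = msa$ncol,
       mean_identity = if (length(ids)) mean(ids) else NA_real_)
}
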