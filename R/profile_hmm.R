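# Profile hidden Markov models for protein domain retrieval: construction
# from seed alignments, local Viterbi/forward scanning in log2-odds space,
# empirical Gumbel E-values, and greedy multi-domain decomposition of
# proteomes.
#
# Architecture: Plan7-style local mode with uniform entry over match
# columns; every match column carries an explicit exit transition, so the
# model defines a proper probability distribution over single-domain paths
# (the brute-force enumeration oracle in the tests sums over exactly this
# path space).  Multi-domain proteins are handled by iterative masking in
# scan_proteome rather than by a begin/end loop.

#' Build a profile HMM from a seed alignment
#'
#' Columns with a gap fraction below 0.5 become match columns.  Sequences
#' are weighted by the Henikoff position-based scheme (weights normalised
#' to mean 1).  Match emissions are the column's weighted residue
#' frequencies mixed with the background: `e = (f_obs + pc * bg) / (1 +
#' pc)`, with `pc = pseudocount_weight` units of background mass per unit
#' of observed mass; transitions receive a uniform pseudocount of total
#' mass `pc` over their target states.  `X` residues are treated as
#' missing and contribute to neither emissions nor weights.
#'
#' @param seed a `lox_msa` seed alignment with at least 2 rows.
#' @param pseudocount_weight total pseudocount mass per distribution.
#' @param id profile identifier.
#' @return an object of class `lox_profile`.
#' @export
build_profile <- function(seed, pseudocount_weight = 1, id = "profile") {
  mat <- msa_matrix(seed)
  if (nrow(mat) < 2) stop("seed alignment needs at least 2 sequences")
  gapfrac <- colMeans(mat == "-")
  match_cols <- which(gapfrac < 0.5)
  L <- length(match_cols)
  if (L < 2) stop("no match columns in seed alignment (all columns too gappy)")
  nseq <- nrow(mat)
  bg <- setNames(rep(1 / 20, 20), AA20)

  # Henikoff position-based sequence weights over match columns
  w <- rep(0, nseq)
  for (j in match_cols) {
    col <- mat[, j]
    res <- col[col %in% AA20]
    if (!length(res)) next
    r <- length(unique(res))
    cnt <- table(res)
    contrib <- ifelse(col %in% AA20, 1 / (r * as.numeric(cnt[col])), 0)
    contrib[is.na(contrib)] <- 0
    w <- w + contrib
  }
  if (all(w == 0)) w <- rep(1, nseq)
  w <- w / mean(w[w > 0])
  w[w == 0] <- min(w[w > 0]) * 1e-3

  pc <- pseudocount_weight
  # match emissions: observed weighted frequencies mixed with the
  # background carrying `pc` units of pseudocount mass per unit of
  # observed mass, so divergent homologs are not over-penalised
  em <- matrix(0, L, 20, dimnames = list(NULL, AA20))
  for (k in seq_len(L)) {
    col <- mat[, match_cols[k]]
    for (a in AA20) em[k, a] <- sum(w[col == a])
    tot <- sum(em[k, ])
    f_obs <- if (tot > 0) em[k, ] / tot else bg
    em[k, ] <- (f_obs + pc * bg) / (1 + pc)
  }

  # transition counts from the seed paths
  cMM <- cMI <- cMD <- cME <- rep(0, L)
  cIM <- cII <- rep(0, L)
  cDM <- cDD <- rep(0, L)
  is_match <- seq_len(ncol(mat)) %in% match_cols
  colidx <- cumsum(is_match)  # match index per alignment column
  for (s in seq_len(nseq)) {
    row <- mat[s, ]
    state <- "B"; at <- 0L
    for (j in seq_len(ncol(mat))) {
      if (is_match[j]) {
        k <- colidx[j]
        new <- if (row[j] == "-") "D" else "M"
        if (state == "M") {
          if (new == "M") cMM[at] <- cMM[at] + w[s] else cMD[at] <- cMD[at] + w[s]
        } else if (state == "I") {
          if (new == "M") cIM[at] <- cIM[at] + w[s]
        } else if (state == "D") {
          if (new == "M") cDM[at] <- cDM[at] + w[s] else cDD[at] <- cDD[at] + w[s]
        }
        state <- new; at <- k
      } else if (row[j] %in% AA20) {
        if (state == "M") { cMI[at] <- cMI[at] + w[s]; state <- "I" }
        else if (state == "I") cII[at] <- cII[at] + w[s]
        # inserts after D are ignored (rare; not representable in Plan7)
      }
    }
    if (state == "M") cME[at] <- cME[at] + w[s]
  }

  p4 <- pc / 4; p2 <- pc / 2
  tMM <- tMI <- tMD <- tME <- rep(NA_real_, L)
  tIM <- tII <- rep(NA_real_, L)
  tDM <- tDD <- rep(NA_real_, L)
  for (k in seq_len(L - 1)) {
    tot <- cMM[k] + cMI[k] + cMD[k] + cME[k] + pc
    tMM[k] <- (cMM[k] + p4) / tot
    tMI[k] <- (cMI[k] + p4) / tot
    tMD[k] <- (cMD[k] + p4) / tot
    tME[k] <- (cME[k] + p4) / tot
    toti <- cIM[k] + cII[k] + pc
    tIM[k] <- (cIM[k] + p2) / toti
    tII[k] <- (cII[k] + p2) / toti
    totd <- cDM[k] + cDD[k] + pc
    tDM[k] <- (cDM[k] + p2) / totd
    tDD[k] <- (cDD[k] + p2) / totd
  }
  tME[L] <- 1
  cons <- apply(em, 1, function(e) AA20[which.max(e)])
  structure(list(id = id, L = L, match_cols = match_cols, em = em, bg = bg,
                 tMM = tMM, tMI = tMI, tMD = tMD, tME = tME,
                 tIM = tIM, tII = tII, tDM = tDM, tDD = tDD,
                 consensus = paste(cons, collapse = "")),
            class = "lox_profile")
}

#' @export
print.lox_profile <- function(x, ...) {
  cat("Profile HMM '", x$id, "': ", x$L, " match columns\n", sep = "")
  cat("Consensus:", x$consensus, "\n")
  invisible(x)
}

# log2-odds emission rows for a residue vector (X and unknowns -> 0).
profile_emission_odds <- function(profile, chars) {
  lo <- log2(profile$em) - log2(matrix(profile$bg, profile$L, 20, byrow = TRUE,
                                       dimnames = list(NULL, AA20)))
  idx <- match(chars, AA20)
  out <- matrix(0, length(chars), profile$L)
  known <- !is.na(idx)
  out[known, ] <- t(lo[, idx[known], drop = FALSE])
  out
}

# Shared DP for Viterbi (max) and forward (log-sum); log2-odds space.
# Iterates over match columns; within a column the insert-state recurrence
# (a running max / geometric-decay sum along the sequence) is vectorised
# with cummax / rescaled cumsum.
profile_dp <- function(profile, sequence, forward = FALSE) {
  chars <- seq_chars(toupper(sequence))
  n <- length(chars); L <- profile$L
  lem <- profile_emission_odds(profile, chars)
  l2 <- function(x) ifelse(is.na(x) | x <= 0, -Inf, log2(x))
  lMM <- l2(profile$tMM); lMI <- l2(profile$tMI); lMD <- l2(profile$tMD)
  lME <- l2(profile$tME); lIM <- l2(profile$tIM); lII <- l2(profile$tII)
  lDM <- l2(profile$tDM); lDD <- l2(profile$tDD)
  entry <- -log2(L)
  NEG <- -Inf
  lag <- function(v) c(NEG, v[-n])
  # elementwise log2-sum-exp of vectors whose running max may be -Inf
  lse <- function(...) {
    xs <- list(...)
    m <- do.call(pmax, xs)
    ok <- is.finite(m)
    s <- rep(0, length(m))
    for (x in xs) s[ok] <- s[ok] + 2^(x[ok] - m[ok])
    m[ok] <- m[ok] + log2(s[ok])
    m
  }
  VM <- matrix(NEG, n, L); VI <- matrix(NEG, n, L); VD <- matrix(NEG, n, L)
  iseq <- seq_len(n)
  for (j in seq_len(L)) {
    if (j == 1) {
      vm <- lem[, 1] + entry
      vd <- rep(NEG, n)
    } else {
      a <- rep(entry, n)
      b <- lag(VM[, j - 1]) + lMM[j - 1]
      cc <- lag(VI[, j - 1]) + lIM[j - 1]
      d <- lag(VD[, j - 1]) + lDM[j - 1]
      vm <- lem[, j] + if (forward) lse(a, b, cc, d) else pmax(a, b, cc, d)
      vd <- if (forward) lse(VM[, j - 1] + lMD[j - 1], VD[, j - 1] + lDD[j - 1])
            else pmax(VM[, j - 1] + lMD[j - 1], VD[, j - 1] + lDD[j - 1])
    }
    VM[, j] <- vm
    VD[, j] <- vd
    if (j < L) {
      # I_j runs along the sequence with self-loop decay c = log2 t(I->I):
      # VI[i] = lMI + (i-1-k) c + "sum/max over k<=i-1" VM[k]
      cdec <- lII[j]
      if (forward) {
        u <- vm - iseq * cdec
        Mx <- suppressWarnings(max(u[is.finite(u)]))
        if (!is.finite(Mx)) {
          VI[, j] <- NEG
        } else {
          cs <- cumsum(2^(u - Mx))
          v <- log2(c(0, cs[-n])) + Mx + lMI[j] + (iseq - 1) * cdec
          VI[, j] <- v
        }
      } else {
        cm <- cummax(vm - iseq * cdec)
        VI[, j] <- c(NEG, cm[-n]) + lMI[j] + (iseq - 1) * cdec
      }
    }
  }
  ends <- sweep(VM, 2, lME, "+")
  list(VM = VM, VI = VI, VD = VD, ends = ends, lem = lem, chars = chars,
       trans = list(lMM = lMM, lMI = lMI, lMD = lMD, lME = lME,
                    lIM = lIM, lII = lII, lDM = lDM, lDD = lDD),
       entry = entry)
}

#' Forward score of a protein under a profile HMM
#'
#' Total log2-odds of the sequence summed over all local single-domain
#' paths; always at least the Viterbi score.
#'
#' @param profile a `lox_profile`.
#' @param sequence protein string.
#' @return forward score in bits.
#' @export
forward_score <- function(profile, sequence) {
  dp <- profile_dp(profile, sequence, forward = TRUE)
  log2sumexp(as.vector(dp$ends))
}

#' Best local domain hit of a profile in a protein (Viterbi)
#'
#' Bit score is the log2 odds of the best state path against the
#' background null; hits are reported only above 0 bits.  Tie-break on
#' equal scores: smallest envelope end, then smallest exit column.
#'
#' @param profile a `lox_profile`.
#' @param sequence protein string.
#' @param protein_id id recorded in the hit.
#' @return a one-row data.frame (protein, profile, start, end, bits, and a
#'   list-column `map` of matched column/residue indices), or `NULL` when
#'   no path scores above 0 bits.
#' @export
viterbi_scan <- function(profile, sequence, protein_id = "query") {
  if (!nzchar(sequence)) stop("empty sequence")
  dp <- profile_dp(profile, sequence, forward = FALSE)
  score <- max(dp$ends)
  if (!is.finite(score) || score <= 0) return(NULL)
  hit <- which(dp$ends == score, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
  i <- hit[1]; j <- hit[2]
  # traceback
  eps <- 1e-9
  tr <- dp$trans
  path_i <- integer(0); path_j <- integer(0)
  state <- "M"
  end_i <- i
  repeat {
    if (state == "M") {
      path_i <- c(i, path_i); path_j <- c(j, path_j)
      v <- dp$VM[i, j] - dp$lem[i, j]
      if (abs(v - dp$entry) < eps) break
      if (i > 1 && j > 1) {
        if (abs(dp$VM[i - 1, j - 1] + tr$lMM[j - 1] - v) < eps) {
          i <- i - 1; j <- j - 1; state <- "M"; next
        }
        if (abs(dp$VI[i - 1, j - 1] + tr$lIM[j - 1] - v) < eps) {
          i <- i - 1; j <- j - 1; state <- "I"; next
        }
        if (abs(dp$VD[i - 1, j - 1] + tr$lDM[j - 1] - v) < eps) {
          i <- i - 1; j <- j - 1; state <- "D"; next
        }
      }
      break
    } else if (state == "I") {
      v <- dp$VI[i, j]
      if (i > 1 && abs(dp$VM[i - 1, j] + tr$lMI[j] - v) < eps) {
        i <- i - 1; state <- "M"
      } else {
        i <- i - 1; state <- "I"
      }
    } else {
      v <- dp$VD[i, j]
      if (abs(dp$VM[i, j - 1] + tr$lMD[j - 1] - v) < eps) {
        j <- j - 1; state <- "M"
      } else {
        j <- j - 1; state <- "D"
      }
    }
  }
  out <- data.frame(protein = protein_id, profile = profile$id,
                    start = path_i[1], end = end_i, bits = score,
                    stringsAsFactors = FALSE)
  out$map <- list(data.frame(column = path_j, position = path_i))
  out
}

.null_cache <- new.env(parent = emptyenv())

#' Empirical Gumbel E-value for a profile bit score
#'
#' Fits a Gumbel law by the method of moments to forward scores of a
#' seeded null sample (residue-shuffled copies of `sequence` when given,
#' otherwise i.i.d. background sequences of length `null_length`), then
#' reports `E = database_size * P(S > score)`.
#'
#' @param profile a `lox_profile`.
#' @param score_bits observed forward/Viterbi bit score.
#' @param database_size number of sequences searched (linear scaling of E).
#' @param null_sample_size number of null sequences (>= 100).
#' @param seed RNG seed for the null sample.
#' @param sequence optional sequence to shuffle for the null.
#' @param null_length length of i.i.d. null sequences when `sequence` is
#'   not given.
#' @return E-value (non-negative), monotone decreasing in `score_bits`.
#' @export
estimate_evalue <- function(profile, score_bits, database_size = 1,
                            null_sample_size = 200, seed = 1,
                            sequence = NULL, null_length = 200) {
  if (null_sample_size < 100) stop("null_sample_size must be >= 100")
  fit <- gumbel_null_fit(profile, null_sample_size, seed, sequence, null_length)
  database_size * gumbel_exceedance(score_bits, fit$mu, fit$beta)
}

gumbel_exceedance <- function(x, mu, beta) {
  # 1 - exp(-exp(-z)) computed stably for large z
  z <- (x - mu) / beta
  -expm1(-exp(-z))
}

gumbel_null_fit <- function(profile, null_sample_size, seed, sequence = NULL,
                            null_length = 200) {
  key <- paste(profile$id, profile$L, null_sample_size, seed,
               if (is.null(sequence)) null_length else substr(sequence, 1, 40),
               sep = "\r")
  if (!is.null(.null_cache[[key]])) return(.null_cache[[key]])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  scores <- vapply(seq_len(null_sample_size), function(r) {
    s <- if (is.null(sequence)) {
      paste(sample(AA20, null_length, replace = TRUE, prob = profile$bg),
            collapse = "")
    } else {
      paste(sample(seq_chars(sequence)), collapse = "")
    }
    forward_score(profile, s)
  }, 0)
  s <- sd(scores)
  if (!is.finite(s) || s < 1e-9) stop("degenerate null score distribution (zero variance)")
  beta <- s * sqrt(6) / pi
  mu <- mean(scores) - 0.5772156649015329 * beta
  fit <- list(mu = mu, beta = beta)
  .null_cache[[key]] <- fit
  fit
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Scan a proteome with a set of profiles
#'
#' Per protein and profile, domains are found by iterative Viterbi scanning
#' with envelope masking; across profiles, hits are combined by a greedy
#' non-overlapping decomposition (accept in decreasing bit score, reject
#' hits overlapping an accepted one by more than `overlap_tol` residues).
#' E-values come from a per-profile Gumbel calibration on i.i.d. background
#' sequences, scaled by the number of proteins searched.
#'
#' @param profiles list of `lox_profile` objects.
#' @param proteins a `lox_records` data.frame.
#' @param inclusion_evalue report hits with `E <= inclusion_evalue`.
#' @param seed seed for E-value calibration.
#' @param null_sample_size null sample size per profile.
#' @param overlap_tol residues of tolerated overlap between accepted hits.
#' @param max_hits_per_profile cap on masked re-scans per protein/profile.
#' @return data.frame of hits (protein, profile, start, end, bits, evalue),
#'   sorted by protein then start; 1-based inclusive coordinates.
#' @export
scan_proteome <- function(profiles, proteins, inclusion_evalue = 1e-5,
                          seed = 1, null_sample_size = 200, overlap_tol = 10,
                          max_hits_per_profile = 8) {
  if (inclusion_evalue <= 0) stop("inclusion_evalue must be > 0")
  if (is.null(names(profiles))) {
    names(profiles) <- vapply(profiles, `[[`, "", "id")
  }
  db <- nrow(proteins)
  null_len <- min(300L, max(60L, as.integer(stats::median(nchar(proteins$sequence)))))
  fits <- lapply(profiles, gumbel_null_fit, null_sample_size = null_sample_size,
                 seed = seed, null_length = null_len)
  res <- list()
  for (p in seq_len(nrow(proteins))) {
    cand <- list()
    for (pf in names(profiles)) {
      seqv <- proteins$sequence[p]
      for (rep in seq_len(max_hits_per_profile)) {
        hit <- viterbi_scan(profiles[[pf]], seqv, proteins$id[p])
        if (is.null(hit)) break
        ev <- db * gumbel_exceedance(hit$bits, fits[[pf]]$mu, fits[[pf]]$beta)
        if (ev > inclusion_evalue) break
        hit$evalue <- ev
        cand[[length(cand) + 1]] <- hit
        # mask the envelope and rescan for further copies
        chars <- seq_chars(seqv)
        chars[hit$start:hit$end] <- "X"
        seqv <- paste(chars, collapse = "")
      }
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand$bits, cand$start), , drop = FALSE]
    acc <- cand[0, , drop = FALSE]
    for (h in seq_len(nrow(cand))) {
      ov <- FALSE
      if (nrow(acc)) {
        o <- pmin(acc$end, cand$end[h]) - pmax(acc$start, cand$start[h]) + 1
        ov <- any(o > overlap_tol)
      }
      if (!ov) acc <- rbind(acc, cand[h, , drop = FALSE])
    }
    res[[length(res) + 1]] <- acc[order(acc$start), , drop = FALSE]
  }
  if (!length(res)) {
    return(data.frame(protein = character(0), profile = character(0),
                      start = integer(0), end = integer(0),
                      bits = numeric(0), evalue = numeric(0)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
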