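# Sequence-feature annotation: transmembrane helices, signal peptides,
# proline-rich regions, propeptides, and assembly of canonical domain
# architecture strings.  The detectors are documented heuristics standing
# in for the dedicated predictors commonly used in the field; every
# threshold is an argument with the defaults below.

# Kyte-Doolittle hydropathy scale (J Mol Biol 1982, 157:105).
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2, X = 0)

# Sliding-window mean hydropathy; returns one value per window start.
kd_window_means <- function(chars, window) {
  v <- unname(KD_SCALE[chars])
  v[is.na(v)] <- 0
  n <- length(v)
  if (n < window) return(numeric(0))
  cs <- c(0, cumsum(v))
  (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
}

#' Detect transmembrane helices by hydropathy
#'
#' Kyte-Doolittle means over 19-residue windows; windows with mean at or
#' above `threshold` are merged when they overlap, and a merged region is
#' kept if it spans at least `min_len` residues.  Score is the maximum
#' window mean inside the region.
#'
#' @param sequence protein string (length >= 19).
#' @param window window size.
#' @param threshold mean-hydropathy cutoff per window.
#' @param min_len minimum merged-region length.
#' @return data.frame (kind, start, end, score), 1-based inclusive.
#' @export
detect_tm_helices <- function(sequence, window = 19L, threshold = 1.6,
                              min_len = 15L) {
  chars <- seq_chars(toupper(sequence))
  means <- kd_window_means(chars, window)
  out <- data.frame(kind = character(0), start = integer(0), end = integer(0),
                    score = numeric(0), stringsAsFactors = FALSE)
  flagged <- which(means >= threshold)
  if (!length(flagged)) return(out)
  runs <- split(flagged, cumsum(c(1, diff(flagged) > 1)))
  for (r in runs) {
    start <- min(r); end <- max(r) + window - 1L
    if (end - start + 1L >= min_len) {
      out <- rbind(out, data.frame(kind = "tm_region", start = start,
                                   end = end, score = max(means[r]),
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Detect an N-terminal signal peptide
#'
#' Reports a signal peptide iff (a) some 8-residue window with mean
#' Kyte-Doolittle hydropathy >= `h_threshold` starts within residues 1-12
#' (the hydrophobic h-region), and (b) an A-x-A-type cleavage motif
#' (`[AGSV] x [AGS]`) has its last residue within positions 15-35.  The
#' region ends at the first such motif position.
#'
#' @param sequence protein string (length >= 25).
#' @param h_threshold hydrophobic window mean cutoff.
#' @param h_window hydrophobic window length.
#' @param h_start_max latest allowed window start.
#' @param cleave_min,cleave_max allowed positions of the motif's last
#'   residue.
#' @return one-row data.frame (kind, start, end, score) or `NULL`.
#' @export
detect_signal_peptide <- function(sequence, h_threshold = 2.0, h_window = 8L,
                                  h_start_max = 12L, cleave_min = 15L,
                                  cleave_max = 35L) {
  chars <- seq_chars(toupper(sequence))
  if (length(chars) < 25) return(NULL)
  means <- kd_window_means(chars, h_window)
  k <- min(h_start_max, length(means))
  if (k < 1 || max(means[seq_len(k)]) < h_threshold) return(NULL)
  upto <- min(cleave_max, length(chars))
  for (e in seq(cleave_min, upto)) {
    if (e < 3) next
    if (chars[e - 2] %in% c("A", "G", "S", "V") &&
        chars[e] %in% c("A", "G", "S")) {
      return(data.frame(kind = "signal_peptide", start = 1L, end = as.integer(e),
                        score = max(means[seq_len(k)]), stringsAsFactors = FALSE))
    }
  }
  NULL
}

#' Detect proline-rich regions
#'
#' Sliding windows of `window` residues with a proline fraction at or
#' above `min_fraction` are flagged and merged; merged regions fully
#' inside an excluded region (signal peptide, accepted domain hits) are
#' dropped.
#'
#' @param sequence protein string.
#' @param excluded optional data.frame with `start`/`end` columns.
#' @param window window length.
#' @param min_fraction proline fraction cutoff.
#' @return data.frame (kind, start, end, score = max window fraction).
#' @export
detect_proline_rich <- function(sequence, excluded = NULL, window = 25L,
                                min_fraction = 0.25) {
  chars <- seq_chars(toupper(sequence))
  n <- length(chars)
  out <- data.frame(kind = character(0), start = integer(0), end = integer(0),
                    score = numeric(0), stringsAsFactors = FALSE)
  if (n < window) return(out)
  isP <- as.numeric(chars == "P")
  cs <- c(0, cumsum(isP))
  frac <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  flagged <- which(frac >= min_fraction)
  if (!length(flagged)) return(out)
  runs <- split(flagged, cumsum(c(1, diff(flagged) > 1)))
  for (r in runs) {
    start <- min(r); end <- max(r) + window - 1L
    drop <- FALSE
    if (!is.null(excluded) && nrow(excluded)) {
      drop <- any(start >= excluded$start & end <= excluded$end)
    }
    if (!drop) {
      out <- rbind(out, data.frame(kind = "proline_rich", start = start,
                                   end = end, score = max(frac[r]),
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

# Trim detected regions so they do not overlap occupied intervals
# (signal peptide, accepted domain hits); a region is reduced to its
# largest unoccupied sub-interval and dropped if nothing remains.
clip_regions <- function(regions, occupied, min_len = 10L) {
  if (is.null(occupied) || !nrow(occupied)) return(regions)
  keep <- list()
  for (r in seq_len(nrow(regions))) {
    s <- regions$start[r]; e <- regions$end[r]
    free <- rep(TRUE, e - s + 1L)
    for (o in seq_len(nrow(occupied))) {
      a <- max(s, occupied$start[o]); b <- min(e, occupied$end[o])
      if (a <= b) free[(a - s + 1L):(b - s + 1L)] <- FALSE
    }
    if (!any(free)) next
    runs <- rle(free)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    best <- which(runs$values)[which.max(runs$lengths[runs$values])]
    if (runs$lengths[best] < min_len) next
    out <- regions[r, , drop = FALSE]
    out$start <- s + starts[best] - 1L
    out$end <- s + ends[best] - 1L
    keep[[length(keep) + 1]] <- out
  }
  if (!length(keep)) regions[0, , drop = FALSE] else do.call(rbind, keep)
}

# canonical token for a feature/domain kind
arch_token <- function(kind) {
  switch(kind,
         signal_peptide = "SP", tm_region = "TM", proline_rich = "PRORICH",
         propeptide = "PROPEP", toupper(kind))
}

#' Assemble the canonical domain architecture of a protein
#'
#' Orders accepted domain hits and detected features N to C, labels
#' unannotated stretches of at least `propep_min` residues that precede a
#' domain (and are not proline-rich) as propeptide, and builds the
#' canonical string with run-length collapsing of identical adjacent
#' tokens (`SP+4xSRCR+LOX`).  Transmembrane regions may overlap a domain;
#' an overlapped TM is placed after the token it overlaps.
#'
#' @param protein_id id recorded in the result.
#' @param sequence protein string.
#' @param hits data.frame of non-overlapping domain hits for this protein
#'   (columns profile, start, end).
#' @param features data.frame of feature regions (kind, start, end).
#' @param propep_min minimum propeptide length in residues.
#' @param pro_fraction proline fraction above which a stretch counts as
#'   proline-rich rather than propeptide.
#' @return list with `protein`, `tokens` (N-to-C) and `architecture`
#'   (canonical string).
#' @export
assemble_architecture <- function(protein_id, sequence, hits = NULL,
                                  features = NULL, propep_min = 50L,
                                  pro_fraction = 0.25) {
  items <- data.frame(token = character(0), start = integer(0),
                      end = integer(0), tm = logical(0))
  if (!is.null(hits) && nrow(hits)) {
    items <- rbind(items, data.frame(token = toupper(hits$profile),
                                     start = hits$start, end = hits$end,
                                     tm = FALSE))
  }
  if (!is.null(features) && nrow(features)) {
    items <- rbind(items, data.frame(token = vapply(features$kind, arch_token, ""),
                                     start = features$start, end = features$end,
                                     tm = features$kind == "tm_region"))
  }
  if (nrow(items) == 0) {
    return(list(protein = protein_id, tokens = character(0), architecture = ""))
  }
  main <- items[!items$tm, , drop = FALSE]
  main <- main[order(main$start, main$end), , drop = FALSE]
  if (nrow(main) > 1) {
    ov <- main$start[-1] - main$end[-nrow(main)] - 1L
    if (any(ov < -10L)) {
      bad <- which(ov < -10L)[1]
      stop("overlapping regions in architecture assembly: ",
           main$token[bad], " / ", main$token[bad + 1])
    }
  }
  # label long unannotated stretches before a domain as propeptide
  chars <- seq_chars(toupper(sequence))
  gaps <- data.frame(token = character(0), start = integer(0), end = integer(0),
                     tm = logical(0))
  bounds <- c(0L, main$end)
  nexts <- c(main$start, length(chars) + 1L)
  for (g in seq_along(bounds)) {
    gs <- bounds[g] + 1L; ge <- nexts[g] - 1L
    if (g > length(main$start)) break
    if (ge - gs + 1L >= propep_min) {
      pf <- mean(chars[gs:ge] == "P")
      if (pf < pro_fraction) {
        gaps <- rbind(gaps, data.frame(token = "PROPEP", start = gs, end = ge,
                                       tm = FALSE))
      }
    }
  }
  main <- rbind(main, gaps)
  # place overlapped TM regions after the token they overlap
  tms <- items[items$tm, , drop = FALSE]
  if (nrow(tms)) {
    tms$start <- vapply(seq_len(nrow(tms)), function(t) {
      ov <- main$start <= tms$end[t] & main$end >= tms$start[t]
      if (any(ov)) as.integer(max(main$end[ov])) else as.integer(tms$start[t])
    }, 0L)
    main <- rbind(main, tms)
  }
  main <- main[order(main$start, main$end), , drop = FALSE]
  tokens <- main$token
  # run-length collapse
  r <- rle(tokens)
  canon <- paste(ifelse(r$lengths > 1, paste0(r$lengths, "x", r$values),
                        r$values), collapse = "+")
  list(protein = protein_id, tokens = tokens, architecture = canon)
}

#' Annotate a set of proteins and build their architectures
#'
#' Runs the three feature detectors on every protein, combines them with
#' the accepted domain hits of [scan_proteome()], and assembles canonical
#' architecture strings.
#'
#' @param proteins a `lox_records` data.frame.
#' @param hits hit table from [scan_proteome()].
#' @param ... passed to [assemble_architecture()].
#' @return list with `features` (data.frame protein, kind, start, end,
#'   score) and `architectures` (data.frame protein, architecture).
#' @export
annotate_proteins <- function(proteins, hits, ...) {
  feats <- list(); archs <- list()
  for (i in seq_len(nrow(proteins))) {
    id <- proteins$id[i]; s <- proteins$sequence[i]
    h <- hits[hits$protein == id, , drop = FALSE]
    f <- list()
    sp <- if (nchar(s) >= 25) detect_signal_peptide(s) else NULL
    if (!is.null(sp)) f[[length(f) + 1]] <- sp
    excl <- rbind(
      if (!is.null(sp)) sp[, c("start", "end")],
      if (nrow(h)) h[, c("start", "end")]
    )
    pr <- detect_proline_rich(s, excluded = excl)
    if (nrow(pr)) pr <- clip_regions(pr, excl)
    if (nrow(pr)) f[[length(f) + 1]] <- pr
    covered <- rbind(excl, if (nrow(pr)) pr[, c("start", "end")])
    tm <- if (nchar(s) >= 19) detect_tm_helices(s) else NULL
    if (!is.null(tm) && nrow(tm)) {
      # keep TMs not inside the signal peptide or a proline-rich region
      keep <- vapply(seq_len(nrow(tm)), function(k) {
        inside_sp <- !is.null(sp) && tm$start[k] <= sp$end
        !inside_sp
      }, TRUE)
      if (any(keep)) f[[length(f) + 1]] <- tm[keep, , drop = FALSE]
    }
    feat <- if (length(f)) do.call(rbind, f) else
      data.frame(kind = character(0), start = integer(0), end = integer(0),
                 score = numeric(0))
    a <- assemble_architecture(id, s, hits = h, features = feat, ...)
    if (nrow(feat)) feat <- cbind(protein = id, feat)
    feats[[i]] <- feat
    archs[[i]] <- data.frame(protein = id, architecture = a$architecture,
                             stringsAsFactors = FALSE)
  }
  list(features = do.call(rbind, feats[lengths(feats) > 0]),
       architectures = do.call(rbind, archs))
}
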