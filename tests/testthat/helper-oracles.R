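# Independent oracles used by the tests: brute-force path enumeration for
# the profile HMM, matrix exponentials by scaling-and-squaring for the
# substitution process, exhaustive state summation for tree likelihoods,
# a plain quadratic Smith-Waterman, and exhaustive Dollo loss sets.
# These deliberately re-derive every quantity from first principles and
# share no DP code with the implementation.

# ---- profile HMM path enumeration -------------------------------------

# Sum (forward) and max (Viterbi) of path odds over all local
# single-domain paths of a profile on a sequence.  Only usable for tiny
# profiles/sequences.
oracle_profile_paths <- function(profile, sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars); L <- profile$L
  bg <- profile$bg
  oddsM <- function(j, a) {
    if (!a %in% colnames(profile$em)) return(1)  # X / unknown
    profile$em[j, a] / bg[[a]]
  }
  total <- 0
  best <- 0
  rec <- function(state, i, j, w) {
    if (state == "M") {
      done <- w * profile$tME[j]
      total <<- total + done
      best <<- max(best, done)
      if (j < L) {
        if (i < n) rec("M", i + 1, j + 1, w * profile$tMM[j] * oddsM(j + 1, chars[i + 1]))
        if (i < n) rec("I", i + 1, j, w * profile$tMI[j])
        rec("D", i, j + 1, w * profile$tMD[j])
      }
    } else if (state == "I") {
      if (i < n) {
        rec("M", i + 1, j + 1, w * profile$tIM[j] * oddsM(j + 1, chars[i + 1]))
        rec("I", i + 1, j, w * profile$tII[j])
      }
    } else {
      if (j < L) {
        if (i < n) rec("M", i + 1, j + 1, w * profile$tDM[j] * oddsM(j + 1, chars[i + 1]))
        rec("D", i, j + 1, w * profile$tDD[j])
      }
    }
  }
  for (i0 in seq_len(n)) {
    for (j0 in seq_len(L)) {
      rec("M", i0, j0, (1 / L) * oddsM(j0, chars[i0]))
    }
  }
  list(forward_bits = unname(log2(total)), viterbi_bits = unname(log2(best)))
}

# ---- matrix exponential (scaling and squaring, independent of eigen) --

oracle_expm <- function(A) {
  k <- max(0, ceiling(log2(max(1, max(abs(A))))) + 4)
  B <- A / 2^k
  S <- diag(nrow(A))
  term <- diag(nrow(A))
  for (m in 1:18) {
    term <- term %*% B / m
    S <- S + term
  }
  for (i in seq_len(k)) S <- S %*% S
  S
}

# Transition probabilities from a lox_model by series expansion.
oracle_prob_matrix <- function(model, t, rate = 1) {
  oracle_expm(model$Q * t * rate)
}

# ---- exhaustive tree likelihood ---------------------------------------

# Likelihood of one site by explicit summation over all internal-node
# state assignments.  states: named residue (or NA) per tip.
oracle_site_lik <- function(tree, states, model, rate = 1) {
  nt <- length(tree$tip.label)
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
  internals <- sort(unique(tree$edge[, 1]))
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e) {
    oracle_prob_matrix(model, tree$edge.length[e], rate)
  })
  aa <- rownames(model$Q)
  tipstate <- match(states[tree$tip.label], aa)
  combos <- as.matrix(expand.grid(rep(list(seq_along(aa)), length(internals))))
  total <- 0
  for (r in seq_len(nrow(combos))) {
    assign_state <- combos[r, ]
    names(assign_state) <- internals
    state_of <- function(node) {
      if (node <= nt) tipstate[node] else assign_state[[as.character(node)]]
    }
    p <- model$freq[[state_of(root)]]
    ok <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      s1 <- state_of(tree$edge[e, 1]); s2 <- state_of(tree$edge[e, 2])
      if (is.na(s2)) next  # missing tip: sums to 1
      p <- p * Ps[[e]][s1, s2]
    }
    total <- total + p
  }
  total
}

# ---- quadratic Smith-Waterman oracle ----------------------------------

oracle_sw_score <- function(a, b, submat, gap_open, gap_extend) {
  ac <- strsplit(toupper(a), "")[[1]]; bc <- strsplit(toupper(b), "")[[1]]
  n <- length(ac); m <- length(bc)
  M <- matrix(-Inf, n + 1, m + 1); X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  sc <- function(x, y) {
    if (!x %in% rownames(submat)) x <- "X"
    if (!y %in% rownames(submat)) y <- "X"
    submat[x, y]
  }
  for (i in 1:n) {
    for (j in 1:m) {
      diag <- max(0, M[i, j], X[i, j], Y[i, j])
      M[i + 1, j + 1] <- sc(ac[i], bc[j]) + diag
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             Y[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             X[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# ---- exhaustive Dollo loss sets ---------------------------------------

# Minimal number of loss branches for a character, given the gain node,
# by brute force over subsets of edges inside the gain clade.
oracle_dollo_min_losses <- function(tree, states, gain_label) {
  nt <- length(tree$tip.label)
  gain <- if (gain_label %in% tree$tip.label) match(gain_label, tree$tip.label)
          else nt + match(gain_label, tree$node.label)
  below <- function(node) {
    if (node <= nt) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, below))
  }
  clade_tips <- below(gain)
  inside_edges <- which(vapply(seq_len(nrow(tree$edge)), function(e) {
    all(below(tree$edge[e, 2]) %in% clade_tips)
  }, TRUE))
  st <- states[tree$tip.label]
  known1 <- which(st == "1"); known0 <- which(st == "0")
  check <- function(loss_edges) {
    lost <- unique(unlist(lapply(loss_edges, function(e) below(tree$edge[e, 2]))))
    present <- setdiff(clade_tips, lost)
    all(known1 %in% present) && !any(known0 %in% present)
  }
  for (k in 0:length(inside_edges)) {
    combos <- if (k == 0) list(integer(0)) else
      utils::combn(inside_edges, k, simplify = FALSE)
    for (cmb in combos) if (check(cmb)) return(k)
  }
  Inf
}

# ---- small simulation helper ------------------------------------------

# Evolve i.i.d. root sequences down a tree (uniform rates), returning a
# lox_msa; used by recovery and bootstrap tests.
sim_alignment <- function(tree, len, model, seed, gamma_cats = NULL) {
  set.seed(seed)
  aa <- rownames(model$Q)
  root_chars <- sample(aa, len, TRUE, prob = model$freq)
  rates <- if (is.null(gamma_cats)) rep(1, len) else
    sample(gamma_cats, len, replace = TRUE)
  res <- list()
  nt <- length(tree$tip.label)
  rec <- function(node, chars) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (!length(kids)) {
      res[[tree$tip.label[node]]] <<- paste(chars, collapse = "")
      return()
    }
    for (k in kids) {
      e <- which(tree$edge[, 2] == k)
      rec(k, loxevo:::evolve_chars(chars, tree$edge.length[e], model, rates,
                                   rep(FALSE, len)))
    }
  }
  rec(setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1], root_chars)
  new_msa(names(res), unlist(res))
}
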