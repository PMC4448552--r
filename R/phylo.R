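# Maximum-likelihood phylogenetics: Felsenstein pruning with discrete
# gamma and invariant sites, neighbor joining, per-branch length
# optimisation, NNI hill climbing, AIC model selection and nonparametric
# bootstrap.

# Compress an alignment into unique site patterns.
# Returns list(states: tips x patterns integer matrix (NA = missing),
#              weights, ids)
msa_patterns <- function(msa) {
  mat <- msa_matrix(msa)
  idx <- matrix(match(mat, AA20), nrow(mat), ncol(mat))  # NA for gap/X
  key <- apply(idx, 2, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[first])))
  list(states = idx[, first, drop = FALSE], weights = w, ids = msa$ids)
}

# Pruning partial likelihoods for one rate category.
# Returns site log-likelihood vector over patterns.
pruning_site_loglik <- function(tree, pat, model, rate) {
  nt <- length(tree$tip.label)
  S <- ncol(pat$states)
  tipmap <- match(tree$tip.label, pat$ids)
  if (anyNA(tipmap)) {
    stop("tree tips not in alignment: ",
         paste(tree$tip.label[is.na(tipmap)], collapse = ", "))
  }
  attr(tree, "order") <- NULL  # never trust a precomputed order label
  post <- ape::reorder.phylo(tree, "postorder")
  Ps <- lapply(seq_len(nrow(post$edge)), function(e) {
    prob_matrix(model, post$edge.length[e], rate)
  })
  get_tip_partial <- function(tip) {
    st <- pat$states[tipmap[tip], ]
    m <- matrix(0, 20, S)
    known <- !is.na(st)
    m[cbind(st[known], which(known))] <- 1
    m[, !known] <- 1
    m
  }
  acc <- vector("list", nt + tree$Nnode)
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1]; chd <- post$edge[e, 2]
    child_part <- if (chd <= nt) get_tip_partial(chd) else acc[[chd]]
    up <- Ps[[e]] %*% child_part
    acc[[par]] <- if (is.null(acc[[par]])) up else acc[[par]] * up
  }
  root <- tree_root(tree)
  lik <- colSums(model$freq * acc[[root]])
  log(lik)
}

#' Log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning over site patterns, with the model's discrete-gamma
#' categories and invariant-site class mixed per site.  Gaps and `X` are
#' missing data (unit partial likelihoods).
#'
#' @param tree [ape::phylo]; tip labels must match alignment rows.
#' @param msa a `lox_msa`.
#' @param model a `lox_model` (empirical frequencies are filled in from
#'   the alignment when the model is +F).
#' @return total log-likelihood (natural log).
#' @export
tree_loglik <- function(tree, msa, model) {
  model <- model_with_empirical_freq(model, msa)
  pat <- msa_patterns(msa)
  tree_loglik_pat(tree, pat, model)
}

tree_loglik_pat <- function(tree, pat, model) {
  mix <- model_site_rates(model)
  S <- ncol(pat$states)
  sitelik <- matrix(0, length(mix$rates), S)
  for (c in seq_along(mix$rates)) {
    r <- mix$rates[c]
    if (r == 0) {
      # invariant class: nonzero only for patterns compatible with a
      # single residue at every non-missing tip
      lik <- numeric(S)
      for (s in seq_len(S)) {
        st <- unique(pat$states[, s])
        st <- st[!is.na(st)]
        lik[s] <- if (length(st) == 0) 1 else if (length(st) == 1) model$freq[st] else 0
      }
      sitelik[c, ] <- lik
    } else {
      sitelik[c, ] <- exp(pruning_site_loglik(tree, pat, model, r))
    }
  }
  persite <- as.vector(mix$weights %*% sitelik)
  sum(pat$weights * log(persite))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining ([ape::nj()]) with negative branch-length
#' estimates clamped to zero.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @return unrooted [ape::phylo].
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix is not symmetric")
  if (any(!is.finite(D))) stop("non-finite distances")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (nrow(D) == 2) {
    tree <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);", rownames(D)[1],
                                          D[1, 2] / 2, rownames(D)[2], D[1, 2] / 2))
    return(tree)
  }
  tree <- ape::nj(stats::as.dist(D))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Pairwise distances from an alignment
#'
#' Proportion of differing sites over columns where both rows have
#' residues, Kimura-corrected (`d = -ln(1 - p - p^2/5)`, `p` capped at
#' 0.85); pairs with no comparable columns get the cap distance.
#'
#' @param msa a `lox_msa`.
#' @return symmetric distance matrix.
#' @export
msa_distances <- function(msa) {
  mat <- msa_matrix(msa)
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      comp <- mat[i, ] %in% AA20 & mat[j, ] %in% AA20
      p <- if (any(comp)) mean(mat[i, comp] != mat[j, comp]) else 0.85
      D[i, j] <- D[j, i] <- kimura_distance(p)
    }
  }
  D
}

#' Optimise branch lengths by cyclic univariate search
#'
#' Each branch length is optimised by bracketed scalar search (tolerance
#' 1e-6) holding the others fixed; passes repeat until the log-likelihood
#' improves by less than `tol_lnl`.  The log-likelihood never decreases.
#'
#' @param tree [ape::phylo].
#' @param msa a `lox_msa`.
#' @param model a `lox_model`.
#' @param max_passes maximum optimisation sweeps.
#' @param tol_lnl convergence tolerance on the log-likelihood.
#' @param max_branch upper bracket for a single branch length.
#' @return list with `tree` (optimised lengths) and `loglik`.
#' @export
optimize_branch_lengths <- function(tree, msa, model, max_passes = 5,
                                    tol_lnl = 1e-4, max_branch = 10) {
  model <- model_with_empirical_freq(model, msa)
  pat <- msa_patterns(msa)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.1, nrow(tree$edge))
  cur <- tree_loglik_pat(tree, pat, model)
  for (pass in seq_len(max_passes)) {
    before <- cur
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(x) {
        tree$edge.length[e] <- x
        tree_loglik_pat(tree, pat, model)
      }
      opt <- optimize(f, c(0, max_branch), maximum = TRUE, tol = 1e-6)
      if (opt$objective > cur) {
        tree$edge.length[e] <- opt$maximum
        cur <- opt$objective
      }
    }
    if (cur - before < tol_lnl) break
  }
  list(tree = tree, loglik = cur)
}

#' NNI hill-climbing tree search
#'
#' Starting from a given tree (default: neighbor joining on Kimura
#' distances), evaluates all nearest-neighbour-interchange alternatives
#' with branch re-optimisation and accepts the best strict improvement
#' until a local optimum; optional random multi-start keeps the
#' highest-likelihood result.
#'
#' @param msa a `lox_msa`.
#' @param model a `lox_model`.
#' @param start optional starting tree.
#' @param starts number of starts (start 1 = NJ, others random topologies).
#' @param seed seed for random starts.
#' @param max_rounds NNI acceptance rounds per start.
#' @return list with `tree`, `loglik`.
#' @export
nni_search <- function(msa, model, start = NULL, starts = 1, seed = 1,
                       max_rounds = 20) {
  model <- model_with_empirical_freq(model, msa)
  if (length(msa$ids) < 4) {
    t0 <- nj_tree(msa_distances(msa))
    o <- optimize_branch_lengths(t0, msa, model)
    return(o)
  }
  best <- NULL
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (s in seq_len(starts)) {
    t0 <- if (s == 1) (start %||% nj_tree(msa_distances(msa))) else
      ape::rtree(length(msa$ids), tip.label = sample(msa$ids))
    t0 <- ape::unroot(t0)
    o <- optimize_branch_lengths(t0, msa, model, max_passes = 2)
    for (round in seq_len(max_rounds)) {
      nbr <- phangorn::nni(o$tree)
      cand <- NULL
      for (k in seq_along(nbr)) {
        nb <- nbr[[k]]  # [[ restores shared tip labels of the multiPhylo
        nb$edge.length <- rep(0.1, nrow(nb$edge))
        on <- optimize_branch_lengths(nb, msa, model, max_passes = 2)
        if (on$loglik > o$loglik + 1e-6 &&
            (is.null(cand) || on$loglik > cand$loglik)) cand <- on
      }
      if (is.null(cand)) break
      o <- cand
    }
    if (is.null(best) || o$loglik > best$loglik) best <- o
  }
  best
}

#' Model selection by AIC on a fixed topology
#'
#' Fits every candidate model on the given topology (default: NJ on
#' Kimura distances), optimising branch lengths, the gamma shape and the
#' invariant proportion by coordinate search, and ranks by AIC.
#' Parameter count = branches + alpha (if gamma) + p_inv (if +I) + 19
#' (if +F).
#'
#' @param msa a `lox_msa`.
#' @param candidates list of `lox_model` objects; default grid is
#'   \{WAG, LG, JTT\} x \{+G, none\} x \{+I, none\} x \{+F, model\}.
#' @param topology optional fixed tree.
#' @return data.frame (model, loglik, k, AIC, dAIC) sorted by AIC, with
#'   the fitted models in attribute `fits`.
#' @export
select_model <- function(msa, candidates = NULL, topology = NULL) {
  if (is.null(candidates)) {
    candidates <- list()
    for (mx in c("WAG", "LG", "JTT")) {
      for (g in c(TRUE, FALSE)) for (i in c(TRUE, FALSE)) for (f in c(TRUE, FALSE)) {
        candidates[[length(candidates) + 1]] <-
          subst_model(mx, gamma_shape = if (g) 1 else NULL,
                      p_inv = if (i) 0.1 else NULL,
                      freq = if (f) "empirical" else "model")
      }
    }
  }
  if (!length(candidates)) stop("no candidate models")
  topo <- topology %||% nj_tree(msa_distances(msa))
  rows <- list(); fits <- list()
  for (m in candidates) {
    fit <- fit_model_on_topology(topo, msa, m)
    k <- nrow(topo$edge) +
      (!is.null(m$gamma_shape)) + (!is.null(m$p_inv)) + if (m$plus_f) 19 else 0
    rows[[length(rows) + 1]] <- data.frame(
      model = m$name, loglik = fit$loglik, k = k,
      AIC = -2 * fit$loglik + 2 * k, stringsAsFactors = FALSE)
    fits[[m$name]] <- fit
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$AIC), ]
  out$dAIC <- out$AIC - out$AIC[1]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

# Optimise branch lengths and rate parameters of one model on a topology.
fit_model_on_topology <- function(tree, msa, model, cycles = 2) {
  model <- model_with_empirical_freq(model, msa)
  pat <- msa_patterns(msa)
  o <- optimize_branch_lengths(tree, msa, model, max_passes = 2)
  for (cy in seq_len(cycles)) {
    if (!is.null(model$gamma_shape)) {
      f <- function(a) {
        m2 <- model; m2$gamma_shape <- a
        tree_loglik_pat(o$tree, pat, m2)
      }
      opt <- optimize(f, c(0.05, 50), maximum = TRUE, tol = 1e-3)
      if (opt$objective > o$loglik) {
        model$gamma_shape <- opt$maximum
        o$loglik <- opt$objective
      }
    }
    if (!is.null(model$p_inv)) {
      f <- function(p) {
        m2 <- model; m2$p_inv <- p
        tree_loglik_pat(o$tree, pat, m2)
      }
      opt <- optimize(f, c(0, 0.8), maximum = TRUE, tol = 1e-3)
      if (opt$objective > o$loglik) {
        model$p_inv <- opt$maximum
        o$loglik <- opt$objective
      }
    }
    o <- optimize_branch_lengths(o$tree, msa, model, max_passes = 2)
  }
  list(tree = o$tree, loglik = o$loglik, model = model)
}

#' Nonparametric bootstrap support
#'
#' Resamples alignment columns with replacement (seeded); each replicate
#' is analysed by neighbor joining on Kimura distances (optionally
#' followed by NNI search).  Support of a bipartition of the best tree is
#' the percentage of replicate trees containing it.
#'
#' @param msa a `lox_msa`.
#' @param best_tree tree to annotate.
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @param nni logical: run NNI search per replicate (slower).
#' @param model model for NNI search.
#' @return list with `tree` (node labels = integer supports), `supports`
#'   (named by split key) and `sample` (the replicate trees, `multiPhylo`).
#' @export
bootstrap_support <- function(msa, best_tree, n_replicates = 100, seed = 1,
                              nni = FALSE, model = NULL) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mat <- msa_matrix(msa)
  trees <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    rep_msa <- new_msa(msa$ids, apply(mat[, cols, drop = FALSE], 1, paste, collapse = ""))
    tr <- nj_tree(msa_distances(rep_msa))
    if (nni) tr <- nni_search(rep_msa, model, start = tr)$tree
    trees[[r]] <- tr
  }
  class(trees) <- "multiPhylo"
  freqs <- bipartition_frequencies(trees)
  sup <- round(100 * freqs)
  out <- best_tree
  nt <- length(out$tip.label)
  labs <- rep("", out$Nnode)
  for (n in seq_len(out$Nnode)) {
    key <- split_key_for_node(out, nt + n)
    if (!is.null(key) && !is.na(sup[key])) labs[n] <- as.character(sup[key])
  }
  out$node.label <- labs
  list(tree = out, supports = sup, sample = trees)
}
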