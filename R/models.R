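# Amino-acid substitution models: published exchangeability matrices,
# rate-matrix construction, transition probabilities and the discrete-gamma
# approximation to among-site rate variation.

.model_cache <- new.env(parent = emptyenv())

# Read a bundled exchangeability/frequency table (WAG, LG, JTT).
load_model_table <- function(name) {
  key <- toupper(name)
  if (!is.null(.model_cache[[key]])) return(.model_cache[[key]])
  if (key == "POISSON") {
    R <- matrix(1, 20, 20, dimnames = list(AA20, AA20))
    diag(R) <- 0
    out <- list(R = R, freq = setNames(rep(1 / 20, 20), AA20))
  } else {
    f <- system.file("extdata", "models", paste0(tolower(name), ".tsv"),
                     package = "loxevo")
    if (!nzchar(f)) stop("unknown substitution matrix: ", name)
    lines <- readLines(f)
    body <- lines[!startsWith(lines, "#")]
    split_at <- which(startsWith(lines, "# frequencies"))
    mat_lines <- lines[seq_len(split_at - 1)]
    mat_lines <- mat_lines[!startsWith(mat_lines, "#")]
    R <- as.matrix(read.table(text = mat_lines, header = TRUE, row.names = 1,
                              check.names = FALSE))
    fr_lines <- lines[(split_at + 1):length(lines)]
    fr <- read.table(text = fr_lines, header = TRUE, row.names = 1,
                     check.names = FALSE)
    freq <- setNames(as.numeric(fr[1, ]), colnames(fr))
    out <- list(R = R[AA20, AA20], freq = freq[AA20] / sum(freq))
  }
  .model_cache[[key]] <- out
  out
}

#' Construct an amino-acid substitution model
#'
#' Builds a reversible rate matrix `Q` from a published exchangeability
#' table and stationary frequencies, optionally with discrete-gamma
#' among-site rate variation (4 categories) and a proportion of invariant
#' sites.  `Q` is normalised so the expected substitution rate is 1 per
#' unit branch length at `p_inv = 0`; when `p_inv > 0` the variable-site
#' rates are rescaled by `1 / (1 - p_inv)` so branch lengths keep the unit
#' of expected substitutions per site.
#'
#' @param matrix one of `"WAG"`, `"LG"`, `"JTT"`, `"POISSON"`.
#' @param gamma_shape gamma shape parameter `alpha` (`NULL` = no rate
#'   variation).
#' @param k number of discrete gamma categories.
#' @param p_inv proportion of invariant sites in `[0, 1)` (`NULL` = none).
#' @param freq `"model"` for the published frequencies, `"empirical"`
#'   (+F) to estimate them from an alignment at fit time, or a numeric
#'   vector of 20 frequencies.
#' @return an object of class `lox_model`.
#' @export
subst_model <- function(matrix = "WAG", gamma_shape = NULL, k = 4L,
                        p_inv = NULL, freq = "model") {
  tab <- load_model_table(matrix)
  plus_f <- identical(freq, "empirical")
  if (is.numeric(freq)) {
    if (length(freq) != 20) stop("freq must have 20 entries")
    pi <- setNames(freq / sum(freq), AA20)
  } else {
    pi <- tab$freq
  }
  if (!is.null(p_inv) && (p_inv < 0 || p_inv >= 1)) {
    stop("p_inv must be in [0, 1)")
  }
  if (!is.null(gamma_shape) && gamma_shape <= 0) stop("gamma_shape must be > 0")
  m <- structure(list(
    name = model_label(matrix, gamma_shape, p_inv, plus_f),
    matrix = toupper(matrix), R = tab$R, freq = pi,
    gamma_shape = gamma_shape, k = as.integer(k),
    p_inv = p_inv, plus_f = plus_f
  ), class = "lox_model")
  if (!plus_f) m <- model_finalize(m)
  m
}

model_label <- function(matrix, gamma_shape, p_inv, plus_f) {
  paste0(toupper(matrix),
         if (!is.null(gamma_shape)) "+G" else "",
         if (!is.null(p_inv)) "+I" else "",
         if (plus_f) "+F" else "")
}

# Fill in Q and its eigen-decomposition once frequencies are fixed.
model_finalize <- function(m) {
  pi <- m$freq
  Q <- m$R * rep(pi, each = 20)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  # symmetric similarity transform for a stable eigendecomposition
  sp <- sqrt(pi)
  B <- Q * (sp / rep(sp, each = 20))   # B[i,j] = sqrt(pi_i)/sqrt(pi_j) Q[i,j]
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  m$Q <- Q
  m$eig <- list(values = e$values,
                U = e$vectors / sp,          # row-scaled: diag(1/sp) %*% V
                Uinv = t(e$vectors * sp))    # t(diag(sp) %*% V)
  m$finalized <- TRUE
  m
}

#' @export
print.lox_model <- function(x, ...) {
  cat("Substitution model:", x$name, "\n")
  if (!is.null(x$gamma_shape)) cat("  gamma shape:", x$gamma_shape, "k =", x$k, "\n")
  if (!is.null(x$p_inv)) cat("  p_inv:", x$p_inv, "\n")
  invisible(x)
}

# Attach empirical (+F) frequencies from an alignment (Laplace +1 counts).
model_with_empirical_freq <- function(m, msa) {
  if (!m$plus_f) return(m)
  cnt <- setNames(rep(1, 20), AA20)
  for (s in msa$seqs) {
    tab <- table(factor(seq_chars(s), levels = AA20))
    cnt <- cnt + as.numeric(tab)
  }
  m$freq <- cnt / sum(cnt)
  model_finalize(m)
}

#' Transition probability matrix P(t)
#'
#' @param model a finalized `lox_model`.
#' @param t branch length (expected substitutions per site), `t >= 0`.
#' @param rate optional rate multiplier (gamma category rate).
#' @return 20x20 matrix with rows summing to 1.
#' @export
prob_matrix <- function(model, t, rate = 1) {
  if (t < 0) stop("negative branch length")
  e <- model$eig
  P <- e$U %*% (exp(e$values * t * rate) * e$Uinv)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(AA20, AA20)
  P
}

#' Discrete-gamma category rates (mean of each quantile bin)
#'
#' Yang's discretisation of Gamma(alpha, alpha) into `k` equiprobable
#' categories, each represented by its conditional mean; the rates average
#' exactly 1.
#'
#' @param alpha shape parameter (> 0).
#' @param k number of categories.
#' @return numeric vector of `k` increasing rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  if (alpha <= 0) stop("alpha must be > 0")
  b <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  p <- pgamma(b, shape = alpha + 1, rate = alpha)
  r <- k * diff(p)
  r / mean(r) * 1  # exact mean 1 despite rounding in the tail quantile
}

# Rates and weights for the full among-site mixture of a model
# (gamma categories and the invariant class, if any).
model_site_rates <- function(model) {
  if (is.null(model$gamma_shape)) {
    rates <- 1
    weights <- 1
  } else {
    rates <- discrete_gamma_rates(model$gamma_shape, model$k)
    weights <- rep(1 / model$k, model$k)
  }
  if (!is.null(model$p_inv) && model$p_inv > 0) {
    rates <- c(0, rates / (1 - model$p_inv))
    weights <- c(model$p_inv, weights * (1 - model$p_inv))
  }
  list(rates = rates, weights = weights)
}
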