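# Substitution models: empirical amino-acid matrices (WAG, JTT, LG), GTR for
# DNA, discrete-gamma rate heterogeneity and transition probabilities.
#
# The rate matrix is built as Q = S diag(pi) with the diagonal set for zero row
# sums and rescaled so the mean instantaneous rate -sum_i pi_i Q_ii equals 1,
# keeping branch lengths in expected-substitutions-per-site units.

# Published amino-acid exchangeabilities/frequencies as shipped by phangorn
# (lower triangle, PAML state order, identical to the original publications).
.aa_model_store <- function(name) {
  tmp <- get(paste0(".", name), environment(phangorn::pml))
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- tmp$Q
  S <- S + t(S)
  freq <- as.numeric(tmp$bf)
  dimnames(S) <- list(.AA_STATES, .AA_STATES)
  names(freq) <- .AA_STATES
  list(S = S, freq = freq)
}

#' Build a substitution model
#'
#' Supported models: `WAG`, `JTT`, `LG` (amino acid, published empirical
#' exchangeabilities) and `GTR` (DNA).  The returned rate matrix is reversible,
#' has zero row sums and unit mean rate.  `alpha` and `k` attach a discrete
#' gamma model of among-site rate variation (`k` equal-probability categories).
#'
#' @param name model name.
#' @param frequencies `"model"` (published/default values; uniform for GTR),
#'   `"empirical"` (counted from `aln` with add-one pseudocounts), or
#'   `"user"` (taken from `freq`).
#' @param freq stationary frequencies when `frequencies = "user"`.
#' @param rates for GTR: the six exchangeabilities in order ac, ag, at, cg,
#'   ct, gt; default all 1 (equal-rates model).
#' @param alpha gamma shape parameter (> 0), or `NULL` for rate homogeneity.
#' @param k number of gamma categories (used when `alpha` is set).
#' @param aln alignment for `frequencies = "empirical"`.
#' @return object of class `subst_model` with fields `name`, `alphabet`, `S`
#'   (exchangeabilities), `freq`, `Q`, `alpha`, `k`, and the cached symmetric
#'   eigendecomposition used for transition probabilities.
#' @export
build_model <- function(name = c("WAG", "JTT", "LG", "GTR"),
                        frequencies = c("model", "empirical", "user"),
                        freq = NULL, rates = NULL, alpha = NULL, k = 4L,
                        aln = NULL) {
  name <- match.arg(toupper(name), c("WAG", "JTT", "LG", "GTR"))
  frequencies <- match.arg(frequencies)
  if (name == "GTR") {
    alphabet <- "dna"
    if (is.null(rates)) rates <- rep(1, 6)
    if (length(rates) != 6 || any(rates <= 0))
      stop("GTR requires 6 positive exchangeabilities", call. = FALSE)
    S <- matrix(0, 4, 4, dimnames = list(.DNA_STATES, .DNA_STATES))
    S[lower.tri(S)] <- rates  # column-major fill = ac, ag, at, cg, ct, gt
    S <- S + t(S)
    base_freq <- rep(0.25, 4)
  } else {
    alphabet <- "aa"
    if (!is.null(rates)) stop("exchangeabilities are fixed for ", name,
                              call. = FALSE)
    st <- .aa_model_store(name)
    S <- st$S
    base_freq <- st$freq
  }
  nst <- ncol(S)
  pi <- switch(frequencies,
    model = base_freq,
    empirical = {
      if (is.null(aln)) stop("empirical frequencies need an alignment",
                             call. = FALSE)
      .empirical_frequencies(aln)
    },
    user = {
      if (is.null(freq) || length(freq) != nst)
        stop("user frequencies must have length ", nst, call. = FALSE)
      freq
    })
  if (abs(sum(pi) - 1) > 1e-6)
    stop("frequencies must sum to 1 (got ", format(sum(pi)), ")",
         call. = FALSE)
  if (any(pi <= 0)) stop("all stationary frequencies must be positive",
                         call. = FALSE)
  pi <- pi / sum(pi)
  if (!is.null(alpha) && alpha <= 0)
    stop("gamma shape alpha must be positive", call. = FALSE)
  .finish_model(name, alphabet, S, pi, alpha, as.integer(k))
}

# Assemble Q, normalize, cache the symmetric eigendecomposition.
.finish_model <- function(name, alphabet, S, pi, alpha, k) {
  Q <- S * rep(pi, each = nrow(S))      # Q_ij = S_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  sp <- sqrt(pi)
  A <- Q * (sp %o% (1 / sp))            # diag(sqrt pi) Q diag(1/sqrt pi), symmetric
  A <- (A + t(A)) / 2
  eig <- eigen(A, symmetric = TRUE)
  structure(list(
    name = name, alphabet = alphabet, S = S, freq = pi, Q = Q,
    alpha = alpha, k = k,
    eig_values = eig$values,
    eig_left = eig$vectors / sp,        # diag(1/sqrt pi) U
    eig_rightT = t(eig$vectors * sp)    # t(U) diag(sqrt pi) -> U^T on right
  ), class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("subst_model: %s (%s)%s\n", x$name, x$alphabet,
              if (is.null(x$alpha)) "" else
                sprintf(" +G%d alpha=%.4g", x$k, x$alpha)))
  invisible(x)
}

# Character frequencies over non-ambiguous characters with add-one
# pseudocounts (avoids zeros for rare residues).
.empirical_frequencies <- function(aln) {
  states <- alphabet_states(aln$alphabet)
  counts <- table(factor(tolower(aln$mat), levels = states))
  as.numeric(counts + 1) / sum(counts + 1)
}

#' Replace model pieces, recomputing the cached decomposition
#' @param model a `subst_model`.
#' @param alpha,freq,rates optional replacements (rates: GTR only).
#' @return updated `subst_model`.
#' @export
update_model <- function(model, alpha = model$alpha, freq = NULL,
                         rates = NULL) {
  if (!is.null(rates)) {
    if (model$name != "GTR") stop("exchangeabilities are fixed for ",
                                  model$name, call. = FALSE)
    return(build_model("GTR", frequencies = "user",
                       freq = if (is.null(freq)) model$freq else freq,
                       rates = rates, alpha = alpha, k = model$k))
  }
  pi <- if (is.null(freq)) model$freq else freq
  if (abs(sum(pi) - 1) > 1e-6 || any(pi <= 0))
    stop("invalid frequencies", call. = FALSE)
  if (!is.null(alpha) && alpha <= 0) stop("alpha must be positive",
                                          call. = FALSE)
  .finish_model(model$name, model$alphabet, model$S, pi / sum(pi),
                alpha, model$k)
}

#' Parse a model specification string
#'
#' Accepts the usual `NAME[+G[k]][+F]` syntax, e.g. `"WAG+G4"`, `"LG+G4+F"`,
#' `"GTR+G"`.  `+F` requests empirical frequencies counted from `aln`.
#'
#' @param spec model string.
#' @param aln alignment (required for `+F`).
#' @param alpha gamma shape to install when `+G` is present (may be fitted
#'   later with [estimate_alpha()]); defaults to 1.
#' @return a `subst_model`.
#' @export
parse_model_spec <- function(spec, aln = NULL, alpha = 1) {
  parts <- strsplit(toupper(spec), "+", fixed = TRUE)[[1]]
  name <- parts[1]
  k <- NULL; use_f <- FALSE
  for (p in parts[-1]) {
    if (grepl("^G[0-9]*$", p)) {
      k <- if (nchar(p) > 1) as.integer(substring(p, 2)) else 4L
    } else if (p == "F") use_f <- TRUE
    else stop("unrecognized model component '+", p, "' in '", spec, "'",
              call. = FALSE)
  }
  build_model(name,
              frequencies = if (use_f) "empirical" else "model",
              alpha = if (is.null(k)) NULL else alpha,
              k = if (is.null(k)) 4L else k, aln = aln)
}

#' Discretize a gamma distribution into equal-probability rate categories
#'
#' Mean-of-slice discretization: category `i` gets the mean of the
#' gamma(shape = alpha, rate = alpha) distribution over its quantile slice
#' `[(i-1)/k, i/k]`, computed in closed form from the incomplete-gamma
#' function.  The rates are renormalized post hoc so their mean is exactly 1.
#'
#' @param alpha shape parameter (> 0).
#' @param k number of categories (>= 1).
#' @return object of class `gamma_categories`: `rates` (increasing, mean 1)
#'   and `probabilities` (all `1/k`).
#' @export
discretize_gamma <- function(alpha, k) {
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be positive",
                                             call. = FALSE)
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k == 1)
    return(structure(list(rates = 1, probabilities = 1),
                     class = "gamma_categories"))
  q <- stats::qgamma(seq_len(k - 1) / k, shape = alpha, rate = alpha)
  # E[X; X in slice] * k, via the incomplete-gamma identity for gamma means
  upper <- c(stats::pgamma(q, shape = alpha + 1, rate = alpha), 1)
  lower <- c(0, stats::pgamma(q, shape = alpha + 1, rate = alpha))
  rates <- k * (upper - lower)
  rates <- rates / mean(rates)
  structure(list(rates = rates, probabilities = rep(1 / k, k)),
            class = "gamma_categories")
}

# Category rates for a model (1 when no gamma component).
.model_rates <- function(model) {
  if (is.null(model$alpha)) 1 else discretize_gamma(model$alpha, model$k)$rates
}

#' Transition probability matrix P(t) = exp(Q t r)
#'
#' Computed from the cached symmetric eigendecomposition of the reversible
#' rate matrix.  Tiny negative entries from roundoff are clamped to zero.
#'
#' @param model a `subst_model`.
#' @param t branch length (>= 0).
#' @param rate rate multiplier (e.g. a gamma category rate).
#' @return stochastic matrix (rows sum to 1).
#' @export
transition_probabilities <- function(model, t, rate = 1) {
  if (t < 0) stop("branch length must be >= 0", call. = FALSE)
  P <- model$eig_left %*% (exp(model$eig_values * (t * rate)) *
                             model$eig_rightT)
  P[P < 0] <- 0
  P
}
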