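# Native phylogenetic likelihood engine: Felsenstein pruning over compressed
# site patterns with per-node scaling, a discrete-gamma rate mixture,
# derivative-free branch-length optimization, gamma-shape estimation and
# empirical-Bayes site rates.
#
# All evaluation runs on unique site patterns; per-site values are broadcast
# back to original site indices at the API boundary.

#' Prepare alignment data for likelihood evaluation
#'
#' Encodes (a subset of) the alignment columns as per-taxon partial-likelihood
#' matrices over unique patterns.  Optional per-site weights (e.g. Lasso
#' weights) are accumulated into the pattern weights, so a weighted total
#' log-likelihood is a single pattern-weighted sum.
#'
#' @param aln an [msa].
#' @param model a `subst_model`.
#' @param sites optional 1-based site indices to restrict to.
#' @param site_weights optional positive per-site weights (parallel to
#'   `sites`, or to all sites when `sites` is `NULL`); default 1.
#' @return an object of class `ll_data`.
#' @export
ll_data <- function(aln, model, sites = NULL, site_weights = NULL) {
  if (model$alphabet != aln$alphabet)
    stop("model alphabet (", model$alphabet, ") does not match alignment (",
         aln$alphabet, ")", call. = FALSE)
  m <- n_sites(aln)
  if (is.null(sites)) sites <- seq_len(m)
  if (any(sites < 1 | sites > m)) stop("site index out of range", call. = FALSE)
  if (is.null(site_weights)) site_weights <- rep(1, length(sites))
  if (length(site_weights) != length(sites) || any(site_weights <= 0))
    stop("site_weights must be positive and parallel to sites", call. = FALSE)
  sub <- aln$mat[, sites, drop = FALSE]
  key <- apply(sub, 2, paste, collapse = "\r")
  first <- !duplicated(key)
  pat_id <- match(key, key[first])
  pats <- sub[, first, drop = FALSE]
  pat_w <- as.vector(tapply(site_weights, pat_id, sum))
  ctr <- alphabet_contrast(aln$alphabet)
  S <- ncol(ctr)
  tipp <- lapply(seq_len(nrow(pats)), function(i) {
    idx <- match(pats[i, ], rownames(ctr))
    t(ctr[idx, , drop = FALSE])
  })
  structure(list(model = model, taxa = aln$taxa, tipp = tipp,
                 pat_w = pat_w, site_to_pattern = pat_id, sites = sites,
                 S = S, p = ncol(pats), tag = "full"),
            class = "ll_data")
}

.count <- function(counter, tag, n = 1) {
  if (!is.null(counter)) {
    cur <- counter[[tag]]
    counter[[tag]] <- if (is.null(cur)) n else cur + n
  }
}

# Validate a tree against the prepared data and flatten it for the compiled
# kernels (0-based postorder edge matrix, tip-to-taxon map, model context).
.tree_ctx <- function(tree, dat) {
  phy <- ape::reorder.phylo(tree, "postorder")
  len <- phy$edge.length
  if (is.null(len)) stop("tree has no branch lengths", call. = FALSE)
  if (any(len < 0)) stop("negative branch length", call. = FALSE)
  tipidx <- match(phy$tip.label, dat$taxa)
  if (anyNA(tipidx) || length(tipidx) != length(dat$taxa))
    stop("tree taxa do not match the alignment", call. = FALSE)
  ntip <- length(phy$tip.label)
  list(phy = phy, E = phy$edge, len = len, ntip = ntip,
       nn = ntip + phy$Nnode, root = phy$edge[nrow(phy$edge), 1],
       tipidx = tipidx)
}

.model_ctx <- function(model) {
  list(eig_left = model$eig_left, eig_rightT = model$eig_rightT,
       eig_values = model$eig_values, freq = model$freq,
       rates = .model_rates(model))
}

# Postorder peel (compiled).  Returns the gamma-mixed per-pattern
# log-likelihoods and the per-category matrix behind them.
.peel <- function(tree, dat, counter = NULL) {
  tc <- .tree_ctx(tree, dat)
  .count(counter, dat$tag)
  res <- .peel_catlogs_cpp(tc$E - 1L, tc$len, tc$ntip, tc$nn, tc$root - 1L,
                           tc$tipidx - 1L, dat$tipp, .model_ctx(dat$model))
  list(pat_ll = as.vector(res$pat_ll), catlogs = res$catlogs,
       rates = .model_rates(dat$model))
}

#' Per-site log-likelihoods of a tree
#'
#' Felsenstein pruning under the model's gamma mixture; pattern compression is
#' used internally and values are broadcast back to original sites, so the sum
#' of the vector equals the tree log-likelihood.
#'
#' @param tree a `phylo` whose tip labels match the alignment taxa.
#' @param aln an [msa] (or a prepared [ll_data] in place of `aln`+`model`).
#' @param model a `subst_model`.
#' @return numeric vector of per-site log-likelihoods with attribute
#'   `"total"`.
#' @export
site_log_likelihoods <- function(tree, aln, model = NULL) {
  dat <- if (inherits(aln, "ll_data")) aln else ll_data(aln, model)
  pe <- .peel(tree, dat)
  out <- pe$pat_ll[dat$site_to_pattern]
  attr(out, "total") <- sum(pe$pat_ll * dat$pat_w)
  out
}

#' Total (optionally site-weighted) log-likelihood of a tree
#'
#' @inheritParams site_log_likelihoods
#' @param counter optional environment collecting evaluation counts.
#' @return numeric scalar; with site weights in the `ll_data`, the weighted
#'   sum of per-site log-likelihoods.
#' @export
total_log_likelihood <- function(tree, aln, model = NULL, counter = NULL) {
  dat <- if (inherits(aln, "ll_data")) aln else ll_data(aln, model)
  pe <- .peel(tree, dat, counter = counter)
  sum(pe$pat_ll * dat$pat_w)
}

#' Optimize branch lengths by coordinate-wise scalar search
#'
#' Each branch is optimized in turn against the (pattern-weighted)
#' log-likelihood with a safeguarded Newton step in log branch length
#' (analytic first and second derivatives; bracketed golden-section fallback),
#' within bounds `[1e-8, 100]`.  Branches are swept in postorder until a full
#' sweep improves the log-likelihood by less than `tol` or `max_sweeps` is
#' reached; a sweep that ever fails to improve the exact log-likelihood is
#' replayed as a strict coordinate ascent, so the log-likelihood never
#' decreases across sweeps.
#'
#' @inheritParams site_log_likelihoods
#' @param tol sweep-to-sweep convergence threshold in log-likelihood units.
#' @param max_sweeps sweep cap; non-convergence sets a warning flag.
#' @param counter optional environment collecting evaluation counts.
#' @return the tree with optimized `edge.length` and attributes `"loglik"`,
#'   `"converged"`.
#' @export
optimize_branch_lengths <- function(tree, aln, model = NULL, tol = 0.01,
                                    max_sweeps = 32, counter = NULL) {
  dat <- if (inherits(aln, "ll_data")) aln else ll_data(aln, model)
  tc <- .tree_ctx(tree, dat)
  res <- .optimize_edges_cpp(tc$E - 1L, tc$len, tc$ntip, tc$nn, tc$root - 1L,
                             tc$tipidx - 1L, dat$tipp, .model_ctx(dat$model),
                             dat$pat_w, tol, max_sweeps, 1e-8, 100)
  # count complete per-site likelihood passes; one-branch objective
  # evaluations are tracked separately (they touch a single edge, not the
  # whole tree)
  .count(counter, dat$tag, res$n_passes)
  .count(counter, paste0(dat$tag, "_edge"), res$n_edge_evals)
  phy <- tc$phy
  phy$edge.length <- as.vector(res$len)
  if (!res$converged)
    warning("branch-length optimization did not converge in ",
            max_sweeps, " sweeps")
  attr(phy, "loglik") <- res$loglik
  attr(phy, "converged") <- res$converged
  phy
}

#' Maximum-likelihood estimate of the gamma shape parameter
#'
#' Bounded scalar search for alpha on a log scale over `[0.02, 100]`
#' (relative tolerance 1e-3) on a fixed tree topology, alternating with
#' branch-length optimization.
#'
#' @inheritParams site_log_likelihoods
#' @param optimize_bl alternate alpha search with branch-length optimization
#'   (two rounds); when `FALSE` the supplied branch lengths are kept fixed.
#' @param rounds number of alternation rounds.
#' @return the alpha estimate, with attributes `"tree"` (branch lengths as
#'   last optimized) and `"loglik"`.
#' @export
estimate_alpha <- function(tree, aln, model = NULL, optimize_bl = TRUE,
                           rounds = 2) {
  dat <- if (inherits(aln, "ll_data")) aln else ll_data(aln, model)
  if (is.null(dat$model$alpha))
    stop("model has no gamma component; build it with alpha set",
         call. = FALSE)
  cur <- tree
  alpha <- dat$model$alpha
  ll <- NA_real_
  for (ro in seq_len(if (optimize_bl) rounds else 1)) {
    if (optimize_bl) {
      dat$model <- update_model(dat$model, alpha = alpha)
      cur <- optimize_branch_lengths(cur, dat)
    }
    f <- function(la) {
      dat$model <- update_model(dat$model, alpha = exp(la))
      total_log_likelihood(cur, dat)
    }
    opt <- stats::optimize(f, interval = log(c(0.02, 100)), maximum = TRUE,
                           tol = 1e-3)
    alpha <- exp(opt$maximum)
    ll <- opt$objective
  }
  structure(alpha, tree = cur, loglik = ll)
}

#' Empirical-Bayes site-specific evolutionary rates
#'
#' Posterior mean of the gamma category rate at each site given the tree and
#' data: `sum_k r_k P(site | r_k) / sum_k P(site | r_k)` (equal category
#' priors).  The standardized copy is the zero-mean, unit-variance transform
#' (sample standard deviation).
#'
#' @inheritParams site_log_likelihoods
#' @return object of class `site_rates`: `raw` (posterior-mean relative
#'   rates) and `standardized`; with a single rate category both are
#'   degenerate (`raw = 1`, `standardized = 0`) and attribute
#'   `"degenerate"` is set.
#' @export
site_rates_empirical_bayes <- function(tree, aln, model = NULL) {
  dat <- if (inherits(aln, "ll_data")) aln else ll_data(aln, model)
  pe <- .peel(tree, dat)
  k <- nrow(pe$catlogs)
  if (k == 1) {
    m <- length(dat$site_to_pattern)
    return(structure(list(raw = rep(1, m), standardized = rep(0, m)),
                     class = "site_rates", degenerate = TRUE))
  }
  mx <- apply(pe$catlogs, 2, max)
  w <- exp(sweep(pe$catlogs, 2, mx))
  post <- sweep(w, 2, colSums(w), "/")
  rate_pat <- as.vector(pe$rates %*% post)
  raw <- rate_pat[dat$site_to_pattern]
  s <- stats::sd(raw)
  std <- if (s < 1e-12) rep(0, length(raw)) else (raw - mean(raw)) / s
  structure(list(raw = raw, standardized = std), class = "site_rates",
            degenerate = s < 1e-12)
}

# ---- tabular interfaces ----------------------------------------------------

#' Write per-site log-likelihoods of a set of trees as TSV
#'
#' Long format with columns `tree_id`, `site` (1-based), `ll`.
#'
#' @param X numeric matrix, rows = trees, columns = sites.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_site_ll_tsv <- function(X, path) {
  df <- data.frame(
    tree_id = rep(seq_len(nrow(X)), each = ncol(X)),
    site = rep(seq_len(ncol(X)), nrow(X)),
    ll = as.vector(t(X)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a site-weights TSV (columns: site, weight)
#'
#' Weights must be strictly positive, mirroring weighted-likelihood engines
#' that only accept positive site weight vectors.
#'
#' @param path input file.
#' @return data.frame with integer `site` and numeric `weight`.
#' @export
read_site_weights_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("site", "weight") %in% names(df)))
    stop("expected columns 'site' and 'weight'", call. = FALSE)
  if (any(df$weight <= 0))
    stop("site weights must be strictly positive", call. = FALSE)
  df$site <- as.integer(df$site)
  df
}
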