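# Positive-coefficient Lasso site sampling: build the training design matrix
# from per-site log-likelihoods of random trees, fit the regularization path
# by cyclic coordinate descent with coefficients clamped to be non-negative,
# pick the penalty matching a target site fraction zeta, and evaluate the
# weighted approximation.
#
# The objective is least squares plus an L1 penalty,
#   sum_j (LL(T_j) - b0 - sum_i b_i LL_i(T_j))^2 + lambda * sum_i |b_i|,
# with b_i >= 0.  Columns are centered and scaled to unit L2 norm before
# fitting so selection is scale-free; the response is centered (not scaled)
# and the intercept recovered analytically.

#' Build a Lasso training set from random trees
#'
#' Generates `eta` random stepwise-addition topologies with i.i.d.
#' exponential branch lengths and computes exact per-site log-likelihoods for
#' each (no branch-length or model-parameter optimization during training).
#'
#' @param aln an [msa].
#' @param model a `subst_model`.
#' @param eta number of training trees (>= 2).  The study protocol uses 2000
#'   for 15-taxon alignments and 4000 for 30-60 taxa.
#' @param bl_mean exponential mean of training branch lengths (default 0.1).
#' @param rng_seed integer root seed; tree `j` draws from substreams derived
#'   from it, so the set is reproducible and extendable.
#' @return object of class `lasso_training`: `trees` (list of `phylo`), `X`
#'   (`eta` x m matrix of per-site log-likelihoods), `y` (row sums of `X`),
#'   `eta`, `seed`, `model`.
#' @export
build_training_set <- function(aln, model, eta, bl_mean = 0.1, rng_seed = 1) {
  if (eta < 2) stop("eta must be >= 2", call. = FALSE)
  dat <- ll_data(aln, model)
  m <- n_sites(aln)
  X <- matrix(0, eta, m)
  trees <- vector("list", eta)
  for (j in seq_len(eta)) {
    tr <- random_stepwise_topology(aln$taxa,
                                   derive_seed(rng_seed, paste0("topo-", j)))
    tr <- draw_branch_lengths(tr, mean = bl_mean,
                              rng_seed = derive_seed(rng_seed,
                                                     paste0("bl-", j)))
    trees[[j]] <- tr
    X[j, ] <- site_log_likelihoods(tr, dat)
  }
  structure(list(trees = trees, X = X, y = rowSums(X), eta = eta,
                 seed = rng_seed, bl_mean = bl_mean, model = model),
            class = "lasso_training")
}

#' @export
print.lasso_training <- function(x, ...) {
  cat(sprintf("lasso_training: eta=%d trees, m=%d sites\n",
              x$eta, ncol(x$X)))
  invisible(x)
}

#' Standardize the Lasso design matrix
#'
#' Columns are centered and divided by their (centered) L2 norm; the response
#' is centered by its mean.  Zero-variance columns cannot be scaled: they are
#' flagged and forced out of the model (coefficient fixed at zero).
#'
#' @param ts a `lasso_training` (or any list with `X`, `y`).
#' @return list with `X_std`, `y_centered`, `col_means`, `col_norms`,
#'   `y_center`, and `dropped` (indices of zero-variance columns).
#' @export
standardize_design <- function(ts) {
  X <- ts$X; y <- ts$y
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  nrm <- sqrt(colSums(Xc * Xc))
  dropped <- which(nrm < 1e-10)
  nrm_safe <- ifelse(nrm < 1e-10, 1, nrm)
  Xs <- sweep(Xc, 2, nrm_safe, "/")
  if (length(dropped)) Xs[, dropped] <- 0
  list(X_std = Xs, y_centered = y - mean(y), col_means = mu,
       col_norms = nrm_safe, y_center = mean(y), dropped = dropped)
}

#' Fit the positive-coefficient Lasso path by coordinate descent
#'
#' Cyclic coordinate descent with the one-sided soft threshold (coefficients
#' clamped to be >= 0) and warm starts along a decreasing penalty grid of
#' `grid_points` values on a log scale with ratio `grid_ratio` between the
#' smallest and largest penalty.  The grid maximum is the smallest penalty at
#' which the solution is entirely zero, computed from the largest positive
#' column-response correlation.  Convergence at a grid point: largest
#' coefficient update below `1e-4` times the largest absolute coefficient.
#'
#' @param X_std standardized design (columns centered, unit L2 norm).
#' @param y_centered centered response.
#' @param grid_points number of penalties (default 100).
#' @param grid_ratio smallest/largest penalty ratio (default 1e-7).
#' @param dropped columns to hold at zero (from [standardize_design()]).
#' @param max_sweeps coordinate-descent sweep cap per grid point.
#' @param conv_tol convergence threshold: a grid point is converged when the
#'   largest coefficient update falls below `conv_tol` times the largest
#'   coefficient (default `1e-4`).
#' @param trace_objective record the penalized objective after every sweep
#'   (attribute `"objective_trace"`, one vector per grid point).
#' @return object of class `lasso_path`: `lambda` (decreasing), `beta`
#'   (m x grid_points matrix of standardized coefficients), `nonzero`
#'   (active-set size per grid point).
#' @export
fit_positive_lasso_path <- function(X_std, y_centered, grid_points = 100,
                                    grid_ratio = 1e-7, dropped = integer(0),
                                    max_sweeps = 1000,
                                    trace_objective = FALSE,
                                    conv_tol = 1e-4) {
  m <- ncol(X_std)
  cory <- as.vector(crossprod(X_std, y_centered))
  if (length(dropped)) cory[dropped] <- 0
  lam_max <- 2 * max(cory, 0)
  if (lam_max <= 0)
    stop("no positive site-response correlation; nothing to select",
         call. = FALSE)
  # nudge above the exact threshold so the first grid point is all-zero
  lam_max <- lam_max * (1 + 1e-10)
  lambda <- exp(seq(log(lam_max), log(lam_max * grid_ratio),
                    length.out = grid_points))
  beta <- numeric(m)
  r <- y_centered
  B <- matrix(0, m, grid_points)
  nonzero <- integer(grid_points)
  free <- setdiff(seq_len(m), dropped)
  obj_trace <- if (trace_objective) vector("list", grid_points) else NULL
  thr <- 0
  cd_sweep <- function(idx) {
    dmax <- 0
    for (i in idx) {
      bi <- beta[i]
      corr <- sum(X_std[, i] * r) + bi
      bn <- corr - thr
      if (bn < 0) bn <- 0
      d <- bn - bi
      if (d != 0) {
        r <<- r - X_std[, i] * d
        beta[i] <<- bn
        if (abs(d) > dmax) dmax <- abs(d)
      }
    }
    dmax
  }
  objective <- function(lam) sum(r * r) + lam * sum(beta)
  for (gi in seq_along(lambda)) {
    thr <- lambda[gi] / 2
    trace_gi <- numeric(0)
    outer_it <- 0L
    converged <- FALSE
    repeat {
      outer_it <- outer_it + 1L
      d_full <- cd_sweep(free)
      if (trace_objective) trace_gi <- c(trace_gi, objective(lambda[gi]))
      if (d_full < conv_tol * max(beta, 1e-12)) { converged <- TRUE; break }
      for (s in seq_len(max_sweeps)) {
        act <- which(beta > 0)
        if (length(act) == 0) break
        d_act <- cd_sweep(act)
        if (trace_objective) trace_gi <- c(trace_gi, objective(lambda[gi]))
        if (d_act < conv_tol * max(beta, 1e-12)) break
      }
      if (outer_it >= 50L) break
    }
    if (!converged && outer_it >= 50L)
      warning("coordinate descent did not fully converge at grid point ", gi)
    B[, gi] <- beta
    nonzero[gi] <- sum(beta > 0)
    if (trace_objective) obj_trace[[gi]] <- trace_gi
  }
  structure(list(lambda = lambda, beta = B, nonzero = nonzero,
                 grid_ratio = grid_ratio),
            class = "lasso_path", objective_trace = obj_trace)
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf("lasso_path: %d grid points, lambda %0.4g..%0.4g, nonzero %d..%d\n",
              length(x$lambda), x$lambda[1], x$lambda[length(x$lambda)],
              x$nonzero[1], x$nonzero[length(x$nonzero)]))
  invisible(x)
}

#' Select a site sample from the Lasso path for a target fraction
#'
#' Walks the penalty grid from the largest penalty down and takes the first
#' grid point whose fraction of non-zero coefficients reaches `zeta`; the
#' achieved fraction is reported rather than truncating coefficients.
#' Coefficients are mapped back to the original scale
#' (`weight_i = beta_i / norm_i`), so all weights are positive, and the
#' intercept is recovered analytically.
#'
#' @param path a `lasso_path`.
#' @param zeta target fraction of sites in (0, 1].
#' @param std the standardization info from [standardize_design()].
#' @param meta optional list of training metadata to carry along (eta, seed,
#'   model id).
#' @return object of class `lasso_sample`: `sites` (1-based, increasing),
#'   `weights` (positive), `intercept`, `lambda`, `zeta_target`,
#'   `zeta_achieved`, `m`, `meta`.
#' @export
select_sample <- function(path, zeta, std, meta = list()) {
  m <- nrow(path$beta)
  frac <- path$nonzero / m
  hit <- which(frac >= zeta)
  if (length(hit) == 0)
    stop("target fraction zeta = ", zeta, " is not reachable: the grid ",
         "minimum attains only ", max(frac), " (the achievable fraction is ",
         "limited from above by the smallest penalty in the grid)",
         call. = FALSE)
  gi <- hit[1]
  b <- path$beta[, gi]
  sites <- which(b > 0)
  w <- b[sites] / std$col_norms[sites]
  intercept <- std$y_center - sum(w * std$col_means[sites])
  structure(list(sites = sites, weights = unname(w), intercept = intercept,
                 lambda = path$lambda[gi], zeta_target = zeta,
                 zeta_achieved = length(sites) / m, m = m, meta = meta),
            class = "lasso_sample")
}

#' @export
print.lasso_sample <- function(x, ...) {
  cat(sprintf(
    "lasso_sample: %d/%d sites (zeta %.4f, target %.4f), lambda %.4g\n",
    length(x$sites), x$m, x$zeta_achieved, x$zeta_target, x$lambda))
  invisible(x)
}

#' Train a Lasso site sample end to end
#'
#' Convenience pipeline: [build_training_set()] (or a prebuilt one) ->
#' [standardize_design()] -> [fit_positive_lasso_path()] -> [select_sample()].
#'
#' @param aln an [msa].
#' @param model a `subst_model`.
#' @param eta number of training trees.
#' @param zeta target site fraction.
#' @param rng_seed root seed.
#' @param bl_mean training branch-length mean.
#' @param training optional prebuilt `lasso_training` (overrides `eta`,
#'   `rng_seed`).
#' @return a `lasso_sample` with attribute `"training"` (the training set).
#' @export
train_lasso <- function(aln, model, eta = 2000, zeta = 0.05, rng_seed = 1,
                        bl_mean = 0.1, training = NULL) {
  ts <- if (is.null(training))
    build_training_set(aln, model, eta, bl_mean = bl_mean,
                       rng_seed = rng_seed)
  else training
  std <- standardize_design(ts)
  path <- fit_positive_lasso_path(std$X_std, std$y_centered,
                                  dropped = std$dropped)
  smp <- select_sample(path, zeta, std,
                       meta = list(eta = ts$eta, seed = ts$seed,
                                   model = ts$model$name))
  attr(smp, "training") <- ts
  smp
}

#' Approximate a tree's log-likelihood from a site sample
#'
#' `intercept + sum_k weight_k * LL_{site_k}(tree)`.  When a tree is given,
#' per-site log-likelihoods are computed at the selected sites only.  With
#' `use_intercept = FALSE` the weighted sum alone is returned; the intercept
#' shifts every tree equally, so rankings are unchanged.
#'
#' @param x either a numeric vector of per-site log-likelihoods over all `m`
#'   sites, or a `phylo` (then `aln`, `model` are required).
#' @param sample a `lasso_sample`.
#' @param aln,model alignment and model when `x` is a tree.
#' @param use_intercept include the regression intercept (default `TRUE`).
#' @return numeric scalar.
#' @export
approximate_log_likelihood <- function(x, sample, aln = NULL, model = NULL,
                                       use_intercept = TRUE) {
  b0 <- if (use_intercept) sample$intercept else 0
  if (is.numeric(x)) {
    if (max(sample$sites) > length(x))
      stop("sample site index exceeds site log-likelihood vector",
           call. = FALSE)
    return(b0 + sum(sample$weights * x[sample$sites]))
  }
  dat <- if (inherits(aln, "ll_data")) aln
         else ll_data(aln, model, sites = sample$sites,
                      site_weights = sample$weights)
  b0 + total_log_likelihood(x, dat)
}

#' Prepared evaluation data for a Lasso sample
#'
#' Restricts the alignment to the selected sites with the Lasso weights folded
#' into the pattern weights, so approximate evaluation costs only the sampled
#' fraction.
#'
#' @param aln an [msa].
#' @param model a `subst_model`.
#' @param sample a `lasso_sample`.
#' @return an [ll_data] tagged `"approx"`.
#' @export
sample_ll_data <- function(aln, model, sample) {
  dat <- ll_data(aln, model, sites = sample$sites,
                 site_weights = sample$weights)
  dat$tag <- "approx"
  dat
}

# ---- serialization ---------------------------------------------------------

#' Serialize a Lasso sample to JSON / site-weights TSV
#'
#' The JSON carries 1-based site indices, weights, intercept, penalty, target
#' and achieved fractions and training metadata.  The TSV (columns `site`,
#' `weight`) is the positive site-weight vector accepted by weighted
#' likelihood evaluation.
#'
#' @param sample a `lasso_sample`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lasso_sample <- function(sample, path) {
  jsonlite::write_json(
    list(sites = sample$sites, weights = sample$weights,
         intercept = sample$intercept, lambda = sample$lambda,
         zeta_target = sample$zeta_target,
         zeta_achieved = sample$zeta_achieved, m = sample$m,
         meta = sample$meta),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lasso_sample
#' @export
read_lasso_sample <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(sites = as.integer(x$sites), weights = as.numeric(x$weights),
                 intercept = x$intercept, lambda = x$lambda,
                 zeta_target = x$zeta_target,
                 zeta_achieved = x$zeta_achieved, m = as.integer(x$m),
                 meta = as.list(x$meta)),
            class = "lasso_sample")
}

#' @rdname write_lasso_sample
#' @export
write_site_weights_tsv <- function(sample, path) {
  utils::write.table(
    data.frame(site = sample$sites, weight = sample$weights),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
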