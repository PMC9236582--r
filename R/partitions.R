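# Partitioned-model training: a separate substitution model is fitted per
# gene partition (gamma shape and, for DNA, empirical frequencies), per-site
# log-likelihoods are computed under each site's partition model, and the
# Lasso is applied either once to the concatenated design (a single sample
# over all sites) or independently per partition (one sample each, summed at
# evaluation time).
#
# Both variants share the same training trees (one topology and branch-length
# set per training index), so the concatenated design matrix is exactly the
# column-concatenation of the per-partition designs.  Branch lengths are
# shared across partitions; only rates (alpha) and frequencies are unlinked.

# Fit a per-partition model: alpha by ML on a parsimony stepwise tree with
# optimized branch lengths; frequencies empirical for DNA, model defaults for
# AA matrices.
.fit_partition_model <- function(sub_aln, base_spec, rng_seed) {
  model <- parse_model_spec(base_spec, aln = sub_aln)
  det <- apply(sub_aln$mat, 2, function(col)
    !all(col %in% .fully_ambiguous_codes(sub_aln$alphabet)))
  if (sum(det) < 2)
    stop("partition has fewer than 2 determined sites", call. = FALSE)
  if (!is.null(model$alpha)) {
    ptree <- parsimony_stepwise_tree(sub_aln, rng_seed)
    ptree <- draw_branch_lengths(ptree, mean = 0.1,
                                 rng_seed = derive_seed(rng_seed, "init-bl"))
    a <- estimate_alpha(ptree, sub_aln, model, optimize_bl = TRUE)
    model <- update_model(model, alpha = as.numeric(a))
  }
  model
}

# Shared training trees for a partitioned run (same streams as
# build_training_set, so a one-partition scheme reproduces the unpartitioned
# training exactly).
.training_trees <- function(taxa, eta, bl_mean, rng_seed) {
  lapply(seq_len(eta), function(j) {
    tr <- random_stepwise_topology(taxa,
                                   derive_seed(rng_seed, paste0("topo-", j)))
    draw_branch_lengths(tr, mean = bl_mean,
                        rng_seed = derive_seed(rng_seed, paste0("bl-", j)))
  })
}

# Per-partition design matrices under per-partition models, on shared trees.
.partition_designs <- function(aln, scheme, models, trees) {
  npart <- nrow(scheme$partitions)
  lapply(seq_len(npart), function(pid) {
    sub <- partition_slice(aln, scheme, pid)
    dat <- ll_data(sub, models[[pid]])
    Xp <- matrix(0, length(trees), n_sites(sub))
    for (j in seq_along(trees))
      Xp[j, ] <- site_log_likelihoods(trees[[j]], dat)
    Xp
  })
}

#' Train a single Lasso sample over a partitioned alignment
#'
#' Fits a separate model per partition, computes each site's training
#' log-likelihoods under its partition's model, and runs one Lasso over all
#' sites of the concatenated design.
#'
#' @param aln an [msa].
#' @param scheme a `partition_scheme` covering `aln`.
#' @param eta number of shared training trees.
#' @param zeta target fraction of sites.
#' @param rng_seed root seed.
#' @param base_spec model specification applied per partition (a
#'   partition-file model token overrides it for that partition).
#' @param bl_mean training branch-length mean.
#' @return a `lasso_sample` (sites indexed on the full alignment) with
#'   attributes `"models"` (per-partition fitted models) and `"training"`.
#' @export
train_concatenated <- function(aln, scheme, eta, zeta, rng_seed = 1,
                               base_spec = "GTR+G", bl_mean = 0.1) {
  npart <- nrow(scheme$partitions)
  models <- lapply(seq_len(npart), function(pid) {
    spec <- scheme$partitions$model[pid]
    if (is.na(spec)) spec <- base_spec
    .fit_partition_model(partition_slice(aln, scheme, pid), spec,
                         derive_seed(rng_seed, paste0("partmodel-", pid)))
  })
  trees <- .training_trees(aln$taxa, eta, bl_mean, rng_seed)
  designs <- .partition_designs(aln, scheme, models, trees)
  m <- n_sites(aln)
  X <- matrix(0, eta, m)
  for (pid in seq_len(npart))
    X[, scheme$site_partition == pid] <- designs[[pid]]
  ts <- structure(list(trees = trees, X = X, y = rowSums(X), eta = eta,
                       seed = rng_seed, bl_mean = bl_mean,
                       model = models[[1]]),
                  class = "lasso_training")
  std <- standardize_design(ts)
  path <- fit_positive_lasso_path(std$X_std, std$y_centered,
                                  dropped = std$dropped)
  smp <- select_sample(path, zeta, std,
                       meta = list(eta = eta, seed = rng_seed,
                                   model = "partitioned-concatenated"))
  attr(smp, "models") <- models
  attr(smp, "training") <- ts
  smp
}

#' Train one Lasso sample per partition
#'
#' Same per-partition models and shared training trees as
#' [train_concatenated()], but an independent standardization, path and
#' selection per partition; the whole-alignment approximation is the sum of
#' the per-partition approximations.
#'
#' @inheritParams train_concatenated
#' @return object of class `partition_samples`: list with `samples` (one
#'   `lasso_sample` per partition, sites indexed on the full alignment),
#'   `models`, `scheme`.
#' @export
train_per_partition <- function(aln, scheme, eta, zeta, rng_seed = 1,
                                base_spec = "GTR+G", bl_mean = 0.1) {
  npart <- nrow(scheme$partitions)
  models <- lapply(seq_len(npart), function(pid) {
    spec <- scheme$partitions$model[pid]
    if (is.na(spec)) spec <- base_spec
    .fit_partition_model(partition_slice(aln, scheme, pid), spec,
                         derive_seed(rng_seed, paste0("partmodel-", pid)))
  })
  trees <- .training_trees(aln$taxa, eta, bl_mean, rng_seed)
  designs <- .partition_designs(aln, scheme, models, trees)
  samples <- vector("list", npart)
  for (pid in seq_len(npart)) {
    Xp <- designs[[pid]]
    ts <- structure(list(trees = trees, X = Xp, y = rowSums(Xp), eta = eta,
                         seed = rng_seed, bl_mean = bl_mean,
                         model = models[[pid]]),
                    class = "lasso_training")
    std <- standardize_design(ts)
    path <- fit_positive_lasso_path(std$X_std, std$y_centered,
                                    dropped = std$dropped)
    smp <- select_sample(path, zeta, std,
                         meta = list(eta = eta, seed = rng_seed,
                                     model = scheme$partitions$name[pid]))
    # re-index sites onto the full alignment
    psites <- which(scheme$site_partition == pid)
    smp$sites <- psites[smp$sites]
    smp$m <- n_sites(aln)
    samples[[pid]] <- smp
  }
  structure(list(samples = samples, models = models, scheme = scheme),
            class = "partition_samples")
}

#' Approximate log-likelihood under partitioned samples
#'
#' Sum over partitions of each partition's Lasso approximation, each computed
#' under its partition's fitted model.
#'
#' @param tree a `phylo`.
#' @param ps a `partition_samples`.
#' @param aln the full [msa].
#' @param use_intercept include the per-partition intercepts.
#' @return numeric scalar.
#' @export
partition_approximate_ll <- function(tree, ps, aln, use_intercept = TRUE) {
  tot <- 0
  for (pid in seq_along(ps$samples)) {
    smp <- ps$samples[[pid]]
    dat <- ll_data(aln, ps$models[[pid]], sites = smp$sites,
                   site_weights = smp$weights)
    dat$tag <- "approx"
    tot <- tot + total_log_likelihood(tree, dat) +
      if (use_intercept) smp$intercept else 0
  }
  tot
}

#' Exact partitioned log-likelihood (sum over partition models)
#'
#' @param tree a `phylo`.
#' @param aln the full [msa].
#' @param scheme a `partition_scheme`.
#' @param models list of per-partition `subst_model`s.
#' @return numeric scalar: the sum of each partition's exact log-likelihood
#'   under its own model.
#' @export
partition_total_ll <- function(tree, aln, scheme, models) {
  tot <- 0
  for (pid in seq_along(models)) {
    sub <- partition_slice(aln, scheme, pid)
    tot <- tot + total_log_likelihood(tree, ll_data(sub, models[[pid]]))
  }
  tot
}
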