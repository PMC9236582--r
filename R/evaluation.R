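# Evaluation harness: approximation accuracy metrics on held-out test trees
# and the naive site-sampling baselines (uniform random sites, fastest-rate
# sites) the Lasso is compared against.

#' Accuracy of a site-sample approximation on test trees
#'
#' For each test tree the exact (all-sites) and approximate (sampled, Lasso-
#' weighted) log-likelihoods are compared.  Reported metrics: squared Pearson
#' correlation, Spearman rank correlation, and the percentage error
#' `|approx - exact| / |exact| * 100` (mean and standard deviation).
#'
#' @param sample a `lasso_sample` (or any list with `sites`, `weights`,
#'   `intercept`).
#' @param test_trees list of `phylo` test trees.
#' @param aln an [msa].
#' @param model a `subst_model`.
#' @param optimize_bl when `TRUE`, each test tree's branch lengths are first
#'   ML-optimized on the full alignment (the test protocol for trees whose
#'   lengths were not estimated from data).
#' @param exact_ll optional precomputed exact log-likelihoods (skips the
#'   exact pass; trees are then used as given).
#' @return object of class `accuracy_report`: `r_squared`, `spearman_rho`,
#'   `mean_pct_error`, `sd_pct_error`, `n_trees`, and `per_tree`
#'   (data.frame: tree_id, exact_ll, approx_ll, pct_error).
#' @export
evaluate_sample <- function(sample, test_trees, aln, model,
                            optimize_bl = FALSE, exact_ll = NULL) {
  if (length(test_trees) < 2) stop("need at least 2 test trees",
                                   call. = FALSE)
  full_dat <- ll_data(aln, model)
  adat <- ll_data(aln, model, sites = sample$sites,
                  site_weights = sample$weights)
  adat$tag <- "approx"
  n <- length(test_trees)
  exact <- numeric(n); approx <- numeric(n)
  for (i in seq_len(n)) {
    tr <- test_trees[[i]]
    if (optimize_bl) {
      tr <- optimize_branch_lengths(tr, full_dat)
      exact[i] <- attr(tr, "loglik")
    } else if (!is.null(exact_ll)) {
      exact[i] <- exact_ll[i]
    } else {
      exact[i] <- total_log_likelihood(tr, full_dat)
    }
    approx[i] <- sample$intercept + total_log_likelihood(tr, adat)
  }
  pct <- abs(approx - exact) / abs(exact) * 100
  structure(list(
    r_squared = stats::cor(exact, approx)^2,
    spearman_rho = stats::cor(exact, approx, method = "spearman"),
    mean_pct_error = mean(pct), sd_pct_error = stats::sd(pct),
    n_trees = n,
    per_tree = data.frame(tree_id = seq_len(n), exact_ll = exact,
                          approx_ll = approx, pct_error = pct)
  ), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(
    "accuracy_report (%d trees): r2 %.4f, spearman %.4f, %%err %.4g +/- %.4g\n",
    x$n_trees, x$r_squared, x$spearman_rho, x$mean_pct_error,
    x$sd_pct_error))
  invisible(x)
}

#' Write a per-tree accuracy table as TSV
#' @param report an `accuracy_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_accuracy_tsv <- function(report, path) {
  utils::write.table(report$per_tree, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Uniform random site sample (naive baseline)
#'
#' `floor(zeta * m)` sites drawn uniformly without replacement, each with
#' weight `m / tau` (uniform inflation, an unbiased estimator of the total
#' log-likelihood) and zero intercept.
#'
#' @param m number of alignment sites.
#' @param zeta sampling fraction in (0, 1].
#' @param rng_seed integer seed.
#' @return a `lasso_sample`.
#' @export
random_site_sample <- function(m, zeta, rng_seed) {
  tau <- max(1L, floor(zeta * m))
  sites <- .with_seed(rng_seed, "random-sites",
                      sort(sample.int(m, tau)))
  structure(list(sites = sites, weights = rep(m / tau, tau), intercept = 0,
                 lambda = NA_real_, zeta_target = zeta,
                 zeta_achieved = tau / m, m = m,
                 meta = list(baseline = "random", seed = rng_seed)),
            class = "lasso_sample")
}

#' Fastest-rate site sample (naive baseline)
#'
#' The `floor(zeta * m)` sites with the highest standardized evolutionary
#' rate, ties broken by site index; weights `m / tau`, zero intercept.
#'
#' @param rates a `site_rates` object (see [site_rates_empirical_bayes()]).
#' @param m number of alignment sites.
#' @param zeta sampling fraction in (0, 1].
#' @return a `lasso_sample`.
#' @export
rate_based_sample <- function(rates, m, zeta) {
  if (length(rates$standardized) != m)
    stop("rates length does not match m", call. = FALSE)
  tau <- max(1L, floor(zeta * m))
  ord <- order(-rates$standardized, seq_len(m))
  sites <- sort(ord[seq_len(tau)])
  structure(list(sites = sites, weights = rep(m / tau, tau), intercept = 0,
                 lambda = NA_real_, zeta_target = zeta,
                 zeta_achieved = tau / m, m = m,
                 meta = list(baseline = "rate")),
            class = "lasso_sample")
}
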