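test_that("per-site log-likelihoods match the exhaustive ancestral-state oracle", {
  for (seed in 1:8) {
    inst <- random_oracle_instance(seed)
    mine <- site_log_likelihoods(inst$tree, inst$aln, inst$model)
    oracle <- brute_site_ll(inst$tree, inst$aln, inst$model)
    expect_equal(as.vector(mine), oracle, tolerance = 1e-8)
    expect_equal(attr(mine, "total"), sum(oracle), tolerance = 1e-8)
  }
})

test_that("likelihood engine agrees with phangorn on gamma-mixed models", {
  set.seed(77)
  tr <- draw_branch_lengths(random_stepwise_topology(paste0("t", 1:7), 3),
                            0.1, 4)
  aa <- random_alignment(7, 60, "aa", seed = 5)
  mod <- build_model("WAG", alpha = 0.7, k = 4)
  pd <- phangorn::phyDat(aa$mat, type = "AA")
  fit <- phangorn::pml(tr, pd, model = "WAG", k = 4, shape = 0.7)
  expect_equal(total_log_likelihood(tr, aa, mod), fit$logLik,
               tolerance = 1e-9)
  dna <- random_alignment(7, 80, "dna", seed = 6)
  mod2 <- build_model("GTR", alpha = 1.2, k = 4)
  pd2 <- phangorn::phyDat(dna$mat, type = "DNA")
  fit2 <- phangorn::pml(tr, pd2, model = "JC", k = 4, shape = 1.2)
  expect_equal(total_log_likelihood(tr, dna, mod2), fit2$logLik,
               tolerance = 1e-9)
})

test_that("two identical taxa at zero distance give ln(1/4) per site", {
  aln <- msa(matrix(c("a", "a"), 2, 1, dimnames = list(c("a", "b"), NULL)),
             "dna")
  ll <- site_log_likelihoods(two_taxon_tree(0, 0), aln, build_model("GTR"))
  expect_equal(as.vector(ll), log(0.25), tolerance = 1e-6)
})

test_that("the likelihood is invariant to virtual root placement", {
  inst <- random_oracle_instance(9)
  tr <- inst$tree
  base <- site_log_likelihoods(tr, inst$aln, inst$model)
  internals <- unique(tr$edge[, 1])
  for (node in internals) {
    rerooted <- ape::unroot(ape::root(tr, node = node, resolve.root = FALSE))
    rr <- site_log_likelihoods(rerooted, inst$aln, inst$model)
    expect_equal(as.vector(rr), as.vector(base), tolerance = 1e-10)
  }
})

test_that("totals are additive and pattern compression is exact", {
  inst <- random_oracle_instance(12)
  aln <- inst$aln
  ll <- site_log_likelihoods(inst$tree, aln, inst$model)
  expect_equal(attr(ll, "total"), sum(ll), tolerance = 1e-9)
  # duplicating every site doubles the total exactly
  dup <- msa(cbind(aln$mat, aln$mat), aln$alphabet)
  expect_equal(total_log_likelihood(inst$tree, dup, inst$model),
               2 * attr(ll, "total"), tolerance = 1e-9)
  # single-site alignment equals its per-site value
  one <- msa(aln$mat[, 1, drop = FALSE], aln$alphabet)
  expect_equal(total_log_likelihood(inst$tree, one, inst$model), ll[1],
               tolerance = 1e-10)
})

test_that("likelihood is invariant to taxon row order", {
  inst <- random_oracle_instance(15)
  aln <- inst$aln
  perm <- sample(n_taxa(aln))
  aln2 <- msa(aln$mat[perm, , drop = FALSE], aln$alphabet)
  expect_equal(total_log_likelihood(inst$tree, aln2, inst$model),
               total_log_likelihood(inst$tree, aln, inst$model),
               tolerance = 1e-10)
})

test_that("under JC the site likelihood depends only on the pattern class", {
  # permuting state labels within a column leaves the JC likelihood unchanged
  tr <- draw_branch_lengths(random_stepwise_topology(paste0("t", 1:5), 2),
                            0.2, 3)
  mod <- build_model("GTR")
  aln <- random_alignment(5, 20, "dna", seed = 31)
  ll <- site_log_likelihoods(tr, aln, mod)
  states <- c("a", "c", "g", "t")
  perm <- c(g = "t", t = "g", a = "c", c = "a")
  aln2 <- msa(matrix(perm[aln$mat], nrow(aln$mat),
                     dimnames = dimnames(aln$mat)), "dna")
  ll2 <- site_log_likelihoods(tr, aln2, mod)
  expect_equal(as.vector(ll2), as.vector(ll), tolerance = 1e-10)
})

test_that("branch-length optimization recovers the closed-form JC distance", {
  set.seed(8)
  m <- 2000
  p_diff <- 0.15
  s1 <- sample(c("a", "c", "g", "t"), m, replace = TRUE)
  s2 <- s1
  flip <- seq_len(round(p_diff * m))
  s2[flip] <- vapply(s1[flip], function(x)
    sample(setdiff(c("a", "c", "g", "t"), x), 1), "")
  aln <- msa(rbind(a = s1, b = s2), "dna")
  fit <- optimize_branch_lengths(two_taxon_tree(0.05, 0.05), aln,
                                 build_model("GTR"))
  d_hat <- sum(fit$edge.length)
  d_jc <- -3 / 4 * log(1 - 4 * p_diff / 3)
  expect_equal(d_hat, d_jc, tolerance = 1e-4)
})

test_that("branch-length optimization never decreases the log-likelihood", {
  for (seed in 1:12) {
    inst <- random_oracle_instance(seed + 40)
    before <- total_log_likelihood(inst$tree, inst$aln, inst$model)
    opt <- optimize_branch_lengths(inst$tree, inst$aln, inst$model)
    expect_gte(attr(opt, "loglik") + 1e-9, before)
    # re-optimizing a converged optimum changes little (ridged instances
    # can hit the sweep cap without converging; those are flagged)
    if (isTRUE(attr(opt, "converged"))) {
      opt2 <- suppressWarnings(optimize_branch_lengths(opt, inst$aln,
                                                       inst$model))
      expect_lt(abs(attr(opt2, "loglik") - attr(opt, "loglik")), 0.011)
    }
  }
})

test_that("branch-length optima agree with phangorn", {
  bundle <- dna_bundle(8, 500, seed = 61)
  aln <- bundle$alignment
  tr <- draw_branch_lengths(random_stepwise_topology(aln$taxa, 3), 0.1, 4)
  mine <- optimize_branch_lengths(tr, aln, bundle$model)
  pd <- phangorn::phyDat(aln$mat, type = "DNA")
  fit <- phangorn::pml(tr, pd, model = "JC", k = 4,
                       shape = bundle$model$alpha)
  fit <- phangorn::optim.pml(fit, optEdge = TRUE,
                             control = phangorn::pml.control(trace = 0))
  expect_equal(attr(mine, "loglik"), fit$logLik, tolerance = 0.05)
})

test_that("alpha estimation recovers the simulating shape", {
  tr <- draw_branch_lengths(
    random_stepwise_topology(paste0("t", 1:15), 71), 0.1, 72)
  mod <- build_model("GTR", alpha = 0.5, k = 4)
  aln <- simulate_alignment(tr, mod, 5000, 73)
  a <- estimate_alpha(tr, aln, mod, optimize_bl = TRUE)
  expect_gte(as.numeric(a), 0.4)
  expect_lte(as.numeric(a), 0.62)
})

test_that("alpha estimates maximize the likelihood against a grid scan", {
  bundle <- dna_bundle(6, 400, seed = 81, alpha = 0.7)
  aln <- bundle$alignment
  tr <- bundle$tree
  mod <- bundle$model
  a <- estimate_alpha(tr, aln, mod, optimize_bl = FALSE)
  grid <- exp(seq(log(0.05), log(20), length.out = 50))
  grid_ll <- vapply(grid, function(g)
    total_log_likelihood(tr, aln, update_model(mod, alpha = g)), 0)
  best <- grid[which.max(grid_ll)]
  ll_a <- total_log_likelihood(tr, aln, update_model(mod, alpha = as.numeric(a)))
  expect_gte(ll_a, max(grid_ll) - 0.02)
  # data simulated without rate heterogeneity push alpha to the
  # homogeneous (upper) region
  ctree <- draw_branch_lengths(
    random_stepwise_topology(paste0("t", 1:8), 5), 0.1, 6)
  hom <- build_model("GTR")              # single rate category
  haln <- simulate_alignment(ctree, hom, 2000, 7)
  ac <- estimate_alpha(ctree, haln, build_model("GTR", alpha = 1, k = 4),
                       optimize_bl = FALSE)
  expect_gte(as.numeric(ac), 50)
})

test_that("empirical-Bayes site rates rank variable sites above constant ones", {
  bundle <- dna_bundle(8, 400, seed = 91)
  aln <- bundle$alignment
  # force one constant and one saturated column
  aln$mat[, 1] <- "a"
  aln$mat[, 2] <- rep(c("a", "c", "g", "t"), 2)
  sr <- site_rates_empirical_bayes(bundle$tree, aln, bundle$model)
  expect_lt(sr$raw[1], sr$raw[2])
  expect_equal(mean(sr$standardized), 0, tolerance = 1e-10)
  expect_equal(sd(sr$standardized), 1, tolerance = 1e-10)
  # k = 1 degenerates to flagged zeros
  mod1 <- build_model("GTR")
  sr1 <- site_rates_empirical_bayes(bundle$tree, aln, mod1)
  expect_true(all(sr1$standardized == 0))
  expect_true(attr(sr1, "degenerate"))
})

test_that("site rates correlate with the simulating rates", {
  bm <- benchmark_bundle()
  sr <- benchmark_rates()
  rho <- cor(sr$raw, bm$true_rates, method = "spearman")
  expect_gte(rho, 0.7)
})

test_that("weighted evaluation matches manual weighting and the TSV survives a round trip", {
  inst <- random_oracle_instance(24)
  ll <- site_log_likelihoods(inst$tree, inst$aln, inst$model)
  sites <- c(1L, 2L)
  w <- c(0.5, 2.25)
  dat <- ll_data(inst$aln, inst$model, sites = sites, site_weights = w)
  expect_equal(total_log_likelihood(inst$tree, dat),
               sum(w * ll[sites]), tolerance = 1e-9)
  smp <- structure(list(sites = sites, weights = w, intercept = 1.5, m = 4),
                   class = "lasso_sample")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_site_weights_tsv(smp, f)
  back <- read_site_weights_tsv(f)
  expect_equal(back$site, sites)
  expect_equal(back$weight, w)
  X <- rbind(ll, ll + 1)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_site_ll_tsv(X, f2)
  tab <- read.table(f2, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 2 * length(ll))
  expect_equal(tab$ll[tab$tree_id == 1], as.vector(ll))
})
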