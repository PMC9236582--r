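# Shared fixtures, built in code and memoized across test files.  Expensive
# objects (the benchmark bundle, optimized test trees, trained samples) are
# computed once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]]))
    .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# tiny helper: a phylo for n=2 taxa
two_taxon_tree <- function(t1, t2, labels = c("a", "b")) {
  structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                 edge.length = c(t1, t2), Nnode = 1L, tip.label = labels),
            class = "phylo")
}

random_alignment <- function(n, m, alphabet = "dna", seed = 1) {
  set.seed(seed)
  states <- if (alphabet == "dna") c("a", "c", "g", "t") else
    strsplit("arndcqeghilkmfpstwyv", "")[[1]]
  mat <- matrix(sample(states, n * m, replace = TRUE), n, m,
                dimnames = list(paste0("t", seq_len(n)), NULL))
  msa(mat, alphabet)
}

# 15-taxon WAG+G4 benchmark bundle (the standard study conditions at reduced
# scale), plus derived objects reused by several acceptance checks.
benchmark_bundle <- function() {
  fixture("benchmark", function() make_benchmark(seed = 1))
}

benchmark_training <- function(seed = 101) {
  fixture(paste0("training-", seed), function() {
    bm <- benchmark_bundle()
    build_training_set(bm$alignment, bm$model, eta = 200, rng_seed = seed)
  })
}

benchmark_sample <- function(seed = 101, zeta = 0.05) {
  fixture(paste0("sample-", seed, "-", zeta), function() {
    ts <- benchmark_training(seed)
    std <- standardize_design(ts)
    path <- fit_positive_lasso_path(std$X_std, std$y_centered,
                                    dropped = std$dropped)
    select_sample(path, zeta, std,
                  meta = list(eta = ts$eta, seed = seed))
  })
}

# 50 test trees with full-MSA ML branch lengths and their exact LLs
benchmark_test_trees <- function() {
  fixture("test-trees", function() {
    bm <- benchmark_bundle()
    dat <- ll_data(bm$alignment, bm$model)
    trees <- vector("list", 50)
    exact <- numeric(50)
    for (i in 1:50) {
      tr <- random_stepwise_topology(bm$alignment$taxa,
                                     derive_seed(7, paste0("test-", i)))
      tr <- draw_branch_lengths(tr, 0.1, derive_seed(7, paste0("tbl-", i)))
      tr <- optimize_branch_lengths(tr, dat)
      exact[i] <- attr(tr, "loglik")
      trees[[i]] <- tr
    }
    list(trees = trees, exact = exact)
  })
}

# empirical-Bayes site rates on the benchmark (parsimony tree, ML lengths)
benchmark_rates <- function() {
  fixture("rates", function() {
    bm <- benchmark_bundle()
    ptree <- parsimony_stepwise_tree(bm$alignment, 55)
    ptree <- draw_branch_lengths(ptree, 0.1, 56)
    ptree <- optimize_branch_lengths(ptree, ll_data(bm$alignment, bm$model))
    site_rates_empirical_bayes(ptree, bm$alignment, bm$model)
  })
}

# small DNA bundle for search tests
dna_bundle <- function(n_taxa, m, seed, bl_mean = 0.1, alpha = 0.8) {
  fixture(paste0("dna-", n_taxa, "-", m, "-", seed), function()
    make_benchmark(n_taxa = n_taxa, m = m, model_spec = "GTR+G",
                   alpha = alpha, bl_mean = bl_mean, seed = seed))
}

# ---- shared expensive protocol runs (used by module and acceptance tests) --

# 8-taxon topology recovery: standard search from 5 random starts
search8_recovery <- function() {
  fixture("search8-recovery", function() {
    bundle <- fixture("search8", function()
      make_benchmark(n_taxa = 8, m = 1000, model_spec = "GTR+G",
                     alpha = 0.8, seed = 42))
    aln <- bundle$alignment
    hits <- 0
    for (s in 1:5) {
      start <- draw_branch_lengths(
        random_stepwise_topology(aln$taxa, 100 + s), 0.1, 200 + s)
      res <- greedy_spr_search(start, aln, bundle$model, "full")
      if (phangorn::RF.dist(res$tree, bundle$tree) == 0) hits <- hits + 1
    }
    hits
  })
}

# 12-taxon standard vs two-phase comparison from a common start
search12_cmp <- function() {
  fixture("search12-cmp", function() {
    bundle <- fixture("search12", function()
      make_benchmark(n_taxa = 12, m = 4000, model_spec = "GTR+G",
                     alpha = 0.8, seed = 13))
    aln <- bundle$alignment; mod <- bundle$model
    smp <- fixture("search12-sample", function()
      train_lasso(aln, mod, eta = 300, zeta = 0.05, rng_seed = 77))
    start <- draw_branch_lengths(
      random_stepwise_topology(aln$taxa, 5), 0.1, 6)
    std <- greedy_spr_search(start, aln, mod, "full", radius = 5)
    twp <- two_phase_search(start, aln, mod, smp, radius = 5)
    list(std = std, twp = twp)
  })
}

# Two-partition simulated bundle plus both trained variants.  Each gene
# region has 2000 sites, the scale of the individual gene partitions in the
# partitioned analyses this emulates; the two regions differ strongly in
# rate heterogeneity.
two_part_bundle <- function() {
  fixture("two-part", function() {
    tr <- draw_branch_lengths(
      random_stepwise_topology(paste0("t", 1:10), 31), 0.1, 32)
    slow <- build_model("GTR", alpha = 0.3, k = 4)
    fast <- build_model("GTR", alpha = 3.0, k = 4)
    aln0 <- random_alignment(3, 4000, "dna", seed = 1)
    f <- tempfile()
    writeLines(c("GTR+G, slow = 1-2000", "GTR+G, fast = 2001-4000"), f)
    sch0 <- parse_partitions(f, aln0)
    aln <- simulate_alignment(tr, list(slow, fast), 4000, 33,
                              partition_scheme = sch0)
    list(tree = tr, aln = aln, scheme = sch0,
         true_models = list(slow, fast))
  })
}

two_part_cat <- function() {
  fixture("two-part-cat", function() {
    b <- two_part_bundle()
    train_concatenated(b$aln, b$scheme, eta = 200, zeta = 0.05,
                       rng_seed = 41)
  })
}

two_part_pp <- function() {
  fixture("two-part-pp", function() {
    b <- two_part_bundle()
    train_per_partition(b$aln, b$scheme, eta = 200, zeta = 0.05,
                        rng_seed = 41)
  })
}

# concatenated vs per-partition accuracy on shared random test trees
two_part_accuracy <- function() {
  fixture("two-part-acc", function() {
    b <- two_part_bundle()
    aln <- b$aln
    smp_cat <- two_part_cat()
    ps <- two_part_pp()
    models <- attr(smp_cat, "models")
    test_trees <- lapply(1:40, function(i)
      draw_branch_lengths(random_stepwise_topology(aln$taxa, 700 + i), 0.1,
                          800 + i))
    exact <- vapply(test_trees, function(tr)
      partition_total_ll(tr, aln, b$scheme, models), 0)
    approx_cat <- vapply(test_trees, function(tr)
      smp_cat$intercept + sum(vapply(seq_along(models), function(pid) {
        sel <- smp_cat$sites %in% which(b$scheme$site_partition == pid)
        if (!any(sel)) return(0)
        dat <- ll_data(aln, models[[pid]], sites = smp_cat$sites[sel],
                       site_weights = smp_cat$weights[sel])
        total_log_likelihood(tr, dat)
      }, 0)), 0)
    approx_pp <- vapply(test_trees, function(tr)
      partition_approximate_ll(tr, ps, aln), 0)
    list(r2_cat = cor(exact, approx_cat)^2,
         r2_pp = cor(exact, approx_pp)^2)
  })
}
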