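# Independent likelihood oracle: exhaustive summation over all ancestral
# (internal-node) state assignments, category by category.  Deliberately
# shares no code with the package's pruning engine.

brute_site_ll <- function(tree, aln, model) {
  ctr <- sitelasso:::alphabet_contrast(aln$alphabet)
  S <- length(sitelasso:::alphabet_states(aln$alphabet))
  E <- tree$edge
  len <- tree$edge.length
  ntip <- length(tree$tip.label)
  internals <- sort(unique(E[, 1]))
  root <- setdiff(internals, E[, 2])
  stopifnot(length(root) == 1)
  rates <- if (is.null(model$alpha)) 1 else
    discretize_gamma(model$alpha, model$k)$rates
  tipcode <- lapply(seq_len(ntip), function(i)
    ctr[match(aln$mat[match(tree$tip.label[i], aln$taxa), ],
              rownames(ctr)), , drop = FALSE])
  m <- n_sites(aln)
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), length(internals))))
  colnames(grid) <- as.character(internals)
  out <- numeric(m)
  for (site in seq_len(m)) {
    site_lik <- 0
    for (r in rates) {
      lik <- model$freq[grid[, as.character(root)]]
      for (ei in seq_len(nrow(E))) {
        P <- transition_probabilities(model, len[ei], r)
        par_states <- grid[, as.character(E[ei, 1])]
        ch <- E[ei, 2]
        if (ch <= ntip) {
          tv <- as.vector(P %*% tipcode[[ch]][site, ])
          lik <- lik * tv[par_states]
        } else {
          lik <- lik * P[cbind(par_states, grid[, as.character(ch)])]
        }
      }
      site_lik <- site_lik + sum(lik) / length(rates)
    }
    out[site] <- log(site_lik)
  }
  out
}

random_oracle_instance <- function(seed) {
  set.seed(seed)
  n <- sample(3:5, 1)
  m <- sample(2:10, 1)
  alphabet <- if (seed %% 3 == 0) "aa" else "dna"
  gamma <- seed %% 2 == 0
  mod <- if (alphabet == "dna")
    build_model("GTR", rates = runif(6, 0.3, 3), frequencies = "user",
                freq = as.vector(gtools_dirichlet(4)),
                alpha = if (gamma) runif(1, 0.3, 2) else NULL)
  else
    build_model(sample(c("WAG", "JTT", "LG"), 1),
                alpha = if (gamma) runif(1, 0.3, 2) else NULL)
  tr <- random_stepwise_topology(paste0("t", seq_len(n)), seed)
  tr <- draw_branch_lengths(tr, 0.15, seed + 1)
  aln <- random_alignment(n, m, alphabet, seed = seed + 2)
  # sprinkle ambiguity
  if (seed %% 4 == 0) aln$mat[1, 1] <- "-"
  list(tree = tr, aln = aln, model = mod)
}

# small dirichlet draw without extra dependencies
gtools_dirichlet <- function(k) {
  x <- rgamma(k, 2, 1)
  x / sum(x)
}
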