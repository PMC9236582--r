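# Sequence simulation along trees under the same substitution models the
# engine evaluates, and the deterministic benchmark bundle used throughout the
# test harness.
#
# Gamma rate variation in simulation uses the same discretized categories as
# inference (not the continuous gamma), so that rate- and alpha-recovery
# tests are free of discretization bias.

#' Simulate an alignment along a tree
#'
#' Root states are drawn from the stationary frequencies; each site draws a
#' gamma rate category uniformly (equal category probabilities); states evolve
#' edge by edge through the model's transition probabilities.  With a
#' partition scheme, each partition evolves under its own model.
#'
#' @param tree a `phylo` with branch lengths.
#' @param model a `subst_model`, or a list of models (one per partition) when
#'   `partition_scheme` is given.
#' @param m number of sites.
#' @param rng_seed integer seed.
#' @param partition_scheme optional `partition_scheme` over the `m` sites.
#' @return an [msa] with attributes `"true_rates"` (the per-site category
#'   rates actually used) and `"root_states"`.
#' @export
simulate_alignment <- function(tree, model, m, rng_seed,
                               partition_scheme = NULL) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree needs branch lengths",
                                      call. = FALSE)
  if (is.null(partition_scheme)) {
    models <- list(model)
    site_part <- rep(1L, m)
  } else {
    models <- if (inherits(model, "subst_model"))
      rep(list(model), nrow(partition_scheme$partitions)) else model
    site_part <- partition_scheme$site_partition
    if (length(site_part) != m)
      stop("partition scheme covers ", length(site_part),
           " sites but m = ", m, call. = FALSE)
  }
  alphabet <- models[[1]]$alphabet
  states <- alphabet_states(alphabet)
  S <- length(states)
  phy <- ape::reorder.phylo(tree, "postorder")
  E <- phy$edge; len <- phy$edge.length
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  root <- E[nrow(E), 1]
  .with_seed(rng_seed, "simulate-alignment", {
    rates <- numeric(m); node_state <- matrix(0L, nn, m)
    for (pi in seq_along(models)) {
      idx <- which(site_part == pi)
      if (length(idx) == 0) next
      mod <- models[[pi]]
      cat_rates <- .model_rates(mod)
      cat_draw <- sample.int(length(cat_rates), length(idx), replace = TRUE)
      rates[idx] <- cat_rates[cat_draw]
      node_state[root, idx] <- sample.int(S, length(idx), replace = TRUE,
                                          prob = mod$freq)
    }
    # preorder: parents before children
    for (ei in rev(seq_len(nrow(E)))) {
      par <- E[ei, 1]; ch <- E[ei, 2]
      for (pi in seq_along(models)) {
        idx <- which(site_part == pi)
        if (length(idx) == 0) next
        mod <- models[[pi]]
        ur <- sort(unique(rates[idx]))
        for (r in ur) {
          ii <- idx[rates[idx] == r]
          P <- transition_probabilities(mod, len[ei], r)
          ps <- node_state[par, ii]
          for (s in seq_len(S)) {
            sel <- ii[ps == s]
            if (length(sel))
              node_state[ch, sel] <- sample.int(S, length(sel),
                                                replace = TRUE, prob = P[s, ])
          }
        }
      }
    }
    mat <- matrix(states[node_state[seq_len(ntip), , drop = FALSE]],
                  ntip, m, dimnames = list(phy$tip.label, NULL))
    out <- msa(mat, alphabet = alphabet,
               partition_map = if (is.null(partition_scheme)) NULL
                               else site_part)
    attr(out, "true_rates") <- rates
    attr(out, "root_states") <- states[node_state[root, ]]
    out
  })
}

#' Deterministic synthetic benchmark bundle
#'
#' Generates a true tree (random stepwise-addition topology with exponential
#' branch lengths), simulates an alignment along it, and returns everything a
#' test protocol needs: alignment, true tree, true per-site rates and the
#' generating model.
#'
#' @param n_taxa number of taxa (default 15).
#' @param m number of sites (default 2000).
#' @param model_spec model string (default `"WAG+G4"`, the study model).
#' @param alpha gamma shape (default 0.93).
#' @param bl_mean exponential branch-length mean for the true tree.
#' @param seed integer root seed; the bundle is bitwise-reproducible from it.
#' @return list with `alignment`, `tree`, `true_rates`, `model`, `seed`.
#' @export
make_benchmark <- function(n_taxa = 15, m = 2000, model_spec = "WAG+G4",
                           alpha = 0.93, bl_mean = 0.1, seed = 1) {
  tree <- random_stepwise_topology(paste0("t", seq_len(n_taxa)),
                                   derive_seed(seed, "benchmark-topology"))
  tree <- draw_branch_lengths(tree, mean = bl_mean,
                              rng_seed = derive_seed(seed, "benchmark-bl"))
  model <- parse_model_spec(model_spec, alpha = alpha)
  aln <- simulate_alignment(tree, model, m,
                            rng_seed = derive_seed(seed, "benchmark-sim"))
  list(alignment = aln, tree = tree, true_rates = attr(aln, "true_rates"),
       model = model, seed = seed)
}
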