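# Unrooted binary trees: construction by stepwise addition (random and
# parsimony-guided), branch-length sampling, Newick I/O and SPR neighborhood
# enumeration with a rearrangement radius.
#
# Trees are ape "phylo" objects, stored unrooted with a virtual root at an
# arbitrary internal node; every likelihood is invariant to its placement
# (reversibility), which is a tested property rather than a representation
# detail.  Internally some operations use a flat edge list (tips 1..n,
# internal nodes > n, arbitrary ids).

# ---- edge-list <-> phylo ---------------------------------------------------

# DFS from `root` (an internal node id) over an edge list, renumbering
# internal nodes to the ape convention (root = n+1, preorder).
.edges_to_phylo <- function(E, len, labels, root = NULL) {
  n <- length(labels)
  maxid <- max(E)
  adj <- vector("list", maxid)
  for (i in seq_len(nrow(E))) {
    adj[[E[i, 1]]] <- c(adj[[E[i, 1]]], i)
    adj[[E[i, 2]]] <- c(adj[[E[i, 2]]], i)
  }
  if (is.null(root)) {
    ids <- unique(as.vector(E))
    root <- min(ids[ids > n])
  }
  newid <- integer(maxid)
  newid[seq_len(n)] <- seq_len(n)
  counter <- n
  k <- nrow(E)
  edge <- matrix(0L, k, 2)
  elen <- numeric(k)
  out <- 0L
  stack_node <- integer(k + 1); stack_edge <- integer(k + 1)
  stack_parent <- integer(k + 1)
  top <- 1L
  stack_node[1] <- root; stack_edge[1] <- 0L; stack_parent[1] <- 0L
  while (top > 0L) {
    node <- stack_node[top]; inc <- stack_edge[top]; par <- stack_parent[top]
    top <- top - 1L
    if (node > n) { counter <- counter + 1L; id <- counter }
    else id <- node
    newid[node] <- id
    if (par > 0L) {
      out <- out + 1L
      edge[out, ] <- c(par, id)
      elen[out] <- len[inc]
    }
    for (ei in adj[[node]]) {
      if (ei == inc) next
      nb <- if (E[ei, 1] == node) E[ei, 2] else E[ei, 1]
      top <- top + 1L
      stack_node[top] <- nb; stack_edge[top] <- ei; stack_parent[top] <- id
    }
  }
  structure(list(edge = edge, edge.length = elen,
                 Nnode = counter - n, tip.label = labels),
            class = "phylo")
}

.phylo_to_edges <- function(phy) {
  list(E = phy$edge,
       len = if (is.null(phy$edge.length)) numeric(nrow(phy$edge))
             else phy$edge.length,
       n = length(phy$tip.label), labels = phy$tip.label)
}

# Canonical topology signature: the sorted set of non-trivial splits, each
# written as the sorted leaf set on the side not containing leaf 1.
.topology_key <- function(E, n) {
  maxid <- max(E)
  adj <- vector("list", maxid)
  for (i in seq_len(nrow(E))) {
    adj[[E[i, 1]]] <- c(adj[[E[i, 1]]], i)
    adj[[E[i, 2]]] <- c(adj[[E[i, 2]]], i)
  }
  below <- vector("list", maxid)
  splits <- character(0)
  # postorder from leaf 1 as root: iterative DFS, children before parents
  order_node <- integer(0); order_inc <- integer(0)
  stack_node <- 1L; stack_inc <- 0L
  while (length(stack_node) > 0) {
    node <- stack_node[[length(stack_node)]]
    inc <- stack_inc[[length(stack_inc)]]
    stack_node <- stack_node[-length(stack_node)]
    stack_inc <- stack_inc[-length(stack_inc)]
    order_node <- c(order_node, node); order_inc <- c(order_inc, inc)
    for (ei in adj[[node]]) {
      if (ei == inc) next
      nb <- if (E[ei, 1] == node) E[ei, 2] else E[ei, 1]
      stack_node <- c(stack_node, nb); stack_inc <- c(stack_inc, ei)
    }
  }
  for (i in rev(seq_along(order_node))) {
    node <- order_node[i]; inc <- order_inc[i]
    kids <- integer(0)
    for (ei in adj[[node]]) {
      if (ei == inc) next
      nb <- if (E[ei, 1] == node) E[ei, 2] else E[ei, 1]
      kids <- c(kids, nb)
    }
    leaves <- if (node <= n && node != 1L) node else integer(0)
    for (kd in kids) leaves <- c(leaves, below[[kd]])
    leaves <- sort(leaves)
    below[[node]] <- leaves
    if (inc > 0 && length(leaves) >= 2 && length(leaves) <= n - 2)
      splits <- c(splits, paste(leaves, collapse = ","))
  }
  paste(sort(splits), collapse = ";")
}

#' Canonical topology signature of a tree
#'
#' Equal signatures iff the unrooted topologies are identical (RF distance 0).
#' @param tree a `phylo`.
#' @return character scalar.
#' @export
topology_key <- function(tree) {
  te <- .phylo_to_edges(tree)
  .topology_key(te$E, te$n)
}

# ---- tree generation -------------------------------------------------------

#' Random stepwise-addition topology
#'
#' Taxa are inserted in a uniformly shuffled order, each onto a uniformly
#' chosen existing edge (the sequential randomized stepwise addition order
#' scheme).  Branch lengths are left at 0; see [draw_branch_lengths()].
#'
#' @param taxa character vector of taxon names (>= 3).
#' @param rng_seed integer seed.
#' @return an unrooted binary `phylo`.
#' @export
random_stepwise_topology <- function(taxa, rng_seed) {
  n <- length(taxa)
  if (n < 3) stop("need at least 3 taxa", call. = FALSE)
  .with_seed(rng_seed, "stepwise-topology", {
    ord <- sample.int(n)
    E <- matrix(c(n + 1L, ord[1], n + 1L, ord[2], n + 1L, ord[3]),
                ncol = 2, byrow = TRUE)
    nextid <- n + 1L
    for (i in seq(4, length.out = max(0, n - 3))) {
      ei <- sample.int(nrow(E), 1L)
      nextid <- nextid + 1L
      a <- E[ei, 1]; b <- E[ei, 2]
      E[ei, ] <- c(a, nextid)
      E <- rbind(E, c(nextid, b), c(nextid, ord[i]))
    }
    .edges_to_phylo(E, numeric(nrow(E)), taxa)
  })
}

#' Draw i.i.d. exponential branch lengths
#'
#' @param tree a `phylo`.
#' @param mean exponential mean (default 0.1 expected substitutions/site).
#' @param rng_seed integer seed.
#' @return the tree with new branch lengths.
#' @export
draw_branch_lengths <- function(tree, mean = 0.1, rng_seed) {
  if (!is.numeric(mean) || mean <= 0)
    stop("branch-length mean must be positive", call. = FALSE)
  .with_seed(rng_seed, "branch-lengths", {
    tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 1 / mean)
    tree
  })
}

# ---- Fitch parsimony -------------------------------------------------------

# Bitmask encoding of a pattern alignment: per taxon, an integer vector over
# patterns; bit s set iff state s is compatible with the character.
.fitch_masks <- function(pat) {
  ctr <- alphabet_contrast(pat$alphabet)
  bits <- 2 ^ (seq_len(ncol(ctr)) - 1)
  code_mask <- as.integer(ctr %*% bits)
  names(code_mask) <- rownames(ctr)
  lapply(seq_len(nrow(pat$patterns)), function(i)
    unname(code_mask[pat$patterns[i, ]]))
}

# Weighted Fitch score of an edge-list tree.
.fitch_score <- function(E, n, masks, weights) {
  maxid <- max(E)
  adj <- vector("list", maxid)
  for (i in seq_len(nrow(E))) {
    adj[[E[i, 1]]] <- c(adj[[E[i, 1]]], i)
    adj[[E[i, 2]]] <- c(adj[[E[i, 2]]], i)
  }
  ids <- unique(as.vector(E))
  root <- min(ids[ids > n])
  order_node <- integer(0); order_inc <- integer(0)
  stack_node <- root; stack_inc <- 0L
  while (length(stack_node) > 0) {
    node <- stack_node[[length(stack_node)]]
    inc <- stack_inc[[length(stack_inc)]]
    stack_node <- stack_node[-length(stack_node)]
    stack_inc <- stack_inc[-length(stack_inc)]
    order_node <- c(order_node, node); order_inc <- c(order_inc, inc)
    for (ei in adj[[node]]) {
      if (ei == inc) next
      nb <- if (E[ei, 1] == node) E[ei, 2] else E[ei, 1]
      stack_node <- c(stack_node, nb); stack_inc <- c(stack_inc, ei)
    }
  }
  state <- vector("list", maxid)
  score <- 0
  for (i in rev(seq_along(order_node))) {
    node <- order_node[i]; inc <- order_inc[i]
    if (node <= n) { state[[node]] <- masks[[node]]; next }
    cur <- NULL
    for (ei in adj[[node]]) {
      if (ei == inc) next
      nb <- if (E[ei, 1] == node) E[ei, 2] else E[ei, 1]
      cs <- state[[nb]]
      if (is.null(cur)) { cur <- cs; next }
      inter <- bitwAnd(cur, cs)
      miss <- inter == 0L
      if (any(miss)) {
        score <- score + sum(weights[miss])
        inter[miss] <- bitwOr(cur[miss], cs[miss])
      }
      cur <- inter
    }
    state[[node]] <- cur
  }
  score
}

#' Maximum-parsimony stepwise-addition tree
#'
#' Taxa are added in a randomized order; each taxon is attached at the edge
#' minimizing the (weighted) Fitch parsimony score, ties broken by edge order.
#'
#' @param aln an [msa].
#' @param rng_seed integer seed controlling the addition order.
#' @return an unrooted binary `phylo` with zero branch lengths and attribute
#'   `"parsimony_score"` (the final Fitch score).
#' @export
parsimony_stepwise_tree <- function(aln, rng_seed) {
  n <- n_taxa(aln)
  if (n < 3) stop("need at least 3 taxa", call. = FALSE)
  pat <- compress_patterns(aln)
  masks <- .fitch_masks(pat)
  w <- pat$pattern_weights
  .with_seed(rng_seed, "parsimony-stepwise", {
    ord <- sample.int(n)
    E <- matrix(c(n + 1L, ord[1], n + 1L, ord[2], n + 1L, ord[3]),
                ncol = 2, byrow = TRUE)
    nextid <- n + 1L
    for (i in seq(4, length.out = max(0, n - 3))) {
      tip <- ord[i]
      best <- Inf; bestE <- 1L
      for (ei in seq_len(nrow(E))) {
        a <- E[ei, 1]; b <- E[ei, 2]
        Ecand <- rbind(E[-ei, , drop = FALSE],
                       c(a, nextid + 1L), c(nextid + 1L, b),
                       c(nextid + 1L, tip))
        sc <- .fitch_score(Ecand, n, masks, w)
        if (sc < best) { best <- sc; bestE <- ei }
      }
      a <- E[bestE, 1]; b <- E[bestE, 2]
      nextid <- nextid + 1L
      E[bestE, ] <- c(a, nextid)
      E <- rbind(E, c(nextid, b), c(nextid, tip))
    }
    phy <- .edges_to_phylo(E, numeric(nrow(E)), aln$taxa)
    attr(phy, "parsimony_score") <- .fitch_score(E, n, masks, w)
    phy
  })
}

#' Fitch parsimony score of a tree
#' @param tree a `phylo` over the alignment's taxa.
#' @param aln an [msa].
#' @return weighted Fitch score (numeric).
#' @export
parsimony_score <- function(tree, aln) {
  pat <- compress_patterns(aln)
  ord <- match(tree$tip.label, aln$taxa)
  if (anyNA(ord)) stop("tree taxa not in alignment", call. = FALSE)
  masks <- .fitch_masks(pat)[ord]
  te <- .phylo_to_edges(tree)
  .fitch_score(te$E, te$n, masks, pat$pattern_weights)
}

# ---- SPR neighborhood ------------------------------------------------------

#' Enumerate SPR neighbors within a rearrangement radius
#'
#' A subtree is pruned at a directed edge and regrafted onto an edge of the
#' remaining tree whose rearrangement distance from the pruning point does not
#' exceed `max_distance` (distance 1 = edges adjacent to the merged edge, so
#' `max_distance = 1` yields exactly the NNI neighborhood).  Regrafting onto
#' the merged edge (a topological no-op) is excluded, and duplicate topologies
#' are removed; enumeration order is deterministic (edge order for pruning,
#' then increasing distance for regrafting).
#'
#' Lazy branch-length rule: the regraft target edge is split in half, the
#' pruned subtree keeps its branch length, and the two edges merged by the
#' pruning are summed, so total tree length is unchanged.
#'
#' @param tree an unrooted binary `phylo` with branch lengths (n >= 4).
#' @param max_distance rearrangement radius (default 5), or `Inf`.
#' @return list of entries `list(move = list(prune_edge, regraft_edge,
#'   distance), tree = phylo)`; `prune_edge`/`regraft_edge` are rows of
#'   `tree$edge` (prune direction: the subtree below the second node).
#' @export
spr_neighbors <- function(tree, max_distance = 5) {
  te <- .phylo_to_edges(tree)
  E <- te$E; len <- te$len; n <- te$n
  if (n < 4) stop("SPR needs at least 4 taxa", call. = FALSE)
  nedge <- nrow(E)
  maxid <- max(E)
  adj <- vector("list", maxid)
  for (i in seq_len(nedge)) {
    adj[[E[i, 1]]] <- c(adj[[E[i, 1]]], i)
    adj[[E[i, 2]]] <- c(adj[[E[i, 2]]], i)
  }
  deg <- lengths(adj)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- list()
  for (ei in seq_len(nedge)) {
    for (dir in 1:2) {
      u <- E[ei, dir]; v <- E[ei, 3 - dir]
      if (deg[u] != 3) next  # pruning point must be internal
      rest <- setdiff(adj[[u]], ei)
      e1 <- rest[1]; e2 <- rest[2]
      a <- if (E[e1, 1] == u) E[e1, 2] else E[e1, 1]
      b <- if (E[e2, 1] == u) E[e2, 2] else E[e2, 1]
      mlen <- len[e1] + len[e2]
      # BFS edge-distances from a (resp. b) on its own side; the pruned side
      # and the merged edge are never crossed.
      dists <- function(start, blocked) {
        d <- rep(NA_integer_, maxid); d[start] <- 0L
        queue <- start
        while (length(queue) > 0) {
          x <- queue[[1]]; queue <- queue[-1]
          for (ee in adj[[x]]) {
            if (ee == ei || ee == e1 || ee == e2) next
            y <- if (E[ee, 1] == x) E[ee, 2] else E[ee, 1]
            if (y == blocked || !is.na(d[y])) next
            d[y] <- d[x] + 1L
            queue <- c(queue, y)
          }
        }
        d
      }
      da <- dists(a, u); db <- dists(b, u)
      # candidate regraft edges with their rearrangement distance
      cand <- integer(0); cd <- integer(0)
      dval <- function(d, node) if (is.na(d[node])) Inf else d[node]
      for (ee in seq_len(nedge)) {
        if (ee == ei || ee == e1 || ee == e2) next
        x <- E[ee, 1]; y <- E[ee, 2]
        dd <- 1 + min(dval(da, x), dval(db, x), dval(da, y), dval(db, y))
        if (!is.finite(dd) || dd > max_distance) next
        cand <- c(cand, ee); cd <- c(cd, as.integer(dd))
      }
      if (length(cand) == 0) next
      ordc <- order(cd, cand)
      for (ci in ordc) {
        ee <- cand[ci]
        x <- E[ee, 1]; y <- E[ee, 2]
        keep <- setdiff(seq_len(nedge), c(e1, e2, ee))
        E2 <- rbind(E[keep, , drop = FALSE],
                    c(a, b), c(x, u), c(u, y))
        len2 <- c(len[keep], mlen, len[ee] / 2, len[ee] / 2)
        key <- .topology_key(E2, n)
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- list(
          move = list(prune_edge = c(u, v), regraft_edge = c(x, y),
                      distance = cd[ci]),
          tree = .edges_to_phylo(E2, len2, te$labels))
      }
    }
  }
  out
}

#' Read / write multi-tree Newick files (one tree per line)
#' @param path file path.
#' @return for `read_trees`, a list of `phylo` objects.
#' @export
read_trees <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "phylo")) list(tr) else unclass(tr)
}

#' @rdname read_trees
#' @param trees a `phylo` or list of `phylo` objects.
#' @export
write_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, file = path, digits = 12)
  invisible(path)
}
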