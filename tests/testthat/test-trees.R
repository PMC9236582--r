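test_that("random stepwise topologies are valid unrooted binary trees", {
  expect_error(random_stepwise_topology(c("a", "b"), 1), "3 taxa")
  t3 <- random_stepwise_topology(c("a", "b", "c"), 1)
  expect_equal(nrow(t3$edge), 3)        # the unique 3-taxon topology
  for (n in c(5, 9, 14)) {
    tr <- random_stepwise_topology(paste0("t", 1:n), n)
    expect_equal(nrow(tr$edge), 2 * n - 3)
    expect_equal(sort(tr$tip.label), sort(paste0("t", 1:n)))
    expect_true(ape::is.binary(tr))
  }
  # determinism
  expect_identical(topology_key(random_stepwise_topology(paste0("t", 1:8), 5)),
                   topology_key(random_stepwise_topology(paste0("t", 1:8), 5)))
})

test_that("4-taxon stepwise addition is uniform over the 3 topologies", {
  keys <- vapply(1:3000, function(s)
    topology_key(random_stepwise_topology(paste0("t", 1:4), s)), "")
  counts <- table(keys)
  expect_equal(length(counts), 3)
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("branch lengths are exponential with the requested mean", {
  big <- random_stepwise_topology(paste0("t", 1:10), 1)
  draws <- unlist(lapply(1:600, function(s)
    draw_branch_lengths(big, 0.1, s)$edge.length))
  expect_gt(length(draws), 10000)
  expect_gt(mean(draws), 0.097)
  expect_lt(mean(draws), 0.103)
  expect_identical(draw_branch_lengths(big, 0.1, 7)$edge.length,
                   draw_branch_lengths(big, 0.1, 7)$edge.length)
  expect_error(draw_branch_lengths(big, 0, 1), "positive")
})

test_that("newick round trip preserves topology and branch lengths", {
  tr <- draw_branch_lengths(random_stepwise_topology(paste0("t", 1:9), 3),
                            0.1, 4)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_trees(tr, f)
  back <- read_trees(f)[[1]]
  expect_equal(phangorn::RF.dist(tr, back), 0)
  o <- order(tr$edge.length); ob <- order(back$edge.length)
  expect_equal(sort(tr$edge.length), sort(back$edge.length),
               tolerance = 1e-10)
})

test_that("parsimony stepwise addition beats random topologies on Fitch score", {
  bundle <- dna_bundle(6, 300, seed = 33, bl_mean = 0.25)
  aln <- bundle$alignment
  wins <- 0
  for (s in 1:20) {
    pt <- parsimony_stepwise_tree(aln, s)
    rt <- random_stepwise_topology(aln$taxa, s + 1000)
    sp <- parsimony_score(pt, aln)
    sr <- parsimony_score(rt, aln)
    expect_lte(sp, sr)
    expect_equal(sp, attr(pt, "parsimony_score"))
  }
  # constant alignment: any topology scores 0
  cmat <- matrix("a", 4, 10, dimnames = list(paste0("t", 1:4), NULL))
  ct <- parsimony_stepwise_tree(msa(cmat, "dna"), 1)
  expect_s3_class(ct, "phylo")
  expect_equal(attr(ct, "parsimony_score"), 0)
})

test_that("parsimony stepwise addition recovers a strong-signal topology", {
  # long internal edges, short tips: near-perfect signal
  true <- ape::read.tree(text =
    "((a:0.05,b:0.05):0.4,(c:0.05,d:0.05):0.4,(e:0.05,f:0.05):0.4);")
  mod <- build_model("GTR")
  hits <- 0
  for (s in 1:10) {
    aln <- simulate_alignment(true, mod, 1000, 500 + s)
    pt <- parsimony_stepwise_tree(aln, s)
    if (phangorn::RF.dist(pt, true) == 0) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("parsimony scores agree with the phangorn oracle", {
  bundle <- dna_bundle(7, 120, seed = 44)
  aln <- bundle$alignment
  pd <- phangorn::phyDat(aln$mat, type = "DNA")
  for (s in 1:5) {
    tr <- random_stepwise_topology(aln$taxa, s)
    expect_equal(parsimony_score(tr, aln),
                 phangorn::parsimony(tr, pd, method = "fitch"))
  }
})

test_that("SPR neighborhoods have the known sizes and equal NNI at radius 1", {
  t4 <- draw_branch_lengths(random_stepwise_topology(paste0("t", 1:4), 1),
                            0.1, 2)
  expect_equal(length(spr_neighbors(t4, Inf)), 2)
  t5 <- draw_branch_lengths(random_stepwise_topology(paste0("t", 1:5), 1),
                            0.1, 2)
  expect_equal(length(spr_neighbors(t5, Inf)), 12)  # 2(n-3)(2n-7)
  for (n in c(6, 8)) {
    tr <- draw_branch_lengths(random_stepwise_topology(paste0("t", 1:n), n),
                              0.1, n + 1)
    expect_equal(length(spr_neighbors(tr, Inf)), 2 * (n - 3) * (2 * n - 7))
    nb1 <- spr_neighbors(tr, 1)
    expect_equal(length(nb1), 2 * (n - 3))          # NNI count
    nni_keys <- sort(unique(vapply(phangorn::nni(tr), topology_key, "")))
    my_keys <- sort(vapply(nb1, function(x) topology_key(x$tree), ""))
    expect_identical(my_keys, nni_keys)
  }
})

test_that("every SPR neighbor changes the topology and conserves tree length", {
  tr <- draw_branch_lengths(random_stepwise_topology(paste0("t", 1:8), 2),
                            0.1, 3)
  key0 <- topology_key(tr)
  nbs <- spr_neighbors(tr, 5)
  expect_gt(length(nbs), 0)
  for (x in nbs) {
    expect_false(identical(topology_key(x$tree), key0))
    expect_gt(phangorn::RF.dist(x$tree, tr), 0)
    expect_equal(sum(x$tree$edge.length), sum(tr$edge.length),
                 tolerance = 1e-12)
    expect_equal(nrow(x$tree$edge), nrow(tr$edge))
    expect_lte(x$move$distance, 5)
  }
})

test_that("SPR moves are invertible", {
  tr <- draw_branch_lengths(random_stepwise_topology(paste0("t", 1:7), 9),
                            0.1, 10)
  key0 <- topology_key(tr)
  nbs <- spr_neighbors(tr, Inf)
  for (x in nbs[seq(1, length(nbs), by = 4)]) {
    back_keys <- vapply(spr_neighbors(x$tree, Inf),
                        function(y) topology_key(y$tree), "")
    expect_true(key0 %in% back_keys)
  }
})
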