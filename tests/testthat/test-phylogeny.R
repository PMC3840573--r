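test_that("K2P distance reduces to its closed form on pure-transition and pure-transversion pairs", {
  # one transition among 4 sites: P = 1/4, Q = 0
  d <- pairwise_distance(c(a = "AAAA", b = "GAAA"))
  expect_equal(d["a", "b"], -0.5 * log(0.5), tolerance = 1e-12)
  # one transversion among 4 sites: P = 0, Q = 1/4
  d <- pairwise_distance(c(a = "AAAA", b = "CAAA"))
  expect_equal(d["a", "b"], -0.5 * log(0.75) - 0.25 * log(0.5), tolerance = 1e-12)
})

test_that("Jukes-Cantor distance matches its closed form", {
  d <- pairwise_distance(c(a = "AAAA", b = "GAAA"), model = "jc")
  expect_equal(d["a", "b"], -0.75 * log(1 - (4 / 3) * 0.25), tolerance = 1e-12)
})

test_that("gapped and ambiguous columns are pairwise-deleted, not counted as differences", {
  d <- pairwise_distance(c(a = "AG-AN", b = "AAAAA"))
  # usable columns: 1, 2, 4 -> one transition among 3
  expect_equal(d["a", "b"],
               -0.5 * log(1 - 2 / 3), tolerance = 1e-12)
  expect_error(pairwise_distance(c(a = "----A", b = "AAAA-")), "no shared")
})

test_that("saturated pairs are an error naming the offending sequences", {
  expect_error(pairwise_distance(c(x1 = "ACGTACGT", x2 = "GTACGTAC")),
               "saturated.*x1.*x2")
})

test_that("distances agree with an independent reference implementation", {
  set.seed(31)
  base <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  aln <- c(s1 = base,
           s2 = mutate_sequence(base, 20),
           s3 = mutate_sequence(base, 35))
  bin <- ape::as.DNAbin(t(sapply(strsplit(tolower(aln), ""), identity)))
  expect_equal(
    unclass(pairwise_distance(aln, "k2p"))[lower.tri(diag(3))],
    unclass(as.matrix(ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE)))[lower.tri(diag(3))],
    tolerance = 1e-10)
  expect_equal(
    unclass(pairwise_distance(aln, "jc"))[lower.tri(diag(3))],
    unclass(as.matrix(ape::dist.dna(bin, model = "JC69", pairwise.deletion = TRUE)))[lower.tri(diag(3))],
    tolerance = 1e-10)
})

test_that("neighbor joining solves the 3-taxon star exactly", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  got <- ape::cophenetic.phylo(tr)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(got, d, tolerance = 1e-9)
})

test_that("neighbor joining recovers topology and path lengths from random additive matrices", {
  set.seed(7)
  for (rep in 1:100) {
    gen <- random_additive_matrix(sample(4:8, 1))
    est <- nj_tree(gen$d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(gen$tree), est)), 0)
    got <- ape::cophenetic.phylo(est)
    got <- got[rownames(gen$d), colnames(gen$d)]
    expect_equal(got, gen$d, tolerance = 1e-6)
  }
})

test_that("neighbor joining is deterministic under input permutation even with tied joins", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  ref <- ape::write.tree(nj_tree(d))
  set.seed(5)
  for (rep in 1:5) {
    p <- sample(4)
    expect_identical(ape::write.tree(nj_tree(d[p, p])), ref)
  }
})

test_that("bootstrap replicates are reproducible and leave the caller's RNG stream untouched", {
  set.seed(12)
  base <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
  aln <- c(a = base, b = mutate_sequence(base, 6),
           c = mutate_sequence(base, 14), d = mutate_sequence(base, 20))
  set.seed(77); after_plain <- runif(1)
  set.seed(77)
  b1 <- bootstrap_trees(aln, 10, seed = 3)
  after_boot <- runif(1)
  expect_identical(after_boot, after_plain)
  b2 <- bootstrap_trees(aln, 10, seed = 3)
  expect_identical(vapply(b1, ape::write.tree, character(1)),
                   vapply(b2, ape::write.tree, character(1)))
})

test_that("majority-rule consensus keeps only bipartitions in a strict majority", {
  t_ab <- ape::read.tree(text = "((a,b),(c,d));")
  t_ac <- ape::read.tree(text = "((a,c),(b,d));")
  cons <- majority_consensus(list(t_ab, t_ab, t_ab, t_ac))
  expect_identical(cons$supports$bipartition, "c|d")
  expect_equal(cons$supports$support, 75)
  # an even split (exactly 50%) is excluded on both sides -> star tree
  star <- majority_consensus(list(t_ab, t_ab, t_ac, t_ac))
  expect_identical(nrow(star$supports), 0L)
  expect_identical(star$tree$Nnode, 1L)
})

test_that("consensus is invariant to the order of the input trees", {
  set.seed(41)
  base <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  aln <- c(a = base, b = mutate_sequence(base, 8), c = mutate_sequence(base, 20),
           d = mutate_sequence(base, 30), e = mutate_sequence(base, 40))
  reps <- bootstrap_trees(aln, 25, seed = 9)
  c1 <- majority_consensus(reps)
  c2 <- majority_consensus(rev(reps))
  expect_identical(c1$supports[order(c1$supports$bipartition), ],
                   c2$supports[order(c2$supports$bipartition), ])
  expect_equal(as.numeric(ape::dist.topo(c1$tree, c2$tree)), 0)
})

test_that("support mapped on a best tree equals the replicate bipartition frequencies", {
  set.seed(55)
  base <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  aln <- c(a = base, b = mutate_sequence(base, 5), c = mutate_sequence(base, 30),
           d = mutate_sequence(base, 33), e = mutate_sequence(base, 60))
  best <- nj_tree(pairwise_distance(aln))
  reps <- bootstrap_trees(aln, 40, seed = 2)
  mp <- map_support(best, reps, hide_below = 50)
  expect_identical(nrow(mp$supports), 2L)  # 5 taxa -> 2 internal bipartitions
  # exact supports kept even when masked in labels
  for (i in seq_len(nrow(mp$supports))) {
    key <- mp$supports$bipartition[i]
    side <- strsplit(key, "|", fixed = TRUE)[[1]]
    freq <- 100 * mean(vapply(reps, function(t) {
      # independent check: is there an edge splitting exactly this leaf set?
      n <- length(t$tip.label)
      any(vapply(setdiff(unique(t$edge[, 2]), seq_len(n)), function(nd) {
        tips <- ape::extract.clade(t, nd)$tip.label
        setequal(tips, side) || setequal(setdiff(t$tip.label, tips), side)
      }, logical(1)))
    }, logical(1)))
    expect_equal(mp$supports$support[i], freq, tolerance = 1e-9)
  }
  # labels below the threshold are masked, values preserved
  lab_nodes <- mp$supports$node[mp$supports$support >= 50]
  lab <- mp$tree$node.label[lab_nodes - length(best$tip.label)]
  expect_true(all(nzchar(lab)))
  hidden <- mp$supports$node[mp$supports$support < 50]
  if (length(hidden) > 0L) {
    expect_true(all(mp$tree$node.label[hidden - length(best$tip.label)] == ""))
  }
})
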