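# Shared fixtures and independent oracles used across the test files.

fixture_tree <- function() {
  read_dated_tree(system.file("extdata", "mammal_dated_tree.nwk",
                              package = "retrotrace"))
}

fixture_presence <- function() {
  read_presence_matrix(system.file("extdata", "ppp1r2_presence.tsv",
                                   package = "retrotrace"))
}

fixture_peptides <- function() {
  read_peptide_table(system.file("extdata", "ppp1r2p9_sperm_peptides.tsv",
                                 package = "retrotrace"))
}

presence_vector <- function(tree, carriers, absent_default = 0) {
  p <- setNames(rep(absent_default, tree$n_tips), tree$phylo$tip.label)
  p[carriers] <- 1
  p
}

# --- independent oracles -----------------------------------------------------

# Dollo origin by exhaustive search: the node with the smallest clade that
# still contains every carrier.
dollo_oracle_node <- function(phy, carriers) {
  n <- length(phy$tip.label)
  nodes <- c(seq_len(n), n + seq_len(phy$Nnode))
  clades <- lapply(nodes, function(nd) {
    if (nd <= n) phy$tip.label[nd] else ape::extract.clade(phy, nd)$tip.label
  })
  ok <- vapply(clades, function(cl) all(carriers %in% cl), logical(1))
  sizes <- vapply(clades, length, integer(1))
  sizes[!ok] <- Inf
  nodes[which.min(sizes)]
}

# minimal number of disjoint subtrees below `origin` whose tips are exactly
# the absent set, by exhaustive subset search (small trees only)
min_loss_count_oracle <- function(phy, origin, absent) {
  n <- length(phy$tip.label)
  below <- setdiff(ape::prop.part(phy)[[1]], integer(0))  # placeholder
  # nodes strictly below origin
  all_nodes <- c(seq_len(n), n + seq_len(phy$Nnode))
  desc_tips <- lapply(all_nodes, function(nd) {
    if (nd <= n) phy$tip.label[nd] else ape::extract.clade(phy, nd)$tip.label
  })
  origin_tips <- desc_tips[[origin]]
  cand <- all_nodes[vapply(all_nodes, function(nd) {
    nd != origin && all(desc_tips[[nd]] %in% origin_tips)
  }, logical(1))]
  if (length(absent) == 0L) return(0L)
  best <- Inf
  k_max <- min(length(cand), length(absent))
  for (k in 1:k_max) {
    for (comb in utils::combn(length(cand), k, simplify = FALSE)) {
      tips <- unlist(desc_tips[cand[comb]])
      if (length(tips) == length(unique(tips)) && setequal(tips, absent)) {
        best <- min(best, k)
      }
    }
    if (is.finite(best)) break  # combinations scanned in increasing size
  }
  best
}

# Fitch parsimony minimum by brute force over all internal-node assignments
fitch_oracle_count <- function(phy, tip_states) {
  n <- length(phy$tip.label)
  internals <- n + seq_len(phy$Nnode)
  bases <- c("A", "C", "G", "T")
  grids <- do.call(expand.grid, rep(list(bases), length(internals)))
  best <- Inf
  for (g in seq_len(nrow(grids))) {
    assign <- c(tip_states[phy$tip.label], as.character(unlist(grids[g, ])))
    names(assign) <- NULL
    cost <- sum(assign[phy$edge[, 1]] != assign[phy$edge[, 2]])
    best <- min(best, cost)
  }
  best
}

# random additive distance matrix from a random tree; returns both
random_additive_matrix <- function(n_taxa) {
  phy <- ape::rtree(n_taxa, br = function(k) runif(k, 0.05, 1))
  d <- ape::cophenetic.phylo(phy)
  taxa <- sort(rownames(d))
  list(tree = phy, d = d[taxa, taxa])
}

# apply a fixed number of random substitutions to a sequence
mutate_sequence <- function(seq, n_subst) {
  chars <- strsplit(seq, "")[[1]]
  idx <- sample.int(length(chars), n_subst)
  for (i in idx) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}
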