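#' @name phylogeny
#' @title Distance phylogenies with bootstrap support
#'
#' @description
#' A fully deterministic distance pipeline for pseudogene alignments:
#' Kimura two-parameter (or Jukes-Cantor) distances with pairwise deletion of
#' gap columns, neighbor-joining with a documented lexicographic tie-break,
#' nonparametric bootstrap over alignment columns, strict majority-rule
#' consensus, and mapping of bipartition support onto a best tree.  Trees are
#' `ape::phylo` objects throughout.
NULL

.VALID_BASES <- c("A", "C", "G", "T")
.PURINES <- c("A", "G")

# Split an alignment (named character vector, equal lengths) into a
# character matrix of upper-case bases.
.aln_matrix <- function(alignment) {
  if (is.null(names(alignment))) stop("alignment sequences must be named")
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) stop("aligned sequences must have equal length")
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(mat) <- names(alignment)
  mat
}

#' Pairwise evolutionary distances from an alignment
#'
#' Distances are computed over the columns where both sequences carry an
#' unambiguous base (pairwise deletion).  Under the Kimura two-parameter
#' model, with transition proportion P and transversion proportion Q,
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`; under Jukes-Cantor,
#' `d = -3/4 log(1 - 4p/3)` with p the total difference proportion.
#'
#' @param alignment Named character vector of aligned sequences (gaps `-`).
#' @param model `"k2p"` (default) or `"jc"`.
#' @return Symmetric numeric matrix of substitutions/site with taxa as
#'   dimnames.
#' @examples
#' pairwise_distance(c(a = "AAAA", b = "GAAA"))[1, 2] # -0.5 * log(0.5)
#' @export
pairwise_distance <- function(alignment, model = c("k2p", "jc")) {
  model <- match.arg(model)
  mat <- .aln_matrix(alignment)
  n <- nrow(mat)
  if (n < 2L) stop("need at least 2 sequences")
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- mat[i, ] %in% .VALID_BASES & mat[j, ] %in% .VALID_BASES
      m <- sum(ok)
      if (m == 0L) stop("no shared ungapped sites between ",
                        rownames(mat)[i], " and ", rownames(mat)[j])
      a <- mat[i, ok]; b <- mat[j, ok]
      diff <- a != b
      ts <- diff & ((a %in% .PURINES) == (b %in% .PURINES))
      P <- sum(ts) / m
      Q <- sum(diff & !ts) / m
      dist <- if (model == "k2p") {
        if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
          stop("saturated pair: ", rownames(mat)[i], " vs ", rownames(mat)[j])
        }
        -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
      } else {
        p <- P + Q
        if (1 - 4 * p / 3 <= 0) {
          stop("saturated pair: ", rownames(mat)[i], " vs ", rownames(mat)[j])
        }
        -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- d[j, i] <- dist
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor joining on a distance matrix.  When several
#' pairs minimise the Q criterion the pair whose sorted cluster labels come
#' first lexicographically is joined, and children are emitted in sort-key
#' order, so the same matrix yields a byte-identical newick string regardless
#' of the row order it is supplied in.
#'
#' @param d Symmetric distance matrix with taxon dimnames.
#' @return Unrooted `ape::phylo` tree with branch lengths.
#' @export
nj_tree <- function(d) {
  if (is.null(dimnames(d))) stop("distance matrix needs taxon dimnames")
  taxa <- rownames(d)
  r <- length(taxa)
  if (r < 3L) stop("neighbor joining needs at least 3 taxa")
  # clusters: newick fragment + sort key (lexicographically smallest member)
  frag <- setNames(taxa, taxa)
  key <- setNames(taxa, taxa)
  D <- d
  fmt <- function(x) sprintf("%.10g", x)
  while (nrow(D) > 3L) {
    rr <- nrow(D)
    R <- rowSums(D)
    Q <- (rr - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ord <- order(
      pmin(key[rownames(D)[cand[, 1]]], key[rownames(D)[cand[, 2]]]),
      pmax(key[rownames(D)[cand[, 1]]], key[rownames(D)[cand[, 2]]])
    )
    i <- cand[ord[1], 1]; j <- cand[ord[1], 2]
    # canonical child order: smaller sort key first, so equal inputs give
    # byte-identical newick regardless of matrix row order
    if (key[[rownames(D)[j]]] < key[[rownames(D)[i]]]) { k <- i; i <- j; j <- k }
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (rr - 2))
    lj <- D[i, j] - li
    ni <- rownames(D)[i]; nj <- rownames(D)[j]
    new_name <- paste0("(", ni, ",", nj, ")")
    new_frag <- paste0("(", frag[[ni]], ":", fmt(li), ",", frag[[nj]], ":", fmt(lj), ")")
    others <- setdiff(rownames(D), c(ni, nj))
    newd <- (D[ni, others] + D[nj, others] - D[ni, nj]) / 2
    D <- D[others, others, drop = FALSE]
    D <- rbind(cbind(D, newd), c(newd, 0))
    rownames(D)[nrow(D)] <- colnames(D)[ncol(D)] <- new_name
    frag[[new_name]] <- new_frag
    key[[new_name]] <- min(key[[ni]], key[[nj]])
  }
  nm <- rownames(D)
  lens <- c((D[1, 2] + D[1, 3] - D[2, 3]) / 2,
            (D[1, 2] + D[2, 3] - D[1, 3]) / 2,
            (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  o <- order(key[nm])  # canonical order of the final three clusters
  nm <- nm[o]; lens <- lens[o]
  nwk <- paste0("(", frag[[nm[1]]], ":", fmt(lens[1]), ",",
                frag[[nm[2]]], ":", fmt(lens[2]), ",",
                frag[[nm[3]]], ":", fmt(lens[3]), ");")
  ape::read.tree(text = nwk)
}

#' Bootstrap replicate trees
#'
#' Resamples alignment columns with replacement, recomputes distances and a
#' neighbor-joining tree per replicate.  Replicates whose resampled matrix is
#' saturated or degenerate are recomputed from a fresh draw (up to 100 extra
#' attempts each) so the requested number of trees is always returned.
#'
#' @param alignment Named character vector of aligned sequences.
#' @param n_replicates Number of bootstrap replicates.
#' @param seed Integer seed; the replicate stream is reproducible.
#' @param model Distance model, see [pairwise_distance()].
#' @return List of `ape::phylo` trees.
#' @export
bootstrap_trees <- function(alignment, n_replicates, seed = 1L, model = "k2p") {
  stopifnot(n_replicates >= 1)
  mat <- .aln_matrix(alignment)
  L <- ncol(mat)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    tries <- 0L
    repeat {
      cols <- sample.int(L, L, replace = TRUE)
      rep_aln <- setNames(apply(mat[, cols, drop = FALSE], 1, paste, collapse = ""),
                          rownames(mat))
      t <- tryCatch(nj_tree(pairwise_distance(rep_aln, model)), error = function(e) NULL)
      if (!is.null(t)) break
      tries <- tries + 1L
      if (tries > 100L) stop("bootstrap replicate ", b, " repeatedly failed")
    }
    out[[b]] <- t
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Non-trivial bipartitions of an unrooted tree, canonicalised so the reported
# side never contains the reference taxon (first element of `taxa`).
.bipartitions <- function(tree, taxa) {
  n <- length(tree$tip.label)
  ref <- taxa[1]
  out <- character(0)
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(n))
  for (node in internal) {
    tips <- ape::extract.clade(tree, node)$tip.label
    side <- if (ref %in% tips) setdiff(taxa, tips) else tips
    if (length(side) >= 2L && length(side) <= length(taxa) - 2L) {
      out <- c(out, paste(sort(side), collapse = "|"))
    }
  }
  unique(out)
}

#' Strict majority-rule consensus of bootstrap trees
#'
#' Includes exactly the bipartitions present in more than `threshold` of the
#' input trees (strict `>`; a bipartition in exactly half is excluded).
#'
#' @param trees List of `ape::phylo` trees over the same leaf set.
#' @param threshold Inclusion threshold as a fraction (default 0.5).
#' @return List with `tree` (an `ape::phylo`; internal node labels carry the
#'   support as percent) and `supports` (data.frame of included bipartitions
#'   with their percent frequency).
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  stopifnot(length(trees) >= 1)
  taxa <- sort(trees[[1]]$tip.label)
  for (t in trees) {
    if (!setequal(t$tip.label, taxa)) stop("trees have mismatched leaf sets")
  }
  counts <- table(unlist(lapply(trees, .bipartitions, taxa = taxa)))
  freq <- as.numeric(counts) / length(trees)
  names(freq) <- names(counts)
  keep <- freq[freq > threshold]
  # clades (sides not containing taxa[1]) are nested; build the tree top-down
  clades <- lapply(names(keep), function(k) strsplit(k, "\\|")[[1]])
  support <- round(100 * unname(keep), 1)
  ord <- order(vapply(clades, length, integer(1)), decreasing = TRUE)
  clades <- clades[ord]; support <- support[ord]
  build <- function(members, avail_idx) {
    # children clades: maximal kept clades strictly inside `members`
    inside <- avail_idx[vapply(avail_idx, function(i) {
      all(clades[[i]] %in% members) && length(clades[[i]]) < length(members)
    }, logical(1))]
    parts <- character(0)
    used <- character(0)
    while (length(inside) > 0L) {
      i <- inside[1]
      parts <- c(parts, paste0(build(clades[[i]], inside[-1]), support[i]))
      used <- c(used, clades[[i]])
      inside <- inside[vapply(inside, function(j) !any(clades[[j]] %in% used), logical(1))]
    }
    singles <- setdiff(members, used)
    paste0("(", paste(c(parts, sort(singles)), collapse = ","), ")")
  }
  idx <- seq_along(clades)
  top <- idx[vapply(idx, function(i) length(clades[[i]]) < length(taxa) - 1L, logical(1))]
  nwk <- paste0(build(taxa, top), ";")
  cons <- ape::read.tree(text = nwk)
  list(
    tree = cons,
    supports = data.frame(bipartition = names(keep)[ord],
                          support = support, stringsAsFactors = FALSE)
  )
}

#' Map bootstrap support onto a best tree
#'
#' Annotates each internal edge of `best_tree` with the percentage of
#' replicate trees containing the same bipartition.  All values are retained
#' in the returned data; values below `hide_below` are masked only in the
#' rendering labels (the convention used when drawing published trees).
#'
#' @param best_tree `ape::phylo` to annotate.
#' @param replicate_trees List of replicate trees over the same leaf set.
#' @param hide_below Rendering threshold in percent (default 50).
#' @return List with `tree` (node labels = support, masked below threshold),
#'   `supports` (data.frame with bipartition, node and exact percent).
#' @export
map_support <- function(best_tree, replicate_trees, hide_below = 50) {
  taxa <- sort(best_tree$tip.label)
  for (t in replicate_trees) {
    if (!setequal(t$tip.label, taxa)) stop("trees have mismatched leaf sets")
  }
  rep_bips <- lapply(replicate_trees, .bipartitions, taxa = taxa)
  n_tips <- length(best_tree$tip.label)
  internal_nodes <- n_tips + seq_len(best_tree$Nnode)
  labels <- character(best_tree$Nnode)
  rows <- list()
  for (k in seq_along(internal_nodes)) {
    node <- internal_nodes[k]
    if (node == n_tips + 1L) { labels[k] <- ""; next }  # root of the stored orientation
    tips <- ape::extract.clade(best_tree, node)$tip.label
    side <- if (taxa[1] %in% tips) setdiff(taxa, tips) else tips
    if (length(side) < 2L || length(side) > length(taxa) - 2L) { labels[k] <- ""; next }
    key <- paste(sort(side), collapse = "|")
    pct <- 100 * mean(vapply(rep_bips, function(b) key %in% b, logical(1)))
    rows[[length(rows) + 1L]] <- data.frame(bipartition = key, node = node,
                                            support = pct, stringsAsFactors = FALSE)
    labels[k] <- if (pct >= hide_below) as.character(round(pct)) else ""
  }
  out <- best_tree
  out$node.label <- labels
  list(tree = out,
       supports = if (length(rows)) do.call(rbind, rows) else
         data.frame(bipartition = character(), node = integer(), support = numeric()))
}
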