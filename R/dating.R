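#' @name origin_dating
#' @title Dating retroposition events from presence/absence on a dated tree
#'
#' @description
#' Under Dollo parsimony a pseudogene is gained exactly once and can only be
#' lost thereafter.  Given a rooted ultrametric species tree with node ages in
#' millions of years (Mya) and the presence/absence of a pseudogene across the
#' leaves, the gain must sit on the stem branch of the carriers' most recent
#' common ancestor: the event happened no later than the crown age of that
#' clade and no earlier than the next split above it.  Absences inside the
#' carrier clade are explained by losses.  Taxa whose state is unknown (e.g.
#' fragmentary assemblies) are excluded from both the MRCA computation and the
#' loss cost.
NULL

#' Load a dated species tree
#'
#' Reads a rooted newick tree whose branch lengths are in Mya and whose leaves
#' are all at the present, and indexes its node ages.
#'
#' @param path Path to a newick file, or an `ape::phylo` object.
#' @param tol Tolerance (Mya) on the ultrametricity check.
#' @return Object of class `dated_tree`: list with `phylo`, `ages` (numeric,
#'   indexed by ape node number; leaves 0) and `n_tips`.
#' @export
read_dated_tree <- function(path, tol = 1e-6) {
  phy <- if (inherits(path, "phylo")) path else ape::read.tree(path)
  if (is.null(phy) || !inherits(phy, "phylo")) stop("could not read a tree from ", path)
  if (!ape::is.rooted(phy)) stop("dated tree must be rooted")
  if (!ape::is.ultrametric(phy, tol = max(tol, 1e-6), option = 2)) {
    stop("dated tree must be ultrametric (all leaves at the present)")
  }
  n_tips <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)  # distance from the root
  ages <- max(depth) - depth                # leaves sit at age ~0
  ages[seq_len(n_tips)] <- 0
  structure(list(phylo = phy, ages = ages, n_tips = n_tips), class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  cat("Dated species tree:", x$n_tips, "taxa, root age",
      round(max(x$ages), 2), "Mya\n")
  invisible(x)
}

# Human-readable label for a node: tip label, internal node label, or number.
.node_label <- function(tree, node) {
  phy <- tree$phylo
  if (node <= tree$n_tips) return(phy$tip.label[node])
  lab <- phy$node.label[node - tree$n_tips]
  if (!is.null(lab) && !is.na(lab) && nzchar(lab)) lab else paste0("node", node)
}

.parent_of <- function(phy, node) {
  p <- phy$edge[phy$edge[, 2] == node, 1]
  if (length(p) == 0L) NA_integer_ else p
}

.children_of <- function(phy, node) phy$edge[phy$edge[, 1] == node, 2]

# Normalize a presence vector to "present"/"absent"/"unknown".
.normalize_presence <- function(presence) {
  if (is.null(names(presence))) stop("presence vector must be named by taxon")
  out <- vapply(presence, function(v) {
    if (is.na(v) || v %in% c("?", "unknown", "NA")) return("unknown")
    if (v %in% c(1, "1", TRUE, "present", "+")) return("present")
    if (v %in% c(0, "0", FALSE, "absent", "-")) return("absent")
    stop("unrecognised presence state: ", v)
  }, character(1))
  names(out) <- names(presence)
  out
}

#' Origination interval of a pseudogene under Dollo parsimony
#'
#' The gain is placed on the stem branch of the carriers' MRCA; the event is
#' bracketed between the crown age of that clade (lower, most recent bound)
#' and the age of the next node above it (upper, oldest bound).  When the MRCA
#' is the root the upper bound is the root age and the interval is flagged
#' open-ended.
#'
#' @param presence Named vector over taxa with states present/absent/unknown
#'   (also accepts 1/0/NA).
#' @param tree A `dated_tree`.
#' @return List with `lower`, `upper` (Mya), `origin_node` (ape node number of
#'   the carriers' MRCA), `origin_branch` (label of the clade whose stem
#'   carries the gain) and `open_ended`.
#' @examples
#' tre <- read_dated_tree(system.file("extdata", "mammal_dated_tree.nwk",
#'                                    package = "retrotrace"))
#' carriers <- setNames(rep(0, tre$n_tips), tre$phylo$tip.label)
#' carriers[c("Hosa", "Patr", "Gogo", "Poab", "Nole", "Mamu", "Chae")] <- 1
#' dollo_origin_interval(carriers, tre)
#' @export
dollo_origin_interval <- function(presence, tree) {
  stopifnot(inherits(tree, "dated_tree"))
  st <- .normalize_presence(presence)
  extra <- setdiff(names(st), tree$phylo$tip.label)
  if (length(extra) > 0L) stop("presence taxa not in tree: ", paste(extra, collapse = ", "))
  carriers <- names(st)[st == "present"]
  if (length(carriers) == 0L) stop("no carrier taxa: cannot place a gain")
  phy <- tree$phylo
  mrca <- if (length(carriers) == 1L) {
    which(phy$tip.label == carriers)
  } else {
    ape::getMRCA(phy, carriers)
  }
  parent <- .parent_of(phy, mrca)
  root <- tree$n_tips + 1L
  open_ended <- is.na(parent)
  list(
    lower = unname(tree$ages[mrca]),
    upper = unname(if (open_ended) tree$ages[root] else tree$ages[parent]),
    origin_node = mrca,
    origin_branch = .node_label(tree, mrca),
    open_ended = open_ended
  )
}

#' Loss events implied by absences inside the carrier clade
#'
#' Returns the minimal set of branches below the origin on which a single
#' loss each explains every absent leaf: the stem branches of the maximal
#' subtrees whose known-state leaves are all absent.  Subtrees containing
#' only unknown-state leaves incur no loss.
#'
#' @param presence Named presence vector (see [dollo_origin_interval()]).
#' @param tree A `dated_tree`.
#' @param origin_node Ape node number of the gain clade; defaults to the
#'   carriers' MRCA.
#' @return data.frame with one row per loss: `branch` (label of the lost
#'   clade), `node`, `age_low`, `age_high` (bounds of the branch in Mya).
#' @export
infer_losses <- function(presence, tree, origin_node = NULL) {
  stopifnot(inherits(tree, "dated_tree"))
  st <- .normalize_presence(presence)
  phy <- tree$phylo
  if (is.null(origin_node)) origin_node <- dollo_origin_interval(presence, tree)$origin_node
  # leaf states below each node
  state_of_leaf <- function(tip) {
    lab <- phy$tip.label[tip]
    if (lab %in% names(st)) st[[lab]] else "unknown"
  }
  # all-absent = every known leaf below is absent, and >= 1 known leaf exists
  leaves_below <- function(node) {
    if (node <= tree$n_tips) return(node)
    unlist(lapply(.children_of(phy, node), leaves_below))
  }
  losses <- list()
  walk <- function(node) {
    lv <- leaves_below(node)
    states <- vapply(lv, state_of_leaf, character(1))
    known <- states[states != "unknown"]
    if (length(known) > 0L && all(known == "absent")) {
      parent <- .parent_of(phy, node)
      losses[[length(losses) + 1L]] <<- data.frame(
        branch = .node_label(tree, node),
        node = node,
        age_low = unname(tree$ages[node]),
        age_high = unname(if (is.na(parent)) tree$ages[node] else tree$ages[parent]),
        stringsAsFactors = FALSE
      )
      return(invisible())  # maximal subtree: do not descend
    }
    if (node > tree$n_tips) for (ch in .children_of(phy, node)) walk(ch)
  }
  for (ch in if (origin_node <= tree$n_tips) integer() else .children_of(phy, origin_node)) walk(ch)
  if (length(losses) == 0L) {
    return(data.frame(branch = character(), node = integer(),
                      age_low = numeric(), age_high = numeric()))
  }
  do.call(rbind, losses)
}

#' Read a presence/absence matrix
#'
#' Tab-separated file with a `taxon` column and one column per pseudogene;
#' cells are 1 (present), 0 (absent) or `?` (unknown).
#'
#' @param path Path to the TSV file.
#' @return Character matrix with taxa as rownames and states
#'   present/absent/unknown.
#' @export
read_presence_matrix <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                    colClasses = "character")
  if (!"taxon" %in% names(tab)) stop("presence matrix needs a 'taxon' column")
  taxa <- tab$taxon
  cols <- setdiff(names(tab), "taxon")
  m <- sapply(cols, function(cn) {
    .normalize_presence(setNames(tab[[cn]], taxa))
  })
  rownames(m) <- taxa
  m
}

#' Date every pseudogene in a presence matrix
#'
#' @param presence_matrix Matrix as from [read_presence_matrix()] (taxa as
#'   rownames, pseudogenes as columns).
#' @param tree A `dated_tree`.
#' @return data.frame with one row per pseudogene: origination bounds, origin
#'   branch, open-ended flag, number of inferred losses and the lost clades.
#' @export
date_all <- function(presence_matrix, tree) {
  out <- lapply(colnames(presence_matrix), function(pg) {
    pres <- setNames(presence_matrix[, pg], rownames(presence_matrix))
    if (!any(pres == "present" | pres == "1", na.rm = TRUE)) {
      return(data.frame(pseudogene = pg, lower = NA_real_, upper = NA_real_,
                        origin_branch = NA_character_, open_ended = NA,
                        n_losses = NA_integer_, losses = NA_character_,
                        stringsAsFactors = FALSE))
    }
    iv <- dollo_origin_interval(pres, tree)
    ls <- infer_losses(pres, tree, iv$origin_node)
    data.frame(
      pseudogene = pg, lower = iv$lower, upper = iv$upper,
      origin_branch = iv$origin_branch, open_ended = iv$open_ended,
      n_losses = nrow(ls),
      losses = paste(ls$branch, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
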