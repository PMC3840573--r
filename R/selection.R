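#' @name selection_scan
#' @title Site-wise selection from substitution counts
#'
#' @description
#' A counting (SLAC-style) test for site-wise selection on a codon alignment:
#' ancestral sequences are reconstructed by Fitch parsimony at the nucleotide
#' level, synonymous and non-synonymous substitutions are counted per codon
#' site over all branches with Nei-Gojobori-style expected-site
#' normalisation, and each site is tested against the neutral expectation
#' with a binomial test.  Per-site reports from external likelihood methods
#' (FEL, REL, FUBAR, MEME) are consumed as tables and combined with the
#' counting test under a fixed consensus rule: a site is called when at least
#' two distinct methods pass their thresholds in the same direction.
NULL

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

# --- Fitch parsimony ancestral reconstruction --------------------------------

# postorder of internal nodes for an ape phylo
.postorder_internal <- function(phy) {
  n <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  unique(po$edge[, 1])
}

#' Ancestral sequences by Fitch parsimony
#'
#' Reconstructs one nucleotide state per internal node and alignment column
#' with the Fitch algorithm.  Ties in the up-pass are resolved toward the
#' state carried by the `reference` sequence at that column when it is in the
#' candidate set, otherwise toward the alphabetically first state, which
#' makes the reconstruction deterministic.
#'
#' @param alignment Named character vector of aligned nucleotide sequences
#'   (no gaps within codons that should be counted; columns with non-ACGT
#'   characters are reconstructed as `N` and skipped downstream).
#' @param tree Binary `ape::phylo` over the alignment's taxa (the basal
#'   trifurcation of an unrooted tree is accepted; any other polytomy is an
#'   error).
#' @param reference Optional taxon name used for tie-breaking.
#' @return List with `states` (character matrix: rows = all nodes in ape
#'   numbering, columns = sites) and `parsimony_count` (integer vector of the
#'   minimum substitution count per column).
#' @export
ancestral_states <- function(alignment, tree, reference = NULL) {
  mat <- .aln_matrix(alignment)
  if (!all(tree$tip.label %in% rownames(mat))) stop("tree tips missing from alignment")
  mat <- mat[tree$tip.label, , drop = FALSE]
  n <- length(tree$tip.label)
  root <- n + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  n_kids <- vapply(kids, length, integer(1))
  bad <- names(n_kids)[n_kids > 2 & as.integer(names(n_kids)) != root]
  if (length(bad) > 0L || n_kids[[as.character(root)]] > 3L) {
    stop("tree has unresolved polytomies; Fitch reconstruction requires a binary tree")
  }
  L <- ncol(mat)
  n_nodes <- n + tree$Nnode
  states <- matrix(NA_character_, n_nodes, L)
  states[seq_len(n), ] <- mat
  counts <- integer(L)
  po <- .postorder_internal(tree)
  parent_of <- integer(n_nodes)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  ref_states <- if (!is.null(reference)) {
    if (!reference %in% rownames(mat)) stop("reference taxon not in alignment")
    mat[reference, ]
  } else NULL
  for (s in seq_len(L)) {
    col <- mat[, s]
    if (!all(col %in% .VALID_BASES)) {
      states[, s] <- c(col, rep("N", tree$Nnode))
      counts[s] <- NA_integer_
      next
    }
    sets <- vector("list", n_nodes)
    for (i in seq_len(n)) sets[[i]] <- col[i]
    cnt <- 0L
    for (node in po) {
      cs <- lapply(kids[[as.character(node)]], function(k) sets[[k]])
      acc <- cs[[1]]
      for (k in 2:length(cs)) {
        inter <- intersect(acc, cs[[k]])
        if (length(inter) > 0L) acc <- inter
        else { acc <- union(acc, cs[[k]]); cnt <- cnt + 1L }
      }
      sets[[node]] <- acc
    }
    pick <- function(cand) {
      if (!is.null(ref_states) && ref_states[s] %in% cand) ref_states[s] else sort(cand)[1]
    }
    assign_state <- character(n_nodes)
    # preorder: root first, then follow edges down
    ord <- c(root, tree$edge[order(seq_len(nrow(tree$edge))), 2])
    assign_state[root] <- pick(sets[[root]])
    pre <- ape::reorder.phylo(tree, "cladewise")$edge
    for (e in seq_len(nrow(pre))) {
      p <- pre[e, 1]; ch <- pre[e, 2]
      if (ch <= n) next
      ps <- assign_state[p]
      assign_state[ch] <- if (ps %in% sets[[ch]]) ps else pick(sets[[ch]])
    }
    states[(n + 1L):n_nodes, s] <- assign_state[(n + 1L):n_nodes]
    counts[s] <- cnt
  }
  rownames(states) <- c(tree$tip.label, paste0("node", (n + 1L):n_nodes))
  list(states = states, parsimony_count = counts)
}

# --- Nei-Gojobori style counting --------------------------------------------

# synonymous site count of one codon (0..3); changes to stop codons count as
# non-synonymous; stop codons themselves return NA
.syn_sites <- function(codon, code = .codon_table()) {
  if (codon %in% .STOP_CODONS) return(NA_real_)
  aa <- code[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(.VALID_BASES, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (!alt %in% .STOP_CODONS && code[[alt]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# observed syn/nonsyn counts between two codons, averaged over minimal
# substitution pathways that avoid stop-codon intermediates (all pathways
# used if every one is blocked)
.pathway_counts <- function(from, to, code = .codon_table()) {
  diff_pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  d <- length(diff_pos)
  if (d == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (d == 1L) list(diff_pos) else {
    if (d == 2L) list(diff_pos, rev(diff_pos)) else {
      idx <- list()
      for (a in 1:3) for (b in 1:3) for (cc in 1:3) {
        if (length(unique(c(a, b, cc))) == 3L) idx[[length(idx) + 1L]] <- diff_pos[c(a, b, cc)]
      }
      idx
    }
  }
  tally <- function(order, allow_stops) {
    cur <- from
    syn <- 0; nonsyn <- 0
    for (pos in order) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(to, pos, pos)
      if (!allow_stops && nxt %in% .STOP_CODONS) return(NULL)
      aa_cur <- if (cur %in% .STOP_CODONS) "*" else code[[cur]]
      aa_nxt <- if (nxt %in% .STOP_CODONS) "*" else code[[nxt]]
      if (aa_cur == aa_nxt) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  res <- Filter(Negate(is.null), lapply(perms, tally, allow_stops = FALSE))
  if (length(res) == 0L) res <- lapply(perms, tally, allow_stops = TRUE)
  colMeans(do.call(rbind, res))
}

#' Per-site substitution counts over a phylogeny
#'
#' For every codon site, walks each branch between reconstructed ancestral
#' (and extant) codons, accumulating observed synonymous (OS) and
#' non-synonymous (ON) substitutions — multi-nucleotide changes averaged over
#' minimal pathways avoiding stops — and expected synonymous (ES) and
#' non-synonymous (EN) site counts averaged over the parent and child codons.
#' By construction `ES + EN = 3 * number of branches` at every countable
#' site.
#'
#' @param alignment Named character vector of aligned coding sequences
#'   (length divisible by 3, parental reading frame).
#' @param tree Binary `ape::phylo`.
#' @param reference Optional taxon for Fitch tie-breaking.
#' @return data.frame with columns `site`, `ES`, `EN`, `OS`, `ON`, `dN`,
#'   `dS`, `omega` (NA when dS = 0); sites containing ambiguity characters or
#'   in-frame stops in extant sequences are returned with NA counts and a
#'   warning.
#' @export
count_site <- function(alignment, tree, reference = NULL) {
  L <- unique(nchar(alignment))
  stopifnot(length(L) == 1L)
  if (L %% 3 != 0) stop("aligned length must be divisible by 3")
  anc <- ancestral_states(alignment, tree, reference)
  states <- anc$states
  code <- .codon_table()
  edges <- tree$edge
  n_sites <- L %/% 3
  out <- data.frame(site = seq_len(n_sites), ES = NA_real_, EN = NA_real_,
                    OS = NA_real_, ON = NA_real_)
  skipped <- 0L
  for (s in seq_len(n_sites)) {
    cols <- (3 * (s - 1) + 1):(3 * s)
    codons <- apply(states[, cols, drop = FALSE], 1, paste, collapse = "")
    if (any(!strsplit(paste(codons, collapse = ""), "")[[1]] %in% .VALID_BASES)) {
      skipped <- skipped + 1L
      next
    }
    ES <- 0; EN <- 0; OS <- 0; ON <- 0
    usable <- TRUE
    for (e in seq_len(nrow(edges))) {
      cp <- codons[edges[e, 1]]
      cc <- codons[edges[e, 2]]
      sp <- .syn_sites(cp, code); sc <- .syn_sites(cc, code)
      if (is.na(sp) || is.na(sc)) { usable <- FALSE; break }
      es <- (sp + sc) / 2
      ES <- ES + es; EN <- EN + (3 - es)
      pc <- .pathway_counts(cp, cc, code)
      OS <- OS + pc[["syn"]]; ON <- ON + pc[["nonsyn"]]
    }
    if (!usable) { skipped <- skipped + 1L; next }
    out$ES[s] <- ES; out$EN[s] <- EN; out$OS[s] <- OS; out$ON[s] <- ON
  }
  if (skipped > 0L) {
    warning(skipped, " site(s) skipped (ambiguity characters or stop codons)")
  }
  out$dS <- out$OS / out$ES
  out$dN <- out$ON / out$EN
  out$omega <- ifelse(is.na(out$dS) | out$dS == 0, NA_real_, out$dN / out$dS)
  out
}

#' Binomial site test on substitution counts
#'
#' Under neutrality (or a supplied background omega) each observed
#' substitution at a site is non-synonymous with probability
#' `omega * EN / (omega * EN + ES)`.  The test reports
#' `p_positive = P(X >= ON)` (excess of non-synonymous changes) and
#' `p_negative = P(X <= ON)` (scarcity) for `X ~ Binomial(OS + ON, p)`.
#' Sites with no substitutions return p = 1 in both directions.
#'
#' @param counts data.frame from [count_site()] (columns ES, EN, OS, ON).
#' @param omega Background dN/dS used for the null probability; default 1
#'   (strict neutrality).
#' @return Input data.frame with `p_positive` and `p_negative` columns added.
#' @export
slac_site_test <- function(counts, omega = 1) {
  p_nonsyn <- omega * counts$EN / (omega * counts$EN + counts$ES)
  n_subst <- counts$OS + counts$ON
  counts$p_positive <- ifelse(
    is.na(n_subst) | n_subst == 0, 1,
    pbinom(counts$ON - 1, n_subst, p_nonsyn, lower.tail = FALSE)
  )
  counts$p_negative <- ifelse(
    is.na(n_subst) | n_subst == 0, 1,
    pbinom(counts$ON, n_subst, p_nonsyn)
  )
  counts
}

#' Whole-alignment counting scan
#'
#' End-to-end SLAC-style scan: checks the minimum-sequence requirement
#' (site-wise selection tests are unreliable on few sequences, so alignments
#' with fewer than `min_sequences` are refused), reconstructs ancestors,
#' counts substitutions per site, estimates the global omega from the summed
#' counts and runs the binomial site test.
#'
#' @param alignment Named character vector of aligned coding sequences.
#' @param tree Binary `ape::phylo`.
#' @param reference Optional tie-break taxon.
#' @param min_sequences Minimum number of sequences (default 10).
#' @param neutral_null If `TRUE` (default) the site test uses omega = 1;
#'   otherwise the global omega estimated from the whole alignment.
#' @return List with `counts` (per-site data.frame incl. p-values) and
#'   `global_omega`.
#' @export
slac_scan <- function(alignment, tree, reference = NULL, min_sequences = 10,
                      neutral_null = TRUE) {
  if (length(alignment) < min_sequences) {
    stop("selection scan requires at least ", min_sequences, " sequences; got ",
         length(alignment))
  }
  counts <- count_site(alignment, tree, reference)
  tot <- colSums(counts[, c("ES", "EN", "OS", "ON")], na.rm = TRUE)
  global_omega <- if (tot[["OS"]] > 0 && tot[["ES"]] > 0 && tot[["EN"]] > 0) {
    (tot[["ON"]] / tot[["EN"]]) / (tot[["OS"]] / tot[["ES"]])
  } else NA_real_
  counts <- slac_site_test(counts, omega = if (neutral_null || is.na(global_omega)) 1 else global_omega)
  list(counts = counts, global_omega = global_omega)
}

# --- multi-method consensus --------------------------------------------------

.METHOD_RULES <- list(
  SLAC = function(kind, value) kind == "p_value" & value < 0.1,
  FEL = function(kind, value) kind == "p_value" & value < 0.1,
  MEME = function(kind, value) kind == "p_value" & value < 0.1,
  FUBAR = function(kind, value) kind == "posterior" & value > 0.9,
  REL = function(kind, value) kind == "bayes_factor" & value > 50
)

#' Read per-site selection reports
#'
#' Tab-separated columns: `method`, `site`, `stat_kind`
#' (p_value/posterior/bayes_factor), `value`, `direction`
#' (positive/negative).
#'
#' @param path Path to the TSV file.
#' @return data.frame.
#' @export
read_site_reports <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Consensus selection calls across methods
#'
#' A method supports a site when its statistic passes that method's
#' threshold: p < 0.1 for SLAC, FEL and MEME; posterior probability > 0.9 for
#' FUBAR; Bayes factor > 50 for REL (all strict).  A site enters the
#' consensus set when at least two distinct methods support it in the same
#' direction.  Rows naming unknown methods are rejected with a warning.
#' The result is independent of row order and of duplicated rows.
#'
#' @param reports data.frame with columns `method`, `site`, `stat_kind`,
#'   `value`, `direction`.
#' @return data.frame with `site`, `direction`, `n_methods`, `methods`,
#'   sorted by site then direction.
#' @export
consensus_calls <- function(reports) {
  known <- reports$method %in% names(.METHOD_RULES)
  if (any(!known)) {
    warning("rejecting rows with unknown method(s): ",
            paste(unique(reports$method[!known]), collapse = ", "))
    reports <- reports[known, , drop = FALSE]
  }
  if (nrow(reports) == 0L) {
    return(data.frame(site = integer(), direction = character(),
                      n_methods = integer(), methods = character()))
  }
  pass <- vapply(seq_len(nrow(reports)), function(i) {
    .METHOD_RULES[[reports$method[i]]](reports$stat_kind[i], reports$value[i])
  }, logical(1))
  sup <- unique(reports[pass, c("method", "site", "direction")])
  if (nrow(sup) == 0L) {
    return(data.frame(site = integer(), direction = character(),
                      n_methods = integer(), methods = character()))
  }
  agg <- aggregate(method ~ site + direction, data = sup,
                   FUN = function(m) paste(sort(unique(m)), collapse = ","))
  agg$n_methods <- vapply(strsplit(agg$method, ","), length, integer(1))
  out <- agg[agg$n_methods >= 2L, c("site", "direction", "n_methods", "method")]
  names(out)[4] <- "methods"
  out <- out[order(out$site, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  out
}
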