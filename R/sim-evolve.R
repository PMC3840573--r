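#' @name sim_evolve
#' @title Lineage evolution of retroposed copies along a dated tree
#'
#' @description
#' Evolves a set of retroposed copies (all descended from one parental
#' transcript, hence sharing its coordinate system) down an ultrametric
#' species tree: HKY-like substitutions, small indels, opaque repeat-element
#' insertions and whole-copy losses, all Poisson in branch length.  Because
#' every change is tracked against a global column registry, the emitted
#' multiple alignment of surviving copies plus the parental sequence is exact
#' by construction, as are the presence/absence matrix and the event table.
NULL

# HKY-like single-base substitution: transition with prob kappa/(kappa+2),
# each transversion with prob 1/(kappa+2)
.substitute_base <- function(base, kappa) {
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  if (runif(1) < kappa / (kappa + 2)) {
    transition[[base]]
  } else {
    sample(setdiff(.VALID_BASES, c(base, transition[[base]])), 1)
  }
}

# registry: environment with `cols` (ordered column ids) and `next_id`
.new_registry <- function(n) {
  reg <- new.env(parent = emptyenv())
  reg$cols <- as.character(seq_len(n))
  reg$next_id <- n + 1L
  reg
}

.registry_insert_after <- function(reg, after_col, k) {
  ids <- as.character(seq(reg$next_id, length.out = k))
  reg$next_id <- reg$next_id + k
  at <- if (is.na(after_col)) 0L else match(after_col, reg$cols)
  reg$cols <- append(reg$cols, ids, after = at)
  ids
}

# one branch of evolution for one copy state (named char vector, names = col ids)
.evolve_branch <- function(state, t_mya, config, reg, copy_name, branch_label, events) {
  live <- function() names(state)[nchar(state) > 0L]
  scale <- t_mya / 100
  n_sub <- rpois(1, config$subst_rate * scale * length(live()))
  for (i in seq_len(n_sub)) {
    lv <- live()
    if (length(lv) == 0L) break
    p <- sample(lv, 1)
    state[[p]] <- .substitute_base(state[[p]], config$kappa)
  }
  n_indel <- rpois(1, config$indel_rate * scale * length(live()))
  for (i in seq_len(n_indel)) {
    lv <- live()
    if (length(lv) == 0L) break
    len <- 1L + rgeom(1, 1 / 3)  # mean 3
    if (runif(1) < 0.5) {
      # deletion of a run of live positions
      start <- sample(seq_along(lv), 1)
      del <- lv[start:min(length(lv), start + len - 1L)]
      state[del] <- ""
      events$rows[[length(events$rows) + 1L]] <- .new_truth_row(
        paste0(copy_name, "_del", length(events$rows) + 1L), "deletion",
        branch_label, copy_length = length(del),
        detail = paste0("copy=", copy_name))
    } else {
      after <- sample(lv, 1)
      ids <- .registry_insert_after(reg, after, len)
      ins <- setNames(sample(.VALID_BASES, len, replace = TRUE), ids)
      state <- c(state, ins)
    }
  }
  n_rep <- rpois(1, config$repeat_insert_rate * scale)
  for (i in seq_len(n_rep)) {
    lv <- live()
    if (length(lv) == 0L) break
    elem <- if (runif(1) < 0.8) c("Alu_like", 300L) else c("L1_like", 6000L)
    len <- as.integer(elem[2])
    after <- sample(lv, 1)
    ids <- .registry_insert_after(reg, after, len)
    state <- c(state, setNames(sample(.VALID_BASES, len, replace = TRUE), ids))
    events$rows[[length(events$rows) + 1L]] <- .new_truth_row(
      paste0(copy_name, "_rep", length(events$rows) + 1L), "repeat_insertion",
      branch_label, copy_length = len,
      detail = paste0("copy=", copy_name, ";element=", elem[1]))
  }
  list(state = state, n_subst = n_sub)
}

#' Evolve retroposed copies along a dated species tree
#'
#' @param transcript The `parental_transcript` all copies derive from.
#' @param copies data.frame with one row per ancestral copy: columns `name`,
#'   `trunc5_extent` (nt removed from the 5' end) and optional `tail_len`
#'   (polyA tract length, default `config$polyA_tail_len`).  Such rows can be
#'   built directly from [retropose()] truth records.
#' @param tree A `dated_tree` (see [read_dated_tree()]) or an ultrametric
#'   rooted `ape::phylo` with branch lengths in Mya.
#' @param config A [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @param forced_losses Optional data.frame with columns `copy` and `branch`
#'   (label of the node/tip whose stem branch carries the loss) deterministic
#'   losses in addition to the stochastic `loss_rate`.
#' @param background Optional named chromosome vector used to assemble
#'   per-taxon genomes (flanking sequence is held fixed; only the copies
#'   evolve).  When supplied, each copy is assigned a random insertion site.
#' @return List with:
#'   * `alignment`: named character vector — one row per surviving
#'     copy-taxon pair (`<copy>@<taxon>`) plus the unevolved `parental` row,
#'     gap-consistent by construction;
#'   * `presence`: taxa x copies character matrix (present/absent);
#'   * `events`: truth table of loss/deletion/repeat events;
#'   * `branch_stats`: per copy and branch, realised substitution counts and
#'     branch lengths;
#'   * `sequences`: list per taxon of surviving copy sequences (gaps
#'     removed);
#'   * `genomes`: per-taxon genomes with final copy coordinates (`NULL`
#'     unless `background` is given) as list(genome, loci).
#' @export
evolve_along_tree <- function(transcript, copies, tree, config,
                              seed = config$seed, forced_losses = NULL,
                              background = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(tree, "dated_tree")) tree <- tree$phylo
  if (!ape::is.ultrametric(tree, tol = 1e-6, option = 2)) {
    stop("species tree must be ultrametric with ages in Mya")
  }
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(transcript$sequence)
  tx_chars <- strsplit(transcript$sequence, "")[[1]]
  n_tips <- length(tree$tip.label)
  root <- n_tips + 1L
  node_label <- function(node) {
    if (node <= n_tips) tree$tip.label[node]
    else {
      lab <- tree$node.label[node - n_tips]
      if (!is.null(lab) && !is.na(lab) && nzchar(lab)) lab else paste0("node", node)
    }
  }
  # shared registry over parental coordinates; per-copy tail columns appended
  reg <- .new_registry(L)
  root_states <- list()
  for (i in seq_len(nrow(copies))) {
    nm <- copies$name[i]
    trunc <- copies$trunc5_extent[i]
    tail_len <- if ("tail_len" %in% names(copies) && !is.na(copies$tail_len[i])) {
      copies$tail_len[i]
    } else config$polyA_tail_len
    keep <- (trunc + 1L):L
    st <- setNames(tx_chars[keep], as.character(keep))
    if (tail_len > 0L) {
      ids <- .registry_insert_after(reg, as.character(L), tail_len)
      st <- c(st, setNames(rep("A", tail_len), ids))
    }
    root_states[[nm]] <- st
  }
  events <- new.env(parent = emptyenv()); events$rows <- list()
  stats <- list()
  leaf_states <- list()   # leaf_states[[copy]][[taxon]]
  for (nm in names(root_states)) leaf_states[[nm]] <- list()
  recurse <- function(node, states, present) {
    for (child in tree$edge[tree$edge[, 1] == node, 2]) {
      t_br <- tree$edge.length[which(tree$edge[, 2] == child)]
      lbl <- node_label(child)
      ch_states <- states
      ch_present <- present
      for (nm in names(states)) {
        if (!ch_present[[nm]]) next
        forced <- !is.null(forced_losses) &&
          any(forced_losses$copy == nm & forced_losses$branch == lbl)
        stochastic <- config$loss_rate > 0 &&
          runif(1) < 1 - exp(-config$loss_rate * t_br / 100)
        if (forced || stochastic) {
          ch_present[[nm]] <- FALSE
          events$rows[[length(events$rows) + 1L]] <- .new_truth_row(
            paste0(nm, "_loss_", lbl), "loss", lbl,
            detail = paste0("copy=", nm))
          next
        }
        ev <- .evolve_branch(ch_states[[nm]], t_br, config, reg, nm, lbl, events)
        ch_states[[nm]] <- ev$state
        stats[[length(stats) + 1L]] <<- data.frame(
          copy = nm, branch = lbl, length_mya = t_br, n_subst = ev$n_subst,
          stringsAsFactors = FALSE)
      }
      if (child <= n_tips) {
        for (nm in names(ch_states)) {
          if (ch_present[[nm]]) leaf_states[[nm]][[tree$tip.label[child]]] <<- ch_states[[nm]]
        }
      } else {
        recurse(child, ch_states, ch_present)
      }
    }
  }
  recurse(root, root_states, setNames(rep(TRUE, length(root_states)), names(root_states)))
  # emit alignment over the final global column order
  col_order <- reg$cols
  emit_row <- function(state) {
    chars <- rep("-", length(col_order))
    hit <- match(names(state), col_order)
    chars[hit] <- ifelse(nchar(state) > 0L, state, "-")
    paste(chars, collapse = "")
  }
  aln <- c(parental = emit_row(setNames(tx_chars, as.character(seq_len(L)))))
  presence <- matrix("absent", nrow = n_tips, ncol = nrow(copies),
                     dimnames = list(tree$tip.label, copies$name))
  sequences <- setNames(vector("list", n_tips), tree$tip.label)
  for (nm in names(leaf_states)) {
    for (taxon in names(leaf_states[[nm]])) {
      st <- leaf_states[[nm]][[taxon]]
      aln[[paste0(nm, "@", taxon)]] <- emit_row(st)
      presence[taxon, nm] <- "present"
      seq_chars <- st[match(col_order, names(st))]
      seq_chars <- seq_chars[!is.na(seq_chars) & nchar(seq_chars) > 0L]
      sequences[[taxon]][[nm]] <- paste(seq_chars, collapse = "")
    }
  }
  genomes <- NULL
  if (!is.null(background)) {
    # fixed background insertion sites shared across taxa
    sites <- data.frame(
      copy = copies$name,
      chromosome = sample(names(background), nrow(copies), replace = TRUE),
      stringsAsFactors = FALSE)
    sites$bg_pos <- vapply(sites$chromosome, function(ch) {
      sample.int(nchar(background[[ch]]) + 1L, 1)
    }, integer(1))
    genomes <- list()
    for (taxon in tree$tip.label) {
      g <- background
      loci <- list()
      for (ch in names(background)) {
        here <- sites[sites$chromosome == ch, , drop = FALSE]
        here <- here[order(here$bg_pos), , drop = FALSE]
        offset <- 0L
        for (k in seq_len(nrow(here))) {
          nm <- here$copy[k]
          s <- sequences[[taxon]][[nm]]
          if (is.null(s)) next
          pos <- here$bg_pos[k] + offset
          g[[ch]] <- paste0(substr(g[[ch]], 1L, pos - 1L), s,
                            substr(g[[ch]], pos, nchar(g[[ch]])))
          loci[[length(loci) + 1L]] <- data.frame(
            copy = nm, chromosome = ch, start = pos,
            end = pos + nchar(s) - 1L, stringsAsFactors = FALSE)
          offset <- offset + nchar(s)
        }
      }
      genomes[[taxon]] <- list(
        genome = g,
        loci = if (length(loci)) do.call(rbind, loci) else
          data.frame(copy = character(), chromosome = character(),
                     start = integer(), end = integer()))
    }
  }
  list(
    alignment = aln,
    presence = presence,
    events = if (length(events$rows)) do.call(rbind, events$rows) else
      .new_truth_row("x", "none")[0, ],
    branch_stats = if (length(stats)) do.call(rbind, stats) else
      data.frame(copy = character(), branch = character(),
                 length_mya = numeric(), n_subst = integer()),
    sequences = sequences,
    genomes = genomes
  )
}

#' Simulate a neutral codon alignment along a tree
#'
#' Evolves sense codons by the HKY-like nucleotide process with no selective
#' distinction between synonymous and non-synonymous changes (omega = 1);
#' substitutions that would create a stop codon are redrawn, which keeps the
#' sequences translatable while leaving the process neutral at essentially
#' all sites.
#'
#' @param tree Rooted `ape::phylo` with branch lengths in Mya (need not be
#'   ultrametric).
#' @param n_codons Number of codon sites.
#' @param config A [sim_config()] (uses `subst_rate` and `kappa`).
#' @param seed RNG seed; defaults to `config$seed`.
#' @return Named character vector of leaf coding sequences (length
#'   `3 * n_codons`).
#' @export
simulate_codon_alignment <- function(tree, n_codons, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  sense <- .sense_codons()
  root_seq <- strsplit(paste(sample(sense, n_codons, replace = TRUE), collapse = ""), "")[[1]]
  n_tips <- length(tree$tip.label)
  out <- setNames(character(n_tips), tree$tip.label)
  recurse <- function(node, seqchars) {
    for (child in tree$edge[tree$edge[, 1] == node, 2]) {
      t_br <- tree$edge.length[which(tree$edge[, 2] == child)]
      s <- seqchars
      n_sub <- rpois(1, config$subst_rate * (t_br / 100) * length(s))
      applied <- 0L
      guard <- 0L
      while (applied < n_sub && guard < 50L * (n_sub + 1L)) {
        guard <- guard + 1L
        p <- sample.int(length(s), 1)
        b <- .substitute_base(s[p], config$kappa)
        cod_idx <- (p - 1L) %/% 3L
        cod <- s[(cod_idx * 3L + 1L):(cod_idx * 3L + 3L)]
        cod[(p - 1L) %% 3L + 1L] <- b
        if (paste(cod, collapse = "") %in% .STOP_CODONS) next
        s[p] <- b
        applied <- applied + 1L
      }
      if (child <= n_tips) out[[tree$tip.label[child]]] <<- paste(s, collapse = "")
      else recurse(child, s)
    }
  }
  recurse(n_tips + 1L, root_seq)
  out
}
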