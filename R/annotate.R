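#' @name pseudogene_annotator
#' @title Classifying pseudogenes and assessing their coding potential
#'
#' @description
#' Implements the classification rule for retroposed gene copies — a copy on
#' the same chromosome as its parent or a paralog and nearby, and/or carrying
#' introns, is a duplicated pseudogene; a copy on a different chromosome with
#' polyA traits, a truncated 5'UTR and no introns is a processed pseudogene —
#' together with the functionality checks applied to each copy: genomic polyA
#' tract, polyadenylation signals, Kozak context, open-reading-frame
#' integrity in the parental frame, and distance to the nearest
#' (non-pseudogene) gene.
NULL

#' Classify a pseudogene as processed or duplicated
#'
#' The duplicated rule takes precedence: a copy near its parent or an
#' existing paralog on the same chromosome is called duplicated even when it
#' shows processed hallmarks (a tandem duplication of a processed copy is
#' itself a duplicated pseudogene).  A copy on a different chromosome is
#' called processed only when all three hallmarks hold: polyA trait,
#' 5'UTR truncation and no introns.  Copies satisfying neither rule are
#' reported as ambiguous, never silently coerced.
#'
#' @param candidate List with `chromosome`, `start`, `end`, and flags
#'   `intronless`, `polyA_trait`, `utr5_truncated`.
#' @param parent_locus List with `chromosome`, `start`, `end` of the parental
#'   gene.
#' @param paralog_loci Optional list of loci (same shape) of previously
#'   annotated copies.
#' @param nearby_window Distance (bp) within which a same-chromosome copy
#'   counts as "nearby"; default 1 Mb.
#' @return One of `"processed"`, `"duplicated"`, `"ambiguous"`.
#' @export
classify_pseudogene <- function(candidate, parent_locus, paralog_loci = list(),
                                nearby_window = 1e6) {
  near <- function(locus) {
    if (is.null(locus) || !identical(candidate$chromosome, locus$chromosome)) return(FALSE)
    gap <- max(0, max(candidate$start, locus$start) -
                 min(candidate$end, locus$end) - 1)
    gap <= nearby_window
  }
  sources <- c(list(parent_locus), paralog_loci)
  if (any(vapply(sources, near, logical(1))) || !isTRUE(candidate$intronless)) {
    return("duplicated")
  }
  on_other_chrom <- !identical(candidate$chromosome, parent_locus$chromosome)
  if (on_other_chrom && isTRUE(candidate$polyA_trait) &&
      isTRUE(candidate$utr5_truncated) && isTRUE(candidate$intronless)) {
    return("processed")
  }
  "ambiguous"
}

#' Detect a genomic polyA tract downstream of a copy
#'
#' A simple run test standing in for dedicated polyA predictors: the trait is
#' present when a run of at least `min_run` consecutive A occurs within
#' `window` nt downstream of the aligned 3' end.
#'
#' @param downstream_seq Genomic sequence immediately downstream of the
#'   copy's aligned 3' end.
#' @param min_run Minimum A-run length (default 8).
#' @param window Search window in nt (default 50); must be >= `min_run`.
#' @return List with `trait` (logical) and `position` (1-based start of the
#'   first qualifying run, NA when absent).
#' @export
detect_polyA_trait <- function(downstream_seq, min_run = 8L, window = 50L) {
  if (window < min_run) stop("window must be >= min_run")
  seg <- toupper(substr(downstream_seq, 1L, window))
  m <- regexpr(paste0("A{", min_run, ",}"), seg)
  if (m > 0) list(trait = TRUE, position = as.integer(m))
  else list(trait = FALSE, position = NA_integer_)
}

#' Find polyadenylation signals
#'
#' Reports every occurrence (including overlapping ones) of the canonical
#' AATAAA and the common ATTAAA variant hexamers.
#'
#' @param seq Nucleotide sequence (parental-mRNA coordinates of the copy).
#' @return data.frame with columns `motif` and `position` (1-based start),
#'   ordered by position.
#' @export
detect_polyA_signals <- function(seq) {
  seq <- toupper(seq)
  m <- gregexpr("(?=(AATAAA|ATTAAA))", seq, perl = TRUE)[[1]]
  if (m[1] < 0) return(data.frame(motif = character(), position = integer()))
  pos <- as.integer(m)
  data.frame(motif = substr(rep(seq, length(pos)), pos, pos + 5L),
             position = pos, stringsAsFactors = FALSE)
}

#' Assess the open reading frame of a copy in the parental frame
#'
#' Walks the parental reading frame through the candidate's pairwise
#' alignment.  Indels whose length is not a multiple of 3 shift the frame;
#' an in-frame stop before the parental stop codon is a premature stop; a
#' missing start ATG (or no alignment over the CDS at all) means no ORF.
#'
#' @param aln_query Gapped parental (query) alignment string.
#' @param aln_subject Gapped candidate (subject) alignment string.
#' @param query_start Parental mRNA position of the first query character.
#' @param transcript Parental transcript (`cds_start`, `cds_end`).
#' @return List with `status` (one of intact, premature_stop, frameshift,
#'   no_orf) and `disabling_positions` (codon indices of the first disabling
#'   events; empty when intact).
#' @export
assess_orf <- function(aln_query, aln_subject, query_start, transcript) {
  q <- strsplit(toupper(aln_query), "")[[1]]
  s <- strsplit(toupper(aln_subject), "")[[1]]
  stopifnot(length(q) == length(s))
  q_pos <- cumsum(q != "-") + query_start - 1L
  in_cds <- q_pos >= transcript$cds_start & q_pos <= transcript$cds_end & q != "-"
  # columns spanning the CDS region (including insertion columns inside it)
  if (!any(in_cds)) return(list(status = "no_orf", disabling_positions = integer()))
  first_col <- min(which(in_cds)); last_col <- max(which(in_cds))
  cols <- first_col:last_col
  # start codon must be present and intact
  start_cols <- which(q_pos %in% (transcript$cds_start:(transcript$cds_start + 2L)) & q != "-")
  start_ok <- length(start_cols) == 3L && identical(s[start_cols], c("A", "T", "G"))
  if (!start_ok) return(list(status = "no_orf", disabling_positions = integer()))
  # frameshift: any indel run inside the CDS with length % 3 != 0
  disabling <- integer()
  run_kind <- ifelse(q[cols] == "-", "ins", ifelse(s[cols] == "-", "del", "m"))
  r <- rle(run_kind)
  off <- c(0L, cumsum(r$lengths))
  for (k in seq_along(r$values)) {
    if (r$values[k] %in% c("ins", "del") && r$lengths[k] %% 3L != 0L) {
      col0 <- cols[off[k] + 1L]
      codon_idx <- (q_pos[col0] - transcript$cds_start) %/% 3L + 1L
      disabling <- c(disabling, codon_idx)
    }
  }
  if (length(disabling) > 0L) {
    return(list(status = "frameshift", disabling_positions = unique(disabling)))
  }
  # no frame disruption: translate the candidate bases over the CDS columns
  cand <- s[cols]
  cand <- cand[cand != "-"]
  n_cod <- length(cand) %/% 3L
  code <- .codon_table()
  for (i in seq_len(n_cod - 1L)) {  # exclude the terminal (parental stop) codon
    codon <- paste(cand[(3L * i - 2L):(3L * i)], collapse = "")
    if (codon %in% .STOP_CODONS) {
      return(list(status = "premature_stop", disabling_positions = i))
    }
  }
  list(status = "intact", disabling_positions = integer())
}

#' Is the Kozak context conserved around a start codon?
#'
#' True when the base at position -3 (relative to the A of ATG, which is +1)
#' is a purine and the base at +4 is G.
#'
#' @param seq Nucleotide sequence containing the start codon.
#' @param atg_pos 1-based position of the A of the ATG in `seq`.
#' @return Logical; `FALSE` with a warning when fewer than 3 nt upstream or
#'   4 nt from the ATG are available.
#' @export
kozak_conserved <- function(seq, atg_pos) {
  seq <- toupper(seq)
  if (atg_pos < 4L || atg_pos + 3L > nchar(seq)) {
    warning("insufficient context around ATG for Kozak assessment")
    return(FALSE)
  }
  substr(seq, atg_pos - 3L, atg_pos - 3L) %in% c("A", "G") &&
    substr(seq, atg_pos + 3L, atg_pos + 3L) == "G"
}

#' Distance from a pseudogene to the nearest non-pseudogene gene
#'
#' Minimum edge-to-edge distance (1-based inclusive intervals: adjacent
#' intervals are 0 apart only when overlapping; `[100,200]` to `[300,400]`
#' is 99) to any gene on the same chromosome that is not itself annotated as
#' a pseudogene.
#'
#' @param candidate List with `chromosome`, `start`, `end`.
#' @param genes data.frame with columns `chromosome`, `start`, `end` and
#'   optional logical `is_pseudogene` (pseudogene neighbours are ignored).
#' @return Distance in bp (0 when overlapping); `NA` with a message when the
#'   chromosome carries no eligible gene.
#' @export
distance_to_nearest_gene <- function(candidate, genes) {
  if (!"is_pseudogene" %in% names(genes)) genes$is_pseudogene <- FALSE
  g <- genes[genes$chromosome == candidate$chromosome & !genes$is_pseudogene, ,
             drop = FALSE]
  if (nrow(g) == 0L) {
    message("no non-pseudogene gene on chromosome ", candidate$chromosome)
    return(NA_real_)
  }
  d <- pmax(0, pmax(candidate$start, g$start) - pmin(candidate$end, g$end) - 1)
  min(d)
}

#' Convert BED intervals (0-based half-open) to 1-based inclusive
#'
#' @param bed data.frame with `start` and `end` in BED convention.
#' @return Same data.frame with `start` incremented (end is already the last
#'   covered base in 1-based inclusive coordinates).
#' @export
bed_to_inclusive <- function(bed) {
  bed$start <- bed$start + 1L
  bed
}
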