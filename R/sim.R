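#' @name retro_sim
#' @title Retroposition simulator
#'
#' @description
#' Generates synthetic parental transcripts (5'UTR / CDS / 3'UTR with a Kozak
#' context and polyadenylation signals), random genomic background, and the
#' two copy-creating events — retroposition (5'-truncated, polyA-tailed,
#' intronless insertion at a random genomic location) and tandem duplication
#' (nearby insertion that may retain introns) — together with lineage
#' evolution along a dated species tree.  Every event is recorded in a
#' machine-readable truth table so downstream classification, dating and
#' selection analyses can be validated in a closed loop.
NULL

#' Simulation configuration
#'
#' Defaults mirror the structure of the system the package was designed
#' around: a 3,475-nt parental mRNA whose 618-nt CDS occupies positions
#' 377-994, a geometric 5'-truncation (the reverse transcriptase dissociates
#' before reaching the cap), and a mammalian-scale neutral substitution rate.
#'
#' @param seed Integer RNG seed; a fixed seed makes all outputs
#'   byte-identical across runs.
#' @param n_taxa Number of extant taxa to simulate.
#' @param utr5_len,cds_len,utr3_len Transcript segment lengths (nt);
#'   `cds_len` must be divisible by 3.
#' @param trunc5_mean Mean 5'-truncation (nt) of a retroposed copy.
#' @param polyA_tail_len Length of the appended genomic polyA tract (nt).
#' @param n_polyA_signals Number of AATAAA/ATTAAA hexamers planted in the
#'   3'UTR (default 4).
#' @param subst_rate Substitutions / site / 100 Mya.
#' @param indel_rate Small indel events / site / 100 Mya.
#' @param repeat_insert_rate Repeat-element insertions / copy / 100 Mya.
#' @param dup_probability Per-copy probability of a tandem duplication event.
#' @param nearby_window Maximum distance (bp) between a duplicated copy and
#'   its source locus.
#' @param kappa Transition/transversion rate ratio of the HKY-like
#'   substitution process.
#' @param loss_rate Whole-copy loss events / copy / 100 Mya.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L, n_taxa = 18L,
                       utr5_len = 376L, cds_len = 618L, utr3_len = 2481L,
                       trunc5_mean = 300, polyA_tail_len = 30L,
                       n_polyA_signals = 4L,
                       subst_rate = 0.2, indel_rate = 0.02,
                       repeat_insert_rate = 0.2, dup_probability = 0.05,
                       nearby_window = 1e6, kappa = 2.0, loss_rate = 0) {
  if (cds_len %% 3 != 0) stop("cds_len must be divisible by 3")
  if (cds_len < 9) stop("cds_len must allow start, one internal and stop codon")
  if (utr5_len < 3) stop("utr5_len must be >= 3 (Kozak context needs 3 nt upstream of ATG)")
  rates <- c(subst_rate, indel_rate, repeat_insert_rate, loss_rate)
  if (any(rates < 0)) stop("rates must be >= 0")
  if (dup_probability < 0 || dup_probability > 1) stop("dup_probability must be in [0, 1]")
  if (trunc5_mean < 0 || polyA_tail_len < 0 || nearby_window < 0) {
    stop("trunc5_mean, polyA_tail_len and nearby_window must be >= 0")
  }
  structure(list(
    seed = as.integer(seed), n_taxa = as.integer(n_taxa),
    utr5_len = as.integer(utr5_len), cds_len = as.integer(cds_len),
    utr3_len = as.integer(utr3_len), trunc5_mean = trunc5_mean,
    polyA_tail_len = as.integer(polyA_tail_len),
    n_polyA_signals = as.integer(n_polyA_signals),
    subst_rate = subst_rate, indel_rate = indel_rate,
    repeat_insert_rate = repeat_insert_rate,
    dup_probability = dup_probability, nearby_window = nearby_window,
    kappa = kappa, loss_rate = loss_rate
  ), class = "sim_config")
}

.random_bases <- function(n) {
  if (n == 0L) return("")
  paste(sample(.VALID_BASES, n, replace = TRUE), collapse = "")
}

.sense_codons <- function() {
  cods <- apply(expand.grid(.VALID_BASES, .VALID_BASES, .VALID_BASES), 1, paste, collapse = "")
  setdiff(cods, .STOP_CODONS)
}

#' Simulate a parental transcript
#'
#' Builds an mRNA of length `utr5_len + cds_len + utr3_len` whose CDS starts
#' with ATG in a Kozak context (A/G at -3, G at +4), contains no internal
#' in-frame stop, ends with a stop codon, and whose 3'UTR carries the
#' configured number of polyadenylation signals.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return Object of class `parental_transcript`: list with `id`, `sequence`,
#'   `cds_start`, `cds_end`, `polyA_signal_positions` (1-based starts of all
#'   AATAAA/ATTAAA occurrences in the final sequence).
#' @examples
#' tx <- simulate_parental_transcript(sim_config(seed = 7))
#' nchar(tx$sequence)  # 3475
#' c(tx$cds_start, tx$cds_end)  # 377 994
#' @export
simulate_parental_transcript <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  sense <- .sense_codons()
  # 5'UTR: random, Kozak -3 position forced to purine
  utr5 <- strsplit(.random_bases(config$utr5_len), "")[[1]]
  utr5[config$utr5_len - 2L] <- sample(c("A", "G"), 1)
  # avoid a spurious polyA signal being the only one: not needed, we scan at the end
  n_internal <- config$cds_len / 3L - 2L
  codon2_pool <- sense[substr(sense, 1, 1) == "G"]  # Kozak +4 = G
  internal <- c(sample(codon2_pool, 1),
                if (n_internal > 1L) sample(sense, n_internal - 1L, replace = TRUE))
  cds <- paste0("ATG", paste(internal, collapse = ""), sample(.STOP_CODONS, 1))
  utr3 <- strsplit(.random_bases(config$utr3_len), "")[[1]]
  # plant polyA signals, the last one near the 3' terminus
  if (config$n_polyA_signals > 0L && config$utr3_len >= 6L) {
    n_sig <- config$n_polyA_signals
    anchor <- max(1L, config$utr3_len - 30L - 5L)
    starts <- unique(c(
      if (n_sig > 1L) sort(sample(seq_len(max(1L, anchor - 6L)), n_sig - 1L)),
      anchor
    ))
    # drop overlapping plants
    starts <- starts[c(TRUE, diff(starts) >= 6L)]
    for (s in starts) {
      motif <- sample(c("AATAAA", "ATTAAA"), 1)
      utr3[s:(s + 5L)] <- strsplit(motif, "")[[1]]
    }
  }
  sequence <- paste0(paste(utr5, collapse = ""), cds, paste(utr3, collapse = ""))
  tx <- structure(list(
    id = "parental",
    sequence = sequence,
    cds_start = config$utr5_len + 1L,
    cds_end = config$utr5_len + config$cds_len,
    polyA_signal_positions = detect_polyA_signals(sequence)$position
  ), class = "parental_transcript")
  tx
}

#' @export
print.parental_transcript <- function(x, ...) {
  cat("Parental transcript '", x$id, "': ", nchar(x$sequence), " nt, CDS [",
      x$cds_start, ", ", x$cds_end, "], ",
      length(x$polyA_signal_positions), " polyA signal(s)\n", sep = "")
  invisible(x)
}

#' Random genomic background
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_len Length of each chromosome (nt); recycled.
#' @param seed Optional RNG seed.
#' @return Named character vector of chromosome sequences.
#' @export
random_genome <- function(n_chromosomes = 2L, chrom_len = 20000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- rep_len(chrom_len, n_chromosomes)
  setNames(vapply(lens, .random_bases, character(1)),
           paste0("chr", seq_len(n_chromosomes)))
}

.new_truth_row <- function(event_id, event_kind, donor_branch = NA_character_,
                           chromosome = NA_character_, position = NA_integer_,
                           trunc5_extent = NA_integer_, copy_length = NA_integer_,
                           has_polyA_tail = NA, retains_introns = NA,
                           detail = NA_character_) {
  data.frame(event_id = event_id, event_kind = event_kind,
             donor_branch = donor_branch, insertion_chromosome = chromosome,
             insertion_position = position, trunc5_extent = trunc5_extent,
             copy_length = copy_length, has_polyA_tail = has_polyA_tail,
             retains_introns = retains_introns, detail = detail,
             stringsAsFactors = FALSE)
}

#' Retropose a transcript into a genome
#'
#' Emulates the creation of a processed pseudogene: the transcript is
#' 5'-truncated by a geometric draw (mean `trunc5_mean`, capped so at least
#' half of the CDS survives), a polyA tract is appended, and the copy is
#' inserted at a uniformly random genomic position.  The copy is intronless
#' by construction.
#'
#' @param transcript A `parental_transcript` (or any list with `sequence`,
#'   `cds_start`, `cds_end`).
#' @param genome Named character vector of chromosome sequences.
#' @param config A [sim_config()].
#' @param event_id Identifier recorded in the truth table.
#' @param donor_branch Optional label of the tree branch on which the event
#'   occurred.
#' @return List with `genome` (modified), `truth` (one-row data.frame) and
#'   `copy` (the inserted sequence).
#' @export
retropose <- function(transcript, genome, config, event_id = "retro1",
                      donor_branch = NA_character_) {
  stopifnot(inherits(config, "sim_config"))
  if (length(genome) == 0L || all(nchar(genome) == 0L)) stop("genome is empty")
  L <- nchar(transcript$sequence)
  max_trunc <- transcript$cds_start - 1L +
    floor((transcript$cds_end - transcript$cds_start + 1L) / 2)
  trunc <- if (config$trunc5_mean <= 0) 0L else {
    min(rgeom(1, 1 / (1 + config$trunc5_mean)), max_trunc)
  }
  copy <- paste0(substr(transcript$sequence, trunc + 1L, L),
                 strrep("A", config$polyA_tail_len))
  chrom <- sample(names(genome), 1)
  pos <- sample.int(nchar(genome[[chrom]]) + 1L, 1)  # copy starts at this base
  genome[[chrom]] <- paste0(substr(genome[[chrom]], 1L, pos - 1L), copy,
                            substr(genome[[chrom]], pos, nchar(genome[[chrom]])))
  truth <- .new_truth_row(event_id, "retroposition", donor_branch,
                          chrom, pos, as.integer(trunc), nchar(copy),
                          has_polyA_tail = TRUE, retains_introns = FALSE)
  list(genome = genome, truth = truth, copy = copy)
}

#' Tandemly duplicate a genomic locus
#'
#' Copies `[start, end]` of a chromosome and reinserts it on the same
#' chromosome within `nearby_window` bp of the source, outside the source
#' interval itself.  Intron retention and polyA-tail state are propagated
#' from the source locus annotation.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param locus List with `chromosome`, `start`, `end` and optional
#'   `retains_introns`, `has_polyA_tail` flags describing the source copy.
#' @param config A [sim_config()].
#' @param event_id Identifier recorded in the truth table.
#' @param donor_branch Optional branch label.
#' @return List with `genome`, `truth`, `copy`.
#' @export
duplicate_locus <- function(genome, locus, config, event_id = "dup1",
                            donor_branch = NA_character_) {
  stopifnot(inherits(config, "sim_config"))
  chrom <- locus$chromosome
  if (!chrom %in% names(genome)) stop("locus chromosome not in genome")
  clen <- nchar(genome[[chrom]])
  if (locus$start < 1L || locus$end > clen || locus$start > locus$end) {
    stop("locus out of genome bounds")
  }
  copy <- substr(genome[[chrom]], locus$start, locus$end)
  w <- config$nearby_window
  lo <- max(1L, locus$start - w)
  hi <- min(clen + 1L, locus$end + 1L + w)
  candidates <- c(lo:locus$start, (locus$end + 1L):hi)  # outside the source interior
  pos <- if (w == 0) locus$end + 1L else sample(candidates, 1)
  genome[[chrom]] <- paste0(substr(genome[[chrom]], 1L, pos - 1L), copy,
                            substr(genome[[chrom]], pos, clen))
  truth <- .new_truth_row(event_id, "duplication", donor_branch,
                          chrom, as.integer(pos), copy_length = nchar(copy),
                          has_polyA_tail = isTRUE(locus$has_polyA_tail),
                          retains_introns = isTRUE(locus$retains_introns))
  list(genome = genome, truth = truth, copy = copy)
}
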