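#' @name homology_screen
#' @title Screening a genome for retroposed copies of a transcript
#'
#' @description
#' Finds candidate pseudogene loci by exact k-mer seeding followed by local
#' (Smith-Waterman) alignment of the parental mRNA against the seeded genomic
#' window, on both strands, and applies the two retention filters used when
#' screening databases for retroposed copies: a retrieval filter
#' (similarity > 60% and mRNA coverage > 35%, both strict) and a stricter
#' phylogeny filter (CDS coverage > 85% and similarity > 60%).
NULL

.revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# seed matches of transcript k-mers in a sequence; returns genomic windows
# likely to contain a copy
.seed_windows <- function(chrom_seq, transcript_seq, seed_k) {
  Lg <- nchar(chrom_seq); Lt <- nchar(transcript_seq)
  if (Lg < seed_k || Lt < seed_k) return(list())
  t_kmers <- substring(transcript_seq, 1:(Lt - seed_k + 1L), seed_k:Lt)
  g_kmers <- substring(chrom_seq, 1:(Lg - seed_k + 1L), seed_k:Lg)
  hit <- !is.na(match(g_kmers, t_kmers))
  g_pos <- which(hit)
  if (length(g_pos) == 0L) return(list())
  # cluster genomic seed positions: a gap larger than the transcript length
  # starts a new candidate locus
  breaks <- c(0L, which(diff(g_pos) > Lt), length(g_pos))
  windows <- list()
  for (b in seq_len(length(breaks) - 1L)) {
    grp <- g_pos[(breaks[b] + 1L):breaks[b + 1L]]
    windows[[b]] <- c(max(1L, min(grp) - Lt), min(Lg, max(grp) + Lt + seed_k))
  }
  windows
}

#' Search a genome for copies of a transcript
#'
#' Exact k-mer seeding identifies candidate windows; each window is then
#' aligned locally to the parental mRNA (match +1, mismatch -1, gap open 2,
#' gap extend 1).  The reverse complement of every chromosome is searched as
#' well, and minus-strand hits are reported in parental-mRNA orientation with
#' plus-strand genomic coordinates.  Overlapping hits are resolved greedily
#' by score.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param transcript A `parental_transcript` (or list with `sequence`,
#'   `cds_start`, `cds_end`).
#' @param seed_k Seed length (>= 8).
#' @param min_score Minimum local alignment score to report.
#' @param taxon Taxon label attached to the candidates.
#' @return List of `pseudogene_candidate` objects: each has `id`, `taxon`,
#'   `chromosome`, `start`, `end` (1-based inclusive, plus strand), `strand`,
#'   `score`, `query_start` (first aligned parental position),
#'   `aln_query`/`aln_subject` (gapped alignment strings), `similarity`,
#'   `coverage_mrna`, `coverage_cds`.
#' @export
search_hits <- function(genome, transcript, seed_k = 11L, min_score = 30,
                        taxon = "taxon") {
  if (seed_k < 8L) stop("seed_k must be >= 8")
  if (length(genome) == 0L || all(nchar(genome) == 0L)) return(list())
  tseq <- toupper(transcript$sequence)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  hits <- list()
  for (chrom in names(genome)) {
    cseq <- toupper(genome[[chrom]])
    clen <- nchar(cseq)
    for (strand in c("+", "-")) {
      sseq <- if (strand == "+") cseq else .revcomp(cseq)
      for (win in .seed_windows(sseq, tseq, seed_k)) {
        wseq <- substr(sseq, win[1], win[2])
        aln <- Biostrings::pairwiseAlignment(
          pattern = tseq, subject = wseq, type = "local",
          substitutionMatrix = submat, gapOpening = 2, gapExtension = 1)
        if (Biostrings::score(aln) < min_score) next
        q_start <- Biostrings::start(Biostrings::pattern(aln))
        s_start <- win[1] + Biostrings::start(Biostrings::subject(aln)) - 1L
        s_end <- win[1] + Biostrings::end(Biostrings::subject(aln)) - 1L
        if (strand == "+") {
          g_start <- s_start; g_end <- s_end
        } else {
          g_start <- clen - s_end + 1L; g_end <- clen - s_start + 1L
        }
        cand <- structure(list(
          id = NA_character_, taxon = taxon, chromosome = chrom,
          start = g_start, end = g_end, strand = strand,
          score = Biostrings::score(aln),
          query_start = q_start,
          aln_query = as.character(Biostrings::alignedPattern(aln)),
          aln_subject = as.character(Biostrings::alignedSubject(aln))
        ), class = "pseudogene_candidate")
        m <- similarity_and_coverage(cand, transcript)
        cand$similarity <- m[["similarity"]]
        cand$coverage_mrna <- m[["coverage_mrna"]]
        cand$coverage_cds <- m[["coverage_cds"]]
        hits[[length(hits) + 1L]] <- cand
      }
    }
  }
  if (length(hits) == 0L) return(list())
  # greedy non-overlap by score
  ord <- order(vapply(hits, function(h) h$score, numeric(1)), decreasing = TRUE)
  kept <- list()
  for (i in ord) {
    h <- hits[[i]]
    clash <- any(vapply(kept, function(k) {
      k$chromosome == h$chromosome && h$start <= k$end && k$start <= h$end
    }, logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- h
  }
  # stable ordering and ids
  ord2 <- order(vapply(kept, function(h) h$chromosome, character(1)),
                vapply(kept, function(h) h$start, numeric(1)))
  kept <- kept[ord2]
  for (i in seq_along(kept)) kept[[i]]$id <- paste0(taxon, "_hit", i)
  kept
}

#' Similarity and coverage of a candidate against the parental transcript
#'
#' Similarity is the percentage of identical columns among aligned
#' (gap-free in both sequences) columns, the percent-identity convention of
#' local aligners.  mRNA coverage is the percentage of distinct parental
#' mRNA positions aligned to a genomic base; CDS coverage is the analogous
#' percentage over the parental CDS window.
#'
#' @param candidate A `pseudogene_candidate` (needs `aln_query`,
#'   `aln_subject`, `query_start`).
#' @param transcript Parental transcript with `sequence`, `cds_start`,
#'   `cds_end`.
#' @return Named numeric vector: `similarity`, `coverage_mrna`,
#'   `coverage_cds` (percent).
#' @export
similarity_and_coverage <- function(candidate, transcript) {
  q <- strsplit(toupper(candidate$aln_query), "")[[1]]
  s <- strsplit(toupper(candidate$aln_subject), "")[[1]]
  if (length(q) != length(s) || length(q) == 0L) stop("empty or invalid alignment")
  both <- q != "-" & s != "-"
  if (!any(both)) stop("alignment has no aligned columns")
  similarity <- 100 * sum(q[both] == s[both]) / sum(both)
  # parental coordinate of each query character
  q_pos <- cumsum(q != "-") + candidate$query_start - 1L
  aligned_pos <- unique(q_pos[both])
  L <- nchar(transcript$sequence)
  cds <- transcript$cds_start:transcript$cds_end
  c(similarity = similarity,
    coverage_mrna = 100 * length(aligned_pos) / L,
    coverage_cds = 100 * sum(aligned_pos %in% cds) / length(cds))
}

#' Retrieval filter on screened candidates
#'
#' Keeps candidates with similarity strictly above 60% and parental-mRNA
#' coverage strictly above 35%.
#'
#' @param candidates List of `pseudogene_candidate` objects (metrics
#'   computed).
#' @return Filtered list.
#' @export
filter_retrieval <- function(candidates) {
  Filter(function(h) h$similarity > 60 && h$coverage_mrna > 35, candidates)
}

#' Phylogeny-set filter on screened candidates
#'
#' Keeps candidates with parental-CDS coverage strictly above 85% and
#' similarity strictly above 60% — the stricter filter applied before
#' alignment-based phylogenetic reconstruction, which drops fragments whose
#' homology lies mostly outside the CDS.
#'
#' @param candidates List of `pseudogene_candidate` objects.
#' @return Filtered list.
#' @export
filter_phylo_set <- function(candidates) {
  Filter(function(h) h$coverage_cds > 85 && h$similarity > 60, candidates)
}

#' Tabulate candidates
#'
#' @param candidates List of `pseudogene_candidate` objects.
#' @return data.frame with one row per candidate.
#' @export
candidates_table <- function(candidates) {
  if (length(candidates) == 0L) {
    return(data.frame(id = character(), taxon = character(),
                      chromosome = character(), start = integer(),
                      end = integer(), strand = character(),
                      similarity = numeric(), coverage_mrna = numeric(),
                      coverage_cds = numeric()))
  }
  do.call(rbind, lapply(candidates, function(h) {
    data.frame(id = h$id, taxon = h$taxon, chromosome = h$chromosome,
               start = h$start, end = h$end, strand = h$strand,
               similarity = h$similarity, coverage_mrna = h$coverage_mrna,
               coverage_cds = h$coverage_cds, stringsAsFactors = FALSE)
  }))
}

#' @export
print.pseudogene_candidate <- function(x, ...) {
  cat(sprintf("%s %s:%d-%d(%s) sim=%.1f covmRNA=%.1f covCDS=%.1f\n",
              x$id, x$chromosome, x$start, x$end, x$strand,
              x$similarity, x$coverage_mrna, x$coverage_cds))
  invisible(x)
}
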