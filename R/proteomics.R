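#' @name proteomics
#' @title Peptide-level verification of pseudogene-encoded proteins
#'
#' @description
#' Tools to re-derive the quantitative columns of a peptide identification
#' table: theoretical monoisotopic mass and m/z per charge state, residue
#' coverage of the target protein, tryptic-context checks, and a row-by-row
#' verification report.  Scores produced by the search engine are consumed,
#' never recomputed.
NULL

# Monoisotopic residue masses (Da), standard 20 amino acids.
# Values are the residue (water-free) masses used by all major search engines.
.RESIDUE_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# Average residue masses (Da), for the MW column of protein summaries.
.RESIDUE_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.WATER_MONO <- 18.010565
.WATER_AVG <- 18.01524
.PROTON_MASS <- 1.007276
.MET_OXIDATION <- 15.99491

# EMBOSS pKa set used for isoelectric point estimation.
.PKA <- list(
  nterm = 8.6, cterm = 3.6,
  side = c(C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1)
)

#' Theoretical monoisotopic mass of a peptide
#'
#' Sums the monoisotopic residue masses, adds one water for the termini, and
#' adds any fixed/variable modification deltas.
#'
#' @param peptide Character scalar of one-letter residue codes.  Flanking
#'   tryptic context in `"K.PEPTIDE.R"` notation is stripped first.
#' @param modifications Numeric vector of mass deltas in Da (e.g. one
#'   `15.99491` entry per oxidised Met).  Positions are not needed for the
#'   mass sum.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("G") # 75.0320
#' monoisotopic_mass("SSSGSSVATSGQQSGGTIQDVK")
#' @export
monoisotopic_mass <- function(peptide, modifications = numeric()) {
  res <- strip_flanks(peptide)
  if (nchar(res) == 0L) stop("empty peptide")
  aa <- strsplit(res, "")[[1]]
  unknown <- setdiff(aa, names(.RESIDUE_MONO))
  if (length(unknown) > 0L) {
    stop("unknown residue(s): ", paste(unique(unknown), collapse = ", "))
  }
  sum(.RESIDUE_MONO[aa]) + .WATER_MONO + sum(modifications)
}

#' Mass-to-charge ratio of a protonated peptide
#'
#' @param mass Neutral monoisotopic mass in Da.
#' @param z Charge state (positive integer).
#' @return m/z in Thomson: `(mass + z * 1.007276) / z`.
#' @examples
#' mz(monoisotopic_mass("SSSGSSVATSGQQSGGTIQDVK"), 2) # 1034.49
#' @export
mz <- function(mass, z) {
  if (!is.numeric(z) || length(z) != 1L || z < 1 || z != round(z)) {
    stop("charge state z must be a positive integer")
  }
  (mass + z * .PROTON_MASS) / z
}

#' Strip "K.PEPTIDE.R" flanking notation
#'
#' @param peptide Peptide string, with or without single-residue flanks
#'   separated by dots (`-` marks a protein terminus).
#' @return Bare residue string.
#' @export
strip_flanks <- function(peptide) {
  peptide <- gsub("\\s|\\*", "", peptide)
  m <- regmatches(peptide, regexec("^(?:[A-Z-]\\.)?([A-Z]+)(?:\\.[A-Z-])?$", peptide))[[1]]
  if (length(m) == 2L) return(m[2])
  peptide
}

#' Map peptides onto a protein sequence
#'
#' Exact substring search; every occurrence is reported with its 1-based
#' inclusive residue range.  The tryptic context (preceded by K/R or the
#' protein start; ending in K/R or at the protein end) is recorded as a flag,
#' not used as a filter.  When several proteins are supplied, peptides hitting
#' more than one are flagged `ambiguous` (they cannot be assigned
#' unequivocally).
#'
#' @param peptides Character vector of peptide sequences (flanks allowed).
#' @param proteins Named character vector of protein sequences.
#' @return data.frame with columns `peptide`, `protein`, `start`, `end`,
#'   `tryptic`, `ambiguous`.
#' @export
map_peptides <- function(peptides, proteins) {
  if (is.null(names(proteins))) names(proteins) <- paste0("protein", seq_along(proteins))
  rows <- list()
  hit_proteins <- lapply(peptides, function(p) character())
  names(hit_proteins) <- peptides
  for (pep in peptides) {
    bare <- strip_flanks(pep)
    if (!grepl("^[A-Z]+$", bare) || !all(strsplit(bare, "")[[1]] %in% names(.RESIDUE_MONO))) {
      warning("rejecting peptide with non-amino-acid characters: ", pep)
      next
    }
    for (pr in names(proteins)) {
      seqs <- proteins[[pr]]
      starts <- as.integer(gregexpr(bare, seqs, fixed = TRUE)[[1]])
      starts <- starts[starts > 0L]
      if (length(starts) > 0L) hit_proteins[[pep]] <- union(hit_proteins[[pep]], pr)
      for (s in starts) {
        e <- s + nchar(bare) - 1L
        nterm_ok <- s == 1L || substr(seqs, s - 1L, s - 1L) %in% c("K", "R")
        cterm_ok <- e == nchar(seqs) || substr(seqs, e, e) %in% c("K", "R")
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = bare, protein = pr, start = s, end = e,
          tryptic = nterm_ok && cterm_ok, ambiguous = NA,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(peptide = character(), protein = character(),
                      start = integer(), end = integer(),
                      tryptic = logical(), ambiguous = logical()))
  }
  out <- do.call(rbind, rows)
  out$ambiguous <- vapply(out$peptide, function(p) length(hit_proteins[[p]]) > 1L, logical(1))
  names(out$ambiguous) <- NULL
  rownames(out) <- NULL
  out
}

#' Residue coverage of a protein by peptide matches
#'
#' Merges the matched residue ranges and reports the covered fraction.
#' Duplicate and overlapping ranges count once.
#'
#' @param matches data.frame with `start` and `end` columns (1-based
#'   inclusive), or a 2-column matrix.
#' @param protein_length Protein length in residues.
#' @return List with `fraction` (covered residues / length), `covered`
#'   (integer count) and `intervals` (merged ranges as a 2-column matrix).
#' @examples
#' peptide_coverage(data.frame(start = c(17, 19), end = c(40, 41)), 202)
#' @export
peptide_coverage <- function(matches, protein_length) {
  if (is.matrix(matches)) matches <- data.frame(start = matches[, 1], end = matches[, 2])
  stopifnot(protein_length >= 1)
  if (nrow(matches) == 0L) {
    return(list(fraction = 0, covered = 0L,
                intervals = matrix(integer(), ncol = 2, dimnames = list(NULL, c("start", "end")))))
  }
  if (any(matches$start < 1 | matches$end > protein_length | matches$start > matches$end)) {
    stop("match range out of protein bounds")
  }
  mask <- logical(protein_length)
  for (i in seq_len(nrow(matches))) mask[matches$start[i]:matches$end[i]] <- TRUE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind(start = starts[r$values], end = ends[r$values])
  list(fraction = sum(mask) / protein_length, covered = sum(mask), intervals = iv)
}

#' Theoretical monoisotopic m/z, allowing variable Met oxidation
#'
#' Computes the m/z for 0..n oxidised methionines and returns the candidate
#' closest to the observed value (or the unmodified one when no observation
#' is given).
#'
#' @param peptide Peptide sequence (flanks allowed).
#' @param z Charge state.
#' @param observed_mz Observed m/z used to select the oxidation count, or
#'   `NULL`.
#' @return List with `mz`, `n_oxidation`, and `delta` (theoretical minus
#'   observed; `NA` when no observation).
#' @export
theoretical_mz <- function(peptide, z, observed_mz = NULL) {
  bare <- strip_flanks(peptide)
  n_met <- sum(strsplit(bare, "")[[1]] == "M")
  cand <- vapply(0:n_met, function(k) {
    mz(monoisotopic_mass(bare, rep(.MET_OXIDATION, k)), z)
  }, numeric(1))
  if (is.null(observed_mz) || is.na(observed_mz)) {
    return(list(mz = cand[1], n_oxidation = 0L, delta = NA_real_))
  }
  k <- which.min(abs(cand - observed_mz))
  list(mz = cand[k], n_oxidation = k - 1L, delta = cand[k] - observed_mz)
}

#' Protein summary: masses and isoelectric point
#'
#' @param sequence Protein residue sequence.
#' @return List with `length`, `monoisotopic_mass`, `average_mass`, `pI`.
#' @export
protein_record <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  stopifnot(length(aa) > 0, all(aa %in% names(.RESIDUE_MONO)))
  list(
    length = length(aa),
    monoisotopic_mass = sum(.RESIDUE_MONO[aa]) + .WATER_MONO,
    average_mass = sum(.RESIDUE_AVG[aa]) + .WATER_AVG,
    pI = isoelectric_point(sequence)
  )
}

#' Isoelectric point by bisection on the Henderson-Hasselbalch charge sum
#'
#' Uses the EMBOSS pKa set.  Vendor software uses other pKa tables, so values
#' agree with published tables only to a few tenths of a pH unit.
#'
#' @param sequence Protein residue sequence.
#' @param tol Bisection tolerance on pH.
#' @return Estimated pI.
#' @export
isoelectric_point <- function(sequence, tol = 1e-4) {
  aa <- strsplit(sequence, "")[[1]]
  counts <- table(factor(aa, levels = names(.RESIDUE_MONO)))
  net_charge <- function(ph) {
    pos <- 1 / (1 + 10^(ph - .PKA$nterm)) +
      sum(vapply(c("K", "R", "H"), function(r) {
        counts[[r]] / (1 + 10^(ph - .PKA$side[[r]]))
      }, numeric(1)))
    neg <- 1 / (1 + 10^(.PKA$cterm - ph)) +
      sum(vapply(c("D", "E", "C", "Y"), function(r) {
        counts[[r]] / (1 + 10^(.PKA$side[[r]] - ph))
      }, numeric(1)))
    pos - neg
  }
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Read a peptide identification table
#'
#' Expects tab-separated columns `peptide`, `start`, `end`, `n_spectra`,
#' `mz_observed`, `z`, `score` (the layout of a search-engine peptide report).
#'
#' @param path Path to the TSV file.
#' @return data.frame.
#' @export
read_peptide_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide", "start", "end", "n_spectra", "mz_observed", "z", "score")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) stop("peptide table missing column(s): ", paste(missing, collapse = ", "))
  tab
}

#' Verify a peptide identification table
#'
#' Re-derives, for every row: the theoretical monoisotopic m/z at the reported
#' charge (allowing variable Met oxidation), whether it reproduces the
#' observed m/z within `mz_tol`, whether the reported residue range matches an
#' exact occurrence in the protein (when a sequence is supplied), and whether
#' the score clears the identification threshold (strict `>`).
#'
#' @param table data.frame as returned by [read_peptide_table()].
#' @param protein Optional protein residue sequence for mapping checks.
#' @param score_threshold Identification threshold on the engine score;
#'   a row passes only with score strictly above it.  Default 65.
#' @param mz_tol Tolerance on |theoretical - observed| m/z in Th.
#' @return List with `rows` (per-row report) and `summary` (distinct peptides,
#'   total spectra, covered fraction when ranges are available).
#' @export
verify_peptide_table <- function(table, protein = NULL, score_threshold = 65,
                                 mz_tol = 0.02) {
  bare <- vapply(table$peptide, strip_flanks, character(1))
  thr <- lapply(seq_len(nrow(table)), function(i) {
    theoretical_mz(bare[i], table$z[i], table$mz_observed[i])
  })
  rows <- data.frame(
    peptide = bare,
    z = table$z,
    mz_observed = table$mz_observed,
    mz_theoretical = vapply(thr, function(x) x$mz, numeric(1)),
    n_oxidation = vapply(thr, function(x) x$n_oxidation, integer(1)),
    mz_delta = vapply(thr, function(x) x$delta, numeric(1)),
    mass_ok = vapply(thr, function(x) abs(x$delta) <= mz_tol, logical(1)),
    score = table$score,
    score_ok = table$score > score_threshold,
    stringsAsFactors = FALSE
  )
  if (!is.null(protein)) {
    rows$range_ok <- vapply(seq_len(nrow(table)), function(i) {
      s <- table$start[i]
      substr(protein, s, s + nchar(bare[i]) - 1L) == bare[i]
    }, logical(1))
  }
  cov <- if (!is.null(protein)) {
    peptide_coverage(table[, c("start", "end")], nchar(protein))$fraction
  } else if (all(c("start", "end") %in% names(table))) {
    peptide_coverage(table[, c("start", "end")], max(table$end))$fraction
  } else NA_real_
  list(
    rows = rows,
    summary = list(
      n_peptides = length(unique(bare)),
      n_spectra = sum(table$n_spectra),
      coverage = cov
    )
  )
}
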