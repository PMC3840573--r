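#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) stop("sequences must be named")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a multiple sequence alignment from FASTA
#'
#' @param path Path to an aligned FASTA file (equal-length rows, gaps `-`).
#' @return Named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  aln <- read_fasta(path)
  if (length(unique(nchar(aln))) != 1L) stop("alignment rows have unequal length")
  aln
}
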