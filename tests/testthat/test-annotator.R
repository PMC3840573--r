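parent <- list(chromosome = "chr1", start = 100000L, end = 110000L)

test_that("an intronless, polyA-tailed, 5'-truncated copy on another chromosome is processed", {
  cand <- list(chromosome = "chr7", start = 500L, end = 3500L,
               intronless = TRUE, polyA_trait = TRUE, utr5_truncated = TRUE)
  expect_identical(classify_pseudogene(cand, parent), "processed")
})

test_that("a copy retaining introns is duplicated regardless of location", {
  cand <- list(chromosome = "chr7", start = 500L, end = 3500L,
               intronless = FALSE, polyA_trait = TRUE, utr5_truncated = TRUE)
  expect_identical(classify_pseudogene(cand, parent), "duplicated")
})

test_that("a same-chromosome copy near its parent is duplicated", {
  cand <- list(chromosome = "chr1", start = 150000L, end = 153000L,
               intronless = TRUE, polyA_trait = TRUE, utr5_truncated = TRUE)
  expect_identical(classify_pseudogene(cand, parent), "duplicated")
})

test_that("the duplicated rule takes precedence: a processed-looking copy beside a paralog is duplicated", {
  paralog <- list(chromosome = "chr9", start = 2000L, end = 5000L)
  cand <- list(chromosome = "chr9", start = 6000L, end = 9000L,
               intronless = TRUE, polyA_trait = TRUE, utr5_truncated = TRUE)
  expect_identical(classify_pseudogene(cand, parent, paralog_loci = list(paralog)),
                   "duplicated")
})

test_that("copies satisfying neither rule are reported ambiguous, never coerced", {
  # different chromosome but missing the polyA trait
  cand <- list(chromosome = "chr7", start = 500L, end = 3500L,
               intronless = TRUE, polyA_trait = FALSE, utr5_truncated = TRUE)
  expect_identical(classify_pseudogene(cand, parent), "ambiguous")
  # same chromosome as the parent but far beyond the window
  far <- list(chromosome = "chr1", start = 5e7, end = 5e7 + 3000,
              intronless = TRUE, polyA_trait = TRUE, utr5_truncated = TRUE)
  expect_identical(classify_pseudogene(far, parent), "ambiguous")
})

test_that("the genomic polyA trait needs a run of at least 8 A within the window", {
  expect_true(detect_polyA_trait(paste0("GGG", strrep("A", 8)))$trait)
  expect_identical(detect_polyA_trait(paste0("GGG", strrep("A", 8)))$position, 4L)
  expect_false(detect_polyA_trait(paste0("GGG", strrep("A", 7), "G"))$trait)
  # run entirely beyond the search window is not a trait
  expect_false(detect_polyA_trait(paste0(strrep("C", 45), strrep("A", 8)),
                                  window = 50)$trait)
  expect_error(detect_polyA_trait("AAAA", min_run = 8, window = 4), "window")
})

test_that("overlapping polyadenylation signals are each reported", {
  sig <- detect_polyA_signals("AATAAATTAAA")
  expect_identical(sig$position, c(1L, 6L))
  expect_identical(sig$motif, c("AATAAA", "ATTAAA"))
  expect_identical(nrow(detect_polyA_signals("CCCCCCCC")), 0L)
})

test_that("a perfect copy of the parental transcript has an intact reading frame", {
  tx <- simulate_parental_transcript(sim_config(seed = 11))
  res <- assess_orf(tx$sequence, tx$sequence, 1L, tx)
  expect_identical(res$status, "intact")
  expect_identical(res$disabling_positions, integer())
})

test_that("an in-frame stop at codon 50 is reported as a premature stop at codon 50", {
  tx <- simulate_parental_transcript(sim_config(seed = 11))
  mutated <- tx$sequence
  pos <- tx$cds_start + 3L * 49L  # first base of codon 50
  substr(mutated, pos, pos + 2L) <- "TAA"
  res <- assess_orf(tx$sequence, mutated, 1L, tx)
  expect_identical(res$status, "premature_stop")
  expect_identical(res$disabling_positions, 50L)
})

test_that("a single-base deletion inside the CDS shifts the frame at the right codon", {
  tx <- simulate_parental_transcript(sim_config(seed = 11))
  chars <- strsplit(tx$sequence, "")[[1]]
  del_at <- tx$cds_start + 9L  # 10th CDS base, codon 4
  subject <- chars
  subject[del_at] <- "-"
  res <- assess_orf(tx$sequence, paste(subject, collapse = ""), 1L, tx)
  expect_identical(res$status, "frameshift")
  expect_identical(res$disabling_positions, 4L)
})

test_that("an in-frame (length 3) indel does not count as a frameshift", {
  tx <- simulate_parental_transcript(sim_config(seed = 11))
  chars <- strsplit(tx$sequence, "")[[1]]
  at <- tx$cds_start + 30L
  query <- append(chars, c("-", "-", "-"), after = at)
  subject <- append(chars, c("C", "C", "C"), after = at)
  res <- assess_orf(paste(query, collapse = ""), paste(subject, collapse = ""), 1L, tx)
  expect_true(res$status %in% c("intact", "premature_stop"))
  expect_false(res$status == "frameshift")
})

test_that("a destroyed start codon means no ORF", {
  tx <- simulate_parental_transcript(sim_config(seed = 11))
  mutated <- tx$sequence
  substr(mutated, tx$cds_start, tx$cds_start) <- "C"
  expect_identical(assess_orf(tx$sequence, mutated, 1L, tx)$status, "no_orf")
})

test_that("Kozak conservation requires a purine at -3 and G at +4", {
  expect_true(kozak_conserved("GCCACCATGG", 7L))
  expect_true(kozak_conserved("GCCGCCATGG", 7L))
  expect_false(kozak_conserved("GCCTCCATGG", 7L))
  expect_false(kozak_conserved("GCCACCATGT", 7L))
  expect_warning(res <- kozak_conserved("ATGGGG", 1L), "context")
  expect_false(res)
})

test_that("gene distance uses 1-based inclusive edge-to-edge arithmetic and skips pseudogene neighbours", {
  cand <- list(chromosome = "chr1", start = 100L, end = 200L)
  genes <- data.frame(chromosome = "chr1", start = 300L, end = 400L)
  expect_equal(distance_to_nearest_gene(cand, genes), 99)
  overlapping <- data.frame(chromosome = "chr1", start = 150L, end = 400L)
  expect_equal(distance_to_nearest_gene(cand, overlapping), 0)
  pseudo_only <- data.frame(chromosome = "chr1", start = 300L, end = 400L,
                            is_pseudogene = TRUE)
  expect_message(res <- distance_to_nearest_gene(cand, pseudo_only), "no non-pseudogene")
  expect_true(is.na(res))
})

test_that("BED half-open intervals convert to 1-based inclusive", {
  out <- bed_to_inclusive(data.frame(start = c(0L, 99L), end = c(100L, 200L)))
  expect_identical(out$start, c(1L, 100L))
  expect_identical(out$end, c(100L, 200L))
})

test_that("classification recovers simulator truth perfectly at zero mutation rates", {
  cfg <- sim_config(seed = 1, subst_rate = 0, indel_rate = 0,
                    repeat_insert_rate = 0)
  tx <- simulate_parental_transcript(cfg)
  parent_locus <- list(chromosome = "chrP", start = 1L, end = nchar(tx$sequence))
  n_correct <- 0L; n_total <- 0L
  for (trial in 1:10) {
    genome <- random_genome(2, 50000, seed = 100 + trial)
    r <- retropose(tx, genome, cfg, event_id = paste0("retro", trial))
    tr <- r$truth
    retro_cand <- list(
      chromosome = tr$insertion_chromosome,
      start = tr$insertion_position,
      end = tr$insertion_position + tr$copy_length - 1L,
      intronless = !tr$retains_introns,
      polyA_trait = tr$has_polyA_tail,
      utr5_truncated = tr$trunc5_extent > 0L)
    got <- classify_pseudogene(retro_cand, parent_locus)
    n_total <- n_total + 1L
    if (got == "processed") n_correct <- n_correct + 1L
    # now duplicate that copy in place: the duplicate sits near its paralog
    d <- duplicate_locus(r$genome, list(
      chromosome = tr$insertion_chromosome, start = retro_cand$start,
      end = retro_cand$end, has_polyA_tail = TRUE, retains_introns = FALSE),
      sim_config(seed = trial, nearby_window = 5000), event_id = "dup")
    dup_cand <- list(
      chromosome = d$truth$insertion_chromosome,
      start = d$truth$insertion_position,
      end = d$truth$insertion_position + d$truth$copy_length - 1L,
      intronless = !d$truth$retains_introns,
      polyA_trait = d$truth$has_polyA_tail,
      utr5_truncated = retro_cand$utr5_truncated)
    got_dup <- classify_pseudogene(dup_cand, parent_locus,
                                   paralog_loci = list(retro_cand))
    n_total <- n_total + 1L
    if (got_dup == "duplicated") n_correct <- n_correct + 1L
  }
  expect_identical(n_correct, n_total)  # accuracy 1.0
})
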