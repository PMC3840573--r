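test_that("simulated parental transcripts satisfy every structural post-condition", {
  for (seed in c(1, 7, 42)) {
    cfg <- sim_config(seed = seed)
    tx <- simulate_parental_transcript(cfg)
    expect_identical(nchar(tx$sequence), 3475L)
    expect_identical(c(tx$cds_start, tx$cds_end), c(377L, 994L))
    cds <- substr(tx$sequence, tx$cds_start, tx$cds_end)
    expect_identical(substr(cds, 1, 3), "ATG")
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))  # no internal stop
    expect_true(kozak_conserved(tx$sequence, tx$cds_start))
    # at least one polyadenylation signal, one of them near the 3' terminus
    expect_gt(length(tx$polyA_signal_positions), 0)
    expect_true(any(tx$polyA_signal_positions > nchar(tx$sequence) - 50))
  }
})

test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 123)
  expect_identical(simulate_parental_transcript(cfg)$sequence,
                   simulate_parental_transcript(cfg)$sequence)
  tre <- fixture_tree()
  tx <- simulate_parental_transcript(cfg)
  copies <- data.frame(name = "pg1", trunc5_extent = 100L)
  r1 <- evolve_along_tree(tx, copies, tre, cfg, seed = 9)
  r2 <- evolve_along_tree(tx, copies, tre, cfg, seed = 9)
  expect_identical(r1$alignment, r2$alignment)
  expect_identical(r1$events, r2$events)
})

test_that("configuration validation rejects impossible study conditions", {
  expect_error(sim_config(cds_len = 100), "divisible by 3")
  expect_error(sim_config(utr5_len = 2), "Kozak")
  expect_error(sim_config(subst_rate = -1), ">= 0")
  expect_error(sim_config(dup_probability = 1.5), "dup_probability")
})

test_that("retroposition truth records replay to the exact inserted sequence", {
  cfg <- sim_config(seed = 8)
  tx <- simulate_parental_transcript(cfg)
  genome <- random_genome(2, 20000, seed = 8)
  r <- retropose(tx, genome, cfg, event_id = "e1")
  tr <- r$truth
  expect_identical(tr$event_kind, "retroposition")
  expect_false(tr$retains_introns)
  # replay: truncate + tail, then read back from the genome at the recorded locus
  replay <- paste0(substr(tx$sequence, tr$trunc5_extent + 1L, nchar(tx$sequence)),
                   strrep("A", cfg$polyA_tail_len))
  expect_identical(nchar(replay), tr$copy_length)
  extracted <- substr(r$genome[[tr$insertion_chromosome]],
                      tr$insertion_position,
                      tr$insertion_position + tr$copy_length - 1L)
  expect_identical(extracted, replay)
  # truncation never removes more than the 5'UTR plus half the CDS
  expect_lte(tr$trunc5_extent, (tx$cds_start - 1L) +
               floor((tx$cds_end - tx$cds_start + 1L) / 2))
})

test_that("tandem duplication inserts an identical copy adjacent to its source when the window is 0", {
  cfg <- sim_config(seed = 4, nearby_window = 0)
  genome <- random_genome(1, 5000, seed = 4)
  locus <- list(chromosome = "chr1", start = 1001L, end = 1500L,
                retains_introns = TRUE)
  src <- substr(genome[["chr1"]], 1001, 1500)
  r <- duplicate_locus(genome, locus, cfg)
  expect_identical(r$truth$event_kind, "duplication")
  expect_true(r$truth$retains_introns)
  expect_identical(r$truth$insertion_position, 1501L)
  expect_identical(substr(r$genome[["chr1"]], 1501, 2000), src)
  expect_identical(nchar(r$genome[["chr1"]]), 5500L)
})

test_that("with all mutation rates at zero every lineage carries the ancestral copy unchanged", {
  cfg <- sim_config(seed = 2, subst_rate = 0, indel_rate = 0,
                    repeat_insert_rate = 0)
  tx <- simulate_parental_transcript(cfg)
  tre <- fixture_tree()
  copies <- data.frame(name = "pg1", trunc5_extent = 150L)
  r <- evolve_along_tree(tx, copies, tre, cfg)
  rows <- r$alignment[grepl("^pg1@", names(r$alignment))]
  expect_identical(length(rows), tre$n_tips)
  expect_identical(length(unique(rows)), 1L)  # identical across all taxa
  # a copy row is a leading truncation gap block then contiguous sequence
  expect_true(all(grepl("^-*[ACGT]+$", rows)))
  expect_true(all(r$presence == "present"))
  expect_identical(nrow(r$events), 0L)
  # degapped copy equals the truncated transcript plus its polyA tail
  seq1 <- gsub("-", "", rows[[1]])
  expect_identical(seq1, paste0(substr(tx$sequence, 151, nchar(tx$sequence)),
                                strrep("A", cfg$polyA_tail_len)))
})

test_that("forced losses remove the copy from exactly the clade below the named branch", {
  cfg <- sim_config(seed = 6, subst_rate = 0, indel_rate = 0,
                    repeat_insert_rate = 0)
  tx <- simulate_parental_transcript(cfg)
  tre <- fixture_tree()
  copies <- data.frame(name = "pgX", trunc5_extent = 0L)
  r <- evolve_along_tree(tx, copies, tre, cfg,
                         forced_losses = data.frame(copy = "pgX", branch = "Glires"))
  lost <- rownames(r$presence)[r$presence[, "pgX"] == "absent"]
  expect_true(setequal(lost, c("Mumu", "Rano", "Orcu")))
  expect_identical(r$events$event_kind, "loss")
  expect_identical(r$events$donor_branch, "Glires")
})

test_that("realised substitution totals match the Poisson expectation of the study conditions", {
  cfg <- sim_config(subst_rate = 0.2, indel_rate = 0, repeat_insert_rate = 0)
  tx <- simulate_parental_transcript(sim_config(seed = 1))
  tre <- fixture_tree()
  copies <- data.frame(name = "pg1", trunc5_extent = 0L)
  seq_len_nt <- nchar(tx$sequence) + cfg$polyA_tail_len
  total_branch <- sum(tre$phylo$edge.length)
  lambda <- cfg$subst_rate / 100 * total_branch * seq_len_nt
  seeds <- 1:5
  totals <- vapply(seeds, function(s) {
    sum(evolve_along_tree(tx, copies, tre, cfg, seed = s)$branch_stats$n_subst)
  }, numeric(1))
  # mean of 5 independent Poisson sums within 3 standard errors of lambda
  se <- sqrt(lambda / length(seeds))
  expect_lt(abs(mean(totals) - lambda), 3 * se)
})

test_that("neutral codon alignments contain no stop codons in the reading frame", {
  phy <- ape::rtree(8)
  phy$edge.length <- phy$edge.length * 50
  aln <- simulate_codon_alignment(phy, 60, sim_config(seed = 10, subst_rate = 1))
  expect_true(all(nchar(aln) == 180L))
  for (s in aln) {
    codons <- substring(s, seq(1, 178, 3), seq(3, 180, 3))
    expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("per-taxon genomes assembled from a background replay each copy at its recorded locus", {
  cfg <- sim_config(seed = 14, subst_rate = 0.3)
  tx <- simulate_parental_transcript(cfg)
  tre <- fixture_tree()
  copies <- data.frame(name = c("pg1", "pg2"), trunc5_extent = c(0L, 200L))
  bg <- random_genome(2, 10000, seed = 14)
  r <- evolve_along_tree(tx, copies, tre, cfg, background = bg)
  for (taxon in c("Hosa", "Modo")) {
    g <- r$genomes[[taxon]]
    for (i in seq_len(nrow(g$loci))) {
      loc <- g$loci[i, ]
      expect_identical(
        substr(g$genome[[loc$chromosome]], loc$start, loc$end),
        r$sequences[[taxon]][[loc$copy]])
    }
  }
})
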