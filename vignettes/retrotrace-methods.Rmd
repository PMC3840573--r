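---
title: "retrotrace: methods, models and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{retrotrace: methods, models and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `retrotrace`, the
parameters and their defaults, the numerical conventions, and the design
decisions that shape the code. The worked example lives in the README; here
the focus is on *why* the package computes what it computes.

## 1. The biological model

A processed pseudogene is the genomic fossil of an mRNA: reverse
transcription of a spliced transcript followed by reinsertion. Three
hallmarks identify it — no introns, a 5'-truncated body (reverse
transcriptase dissociates before reaching the cap), and a genomically
encoded polyA tract at the 3' junction. A duplicated pseudogene instead
arises by tandem DNA duplication: it sits near its source locus and may
retain introns. These two routes have different evolutionary dynamics, so
the package keeps the classification explicit and three-valued
(`processed` / `duplicated` / `ambiguous`); nothing is silently coerced.

Once copies are identified across species, each copy's phylogenetic
distribution dates it. Under Dollo parsimony a copy is gained once and can
only be lost. The gain therefore sits on the stem branch of the carriers'
most recent common ancestor: the origination interval is
`[crown age of the carriers' MRCA, age of the next node above]`, open-ended
when the MRCA is the root. Absences inside the carrier clade are charged as
losses on the stems of the maximal all-absent subtrees. Taxa whose state is
unknown (fragmentary assemblies) are excluded from both the MRCA computation
and the loss cost: an unknown can neither extend the carrier clade nor prove
a loss.

A retrocopy may remain functional. The package assesses functionality along
independent lines that are deliberately kept as separate functions rather
than one composite score: reading-frame integrity in the parental frame,
Kozak context, site-wise selection (a counting test plus a consensus over
external likelihood methods), and peptide-level proteomic verification.

## 2. The simulator and its parameters

`sim_config()` defaults describe the study system the package was designed
around and are the *study conditions*, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `utr5_len` / `cds_len` / `utr3_len` | 376 / 618 / 2481 | a 3,475-nt parental mRNA whose CDS occupies positions 377–994 (17% of the transcript) |
| `trunc5_mean` | 300 | geometric 5'-truncation; mean chosen so most copies lose much of the 5'UTR while the CDS usually survives. Truncation is capped so at least half the CDS remains (a copy with less is not recoverable as a CDS-bearing candidate) |
| `polyA_tail_len` | 30 | genomic polyA tract appended at retroposition |
| `n_polyA_signals` | 4 | AATAAA/ATTAAA hexamers planted in the 3'UTR, one near the terminus |
| `subst_rate` | 0.2 / site / 100 Mya | mammalian-scale neutral rate |
| `indel_rate` | 0.02 / site / 100 Mya | small indels, geometric length (mean 3) |
| `repeat_insert_rate` | 0.2 / copy / 100 Mya | opaque repeat insertions, 300 nt ("Alu-like", 80%) or 6,000 nt ("L1-like", 20%) |
| `kappa` | 2.0 | transition/transversion ratio of the HKY-like process |

All stochastic processes are Poisson in branch length (Mya). Substitutions
use a single-base HKY-like kernel: a transition with probability
κ/(κ+2), each transversion with probability 1/(κ+2).

**Exact truth by construction.** Every copy shares the parental transcript's
coordinate system through a global column registry: insertions allocate new
column identifiers, deletions blank positions without removing columns. The
emitted multiple alignment of surviving copies plus the parental row is
therefore exact, not estimated, as are the presence/absence matrix and the
event table. At zero mutation rates every lineage carries the ancestral copy
unchanged, and the test suite verifies byte-identical replay of truth
records into sequences and genomes.

**Realism limits.** The simulator is a validation instrument, not a genome
model: background sequence is i.i.d. uniform (no isochores, no repeats
except the simulated insertions), rates are uniform across sites and
lineages, indels never straddle the copy boundary, repeat insertions are
random sequence rather than real Alu/L1 consensus, and tandem duplication
copies a fixed interval without conversion or inversion. These limits are
acceptable because the simulator's job is closed-loop validation of the
screening/annotation/dating logic, where the truth table is the point.

## 3. Numerical choices

**Distances.** Kimura 2-parameter:
`d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with transition proportion P
and transversion proportion Q; Jukes–Cantor: `d = -3/4 log(1 - 4p/3)`.
Columns where either sequence has a gap or ambiguity are pairwise-deleted.
Saturated pairs (log argument ≤ 0) are an error naming the pair — never a
silent NA — because a saturated distance poisons neighbor joining
downstream. The implementation is checked against `ape::dist.dna` in the
test suite.

**Neighbor joining.** Standard Saitou–Nei. Ties in the Q criterion are
broken lexicographically on cluster sort keys (the smallest member label),
and children are emitted in sort-key order, so the same matrix yields a
byte-identical newick string regardless of row order. Determinism here is a
correctness property: bootstrap replicates and consensus trees must not
depend on data-frame ordering.

**Bootstrap and consensus.** Columns are resampled with replacement;
replicates whose resampled matrix is saturated are redrawn (up to 100
attempts) so the requested replicate count is always honoured. The
majority-rule consensus keeps bipartitions present in strictly more than
50% of replicates — a split in exactly half is excluded. Bipartitions are
canonicalised as the side not containing the alphabetically first taxon.
`map_support()` retains all exact support values in its data frame and masks
values below the rendering threshold only in the node labels, which is the
convention used when drawing published trees.

**Dollo dating.** The origin node is the carriers' MRCA; an exhaustive
smallest-covering-clade oracle in the test suite confirms it on 500 random
patterns. Loss inference returns the stems of maximal subtrees whose
known-state leaves are all absent; subset-enumeration tests confirm
minimality and exact coverage.

**Selection counting test.** Ancestral nucleotides come from Fitch parsimony
with deterministic tie-breaking (toward a chosen reference taxon, else
alphabetical). Per codon site and branch, expected synonymous sites are the
parent/child average of the codon's synonymous-site count (changes to stop
codons count as non-synonymous; `ES + EN = 3 ×` branches by construction),
and observed counts average over the minimal substitution pathways that
avoid stop-codon intermediates (all pathways are used only if every one is
blocked). The site test is binomial: under a background ω each observed
substitution is non-synonymous with probability `ω·EN / (ω·EN + ES)`;
`p_positive = P(X ≥ ON)`, `p_negative = P(X ≤ ON)`. Sites with ambiguity
characters or stop codons — including stops introduced at internal nodes by
the reconstruction — are skipped with a warning rather than guessed. Scans
of fewer than 10 sequences are refused outright: site-wise counting tests on
tiny samples are noise.

**Consensus over methods.** Fixed thresholds, all strict: p < 0.1 (SLAC,
FEL, MEME), posterior > 0.9 (FUBAR), Bayes factor > 50 (REL); a site is
called only when at least two *distinct* methods agree in direction. The
call set is invariant to row order and duplication, and unknown method names
are rejected with a warning, not ignored.

**Peptide masses.** Monoisotopic residue masses (G 57.02146 … W 186.07931)
plus one water (18.010565 Da); `m/z = (M + z·1.007276)/z`. Met oxidation
(+15.99491 Da) is a variable modification: `theoretical_mz()` tries 0…nMet
oxidations and selects the candidate closest to the observed value. In the
shipped identification-table fixture the five Met-free peptides match to
2 decimals unmodified and all three Met-containing peptides match with
exactly one oxidation. Residue coverage is the union of matched residue
ranges divided by protein length; for the fixture this gives 75/202 = 37.1%,
one residue more than the 36.5% quoted by the original search engine, whose
counting convention is unknown — the discrepancy is reported, not
reconciled by guessing. The isoelectric point uses the EMBOSS pKa set and
bisection; vendor software uses other tables, so published pI values are
matched only to a few tenths of a unit.

## 4. Design decisions

- **Strict inequalities everywhere.** Similarity > 60, mRNA coverage > 35,
  CDS coverage > 85, identification score > 65, consensus thresholds, and
  the > 50% consensus rule are all strict. Boundary cases are tested
  explicitly.
- **Two screening filters, not one.** The retrieval filter (similarity and
  mRNA coverage) is deliberately permissive; the phylogeny-set filter (CDS
  coverage) is stricter because alignment-based tree building needs
  near-complete CDS homology. They are separate functions so the funnel is
  auditable.
- **Duplicated-rule precedence.** A tandem duplicate of a processed copy
  shows every processed hallmark yet is a duplicated pseudogene; proximity
  to a paralog therefore overrides the hallmark rule.
- **Local alignment honesty.** A Smith–Waterman hit may legitimately extend
  a few noisy columns past a truncated copy's edge (short net-positive
  segments), so similarity for truncated copies can fall marginally below
  100% even at zero divergence. The recall-1/similarity-100 invariant is
  therefore stated — and tested — for full-length copies, where the query is
  fully consumed and no such extension exists.
- **Simulation sizes are the package's choice.** Oracle-based property
  tests use 100 random additive matrices (≤ 8 taxa), 500 random Dollo
  patterns (≤ 10 leaves), brute-force Fitch on ≤ 6 taxa, and a 200-codon,
  12-taxon neutral alignment for the counting test's type-I error; these
  sizes balance coverage against a single-CPU test budget and were fixed
  before outcomes were inspected.
- **Fixtures are text and small.** The dated mammal tree stores the younger
  bound wherever its calibration sources give a range (the companion table
  `node_age_ranges.tsv` documents the ranges); the identification-table
  fixture mirrors a published peptide report's layout.

## 5. Limitations

- The counting selection test is a SLAC surrogate: it shares SLAC's
  counting philosophy but not HyPhy's likelihood machinery; its p-values are
  conservative at low substitution counts, and power at a handful of
  branches is limited. Use it as a screen, with the multi-method consensus
  for calls.
- Distance trees with bootstrap are not a substitute for ML tree searches;
  the package's phylogeny module targets reproducibility and support
  bookkeeping, not topology optimality.
- The annotator's polyA-trait detector is a run test, not a trained
  polyadenylation model; the Kozak check is the two-position consensus
  (purine at −3, G at +4) only.
- Dollo dating inherits the species tree's calibrations; intervals are only
  as good as the node ages supplied, and incomplete lineage sorting or
  independent parallel insertions (both violations of the Dollo assumption)
  would bias origins older.
- The screen's sensitivity depends on the exact-match seed length
  (default k = 11); heavily diverged or heavily rearranged copies may be
  missed, which matters when interpreting absences as losses.
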