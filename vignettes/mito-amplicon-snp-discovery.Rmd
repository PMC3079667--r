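---
title: "Amplicon-based mitochondrial SNP discovery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplicon-based mitochondrial SNP discovery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliSNP)
```

# The experimental design being modelled

`ampliSNP` models a combinatorial dual-barcode amplicon resequencing
experiment over a mitochondrial genome. Individuals are partitioned into
groups of up to 36; within a group each individual receives a unique
(forward MID, reverse MID) pair drawn from 6 forward × 6 reverse 10-bp
tags. Every individual is amplified over a panel of 20 amplicons (311–384
bp inserts, 7,215 bp total) spanning 10 mitochondrial regions, pooled per
group, and sequenced in a dedicated plate region, so the same MID pairs can
be reused across groups without ambiguity. The traceability contract is
strict: a read is attributed to an individual only when *both* terminal
MIDs decode. With a 576-sample, 16-group layout this yields 11,520 PCR
reactions, 10,920 of them for the analysis species.

Because the data type is sequence-and-count shaped, the package follows
Bioconductor conventions: S4 classes with validity methods for the central
objects (`ReferenceSequence`, `AmpliconPanel`, `ExperimentDesign`,
`SimulatedRun`, `DemuxResult`, `AmpliconPileup`, `VariantCallSet`),
accessor generics rather than slot access, and `show()` methods. Sequences
are handled as plain upper-case ACGT strings internally, with
`Biostrings` at the FASTA/FASTQ boundaries.

# Barcode decoding

MID decoding uses Levenshtein (edit) distance, not Hamming distance,
because indels dominate pyrosequencing error. A terminal window of 12
bases (MID length + 2) is compared against each tag of the role's set by
*prefix* edit distance — the minimum distance between the tag and any
prefix of the window — so terminal indels do not shift the comparison. The
unique tag within `max_mid_errors = 2` wins; a tie yields no assignment,
never an arbitrary choice. Tag sets are validated to be pairwise at edit
distance ≥ 5, which makes 2-error decoding provably unambiguous (by the
triangle inequality a window within 2 of two tags would force the tags
within 4 of each other); a tie therefore indicates ≥ 3 errors and the read
is rightly distrusted. Single-MID rescue is deliberately not implemented:
assignment requires the full read including both MIDs.

Reads that fail are partitioned into reason codes (`missing-MID`,
`ambiguous-MID`, `unknown-pair`, `primer-mismatch`, `empty-insert`), and
`demuxStats()` reports the assignment percentage at one decimal.

# Amplicon routing, trimming and alignment

All 20 amplicons co-occur in each pool, so each read is routed by matching
both primers (≤ 2 edits each, again prefix edit distance) against the
post-MID termini; the unique best total distance wins. Inserts are trimmed
of MIDs and primer binding sites — densities are therefore per insert base,
matching the panel accounting — and reverse-strand reads are
reverse-complemented so inserts are reference-oriented with the original
strand retained.

Alignment is semi-global affine-gap dynamic programming implemented in
C++: the insert is consumed in full, unaligned reference ends are free.
Scoring defaults are match +1, mismatch −1, gap open −2, gap extend −1 (a
gap of length $L$ costs $2 + (L-1)$). The vendor software this stage
replaces ran with unstated "default stringency" settings, so the scoring
scheme is exposed as configuration (`alignParams()`) with these stated
defaults. Two determinism measures matter for reproducibility:

* tie-breaking in the traceback prefers match/mismatch over deletion over
  insertion and takes the leftmost end column, so a given input always
  yields the same alignment;
* indels are left-normalized within homopolymer runs before pileup entry,
  so identical events from different reads aggregate at one canonical
  anchor (deletions at their first deleted base, insertions at the base
  they follow).

Reads whose alignment identity (match columns / alignment columns) falls
below `min_identity = 0.70` are excluded and counted in the pileup QC
ledger. This cutoff is this package's explicit substitute for the vendor
software's unstated low-quality trimming, surfaced as configuration.
Inserts longer than twice the amplicon are flagged unalignable.

# The pileup

`AmpliconPileup` keeps base counts per (individual, amplicon, 1-based
reference position, strand), with `depth` counting every read spanning the
position — including reads that delete it — plus separate deletion and
insertion event ledgers keyed by normalized anchor. Multi-base insertions
are keyed by their full inserted sequence, so 2-bp events (the D-loop-type
indels the panel design cares about) are first-class. Supporting coverage
for a variant counts only reads that truly show the alternate allele;
reads covering the site without the variant enter the denominator only.

# The validation cascade

Candidates are any non-reference allele observed at least once. Stages run
in fixed order; each stage's survivor set is a subset of the previous
one's, and `filterTrace()` records the funnel:

1. **Artifact rejection.** Homopolymer under-read flag: 1-base deletion
   whose base sits inside or adjacent to a reference run of
   ≥ `min_hp_len = 3` identical bases (threshold chosen to cover the
   artifact class being filtered; it is configuration, not biology).
   Carry-forward flag: 1-base insertion equal to a reference base 1–2
   positions upstream. A flagged candidate is rejected only when no
   override-strength evidence exists — ≥ 2 individuals each showing it at
   ≥ 0.95 of depth with > 20 double-stranded reads. The original
   adjudication of these artifacts was manual flowgram inspection; the
   override is the codified substitute, and its thresholds are exposed.
2. **Double-strand support**, per individual: ≥ 1 forward and ≥ 1 reverse
   supporting read. This is enforced per individual, not per cohort,
   because validation rests on per-individual replicate reads.
3. **Replicate support.** An individual passes outright at ≥ 90 % support
   of covering depth *and* > 10 supporting reads in total. "More than 10
   supporting reads in both read directions" is read as a total with both
   directions represented (the companion rescue wording speaks of a
   singular total); the stricter per-direction reading is available as
   `strict_direction = TRUE`. Individuals at ≥ 90 % but ≤ 10 reads pass
   only by rescue: another individual must pass outright for the same
   variant. The 90 % denominator is the individual's covering depth at the
   site after QC; reads truncated before the site never enter it.
   Zero-depth individuals are excluded, not failed.
4. **Multiple individuals.** Variants passing in fewer than 2 individuals
   are rejected as uninformative and possibly PCR/sequencing error.

Validated substitutions are classified as transitions (A↔G, C↔T) or
transversions; validated alternates sharing a position form a multiallelic
group and count once per allele in per-region totals.

# The read simulator

`simulateHaplotypes()` + `simulateReads()` generate the data every
downstream stage is tested against, with per-read provenance (sample,
amplicon, strand, applied errors) so assignments can be audited
exhaustively. Defaults encode the study-scale conditions:

* depth per (individual, amplicon): rounded normal truncated at 0, mean
  27.3, SD 11.74 — the only depth information the design states is this
  mean ± SD, so no heavier-tailed family is assumed;
* strand balance 0.5 — both-strand evidence is required downstream but no
  orientation ratio is stated, so symmetry is the neutral choice;
* error model: substitutions per base, homopolymer under-reads per run of
  ≥ 3, one carry-forward insertion per read with probability
  `carry_forward_rate` (inserted base duplicates the base 1–2 upstream,
  biased to follow a different intervening base, mimicking flow-order
  carry-forward), and truncation removing one MID end (the MID plus a
  random slice of primer) with probability `truncation_rate`;
* qualities are a constant Q30 placeholder: every filter in the cascade is
  count-based, so quality strings are carried for format compatibility
  only.

What the simulator does **not** emulate — and therefore what passing tests
cannot certify about real data: flow-space signal and quality-correlated
error profiles, chimeric reads, contamination and index hopping, PCR
duplicates, per-plate-region yield variation (real runs show unexplained
region-to-region yield differences), and amplicon-specific dropout. The
simulator's truncation model is a proxy for the real "short reads missing
a MID" loss mode, whose true rate is not known; the packaged default 0.015
keeps assignment in the high-90s as observed in practice.

# Problem sizes and numerical choices

Tests and the acceptance script run a desk-scale layout: 2 groups × 12
samples × 4 amplicons (≈ 2,400 reads at depth 25), a deliberate stand-in
for the full 16 × 36 × 20 design that preserves every structural feature
(MID reuse across groups, pooled amplicons, both strands, rescue-eligible
carriers). The noise-free end-to-end identity check uses fixed depth 25 so
that every carrier clears the > 10-read threshold deterministically;
noisy replicates use depth 25 ± 6. Recovery is then exact: with error
rates at zero the validated set equals the planted set with zero false
positives, and across 20 seeded replicates at realistic 454 error rates
(substitutions 0.002/base, under-reads 0.1/run, carry-forward 0.05/read)
no artifact indel validates.

Densities are reported at 6 decimals via `round()` (round-half-even).
Assignment percentages are reported at one decimal. The reference is
treated as linear: no panel amplicon spans the circular origin, so
circular coordinate arithmetic is out of scope. All sequence fixtures
shipped with the package are synthetic stand-ins (reference, primers, MIDs
and the sample roster are generated, and named `_synthetic`); insert
lengths, the plate layout and the published per-amplicon variant counts
are the real panel's configuration. `inst/scripts/make_fixtures.R`
regenerates all of them from a fixed seed.

# Known limitations

* mtDNA is treated as effectively haploid per individual: no heteroplasmy
  modelling, no genotype likelihoods.
* The candidate enumerator is exhaustive (any non-reference allele), so
  raw candidate counts scale with error rates and are not comparable
  across error models — only the post-cascade set is.
* The known/novel comparison in `snpMap()` is a generic prior-panel diff;
  no literature panel ships with the package.
* Population-sharing summaries expose both natural denominators (all
  validated variants, SNPs only) because the choice is not fixed by the
  method; on synthetic location structure they are verified against direct
  recounts, not against any real-world sharing figures.
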