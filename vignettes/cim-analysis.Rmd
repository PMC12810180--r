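---
title: "Calling and interpreting crosslink-induced mutations in CLASH data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and interpreting crosslink-induced mutations in CLASH data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cimclash)
```

## The problem

CLASH and CLASH-like protocols (iCLIP, CLEAR-CLIP) UV-crosslink an
Argonaute or PIWI protein to its bound mRNA, purify the complex, and ligate
the guide small RNA to the co-purified mRNA fragment.  A single chimeric
("hybrid") read therefore names both partners of an interaction: a miRNA or
piRNA arm and the mRNA target fragment.  Reverse transcription across the
residual crosslinked peptide is error-prone, leaving crosslink-induced
mutations (CIMs) — single-base deletions and substitutions at or near the
crosslinked nucleotide — as a molecular footprint of the bound protein at
single-nucleotide resolution.

`cimclash` decomposes chimeric reads into their two arms, calls CIMs on the
mRNA arm from CIGAR/MD alignment tags, maps each CIM into the coordinate
system of the targeting small RNA, profiles guide:target base pairing around
CIMs, aggregates hybrids into target sites with abundance and score tiers,
and scores functional relevance via CIM enrichment and rank-based /
permutation fold-change statistics.  A bundled synthetic CLASH generator
with a complete truth table makes every stage testable without external
sequencing data.

## Pipeline model and assumptions

The pipeline (`run_pipeline()`) runs:

1. **Preprocess** — 3' adapter removal (first position where the read
   matches an adapter prefix over ≥ 5 bases), 3' quality trimming (BWA-style
   partial-sum cut at Q30), length filter (17–70 nt), and deduplication.
   Deduplication keys on the read sequence alone; the collapsed read count
   becomes the read's *weight*, the unit of every downstream tally.  Weight
   is conserved at every stage: reads are only classified, or dropped with a
   counted reason, and the manifest records the accounting.
2. **Hybrid detection** — a seed-and-extend aligner (exact 12-mer anchoring
   to shortlist references, then a local Gotoh alignment with match +1,
   mismatch −1, gap open −6, gap extend −1; a 1-nt gap costs 7) aligns each
   read against the small RNA and transcript references.  A read becomes a
   hybrid when a small-RNA segment 5' of a transcript segment jointly covers
   it with ≤ 4 nt arm overlap, ≤ 4 nt unaligned bases at each end and ≤ 4 nt
   between the arms.  Ties are resolved by total alignment score, then arm
   length, then lexicographic reference ids, so decomposition is
   deterministic.  Externally produced MD-tagged SAM (e.g. from a
   genome-scale aligner run with all alignments reported) can be ingested
   instead via `ingest_sam()`.
3. **CIM calling** — `extract_mutations()` walks CIGAR and MD jointly,
   emitting one record per deleted reference base and per mismatch
   (insertions are parsed but excluded from CIM statistics, since the
   crosslink footprint consists of deletions and substitutions).  Two
   filters follow, in this order: mutations inside the junction overlap are
   removed (they could belong to either arm), and reads whose mutated arm
   sequence also occurs exactly elsewhere in the transcript set — e.g. in a
   sister transposon-family copy — lose all their mutation annotations
   (`filter_ambiguous()`; the read itself is kept).
4. **Pairing geometry** — mRNA regions shorter than the guide are extended
   with transcript context and scanned for the best-pairing window of guide
   length (`extend_site()`); a window of guide length is likewise scanned
   within longer regions.  Small RNA position *i* pairs antiparallel with
   window base *L − i + 1*.  "Paired" means Watson–Crick only by default;
   G:U wobbles are tracked separately and can be counted as paired
   (`count_gu = TRUE`) — the stricter reading is the default because the
   field does not agree on whether wobbles stabilise Argonaute targeting.
   The seed is positions 2–7 (a `seed_range` argument accommodates the
   2–8 convention), non-seed 8–21 clipped to the guide length.
5. **Sites and tiers** — hybrids sharing a guide and an identical extended
   window form one target site; weights and per-kind CIM-carrying weights
   are summed.  Abundance tiers: high ≥ 5 read equivalents, medium [2, 5),
   low < 2.  Score tiers are tertiles over sites (top ⌈n/3⌉, then
   ⌈(n−top)/2⌉, remainder low).  Poor-score flags use the conventional
   external-tool thresholds (pirScan < −15, miRanda < 140, strict).
6. **Non-hybrid CIM map and enrichment** — mRNA-only reads also carry CIMs.
   Their per-position deletion map is compared inside vs outside each site
   window with a one-sided Mann–Whitney test (region greater; significant
   at p ≤ 0.01), and each hybrid/site is annotated with the outcome.
   Deletions, not substitutions, are the default signal: substitutions have
   a much higher sequencing background.

### Statistics

`group_compare()` reports a two-sided Mann–Whitney U test with midrank tie
handling — exact by full enumeration of label arrangements when
n₁ + n₂ ≤ 12, otherwise the tie-corrected normal approximation with
continuity correction — together with a label-permutation test on the
difference of group medians, `p = (1 + #{|perm| ≥ |obs|}) / (1 + n_perm)`,
n_perm = 10000 by default, fully seed-determined.  The permutation statistic
(median difference), two-sidedness and the +1 smoothing are this package's
choices: robust against outliers in fold-change data and never reporting
p = 0.  `region_enrichment_test()` is one-sided because "enriched" is
directional; a region spanning the whole transcript leaves the test
undefined, and an all-tied comparison reports p = 1.

`window_count()` counts reads whose 5' ends fall in a 50-nt half-open window
centred on the transcript coordinate opposite guide position 10 (a 100-nt
window is a single argument away).  `rpkm()` and
`classify_wago_targets()` (IP/input > 2 after a +1 pseudocount, strict)
implement the conventional normalisation and target definitions.
`ratio_mutant_over_wt()` uses a +1 pseudocount by default and drops sites
with zero signal in both conditions.

### Numerical and interface conventions

All coordinates are 1-based closed intervals inside R (the Bioconductor
convention) and in the TSV outputs; BED output is 0-based half-open and
bedGraph follows BED.  Window-scan ties resolve to the smallest start.
Deletion read coordinates are reported as the first read base after the
deleted reference base; a deletion counts as inside the junction overlap
when both flanking read bases are.  The built-in pairing scorer (+2 per
Watson–Crick seed pair, +1 per Watson–Crick non-seed pair, +0.5 per wobble)
is a deliberately simple stand-in for external target scorers; per-site
scores from pirScan- or miRanda-like tools can be supplied wherever a score
is consumed, with their published poor-score thresholds.

## The synthetic CLASH generator

`simulate_references()` and `simulate_library()` emulate the data-generating
process end to end, with every quantity recorded in a truth table:

* random transcripts and guides (uniform base composition; guides with
  homopolymer runs ≥ 5 nt are excluded — a run in the guide puts a run in
  the target window, where the position of a deleted base is undefined);
* one pairing window per guide planted into a transcript, either with a
  perfect seed or with one seed mismatch compensated by full non-seed
  pairing, plus background mismatches outside the seed (10% per position by
  default);
* per-site crosslink positions: the deletion-side crosslink is drawn from
  `round(Normal(11.5, 1))` in guide coordinates; the substitution sits
  2 nt (± 1 with probability 0.2) before it on the guide, reflecting the
  interpretation that deletions mark the stall site of the reverse
  transcriptase while substitutions arise as it misincorporates shortly
  after bypassing the crosslink.  Coupling the two (rather than drawing the
  substitution independently from `Normal(9.5, 1)`) keeps the substitution
  marginal centred at 9.5 while making the per-site deletion−substitution
  offset a stable −2 — with independent draws the weighted offset mode
  flips between −3 and −1 at realistic site counts;
* uridine preference: the origin base under each crosslink is drawn
  (T with probability 0.6, others uniform) and the *guide* base opposite it
  is set to its Watson–Crick partner.  This inverts the biological causality
  (in vivo, crosslinks seek uridines; here the sequence adapts to the
  crosslink) but is read-level equivalent and, unlike rejection sampling on
  transcript bases, neither biases nor widens the positional law;
* per-read mutation probability 0.6 (half deletions) — far above the
  frequencies seen in real libraries, deliberately: the generator's job is
  to power positional, pairing and spectrum analyses at desk scale, and the
  per-read rate is an explicit dial (`cim_prob`) rather than a claim about
  chemistry.  T→C makes up 85% of T substitutions and C→T 84% of C
  substitutions, per the observed spectra;
* fragments Uniform(18, 35) nt around the window (shorter-than-guide
  fragments lie inside it, longer ones contain it).  The lower bound equals
  the aligner's minimum reported mRNA segment, so every emitted hybrid is
  in principle detectable.  Mutation-carrying fragments are ≥ 25 nt with
  ≥ 12 intact bases flanking the mutation, guaranteeing an exact 12-mer
  anchor on both sides of a deletion;
* deletions are placed only where the gapped alignment is strictly optimal:
  the deleted base must differ from both neighbours, and any ±1
  frame-shifted ungapped competitor must pay more than the 7-point gap cost
  on either side.  Without this, a deletion inside a quasi-repeat is
  genuinely unlocalisable and no aligner could recover the planted truth;
* chimeric junctions are emitted clean: fragment starts are resampled until
  the transcript context 5' of the fragment cannot extend the mRNA arm into
  the guide arm (beyond 4 nt for window-containing fragments, at all for
  shorter ones), including through single-gap extensions.  Junction-
  ambiguous chimeras are exercised with constructed reads in the unit
  tests instead;
* PCR duplicates (multiplicity 1 + Geometric(0.7)), uniform per-base
  sequencing errors, and a 3' adapter on every read.

What passing tests on this generator do **not** show about real data:
ligation biases, reverse-transcription drop-off, structured (non-uniform)
quality and error profiles, multi-way chimeras, spliced genome-space
alignment, and genuinely ambiguous junctions or repeat-embedded deletions
are all absent or excluded by construction.  The generator validates the
*machinery* — decomposition, CIM arithmetic, coordinate mapping, filters,
statistics — not the biology.

```{r quick-run}
cfg <- sim_config(n_hybrid_reads = 300, n_nonhybrid_reads = 50, seed = 42)
sim <- simulate_library(cfg)
res <- run_pipeline(sim$reads, sim$refs, adapter = cfg$adapter)
head(res$sites[, c("srna_id", "transcript_id", "window_start",
                   "total_weight", "cim_del_weight", "abundance_tier")])
res$profile[9:13, ]
evaluate_cim_calls(res$cims, res$reads, sim$truth)[c("precision", "recall")]
```

## Design choices where the design was open

* **Dedup key**: sequence only (not sequence + quality); representative id
  is the lexicographically smallest, for reproducible output.
* **Arm order**: the guide arm must be 5' of the mRNA arm by default
  (`any_order = FALSE`), matching the ligation chemistry; relaxable.
* **Ambiguity filter**: "perfectly align elsewhere" is read strictly as an
  exact substring occurrence away from the called locus
  (`max_alt_mismatch = 0`, relaxable).  Filters only ever remove records,
  and run junction-first, ambiguity-second.
* **Fractional weights** arise only from even splitting over equally good
  assignments upstream (ingested alignments); the built-in decomposition is
  deterministic and never splits.
* **Tie-break order in decomposition** puts total alignment score before
  reference-id lexicography; a pure lexicographic tie-break can prefer a
  mismatched paralogous window over the error-free one.
* **Evaluation metric**: `evaluate_cim_calls()` reports both record-level
  and read-weight-level precision/recall.  The weighted view matches the
  pipeline's accounting — a duplicated genuine crosslink carries its read
  count while a one-off sequencing artifact counts once.

## Problem sizes

The bundled analyses run at desk scale by design: reference sets of tens to
hundreds of transcripts of ~300 nt, libraries of 300–5000 chimeric
templates, 10⁴ permutations, and exact Mann–Whitney enumeration up to
combined n = 12.  These sizes keep the entire test suite and the
reproduction script in the minutes range on a single core while leaving
every statistic well-powered.

## Known limitations

The built-in aligner reports one best local alignment per (read, reference)
pair and transcript-space coordinates only; genome-space (spliced)
alignment, multi-way chimeras and intermolecular mRNA–mRNA hybrids are out
of scope.  Equivalence with any external chimera-calling toolchain is not
claimed — external alignments are supported through SAM ingestion instead.
The exact Mann–Whitney enumeration is exponential and intentionally capped;
larger samples use the standard tie-corrected approximation.  CIMs mark
crosslinks, not function: absence of a CIM at a site is not evidence of
non-functionality, and the package's regulatory readouts (22G windows,
mutant/wild-type ratios) are comparative, not mechanistic.
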