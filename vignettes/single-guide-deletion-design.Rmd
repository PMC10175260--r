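---
title: "Designing LCR-mediated deletions with a single CRISPR guide"
author: "scoredel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing LCR-mediated deletions with a single CRISPR guide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scoredel)
```

## The problem and the model

Recurrent microdeletions such as the 22q11.2 "A-D" (~3 Mb) and "A-B"
(~1.5 Mb) deletions are flanked by low copy repeats (LCRs) — segmental
duplication blocks sharing high sequence identity. Engineering such a
deletion with two independent guides is inefficient because both cuts
must land in the same cell. The single-guide alternative exploits the
repeat homology: one Cas9 guide whose 20-nt protospacer (plus an NGG
PAM) occurs in *both* flanking repeats produces two simultaneous
double-strand breaks; non-homologous end joining (NHEJ) across the two
blunt ends then yields either the deletion of the intervening segment
or, less usefully, its inversion.

`scoredel` implements that design procedure and the downstream clone
screen as testable computations:

1. **Guide enumeration** (`enumerate_guides`): every 20-mer followed by
   a PAM-matching 3-mer, on both strands, entirely inside a repeat
   interval. The blunt cut is placed 3 bp 5' of the PAM (between
   protospacer positions 17 and 18), the standard SpCas9 convention;
   nothing in the design depends on a different cut model, but the cut
   coordinate is what deletion sizes are computed from.
2. **Shared-guide search** (`find_shared_guides`): protospacers with an
   exact, PAM-compatible occurrence in both repeats. Exactness is
   deliberate — the guide must cut both repeats with full
   complementarity; near-matches are the off-target module's concern.
   Opposite-strand occurrence pairs are reported but flagged, since the
   junction model assumes direct-orientation repeats (the 22q11.2
   situation).
3. **Off-target filter** (`scan_offtargets`,
   `apply_specificity_filter`): a guide is rejected when any
   PAM-adjacent site *outside* the designated on-target span lies at
   Hamming distance below `min_mismatches` (default 4, i.e. sites with
   fewer than four mismatches disqualify). Mismatches are counted
   uniformly over all 20 positions; no seed-region weighting, no
   bulges, and N never matches anything — all conservative choices.
   NGG is required at candidate sites by default; `allow_nag = TRUE`
   admits the weaker NAG class.
4. **Cross-assembly verification** (`verify_guides`): the shared-guide
   check and the specificity filter are re-run independently per
   assembly (e.g. GRCh38 and GRCh37) and the verdict is their strict
   conjunction, guarding against reference-update artifacts.
   Assemblies are linked by annotation *names*; no liftover.
5. **Product prediction** (`predict_products`): for cut boundaries
   `a < b`, the deletion product has size `b - a` and junction
   `genome[a-k, a) + genome[b, b+k)`; the inversion product
   reverse-complements the intervening segment in place. With
   perfectly homologous repeats and same-offset cuts, the deletion
   junction reconstitutes an intact guide site — a useful string-level
   invariant that the tests assert. Duplication products are not
   modelled (they involve inter-chromatid events not predictable from
   one haplotype sequence). The junction flank default `k = 30` is a
   primer-design-friendly window.

## Clone screening

Edited clones are screened by genomic qPCR. `relative_copy_number`
implements the delta-delta-Ct chain: replicate Cts are averaged per
(sample, gene) — plain arithmetic mean, no outlier rejection — then
`dCt = Ct(gene) - Ct(reference)` within a sample,
`ddCt = dCt(sample) - dCt(calibrator)`, and relative copy number
`2^-ddCt`. The reference gene (RPPH1, outside the deletion) has RCN 1
by construction; a heterozygous deletion is expected at 0.5.

`classify_clones` turns RCNs into calls using marker genes inside the
deletion (e.g. TBX1 for the A-B design) versus flanking it (e.g.
CRKL): *deletion* when every in-region RCN is at most `del_max` and
every flanking RCN sits in the diploid band; *no_deletion* when
everything is diploid; *ambiguous* otherwise. The thresholds
(`del_max = 0.7`, band `0.8–1.2`) are explicit midpoints between the
heterozygous expectation 0.5 and diploid 1.0 — the screening decision
in the laboratory is usually visual, so these are a documented,
configurable stand-in.

`insilico_pcr` validates screening primers by exact matching (both
orientations); product length is the inclusive outer-primer span, the
convention under which the shipped seven-gene panel
(`inst/extdata/qpcr_primers_22q11.tsv`) reproduces its printed sizes
(TBX1 101 bp, HIRA 84, COMT 83, CRKL 103, BID 78, MAPK1 70, RPPH1
120). It is a validation tool, not a primer designer: no mismatch
tolerance, no 3'-anchoring or thermodynamic model.

`region_log2fc` summarises expression or protein-abundance matrices
the way dosage figures are drawn: per-feature
`log2((mean_del + c) / (mean_ctl + c))` with pseudocount `c = 0.5` for
stability near zero, then means over features overlapping the deleted
interval versus other features on the same contig. Swapping group
labels negates everything (antisymmetry), which the tests exploit. No
differential-expression testing is re-implemented here — shrinkage,
dispersion estimation and FDR belong to dedicated DE packages and are
out of scope; this module reproduces only the dosage-summary
computation.

## Synthetic data and what it does (not) show

All tests run on seeded generators with machine-readable truth tables.

`simulate_locus` builds `flank | LCR_A | spacer | LCR_B | flank`. Two
choices matter:

* **Repeat background is free of GG and CC dinucleotides**, hence free
  of NGG PAMs on either strand, so the only Cas9 sites inside a repeat
  are the planted ones. This makes "the planted guide is exactly the
  shared guide set" a well-defined truth even at 100% repeat identity
  (two identical repeats with unconstrained background would share
  every guide they contain). The cost is mildly unrealistic repeat
  composition; real LCRs are PAM-dense, which affects guide *counts*,
  not the correctness properties tested here.
* **Divergence never touches planted footprints.** When identity < 1,
  mutated positions are sampled outside the planted protospacer+PAM
  blocks, so truth tables stay valid by construction.

Decoy off-target sites are copies of the planted protospacer mutated
at exactly the requested number of positions, with AGG PAMs, injected
into the flanks — outside the exempt on-target span — so the
specificity boundary (reject at 3 mismatches, accept at 4) can be
asserted exactly. Default dimensions are the engineered 22q11.2 A-B
locus scaled to desk size: 5-kb repeats, 50-kb spacer (for the ~1.5-Mb
segment), 10-kb flanks; the scaling changes deletion size, not any
tested property, and keeps the full suite and the acceptance script in
tens of seconds on one CPU.

`simulate_ct` draws
`Ct = base_ct(gene) - log2(copy_number/2) + N(0, sd)` per replicate;
`simulate_expression` draws log-normal control means, scales in-region
deletion means by the dosage factor (default 0.5), and samples
negative-binomial counts (`variance = mu + dispersion * mu^2`,
dispersion 0.1, 3 samples per group, 200 in-region and 1000 flanking
features by default). None of these emulate amplification-efficiency
drift, plate effects, batch structure or library-size variation:
passing tests demonstrate that the *computations* are correct under
their stated model, not that real screens are noise-free.

## Numerical notes and a known statistical limit

The delta-delta-Ct estimate is a difference of four triplicate means,
so its standard deviation in log2 units is `2 * sigma / sqrt(3)` for
per-replicate Ct noise `sigma`: 0.115 cycles at `sigma = 0.1`, 0.231
at `sigma = 0.2`. At `sigma = 0.2` the diploid band 0.8–1.2 is only
about 1.2–1.4 standard deviations wide, so roughly one diploid cell in
five falls outside it and a 50-clone screen essentially never
classifies perfectly; accuracy plateaus around 70–90%. This is a
property of the estimator, not of the implementation — the noise-free
chain is exact (0.5 and 1.0 to machine precision), and the ±10%
coverage property is asserted in the tests at `sigma = 0.05`, where
the closed form above predicts ~98% coverage. Screens needing sharper
calls at higher noise must raise replicate counts, not thresholds.

Other numerics: interval logic is 0-based half-open throughout (BED
taken as-is; any 1-based display is formatting); guide output order is
deterministic (position then strand; protospacer-lexicographic for
shared sets); junction flanks clip at contig ends; soft-masked
lowercase is uppercased and treated as ordinary sequence (no masking
rule is assumed); ambiguity codes other than N are rejected unless
explicitly mapped to N.

The off-target search ships two engines on purpose: a vectorised
shift-comparison scan and a position-by-position brute force that is
exact by construction (`method = "bruteforce"`). The brute force is a
first-class mode, not a test fixture; the fast engine is
equivalence-tested against it and against an independent oracle in the
test suite across thresholds 0–4. Genome-scale scanning of a full
human assembly is supported as input but is not a test requirement.

## Limitations

* No on-target efficiency scoring (Doench/Azimuth), no CFD/MIT
  off-target scores, no bulge-tolerant alignment search.
* No repair-outcome modelling: the deletion/inversion products are
  idealised NHEJ joins without indel spectra.
* Exempt-region semantics put everything outside the designated
  on-target span in play as "nontarget"; whether additional paralogous
  repeats should be exempt is a user decision via
  `specificity_policy(exempt_intervals = ...)`.
* In-silico PCR is exact-match only, by design.
* The dosage summary assumes pre-normalized, non-negative abundances.
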