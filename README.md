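# scoredel

Single-guide CRISPR deletion design and clone screening for copy
number variants flanked by low copy repeats (LCRs), such as the
22q11.2 A–B (~1.5 Mb) and A–D (~3 Mb) microdeletions.

Recurrent microdeletions arise between segmental-duplication blocks
whose high mutual identity also offers an engineering shortcut: a
single Cas9 guide whose 20-nt protospacer (with an NGG PAM) occurs in
*both* CNV-flanking repeats cuts twice at once, and non-homologous end
joining of the two blunt ends deletes (or inverts) the intervening
segment. `scoredel` is for researchers building such isogenic deletion
models: it finds the shared guides, screens them for specificity,
verifies them across genome assemblies, predicts the rearrangement
products, and implements the downstream qPCR clone screen and
region-dosage summaries.

## What it computes

* **Guide sites.** All protospacer+PAM occurrences on both strands
  inside a repeat interval; blunt cut 3 bp 5′ of the PAM.
* **Shared guides.** Protospacers with exact occurrences in both
  flanking repeats (the single-guide design criterion), with all cut
  pairs and predicted deletion/inversion products
  (size = cut_b − cut_a; junction = `genome[a−k,a) + genome[b,b+k)`).
* **Specificity.** Genome-wide mismatch-tolerant search; a guide is
  rejected when any PAM-adjacent site outside the designated on-target
  span has fewer than `min_mismatches` (default 4) mismatches. A
  brute-force engine, exact by construction, is a first-class mode.
* **Cross-assembly verification.** The design re-checked independently
  per assembly (e.g. GRCh38 and GRCh37); the verdict is the strict
  conjunction.
* **Clone screen.** Relative copy number by the ΔΔCt method
  (RCN = 2^−ΔΔCt against a reference gene, default RPPH1, and a
  diploid calibrator sample); deletion calls from in-region versus
  flanking marker genes; exact-match in-silico PCR of the screening
  primer panel (shipped in `inst/extdata/qpcr_primers_22q11.tsv`).
* **Dosage summaries.** Per-feature log2 fold change
  (deletion vs control, pseudocount 0.5) and in-region vs flanking
  means, the computation behind "genes inside the deletion drop by
  ~one log2 unit" figures.
* **Synthetic data.** Seeded generators for two-repeat loci with
  planted guides and graded off-target decoys, Ct tables with known
  copy number, and dosage-affected expression matrices — each with a
  truth table, so every computation above is testable at desk scale.

## Worked example

Design a deletion on a simulated 22q-like locus (5-kb repeats, 50-kb
spacer) with one planted shared guide and a 4-mismatch decoy:

```r
library(scoredel)

loc   <- simulate_locus(seed = 7, decoy_spec = 4L)
lcr_a <- loc$intervals[loc$intervals$name == "LCR_A", ]
lcr_b <- loc$intervals[loc$intervals$name == "LCR_B", ]

shared <- find_shared_guides(loc$genomes, lcr_a, lcr_b)
as.data.frame(shared)
#>            protospacer n_occ_a n_occ_b multi_site opposite_strand deletion_size
#> 1 CATCTGTACATAGCTAGATC       1       1      FALSE           FALSE         55000

pol <- specificity_policy(exempt_intervals = exempt_span(lcr_a, lcr_b))
scan_offtargets(shared[[1]]$protospacer, loc$genomes, pol)
#>   contig strand start mismatches pam exempt
#> 1 chrSim      + 11191          0 AGG   TRUE
#> 2 chrSim      + 66191          0 AGG   TRUE

guide_products(loc$genomes, shared[[1]])[, c("kind", "cut_a", "cut_b", "size")]
#>        kind cut_a cut_b  size
#> 1  deletion 11208 66208 55000
#> 2 inversion 11208 66208 55000
```

The one shared guide is the planted one; its only sub-threshold sites
are the two on-target occurrences (0 mismatches, exempt — cutting both
repeats is the point), so the guide is accepted; the decoy at distance
4 does not disqualify it. The predicted deletion spans repeat start to
repeat start (55 kb here), and the deletion junction reconstitutes an
intact guide site because the repeat copies are identical.

Screening clones from qPCR Ct values:

```r
cn  <- matrix(c(1L, 2L, 2L, 2L), nrow = 2,
              dimnames = list(c("clone1", "WTC"), c("TBX1", "CRKL")))
tbl <- simulate_ct(cn, base_ct = c(TBX1 = 26, CRKL = 25, RPPH1 = 20),
                   calibrator_sample = "WTC", noise_sd = 0, seed = 1)
rcn <- relative_copy_number(tbl)
classify_clones(rcn, "TBX1", "CRKL", exclude_samples = "WTC")
#>   sample     call rcn_TBX1 rcn_CRKL
#> 1 clone1 deletion      0.5        1
```

A heterozygous deletion shows RCN 0.5 at the in-region marker (TBX1)
and 1.0 at the flanking marker (CRKL).

A command-line front end with `design`, `simulate`, `offtarget`,
`verify`, `pcr`, `screen-qpcr` and `dosage` subcommands is installed
at `system.file("scripts", "scoredel", package = "scoredel")`.

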