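---
title: "Detecting and validating CRISPR spacer arrays in metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and validating CRISPR spacer arrays in metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cascr)
```

## The problem

CRISPR loci record a cell's history of viral encounters as an array of
near-identical *repeats* (19–38 nt here) alternating with variable
*spacers* (19–48 nt) sampled from invading DNA. Mining spacers out of
shotgun metagenomes links bacterial and archaeal hosts to the viruses
that infect them, and — aggregated over many samples — reveals which
viral genes are preferentially targeted. The catch is that microbial
genomes are full of tandem repeats whose geometry mimics CRISPR arrays,
so naive repeat-finding has a high false-discovery rate. `cascr`
therefore splits the problem in two:

1. **Detection** — a permissive scan proposes candidate repeat-spacer
   arrays;
2. **Validation** — each candidate must present independent evidence
   before its spacers are trusted.

## Detection model

Detection follows the classic exact-word scan of repeat finders. A seed
is a set of at least `min_repeats` occurrences of the same
`search_window`-mer (default 8) whose successive distances lie in
`[spacer_len_min + repeat_len_min, spacer_len_max + repeat_len_max]` —
the only spacings consistent with a repeat-spacer period. Anchors are
extended column by column while at least `column_consensus_min`
(default 0.75) of the instances agree with the per-column consensus
(ties in the consensus go A < C < G < T).

Three further rules are the package's own design choices, made where a
column-consensus extender is genuinely underdetermined:

* **Boundary polish.** After extension, terminal repeat columns are
  trimmed until they are perfectly conserved across instances. With a
  0.75 threshold and, say, four instances, a random flanking column has
  a ~20% chance of clearing the consensus bar, so unpolished extension
  systematically overshoots array boundaries by a base or two; the
  polish removes that bias at the cost of slightly shortening repeats
  in noisy reads (where terminal sequencing errors now trim a column).
* **Edge-clipped units are dropped.** A read or contig that ends inside
  a flanking repeat leaves that unit's true extent unknowable; guessing
  shifts every spacer boundary in the array. Units touching the
  sequence ends are therefore dropped, and the array is reported only
  if the remaining units still satisfy every length invariant. This is
  the main reason read-level precision trails contig-level precision,
  the same ordering reported for the original pipeline.
* **Dissimilar spacers.** True spacers are independent captures, so a
  candidate whose "spacers" are near-identical (pairwise identity above
  `max_spacer_identity`, default 0.8) is a tandem repeat with a
  conserved gap, not a CRISPR array, and is discarded.

Overlapping candidates keep the one with more repeats, then the longer,
then the leftmost. All coordinates in the package are 0-based,
half-open, forward strand.

## Validation model

A candidate array is *bona fide* when any of three conditions holds:

* **(i) Cas homology** — the sequence carrying the array (the whole
  read or contig, not a window) has a translated-search hit to a known
  Cas protein at E ≤ `cas_e_max` (default 1e−12);
* **(ii) repeat homology** — the consensus repeat hits a known-repeat
  database at E ≤ `repeat_e_max` (default 1e−5, word size 4; both
  orientations are searched, since repeat databases store an arbitrary
  strand);
* **(iii) spacer regularity** — the population standard deviation
  (÷ n) of spacer lengths is ≤ `spacer_sd_max` (default 2 bp).

*Conservative* mode requires (i) or (ii); *liberal* mode also accepts
(iii). The conservative spacer set is therefore always nested inside
the liberal one. A single-spacer array has SD 0 by definition and so
passes (iii); such arrays are flagged (`single_spacer`) so users can
filter them. Position frequency matrices of repeat sets
(`repeat_pfm()`), with per-column information content
`2 + Σ f log2 f` bits, provide the diagnostic that bona fide repeat
collections carry strong positional signal while false-positive repeat
collections look uniform.

## The search engine

Rather than shelling out to an external aligner, `cascr` includes a
seeded local-alignment search: every exact shared word seeds a windowed
Smith–Waterman extension (compiled code) around the seed diagonal, with
affine gaps costing `gap_open + L·gap_extend`. Raw scores are converted
to bit scores and E-values with Karlin–Altschul statistics: λ solves
`Σ pᵢpⱼ exp(λ sᵢⱼ) = 1` (bisection-free root finding to 1e−9) and K is
computed by the lattice-case series truncated at 1e−9. For the default
nucleotide scheme (+1/−2, gaps 2/1) this reproduces the published
ungapped reference parameters (λ 1.3327, K 0.621) to a fraction of a
percent. Gapped searches reuse the ungapped λ and K — a documented
approximation that is adequate for the loose thresholding this pipeline
needs (the contracts here are E-value *cutoffs*, never exact parity
with any external tool's E-values). Tests verify that whenever the
optimal local alignment contains an exact seed word, the seeded search
returns exactly the full Smith–Waterman optimum (500 random pairs per
run, checked against an independent dynamic-programming oracle).

Defaults: nucleotide match +1, mismatch −2, gap open 2, gap extend 1;
protein BLOSUM62 with gap open 11, extend 1, seed word 4. Word sizes
for the pipeline's searches follow the upstream protocol: 4 for repeat
validation, 7 for spacer-to-virome matching (E ≤ 0.1), translated Cas
search at E ≤ 1e−12, protein annotation at E ≤ 1e−3.

## Downstream analyses

* **Abundance.** Read-level surveys report spacers per Mbp of raw
  reads; contig-level surveys report *normalized spacer abundance*:
  the sum over spacers of mean per-base read depth (from SAM mappings
  or a coverage table) divided by mapped read Gbp. Correlations with
  sample covariates (depth, GC) use the plain product-moment
  correlation with a t-based two-sided p-value, uncorrected.
* **Protospacer targets.** Virome sequences that themselves carry
  liberal-bona-fide arrays are removed first, so spacer-to-array hits
  are not mistaken for protospacers. Spacers are then matched at
  word size 7, E ≤ 0.1, keeping one best HSP per (spacer, contig).
  ORFs are called only on matched contigs — deliberately *after* the
  search, so matches spanning two adjacent genes remain visible — by a
  transparent ATG-to-stop caller (min 30 aa, both strands). This
  replaces a published gene caller on purpose: gene coordinates are
  needed only to assign matches, and an auditable caller keeps the
  assignment reproducible. Matches are assigned to every overlapping
  ORF (≥ 1 nt); two adjacent overlapped ORFs set the spanning flag.
  Great-circle distances between the samples of a spacer and its
  matched virome use the haversine formula on a 6371.0088 km sphere.
* **Enrichment.** Each ORF is annotated with the function label whose
  hits accumulate the highest total bit score (ties: more hits, then
  lexicographic). Free-text labels collapse onto reporting categories
  through an ordered keyword map; the default map shipping in
  `inst/extdata/` is this package's explicit, overridable best effort —
  the exact grouping behind published category tables is not specified
  anywhere. Expected counts are `n_matched × background frequency`
  with the background built from *all* database ORFs through the
  identical annotation pipeline ("no hits" included), so expected
  counts conserve `n_matched`. Fold changes are reported
  half-away-from-zero at one decimal with full precision retained in
  machine output. Printed tables that round *expected* before printing
  can show folds that differ from the printed-integer ratio in the last
  decimal; this package always recomputes from the unrounded values.

## The synthetic generator and what it does (not) show

`make_genomes()` builds uniform-random genomes with planted arrays and
tandem-repeat decoys at recorded offsets, and `simulate_reads()` draws
reads with normal lengths and a linear 3'-increasing substitution ramp
(`p0 → p1`) — a simple stand-in for pyrosequencing-style error accrual;
indels are not modelled. One generator property is worth stating
plainly: the columns immediately flanking each planted repeat are
guaranteed non-uniform across instances (one spacer base is resampled
when chance would make them uniform). Without this, roughly one fixture
in six contains an array whose boundaries are *genuinely ambiguous in
the sequence itself* — no sequence-only detector could recover the
planted coordinates — and the truth table would be ill-defined.

The benchmark conditions are fixed once: 10 genomes × 100 kb, 5
carrying one planted array each (repeat lengths 26–32 nt, 3–5 spacers
of 26–45 nt), 5 carrying tandem-repeat decoys (periods that either
violate the spacer bounds or have conserved gaps), a 20-entry
known-repeat database containing the 5 planted repeats, and a 5-protein
toy Cas database. Under these conditions detection plus liberal
validation reaches precision 1.0 and sensitivity 1.0 at the
100%-identity rule, and read-level runs with increasing `p1` degrade
monotonically. Problem sizes elsewhere in the test-suite (2 kb negative
controls over 100 seeds, 250–1500 simulated reads, 500 oracle pairs)
were chosen as the smallest sizes at which the property being tested is
statistically unambiguous.

Uniform-random backgrounds are the easy case: real genomes have skewed
composition, low-complexity tracts, and genuine tandem families, so
passing these tests bounds correctness of the machinery, not
performance on real data. Real-data features deliberately not emulated:
indels and chimeras in reads, assembly artifacts, compositional bias,
degenerate IUPAC codes (rejected at ingest), and arrays with highly
diverged repeat instances.

## Evaluation semantics

`evaluate_predictions()` counts a prediction as a true positive when it
matches a planted spacer exactly (string or reverse complement — the
100%-identity rule); below 1.0, greedy length-sorted clustering assigns
membership at global identity over the shorter sequence, mirroring
common clustering practice (novelty analyses use 0.98). `tp` counts
predictions, `fn` counts truth spacers no prediction matched, so
duplicated correct predictions inflate neither sensitivity nor
precision denominators asymmetrically. Undefined ratios (empty
prediction sets) are NA-flagged, never silently 0.

## Known limitations

* Gapped E-values reuse ungapped λ/K; absolute E-values differ from
  external tools (thresholds are the contract).
* The ORF caller is ATG-to-stop; GTG/TTG starts and partial ORFs at
  contig edges are not called.
* Condition (i) searches the whole carrying sequence, so a Cas gene
  anywhere on a long contig validates every array on it.
* One best HSP per (spacer, contig) means multi-copy protospacers on
  one contig count once.
* The detector requires ≥ `min_repeats` full repeat units after edge
  clipping; very short reads lose truncated arrays by design.
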