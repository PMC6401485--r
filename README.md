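# cascr — CRISPR spacer discovery, validation, and protospacer target analysis

`cascr` finds CRISPR repeat-spacer arrays in metagenomic reads and
assembled contigs and decides which of them to believe. It is written
for microbial ecologists and virologists who mine shotgun metagenomes
for spacers — the 19–48 nt fragments of foreign (usually viral) DNA
that prokaryotes archive between near-identical repeats — and who then
use those spacers to link hosts to their viruses and to ask which viral
genes are preferentially targeted.

Repeat structures that merely *look* like CRISPR arrays are common in
microbial genomes, so detection alone has a high false-discovery rate.
`cascr` therefore uses a two-stage design:

1. **Detection** (CRT-style): an exact-match word scan finds ≥ *m*
   occurrences of the same *k*-mer (defaults *k* = 8, *m* = 3) spaced
   consistently with a repeat+spacer period, extends them column by
   column while ≥ 75% of instances agree with the column consensus,
   and enforces repeat lengths 19–38 nt, spacer lengths 19–48 nt, and
   mutually dissimilar spacers.
2. **Validation**: a candidate array is *bona fide* if
   (i) its carrying sequence has a translated-search hit to a known
   Cas protein (E ≤ 1e−12), (ii) its consensus repeat hits a
   known-repeat database (E ≤ 1e−5, word size 4), or (iii) the
   population SD of its spacer lengths is ≤ 2 bp.
   **Conservative** mode requires (i) or (ii); **liberal** mode also
   accepts (iii).

Alignment is done by a built-in seeded local-alignment search
(word seeding, compiled banded Smith–Waterman extension) with
Karlin–Altschul statistics: bit = (λ·S − ln K)/ln 2 and
E = K·m·n·e^(−λS), with λ solving Σ pᵢpⱼ e^(λsᵢⱼ) = 1 and K from the
lattice-case series. Downstream modules cover spacer-to-virome
protospacer matching (word 7, E ≤ 0.1) with ORF assignment and
spanning-spacer detection, normalized spacer abundance
(cumulative spacer coverage per mapped Gbp), cumulative-bit-score
functional annotation with actual/expected fold-change enrichment, and
great-circle distances between sampling sites. A synthetic-metagenome
generator with planted truth supports sensitivity/precision
benchmarking end to end.

## Worked example

Plant one array (4 × 28-nt repeat, spacers of 33/35/34 nt) in 3 kb of
random sequence, detect it, and validate against a 20-entry repeat
database that contains the planted repeat:

```r
library(cascr)
set.seed(4)
rnd <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")
repeat_seq <- rnd(28)
spacers <- vapply(c(33, 35, 34), rnd, character(1))
ins <- paste0(repeat_seq, spacers[1], repeat_seq, spacers[2],
              repeat_seq, spacers[3], repeat_seq)
contig <- seq_records(paste0(rnd(1500), ins, rnd(1500)), id = "contig1")

a <- find_arrays(contig)[[1]]
c(a$start, a$end)
#> [1] 1500 1714
a$consensus_repeat
#> [1] "TGGGGTGCACGTCCCCTATGGGGATTAA"

repeat_db <- build_search_db(
  seq_records(c(repeat_seq, replicate(19, rnd(30))),
              id = sprintf("rep%02d", 1:20)), 4)
ev <- validate_array(a, contig, cas_db = NULL, repeat_db = repeat_db)
round(ev$spacer_sd, 3); signif(ev$repeat_hit$evalue, 2)
#> [1] 0.816
#> [1] 6.5e-13
ev$bona_fide_conservative
#> [1] TRUE
extract_bona_fide_spacers(list(ev), "conservative")$id
#> [1] "contig1|array1|spacer1" "contig1|array1|spacer2" "contig1|array1|spacer3"
```

The array is recovered at its exact planted coordinates (1500–1714,
0-based half-open); the consensus repeat equals the planted repeat; the
repeat-database hit (E = 6.5e−13 ≤ 1e−5) makes the array bona fide even
in conservative mode, and its three spacers are exported under
`{seq_id}|array{i}|spacer{j}` ids. (With no Cas database supplied,
condition (i) is evaluated as false with a warning.)

A thin command-line front end is installed with the package
(`system.file("cli", "casc", package = "cascr")`) with subcommands
`run`, `simulate`, `evaluate`, and `enrich`.

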