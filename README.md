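# dotvntr

Dot-plot discovery of variable-number tandem repeats (VNTRs) in
protein-coding genes, from genome assemblies.

## What it does, and for whom

Long-read assemblies make both alleles of a gene available end to end, so a
coding-region VNTR — a unit of ~10 bp to 1 kb repeated in tandem, with copy
number differing between strains — shows up directly in a dot plot of the
reference CDS against the strain allele as a block of parallel lines offset
from the main diagonal. `dotvntr` is for genomicists comparing annotated
assemblies (e.g. inbred mouse strains against a reference) who want those
blocks found, measured and flagged deterministically.

The package implements the full scan:

* **seqio** — read FASTA/GFF3, extract spliced strand-resolved CDS, pair
  orthologs by gene ID (longest transcript canonical), write TSV calls and
  BED blocks;
* **chunker** — the 10 kb comparison windows: short CDS centre-padded with
  `N`, long CDS split, 0.1–10 kb tails padded, smaller tails dropped;
* **anchors** — the dot-plot primitive: exact 12-mer seeds extended
  ungapped under an X-drop rule (+5/−4, X = 30, score ≥ 70), plus a fixed
  750 × 750 pixel raster (830 × 830 with axes) for visualization;
* **detector** — groups off-diagonal anchors into signal blocks, estimates
  the repeat unit as the fundamental period of the parallel-diagonal
  family, counts copies per allele as span/unit, and flags polymorphism
  when the height/width ratio `r = strain span / reference span` leaves
  the band (0.9, 1.1), for blocks above 0.80 confidence; arrays of ≤ 5
  copies are rejected;
* **repeatstats** — unit decomposition, GC content, nucleotide diversity π
  (average pairwise per-site difference among units), Welch test for GC
  enrichment, per-gene summaries;
* **haplopaint** — mosaic painting of MHC-like haplotypes: 100 kb slices,
  per-10 kb-window SNP counts against each donor, windows with fewer than
  3 SNPs re-labelled to the highest-hierarchy qualifying donor
  (default order `b k d a q c g z`);
* **simgen** — a seeded generator for ortholog pairs with planted arrays,
  annotated toy genome pairs, and mosaic haplotypes, with exact ground
  truth.

In notation: for a detected block with spans `w_ref` and `w_strain` and
fundamental period `u`, copy numbers are `c_x = w_x / u`, the ratio is
`r = w_strain / w_ref`, and π over units `s_1..s_n` is
`π = (2 / n(n−1)) Σ_{i<j} d(s_i, s_j) / u` with `d` the Hamming distance
over unambiguous sites.

## Worked example

An ortholog pair built with one exact 42 bp unit repeated 11 times in the
reference allele and 25 times in the strain allele, inside 1 kb unique
flanks:

```r
library(dotvntr)

pair <- gen_vntr_pair(unit_len = 42, copies_a = 11, copies_b = 25,
                      divergence = 0, flank_len = 1000, seed = 7)
call <- scan_pair(pair$seq_a, pair$seq_b, gene_id = "Ifi207_like")
call$blocks
#>      gene_id a_start a_end b_start b_end unit_len copies_a copies_b        r
#>  Ifi207_like    1000  1462    1000  2050       42       11       25 2.272727
#>  confidence n_diagonals
#>           1          35
call$flagged; call$reason
#> TRUE "ratio_high"
```

One block: the repeat unit is 42 bp, the reference allele carries 11.0
copies (span 462 bp starting right after the 1 kb flank), the strain 25.0
copies (1050 bp), `r = 1050/462 = 2.27` falls far above 1.1, so the gene is
flagged as a copy-number polymorphism candidate. All 35 expected parallel
diagonals (11 + 25 − 1) carry anchors, so confidence is 1. Decomposing the
strain block confirms the planted array:

```r
units <- decompose_units(pair$seq_b, call$blocks[, c("b_start", "b_end")],
                         call$blocks$unit_len)
c(units$n_units, units$gc, units$pi)
#> 25 0.5 0     # 25 identical units; pi = 0 at zero divergence
```

For whole annotated genomes, `run_scan()` drives
extract → pair → anchors → detect → flag and writes `vntr_calls.tsv` plus
per-allele block BEDs, ranked by confidence. A thin CLI wraps the same
functions (`inst/scripts/dotvntr.R`, subcommands `scan`, `simulate`,
`paint`).

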