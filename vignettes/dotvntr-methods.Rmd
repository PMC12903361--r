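---
title: "Dot-plot geometry for coding-region VNTR discovery: methods and design"
author: "dotvntr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dot-plot geometry for coding-region VNTR discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Variable-number tandem repeats (VNTRs) inside protein-coding sequences —
units of roughly 10 bp to 1 kb repeated in tandem, with copy numbers that
differ between individuals or inbred strains — are effectively invisible to
short-read variant calling: reads map ambiguously inside the array and the
signal dissolves into coverage fluctuations and spurious heterozygous SNPs.
With long-read genome assemblies, however, both alleles of a gene are
available end to end, and a VNTR announces itself in the simplest possible
display: a dot plot of the reference coding sequence against the strain
allele shows a block of parallel lines offset from the main diagonal, one
line per pair of repeat copies.

`dotvntr` turns that visual signature into a deterministic geometric
computation. The pipeline is: extract and pair orthologous CDS from two
annotated assemblies; compute ungapped local match segments ("anchors", the
line primitives of a dot plot); group off-diagonal anchors into repeat
signal blocks; estimate each block's fundamental period (the repeat unit
length) and per-allele copy numbers; and flag copy-number polymorphism by
the block's height/width ratio. A separate component paints a query
haplotype of an MHC-like locus by per-window SNP density against a donor
panel under a fixed precedence order. A seeded simulator generates every
input the pipeline consumes, with machine-readable ground truth, and is the
basis of the test suite.

# The dot-plot primitive: seed-and-extend anchors

An anchor is a maximal ungapped local match between the two sequences. We
find them with exact 12 bp seeds extended in both directions under an
X-drop rule: match +5, mismatch −4, stop when the running score falls 30
below its maximum, report the maximal-scoring extent, keep segments with
score ≥ 70 and identity ≥ 0.7. `N` never seeds and always scores as a
mismatch, so ambiguity padding cannot create signal. Transitions are not
privileged: a uniform −4 replaces 4-way substitution scoring, because the
finer split is not material to whether a diagonal line exists. With these
cutoffs, a reportable anchor needs at least 14 exact-matching bases, and two
unrelated random 2 kb sequences essentially never produce one — which is
what makes the unique-flank negative controls clean.

Two implementation details matter for precision:

* **One extension per diagonal region.** In a tandem array every k-mer
  recurs on every copy diagonal; a scan frontier per diagonal skips seeds
  inside already-scanned regions, keeping the cost near-linear per diagonal.
  Because seeds are visited in ascending order on both axes, anchor sets are
  exactly symmetric under exchanging the two sequences.
* **Boundary-precision end trim.** The +5/−4 maximal-score extent is right
  for sensitivity but lets an anchor wander past a repeat boundary through a
  ~50%-identity tail — and it does so *coherently*: all copy diagonals are
  unit multiples, so every anchor in the family compares the same flank
  bases against the same unit phase and overshoots by the same amount. Each
  anchor is therefore re-trimmed to its maximal-scoring subsegment under a
  stricter +1/−3 scheme, so retained ends need ≥ 75% local identity. Exact
  matches are untouched; residual overshoot is a base or two, only when the
  flank happens to continue the unit.

The fixed-size raster (750 × 750 pixel plot area; 830 × 830 with the axis
margin) exists for visualization and for any plugged-in image-based
detector. Detection itself operates in sequence space on the anchors:
exact coordinates beat pixel quantization for period and copy-number
estimation, and the raster is a lossy projection of the same geometry.

# Chunking

Coding sequences are compared in fixed 10 kb windows. A CDS shorter than
the window is centre-padded with `N` to the window length (an odd remainder
adds the extra base on the right — a deterministic tie-break); a longer CDS
is split into full windows, and a trailing fragment of 100 bp to 10 kb is
centre-padded into a final window while shorter tails are dropped and
logged. The retained interval [100 bp, 10 kb) reads the bounding values as
inclusive-exclusive; tails under 100 bp carry no detectable repeat signal at
the anchor score floor. Because `N` neither seeds nor matches, padding is
geometrically inert.

The scan path computes anchors over the full (un-split) CDS pair in native
coordinates, which is exactly the union of the per-window dot plots without
boundary artifacts; the block detector additionally merges blocks that abut
within one unit length on both axes, so window-split anchor sets (e.g. from
an external dot-plot stage) reassemble real arrays. We verified both routes
agree on arrays split mid-way.

# From anchors to repeat blocks

The detector realizes three annotation criteria. A region is a candidate
block where the reference axis is covered by **two or more distinct
diagonals** — a unique alignment contributes one diagonal; only repeats
produce parallel families. Candidate runs closer than 500 bp are joined,
then:

1. **Copy-number floor.** Estimated copies (block span divided by unit
   length) must strictly exceed 5 on at least one allele; a 5-copy array is
   rejected. The comparison is made at 0.1-copy resolution because block
   edges are localized to a few bp.
2. **Gap splitting.** Within a candidate, a projected gap wider than
   `max(2 × unit, 500 bp)` splits the block: separate arrays with a unique
   spacer are separate signals.
3. **Clutter rejection.** A block whose anchors average shorter than half a
   unit *and* cover less than 30% of the bounding box is scattered
   microhomology, not a repeat. (These two thresholds are this package's
   quantification of "short lines and points with no clear outline".)

Within a block, the diagonal values of its anchors are clustered with a
±2 bp tolerance, weighted by anchor length. The **fundamental period** is
the smallest observed off-diagonal offset `d` such that (nearly all —
weighted fraction ≥ 0.9) offsets sit within tolerance of integer multiples
of `d`. Candidates are the observed offsets themselves, which prevents the
degenerate answer `d = 1`; ties break toward smaller `d`. Offsets are taken
relative to the heaviest diagonal (the block's backbone), so the same rule
serves self-plots (backbone 0) and cross-allele plots.

Block spans use **edge consensus**: the modal anchor start/end within one
unit of the extreme. In an exact array the entire parallel family starts
and ends on the array boundary, while overshooting extensions scatter — so
the mode is the boundary. Copy numbers are span/unit per allele, and the
height/width ratio is

r = strain-axis span / reference-axis span.

The orientation is fixed and recorded because the flagging band (0.9, 1.1)
is not symmetric under r → 1/r. A block's **confidence** is the fraction
of expected parallel diagonals that carry an anchor (`⌊(spanA + spanB)/unit⌋
− 1` expected, i.e. `copiesA + copiesB − 1` for exact arrays) times the
anchor coverage of the bounding box, clamped to [0, 1]; a noiseless exact
array scores exactly 1. Calls are ranked by confidence; blocks at or below
0.80 are ignored for flagging; a remaining block with r < 0.9 or r > 1.1
flags the gene as a length-polymorphism candidate.

When two arrays of the *same* unit sit on one gene, the cross-array
rectangles are also genuine homology; the detector keeps, per
reference-axis run, the strain-side cluster consistent with the colinear
backbone (the nearest anchor reaching well outside the run), so the
reported blocks are the on-path ones.

The trained object-detection stage used to box dot-plot images is replaced
here by this deterministic detector; the raster plus `export_pgm` keep the
image route open for any external model, but all reported numbers come from
sequence-space geometry.

# Repeat statistics

`decompose_units` cuts a block into unit-length windows at the phase
(0 … unit−1) maximizing mean pairwise unit identity, computed per column
from base counts. When the block length is a whole number of units, the two
sub-unit overhangs of an off-phase cut are rejoined into one wrapped unit —
a tandem array is circular in phase — which makes the recovered unit
multiset invariant under rotation of the block start; remaining ties pick
the lexicographically smallest unit. Sub-unit overhang is reported
separately (`overhang_bp`) and `copies` counts whole units.

Nucleotide diversity π is the average pairwise per-site difference among
units, with no finite-sample correction; sites with `N` in either unit of a
pair drop out of that pair's numerator and denominator. Units of unequal
length (indel-containing arrays) are pairwise globally aligned
(`Biostrings::pairwiseAlignment`), differences normalized by mean unit
length, and the result is flagged `aligned = TRUE` — both direct and
alignment-based modes are available because either convention is defensible.
GC content is (G+C)/(A+C+G+T), and GC enrichment of VNTRs over background
(e.g. whole-ORF averages) uses the two-sided Welch test from `stats::t.test`
— the unequal-variance variant, since repeat sets and ORF backgrounds have
no reason to share a variance.

# Haplotype painting

For MHC-like loci the question is mosaic ancestry: which stretches of a
query haplotype are effectively identical to which named donor haplotype.
The query is sliced into 100 kb fragments; each fragment is anchored to
every donor; substitutions are counted per non-overlapping 10 kb window; a
window qualifies for a donor when it carries **strictly fewer than 3
substitutions** (0.3 per mille) and at least 50% anchored coverage; and a
qualifying window takes the **highest-hierarchy** qualifying donor —
default order b, k, d, a, q, c, g, z — else keeps the query's own label.
Only donors ranked above the query's own label compete. Adjacent same-label
windows merge into segments; a sub-window remainder folds into the last
window, and a sub-window final fragment folds into the previous fragment.

Tiled (not sliding) 10 kb windows realize the "continuous region over
10 kb" reading: a single qualifying window already spans 10 kb. Indels
inside anchored regions are not counted — the threshold speaks of SNPs —
and a fragment position counts as a substitution only if *no* anchor
covering it matches the donor there, which stops a neighboring segment's
anchor from bleeding mismatches across a mosaic breakpoint. Unaligned
windows (coverage sentinel `Inf`) never qualify for any donor.

# The simulator

`gen_vntr_pair` plants one ancestral unit (exact GC base count at the
requested bias) repeated in tandem, with i.i.d. per-site substitutions at
the divergence rate applied independently to every copy, inside flanks
shared by both alleles. Flanks are rejection-sampled to contain no repeated
12-mer (including wrap-around k-mers of the unit), so negative controls are
negative by construction. `gen_annotated_genome` lays out single- and
multi-exon genes on both strands of a toy chromosome pair, with a stated
fraction carrying planted copy-number polymorphism whose ratio lies outside
the flagging band; planted arrays default to 20–80 bp units, 7–18 copies
and 0.5% per-copy divergence — the regime the real gene families occupy
(most units 10–100 bp, most copy numbers 5–20, within-array diversity
typically below a few percent). `gen_mosaic_haplotype` concatenates donor
segments and plants an exact number of noise substitutions per 10 kb
window, so threshold arithmetic in tests is exact rather than Poisson.

All generation runs under R's Mersenne-Twister with all three RNG kinds
pinned (`Mersenne-Twister`/`Inversion`/`Rejection`) and the caller's RNG
state restored afterwards. This is a fully specified scheme that is stable
across platforms in R ≥ 3.6; we preferred it to hand-rolling a generator,
which would add failure modes without adding portability.

What the simulator does *not* emulate: transposon-derived repeat
background, CpG mutation bias, polymerase-slippage length dynamics,
assembly base errors, or annotation errors. Passing tests therefore
demonstrate the geometry and the decision rules, not robustness to every
artifact of real assemblies; on real data the confidence gate and the
manual-review flag carry that weight.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere inside the package;
  conversion happens only at the GFF3 (1-based inclusive) and BED
  boundaries.
* Canonical transcript per gene = longest CDS, ties broken
  lexicographically by transcript ID; ortholog pairing is strictly by
  shared gene ID, with absences reported to a skip list rather than raised.
* Period-estimation tolerance is ±2 bp; the support threshold (0.9 of
  anchor-length weight) absorbs stray diagonals from divergent copies.
* Sequences shorter than the seed yield empty anchor sets, not errors;
  empty anchor sets yield empty block tables; a block with no supporting
  anchors is a contract violation and raises.
* π is undefined (NA with a warning) below two units; GC is undefined for
  all-N input; the Welch test returns t = 0, p = 1 when both samples are
  constant and equal.
* Identical inputs and configuration give byte-identical outputs at every
  stage; there is no hidden randomness outside the seeded simulator.

# Problem sizes in the shipped tests

The test suite regenerates all fixtures in code. Recovery is exercised on
200 seeded arrays sampling unit length log-uniformly over 10–990 bp and
copy number log-uniformly over 6–600 — the extremes reported for real
coding VNTRs — under a 25 kb cap on total array length, the realistic
coding-sequence regime (the extremes do not co-occur in real genes); 50 of
the 200 are noiseless and must be recovered exactly, and the remainder
carry up to 5% per-copy divergence with a ≥ 90% exact-recovery bar. The π
implementation is checked against a brute-force all-pairs Hamming oracle on
1000 seeded unit sets, and anchor diagonal families against a brute-force
all-substring matcher for units from 7 to 500 bp. Painting is verified on
planted mosaics with exact window-level truth.

# Known limitations

* Short VNTRs are out of reach by construction: an anchor needs ~14 exact
  bases, so arrays of very short units with high divergence may not form
  clean diagonal families. (Short tandem repeats are the territory of
  short-read callers.)
* Inverted repeats are invisible: the comparison is forward-strand only,
  which is the right frame for CDS-vs-CDS of the same gene.
* Indel-rich arrays shift diagonals off the unit grid; the ±2 bp tolerance
  absorbs small drift, but pervasive length heterogeneity within the array
  degrades period support (the confidence score reflects this).
* r compares spans, not alignments; a block flagged by r still deserves
  inspection of the underlying alleles, which is exactly the role the flag
  plays.
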