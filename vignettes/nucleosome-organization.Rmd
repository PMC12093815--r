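---
title: "Measuring nucleosome organization from MNase-Seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring nucleosome organization from MNase-Seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucorg)
```

## The measurement problem

Micrococcal nuclease digests linker DNA and leaves nucleosome-protected
fragments of roughly one wrap (~147 bp). After paired-end sequencing,
each properly paired template is a genomic interval whose midpoint
estimates the dyad (central base pair) of the nucleosome that protected
it. Aggregating millions of such midpoints gives a dyad-density map in
which well-positioned nucleosomes appear as sharp peaks and the phased
array downstream of a transcription start site (TSS) appears as a
regular comb with period equal to the nucleosome repeat length (NRL).

Remodeler mutants change this map in two characteristic, small ways at
their target genes: the +1 nucleosome slides downstream into the gene
body (tens of bp), and the array spacing changes by a few bp. Both
effects are far smaller than a nucleosome footprint, so the pipeline's
job is to measure shifts of 10–25 bp and NRL changes of ~2 bp reliably
in the presence of positional fuzziness (per-nucleosome dyad scatter
with sd in the tens of bp) and background digestion.

## Pipeline and parameters

**Fragment filters.** Size selection keeps fragments of 140–160 bp
inclusive — the mono-nucleosome band, tight enough that the midpoint is a
good dyad proxy. Fragments overlapping an exclusion list by ≥ 1 bp are
removed; the stock region is the yeast rDNA locus
(chrXII:451,000–469,000, treated as 0-based half-open), whose repeat
structure distorts coverage. Datasets are subsampled without replacement
to a common depth (default 5 × 10⁶ fragments) so coverage statistics are
comparable between samples; the subsample is uniform and
seed-deterministic. The canonical order is filter → exclude → subsample;
since the two filters are order-independent selections, only the
subsample stage depends on the ordering, and it is drawn on the
identically ordered survivor list.

**Dyad tracks.** Each fragment midpoint (`floor((start+end)/2)` in
0-based coordinates; the floor makes even-length fragments deterministic)
is extended ±50 bp, so each fragment contributes a 101 bp footprint —
approximately a nucleosome — and the per-base sum is the dyad-coverage
track. "Extension" is read as symmetric; a one-sided reading would
shift every feature by 25 bp but is not what a nucleosome footprint
means, and the radius is configurable. The genome-wide track sum is
exactly `fragments × 101` when no footprint is clipped at a chromosome
edge, which the tests assert as a conservation law.

**Nucleosome calling.** The caller is a fully specified stand-in for
peak callers of the DANPOS family: per-base coverage is capped (default
200, suppressing clonal pile-ups), smoothed with a discrete Gaussian
kernel (sd 15 bp, truncated at ±4 sd and renormalized to unit mass,
zero-padded at edges), and strict local maxima above a height threshold
are accepted greedily in height order subject to a minimum inter-summit
distance of 110 bp. 110 bp is deliberately below the 147 bp footprint so
closely packed genuine nucleosomes survive, while smoothing noise within
one nucleosome cannot produce two calls. The height threshold defaults
to 5% of the smoothed track's mean over nonzero bases, making the caller
invariant to sequencing depth; an absolute threshold can be supplied.
Ties in height break toward the smaller coordinate, then the
lexicographically smaller chromosome; plateau maxima resolve to their
leftmost base. These choices make the caller deterministic and let a
brute-force subset-enumeration oracle verify the greedy selection on
constructed tracks. We do not attempt to reproduce any particular
external caller's statistical machinery (occupancy tests, FDR): the
downstream analysis needs only summit coordinates and heights.

**+1 assignment and shift classification.** Summits are mapped to
transcript offsets (plus strand `summit − tss`, minus strand
`tss − summit`, downstream positive). Within a search window of −30 to
+250 bp around the TSS, the summit with the *smallest* offset is the +1
nucleosome. The window is a design choice: −30 bp admits slightly
upstream wild-type +1 dyads, +250 bp keeps even strongly shifted mutant
+1 nucleosomes while excluding the +2 of typical arrays. The minimum
inter-summit distance protects the smallest-offset rule from noise: a
spurious summit cannot be accepted within 110 bp of a genuine +1, so at
standard geometries no upstream noise peak can outcompete it. The shift
of a gene is the mutant +1 offset minus the reference +1 offset, per
replicate pair (by replicate index when counts match; against the mean
reference offset otherwise, recorded in the output metadata). A gene is
classified *dependent* when every replicate shift is ≥ 10 bp downstream;
the all-replicates reading of replicate consistency is adopted because a
pooled comparison would let one noisy replicate carry the call. Genes
lacking a +1 in any required sample are excluded from classification
with an explicit reason rather than treated as extreme shifts.

**NRL.** Per gene, the +1 and subsequent summits inside the gene body
are regressed (ordinary least squares) against nucleosome index
0…k−1 using at most the first 8 summits and requiring at least 4; the
slope is the NRL and `r2` reports array regularity. For phased arrays
this is equivalent to autocorrelation-based estimates but is defined per
gene, has a closed form, and is exactly testable; the autocorrelation
route is noted but not implemented. Strain comparisons use a two-tailed
Welch's t-test on per-dataset mean NRLs. With only two or three datasets
per strain this test has very low power — it reproduces the typical
replicate structure of such designs, and the output should be read with
that in mind.

**Composites.** Profiles average raw coverage at each transcript-relative
position over a gene set, reversing minus-strand windows so downstream is
rightward, over a default window of −300…+1300 bp (TSS through roughly
the +6 nucleosome at NRL 165). Genes whose window leaves the chromosome
are dropped and counted. Per-gene-mean normalization is available because
raw composite amplitude scales with depth, but the default is off,
matching the raw-coverage reading of published composite panels. Peak
shifts between two composites are argmax differences within a stated
peak window (leftmost on plateaus); for whole-array displacement the
cross-correlation lag is steadier and is what the recovery tests use.

## The synthetic generator

`sim_config()`/`simulate_experiment()` generate the study conditions the
package is verified under. A toy genome holds `n_genes` genes in
`gene_spacing` bp slots, alternating strand, each with a ground-truth
array: dyads at `tss ± (plus1_offset + k·nrl)`, k = 0…7. Defaults are a
60 bp +1 offset (a typical yeast value; published analyses rarely state
one, and it is configurable), NRL 165 bp, 8 nucleosomes per gene, dyad
fuzziness sd 20 bp, fragment lengths ~N(151, 6²) truncated to
[120, 200] by rejection (rejection rather than clipping keeps the
distribution shape unbiased), 5% uniform background, and ~300 signal
fragments per nucleosome. Condition effects are a signed downstream +1
shift and an NRL change applied to a configurable effect-gene set; the
mirrored minus-strand construction means shifts are defined along the
transcript, not in genome coordinates. Fragment midpoints reproduce the
drawn dyad exactly for any fragment length parity, so the noise-free
generator (`fuzziness_sd = 0`, `background_frac = 0`) yields tracks whose
summits sit exactly on the true dyads — the round-trip identity the test
suite asserts.

What the generator does **not** emulate: MNase sequence preference,
nucleosome-free-region geometry upstream of the TSS, occupancy
heterogeneity between genes, di-nucleosome fragments, and replication or
transcription dynamics. Passing recovery tests therefore demonstrate
that the measurement chain is correct and unbiased under the stated
statistical model, not that real chromatin satisfies that model; on real
data the filters and the replicate-consistency rule carry the burden the
simulator does not model.

## Numerical and degenerate-input choices

Quartiles use linear interpolation (R's type 7), stated because boxplot
statistics differ between conventions. Welch's test refuses groups with
fewer than two values or zero variance, naming the offending group.
Empty fragment files warn and yield empty streams; malformed BED lines
are counted and skipped. bedGraph output omits zero runs and writes
maximal runs (they come from run-length encoding, so write→read is
lossless, asserted elementwise). All stochastic stages (fragment
sampling, subsampling) take explicit seeds; replicate seeds derive
deterministically from the experiment seed, so a configuration is fully
reproducible byte for byte.

## Problem sizes used in verification

The recovery suite simulates 200 genes × 8 nucleosomes at ~300 signal
fragments per nucleosome (≈5 × 10⁵ fragments per sample, four samples
for two-condition/two-replicate designs), which gives the +1-shift
classifier a per-replicate shift noise of ~2 bp — comfortably inside the
10 bp rule — while keeping a full end-to-end run around a minute on one
core. Unit tests use 6–20 gene genomes. These sizes are the package's
verification choices; the pipeline itself streams any genome the input
files describe.

## Known limitations

The caller's greedy selection is not guaranteed globally optimal for
pathological height configurations (the brute-force equivalence is
asserted only for separated, distinct-height cases). The +1 rule picks
the smallest in-window offset, not the highest summit; genes with a
dominant −1 nucleosome inside the window would need a narrower window.
NRL per gene requires ≥ 4 called array nucleosomes and so drops short
genes. The Welch comparison inherits the tiny-n design of typical
MNase-Seq studies and should be treated as descriptive.
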