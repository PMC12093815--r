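# nucorg

Nucleosome-organization analysis for paired-end MNase-Seq in yeast.

ISWI-family chromatin remodelers such as ISW2 position the +1 nucleosome
just downstream of the transcription start site (TSS) at a specific set of
target genes and set the spacing of the downstream array. Loss of the
remodeler lets the +1 nucleosome slide downstream into the gene body and
subtly changes the nucleosome repeat length (NRL). `nucorg` implements the
complete post-alignment analysis used to detect and quantify these
phenotypes, for researchers comparing nucleosome maps between strains:

- **Dyad coverage tracks.** Each sequenced fragment is reduced to its
  midpoint (the estimated nucleosome dyad) after mono-nucleosome size
  selection (140–160 bp, inclusive), exclusion-region filtering (e.g. the
  rDNA locus chrXII:451,000–469,000) and optional subsampling to a fixed
  depth (default 5 × 10⁶ fragments). The dyad is extended ±50 bp, so each
  fragment contributes a 101 bp footprint, and coverage is written as
  bedGraph/wig/bigWig.
- **Nucleosome calls.** Tracks are smoothed with a Gaussian kernel
  (sd 15 bp, truncated at 4 sd) after a per-base clonal cap (200), and
  summits are greedy height-ranked local maxima at least 110 bp apart.
- **+1 assignment and shift classification.** For each gene the summit
  with the smallest transcript offset inside a TSS window (default
  −30…+250 bp) is the +1 nucleosome. A gene is *remodeler-dependent* when
  its +1 shifts downstream by at least 10 bp (mutant − reference, along
  the transcript) in **every** replicate.
- **NRL estimation.** Per gene, ordinary least squares of the +1…+k summit
  positions against nucleosome index 0…k−1 (k ≤ 8); the slope is the NRL.
  Strains are compared by a two-tailed Welch's t-test on per-dataset mean
  NRLs.
- **Composite profiles.** Strand-aware, anchor-aligned average dyad
  coverage over gene sets (default window −300…+1300 bp around the TSS),
  with signed peak-shift annotation between conditions.
- **Synthetic data.** A seeded generator builds toy genomes with
  ground-truth phased arrays (configurable +1 offset, NRL, positional
  fuzziness, fragment-length law, uniform background, and per-gene-set
  condition effects), so every stage is testable by parameter recovery.

## Worked example

Simulate 50 genes with a 24 bp downstream +1 shift injected at 12 of
them, then run the analysis:

```r
library(nucorg)

cfg <- sim_config(seed = 7, n_genes = 50, chrom_length = 150000,
                  effect_genes = sprintf("gene_%04d", 1:12),
                  plus1_shift = 24)
sim <- simulate_experiment(cfg, n_replicates = 2)

one <- function(fr) {
  tr <- build_dyad_track(filter_by_length(fr), sim$chrom_sizes)
  call_nucleosomes(tr)
}
calls_wt  <- lapply(sim$fragments$wt,  one)
calls_mut <- lapply(sim$fragments$mut, one)

tab <- shift_table(calls_wt, calls_mut, sim$genes, threshold = 10)
head(tab, 4)
#>     gene_id shift_r1 shift_r2 mean_shift dependent na_reason
#> 1 gene_0001       26       24       25.0      TRUE      <NA>
#> 2 gene_0002       26       29       27.5      TRUE      <NA>
#> 3 gene_0003       24       23       23.5      TRUE      <NA>
#> 4 gene_0004       25       24       24.5      TRUE      <NA>
sum(tab$dependent, na.rm = TRUE)
#> [1] 12
```

The per-replicate columns are the signed +1 displacements in bp along the
transcript (positive = into the gene body); `dependent` applies the
≥ 10 bp all-replicates rule, and exactly the 12 effect genes are
recovered. NRL estimation on the same calls:

```r
nrl_wt <- gene_nrl_table(calls_wt[[1]], sim$genes)
head(nrl_wt, 3)
#>     gene_id      nrl n_nucs        r2
#> 1 gene_0001 165.2262      8 0.9999968
#> 2 gene_0002 165.0833      8 0.9999881
#> 3 gene_0003 165.2619      8 0.9999711
set_nrl(nrl_wt)[c("mean", "median")]
#> $mean   [1] 165.0319
#> $median [1] 165.0417
```

The regression slope recovers the simulated 165 bp repeat length to a
fraction of a base pair. The whole analysis can also be driven from one
YAML file with `run_pipeline()` (which writes tracks, call tables, the
shift table, NRL summaries, composites and a checksummed manifest), or
from the shell via the thin wrapper `inst/scripts/nucorg.R`.

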