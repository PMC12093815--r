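# Shared fixture builders: small synthetic experiments kept well below
# the study-scale defaults so unit tests stay fast.

tiny_config <- function(seed = 101, n_genes = 20L, frags_per_nuc = 100,
                        ...) {
  sim_config(seed = seed, n_genes = n_genes, chrom_length = 100000L,
             frags_per_nuc = frags_per_nuc, ...)
}

# One sample's calls from a fragment GRanges, with the standard filters.
calls_from_fragments <- function(frags, chrom_sizes,
                                 params = caller_params()) {
  tr <- build_dyad_track(filter_by_length(frags), chrom_sizes)
  call_nucleosomes(tr, params)
}

# A bare DyadTrack from an explicit per-chromosome numeric vector,
# bypassing fragments (for caller unit tests).
track_from_vector <- function(x, chrom = "chrT") {
  structure(list(
    coverage = stats::setNames(IRanges::RleList(S4Vectors::Rle(x),
                                                compress = FALSE), chrom),
    dyad_counts = NULL,
    chrom_sizes = stats::setNames(length(x), chrom),
    extension_radius = 0L, n_fragments_used = NA_integer_,
    provenance = list()), class = "DyadTrack")
}

# Gaussian bump helper for constructed caller inputs.
gaussian_bump <- function(n, center, sd = 15, height = 100) {
  height * exp(-((seq_len(n) - 1 - center)^2) / (2 * sd^2))
}
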