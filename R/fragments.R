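#' Read paired-end fragments from BED or BAM
#'
#' BED (3+ columns): each line is one fragment, 0-based half-open. BAM:
#' one fragment per properly paired template, spanning the leftmost mate
#' start to the rightmost mate end; each pair is counted once. Duplicates
#' are kept.
#'
#' @param path BED or BAM file; format chosen by extension unless given
#' @param format "auto", "bed" or "bam"
#' @return `GRanges` of fragments (strand `*`)
#' @export
read_fragments <- function(path, format = c("auto", "bed", "bam")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read fragments: no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "bed"
  if (format == "bam") return(.read_fragments_bam(path))
  .read_fragments_bed(path)
}

.read_fragments_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (!length(lines)) {
    warning("empty fragment file: ", path)
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  ok <- nf >= 3L & !is.na(start) & !is.na(end) & start >= 0L & end > start
  if (any(!ok))
    warning(sum(!ok), " malformed BED line(s) skipped in ", path)
  if (!any(ok)) return(GenomicRanges::GRanges())
  chrom <- vapply(fields[ok], `[`, "", 1L)
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start[ok] + 1L, end[ok]))
}

.read_fragments_bam <- function(path) {
  flag <- Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                 isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("rname", "pos", "isize"))
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  if (!length(res$pos)) {
    # distinguish "no proper pairs" from a genuinely empty file
    any_param <- Rsamtools::ScanBamParam(what = "flag")
    n_any <- length(Rsamtools::scanBam(path, param = any_param)[[1]]$flag)
    if (n_any > 0)
      stop("BAM has no properly paired reads (", path,
           "); convert fragments to BED input instead")
    warning("empty BAM file: ", path)
    return(GenomicRanges::GRanges())
  }
  keep <- !is.na(res$isize) & res$isize > 0L  # leftmost mate of each pair
  GenomicRanges::GRanges(as.character(res$rname[keep]),
                         IRanges::IRanges(start = res$pos[keep],
                                          width = res$isize[keep]))
}

#' Size-select fragments (closed interval)
#'
#' Keeps fragments whose length satisfies `min_len <= length <= max_len`,
#' the mono-nucleosome selection of the analysis (defaults 140-160 bp).
#'
#' @param frags `GRanges` of fragments
#' @param min_len,max_len inclusive length bounds in bp
#' @return filtered `GRanges`
#' @export
filter_by_length <- function(frags, min_len = 140L, max_len = 160L) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  w <- BiocGenerics::width(frags)
  frags[w >= min_len & w <= max_len]
}

#' Remove fragments overlapping exclusion regions
#'
#' A fragment is removed iff it overlaps any region by at least 1 bp.
#' The canonical use is the yeast rDNA locus; see [rdna_region()].
#'
#' @param frags `GRanges` of fragments
#' @param regions `GRanges` of regions, or a BED path
#' @return filtered `GRanges`
#' @export
exclude_regions <- function(frags, regions) {
  if (is.character(regions)) regions <- rtracklayer::import(regions,
                                                            format = "BED")
  if (!length(regions)) return(frags)
  hits <- GenomicRanges::findOverlaps(
    frags, regions, minoverlap = 1L, ignore.strand = TRUE)
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop)) frags[-drop] else frags
}

#' The S. cerevisiae rDNA exclusion region
#'
#' chrXII 451000-469000 (0-based half-open), the locus whose reads are
#' removed before dyad-coverage construction.
#'
#' @param chrom chromosome name used by the alignment
#' @return `GRanges` of length 1
#' @export
rdna_region <- function(chrom = "chrXII") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(451001L, 469000L))
}

#' Subsample fragments without replacement
#'
#' Draws exactly `min(n, available)` fragments uniformly without
#' replacement, deterministically for a given seed; the genomic order of
#' the survivors is preserved. Warns when fewer than `n` are available.
#'
#' @param frags `GRanges` of fragments
#' @param n target count (default 5e6, the standard depth normalization)
#' @param seed RNG seed
#' @return subsampled `GRanges`
#' @export
subsample_fragments <- function(frags, n = 5000000L, seed = 1L) {
  if (n < 0) stop("n must be >= 0")
  avail <- length(frags)
  if (avail <= n) {
    if (avail < n)
      warning("only ", avail, " fragments available; requested ", n)
    return(frags)
  }
  idx <- withr::with_seed(as.integer(seed) %% 2147483587,
                          sample.int(avail, n))
  frags[sort(idx)]
}

#' Fragment dyad position
#'
#' The estimated nucleosome dyad of a fragment is its midpoint:
#' `floor((start0 + end0) / 2)` in 0-based coordinates (even-length
#' fragments have no exact centre; the floor is taken for determinism).
#'
#' @param frags `GRanges` of fragments
#' @return integer vector of 0-based dyad positions
#' @export
fragment_dyad <- function(frags) {
  as.integer((BiocGenerics::start(frags) - 1L +
                BiocGenerics::end(frags)) %/% 2L)
}
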