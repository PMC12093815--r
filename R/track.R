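#' Build an extended-dyad coverage track
#'
#' Each fragment contributes +1 coverage to every base in
#' `[dyad - extension_radius, dyad + extension_radius]` (0-based, clipped
#' at chromosome edges), approximating a nucleosome footprint around the
#' fragment-midpoint dyad. The default radius of 50 bp gives the standard
#' 101 bp footprint per fragment.
#'
#' The returned `DyadTrack` also records the unextended per-base dyad
#' counts (used downstream to report raw dyads under each called summit),
#' the number of fragments used, and the filter provenance.
#'
#' @param frags `GRanges` of fragments
#' @param chrom_sizes named integer vector of chromosome lengths
#' @param extension_radius bp added on each side of the dyad
#' @param provenance optional named list recorded in the track
#' @return an object of class `DyadTrack`
#' @export
build_dyad_track <- function(frags, chrom_sizes, extension_radius = 50L,
                             provenance = list()) {
  chrom <- as.character(GenomeInfoDb::seqnames(frags))
  unknown <- setdiff(unique(chrom), names(chrom_sizes))
  if (length(unknown))
    stop("fragments on chromosome(s) absent from chrom_sizes: ",
         paste(unknown, collapse = ", "))
  dyad <- fragment_dyad(frags)                    # 0-based
  si <- .seqinfo(chrom_sizes)
  ext <- GenomicRanges::GRanges(
    chrom,
    IRanges::IRanges(start = pmax(dyad - extension_radius, 0L) + 1L,
                     end = pmin(dyad + extension_radius,
                                unname(chrom_sizes[chrom]) - 1L) + 1L),
    seqinfo = si)
  pts <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = dyad + 1L, width = 1L), seqinfo = si)
  structure(list(
    coverage = GenomicRanges::coverage(ext),
    dyad_counts = GenomicRanges::coverage(pts),
    chrom_sizes = chrom_sizes,
    extension_radius = as.integer(extension_radius),
    n_fragments_used = length(frags),
    provenance = provenance), class = "DyadTrack")
}

#' @export
print.DyadTrack <- function(x, ...) {
  cat("DyadTrack:", length(x$coverage), "chromosome(s),",
      x$n_fragments_used, "fragments, extension_radius",
      x$extension_radius, "bp\n")
  invisible(x)
}

#' Genome-wide sum of a track
#' @param track a `DyadTrack`
#' @return total coverage summed over all chromosomes
#' @export
track_sum <- function(track) {
  sum(vapply(track$coverage, function(r) sum(as.numeric(r)), 0))
}

# RleList -> GRanges of maximal nonzero runs (bedGraph-ready).
.track_granges <- function(cov, chrom_sizes) {
  grl <- lapply(names(cov), function(ch) {
    r <- cov[[ch]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r) + 1L
    keep <- S4Vectors::runValue(r) != 0
    if (!any(keep)) return(NULL)
    GenomicRanges::GRanges(ch, IRanges::IRanges(starts[keep], ends[keep]),
                           score = S4Vectors::runValue(r)[keep])
  })
  gr <- do.call(c, c(grl[!vapply(grl, is.null, TRUE)],
                     list(GenomicRanges::GRanges())))
  GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
  GenomeInfoDb::seqlengths(gr) <- unname(chrom_sizes)
  gr
}

#' Write a dyad track to disk
#'
#' bedGraph output omits zero runs and merges adjacent equal values into
#' maximal runs (they arise from run-length encoding, so this is exact);
#' write/read round trips reproduce the in-memory array losslessly.
#' bigWig is available where the runtime supports it; wig is provided for
#' browser compatibility.
#'
#' @param track a `DyadTrack`
#' @param path output path
#' @param format one of "bedGraph", "wig", "bigWig"
#' @return the path, invisibly
#' @export
write_track <- function(track, path, format = c("bedGraph", "wig",
                                                "bigWig")) {
  format <- match.arg(format)
  gr <- .track_granges(track$coverage, track$chrom_sizes)
  if (length(gr) == 0 && format == "bedGraph") {
    file.create(path)  # all-zero track: zero runs are omitted
    return(invisible(path))
  }
  rtracklayer::export(gr, path, format = format)
  invisible(path)
}

#' Read a coverage track written by [write_track()]
#'
#' @param path bedGraph/wig/bigWig path
#' @param chrom_sizes named integer vector of chromosome lengths
#' @return a `DyadTrack` (dyad counts and fragment count are not stored in
#'   track files, so those fields are NULL/NA)
#' @export
read_track <- function(path, chrom_sizes) {
  fmt <- if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)) "bigWig"
         else if (grepl("\\.wig$", path, ignore.case = TRUE)) "wig"
         else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  GenomeInfoDb::seqlevels(gr) <- union(GenomeInfoDb::seqlevels(gr),
                                       names(chrom_sizes))
  GenomeInfoDb::seqlengths(gr) <- unname(
    chrom_sizes[GenomeInfoDb::seqlevels(gr)])
  w <- if (length(gr)) as.numeric(gr$score) else 1L
  cov <- GenomicRanges::coverage(gr, weight = w)
  structure(list(coverage = cov[names(chrom_sizes)], dyad_counts = NULL,
                 chrom_sizes = chrom_sizes, extension_radius = NA_integer_,
                 n_fragments_used = NA_integer_, provenance = list()),
            class = "DyadTrack")
}

#' Write a per-locus track excerpt
#'
#' Emits the bedGraph restricted to one genomic window, for genome-browser
#' inspection of individual genes.
#'
#' @param track a `DyadTrack`
#' @param chrom chromosome name
#' @param start0,end0 0-based half-open window
#' @param path output bedGraph path
#' @export
write_locus_excerpt <- function(track, chrom, start0, end0, path) {
  if (!chrom %in% names(track$chrom_sizes))
    stop("unknown chromosome: ", chrom)
  gr <- .track_granges(track$coverage, track$chrom_sizes)
  win <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
  slice <- GenomicRanges::restrict(IRanges::subsetByOverlaps(gr, win),
                                   start = start0 + 1L, end = end0)
  rtracklayer::export(slice, path, format = "bedGraph")
  invisible(path)
}
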