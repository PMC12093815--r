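#' Read a two-column chromosome sizes file
#'
#' @param path TSV with columns chrom name and length in bp (no header).
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "integer"))
  if (any(df$size <= 0)) stop("chromosome sizes must be positive")
  stats::setNames(df$size, df$chrom)
}

#' Write chromosome sizes as two-column TSV
#'
#' @param chrom_sizes named integer vector
#' @param path output path
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  utils::write.table(data.frame(names(chrom_sizes), unname(chrom_sizes)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Seqinfo from a named sizes vector.
.seqinfo <- function(chrom_sizes) {
  GenomeInfoDb::Seqinfo(seqnames = names(chrom_sizes),
                        seqlengths = unname(chrom_sizes))
}

# Derive a child seed from a base seed; stays below 2^31.
.child_seed <- function(seed, k) {
  (as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483587
}

.is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

#' Validate a gene model table
#'
#' Genes are given in 0-based coordinates: `tss` is the position of the
#' first transcribed base and `body_end` the far end of the gene body along
#' the transcript, so `tss < body_end` on the plus strand and
#' `tss > body_end` on the minus strand.
#'
#' @param genes data.frame with columns gene_id, chrom, tss, strand, body_end
#' @return the validated data.frame (invisibly usable)
#' @export
validate_genes <- function(genes) {
  need <- c("gene_id", "chrom", "tss", "strand", "body_end")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in gene table")
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  plus <- genes$strand == "+"
  bad <- (plus & genes$tss >= genes$body_end) |
    (!plus & genes$tss <= genes$body_end)
  if (any(bad)) stop("tss/body_end inconsistent with strand for: ",
                     paste(utils::head(genes$gene_id[bad], 5), collapse = ", "))
  genes
}

#' Read gene models from BED6 or GFF3
#'
#' The TSS is the strand-aware 5' end. GFF3 coordinates (1-based, closed)
#' and BED coordinates (0-based, half-open) are both converted to the
#' package's 0-based `tss`/`body_end` convention.
#'
#' @param path BED6 or GFF3 file (format chosen by extension)
#' @return gene model data.frame
#' @export
read_genes <- function(path) {
  fmt <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed"
  gr <- rtracklayer::import(path, format = fmt)
  if (fmt == "gff3") {
    keep <- as.character(gr$type) %in% c("gene", "transcript", "mRNA")
    if (any(keep)) gr <- gr[keep]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
      if (!is.null(gr$Name)) as.character(gr$Name) else
        paste0("gene_", seq_along(gr))
  } else {
    ids <- if (!is.null(gr$name)) as.character(gr$name) else
      paste0("gene_", seq_along(gr))
  }
  st <- as.character(BiocGenerics::strand(gr))
  if (any(st == "*")) stop("gene annotation must be stranded")
  start0 <- BiocGenerics::start(gr) - 1L   # 0-based inclusive
  end0ex <- BiocGenerics::end(gr)          # 0-based exclusive
  tss <- ifelse(st == "+", start0, end0ex - 1L)
  body_end <- ifelse(st == "+", end0ex, start0 - 1L)
  validate_genes(data.frame(
    gene_id = ids, chrom = as.character(GenomeInfoDb::seqnames(gr)),
    tss = as.integer(tss), strand = st, body_end = as.integer(body_end),
    stringsAsFactors = FALSE))
}

#' Write gene models as BED6
#' @param genes gene model data.frame
#' @param path output path
#' @export
write_genes_bed <- function(genes, path) {
  genes <- validate_genes(genes)
  if (nrow(genes) == 0) {
    file.create(path)
    return(invisible(path))
  }
  plus <- genes$strand == "+"
  # body_end is exclusive along the transcript on both strands
  start0 <- ifelse(plus, genes$tss, genes$body_end + 1L)
  end0 <- ifelse(plus, genes$body_end, genes$tss + 1L)
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(start0 + 1L, end0),
                               strand = genes$strand)
  gr$name <- genes$gene_id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write gene models as minimal GFF3
#' @param genes gene model data.frame
#' @param path output path
#' @param source source field for column 2
#' @export
write_genes_gff3 <- function(genes, path, source = "nucorg") {
  genes <- validate_genes(genes)
  plus <- genes$strand == "+"
  start1 <- ifelse(plus, genes$tss + 1L, genes$body_end + 2L)
  end1 <- ifelse(plus, genes$body_end, genes$tss + 1L)
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, source, start1, end1, genes$strand,
                     genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

# Transcript-relative offset of a genomic position from the TSS
# (downstream positive), all 0-based. Recycles over pos for a scalar
# gene (tss, strand).
.transcript_offset <- function(pos, tss, strand) {
  sgn <- ifelse(strand == "+", 1L, -1L)
  sgn * (pos - tss)
}
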