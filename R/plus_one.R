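#' Assign the +1 nucleosome of each gene
#'
#' Summits are transformed to transcript-relative offsets from the TSS
#' (downstream positive; plus strand `summit - tss`, minus strand
#' `tss - summit`). Among summits whose offset lies in `window`, the one
#' with the smallest offset is the +1 nucleosome. Genes without an
#' eligible summit get an NA assignment.
#'
#' @param calls data.frame of nucleosome calls for one sample
#' @param genes gene model data.frame (see [validate_genes()])
#' @param window numeric length-2: offset window around the TSS searched
#'   for the +1 summit (default c(-30, 250))
#' @return data.frame (gene_id, chrom, strand, tss, summit, offset)
#' @export
assign_plus_one <- function(calls, genes, window = c(-30, 250)) {
  genes <- validate_genes(genes)
  by_chrom <- split(calls$summit, calls$chrom)
  res <- lapply(seq_len(nrow(genes)), function(i) {
    s <- by_chrom[[genes$chrom[i]]]
    if (is.null(s) || !length(s))
      return(c(summit = NA_integer_, offset = NA_integer_))
    off <- .transcript_offset(s, genes$tss[i], genes$strand[i])
    ok <- off >= window[1] & off <= window[2]
    if (!any(ok)) return(c(summit = NA_integer_, offset = NA_integer_))
    j <- which(ok)[which.min(off[ok])]
    c(summit = s[j], offset = off[j])
  })
  res <- do.call(rbind, res)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             strand = genes$strand, tss = genes$tss,
             summit = as.integer(res[, "summit"]),
             offset = as.integer(res[, "offset"]),
             stringsAsFactors = FALSE)
}

#' Shift of the +1 nucleosome between two assignments of one gene
#'
#' Signed, along the transcript: positive means the mutant +1 sits
#' further downstream (into the gene body) than the reference.
#'
#' @param wt,mut single rows of [assign_plus_one()] output for one gene
#' @return signed shift in bp
#' @export
compute_shift <- function(wt, mut) {
  if (!identical(wt$gene_id, mut$gene_id))
    stop("gene mismatch: ", wt$gene_id, " vs ", mut$gene_id)
  mut$offset - wt$offset
}

#' Classify a gene as remodeler-dependent
#'
#' TRUE iff the +1 shift is at least `threshold` bp downstream in every
#' replicate — the all-replicates rule.
#'
#' @param shifts numeric vector of per-replicate shifts (bp)
#' @param threshold minimum downstream shift in bp (default 10)
#' @return logical flag
#' @export
classify_dependent <- function(shifts, threshold = 10) {
  if (!length(shifts)) stop("no replicate shifts supplied")
  if (anyNA(shifts)) stop("replicate shifts contain NA; ",
                          "genes missing a +1 call are unclassified")
  all(shifts >= threshold)
}

#' Per-gene +1 shift table between two strains
#'
#' Assigns the +1 nucleosome per sample, computes per-replicate shifts
#' (mutant minus reference, along the transcript), the mean shift, and the
#' dependence flag under the all-replicates rule. With equal replicate
#' counts, replicate r of the mutant is compared with replicate r of the
#' reference; with unequal counts each mutant replicate is compared with
#' the mean reference offset (recorded in the `pairing` attribute). Genes
#' lacking a +1 call in any required sample are left unclassified with the
#' reason in `na_reason`.
#'
#' @param wt_calls list of call data.frames, one per reference replicate
#' @param mut_calls list of call data.frames, one per mutant replicate
#' @param genes gene model data.frame
#' @param window +1 search window, as [assign_plus_one()]
#' @param threshold dependence threshold in bp
#' @return data.frame with one row per gene: per-replicate `shift_r*`
#'   columns, `mean_shift`, `dependent` (NA when unclassified), `na_reason`
#' @export
shift_table <- function(wt_calls, mut_calls, genes, window = c(-30, 250),
                        threshold = 10) {
  if (!length(wt_calls) || !length(mut_calls))
    stop("need at least one reference and one mutant replicate")
  genes <- validate_genes(genes)
  if (!nrow(genes)) stop("no genes to classify")
  wt_off <- sapply(wt_calls, function(cc)
    assign_plus_one(cc, genes, window)$offset)
  mut_off <- sapply(mut_calls, function(cc)
    assign_plus_one(cc, genes, window)$offset)
  wt_off <- matrix(wt_off, nrow = nrow(genes))
  mut_off <- matrix(mut_off, nrow = nrow(genes))
  paired <- ncol(wt_off) == ncol(mut_off)
  shifts <- if (paired) mut_off - wt_off
            else mut_off - rowMeans(wt_off)
  colnames(shifts) <- paste0("shift_r", seq_len(ncol(shifts)))
  missing_wt <- rowSums(is.na(wt_off)) > 0
  missing_mut <- rowSums(is.na(mut_off)) > 0
  na_reason <- rep(NA_character_, nrow(genes))
  na_reason[missing_mut] <- "no_plus_one_in_mutant"
  na_reason[missing_wt] <- "no_plus_one_in_reference"
  na_reason[missing_wt & missing_mut] <- "no_plus_one_in_both"
  unclassified <- missing_wt | missing_mut
  mean_shift <- ifelse(unclassified, NA_real_, rowMeans(shifts))
  dependent <- rep(NA, nrow(genes))
  ok <- !unclassified
  if (any(ok))
    dependent[ok] <- apply(shifts[ok, , drop = FALSE] >= threshold, 1, all)
  out <- data.frame(gene_id = genes$gene_id, shifts,
                    mean_shift = mean_shift, dependent = dependent,
                    na_reason = na_reason, stringsAsFactors = FALSE)
  attr(out, "pairing") <- if (paired) "by_replicate_index"
                          else "mutant_vs_mean_reference"
  attr(out, "threshold") <- threshold
  out
}

#' Write the shift table / the dependent-gene BED
#'
#' @param tab [shift_table()] output
#' @param path output path
#' @export
write_shift_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_shift_table
#' @param genes gene model data.frame (for coordinates)
#' @export
write_dependent_bed <- function(tab, genes, path) {
  dep <- tab$gene_id[!is.na(tab$dependent) & tab$dependent]
  write_genes_bed(genes[genes$gene_id %in% dep, , drop = FALSE], path)
  invisible(path)
}
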