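#' Nucleosome repeat length of one phased array
#'
#' Ordinary least squares of transcript-relative summit position against
#' nucleosome index 0..N-1, over the first `min(N, max_nucs)` summits from
#' the +1 onward. The slope is the NRL; equivalent to the autocorrelation
#' estimate for well-phased arrays but defined per gene and exactly
#' testable.
#'
#' @param offsets numeric vector of transcript offsets of the gene's
#'   +1..+N summits, in transcript order
#' @param min_nucs minimum array length; fewer summits returns NULL
#' @param max_nucs at most this many summits enter the regression
#' @return list (nrl, n_nucs, r2) or NULL
#' @export
estimate_gene_nrl <- function(offsets, min_nucs = 4L, max_nucs = 8L) {
  n <- length(offsets)
  if (n < min_nucs) return(NULL)
  m <- min(n, max_nucs)
  y <- as.numeric(offsets[seq_len(m)])
  x <- seq_len(m) - 1
  fit <- stats::lm(y ~ x)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) NA_real_ else
    1 - sum(stats::residuals(fit)^2) / tss  # exact also for perfect fits
  list(nrl = unname(stats::coef(fit)["x"]), n_nucs = m, r2 = r2)
}

#' Per-gene NRL table
#'
#' For each gene, finds the +1 summit (see [assign_plus_one()]) and the
#' downstream summits within the gene body, then estimates the NRL by
#' [estimate_gene_nrl()]. Genes without a +1 or with fewer than `min_nucs`
#' array summits get NA.
#'
#' @param calls data.frame of nucleosome calls for one sample
#' @param genes gene model data.frame
#' @param window +1 search window
#' @param min_nucs,max_nucs as [estimate_gene_nrl()]
#' @return data.frame (gene_id, nrl, n_nucs, r2)
#' @export
gene_nrl_table <- function(calls, genes, window = c(-30, 250),
                           min_nucs = 4L, max_nucs = 8L) {
  genes <- validate_genes(genes)
  plus1 <- assign_plus_one(calls, genes, window)
  by_chrom <- split(calls$summit, calls$chrom)
  res <- lapply(seq_len(nrow(genes)), function(i) {
    if (is.na(plus1$offset[i]))
      return(c(nrl = NA_real_, n_nucs = NA_real_, r2 = NA_real_))
    s <- by_chrom[[genes$chrom[i]]]
    off <- .transcript_offset(s, genes$tss[i], genes$strand[i])
    body_len <- abs(genes$body_end[i] - genes$tss[i])
    arr <- sort(off[off >= plus1$offset[i] & off <= body_len])
    est <- estimate_gene_nrl(arr, min_nucs, max_nucs)
    if (is.null(est))
      return(c(nrl = NA_real_, n_nucs = length(arr), r2 = NA_real_))
    c(nrl = est$nrl, n_nucs = est$n_nucs, r2 = est$r2)
  })
  res <- do.call(rbind, res)
  data.frame(gene_id = genes$gene_id, nrl = res[, "nrl"],
             n_nucs = as.integer(res[, "n_nucs"]), r2 = res[, "r2"],
             stringsAsFactors = FALSE)
}

#' Summarise NRL over a gene set
#'
#' Boxplot-style summary: median, quartiles (linear interpolation,
#' quantile type 7), 1.5x IQR whiskers clipped to the data range, plus the
#' mean NRL used for between-strain Welch tests.
#'
#' @param nrl_tab [gene_nrl_table()] output, or a numeric vector of NRLs
#' @param gene_set optional character vector restricting to a gene set
#' @return list (n, mean, median, q1, q3, iqr, whisker_lo, whisker_hi)
#' @export
set_nrl <- function(nrl_tab, gene_set = NULL) {
  x <- if (is.numeric(nrl_tab)) nrl_tab else {
    tab <- nrl_tab
    if (!is.null(gene_set)) tab <- tab[tab$gene_id %in% gene_set, ,
                                       drop = FALSE]
    tab$nrl
  }
  x <- x[!is.na(x)]
  if (!length(x)) stop("empty gene set: no NRL estimates to summarise")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  list(n = length(x), mean = mean(x), median = q[2], q1 = q[1], q3 = q[3],
       iqr = iqr,
       whisker_lo = max(min(x), q[1] - 1.5 * iqr),
       whisker_hi = min(max(x), q[3] + 1.5 * iqr))
}

#' Two-tailed Welch's t-test on per-replicate mean NRLs
#'
#' Compares the mean NRL of two strains across their replicate datasets
#' with unequal-variance (Welch-Satterthwaite) degrees of freedom. With
#' n = 2 or 3 datasets per strain, as in typical MNase-Seq designs, power
#' is very low; interpret p accordingly.
#'
#' @param group_a,group_b numeric vectors of per-replicate mean NRLs
#' @return list (t, df, p) of class `WelchResult`
#' @export
welch_t <- function(group_a, group_b) {
  for (g in list(a = group_a, b = group_b)) stopifnot(is.numeric(g))
  if (length(group_a) < 2 || stats::var(group_a) == 0)
    stop("group_a needs >= 2 values with nonzero variance")
  if (length(group_b) < 2 || stats::var(group_b) == 0)
    stop("group_b needs >= 2 values with nonzero variance")
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE,
                      alternative = "two.sided")
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value), class = "WelchResult")
}

#' @export
print.WelchResult <- function(x, ...) {
  cat(sprintf("Welch's t-test: t = %.4g, df = %.4g, p = %.4g\n",
              x$t, x$df, x$p))
  invisible(x)
}
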