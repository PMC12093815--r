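#' Configuration for the synthetic MNase-Seq generator
#'
#' Builds a validated configuration describing a toy genome of regularly
#' spaced genes, each carrying a phased nucleosome array downstream of its
#' TSS: a +1 nucleosome at `plus1_offset` bp and further dyads every `nrl`
#' bp. Observed dyads scatter around the true positions with Gaussian sd
#' `fuzziness_sd`, fragment lengths follow a truncated normal mimicking a
#' mono-nucleosome size selection, and a `background_frac` fraction of
#' fragments is placed uniformly over the genome. Condition effects are a
#' signed downstream +1 shift (`plus1_shift`) and a spacing change
#' (`nrl_delta`) applied at `effect_genes`.
#'
#' When `depth` is NULL it is chosen so that, after accounting for
#' background, each nucleosome receives `frags_per_nuc` signal fragments on
#' average.
#'
#' @param seed integer RNG seed for all stochastic stages
#' @param n_chroms number of chromosomes
#' @param chrom_length chromosome length in bp (all chromosomes equal)
#' @param n_genes number of genes
#' @param gene_spacing bp between successive gene slots
#' @param plus1_offset bp from TSS to the +1 dyad (downstream)
#' @param nrl nucleosome repeat length in bp
#' @param n_nucs_per_gene nucleosomes per gene array
#' @param fuzziness_sd positional sd of observed dyads around truth, bp
#' @param frag_len_mean,frag_len_sd fragment length law, bp
#' @param frag_len_bounds closed interval of admissible fragment lengths
#' @param depth total fragments per sample (NULL: from `frags_per_nuc`)
#' @param frags_per_nuc mean signal fragments per nucleosome used to derive
#'   `depth` when `depth` is NULL
#' @param background_frac fraction of fragments placed uniformly
#' @param effect_genes character vector of gene ids receiving the condition
#'   effect
#' @param plus1_shift signed bp shift of effect-gene arrays (downstream
#'   positive, along the transcript)
#' @param nrl_delta signed bp change of effect-gene spacing
#' @return an object of class `SimConfig`
#' @export
sim_config <- function(seed = 1L, n_chroms = 1L, chrom_length = 600000L,
                       n_genes = 200L, gene_spacing = 3000L,
                       plus1_offset = 60L, nrl = 165L,
                       n_nucs_per_gene = 8L, fuzziness_sd = 20,
                       frag_len_mean = 151, frag_len_sd = 6,
                       frag_len_bounds = c(120L, 200L),
                       depth = NULL, frags_per_nuc = 300,
                       background_frac = 0.05,
                       effect_genes = character(),
                       plus1_shift = 0L, nrl_delta = 0L) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              gene_spacing = as.integer(gene_spacing),
              plus1_offset = as.integer(plus1_offset), nrl = as.integer(nrl),
              n_nucs_per_gene = as.integer(n_nucs_per_gene),
              fuzziness_sd = fuzziness_sd,
              frag_len_mean = frag_len_mean, frag_len_sd = frag_len_sd,
              frag_len_bounds = as.integer(frag_len_bounds),
              background_frac = background_frac,
              effect_genes = as.character(effect_genes),
              plus1_shift = as.integer(plus1_shift),
              nrl_delta = as.integer(nrl_delta))
  if (is.null(depth)) {
    n_sig <- cfg$n_genes * cfg$n_nucs_per_gene * frags_per_nuc
    depth <- if (n_sig == 0) 0 else round(n_sig / (1 - background_frac))
  }
  cfg$depth <- as.integer(depth)
  class(cfg) <- "SimConfig"
  validate_sim_config(cfg)
}

#' Validate a SimConfig
#' @param cfg a `SimConfig`
#' @return cfg, invisibly checked; stops with the offending fields otherwise
#' @export
validate_sim_config <- function(cfg) {
  bad <- character()
  if (!(cfg$frag_len_bounds[1] <= cfg$frag_len_mean &&
        cfg$frag_len_mean <= cfg$frag_len_bounds[2]))
    bad <- c(bad, sprintf("frag_len_mean %s outside frag_len_bounds [%d,%d]",
                          cfg$frag_len_mean, cfg$frag_len_bounds[1],
                          cfg$frag_len_bounds[2]))
  if (!(cfg$background_frac >= 0 && cfg$background_frac < 1))
    bad <- c(bad, sprintf("background_frac %s not in [0,1)",
                          cfg$background_frac))
  if (cfg$nrl <= 0) bad <- c(bad, "nrl must be > 0")
  if (cfg$nrl + cfg$nrl_delta <= 0)
    bad <- c(bad, "nrl + nrl_delta must be > 0")
  if (cfg$depth < 0) bad <- c(bad, "depth must be >= 0")
  if (cfg$fuzziness_sd < 0) bad <- c(bad, "fuzziness_sd must be >= 0")
  if (cfg$n_genes < 0) bad <- c(bad, "n_genes must be >= 0")
  if (cfg$n_genes > 0) {
    cap <- cfg$n_chroms * (cfg$chrom_length %/% cfg$gene_spacing)
    if (cfg$n_genes > cap)
      bad <- c(bad, sprintf(
        "%d genes do not fit: %d chrom(s) of %d bp hold at most %d slots of %d bp",
        cfg$n_genes, cfg$n_chroms, cfg$chrom_length, cap, cfg$gene_spacing))
  }
  if (length(bad)) stop("invalid SimConfig:\n  ",
                        paste(bad, collapse = "\n  "))
  cfg
}

# Margin between a gene slot boundary and its TSS; leaves room for
# upstream composite windows and keeps neighbouring arrays apart.
.SLOT_MARGIN <- 500L

#' Build a toy genome: chromosome sizes and a gene annotation
#'
#' Genes occupy successive slots of `gene_spacing` bp, alternating strand.
#' A plus-strand gene has its TSS `.SLOT_MARGIN` bp into the slot and its
#' body running rightward; a minus-strand gene is the mirror image anchored
#' at the right edge of the slot. Deterministic given the configuration.
#'
#' @param config a `SimConfig`
#' @return list with `chrom_sizes` (named integer vector) and `genes`
#'   (gene model data.frame)
#' @export
build_toy_genome <- function(config) {
  config <- validate_sim_config(config)
  chrom_names <- paste0("chrS", seq_len(config$n_chroms))
  chrom_sizes <- stats::setNames(rep(config$chrom_length, config$n_chroms),
                                 chrom_names)
  if (config$n_genes == 0) {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        tss = integer(), strand = character(),
                        body_end = integer(), stringsAsFactors = FALSE)
    return(list(chrom_sizes = chrom_sizes, genes = genes))
  }
  per_chrom <- config$chrom_length %/% config$gene_spacing
  idx <- seq_len(config$n_genes) - 1L
  chrom <- chrom_names[idx %/% per_chrom + 1L]
  slot_start <- (idx %% per_chrom) * config$gene_spacing
  strand <- ifelse(idx %% 2L == 0L, "+", "-")
  body_len <- config$plus1_offset + config$n_nucs_per_gene * config$nrl
  tss <- ifelse(strand == "+", slot_start + .SLOT_MARGIN,
                slot_start + config$gene_spacing - .SLOT_MARGIN)
  body_end <- ifelse(strand == "+", tss + body_len, tss - body_len)
  genes <- data.frame(gene_id = sprintf("gene_%04d", idx + 1L),
                      chrom = chrom, tss = as.integer(tss), strand = strand,
                      body_end = as.integer(body_end),
                      stringsAsFactors = FALSE)
  bad <- genes$body_end < 0 | genes$body_end >= config$chrom_length |
    genes$tss < 0 | genes$tss >= config$chrom_length
  if (any(bad))
    stop("gene(s) do not fit on their chromosome: ",
         paste(genes$gene_id[bad], collapse = ", "),
         " (chrom_length=", config$chrom_length,
         ", gene_spacing=", config$gene_spacing, ")")
  list(chrom_sizes = chrom_sizes, genes = validate_genes(genes))
}

#' Place ground-truth nucleosome arrays for two conditions
#'
#' For a plus-strand gene the true dyads of the reference condition ("wt")
#' are `tss + plus1_offset + k * nrl`, k = 0..n_nucs_per_gene-1; minus
#' strands are mirrored about the TSS. In the "mut" condition, effect genes
#' have every dyad displaced downstream by `plus1_shift` and re-phased with
#' spacing `nrl + nrl_delta`; all other genes are identical to "wt".
#'
#' @param annotation result of [build_toy_genome()] (or a compatible list
#'   with `genes` and `chrom_sizes`)
#' @param config a `SimConfig`
#' @return data.frame (gene_id, condition, k, dyad_pos, strand, chrom): the
#'   ground-truth table
#' @export
place_arrays <- function(annotation, config) {
  config <- validate_sim_config(config)
  genes <- validate_genes(annotation$genes)
  if (nrow(genes) == 0) stop("annotation has no genes")
  unknown <- setdiff(config$effect_genes, genes$gene_id)
  if (length(unknown))
    stop("effect_genes not in annotation: ", paste(unknown, collapse = ", "))
  k <- seq_len(config$n_nucs_per_gene) - 1L
  one_condition <- function(condition) {
    eff <- if (condition == "mut") genes$gene_id %in% config$effect_genes
           else rep(FALSE, nrow(genes))
    shift <- ifelse(eff, config$plus1_shift, 0L)
    step <- ifelse(eff, config$nrl + config$nrl_delta, config$nrl)
    # outer over genes x k in transcript coordinates, then to genome
    off <- outer(config$plus1_offset + shift, rep(1L, length(k))) +
      outer(step, k)
    sgn <- ifelse(genes$strand == "+", 1L, -1L)
    pos <- genes$tss + sgn * off
    data.frame(gene_id = rep(genes$gene_id, times = length(k)),
               condition = condition,
               k = rep(k, each = nrow(genes)),
               dyad_pos = as.integer(pos),
               strand = rep(genes$strand, times = length(k)),
               chrom = rep(genes$chrom, times = length(k)),
               stringsAsFactors = FALSE)
  }
  truth <- rbind(one_condition("wt"), one_condition("mut"))
  sizes <- annotation$chrom_sizes
  bad <- truth$dyad_pos < 0 | truth$dyad_pos >= sizes[truth$chrom]
  if (any(bad))
    stop("nucleosome array exceeds chromosome bounds for gene(s): ",
         paste(unique(truth$gene_id[bad]), collapse = ", "))
  truth <- truth[order(truth$condition, truth$gene_id, truth$k), ]
  rownames(truth) <- NULL
  truth
}

#' Write / read the ground-truth dyad table
#' @param truth ground-truth data.frame from [place_arrays()]
#' @param path TSV path
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

# Truncated-normal fragment lengths by rejection sampling: draws outside
# the closed bounds are redrawn, keeping the in-range shape unbiased.
.draw_lengths <- function(n, mean, sd, bounds) {
  len <- as.integer(round(stats::rnorm(n, mean, sd)))
  for (i in 1:100) {
    bad <- which(len < bounds[1] | len > bounds[2])
    if (!length(bad)) return(len)
    len[bad] <- as.integer(round(stats::rnorm(length(bad), mean, sd)))
  }
  stop("fragment-length rejection sampling did not converge; ",
       "check frag_len_mean/sd against frag_len_bounds")
}

#' Sample paired-end fragments from a ground-truth nucleosome map
#'
#' Each signal fragment picks a (gene, nucleosome) row of the truth table
#' uniformly, draws an observed dyad Normal(true dyad, fuzziness_sd)
#' rounded to integer, a length from the truncated normal fragment-length
#' law, and covers `[dyad - floor(len/2), dyad - floor(len/2) + len)`.
#' Background fragments are uniform over the genome with the same length
#' law. Exactly `depth` fragments are emitted; seeded and reproducible.
#'
#' @param truth ground-truth table from [place_arrays()]
#' @param config a `SimConfig`
#' @param chrom_sizes named integer vector of chromosome lengths
#' @param condition which condition of `truth` to sample ("wt" or "mut")
#' @param seed RNG seed (defaults to `config$seed`)
#' @return `GRanges` of fragments with seqlengths set
#' @export
sample_fragments <- function(truth, config, chrom_sizes,
                             condition = "wt", seed = config$seed) {
  config <- validate_sim_config(config)
  tt <- truth[truth$condition == condition, , drop = FALSE]
  if (config$depth > 0 && nrow(tt) == 0)
    stop("no ground-truth rows for condition '", condition, "'")
  withr::with_seed(as.integer(seed) %% 2147483587, {
    n_bg <- as.integer(round(config$depth * config$background_frac))
    n_sig <- config$depth - n_bg
    chrom <- character(0); start0 <- integer(0); len <- integer(0)
    if (n_sig > 0) {
      rows <- sample.int(nrow(tt), n_sig, replace = TRUE)
      dyad <- as.integer(round(stats::rnorm(
        n_sig, tt$dyad_pos[rows], config$fuzziness_sd)))
      l <- .draw_lengths(n_sig, config$frag_len_mean, config$frag_len_sd,
                         config$frag_len_bounds)
      s <- dyad - l %/% 2L
      cs <- unname(chrom_sizes[tt$chrom[rows]])
      s <- pmax(0L, pmin(s, cs - l))  # keep fragments on the chromosome
      chrom <- c(chrom, tt$chrom[rows]); start0 <- c(start0, s)
      len <- c(len, l)
    }
    if (n_bg > 0) {
      ci <- sample.int(length(chrom_sizes), n_bg, replace = TRUE,
                       prob = chrom_sizes / sum(chrom_sizes))
      l <- .draw_lengths(n_bg, config$frag_len_mean, config$frag_len_sd,
                         config$frag_len_bounds)
      cs <- unname(chrom_sizes[ci])
      s <- as.integer(floor(stats::runif(n_bg) * (cs - l + 1)))
      chrom <- c(chrom, names(chrom_sizes)[ci]); start0 <- c(start0, s)
      len <- c(len, l)
    }
  })
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = start0 + 1L, width = len),
    seqinfo = .seqinfo(chrom_sizes))
  if (length(gr)) {
    gr$name <- sprintf("frag_%07d", seq_along(gr))
    gr$score <- 0L
  }
  gr
}

#' Write fragments as 6-column BED
#'
#' 0-based half-open intervals; name, score 0, strand ".".
#' @param frags `GRanges` of fragments
#' @param path output BED path
#' @export
write_fragments_bed <- function(frags, path) {
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(frags)),
    start = BiocGenerics::start(frags) - 1L,
    end = BiocGenerics::end(frags),
    name = if (!is.null(frags$name)) frags$name else
      sprintf("frag_%07d", seq_along(frags)),
    score = 0L, strand = ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate a complete two-condition MNase-Seq experiment
#'
#' Convenience wrapper: builds the toy genome, places ground-truth arrays,
#' and samples fragments for each condition and replicate (each replicate
#' gets a distinct seed derived from `config$seed`).
#'
#' @param config a `SimConfig`
#' @param n_replicates replicates per condition
#' @return list with `chrom_sizes`, `genes`, `truth`, and `fragments` — a
#'   nested list `fragments[[condition]][[replicate]]` of `GRanges`
#' @export
simulate_experiment <- function(config, n_replicates = 2L) {
  genome <- build_toy_genome(config)
  truth <- place_arrays(genome, config)
  frags <- list()
  for (cond in c("wt", "mut")) {
    frags[[cond]] <- lapply(seq_len(n_replicates), function(r) {
      sample_fragments(truth, config, genome$chrom_sizes, condition = cond,
                       seed = .child_seed(config$seed,
                                          r + 1000L * (cond == "mut")))
    })
  }
  list(chrom_sizes = genome$chrom_sizes, genes = genome$genes,
       truth = truth, fragments = frags)
}
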