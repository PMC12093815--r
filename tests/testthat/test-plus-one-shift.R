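make_calls <- function(summits, chrom = "chrT") {
  data.frame(chrom = chrom, summit = as.integer(summits),
             height = 1, raw_dyads = NA_integer_,
             stringsAsFactors = FALSE)
}

plus_gene <- data.frame(gene_id = "g1", chrom = "chrT", tss = 1000L,
                        strand = "+", body_end = 2400L,
                        stringsAsFactors = FALSE)
minus_gene <- data.frame(gene_id = "g1", chrom = "chrT", tss = 1000L,
                         strand = "-", body_end = 100L,
                         stringsAsFactors = FALSE)

test_that("+1 assignment picks the smallest in-window transcript offset", {
  a <- assign_plus_one(make_calls(c(940, 1060, 1225)), plus_gene)
  expect_equal(a$summit, 1060)
  expect_equal(a$offset, 60)  # 940 is upstream beyond -30, excluded

  # strand mirror: a summit 60 bp leftward of a minus-strand TSS is +1
  am <- assign_plus_one(make_calls(940), minus_gene)
  expect_equal(am$offset, 60)

  # no summit in window -> NA assignment
  a0 <- assign_plus_one(make_calls(c(500, 2000)), plus_gene)
  expect_true(is.na(a0$summit))

  # window edges are inclusive
  aw <- assign_plus_one(make_calls(970), plus_gene, window = c(-30, 250))
  expect_equal(aw$offset, -30)
})

test_that("shifts are signed transcript displacements, antisymmetric", {
  wt <- assign_plus_one(make_calls(1060), plus_gene)
  mut <- assign_plus_one(make_calls(1084), plus_gene)
  expect_equal(compute_shift(wt, mut), 24)
  expect_equal(compute_shift(wt, wt), 0)
  expect_equal(compute_shift(mut, wt), -compute_shift(wt, mut))

  other <- assign_plus_one(make_calls(1060),
                           transform(plus_gene, gene_id = "g2"))
  expect_error(compute_shift(wt, other), "mismatch")
})

test_that("dependence requires the threshold in every replicate", {
  expect_true(classify_dependent(c(12, 15, 11), threshold = 10))
  expect_false(classify_dependent(c(12, 8), threshold = 10))
  expect_true(classify_dependent(10, threshold = 10))  # boundary, >= rule
  expect_error(classify_dependent(numeric(0)), "no replicate")
  expect_error(classify_dependent(c(12, NA)), "NA")
})

test_that("shift_table composes assignments, means and flags", {
  wt <- list(make_calls(1060), make_calls(1062))
  mut <- list(make_calls(1084), make_calls(1088))
  tab <- shift_table(wt, mut, plus_gene)
  expect_equal(tab$shift_r1, 24)
  expect_equal(tab$shift_r2, 26)
  expect_equal(tab$mean_shift, 25)  # arithmetic mean of replicate shifts
  expect_true(tab$dependent)
  expect_equal(attr(tab, "pairing"), "by_replicate_index")

  # unequal replicate counts: mutant vs mean reference offset
  tab2 <- shift_table(wt, mut[1], plus_gene)
  expect_equal(attr(tab2, "pairing"), "mutant_vs_mean_reference")
  expect_equal(tab2$shift_r1, 84 - 61)

  # a missing +1 leaves the gene unclassified with a reason
  tab3 <- shift_table(list(make_calls(5000)), mut[1], plus_gene)
  expect_true(is.na(tab3$dependent))
  expect_equal(tab3$na_reason, "no_plus_one_in_reference")

  expect_error(shift_table(list(), mut, plus_gene), "replicate")
})

test_that("raising the threshold never gains dependent genes", {
  cfg <- tiny_config(seed = 111, n_genes = 20, frags_per_nuc = 80,
                     effect_genes = sprintf("gene_%04d", 1:5),
                     plus1_shift = 15L)
  sim <- simulate_experiment(cfg, n_replicates = 2)
  calls <- lapply(sim$fragments, function(reps)
    lapply(reps, calls_from_fragments, chrom_sizes = sim$chrom_sizes))
  counts <- vapply(c(5, 10, 15, 20), function(thr) {
    tab <- shift_table(calls$wt, calls$mut, sim$genes, threshold = thr)
    sum(tab$dependent, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("mirroring the genome leaves offsets and shifts unchanged", {
  # odd fixed fragment length: the floor-midpoint dyad then mirrors
  # exactly, so the symmetry holds to the base pair
  cfg <- tiny_config(seed = 121, n_genes = 10, frags_per_nuc = 80,
                     effect_genes = sprintf("gene_%04d", 1:3),
                     plus1_shift = 24L, frag_len_sd = 0,
                     frag_len_mean = 151)
  sim <- simulate_experiment(cfg, n_replicates = 1)
  L <- unname(sim$chrom_sizes[1])

  mirror_frags <- function(fr) {
    s <- BiocGenerics::start(fr); e <- BiocGenerics::end(fr)
    GenomicRanges::GRanges(as.character(GenomeInfoDb::seqnames(fr)),
                           IRanges::IRanges(L - e + 1, L - s + 1),
                           seqinfo = GenomeInfoDb::seqinfo(fr))
  }
  mirror_genes <- function(g) {
    transform(g, tss = L - 1 - tss, body_end = L - 1 - body_end,
              strand = ifelse(strand == "+", "-", "+"))
  }
  tab <- shift_table(
    list(calls_from_fragments(sim$fragments$wt[[1]], sim$chrom_sizes)),
    list(calls_from_fragments(sim$fragments$mut[[1]], sim$chrom_sizes)),
    sim$genes)
  tab_m <- shift_table(
    list(calls_from_fragments(mirror_frags(sim$fragments$wt[[1]]),
                              sim$chrom_sizes)),
    list(calls_from_fragments(mirror_frags(sim$fragments$mut[[1]]),
                              sim$chrom_sizes)),
    mirror_genes(sim$genes))
  expect_equal(tab_m$mean_shift, tab$mean_shift)
  expect_equal(tab_m$dependent, tab$dependent)
})
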