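.default_config <- function() {
  list(seed = 1L, reference_condition = "wt",
       filter = list(min_len = 140L, max_len = 160L),
       exclude = NULL,
       subsample = list(n = 5000000L),
       extend = 50L,
       caller = list(bandwidth = 15, min_distance = 110L, cap = 200),
       shift = list(threshold = 10, window = c(-30L, 250L)),
       nrl = list(min_nucs = 4L, max_nucs = 8L),
       composite = list(window = c(-300L, 1300L), normalization = "none"))
}

# An explicit null in the config (e.g. subsample: {n: null} to disable
# subsampling) is honoured; only absent fields receive defaults.
.merge_defaults <- function(x, d) {
  for (nm in names(d)) {
    if (!nm %in% names(x)) x[nm] <- list(d[[nm]])
    else if (is.list(d[[nm]]) && is.list(x[[nm]]))
      x[[nm]] <- .merge_defaults(x[[nm]], d[[nm]])
  }
  x
}

#' Validate a pipeline run configuration
#'
#' Reads a YAML file (or accepts an equivalent list), fills in the
#' standard defaults (fragment lengths 140-160 bp, 50 bp dyad extension,
#' 5e6-fragment subsampling, 10 bp shift threshold), and reports every
#' violation with its field path. A configuration either names a
#' `simulate` block (synthetic experiment; see [sim_config()]) or a
#' `samples` table plus `genes` and `chrom_sizes` paths.
#'
#' @param config YAML path or list
#' @return validated `RunConfig` list with defaults filled in
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- .merge_defaults(config, .default_config())
  errs <- character()
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  chk(.is_count(cfg$seed), "seed: must be a non-negative integer")
  chk(cfg$filter$min_len <= cfg$filter$max_len,
      "filter: min_len must be <= max_len")
  chk(is.null(cfg$subsample$n) || .is_count(cfg$subsample$n),
      "subsample.n: must be a non-negative integer or null")
  chk(.is_count(cfg$extend), "extend: must be a non-negative integer")
  chk(length(cfg$shift$window) == 2 &&
        cfg$shift$window[1] < cfg$shift$window[2],
      "shift.window: must be an increasing pair")
  chk(length(cfg$composite$window) == 2 &&
        cfg$composite$window[1] < cfg$composite$window[2],
      "composite.window: must be an increasing pair")
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    n_rep <- if (is.null(sim$n_replicates)) 2L else sim$n_replicates
    chk(.is_count(n_rep) && n_rep >= 1, "simulate.n_replicates: must be >= 1")
    sim$n_replicates <- NULL
    sim$seed <- cfg$seed
    sc <- tryCatch(do.call(sim_config, sim), error = function(e)
      { errs <<- c(errs, paste0("simulate: ", conditionMessage(e))); NULL })
    cfg$sim_config <- sc
    cfg$n_replicates <- as.integer(n_rep)
  } else {
    chk(!is.null(cfg$samples) && length(cfg$samples) > 0,
        "samples: required when no simulate block is given")
    chk(!is.null(cfg$genes), "genes: annotation path required")
    chk(!is.null(cfg$chrom_sizes), "chrom_sizes: path required")
    if (!is.null(cfg$samples)) {
      smp <- do.call(rbind, lapply(cfg$samples, function(s)
        data.frame(name = s$name %||% NA, condition = s$condition %||% NA,
                   replicate = s$replicate %||% NA,
                   fragments = s$fragments %||% NA,
                   stringsAsFactors = FALSE)))
      dup <- smp$name[duplicated(smp$name)]
      chk(!length(dup), paste0("samples: duplicate sample name(s): ",
                               paste(unique(dup), collapse = ", ")))
      for (i in seq_len(nrow(smp))) {
        chk(!is.na(smp$fragments[i]) && file.exists(smp$fragments[i]),
            sprintf("samples[%d].fragments: file not found: %s",
                    i, smp$fragments[i]))
        chk(!is.na(smp$condition[i]),
            sprintf("samples[%d].condition: required", i))
      }
      cfg$sample_table <- smp
    }
    if (!is.null(cfg$genes))
      chk(file.exists(cfg$genes),
          paste0("genes: file not found: ", cfg$genes))
    if (!is.null(cfg$chrom_sizes))
      chk(file.exists(cfg$chrom_sizes),
          paste0("chrom_sizes: file not found: ", cfg$chrom_sizes))
  }
  if (length(errs))
    stop("invalid run configuration:\n  ", paste(errs, collapse = "\n  "))
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.log_line <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  message(msg)
}

#' Run the full nucleosome-organization pipeline
#'
#' Orchestrates simulate (optional) -> fragment filtering -> dyad tracks
#' -> nucleosome calls -> +1 shift classification -> NRL statistics ->
#' composite profiles, writing every stage product plus a manifest (file
#' checksums, parameters, seeds, versions) and a run log with record
#' counts at each filter. Reruns with the same configuration reproduce
#' identical outputs.
#'
#' @param config a validated `RunConfig` (see [validate_config()]), a
#'   config list, or a YAML path
#' @param outdir output directory (created; defaults to `config$outdir`)
#' @return report list: sample table with per-stage fragment counts,
#'   dependent-gene calls, NRL summaries, Welch test, composite peak
#'   shift, and output paths
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- validate_config(config)
  outdir <- outdir %||% cfg$outdir %||% stop("no output directory given")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  cat("", file = log_path)
  failed <- file.path(outdir, "FAILED")
  if (file.exists(failed)) unlink(failed)
  stage <- function(name, sample, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage=", name, " sample=", sample, " : ",
                        conditionMessage(e)), failed)
      stop("pipeline failed at stage '", name, "' (sample ", sample,
           "): ", conditionMessage(e), call. = FALSE)
    })
  }
  outputs <- character()
  emit <- function(path) { outputs <<- c(outputs, path); path }

  # ---- inputs: simulated or provided ----
  if (!is.null(cfg$sim_config)) {
    .log_line(log_path, "simulate: ", cfg$sim_config$n_genes, " genes, ",
              cfg$n_replicates, " replicates/condition, depth ",
              cfg$sim_config$depth)
    sim <- stage("simulate", "-", simulate_experiment(cfg$sim_config,
                                                      cfg$n_replicates))
    genes <- sim$genes
    chrom_sizes <- sim$chrom_sizes
    emit(write_chrom_sizes(chrom_sizes,
                           file.path(outdir, "chrom_sizes.tsv")))
    emit(write_genes_gff3(genes, file.path(outdir, "genes.gff3")))
    emit(write_genes_bed(genes, file.path(outdir, "genes.bed")))
    emit(write_ground_truth(sim$truth,
                            file.path(outdir, "ground_truth.tsv")))
    smp <- expand.grid(replicate = seq_len(cfg$n_replicates),
                       condition = c("wt", "mut"),
                       stringsAsFactors = FALSE)
    smp$name <- paste0(smp$condition, "_r", smp$replicate)
    smp$fragments <- file.path(outdir, paste0(smp$name, ".bed"))
    for (i in seq_len(nrow(smp)))
      emit(write_fragments_bed(
        sim$fragments[[smp$condition[i]]][[smp$replicate[i]]],
        smp$fragments[i]))
    frag_list <- lapply(seq_len(nrow(smp)), function(i)
      sim$fragments[[smp$condition[i]]][[smp$replicate[i]]])
  } else {
    genes <- stage("read_genes", "-", read_genes(cfg$genes))
    chrom_sizes <- stage("read_chrom_sizes", "-",
                         read_chrom_sizes(cfg$chrom_sizes))
    smp <- cfg$sample_table
    frag_list <- lapply(seq_len(nrow(smp)), function(i)
      stage("read_fragments", smp$name[i],
            read_fragments(smp$fragments[i])))
  }
  excl <- if (is.null(cfg$exclude)) NULL
          else if (identical(cfg$exclude, "rdna")) rdna_region()
          else rtracklayer::import(cfg$exclude, format = "BED")

  # ---- per-sample: filter, track, call ----
  smp$n_input <- vapply(frag_list, length, 0L)
  tracks <- list(); calls <- list()
  smp$n_filtered <- smp$n_excluded <- smp$n_used <- NA_integer_
  for (i in seq_len(nrow(smp))) {
    nm <- smp$name[i]
    fr <- stage("filter_by_length", nm,
                filter_by_length(frag_list[[i]], cfg$filter$min_len,
                                 cfg$filter$max_len))
    smp$n_filtered[i] <- length(fr)
    if (!is.null(excl)) fr <- stage("exclude_regions", nm,
                                    exclude_regions(fr, excl))
    smp$n_excluded[i] <- length(fr)
    if (!is.null(cfg$subsample$n))
      fr <- stage("subsample", nm, suppressWarnings(
        subsample_fragments(fr, cfg$subsample$n,
                            seed = .child_seed(cfg$seed, i))))
    smp$n_used[i] <- length(fr)
    .log_line(log_path, nm, ": ", smp$n_input[i], " in -> ",
              smp$n_filtered[i], " size-selected -> ", smp$n_excluded[i],
              " after exclusion -> ", smp$n_used[i], " used")
    tr <- stage("build_dyad_track", nm,
                build_dyad_track(fr, chrom_sizes,
                                 extension_radius = cfg$extend,
                                 provenance = list(sample = nm,
                                                   filter = cfg$filter,
                                                   seed = cfg$seed)))
    emit(write_track(tr, file.path(outdir, paste0(nm, ".bedGraph"))))
    params <- caller_params(bandwidth = cfg$caller$bandwidth,
                            min_distance = cfg$caller$min_distance,
                            max_height_cap = cfg$caller$cap)
    cl <- stage("call_nucleosomes", nm, call_nucleosomes(tr, params))
    emit(write_calls(cl, file.path(outdir, paste0(nm, "_calls.tsv"))))
    .log_line(log_path, nm, ": ", nrow(cl), " nucleosome calls")
    tracks[[nm]] <- tr; calls[[nm]] <- cl
  }

  ref <- cfg$reference_condition
  conds <- unique(smp$condition)
  mut_cond <- setdiff(conds, ref)
  report <- list(samples = smp, outdir = outdir)

  # ---- +1 shifts and dependence classification ----
  if (length(mut_cond) == 1 && ref %in% conds) {
    wt_calls <- calls[smp$name[smp$condition == ref]]
    mut_calls <- calls[smp$name[smp$condition == mut_cond]]
    tab <- stage("shift_table", "-",
                 shift_table(wt_calls, mut_calls, genes,
                             window = cfg$shift$window,
                             threshold = cfg$shift$threshold))
    emit(write_shift_table(tab, file.path(outdir, "shifts.tsv")))
    emit(write_dependent_bed(tab, genes,
                             file.path(outdir, "dependent_genes.bed")))
    report$shift_table <- tab
    report$dependent_genes <- tab$gene_id[!is.na(tab$dependent) &
                                            tab$dependent]
    report$n_dependent <- length(report$dependent_genes)
    .log_line(log_path, "shifts: ", report$n_dependent,
              " dependent gene(s) at threshold ", cfg$shift$threshold,
              " bp")
  }

  # ---- NRL ----
  nrl_tabs <- lapply(calls, gene_nrl_table, genes = genes,
                     window = cfg$shift$window,
                     min_nucs = cfg$nrl$min_nucs,
                     max_nucs = cfg$nrl$max_nucs)
  for (nm in names(nrl_tabs))
    emit(write_shift_table(nrl_tabs[[nm]],
                           file.path(outdir, paste0(nm, "_nrl.tsv"))))
  sample_means <- vapply(nrl_tabs, function(tt)
    mean(tt$nrl, na.rm = TRUE), 0)
  report$nrl_sample_means <- sample_means
  if (length(mut_cond) == 1 && ref %in% conds) {
    a <- sample_means[smp$name[smp$condition == ref]]
    b <- sample_means[smp$name[smp$condition == mut_cond]]
    report$welch <- tryCatch(welch_t(a, b), error = function(e) {
      .log_line(log_path, "welch: skipped (", conditionMessage(e), ")")
      NULL
    })
    if (!is.null(report$welch))
      .log_line(log_path, sprintf(
        "welch on mean NRL: t=%.3f df=%.2f p=%.3g", report$welch$t,
        report$welch$df, report$welch$p))
  }

  # ---- composites ----
  comp <- list()
  for (cond in conds) {
    nms <- smp$name[smp$condition == cond]
    profs <- lapply(nms, function(nm)
      composite_profile(tracks[[nm]], genes,
                        window = cfg$composite$window,
                        normalization = cfg$composite$normalization))
    avg <- profs[[1]]
    if (length(profs) > 1)
      avg$values <- Reduce(`+`, lapply(profs, `[[`, "values")) /
        length(profs)
    comp[[cond]] <- avg
    emit(write_composite_tsv(avg, file.path(
      outdir, paste0("composite_", cond, ".tsv"))))
  }
  report$composites <- comp
  if (length(mut_cond) == 1 && ref %in% conds) {
    pw <- c(0, max(cfg$shift$window))
    report$composite_plus1_shift <-
      peak_shift(comp[[ref]], comp[[mut_cond]], pw)
    .log_line(log_path, "composite +1 peak shift: ",
              report$composite_plus1_shift, " bp")
  }

  # ---- manifest ----
  manifest <- list(
    package_version = as.character(utils::packageVersion("nucorg")),
    r_version = R.version.string,
    seed = cfg$seed,
    parameters = cfg[c("filter", "subsample", "extend", "caller",
                       "shift", "nrl", "composite")],
    files = lapply(stats::setNames(outputs, basename(outputs)),
                   function(p) list(path = p,
                                    md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  report$manifest <- file.path(outdir, "manifest.json")
  .log_line(log_path, "done: ", length(outputs), " output file(s)")
  report
}
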