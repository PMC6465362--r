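# End-to-end pipeline: simulate -> call -> cohort stats -> CIMP -> genes ->
# clustering, from one hierarchical JSON config, with a provenance manifest.

#' Build / validate a pipeline configuration
#'
#' Unknown keys anywhere in the hierarchy are rejected (typo safety). The
#' `sim` block takes [sim_config()] arguments, the `call` block
#' [pmd_call_config()] arguments.
#'
#' @param config named list (or path to a JSON file with the same shape).
#' @return validated `PipelineConfig` list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(
    outdir = "pmdscape_out",
    seed = 1L,
    sim = list(),
    call = list(),
    freq_tile_bp = 3e4,
    map_tile_bp = 1e4,
    binary_tile_bp = 5e3,
    n_shuffles = 20,
    cimp_threshold = 0.30,
    aggregate_bin_bp = 1e5)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown pipeline config keys: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config)
  if (length(cfg$sim)) {
    bad <- setdiff(names(cfg$sim), names(formals(sim_config)))
    if (length(bad))
      stop("unknown sim config keys: ", paste(bad, collapse = ", "))
    if (!is.null(cfg$sim$chrom_lengths))
      cfg$sim$chrom_lengths <- unlist(cfg$sim$chrom_lengths)
  }
  if (length(cfg$call)) {
    bad <- setdiff(names(cfg$call), names(formals(pmd_call_config)))
    if (length(bad))
      stop("unknown call config keys: ", paste(bad, collapse = ", "))
  }
  structure(cfg, class = "PipelineConfig")
}

#' Run the full synthetic-cohort pipeline
#'
#' Stages: (1) simulate a cohort and write it out; (2) call PMDs per
#' sample; (3) cohort statistics (genome fractions, frequency track and
#' curve, shuffle null, aggregate track); (4) CGI/CIMP analysis with beta
#' regression; (5) gene PMD frequencies and TSG exclusion test;
#' (6) clustering and PCA. All outputs are plain text under `outdir`; a
#' manifest records the configuration and per-stage seeds. Rerunning with
#' the same config reproduces every output.
#'
#' @param config a [pipeline_config()] (or list / JSON path accepted by it).
#' @param quiet suppress progress messages.
#' @return (invisibly) list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  cfg <- pipeline_config(unclass(config))
  say <- function(...) if (!quiet) message("[pmdscape] ", ...)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  say("stage simulate")
  sim_args <- cfg$sim
  sim_args$seed <- derive_seed(cfg$seed, 1L)
  scfg <- do.call(sim_config, sim_args)
  cohort <- generate_cohort(scfg)
  write_cohort(cohort, file.path(cfg$outdir, "cohort"))

  say("stage call")
  call_cfg <- do.call(pmd_call_config, cfg$call)
  calls <- lapply(cohort$samples, call_pmds, layout = cohort$layout,
                  config = call_cfg)
  dir.create(file.path(cfg$outdir, "calls"), showWarnings = FALSE)
  for (sid in names(calls)) {
    gr <- calls[[sid]]
    gr$name <- if (length(gr)) sprintf("PMD%04d", seq_along(gr)) else
      character(0)
    write_intervals(gr, file.path(cfg$outdir, "calls",
                                  paste0(sid, ".pmds.bed")))
  }

  say("stage stats")
  fracs <- vapply(calls, genome_fraction, numeric(1),
                  layout = cohort$layout)
  ft <- frequency_track(calls, cohort$layout, cfg$freq_tile_bp)
  curve <- frequency_fraction_curve(ft)
  null <- border_null_distribution(calls, cohort$layout, cfg$freq_tile_bp,
                                   n_shuffles = cfg$n_shuffles,
                                   seed = derive_seed(cfg$seed, 2L))
  agg <- aggregate_pmds_sd(cohort$samples, cohort$layout,
                           cfg$aggregate_bin_bp)
  fwrite(data.table(sample_id = names(fracs), pmd_genome_fraction = fracs),
         file.path(cfg$outdir, "genome_fractions.tsv"), sep = "\t")
  fwrite(as.data.table(ft), file.path(cfg$outdir, "frequency_track.tsv"),
         sep = "\t")
  fwrite(curve, file.path(cfg$outdir, "frequency_curve.tsv"), sep = "\t")
  write_intervals(agg, file.path(cfg$outdir, "aggregate_pmds.bed"))

  say("stage cimp")
  cm <- cgi_matrix(cohort$samples, cohort$layout, calls)
  ci <- cimp_inputs(cm, cfg$cimp_threshold)
  fit <- tryCatch(fit_beta_regression(ci$b_cimp, ci$frac_cgi_in_pmd,
                                      cfg$cimp_threshold),
                  error = function(e) {
                    say("beta regression skipped: ", conditionMessage(e))
                    NULL
                  })
  fwrite(ci, file.path(cfg$outdir, "cimp.tsv"), sep = "\t")
  if (!is.null(fit))
    jsonlite::write_json(unclass(fit), file.path(cfg$outdir,
                                                 "cimp_fit.json"),
                         auto_unbox = TRUE, digits = NA)

  say("stage genes")
  gt <- gene_pmd_frequency(cohort$layout$genes, calls,
                           gene_sets = cohort$layout$gene_sets)
  excl <- if (length(cohort$layout$gene_sets))
    lapply(setNames(nm = names(cohort$layout$gene_sets)),
           function(s) exclusion_test(gt, s))
  else list()
  fwrite(as.data.table(gt), file.path(cfg$outdir, "gene_frequency.tsv"),
         sep = "\t")
  if (length(excl))
    jsonlite::write_json(excl, file.path(cfg$outdir, "exclusion_tests.json"),
                         auto_unbox = TRUE, digits = NA)

  say("stage cluster")
  tm <- tile_matrix(cohort$samples, cohort$layout, cfg$map_tile_bp)
  prof_clust <- tryCatch(cluster_profiles(tm), error = function(e) NULL)
  bin_clust <- pmd_binary_cluster(calls, cohort$layout, cfg$binary_tile_bp)
  pca <- tryCatch(
    pca_top_variable(cohort$samples,
                     covariates = cohort$sample_sheet[, c("covariate"),
                                                      drop = FALSE]),
    error = function(e) {
      say("PCA skipped: ", conditionMessage(e)); NULL
    })
  if (!is.null(pca))
    fwrite(data.table(sample_id = rownames(pca$scores),
                      as.data.table(pca$scores)),
           file.path(cfg$outdir, "pca_scores.tsv"), sep = "\t")
  fwrite(data.table(merge1 = bin_clust$hclust$merge[, 1],
                    merge2 = bin_clust$hclust$merge[, 2],
                    height = bin_clust$hclust$height),
         file.path(cfg$outdir, "pmd_cluster_merges.tsv"), sep = "\t")

  manifest <- list(
    package_version = as.character(utils::packageVersion("pmdscape")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S"),
    seed = cfg$seed,
    stage_seeds = list(simulate = derive_seed(cfg$seed, 1L),
                       shuffle = derive_seed(cfg$seed, 2L)),
    config = unclass(cfg),
    runtime_sec = as.numeric(Sys.time() - t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, calls = calls, genome_fractions = fracs,
                 frequency_track = ft, frequency_curve = curve, null = null,
                 aggregate = agg, cgi_matrix = cm, cimp = ci, cimp_fit = fit,
                 gene_table = gt, exclusion = excl,
                 profile_cluster = prof_clust, binary_cluster = bin_clust,
                 pca = pca, manifest = manifest))
}
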