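#' Generate one synthetic sample methylome
#'
#' Draws the per-sample state (tissue, covariate, global activity, PMD
#' methylation depth), activates permissive domains, jitters their edges,
#' assigns each CpG a true methylation mean according to its region (PMD /
#' background / CGI state / solo-WCGW), then draws beta-distributed per-CpG
#' methylation, negative-binomial coverage and binomial methylated counts.
#' Fully deterministic given `config$seed` and `sample_index`.
#'
#' @param layout `GenomeLayout` from [generate_layout()].
#' @param truth `PmdGroundTruth` skeleton from [generate_layout()].
#' @param sample_index sample number in `1..config$n_samples`.
#' @param config the [sim_config()] used for the layout.
#' @return list with `methylome` (a `SampleMethylome`), `pmds` (planted
#'   per-sample PMD `GRanges`) and `truth_row` (one-row data.table of
#'   per-sample ground truth).
#' @export
generate_sample <- function(layout, truth, sample_index, config) {
  stopifnot(sample_index >= 1, sample_index <= config$n_samples)
  set.seed(derive_seed(config$seed, sample_index))
  sid <- sprintf("S%03d", sample_index)

  covariate <- runif(1) < config$covariate_prob
  activity <- runif(1, config$sample_activity_range[1],
                    config$sample_activity_range[2])
  depth <- runif(1, config$pmd_mean_range[1], config$pmd_mean_range[2])
  tissue <- if (config$n_tissues == 2) 1L + (sample_index - 1L) %% 2L else 1L

  dom <- truth$domain_table
  pmds <- .empty_gr(layout$chrom_lengths)
  active <- logical(0)
  if (!is.null(dom) && nrow(dom)) {
    eligible <- dom$tissue == 0L | dom$tissue == tissue
    p_act <- pmin(0.95, activity * dom$propensity *
                    ifelse(covariate & dom$cov_linked,
                           config$covariate_effect, 1))
    active <- eligible & (runif(nrow(dom)) < p_act)
    if (any(active)) {
      j <- config$boundary_jitter_bp
      ad <- dom[active, ]
      dl <- runif(nrow(ad), 0, j) * sample(c(-1, 1), nrow(ad), replace = TRUE)
      dr <- runif(nrow(ad), 0, j) * sample(c(-1, 1), nrow(ad), replace = TRUE)
      s <- pmax(0, round(ad$start - dl))
      e <- pmin(layout$chrom_lengths[ad$chrom], round(ad$end + dr))
      keep <- e - s >= 1
      pmds <- gr_from_bed0(data.table(chrom = ad$chrom[keep],
                                      start = s[keep], end = e[keep],
                                      name = ad$domain_id[keep]),
                           layout$chrom_lengths)
      pmds <- sort(pmds, ignore.strand = TRUE)
    }
  }

  cp <- copy(truth$cpg_template)
  n <- nrow(cp)
  mu <- rep(config$bg_mean, n)
  conc <- rep(config$bg_concentration, n)

  cpg_gr <- gr_from_bed0(data.table(chrom = cp$chrom, pos0 = cp$pos,
                                    start = cp$pos, end = cp$pos + 1),
                         layout$chrom_lengths)
  in_pmd <- GenomicRanges::countOverlaps(cpg_gr, pmds) > 0
  mu[in_pmd] <- depth
  conc[in_pmd] <- config$pmd_concentration
  solo_in_pmd <- in_pmd & cp$is_solo_wcgw
  mu[solo_in_pmd] <- .clamp(depth + config$solo_offset, 0.02, 0.98)

  ## CGI CpGs override both mean and concentration by island state
  is_cgi_cpg <- rep(FALSE, n)
  gained_cpg <- rep(FALSE, n)
  if (length(layout$cgis)) {
    hits <- GenomicRanges::findOverlaps(cpg_gr, layout$cgis,
                                        ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    cgi_of_cpg <- S4Vectors::subjectHits(hits)
    st <- truth$cgi_states$state[cgi_of_cpg]
    cgi_in_pmd <- .frac_in(layout$cgis, pmds) >= 0.5
    gain_level <- runif(length(layout$cgis), config$cgi_gain_mean_range[1],
                        config$cgi_gain_mean_range[2])
    cgi_mu <- rep(config$cgi_hypo_mean, length(layout$cgis))
    cgi_mu[truth$cgi_states$state == "constitutive"] <-
      config$cgi_constitutive_mean
    gained_now <- truth$cgi_states$state == "gained" & cgi_in_pmd
    cgi_mu[gained_now] <- gain_level[gained_now]
    mu[qh] <- cgi_mu[cgi_of_cpg]
    ## constitutively methylated islands are stably methylated the way the
    ## background is: polarized (near-bimodal) per-CpG levels, not the
    ## intermediate dispersion of PMD-gained islands
    cgi_conc <- rep(config$cgi_concentration, length(layout$cgis))
    cgi_conc[truth$cgi_states$state == "constitutive"] <-
      config$bg_concentration
    conc[qh] <- cgi_conc[cgi_of_cpg]
    is_cgi_cpg[qh] <- TRUE
    gained_cpg[qh] <- gained_now[cgi_of_cpg]
  }

  ## stable regions (background, non-gained islands): the per-CpG level is
  ## anchored by the layout's baseline quantile — identical in every sample
  ## up to a modest wobble — while CpGs in active PMDs (and gained islands)
  ## redraw their disordered intermediate methylation per sample
  in_active_pmd <- (in_pmd & !is_cgi_cpg) | gained_cpg
  p_true <- numeric(n)
  stab <- !in_active_pmd
  if (any(stab)) {
    base <- cp$baseline_p[stab]
    k <- config$cpg_anchor_concentration
    p_true[stab] <- rbeta(sum(stab), base * k, (1 - base) * k)
  }
  if (any(!stab))
    p_true[!stab] <- rbeta(sum(!stab), mu[!stab] * conc[!stab],
                           (1 - mu[!stab]) * conc[!stab])
  Tcov <- rnbinom(n, mu = config$coverage_mean, size = config$coverage_size)
  M <- rbinom(n, Tcov, p_true)

  rec <- data.table(chrom = cp$chrom, pos = cp$pos, strand = "+",
                    M = M, T = Tcov, is_solo_wcgw = cp$is_solo_wcgw)
  meth <- sample_methylome(sid, rec,
                           meta = list(covariate = ifelse(covariate,
                                                          "pos", "neg"),
                                       tissue = tissue))
  meth <- annotate_cpgs(meth, layout)

  ## per-sample truth: planted fraction and expected methylation over the
  ## permissive compartment (active -> depth, inactive -> background)
  ne_bp <- sum(GenomicRanges::width(non_excluded_regions(layout)))
  pmd_bp <- sum(GenomicRanges::width(GenomicRanges::reduce(pmds)))
  perm_bp <- sum(GenomicRanges::width(truth$domains))
  mean_perm <- if (perm_bp > 0)
    (pmd_bp * depth + (perm_bp - pmd_bp) * config$bg_mean) / perm_bp
  else NA_real_
  truth_row <- data.table(
    sample_id = sid, tissue = tissue,
    covariate = ifelse(covariate, "pos", "neg"),
    activity = activity, pmd_mean = depth,
    pmd_genome_fraction = pmd_bp / ne_bp,
    mean_permissive_meth = mean_perm,
    n_active_domains = sum(active))

  list(methylome = meth, pmds = pmds, truth_row = truth_row)
}

#' Generate a full synthetic cohort
#'
#' Runs [generate_layout()] then [generate_sample()] for every sample, and
#' assembles the sample sheet and completed ground truth.
#'
#' @param config a [sim_config()].
#' @return A `SyntheticCohort`: list with `samples` (list of
#'   `SampleMethylome`), `pmds` (named list of planted PMD `GRanges`),
#'   `layout`, `truth` (completed, including `sample_truth`), and
#'   `sample_sheet` (data.table: sample_id, covariate, tissue).
#' @export
generate_cohort <- function(config) {
  gl <- generate_layout(config)
  samples <- vector("list", config$n_samples)
  pmds <- vector("list", config$n_samples)
  rows <- vector("list", config$n_samples)
  for (i in seq_len(config$n_samples)) {
    gs <- generate_sample(gl$layout, gl$truth, i, config)
    samples[[i]] <- gs$methylome
    pmds[[i]] <- gs$pmds
    rows[[i]] <- gs$truth_row
  }
  st <- rbindlist(rows)
  names(samples) <- st$sample_id
  names(pmds) <- st$sample_id
  gl$truth$pmds <- pmds
  gl$truth$sample_truth <- st
  structure(list(samples = samples, pmds = pmds, layout = gl$layout,
                 truth = gl$truth,
                 sample_sheet = st[, c("sample_id", "covariate", "tissue"),
                                   with = FALSE]),
            class = "SyntheticCohort")
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat("SyntheticCohort:", length(x$samples), "samples,",
      format(sum(x$layout$chrom_lengths), big.mark = ","), "bp genome\n")
  if (!is.null(x$truth$sample_truth))
    cat(sprintf("  planted PMD genome fraction: %.2f-%.2f (mean %.2f)\n",
                min(x$truth$sample_truth$pmd_genome_fraction),
                max(x$truth$sample_truth$pmd_genome_fraction),
                mean(x$truth$sample_truth$pmd_genome_fraction)))
  invisible(x)
}
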