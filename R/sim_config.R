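#' Configuration for the synthetic WGBS methylome generator
#'
#' The generator plants a two-level domain architecture: a genome-wide set of
#' PMD-permissive domains is laid out once (shared boundaries), and each
#' sample activates each domain independently with a per-domain propensity
#' scaled by a per-sample global activity factor. Activated domains receive
#' sample-specific boundary jitter and an intermediate, dispersed methylation
#' depth; the rest of the genome stays in the polarized hypermethylated
#' background state. CpG islands are hypomethylated unless they sit inside an
#' active PMD (in which case most of them gain intermediate methylation) or
#' belong to the minority of constitutively methylated islands outside PMDs.
#'
#' Methylation "dispersion" parameters are beta concentrations
#' (`shape1 + shape2`): the background default (0.8) yields a polarized,
#' U-shaped per-CpG distribution (window polarization score alpha < 1), the
#' PMD default (8) an intermediate unimodal one (alpha > 1). This contrast in
#' dispersion — not in the mean — is what the PMD caller keys on.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param n_samples number of cohort samples.
#' @param cpg_spacing mean CpG spacing (bp) outside CpG islands.
#' @param cgi_density_mult CpG density multiplier inside CpG islands.
#' @param excluded_bp length (bp) of the centromere-like excluded block
#'   placed at each chromosome midpoint; 0 disables it.
#' @param never_pmd_fraction target fraction of the non-excluded genome left
#'   outside any PMD-permissive domain.
#' @param domain_len_meanlog,domain_len_sdlog lognormal parameters of
#'   permissive-domain lengths (bp).
#' @param domain_len_range truncation bounds for domain lengths (bp).
#' @param propensity_range domain activation propensity bounds; propensities
#'   are drawn low-frequency-heavy within the range. A ceiling of 0 disables
#'   domain placement entirely.
#' @param sample_activity_range per-sample global activity multiplier bounds;
#'   activation probability is `min(0.95, activity * propensity)`.
#' @param boundary_jitter_bp sample-specific boundary jitter scale: each
#'   activated domain edge is shifted by Uniform(0, jitter) bp, outward or
#'   inward with equal probability.
#' @param pmd_mean_range per-sample PMD methylation depth is drawn uniformly
#'   from this range.
#' @param pmd_concentration beta concentration of per-CpG methylation inside
#'   PMDs.
#' @param bg_mean,bg_concentration background (non-PMD) methylation mean and
#'   beta concentration.
#' @param cgi_per_mb,cgi_len_range CpG island density and length bounds (bp).
#' @param cgi_gain_prob probability that a CGI inside a PMD loses its
#'   hypomethylated state and gains intermediate methylation.
#' @param cgi_constitutive_prob probability that a CGI outside all permissive
#'   domains is constitutively methylated.
#' @param cgi_hypo_mean,cgi_gain_mean_range,cgi_constitutive_mean methylation
#'   means of hypomethylated, PMD-gained (drawn per island and sample) and
#'   constitutively methylated islands.
#' @param cgi_concentration beta concentration for CGI CpG methylation.
#' @param wcgw_prob probability that a CpG is in W-C-G-W (A/T-flanked)
#'   context; a WCGW CpG is "solo" iff both neighboring CpGs are more than
#'   `solo_gap_bp` away.
#' @param solo_gap_bp neighbor-distance threshold defining solo CpGs.
#' @param solo_offset additive methylation offset of solo-WCGW CpGs inside
#'   PMDs (negative: they lose more methylation).
#' @param cpg_anchor_concentration across-sample stability of CpGs in
#'   stable (non-PMD) regions: each CpG's methylation level is anchored at
#'   a layout-level baseline drawn from the regional beta, and per-sample
#'   values wobble around it with this beta concentration. CpGs inside
#'   active PMDs (and gained islands) redraw their disordered intermediate
#'   methylation independently per sample.
#' @param coverage_mean,coverage_size negative-binomial read coverage mean
#'   and size (dispersion) per CpG; zero-coverage CpGs are retained.
#' @param genes_per_mb gene density; gene lengths are lognormal
#'   (`gene_len_meanlog`, `gene_len_sdlog`) truncated to `gene_len_range`.
#' @param gene_len_meanlog,gene_len_sdlog,gene_len_range see above.
#' @param n_tsg number of genes labelled as tumor-suppressor genes.
#' @param tsg_outside_prob probability that a TSG label is assigned to a gene
#'   lying outside all permissive domains.
#' @param covariate_prob Bernoulli probability of the binary clinical
#'   covariate (ER-status analog) per sample.
#' @param covariate_domain_frac fraction of permissive domains whose
#'   activation is covariate-responsive.
#' @param covariate_effect activation-propensity multiplier in
#'   covariate-positive samples for covariate-responsive domains.
#' @param n_tissues 1 or 2; with 2, a fraction `tissue_specific_frac` of
#'   domains is private to one tissue and samples alternate tissue labels.
#' @param tissue_specific_frac see `n_tissues`.
#' @param seed master RNG seed; all per-sample seeds derive from it.
#' @return A validated `SimConfig` list.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 2e7, chr2 = 2e7, chr3 = 2e7),
                       n_samples = 15,
                       cpg_spacing = 100,
                       cgi_density_mult = 8,
                       excluded_bp = 5e5,
                       never_pmd_fraction = 0.25,
                       domain_len_meanlog = log(7.5e5),
                       domain_len_sdlog = 0.45,
                       domain_len_range = c(2.5e5, 3e6),
                       propensity_range = c(0.1, 0.95),
                       sample_activity_range = c(0.4, 1.6),
                       boundary_jitter_bp = 5e4,
                       pmd_mean_range = c(0.40, 0.75),
                       pmd_concentration = 8,
                       bg_mean = 0.85,
                       bg_concentration = 0.8,
                       cgi_per_mb = 8,
                       cgi_len_range = c(500, 1500),
                       cgi_gain_prob = 0.92,
                       cgi_constitutive_prob = 0.27,
                       cgi_hypo_mean = 0.05,
                       cgi_gain_mean_range = c(0.40, 0.70),
                       cgi_constitutive_mean = 0.80,
                       cgi_concentration = 12,
                       wcgw_prob = 0.25,
                       solo_gap_bp = 35,
                       solo_offset = -0.08,
                       cpg_anchor_concentration = 60,
                       coverage_mean = 10,
                       coverage_size = 8,
                       genes_per_mb = 8,
                       gene_len_meanlog = log(3e4),
                       gene_len_sdlog = 0.8,
                       gene_len_range = c(5e3, 2e5),
                       n_tsg = 60,
                       tsg_outside_prob = 0.9,
                       covariate_prob = 0.5,
                       covariate_domain_frac = 0.15,
                       covariate_effect = 1.8,
                       n_tissues = 1,
                       tissue_specific_frac = 0.6,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "SimConfig"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$chrom_lengths), length(cfg$chrom_lengths) >= 1,
            !is.null(names(cfg$chrom_lengths)), all(cfg$chrom_lengths > 0))
  stopifnot(cfg$n_samples >= 1, cfg$cpg_spacing > 0, cfg$cgi_density_mult >= 1)
  probs <- c(cfg$never_pmd_fraction, cfg$propensity_range,
             cfg$cgi_gain_prob, cfg$cgi_constitutive_prob, cfg$wcgw_prob,
             cfg$covariate_prob, cfg$covariate_domain_frac,
             cfg$tissue_specific_frac, cfg$tsg_outside_prob)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  means <- c(cfg$pmd_mean_range, cfg$bg_mean, cfg$cgi_hypo_mean,
             cfg$cgi_gain_mean_range, cfg$cgi_constitutive_mean)
  if (any(means <= 0 | means >= 1))
    stop("methylation means must lie strictly inside (0, 1)")
  stopifnot(cfg$pmd_concentration > 0, cfg$bg_concentration > 0,
            cfg$cgi_concentration > 0, cfg$cpg_anchor_concentration > 0,
            cfg$coverage_mean >= 0,
            cfg$coverage_size > 0, cfg$boundary_jitter_bp >= 0,
            cfg$n_tissues %in% c(1L, 2L),
            all(cfg$domain_len_range > 0),
            diff(cfg$domain_len_range) >= 0,
            diff(cfg$pmd_mean_range) >= 0,
            all(cfg$sample_activity_range > 0))
  if (cfg$domain_len_range[1] >= max(cfg$chrom_lengths))
    stop("domain size distribution incompatible with chromosome length: ",
         names(which.max(cfg$chrom_lengths)))
  invisible(cfg)
}

# deterministic per-sample / per-stage seed derivation, kept below 2^31
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483629)
}
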