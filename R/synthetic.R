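# Synthetic WGBS cohort generator with planted PMDs and full ground truth.
#
# Two-level domain architecture: a shared set of PMD-permissive domains with
# per-domain activation propensities is laid out once; each sample activates
# domains independently (propensity x per-sample activity factor), applies
# boundary jitter, and draws per-CpG methylation from region-appropriate beta
# distributions with beta-binomial count noise.

#' Generate the shared genome layout and ground-truth skeleton
#'
#' Lays out chromosomes, a centromere-like excluded block, PMD-permissive
#' domains (with activation propensities), CpG positions (dense inside CGIs),
#' CpG islands with latent state labels, genes with TSG labels, and
#' solo-WCGW context flags. Per-sample content (activated PMDs, methylation)
#' is added by [generate_sample()] / [generate_cohort()].
#'
#' @param config a [sim_config()] object.
#' @return list with elements `layout` (a `GenomeLayout`) and `truth`
#'   (a `PmdGroundTruth` skeleton: permissive domains + propensities,
#'   CpG template with context labels, CGI states, gene labels).
#' @export
generate_layout <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 0L))
  chrlen <- config$chrom_lengths

  ## excluded centromere-like block at each chromosome midpoint
  excl <- NULL
  if (config$excluded_bp > 0) {
    mid <- floor(chrlen / 2)
    excl <- gr_from_bed0(data.frame(
      chrom = names(chrlen),
      start = pmax(0, mid - floor(config$excluded_bp / 2)),
      end = pmin(chrlen, mid + ceiling(config$excluded_bp / 2))), chrlen)
  }

  ## chromosome arms = non-excluded segments; domains are placed per arm
  arms <- if (is.null(excl)) {
    data.table(chrom = names(chrlen), start = 0, end = as.numeric(chrlen))
  } else {
    whole <- gr_from_bed0(data.frame(chrom = names(chrlen), start = 0,
                                     end = chrlen), chrlen)
    bed0_from_gr(GenomicRanges::setdiff(whole, excl, ignore.strand = TRUE))
  }

  if (nrow(arms) == 0)
    stop("no non-excluded sequence left on any chromosome")
  domains <- .place_domains(arms, config)
  n_dom <- nrow(domains)

  ## per-domain attributes
  if (n_dom > 0) {
    domains$propensity <- config$propensity_range[1] +
      diff(config$propensity_range) * rbeta(n_dom, 1, 2)
    domains$cov_linked <- runif(n_dom) < config$covariate_domain_frac
    if (config$n_tissues == 2) {
      u <- runif(n_dom)
      domains$tissue <- ifelse(u < 1 - config$tissue_specific_frac, 0L,
                               ifelse(u < 1 - config$tissue_specific_frac / 2,
                                      1L, 2L))
    } else {
      domains$tissue <- 0L
    }
    domains$domain_id <- sprintf("D%04d", seq_len(n_dom))
  }

  cgis <- .place_cgis(arms, config)
  genes <- .place_genes(arms, config, chrlen)
  cpgs <- .place_cpgs(arms, cgis, config)

  dom_gr <- if (n_dom) gr_from_bed0(domains, chrlen) else .empty_gr(chrlen)
  cgi_gr <- if (nrow(cgis)) gr_from_bed0(cgis, chrlen) else .empty_gr(chrlen)
  gene_gr <- if (nrow(genes)) gr_from_bed0(genes, chrlen) else
    .empty_gr(chrlen)

  ## CGI latent states: every island is gain-prone with probability
  ## cgi_gain_prob — it hypermethylates in any sample whose PMD covers it
  ## (including jitter-extended edges); islands outside all permissive
  ## domains are additionally constitutively methylated with probability
  ## cgi_constitutive_prob, overriding gain-proneness.
  cgi_states <- data.table(cgi_id = character(), state = character())
  if (nrow(cgis)) {
    in_dom <- .frac_in(cgi_gr, dom_gr) >= 0.5
    gain_prone <- runif(nrow(cgis)) < config$cgi_gain_prob
    constitutive <- !in_dom &
      runif(nrow(cgis)) < config$cgi_constitutive_prob
    state <- ifelse(constitutive, "constitutive",
                    ifelse(gain_prone, "gained", "hypo"))
    cgi_states <- data.table(cgi_id = cgis$name, state = state,
                             in_permissive = in_dom)
  }

  ## TSG labels: each TSG is assigned to an outside-domain gene with
  ## probability tsg_outside_prob, otherwise to an inside-domain gene
  gene_truth <- data.table(gene_id = character(), is_tsg = logical(),
                           tsg_placed_outside = logical())
  gene_sets <- list()
  if (nrow(genes)) {
    ## "outside" placement must survive boundary jitter: a gene just past a
    ## domain edge can be swallowed by a jitter-extended PMD, so the outside
    ## pool keeps a jitter-width margin from every permissive domain
    dom_pad <- if (length(dom_gr))
      suppressWarnings(GenomicRanges::trim(
        GenomicRanges::resize(dom_gr,
                              GenomicRanges::width(dom_gr) +
                                2 * config$boundary_jitter_bp,
                              fix = "center")))
    else dom_gr
    frac_in <- .frac_in(gene_gr, dom_gr)
    outside_pool <- which(.frac_in(gene_gr, dom_pad) == 0)
    inside_pool <- which(frac_in >= 0.5)
    n_tsg <- min(config$n_tsg, nrow(genes))
    want_out <- runif(n_tsg) < config$tsg_outside_prob
    n_out <- min(sum(want_out), length(outside_pool))
    n_in <- min(n_tsg - n_out, length(inside_pool))
    tsg_idx <- c(sample(outside_pool, n_out),
                 sample(inside_pool, n_in))
    gene_truth <- data.table(
      gene_id = genes$name,
      is_tsg = seq_len(nrow(genes)) %in% tsg_idx,
      tsg_placed_outside = seq_len(nrow(genes)) %in% tsg_idx[seq_len(n_out)])
    gene_sets <- list(TSG = genes$name[tsg_idx])
  }

  layout <- genome_layout(chrom_lengths = chrlen, excluded = excl,
                          cgis = cgi_gr, genes = gene_gr,
                          gene_sets = gene_sets)

  ## per-CpG stable-state baseline methylation (sample-independent): the
  ## level a CpG shows whenever it is not inside an active PMD
  cpgs$baseline_p <- .stable_baseline(cpgs, cgi_gr, cgi_states, config)

  truth <- structure(list(
    domains = dom_gr,
    domain_table = if (n_dom) domains else NULL,
    cpg_template = cpgs,
    cgi_states = cgi_states,
    gene_truth = gene_truth,
    pmds = vector("list", config$n_samples),
    sample_truth = NULL,
    config = config
  ), class = "PmdGroundTruth")

  list(layout = layout, truth = truth)
}

# choose domain lengths summing to ~(1 - never_pmd_fraction) of each arm and
# distribute the slack as gaps with a minimum margin (keeps jittered domains
# apart and off arm edges)
.place_domains <- function(arms, config) {
  out <- vector("list", nrow(arms))
  if (config$propensity_range[2] <= 0) # degenerate: no permissive domains
    return(data.table(chrom = character(), start = numeric(),
                      end = numeric()))
  margin <- max(1.1e5, 2 * config$boundary_jitter_bp + 1e4)
  for (a in seq_len(nrow(arms))) {
    avail <- arms$end[a] - arms$start[a]
    if (avail < config$domain_len_range[1] + 2 * margin)
      stop("domain size distribution incompatible with chromosome length: ",
           arms$chrom[a])
    target <- (1 - config$never_pmd_fraction) * avail
    lens <- numeric(0)
    while (sum(lens) < target) {
      l <- .clamp(exp(rnorm(1, config$domain_len_meanlog,
                            config$domain_len_sdlog)),
                  config$domain_len_range[1], config$domain_len_range[2])
      lens <- c(lens, round(l))
    }
    # keep or drop the overshooting last domain, whichever lands closer
    if (length(lens) > 1 &&
        abs(sum(lens) - target) > abs(sum(lens[-length(lens)]) - target))
      lens <- lens[-length(lens)]
    # shrink until the margin budget fits
    while (length(lens) &&
           avail - sum(lens) < (length(lens) + 1) * margin)
      lens <- lens[-length(lens)]
    k <- length(lens)
    if (k == 0) { out[[a]] <- NULL; next }
    free <- avail - sum(lens) - (k + 1) * margin
    w <- rexp(k + 1)
    gaps <- margin + free * w / sum(w)
    starts <- arms$start[a] + cumsum(gaps[seq_len(k)]) +
      cumsum(c(0, lens[-k]))
    out[[a]] <- data.table(chrom = arms$chrom[a], start = round(starts),
                           end = round(starts) + lens)
  }
  rbindlist(out)
}

.place_cgis <- function(arms, config) {
  min_sep <- 5000
  out <- vector("list", nrow(arms))
  for (a in seq_len(nrow(arms))) {
    avail <- arms$end[a] - arms$start[a]
    n <- max(0L, round(config$cgi_per_mb * avail / 1e6))
    if (n == 0) next
    lens <- round(runif(n, config$cgi_len_range[1], config$cgi_len_range[2]))
    # oversample candidate starts, then greedily enforce separation
    cand <- sort(round(runif(3 * n, arms$start[a] + min_sep,
                             arms$end[a] - max(lens) - min_sep)))
    keep <- numeric(0); last <- -Inf
    for (s in cand) {
      if (s - last >= max(config$cgi_len_range) + min_sep) {
        keep <- c(keep, s); last <- s
        if (length(keep) == n) break
      }
    }
    out[[a]] <- data.table(chrom = arms$chrom[a], start = keep,
                           end = keep + lens[seq_along(keep)])
  }
  cgis <- rbindlist(out)
  if (nrow(cgis)) {
    setorder(cgis, chrom, start)
    cgis$name <- sprintf("CGI%05d", seq_len(nrow(cgis)))
  }
  cgis
}

.place_genes <- function(arms, config, chrlen) {
  out <- vector("list", nrow(arms))
  for (a in seq_len(nrow(arms))) {
    avail <- arms$end[a] - arms$start[a]
    n <- max(0L, round(config$genes_per_mb * avail / 1e6))
    if (n == 0) next
    lens <- round(.clamp(exp(rnorm(n, config$gene_len_meanlog,
                                   config$gene_len_sdlog)),
                         config$gene_len_range[1], config$gene_len_range[2]))
    starts <- round(runif(n, arms$start[a], arms$end[a] - lens))
    out[[a]] <- data.table(chrom = arms$chrom[a], start = starts,
                           end = starts + lens,
                           strand = sample(c("+", "-"), n, replace = TRUE))
  }
  genes <- rbindlist(out)
  if (nrow(genes)) {
    setorder(genes, chrom, start)
    genes$name <- sprintf("GENE%05d", seq_len(nrow(genes)))
  }
  genes
}

# CpG positions: homogeneous Poisson process at 1/spacing outside CGIs plus
# extra density inside CGIs; solo-WCGW labels from simulated local context
.place_cpgs <- function(arms, cgis, config) {
  out <- vector("list", nrow(arms))
  for (a in seq_len(nrow(arms))) {
    avail <- arms$end[a] - arms$start[a]
    n_base <- rpois(1, avail / config$cpg_spacing)
    pos <- round(runif(n_base, arms$start[a], arms$end[a] - 1))
    ac <- cgis[cgis$chrom == arms$chrom[a] & cgis$start >= arms$start[a] &
                 cgis$end <= arms$end[a], ]
    if (nrow(ac)) {
      extra_rate <- (config$cgi_density_mult - 1) / config$cpg_spacing
      n_extra <- rpois(nrow(ac), (ac$end - ac$start) * extra_rate)
      extra <- unlist(Map(function(s, e, k) round(runif(k, s, e - 1)),
                          ac$start, ac$end, n_extra))
      pos <- c(pos, extra)
    }
    out[[a]] <- data.table(chrom = arms$chrom[a], pos = sort(unique(pos)))
  }
  cpgs <- rbindlist(out)
  setorder(cpgs, chrom, pos)
  gap_prev <- cpgs[, c(Inf, diff(pos)), by = chrom]$V1
  gap_next <- cpgs[, c(diff(pos), Inf), by = chrom]$V1
  is_wcgw <- runif(nrow(cpgs)) < config$wcgw_prob
  cpgs$is_solo_wcgw <- is_wcgw & gap_prev > config$solo_gap_bp &
    gap_next > config$solo_gap_bp
  ## per-CpG baseline quantile: methylation of stable (non-PMD) regions is
  ## a CpG property shared across samples, not redrawn per sample
  cpgs$baseline_q <- runif(nrow(cpgs))
  cpgs
}

# baseline (non-PMD) methylation level per CpG from its region state:
# background beta for open-sea CpGs, hypo / constitutive beta for island
# CpGs; gained islands are hypo at baseline (they only rise inside PMDs)
.stable_baseline <- function(cpgs, cgi_gr, cgi_states, config) {
  mu <- rep(config$bg_mean, nrow(cpgs))
  conc <- rep(config$bg_concentration, nrow(cpgs))
  if (length(cgi_gr)) {
    gr <- GenomicRanges::GRanges(cpgs$chrom,
                                 IRanges::IRanges(cpgs$pos + 1L,
                                                  cpgs$pos + 1L))
    hits <- GenomicRanges::findOverlaps(gr, cgi_gr, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    st <- cgi_states$state[S4Vectors::subjectHits(hits)]
    mu[qh] <- ifelse(st == "constitutive", config$cgi_constitutive_mean,
                     config$cgi_hypo_mean)
    conc[qh] <- ifelse(st == "constitutive", config$bg_concentration,
                       config$cgi_concentration)
  }
  .clamp(stats::qbeta(cpgs$baseline_q, mu * conc, (1 - mu) * conc),
         1e-3, 1 - 1e-3)
}

# fraction of each query interval covered by a subject set
.frac_in <- function(query, subject) {
  if (!length(query)) return(numeric(0))
  if (!length(subject)) return(rep(0, length(query)))
  red <- GenomicRanges::reduce(subject, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(query, red, ignore.strand = TRUE)
  v <- rep(0, length(query))
  if (length(hits)) {
    ov <- GenomicRanges::pintersect(
      query[S4Vectors::queryHits(hits)], red[S4Vectors::subjectHits(hits)],
      ignore.strand = TRUE)
    w <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
    v[as.integer(names(w))] <- as.numeric(w)
  }
  v / GenomicRanges::width(query)
}
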