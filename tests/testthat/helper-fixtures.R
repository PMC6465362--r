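# Shared fixtures and independent oracles. Expensive cohorts are built once
# per test run and cached.

.fx <- new.env(parent = emptyenv())

# the stated-world default cohort (15 samples, 3 x 20 Mb, coverage mean 10)
# plus its PMD calls; shared by the acceptance criteria
accept_cohort <- function() {
  if (is.null(.fx$accept)) {
    cohort <- generate_cohort(sim_config(seed = 42))
    calls <- lapply(cohort$samples, call_pmds, layout = cohort$layout)
    .fx$accept <- list(cohort = cohort, calls = calls)
  }
  .fx$accept
}

# small cohort for cheap integration tests
small_cohort <- function() {
  if (is.null(.fx$small)) {
    cohort <- generate_cohort(sim_config(
      chrom_lengths = c(chr1 = 6e6, chr2 = 6e6), n_samples = 5, seed = 7))
    calls <- lapply(cohort$samples, call_pmds, layout = cohort$layout)
    .fx$small <- list(cohort = cohort, calls = calls)
  }
  .fx$small
}

# hand-built toy layout: one 10 kb chromosome, CGI [1000,2000), gene
toy_layout <- function() {
  genome_layout(
    c(chrA = 10000),
    excluded = NULL,
    cgis = pmdscape:::gr_from_bed0(
      data.frame(chrom = "chrA", start = 1000, end = 2000, name = "cgi1")),
    genes = pmdscape:::gr_from_bed0(
      data.frame(chrom = "chrA", start = 6000, end = 8000, name = "g1",
                 strand = "+")))
}

gr0 <- function(chrom, start, end, chrom_lengths = NULL, ...) {
  pmdscape:::gr_from_bed0(data.frame(chrom = chrom, start = start,
                                     end = end, ...), chrom_lengths)
}

# bp-Jaccard between two GRanges, 1 when both empty
bp_jaccard <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  interval_set_overlap(a, b)$jaccard
}

## ---- independent oracles -------------------------------------------------

# per-bp occupancy oracle over a small chromosome
bp_occupancy <- function(sets, chrom_len) {
  occ <- matrix(0L, chrom_len, length(sets))
  for (j in seq_along(sets)) {
    b <- pmdscape:::bed0_from_gr(GenomicRanges::reduce(sets[[j]]))
    for (i in seq_len(nrow(b)))
      occ[(b$start[i] + 1):b$end[i], j] <- 1L
  }
  occ
}

# grid + golden-section maximization of the reference R log-likelihood,
# independent of the C++ path
oracle_alpha <- function(M, T, lo = -8, hi = 8) {
  f <- function(la) bb_window_loglik(exp(la), M, T)
  grid <- seq(lo, hi, length.out = 200)
  best <- grid[which.max(vapply(grid, f, numeric(1)))]
  opt <- optimize(f, lower = max(lo, best - 0.2), upper = min(hi, best + 0.2),
                  maximum = TRUE, tol = 1e-10)
  exp(opt$maximum)
}

# brute-force HMM posterior by enumeration of all k^n state paths
oracle_posterior <- function(log_emission, transition, init) {
  n <- nrow(log_emission)
  k <- ncol(log_emission)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  logp <- apply(paths, 1, function(s) {
    lp <- log(init[s[1]]) + log_emission[1, s[1]]
    for (t in seq_len(n - 1))
      lp <- lp + log(transition[s[t], s[t + 1]]) +
        log_emission[t + 1, s[t + 1]]
    lp
  })
  w <- exp(logp - max(logp))
  w <- w / sum(w)
  post <- matrix(0, n, k)
  for (t in seq_len(n))
    for (j in seq_len(k))
      post[t, j] <- sum(w[paths[, t] == j])
  post
}

# draw one beta-binomial window with mean m and shape alpha
rbb_window <- function(n, size, alpha, m) {
  beta <- alpha * (1 - m) / m
  p <- rbeta(n, alpha, beta)
  Tt <- if (length(size) == 1) rep(size, n) else size
  data.frame(M = rbinom(n, Tt, p), T = Tt)
}

# methylome built directly from a count table
toy_methylome <- function(df, id = "toy") {
  sample_methylome(id, df)
}
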