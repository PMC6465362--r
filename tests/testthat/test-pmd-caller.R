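# Polarization scoring, presence decision, HMM decoding and the composed
# caller, each against its independent oracle.

test_that("beta-binomial ML matches the grid/golden-section oracle", {
  set.seed(101)
  worst <- 0
  for (rep in 1:50) {
    alpha_true <- exp(runif(1, -1.5, 1.5))
    m <- runif(1, 0.2, 0.9)
    w <- rbb_window(101, size = rpois(101, 12) + 1, alpha_true, m)
    fit <- pmdscape:::bb_alpha_windows(w$M, w$T, 1L, nrow(w))
    orc <- oracle_alpha(w$M, w$T)
    worst <- max(worst, abs(log(fit$alpha) - log(orc)))
  }
  expect_lt(worst, 1e-6)
})

test_that("polarized and intermediate windows land on either side of 1", {
  w <- data.frame(M = rep(10L, 101), T = rep(10L, 101))
  fit <- pmdscape:::bb_alpha_windows(w$M, w$T, 1L, 101L)
  expect_lt(fit$alpha, 1)
  expect_lt(fit$alpha, oracle_alpha(w$M, w$T) * 1.01 + 1e-3)
  set.seed(5)
  w2 <- data.frame(M = rbinom(101, 50, 0.5), T = rep(50L, 101))
  fit2 <- pmdscape:::bb_alpha_windows(w2$M, w2$T, 1L, 101L)
  expect_gt(fit2$alpha, 1)
  expect_lt(abs(log(fit2$alpha) - log(oracle_alpha(w2$M, w2$T))), 1e-6)
})

test_that("mean constraint makes the fitted beta symmetric at mhat = 0.5", {
  # beta = alpha * (1 - mhat) / mhat = alpha when mhat = 0.5
  expect_identical(bb_window_loglik(2, c(1, 3), c(4, 4)),
                   sum(lbeta(c(1, 3) + 2, c(3, 1) + 2) - lbeta(2, 2)))
})

test_that("alpha estimation recovers known shapes within 15%", {
  set.seed(202)
  for (alpha_true in c(0.3, 1, 3)) {
    est <- replicate(200, {
      w <- rbb_window(101, 12, alpha_true, 0.7)
      pmdscape:::bb_alpha_windows(w$M, w$T, 1L, 101L)$alpha
    })
    expect_lt(abs(median(est) - alpha_true) / alpha_true, 0.15)
  }
})

test_that("windows skip zero-coverage stretches and excluded regions", {
  set.seed(7)
  n <- 600
  pos <- sort(sample.int(2e5, n)) - 1L
  m <- sample_methylome("w", data.table::data.table(
    chrom = "chrA", pos = pos, M = rbinom(n, 10, 0.8), T = 10L))
  layout <- genome_layout(c(chrA = 2e5),
                          excluded = gr0("chrA", 9e4, 1.1e5, c(chrA = 2e5)))
  tr <- window_alpha(m, layout, pmd_call_config())
  expect_gt(nrow(tr), 0)
  expect_true(all(tr$anchor < 9e4 | tr$anchor >= 1.1e5))
  expect_gt(length(unique(tr$run)), 1)
  expect_true(all(tr$alpha > 0))
})

test_that("presence decision: planted vs null vs shuffled order", {
  co <- small_cohort()$cohort
  tr <- window_alpha(co$samples[[1]], co$layout)
  pres <- pmds_present(tr)
  expect_true(pres$present)
  # order-free statistic
  set.seed(9)
  pres2 <- pmds_present(tr[sample.int(nrow(tr)), ])
  expect_identical(pres$present, pres2$present)
  expect_equal(pres$mixture$means, pres2$mixture$means, tolerance = 1e-6)
  # no planted contrast -> absent
  cfgz <- sim_config(chrom_lengths = c(chr1 = 4e6), n_samples = 1,
                     pmd_mean_range = c(0.85, 0.85),
                     pmd_concentration = 0.8, solo_offset = 0, seed = 23)
  coz <- generate_cohort(cfgz)
  trz <- window_alpha(coz$samples[[1]], coz$layout)
  expect_false(pmds_present(trz)$present)
  expect_error(pmds_present(tr[1:100, ]), "at least 200")
})

test_that("HMM posterior equals brute-force enumeration (12 windows)", {
  set.seed(31)
  for (rep in 1:5) {
    le <- matrix(rnorm(24, sd = 2), 12, 2)
    stay <- runif(1, 0.6, 0.99)
    trans <- matrix(c(stay, 1 - stay, 1 - stay, stay), 2, 2)
    init <- c(0.7, 0.3)
    post <- hmm_posterior(le, trans, init)
    expect_true(all(abs(rowSums(post) - 1) < 1e-9))
    expect_lt(max(abs(post - oracle_posterior(le, trans, init))), 1e-9)
  }
})

test_that("segmentation recovers a single planted megabase-scale PMD", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 1e7), n_samples = 1,
                    never_pmd_fraction = 0.8,
                    domain_len_meanlog = log(2e6), domain_len_sdlog = 0.01,
                    domain_len_range = c(2e6, 2e6),
                    propensity_range = c(0.95, 0.95),
                    sample_activity_range = c(1.5, 1.5),
                    boundary_jitter_bp = 0, excluded_bp = 0, seed = 41)
  co <- generate_cohort(cfg)
  expect_identical(length(co$pmds[[1]]), 1L)
  calls <- call_pmds(co$samples[[1]], co$layout)
  main <- calls[which.max(GenomicRanges::width(calls))]
  tol <- 2 * 10 * cfg$cpg_spacing # 2 x window step x mean spacing
  expect_lt(abs(GenomicRanges::start(main) -
                  GenomicRanges::start(co$pmds[[1]])), tol + 1)
  expect_lt(abs(GenomicRanges::end(main) -
                  GenomicRanges::end(co$pmds[[1]])), tol + 1)
  # spurious short segments (the reason the min-length filter exists) must
  # stay below 0.5% of the chromosome
  expect_lt(sum(GenomicRanges::width(calls)) - GenomicRanges::width(main),
            0.005 * 1e7)
})

test_that("calls are disjoint, in-bounds, clipped from excluded regions", {
  sc <- small_cohort()
  for (calls in sc$calls) {
    if (!length(calls)) next
    expect_identical(length(GenomicRanges::reduce(calls)), length(calls))
    expect_identical(sum(GenomicRanges::width(GenomicRanges::intersect(
      calls, sc$cohort$layout$excluded, ignore.strand = TRUE))), 0L)
    expect_true(all(GenomicRanges::width(calls) >= 1e4))
  }
})

test_that("fully methylated uniform sample yields an empty call set", {
  set.seed(51)
  n <- 5e3
  pos <- sort(sample.int(6e5, n)) - 1L
  m <- sample_methylome("flat", data.table::data.table(
    chrom = "chrA", pos = pos, M = 10L, T = 10L))
  layout <- genome_layout(c(chrA = 6e5))
  expect_length(call_pmds(m, layout), 0)
})

test_that("solo-WCGW-only calls overlap all-CpG calls", {
  co <- small_cohort()$cohort
  i <- which.max(co$truth$sample_truth$pmd_genome_fraction)
  all_calls <- small_cohort()$calls[[i]]
  solo_calls <- call_pmds(co$samples[[i]], co$layout,
                          pmd_call_config(mode = "solo_wcgw",
                                          min_cpgs = 51))
  ov <- interval_set_overlap(solo_calls, all_calls)
  expect_gte(ov$jaccard, 0.85)
})

test_that("higher contrast never hurts boundary recovery", {
  jac <- vapply(c(0.70, 0.55, 0.40), function(depth) {
    cfg <- sim_config(chrom_lengths = c(chr1 = 8e6), n_samples = 1,
                      pmd_mean_range = c(depth, depth), seed = 61)
    co <- generate_cohort(cfg)
    bp_jaccard(call_pmds(co$samples[[1]], co$layout), co$pmds[[1]])
  }, numeric(1))
  expect_true(all(diff(jac) >= -0.02)) # non-decreasing up to MC wiggle
})

test_that("aggregate s.d. caller contains the per-sample calls", {
  sc <- small_cohort()
  agg <- aggregate_pmds_sd(sc$cohort$samples, sc$cohort$layout)
  expect_gt(length(agg), 0)
  for (calls in sc$calls) {
    if (!length(calls)) next
    expect_gte(interval_set_overlap(calls, agg)$frac_a_in_b, 0.95)
  }
  # identical samples -> zero s.d. everywhere -> empty track
  same <- rep(sc$cohort$samples[1], 3)
  expect_length(aggregate_pmds_sd(same, sc$cohort$layout), 0)
  # the s.d. is of fractions, not counts: doubling coverage exactly
  # (M, T -> 2M, 2T) leaves the bin s.d. estimates identical
  doubled <- lapply(sc$cohort$samples, function(s) {
    r <- data.table::copy(s$records)
    r$M <- 2L * r$M; r$T <- 2L * r$T
    sample_methylome(s$sample_id, r)
  })
  agg2 <- aggregate_pmds_sd(doubled, sc$cohort$layout)
  bs1 <- attr(agg, "bin_sd"); bs2 <- attr(agg2, "bin_sd")
  expect_equal(bs1$sd, bs2$sd)
})
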