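# Synthetic-methylome generator: determinism, conservation, planted
# structure and parameter recovery.

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 2e6), n_samples = 2, seed = 3)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$truth$sample_truth, b$truth$sample_truth)
  expect_identical(a$samples[[1]]$records, b$samples[[1]]$records)
  expect_identical(pmdscape:::bed0_from_gr(a$pmds[[2]]),
                   pmdscape:::bed0_from_gr(b$pmds[[2]]))
})

test_that("counts are conserved and CpGs sorted/unique", {
  co <- small_cohort()$cohort
  for (s in co$samples) {
    r <- s$records
    expect_true(all(r$M >= 0 & r$M <= r$T))
    expect_false(is.unsorted(r[chrom == "chr1", pos]))
    expect_identical(anyDuplicated(r, by = c("chrom", "pos")), 0L)
  }
})

test_that("propensity ceiling 0 yields no permissive domains or PMDs", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 2e6), n_samples = 2,
                    propensity_range = c(0, 0), seed = 5)
  co <- generate_cohort(cfg)
  expect_length(co$truth$domains, 0)
  expect_true(all(vapply(co$pmds, length, 1L) == 0))
})

test_that("planted PMDs respect chromosome bounds and excluded regions", {
  co <- small_cohort()$cohort
  excl <- co$layout$excluded
  for (p in co$pmds) {
    if (!length(p)) next
    expect_true(all(GenomicRanges::start(p) >= 1))
    expect_true(all(GenomicRanges::end(p) <=
                      co$layout$chrom_lengths[
                        as.character(GenomeInfoDb::seqnames(p))]))
    expect_identical(
      sum(GenomicRanges::width(GenomicRanges::intersect(
        p, excl, ignore.strand = TRUE))), 0L)
    # non-overlapping within the sample
    expect_identical(length(GenomicRanges::reduce(p)), length(p))
  }
})

test_that("never-PMD fraction of the layout matches the configured target", {
  # bp of the non-excluded genome in no PMD-permissive domain (direct
  # interval arithmetic on the ground truth), vs the 25% target
  cfg <- sim_config(n_samples = 30, seed = 11)
  gl <- generate_layout(cfg)
  ne <- non_excluded_regions(gl$layout)
  cov_bp <- sum(GenomicRanges::width(GenomicRanges::intersect(
    gl$truth$domains, ne, ignore.strand = TRUE)))
  never <- 1 - cov_bp / sum(GenomicRanges::width(ne))
  expect_lt(abs(never - cfg$never_pmd_fraction), 0.03)
})

test_that("pooled methylation of planted PMD CpGs recovers the depth", {
  co <- small_cohort()$cohort
  st <- co$truth$sample_truth
  for (i in seq_along(co$samples)) {
    r <- co$samples[[i]]$records
    if (!length(co$pmds[[i]])) next
    gr <- GenomicRanges::GRanges(r$chrom,
                                 IRanges::IRanges(r$pos + 1, r$pos + 1))
    inp <- GenomicRanges::countOverlaps(gr, co$pmds[[i]]) > 0
    keep <- inp & !r$in_cgi & !r$in_shore & !r$in_promoter &
      !r$is_solo_wcgw & r$T > 0
    expect_gt(sum(keep), 5000)
    pooled <- sum(r$M[keep]) / sum(r$T[keep])
    # binomial + beta noise: 3 Monte-Carlo s.e. on the pooled estimate
    mc_se <- sd(r$M[keep] / r$T[keep]) / sqrt(sum(keep))
    expect_lt(abs(pooled - st$pmd_mean[i]), 3 * mc_se + 0.005)
  }
})

test_that("solo-WCGW CpGs inside PMDs sit below their neighbors", {
  co <- small_cohort()$cohort
  i <- which.max(co$truth$sample_truth$pmd_genome_fraction)
  r <- co$samples[[i]]$records
  gr <- GenomicRanges::GRanges(r$chrom,
                               IRanges::IRanges(r$pos + 1, r$pos + 1))
  inp <- GenomicRanges::countOverlaps(gr, co$pmds[[i]]) > 0
  base <- r[inp & !in_cgi & !in_shore & !in_promoter & T > 0]
  m_solo <- base[is_solo_wcgw == TRUE, sum(M) / sum(T)]
  m_rest <- base[is_solo_wcgw == FALSE, sum(M) / sum(T)]
  expect_lt(m_solo, m_rest - 0.04)
})

test_that("non-constitutive CGIs outside the sample's PMDs pool below 0.10", {
  co <- small_cohort()$cohort
  st <- co$truth$cgi_states
  cand <- co$layout$cgis[st$state != "constitutive"]
  outside <- cand[pmdscape:::.frac_in(cand, co$pmds[[1]]) == 0]
  r <- co$samples[[1]]$records
  gr <- GenomicRanges::GRanges(r$chrom,
                               IRanges::IRanges(r$pos + 1, r$pos + 1))
  inh <- GenomicRanges::countOverlaps(gr, outside) > 0 & r$T > 0
  expect_gt(sum(inh), 50)
  expect_lt(sum(r$M[inh]) / sum(r$T[inh]), 0.10)
})

test_that("per-sample planted fractions are wide (10-50% analog)", {
  fr <- accept_cohort()$cohort$truth$sample_truth$pmd_genome_fraction
  expect_gt(sd(fr) / mean(fr), 0.3)
  expect_gt(max(fr) - min(fr), 0.15)
})

test_that("per-tile planted frequency spectrum is mode-0 and low-heavy", {
  co <- accept_cohort()$cohort
  ft <- frequency_track(co$pmds, co$layout, 3e4)
  h <- tabulate(ft$frequency + 1L, nbins = length(co$pmds) + 1L)
  expect_identical(which.max(h) - 1L, 0L)
  expect_lte(median(ft$frequency), length(co$pmds) / 3)
})

test_that("two-tissue mode records labels and disjoint domain sets", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 4e6), n_samples = 4,
                    n_tissues = 2, seed = 13)
  co <- generate_cohort(cfg)
  expect_setequal(unique(co$sample_sheet$tissue), c(1L, 2L))
  expect_true(all(co$truth$domain_table$tissue %in% 0:2))
})

test_that("zero-contrast config still emits valid records", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 2e6), n_samples = 1,
                    pmd_mean_range = c(0.85, 0.85),
                    pmd_concentration = 0.8, solo_offset = 0, seed = 17)
  co <- generate_cohort(cfg)
  r <- co$samples[[1]]$records
  expect_true(all(r$M <= r$T))
  expect_gt(nrow(r), 1000)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(cgi_gain_prob = 1.2), "probabilities")
  expect_error(sim_config(bg_mean = 1), "strictly inside")
  expect_error(sim_config(chrom_lengths = c(chr1 = -5)), "chrom_lengths")
  expect_error(generate_layout(sim_config(
    chrom_lengths = c(tiny = 3e5), excluded_bp = 0)), "incompatible")
})
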