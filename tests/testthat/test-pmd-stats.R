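# Interval algebra, frequency tracks, shuffle nulls and profiles against
# per-bp and analytic oracles.

test_that("genome fractions match arithmetic and the per-bp oracle", {
  layout <- genome_layout(c(chrA = 1000))
  pmds <- gr0("chrA", c(0, 200), c(100, 400), c(chrA = 1000))
  expect_equal(genome_fraction(pmds, layout), 0.30)
  expect_equal(genome_fraction(pmds[0], layout), 0)
  expect_equal(genome_fraction(gr0("chrA", 0, 1000, c(chrA = 1000)),
                               layout), 1)
  set.seed(71)
  for (rep in 1:20) {
    n <- sample.int(8, 1)
    s <- sort(sample.int(990, n))
    gr <- GenomicRanges::reduce(gr0("chrA", s - 1,
                                    pmin(1000, s - 1 +
                                           sample.int(60, n, replace = TRUE)),
                                    c(chrA = 1000)))
    occ <- bp_occupancy(list(gr), 1000)
    expect_equal(genome_fraction(gr, layout), mean(occ))
  }
})

test_that("frequency track definitions: coverage vs border", {
  layout <- genome_layout(c(chrA = 1e5))
  # one PMD spanning tiles 3-5 (tiles of 10 kb), shared by both samples
  pmd <- gr0("chrA", 21000, 48000, c(chrA = 1e5))
  ftc <- frequency_track(list(pmd, pmd), layout, 1e4, mode = "coverage")
  expect_identical(ftc$frequency, c(0L, 0L, 2L, 2L, 2L, rep(0L, 5)))
  ftb <- frequency_track(list(pmd, pmd), layout, 1e4, mode = "border")
  expect_identical(ftb$frequency, c(0L, 0L, 2L, 0L, 2L, rep(0L, 5)))
})

test_that("union/intersection fractions agree with interval arithmetic", {
  sc <- small_cohort()
  layout <- sc$cohort$layout
  ft <- frequency_track(sc$calls, layout, 3e4)
  curve <- frequency_fraction_curve(ft)
  expect_true(all(diff(curve$genome_fraction) <= 1e-12))
  ne_bp <- sum(GenomicRanges::width(non_excluded_regions(layout)))
  union_gr <- GenomicRanges::reduce(do.call(c, unname(sc$calls)))
  union_frac <- sum(GenomicRanges::width(GenomicRanges::intersect(
    union_gr, non_excluded_regions(layout)))) / ne_bp
  # tile-level union >= bp union; equal within one tile per interval edge
  expect_equal(curve$genome_fraction[1], union_frac, tolerance = 0.05)
  # frequency conservation: tile bp sums to the non-excluded genome
  expect_identical(sum(ft$end - ft$start), ne_bp)
  expect_error(frequency_fraction_curve(
    frequency_track(sc$calls, layout, 3e4, mode = "border")),
    "coverage-mode")
})

test_that("per-bp frequency oracle on a toy cohort", {
  layout <- genome_layout(c(chrA = 1200))
  set.seed(73)
  sets <- lapply(1:4, function(i) {
    s <- sort(sample.int(1100, 3))
    GenomicRanges::reduce(gr0("chrA", s - 1, pmin(1200, s + 150),
                              c(chrA = 1200)))
  })
  ft <- frequency_track(sets, layout, 100)
  occ <- bp_occupancy(sets, 1200)
  for (t in seq_len(nrow(ft))) {
    bp <- (ft$start[t] + 1):ft$end[t]
    expect_identical(ft$frequency[t],
                     sum(apply(occ[bp, , drop = FALSE], 2, max)))
  }
})

test_that("shuffles preserve length multisets and genome fraction", {
  sc <- small_cohort()
  layout <- sc$cohort$layout
  p <- sc$calls[[1]]
  sh <- shuffle_pmds(p, layout, seed = 99)
  for (ch in unique(as.character(GenomeInfoDb::seqnames(p)))) {
    expect_identical(
      sort(GenomicRanges::width(sh[GenomeInfoDb::seqnames(sh) == ch])),
      sort(GenomicRanges::width(p[GenomeInfoDb::seqnames(p) == ch])))
  }
  expect_equal(genome_fraction(sh, layout), genome_fraction(p, layout))
  expect_identical(sum(GenomicRanges::width(GenomicRanges::intersect(
    sh, layout$excluded))), 0L)
  # infeasible shuffle errors
  layout2 <- genome_layout(c(chrA = 1000))
  expect_error(shuffle_pmds(gr0("chrA", 0, 999, c(chrA = 1000)),
                            genome_layout(c(chrA = 999)), seed = 1))
})

test_that("single-interval shuffle start is uniform (KS over 2000 seeds)", {
  layout <- genome_layout(c(chrA = 1e5), shore_bp = 0)
  p <- gr0("chrA", 0, 10000, c(chrA = 1e5))
  starts <- vapply(1:2000, function(s)
    GenomicRanges::start(shuffle_pmds(p, layout, seed = s)) - 1L,
    numeric(1))
  ks <- suppressWarnings(stats::ks.test(starts, "punif", 0, 9e4))
  expect_gt(ks$p.value, 0.01)
})

test_that("interval overlap metrics are exact", {
  a <- gr0("chr1", 0, 100)
  b <- gr0("chr1", 50, 150)
  ov <- interval_set_overlap(a, b)
  expect_equal(ov$jaccard, 1 / 3)
  expect_equal(ov$frac_a_in_b, 0.5)
  expect_equal(interval_set_overlap(a, a)$jaccard, 1)
  set.seed(79)
  for (rep in 1:10) {
    sx <- sample.int(900, 5) - 1
    sy <- sample.int(900, 5) - 1
    x <- GenomicRanges::reduce(gr0("c", sx, sx + sample.int(100, 5),
                                   c(c = 1000)))
    y <- GenomicRanges::reduce(gr0("c", sy, sy + sample.int(50, 5),
                                   c(c = 1000)))
    occ <- bp_occupancy(list(x, y), 1000)
    inter <- sum(occ[, 1] & occ[, 2]); uni <- sum(occ[, 1] | occ[, 2])
    expect_equal(interval_set_overlap(x, y)$jaccard, inter / uni)
  }
})

test_that("boundary profiles: constant, step and mirror symmetry", {
  bins <- data.frame(chrom = "chrA",
                     start = seq(0, 99000, 1000),
                     end = seq(1000, 100000, 1000))
  pmds <- gr0("chrA", c(20000, 60000), c(40000, 80000), c(chrA = 1e5))
  flat <- transform(bins, score = 2.5)
  prof <- boundary_profile(flat, pmds, flank_bp = 10000, n_bins = 20)
  expect_true(all(abs(prof$mean_signal - 2.5) < 1e-12))
  # step signal = 1 inside PMDs: profile rises 0 -> 1 across the boundary
  occ <- bp_occupancy(list(pmds), 1e5)
  step <- transform(bins, score = vapply(seq_len(nrow(bins)), function(i)
    mean(occ[(bins$start[i] + 1):bins$end[i], 1]), numeric(1)))
  prof2 <- boundary_profile(step, pmds, flank_bp = 10000, n_bins = 20)
  expect_lt(mean(prof2$mean_signal[1:8]), 0.05)
  expect_gt(mean(prof2$mean_signal[13:20]), 0.95)
  expect_identical(attr(boundary_profile(flat, gr0("chrA", 0, 5000,
                                                   c(chrA = 1e5)),
                                         flank_bp = 10000),
                        "n_excluded"), 1L)
})

test_that("feature density by frequency: conservation and flatness", {
  layout <- genome_layout(c(chrA = 3e5))
  sets <- list(gr0("chrA", 0, 1e5, c(chrA = 3e5)),
               gr0("chrA", 5e4, 2e5, c(chrA = 3e5)))
  ft <- frequency_track(sets, layout, 1e4)
  set.seed(83)
  pts <- data.frame(chrom = "chrA", pos = sample.int(3e5, 3000) - 1L)
  db <- density_by_frequency(pts, ft)
  expect_identical(sum(db$n_features), 3000)
  # uniform points: densities flat within 3 Poisson s.e.
  lambda <- 3000 / 0.3 # per Mb
  for (i in seq_len(nrow(db))) {
    if (is.na(db$density_per_mb[i])) next
    se <- sqrt(lambda / db$mb[i])
    expect_lt(abs(db$density_per_mb[i] - lambda), 3 * se)
  }
  # empty frequency class reported missing
  expect_true(is.na(db$density_per_mb[db$mb == 0][1]) ||
                all(db$mb > 0))
})
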