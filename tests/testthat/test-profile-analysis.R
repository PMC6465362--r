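# Tiling maps, clustering and PCA.

test_that("tile means pool counts and honor the exclusion rule", {
  layout <- toy_layout()
  # chrA annotation: CGI [1000,2000), shores to 4000, promoter [5000,7001)
  m <- annotate_cpgs(sample_methylome("t", data.table::data.table(
    chrom = "chrA",
    pos = c(4100L, 4200L, 1100L, 8100L, 8200L),
    M = c(9L, 0L, 5L, 2L, 2L),
    T = c(10L, 10L, 5L, 4L, 4L))), layout)
  tm <- tile_matrix(list(m), layout, tile_bp = 1000, min_cpgs = 2)
  expect_equal(unname(tm$meth[5, 1]), 9 / 20)  # (9+0)/(10+10)
  expect_true(is.na(tm$meth[2, 1]))            # all-CGI tile -> missing
  expect_equal(unname(tm$meth[9, 1]), 4 / 8)
  # brute force over a random methylome
  set.seed(113)
  pos <- sort(sample.int(9999, 500)) - 1L
  T <- rpois(500, 10)
  m2 <- annotate_cpgs(sample_methylome("bf", data.table::data.table(
    chrom = "chrA", pos = pos, M = rbinom(500, T, 0.6), T = T)), layout)
  tm2 <- tile_matrix(list(m2), layout, tile_bp = 1000, min_cpgs = 1)
  r <- m2$records[T >= 1 & !in_cgi & !in_shore & !in_promoter]
  for (t in seq_len(10)) {
    sel <- r$pos >= (t - 1) * 1000 & r$pos < t * 1000
    want <- if (any(sel)) sum(r$M[sel]) / sum(r$T[sel]) else NA_real_
    expect_equal(unname(tm2$meth[t, 1]), want)
  }
})

test_that("profile clustering: identical samples merge at height zero", {
  m <- matrix(c(1, 2, 3, 4,
                1, 2, 3, 4,
                4, 3, 2, 1) / 5, ncol = 3)
  colnames(m) <- c("a", "b", "c")
  cl <- cluster_profiles(m)
  expect_equal(min(cl$hclust$height), 0, tolerance = 1e-12)
  expect_identical(sort(cl$leaf_order), 1:3)
  # 1 - Pearson distance against direct computation
  expect_equal(as.matrix(cl$dist)["a", "c"], 1 - cor(m[, 1], m[, 3]))
  bad <- cbind(m, d = rep(0.5, 4))
  expect_error(cluster_profiles(bad), "zero-variance")
})

test_that("PCA: reconstruction, single-dimension case, associations", {
  set.seed(127)
  ns <- 8
  meths <- lapply(seq_len(ns), function(i) {
    n <- 120
    sample_methylome(sprintf("S%02d", i), data.table::data.table(
      chrom = "chrA", pos = 100L * (1:n),
      M = rbinom(n, 20, stats::plogis(rnorm(1) + rnorm(n))), T = 20L))
  })
  cov <- data.frame(grp = rep(c("x", "y"), length.out = ns),
                    num = rnorm(ns))
  pc <- pca_top_variable(meths, covariates = cov, min_coverage = 10,
                         top_fraction = 0.5, scale_unit = FALSE)
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  expect_lte(sum(pc$var_explained), 1 + 1e-12)
  expect_identical(nrow(pc$associations), 2L * ncol(pc$scores))
  expect_true(all(pc$associations$p_value >= 0 &
                    pc$associations$p_value <= 1, na.rm = TRUE))
  expect_error(pca_top_variable(meths, min_coverage = 1000), "coverage")
})

test_that("PCA reconstruction error < 1e-8 with all components", {
  set.seed(131)
  ns <- 6
  n <- 60
  base <- matrix(runif(n * ns), n, ns)
  meths <- lapply(seq_len(ns), function(i)
    sample_methylome(sprintf("S%02d", i), data.table::data.table(
      chrom = "chrA", pos = 50L * (1:n),
      M = as.integer(round(base[, i] * 100)), T = 100L)))
  pc <- pca_top_variable(meths, min_coverage = 10, top_fraction = 1,
                         scale_unit = FALSE)
  recon <- pc$scores %*% t(pc$loadings)
  pos_of <- as.integer(sub("chrA ", "", rownames(pc$loadings))) / 50L
  raw <- t(vapply(meths, function(s)
    (s$records$M / s$records$T)[pos_of], numeric(length(pos_of))))
  centered <- sweep(raw, 2, pc$center)
  expect_lt(max(abs(recon - centered)), 1e-8)
  # variance explained equals covariance eigenvalues (brute-force oracle)
  ev <- eigen(stats::cov(centered))$values
  expect_equal(pc$var_explained[seq_len(ncol(pc$scores))],
               (ev / sum(ev))[seq_len(ncol(pc$scores))], tolerance = 1e-8)
})

test_that("one variable dimension puts all variance on PC1", {
  meths <- lapply(1:4, function(i)
    sample_methylome(paste0("s", i), data.table::data.table(
      chrom = "chrA", pos = 100L * (1:12),
      M = c(5L * i, rep(10L, 11)), T = 20L)))
  pc <- pca_top_variable(meths, min_coverage = 10, top_fraction = 1,
                         scale_unit = FALSE)
  expect_equal(pc$var_explained[1], 1, tolerance = 1e-12)
})

test_that("binary PMD clustering distances are Jaccard complements", {
  layout <- genome_layout(c(chrA = 1e5))
  a <- gr0("chrA", 0, 5e4, c(chrA = 1e5))
  b <- gr0("chrA", 5e4, 1e5, c(chrA = 1e5))
  cl <- pmd_binary_cluster(list(s1 = a, s2 = a, s3 = b), layout,
                           tile_bp = 5e3)
  dm <- as.matrix(cl$dist)
  expect_equal(dm["s1", "s2"], 0)
  expect_equal(dm["s1", "s3"], 1)
  expect_identical(cl$linkage, "complete")
  expect_warning(pmd_binary_cluster(list(s1 = a, s2 = b, s3 = a[0]),
                                    layout), "zero PMD tiles")
})

test_that("1 - Jaccard satisfies the triangle inequality", {
  set.seed(137)
  layout <- genome_layout(c(chrA = 2e5))
  for (rep in 1:10) {
    sets <- lapply(1:3, function(i) {
      s <- sort(sample.int(19, 4)) * 1e4
      GenomicRanges::reduce(gr0("chrA", s - 1e4, s, c(chrA = 2e5)))
    })
    names(sets) <- c("a", "b", "c")
    dm <- as.matrix(pmd_binary_cluster(sets, layout, 5e3)$dist)
    expect_lte(dm["a", "c"], dm["a", "b"] + dm["b", "c"] + 1e-12)
    expect_equal(dm, t(dm))
  }
})
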