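# Methylome tiling maps, hierarchical clustering, PCA of top-variable CpGs
# and binary PMD-distribution clustering.

#' Tile x sample weighted-methylation matrix
#'
#' Weighted methylation per tile and sample over eligible CpGs only
#' (CGI/shore/promoter CpGs excluded — their CpG density would otherwise
#' dominate tile means); tiles with fewer than `min_cpgs` eligible CpGs in
#' a sample are missing.
#'
#' @param methylomes list of annotated `SampleMethylome`s.
#' @param layout `GenomeLayout`.
#' @param tile_bp tile size (default 10 kb).
#' @param min_cpgs minimum eligible CpGs per tile and sample.
#' @param min_coverage per-CpG coverage floor.
#' @return A `TileMatrix`: list with `meth` (tile x sample matrix, NA
#'   missing) and `tiles` (`GRanges`).
#' @export
tile_matrix <- function(methylomes, layout, tile_bp = 1e4, min_cpgs = 5,
                        min_coverage = 1) {
  tiles <- tile_genome(layout, tile_bp)
  m <- matrix(NA_real_, length(tiles), length(methylomes),
              dimnames = list(NULL, vapply(methylomes, `[[`, "",
                                           "sample_id")))
  for (j in seq_along(methylomes)) {
    tm <- .tile_wmeth(methylomes[[j]], tiles, min_coverage)
    tm <- tm[tm$n_cpgs >= min_cpgs, ]
    m[tm$tile_id, j] <- tm$wmeth
  }
  structure(list(meth = m, tiles = tiles), class = "TileMatrix")
}

#' Hierarchical clustering of tiled methylation profiles
#'
#' Distance = 1 - Pearson correlation between sample profiles
#' (pairwise-complete over missing tiles), Ward.D linkage on the unsquared
#' distances (the classic "ward.D" semantics).
#'
#' @param tile_mat a [tile_matrix()] result, or a numeric matrix
#'   (rows = features, columns = samples).
#' @param linkage `hclust` method (default `"ward.D"`).
#' @return A `ClusterResult`: list with `hclust` (the tree), `dist`
#'   (distance matrix), `distance` and `linkage` names, `leaf_order`.
#' @export
cluster_profiles <- function(tile_mat, linkage = "ward.D") {
  m <- if (is.list(tile_mat) && !is.null(tile_mat$meth)) tile_mat$meth
  else as.matrix(tile_mat)
  stopifnot(ncol(m) >= 3)
  zerovar <- vapply(seq_len(ncol(m)), function(j)
    sd(m[, j], na.rm = TRUE) < 1e-12, logical(1))
  if (any(zerovar))
    stop("zero-variance sample(s): ",
         paste(colnames(m)[zerovar], collapse = ", "))
  cc <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  if (anyNA(cc)) stop("undefined pairwise correlations (no shared tiles)")
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc, dist = d, distance = "1-pearson",
                 linkage = linkage, leaf_order = hc$order),
            class = "ClusterResult")
}

#' PCA of the top-variable CpGs with covariate association
#'
#' Builds the CpG x sample methylation-fraction matrix over CpGs covered at
#' `min_coverage` or better (in every sample by default, or in at least 90%
#' of samples), keeps the top `top_fraction` most variable CpGs, and runs
#' PCA on the centered (optionally unit-scaled) sample matrix. Covariates
#' are associated with each component by a correlation t-test (numeric) or
#' one-way ANOVA F-test (categorical).
#'
#' @param methylomes list of `SampleMethylome`s.
#' @param covariates data.frame of per-sample covariates (rows parallel to
#'   `methylomes`), optional.
#' @param min_coverage per-CpG coverage threshold (default 10).
#' @param coverage_scope `"all"` (every sample) or `"frac90"`.
#' @param top_fraction fraction of most-variable CpGs kept (default 0.05).
#' @param scale_unit unit-scale CpGs before PCA.
#' @param n_components number of components to keep (default all).
#' @return A `PcaResult`: list with `scores` (sample x component),
#'   `loadings`, `var_explained`, `n_cpgs`, `associations` (data.table:
#'   component, covariate, statistic, p_value).
#' @export
pca_top_variable <- function(methylomes, covariates = NULL,
                             min_coverage = 10,
                             coverage_scope = c("all", "frac90"),
                             top_fraction = 0.05, scale_unit = TRUE,
                             n_components = NULL) {
  coverage_scope <- match.arg(coverage_scope)
  ns <- length(methylomes)
  stopifnot(ns >= 3)
  key <- function(r) paste(r$chrom, r$pos)
  common <- Reduce(intersect, lapply(methylomes, function(s)
    key(s$records)))
  frac <- matrix(NA_real_, length(common), ns)
  covok <- matrix(FALSE, length(common), ns)
  for (j in seq_len(ns)) {
    r <- methylomes[[j]]$records
    i <- match(common, key(r))
    frac[, j] <- ifelse(r$T[i] > 0, r$M[i] / r$T[i], NA)
    covok[, j] <- r$T[i] >= min_coverage
  }
  keep <- if (coverage_scope == "all") rowSums(covok) == ns
  else rowMeans(covok) >= 0.9
  keep <- keep & !is.na(rowSums(frac))
  if (sum(keep) < 10)
    stop("fewer than 10 CpGs pass the coverage filter")
  frac <- frac[keep, , drop = FALSE]
  rownames(frac) <- common[keep]
  vs <- apply(frac, 1, var)
  ntop <- max(10, ceiling(top_fraction * nrow(frac)))
  top <- order(vs, decreasing = TRUE)[seq_len(min(ntop, nrow(frac)))]
  x <- t(frac[top, , drop = FALSE]) # samples x CpGs
  sds <- apply(x, 2, sd)
  if (scale_unit) x <- x[, sds > 1e-12, drop = FALSE]
  pc <- prcomp(x, center = TRUE, scale. = scale_unit)
  if (!is.null(n_components))
    pc$x <- pc$x[, seq_len(min(n_components, ncol(pc$x))), drop = FALSE]
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  rownames(pc$x) <- vapply(methylomes, `[[`, "", "sample_id")
  assoc <- data.table(component = integer(), covariate = character(),
                      statistic = numeric(), p_value = numeric())
  if (!is.null(covariates)) {
    cov_dt <- as.data.frame(covariates)
    for (comp in seq_len(ncol(pc$x))) {
      for (cv in names(cov_dt)) {
        v <- cov_dt[[cv]]
        res <- if (is.numeric(v)) {
          ct <- cor.test(pc$x[, comp], v)
          c(unname(ct$estimate), ct$p.value)
        } else {
          v <- factor(v)
          if (nlevels(v) < 2) c(NA_real_, NA_real_) else {
            an <- anova(aov(pc$x[, comp] ~ v))
            c(an$`F value`[1], an$`Pr(>F)`[1])
          }
        }
        assoc <- rbind(assoc, data.table(component = comp, covariate = cv,
                                         statistic = res[1],
                                         p_value = res[2]))
      }
    }
  }
  structure(list(scores = pc$x, loadings = pc$rotation,
                 center = pc$center, scale = pc$scale,
                 var_explained = ve[seq_len(ncol(pc$x))],
                 n_cpgs = length(top), associations = assoc),
            class = "PcaResult")
}

#' Binary PMD-occupancy clustering
#'
#' Scores PMD presence 0/1 in genomic tiles (default 5 kb), computes
#' pairwise 1 - Jaccard distances between the binary sample vectors, and
#' clusters with complete linkage.
#'
#' @param cohort_pmds named list of per-sample PMD `GRanges`.
#' @param layout `GenomeLayout`.
#' @param tile_bp tile size (default 5 kb).
#' @return A `ClusterResult` (as in [cluster_profiles()]) plus `binary`
#'   (tile x sample 0/1 matrix).
#' @export
pmd_binary_cluster <- function(cohort_pmds, layout, tile_bp = 5e3) {
  stopifnot(length(cohort_pmds) >= 3)
  tiles <- tile_genome(layout, tile_bp)
  ns <- length(cohort_pmds)
  ids <- names(cohort_pmds)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(ns))
  bin <- matrix(0L, length(tiles), ns, dimnames = list(NULL, ids))
  for (j in seq_len(ns))
    bin[, j] <- as.integer(GenomicRanges::countOverlaps(
      tiles, cohort_pmds[[j]], ignore.strand = TRUE) > 0)
  empty <- colSums(bin) == 0
  if (any(empty))
    warning("sample(s) with zero PMD tiles (distance 1 to all): ",
            paste(ids[empty], collapse = ", "))
  d <- matrix(0, ns, ns, dimnames = list(ids, ids))
  for (a in seq_len(ns - 1)) {
    for (b in (a + 1):ns) {
      inter <- sum(bin[, a] & bin[, b])
      uni <- sum(bin[, a] | bin[, b])
      d[a, b] <- d[b, a] <- if (uni == 0) 1 else 1 - inter / uni
    }
  }
  dd <- stats::as.dist(d)
  hc <- stats::hclust(dd, method = "complete")
  structure(list(hclust = hc, dist = dd, distance = "1-jaccard",
                 linkage = "complete", leaf_order = hc$order,
                 binary = bin),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat("Hierarchical clustering:", x$distance, "distance,", x$linkage,
      "linkage,", length(x$leaf_order), "samples\n")
  invisible(x)
}
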