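# CpG-island methylation, element stratification, the B-CIMP statistic and
# its beta regression on PMD-CGI content.

#' Methylation distribution per genomic element class and PMD status
#'
#' Classifies eligible CpGs (coverage >= `min_coverage`) as CGI / shore /
#' promoter / other and in/out PMD per sample, and summarizes the per-CpG
#' methylation fraction distribution of each class.
#'
#' @param methylomes list of annotated `SampleMethylome`s.
#' @param layout `GenomeLayout`.
#' @param pmds_per_sample list of PMD `GRanges`, parallel to `methylomes`.
#' @param min_coverage per-CpG coverage floor.
#' @return data.table with one row per (element, pmd_status): `n_cpgs`,
#'   quartiles and mean of methylation fractions. Empty classes are absent.
#' @export
element_methylation_distribution <- function(methylomes, layout,
                                             pmds_per_sample,
                                             min_coverage = 5) {
  stopifnot(length(methylomes) == length(pmds_per_sample))
  parts <- vector("list", length(methylomes))
  for (j in seq_along(methylomes)) {
    r <- methylomes[[j]]$records
    if (anyNA(r$in_cgi))
      stop("CpG annotation flags missing; run annotate_cpgs() first")
    r <- r[r$T >= min_coverage, ]
    if (!nrow(r)) next
    gr <- GenomicRanges::GRanges(r$chrom,
                                 IRanges::IRanges(r$pos + 1L, r$pos + 1L))
    in_pmd <- GenomicRanges::countOverlaps(
      gr, pmds_per_sample[[j]], ignore.strand = TRUE) > 0
    element <- ifelse(r$in_cgi, "cgi",
                      ifelse(r$in_shore, "shore",
                             ifelse(r$in_promoter, "promoter", "other")))
    parts[[j]] <- data.table(element = element,
                             pmd_status = ifelse(in_pmd, "in", "out"),
                             meth = r$M / r$T)
  }
  dt <- rbindlist(parts)
  out <- dt[, list(n_cpgs = .N,
                   q25 = quantile(meth, 0.25, names = FALSE),
                   median = median(meth),
                   q75 = quantile(meth, 0.75, names = FALSE),
                   mean = mean(meth)),
            by = c("element", "pmd_status")]
  setorder(out, element, pmd_status)
  out[]
}

#' CGI x sample weighted-methylation matrix with in-PMD flags
#'
#' Weighted methylation (`sum M / sum T`) per island over all island CpGs
#' (no element exclusion here — the exclusion rule applies to PMD/tile
#' means, not to island means); islands with fewer than `min_cpgs` covered
#' CpGs in a sample are missing. The per-sample in-PMD flag uses 50%-length
#' overlap (default) or the island midpoint.
#'
#' @param methylomes list of `SampleMethylome`s.
#' @param layout `GenomeLayout` (CGI set must be non-empty).
#' @param pmds_per_sample list of PMD `GRanges`, parallel to `methylomes`.
#' @param overlap_rule `"half"` or `"midpoint"`.
#' @param min_cpgs minimum covered CpGs per island and sample.
#' @return A `CgiMatrix`: list with `meth` (CGI x sample matrix, NA =
#'   missing), `in_pmd` (logical matrix), `cgi` (the island `GRanges`).
#' @export
cgi_matrix <- function(methylomes, layout, pmds_per_sample,
                       overlap_rule = c("half", "midpoint"), min_cpgs = 3) {
  overlap_rule <- match.arg(overlap_rule)
  stopifnot(length(layout$cgis) > 0,
            length(methylomes) == length(pmds_per_sample))
  cgi <- layout$cgis
  ids <- if (!is.null(cgi$name)) cgi$name else
    sprintf("CGI%05d", seq_along(cgi))
  ns <- length(methylomes)
  meth <- matrix(NA_real_, length(cgi), ns,
                 dimnames = list(ids, vapply(methylomes, `[[`, "",
                                             "sample_id")))
  in_pmd <- matrix(FALSE, length(cgi), ns, dimnames = dimnames(meth))
  for (j in seq_len(ns)) {
    r <- methylomes[[j]]$records
    r <- r[r$T >= 1, ]
    gr <- GenomicRanges::GRanges(r$chrom,
                                 IRanges::IRanges(r$pos + 1L, r$pos + 1L))
    hits <- GenomicRanges::findOverlaps(gr, cgi, ignore.strand = TRUE)
    dt <- data.table(ci = S4Vectors::subjectHits(hits),
                     M = r$M[S4Vectors::queryHits(hits)],
                     T = r$T[S4Vectors::queryHits(hits)])
    agg <- dt[, list(wmeth = sum(M) / sum(T), n = .N), by = "ci"]
    agg <- agg[agg$n >= min_cpgs, ]
    meth[agg$ci, j] <- agg$wmeth
    p <- pmds_per_sample[[j]]
    if (length(p)) {
      if (overlap_rule == "half") {
        in_pmd[, j] <- .frac_in(cgi, p) >= 0.5
      } else {
        mid <- floor((GenomicRanges::start(cgi) - 1 +
                        GenomicRanges::end(cgi)) / 2)
        mgr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(cgi),
                                      IRanges::IRanges(mid + 1L, mid + 1L))
        in_pmd[, j] <- GenomicRanges::countOverlaps(
          mgr, p, ignore.strand = TRUE) > 0
      }
    }
  }
  structure(list(meth = meth, in_pmd = in_pmd, cgi = cgi),
            class = "CgiMatrix")
}

#' Fraction of values above the hypermethylation threshold
#'
#' Strict inequality, per the ">30% methylated" definition; missing values
#' are dropped.
#'
#' @param values numeric in `[0, 1]`.
#' @param threshold hypermethylation cutoff (default 0.30).
#' @return fraction of non-missing values strictly above the threshold.
#' @export
hypermethylated_fraction <- function(values, threshold = 0.30) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("all values missing")
  stopifnot(all(v >= 0 & v <= 1))
  mean(v > threshold)
}

#' Per-sample B-CIMP and PMD-CGI content
#'
#' For each sample: `b_cimp` = fraction of non-missing islands with
#' weighted methylation above the threshold, and `frac_cgi_in_pmd` =
#' fraction of non-missing islands flagged in-PMD.
#'
#' @param cgi_mat a [cgi_matrix()] result.
#' @param threshold hypermethylation cutoff.
#' @return data.table (`sample_id`, `b_cimp`, `frac_cgi_in_pmd`,
#'   `n_cgis`).
#' @export
cimp_inputs <- function(cgi_mat, threshold = 0.30) {
  ns <- ncol(cgi_mat$meth)
  out <- data.table(
    sample_id = colnames(cgi_mat$meth),
    b_cimp = vapply(seq_len(ns), function(j)
      hypermethylated_fraction(cgi_mat$meth[, j], threshold), numeric(1)),
    frac_cgi_in_pmd = vapply(seq_len(ns), function(j) {
      okk <- !is.na(cgi_mat$meth[, j])
      if (!any(okk)) return(NA_real_)
      mean(cgi_mat$in_pmd[okk, j])
    }, numeric(1)),
    n_cgis = colSums(!is.na(cgi_mat$meth)))
  out[]
}

#' Cross-sample CGI methylation variability by PMD frequency
#'
#' Cross-sample standard deviation per island, grouped by that island's PMD
#' frequency (number of samples in which it is in-PMD). Frequency classes
#' with fewer than `min_cgis` islands are reported missing.
#'
#' @param cgi_mat a [cgi_matrix()] result.
#' @param min_cgis minimum islands per frequency class.
#' @return data.table (`frequency`, `n_cgis`, `median_sd`, `mean_sd`).
#' @export
cgi_variation_by_frequency <- function(cgi_mat, min_cgis = 3) {
  freq <- rowSums(cgi_mat$in_pmd)
  sds <- apply(cgi_mat$meth, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else sd(v)
  })
  dt <- data.table(frequency = freq, sd = sds)[!is.na(sd)]
  out <- dt[, list(n_cgis = .N,
                   median_sd = median(sd), mean_sd = mean(sd)),
            by = "frequency"]
  out[out$n_cgis < min_cgis,
      c("median_sd", "mean_sd") := list(NA_real_, NA_real_)]
  setorder(out, frequency)
  out[]
}
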