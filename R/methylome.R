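#' Construct a per-sample methylome of CpG counts
#'
#' The atomic measurement: one row per CpG (plus-strand position after
#' strand-collapsing) with methylated (`M`) and total (`T`) read counts and
#' context flags. Records are kept sorted by (chrom, pos) and unique.
#'
#' @param sample_id sample identifier.
#' @param records data.frame/data.table with columns `chrom`, `pos` (0-based),
#'   `M`, `T`, and optionally `strand`, `is_solo_wcgw`, `in_cgi`, `in_shore`,
#'   `in_promoter`.
#' @param meta named list of per-sample metadata (covariates).
#' @return A `SampleMethylome`.
#' @export
sample_methylome <- function(sample_id, records, meta = list()) {
  rec <- as.data.table(records)
  need <- c("chrom", "pos", "M", "T")
  if (!all(need %in% names(rec)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (!"strand" %in% names(rec)) rec$strand <- rep("+", nrow(rec))
  for (fl in c("is_solo_wcgw", "in_cgi", "in_shore", "in_promoter"))
    if (!fl %in% names(rec)) rec[[fl]] <- rep(NA, nrow(rec))
  rec <- rec[, c("chrom", "pos", "strand", "M", "T",
                 "is_solo_wcgw", "in_cgi", "in_shore", "in_promoter"),
             with = FALSE]
  if (nrow(rec)) {
    if (any(rec$M < 0) || any(rec$M > rec$T))
      stop("invalid counts: need 0 <= M <= T")
    if (is.unsorted(order(rec$chrom, rec$pos)) ||
        !identical(order(rec$chrom, rec$pos), seq_len(nrow(rec))))
      setorder(rec, chrom, pos)
    if (anyDuplicated(rec, by = c("chrom", "pos")))
      stop("duplicate (chrom, pos) records in sample ", sample_id)
  }
  structure(list(sample_id = sample_id, records = rec, meta = meta),
            class = "SampleMethylome")
}

#' @export
print.SampleMethylome <- function(x, ...) {
  r <- x$records
  cat("SampleMethylome", x$sample_id, ":", nrow(r), "CpGs on",
      length(unique(r$chrom)), "chromosomes\n")
  if (nrow(r)) {
    cov <- r$T > 0
    cat(sprintf("  mean coverage %.1f; pooled methylation %.3f; %.1f%% covered\n",
                mean(r$T), sum(r$M) / max(1, sum(r$T)), 100 * mean(cov)))
  }
  invisible(x)
}
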