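# Gene-level PMD frequency and gene-set exclusion testing.

#' PMD frequency per gene
#'
#' Frequency = number of cohort samples in which the gene "is a PMD" under
#' the overlap rule: at least half the gene body inside a PMD (default), or
#' the TSS contained in one.
#'
#' @param genes `GRanges` with a `name` column, typically `layout$genes`.
#' @param cohort_pmds list of per-sample PMD `GRanges`.
#' @param overlap_rule `"half"` or `"tss"`.
#' @param gene_sets named list of gene-id vectors; each gene additionally
#'   gets a logical membership column per set.
#' @return A `GeneFrequencyTable`: data.table (`gene_id`, `chrom`, `start`,
#'   `end`, `frequency`, one column per gene set).
#' @export
gene_pmd_frequency <- function(genes, cohort_pmds,
                               overlap_rule = c("half", "tss"),
                               gene_sets = list()) {
  overlap_rule <- match.arg(overlap_rule)
  stopifnot(length(genes) > 0, !is.null(genes$name))
  freq <- integer(length(genes))
  for (p in cohort_pmds) {
    if (!length(p)) next
    if (overlap_rule == "half") {
      freq <- freq + (.frac_in(genes, p) >= 0.5)
    } else {
      tss <- GenomicRanges::resize(genes, width = 1, fix = "start")
      freq <- freq + (GenomicRanges::countOverlaps(
        tss, p, ignore.strand = TRUE) > 0)
    }
  }
  out <- data.table(gene_id = genes$name,
                    chrom = as.character(GenomeInfoDb::seqnames(genes)),
                    start = GenomicRanges::start(genes) - 1L,
                    end = GenomicRanges::end(genes),
                    frequency = freq)
  for (s in names(gene_sets)) out[[s]] <- out$gene_id %in% gene_sets[[s]]
  setattr(out, "n_samples", length(cohort_pmds))
  setattr(out, "class", c("GeneFrequencyTable", class(out)))
  out[]
}

#' Hypergeometric exclusion test for a gene set
#'
#' Tests whether a gene set is over-represented among genes outside PMDs
#' (frequency 0). With universe size `N`, set size `K`, `n` genes outside
#' and `k` set genes outside, the upper-tail probability `P(X >= k)` under
#' `Hypergeometric(N, K, n)` is computed with exact log-factorial
#' arithmetic (`lchoose`).
#'
#' @param table a [gene_pmd_frequency()] result.
#' @param set_name name of a logical gene-set column in `table`.
#' @return list: `p_value`, `N`, `K`, `n_outside`, `k_set_outside`,
#'   `expected` (under the null), `fold`.
#' @export
exclusion_test <- function(table, set_name) {
  if (!set_name %in% names(table)) stop("no such gene set: ", set_name)
  set <- table[[set_name]]
  N <- nrow(table)
  K <- sum(set)
  if (K == 0) stop("empty gene set: ", set_name)
  outside <- table$frequency == 0
  n <- sum(outside)
  k <- sum(set & outside)
  list(p_value = hypergeom_upper_tail(N, K, n, k),
       N = N, K = K, n_outside = n, k_set_outside = k,
       expected = K * n / N,
       fold = if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_)
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' `X` = number of marked items among `n` draws without replacement from a
#' universe of `N` items of which `K` are marked. Summed in log space from
#' exact `lchoose` terms.
#'
#' @param N,K,n,k integers as above.
#' @return `P(X >= k)` in `[0, 1]`.
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  stopifnot(N >= 0, K >= 0, K <= N, n >= 0, n <= N)
  lo <- max(0, n - (N - K))
  hi <- min(K, n)
  if (k <= lo) return(1)
  if (k > hi) return(0)
  i <- k:hi
  terms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(terms)
  min(1, exp(m + log(sum(exp(terms - m)))))
}

#' Per-set PMD-frequency histograms
#'
#' Relative (summing to 1 within each set) and absolute gene-count
#' histograms over frequencies `0..n_samples`, for every gene-set column
#' plus the complement of their union (`"other"`).
#'
#' @param table a [gene_pmd_frequency()] result.
#' @param set_names gene-set columns to summarize; default: all logical
#'   columns.
#' @return data.table (`set`, `frequency`, `count`, `relative`).
#' @export
frequency_distribution_by_set <- function(table, set_names = NULL) {
  if (is.null(set_names))
    set_names <- names(table)[vapply(table, is.logical, logical(1))]
  n <- attr(table, "n_samples")
  if (is.null(n)) n <- max(table$frequency)
  member_any <- if (length(set_names))
    Reduce(`|`, lapply(set_names, function(s) table[[s]]))
  else rep(FALSE, nrow(table))
  groups <- c(setNames(lapply(set_names, function(s) table[[s]]), set_names),
              list(other = !member_any))
  out <- rbindlist(lapply(names(groups), function(g) {
    f <- table$frequency[groups[[g]]]
    cnt <- vapply(0:n, function(fr) sum(f == fr), numeric(1))
    data.table(set = g, frequency = 0:n, count = cnt,
               relative = if (sum(cnt) > 0) cnt / sum(cnt) else NA_real_)
  }))
  out[]
}
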