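# Genomic tiling and per-tile weighted methylation, shared by the aggregate
# PMD caller, frequency tracks and methylome maps.

#' Tile the non-excluded genome
#'
#' Each non-excluded segment is tiled independently from its start; a
#' segment length that is not a multiple of the tile size leaves a truncated
#' last tile. Together the tiles partition the non-excluded genome exactly.
#'
#' @param layout a `GenomeLayout`.
#' @param tile_bp tile size in bp.
#' @return `GRanges` of tiles with a `tile_id` column.
#' @export
tile_genome <- function(layout, tile_bp) {
  stopifnot(tile_bp >= 1)
  segs <- bed0_from_gr(non_excluded_regions(layout))
  out <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    starts <- seq(segs$start[i], segs$end[i] - 1, by = tile_bp)
    out[[i]] <- data.table(chrom = segs$chrom[i], start = starts,
                           end = pmin(starts + tile_bp, segs$end[i]))
  }
  tiles <- rbindlist(out)
  setorder(tiles, chrom, start)
  gr <- gr_from_bed0(tiles, layout$chrom_lengths)
  gr$tile_id <- seq_along(gr)
  gr
}

# weighted methylation (sum M / sum T) per tile for one sample;
# exclude_elements drops CGI/shore/promoter CpGs (the tile-mean convention:
# their high CpG density would otherwise dominate the mean)
.tile_wmeth <- function(methylome, tiles, min_coverage = 1,
                        exclude_elements = TRUE) {
  r <- methylome$records
  keep <- r$T >= max(1L, min_coverage)
  if (exclude_elements) {
    if (anyNA(r$in_cgi))
      stop("CpG annotation flags missing; run annotate_cpgs() first")
    keep <- keep & !r$in_cgi & !r$in_shore & !r$in_promoter
  }
  r <- r[keep, ]
  if (!nrow(r))
    return(data.table(tile_id = integer(), wmeth = numeric(),
                      n_cpgs = integer()))
  gr <- GenomicRanges::GRanges(r$chrom,
                               IRanges::IRanges(r$pos + 1L, r$pos + 1L))
  hits <- GenomicRanges::findOverlaps(gr, tiles, ignore.strand = TRUE)
  dt <- data.table(tile_id = tiles$tile_id[S4Vectors::subjectHits(hits)],
                   M = r$M[S4Vectors::queryHits(hits)],
                   T = r$T[S4Vectors::queryHits(hits)])
  dt[, list(wmeth = sum(M) / sum(T), n_cpgs = .N), by = "tile_id"]
}

#' Aggregate cross-sample PMD track from methylation variability
#'
#' Implements aggregate PMD calling from the cross-sample standard deviation
#' of weighted methylation in genomic bins: per bin and sample the weighted
#' methylation is computed over eligible CpGs (CGI/shore/promoter excluded),
#' bins under-covered in any sample are masked, the cross-sample s.d. is
#' classified with a two-component Gaussian mixture, and adjacent
#' high-s.d. bins are merged into the aggregate track.
#'
#' @param methylomes list of annotated `SampleMethylome`s (>= 3).
#' @param layout a `GenomeLayout`.
#' @param bin_bp bin size (default 100 kb).
#' @param min_coverage per-CpG coverage floor.
#' @param min_cpgs mask a bin if any sample has fewer eligible CpGs.
#' @return `GRanges` aggregate track; attribute `"bin_sd"` holds the
#'   per-bin s.d. table.
#' @export
aggregate_pmds_sd <- function(methylomes, layout, bin_bp = 1e5,
                              min_coverage = 1, min_cpgs = 10) {
  stopifnot(length(methylomes) >= 3)
  tiles <- tile_genome(layout, bin_bp)
  n <- length(methylomes)
  wide <- matrix(NA_real_, length(tiles), n)
  counts <- matrix(0L, length(tiles), n)
  for (j in seq_len(n)) {
    tm <- .tile_wmeth(methylomes[[j]], tiles, min_coverage)
    wide[tm$tile_id, j] <- tm$wmeth
    counts[tm$tile_id, j] <- tm$n_cpgs
  }
  ok <- rowSums(counts >= min_cpgs) == n
  sds <- apply(wide, 1, sd)
  bin_sd <- data.table(tile_id = tiles$tile_id, sd = sds, masked = !ok)
  usable <- which(ok & is.finite(sds))
  empty <- .empty_gr(layout$chrom_lengths)
  attr(empty, "bin_sd") <- bin_sd
  if (length(usable) < 10 || sd(sds[usable]) < 1e-9) return(empty)
  g2 <- fit_gmm1d(sds[usable], 2)
  g1 <- fit_gmm1d(sds[usable], 1)
  if (g2$bic >= g1$bic || diff(g2$means) < 2 * sqrt(sum(g2$weights *
                                                          g2$sds^2)))
    return(empty)
  p_hi <- g2$weights[2] * dnorm(sds[usable], g2$means[2],
                                pmax(g2$sds[2], 1e-6))
  p_lo <- g2$weights[1] * dnorm(sds[usable], g2$means[1],
                                pmax(g2$sds[1], 1e-6))
  is_pmd <- p_hi / (p_hi + p_lo) > 0.5
  sel <- tiles[usable][is_pmd]
  out <- GenomicRanges::reduce(sel, ignore.strand = TRUE)
  attr(out, "bin_sd") <- bin_sd
  out
}
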