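# Cohort-level PMD statistics: genome fractions, per-tile frequency tracks,
# shuffle permutation nulls, overlap metrics, boundary metaprofiles and
# feature-density summaries.

#' Fraction of the non-excluded genome covered by an interval set
#'
#' @param pmds `GRanges`.
#' @param layout `GenomeLayout`.
#' @return fraction in `[0, 1]`.
#' @export
genome_fraction <- function(pmds, layout) {
  ne <- non_excluded_regions(layout)
  cov <- GenomicRanges::intersect(GenomicRanges::reduce(pmds,
                                                        ignore.strand = TRUE),
                                  ne, ignore.strand = TRUE)
  sum(GenomicRanges::width(cov)) / sum(GenomicRanges::width(ne))
}

#' Per-tile PMD frequency across a cohort
#'
#' Tiles the non-excluded genome and counts, per tile, the number of samples
#' whose PMD set touches the tile (`mode = "coverage"`: any-overlap by
#' default, or at least half the tile with `overlap_rule = "half"`) or has a
#' PMD endpoint inside it (`mode = "border"`).
#'
#' @param cohort_pmds list of per-sample PMD `GRanges`.
#' @param layout `GenomeLayout`.
#' @param tile_bp tile size (default 30 kb).
#' @param mode `"coverage"` or `"border"`.
#' @param overlap_rule `"any"` (>= 1 bp) or `"half"` (>= 50% of the tile).
#' @return A `FrequencyTrack`: data.table (`chrom`, `start`, `end`,
#'   `tile_id`, `frequency`) with attributes `tile_bp`, `mode`, `n_samples`.
#' @export
frequency_track <- function(cohort_pmds, layout, tile_bp = 3e4,
                            mode = c("coverage", "border"),
                            overlap_rule = c("any", "half")) {
  mode <- match.arg(mode)
  overlap_rule <- match.arg(overlap_rule)
  stopifnot(length(cohort_pmds) >= 1)
  tiles <- tile_genome(layout, tile_bp)
  freq <- integer(length(tiles))
  for (p in cohort_pmds) {
    p <- GenomicRanges::reduce(p, ignore.strand = TRUE)
    if (!length(p)) next
    if (mode == "coverage") {
      if (overlap_rule == "any") {
        hit <- GenomicRanges::countOverlaps(tiles, p,
                                            ignore.strand = TRUE) > 0
      } else {
        hit <- .frac_in(tiles, p) >= 0.5
      }
    } else {
      b <- bed0_from_gr(p)
      pts <- gr_from_bed0(data.table(
        chrom = rep(b$chrom, 2),
        start = c(b$start, b$end - 1L),
        end = c(b$start + 1L, b$end)), layout$chrom_lengths)
      hit <- GenomicRanges::countOverlaps(tiles, pts,
                                          ignore.strand = TRUE) > 0
    }
    freq <- freq + hit
  }
  out <- bed0_from_gr(tiles)
  out$tile_id <- tiles$tile_id
  out$frequency <- freq
  setattr(out, "tile_bp", tile_bp)
  setattr(out, "mode", mode)
  setattr(out, "n_samples", length(cohort_pmds))
  setattr(out, "class", c("FrequencyTrack", class(out)))
  out[]
}

#' Cumulative genome fraction by PMD frequency
#'
#' For a coverage-mode frequency track, the fraction of the non-excluded
#' genome at PMD frequency `>= f`; non-increasing in `f`, with `f = 1`
#' equal to the cohort union fraction.
#'
#' @param track a coverage-mode `FrequencyTrack`.
#' @return data.table (`frequency`, `genome_fraction`).
#' @export
frequency_fraction_curve <- function(track) {
  if (!identical(attr(track, "mode"), "coverage"))
    stop("frequency_fraction_curve requires a coverage-mode track")
  n <- attr(track, "n_samples")
  bp <- track$end - track$start
  total <- sum(bp)
  data.table(frequency = seq_len(n),
             genome_fraction = vapply(seq_len(n), function(f)
               sum(bp[track$frequency >= f]) / total, numeric(1)))
}

#' Shuffle an interval set within a layout
#'
#' Re-places the intervals of each chromosome uniformly at random without
#' overlap, avoiding excluded regions; interval lengths and counts are
#' preserved exactly per chromosome. Sequential placement in random order
#' with rejection sampling; on repeated failure the chromosome restarts.
#'
#' @param pmds `GRanges` to shuffle.
#' @param layout `GenomeLayout`.
#' @param seed RNG seed.
#' @param max_attempts per-interval placement attempts before a restart.
#' @param max_restarts chromosome restarts before giving up.
#' @return shuffled `GRanges`.
#' @export
shuffle_pmds <- function(pmds, layout, seed, max_attempts = 200,
                         max_restarts = 50) {
  set.seed(seed)
  if (!length(pmds)) return(pmds)
  b <- bed0_from_gr(GenomicRanges::reduce(pmds, ignore.strand = TRUE))
  ne <- bed0_from_gr(non_excluded_regions(layout))
  out <- vector("list", length(unique(b$chrom)))
  ci <- 0
  for (ch in unique(b$chrom)) {
    ci <- ci + 1
    lens <- b[b$chrom == ch, end - start]
    segs <- ne[ne$chrom == ch, ]
    if (sum(lens) >= sum(segs$end - segs$start))
      stop("cannot shuffle ", ch, ": PMD length ", sum(lens),
           " bp >= available ", sum(segs$end - segs$start), " bp")
    placed <- .shuffle_chrom(lens, segs, max_attempts, max_restarts, ch)
    out[[ci]] <- data.table(chrom = ch, start = placed$start,
                            end = placed$end)
  }
  res <- rbindlist(out)
  setorder(res, chrom, start)
  gr_from_bed0(res, layout$chrom_lengths)
}

.shuffle_chrom <- function(lens, segs, max_attempts, max_restarts, chrom) {
  seg_len <- segs$end - segs$start
  for (restart in seq_len(max_restarts)) {
    order_i <- sample.int(length(lens))
    ps <- pe <- numeric(0)
    failed <- FALSE
    for (l in lens[order_i]) {
      done <- FALSE
      for (att in seq_len(max_attempts)) {
        # draw a start uniformly over all positions where the interval fits
        # inside a single non-excluded segment (L - l + 1 starts per segment)
        room <- pmax(0, seg_len - l + 1)
        if (sum(room) == 0) { failed <- TRUE; break }
        u <- runif(1) * sum(room)
        si <- which(cumsum(room) > u)[1]
        s <- segs$start[si] + min(floor(u - c(0, cumsum(room))[si]),
                                  room[si] - 1)
        e <- s + l
        if (!length(ps) || all(e <= ps | s >= pe)) {
          ps <- c(ps, s); pe <- c(pe, e)
          done <- TRUE
          break
        }
      }
      if (!done) { failed <- TRUE; break }
    }
    if (!failed)
      return(data.table(start = sort(ps), end = sort(pe)))
  }
  stop("shuffle placement failed on ", chrom, " after ", max_restarts,
       " restarts (occupancy ", round(sum(lens) / sum(seg_len), 3), ")")
}

#' Observed-vs-null PMD frequency distributions
#'
#' Computes the observed per-tile frequency histogram and its permutation
#' null from repeated cohort shuffles, in border or coverage counting mode.
#'
#' @param cohort_pmds list of per-sample PMD `GRanges`.
#' @param layout `GenomeLayout`.
#' @param tile_bp tile size.
#' @param n_shuffles number of cohort shuffles (>= 2).
#' @param seed RNG seed.
#' @param mode counting mode, as in [frequency_track()].
#' @return A `ShuffleNull`: list with `observed` (FrequencyTrack),
#'   `observed_hist`, `null_hist` (mean counts per frequency), `null_mean`,
#'   `null_sd` (per-tile frequency moments across shuffles),
#'   `observed_mode`, `null_mode`, `frac_zero`, `n_shuffles`, `seed`.
#' @export
border_null_distribution <- function(cohort_pmds, layout, tile_bp = 3e4,
                                     n_shuffles = 50, seed = 1,
                                     mode = c("border", "coverage")) {
  mode <- match.arg(mode)
  if (n_shuffles < 2) stop("need at least 2 shuffles")
  obs <- frequency_track(cohort_pmds, layout, tile_bp, mode = mode)
  n <- attr(obs, "n_samples")
  breaks <- seq(-0.5, n + 0.5, by = 1)
  hcount <- function(f) tabulate(f + 1L, nbins = n + 1L)
  obs_h <- hcount(obs$frequency)
  null_h <- matrix(0, n_shuffles, n + 1L)
  fsum <- fsq <- numeric(nrow(obs))
  for (s in seq_len(n_shuffles)) {
    shuf <- lapply(seq_along(cohort_pmds), function(i)
      shuffle_pmds(cohort_pmds[[i]], layout,
                   seed = derive_seed(seed, s * 1000L + i)))
    ft <- frequency_track(shuf, layout, tile_bp, mode = mode)
    null_h[s, ] <- hcount(ft$frequency)
    fsum <- fsum + ft$frequency
    fsq <- fsq + ft$frequency^2
  }
  null_mean <- fsum / n_shuffles
  null_sd <- sqrt(pmax(0, fsq / n_shuffles - null_mean^2) *
                    n_shuffles / max(1, n_shuffles - 1))
  list(observed = obs,
       observed_hist = setNames(obs_h, 0:n),
       null_hist = setNames(colMeans(null_h), 0:n),
       null_mean = null_mean, null_sd = null_sd,
       observed_mode = which.max(obs_h) - 1L,
       null_mode = which.max(colMeans(null_h)) - 1L,
       frac_zero = obs_h[1] / sum(obs_h),
       n_shuffles = n_shuffles, seed = seed)
}

#' Base-pair overlap metrics between two interval sets
#'
#' @param a,b `GRanges`.
#' @return list: `jaccard` (intersection/union in bp), `frac_a_in_b`,
#'   `frac_b_in_a`.
#' @export
interval_set_overlap <- function(a, b) {
  a <- GenomicRanges::reduce(a, ignore.strand = TRUE)
  b <- GenomicRanges::reduce(b, ignore.strand = TRUE)
  wa <- sum(GenomicRanges::width(a))
  wb <- sum(GenomicRanges::width(b))
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(
    a, b, ignore.strand = TRUE)))
  uni <- wa + wb - inter
  list(jaccard = if (uni > 0) inter / uni else 1,
       frac_a_in_b = if (wa > 0) inter / wa else NA_real_,
       frac_b_in_a = if (wb > 0) inter / wb else NA_real_)
}

#' Average signal profile over PMD boundaries
#'
#' Aligns PMD start and end boundaries (ends mirrored so that left-to-right
#' always reads outside-to-inside) and averages a binned signal track in
#' relative bins across the flank.
#'
#' @param signal data.frame (`chrom`, `start`, `end`, `score`) of
#'   constant-width bins covering the layout (0-based half-open).
#' @param pmds `GRanges`.
#' @param flank_bp half-width of the profile around each boundary.
#' @param n_bins number of profile bins across `2 * flank_bp`.
#' @return data.table (`rel_pos` bin center relative to the boundary,
#'   `mean_signal`, `n`); attribute `n_excluded` counts PMDs shorter than
#'   the flank.
#' @export
boundary_profile <- function(signal, pmds, flank_bp = 1e5, n_bins = 40) {
  sig <- as.data.table(signal)
  stopifnot(all(c("chrom", "start", "end", "score") %in% names(sig)))
  setorder(sig, chrom, start)
  b <- bed0_from_gr(GenomicRanges::reduce(pmds, ignore.strand = TRUE))
  wide <- b$end - b$start >= flank_bp
  n_excluded <- sum(!wide)
  b <- b[wide, ]
  edges <- seq(-flank_bp, flank_bp, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  acc <- numeric(n_bins)
  cnt <- numeric(n_bins)
  lookup <- function(ch, at) {
    s <- sig[sig$chrom == ch, ]
    i <- findInterval(at, s$start)
    v <- rep(NA_real_, length(at))
    okk <- i >= 1 & i <= nrow(s)
    okk[okk] <- at[okk] < s$end[i[okk]]
    v[okk] <- s$score[i[okk]]
    v
  }
  for (i in seq_len(nrow(b))) {
    for (side in 1:2) {
      bound <- if (side == 1) b$start[i] else b$end[i]
      rel <- if (side == 1) centers else -centers # mirror the end boundary
      v <- lookup(b$chrom[i], floor(bound + rel))
      okk <- !is.na(v)
      acc[okk] <- acc[okk] + v[okk]
      cnt[okk] <- cnt[okk] + 1
    }
  }
  out <- data.table(rel_pos = centers, mean_signal = acc / pmax(1, cnt),
                    n = cnt)
  out$mean_signal[cnt == 0] <- NA_real_
  setattr(out, "n_excluded", n_excluded)
  out[]
}

#' Feature density as a function of PMD frequency
#'
#' Maps point or interval features (midpoints) to frequency-track tiles and
#' reports, per frequency class, the feature count and density per Mb of
#' genome at that frequency. Frequency classes with no genomic territory are
#' reported as missing (`NA` density), not zero.
#'
#' @param features `GRanges` (midpoints are used) or data.frame with
#'   `chrom`, `pos`.
#' @param track a `FrequencyTrack`.
#' @return data.table (`frequency`, `n_features`, `mb`, `density_per_mb`).
#' @export
density_by_frequency <- function(features, track) {
  n <- attr(track, "n_samples")
  if (is(features, "GRanges")) {
    mid <- floor((GenomicRanges::start(features) - 1 +
                    GenomicRanges::end(features)) / 2)
    pts <- data.table(chrom = as.character(GenomeInfoDb::seqnames(features)),
                      pos = mid)
  } else {
    pts <- as.data.table(features)[, c("chrom", "pos"), with = FALSE]
  }
  tl <- as.data.table(track)[, c("chrom", "start", "end", "frequency"),
                             with = FALSE]
  freq_of <- rep(NA_integer_, nrow(pts))
  for (ch in unique(pts$chrom)) {
    tt <- tl[tl$chrom == ch, ]
    if (!nrow(tt)) next
    i <- pts$chrom == ch
    k <- findInterval(pts$pos[i], tt$start)
    okk <- k >= 1
    okk[okk] <- pts$pos[i][okk] < tt$end[k[okk]]
    f <- rep(NA_integer_, sum(i))
    f[okk] <- tt$frequency[k[okk]]
    freq_of[i] <- f
  }
  bp_at <- vapply(0:n, function(f)
    sum(tl$end[tl$frequency == f] - tl$start[tl$frequency == f]), numeric(1))
  cnt <- vapply(0:n, function(f) sum(freq_of == f, na.rm = TRUE), numeric(1))
  out <- data.table(frequency = 0:n, n_features = cnt, mb = bp_at / 1e6,
                    density_per_mb = ifelse(bp_at > 0, cnt / (bp_at / 1e6),
                                            NA_real_))
  out[]
}
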