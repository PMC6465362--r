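#' Two-state HMM posterior decoding (scaled forward-backward)
#'
#' @param log_emission n x k matrix of per-observation log emission
#'   densities.
#' @param transition k x k transition matrix (rows sum to 1).
#' @param init initial state distribution.
#' @return n x k matrix of posterior state probabilities (rows sum to 1).
#' @export
hmm_posterior <- function(log_emission, transition, init) {
  n <- nrow(log_emission)
  k <- ncol(log_emission)
  stopifnot(nrow(transition) == k, ncol(transition) == k, length(init) == k)
  emis <- exp(log_emission - apply(log_emission, 1, max))
  fwd <- matrix(0, n, k)
  scale <- numeric(n)
  f <- init * emis[1, ]
  scale[1] <- sum(f)
  fwd[1, ] <- f / scale[1]
  for (t in seq_len(n)[-1]) {
    f <- (fwd[t - 1, ] %*% transition) * emis[t, ]
    scale[t] <- sum(f)
    fwd[t, ] <- f / scale[t]
  }
  bwd <- matrix(0, n, k)
  bwd[n, ] <- 1
  for (t in rev(seq_len(n - 1))) {
    b <- transition %*% (emis[t + 1, ] * bwd[t + 1, ])
    bwd[t, ] <- b / scale[t + 1]
  }
  post <- fwd * bwd
  post / rowSums(post)
}

#' Segment an alpha track into PMDs
#'
#' Decodes the window sequence with a two-state Gaussian-emission HMM on
#' log(alpha) (states = the two mixture components from [pmds_present()]),
#' calls windows with PMD-state posterior above the threshold, merges
#' consecutive PMD windows into genomic intervals spanning the first to last
#' window anchor, clips against excluded regions and drops intervals below
#' the minimum length or CpG count.
#'
#' @param alpha_track an `AlphaTrack`.
#' @param mixture two-component mixture as returned in
#'   `pmds_present()$mixture`, or the full `pmds_present()` result.
#' @param layout a `GenomeLayout`.
#' @param config a [pmd_call_config()].
#' @return `GRanges` of PMDs (sorted, disjoint, outside excluded regions)
#'   with a `mean_log_alpha` metadata column.
#' @export
segment <- function(alpha_track, mixture, layout,
                    config = pmd_call_config()) {
  if (is.list(mixture) && !is.null(mixture$present)) {
    if (!mixture$present) return(.empty_gr(layout$chrom_lengths))
    mixture <- mixture$mixture
  }
  if (is.null(mixture)) return(.empty_gr(layout$chrom_lengths))
  tr <- alpha_track
  stay <- config$persistence^config$step_cpgs
  trans <- matrix(c(stay, 1 - stay, 1 - stay, stay), 2, 2, byrow = TRUE)
  sds <- pmax(mixture$sds, 1e-3)
  out <- list()
  run_ids <- unique(tr$run)
  for (run_id in run_ids) {
    w <- tr[which(tr$run == run_id), ]
    le <- cbind(dnorm(w$log_alpha, mixture$means[1], sds[1], log = TRUE),
                dnorm(w$log_alpha, mixture$means[2], sds[2], log = TRUE))
    post <- hmm_posterior(le, trans, mixture$weights)
    pmd <- post[, 2] > config$posterior_threshold
    if (!any(pmd)) next
    rl <- rle(pmd)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    seg_i <- which(rl$values)
    ## boundaries from the outermost PMD windows' full CpG extent: the HMM
    ## flips only once a window lies (almost) wholly inside a PMD, so
    ## anchor-to-anchor spans shrink every call by ~half a window per side
    seg_start <- w$wstart[starts[seg_i]]
    seg_end <- w$wend[ends[seg_i]] + 1
    if (length(seg_i) > 1) { # neighboring window extents must not overlap
      for (s2 in 2:length(seg_i)) {
        if (seg_start[s2] < seg_end[s2 - 1]) {
          mid <- floor((seg_start[s2] + seg_end[s2 - 1]) / 2)
          seg_end[s2 - 1] <- mid
          seg_start[s2] <- mid
        }
      }
    }
    cpgs <- attr(alpha_track, "cpgs")
    if (!is.null(cpgs)) {
      rr <- cpgs[which(cpgs$run == run_id), ]
      for (s2 in seq_along(seg_i)) {
        seg_start[s2] <- .refine_boundary(
          rr, w, starts[seg_i[s2]], side = "start", seg_start[s2])
        seg_end[s2] <- .refine_boundary(
          rr, w, ends[seg_i[s2]], side = "end", seg_end[s2])
      }
      bad <- seg_end <= seg_start
      seg_start <- seg_start[!bad]; seg_end <- seg_end[!bad]
      seg_i <- seg_i[!bad]
      if (!length(seg_i)) next
    }
    out[[run_id]] <- data.table(
      chrom = w$chrom[1],
      start = seg_start,
      end = seg_end,
      mean_log_alpha = vapply(seg_i, function(s)
        mean(w$log_alpha[starts[s]:ends[s]]), numeric(1)))
  }
  if (!length(out)) return(.empty_gr(layout$chrom_lengths))
  segs <- rbindlist(out)
  segs <- segs[segs$end > segs$start, ]
  if (!nrow(segs)) return(.empty_gr(layout$chrom_lengths))
  gr <- gr_from_bed0(segs, layout$chrom_lengths)
  gr$mean_log_alpha <- segs$mean_log_alpha
  if (length(layout$excluded)) {
    keepcols <- gr$mean_log_alpha
    clipped <- GenomicRanges::setdiff(gr, layout$excluded,
                                      ignore.strand = TRUE)
    hits <- GenomicRanges::findOverlaps(clipped, gr, ignore.strand = TRUE)
    clipped$mean_log_alpha <- NA_real_
    clipped$mean_log_alpha[S4Vectors::queryHits(hits)] <-
      keepcols[S4Vectors::subjectHits(hits)]
    gr <- clipped
  }
  gr <- gr[GenomicRanges::width(gr) >= config$min_length_bp]
  if (length(gr)) {
    ## CpG support: count eligible windows' worth of CpGs inside
    cpg_gr <- gr_from_bed0(data.table(chrom = tr$chrom, start = tr$anchor,
                                      end = tr$anchor + 1),
                           layout$chrom_lengths)
    n_anchor <- GenomicRanges::countOverlaps(gr, cpg_gr,
                                             ignore.strand = TRUE)
    gr <- gr[n_anchor * attr(tr, "config")$step_cpgs >= config$min_cpgs]
  }
  sort(gr, ignore.strand = TRUE)
}

# Likelihood-based boundary refinement at CpG resolution. The HMM flips
# state only once a whole window supports the new state, so raw window
# spans locate boundaries to ~half a window. Here the CpGs spanning the
# flip are re-scored: for every candidate split, outside CpGs under the
# local background (mhat, alpha) and inside CpGs under the local PMD
# parameters, both estimated from flanking stable windows; the split
# maximizing the summed beta-binomial log-likelihood wins.
.refine_boundary <- function(rr, w, widx, side, fallback) {
  pmd_flank <- if (side == "start") widx + 2L else widx - 2L
  bg_flank <- if (side == "start") widx - 3L else widx + 3L
  if (pmd_flank < 1 || pmd_flank > nrow(w) ||
      bg_flank < 1 || bg_flank > nrow(w)) return(fallback)
  zone <- if (side == "start")
    c(w$wstart[widx] - 1L, w$anchor[widx] + 1L)
  else c(w$anchor[widx] - 1L, w$wend[widx] + 1L)
  idx <- which(rr$pos > zone[1] & rr$pos < zone[2] & rr$T > 0)
  if (length(idx) < 10) return(fallback)
  llof <- function(M, T, m, a) {
    m <- .clamp(m, 1e-4, 1 - 1e-4)
    b <- a * (1 - m) / m
    lbeta(M + a, T - M + b) - lbeta(a, b)
  }
  ll_bg <- llof(rr$M[idx], rr$T[idx], w$mhat[bg_flank], w$alpha[bg_flank])
  ll_pmd <- llof(rr$M[idx], rr$T[idx], w$mhat[pmd_flank],
                 w$alpha[pmd_flank])
  n <- length(idx)
  if (side == "start") {
    # split k: CpGs 1..k-1 background, k..n PMD; boundary at pos[k]
    score <- cumsum(c(0, ll_bg[-n])) + rev(cumsum(rev(ll_pmd)))
    k <- which.max(score)
    rr$pos[idx[k]]
  } else {
    # split k: CpGs 1..k PMD, k+1..n background; boundary after pos[k]
    score <- cumsum(ll_pmd) + sum(ll_bg) - cumsum(ll_bg)
    k <- which.max(score)
    rr$pos[idx[k]] + 1
  }
}

#' Call PMDs on one methylome
#'
#' Composition [window_alpha()] then [pmds_present()] then [segment()];
#' returns an empty set when no two-component alpha structure is found.
#'
#' @inheritParams window_alpha
#' @return `GRanges` of PMD calls; attribute `"present"` carries the
#'   [pmds_present()] diagnostics.
#' @export
call_pmds <- function(methylome, layout, config = pmd_call_config()) {
  track <- tryCatch(window_alpha(methylome, layout, config),
                    error = function(e) NULL)
  if (is.null(track) || nrow(track) < 200) {
    out <- .empty_gr(layout$chrom_lengths)
    attr(out, "present") <- list(present = FALSE,
                                 reason = "insufficient alpha windows")
    return(out)
  }
  pres <- pmds_present(track,
                       min_component_sep = config$min_component_sep)
  out <- if (pres$present) segment(track, pres$mixture, layout, config)
  else .empty_gr(layout$chrom_lengths)
  attr(out, "present") <- pres[c("present", "separation", "reason")]
  out
}
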