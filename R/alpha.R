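#' PMD caller configuration
#'
#' Parameters of the windowed polarization score and HMM decoder. The window
#' slides over coverage-eligible CpGs (never across excluded regions); for
#' each window the pooled mean `mhat = sum(M)/sum(T)` is fixed and the
#' beta-binomial shape `alpha` (with `beta = alpha * (1-mhat)/mhat`) is fit
#' by maximum likelihood. `alpha < 1` indicates polarized counts (piled at
#' 0/T: the hypermethylated background), `alpha >= 1` intermediate dispersed
#' methylation (PMD-like).
#'
#' @param window_cpgs CpGs per window (odd, >= 11).
#' @param step_cpgs CpGs between successive window starts.
#' @param min_coverage per-CpG minimum coverage for window eligibility.
#' @param persistence HMM state-persistence probability per CpG step; the
#'   per-window-step stay probability is `persistence^step_cpgs`.
#' @param posterior_threshold PMD-state posterior needed to call a window.
#' @param min_length_bp,min_cpgs minimum PMD size after merging/clipping.
#' @param mode `"all"` or `"solo_wcgw"` (restrict to solo-WCGW CpGs).
#' @param min_component_sep reject the two-component mixture (no PMDs) if
#'   its means differ by less than this in log alpha.
#' @param log_alpha_bounds search bounds for log(alpha).
#' @return A validated `PmdCallConfig` list.
#' @export
pmd_call_config <- function(window_cpgs = 101,
                            step_cpgs = 10,
                            min_coverage = 5,
                            persistence = 0.9995,
                            posterior_threshold = 0.5,
                            min_length_bp = 1e4,
                            min_cpgs = 101,
                            mode = c("all", "solo_wcgw"),
                            min_component_sep = 0.1,
                            log_alpha_bounds = c(-8, 8)) {
  mode <- match.arg(mode)
  stopifnot(window_cpgs >= 11, window_cpgs %% 2 == 1,
            step_cpgs >= 1, persistence > 0.5, persistence < 1,
            posterior_threshold > 0, posterior_threshold < 1,
            min_length_bp > 0, min_cpgs >= 1, min_coverage >= 0)
  structure(as.list(environment()), class = "PmdCallConfig")
}

#' Windowed beta-binomial polarization track
#'
#' Computes, for sliding windows of eligible CpGs, the pooled methylation
#' mean and the maximum-likelihood mean-constrained beta-binomial `alpha`.
#' Windows never span chromosome boundaries or excluded regions.
#'
#' @param methylome a `SampleMethylome`.
#' @param layout a `GenomeLayout`.
#' @param config a [pmd_call_config()].
#' @return An `AlphaTrack`: data.table with one row per window (`chrom`,
#'   `run`, `anchor` = 0-based position of the central CpG, `n_cpgs`,
#'   `mhat`, `alpha`, `log_alpha`, `ok`).
#' @export
window_alpha <- function(methylome, layout, config = pmd_call_config()) {
  r <- methylome$records
  keep <- r$T >= max(1L, config$min_coverage)
  if (config$mode == "solo_wcgw") {
    if (all(is.na(r$is_solo_wcgw)))
      stop("solo_wcgw mode requires solo-WCGW context flags")
    keep <- keep & !is.na(r$is_solo_wcgw) & r$is_solo_wcgw
  }
  r <- r[keep, ]
  if (nrow(r) < config$window_cpgs)
    stop("fewer eligible CpGs (", nrow(r), ") than one window (",
         config$window_cpgs, ")")
  ## runs: maximal stretches of CpGs on one chromosome with no excluded
  ## region in between
  excl <- bed0_from_gr(GenomicRanges::reduce(layout$excluded,
                                             ignore.strand = TRUE))
  r$run <- paste0(r$chrom, ":0")
  if (nrow(excl)) {
    for (ch in unique(r$chrom)) {
      e <- excl[excl$chrom == ch, ]
      if (!nrow(e)) next
      i <- r$chrom == ch
      seg <- findInterval(r$pos[i], sort(e$start))
      r$run[i] <- paste0(ch, ":", seg)
      inside <- r$pos[i] >= e$start[pmax(1, seg)] &
        r$pos[i] < e$end[pmax(1, seg)] & seg >= 1
      if (any(inside)) r$run[i][inside] <- NA
    }
    r <- r[!is.na(r$run), ]
  }
  half <- (config$window_cpgs - 1L) / 2L
  ws <- we <- anchor_idx <- integer(0)
  setorder(r, chrom, pos)
  run_rle <- rle(r$run)
  run_start <- cumsum(c(1L, head(run_rle$lengths, -1)))
  for (k in seq_along(run_rle$values)) {
    n <- run_rle$lengths[k]
    if (n < config$window_cpgs) next
    s0 <- seq.int(1L, n - config$window_cpgs + 1L, by = config$step_cpgs)
    ws <- c(ws, run_start[k] + s0 - 1L)
    we <- c(we, run_start[k] + s0 + config$window_cpgs - 2L)
  }
  if (!length(ws))
    stop("no run long enough for a single window")
  fit <- bb_alpha_windows(as.integer(r$M), as.integer(r$T),
                          as.integer(ws), as.integer(we),
                          config$log_alpha_bounds[1],
                          config$log_alpha_bounds[2])
  mid <- ws + half
  track <- data.table(chrom = r$chrom[mid], run = r$run[mid],
                      anchor = r$pos[mid],
                      wstart = r$pos[ws], wend = r$pos[we],
                      n_cpgs = config$window_cpgs,
                      mhat = fit$mhat, alpha = fit$alpha,
                      log_alpha = log(fit$alpha), ok = fit$ok)
  track <- track[track$ok, ]
  setattr(track, "config", config)
  setattr(track, "cpgs", r[, c("chrom", "pos", "M", "T", "run"),
                           with = FALSE])
  setattr(track, "class", c("AlphaTrack", class(track)))
  track[]
}

#' Mean-constrained beta-binomial window log-likelihood (reference R path)
#'
#' Direct `lbeta`-based evaluation of the same likelihood the C++ kernel
#' maximizes; exposed for verification and diagnostics.
#'
#' @param alpha shape parameter (> 0).
#' @param M,T integer count vectors.
#' @param mhat pooled mean; defaults to `sum(M)/sum(T)`.
#' @return log-likelihood (binomial coefficients omitted).
#' @export
bb_window_loglik <- function(alpha, M, T, mhat = sum(M) / sum(T)) {
  mhat <- .clamp(mhat, 1e-4, 1 - 1e-4)
  beta <- alpha * (1 - mhat) / mhat
  sum(lbeta(M + alpha, T - M + beta) - lbeta(alpha, beta))
}
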