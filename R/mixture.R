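# One-dimensional Gaussian mixtures by EM, used for the "are PMDs present"
# decision on log(alpha) and for aggregate-caller classification of
# cross-sample s.d. values. Deterministic quantile-based initialization.

fit_gmm1d <- function(x, k = 2, max_iter = 500, tol = 1e-8,
                      equal_var = FALSE) {
  x <- x[is.finite(x)]
  n <- length(x)
  stopifnot(n >= 2 * k)
  if (k == 1) {
    mu <- mean(x); s <- sd(x)
    if (!is.finite(s) || s < 1e-9) s <- 1e-9
    ll <- sum(dnorm(x, mu, s, log = TRUE))
    return(list(k = 1, weights = 1, means = mu, sds = s, loglik = ll,
                bic = -2 * ll + 2 * log(n), converged = TRUE))
  }
  ## EM is sensitive to initialization in the minority-component regime;
  ## run from several deterministic quantile-pair starts, keep the best
  inits <- list(c(0.25, 0.75), c(0.10, 0.90), c(0.05, 0.60), c(0.40, 0.95))
  best <- NULL
  for (pr in inits) {
    fit <- .em_gauss(x, quantile(x, probs = pr, names = FALSE),
                     max_iter, tol, equal_var)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ord <- order(best$mu)
  n_par <- if (equal_var) 2 * k else 3 * k - 1
  list(k = k, weights = best$w[ord], means = best$mu[ord],
       sds = best$s[ord], loglik = best$loglik,
       bic = -2 * best$loglik + n_par * log(n),
       converged = best$converged)
}

.em_gauss <- function(x, mu, max_iter, tol, equal_var = FALSE) {
  n <- length(x)
  k <- length(mu)
  s <- rep(max(sd(x) / k, 1e-6), k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * dnorm(x, mu[j], s[j]), numeric(n))
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    resp <- dens / tot
    nk <- colSums(resp)
    if (any(nk < 1e-8)) break # component collapsed; keep last estimates
    w <- nk / n
    mu <- colSums(resp * x) / nk
    s <- sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk)
    if (equal_var) s <- rep(sqrt(sum(nk * s^2) / n), k)
    s[!is.finite(s) | s < 1e-6] <- 1e-6
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  ll <- sum(log(pmax(1e-300, rowSums(vapply(seq_len(k),
    function(j) w[j] * dnorm(x, mu[j], s[j]), numeric(n))))))
  list(mu = mu, s = s, w = w, loglik = ll, converged = converged)
}

#' Decide whether a methylome contains PMDs at all
#'
#' Fits one- and two-component Gaussian mixtures to the window log(alpha)
#' distribution. PMDs are declared present iff the two-component model wins
#' on BIC, the component means are separated by at least two pooled standard
#' deviations (and by at least `min_component_sep` in log alpha), and the
#' high-alpha component lies above log(alpha) = 0 (intermediate, dispersed
#' methylation). The two-component fit is homoskedastic: the polarized
#' background is heavy-tailed on the left (windows dominated by
#' hypomethylated islands), and a free-variance fit degenerates into a
#' narrow-core-plus-wide-tail solution instead of the background/PMD split
#' when the PMD fraction is small.
#'
#' @param alpha_track an `AlphaTrack` from [window_alpha()].
#' @param min_windows minimum number of windows required.
#' @param min_component_sep see [pmd_call_config()].
#' @return list: `present`, `mixture` (two-component fit), `bic1`, `bic2`,
#'   `separation` (in pooled s.d. units), `histogram` (log-alpha histogram
#'   for inspection), `reason`.
#' @export
pmds_present <- function(alpha_track, min_windows = 200,
                         min_component_sep = 0.1) {
  la <- alpha_track$log_alpha[is.finite(alpha_track$log_alpha)]
  if (length(la) < min_windows)
    stop("need at least ", min_windows, " alpha windows; got ", length(la))
  h <- graphics::hist(la, breaks = 50, plot = FALSE)
  if (sd(la) < 1e-6)
    return(list(present = FALSE, mixture = NULL, bic1 = NA, bic2 = NA,
                separation = 0, histogram = h,
                reason = "degenerate alpha distribution (zero variance)"))
  g1 <- fit_gmm1d(la, 1)
  g2 <- fit_gmm1d(la, 2, equal_var = TRUE)
  pooled_sd <- sqrt(sum(g2$weights * g2$sds^2))
  sep_sd <- diff(g2$means) / pooled_sd
  ok_bic <- g2$bic < g1$bic
  ok_sep <- sep_sd >= 2 && diff(g2$means) >= min_component_sep
  ok_high <- g2$means[2] > 0
  present <- ok_bic && ok_sep && ok_high
  reason <- if (present) "two polarization components detected" else
    paste0(c("BIC favors one component"[!ok_bic],
             "components insufficiently separated"[!ok_sep],
             "high component not in the intermediate regime"[!ok_high]),
           collapse = "; ")
  list(present = present, mixture = g2, bic1 = g1$bic, bic2 = g2$bic,
       separation = sep_sd, histogram = h, reason = reason)
}
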