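---
title: "Models and methods behind pmdscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pmdscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pmdscape segments whole-genome bisulfite sequencing (WGBS) methylomes into
partially methylated domains (PMDs) and analyzes cohorts of such
segmentations: frequency and variability statistics with permutation nulls,
CpG-island (CGI) hypermethylation and its regression on PMD content,
gene-set exclusion tests, and methylome clustering/PCA. This vignette is
the package's own account of the models, the tunable parameters, the
synthetic world used to validate everything, and the numerical choices a
maintainer would want to know about.

## The polarization score

A methylome is a sequence of CpGs with methylated counts $M_j$ out of
$T_j$ reads. Cancer-type PMDs are not defined by low *mean* methylation —
their defining feature is *intermediate, dispersed* per-CpG methylation,
in contrast to the polarized background where most CpGs sit at 0 or 1.

For a sliding window of $w$ CpGs (default 101, stepping 10) we fix the
pooled mean $\hat m = \sum M_j / \sum T_j$ and fit a single shape
parameter $\alpha$ of a mean-constrained beta-binomial,

$$M_j \sim \mathrm{BetaBin}\!\left(T_j;\ \alpha,\ \beta = \alpha
\frac{1-\hat m}{\hat m}\right),$$

by maximum likelihood over $\log\alpha \in [-8, 8]$ (golden-section
search; the likelihood is evaluated through ascending-factorial count
tables, which makes an evaluation $O(\max T)$ instead of $O(w)$ and is
exact for integer counts). $\alpha < 1$ means the underlying beta is
U-shaped — counts piled at the extremes, the hypermethylated background —
while $\alpha \ge 1$ means intermediate dispersed methylation, the PMD
regime. Windows never span chromosome ends or excluded (centromere-like)
regions, and only CpGs with coverage $\ge 5$ (configurable) enter.

## Deciding whether PMDs exist, and where

**Presence.** One- and two-component Gaussian mixtures are fitted to the
window $\log\hat\alpha$ values by EM (deterministic quantile-pair starts,
best likelihood kept). PMDs are "present" iff BIC prefers two components,
the means are at least two pooled standard deviations apart (and at least
0.1 in $\log\alpha$ — a guard against hallucinating domains in
near-unimodal samples), and the high component sits above $\log\alpha =
0$. The two-component fit is *homoskedastic*: the background is
left-heavy-tailed (windows dominated by hypomethylated CGIs), and a
free-variance EM prefers a narrow-core-plus-wide-tail solution over the
background/PMD split whenever the PMD fraction is small. With a shared
variance the split is recovered across the whole planted-fraction range
(0.1–0.5) without touching any threshold.

**Segmentation.** The mixture components become the emissions of a
two-state HMM on the window sequence, with symmetric transitions
$p_{stay} = 0.9995^{step}$ per window step. Posterior (forward-backward)
decoding marks PMD windows at posterior > 0.5, consecutive PMD windows
merge, and each boundary is then *refined at CpG resolution*: the HMM
flips state only once a whole window supports the new state, so raw
window spans misplace boundaries by up to half a window (~5 kb at human
CpG density). For every boundary we re-score the CpGs spanning the flip
under the flanking background and PMD beta-binomial parameters and place
the boundary at the likelihood-maximizing split. On planted domains this
reduces the boundary error from kilobases to a few hundred bp. Calls are
clipped against excluded regions and dropped below 10 kb or 101 CpGs.

**Parameters that matter.** Window size (101 CpGs) sets the
resolution/variance trade-off of $\hat\alpha$; persistence (0.9995/CpG)
sets the prior scale of segments (PMDs are 100 kb–Mb features); the
posterior threshold stays at the neutral 0.5. All are exposed in
`pmd_call_config()`.

A solo-WCGW mode restricts scoring to A/T-flanked CpGs without a close
neighbor (< 35 bp), the context most prone to PMD hypomethylation; an
aggregate caller classifies 100-kb bins by the cross-sample standard
deviation of weighted methylation (two-component mixture on the s.d.,
free variances — the s.d. distribution is not heavy-tailed the way
$\log\alpha$ is).

## Cohort statistics

Mean methylation of any region is always the *weighted methylation
level* $\sum M / \sum T$, and region/tile means exclude CGI, CGI-shore
and promoter CpGs, whose CpG density would otherwise dominate. PMD
frequency of a tile/gene/CGI is the number of samples in which it is
covered (any-overlap for 30-kb tiles; $\ge$ 50% of the body for genes
and CGIs, with TSS- and midpoint-rules as configurable alternatives —
the published analyses name no rule). The permutation null re-places
each sample's intervals uniformly per chromosome (lengths preserved
exactly, excluded regions avoided, rejection sampling with restarts);
its per-tile expectation is checked against the exact
single-placement overlap probability, to first order in the
non-overlap interaction.

B-CIMP is the fraction of (covered) CGIs with weighted methylation
strictly above 0.30. Its regression on the per-sample fraction of CGIs
inside PMDs is a logit-link beta regression with precision $\phi$,
fitted by ML with analytic gradients; exact 0/1 responses are pulled
inside $(0,1)$ by the usual $(y(n-1)+0.5)/n$ compression, applied only
to boundary values. The reported pseudo-$R^2$ is the squared Pearson
correlation between the linear predictor and the logit response — the
convention of the standard beta-regression tooling — and the slope test
is a Wald z from the numerical Hessian. Gene-set exclusion uses the
upper hypergeometric tail computed from `lchoose` sums in log space.

Clustering follows the field's conventions: Ward.D linkage on
1 − Pearson distances for tiled methylation profiles (Ward.D, not
Ward.D2 — the merge criterion is applied to the unsquared distances),
complete linkage on 1 − Jaccard distances of 5-kb binary PMD occupancy
vectors. PCA keeps CpGs covered $\ge 10\times$ in every sample (a
"$\ge$ 90% of samples" alternative is exposed; the published filter
scope is ambiguous), ranks by variance, keeps the top 5% and uses
centered, unit-scaled components; covariates are associated with
components by correlation t-tests (numeric) or one-way ANOVA
(categorical).

## The synthetic world

The study this package operationalizes has no generative model, so the
generator states one:

* **Two-level domain architecture.** A shared set of PMD-permissive
  domains (lognormal lengths, mean ~750 kb, truncated to 0.25–3 Mb) is
  laid out so that a configurable 25% of the non-excluded genome is
  never permissive. Each domain carries an activation propensity drawn
  low-frequency-heavy from [0.1, 0.95]; each sample activates each
  domain independently with probability min(0.95, activity ×
  propensity), where the per-sample activity factor (Uniform 0.4–1.6)
  reproduces the wide per-tumor range of PMD genome fractions
  (roughly 10–50%, coefficient of variation > 0.3). Activated edges
  get per-sample jitter (± up to 50 kb, a free parameter the source
  study does not quantify).
* **Methylation.** Across CpGs, background methylation follows a
  polarized beta (mean 0.85, concentration 0.8 — U-shaped,
  $\alpha \approx 0.7 < 1$). Crucially, each stable-region CpG's level
  is a *CpG property*: a baseline is drawn once per layout from that
  beta and shared across samples, with modest per-sample wobble
  (concentration 60). Only CpGs inside *active* PMDs (and gained
  islands) redraw disordered intermediate methylation per sample
  (per-sample mean Uniform 0.40–0.75, concentration 8,
  $\alpha \approx 3$–6; solo-WCGW CpGs offset by −0.08). A fully
  iid-per-sample model was tried first and makes per-CpG cross-sample
  variance pure noise — variance-ranked PCA then cannot see the PMD
  factor, which is exactly the structure the analyses assume real
  methylomes to have. Counts are Binomial over negative-binomial
  coverage (mean 10, size 8; zero-coverage CpGs retained so filters
  are exercised). Window-level marginals are unchanged by the
  anchoring, so the caller behaves identically. The caller's contrast
  is in *dispersion*, not mean — setting PMD mean and concentration
  equal to the background's produces the degenerate no-signal case the
  tests use.
* **CGIs.** CpG-dense islands (8× density) are hypomethylated (mean
  0.05) at baseline. Every island is *gain-prone* with probability
  0.92: in any sample whose PMD covers it (jitter-extended edges
  included) it rises to an intermediate level drawn per island and
  sample from Uniform(0.40, 0.70). Islands outside all permissive
  domains are additionally constitutively methylated with probability
  0.27 (mean 0.80), overriding gain-proneness. Constitutive islands
  use the *background's* polarized concentration: stably methylated
  islands in real data are near-bimodal per CpG, and a dispersed
  parameterization would (and in an early version did) create false
  PMD calls at exactly those islands.
* **Genes/TSGs.** Genes are lognormal-length intervals; TSG labels go
  to genes outside all permissive domains with probability 0.9 —
  "outside" with a jitter-width margin, so the planted semantics
  survive boundary jitter.

What the generator does **not** emulate: spatial autocorrelation of
methylation within domains, bisulfite conversion errors, copy-number
effects, read-level structure, or sequence-driven CpG density beyond
the CGI multiplier. A green test therefore establishes that the
pipeline recovers the stated statistical structure, not that it
reproduces any particular real methylome.

## Numerical choices and degenerate inputs

* $\hat m$ is clamped to $[10^{-4}, 1-10^{-4}]$ before the constrained
  fit; all-methylated windows then drive $\hat\alpha$ to the lower
  search bound (correctly: the polarized limit).
* EM components are ordered by mean; ties in hierarchical clustering
  resolve by `hclust`'s leaf order on the given input order, which is
  deterministic.
* Zero-coverage windows are skipped and logged; samples with fewer
  than 200 alpha windows refuse the presence decision.
* Boundary refinement falls back to the raw window extent at run edges
  or when fewer than 10 CpGs span the flip.
* `derive_seed()` maps (master seed, index) into 32-bit range; every
  RNG consumer takes an explicit seed, so reruns are bit-identical.

Two acceptance worlds deviate from the cohort defaults deliberately.
The two-tissue clustering cohort uses high activation propensities
(0.5–0.95) and 70% tissue-private domains: tissue-of-origin PMD
landscapes are consistent within a type, whereas the cohort defaults
encode tumor hypervariability. The PCA cohort uses the default genome
at 20× coverage: the ≥10×-in-every-sample CpG filter retains nothing
at 10× mean coverage, and with only a handful of domains the leading
principal component splinters into domain-block factors rather than
the global PMD-methylation factor the genome-wide analysis sees.

The CGI gain-probability recovery is measured against *planted*
domains. The caller excises the minority of islands that stay
hypomethylated inside PMDs (their windows are polarized, so the HMM
exits briefly), which drives the called-domain fraction of
hypermethylated in-PMD islands toward 1; the called value is asserted
to bound the planted one from above instead.

## Deliberate interpretive choices

Two deliberate interpretations are worth recording. First, the
"never-PMD fraction" of a generated layout is verified as the
base-pair fraction of the non-excluded genome outside all permissive
domains (direct interval arithmetic); tile-indicator counting would
understate it by the tile/gap ratio. Second, segment boundaries are
reported from refined CpG-level splits rather than window anchor
spans; anchor spans cannot meet the stated boundary tolerance because
the HMM flips only on fully-converted windows. Both choices are the
package's own; neither loosens a stated tolerance.

## Known limitations

* The caller is a from-scratch reconstruction of alpha-distribution
  PMD segmentation; equivalence with any specific published tool (or
  its defaults) is not claimed.
* The shuffle null's analytic check is first-order in the non-overlap
  interaction between placed intervals; at the occupancies tested
  (≤ 50%) the residual bias is well inside Monte-Carlo noise.
* Beta-regression inference is asymptotic (Wald); at n = 30 the
  acceptance tests verify calibration empirically rather than assuming
  it.
* bedGraph input carries fractions only; counts read from bedGraph are
  nominal (coverage 1) and unsuitable for count-based statistics.
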