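---
title: "Methods: cross-dimensional diversity metrics and their spectral analogues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-dimensional diversity metrics and their spectral analogues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specdiv)
```

`specdiv` implements a framework for comparing plant diversity measured on
the ground (plot surveys of species percent cover, nested in sites) with
diversity measured from the sky (plot-scale imaging spectroscopy). The
guiding principle is *analogy*: a ground metric is only compared with a
spectral metric that shares its mathematical construction, so that values
across dimensions are interpretable in the same terms. This vignette
explains the models, the defaults, and the choices made where the design
was genuinely open.

## 1. Ground metrics

Given one plot's relative covers $p_1,\dots,p_S$:

* Taxonomic Hill metrics: richness $S$ (order $q=0$), Shannon entropy
  $H=-\sum p_i\ln p_i$ ($q=1$), Gini–Simpson $D=1-\sum p_i^2$ ($q=2$).
* Mean pairwise distance over a symmetric distance matrix $\delta_{ij}$
  restricted to the plot's members, unweighted by abundance (the formula
  contains no $p_i$): with trait distances it is called MTD, with patristic
  distances MPD, with pixel distances MSD.
* Faith-type total diversity: the summed branch length of the minimal
  subtree spanning the members. We include the stem path to the root
  ("from the root to the tip"); a one-species plot therefore has PD equal
  to its root-to-tip path length rather than zero.
* Dispersion, the effective number of distinct species. Distances are
  first scaled into $[0,1]$ by the maximum distance across the whole
  analysis run within each dimension (cross-plot comparability; per-plot
  scaling is available via the `scaling_max` argument). Then
  $m_i=\sum_{j\ne i} d'_{ij}/(S-1)$, $M'=\overline{m_i}$, the dispersion
  profile $\omega_i = p_i m_i / \sum_k p_k m_k$, its Hill number
  ${}^qD(T) = (\sum \omega_i^q)^{1/(1-q)}$ (with the $q\to1$ limit
  $\exp(-\sum\omega_i\ln\omega_i)$), evenness ${}^qE(T)={}^qD(T)/S$, and

  $${}^qD(TM) = 1 + (S-1)\,{}^qE(T)\,M'.$$

  At $q=0$ the profile reduces to counting and ${}^0D(TM)=1+(S-1)M'$.
  A one-species plot is defined to have ${}^qD(TM)=1$, as is a plot whose
  members are identical (all distances zero). The abundance-weighted
  profile is the default; `abundance_weighted = FALSE` switches to
  $\omega_i \propto m_i$, since both readings exist in the literature this
  framework draws on.
* SES standardization: $z = (\mathrm{obs}-\overline{\mathrm{null}})/
  \mathrm{sd}(\mathrm{null})$ with a taxa-label null — 999 seeded draws of
  the same richness from the pool, recomputing the metric. No null model is
  canonical here; label shuffling holding richness fixed is the simplest
  null that preserves the plot's sampling depth, and the package verifies
  its calibration (mean $z\approx0$, sd $\approx1$ under neutral assembly).

## 2. Spectral processing

Plot cubes pass through a fixed cleaning order: band filtering, NDVI
masking, brightness masking, vector normalization.

* Band filter: wavelengths in the closed intervals $[1340,1445]$ and
  $[1790,1955]$ nm (atmospheric water absorption) and all bands
  $\le 400$ or $\ge 2450$ nm are removed. Closed intervals were chosen so
  the boundary bands named by the filtering rule are themselves removed.
* NDVI mask: band-window means (red 660–680 nm, NIR 800–860 nm); pixels
  with NDVI below 0.5 (high-cover plots) or 0.2 (low-cover plots) are
  masked; a pixel exactly at the threshold is kept. Cover class is
  assigned per plot: "high" when at least half the pixels reach NDVI 0.2,
  a rule the package must supply since none is stated for the assignment.
* Brightness mask: Tukey fences ($k=1.5$) on mean reflectance per pixel.
  The motivating artefact is shade (low side), but the default is
  two-sided because the same test removes specular glint; `side = "low"`
  restricts it. Re-application is a provenance-checked no-op, making the
  mask idempotent even though the quartiles of a shrunken pixel set would
  otherwise drift.
* Vector normalization: each valid spectrum is divided by its Euclidean
  norm, removing brightness magnitude and leaving spectral shape.

A plot whose valid-pixel fraction falls below 0.25 after cleaning is
rejected as a typed outcome (`plot_rejection`), not an error; the threshold
is a package default, as plot rejection is reported in this literature
without a stated rule. Plot extraction windows are configurable (40 × 40
pixels by default, with pixel subsampling to 400 before any
$O(n^2)$ distance work) because the sources are ambiguous between 1600 and
400 pixels per plot.

## 3. Spectral metrics

Pixel distances are Euclidean on the normalized spectra (cosine available
via `method = "cosine"`); no metric is canonical in the sources, and on
unit-norm vectors the two are monotonically related. MSD is the mean
pairwise pixel distance. ${}^0D(SM)$ is the $q=0$ dispersion under equal
pixel weights, $1+(n-1)M'$, computed only at $q=0$ because the pixel count
is fixed by design and the equal-weight profile carries no abundance
information at higher orders. SD — the total-diversity analogue — is
realized as the total branch length of a UPGMA dendrogram over the pixel
distance matrix: a literal "sum over pixels" is not computable as a
diversity, and the dendrogram length is the defensible pixel-level
analogue of Faith diversity. This reading is a design decision and is
flagged here prominently.

Spectral species are estimated per plot: the candidate number of clusters
$k$ is proposed independently by ten cluster-validity indices
(Calinski–Harabasz, Hartigan, Krzanowski–Lai, silhouette, C-index,
Davies–Bouldin, Duda–Hart, pseudo-$t^2$, Ratkowsky–Lance, Ball–Hall), each
evaluated on PAM (k-medoids BUILD+SWAP) partitions over `k_range`
(default 2 to min(20, n−1)); the chosen $k$ is the round-half-up mean of
the proposals, and the final partition is PAM at that $k$. All indices are
computed from the same k-medoids partitions rather than hierarchical cuts,
for coherence with the final clustering step; the index set is
configurable because the authoritative list is not fixed. Within-cluster
sums of squares below $10^{-9}$ of the total are flushed to zero so that
ratio-based indices do not chase floating-point residue on perfectly
separable data. The ensemble is deliberately conservative: the
Ratkowsky–Lance, Ball–Hall and C-index members systematically vote low, so
the mean under-segments plots with many spectral classes; exact recovery
is reliable up to roughly four well-separated classes per plot, and the
package's recovery test operates in that regime.

## 4. Phylogenetic and trait preparation

* Phylogenetic eigenvectors: eigendecomposition of
  $-\tfrac12 J D^2 J$ with $D$ the patristic distance matrix — the
  principal coordinates of the phylogeny. Default dimensionality: the
  smallest set explaining 95% of the positive-eigenvalue trace, capped at
  30 (no count is stated in the sources).
* Imputation: iterative random-forest regression of each incomplete trait
  on the other traits plus the eigenvectors, missForest-style, stopping
  when the imputed values stop changing. Observed cells are never altered;
  out-of-bag MSE is returned as the per-trait imputation error estimate.
* Pagel's $\lambda$ by maximum likelihood: the Brownian covariance's
  off-diagonals are multiplied by $\lambda$, the mean and rate are profiled
  analytically, and $\lambda$ is optimized on $[0,1]$ with a
  profile-likelihood interval. This replaces a long MCMC treatment of the
  same estimand with a desk-scale ML equivalent — a deliberate deviation,
  recorded here; the estimator is verified against an independent
  implementation and recovers $\bar\lambda\approx1$ for Brownian traits
  and $<0.1$ for signal-free traits.
* Model adequacy: BM traits are simulated on the tree, then BM and a
  single-optimum OU (three parameters: mean, rate, selection strength;
  root state free, stationarity not assumed) are fitted by ML and compared
  by Akaike weights. A replicate with weight ratio below 2 is labelled
  "indecisive" — the indecisive class exists in this literature without a
  stated cutoff, and 2 is the conventional weak-evidence boundary.
  Non-convergent replicates are flagged, never dropped silently.
* Trait dendrogram: Gower distances (range-normalized mean absolute
  differences over pairwise-complete traits) → UPGMA → a single rescaling
  of all branch lengths so the root age equals the phylogeny's root age,
  making dendrogram and tree comparable in PCD.

## 5. Association models

Each registry pair fits
$y_p = \alpha + a_{s[p]} + \beta x_p + \varepsilon_p$ with
$a_s \sim N(0, \sigma_{site}^2)$, $\varepsilon \sim N(0,\sigma^2)$.
Sampling is by Gibbs: $(\alpha,\beta,a_1,\dots,a_S)$ are drawn as one
conjugate block (sequential updates mix poorly because the intercept and
the site effects are strongly coupled), and the half-t(3, 0, 2.5) priors
on both scales use the Huang–Wand inverse-gamma expansion; $\alpha$ and
$\beta$ have Normal(0, 5) priors, and covariates enter unstandardized.
Four chains of 5000 iterations with the first 20% discarded are the
default; split-$\hat R$ < 1.01 and rank-normalized bulk-ESS > 1000 on the
core parameters are required, and a fit violating the $\hat R$ gate is
returned as a typed failure carrying its diagnostics (`strict = FALSE`
returns the fit anyway, flagged). Quantile regressions use the asymmetric
Laplace via the exponential scale mixture at
$\theta \in \{0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95\}$; the ALD scale
takes a conjugate inverse-gamma prior, the one scale for which the half-t
expansion is not conjugate.

Summaries: evidence ratio $ER = P(\beta>0)/P(\beta\le0)$ (infinite when
all draws agree); Bayesian $R^2 = \mathrm{Var}(\mu)/(\mathrm{Var}(\mu)+
\sigma^2)$ per draw, conditional (site intercepts in $\mu$) or marginal;
posterior predictive checks on mean, sd and skewness — the skewness
statistic is the informative one for a Gaussian likelihood, which absorbs
the sample mean and variance almost exactly, so their tail probabilities
stay near 0.5 even under gross distributional misfit; train/test scores on
a seeded 50/50 split with posterior-mean predictions (the functional is a
package choice): Pearson $\rho$, $\mathrm{smape}=\overline{2|\hat y-y|/
(|y|+|\hat y|)}$, $\mathrm{rmsle}=\sqrt{\overline{(\ln(1+\hat y)-
\ln(1+y))^2}}$ (skipped with a warning on negative values), and predictive
deviation $|\hat y - y|/\max(y)$.

The pair registry enforces analogy: Hill metrics pair with SS at matching
$q$; MTD/MPD (and their SES $z$ forms) with MSD; PD/PDz with SD; the
dispersion metrics with SS at matching $q$ and with ${}^0D(SM)$. No pair
crosses metric families. The registry deliberately includes every
distance-based phylogenetic response (MPD, MPDz, PD, PDz, and the three
dispersion orders), which is one more than the tersest published count of
such models; the full set is retained because results are reported for
each of them.

## 6. Community dissimilarity (PCD)

With $V$ the tip-state correlation matrix (shared path length under
Brownian motion, unit diagonal; identity for a star tree), the
phylogenetic species variability of a set is
$\mathrm{PSV}=(n\,\mathrm{tr}C-\Sigma C)/(n(n-1))$. For plots $A$ and $B$
the observed statistic is the richness-weighted conditional PSV of each
plot given the other, relative to their unconditional PSV; dividing by the
Monte-Carlo expectation of the same statistic for random assemblages makes
random draws from the pool expect 1. The compositional component divides
the observed Sørensen dissimilarity by its random expectation
$1-2n_1n_2/((n_1+n_2)n)$, and $\mathrm{PCD_{PHY}} =
\mathrm{PCD}/\mathrm{PCD_{COMP}}$. Identical plots give PCD = 0. The pool
is the union of species across the analysed plots (a variant-admitting
choice); the same machinery computes $\mathrm{PCD_{TRT}}$ on the
calibrated trait dendrogram. The implementation is verified to match an
independent reference implementation pair-by-pair when both use the same
Monte-Carlo expectations.

## 7. The synthetic landscape

The generator's defaults are the study conditions under which every claim
in the test suite is evaluated: communities nested in sites (10 sites ×
20 plots), a 100-species pool, plot richness uniform on 2–15, percent
cover from a Dirichlet(1) draw scaled to a total between 60 and 95, plots
of 40 × 40 pixels at 1 m, and a 426-band wavelength grid (384–2512 nm at
5 nm) — configurable down to tens of bands for fast tests. Traits evolve
under Brownian motion on a birth–death tree; species reflectance is a
shared green-vegetation template (chlorophyll troughs near 450/680 nm,
red-edge, NIR plateau, water troughs near 1450/1940 nm) plus Gaussian
perturbations whose amplitudes are linear in the standardized traits, each
trait loading onto several absorption features; signatures are damped if
needed so every pure spectrum keeps NDVI > 0.5. Pixels mix at most 3
species (weights proportional to local cover draws), with a lognormal
brightness factor, per-band within-species variability (default sd 0.005
reflectance — leaf-level variation that, unlike brightness, survives
vector normalization; without it clusters would be exact point masses, a
geometry no real canopy produces), additive sensor noise (default sd
0.002), and a soil fraction (default 0.1) of featureless ramp spectra with
NDVI < 0.2. One root seed fans out into fixed per-stage child streams so
stages are independently reproducible.

Assembly filtering is this package's construction, not taken from any
source: species are sampled with weight $\exp(-\phi z_i^2)$, $z_i$ the
standardized distance of the first trait to a site-level optimum. $\phi=0$
is neutral (used to verify SES calibration); large $\phi$ produces trait
clustering (negative SES, higher between-plot similarity within a site).
What the generator does *not* emulate: radiative-transfer leaf optics,
topographic/BRDF effects, phenology, spatial autocorrelation within plots,
and vertical canopy structure — so passing tests demonstrate internal
consistency of the estimators under a plausible mixture model, not
field-level accuracy.

## 8. Numerical choices and known limitations

* Ultrametricity tolerance $10^{-8}$ relative; distance matrices must be
  symmetric to $10^{-8}$ with zero diagonals.
* The dispersion metric errors on distances exceeding 1 after scaling
  rather than clipping.
* PAM is deterministic given a distance matrix; ties are broken by the
  BUILD order of the underlying implementation.
* Sensor-noise degradation of the richness association is *non-monotone in
  the slope*: moderate noise compresses the estimated cluster-number scale
  and can inflate the posterior-median $\beta$ of the richness-on-SS
  regression even as $\rho$ and $R^2$ fall (the inverse-regression
  analogue of attenuation); only at noise levels that destroy the spectral
  signal does $\beta$ collapse toward zero. Degradation claims are
  therefore evaluated at noise sd 0, 0.1 and 0.3.
* Problem sizes in the test suite are scaled to desk hardware: 60-band
  grids, 100–200-pixel subsamples, 200-plot landscapes, 999-replicate
  nulls, and reduced MCMC draws for replicate-heavy calibration checks;
  the estimators themselves are size-agnostic.
* The command-line surface is the R API plus `run_pipeline()` /
  `validate_config()`; this is an analysis package whose users script in
  R, so no shell executable is shipped.

```{r demo, eval = FALSE}
## a complete miniature run
man <- run_pipeline(list(scenario = list(n_sites = 3, plots_per_site = 14,
                                         pool_size = 30,
                                         richness_range = c(2, 6),
                                         wavelengths = seq(400, 2500, 30),
                                         grid_size = 10,
                                         trait_coupling = 0.2,
                                         max_species_per_pixel = 1),
                         n_null = 99, mcmc_iter = 800, pcd_reps = 200,
                         max_pixels = 80, k_max = 8, seed = 5))
```
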