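# gwHMrisk

Pollution indices, quantitative source apportionment and probabilistic
health-risk assessment for heavy metals (Cr, Mn, Fe, Cu, Zn, Cd, Pb) in
groundwater.

Groundwater surveys of trace metals typically need four analyses run as
one chain, and `gwHMrisk` packages that chain for R users (hydrologists,
environmental-health analysts, regulators):

1. **Pollution indices.** The weighted water quality index
   WQI = Σ Wᵢ·(100·Cᵢ/Sᵢ) against grade-III guideline values Sᵢ, banded
   excellent/good/poor/very poor/unfit, and the unweighted pollution
   evaluation index PEI = Σ Cᵢ/H_mac (low/medium/high).
2. **APCS/MLR receptor modelling.** KMO and Bartlett adequacy checks,
   varimax-rotated PCA on z-scored concentrations, absolute principal
   component scores (factor scores anchored at an artificial
   zero-concentration sample), per-metal least squares
   Cₙ = ξ₀ + Σₖ ξₖ·APCSₖ, and per-metal / overall source-contribution
   percentages.
3. **USEPA-style health risk.** Average daily doses by ingestion and
   dermal contact for adult males, adult females and children; hazard
   quotients HQ = ADD/RfD and the hazard index HI = ΣHQ; incremental
   lifetime cancer risk ILCR = ADD·CSF (1 − e^(−ADD·CSF) beyond 0.01)
   and TCR = ΣILCR for Cr, Cd, Pb.
4. **Monte Carlo uncertainty and source-oriented risk.** 10,000-trial
   simulation with lognormal concentration models and random exposure
   parameters, Table-style summaries (mean, median, SD, 95% CI,
   percentiles, exceedance probabilities), and apportionment of HI/TCR
   to pollution sources via the per-metal share matrix.

Because such surveys rarely release raw data, the package ships a
synthetic generator (`reference_synthetic_spec()`): a three-source
latent mixing model with lognormal scores, right-skewed marginals and
occasional Mn outliers, whose ground truth (`synthetic_truth`) lets the
whole chain be tested for parameter recovery. See
`vignettes/methods.Rmd` for the models, conventions, defaults and their
rationale.

## Worked example

```r
library(gwHMrisk)

sim <- generate_survey(reference_synthetic_spec(), seed = 42)
descriptive_stats(sim$table)[, c("metal", "mean", "sd", "cv_percent")]
#>  metal   mean     sd cv_percent
#>     Cr   5.20   3.30      63.50
#>     Mn 230.52 392.08     170.08
#>     Fe  29.87  18.72      62.68
#>     Cu   1.58   1.10      69.32
#>     Zn  22.32  12.74      57.07
#>     Cd   0.05   0.04      88.85
#>     Pb   2.15   1.57      73.12
```

Mn shows the heavy right tail (CV 170%) the generator is designed to
emulate. Index the water quality and apportion sources:

```r
res <- wqi(sim$table)
mean(res$per_site$wqi)                  # 41.85
table(res$per_site$class)
#> excellent  good  poor  unfit for drinking  very poor
#>        50     7     1                   1          1

apo <- apportion(sim$table, retention = "fixed", n_components = 3)
round(apo$kmo, 3)                       # 0.634
round(apo$overall, 2)                   # 41.44 34.06 24.49  (% per source)
```

Most sites are drinkable (WQI < 100) with a couple of hotspot sites, and
the three recovered factors carry roughly 41/34/24% of the metal load
(the generator's designed truth is ~36/28/36; recovery accuracy is
quantified in the test suite over 20 seeds). Risk, then risk by source:

```r
risk <- health_risk(sim$table)          # deterministic, on column means
sapply(risk, function(x) x$hazard$HI)
#> adult_male adult_female      child
#>      0.432        0.453       1.04
sapply(risk, function(x) x$cancer$TCR)
#>  4.97e-05      5.2e-05   2.49e-05

sr <- apportion_risk(risk, apo$contributions)
subset(sr$table, population == "child" & source != "unapportioned")
#>  population        risk_type source absolute percent
#>       child non_carcinogenic     F1 1.37e-01    13.4
#>       child non_carcinogenic     F2 1.77e-01    17.3
#>       child non_carcinogenic     F3 7.07e-01    69.3
#>       child     carcinogenic     F1 1.70e-06     6.9
#>       child     carcinogenic     F2 2.16e-05    87.4
#>       child     carcinogenic     F3 1.41e-06     5.7
```

Children carry the highest non-carcinogenic burden (HI near 1 in this
synthetic draw, driven by the Mn-heavy factor F3 at 69%), while all TCR
values sit in the "acceptable" 10⁻⁶–10⁻⁴ band, dominated by Cr (factor
F2 here). The Monte Carlo layer (`run_mc_risk()`) and the one-command
pipeline (`run_pipeline()`, or the `inst/cli/gwhmrisk` launcher with
subcommands `simulate | wqi | pei | apportion | risk | mc-risk |
source-risk | run-all`) produce the same quantities with uncertainty
summaries and a reproducible run manifest.

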