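---
title: "Poverty reduction benchmarks from health spending elasticities: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poverty reduction benchmarks from health spending elasticities: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(povbench)
```

## The problem

Out-of-pocket health payments are a major driver of impoverishment in low-
and lower-middle-income countries, and public health spending plausibly
protects households from poverty even though poverty reduction is not the
health sector's primary objective. povbench operationalizes a simple way to
put a price on that protection: estimate how strongly the national poverty
headcount responds to government health spending, and convert that response
into a *poverty reduction benchmark* (PRB) — the dollars of health-sector
spending associated with averting one case of poverty. The analogous cost
per poverty case averted of social-protection-and-labor (SPL) programs,
whose explicit purpose is poverty reduction, provides a yardstick for
judging whether the health-sector figure is of a reasonable order of
magnitude.

## The elasticity model

The estimating equation is a log-log country-fixed-effects panel
regression:

$$\ln(\mathrm{Pov}_{c,t}) = \alpha_c + \beta \,\ln(\mathrm{PHE}_{c,t-1})
  + \gamma' X_{c,t} + \varepsilon_{c,t}$$

where $\mathrm{Pov}_{c,t}$ is the poverty headcount ratio (proportion below
the $1.90/day 2011-PPP line), $\mathrm{PHE}_{c,t-1}$ is per-capita domestic
general government health expenditure (constant 2017 international $)
lagged one year, $X_{c,t}$ contains log GDP per capita and the Gini index,
and $\alpha_c$ absorbs all time-invariant country characteristics. $\beta$
is the elasticity of interest: the percent change in the poverty headcount
per one-percent change in lagged public health spending. Spending is lagged
because the consequences of investments are unlikely to be immediate; a
five-year lag is supported as a sensitivity, as is adding external health
expenditure to the spending aggregate.

`fit_fixed_effects()` implements the within estimator: each variable is
demeaned within country and the slopes obtained by OLS on the demeaned
data. Numerical choices that matter:

* **Degrees of freedom.** Residual degrees of freedom subtract one per
  country, so classical standard errors equal those of the explicit
  dummy-variable (LSDV) regression exactly; the test suite enforces this
  equivalence against an independent `lm()`-based LSDV oracle at 1e-8.
* **R-squared** is reported for the full model including the country
  intercepts (LSDV R²), the convention under which adding fixed effects
  visibly raises fit.
* **Variance.** Classical (homoskedastic) standard errors are the default,
  matching the convention of reporting unadjusted SEs under each
  coefficient; CR1 cluster-robust-by-country is available via
  `vcov_kind = "cluster_by_country"` because serial correlation within
  country is the realistic worry in this design. Whichever vcov the fit
  carries is the one propagated into benchmark uncertainty.
* **Degenerate inputs.** Countries reduced to a single usable row carry no
  within information and are dropped with a warning (lag construction
  routinely creates them); a regressor with no within-country variation
  leaves the demeaned design rank deficient and is a hard error naming the
  column. Time fixed effects are deliberately absent: the specification
  has country effects only.

The specification ladder — pooled bivariate OLS, fixed effects alone, fixed
effects plus controls — is fitted by the pipeline's `fit` stage and rendered
side by side, together with income-group-specific fits, since the
elasticity differs materially between low-income and lower-middle-income
countries.

## From elasticity to a benchmark

For a country with poverty headcount ratio $p$, population $N$, and
per-capita spending $\mathrm{PHE}$, a one-percent spending increase changes
the number of poor by $(\beta/100)\, p\, N$ and costs
$(1/100)\,\mathrm{PHE}\, N$. Dividing cost by cases averted gives the
country PRB:

$$\mathrm{PRB}_c = \frac{\mathrm{PHE}_c}{-\beta\, p_c},$$

in which both $N$ and the size of the percent increase cancel exactly (the
package computes the two-step ratio and tests the cancellation numerically
to 1e-12). Snapshots $(p_c, \mathrm{PHE}_c)$ are taken from each country's
last year of complete data. A non-negative $\beta$ implies no cases
averted; the benchmark is then flagged undefined rather than reported as a
negative price.

### Uncertainty propagation

Estimation uncertainty is propagated by sampling 1000 coefficient vectors
from a multivariate normal with mean equal to the fitted slopes and
covariance equal to the fitted variance-covariance matrix
(`sample_coefficients()`, which draws the full slope vector and extracts
the elasticity component — marginally identical to sampling the elasticity
alone). For each draw the unweighted mean PRB across countries is computed;
the median and the 2.5/97.5 percentiles of these iteration-means form the
point estimate and the 95% uncertainty range (UR). Two documented choices:

* **Draws with $\beta \ge 0$** are dropped from the summary and their count
  reported: an undefined price cannot enter an average. With standard
  errors of the size seen in practice such draws essentially never occur,
  but the policy must be explicit for the procedure to be reproducible.
* **Percentiles** everywhere use inclusive linear interpolation (R's
  `quantile()` type 7), so URs are bit-reproducible. One consequence worth
  noting: because the map $\beta \mapsto K/(-\beta)$ ($K > 0$) is strictly
  increasing on $\beta < 0$, quantiles of the iteration-means coincide with
  the map evaluated at the matching $\beta$ quantiles — exactly so whenever
  the percentile lands on an order statistic, and to interpolation error
  (~1e-8 relative at 1000 draws) otherwise. The test suite checks both
  regimes.
* **"Mean estimate"** is the mean of the iteration-means (consistent with
  the Monte-Carlo procedure); the benchmark evaluated at the point
  elasticity is also reported (`mean_at_point`) since the two differ
  slightly by Jensen's inequality.
* **Which fit feeds which column.** The all-countries column uses the
  pooled fit and each income-group column its own group-specific fit — the
  default because group elasticities and spending levels differ by orders
  of magnitude and a pooled coefficient would misprice the groups; a
  `beta_source = "pooled"` switch applies the pooled fit everywhere. The
  cross-country aggregation is an unweighted mean over countries, with
  population weighting available but off by default.

## SPL program costs

For each country, annual SPL program cost is
`coverage × population × annualized transfer per beneficiary`, and poverty
cases averted are `reduction × pre-transfer poverty × population` when the
reduction is expressed relative to pre-transfer poverty (the default), or
`reduction × population` when it is in percentage points. The ratio is
again independent of population. Because indicator extracts vary in units,
the transfer period (daily/monthly/yearly; annualization 365/12/1) and the
reduction kind are explicit declarations in the input schema rather than
guesses, and are echoed into the run manifest. Cross-country summaries
report the 10th percentile, median, mean, and 90th percentile per income
group and overall, under the same percentile convention as the PRB module.

## The synthetic study frame

`generate_panel()` simulates the estimating equation run forwards, with
known parameters, so that every stage — validation, lag construction,
filtering, estimation, benchmarking, reporting — is testable end to end
without any external download. The default frame mirrors the sample
structure the method targets: 63 countries (20 low-income, 43
lower-middle-income), poverty outcomes over 2002–2019 with a lag-source
record in 2001, country records thinned at random (default missing rate
0.25, giving realistically incomplete reporting), spending around $26 per
capita in low-income and $134 in lower-middle-income countries, GDP per
capita near $1,800/$5,900, Gini near 40, and i.i.d. log-poverty noise with
sd 0.3. Spending and GDP follow geometric paths with drift (4%/2% per year)
so logs are always defined; the Gini follows a slow random walk. One master
seed drives named substreams (panel, noise, missingness, SPL, benchmark
draws) so adding a stream never perturbs the others.

Two generator choices deserve explanation:

* **No clamping.** The generative model is linear in $\ln$ poverty, so
  unbounded Gaussian noise can push a draw above a headcount ratio of 1.
  The generator refuses to truncate — truncation would silently bend the
  data-generating process away from the model being estimated — and
  instead hard-errors, naming the offending draw. Configurations must
  therefore keep the log-poverty distribution several noise standard
  deviations below zero.
* **Poverty levels.** As a consequence, the default fixed effects centre
  group mean poverty near 0.13 (low) and 0.06 (lower-middle) — lower than
  the headcounts typical of the poorest countries — because with noise sd
  0.3 and realistic covariate dispersion, centring low-income poverty near
  0.5 would place roughly 1% of draws above 1 and abort essentially every
  replicate of a Monte-Carlo experiment. The group ordering and all
  spending/GDP/Gini magnitudes are preserved; only the poverty *level* is
  placed conservatively. What passing tests show is therefore estimator
  correctness and calibration under the model's own assumptions — not that
  real extracts satisfy those assumptions (real poverty series are
  bounded, serially dependent, and measured with revision error that the
  generator does not emulate).

`generate_spl_table()` draws SPL indicators from declared ranges and
precomputes each country's true cost from the declared formula, enabling
exact round-trip tests of the cost computation and sort-oracle tests of
the distribution summaries.

## Validation and filtering rules

Input records must carry positive spending (each record is either a
regressor row or a lag source); poverty must lie in (0, 1] when present,
GDP must be positive, Gini within [0, 100]. Records missing poverty, GDP,
Gini, or population are retained as incomplete — usable as lag sources —
and excluded from estimation rows; nothing is imputed. Records with
out-of-range values are rejected with machine-readable reason codes, and
duplicate (country, year) keys are a hard error. The estimation sample
keeps countries with at least two complete rows since 2000 (both bounds
configurable). The lag source must exist at exactly $t-k$; a
nearest-available-year fallback was considered and rejected because it
would make the lag length data-dependent and irreproducible across
extracts. Population may be missing for estimation but is required at the
benchmark stage, which re-checks it.

## Problem sizes and reproducibility

The test suite sizes its experiments to run in well under a minute each:
the estimator/oracle equivalence uses 50 random panels of up to 10
countries × 5 years; the calibration experiment uses 200 replicates of the
63-country × 10-year frame (bias tolerance 0.02, coverage within
[0.90, 0.99]); Monte-Carlo benchmark checks use 1000–1001 draws. The
pipeline writes every artifact with the config hash and master seed in the
manifest and no wall-clock timestamps, so rerunning with an identical
configuration reproduces all CSV/JSON outputs byte-for-byte.

## Limitations

The fixed-effects association is not causal: time-varying confounders
(political change, development assistance) are uncontrolled, and the
package deliberately contains no dynamic-panel or instrumental-variable
machinery. PRBs inherit all limitations of the headcount ratio as an
outcome, and SPL indicator extracts are not fully comparable across
countries. The benchmark is a descriptive planning quantity — a yardstick,
not a price.
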