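---
title: "Bottled-water contaminant analysis and ingestion risk: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bottled-water contaminant analysis and ingestion risk: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquarisk)
```

# The problem

Bottled water is screened for anions (nitrate, nitrite) and elements
(Ba, Be, Ca, Fe, K, Li, Mg, Mn, Mo, Na) by ion chromatography and
ICP-OES. Three features make the resulting tables statistically
awkward:

* **left-censoring** — a sizeable fraction of measurements is reported
  only as "below the limit of detection" (`<LOD`), so naive means and
  tests are biased;
* **strong right skew** — concentrations across brands span orders of
  magnitude (nitrate 0.28–38.87 mg/L in the packaged survey), so
  normal-theory methods are inappropriate;
* **structured grouping** — brands belong to product classes (bottled
  drinking water, BDW, vs bottled mineral water, BMW) and samples to
  seasons, and the questions of interest are contrasts across these
  groups.

aquarisk implements the standard workflow on such data: descriptive
summaries honouring censoring, compliance screening against
regulatory limits and label claims, rank-based group comparisons, and
probabilistic ingestion-risk assessment.

# Data model and censoring rules

A concentration record is one brand x season x analyte measurement
with a `censored` flag; a censored record stores the analyte's LOD as
its value — the bound, not an observation. Fixture tables print
rounded bounds (`<0.1` for Ba whose LOD is 0.098 ug/L); the reader
normalises these to the registry LOD so the invariant "censored value
= LOD" holds exactly.

Two deliberately distinct rules govern summaries:

* **detected** means "not censored", even when the printed value is
  0.0 ug/L (a value below print precision but above the LOD). This is
  what reproduces the survey's detection counts (Li in 21 of 30
  brands, Fe in 2).
* **the mean over detected values** additionally requires the value to
  be strictly positive, which is what reproduces the printed group
  means (Li 2.52 ug/L in BDW excludes the 0.0 entry).

Each analyte lives in its table-header unit (mg/L for nitrate,
nitrite, Ca, K, Mg, Na; ug/L for the trace elements). `convert_units()`
moves between the two scales; risk assessment always converts to mg/L
first, and label comparisons to the label convention (mg/L).

For procedures that need a complete numeric sample (rank tests, the
Monte-Carlo stage), censored values are substituted by LOD/2 by
default — the common convention at low censoring fractions —
with `lod` and `drop` available. Kaplan–Meier/ROS censored-mean
estimators are intentionally out of scope (the exclusion rule above
is the survey's own convention); `substitute_censored()` is the seam
where they would plug in.

# Compliance

Both regulatory and label comparisons use a strict `>`: a measurement
exactly at the limit complies. This is the reading under which the
packaged survey has exactly one regulatory violation (nitrite
0.13 mg/L vs the 0.1 mg/L national limit in one BDW brand in summer)
rather than several borderline ones.

Label claims compare at brand level. Since elements are stored as
season-pooled brand values while anions are per-season, the
`aggregation` setting maps multi-season measurements to one
comparison value; the default `brand_max` ("a brand exceeds its label
if any season does") is a documented choice, not something the data
dictate — the survey's own exceedance percentages are not exactly
recoverable from its printed tables under any simple rule we tried
(`brand_max`, `brand_mean`, `per_season`). Under `brand_max` the
packaged fixtures yield the survey's reported exceedance lists plus
three extras implied by the printed numbers themselves: one extra Na
brand (measured 12.32 vs label 11 mg/L) and two extra Mg brands, one
of which follows from taking a printed label value of literally `0`
at face value. Labels with no value for an analyte leave that
analyte's denominator entirely.

# Risk assessment

Chronic daily intake and hazard quotient are

$$\mathrm{CDI} = \frac{C \cdot IR \cdot EF \cdot ED}{BW \cdot AT},
\qquad \mathrm{HQ} = \frac{\mathrm{CDI}}{RfD},$$

with the exposure profiles children (IR 1 L/day, BW 15 kg, ED 4 y)
and adults (IR 2 L/day, BW 70 kg, ED 40 y), EF 365 days/year and
AT = ED x EF. Under that averaging-time convention CDI reduces to
$C \cdot IR / BW$; the implementation computes both forms, asserts
agreement, and returns the reduced form, which makes CDI exactly
invariant to joint changes of ED and EF — and fixes the
children-to-adults CDI ratio at $(1/15)/(2/70) = 7/3$ for any
concentration.

The Monte-Carlo stage separates the **distribution model** from the
**simulation**. `fit_distribution()` supports:

* `empirical_bootstrap` (default) — resamples the substituted value
  multiset; makes the fewest assumptions;
* `lognormal` — maximum likelihood on the log scale of positive
  values; appropriate given the observed skew;
* `normal` — moment fit, truncated at zero when sampling (documented:
  drawn concentrations are never negative);
* `degenerate` — returned automatically whenever all substituted
  values are equal (e.g. an all-censored analyte under the `lod`
  rule), whatever family was requested.

`simulate_hq()` draws `n_iter` (default 10,000) concentrations with
an explicit seed recorded in the result, maps them through CDI and
HQ, and reports percentiles (default 5/50/95) using the
linear-interpolation order statistic at position
$h = (n-1)p/100 + 1$ (percentile conventions differ across tools;
this one is stated and tested). Because RfD is a constant, every HQ
percentile equals the matching CDI percentile divided by RfD — an
identity the tests assert on every run rather than a numerical
coincidence.

`risk_report()` pools concentrations across water types and seasons
(risk is reported per analyte per age group, not per product class),
skips analytes without an RfD or without a single detected value (Be
and Mo in the packaged survey are all-censored and are skipped with a
message), and runs each analyte x group simulation under a distinct
deterministic offset of the base seed.

**Limitation.** The survey this package transcribes reported
95th-percentile CDIs from a commercial Monte-Carlo tool without
stating the fitted distribution family. Its printed nitrate values
imply a fitted 95th percentile (~16.7 mg/L) below the empirical 95th
percentile of its own printed concentrations (~20 mg/L), so whatever
family it fitted shrank the tail; that choice is not recoverable.
The bootstrap default therefore reproduces the printed 95th-percentile
HQs only approximately (nitrate/children: bootstrap ≈ 0.84 vs printed
0.69; both well below 1), and the package's exact checks target the
deterministic CDI→HQ arithmetic instead.

# Rank-based tests

The Kolmogorov–Smirnov gate (`ks_normality`) computes the one-sample
distance against a normal with the sample mean and SD and the
asymptotic KS p-value; with estimated parameters this p is
anti-conservative (a Lilliefors table would reject more often), which
is acceptable for its role here — motivating rank tests, not
certifying normality.

`mann_whitney_u()` uses exact enumeration of the permutation null
over pooled midranks when both groups have at most 10 values, and
otherwise the tie-corrected normal approximation with **no continuity
correction** (matching the convention of the SPSS output the survey
reported). The two paths agree to within about half the probability
mass of one U atom (~0.03 at n = 10); the exact path is verified
against independent brute-force enumeration by pairwise counting.
`kruskal_wallis()` computes the tie-corrected H against chi-square
with k − 1 degrees of freedom; with two tie-free groups its p equals
the U test's two-sided normal p exactly (H = z²), which the tests
check. Censored values enter rank tests at half-LOD; the resulting
ties among censored records are exactly what the tie corrections
handle. Two-sided alternatives and α = 0.05 throughout; no
multiple-testing adjustment (none is part of the workflow being
reproduced).

`compare_groups()` compares BDW vs BMW per analyte (brand values for
the season-pooled elements, brand x season values for anions) and
summer vs winter for per-season analytes — defaults chosen because
the granularity of the underlying figures is not stated; both
granularities are reachable through the underlying functions.

# Synthetic data

`generate_dataset()` draws
$\log C = \mu_a + b_{\text{brand}} + s\,[\text{summer}] +
\varepsilon$, with $b \sim N(0, \sigma_b^2)$ a per-brand effect,
$s = \log(\text{season multiplier})$ and
$\varepsilon \sim N(0, \sigma_a^2)$, then censors draws below the
configured LOD. Lognormality is the generative choice because the
real tables span orders of magnitude with a long right tail; defaults
(15 brands per type, two seasons, brand SD 0.5, summer multiplier
1.3, nitrate-/nitrite-/Ba-like parameter rows) mirror the survey's
design and observed spread. The generator returns the realized
ground-truth parameters and a matching registry, so tests can check
recovery: the detected mean against $e^{\mu + \sigma^2/2}$, the
simulated 95th-percentile HQ against
$e^{\mu + z_{0.95}\sigma} \cdot (IR/BW)/RfD$, label exceedance
fractions against their closed-form probability under lognormal label
noise, and byte-identical CSV output under a fixed seed.

What a green synthetic test does **not** establish: the generator has
no inter-analyte correlation, no spatial/aquifer structure, and
independent lognormal noise per sample — real surveys violate all
three. It validates the pipeline's arithmetic and plumbing, not the
realism of any particular survey.

# Numerical and design choices

* Percentile convention: type-7 linear interpolation (stated above).
* Exact-test threshold: enumeration up to 10 per group
  (`choose(20, 10)` ≈ 1.8e5 assignments, still instant); beyond that
  the approximation error is far below test-relevant scales.
* Degenerate inputs: constant samples short-circuit to the degenerate
  family; constant groups give H = 0, p = 1 in Kruskal–Wallis; the KS
  gate rejects constant samples as a precondition.
* Seeds: every stochastic function takes an explicit seed, records it
  in its result, and restores the caller's RNG state, so library use
  never perturbs a session's randomness.
* All six fixtures are plain text inside the package; fixture byte
  fidelity is tested by write-then-read round trips at the record
  level (printed censoring bounds are normalised to LODs, see above).
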