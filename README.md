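# aquarisk

Analysis toolkit for bottled-water contaminant surveys with
left-censored concentration data, and for the non-carcinogenic health
risk those contaminants pose to consumers.

It is written for the workflow food-safety and environmental-health
groups use when they screen bottled drinking water (BDW) and bottled
mineral water (BMW) brands across seasons: summarise detection rates
and concentrations of anions (nitrate, nitrite) and elements (Ba, Be,
Ca, Fe, K, Li, Mg, Mn, Mo, Na), check the measurements against
national (INSO) and WHO limits and against the bottle-label claims,
compare groups with rank-based tests, and propagate concentration
variability into ingestion risk by Monte-Carlo simulation.

The package ships a transcription of a two-season survey of 30
brands (15 BDW + 15 BMW, 120 anion samples) as fixtures, so the whole
pipeline runs out of the box, and a synthetic-data generator with
known ground truth for end-to-end testing.

## The model

Chronic daily intake of an analyte at concentration `C` (mg/L) through
drinking-water ingestion is

```
CDI = C x IR x EF x ED / (BW x AT)      [mg/kg bw/day]
```

with IR the ingestion rate (1 L/day children, 2 L/day adults), EF the
exposure frequency (365 days/year), ED the exposure duration (4 y
children, 40 y adults), BW the body weight (15 / 70 kg) and AT the
averaging time. For non-carcinogenic risk AT = ED x EF, so CDI
reduces to `C x IR / BW`. The hazard quotient is

```
HQ = CDI / RfD
```

where RfD is the analyte's oral reference dose (e.g. 1.6 mg/kg/day
for nitrate, 0.1 for nitrite, 0.2 for Ba); HQ > 1 flags potential
adverse effects. The Monte-Carlo stage draws 10,000 concentrations
from a distribution model fitted to the survey values (empirical
bootstrap with half-LOD substitution by default; lognormal, truncated
normal and degenerate families available) and reports percentiles of
CDI and HQ, conventionally the 95th.

Values below the limit of detection (LOD) are kept as left-censored
records; detection rates count them as non-detects, means are taken
over detected positive values, and the simulation substitutes LOD/2
(configurable).

## Worked example

```r
library(aquarisk)

elements <- rbind(load_fixture("table2"), load_fixture("table3"))
detection_rate(elements, "Ba")
#>   analyte n_total n_detected detection_rate
#> 1      Ba      30         23      0.7666667

mean_detected(elements, "Ba", "water_type")
#>   water_type analyte n_used mean_detected
#> 1        BDW      Ba     13      11.30231
#> 2        BMW      Ba     10      15.71000

check_regulatory(load_fixture("table1"), source = "INSO")
#>   brand season analyte measured limit source exceeds
#> 1 BDW13 summer nitrite     0.13   0.1   INSO    TRUE

rr <- risk_report(load_survey(), n_iter = 10000, seed = 7)
rr[rr$analyte == "nitrate", c("analyte", "group", "cdi_p95", "hq_p95", "flagged")]
#>   analyte    group   cdi_p95    hq_p95 flagged
#> 1 nitrate children 1.3506667 0.8441667   FALSE
#> 2 nitrate   adults 0.5788571 0.3617857   FALSE
```

Reading the output: Ba was detected in 23 of the 30 brands (76.6 %),
averaging 11.30 ug/L across the BDW brands where it was detected and
15.71 ug/L across the BMW brands. The only regulatory exceedance in
the whole survey is nitrite in brand BDW13 in summer (0.13 mg/L
against the 0.1 mg/L national limit). The bootstrap 95th-percentile
hazard quotient for nitrate is 0.84 for children and 0.36 for adults
— below 1, so no appreciable non-carcinogenic risk, with children the
more exposed group (their CDI is 7/3 times the adult CDI at any
concentration).

The full pipeline — summary, compliance, rank tests, risk — with CSV
outputs and a run manifest:

```r
run_pipeline(pipeline_config(output_dir = "run1", seed = 1))
```

or from the shell via the launcher `inst/scripts/aquarisk`:

```sh
Rscript inst/scripts/aquarisk run-all --out run1 --seed 1
```

## Documentation

`vignette source: vignettes/bottled-water-risk.Rmd` describes the
statistical model, the censoring rules, the Monte-Carlo design and its
limitations, and the synthetic-data generator.
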