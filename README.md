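# maternalsim

An individual-based (microsimulation) model of maternal and perinatal health
and maternity-service delivery in a constrained health system, patterned on
Malawi. It is written for epidemiologists and health-systems modellers who
want to ask counterfactual questions of the form *"what happens to maternal
and newborn outcomes if the coverage, or the quality, of antenatal,
intrapartum or postnatal care changes?"* — at desk scale, fully reproducibly,
with paired Monte Carlo runs.

## What the model computes

Each simulated person carries demographic and pregnancy state. Monthly,
women conceive, pregnancies progress through gestational-age-specific risks
of complications (anaemia, hypertensive disease, haemorrhage, sepsis,
obstructed labour, uterine rupture, stillbirth, preterm birth, neonatal
encephalopathy, respiratory distress, neonatal sepsis, ...), and care is
sought and delivered through discrete health-system interaction events.

The core mechanisms, in the field's standard notation:

- **Risk composition.** Onset probability `p = min(1, p0 * prod(RR_j))` —
  a baseline per-timestep risk scaled by multiplicative relative risks from
  comorbidity and prevention (e.g. malaria -> preterm labour, IPTp -> less
  malaria).
- **Quality of care.** An indicated intervention is delivered iff all its
  consumable-availability draws, the clinical-competence draw and (for
  BEmONC/CEmONC interventions) the trained-staffing draw succeed:
  `P(delivered) = prod(avail_i) * competence * staffing`.
- **Squeeze and the three delays.** Per event,
  `squeeze = required_minutes / available_minutes - 1` against a depleting
  daily nursing-time ledger; delay three occurs iff `squeeze > 3` (strict).
  Delays one and two are fixed-probability draws.
- **Mortality.** An episode's case fatality under `k` delays and delivered
  treatments with relative risks `rr`:
  `CFR_eff = CFR * prod(1 - (1 - rr) * (1 - a)^k)`, attenuation `a = 0.25`.
- **DALYs.** Disability weights combine additively, capped at 1.0 under
  multimorbidity; YLL from a reference life table; `DALY = YLD + YLL`.
- **Rates.** MMR per 100,000 live births, NMR per 1,000 live births, SBR per
  1,000 total births.
- **Reporting.** Mean-of-annual-means over the reporting period per run;
  across-run 95% t confidence intervals; scenario-minus-comparator
  differences taken run-wise on shared seeds; percentage differences
  *withheld* when the difference CI contains 0; maximum ability to pay =
  significantly averted DALYs x a cost-effectiveness threshold of $62.3.

Sixteen scenarios (a status quo `"SQ"`, plus coverage / coverage-and-quality /
maximised / withdrawn variants of each service and of all services together)
are encoded as override bundles effective 1 January 2023. All randomness
flows through a counter-based RNG keyed by (seed, person, time, event), so
paired runs across scenarios share event-level random numbers — paired
differences are tight and every run is exactly reproducible.

## A worked example

Simulate the status quo against fully maximised services — a model population
of 7,000 persons (1:2000 scale), four paired runs, horizon 2021–2027 with the
scenario switch at 2023 — and summarise 2023–2027:

```r
library(maternalsim)

ps  <- generate_default_parameters()
cfg <- simulation_config(scenarios = c("SQ", "All services max."),
                         n_pop = 7000, ratio = 2000,
                         start_year = 2021, end_year = 2028,
                         runs = 4, base_seed = 1, parameters = ps)
out <- pipeline_end_to_end(cfg, years = 2023:2027)
out$summary[out$summary$outcome %in% c("mmr", "nmr"), ]
```

```
          scenario outcome  mean    lo    hi   diff diff_lo diff_hi pct_diff withheld
 All services max.     mmr  68.0  -4.2 140.2 -275.1  -387.2    -163    -80.2    FALSE
                SQ     mmr 343.2 166.4 519.9     NA      NA      NA       NA       NA
 All services max.     nmr   8.3   4.2  12.3   -7.5    -9.9      -5    -47.5    FALSE
                SQ     nmr  15.7  12.3  19.2     NA      NA      NA       NA       NA
```

Under the status quo the maternal mortality ratio averages 343 per 100,000
live births and the neonatal mortality rate 15.7 per 1,000; maximising the
coverage and quality of every service cuts them by 80% and 47% respectively,
and both paired-difference confidence intervals exclude zero, so the
percentage differences are reported rather than withheld. The economics
report prices the averted DALYs at the cost-effectiveness threshold:

```r
out$economics
```

```
           scenario dalys_averted max_ability_to_pay_usd pct_of_spending
1 All services max.       1296119               80748227              NA
```

i.e. about 1.30 million DALYs averted over 2023–2027 at this desk scale, for
a maximum ability to pay of ~$80.7 million. (Counts are rescaled by the
model-to-real ratio; rates are scale-free. At a 1:2000 ratio with four runs
the per-run maternal death counts are small, which is why the MMR intervals
are wide — the paired differencing is what makes the contrast significant.)

Other entry points: `simulate_run()` (one run, full annual detail),
`build_scenario()` / `apply_scenario()`, `write_parameters()` /
`read_parameters()` (CSV + YAML round trip), `tune_parameters()`
(calibration to coverage targets), `coverage_statistics()`, and the
summary/economics primitives (`across_run_summary()`,
`paired_difference_summary()`, `gated_percentage_difference()`,
`tally_contacts_and_hours()`, `max_ability_to_pay()`,
`project_total_health_spending()`). The methods vignette
(`vignettes/maternal-microsimulation.Rmd`) documents the model, parameter
defaults and design decisions.

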