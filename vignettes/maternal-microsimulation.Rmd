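---
title: "An individual-based model of maternity services in a constrained health system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based model of maternity services in a constrained health system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`maternalsim` simulates, person by person, the pregnancy, labour and early
postnatal period of a population resembling Malawi's, together with the
maternity services that population uses. Its purpose is counterfactual
analysis: what happens to the maternal mortality ratio (MMR), the neonatal
mortality rate (NMR), the stillbirth rate (SBR) and disability-adjusted life
years (DALYs) when the coverage or the quality of antenatal, intrapartum or
postnatal care is raised, maximised, or withdrawn. This vignette describes the
model, its assumptions, the parameters that matter, and the design decisions
taken where more than one reasonable choice existed.

## The natural-history model

Time advances on a monthly master clock. Each month, women of reproductive age
(15–49) who are neither pregnant nor within the six-week postnatal window
conceive with an age-band-specific monthly probability; the bands are constants
chosen so the crude birth rate lands near 35 per 1,000 — the simplest device
consistent with fertility driven by contraceptive use and fecundity, which this
package deliberately does not model mechanistically.

A pregnancy is then exposed, month by month, to gestational-age-windowed onset
risks for the modelled antenatal conditions: ectopic pregnancy and abortion
complications (which end the pregnancy), maternal anaemia, gestational
diabetes, syphilis, malaria in pregnancy, the hypertensive spectrum (mild and
severe gestational hypertension, mild and severe pre-eclampsia, eclampsia),
antepartum haemorrhage, antenatal sepsis, and antepartum stillbirth. Onset
probabilities compose multiplicatively:

$$p = \min\!\left(1,\; p_0 \prod_j RR_j\right)$$

where the relative risks $RR_j$ come from a data-driven link table (for
example malaria → preterm labour, malaria → anaemia, untreated obstructed
labour → uterine rupture, caesarean section → postnatal sepsis, syphilis and
severe pre-eclampsia → stillbirth). Multiplicative composition on the
probability scale with clipping at 1 is the simplest reading of "relative
risks modify baseline risks"; no link function is assumed. Hypertensive
disease progresses one severity step per month at configured probabilities
(mild → severe pre-eclampsia → eclampsia; mild → severe gestational
hypertension), halved under delivered antihypertensive therapy.

Labour begins preterm (monthly draws in gestational months 7–8), at term, or
post-term (a 5% continuation draw at month 9). The classifier uses the
standard obstetric cut-points — preterm below 37 completed weeks, post-term at
42 — which the underlying framework leaves implicit. Intrapartum draws cover
obstructed labour, uterine rupture, intrapartum sepsis, eclampsia, antepartum
haemorrhage and intrapartum stillbirth; rupture and stillbirth are drawn after
treatment of the other complications is resolved, because their risks depend
on whether obstruction was relieved. Mothers then pass through six weekly
postnatal cycles (primary postpartum haemorrhage at birth, secondary
haemorrhage and sepsis weekly) and newborns through four (respiratory distress
syndrome and encephalopathy at birth only, sepsis weekly), telescoped into the
delivery month for accounting. Telescoping means a postnatal death is tallied
to the year of delivery even when the 42-day window crosses a year boundary —
an approximation that matters only at that boundary — and that the delay draws
made at delivery carry over to the postnatal emergency care of the same birth.

## The health-system model

Care seeking for routine services (antenatal initiation, facility delivery,
maternal and newborn postnatal checks) follows multivariable logistic
regressions over centred sociodemographic covariates: wealth quintile,
education, urban residence, parity and age. The intercepts are, by design, the
calibration surface: the default coefficients give population coverage close
to 51% for four-or-more antenatal contacts (ANC4+), 91% facility delivery,
42% maternal and 60% newborn postnatal care. The antenatal schedule draws the
first contact's gestational month from a configured distribution (mode at
month 4) and attends each subsequent monthly contact with a transition
probability (default 0.82), to a maximum of eight contacts. Emergency care
seeking after a complication is a single Bernoulli probability (default 0.65,
a plausible mid-range value; the source estimate for this setting is not
printed in the main literature available here, so it is exposed as a
calibration knob).

Every service contact is a discrete health-system interaction (HSI) with a
facility level, required consumables, and healthcare-worker minutes by cadre
(12 minutes of nursing/midwifery time per ANC contact, 15 per PNC contact).
An indicated intervention is actually delivered only if three independent
draws all succeed: every required consumable is available (item-wise
probabilities, roughly 0.5–0.8), the clinician recognises the need
(competence, roughly 0.7–0.9), and — for interventions classified as basic or
comprehensive emergency obstetric and newborn care (BEmONC/CEmONC) — suitably
trained staff are present. Comprehensive interventions (caesarean section,
obstetric surgery, blood transfusion) additionally require a hospital; there
is no inter-facility referral, so a woman labouring in a health centre cannot
receive them. A missing item blocks only the interventions that need it.

The three-delays framework is explicit. Delays one and two (deciding to seek
and reaching care) are fixed-probability draws (defaults 0.35 and 0.30,
placeholders standing in for institutional survey estimates and exposed as
knobs). Delay three arises from the "squeeze" on healthcare-worker time:
events on a simulated day consume a facility-level nursing budget in queue
order, and each event's squeeze factor is

$$\text{squeeze} = \frac{\text{required minutes}}{\text{remaining minutes}} - 1,$$

with delay three triggered when the squeeze strictly exceeds the threshold
(default 3; boundary equality does not trigger — "exceeds" is read strictly).
The daily budgets are expressed per 1,000 model persons so the mechanism is
approximately invariant to the simulated population size; squeeze is computed
for acute events (deliveries, emergencies), while routine contacts consume
minutes for the time-accounting outputs. Only the nursing/midwifery cadre
enters the squeeze ratio; clinician minutes are recorded for accounting.

Delays do not add a time-to-care clock; they attenuate treatment. With $k$
delays experienced and a treatment of relative risk $rr$, the case-fatality
risk of an episode becomes

$$\text{CFR}_\text{eff} = \text{CFR} \times \prod_\text{treatments delivered}
\Big(1 - (1 - rr)\,(1-a)^k\Big),$$

with attenuation $a = 0.25$ per delay by default. The functional form —
shrinking the treatment *effect* toward null, never harming beyond the
untreated risk — is a package choice; the direction (delays reduce treatment
effectiveness) is the modelled assumption, the shape is not dictated by it.

## Scenarios

Sixteen named scenarios bundle overrides that take effect on 1 January 2023:
a status quo (SQ) comparator; for each of the antenatal, intrapartum and
postnatal services a coverage-only increase, a coverage-plus-quality
increase, a maximised variant and a withdrawn variant; and four "all
services" composites defined as the union of their component bundles.
Coverage targets (e.g. 90% ANC4+ or early PNC) are met by recalibrating the
care-seeking intercept — for ANC also the visit-transition odds, by the same
shift — against the covariate distribution of the current population, so
sociodemographic gradients persist rather than forcing individuals. "Max."
variants instead pin probabilities to 1: all quality factors, emergency care
seeking, and (for intrapartum care) facility delivery. Because those
scenarios stipulate that all required care is sought and received at once,
they also disable delays one and two for the affected services, alongside the
stated disabling of delay three; scenario delivery-probability overrides
(e.g. "set at 90%") replace the whole quality product and are read literally,
bypassing the hospital gate for comprehensive interventions. Care following
ectopic pregnancy or abortion is never modified by any scenario. "Min."
variants zero the service: no routine contacts, no emergency care seeking for
the period (intrapartum: intervention delivery probabilities set to 0 while
facility attendance is unchanged).

## Randomness and pairing

Every stochastic decision draws its uniform from a counter-based generator
keyed by (run seed, unit id, time index, event channel) rather than from a
sequential stream. Two consequences matter. First, runs are exactly
reproducible from their seed regardless of execution order. Second, paired
runs of different scenarios that share a seed consume the *same* uniform for
the same person-time-event, so a scenario that only shifts a probability
produces nested event sets: every death under maximised services is also a
death under the status quo. This is common-random-numbers variance reduction,
and it is what makes paired scenario differences informative at desk scale;
the residual noise in a paired difference is the count of "flipped" events,
which at small populations still dominates the confidence intervals for rare
outcomes such as maternal death.

## Outcomes

Disability weights attach to condition episodes and are combined additively
with a cap at 1.0 under multimorbidity; years lived with disability accrue as
capped per-person-month weights divided by 12, using per-condition default
episode durations. Years of life lost use a packaged synthetic reference life
table with a GBD-standard shape (expectancy 62.7 years at birth); stillbirths
accrue neither. There is no age weighting and no discounting. Rates follow
the standard definitions — MMR per 100,000 live births, NMR per 1,000 live
births, SBR per 1,000 total births by default (a live-birth denominator is
available, since published tables are ambiguous at printed rounding).
Maternal deaths are those in pregnancy or within 42 days of its end; neonatal
deaths within 28 days of birth.

The aggregation layer reproduces the reporting conventions of this model
family: per-run means of annual outcomes over the reporting period
(2023–2030 in the full design), then across-run means with 95% confidence
intervals (t quantiles on n−1 degrees of freedom by default; a
normal-quantile mode exists because the convention is not always stated),
scenario-minus-comparator differences computed run-wise on matched seeds, and
percentage differences *withheld* whenever the difference's interval contains
zero. Maximum ability to pay multiplies significantly averted DALYs by a
cost-effectiveness threshold of $62.3 per DALY; total health spending
projections compound per-capita spending from 2015 at 0.9% a year.

## Calibration

The default parameter values were set by explicit arithmetic: cause-specific
incidence times case fatality, degraded by realistic treatment coverage, was
targeted to land the status-quo MMR in the mid-300s to mid-400s per 100,000,
the NMR near 17 per 1,000 and the SBR near 17–20 per 1,000, with the
maximised and withdrawn service scenarios bracketing the status quo roughly
as published comparisons of this kind do. None of the values is claimed to
equal an externally calibrated estimate. `tune_parameters()` automates the
remaining fit as bounded multiplicative coordinate descent: knobs act on the
odds scale for care-seeking intercepts (the ANC knob also moves the
transition odds) and on the probability scale for risks and case fatality,
with cumulative factors confined to [0.1, 10], a step-doubling line search,
acceptance only on loss reduction, and a full audit trace. The loss is
weighted relative squared error against hard-coded coverage targets
(51/91/42/60). The simulated statistic fed to the loss is deterministic given
its seed, so the optimisation surface is stable; verification in the test
suite re-measures coverage on an independent cohort seed.

## Problem sizes

The package's desk-scale profile — the one used throughout the tests and the
acceptance script — is a model population of 7,000 at a model-to-real ratio
of 1:2000, four paired runs per scenario, and a 2021–2027 horizon with the
intervention at 2023. These sizes keep a full three-scenario experiment under
a minute while leaving enough births (roughly 1,100 per run) for the paired
mortality contrasts to be resolvable. The full-scale design this mirrors uses
a 1:58 ratio, twenty runs and a 2010–2031 horizon; nothing in the code is
specific to the reduced sizes.

## What the synthetic data can and cannot show

The fixture population reproduces configured marginals (sex ratio, a
geometric-decay age pyramid, uniform wealth quintiles, education, urban
residence, parity rising with age, comorbidity flags) but not their joint
structure in any real survey, no districts, no migration, and no secular
trends. Consumable availability is a constant per item, not a stock-out
process. Passing tests therefore demonstrate that the mechanisms — risk
composition, quality gating, delays, the squeeze, the statistical layer —
behave as specified and that the calibrated layer meets its coverage targets;
they do not validate the parameter values against real Malawian data, which
would require the survey and facility-assessment sources themselves.

## Known limitations

No referral between facilities, private-sector care, transport delays or
counselling interventions; no bed-day constraint (bed days are recorded but
never bind); no costing of services; no congenital anomalies, haemolytic
disease or non-sepsis maternal infections; maternal morbidity beyond the
modelled windows carries no lasting disability; postnatal emergencies reuse
the delivery-time delay draws (see telescoping above); and the squeeze is
computed on a single pooled budget per facility level rather than per
facility.
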