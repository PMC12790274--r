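---
title: "Methods: cost-effectiveness microsimulation of AI-based opportunistic osteoporosis screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-effectiveness microsimulation of AI-based opportunistic osteoporosis screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoscreen)
```

## The question the model answers

South Korean adults aged 50+ frequently receive chest radiographs for
unrelated reasons (biennial national health screening, routine care). A
deep-learning classifier can read those images for likely osteoporosis at
the marginal cost of the AI analysis alone — no new imaging, no extra
radiation. The package quantifies whether one such opportunistic AI read at
model entry, followed by confirmatory DXA and pharmacological treatment in
those who follow through, is good value compared with no screening: the
cost per quality-adjusted life year (QALY) gained, in 2025 Korean Won.

## Model structure

**Screening cascade (decision tree).** Each screened individual is flagged
with probability equal to the test's sensitivity (0.8616) if osteoporotic
and one minus its specificity (0.7419) otherwise. Flagged individuals
undergo DXA with probability 0.60; DXA is modelled as a perfect reference
(it is the diagnostic gold standard and no error rates are available for
it in this setting), so false-positive AI flags incur the DXA cost but can
never be treated. Confirmed cases start treatment with probability 0.50,
drawn into alendronate (67.2%) or denosumab (32.8%), fixed thereafter.
The AI read (KRW 15,000, 30% of a DXA) is charged to *every* screened
person — the radiograph itself already exists, so only its analysis is a
cost of the programme. Screening happens once, at entry.

**Microsimulation (annual cycles, horizon age 105).** Each individual's
state tracks age, sex, osteoporosis status, fracture history (counts,
years since last event, worst site ever), treatment clocks and
nursing-home residence. Cycle order:

1. *Fractures.* Hip, vertebral and non-hip-non-vertebral (NHNV) events are
   sampled independently (several sites may fracture in one year). The
   per-site rate is: baseline incidence (sex × site × 10-year age band) ×
   T-score relative risk if osteoporotic × subsequent-fracture multiplier
   (a function of years since the last fracture and the number of prior
   fractures) × effective treatment relative risk; the rate becomes a
   probability via $1 - e^{-\text{rate}}$.
2. *Death.* Baseline life-table probability $q_x$, plus
   attribution-scaled excess: a first-year additive excess in the cycle of
   a hip/vertebral fracture, or a hazard-ratio multiplier on $q_x$
   (declining to 1 over 10 years) for prior hip/vertebral history. Only
   25% of that excess is causally attributed to the fracture; NHNV events
   carry none.
3. *Costs.* First-year fracture costs per event (charged per event even
   when several sites fracture); on a hip event, 10% enter a nursing home
   permanently (KRW 8,103/day thereafter); drug, monitoring
   (physician/pharmacy visits, BMD monitoring) and adverse-event costs
   (extra GP visits plus PPI courses, alendronate only) while on
   treatment.
4. *Utility.* Age-interpolated baseline utility times a single
   post-fracture multiplier — only the most severe fracture counts
   (severity hip > vertebral > NHNV): the first-year multiplier in an
   event cycle, the worst-ever site's subsequent multiplier in all later
   cycles. Death contributes half a cycle of utility and life-years.
5. *Discounting* at 4.5%/year, evaluated at the cycle midpoint; cascade
   costs sit at $t=0$ undiscounted.
6. *Clock advancement*, including treatment-year boundaries: with annual
   persistence $S(k)$, the conditional stop probability after year $k$ is
   $1 - S(k)/S(k-1)$; treatment is capped at 5 years.

**Treatment effect and waning.** On treatment, the drug's per-site
relative risk applies (alendronate 0.67/0.45/0.81, denosumab
0.60/0.32/0.80 for hip/vertebral/NHNV). After stopping, alendronate's
effect declines linearly over the time spent on treatment; denosumab's
vanishes linearly within one year (rebound risk); a step-at-one-year rule
is also selectable. The effective relative risk never exceeds 1.

**Common random numbers.** All randomness derives from labelled child
streams of one master seed (`child_seed`), per purpose and cycle. The two
arms regenerate identical natural-history uniforms; treatment shifts the
event *thresholds*, not the draws. Incremental outcomes are therefore
paired person by person, which reduces the variance of ΔC and ΔQALY by an
order of magnitude and makes "no screening effect ⇒ arms bit-identical" an
exact, testable property. A useful corollary (exploited by
`cascade_grid()`): the simulated result at any DXA-uptake/initiation pair
is an exact function of two boundary simulations, so follow-up grids can
be evaluated at large cohort sizes with no between-point Monte-Carlo
noise.

## Parameters

All published Korean inputs are packaged verbatim in `default_params()`
and validated by `validate_params()`: fracture incidence and T-score
relative risks by sex/site/age band, first-year fracture costs (male costs
~13% above female, stored as explicit values), utility knots (ages 50–90)
and post-fracture multipliers with their 95% CIs, drug profiles
(effects, costs, persistence, monitoring, adverse events), cascade
probabilities, prevalence (fixed: 37.3% women / 7.5% men; age-specific:
15.4/36.6/68.5% women and 3.5/7.5/18% men for 50–59/60–69/70+), discount
rate 4.5%, WTP thresholds KRW 30M and 50M.

Notable interpretation choices, where sources were ambiguous:

* Published estimates of alendronate's vertebral effect circulate both as
  a 44% reduction (RR 0.56) and as RR 0.45; the packaged default is RR
  0.45, and the alternative is reachable via config. The two are not
  silently reconciled.
* Denosumab persistence is published at year 1 (67%) and from year 3
  onward (35%); the year-2 value is the linear midpoint (0.51),
  configurable.
* Age bands are half-open, `80+` meaning [80, 105); band lookup uses the
  current integer age each cycle.
* Baseline utility is linearly interpolated between knots and held
  constant above age 90 (the published knots are non-monotone around
  85–90; they are used as printed).
* Untreated-but-confirmed cases incur no follow-up costs; nursing-home
  admission is permanent; the first-year monitoring DXA for alendronate is
  charged in addition to the confirmatory DXA.

## Synthetic stand-ins

Four inputs the model needs are not published in reusable form. The
`synthetic_inputs` generators provide flagged stand-ins
(`source = "synthetic stand-in"`, listed in every run manifest):

* **Life tables** (`make_life_table`): Gompertz–Makeham hazards calibrated
  so life expectancy at 50 is ≈36 y (women) and ≈31 y (men), forced to
  $q_x = 1$ at 105.
* **Population structure** (`make_population`): 5-year age-band weights
  for a bottom-heavy aging 50+ population (mean entry age ≈63,
  close to the 2023 Korean structure), 52% female.
* **Post-fracture mortality** (`default_post_fracture_mortality`):
  first-year excess death probability 0.10/0.15 (hip, women/men) and
  0.04/0.06 (vertebral); long-term hazard ratio declining from 1.8 to 1.0
  over 10 years; attribution fixed at 0.25.
* **Subsequent-fracture multipliers**
  (`default_subsequent_multipliers`): 2.0 within 2 years of the last
  fracture, 1.5 for years 3–5, 1.2 beyond, +0.2 per prior fracture beyond
  the first, capped at 4.0.
* The PPI cost per adverse-event episode (KRW 10,000) is likewise a
  stand-in.

These magnitudes are order-of-magnitude plausible and chosen once so the
base case lands in the regime that published Korean estimates suggest;
they are never presented as published values. Consequently the package
reproduces the *pattern* of results — the bounds, orderings and
monotonicities the test suite asserts — rather than exact published
ICERs. With the packaged stand-ins the men-only fixed-prevalence ICER
centres slightly above the KRW 50M GDP-based threshold, driven mostly by
the fixed screening outlay against men's small QALY gain; the women-only,
overall and age-specific results sit robustly below the KRW 30M
threshold. What passing tests show about real data is therefore
structural validity plus robustness of the threshold claims, not numeric
reproduction: with true KOSIS life tables and unpublished
mortality/subsequent-fracture inputs, point estimates would shift within
the ranges explored by the sensitivity analyses.

## Uncertainty analyses

**One-way scenarios** (`one_way_table`, `default_scenarios()`): DXA uptake
40–80%, treatment initiation 30–70%, AI cost ±50%, fracture incidence
±20%, fracture costs ±20%, utility decrements ±20%, excess mortality
±50%, drug costs ±20%, drug efficacy ±20% (on 1−RR), single-drug
strategies, the 70+ subgroup, male prevalence 12.2%/15%. All scenarios
share the base case's roster and seeds; `cmd_dsa` writes them in tornado
order.

**PSA** (`run_psa`): beta distributions for incidence rates and
post-fracture utility multipliers (CI-matched where CIs are packaged),
truncated normals for unit costs, log-normals (median = base) for
treatment relative risks capped at 1; independent draws, 10% coefficient
of variation by default where no CI exists — an assumption, exposed as an
argument. Cascade probabilities stay fixed unless `include_cascade =
TRUE`, since the source does not state whether they were redrawn. Zero
dispersion collapses the PSA onto the deterministic result exactly.
`ceac()` reports the fraction of draws with non-negative net monetary
benefit (ties count as cost-effective).

## Numerical choices and problem sizes

Annual cycles with mid-cycle discounting and half-cycle credit at death
approximate continuous time; event-before-death ordering within a cycle is
a convention (the first-year mortality excess still applies in the event
cycle). Treatment clocks tick in whole years because persistence data are
annual. Probabilities are capped at 1 after all multipliers.

Default problem sizes were chosen for stable desk-scale inference: 10⁴–10⁵
individuals for deterministic comparisons (paired SE of ΔQALY ≈
0.0001–0.0004 at 10⁵), 200 × 10⁴ for the PSA (the source's 200 × 250,000
is available by argument), and 4 × 10⁵ for the follow-up grids via the
exact grid composition. The test suite documents each size next to each
assertion.

## Known limitations

* The stand-in inputs above; exact published ICERs are out of reach by
  construction.
* No treatment switching or re-initiation, no repeat screening, no
  imperfect DXA, only three fracture site groups, no inflation or currency
  machinery.
* Fracture events within a cycle are independent across sites; utility
  takes only the most severe fracture (costs are charged per event).
* Monte-Carlo error in ratio estimates: ICER estimates for small subgroups
  (men-only) are noisy because the QALY denominator is small; the package
  reports paired SEs so users can size cohorts accordingly.
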