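---
title: "Modelling the mortality impact of closing the quality-of-care gap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the mortality impact of closing the quality-of-care gap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qocimpact)
```

`qocimpact` estimates how many maternal deaths, neonatal deaths and
stillbirths would be averted if health facilities delivered adequate-quality
care to the women and newborns who already reach them. This vignette is the
package's own account of the model: its assumptions, the choices that were
genuinely open, and what the test suite does and does not demonstrate.

## 1. Effective coverage from linked surveys

The quantity the pipeline starts from is *effective coverage*: the fraction
of the population in need that receives an intervention at adequate
quality. Neither facility surveys nor household surveys measure it alone —
facility checklists know nothing about utilization, and household
respondents cannot report whether the clinic stocked magnesium sulfate. The
linking construction multiplies the two:

$$C_i \;=\; U_{p(i)} \sum_s \text{share}_s \,\cdot\, r_{i,s},$$

where $r_{i,s}$ is the survey-weighted proportion of facilities in stratum
$s$ that are **ready** for intervention $i$, $\text{share}_s$ is the share
of care contacts occurring in stratum $s$, and $U_{p(i)}$ is the
utilization cap of the intervention's period: the ANC4+ proportion for the
8 antenatal interventions, the facility-delivery proportion for the 7
childbirth and 4 postnatal interventions. By construction
$C_i \le U_{p(i)}$: quality improvement alone can never push coverage past
current care-seeking, which is exactly the conservative scenario the
package models.

**Readiness is a strict conjunction.** A facility is ready for an
intervention only if *every* component of its indicator definition is
present — staff training, guidelines, equipment, drugs. There is no
partial-credit scoring: the components are a minimum set, and a missing
uterotonic is not compensated by a spare partograph. `indicator_registry()`
ships the 19 definitions as a controlled vocabulary with one component code
per checklist line item. Three coding choices deserve a note:

* Line items that recur verbatim across interventions (ANC staff training,
  ANC guidelines, the IMPAC guidelines) share one code, as they are one
  observable fact about a facility.
* The injectable-uterotonic item appears in both the AMTSL and the
  labour-induction definitions and is coded separately for each
  (`uterotonic_amtsl`, `uterotonic_induction`). This keeps the 19 readiness
  indicators statistically independent in generated data (section 4), at
  the cost of representing one physical stock item with two codes. Analyses
  of real checklist data would set both codes from the same survey item.
* Components assessed only in SPA surveys carry an `spa_only` flag and are
  excluded from the requirement set when a SARA survey is evaluated. If the
  exclusion empties an indicator entirely, the intervention is flagged
  *absent* (`NA`) rather than trivially ready — we never fabricate
  readiness of 1 from an indicator that the survey could not assess.

**Link validity.** A facility survey and a household survey are combined
only when their fieldwork years differ by at most two years; multi-year
fieldwork is represented by its fractional midpoint (2008–2009 → 2008.5).
Violations are refused with the gap reported, not down-weighted.

**Weights.** Facility readiness proportions use survey weights normalized
within stratum — standard design-based estimation. The stratum taxonomy is
configurable (default `hospital`, `health_center`, `clinic`); when a
household survey reports no stratum breakdown a single national stratum is
used.

## 2. Baseline table, proxies and quartile bounds

Countries with a valid linked pair keep their measured baselines. For every
other country, each intervention's baseline is imputed from the linked
sample: the median centrally, the 25th and 75th percentiles as sensitivity
bounds. Quantiles are order statistics with linear interpolation
(`stats::quantile` type 7, the common default in mainstream statistical
software; no convention is forced by the problem, so we state ours).
Two further choices:

* Bounds substitute quantiles **only** where a value was imputed. Measured
  baselines in linked countries are data, not assumptions, and are held
  fixed across the three runs.
* When a linked country has an *absent* intervention (a SARA survey that
  cannot assess it), that cell is filled with the same quantile proxy and
  its provenance recorded as a proxy, so the baseline table is complete for
  every country × intervention after imputation.

## 3. Scenarios and the mortality engine

**Trajectories.** From the 2016 baseline, scale-up coverage rises linearly
to the country's utilization cap in 2020:
$c(y) = c_0 + (T - c_0)\,(y-2016)/4$. The counterfactual freezes coverage
at $c_0$. When a proxy baseline already exceeds a low-utilization country's
cap (a real situation: a sample median can exceed a 9% facility-delivery
cap), the trajectory is held constant — scale-up never *lowers* coverage.
Interventions outside the modelled set are implicitly constant and
contribute no impact.

**Deaths.** The engine is linear and deterministic. Each (outcome, cause)
envelope $D^{2016}$ is assumed to already reflect baseline coverage, so
deaths under a coverage vector $c$ follow the residual ratio

$$D(c) \;=\; D^{2016}\,
  \frac{\prod_i \bigl(1 - e_i a_i c_i\bigr)}
       {\prod_i \bigl(1 - e_i a_i c^{2016}_i\bigr)},$$

with efficacy $e_i$ and affected fraction $a_i$ folded multiplicatively per
entry. The product form means several interventions acting on one cause
remove shares of the *remaining* deaths, so the joint impact is always at
most the sum of single-intervention impacts: the structure precludes
double counting. A baseline residual of zero is rejected as inconsistent —
perfect baseline prevention contradicts a positive observed envelope.

**Lives saved and attribution.** Lives saved are counterfactual deaths
minus scale-up deaths, per outcome and year. Attribution of the joint
total to individual interventions is not uniquely defined by the model; we
allocate proportionally to single-intervention impacts
($a_i = \text{joint} \times s_i / \sum_j s_j$, all zero when
$\sum_j s_j = 0$), which conserves the joint total to within $10^{-9}$
relative and reduces to the exact answer for a single intervention. This is
a declared convention, not a derived result.

**Rates and reporting.** MMR uses live births ×100,000; NMR live births
×1,000; SBR total births (live + stillbirths) ×1,000. Birth counts and
death envelopes are held constant over 2016–2020 — demographic projection
is a different tool's job — so percent declines in rates equal percent
declines in death counts, a property the suite verifies. Impact is reported
for calendar-year 2020. Global summaries add lives saved across countries,
compute the share of impact by period of care (the "overall" share pools
the three outcomes by raw count, which lets the largest envelopes dominate
— a stated convention), and summarize per-country rate declines by
cross-country quartiles (a boxplot analogue) alongside the mean.

**Direction of the sensitivity bounds.** The quartile bounds act on
*baselines*, but the reported range is on *impact*, and the mapping flips:
with the target capped at current utilization, a lower assumed baseline
leaves more room to improve, so the q25-baseline run yields the *high*
impact bound and the q75-baseline run the *low* one. `sensitivity_range()`
encodes this mapping and then verifies the ordering rather than assuming
it; a crossed triple (conceivable through cap-rule interactions, e.g. a q75
proxy stuck above a country's cap) is flagged with a warning and reported
as-is, never silently reordered.

## 4. What the synthetic-data generator emulates

`generate_country_set()` produces a study set with known ground truth: by
default 17 linked countries (facility survey + household survey, year gap
≤ 2) and 64 countries with household data only, mirroring a design in which
most countries lack a usable facility–household pair.

* **Facility surveys** emulate SPA/SARA component checklists. Per
  intervention and stratum, one *binding* component is drawn Bernoulli with
  the ground-truth readiness probability and all other components are
  present, so the conjunction probability equals the ground truth exactly —
  a closed form that makes parameter-recovery tests sharp while still
  exercising the per-component conjunction logic. Binding components are
  unique to their intervention and (where the checklist allows) not
  SPA-only. The three postnatal indicators whose only intervention-specific
  component is SPA-only degenerate to a guidelines-only check under SARA;
  recovery tests therefore use SPA surveys.
* **Utilization** is drawn from Beta distributions centred on 60% (ANC4+)
  and 66% (facility delivery), matching the mean levels reported for
  large LMIC survey compilations; optional truncated-Gaussian noise
  (default off) emulates household sampling error. Stratum shares are
  Dirichlet draws favouring hospitals.
* **Envelopes** use live births between 50,000 and 3 million per year, NMR
  20–40 per 1,000, MMR 150–800 per 100,000 and SBR 12–30 per 1,000, with
  cause fractions drawn around typical global cause-of-death profiles.
* **Weights** default to 1; a gamma option (mean 1, shape 5) exercises
  weighted estimation without claiming a real sampling design.

What it does **not** emulate: DHS/MICS recode layouts, cluster sampling and
nonresponse, within-facility correlation between components beyond the
binding scheme, readiness trends over time, or any relationship between
quality and care-seeking. Passing tests therefore demonstrate that the
*pipeline machinery* is correct — estimators recover known parameters,
the engine matches closed forms, reporting is conserved and ordered — not
that any particular real-world number is reproduced. The bundled efficacy
matrix respects the qualitative intervention → cause topology (tetanus
toxoid acts on neonatal tetanus, AMTSL on maternal haemorrhage, neonatal
resuscitation on intrapartum deaths, magnesium sulfate on hypertensive
disorders and stillbirth, and so on) but its numeric values are
illustrative; substantive analyses must supply an evidence-reviewed matrix
via `read_efficacy_matrix()`.

## 5. Numerical conventions and degenerate inputs

* Conservation checks (attribution sums, period shares) use a $10^{-9}$
  tolerance; trajectory closed forms are exact to $10^{-12}$.
* Proportions are validated into $[0,1]$ at construction; stratum shares
  and cause fractions must sum to 1 within $10^{-9}$.
* Zero-weight strata, empty quantile inputs, interventions with no linked
  observation, zero birth denominators and baseline residuals of zero are
  all hard errors with named culprits — never silent coercions.
* Seeds are mandatory for every generator; there is no implicit global
  randomness, and a fixed seed reproduces a dataset byte-for-byte.

## 6. Problem sizes used by the test suite

The suite verifies parameter recovery at 5,000 facilities for a single
country (binomial standard errors are then small enough for a sharp 3-SE
check), runs the whole pipeline on an 81-country set with 150 facilities
per linked survey, checks engine–oracle equivalence on 200 randomized
small instances (≤ 3 causes × ≤ 3 interventions), and confirms
byte-identical determinism on a 15-country set. These sizes were chosen so
each property is tested at the scale where its statistics are informative
while the whole suite stays quick to run during development.

## 7. Known limitations

* Readiness is structural: observed availability of inputs, not observed
  clinical practice. Process quality is outside the model.
* The envelope-ratio construction assumes observed deaths are consistent
  with estimated baseline coverage; biases in either propagate directly.
* Holding envelopes and utilization constant to 2020 ignores demographic
  change and any demand response to better quality; both would typically
  increase the estimated impact.
* The proportional attribution rule and the pooled-count "overall" period
  share are conventions; alternatives (e.g. Shapley attribution,
  outcome-normalized shares) would differ in detail.
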