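---
title: "Modelling access to care and intervention effects for congenital disorders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling access to care and intervention effects for congenital disorders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdburden)
```

## The problem

Severe early-onset congenital disorders — structural malformations,
chromosomal disorders such as Down syndrome, recessive single-gene
disorders, rhesus haemolytic disease, neural tube defects — end in
pregnancy loss, early death, disability or cure depending on which
interventions a family can reach. Most countries have no direct
observational data on coverage of the relevant services. `cdburden`
estimates that coverage from a universally available proxy (infant
mortality), models the interventions that change affected birth
prevalence, and allocates every affected pregnancy to a conserved
"envelope" of outcomes so that nothing is double-counted or lost:

* birth outcomes: termination of pregnancy (TOP), stillbirth, livebirth;
* under-5 outcomes of affected livebirths: death, severe disability,
  mild-to-moderate disability, effective cure.

All rates are denominated **per 1000 total births, terminations
included in the denominator**. The choice is stated in output headers;
it is what keeps the envelope closed under the TOP operation.

## Access to optimal care from infant mortality

"Optimal care" means the standard of a high-income setting with
equitable access. The expert (CHERG-derived) stepped mapping assigns an
access fraction to each infant mortality band:

| IMR band (per 1000) | access |
|---|---|
| [0, 10) | 100% |
| [10, 25) | 50% |
| [25, 55) | 15% |
| [55, 100) | 5% |
| [100, ∞) | 0% |

Band edges are half-open real intervals matching the printed integer
ranges (≤9, 10–24, …), so any real-valued IMR falls in exactly one band.

The step discontinuities are undesirable — a country crossing a boundary
jumps in access — so a smooth monotone curve from the Beta family is
fitted to the steps:

$$\mathrm{access}(m) = \begin{cases}
1 & m \le m_{lo} = 9\\
1 - I\!\left(\tfrac{m - 9}{91};\, a, b\right) & 9 < m < 100\\
0 & m \ge m_{hi} = 100
\end{cases}$$

where $I$ is the regularized incomplete beta function. The shape
parameters are chosen by least squares at the interior band midpoints
(17, 0.50), (39.5, 0.15), (77, 0.05); the fit must land within ±0.05 of
every anchor or `fit_access_curve()` raises a calibration error. With
the defaults the fitted shapes are $a \approx 0.475$, $b \approx 2.53$.
This anchor fit is the package's own construction: it reproduces the
published endpoints exactly and the interior to the stated tolerance,
and also stands in for any separate low-IMR smoothing step — no second
smoothing is applied.

```{r}
curve <- fit_access_curve()
curve
access_from_imr(c(9, 17, 39.5, 77, 100), curve)
```

### Consanguinity adjustment

Where customary consanguineous marriage is common, a material share of
infant deaths is caused by recessive disorders and should not be read
as poor access to care. The consanguinity-associated IMR is

$$\mathrm{cIMR} = \frac{\alpha}{0.0625}\, e_{nc}\,
\left[(1 - \mathrm{access}) + \mathrm{access}\,(1 - \rho)\right],$$

linear in the population mean coefficient of consanguinity $\alpha$
(0.0625 = first-cousin offspring), where $e_{nc}$ is the excess infant
mortality per 1000 at the reference level without care and $\rho$ the
fraction of those deaths avertable with optimal care. Defaults are
$e_{nc} = 30$ per 1000 and $\rho = 0.8$ — order-of-magnitude values
from the excess-mortality literature on consanguinity, both
configurable (`consanguinity.e_nocare`, `consanguinity.rho`).

Subtracting cIMR computed at the *unadjusted* access level over-reduces
the IMR (lower IMR implies better access implies fewer
consanguinity-associated deaths), so the adjustment is iterated: access
is re-evaluated on the adjusted IMR and cIMR recomputed. Exactly two
iterations are performed by default; afterwards further iterations
change the result negligibly, which the test suite verifies against a
run-to-convergence fixed-point solver. The adjusted IMR is floored at
1 per 1000 (`consanguinity.imr_floor`) so the curve argument stays
positive; any clamping is recorded and warned about. Whether a floor or
a cap on cIMR is the better degenerate-input rule is genuinely open; we
chose the floor because it bounds the implied access at the curve's
upper end rather than rescaling the subtraction.

HIV-attributable infant mortality is then subtracted
(`final_adjusted_imr()`), and final access is the curve evaluated on
the final adjusted IMR. Both adjustments lower IMR, so final access is
never below unadjusted access. The effect is largest on the steep part
of the development curve (IMR roughly 10–35 per 1000) and small at both
extremes, which the acceptance suite checks as a property.

The neonatal mortality rate is accepted in the input schema for
provenance but unused: IMR was preferred because country series and
projections are available for far longer periods.

## Folic-acid fortification and neural tube defects

Neural tube defect (NTD) prevalence responds to mandatory flour
fortification; voluntary fortification and supplementation programmes
are modelled as having no population effect. Not all NTDs are
folate-preventable: the post-fortification floor for spina bifida plus
anencephaly is 0.7 per 1000, and with encephalocoeles taken as 11.5% of
NTDs the total non-preventable floor is **0.77 per 1000**. The total
floor is carried as an independent constant (`folate.total_floor`)
rather than recomputed from the other two, whose printed arithmetic
does not reconcile exactly (0.7 adjusted by an 11.5% share gives
0.78–0.79); 0.77 is treated as authoritative.

The dose-response is a single exponential in dose $d$ (ppm, mg folic
acid per kg flour):

$$\mathrm{post} = \mathrm{baseline} - \mathrm{reach}\times
(\mathrm{baseline} - 0.77) \times (1 - e^{-k d}),$$

with $k = 1.65$ per ppm, the smallest round coefficient for which a
2 ppm dose at full reach brings every baseline from 1.0 to 6.5 per 1000
below 1 per 1000 — the published calibration anchor. The tabulated
dose-response underlying that anchor is not redistributable, so the
exponential is this package's surrogate; a config hook
(`folate.dose_response_table`, piecewise-linear) accepts tabulated
values and overrides the exponential. Observed pre/post prevalences,
when available, bypass the model entirely.

On ppm: one source caption equates x ppm with x µg per **100 g** flour,
which conflicts with the conventional definition (x µg per g, i.e. mg
per kg). We use the conventional mg-per-kg reading and note the
discrepancy here rather than silently reinterpreting doses.

Fortification is assumed to act proportionally on all NTD subtypes
(`split_ntd_subtypes()`), and small collateral effects on orofacial
clefts and congenital heart disease are included as
`reach × max_effect × (1 − e^{-kd})` with a placeholder
`max_effect = 0.05` for both classes — the evidence supports only a
"small" effect without a number, so the constant is clearly flagged as
a configurable placeholder. Vitamin B12 co-fortification is not
modelled.

## Genetic risk information for recessive disorders

Baseline affected birth prevalence comes from Hardy–Weinberg with a
consanguinity augmentation:
$q^2 + \alpha q (1 - q)$ per birth, where $q$ is the pathogenic allele
frequency.

The effect of risk information depends on *when* a couple learns it and
on the family-size norm $N$ (births per couple; the country's total
fertility rate in the pipeline, evaluated at real $N$ to match the
continuous fertility axis):

* **Retrospective** (after a first affected child, coverage = access to
  services): the maximum-effect convention is that counselled couples
  stop at the first affected birth, giving a proportional fall of
  $1 - (1 - 0.75^N)/(N/4)$ — about 45% at $N = 6$ and 18% at the global
  norm $N = 2.5$, inside the published bands of 50 ± 10% and 15 ± 5%.
  With prenatal diagnosis, couples instead complete their family with
  post-first-affected affected pregnancies terminated and replaced with
  probability $u$ (the uptake), scaling the fall by $u$.
* **Prospective** (before any affected child; coverage defaults to
  zero unless a screening programme is recorded): couples limit their
  family to two healthy children, giving
  $1 - (2/3)/(N/4)$, floored at zero — no effect below $N = 8/3$,
  about 56% at $N = 6$. With prenatal diagnosis every affected
  pregnancy is diagnosable and the fall equals the uptake (0.97 for a
  severe disorder reproduces the >95% reductions reported for
  β-thalassaemia programmes).

The floor encodes a behavioural assumption, not a stopping-rule
outcome: at small norms the stop-at-two-healthy rule would *increase*
affected births, and couples are assumed simply not to apply it. A
consequence worth stating plainly: at norms below ~3.8 the
retrospective fall exceeds the prospective one under these conventions,
so "earlier detection does at least as well" holds only for larger
families or when prenatal diagnosis is available; the tests assert the
ordering exactly there.

Population prevalence after counselling mixes the two coverages:

$$\mathrm{post} = \mathrm{baseline}\left[p(1 - F_{pro}) +
(1 - p)(1 - r\,F_{retro})\right].$$

`simulate_reproductive_outcomes()` implements the two stopping rules as
direct Monte-Carlo simulation (integer $N$; fractional-parity stopping
is undefined) and is used by the tests as an independent cross-check of
the closed forms at 100,000 couples per scenario, within three standard
errors. Replacement of affected children who have died — which would
raise observed prevalence — is noted but not modelled.

## Prenatal diagnosis and termination of pregnancy

Countries fall into four policy groups: **A** legal with registry data
(observed TOP rates pass through, capped at the affected prevalence
with a warning — whether a cap is applied upstream is unstated, so we
cap and log); **B** legal without data (prenatal-diagnosis access is
predicted by the optimal-care model and uptake among the diagnosed is
the EUROCAT registry average, halved for Down syndrome and spina bifida
unless a universal screening policy exists); **C** unclear status with
evidence of widespread availability (computed as B; group membership is
a country-table column, not a hardcoded list); **D** illegal (zero
terminations). EUROCAT averages are input data; the shipped fixture
values are synthetic and labelled as such. Groups C and D likely
understate true TOPs; no correction is attempted — the estimates
deliberately carry that conservatism.

Anti-D prophylaxis coverage for rhesus disease is bounded below by
estimated access to optimal care and, where anti-D is standard
obstetric practice, rises to the coverage of four antenatal visits when
that is higher: `max(access, anc4)`. Efficacy defaults to 1
(`antid.efficacy`), reflecting the near-eradication achieved under full
coverage. Intra-uterine treatment is not modelled.

## The outcome envelope

Access is **binary at the individual level**: a person either has
high-income-standard care or no supportive medical services at all.
For each country-condition:

1. terminations + stillbirths + livebirths = affected prevalence after
   prevention, with stillbirths = (prev − TOP) × sb_frac;
2. livebirths split into under-5 deaths, cured, mild-moderate and
   severe disability. Deaths mix the two access strata:
   $L[\mathrm{access}\, m_{care} + (1-\mathrm{access})\, m_{nocare}]$.
   Survivor disability shares are mixed with **survivor-mass weights**
   per stratum, not the raw access fraction. Worked example: with
   access 0.5, care mortality 0.1, no-care mortality 0.8, the care
   stratum contributes 0.45 of each livebirth as survivors and the
   no-care stratum 0.10, so care-stratum shares get weight
   0.45/0.55 — using raw access (0.5/0.5) would assign no-care
   survivors outcomes they cannot have.

Both identities are enforced to 1e−9 in a 10,000-draw randomized sweep.
Mean age at death is the share-weighted mean of configurable under-5
death-band midpoints (missing when there are no deaths); full
life-table years-of-life-lost integration is structurally possible but
deliberately out of scope, as are uncertainty intervals.

In the pipeline, population TOP applies to malformation, chromosomal
and NTD classes; recessive-disorder terminations are already embedded
in the counselling model and are reported as prevented rather than as
TOPs, to avoid double counting; Rh disease receives anti-D only.

Aggregation to regions weights every per-1000 rate and access fraction
by livebirths and sums absolute counts; the world row equals the
weighted mean of the regional rows, and aggregation is invariant to
country order and to splitting a country into equal-rate halves.
Published regional tables built on UN country data are external
validation requiring inputs this package does not ship; the substituted
checks are the structural properties above.

## The synthetic fixture generator

`generate_fixtures()` produces deterministic, schema-valid country and
condition tables so the full pipeline is testable without downloads. It
emulates the joint structure the model cares about: IMR log-uniform on
2–120 per 1000 (all five bands populated, including the steep 10–35
zone), consanguinity zero for half the countries and uniform 0.005–0.04
for the rest (an Eastern-Mediterranean-like pattern), fertility rising
and antenatal-care coverage falling along the development axis,
HIV-attributable infant mortality for a flagged subset, and TOP groups
spanning A–D. It does **not** emulate real-world features such as
within-country time trends, correlated measurement error in IMR,
regional clustering of fortification policy, or realistic EUROCAT
uptakes — so passing tests demonstrate internal consistency and
calibration of the model machinery, not agreement with any country's
observed data.

Problem sizes used throughout: 50 countries × 4 conditions for
pipeline checks (runs in well under 10 s), 10,000 parameter draws for
the conservation sweep, 100,000 couples per Monte-Carlo scenario.

## Numerical choices

* Curve fitting: Nelder-Mead on log-shape parameters, relative
  tolerance 1e−12; anchors must be met within ±0.05.
* Band membership: half-open intervals, `findInterval` semantics; ties
  at a boundary belong to the upper band.
* Envelope identities asserted to 1e−9; share vectors must sum to 1
  within 1e−9.
* All stochastic components (fixtures, simulator) take explicit seeds
  and restore the caller's RNG state.
* Access is a fraction in [0, 1] internally; CSV outputs render it as
  percent with one decimal.

## Known limitations

Binary access understates intervention impact where services scale up
unevenly; group C/D TOP assumptions understate terminations; the
dose-response and collateral-effect constants are surrogates with
config hooks; baseline prevalences themselves (other than
Hardy–Weinberg recessives) are inputs, not estimates; congenital
infections and teratogenic exposures are out of scope.
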