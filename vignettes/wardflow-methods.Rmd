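---
title: "Characterising atypical intrahospital transfers: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising atypical intrahospital transfers: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`wardflow` operationalises a simple idea: a hospital ward's function is
revealed by the patients it actually treats, and a transfer between two
wards whose revealed functions share nothing is worth distinguishing from
the routine traffic between related services. This vignette records the
statistical models, the tunable parameters and their defaults, what the
synthetic cohort generator does and does not emulate, and the numerical
and design choices a maintainer should know about.

## 1. Ward profiles: HHI and equivalent market size

Each spell contributes one speciality label — the treatment function code
(TFC) of its **last** consultant episode, on the grounds that admitting
codes are broad (general medicine) and later codes more specific
(cardiology). The label is deposited once on every *distinct* ward the
patient entered during the spell; the unit of deposit is the spell, not
the patient, so a patient with two spells deposits twice. Profiling uses
the *full* population — elective and day-case spells included — because
ward function is defined by total usage, while the outcome models use
only the included emergency cohort. With per-ward speciality shares
$S_1,\dots,S_N$,

$$\mathrm{HHI} = \sum_{i=1}^{N} S_i^2, \qquad
  \mathrm{EMS} = \Big[\tfrac{1}{\mathrm{HHI}}\Big],$$

and the ward is assigned its EMS largest-share specialities. Numerical
choices:

* **Rounding.** EMS uses round-half-up (`floor(1/hhi + 0.5)`), which is
  deterministic across platforms, unlike banker's rounding.
* **Ties** between equal shares are broken by lexicographic speciality
  code, so assignment is reproducible.
* **Low-evidence wards.** Wards with fewer than `min_deposits` (default
  10) deposits get the union of all specialities observed on them instead
  of an EMS-based subset, so a thinly observed ward can never generate an
  atypical transfer. Dropping such wards instead would silently delete
  transfers; the conservative union keeps them with a neutral label.
* Shares sum to 1 by construction; `compute_hhi()` refuses all-zero count
  vectors rather than returning `NaN`.

A `mode = "first"` switch re-profiles using the first episode's TFC; it
backs the sensitivity variant in which admitting rather than final
specialities define ward function.

## 2. The transfer decision rule

Transfers are any change of ward location, rebuilt from the event log
after merging back-to-back rows on the same ward (tolerance 15 minutes,
the nominal resolution of the data; larger gaps warn but do not reject,
since no gap rule is defined for the source data model). Moves *out of*
an ED location are excluded, but the ED stay itself is kept so the
admission timestamp — and hence LOS and the out-of-hours flag — is
preserved. The three classes are mutually exclusive, evaluated as **site**
(different hospital sites) before **atypical** (disjoint assigned
speciality sets) before **regular**. Cross-site moves are therefore never
also counted as atypical.

Short-stay procedure wards (endoscopy and similar) would otherwise
dominate the atypical list through reciprocal day-trips. A ward is exempt
when its mean stay over the whole population is at most `threshold_hours`
(default 6) *and* its catalogue row is flagged `is_procedure_ward` — the
flag stands in for the manual verification step that a ward really
functions as a temporary procedure location, which cannot be recovered
from data alone. Exempt-ward transfers are classified regular, not
dropped. Setting `threshold_hours = 0` disables the exemption and can
only increase the atypical count, a monotonicity the tests exercise.

Pair statistics pool `a→b` with `b→a` by default (`direction =
"unordered"`): reciprocal trips represent one route. The ordered variant
is a config switch, since the underlying convention cannot be recovered
from published counts.

Undefined in the source data model and decided here: "informal movements"
have no heuristic — the flagged-ward mechanism is the only drop rule; and
whether shares are computed over spells or distinct patients is exposed
as the deposit unit (spell, the default, since deposits are made per
spell journey).

## 3. Outcome models

Among emergency spells with at least one transfer (single-ward, elective
and maternity/paediatric spells excluded, each exclusion a pure
predicate):

* **LOS** (days, admission to discharge, 15-minute resolution) is
  modelled by a gamma GLM with log link; transfer counts enter as
  continuous integers. Effects are reported as **average marginal
  effects**: for a log link, $\mathrm{AME}_v = \tfrac1n \sum_i \beta_v
  \mu_i$ — the derivative convention (`type = "derivative"`), matching
  the `margins`-style response-scale `dydx`; a one-unit finite-difference
  version is available via `type = "unit"`. Confidence intervals use the
  delta method with the cluster-robust covariance.
* **30-day readmission** and **in-hospital mortality** use logistic
  models reported as odds ratios. The readmission model additionally
  adjusts for LOS; the mortality model omits discharge destination
  (death determines it). Index admissions are built iteratively: every
  included spell not ending in death is an index; a readmission is any
  subsequent *emergency* admission of the same patient to any site,
  except pregnancy-related ones, within `(discharge, discharge + 30
  \times 24\,h]` — the boundary is inclusive at exactly 30 days, a
  convention this package fixes since none is stated for the source data
  model.
* **Clustering.** All covariances are CR1 cluster-robust by patient:
  the HC0 sandwich aggregated within patients, scaled by $G/(G-1)$
  (delegated to `sandwich::vcovCL`); with one spell per patient it
  reduces to the heteroskedasticity-robust estimator.
* **Reference levels**: youngest age band, female, usual residence, and
  the modal major diagnostic category. Exposure AMEs and ORs are
  invariant to these choices.
* **Positivity filter** (logistic models): diagnostic categories with
  zero outcome events or fewer than `min_category_size = 10`
  observations are removed with a logged row count — the rule form of
  removing named rare categories, and it protects small cohorts from
  quasi-separation. True separation (a diverging coefficient, |β| > 15)
  is a hard error naming the covariate; missingness is complete-case
  with a logged count.
* An age-by-atypical interaction is available behind
  `interaction_age_atypical` (off by default).

**Diagnostics** are randomised-quantile-residual based: residuals are
uniform under a well-specified model, tested by Kolmogorov–Smirnov; the
variance of their probit transform is a dispersion ratio (1 under
correct specification, flagged outside [0.8, 1.25]); standardised Pearson
residuals feed the outlier sensitivity variant, which uses the Pearson
definition with cutoff 3 (the residual type is a config choice; the
convention used in the original analysis is not recoverable).

The six sensitivity variants re-estimate the LOS model: (1) survivors
only; (2) infection-negative only; (3) adding a 12-level approximate
month (admission days binned by 30, cycling over 12, for anonymised
dates); (4) alternative surgical-severity columns; (5) first-TFC
profiles, which re-runs profiling, classification and exposure counting;
(6) refit after dropping |standardised residual| > 3.

## 4. What the synthetic generator emulates

`generate_cohort()` draws a three-site network whose per-site catalogue
is: an ED location, a short-stay endoscopy-style procedure ward, four
single-speciality specialist wards, two paired-speciality wards
(cardiology–renal, trauma–neurosurgery) and two diffuse general wards
(mixture weights 0.4/0.2/0.2/0.2). The template guarantees every
speciality at least two host wards per site, so within-speciality moves
never have to leave the patient's speciality, and ward profiles stay well
separated: with the expected level of atypical-visitor contamination the
EMS of a specialist ward sits safely inside the window that rounds to 1,
a paired ward inside (0.4, 0.667] → 2, and a general ward inside
(0.222, 0.286] → 4. This separation was designed analytically from the
EMS rounding windows, not tuned.

Each spell has a latent speciality that drives ward choice. Moves are
drawn i.i.d. per move: cross-site with probability `p_site = 0.055`,
cross-speciality (atypical) with `p_atypical = 0.08`, a procedure-ward
detour with forced return with `p_procedure = 0.04`, otherwise a
within-speciality move. Atypical detours are planted at the end of the
trajectory so that the drawn move types coincide exactly with the true
classification rule applied to the true speciality sets — the property
the planted-recovery tests rely on. Move counts are Poisson(1.1), so
roughly half of the spells that move at all move exactly once. TFC
sequences start at a division-level admitting code (general medicine or
general surgery) and end at the latent speciality in ~60% of spells,
mirroring code refinement over an admission; the remainder record only
the latent code.

Outcomes invert the analysis models: LOS is gamma (shape 2) with log-mean
`1.55 + 0.25·atypical + 0.15·regular + 0.28·site` plus small covariate
effects and a patient-level log-normal frailty (sd 0.25, shared across a
patient's spells, inducing the within-patient correlation that makes
clustered standard errors matter; it shifts only the marginal intercept).
Mortality is logistic with a site-transfer coefficient of `log(0.72)`;
readmission uses a latent exponential time-to-readmission with
$P(T \le 30)$ matching the logistic model, materialised as a real
subsequent emergency spell, so the index builder can rediscover it from
timestamps alone. A small fraction of patients receive a
pregnancy-category subsequent admission that must *not* count. Stay
timestamps are written back so the rebuilt LOS equals the drawn value
exactly; ED and procedure stays keep fixed short durations (1–4 h) and
other stays share the remainder proportionally.

Default margins (55% over-65, ~5–6% in-hospital mortality, ~13% of
included spells with an atypical move, median LOS around 7 days, ~53% of
movers moving once) were chosen once to resemble a large urban emergency
inpatient population; they are conveniences, not contracts. The per-move
atypical probability 0.08 was chosen so the *spell-level* atypical
exposure lands near 13%; configurations with other values (e.g. a 0.13
per-move rate) are exercised explicitly in tests.

What the generator does **not** emulate: bed-occupancy queues and
capacity feedback (the documented driver of real atypical transfers),
seasonal and weekly census patterns beyond the admission timestamp,
informal or unrecorded movements, TFC recording errors, and conditional
(rather than marginal) calibration of the readmission process. Passing
the planted-recovery tests therefore shows the pipeline is correct and
well-calibrated under its own assumptions — not that real hospital data
are this clean: real ward mixtures are less separated, so EMS-based
assignment will misclassify some borderline wards, a limitation shared
with any revealed-function approach.

## 5. Problem sizes and reproducibility

All randomness flows from a single integer seed; the same seed reproduces
every output byte for byte. The test suite and acceptance script use a
default cohort of 20,000 patients for structure- and
coefficient-recovery checks (generation plus the full pipeline takes a
few seconds), and 50 replicate cohorts of 5,000 patients for the
cluster-robust coverage study with an acceptance band of [90%, 100%] —
sizes chosen as the package's own balance between Monte-Carlo precision
and a fast default test run. The descriptive table (Kruskal–Wallis for
continuous, chi-square without continuity correction for categorical
variables) flags constant variables and empty strata instead of testing
them.

## 6. Known limitations

* Ward speciality sets are assignment sets, not probabilistic profiles;
  a transfer between two borderline-multispeciality wards can flip class
  under small share perturbations (mitigated, not removed, by
  `min_deposits`).
* The 6-hour procedure-ward rule depends on an externally supplied
  catalogue flag; without it, short-stay assessment units would be
  pruned too.
* AMEs assume the exposure enters linearly on the link scale; count
  nonlinearity is not modelled.
* The readmission generator is calibrated marginally, so logistic
  coefficient recovery for readmission is approximate by design; LOS
  coefficient recovery is exact in expectation and is the quantity the
  acceptance checks target.
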