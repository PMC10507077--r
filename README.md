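# wardflow

Hospital inpatients rarely stay on one ward: as their needs evolve — or as
beds run out — they are moved between wards, sites, and services. Most of
these moves follow well-worn routes between related specialities, but a
minority cross between wards that share no speciality at all. `wardflow`
implements a data-driven pipeline for finding and quantifying these
**atypical intrahospital transfers** from routine electronic health record
(EHR) ward-entry logs, and for estimating their association with length of
stay (LOS), 30-day emergency readmission, and in-hospital mortality. It is
aimed at health-services researchers and hospital analytics teams working
with spell-level EHR extracts.

## The method

**Ward speciality profiles.** Each hospital spell carries an ordered
sequence of treatment function codes (TFCs); the last code is taken as the
best summary of the patient's speciality and is "deposited" once on every
distinct ward the patient entered. For a ward with speciality shares
`S_1, ..., S_N` the concentration of its casemix is the
Herfindahl–Hirschman index

```
HHI = Σ_i S_i²,          1/N ≤ HHI ≤ 1
```

and its *equivalent market size* `EMS = round(1/HHI)` is the effective
number of specialities it serves. Each ward is assigned its `EMS`
largest-share specialities.

**Transfer classification.** Every ward-to-ward move (excluding moves out
of the emergency department) is classified, in precedence order:

1. **site** — the two wards are on different hospital sites;
2. **atypical** — the wards' assigned speciality sets are disjoint, and
   neither ward is an exempt short-stay procedure ward (mean stay ≤ 6 h
   and flagged as a procedure location, e.g. endoscopy);
3. **regular** — everything else.

**Outcome models.** Among emergency spells with at least one transfer,
per-spell transfer counts enter a gamma log-link GLM for LOS (reported as
average marginal effects in days) and logistic models for 30-day emergency
readmission and in-hospital mortality (reported as odds ratios), adjusted
for demographics, comorbidity, admission timing, procedures and diagnostic
casemix, with patient-clustered sandwich standard errors (CR1). Six
sensitivity variants (death/infection exclusion, seasonality dummies,
alternative surgical coding, first-TFC profiles, residual-outlier removal)
are bundled in `run_sensitivity_suite()`.

Because real hospital EHR extracts cannot be shared, the package ships a
synthetic multi-site cohort generator (`generate_cohort()`) with planted
ward speciality sets, planted atypical/site transfer rates, and
gamma/logistic outcome models, so the entire pipeline is testable against
known ground truth.

## Worked example

```r
library(wardflow)

sim <- generate_cohort(sim_config(seed = 1, n_patients = 5000))
res <- run_pipeline(sim$cohort)
res
#> <wardflow_results>
#>             stage rows
#>            spells 6489
#>          included 2220
#>         transfers 3762
#>        classified 3762
#>     analysis_rows 2220
#>  readmission_rows 2083
#>    mortality_rows 2220
#>
#> Length of stay (gamma GLM, AME in days):
#>        term      ame        se    lower    upper
#>  n_atypical 1.942678 0.4289593 1.101933 2.783422
#>   n_regular 1.369355 0.1647192 1.046511 1.692198
#>      n_site 2.411498 0.4729535 1.484526 3.338470
#>
#> Unique atypical ward pairs: 57
```

6,489 synthetic spells are reconstructed from the event log; 2,220
emergency spells with ≥ 1 transfer form the analysis cohort. Holding the
adjustment set fixed, each additional atypical transfer is associated with
an extra 1.9 days of stay (95% CI 1.1–2.8) in this simulated cohort, with
regular and site transfers at 1.4 and 2.4 days respectively — consistent
with the generating log-scale effects 0.25/0.15/0.28. The ward profile
table shows the recovered speciality structure:

```r
head(res$profiles$profiles[, c("ward_id", "total_deposits", "hhi", "ems",
                               "specialities")], 4)
#>   ward_id total_deposits       hhi ems             specialities
#> 1   S1W01            674 0.1302908   8 cardiology|elderly_care|...
#> 3   S1W03            251 0.7918128   1               cardiology
#> 7   S1W07            408 0.4896674   2         cardiology|renal
#> 8   S1W08            333 0.4635356   2 neurosurgery|trauma_orthopaedics
```

Specialist wards concentrate to a single speciality (`hhi ≈ 0.8`,
`ems = 1`), paired wards to two, while the ED location (`S1W01`) is
maximally mixed. `write_results(res, "out/")` exports all tables,
per-site chord-diagram matrices and a JSON manifest;
`inst/cli/wardflow.R` wraps simulation and the pipeline for shell use.

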