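# y90ici

In silico clinical trials of yttrium-90 radioembolization (Y90-RE) combined
with immune checkpoint inhibitors (ICIs) for hepatocellular carcinoma.

Radioembolization is a local therapy: a beta-emitting Y90 source delivers a
decaying radiation dose to one perfused tumor territory. Checkpoint
inhibitors are systemic: they boost immune-mediated kill of tumor cells
everywhere, including out-of-field disease. Whether to give them together
or in sequence — and at what doses and with what gap — is an open protocol
design question that is expensive to answer with real trials. `y90ici` is
for modelers and trial designers who want to explore that design space with
a mechanistic tumor-immune model on large virtual patient cohorts.

## The model

Four compartments (absolute cell counts): targeted tumor cells `TI`,
non-targeted tumor cells `TNI` (never irradiated), radiation-inactivated
antigen-releasing cells `I`, and circulating lymphocytes `L`. Between dose
events,

    dTI/dt  = a·TI  − ω₁′(t)·TI·L/(g + TI + TNI)
    dTNI/dt = a·TNI − ω₁′(t)·TNI·L/(g + TI + TNI)
    dI/dt   = −r·I
    dL/dt   = ω₂·(TI+TNI)·L/(g+TI+TNI) + ω₃·I·L/(g+I) + s − f·L

with the checkpoint-inhibitor boost
`ω₁′(t) = ω₁·(1 + δ_durva·Cmax·2^(−(t−t_last)/21 d))` resetting at each
biweekly dose. Radiation acts as instantaneous events: linear-quadratic
survival `exp(−αT·D − βT·D²)` for the targeted tumor (killed cells move to
`I`), linear survival `exp(−αL·D)` for lymphocytes. The exponentially
decaying Y90 source (half-life 2.6 d) is discretized into 26 daily dose
fractions summing exactly to the prescription; the tumor's effective dose
is `q ×` physical dose, with the effectiveness `q ~ N(0.12, 0.04)`
calibrated so that simulated 6-month RECIST responses under Y90 monotherapy
match the clinical profile CR 79% / PR 20%.

Endpoints: progression-free survival (RECIST progression of the targeted
lesion, nadir-referenced) and cumulative distant metastasis (non-targeted
volume exceeding the 0.1 cc detection limit), summarized with Kaplan-Meier
curves, medians, time-point rates and log-rank tests.

## A worked example

```r
library(y90ici)

coh <- sample_cohort(cohort_spec(n = 1000, seed = 42))
res <- run_trial(coh, dose = 400, delta = 0.12, interval = 60,
                 arms = c("Y90_mono", "A", "B", "C"), horizon_months = 120)
res
#> trial_result: 1000 patients x 4 arms (dose 400 Gy, delta 0.12 , interval 60 d)
#>       arm    n pfs_median pfs_lcl pfs_ucl pfs_rate_1y pfs_rate_3y pfs_rate_5y
#>  Y90_mono 1000      5.394   5.386   5.403       0.361       0.233       0.120
#>         A 1000     41.618  37.723  46.192       0.999       0.541       0.409
#>         B 1000     38.748  34.849  43.328       0.997       0.525       0.392
#>         C 1000     36.460  32.540  40.868       0.997       0.505       0.380
#>  dm_rate_1y dm_rate_3y dm_rate_5y
#>       0.990      1.000      1.000
#>       0.803      0.805      0.849
#>       0.894      0.895      0.943
#>       0.870      0.870      0.945
```

Reading the table: concurrent administration (arm A) reaches a median PFS
of ~42 months versus ~39 when Y90 precedes the ICI course by 60 days
(arm B) and ~36 for the reverse order (arm C); Y90 alone controls the
targeted lesion for only ~5 months. Arm A also has the lowest 3-year
cumulative distant-metastasis rate (80.5%): starting the systemic drug
while radiation-released antigen is still recruiting lymphocytes protects
the out-of-field lesion best, and giving radiation first (arm B) costs
less than giving it last. Pairwise log-rank tests are in
`res$comparisons`; per-patient event times in `res$events`.

Calibrating the Y90 effectiveness distribution to a clinical response
profile:

```r
fit <- fit_q_distribution(response_target(0.79, 0.20, 0, 0), coh,
                          dose = 400, seed = 2)
fit
#> q_fit: truncated-normal effectiveness, mu = 0.1208 , sigma = 0.0324
#> achieved proportions: CR=79.5% PR=20.2% SD=0.3% PD=0 %
```

Dose-grid and inter-drug-interval sweeps (`dose_grid_sweep()`,
`interval_sweep()`) produce the heat-map tables behind protocol
optimization; a thin command-line driver with `calibrate`, `simulate`,
`trial`, `sweep-dose` and `sweep-interval` subcommands is installed at
`inst/cli/y90ici.R`.

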