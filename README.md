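# twinfrail

Estimating the effect of a longitudinal marker on a left-truncated
time-to-event outcome in twin pairs.

## The problem

In ageing research the natural time scale is age, and cohort members
enrol at different ages: a subject is observed only if still event-free
at enrolment (left truncation / delayed entry). In twin studies the two
event times of a pair are additionally dependent. Standard joint
longitudinal–survival software handles either clustering without
delayed entry or delayed entry without time-varying markers, but not
both. twinfrail is for biostatisticians who need the combination: a
repeatedly measured marker (e.g. bone mineral density), an age-scale
event outcome (e.g. fracture), and paired subjects.

## The model

For twin *j* of pair *i*, the marker trajectory and conditional hazard
are

    M_ij(t) = beta0 + beta1 t + b_ij0 + b_ij1 t + u_i,
    y_ijk   = M_ij(t_k) + e_ijk,              e_ijk ~ N(0, sigma_e^2)
    h_ij(t | v_i) = lambda rho t^(rho-1) v_i exp{gamma' x_ij + alpha M_ij(t)}

with subject random effects (b_ij0, b_ij1) ~ N(0, Sigma_b), a
pair-shared marker effect u_i ~ N(0, sigma_u^2), and a pair-shared
gamma frailty v_i with mean 1 and variance theta. Conditioning on both
pair members surviving to their entry ages leaves the frailty gamma
with an increased rate (the *updated* gamma frailty distribution), and
every likelihood in the package uses that update; `alpha` is the
parameter of interest.

Four estimators of `alpha` (and theta, lambda, rho) are provided:

| method | idea |
|---|---|
| `locf` / `naive` | marker carried forward between observations; `naive` drops the delayed-entry frailty update |
| `orc` | marker values on a dense age grid replaced by BLUP predictions from one twin-structured linear mixed model |
| `rrc` | as ORC, but the mixed model is refitted on the risk set at each event age, using only past measurements |
| `jm` | two-stage joint likelihood: subject BLUPs plugged in, pair effect u integrated numerically, sigma_e^2 estimated |

A data simulator reproducing this design (shared frailty, delayed
entry, dense/sparse observation grids, measurement error) and a
Monte-Carlo harness (relative bias, SD, MCSE, MSE, coverage) are
included; see the methods vignette
(`vignettes/twin-frailty-methods.Rmd`) for the full account.

## Worked example

```r
library(twinfrail)

cfg <- sim_config(n_pairs = 500, alpha = 1, sigma_e = 0.1,
                  grid = list(type = "sparse", max_k = 3), seed = 7)
dat <- simulate_dataset(cfg)
dat
#> twin_data: 415 complete pairs, 830 subjects, 154 events, 1661 marker observations

locf <- fit_frailty(build_locf_startstop(dat))
locf
#> Shared gamma-frailty Weibull fit (415 pairs, 154 events)
#>          estimate          se
#> alpha  0.88229712 0.495100887
#> lambda 0.00067987 0.000444144
#> rho    2.24614672 0.179975201
#> theta  0.45032981 0.333351085
#> logLik: -656.3432  converged: TRUE

stage1 <- fit_lmm(dat$longitudinal)          # twin-structured LMM (ML)
jm <- fit_jm(dat, stage1)                    # two-stage joint model
jm
#> Two-stage joint model fit (415 pairs, 154 events, 20 GH nodes)
#>              estimate           se
#> alpha    0.7379786452 0.7411820875
#> theta    0.4532961607 0.3346113149
#> lambda   0.0008068023 0.0006682142
#> rho      2.2246468480 0.1823949052
#> sigma_u2 0.0072623511 0.0006643647
#> sigma_e2 0.0082341308 0.0003301240
#> logLik: 663.6436  converged: TRUE
```

Of 500 simulated pairs, 415 survive truncation with both members under
observation. Each fit reports the marker effect `alpha`, the frailty
variance `theta` (within-pair dependence of the event times beyond
what the marker explains), the Weibull baseline `lambda`, `rho`, and —
for the joint model — the pair-effect and residual variances of the
marker. At 415 pairs the standard errors are wide; the simulation
scenarios in `inst/scenarios/` use 2000 pairs per replicate, where the
marker-effect SD is around 0.3.

A Monte-Carlo comparison on one of the bundled designs:

```r
spec <- read_scenario_config(system.file("scenarios", "table1_a1.yaml",
                                         package = "twinfrail"))
spec$n_reps <- 50                      # 1000 in the full study
res <- run_scenario(spec)
summarize_mc(res)
```

A thin command-line interface wrapping the same functions is installed
at `exec/twinfrail` (`simulate`, `fit`, `mc`, `summarize`).

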