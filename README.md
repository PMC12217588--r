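# twosexlt

Age-stage, two-sex life table analysis for individual-level arthropod
cohort data.

The age-stage, two-sex life table follows every individual in a cohort
daily from the egg until death — recording stage entries, sex, and daily
egg counts — and turns those records into the standard demographic
machinery: age-stage survival `s_xj`, age-specific survival `l_x` and
fecundity `m_x`, the net reproductive rate `R0 = Σ l_x m_x`, the intrinsic
rate of increase `r` solving the discrete Euler–Lotka equation

    Σ_x e^(−r(x+1)) l_x m_x = 1        (bisection, residual < 1e-10)

the finite rate `λ = e^r`, and the mean generation time `T = ln(R0)/r`.
Uncertainty comes from bootstrapping whole individuals; treatment
comparisons use a paired bootstrap test whose percentile interval of
differences must exclude zero. A renewal-equation projection propagates a
pulse of eggs through the schedules day by day, and a calibrated synthetic
cohort generator (with presets mimicking published two-spotted spider mite
cohorts under plasma-activated water irrigation) makes every analysis
reproducible without raw laboratory data.

See `vignettes/lifetable-methods.Rmd` for the conventions (census timing,
death-age, the `x + 1` exponent and the matching projection recursion),
the bootstrap design, and the generator calibration.

## Worked example

```r
library(twosexlt)

co <- generate_cohort(preset_spec("control"), seed = 101)
co
#> Cohort 'control': n01 = 50 (0 excluded)
#>   females 43, males 4, died immature 3, censored 0
#>   max observed age 49 d, total eggs 2082

fit <- solve_intrinsic_rate(compute_schedules(co))
fit
#> Demographic parameters ('control'):
#>   R0 = 41.6400 offspring/individual
#>   r  = 0.152588 /day   lambda = 1.164845 /day   T = 24.4387 days
#>   Euler-Lotka residual -8.08e-11 after 34 bisection iterations

bootstrap_cohort(co, B = 2000, seed = 1, parameters = c("R0", "r"))
#>    parameter   estimate boot_mean          se      ci_lo      ci_hi    B B_valid degenerate seed
#> R0        R0 41.6400000 41.726540 3.200054469 35.4600000 47.8805000 2000    2000      FALSE    1
#> r          r  0.1525881  0.152543 0.003457586  0.1453979  0.1589925 2000    2000      FALSE    1

paw1 <- generate_cohort(preset_spec("paw1"), seed = 102)
paired_bootstrap_test(co, paw1, "r", B = 2000, seed = 2)
#>   parameter treatment_a treatment_b estimate_a estimate_b difference      ci_lo     ci_hi significant level    B B_valid seed
#> 1         r     control        paw1  0.1525881  0.1059163 0.04667181 0.03203579 0.0653538        TRUE  0.95 2000    2000    2

pr <- project_population(compute_schedules(co), initial_eggs = 10, horizon = 60)
tail(as.data.frame(pr), 1)
#>    day   births      egg    larva protonymph deutonymph adult_female adult_male    total
#> 61  60 2257.726 9974.231 3127.367   2084.165   2425.497     2028.357   253.4642 19893.08
realized_growth_rate(pr, 20)
#> [1] 0.1422817
```

Published-value identities run through the same pipeline on count-exact
reconstruction cohorts:

```r
net_reproductive_rate(compute_schedules(reference_cohort("control")))
#> [1] 40.94
stage_summaries(reference_cohort("paw2"))$immature_mortality
#> [1] 0.26
```

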