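# cultspread

Tools for simulating how socially learned behaviours spread through a
spatially structured animal population, and for asking when *local
traditions* — different sub-populations stably dominated by different
variants of the same behaviour — can emerge and persist.

The motivating system is a cultural diffusion experiment in wild great
tits, where two equivalent techniques for opening a puzzle box ("slide
left" vs "slide right") were seeded at different woodland feeding
stations and their spread monitored. The package models that situation
in general form: a metapopulation of `J` sub-populations in which naive
individuals learn a two-solution task from local solvers, with a
conformist (positive frequency-dependent) bias, while individuals of all
classes move between sub-populations at a distance-weighted rate.

## The model

Within sub-population `j`, individuals are naive (`U`), solvers using
solution 1 (`S1`) or solvers using solution 2 (`S2`). Learning and
preference switching follow the acquisition function

    f_lambda(x) = [ (1/x - 1)^lambda + 1 ]^-1

where `x` is the local prevalence of solution 1 among solvers and
`lambda >= 0` is the conformity strength: `lambda = 1` is unbiased
proportional copying, `lambda > 1` disproportionately favours the locally
common solution. Movement between sub-populations `j` and `i` occurs at
rate `m / d_ji` (distance-weighted) proportional to the destination's
size, which keeps every sub-population at carrying capacity.

In the rescaled (dimensionless) form used for all theoretical analyses,
with `s_k` the solver fractions, `n_s = s1 + s2`, `n^(j)` the
sub-population size fractions and `r = m / alpha` the movement rate
relative to the learning rate:

    ds_k^(j)/dtau = n^(j) n_s^(j) [ f_lambda(s_k^(j)/n_s^(j)) - s_k^(j) ]
                    + r * sum_{i != j} n^(i)/d_ji * (s_k^(i) - s_k^(j))

Final states are summarised by `p_tot` (overall prevalence of solution 1
among solvers) and `p_var` (spatial variance of local prevalence) and
classified into five emerging patterns: strong local traditions
(`p_var > 0.1`), weak local traditions (`p_var > 0.01`), domination of
solution 1 (`p_tot > 0.66`), domination of solution 2 (`p_tot < 0.33`),
or a mixture of solutions everywhere.

Beyond the core simulator the package provides phase-diagram sweeps over
`(lambda, r)`, least-squares calibration of `(m, alpha)` against daily
diffusion curves, randomised-seeding sensitivity analyses, and synthetic
landscape / diffusion-curve generators, so every analysis can be run
self-contained.

## Worked example

```r
library(cultspread)

tp <- make_two_patch(0.5)   # two equal patches, 1% opposed innovators
eq <- steady_state(tp$landscape, tp$seeding, lambda = 3.5, r = 0.35)
tidy(eq)
#> # A tibble: 2 x 3
#>   id       s1    s2
#>   <chr> <dbl> <dbl>
#> 1 P1    0.788 0.212
#> 2 P2    0.212 0.788
glance(eq)
#> # A tibble: 1 x 7
#>   converged stopped_by      time max_abs_deriv p_tot p_var category
#>   <lgl>     <chr>          <dbl>         <dbl> <dbl> <dbl> <fct>
#> 1 TRUE      derivative_tol   100      2.08e-16   0.5 0.166 strong_local_traditions
```

With strong conformity (`lambda = 3.5`) each patch ends up dominated by
the solution seeded in it (79% vs 21%): a local tradition, flagged by the
across-patch prevalence variance 0.166 exceeding the 0.1 threshold while
`p_tot = 0.5` shows neither solution won globally. Rerunning with
`lambda = 1` (no conformist bias) gives `p_var ~ 0` and category
`mixture`: movement homogenises the two patches completely.

A phase diagram over both parameters, and its plot:

```r
pd <- phase_diagram(tp$landscape, tp$seeding,
                    lambda_grid = seq(1, 5, length.out = 11),
                    r_grid = seq(0, 2, length.out = 11))
autoplot(pd)
```

`run_experiment()` exposes the canned designs (`two_patch_phase`,
`three_patch_phase`, `single_population_portrait`, `randomized_seeding`,
`calibration_scan`) and writes their tables plus a reproducibility
manifest; `inst/scripts/cultspread` wraps them for shell use.

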