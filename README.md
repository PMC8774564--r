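# irlayers

Multi-component T1 relaxometry from low-resolution inversion-recovery MRI.

Cortical layers, white matter and CSF are thinner than (or mixed within)
the voxels of a fast low-resolution acquisition, so every voxel's
inversion-recovery (IR) signal is a blend of several compartments with
different longitudinal relaxation times. `irlayers` decomposes that blend:
it fits the multi-component magnitude IR model

```
M(TI_i) = sum_{j=1..n} M0_j * | 1 - 2 exp(-TI_i / T1_j) |,   n <= 7
```

to a voxel's TI series by bound-constrained nonlinear least squares,
minimising `F(theta) = sum_i (y_i - M(TI_i))^2` with a trust-region
solver (two-dimensional subspace subproblem, Coleman–Li interior
scaling, analytic Jacobian) restarted from many random points inside the
parameter bounds — the multi-start is what rescues the fit from the local
minima that plague multiexponential objectives. `T1_j` identifies a tissue
compartment; `M0_j` is proportional to its volume fraction.

The package is aimed at quantitative-MRI researchers who want to

* fit single-voxel IR series (CSV) or whole 4D NIfTI series voxel by voxel,
* simulate the validation conditions (multi-component single-voxel series
  with controlled Gaussian noise; a two-pool imaging phantom with optional
  Rician noise), and
* reproduce the error-table experiments that characterise the estimator
  (accuracy vs number of starts, vs noise level/SNR, and on the phantom).

## Worked example

Simulate a noisy three-component voxel and fit it with 50 random starts:

```r
library(irlayers)

sim <- simulate_voxel_series(voxel_sim_spec(t1_ms = c(700, 1100, 1700)),
                             variance = 1, seed = 42)
fit <- ir_fit(sim$series, n_components = 3, n_starts = 50, seed = 7)
fit
#> Multi-component IR fit: 3 component(s), 50 start(s)
#>   objective (SSE): 103.45   MSE: 0.985238   best start: 32
#> # A tibble: 3 x 3
#>   component    m0 t1_ms
#>       <int> <dbl> <dbl>
#> 1         1  123.  701.
#> 2         2  331. 1101.
#> 3         3  163. 1695.
```

The MSE (~0.99) sits at the injected noise variance (1), i.e. the model
explains everything but the noise. Comparing against the simulated ground
truth after permutation-safe component matching:

```r
component_errors(fit, sim$truth)
#> # A tibble: 6 x 5
#>   family component truth estimate rel_error_pct
#>   <chr>      <int> <dbl>    <dbl>         <dbl>
#> 1 m0             1  122.     123.        0.885
#> 2 m0             2  334.     331.        0.889
#> 3 m0             3  161.     163.        1.28
#> 4 t1             1  700      701.        0.118
#> 5 t1             2 1100     1101.        0.0752
#> 6 t1             3 1700     1695.        0.276
```

All three T1 values are recovered to a fraction of a percent.
`autoplot(fit)` draws the data, the fitted total curve and the
per-component curves; `tidy()` / `glance()` give broom-style summaries.

Volumes work the same way: `read_volume_series("series.nii", "ti_ms.txt")`
then `fit_volume(vol, n_components = 2, seed = 1)` returns per-component
M0/T1 maps (NA outside the mask) that `write_component_maps()` saves as
NIfTI.

A command-line interface wraps the same functions
(`inst/cli/irlayers`): subcommands `simulate-voxel`, `simulate-phantom`,
`fit-series`, `fit-volume`, `table1`, `table2`, `table3`, each with
`--seed`, `--out`, `--config` and solver flags, each writing CSV/NIfTI
outputs plus a provenance JSON.

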