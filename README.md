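# hrfboost

Tools for studying a specific, consequential modeling choice in task fMRI:
accounting for hemodynamic response latency with the **informed basis set**
(the canonical double-gamma HRF plus its first temporal derivative) and
carrying the resulting **derivative boost** forward to group analysis.

The intended user is a neuroimaging methodologist or analyst who wants to
understand — on data with known ground truth — why a model that clearly
improves single-subject fits can fail to improve, or even degrade, group
activation maps.

## The model in brief

First level, per voxel, ordinary least squares:

```
y(t) = X β + ε,   X_i = f_i(t) ⊗ u(t)
```

with `f1` the canonical HRF (difference of two gamma densities, peaking at
5 s, unit peak) and `f2` its temporal derivative, orthogonalized so that β1
keeps its canonical-only interpretation. When the true response is shifted
by δ, β1 is attenuated; the **derivative boost**

```
H = sqrt(β1² Σx1² + β2² Σx2²) · sign(β1)
```

restores the lost amplitude. Boosted contrasts replace β1 by `H/√Σx1²`
only in voxels whose fitted response peaks inside a time-to-peak range —
(4, 6) s constrained, (3, 7) s full.

Second level is the summary-statistics random-effects model,
`t = mean / sqrt(var/N)` across subjects, followed by random-field-theory
cluster-extent inference (primary p < 0.001, cluster p < 0.05 FWE) whose
smoothness input is estimated from the images by the neighbor-correlation
(Flitney–Jenkinson) estimator, `FWHM = sqrt(-2 ln2 / ln ρ₁)` voxels per
axis.

The package includes synthetic generators for every level — single-voxel
latency-shifted series, multi-subject 4D cohorts with per-subject latency /
amplitude / noise and spatial smoothing, and stationary smooth Gaussian
fields — so that every statistic the pipeline produces can be checked
against ground truth or closed forms. See the methods vignette
(`vignettes/informed-basis-boost.Rmd`) for assumptions, parameter defaults
and design notes.

## A worked example

```r
library(hrfboost)

events <- periodic_events(total_duration = 400)   # 10 s on / 10 s off, 0.05 Hz
design <- build_design(events, tr = 0.5, n_scans = 800, basis = "informed")

# a noiseless voxel whose response peaks 1 s late, true amplitude 2
y   <- simulate_voxel_series(voxel_sim_spec(shift = 1, amplitude = 2))$series
fit <- fit_ols(y, design)
w   <- canonical_weights(design)

contrast_image(fit, w)$values
#> [1] 1.898946
boosted_contrast(fit, w, ttp_range("boost_constrained"))$contrast$values
#> [1] 1.944014
```

The canonical estimate is attenuated by the latency mismatch (1.899 < 2);
the boost recovers the amplitude to within ~3%. The shift-grid experiment
shows the whole first-level pattern:

```r
run_shift_simulation(list(shifts = c(-2, -1, 0, 1, 2)))
#>   shift     model  beta1       t r_squared
#>      -2 canonical 0.8127   39.70    0.6639
#>      -2  informed 0.8127  280.34    0.9933
#>      -1 canonical 0.9505   85.87    0.9024
#>      -1  informed 0.9505 1136.85    0.9994
#>       0 canonical 1.0000     Inf    1.0000
#>       0  informed 1.0000     Inf    1.0000
#>       1 canonical 0.9495   85.68    0.9020
#>       1  informed 0.9495 1129.86    0.9994
#>       2 canonical 0.8051   38.33    0.6480
#>       2  informed 0.8051  267.69    0.9928
```

Reading the table: a latency shift degrades the canonical-only fit (R² and
β1 fall off symmetrically with |shift|); adding the derivative restores R²
essentially to its unshifted level and (with noise) improves T, but leaves
β1 unchanged — which is exactly why a group analysis that carries forward
only β1 gains nothing, and why the boost exists. (The infinite T at shift 0
is the exact-fit sentinel of this noiseless illustration.)

The group-level experiment — three strategies (canonical, constrained
boost, full boost) over simulated child-like/adult-like cohorts, with
variance maps, smoothness estimates and cluster inference — runs via:

```r
run_cohort_comparison(list(n_replicates = 5), out_dir = "out")
```

or from the command line:

```sh
Rscript inst/cli/hrfboost run-all --seed 1 --out-dir out
```

CLI subcommands `simulate-voxel`, `simulate-cohort`, `first-level`,
`boost`, `group`, `smoothness`, `inference`, `run-all` chain through
NIfTI/TSV/JSON files; see `?run_cli`.

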