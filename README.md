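# mechpath

Transition path sampling, reaction-coordinate discovery, and rate
constants on toy energy landscapes.

`mechpath` is a desk-scale R implementation of the rare-event workflow
used to resolve the mechanism and kinetics of enzymatic reaction steps
(for example the acylation/deacylation half-reactions of a serine
hydrolase such as a PET-degrading esterase):

- **Aimless shooting** (flexible-length transition path sampling):
  Maxwell–Boltzmann velocities `V0` drawn at a putative transition
  state, propagated forward with `V0` and backward with `-V0` until
  basin commitment; reactive moves seed the next shooting point.
- **Inertial likelihood maximization (iLMax)**: fits the sigmoidal
  committor model `p(product) = [1 + erf(r + a_v·ṙ)]/2` with
  `r = c0 + Σ c_i·CV_i` to the shooting fates, with automatic model-size
  selection (`two_line_select`).
- **Committor histogram validation**: configurations at `r ≈ 0` are
  relaunched with random velocities; a good RC yields a p_B histogram
  peaked at 0.5.
- **Umbrella sampling + MBAR**: harmonic windows along the RC, window
  free energies from the multistate Bennett acceptance ratio with
  decorrelation-aware subsampling, potential of mean force with
  uncertainties, and barrier height ΔG‡.
- **Reactive flux**: transmission coefficient
  `κ(t) = ⟨q̇0·θ(q(t))⟩ / (½⟨|q̇0|⟩)` with plateau detection.
- **Eyring rates**: `k = κ·(k_B·T/h)·exp(−ΔG‡/k_B·T)` with propagated
  barrier uncertainty.

Instead of a QM/MM engine, trajectories come from built-in Langevin
dynamics (BAOAB integrator, C++ core) on analytic double-well
landscapes with tunable barrier height (5–20 k_BT) and friction, so
every estimator can be validated against closed-form ground truth in
minutes on one CPU. External collective-variable time series (CSV) can
be substituted for the toy dynamics in the analysis stages.

## Worked example

Rate constants from barrier heights and transmission coefficients:

```r
library(mechpath)
acyl   <- eyring_rate(16.1, dG_err = 0.6, kappa = 1.00, T = 310)
deacyl <- eyring_rate(18.2, kappa = 0.89, T = 310)
acyl
#> <rate_estimate: k = 28.84 +/- 17.95 1/s (dG = 16.1 kcal/mol, kappa = 1, T = 310 K)>
deacyl
#> <rate_estimate: k = 0.8489 +/- 0 1/s (dG = 18.2 kcal/mol, kappa = 0.89, T = 310 K)>
rate_ratio(acyl, deacyl)
#> [1] 33.96874
```

A 16.1 kcal/mol barrier at 310 K with full transmission gives
k ≈ 28.8 s⁻¹; the 2.1 kcal/mol higher second barrier slows its step by a
factor of ~34, so that step is rate-limiting. The `k_err` on the first
estimate (±17.9 s⁻¹) is the downward excursion of the rate at a
one-sigma-higher barrier (16.7 kcal/mol).

The full pipeline on the bundled double-well quickstart (barrier
8 k_BT, Langevin friction 1, eight independent shooting chains from the
saddle):

```r
config <- yaml::read_yaml(system.file("extdata", "quickstart.yaml", package = "mechpath"))
config$output_dir <- tempfile("qs")
manifest <- run_pipeline(config)
#> <run_manifest>
#>   seed_points    ok
#>   shooting       ok
#>   decorrelation  ok
#>   rc_fit         ok
#>   committor      ok
#>   umbrella       ok
#>   kinetics       ok
jsonlite::fromJSON(file.path(config$output_dir, "results.json"))
```

prints (seed 7, ~2 minutes):

| quantity | value | meaning |
|---|---|---|
| `reactive_fraction` | 0.559 | fraction of shooting moves whose two halves committed to opposite basins |
| `rc.coeffs.x_1` | +13.1 | the fitted RC is ∝ x — the true separatrix coordinate (scale is arbitrary; positive = product side) |
| `committor.mean`, `pass` | 0.47, `TRUE` | p_B histogram of the 40 best candidates is centered on ½: the RC is validated |
| `barrier.dG` | 7.55 k_BT | MBAR barrier along the RC (analytic truth: 8 k_BT at this sampling depth) |
| `kappa.plateau` | 0.835 | reactive-flux plateau: ~17% of crossings recross at friction 1 |
| `rate.k` | 2.8×10⁹ s⁻¹ | Eyring rate for a 7.55 k_BT barrier at 310 K with κ = 0.835 |

Artifacts (JSON-lines shooting ensemble, RC model JSON, committor and
PMF CSVs, manifest with per-stage seeds) are written under
`output_dir`; rerunning the same config reproduces them byte-for-byte.

## Package layout

| module | contents |
|---|---|
| `R/toy-systems.R` | analytic potentials, BAOAB Langevin propagator, Maxwell–Boltzmann velocities |
| `R/collective-variables.R` | distances/angles/dihedrals/differences with analytic gradients and rates |
| `R/shooting.R` | basins, aimless-shooting moves and campaigns, decorrelation filter, `find_ts` |
| `R/rc-discovery.R` | `ilmax_fit`, `two_line_select`, RC model I/O |
| `R/committor.R` | TS candidate selection, committor trials, histogram test |
| `R/free-energy.R` | umbrella windows/sampling, MBAR solver, PMF, barrier height |
| `R/kinetics.R` | reactive flux κ(t), Eyring rates, rate ratios |
| `R/workflow-io.R` | YAML run configs, `run_pipeline`, external CV series import |

The methods vignette (`vignettes/rare-event-pipeline.Rmd`) documents the
models, the numerical choices, and what the toy-system validations do
and do not demonstrate about real molecular systems.
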