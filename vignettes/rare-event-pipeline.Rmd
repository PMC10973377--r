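---
title: "Resolving reaction mechanisms with transition path sampling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving reaction mechanisms with transition path sampling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechpath)
```

## The problem

Chemical steps in enzyme catalysis -- for example the acylation and
deacylation half-reactions of a serine hydrolase -- are rare events: the
system spends almost all of its time in metastable basins (reactant,
product) and crosses the barrier in fleeting, unbiased trajectories that
ordinary simulation almost never observes.  Characterizing such a step
means answering four questions:

1. **Which coordinate carries the reaction?**  A reaction coordinate (RC)
   is a scalar function of configuration whose isosurface at 0 coincides
   with the stochastic separatrix, the set of configurations equally
   likely to relax to either basin.
2. **Is the proposed RC right?**  Validated by the committor test: points
   at RC = 0 must have committor probability near one half.
3. **How high is the barrier?**  The potential of mean force (PMF) along
   the RC, from biased sampling.
4. **How fast is the reaction?**  Transition-state theory corrected by a
   transmission coefficient, through the Eyring equation.

`mechpath` implements the full chain of methods used to answer these
questions -- flexible-length aimless shooting, inertial likelihood
maximization, committor histogram analysis, umbrella sampling with MBAR,
reactive flux, and Eyring rates -- as reusable components, exercised on
analytic toy landscapes where every answer is known in closed form.  The
toy systems replace the expensive QM/MM force evaluations of a real
enzyme study; everything downstream of the force call is the same
machinery.

## Toy landscapes as the synthetic-data generator

The generator emulates the statistical structure of barrier-crossing
trajectories, not their chemistry:

- **Two metastable basins** separated by a barrier of tunable height.
  `double_well_1d` is $V(x) = b\,((x/a)^2 - 1)^2 + t\,x$ with minima near
  $x = \pm a$ and saddle height $b$ at $x = 0$; defaults use reduced units
  ($k_B = 1$, so $b$ is in units of $k_B T$ at $T = 1$).  Barriers of
  5–20 $k_B T$ reproduce the rare-but-not-unreachable regime of enzyme
  chemistry at the toy scale; the package defaults use $b = 8\,k_B T$.
- **A true RC hidden among irrelevant coordinates.**
  `tilted_double_well_2d` adds a harmonic transverse coordinate (and
  optionally a linear tilt and bilinear coupling); with zero coupling the
  separatrix is exactly the $x$ axis, giving a ground truth for RC
  discovery.  `linear_combo_nd` embeds the double well along an arbitrary
  unit vector in $n$ dimensions with harmonic confinement orthogonal to
  it, so the true RC is a known linear combination of many candidate
  coordinates.
- **Maxwell–Boltzmann velocities** at a stated temperature
  (`draw_velocities`), each component with variance $k_B T / m_i$.
- **Tunable friction.**  Dynamics are Langevin, integrated with the BAOAB
  splitting (velocity Verlet in the frictionless limit).  Friction
  $\gamma$ controls recrossing and therefore the transmission
  coefficient, which is how the toy systems emulate everything from
  ballistic ($\kappa = 1$) to diffusive ($\kappa \ll 1$) barrier
  dynamics.

What the generator does **not** emulate: anharmonic multi-state PMFs with
shoulders, high-dimensional entropic bottlenecks, non-Markovian friction,
and chemically meaningful CVs (bond distances during bond breaking).
Passing tests on these landscapes therefore demonstrate the correctness
of the estimators, not the adequacy of any particular CV set for a real
enzyme.

Units: in `"reduced"` mode energies are in $k_B T$ and time is the
natural unit of $\sqrt{m\,a^2 / k_B T}$.  The `"biomolecular"` mode keeps
energies in kcal/mol with $k_B = 0.0019872041$ kcal/(mol K), which is
what the Eyring stage consumes; its prefactor $k_B T / h$ is evaluated in
SI so rates come out in s$^{-1}$.

## Aimless shooting

A shooting move draws fresh Maxwell–Boltzmann velocities $V_0$ at a
putative transition-state configuration and integrates forward with
$V_0$ and backward with $-V_0$, each half until it first satisfies a
basin definition (flexible length) or reaches a step cap (default
$10^4$; timeouts count as non-reactive).  Basins are conjunctions of
strict CV inequalities; a configuration satisfying both basin
definitions at once is reported as a configuration error rather than
classified arbitrarily.  A move is *reactive* when the halves commit to
opposite basins; the next shooting point is then taken from the forward
trajectory at a uniformly random time offset (the analogue of the
1–10 fs offset used with 1 fs timesteps in QM/MM practice, here
`offset_window = c(dt, 10 dt)`).  Rejected moves resample velocities at
the same point, and all attempted moves are retained for likelihood
maximization -- non-reactive fates are informative data, not waste.

Chains started from a hand-seeded transition state are initially biased;
`decorrelation_filter()` drops, per chain, the shortest prefix such that
no CV shows a significant sample autocorrelation (lags 1–20, normal
bands $\pm z_{1-\alpha'/2}/\sqrt{n}$) over the retained suffix.  The
working level $\alpha = 0.05$ is Bonferroni-corrected across CVs *and*
lags; correcting over CVs alone would reject most white-noise chains
outright (with 20 lags at 5% each, a clean suffix passes only
$\approx 0.36$ of the time), which would defeat the filter's purpose.

`find_ts()` seeds the first transition state the same way an automated
workflow does against an MD engine: harmonic restraints drag the
bond-forming/breaking CVs linearly from their reactant values to their
product targets, intermediate frames are harvested, and each uncommitted
frame is verified by five shooting moves, kept if at least one is
reactive.  Verified frames are returned sorted by their verification
success count, because one-in-five verification is permissive enough
that an occasional frame well off the separatrix passes by luck.

## Inertial likelihood maximization

Shooting fates are Bernoulli observations of the committor.  The model is

$$p(\text{product} \mid x, v) \;=\; \tfrac12\bigl[1 + \operatorname{erf}(r + a_v \dot r)\bigr],
\qquad r = c_0 + \textstyle\sum_i c_i\,\mathrm{CV}_i,$$

with $\dot r = \sum_i c_i\,\mathrm{d CV}_i/\mathrm{d}t$ entering only in
the inertial variant; the velocity term rewards coordinates whose
initial rate of change predicts the outcome, i.e. coordinates with high
transmission.  The error-function link is the standard choice in
aimless-shooting likelihood maximization.  Since
$\tfrac12[1+\operatorname{erf}(z)] = \Phi(\sqrt2 z)$, the objective is
evaluated through `pnorm(..., log.p = TRUE)` with an analytic gradient,
optimized by multi-start BFGS (5 seeded starts, relative tolerance
$10^{-12}$).  The non-inertial special case is exactly probit
regression, which provides an independent cross-check in the tests
(`glm(..., binomial("probit"))` coefficients divided by $\sqrt2$).

Numerical choices: CVs are standardized internally and coefficients are
reported back in raw CV units, mirroring the convention in which printed
RC forms carry small coefficients on radian-scale CVs.  Constant CVs are
excluded with a warning.  Perfectly separable fates would push the
coefficients to infinity (the erf saturates; the likelihood gains
nothing), so the standardized coefficient norm is capped at 20 and the
model flagged `separable`.  Records whose forward half timed out are
excluded from the likelihood.  After fitting, the sign convention is
enforced so that product-committed shooting points have higher mean $r$
than reactant-committed ones: negative RC values denote progress toward
reactant, positive toward product.

**Model size selection** (`two_line_select`) scans $k = 1..k_{\max}$ with
greedy forward selection and fits a broken line to $(k, \log L_k)$.  The
breakpoint minimizing the summed residual of the two segments is
accepted only if the likelihood curve genuinely turns from steep to
flat there -- first-segment slope at least 10 times the second.  The
ratio threshold was chosen from the structure of the two regimes rather
than tuned: with informative CVs present the slope ratio at the true
support size is in the hundreds (each missing informative CV is worth
hundreds of log-likelihood units, each noise CV only $\sim 1$), while
for pure noise the greedy gains decay gently and the ratio stays below
$\sim 3$; any threshold in the intervening decade behaves identically.
A featureless curve falls back to the single best CV.

## Committor analysis and the histogram test

`select_ts_candidates()` takes the shooting points with smallest $|r|$
(deterministic tie-break by provenance), and `committor_analysis()` runs
one-directional trials from each with fresh Maxwell–Boltzmann
velocities, to commitment or timeout.  $p_B$ is the committed-to-product
fraction; timeouts are excluded from the denominator and reported.  The
histogram test summarizes the $p_B$ distribution in 10 right-closed bins
on $[0,1]$.  "Peaked near one half" is made operational as: mean
$p_B \in [0.45, 0.55]$, at least 40% of points with
$p_B \in [0.4, 0.6]$, and no mode in an extreme bin.  The third clause
matters because a *bimodal* histogram (half the points at 0, half at 1)
has a perfect mean yet is the signature of a coordinate orthogonal to
the true separatrix.

## Umbrella sampling and MBAR

Windows are spaced evenly along the restrained quantity (the fitted RC
or a bare CV); the package defaults mirror standard practice for
dimensionless RCs -- width 0.25, restraint 50 energy-units per RC-unit²,
five independent simulations per window, with the window range extended
slightly past the RC values observed at the committed endpoints of
reactive shooting trajectories (`range: auto` in the pipeline
configuration).  Restraints are applied through chain-rule forces
$-k(q - q_0)\nabla q$; for toy systems $\nabla q$ is analytic for
coordinate projections, affine RC models, and interparticle distances
(angle/dihedral restraints are not supported by the toy integrator).  An
optional linear force-constant ramp equilibrates windows started from
off-center configurations; ramp and equilibration samples are excluded
from the record.  `pathway_restraints()` adds half-harmonic walls on
each constituent CV at the envelope its values spanned over reactive
shooting records (plus a 5% margin), so windows far along a composite
RC cannot wander into regions the unbiased reactive trajectories never
visited -- without the walls, the harmonic window bias alone constrains
only one linear combination of coordinates.

Each window series is reduced by its statistical inefficiency
$g = 1 + 2\sum_t \hat\rho_t$ (initial positive sequence, subsample
stride $\lceil g \rceil$) before estimation.  The window free energies
solve the MBAR self-consistent equations

$$f_k = -\log \sum_n \frac{\exp(-u_k(x_n))}{\sum_{k'} N_{k'} \exp(f_{k'} - u_{k'}(x_n))}$$

by damped-free self-consistent iteration with a Newton polish (gauge
$f_1 = 0$, tolerance $10^{-8}\,k_BT$; all sums via log-sum-exp).  The
tests cross-check the solver against an independent route -- direct BFGS
minimization of the convex MBAR objective -- to $10^{-6}\,k_BT$, and
against Zwanzig exponential averaging in the two-state case.  The PMF is
the negative log of binned unbiased MBAR weights (100 bins by default),
shifted so its minimum is zero.  Per-bin uncertainties are first-order
delta-method standard errors from the normalized weights
($\mathrm{SE}(G_i) = k_BT\sqrt{(1-p_i)/(p_i\,n^{\mathrm{eff}}_i)}$ with
the Kish effective count $n^{\mathrm{eff}}_i = (\sum w)^2/\sum w^2$);
this is a deliberate simplification of the full asymptotic covariance,
adequate for error bars whose own error is not propagated further.
Adjacent windows with no mutual overlap (no sample plausible under both
biases at $\le 15\,k_BT$) are reported as an error naming the gap.

`barrier_height()` is arithmetic on the profile: the reactant minimum is
located inside a user-stated interval, the far-side minimum outside it,
and $\Delta G^\ddagger$ is the maximum between the two minima, with the
two bins' uncertainties combined in quadrature; monotone profiles are an
error, not a zero barrier.

## Reactive flux and rates

From trials launched at the dividing surface with recorded initial RC
rate $\dot q_0$,

$$\kappa(t) \;=\; \frac{\langle \dot q_0\,\theta(q(t))\rangle}{\tfrac12\langle |\dot q_0| \rangle},$$

with $\theta(q) = 1$ for $q > 0$, evaluated from each trajectory's first
post-launch frame.  Trajectories are stored to commitment and $\theta$
is frozen at its committed value afterwards, so $\kappa(t)$ is exactly
constant once the last trajectory has committed; the plateau is the mean
over the longest terminal interval where the smoothed $|d\kappa/dt|$
stays below 1% of $\kappa(0^+)$ per unit time, intersected with that
frozen region.  This makes the plateau coincide -- to summation order --
with the direct recrossing recount
$\sum_i \dot q_{0,i}\,\theta_i(\infty) / \tfrac12\sum_i |\dot q_{0,i}|$,
which the tests verify at $10^{-12}$.  Note that $\kappa(0^+) = 1$ holds
in expectation by Maxwell–Boltzmann symmetry; on a finite trial set the
estimator carries the sampling error of the $\dot q_0$ asymmetry, which
is why the tests assert the short-time limit within its standard error
rather than exactly.

`eyring_rate()` computes $k = \kappa\,(k_B T/h)\,e^{-\Delta G^\ddagger / k_B T}$
with the prefactor in SI and the exponent in kcal/mol.  The propagated
uncertainty is the downward excursion at a one-sigma-higher barrier,
$k_{\mathrm{err}} = k - k(\Delta G^\ddagger + \sigma)$: with
$\Delta G^\ddagger = 16.1 \pm 0.6$ kcal/mol, $\kappa = 1$, $T = 310$ K
this reproduces a $\pm 17.9\,\mathrm{s}^{-1}$ band around
$28.8\,\mathrm{s}^{-1}$, matching the arithmetic of published estimates
of this form; the rule is declared here because barrier-uncertainty
propagation conventions differ across the literature.

## Orchestration, reproducibility, and problem sizes

`run_pipeline()` executes seeding → shooting → decorrelation → RC fit →
committor validation → umbrella/MBAR → reactive flux → Eyring from one
YAML configuration, persisting each stage (JSON-lines ensemble, JSON RC
model, CSV committor table and PMF, JSON results and manifest).  Unknown
configuration keys are rejected; jointly satisfiable basin definitions
are rejected at validation with the offending conditions named.  Every
stochastic operation takes an explicit seed; campaign seeds spawn
per-chain/per-move/per-trial streams through a deterministic integer
hash (`derive_seed`), so identical configurations produce byte-identical
artifacts.  External CV time series (CSV with a uniform-stride `time`
column) can replace toy trajectories for the analysis stages, with
finite-difference rates substituting for analytic ones.

The bundled quickstart and the test suite run at deliberately desk-scale
sizes -- hundreds to thousands of shooting moves, 33-window umbrella runs
with $5 \times 20{,}000$ steps, committor panels of 100 points × 10
trials -- chosen so each stage's statistical error sits comfortably below
the tolerances being asserted (e.g. PMF recovery to better than
$0.1\,k_BT$ RMS) while the whole suite completes in minutes on one CPU.

## Known limitations

- Toy dynamics only: no PBC, constraints, barostats, or external MD
  engine coupling; umbrella restraints cover linear-in-coordinates
  quantities and distances.
- The inertial term $a_v \dot r$ is one committed functional form among
  several used in the literature.
- MBAR per-bin uncertainties are first-order; they are not a substitute
  for replicate-level error estimation when error bars themselves are
  the quantity of interest.
- The committor-based flux estimator assumes trials are launched close
  to the $r = 0$ surface; launching from a shell of finite $|r|$ biases
  $\kappa(0^+)$ low.
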