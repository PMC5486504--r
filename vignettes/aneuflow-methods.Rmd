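---
title: "Methods: idealized aneurysm hemodynamics and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: idealized aneurysm hemodynamics and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(aneuflow)
```

# Scope and model

`aneuflow` studies how sidewall-aneurysm morphology shapes the wall shear
stress (WSS) environment of the sac, and how the resulting hemodynamic
metrics separate ruptured from unruptured aneurysms in a cohort. The
pipeline has four stages — parametric geometry, pulsatile flow simulation,
WSS metric extraction, and cohort statistics — plus a synthetic cohort
generator that stands in for patient angiographic data.

## The 2-D reduction

Patient aneurysms are 3-D; this package deliberately works with planar
sidewall profiles: a straight parent channel of height equal to the vessel
caliber, with the sac attached to one wall. The reduction keeps every metric
definition intact as a ratio of measures — "dome area" becomes sac boundary
arc length, surface integrals become arc-length-weighted sums — while
keeping the flow solver small enough to be fully validated against
closed-form solutions. The price is quantitative: a 2-D channel does not
reproduce 3-D inflow-jet impingement, so absolute sac-WSS magnitudes are
lower than patient-scale values and only *relative* contrasts (narrow vs
wide, ruptured vs unruptured calibration) are meaningful. The test suite
and acceptance script therefore check directions, ratios and analytic
benchmarks, never patient-table magnitudes.

## Geometry and morphology

Two shape families span the clinically reported aspect-ratio range
(roughly 0.5–3.1):

* **hemispherical bump** — a half-disc of radius $r$; neck width $2r$,
  aspect ratio exactly 0.5; the canonical wide-necked sac;
* **circular sac with constricted neck** — a disc of radius $r$ centered
  $c$ above the wall, joined to the lumen by a neck of width $w < 2r$;
  height $= c + r$, so deep high-AR sacs are produced by raising $c$. The
  feasibility constraint $c \ge \sqrt{r^2 - (w/2)^2}$ keeps the disc from
  protruding below the wall outside the neck.

Morphology follows the clinical conventions: *height* is the maximum
distance from the neck midpoint to the sac boundary (the stated definition
reads as a maximal distance; measuring perpendicular to the neck plane is
the plausible alternative, and for these symmetric shapes the two coincide
at the dome tip). *Aspect ratio* is height/neck. The neck classification is
narrow iff AR ≥ 1.4 **and** neck < 4 mm; the 4 mm clause is read as an
override, so a high-AR sac with a ≥ 4 mm neck is wide-necked — the clinical
wide-neck convention. The boundary value AR = 1.4 is narrow (inclusive).

## Flow solver

The solver integrates the unsteady incompressible Navier–Stokes equations
on a uniform staggered (MAC) grid with masked solid cells, using a
finite-volume discretization and SIMPLE pressure–velocity coupling:

* first-order upwind convective fluxes, central diffusion;
* implicit Euler in time, default $\Delta t = T/200$ per cardiac cycle;
* under-relaxation 0.7 (velocity) / 0.3 (pressure), Gauss–Seidel momentum
  sweeps, Jacobi-preconditioned conjugate gradients for the
  pressure-correction Poisson equation (the correction matrix is symmetric
  positive definite with the outlet Dirichlet condition);
* per-time-step convergence to a scaled mass-imbalance tolerance of
  $10^{-6}$ (relative to the instantaneous inlet mass flux) plus a relative
  velocity-change tolerance; non-convergence is a hard error carrying the
  residual history — no silent fallback.

Boundary conditions are the study's: flat (uniform) inlet velocity scaled
to the instantaneous waveform, zero gauge pressure with zero-gradient
velocity at the outlet, rigid no-slip walls. Wall shear is recovered from
the half-cell one-sided gradient next to masked cells; on axis-aligned
walls the staircase error vanishes, which is what the channel benchmarks
exercise. Staircase masking was chosen over body-fitted meshing because a
constricted (overhanging) neck cannot be represented by a single-valued
wall height.

The inflow waveform is the single harmonic
$Q(t) = Q_\text{mean} + (Q_\text{max} - Q_\text{mean})\sin(2\pi f t)$ —
the only waveform datum available is the (mean, max, rate) triple, and this
form reproduces all three. Three cycles are integrated from rest and the
last is analyzed; with the physiological viscous time scale
$\rho H^2/\mu \approx 3$ s against a 0.94 s period, the start-up transient
decays by more than $e^{-8}$ within two cycles (the 3-vs-4-cycle agreement
is regression-tested at 1%).

**Dimensional matching.** The 2-D channel is tied to the circular-vessel
physiology through the reference diameter $D$: the inlet velocity is
$U(t) = 4Q(t)/(\pi D^2)$, so with $D$ equal to the channel caliber the
caliber-based channel Reynolds number equals the printed vessel Reynolds
number. The printed pair (Re 364, α 2.32) is internally consistent only to
about 1–2% under the circular-vessel formulas; the package treats $D$ as
derivable from either number (`diameter_from_reynolds`,
`diameter_from_womersley`) and the acceptance script reports both
cross-checks rather than asserting one.

**Validation design.** The analytic oracles (plane Poiseuille
$u = 6qy(h-y)/h^3$ and the oscillatory profile
$\hat u \propto 1 - \cosh\lambda(y-h/2)/\cosh(\lambda h/2)$,
$\lambda = \sqrt{i\omega/\nu}$) hold for *developed* flow, so the
benchmarks run at a low channel Reynolds number (Re ≈ 5, entrance length
under 1 mm) while keeping the physiological Womersley number α ≈ 2.3 —
the oscillatory profile shape depends on α, not on Re. Benchmarks use 8–32
cells across the channel and a 10 mm channel; the cohort runs use the
physiological Re 364 at a coarse 0.405 mm grid (caliber/8), where the
advective CFL exceeds 1 and the solver warns: implicit stepping remains
stable and the end-to-end checks are directional, not quantitative.

## WSS metrics

Per wall element $i$, the cycle average
$\mathrm{WSS}_i = \frac{1}{T}\int_0^T |\mathrm{wss}_i|\,dt$ is computed by
trapezoidal quadrature with periodic closure (the sample at the cycle start
is identified with the cycle end). Metrics:

* **MWSS** — arc-length-weighted sac mean of the time-averaged field;
* **HWSS** — sac maximum. The source definition ("highest magnitude") does
  not say whether the maximum is taken over the time-averaged field or over
  elements *and* times; the default is the max of the time-averaged field,
  with `hwss_mode = "peak"` for the instantaneous reading;
* **PWSS** — weighted mean over the parent reference segment, by default
  2 mm of the sac-bearing wall centered 10 mm upstream of the nearer neck
  endpoint. The 10 mm distance is the stated convention; the extent and
  wall side are not, so both are configurable (upstream is the default as
  the hemodynamic reference side). PWSS averages the time-averaged (cycle
  mean) field; for this definition averaging over time and elements
  commutes;
* **LSAR** — the fraction of sac arc length with time-averaged WSS
  *strictly below* $0.1 \cdot$ PWSS ("below 10%" is read strictly, so
  boundary elements are not low-shear);
* **M-P** and **H-P** ratios — MWSS/PWSS and HWSS/PWSS.

Sac arc-length weights are obtained by projecting the true boundary
polyline onto the nearest sac wall faces, so the sac weight total equals
the true arc length rather than the staircase perimeter (which would
overestimate a semicircle by ~27%); parent-wall weights equal the cell size
exactly. These definitions make the invariants structural: LSAR ∈ [0, 1],
HWSS ≥ MWSS, and scaling the whole field leaves LSAR and the ratios
unchanged because the threshold tracks PWSS.

## Synthetic cohort generator

The generator emulates the study population: 72 aneurysms, 41 ruptured and
31 unruptured, each label split between neck strata. The published tables
do not report per-label stratum counts, so both labels default to an even
split — a choice made once, documented here.

**Metric mode** draws MWSS, HWSS, PWSS, LSAR per record from group
distributions calibrated to the published four-group descriptives:
truncated normal (at zero; LSAR additionally at one) for mean ± SD entries,
log-normal matched to median/quartiles for the skew-reported wide-stratum
MWSS. The single printed "quartiles" figure is ambiguous (IQR or Q3); the
default reading is IQR with Q3 available via
`quartile_interpretation = "q3"`, and neither is asserted as the source's
intent. The ratios are never sampled: they are recomputed from the sampled
base metrics, which guarantees the metric invariants but means the ratio
moments follow from the base calibration rather than matching the printed
ratio rows exactly. `HWSS >= MWSS` is enforced by redrawing the pair, which
slightly reshapes both tails where the calibrated distributions overlap —
the price of internal consistency. Morphology is drawn uniformly over the
stratum-consistent clinical ranges (AR 1.4–3.1 narrow, 0.49–1.39 wide;
heights within the reported 2.5–15.7 mm span).

**Geometry mode** draws shape parameters per stratum (deep constricted-neck
sacs for narrow; hemispherical bumps and shallow/wide circular sacs for
wide), verifies each accepted geometry post hoc with `classify_neck`, and
rejects mis-stratified draws (a stratum rejecting > 90% of draws is an
infeasible specification and errors). Each record derives an independent
RNG substream from the global seed, so cohorts are reproducible under
parallel or per-record execution.

What the generator does *not* emulate: angiographic segmentation error,
within-patient correlation of multiple aneurysms (records are independent,
as the source statistics also assumed), or any real geometry–hemodynamics
joint distribution in metric mode. Passing tests on synthetic cohorts
demonstrates the machinery and the calibrated contrasts, not clinical
validity on real populations.

## Statistics

The statistical arm mirrors the SPSS-style procedure:

* **Normality gate** — one-sample Kolmogorov–Smirnov against a normal with
  estimated moments, with Lilliefors-corrected critical values (the
  uncorrected estimated-parameter KS test is anti-conservative). Which
  exact KS variant the original software applied is unknowable; the
  Lilliefors choice is documented, not attributed. The gate is applied per
  variable per group; both groups must pass at p ≥ 0.05 for the t test.
* **Two-group tests** — equal-variance independent-samples t test (Welch
  via `var_equal = FALSE`), otherwise Mann–Whitney U: exact enumeration
  when the smaller group has ≤ 8 observations and there are no ties,
  tie-corrected normal approximation with continuity correction otherwise.
  Descriptives are style-matched: mean ± SD under the t test, median with
  both quartiles otherwise (the single printed "quartiles" number is
  ambiguous, so Q1 and Q3 are both reported).
* **Spearman correlations** between hemodynamic and morphology factors,
  average ranks under ties, two-sided p.
* **Univariate screen** at p < 0.05 feeding **backward stepwise binary
  logistic regression** with Wald-p removal at 0.10 (the screening
  threshold is stated; the removal threshold is the common default). The
  removal trace is recorded and replaying it reproduces the final
  coefficients bit for bit. Complete separation is detected and flagged
  rather than reported as converged coefficients. No multiple-testing
  correction is applied across metrics, matching the source procedure;
  this is a faithful-reproduction choice, not a statistical
  recommendation.

## Numerical choices and degenerate inputs

* Time quadrature: trapezoid with periodic closure; exact for constants,
  0.1%-level for rectified sinusoids at 1000 samples/cycle.
* Zero inflow yields identically zero fields and converges immediately;
  zero PWSS makes the ratios undefined and is a hard error.
* Ties in classification: AR ≥ 1.4 inclusive; LSAR threshold strict.
* Meshing floor: cell size ≤ caliber/8 and ≥ 8 rows across the parent;
  a sac too small for any cell center errors rather than silently
  vanishing.
* Lilliefors needs n ≥ 5; smaller groups fall back to Mann–Whitney.
* Problem sizes used by the shipped tests and acceptance script: channel
  benchmarks at 8–32 cells across a 10 mm channel, cohort CFD at
  0.405 mm cells with 60 steps/cycle over 8 records, statistical
  simulations at 100–2000 replicates. These sizes make the whole
  validation run in minutes on one core while keeping every check
  well-resolved; they are stated here so results are reproducible at the
  same sizes.

## Known limitations

Rigid walls and Newtonian rheology (as in the source model); 2-D planar
geometry (no jet impingement, no secondary flow); first-order convection
upwinding at coarse cohort resolutions; single-harmonic waveform; metric
magnitudes not comparable to 3-D patient values (directions and ratios
are). Oscillatory shear index and WSS-gradient metrics are out of scope.
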