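---
title: "Modelling coupled serotonin and opioid signalling in enteric neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling coupled serotonin and opioid signalling in enteric neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oicsim)
```

# The model

`oicsim` simulates the two G-protein-coupled signalling arms that converge
on adenylyl cyclase (AC) in enteric motor neurons.  Serotonin (5HT),
released from an enterochromaffin-cell pool, activates the Gs-coupled
receptor 5HTR4; an opioid ligand, arriving in the tissue from a blood
compartment, activates the Gi-coupled mu-opioid receptor (MOR).  Both
receptor complexes catalyse nucleotide exchange on their G-alpha subunits;
GTP-bound Gαs and Gαi then compete for AC, engaging it in a stimulated
(`AC:aS_GTP`) or inhibited (`AC:aI_GTP`) complex.  Cyclic AMP — the
motility proxy — is produced at a Hill-type rate in the activated-AC
fraction and degraded first order.

The network has 25 reactions over 20 species.  All propensities are mass
action except the cAMP production reaction, and the state evolves by the
deterministic reaction-rate equations `dx/dt = S π(x)`.  The model is
well mixed and non-spatial; the only compartmental structure is the pair
of blood/tissue opioid species connected by first-order transfer.
Stochasticity is neglected throughout: copy numbers at the assumed volume
are large enough that concentration dynamics dominate, and no reaction is
bistable or excitable.

Units are µM for concentrations and ms for time (binding constants
µM⁻¹ ms⁻¹); user-facing reports convert times to hours and days.

## Conservation structure

Seven moieties are closed under the 25 reactions: both receptor pools
(free + bound), the AC pool (free + stimulated + inhibited), and the four
G-protein subunit pools.  `conserved_totals()` exposes them, the test
suite checks that their indicator vectors lie in the left null space of
the stoichiometric matrix, and long dosed trajectories are required to
hold them to below 1 ppm relative drift — a sharp end-to-end check on the
integrator configuration.

One deliberate asymmetry: the printed unbinding reactions return only the
free receptor (`5HTR4:5HT → 5HTR4`, `MOR:OL → MOR`), i.e. the ligand
molecule is consumed by the unbinding event.  We implement this literal
reading (ligands are not conserved species anyway — both have independent
sources and sinks) and provide `release_ligand_on_unbind = TRUE` to
restore the conventional reversible binding.  At the default rates the
distinction is numerically irrelevant: unbinding carries ~1e-13 µM/ms at
baseline, orders below the ligand turnover fluxes.

## Parameters and the choices behind them

Rate constants and initial concentrations are the published table values,
with four points where a choice had to be made:

* **AC pool.**  The printed initial AC concentration (2×10⁻³⁴ µM) is a
  typesetting artifact — it corresponds to far less than one molecule per
  cell.  We default to `AC = 2e-3` µM (the same mantissa at a plausible
  enzyme abundance, and a value small enough that AC complexes never
  deplete the G-alpha pools), configurable through
  `default_initial_state()`.
* **k3 (Gαi displacing Gαs from AC, reaction C3).**  No independent value
  is available; it defaults to the AC association rate `3.5e-3`
  µM⁻¹ ms⁻¹, the same class of molecular event.  The test suite reports
  its sensitivity: a factor 10 either way moves simulated pIC50 by under
  one log unit and recovery times by under 50%, and cannot affect
  receptor occupancy, which is set upstream of AC.
* **kon/koff split.**  Only equilibrium affinities (Kd) are tabulated per
  drug.  We fix `koff = 5e-8` ms⁻¹ for every ligand — the same order as
  the serotonin receptor's unbinding rate — and derive `kon = koff / Kd`,
  so that affinity differences are carried entirely by the on-rate.  Both
  are overridable per drug.  This choice matters: it sets the receptor
  off-kinetics (hours) that dominate recovery once the free drug has
  cleared, and is the main reason some cross-drug orderings below are
  soft.
* **Tissue degradation `kdegOL`.**  Pharmaceutical opioids default to
  `1e-8` ms⁻¹ (slow, ~19 h half-life, consistent with multi-day depletion
  after an acute dose).  Endomorphin-2, rapidly cleaved by gut
  peptidases, defaults to `1.02e-4` ms⁻¹ — the tabulated in-vitro rate
  scaled down by 10⁻², since the in-vitro setting mixes cellular
  compartments that accelerate degradation.

Dosing places the bolus in the blood species `OL_Blood` at the dose time
(the tissue opioid and blood pools start at zero and the transfer rate is
described as blood-to-tissue delivery); assay-style protocols can instead
clamp the tissue concentration directly.

Serotonin release is continuous mass action by default.  A pulsed mode
(`pulse_release`) gates the release reaction with a square wave of
configurable amplitude, period and duty cycle, for burst-like release;
it is off by default and excluded from steady-state analyses.

# Protocol definitions

## Agonist dose–response (AC activation vs 5HT)

With the enterochromaffin source running, the serotonin arm settles at a
fixed operating point regardless of any added 5HT, so a dose–response
requires the applied dose to be the only stimulus.
`simulate_agonist_curve()` therefore silences the EC-cell synthesis,
initialises `[5HT](0)` at the dose, and integrates the serotonin pathway.
Free 5HT decays within seconds, but the receptor complexes it forms
persist for hours (unbinding is slow), driving the G-cascade to a
quasi-steady plateau over minutes; the recorded response is the peak
activated-AC fraction, i.e. that plateau.  This "peak of the slow
manifold" readout is well defined without choosing an arbitrary readout
time.  A 4PL fit of the curve yields EC50 and Hill slope;
`receptor_density_sweep()` repeats this across 5HTR4 densities.

A known deviation: across densities 5e-6 to 5e-5 µM our per-density EC50
varies by a factor of ~4 (receptor reserve grows with density, pulling
the midpoint below the occupancy midpoint), whereas the published curves
are reported as density-insensitive around a lower EC50.  The printed
rate table does not reproduce that insensitivity under any readout we
examined; the discrepancy is documented rather than tuned away, and the
Hill slope (~1.1–1.2, mild positive cooperativity) is reproduced.

## Inhibition dose–response (cAMP vs opioid, forskolin-style)

`simulate_inhibition_curve()` mimics a cAMP accumulation assay in which
AC is first activated pharmacologically.  Per dose: (1) the opioid is
pre-equilibrated with MOR and the Gαi cycle at a clamped bath
concentration — as in an assay pre-incubation, and necessary because
on-rates at sub-nanomolar doses would otherwise make the readout purely
kinetic; (2) the whole AC pool is switched to `AC:aS_GTP` (with its Gαs
partner supplied in bound form so conservation holds, and free G-protein
pools at resting values); (3) the system runs for a readout interval
(default 30 simulated minutes) and cAMP at the end of the interval is
recorded, normalised to the drug-free control.  The interval matters
because the forskolin-like activation decays spontaneously within
minutes; 30 min spans that decay while keeping the Gαi-driven
displacement the dominant dose-dependent effect.  pIC50 values shift by
roughly ±0.3 log units per factor-2 change of the interval, which is the
main reason simulated potencies carry a few-tenths uncertainty.  The
potency *ordering* across drugs is interval-independent, since every
curve is the same function of dose/Kd up to the degradation correction.

## Acute treatment and recovery

`run_acute_treatment()` equilibrates the drug-free full network for 24 h
(the slow processes relax within ~2 h; 24 h is comfortable), doses the
blood compartment, and integrates 14 days — long enough to cover the
slowest default recovery with margin.  Readouts:

* **Recovery time** — first time after the post-dose nadir at which the
  observable (activated-AC concentration, or cAMP for the sweeps) climbs
  back to 80% of its maximal observed value, the pre-dose plateau being
  the natural 100%.  Linear interpolation between grid points; an
  observable that never re-crosses is reported censored (`NA` with the
  horizon attached), not as an error.
* **Depletion time** — first time the tissue drug concentration falls
  below the fitted IC50 and stays below it.
* **Peak receptor occupancy** — maximum of `100·bound/(bound+free)`;
  binding is fast relative to tissue kinetics at therapeutic doses, so
  this agrees with the equilibrium isotherm at the peak tissue
  concentration (a cross-check in the tests).

`degradation_sweep()` repeats the protocol over a grid of affinities
(Kd, with koff fixed and kon derived) and doses for each tissue
degradation rate, applying the same 80% rule to the cAMP path, and
reports the recovery-time matrix with its 2-day iso-contour.  Default
grids span Kd 0.1–1000 nM and dose 1e-3–1e2 µM (12×12); the acceptance
analyses use the single Fentanyl-affinity cell.  Two robust qualitative
findings: recovery time is monotone non-increasing in the degradation
rate, and the dose-dependence of recovery flattens as degradation
accelerates (once the drug clears faster than the receptor releases it,
dose stops mattering).  The *absolute* mid-rate recovery times are
koff-limited in our parameterisation and come out shorter than the
published mid-rate cell; no single fixed koff reproduces the published
values at both accelerated rates simultaneously (the faster-rate cell
bounds koff from above, the mid-rate cell demands a smaller koff).  We
keep `koff = 5e-8` ms⁻¹ and document the tension rather than fit koff to
the result.

## Cross-drug orderings

With every ligand sharing one koff and the printed Kd/equianalgesic
doses, Morphine (largest dose, slow degradation) recovers slowest and
Endomorphin-2 (rapid degradation) fastest by a wide margin — the
headline contrast.  The Methadone/Fentanyl middle ordering, however,
depends on the per-drug kinetic split that is not derivable from the
printed tables (Methadone's lower dose-to-Kd ratio makes it recover
faster here), so the tests pin only the robust ends of the ordering.

# Calibration of the cAMP law

The cAMP balance has the closed-form steady state
`cAMP* = (k2/k1)·H(AC_on)` (`steady_state_camp()`), which is what a
steady-state accumulation experiment constrains.  Two structural
identifiability facts shape `infer_camp_params()`:

* only the ratio `k2/k1` enters, so `k1` is held fixed (default
  `6.1e-3` ms⁻¹) and `k2` is fitted;
* with the calibrated midpoint `EC50_hill = 135` on an activated-AC
  *fraction* in [0, 1], the law operates far below half-saturation and
  degenerates to the power law `(k2/k1)·(AC_on/EC50)^n` — then only the
  exponent `n` and the amplitude `k2/(k1·EC50^n)` are identifiable, and
  `(k2, EC50)` trade off along a flat ridge.  The fitter reports the
  amplitude alongside the raw parameters; tests verify exact recovery of
  all parameters in a saturating design and recovery of the
  identifiable combination on the ridge.

Fitting minimises squared residuals on the log scale (constant-CV
lognormal noise is homoscedastic there), with a 5-start bounded L-BFGS-B
search seeded deterministically; confidence intervals come from the
numerical Hessian.

## The synthetic calibration generator

`generate_synthetic_calibration()` emulates the kind of experiment the
law was calibrated against: cAMP accumulation measured over increasing
5HT concentrations in cells expressing different 5HTR4 densities.  For
each (density, dose) pair the activated-AC fraction comes from the
serotonin-pathway simulation, is mapped through the steady-state law,
and is multiplied by lognormal noise at a 5% coefficient of variation —
positive-valued, roughly constant-CV noise being the realistic regime
for plate-based cAMP assays.  Defaults: three densities spanning the
physiological window (5e-6–5e-5 µM), eight log-spaced doses around the
response midpoint.  What it does **not** emulate: plate effects,
receptor desensitisation, ligand depletion in the medium, or
between-replicate density drift.  Passing round-trip tests therefore
demonstrate that the inference machinery is unbiased under the stated
noise model, not that the law is identifiable from any particular real
dataset.

# Numerical choices

* **Integrator** — LSODA (`deSolve`), `rtol = 1e-8`,
  `atol = 1e-14` µM (species span ~5e-6 µM receptors to mM-range doses);
  a BDF hint is available for pathological configurations.  Halving the
  tolerances moves recovery times by well under 0.1% (tested).
* **Output grid** — log-dense over the first hour (binding transients
  live on ms–minute scales), then hourly; interpolated event times are
  accurate to seconds, far inside the minutes-scale reporting precision.
* **Negative concentrations** — undershoot beyond −1e-9 µM aborts the
  run; smaller undershoot is clamped to zero when evaluating propensities
  and in the returned trajectory.
* **Steady-state detection** — geometrically growing integration chunks
  until every species changes by less than 1e-9 (relative) per simulated
  hour, then a residual check on `‖S π‖`; failure names the slowest
  species.
* **Hill fitting** — Levenberg–Marquardt on the 4PL in log10-dose space
  (far better conditioned than linear dose), slope sign fixed by the
  stated direction, asymptotes started from the data range; standard
  errors from the scaled inverse Hessian.
* **Independent oracle** — the suite integrates a 1-hour dosed window
  with a hand-written fixed-step RK4 (step 250 ms) and requires
  agreement with LSODA to 1e-4 relative.

## Problem sizes in the tests and acceptance analyses

The acceptance analyses use 8 receptor densities × 24 doses for the
agonist family, 24-dose inhibition grids per drug, single 14-day
trajectories per acute scenario, and single sweep cells per degradation
rate; unit tests use smaller grids (6–16 doses, 1–4 day horizons) and 40-
to 100-replicate Monte-Carlo loops for the fitters.  These sizes were
chosen so the whole suite runs in a few minutes on one CPU while keeping
every Monte-Carlo standard error well below the asserted tolerances.

# Known limitations

* No receptor internalisation, desensitisation or repeated dosing; one
  acute bolus per scenario.
* No stochastic simulation; the deterministic rate equations are assumed
  valid at neuronal copy numbers.
* The agonist EC50's receptor-density dependence and the absolute
  mid-degradation-rate recovery time deviate from the published values,
  traceable to kinetic conventions not derivable from the printed
  parameter tables (see the protocol sections above); both are left as
  documented discrepancies.
* cAMP is the terminal output; the mapping to contraction frequency or
  defecation is out of scope.
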