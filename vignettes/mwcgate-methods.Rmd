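---
title: "Modelling pentameric channel gating with a three-state MWC model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pentameric channel gating with a three-state MWC model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwcgate)
```

## The scientific problem

Proton-gated pentameric ligand-gated ion channels such as GLIC do not switch
directly from a resting to an open conformation. Fluorescence-quenching
sensors placed at the subunit interfaces report a fast *pre-activation*
step — a quaternary compaction of the extracellular domain (ECD) and a
motion of the M2-M3 loop — that occurs at lower proton concentrations than
pore opening itself. `mwcgate` provides the machinery to dissect the two
steps quantitatively from joint steady-state fluorescence and
electrophysiological pH-titration data.

## The model

The pentamer is treated as a concerted (Monod-Wyman-Changeux) system in
equilibrium between three states: resting (R), pre-active (pA) and active
(A). Two classes of proton-binding sites are carried, each in
`n_sites = 5` identical, independent copies (one per subunit). With
$h = [\mathrm{H^+}] = 10^{-\mathrm{pH}}$, the statistical weights are

$$
w_A = (1 + h/K_A)^5 (1 + h/K_{A'})^5,\qquad
w_{pA} = L_A\,(1 + h/K_{pA})^5 (1 + h/K_{pA'})^5,
$$
$$
w_R = L_{pA} L_A\,(1 + h/K_R)^5 (1 + h/K_{R'})^5,
$$

and each state's population is its weight over the sum
(`state_fractions()`). $L_{pA} = \bar R/\bar{pA}$ and
$L_A = \bar{pA}/\bar A$ are the zero-ligand isomerization constants; the
site-class assignment used for the sensors is $K_R > K_{pA} = K_A$ (class
1 drives pre-activation only) and $K_{R'} = K_{pA'} > K_{A'}$ (class 2,
"primed", drives activation only).

Two observables are built on the populations:

* **fluorescence** (F/F~SDS~ scale): $F = \bar R F_R + \bar{pA} F_{pA} +
  \bar A F_A$, with the working hypothesis $F_{pA} = F_A$ (quenching is
  complete at pre-activation). The packaged optics are 0.70/0.30/0.30 for
  the ECD-compaction sensor (Bim136-Q101W, quenched) and 0.56/0.92/0.92
  for the M2-M3-loop sensor (Bim250-Y197, de-quenched);
* **current**: the active fraction $\bar A$, optionally divided by its
  maximum over the grid to mirror the normalization of peak-current
  recordings.

The model deliberately contains no desensitized state (peak currents are
used precisely to avoid it) and no kinetics: everything is steady-state.

### Conventions and definitions

* $[\mathrm{H^+}] = 10^{-\mathrm{pH}}$ exactly; activity corrections are
  not applied, and $\mathrm{pH}_{50} = -\log_{10}\mathrm{EC}_{50}$.
* $L_{pA}$ and $L_A$ are implemented as zero-ligand constants. Their
  operational definition "at pH 8" is an excellent approximation of the
  zero-ligand value (at $10^{-8}$ M binding to sites with
  $K \ge 10^{-7}$ M is negligible), so the distinction is immaterial at
  the affinities relevant here.
* `half_transition_pH()` finds midpoints by sign scan plus bisection to
  below $10^{-4}$ pH. State fractions cross the absolute level 0.5 by
  default; the fluorescence observable uses the midpoint of its extreme
  values over the scan range (and `level = "amplitude"` extends that
  convention to fractions whose range does not span 0.5).
* `apparent_hill()` reports the standard Hill coefficient,
  $n_H = \mathrm{d\,logit}(y)/\mathrm{d}\ln h$ at the midpoint, by a
  centered finite difference with a 0.01-pH step (the pH-derivative
  divided by $\ln 10$).

### Numerical stability

All state-weight products are evaluated in log space (`log1p` terms,
maximum subtracted before exponentiation), so populations are stable for
$h$ from $10^{-14}$ to 1 M even when $h/K$ reaches $10^8$ and the naive
$(1+h/K)^5$ would overflow. `L = 0` is admitted (its weight is exactly
zero).

## Data preparation

* **Fluorescence** is divided by the per-series fluorescence of the
  SDS-denatured protein (`normalize_fluorescence()`), the F/F~SDS~ scale
  on which the optics are defined. A second normalization is an error.
* **Currents** are corrected for rundown (`rundown_correct()`): reference
  applications of a mid-range pH are interleaved (every third or fourth
  application and at both ends), each reference is expressed relative to
  the first, and the factor is interpolated *piecewise-linearly in
  application index* between consecutive references; test responses are
  divided by it. The linear choice is ours (the protocol only states that
  references were interleaved); it is exact for linear rundown and an
  exponential alternative is available behind `method = "exponential"`.
* **Renormalization** (`renormalize_to_reference()`) affinely maps a
  series so its fitted plateau-to-plateau range matches a reference
  construct's — used when a mutation alters the resting-state fluorescence
  itself rather than the transition, or when responses are expressed
  relative to a potentiated condition. The affine coefficients are kept in
  the provenance.

## Hill fitting

`fit_hill_fluorescence()` fits
$y = F_0 + \Delta F_\mathrm{signed}\, h^{n_H}/(h^{n_H} +
\mathrm{EC}_{50}^{n_H})$ with a *signed* amplitude, the only form
consistent with reporting a low-proton plateau $F_0$ and an absolute
$\Delta F_{max}$ while admitting both quenching directions;
`fit_hill_current()` fits $y = I_{max} h^{n_H}/(h^{n_H} +
\mathrm{EC}_{50}^{n_H})$. Fitting is multi-start trust-region least
squares (`minpack.lm`), with at least five log-spaced EC~50~ starting
values; ties are broken by lowest RSS, then lowest $n_H$. Conventions that
matter:

* `exclude_below_pH = 3.5` drops the lowest-pH point(s) before fitting,
  for constructs whose sub-3.5 point deviates opposite to the quenching
  direction (an artifact the generator can emulate);
* `nH_upper_bound` and `fix_nH` reproduce the constrained-fit conventions
  for very steep or poorly determined curves (the bound is reported as
  active when hit);
* bell-shaped series — an interior extremum separated from *both* ends by
  more than four times the robust noise estimate — are flagged
  `not_fitted_bell` and never fitted, the treatment applied to the one
  sensor with a non-monotone response;
* current series whose amplitude is below four times the robust noise
  estimate are rejected as non-functional. (The experimental criterion is
  an absolute current cutoff; the package sees only normalized responses,
  so a signal-to-noise criterion stands in.)

`compare_groups()` tests per-replicate midpoints with Welch two-sample
t-tests, Holm-adjusted across the mutants-versus-parent family. This is a
documented stand-in for the Dunnett procedure used with the original
summary tables; it controls the family-wise error rate without relying on
Dunnett's equal-variance assumption, and the output labels the method.

## The stepwise MWC calibration

A joint fit of all constants is not identifiable, so the calibration is
staged, each stage inheriting the previous one's constants:

1. **Anchor fit** (`step1_anchor_fit()`). A pore-opening-dead mutant
   reduces the model to two states (R/pA). A single curve constrains only
   two quantities (midpoint and amplitude), so of $(K_R, K_{pA}, L_{pA})$
   one must be fixed: the anchor $L_{pA} = 100$ by default. The
   conditional $(K_R, K_{pA})$ are then well determined
   ($K_R \ge K_{pA}$ enforced by parameterization). If asked to fit all
   three jointly the function *refuses*: it profiles the loss along
   $L_{pA}$ (tenfold displacement, affinities re-optimized) and errors
   when the RMS residual change stays within instrument noise (0.01
   F/F~SDS~), or when the Hessian condition number at the optimum exceeds
   $10^3$.
2. **Sensor pre-activation** (`step1_fit_LpA()`): with the affinities
   fixed, each construct's $L_{pA}$ is a one-dimensional fit.
3. **Activation** (`step2_activation_fit()`): the primed site class and
   $L_A$ are fitted jointly to the sensor's fluorescence and
   max-normalized current with equal weight. The absolute primed-site
   affinities are **fixed by convention** by default
   (`fit_config(activation_affinities = ...)`): profiling shows a broad
   loss ridge trading $(K_{R'}, K_{A'})$ against $L_A$ at realistic noise,
   so they are not identifiable from steady-state curves and the
   multiplication factors below are defined *relative to the convention*.
   Setting `activation_affinities = NULL` fits them freely (and recovers
   them exactly on noise-free self-generated data, where the ridge
   collapses).
4. **Polish**: `calibrate_sensor()` finally re-optimizes the sensor's
   $(L_{pA}, L_A)$ in the full three-state model. The step-2 $L_{pA}$
   comes from the two-state reduction, which is biased low once the
   active state contributes to the quench tail; since mutants are fitted
   in the three-state family, the sensor must be too, or every
   pre-activation factor inherits the bias.
5. **Mutants** (`fit_mutant_multipliers()`): only the two isomerization
   constants vary, as fold-changes $f_{L_{pA}}, f_{L_A}$ fitted in log
   space (bounds $10^{-4}$–$10^8$), from deterministic log-grid starts
   plus seeded random ones. Constructs without currents are fitted in
   two-state-only mode ($f_{L_A}$ not reported). Fits whose RSS per point
   exceeds three times the sensor's are flagged `poor`.
6. **Anchor sensitivity** (`sensitivity_scan()`): the whole pipeline is
   re-run per anchor value (100, 1000, 100,000 by default). Absolute
   constants shift with the anchor; the mutant *rank order* by either
   factor should not.

The fluorescence/current loss weighting is equal after normalization (the
original analysis was manual, so no weighting is stated anywhere); it is
configurable.

### Why two site classes

`single_site_separation_scan()` documents the failure of the single-site
three-state model by exhaustive log-grid search: under full-amplitude
constraints (resting fraction $\ge 0.95$ at the high-pH end, active
fraction $\ge 0.95$ at the low-pH end, agonist ordering
$K_R \ge K_{pA} \ge K_A$), no combination separates the fluorescence and
current midpoints by as much as fivefold in proton concentration, whereas
the loop sensor's observed separation exceeds an order of magnitude. The
acceptance suite runs the scan at 12 grid points per dimension
(≈ 52,000 admissible-orderings combinations after filtering); the
function defaults to 16 per dimension (≈ 2 × 10⁵) and scales to larger
grids in chunks.

## The synthetic-data generator

`generator_spec()` freezes the study conditions the package is tested
under: an 11-point pH grid from 8.0 to 3.0 in 0.5 steps, additive Gaussian
noise of σ = 0.02 on the normalized scale (σ = 0.01 in the
parameter-recovery analyses, the value used with per-replicate fits),
three replicates per construct — with the sensor itself measured at the
table's replicate counts (17 fluorescence series, 12 recordings) in the
end-to-end recovery test — reference applications every three test
applications, and a linear 20% rundown across a recording. Per-construct
truths are built from the frozen reference parameter sets
(`glic_reference_truth()`), which were tuned once so that the model
midpoints sit at the published sensor values (5.85/5.42 and 5.83/4.66)
with a maximal pre-active fraction near 0.5 for the compaction sensor,
near 0.9 for the loop sensor, and an activation drive strong enough that
several-hundred-fold $L_A$ multipliers still saturate the current — the
published panel renormalizes only one construct for failing to reach full
activation.

Two deliberate numerical choices: the default F~SDS~ is 1024, an exact
binary power, so generating and then normalizing is bit-exact and the
σ = 0 contract ("output equals truth exactly") holds literally; and each
functional construct's reference pH is chosen as the grid pH nearest its
half-maximal current, as the recording protocol prescribes a mid-range
reference (a fixed reference pH would leave strongly shifted mutants with
noise-dominated references).

What the generator does *not* emulate: spectra and photobleaching,
heteroscedastic noise across pH (unreported for the real data; the
homoscedastic default is a choice), oocyte expression variability beyond a
per-replicate scale factor, and any kinetic structure. Passing
recovery tests therefore demonstrate correctness of the estimation
machinery under the stated noise model, not robustness to every artifact
of real recordings.

## Geometry metrics

For multi-model PDB trajectories (read via `bio3d`, altloc resolved by
highest occupancy then alphabetical, hydrogens dropped):

* **twist angle**: per subunit, the signed pseudo-dihedral (subunit ECD
  centroid, whole ECD centroid, whole TMD centroid, subunit TMD centroid),
  positive when the ECD is rotated counterclockwise viewed from the
  extracellular side. The originally cited twist definition is not spelled
  out anywhere we can reach, so this centroid construction is our
  documented interpretation — residue ranges and sign are configurable;
* **pair distances**: Cα, Cβ, named-atom or side-chain-centroid points
  (heavy atoms beyond Cβ; all heavy atoms for non-standard residues such
  as a modelled fluorophore), for all five subunits or all five ordered
  (i, i+1) interfaces in file chain order;
* **ring radius**: the channel axis is the total-least-squares line
  through the ten per-chain ECD/TMD centroids; the radius at a pore-lining
  residue (e.g. the Ile233/I9′ gate) is the mean perpendicular distance of
  the ring atoms to the axis, optionally minus 1.7 Å of carbon van der
  Waals radius. This is a geometric approximation, not a
  solvent-accessible channel tracing; no numeric equivalence with
  channel-profiling servers is claimed;
* **RMSD**: Kabsch superposition (no reflection) via `bio3d::rmsd` after
  strict (chain, residue, atom) correspondence;
* **asymmetry**: per-frame mean/SD/range of a metric across subunits or
  interfaces, with a helper flagging whether the spread declines along a
  trajectory (the symmetrization expected on approach to the compact
  state).

`build_synthetic_pentamer()` constructs C5-symmetric pseudo-Cα pentamers
with controllable twist, layer separation and radial ECD compaction; every
metric on it equals its construction parameter, which is how the geometry
suite is validated without shipping coordinate files.

## Orchestration

`run_pipeline()` ties the stages together from a construct roster
(sensor/anchor/mutant roles, parent links, per-construct fitting options)
given as a list or YAML/JSON file: preparation, per-replicate Hill fits, a
summary table with midpoint shifts and significance stars, the MWC
calibration and factor table across anchors, predicted-curve CSVs and a
run log. Failures are collected per construct (status 2) rather than
aborting. Given fixed seeds, reruns are byte-identical.

## Known limitations

* Absolute activation-site affinities are reported only as a convention
  (see above); comparisons of factors are meaningful within one
  convention and anchor, and rank orders across anchors.
* The pre-activation transition is modelled as a single concerted step;
  systematically shallower experimental fluorescence curves than the
  model predicts would indicate intermediate sub-states that this model
  cannot express.
* Replicate aggregation is mean ± SD for display only; all fitting is per
  replicate or on pooled points, never on averaged curves.
* The geometry module measures rigid descriptors on given coordinates; it
  performs no flexible fitting, docking or side-chain modelling.
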