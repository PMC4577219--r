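---
title: "Modeling irreversible electroporation of liver tumors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling irreversible electroporation of liver tumors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Irreversible electroporation (IRE) ablates tissue with trains of short
(~90 µs) high-voltage pulses delivered between pairs of needle
electrodes. Cell death is field-mediated: tissue exposed to a field above
the IRE threshold (here 700 V/cm for liver, 800 V/cm for tumor) is
irreversibly permeabilized. Because the mechanism is not primarily
thermal, IRE is attractive for tumors abutting major vessels, where the
heat-sink effect compromises radiofrequency or microwave ablation — but
the highly conductive blood redistributes the electric field, so
patient-specific numerical planning is needed. `ireplan` implements that
planning chain on voxel grids: scene construction, a nonlinear stationary
electric solve per energized electrode pair, combination of per-pair
fields into coverage and lesion volumes, a duty-cycle bioheat model, and
Arrhenius damage accounting.

## Electric model

For each pulse train the potential solves the stationary current
continuity equation

$$\nabla \cdot (\sigma(|\mathbf E|)\, \nabla \varphi) = 0,$$

with the applied voltage on the active segment of one needle, 0 V on the
other, no normal current through the outer boundary, inactive needles as
floating conductors (their metal stays at σ = 10⁶ S/m with no potential
constraint — physically what an unconnected needle is), and insulated
shafts as perfect insulators (excluded from the system; this is the only
deliberate departure from treating them as σ = 10⁻⁶ voxels, and is
numerically cleaner at identical physics).

Electroporation makes conductivity field-dependent. Each tissue has an
initial conductivity σ₀ below an onset field `E_rev` and a final
conductivity σ_f at or above its IRE threshold `E_irr`
(liver 0.091→0.45 S/m, tumor 0.4→1.6 S/m, vessel 0.7→1.05 S/m). The
transition shape between the thresholds is not settled in the
electroporation literature; the package defaults to a continuous linear
ramp and offers a logistic (`"sigmoid"`) variant. The onset `E_rev` is
not tabulated in the source literature either; the default is
`E_irr / 2`, configurable, and — as shown by a sensitivity experiment
during development — the downstream coverage results are nearly
insensitive to both choices, because the monotone update (below)
dominates the dynamics.

The nonlinearity is handled the standard way: six stationary solves with
the conductivity updated between solves,

$$\sigma_{n+1}(\mathbf x) = \max\bigl(\sigma_n(\mathbf x),\,
\sigma(|\mathbf E_n(\mathbf x)|)\bigr).$$

The `max` makes the update monotone, which guarantees a non-decreasing
dissipated power across iterations (by the Dirichlet variational
principle, raising σ pointwise can only raise the minimum of the energy
functional), so the per-iteration current trace returned by
`field_iteration_trace()` is non-decreasing by construction.

### Discretization and solver

Cell-centered finite volumes on the voxel grid with harmonic averaging of
σ on faces (the correct flux-preserving average for discontinuous
coefficients) and a 7-point stencil. The reduced symmetric
positive-definite system — Dirichlet rows eliminated symmetrically — is
solved by Jacobi-preconditioned conjugate gradients (relative residual
10⁻⁸, deterministic) implemented in compiled code; outer conductivity
iterations warm-start from the previous potential.

Two independent current estimators are always computed: total dissipated
power divided by the applied voltage (primary; the discrete energy is
exact for the discrete solution) and the net flux through a mid-plane
between the electrodes. In an exactly solved discrete system the two
agree identically by charge conservation, so their difference is a
built-in integrity check: beyond 10 % the solve errors out, and the
acceptance suite requires agreement within 2 %.

### Coverage semantics: the peak field

A subtle point drives the headline coverage result. The tumor is several
times more conductive than liver (0.4–1.6 vs 0.091–0.45 S/m), and a
conductive inclusion shields its interior: the converged field inside the
tumor settles at roughly half the surrounding field (the package
reproduces the analytic sphere-inclusion law
E_in = 3σ_out/(2σ_out+σ_in)·E₀ to a few percent). Evaluated on the
final-iteration field, the tumor could *never* show full coverage at
800 V/cm — yet clinical planning computations report exactly that.

The resolution is physical: the conductivity iterations represent the
poration dynamics during pulse delivery, and electroporation is
cumulative and effectively instantaneous. Early in the delivery — before
the tumor's own conductivity has risen — the interior field transiently
exceeds the threshold; the cells porated at that moment stay porated,
which is precisely what the monotone σ-update records. Coverage and
lesion volumes are therefore evaluated on the voxelwise **peak** field
across iterations (`E_peak`), while predicted currents use the final
(sustained-state) solve, which is what a generator ammeter sees. On the
synthetic case this reproduces both published behaviors simultaneously:
the whole tumor above ~900 V/cm after the first two trains, and per-train
currents within a few percent of the reference computation.

Fields from successive trains combine by voxelwise maximum
(`run_protocol()`), the standard rule when several electrode pairs are
energized sequentially.

## Thermal model

Joule heating σ|E|² acts only during the ~90 µs pulse; at 1 Hz the duty
cycle is 9·10⁻⁵, so the source is scaled by the duty cycle and the Pennes
bioheat equation

$$\rho c \frac{\partial T}{\partial t} = \nabla\cdot(k \nabla T)
 - \omega_b \rho_b c_b (T - T_b) + q''' + \text{duty}\cdot\sigma|\mathbf E|^2$$

is advanced with unconditionally stable backward-Euler steps (default
dt = 1 s, one pulse period) on the same 7-point stencil. The Joule
density is *energy-consistent*: each stencil face's dissipated power
w·Δφ² is attributed to its two cells (metal faces give their whole power
to the tissue side), so the volume integral of the source equals U·I
exactly. This matters: a center-point σ|E|² evaluation loses roughly a
third of the delivered energy around sub-voxel needles — exactly the
logarithmically concentrated shell that drives the near-electrode
temperature spike — and was observed during development to suppress peak
temperatures from above 100 °C to ~60 °C at 1 mm spacing. Trains are
contiguous at the pulse rate by default (the delivery is modeled at a
constant 1 Hz; ECG-synchronized timing would be somewhat faster and
hotter); an inter-train gap is configurable. The outer faces are held at
body temperature (310 K) — the domain should extend ≥ 2 cm beyond the
electrode array so this choice is immaterial — or can be made adiabatic
for energy-conservation checks.

Thermal damage uses first-order Arrhenius kinetics,
Ω(t) = ∫ ζ·exp(−E_a/RT) dτ with E_a = 5.06·10⁵ J/mol and
ζ = 2.984·10⁸⁰ s⁻¹; Ω = 1 corresponds to a 63 % damage probability via
P = 1 − exp(−Ω). With these constants the damage rate is negligible below
~45 °C and nearly instantaneous above ~85 °C, so the Ω ≥ 1 volume tracks
the volume that spent tens of seconds above ~50 °C.

Deliberate omissions, mirroring the model this package emulates: no
boiling or gas-formation term (temperatures above 100 °C are reported
with a warning, not capped), no perfusion shutdown in damaged tissue, no
convective blood flow in the vessel lumen (the vessel is a perfused
tissue, so its true heat-sink effect is underestimated), no microsecond
in-pulse transients.

## Parameters that matter

| parameter | default | unit | note |
|---|---|---|---|
| σ₀ → σ_f liver | 0.091 → 0.45 | S/m | literature values |
| σ₀ → σ_f tumor | 0.4 → 1.6 | S/m | extrapolated in the literature |
| σ₀ → σ_f vessel | 0.7 → 1.05 | S/m | wall + blood lumped |
| E_irr liver / tumor / vessel | 700 / 800 / 700 | V/cm | vessel value reuses liver's (not published) |
| E_rev | E_irr / 2 | V/cm | onset of σ rise; not published, low sensitivity |
| α_T | 1.5 | %/K | conductivity thermal coefficient |
| k, ρ, c (tissue) | 0.52, 1079, 3540 | SI | thermal properties |
| ω_b | 0.018 | 1/s | 1.8 mL/s/100 mL blood perfusion |
| tumor perfusion | 0.009 | 1/s | reported lower than liver, unquantified → 0.5× |
| q''' | 10740 | W/m³ | metabolic heat (tissue only) |
| electrode radius | 0.5 | mm | needle gauge rarely reported |
| pulse width / rate | 90 µs / 1 Hz | | duty 9·10⁻⁵ |
| dt | 1 | s | one pulse period |

All internal computation is SI; fields are exposed in V/cm
(1 V/cm = 100 V/m), geometry in mm, volumes in cm³.

## The synthetic case

`synthetic_case()` builds a deterministic phantom of the clinical
scenario the package targets: an 80 mm liver cube, an ellipsoidal
14 × 9 × 15 mm tumor (0.99 cm³ analytically) at the center, an 8 mm
hepatic-vein-like cylinder parallel to the needles and touching the tumor
surface, and four parallel needles (20 mm exposure, 0.5 mm radius) whose
tip positions are reconstructed by exact trilateration from the six
clinical pairwise distances (18, 14, 12, 15, 12, 17 mm; the fourth tip
resolves out of plane by 6.7 mm, consistent with near-parallel insertion
at different depths). The vessel sits in the widest angular gap between
the needles so no needle pierces the lumen; its exact position and
diameter are configurable because the clinical report does not state
them. The shipped 18-train protocol (660 pulses, 1540–3000 V) attaches to
the scene.

What the phantom does *not* emulate: the patient's true liver boundary
and segmented vessel tree, the exact tumor orientation relative to the
needles, electrode insertion curvature, and ECG-gated pulse timing. A
green acceptance run therefore establishes that the solver chain
reproduces the *mechanisms* and the in-paper arithmetic — not the
patient-specific lesion numbers, which would require the original
segmented imaging.

## Numerical choices and edge cases

- **Voxel membership** is a center-point test; rasterized volumes
  converge to the closed forms as spacing shrinks (tested at 2/1/0.5 mm).
  Needles thinner than a voxel still rasterize to a connected line of
  voxels (thin-structure guarantee).
- **Sub-voxel needles**: a 0.5 mm-radius needle on a 1 mm grid has an
  effective electrical radius of ~0.7 mm that shrinks as the grid is
  refined, so predicted currents drift by ~9 % between 1 and 0.5 mm
  spacing. This is the expected log-singular thin-wire behavior, not a
  solver defect; the grid-consistency test uses resolved (2 mm radius)
  needles, where halving the spacing changes the current by ~2 %.
- **Two-wire validation** against I = UπσL/arccosh(d/2a) is run in a
  slab-spanning quasi-2D configuration at 0.5 mm spacing, because the
  formula is the two-dimensional (infinite-needle) conductance; in an
  open domain, end-spreading adds ~20 % current and would be wrongly
  attributed to solver error.
- **Ties and degeneracies**: zero applied voltage is allowed and yields a
  zero field; ellipsoids missing the grid warn and label nothing;
  degenerate segments and non-positive spacings error; the Arrhenius
  increment underflows to exactly 0 at very low temperature.
- **Tolerances**: CG relative residual 10⁻⁸ (electric) and 10⁻⁹
  (thermal); the current-estimator cross-check errors beyond 10 %
  disagreement; implicit thermal steps are unconditionally stable so dt
  is a pure accuracy knob (halving dt moves the final damage volume by
  < 3 %).

## Known limitations

- The stationary conductivity iteration has no pulse-number dependence:
  a 20-pulse test train and a 70-pulse treatment train at equal voltage
  produce identical fields, and thresholds calibrated on 8-pulse
  protocols are applied to 70-pulse trains (actual thresholds are likely
  lower; the computed lesion is then conservative).
- Currents for high-dose treatment trains are expected to under-predict
  generator readings (the reference computation showed errors to −28 %),
  because σ_f saturates while real tissue conductivity keeps climbing
  with pulse number and temperature; the per-train error report makes
  this visible so users can refit σ_f, but no refit is attempted.
- The patient-specific headline volumes (19.9 cm³ lesion vs 20.03 cm³ CT
  hypodensity) require the original segmented MRI/CT geometry and are out
  of scope; the synthetic-case lesion is checked only for order of
  magnitude.
- No mesh-based geometry, no MRI/CT segmentation, no electrode-path
  reconstruction, no ECG gating, no protocol optimization.
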