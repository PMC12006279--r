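---
title: "PWV-based blood-pressure prediction: models, testbed and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PWV-based blood-pressure prediction: models, testbed and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(pwvbp)
```

## The problem

Cuffless blood-pressure monitors commonly estimate BP from pulse wave
velocity (PWV): the transit time of a pulse feature between two arterial
sites gives one wave speed, and a calibrated model converts the
continuously measured cross-sectional area `A(t)` into pressure. The
Bramwell–Hill relation ties the two together,

$$ \mathrm{PWV}(t) = \sqrt{\frac{A(t)}{\rho}\,\frac{dP}{dA}}, $$

so pressure can be reconstructed as a line integral in area:

$$ P(t) = P_0 + \rho \int_{A_0}^{A(t)} \mathrm{PWV}^2\,\frac{dA}{A}. $$

The catch is that the arterial wall stiffens with pressure (collagen
recruitment), so PWV is not constant within a cardiac cycle — it can swing
by tens of percent between diastole and systole. Closing the integral with
a single (diastolic) wave speed gives the conventional model

$$ \text{M1:}\quad P(t) = P_0 + \rho\,\mathrm{PWV}_d^2 \ln\frac{A(t)}{A_0}, $$

which is exact only for a linearly elastic vessel and otherwise
systematically *underpredicts* systolic pressure. Assuming instead that
PWV scales linearly with area between its diastolic and systolic
endpoints, $\mathrm{PWV}(t) = C_1 + m A(t)$ with
$m = (\mathrm{PWV}_s - \mathrm{PWV}_d)/(A_s - A_d)$ and
$C_1 = \mathrm{PWV}_d - m A_d$, the integral closes as

$$ \text{M2:}\quad P(t) = P_0 + \rho\left( C_1^2 \ln\frac{A}{A_0}
   + m^2\,\frac{A^2 - A_0^2}{2} + 2 C_1 m\,(A - A_0) \right). $$

The package implements both models (`predict_m1()`, `predict_m2()`), the
model-free quadrature oracle (`predict_general()`), the estimation chain
that feeds them, and a deterministic 1D testbed that supplies ground
truth. Both models are calibrated at the diastolic instant
(`P0 = P_d`, `A0 = A_d` at the same sample), so the diastolic prediction
error is zero by construction and all scoring happens at peak systole.

## The estimation chain

* **Diastolic PWV** (`estimate_pwvd()`): foot-to-foot transit time of the
  area waveform between two stations 60 mm apart (36 mm and 96 mm from the
  inlet), with the foot located by the intersecting-tangents rule
  (`detect_foot()`): the crossing of the horizontal line through the cycle
  minimum with the tangent at the maximal upstroke slope. The derivative
  maximum is refined by parabolic interpolation; at 1 ms sampling a
  10 m/s wave crosses 60 mm in only 6 samples, so integer-sample timing
  would quantise PWV by ~17%.
* **Time-varying PWV** (`theoretical_pwv()`): Bramwell–Hill evaluated
  pointwise with `dP/dA` as the ratio of central-difference time
  gradients. The ratio is chosen over re-gridding P against A because the
  dicrotic phase makes A non-monotone in time.
* **Systolic PWV** (`extract_pwvs()`): the maximum of the smoothed
  theoretical PWV(t). No transit-time estimator is attempted for the
  systolic point — reflections distort the peak differently at the two
  stations, which is precisely why a practical systolic PWV measurement
  does not exist; the package mirrors that choice.
* **Scaling** (`build_scaling()`): the exact two-point line through
  `(A_d, PWV_d)` and `(A_s, PWV_s)`; `fit_linear_scaling()` quantifies how
  linear PWV actually is in A over the systolic upstroke (foot to area
  maximum, time-ordered samples).

### Numerical controls

`theoretical_pwv()` masks samples where `|dA/dt|` is below 2% of its cycle
maximum: the gradient ratio is 0/0-indeterminate at area extrema and
produces sharp over/undershoots there. Masked samples are filled — and the
rest smoothed — by a robust local-linear regression (tricube distance
weights, bisquare robustness weights, 3 iterations). The window is 21
samples (~21 ms at the default sampling): wide enough to suppress
gradient noise, narrow enough not to flatten the systolic PWV peak. A 51
sample window was tried and rejected — on a ~100 ms upstroke it biases
PWV(t) by up to ~1% and degrades the upstroke PWV–area linearity from
R² ≈ 0.9998 to ≈ 0.987, which misrepresents the underlying law. All three
controls (mask threshold, window, iterations) are exposed as arguments and
in the scenario config.

## The 1D surrogate testbed

No waveform data ship with the package; ground truth comes from a 1D
nonlinear pulse-propagation solver (`simulate_pulse_1d()`) that stands in
for a full 3D fluid–structure simulation. It integrates the mass and
momentum equations of a compliant tube,

$$ \partial_t A + \partial_x Q = 0, \qquad
   \partial_t Q + \partial_x(Q^2/A) + \frac{A}{\rho}\partial_x P
   = -K_f \frac{\mu}{\rho} \frac{Q}{A}, \qquad P = \text{law}(A), $$

with a prescribed pulsatile inflow and a three-element Windkessel outlet.
Wave propagation, outlet reflection and nonlinear stiffening — the three
phenomena the estimation chain is sensitive to — are all present; 3D wall
mechanics (fiber angles, tissue support, wall thickness mechanics) are
deliberately absent. Consequences: the testbed reproduces the *phenomena*
(PWV rising with pressure, reflection-distorted waveforms, M1
underprediction) but not any specific published waveform or error
magnitude, and passing tests say nothing about sensor noise, motion
artefacts or subject variability in real recordings.

### Tube laws

Three monotone `P(A)` families (`tube_law()`), each existing so that one
link of the chain has a closed-form answer:

* `constant_pwv` (`P = P_ref + ρc₀² ln(A/A_ref)`) — the linear-elastic
  limit; M1 is exact here, which pins down the null case.
* `linear_pwv` (`PWV(A) = a + b(A − A_ref)`, pressure integrated in closed
  form) — makes the M2 scaling hypothesis literally true, so M2 is exact.
* `exponential` (`P = P_ref + β(e^{γ(A/A_ref−1)} − 1)`) — a generic
  collagen-style stiffening law on which neither model is exact; the
  default surrogate wall.

All laws are restricted to `[0.5, 2]·A_ref`, where they are monotone and
physically meaningful. The default parameters per artery (radial β = 5300
Pa, γ = 20; carotid β = 18700 Pa, γ = 4, both at `P_ref` = 75 mmHg and the
pressure-free lumen area) were chosen once so that, at physiological pulse
pressures, diastolic PWV and the within-cycle PWV swing fall in the ranges
reported for each vessel (radial ~10 m/s with a ~45–50% swing, carotid
~8.4 m/s with ~19%). No empirical P–A curve is fitted.

### Inflow and Windkessel

The inlet flow (`inlet_flow_spec()`) is a canonical pulse — baseline plus
periodised Gaussian systolic and dicrotic bumps — with closed-form mean
and peak normalisation. Defaults: 0.8 s period, systolic peak at 13% of
the cycle, 24 ms Gaussian width (10–90% rise ~60 ms, physiological for
both sites), mean/peak flows of 0.3/1.2 mL/s (radial) and 6.5/20 mL/s
(carotid). Upstroke duration matters beyond realism: the tangent-intersection
fiducial back-tracks from the max-slope point by roughly half the rise
time, so a slow unphysiological upstroke amplifies small inter-station
shape distortions into a several-percent transit-time bias.

The outlet (`wk3_params()`) uses the exact integrating-factor step for the
capacitor (`wk3_outlet_advance()`): unconditionally stable and exact for
step-constant inflow, which removes the solver-coupling failure mode an
explicit update would have. The venous reference pressure is 0 Pa,
consistent with estimating total resistance as `P_mean/Q_mean`
(`initial_estimates()`). `Rp` is matched to the characteristic impedance
`ρc_d/A_d` at station S1 and `Rd = RT − Rp` (`split_resistances()`).
`wk3_tune()` turns the usual manual tune-until-physiological loop into a
deterministic algorithm: multiplicative RT rescaling by achieved vs target
mean pressure, re-split at the latest diastolic state, and a damped
(exponent 0.7) multiplicative compliance update from the achieved vs
target pulse pressure, until diastolic BP lies in [65, 85] mmHg and
systolic BP in [110, 130] mmHg. The initial time constant is taken from
the published outlet sets for the same vessels (`tau = Rd·C`: ~1.22 s
radial, ~0.48 s carotid), which lands the default scenarios inside both
windows without any iteration. The published parameter sets themselves
ship as fixtures (`wk3_radial_paper()`, `wk3_carotid_paper()`) but are not
reused verbatim — they were tuned against a different (3D) upstream
domain.

### Numerics

The solver is a two-step Richtmyer (Lax–Wendroff-type) predictor–corrector
on the conservative form, with the pressure-gradient term folded into a
celerity potential `B(A) = ∫c²dA` (closed form per law). Boundaries close
on Riemann invariants `u ± ∫(c/A)dA` (tabulated once per law on a 4001
point grid): the inlet prescribes `Q(t)` and takes area from the outgoing
invariant; the outlet solves the coupled invariant/Windkessel relation by
bisection. The output sampling interval (default 1 ms) is decoupled from
the solver step: an advective CFL bound at the law's maximum expected wave
speed (default headroom up to 160 mmHg, safety factor 1.3, target Courant
number 0.9) fixes an integer number of sub-steps per output sample, and
the CFL condition is re-checked at run time every step. Default problem
sizes — 201 grid nodes over 110 mm, 8 cycles of 0.8 s at 1 ms output
sampling — give last-vs-previous-cycle pressure residuals far below
0.5 mmHg, volume-balance defects around 1e-5 of stroke volume, and
station pressures that change by less than 0.01% when both grid spacings
are halved; a full two-artery benchmark runs in well under a minute on one
core.

Initial conditions are uniform: `A = A(P_init)`, `Q = Q(0)`, capacitor at
`P_init` (default: the law's reference pressure, i.e. the diastolic
target), which keeps the transient to the periodic orbit short. The
kinematic generator (`kinematic_dataset()`) provides a solver-free
alternative for estimator tests: station S2 is the S1 waveform delayed
rigidly at the diastolic speed (`pure_delay`) or per-sample at the
instantaneous analytic speed (`pwv_delay`, which distorts the wave shape
exactly as differential wave speed would).

### Degenerate inputs and tie-breaks

Foot detection breaks minimum ties toward the latest minimum before the
largest upstroke (with a recorded warning), rejects flat or falling
signals, and clamps the parabolic refinement to ±half a sample. Transit
times at or below two samples raise a resolution warning; non-positive
transit times (swapped stations) are errors. `theoretical_pwv()` treats
negative `dP/dA` at more than 10% of unmasked samples as non-physical
input. `predict_general()` follows the time path from the calibration
sample in both directions, so dicrotic down–up passes cancel consistently.

## Known limitations

* The surrogate cannot reproduce published absolute error magnitudes —
  those belong to a specific 3D simulation; only the qualitative ordering
  (M1 underpredicts; M2 removes most of the peak error) carries over.
* Foot-to-foot PWV in a short, reflective vessel is biased toward the wave
  speed at the tangent point rather than the true diastolic speed; with
  the default physiological upstroke this bias is ~1–2.5%, and it is the
  dominant contribution to M2's residual error.
* One vessel, one fixed heart rate, no noise by default; robustness to
  noise must be studied by adding it explicitly (all randomness is
  seed-controlled).
* Tapering, branching, viscoelastic walls and 3D tissue support are out of
  scope by design.
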