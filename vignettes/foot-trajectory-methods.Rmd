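---
title: "Stride-wise foot trajectory estimation: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stride-wise foot trajectory estimation: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaittraj)
```

## The estimation problem

A shoe-mounted inertial measurement unit (IMU) senses a 3-axis angular rate
$\omega(t)$ (rad/s) and a 3-axis specific force $a_s(t)$ (in units of g),
both in the moving sensor frame. Clinical gait analysis needs the foot's
*trajectory* — position $s(t)$, velocity $v(t)$ and orientation $q(t)$ in a
world frame — but no external positioning is available. The only way out is
strapdown integration: track the sensor-to-world rotation from the gyroscope,
rotate the accelerations into the world frame, subtract gravity, and
integrate twice.

Double integration of noisy accelerations diverges within seconds, so the
pipeline works stride by stride. A *stride* runs between two consecutive
mid-stance instants $t_{ms}$, $t_{ms+1}$ — the moments of minimal gyroscope
energy, when the loaded foot is quasi-stationary. Three assumptions anchor
the integrals:

* **zero velocity** at both mid-stances, $v(t_{ms}) = v(t_{ms+1}) = 0$;
* **zero movement acceleration** there, $a(t_{ms}) = a(t_{ms+1}) = 0$;
* **level floor**: equal (zero) vertical position at both mid-stances.

The world frame has gravity along $-y$; an ideal resting accelerometer reads
the specific force $(0, 1, 0)$ g. Quaternions are scalar-first, Hamilton
convention, and always map sensor-frame vectors into the world frame.

## Orientation estimation

All three trackers share the initial condition. At mid-stance the
accelerometer is assumed to measure pure gravity, so the inclination follows
from $\alpha_z = \operatorname{atan2}(-a_x, a_y)$ and
$\alpha_x = \operatorname{atan2}(a_z, \sqrt{a_x^2 + a_y^2})$, composed as a
rotation about $z$ then $x$. Heading about the vertical is unobservable
without a magnetometer and is fixed at zero; consequently all downstream
positions are expressed in a per-stride frame aligned with the initial foot
direction, and stride length is the *norm* of the horizontal displacement.

1. **Gyroscope integration** propagates
   $\dot q_\omega = \tfrac12\, q \otimes (0, \omega)$ with the first-order
   update $q(t) = \mathrm{normalize}\{q(t - \Delta t) + \dot q_\omega \Delta t\}$.
   Deliberately first order — the benchmarked estimators use exactly this
   update, so the package does too rather than an exponential-map integrator.
2. **Madgwick complementary filter** (magnetometer-free): when an
   accelerometer sample is trustworthy, the quaternion rate is corrected by a
   normalised gradient step, $\dot q = \dot q_\omega - \beta\,
   \nabla\epsilon / \lVert \nabla\epsilon \rVert$, where $\epsilon$ is the
   difference between the specific-force direction predicted from $q$
   (the second row of $R(q)$, i.e. $-R^T g_w$) and the measured $a_s$.
   The error is prediction minus measurement of the *same physical quantity*
   (specific force), so $\epsilon = 0$ under perfect tracking; the closed-form
   Jacobian of the prediction is verified against central finite differences
   in the test suite rather than trusted from derivation.
3. **Euston/Mahony explicit complementary filter** (airspeed path removed):
   the angular mismatch $e = \hat g_s \times \hat a_s$ between predicted and
   measured gravity direction feeds back onto the measured rate,
   $\omega^* = \omega + k_P e + k_I \int e\,dt$, before the same quaternion
   update. The integral term (trapezoidal accumulation) exists to absorb
   constant gyro bias and is reset at each stride start, because the pipeline
   re-initialises per stride.

Accelerometer corrections are *gated*: they apply only when
$\bigl|\lVert a_s\rVert - 1\bigr| \le \gamma$ (the reading is dominated by
gravity) and never during swing. The swing phase is not annotated in the
input, so the package marks swing where $\lVert\omega\rVert$ exceeds a
threshold (default 1.5 rad/s), with morphological closing over 50 ms to
bridge brief dips; both settings are exposed. With $\beta = 0$ or
$k_P = k_I = 0$ each filter degenerates *bit-for-bit* to gyroscope
integration — an identity the tests assert, since it pins down the shared
update path.

### Filter parameters

| parameter | units | default | role |
|---|---|---|---|
| $\beta$ | rad/s | 0.046 | Madgwick gain, proportional to the maximal gyro error; 0.046 rad/s corresponds to about 3.04°/s via $\beta = \sqrt{3/4}\,\tilde\omega_{max}$ |
| $\gamma$ (Madgwick) | g | 0.24 | gravity-band half-width for updates |
| $k_P$ | rad/s | 0.0046 | proportional gain; crossover between accelerometer- and gyro-dominated estimation |
| $k_I$ | rad/s | 0 | bias-integrator gain; for one-stride integration times a zero gain is appropriate |
| $\gamma$ (Euston) | g | 2.50 | the explicit filter tolerates far more movement in its updates |

Both relations found in the literature between $\beta$ and the maximal
gyroscope error are implemented
(`madgwick_max_gyro_error(relation = "madgwick")` giving
$2/\sqrt{3}\,\beta$, and `"four_thirds"` giving $4\beta/3$); the default is
the one consistent with the 0.046 rad/s ↔ 3.04°/s correspondence above.

## From acceleration to trajectory

With the tracked quaternions, $a_w = R(q)\,a_s$; the movement acceleration
is $a = (a_w - (0,1,0))\,g$ in m/s². Orientation error leaks gravity into
$a$, so before integration each axis is dedrifted with a piecewise-linear
function forcing $a = 0$ at both mid-stances. The "piecewise" shape is two
segments joined with value zero at the sample of maximal acceleration norm:
drift is attributed to the low-dynamics ends of the stride and the swing
peak is left untouched. A single-line fallback (`dedrift = "linear"`) is
available; the joint rule is a documented package default, not a prescription
from the benchmarked methods, whose published description leaves it open.

Three double-integration schemes then produce $v$ and $s$:

* **Direct**: cumulative trapezoid per axis, followed by subtraction of the
  straight line through the velocity endpoints (zero-velocity assumption);
  position by a second trapezoid, with the vertical axis linearly dedrifted
  once more (level floor). Parameter-free.
* **Direct & reverse**: the acceleration is also flipped in time and sign,
  integrated, and re-indexed back, giving a second velocity estimate
  anchored at the known *final* value. The two are fused with a sigmoid
  weight $w(t) \in [0,1]$ (logistic with midpoint $t_0$, steepness $\eta$,
  on normalised stride time, rescaled so $w$ is exactly 0 and 1 at the
  endpoints). Defaults $t_0 = 0.6$, $\eta = 0.08$: trust the forward
  integral until late swing, then hand over to the end-anchored one. The
  vertical position is fused the same way; ground-plane position is the
  plain integral of the fused velocity, deliberately left undedrifted —
  only axes with known boundary values are corrected.
* **Analytic**: the acceleration is projected by least squares onto a
  zero-DC Fourier basis ($\cos, \sin(2\pi k t/T)$, $k = 1..N$) on the exact
  stride duration $T$ — not an FFT grid, because strides are short and not
  power-of-two — and integrated term by term. Forcing the DC coefficient to
  zero encodes the cyclic boundary condition: the analytic velocity returns
  to zero at $t_{ms+1}$ by construction. The vertical double integral is
  also analytic in this basis. Ground-plane position has no cyclic boundary
  condition, so it instead integrates a least-squares B-spline fit of the
  velocity analytically (the antiderivative of a B-spline in B-form is again
  a B-spline, one order higher, via the de Boor coefficient recursion).

All three schemes guarantee $v = 0$ and $s_y = 0$ at both stride boundaries
*exactly* (not to a tolerance). Two numerical details make that literal:
endpoint-anchored corrections compute the interpolation fraction before
multiplying (so the endpoint terms cancel in floating point), and the
analytic scheme removes the sub-machine-precision linear residual left by
evaluating $\sin(2\pi k)$ in floating point.

### Analytic-basis parameters

`n_fourier` defaults to 60, the order needed for sub-5% reconstruction of
*unfiltered* foot-IMU accelerations (no low-pass prefilter is applied in
this pipeline; an optional Butterworth stage was considered and rejected as
a deviation from the benchmarked processing). Note the hard constraint
$N < n/2$: at 102.4 Hz a 1.1 s stride has ~113 samples, so the package's own
benchmark runs use `n_fourier = 45`, which keeps content up to ~40 Hz.
B-splines default to cubic (`spline_order = 3`) with the number of uniform
interior knots doubled until the relative reconstruction error (RMS residual
over RMS signal) meets the `smoothness` goal, default 5%.

## The synthetic stride simulator

No public reference dataset with synchronized optical ground truth exists
for this task, so validation rests on simulated strides with *exact* ground
truth. A stride is built from closed-form profiles on the movement window
(the stride minus a quasi-static stance margin at each end,
`stance_fraction` = 0.55 of the duration):

* horizontal displacement: minimum-jerk reach of `stride_length`
  (1.2 m default, ~1.1 s duration — normal-paced adult gait);
* clearance: a smooth two-lobe profile (sin⁴ envelope with a centre dip)
  peaking at `max_clearance` (0.12 m default for a laterally mounted sensor);
* lateral sway: a single 0.02 m lobe returning to the line of progression;
* orientation: one sagittal plantarflexion–dorsiflexion cycle (±~25° from a
  40° amplitude profile) plus a 5° transversal/frontal wobble, on top of a
  static mounting tilt (5° about x, 10° about z by default).

Every profile has zero value, slope and curvature at the stride boundaries,
so the zero-velocity, zero-acceleration and level-floor assumptions hold
*exactly* — the simulator realises the estimators' model. The lateral and
wobble components also guarantee that every axis attains a non-degenerate
range, which the range-normalised grid-search objective divides by.

The IMU signals invert the measurement model: specific force
$R^T(a_w/g + (0,1,0))$, body rates from central quaternion differences of
the closed-form orientation at 1/20 of the sampling interval (discretisation
error far below the estimators' first-order error), then Gaussian noise
(defaults: 0.01 g accel, 0.01 rad/s gyro — consumer-grade MEMS after
calibration), a constant gyro bias (~0.8°/s overall) and an optional
constant sensor-frame accelerometer bias used for drift-robustness
experiments. All randomness flows through one seed; the caller's RNG state
is untouched.

What passing tests on these strides do *not* show: robustness to turning
gait, stairs, shuffling or freezing, soft-tissue artefacts, sensor
saturation, or mis-detected mid-stances. The simulator emulates straight,
level, healthy walking within the estimators' own assumptions.

## Evaluation harness

Errors are pooled per sample over all strides, per variable and axis;
*accuracy* is the mean signed error and *precision* its standard deviation.
Orientation errors are compared as intrinsic z–x–y Euler angles of the
sensor-to-world rotation (z = sagittal, x = transversal, y = frontal — the
convention is recorded on every result, since the decomposition order is a
package choice). Grid search minimises the mean over variables of
RMSE/range, the range taken over the whole reference dataset
($\rho_i = \max - \min$ of the reference course). Grids: $\beta$ and $k_P$
on $10^{-i/3}$, $i = 0..9$; $t_0 = 0.05i$, $i = 0..20$; $\eta$
log-spaced on $[0.01, 0.5]$ via $10^{\kappa - i\delta}$ with
$\kappa = \log_{10}\tfrac12$, $\delta = (\log_{10}\tfrac12 + 2)/9$; $\gamma$
a fixed list sampling stance-update coverage roughly evenly. Ties break to
the first grid point; output is deterministic. `rank_methods()` orders
methods by the mean over endpoints of $(|\text{accuracy}| +
\text{precision})/2$, stated in its output attribute. Execution times are
reported for information only — they are hardware facts, not accuracy
claims.

Problem sizes in the shipped tests and acceptance script — up to 100
simulated strides, 50-stride grid searches, 20-seed property checks — were
chosen as the smallest sizes at which the pooled statistics stabilise.

## Known limitations

* First-order quaternion integration: orientation error grows with
  $\Delta t$; at 102.4 Hz the worst-case simulated angle error is a few
  degrees over a dynamic stride.
* Heading is per-stride only; trajectories of consecutive strides share no
  common azimuth.
* The piecewise-dedrift joint rule and the swing-detection threshold are
  package defaults where the benchmarked methods leave details open; both
  are configurable and recorded in run metadata.
* The grid-search optimum on synthetic data need not coincide with optima
  reported on any particular real dataset; it is the harness, not the
  answer, that transfers.
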