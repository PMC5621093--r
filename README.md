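# gaittraj

Stride-wise foot trajectory estimation from shoe-mounted inertial sensors.

Mobile gait analysis systems strap an IMU to the shoe and reconstruct, for
every stride, where the foot went: stride length, clearance (the vertical
path of the sensor during swing), velocity and foot orientation. These are
the quantities clinicians track in movement disorders, and they cannot be
measured directly — they must be *integrated* out of a 3-axis gyroscope
(rad/s) and a 3-axis accelerometer (g) sampled at ~100 Hz. `gaittraj`
implements the full per-stride processing chain and the harness to compare
its interchangeable parts, for researchers building or validating
IMU-based gait pipelines.

## The methods

Between two consecutive mid-stances $t_{ms}, t_{ms+1}$ (minimal gyroscope
energy; the foot is quasi-stationary) the pipeline assumes zero velocity,
zero movement acceleration and a level floor at both boundaries, and runs:

1. **Initial inclination** from the resting accelerometer,
   $\alpha_z = \operatorname{atan2}(-a_x, a_y)$,
   $\alpha_x = \operatorname{atan2}(a_z, \sqrt{a_x^2+a_y^2})$ (heading is
   unobservable and set to zero).
2. **Orientation tracking** with one of three estimators, all built on the
   first-order quaternion update
   $q(t) = \mathrm{normalize}\{q(t-\Delta t) + \tfrac12 q \otimes (0,\omega)\,\Delta t\}$:
   plain gyroscope integration; a magnetometer-free **Madgwick**
   complementary filter ($\dot q = \dot q_\omega - \beta \nabla\epsilon /
   \lVert\nabla\epsilon\rVert$, gated to near-1 g, non-swing samples); or an
   **Euston/Mahony** explicit complementary filter
   ($\omega^* = \omega + k_P e + k_I \int e\,dt$ with
   $e = \hat g_s \times \hat a_s$).
3. **Gravity removal** in the world frame with piecewise-linear dedrifting
   so that $a(t_{ms}) = a(t_{ms+1}) = 0$.
4. **Double integration** by one of three schemes: **direct** (trapezoid +
   linear dedrifting of velocity and vertical position), **direct &
   reverse** (fusion of a forward and a time-reversed, end-anchored
   integral through a sigmoid weight $w(t)$ — no explicit dedrifting), or
   **analytic** (zero-DC Fourier decomposition integrated term by term for
   the cyclic axes, B-spline antiderivatives for ground-plane position).

Any of the 3 × 3 combinations can be selected. A synthetic gait simulator
with exact closed-form ground truth and a benchmarking module (pooled error
distributions, accuracy = mean / precision = SD, range-normalised grid
search, method ranking) complete the package. The methods vignette
(`vignettes/foot-trajectory-methods.Rmd`) documents the models, parameters
and numerical choices in detail.

## Worked example

```r
library(gaittraj)

# simulate one stride with known ground truth (1.2 m, 1.1 s, noisy IMU)
spec <- synthetic_stride_spec(stride_length = 1.2, seed = 42)
sim  <- simulate_stride(spec)

# reconstruct it with the Madgwick filter + direct & reverse integration
fit <- run_pipeline(sim$recording,
                    orient_method = "madgwick",
                    integ_method  = "direct_reverse")
fit
#> <foot_trajectory> madgwick orientation + direct_reverse integration
#>   stride length 1.198 m, duration 1.104 s, max clearance 0.117 m
```

The true stride length was 1.200 m and the true peak clearance 0.120 m: the
reconstruction is within 2 mm and 3 mm respectively under realistic sensor
noise and gyro bias. `glance(fit)` returns the same summary as a one-row
tibble (plus the fraction of stance samples that received an accelerometer
orientation update), `tidy(fit)` the per-sample velocity/position series in
long form, and `autoplot(fit)` the clearance curve and sagittal path.
`write_trajectory_csv()` exports `time_s, vx, vy, vz, sx, sy, sz` with a
JSON metadata side-car.

Dataset-level tools follow the same pattern:

```r
ds <- simulate_dataset(50, seed = 1)
benchmark_integration(ds)          # accuracy ± precision per endpoint/scheme
grid_search(ds, "direct_reverse")  # exhaustive (t0, eta) search
```

A thin command-line wrapper with `simulate`, `run`, `gridsearch` and
`benchmark` subcommands ships in `inst/cli/gaittraj`.

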