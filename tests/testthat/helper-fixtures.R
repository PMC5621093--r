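# Shared fixtures: deterministic random rotations and hand-built strides.

random_unit_quats <- function(n, seed = 42) {
  set.seed(seed)
  q <- matrix(rnorm(4 * n), n, 4)
  q / sqrt(rowSums(q^2))
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

# A stride recording with constant gyro/accel rows (defaults: at rest).
constant_stride <- function(n = 64, dt = 1 / 102.4,
                            gyro = c(0, 0, 0), accel = c(0, 1, 0)) {
  stride_recording(tibble::tibble(
    time_s = (seq_len(n) - 1) * dt,
    gx = gyro[1], gy = gyro[2], gz = gyro[3],
    ax = accel[1], ay = accel[2], az = accel[3]
  ))
}

# Noise-free simulator spec.
clean_spec <- function(...) {
  synthetic_stride_spec(accel_noise_sd = 0, gyro_noise_sd = 0,
                        gyro_bias = c(0, 0, 0), ...)
}
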