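# Analytic double integration: decomposition of the acceleration signal in a
# zero-DC Fourier basis (cyclic boundary conditions) or a B-spline basis
# (non-cyclic), followed by term-wise analytic integration.

#' Analytic-integration basis parameters
#'
#' @param basis `"fourier"` or `"bspline"`.
#' @param n_fourier Number of Fourier harmonics. Default 60 (chosen for < 5%
#'   average reconstruction error on unfiltered foot-IMU signals); must stay
#'   below half the number of samples per stride.
#' @param spline_order Polynomial degree of the B-spline basis. Default 3.
#' @param smoothness Relative reconstruction-error goal used to select the
#'   number of B-spline control points automatically. Default 0.05.
#' @return A list of class `analytic_params`.
#' @export
analytic_params <- function(basis = c("fourier", "bspline"), n_fourier = 60,
                            spline_order = 3, smoothness = 0.05) {
  basis <- match.arg(basis)
  stopifnot(n_fourier >= 1, spline_order >= 1, smoothness > 0)
  structure(
    list(basis = basis, n_fourier = as.integer(n_fourier),
         spline_order = as.integer(spline_order), smoothness = smoothness),
    class = "analytic_params"
  )
}

#' Zero-DC Fourier decomposition of a per-stride signal
#'
#' Least-squares projection of `x` onto `{cos(2 pi k t / T), sin(2 pi k t / T)}`,
#' `k = 1..n_terms`, with the DC component forced to zero: the movement
#' acceleration is zero at both stride boundaries, so the signal is treated
#' as one period of a zero-mean cycle. The basis period is the exact stride
#' duration `T = (n - 1) delta_t`, not a power-of-two grid.
#'
#' @param x Numeric sequence.
#' @param delta_t Sampling interval in s.
#' @param n_terms Number of harmonics; must satisfy `n_terms < length(x) / 2`.
#' @return List of class `fourier_decomposition` with `c1` (cosine) and `c2`
#'   (sine) coefficients, period `T`, `fitted` values and the relative
#'   reconstruction error `rel_error` (RMS residual / RMS signal).
#' @export
fourier_decompose <- function(x, delta_t, n_terms = 60) {
  n <- length(x)
  stopifnot(n >= 4, delta_t > 0)
  n_terms <- as.integer(n_terms)
  if (n_terms < 1) stop("n_terms must be >= 1")
  if (n_terms >= n / 2) {
    stop(sprintf("n_terms = %d over-parameterises a %d-sample stride (need n_terms < n/2)",
                 n_terms, n))
  }
  period <- (n - 1) * delta_t
  tau <- (seq_len(n) - 1) / (n - 1) # t / T, exact at both endpoints
  k <- seq_len(n_terms)
  phase <- 2 * pi * outer(tau, k)
  M <- cbind(cos(phase), sin(phase))
  fit <- stats::lm.fit(M, x)
  coefs <- unname(fit$coefficients)
  coefs[is.na(coefs)] <- 0
  fitted <- as.numeric(M %*% coefs)
  rms_x <- sqrt(mean(x^2))
  rel <- if (rms_x > 0) sqrt(mean((x - fitted)^2)) / rms_x else 0
  structure(
    list(c1 = coefs[k], c2 = coefs[n_terms + k], period = period,
         n_terms = n_terms, n = n, delta_t = delta_t,
         fitted = fitted, rel_error = rel),
    class = "fourier_decomposition"
  )
}

#' Analytic integral of a Fourier decomposition
#'
#' Term-wise antiderivatives of the basis functions, evaluated on the sample
#' grid, with integration constants fixed by a zero initial value at the
#' first mid-stance (for both the single and the double integral). For the
#' single integral the zero-DC construction also forces a zero final value
#' (cyclic boundary condition).
#'
#' @param decomp A `fourier_decomposition`.
#' @param order 1 (velocity from acceleration) or 2 (position from
#'   acceleration).
#' @return Numeric sequence over the sample grid.
#' @export
fourier_integrate <- function(decomp, order = 1) {
  stopifnot(inherits(decomp, "fourier_decomposition"), order %in% c(1, 2))
  n <- decomp$n
  tau <- (seq_len(n) - 1) / (n - 1)
  t <- tau * decomp$period
  out <- numeric(n)
  for (k in seq_len(decomp$n_terms)) {
    om <- 2 * pi * k / decomp$period
    ph <- 2 * pi * k * tau
    c1 <- decomp$c1[k]; c2 <- decomp$c2[k]
    if (order == 1) {
      out <- out + c1 / om * sin(ph) + c2 / om * (1 - cos(ph))
    } else {
      out <- out + c1 / om^2 * (1 - cos(ph)) + c2 / om * (t - sin(ph) / om)
    }
  }
  out
}

# --- B-spline decomposition and analytic antiderivative -------------------

# Least-squares B-spline fit with automatic refinement of the uniform
# interior-knot grid until the relative reconstruction error meets `tol`.
fit_bspline <- function(x, t, degree = 3, tol = 0.05) {
  n <- length(x)
  ord <- degree + 1L
  stopifnot(length(t) == n, n > ord)
  rms_x <- sqrt(mean(x^2))
  n_interior <- 0L
  repeat {
    interior <- if (n_interior > 0) {
      seq(t[1], t[n], length.out = n_interior + 2L)[-c(1L, n_interior + 2L)]
    } else {
      numeric(0)
    }
    knots <- c(rep(t[1], ord), interior, rep(t[n], ord))
    B <- splines::splineDesign(knots, t, ord = ord)
    fit <- stats::lm.fit(B, x)
    coefs <- unname(fit$coefficients)
    coefs[is.na(coefs)] <- 0
    resid <- x - as.numeric(B %*% coefs)
    rel <- if (rms_x > 0) sqrt(mean(resid^2)) / rms_x else 0
    at_cap <- (length(coefs) * 2L) >= n
    if (rel <= tol || at_cap) {
      return(list(knots = knots, coefs = coefs, ord = ord, rel_error = rel,
                  fitted = x - resid))
    }
    n_interior <- max(n_interior * 2L, 2L)
  }
}

# Antiderivative of a B-spline in B-form (de Boor): a spline of one order
# higher on the knot vector extended by one replicate at each end, with
# coefficients the scaled cumulative sums of the input coefficients.
bspline_antiderivative <- function(spl) {
  k <- spl$ord - 1L # polynomial degree
  tt <- spl$knots
  nc <- length(spl$coefs)
  dt <- (tt[(1:nc) + spl$ord] - tt[1:nc]) / spl$ord
  list(
    knots = c(tt[1], tt, tt[length(tt)]),
    coefs = c(0, cumsum(spl$coefs * dt)),
    ord = spl$ord + 1L
  )
}

bspline_eval <- function(spl, t) {
  B <- splines::splineDesign(spl$knots, t, ord = spl$ord)
  as.numeric(B %*% spl$coefs)
}

#' Analytic integration in a B-spline basis
#'
#' Fits a least-squares B-spline (uniform interior knots, refined until the
#' relative reconstruction error meets the smoothness goal) to the signal
#' and integrates the spline analytically — the antiderivative of a B-spline
#' is again a B-spline, one order higher. Integration constants are fixed by
#' zero initial values. Suited to non-cyclic boundary conditions such as the
#' ground-plane position.
#'
#' @param x Numeric sequence.
#' @param delta_t Sampling interval in s.
#' @param order 1 or 2: integrate once or twice.
#' @param params An [analytic_params()] providing `spline_order` and
#'   `smoothness`.
#' @return Numeric sequence over the sample grid.
#' @export
bspline_analytic_integrate <- function(x, delta_t, order = 1,
                                       params = analytic_params(basis = "bspline")) {
  stopifnot(order %in% c(1, 2))
  n <- length(x)
  t <- (seq_len(n) - 1) * delta_t
  if (all(x == 0)) return(numeric(n))
  spl <- fit_bspline(x, t, degree = params$spline_order, tol = params$smoothness)
  anti <- bspline_antiderivative(spl)
  if (order == 2) anti <- bspline_antiderivative(anti)
  y <- bspline_eval(anti, t)
  y - y[1]
}

#' Analytic double integration of a stride
#'
#' Velocity on every axis and the vertical double integral come from the
#' zero-DC Fourier decomposition (cyclic boundary conditions); the
#' ground-plane position comes from analytic B-spline integration of the
#' fused velocity (non-cyclic boundary). As in the numeric schemes, the
#' boundary conditions v = 0 and sy = 0 at both mid-stances are enforced
#' exactly (the residual linear drift left by finite-precision evaluation of
#' the basis functions is removed per axis).
#'
#' @param a A `world_accel_track` from [remove_gravity()].
#' @param delta_t Sampling interval in s.
#' @param params An [analytic_params()].
#' @param time_s Optional timestamps.
#' @return A `trajectory_estimate`.
#' @export
integrate_analytic <- function(a, delta_t, params = analytic_params(),
                               time_s = NULL) {
  am <- accel_matrix(a)
  n <- nrow(am)
  time_s <- traj_time(a, time_s, n, delta_t)
  v <- matrix(0, n, 3)
  decomps <- vector("list", 3)
  for (ax in 1:3) {
    decomps[[ax]] <- fourier_decompose(am[, ax], delta_t, params$n_fourier)
    v[, ax] <- linear_dedrift(fourier_integrate(decomps[[ax]], order = 1))
  }
  s <- matrix(0, n, 3)
  s[, 1] <- bspline_analytic_integrate(v[, 1], delta_t, 1, params)
  s[, 3] <- bspline_analytic_integrate(v[, 3], delta_t, 1, params)
  s[, 2] <- linear_dedrift(fourier_integrate(decomps[[2]], order = 2))
  new_trajectory(time_s, v, s, "analytic", delta_t)
}
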