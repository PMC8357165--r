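#' Stimulus pulse amplitude from shape, duration and energy
#'
#' Each pulse shape has a closed-form energy `E = c * A^2 * D` with a
#' shape-specific coefficient `c` (rectangular 1, Gaussian 0.3957,
#' rectangular trapezoid 2/3, triangular and both ramps 1/3). The amplitude
#' is obtained by inverting the shape's energy formula, so pulses of
#' different shapes can be compared at equal energy.
#'
#' @param shape One of `"rectangular"`, `"gaussian"`, `"rectangular_trapezoid"`,
#'   `"triangular"`, `"rising_ramp"`, `"decreasing_ramp"`.
#' @param duration Pulse duration D (s).
#' @param energy Pulse energy E (arbitrary units, (s^-1)^2 s).
#' @return Amplitude A (s^-1).
#' @examples
#' pulse_amplitude("rectangular", 0.1, 40)   # 20.00
#' pulse_amplitude("triangular", 0.1, 40)    # 34.64
#' @export
pulse_amplitude <- function(shape, duration, energy) {
  shape <- match.arg(shape, pulse_shapes())
  stopifnot(duration > 0, energy > 0)
  coef <- switch(shape,
    rectangular = 1,
    gaussian = 0.3957,
    rectangular_trapezoid = 2 / 3,
    triangular = 1 / 3,
    rising_ramp = 1 / 3,
    decreasing_ramp = 1 / 3)
  sqrt(energy / (coef * duration))
}

#' @rdname pulse_amplitude
#' @export
pulse_shapes <- function() {
  c("rectangular", "gaussian", "rectangular_trapezoid", "triangular",
    "rising_ramp", "decreasing_ramp")
}

#' Stimulus pulse specification
#'
#' @param shape Pulse shape, see [pulse_shapes()].
#' @param duration Pulse duration (s).
#' @param energy Pulse energy (a.u.).
#' @return An object of class `pulse_spec` with the derived amplitude.
#' @export
pulse_spec <- function(shape = "decreasing_ramp", duration = 0.1, energy = 40) {
  shape <- match.arg(shape, pulse_shapes())
  structure(list(shape = shape, duration = duration, energy = energy,
                 amplitude = pulse_amplitude(shape, duration, energy)),
            class = "pulse_spec")
}

# width of the truncated Gaussian pulse, as a fraction of D, solved once so
# that the discrete-shape energy reproduces the printed coefficient 0.3957:
# c * sqrt(pi) * erf(1 / (2 c)) = 0.3957 with sigma = c * D.
gaussian_pulse_sigma_frac <- function() {
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  stats::uniroot(function(cc) cc * sqrt(pi) * erf(1 / (2 * cc)) - 0.3957,
                 c(0.05, 1), tol = 1e-12)$root
}

#' Sampled stimulus pulse waveform
#'
#' Samples the pulse at midpoints of the integration steps, so the discrete
#' energy `sum(u^2) * dt` tracks the analytic energy closely.
#'
#' @param spec A [pulse_spec()].
#' @param dt Sampling step (s); must satisfy `dt <= duration / 10`.
#' @return Numeric vector of `round(duration / dt)` samples (s^-1).
#' @export
pulse_waveform <- function(spec, dt) {
  stopifnot(inherits(spec, "pulse_spec"), dt > 0)
  if (dt > spec$duration / 10)
    stop("`dt` must be at most duration/10 to resolve the pulse", call. = FALSE)
  D <- spec$duration
  A <- spec$amplitude
  n <- round(D / dt)
  t <- (seq_len(n) - 0.5) * dt
  u <- switch(spec$shape,
    rectangular = rep(A, n),
    gaussian = {
      sig <- gaussian_pulse_sigma_frac() * D
      A * exp(-(t - D / 2)^2 / (2 * sig^2))
    },
    rectangular_trapezoid = ifelse(t <= D / 2, A, A * 2 * (1 - t / D)),
    triangular = ifelse(t <= D / 2, A * 2 * t / D, A * 2 * (1 - t / D)),
    rising_ramp = A * t / D,
    decreasing_ramp = rev(A * t / D))
  u
}

#' Stimulation onset times for open-loop protocols
#'
#' Periodic stimulation places onsets on a fixed inter-stimulus period
#' starting at the opening of the active window; Poisson stimulation draws
#' exponential inter-arrival times with the requested mean, with successive
#' onsets kept at least `min_sep` apart so pulses never overlap.
#'
#' @param mode `"periodic"` or `"poisson"`.
#' @param window Numeric length-2, the active stimulation window (s).
#' @param rate Pulses per second for `"periodic"`.
#' @param lambda Mean inter-arrival time (s) for `"poisson"`.
#' @param min_sep Minimum onset separation (s); typically the pulse duration.
#' @param seed Integer seed for the Poisson draws.
#' @return Numeric vector of onset times (s), possibly empty.
#' @export
generate_onsets <- function(mode = c("periodic", "poisson"), window,
                            rate = NULL, lambda = NULL, min_sep = 0,
                            seed = 1) {
  mode <- match.arg(mode)
  stopifnot(length(window) == 2)
  if (window[2] <= window[1]) return(numeric(0))
  if (mode == "periodic") {
    stopifnot(is.numeric(rate), rate > 0)
    return(seq(window[1], window[2], by = 1 / rate))
  }
  stopifnot(is.numeric(lambda), lambda > 0)
  onsets <- numeric(0)
  withr::with_seed(seed, {
    t <- window[1] + stats::rexp(1, rate = 1 / lambda)
    while (t <= window[2]) {
      onsets <- c(onsets, t)
      gap <- max(stats::rexp(1, rate = 1 / lambda), min_sep)
      t <- t + gap
    }
  })
  onsets
}

#' Difference-of-Gaussians spatial coupling kernel
#'
#' Maps the one-channel stimulus onto the sheet as a centre-surround
#' receptive field on the relay-nucleus input: an excitatory Gaussian of
#' width `sigma_e` minus an inhibitory one of width `sigma_i`, both in node
#' units, evaluated literally as
#' `w(r) = exp(-d^2/sigma_e^2) / (2 pi sigma_e) - exp(-d^2/sigma_i^2) / (2 pi sigma_i)`
#' with `d` the Euclidean node-index distance from the centre.
#'
#' @param grid An [grid_spec()] object.
#' @param center Integer (x, y) node index of the kernel centre, 0-based.
#' @param sigma_e,sigma_i Excitatory and inhibitory widths (node units);
#'   `sigma_e < sigma_i` gives the centre-surround structure.
#' @return Numeric vector of per-node weights in row-major node order
#'   (x fastest), length `nx * ny`.
#' @export
dog_kernel <- function(grid, center = c(7, 7), sigma_e = 1, sigma_i = 2) {
  stopifnot(inherits(grid, "nft_grid"), sigma_e > 0, sigma_i > 0)
  if (any(center < 0) || center[1] > grid$nx - 1 || center[2] > grid$ny - 1)
    stop("kernel centre must be a node inside the grid", call. = FALSE)
  margin <- min(center[1], grid$nx - 1 - center[1],
                center[2], grid$ny - 1 - center[2])
  if (3 * sigma_i > margin)
    warning("DoG kernel support (3 sigma_i) reaches the grid boundary",
            call. = FALSE)
  x <- rep(0:(grid$nx - 1), times = grid$ny)
  y <- rep(0:(grid$ny - 1), each = grid$nx)
  d2 <- (x - center[1])^2 + (y - center[2])^2
  exp(-d2 / sigma_e^2) / (2 * pi * sigma_e) -
    exp(-d2 / sigma_i^2) / (2 * pi * sigma_i)
}

#' Stimulation protocol
#'
#' Bundles the delivery mode with the pulse and the spatial coupling.
#' `"sham"` carries no pulse; `"periodic"` (STIM-P) uses a fixed rate;
#' `"poisson"` (STIM-R) draws Poisson onsets with mean interval `lambda`;
#' `"closed_loop"` (STIM-CL) fires when the online-estimated phase of the
#' ongoing activity, tracked at central frequency `f0`, enters a hysteresis
#' window around `target_phase`.
#'
#' @param mode One of `"sham"`, `"periodic"`, `"poisson"`, `"closed_loop"`.
#' @param pulse A [pulse_spec()] (ignored for `"sham"`).
#' @param rate Pulses per second for `"periodic"`.
#' @param lambda Mean inter-stimulus interval (s) for `"poisson"`.
#' @param f0 Central frequency (Hz) tracked by the closed-loop phase
#'   estimator.
#' @param target_phase Closed-loop target phase in degrees, sine reference
#'   (0 = rising zero-cross, 90 = up-peak).
#' @param hysteresis Half-width of the closed-loop trigger window (degrees).
#' @param dog_center,dog_sigma_e,dog_sigma_i Spatial coupling, see
#'   [dog_kernel()].
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(mode = c("sham", "periodic", "poisson", "closed_loop"),
                          pulse = pulse_spec(), rate = 0.85, lambda = 1 / 0.85,
                          f0 = 0.85, target_phase = 0, hysteresis = 9,
                          dog_center = c(7, 7), dog_sigma_e = 1,
                          dog_sigma_i = 2) {
  mode <- match.arg(mode)
  if (mode != "sham") stopifnot(inherits(pulse, "pulse_spec"))
  stopifnot(target_phase >= 0, target_phase < 360, hysteresis > 0,
            dog_sigma_e < dog_sigma_i)
  structure(list(mode = mode,
                 pulse = if (mode == "sham") NULL else pulse,
                 rate = rate, lambda = lambda, f0 = f0,
                 target_phase = target_phase, hysteresis = hysteresis,
                 dog_center = dog_center, dog_sigma_e = dog_sigma_e,
                 dog_sigma_i = dog_sigma_i),
            class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat("<stim_protocol>", toupper(x$mode), "\n")
  if (!is.null(x$pulse))
    cat(sprintf("  pulse: %s, D %g s, E %g a.u. (A = %.2f s^-1)\n",
                x$pulse$shape, x$pulse$duration, x$pulse$energy,
                x$pulse$amplitude))
  if (x$mode == "periodic") cat(sprintf("  rate %g Hz\n", x$rate))
  if (x$mode == "poisson") cat(sprintf("  mean interval %g s\n", x$lambda))
  if (x$mode == "closed_loop")
    cat(sprintf("  f0 %g Hz, target %g deg, hysteresis +/-%g deg\n",
                x$f0, x$target_phase, x$hysteresis))
  invisible(x)
}

#' Assemble the noisy input field with stimulation
#'
#' Builds the per-node input drive `phi_n(r, t) = v(r, t) + w(r) * u(t)`
#' where `v` is i.i.d. Gaussian noise (mean `phi_n0`, SD `noise_sd`, one
#' draw per node per step), `w` the Difference-of-Gaussians weight map, and
#' `u` the pulse train. Mainly a diagnostic surface: the simulator composes
#' the same field internally from the identical noise stream.
#'
#' @param grid An [grid_spec()].
#' @param params An [nft_params()] (supplies `phi_n0` and `noise_sd`).
#' @param onsets Onset times (s) relative to the stream start.
#' @param pulse A [pulse_spec()] or `NULL` for no stimulation.
#' @param dog Per-node weights from [dog_kernel()]; defaults to the
#'   standard centre-surround map.
#' @param duration Stream duration (s).
#' @param seed Noise stream seed.
#' @return Matrix of `nx*ny` rows by `duration/dt` columns (s^-1).
#' @export
assemble_input_field <- function(grid, params, onsets = numeric(0),
                                 pulse = NULL, dog = NULL, duration = 1,
                                 seed = 1) {
  stopifnot(inherits(grid, "nft_grid"), inherits(params, "nft_params"))
  n_steps <- round(duration / grid$dt)
  field <- nft_noise_stream_cpp(as.integer(seed), n_steps, grid$nx * grid$ny,
                                params$phi_n0, params$noise_sd)
  if (!is.null(pulse) && length(onsets) > 0) {
    if (is.null(dog)) dog <- dog_kernel(grid)
    u <- pulse_waveform(pulse, grid$dt)
    for (on in onsets) {
      k0 <- round(on / grid$dt)
      idx <- (k0 + 1):min(k0 + length(u), n_steps)
      if (length(idx) > 0)
        field[, idx] <- field[, idx] + outer(dog, u[seq_along(idx)])
    }
  }
  field
}
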