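# Closed-loop phase-lock driver: streaming phase estimation of the ongoing
# activity at a fixed central frequency, and a one-shot hysteresis trigger.

polymul <- function(p, q) {
  r <- numeric(length(p) + length(q) - 1)
  for (i in seq_along(p))
    r[i:(i + length(q) - 1)] <- r[i:(i + length(q) - 1)] + p[i] * q
  r
}

poly_from_roots <- function(roots) {
  p <- 1 + 0i
  for (z in roots) p <- polymul(p, c(1, -z))
  Re(p)
}

# rational transfer-function value at normalised angular frequency w
# (rad/sample); coefficients in descending powers of z
iir_response <- function(b, a, w) {
  vapply(w, function(wi) {
    z <- exp(-1i * wi * (0:(max(length(b), length(a)) - 1)))
    sum(b * z[seq_along(b)]) / sum(a * z[seq_along(a)])
  }, complex(1))
}

#' Design the closed-loop phase-estimation filters
#'
#' Two cascaded IIR stages track the phase of the ongoing activity at the
#' central frequency `f0`. The inverse-notch resonator selects the `f0`
#' component: zeros at `z = -1, -1, 1` (zero DC and Nyquist gain), poles at
#' `0.9999 exp(+/- i omega0)` and the origin, numerator scale `1e-4`, with
#' `omega0 = 2 pi f0 h`. The quadrature stage produces a phase-shifted
#' companion: zeros `-0.5 exp(+/- i 0.495 pi), -0.9`, poles
#' `0.9999 exp(+/- i omega0), 0.999`, numerator scale half the ratio of the
#' summed denominator to summed numerator coefficients.
#'
#' The quadrature stage's complex response at `omega0` (gain `quad_gain`,
#' shift `quad_shift`) is stored with the coefficients: phase recovery uses
#' it to reconstruct the in-phase/quadrature pair exactly at the tracked
#' frequency, whatever the stage's actual shift there. The estimator is
#' designed to run at the integration rate (`h` of order 1e-4 s), where the
#' quadrature shift is well conditioned; at coarser tick rates the printed
#' pole set pushes the shift towards 180 degrees and phase recovery
#' degrades.
#'
#' @param f0 Central frequency (Hz).
#' @param h_ctrl Controller tick period (s); must satisfy `f0 < 1/(2 h_ctrl)`.
#' @param env_decay_rate Envelope peak-decay rate (s^-1).
#' @param phase_smooth Length (s) of the sliding vector average applied to
#'   the in-phase/quadrature pair in the trigger path; the reported phase is
#'   unsmoothed. Set 0 to disable.
#' @param target_phase,hysteresis Trigger target and half-window (degrees).
#' @param rearm_phase Phase (degrees) that must be reached to re-arm the
#'   one-shot trigger.
#' @return An object of class `nft_controller` holding both coefficient sets
#'   and the trigger configuration.
#' @export
design_controller <- function(f0 = 0.85, h_ctrl = 1e-4,
                              env_decay_rate = 12.5, phase_smooth = 0.15,
                              target_phase = 0, hysteresis = 9,
                              rearm_phase = 342) {
  stopifnot(f0 > 0, h_ctrl > 0)
  if (f0 >= 1 / (2 * h_ctrl))
    stop("`f0` must be below the controller Nyquist frequency", call. = FALSE)
  w0 <- 2 * pi * f0 * h_ctrl
  notch_b <- 1e-4 * poly_from_roots(c(-1, -1, 1))
  notch_a <- poly_from_roots(c(0.9999 * exp(1i * w0), 0.9999 * exp(-1i * w0), 0))
  quad_b0 <- poly_from_roots(c(-0.5 * exp(1i * 0.495 * pi),
                               -0.5 * exp(-1i * 0.495 * pi), -0.9))
  quad_a <- poly_from_roots(c(0.9999 * exp(1i * w0), 0.9999 * exp(-1i * w0),
                              0.999))
  quad_b <- 0.5 * sum(quad_a) / sum(quad_b0) * quad_b0
  hq <- iir_response(quad_b, quad_a, w0)
  structure(list(
    f0 = f0, h_ctrl = h_ctrl, omega0 = w0,
    notch_b = notch_b, notch_a = notch_a,
    quad_b = quad_b, quad_a = quad_a,
    quad_gain = Mod(hq), quad_shift = Arg(hq),
    env_decay = exp(-env_decay_rate * h_ctrl),
    env_counter_limit = as.integer(round(1 / (f0 * h_ctrl))),
    smooth_len = as.integer(max(1, round(phase_smooth / h_ctrl))),
    smooth_advance = 0,
    target_deg = target_phase, hysteresis_deg = hysteresis,
    rearm_deg = rearm_phase),
    class = "nft_controller")
}

#' @export
print.nft_controller <- function(x, ...) {
  cat(sprintf("<nft_controller> f0 %g Hz at %g s ticks; quad shift %.1f deg, gain %.3f\n",
              x$f0, x$h_ctrl, x$quad_shift * 180 / pi, x$quad_gain))
  cat(sprintf("  trigger: target %g deg +/- %g, re-arm at %g deg\n",
              x$target_deg, x$hysteresis_deg, x$rearm_deg))
  invisible(x)
}

#' Frequency response of a controller stage
#'
#' @param ctrl An [design_controller()] object.
#' @param freqs Frequencies (Hz).
#' @param stage `"notch"` or `"quad"`.
#' @return A tibble with `freq`, complex `response` and `gain_db`.
#' @export
controller_response <- function(ctrl, freqs, stage = c("notch", "quad")) {
  stage <- match.arg(stage)
  w <- 2 * pi * freqs * ctrl$h_ctrl
  h <- if (stage == "notch") iir_response(ctrl$notch_b, ctrl$notch_a, w)
       else iir_response(ctrl$quad_b, ctrl$quad_a, w)
  tibble::tibble(freq = freqs, response = h, gain_db = 20 * log10(Mod(h)))
}

#' Run the streaming phase estimator over a signal
#'
#' Applies the full online pipeline sample by sample: inverse-notch filter,
#' peak-hold envelope normalisation with exponential decay, quadrature
#' filter, elliptical phase recovery and the one-shot hysteresis trigger.
#' The returned phase follows the sine convention of the tracked component
#' (0 deg = rising zero-cross, 90 deg = up-peak).
#'
#' @param x Numeric signal sampled at the controller tick rate, or a data
#'   frame with a numeric column `x`.
#' @param ctrl An [design_controller()] object.
#' @return A tibble with per-tick columns `t`, `phase` (degrees in
#'   `[0, 360)`), `envelope` and logical `fire`.
#' @export
controller_run <- function(x, ctrl) {
  if (is.data.frame(x)) x <- x$x
  stopifnot(is.numeric(x), inherits(ctrl, "nft_controller"))
  out <- nft_controller_run_cpp(as.numeric(x), controller_cfg(ctrl))
  tibble::tibble(t = (seq_along(x) - 1) * ctrl$h_ctrl,
                 phase = out$phase, envelope = out$envelope, fire = out$fire)
}

# flatten the controller object into the list the C++ core consumes
controller_cfg <- function(ctrl, decim = 1L, ema_alpha = 0) {
  list(notch_b = ctrl$notch_b, notch_a = ctrl$notch_a,
       quad_b = ctrl$quad_b, quad_a = ctrl$quad_a,
       quad_gain = ctrl$quad_gain, quad_shift = ctrl$quad_shift,
       env_decay = ctrl$env_decay,
       env_counter_limit = ctrl$env_counter_limit,
       smooth_len = ctrl$smooth_len,
       smooth_advance = ctrl$smooth_advance,
       target_deg = ctrl$target_deg, hysteresis_deg = ctrl$hysteresis_deg,
       rearm_deg = ctrl$rearm_deg,
       decim = as.integer(decim), ema_alpha = ema_alpha)
}

#' Offline reference phase of a narrow-band component
#'
#' Computes the instantaneous phase of `x` in a band centred on `f0` via the
#' analytic signal (FFT construction), in the sine convention used by the
#' online estimator: 0 deg at the rising zero-cross, 90 deg at the up-peak.
#' This is the acausal reference against which the streaming estimator is
#' validated.
#'
#' @param x Numeric signal or data frame with columns `t` and `x`.
#' @param rate Sampling rate (Hz).
#' @param band Length-2 passband (Hz); default the slow-oscillation band.
#' @return Numeric vector of phases in degrees `[0, 360)`.
#' @export
offline_phase <- function(x, rate, band = c(0.5, 1.25)) {
  if (is.data.frame(x)) x <- x$x
  xf <- zero_phase_bandpass(x, band, rate)
  an <- analytic_signal(xf)
  (Arg(an) * 180 / pi + 90) %% 360
}

# analytic signal via the frequency-domain construction
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Circular mean of angles in degrees
#'
#' @param deg Angles in degrees.
#' @return Circular mean in degrees `[0, 360)`.
#' @export
circular_mean <- function(deg) {
  (Arg(mean(exp(1i * deg * pi / 180))) * 180 / pi) %% 360
}

#' Signed circular distance between angles, degrees in `(-180, 180]`
#' @param a,b Angles in degrees.
#' @return Signed difference `a - b` wrapped to `(-180, 180]`.
#' @export
circular_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}
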