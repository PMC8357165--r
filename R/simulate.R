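#' Simulate the corticothalamic neural field
#'
#' Integrates the four-population field equations on the periodic sheet with
#' explicit Euler stepping, corticothalamic conduction delays of `t0/2`
#' implemented as ring buffers, per-node Gaussian input noise and, optionally,
#' spatially localised stimulation. The run is preceded by a stimulation-free
#' burn-in (default 6 s) started from the requested initial state; the main
#' run's EEG-like output `x(t)` is the spatial average of the excitatory
#' field, stored at `grid$store_rate` and mean-subtracted.
#'
#' Open-loop stimulation (periodic or Poisson onsets) is active only inside
#' `[stim_margin, duration - stim_margin]`; the same margin is applied to
#' closed-loop triggering. With identical `seed`, all protocols consume a
#' bit-identical noise stream, so a SHAM run is an exact noise-paired
#' baseline for any stimulated run.
#'
#' @param params An [nft_params()].
#' @param grid An [grid_spec()].
#' @param protocol A [stim_protocol()].
#' @param duration Main-run length (s).
#' @param seed Integer seed; drives the noise stream and any Poisson onsets.
#' @param init `"zero"` (all states zero, the standard start) or `"steady"`
#'   (start at the deterministic fixed point).
#' @param burn_in Burn-in length (s) preceding the main run.
#' @param stim_margin Stimulation-free head and tail of the main run (s).
#' @param ctrl_decim Closed-loop controller tick in integration steps
#'   (default 1: the controller runs at the integration rate; set
#'   `round(1/(dt*store_rate))` for stored-rate operation).
#' @param store_fields Keep the full excitatory field at the store rate
#'   (memory heavy; short runs only).
#' @param store_ctrl_trace Keep the closed-loop phase/envelope trace at the
#'   store rate.
#' @return An object of class `nft_sim` with elements `trace` (tibble `t`,
#'   `x`), `stim_onsets` (s), `seed`, `params`, `grid`, `protocol`,
#'   `duration`, `x_mean` (the subtracted temporal mean, s^-1) and
#'   optionally `fields` / `ctrl_trace`.
#' @examples
#' \donttest{
#' sim <- simulate_nft(nft_params(), grid_spec(), stim_protocol("sham"),
#'                     duration = 30, seed = 1)
#' head(sim$trace)
#' }
#' @export
simulate_nft <- function(params, grid, protocol = stim_protocol("sham"),
                         duration, seed = 1, init = c("zero", "steady"),
                         burn_in = 6, stim_margin = 5, ctrl_decim = 1L,
                         store_fields = FALSE, store_ctrl_trace = FALSE) {
  validate_nft_params(params)
  stopifnot(inherits(grid, "nft_grid"), inherits(protocol, "stim_protocol"),
            duration > 0)
  init <- match.arg(init)
  dt <- grid$dt
  n_nodes <- grid$nx * grid$ny

  par_cpp <- list(alpha = params$alpha, beta = params$beta, t0 = params$t0,
                  r_e = params$r_e, gamma_e = params$gamma_e,
                  Q_max = params$Q_max, theta = params$theta,
                  sigma_rho = params$sigma_rho,
                  nu = unname(params$nu[nu_names] * 1e-3),
                  phi_n0 = params$phi_n0, noise_sd = params$noise_sd)

  init_state <- list()
  if (init == "steady") {
    ss <- solve_steady_state(params)
    init_state <- list(V_e0 = ss$V_e0, V_r0 = ss$V_r0, V_s0 = ss$V_s0,
                       phi_e0 = ss$phi_e0, phi_s0 = ss$phi_s0)
  }

  window <- c(stim_margin, duration - stim_margin)
  if (window[2] < window[1]) window <- c(0, 0)

  onsets <- numeric(0)
  dog <- numeric(n_nodes)
  pulse <- numeric(0)
  if (protocol$mode != "sham") {
    pulse <- pulse_waveform(protocol$pulse, dt)
    dog <- dog_kernel(grid, protocol$dog_center, protocol$dog_sigma_e,
                      protocol$dog_sigma_i)
    if (protocol$mode == "periodic") {
      onsets <- generate_onsets("periodic", window, rate = protocol$rate)
    } else if (protocol$mode == "poisson") {
      onsets <- generate_onsets("poisson", window, lambda = protocol$lambda,
                                min_sep = protocol$pulse$duration, seed = seed)
    }
  }
  onset_steps <- as.integer(round(onsets / dt))

  closed_loop <- protocol$mode == "closed_loop"
  ctrl_cfg <- NULL
  if (closed_loop) {
    ctrl <- design_controller(f0 = protocol$f0, h_ctrl = dt * ctrl_decim,
                              target_phase = protocol$target_phase,
                              hysteresis = protocol$hysteresis)
    ctrl_cfg <- controller_cfg(ctrl, decim = ctrl_decim,
                               ema_alpha = dt * ctrl_decim / 10)
  }

  res <- nft_simulate_cpp(par_cpp, unclass(grid), duration, as.integer(seed),
                          dog, pulse, onset_steps, closed_loop, ctrl_cfg,
                          init_state, burn_in, store_fields,
                          as.integer(round(window[1] / dt)),
                          as.integer(round(window[2] / dt)),
                          store_ctrl_trace)

  x_raw <- res$x_raw
  x_mean <- mean(x_raw)
  n <- length(x_raw)
  trace <- tibble::tibble(t = (seq_len(n) - 1) / grid$store_rate,
                          x = x_raw - x_mean)
  stim_onsets <- if (closed_loop) res$cl_onset_steps * dt else onsets

  out <- structure(list(
    trace = trace, stim_onsets = stim_onsets, seed = as.integer(seed),
    params = params, grid = grid, protocol = protocol, duration = duration,
    x_mean = x_mean), class = "nft_sim")
  if (store_fields) out$fields <- res$phi_e_fields
  if (store_ctrl_trace && !is.null(res$ctrl_trace)) {
    ct <- res$ctrl_trace
    out$ctrl_trace <- tibble::tibble(
      t = (seq_along(ct$phase) - 1) / grid$store_rate,
      phase = ct$phase, envelope = ct$envelope, fire = ct$fire == 1)
  }
  out
}

#' @export
print.nft_sim <- function(x, ...) {
  cat(sprintf("<nft_sim> %s run, %g s at %d Hz (seed %d)\n",
              toupper(x$protocol$mode), x$duration, x$grid$store_rate, x$seed))
  cat(sprintf("  %d stored samples, sd(x) = %.4g s^-1, %d stimulus onsets\n",
              nrow(x$trace), stats::sd(x$trace$x), length(x$stim_onsets)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.nft_sim <- function(x, ...) x$trace

#' @export
glance.nft_sim <- function(x, ...) {
  tibble::tibble(mode = x$protocol$mode, duration = x$duration,
                 store_rate = x$grid$store_rate, n = nrow(x$trace),
                 sd_x = stats::sd(x$trace$x), mean_level = x$x_mean,
                 n_onsets = length(x$stim_onsets), seed = x$seed)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.nft_sim <- function(object, window = NULL, ...) {
  tr <- object$trace
  if (!is.null(window)) tr <- dplyr::filter(tr, .data$t >= window[1],
                                            .data$t <= window[2])
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$t, y = .data$x)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = expression(x(t) ~ (s^-1)),
                  title = sprintf("%s simulation", toupper(object$protocol$mode)))
  ons <- object$stim_onsets
  if (!is.null(window) && length(ons))
    ons <- ons[ons >= window[1] & ons <= window[2]]
  if (length(ons))
    p <- p + ggplot2::geom_vline(xintercept = ons, colour = "orange",
                                 alpha = 0.5, linewidth = 0.2)
  p
}
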