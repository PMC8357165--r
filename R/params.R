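#' Model parameters for the corticothalamic neural field
#'
#' Builds the parameter set of the four-population neural-field model
#' (cortical excitatory `e`, cortical inhibitory `i`, thalamic reticular `r`,
#' thalamic relay `s`). The defaults are the slow-wave-sleep operating point
#' that exhibits both slow oscillations and sleep spindles, an intermediate
#' state at two thirds of the way along the N2-to-N3 connection-strength
#' trajectory with steady input drive 1 s^-1.
#'
#' The reduced-parameter convention is used throughout: the inhibitory
#' cortical population receives the same connection strengths as the
#' excitatory one (`nu_ie = nu_ee`, `nu_ii = nu_ei`, `nu_is = nu_es`), so only
#' one cortical input set is stored.
#'
#' @param alpha Inverse decay time of the synapto-dendritic response (s^-1).
#' @param beta Inverse rise time of the synapto-dendritic response (s^-1).
#' @param t0 Corticothalamic round-trip conduction delay (s); each one-way
#'   delay (`es`, `se`, `re`) is `t0/2`.
#' @param r_e Characteristic axonal range of the excitatory population (m).
#' @param gamma_e Temporal damping rate of cortical pulse propagation (s^-1).
#' @param Q_max Maximum population firing rate (s^-1).
#' @param theta Mean firing threshold voltage (V).
#' @param sigma_rho Sigmoid slope scale (V); relates to the threshold spread
#'   `sigma` by `sigma_rho = sigma * sqrt(3) / pi`.
#' @param nu Named numeric vector of connection strengths in mV s for
#'   `ee, ei, es, re, rs, se, sr, sn`. Signs encode excitation (positive)
#'   and inhibition (negative).
#' @param phi_n0 Mean of the input drive field (s^-1).
#' @param noise_sd Standard deviation of the Gaussian input noise, per node
#'   and per integration sample (s^-1).
#'
#' @return An object of class `nft_params` (a validated list).
#' @examples
#' p <- nft_params()
#' p$nu[["ee"]]
#' @export
nft_params <- function(alpha = 45, beta = 186, t0 = 0.085, r_e = 0.086,
                       gamma_e = 116, Q_max = 340, theta = 0.01292,
                       sigma_rho = 0.0038,
                       nu = c(ee = 5.54, ei = -5.65, es = 1.53, re = 0.286,
                              rs = 1.12, se = 2.69, sr = -1.73, sn = 9.22),
                       phi_n0 = 1, noise_sd = 3.11) {
  p <- structure(
    list(alpha = alpha, beta = beta, t0 = t0, r_e = r_e, gamma_e = gamma_e,
         Q_max = Q_max, theta = theta, sigma_rho = sigma_rho,
         nu = nu, phi_n0 = phi_n0, noise_sd = noise_sd),
    class = "nft_params")
  validate_nft_params(p)
  p
}

nu_names <- c("ee", "ei", "es", "re", "rs", "se", "sr", "sn")

validate_nft_params <- function(p) {
  stopifnot(inherits(p, "nft_params"))
  for (f in c("alpha", "beta", "gamma_e", "Q_max", "sigma_rho")) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || p[[f]] <= 0)
      stop(sprintf("`%s` must be a positive scalar", f), call. = FALSE)
  }
  if (!is.numeric(p$t0) || p$t0 < 0) stop("`t0` must be >= 0", call. = FALSE)
  if (!all(nu_names %in% names(p$nu)))
    stop("`nu` must contain strengths for: ", paste(nu_names, collapse = ", "),
         call. = FALSE)
  if (p$nu[["ei"]] > 0 || p$nu[["sr"]] > 0)
    stop("`nu_ei` and `nu_sr` are inhibitory and must not be positive",
         call. = FALSE)
  for (f in c("ee", "es", "re", "rs", "se", "sn")) {
    if (p$nu[[f]] < 0)
      stop(sprintf("`nu_%s` must be non-negative (excitatory)", f),
           call. = FALSE)
  }
  if (!is.numeric(p$noise_sd) || p$noise_sd < 0)
    stop("`noise_sd` must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.nft_params <- function(x, ...) {
  cat("<nft_params> corticothalamic neural-field parameters\n")
  cat(sprintf("  alpha %g, beta %g s^-1; t0 %g s; r_e %g m; gamma_e %g s^-1\n",
              x$alpha, x$beta, x$t0, x$r_e, x$gamma_e))
  cat(sprintf("  sigmoid: Q_max %g s^-1, theta %g V, sigma_rho %g V\n",
              x$Q_max, x$theta, x$sigma_rho))
  cat("  nu (mV s): ",
      paste(sprintf("%s=%g", names(x$nu), x$nu), collapse = ", "), "\n")
  cat(sprintf("  input: phi_n0 %g s^-1, noise_sd %g s^-1\n",
              x$phi_n0, x$noise_sd))
  invisible(x)
}

#' Spatial grid and integration settings
#'
#' The cortical sheet is a square of `nx` by `ny` nodes with toroidal
#' (periodic) boundaries. Defaults reproduce the reference setup: 256 nodes
#' on a 0.5 m sheet integrated with an explicit Euler step of 1e-4 s and
#' stored at 100 samples per second.
#'
#' @param nx,ny Node counts per side.
#' @param side_length Physical side length of the sheet (m).
#' @param dt Integration time step (s).
#' @param store_rate Output sampling rate (samples per second); `1/dt` must be
#'   an integer multiple of `store_rate`.
#' @return An object of class `nft_grid`.
#' @export
grid_spec <- function(nx = 16, ny = 16, side_length = 0.5, dt = 1e-4,
                      store_rate = 100) {
  stopifnot(nx >= 2, ny >= 2, side_length > 0, dt > 0, store_rate > 0)
  decim <- 1 / (dt * store_rate)
  if (abs(decim - round(decim)) > 1e-8)
    stop("`store_rate` must divide 1/dt evenly", call. = FALSE)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 side_length = side_length, dt = dt,
                 store_rate = as.integer(store_rate)),
            class = "nft_grid")
}

#' @export
print.nft_grid <- function(x, ...) {
  cat(sprintf("<nft_grid> %d x %d nodes, %.3g m side, dt %g s, stored at %d Hz\n",
              x$nx, x$ny, x$side_length, x$dt, x$store_rate))
  invisible(x)
}

#' Interpolate connection strengths between two sleep-stage parameter sets
#'
#' Produces the parameter set at a given fraction along the straight-line
#' trajectory in connection-strength space between two operating points
#' (for instance the published spindle-dominated N2 and slow-wave N3 sets).
#' Only the connection strengths `nu` are interpolated; all remaining
#' constants must agree between the endpoints and are carried over unchanged.
#'
#' @param params_a,params_b Endpoint [nft_params()] objects.
#' @param fraction Position along the trajectory in `[0, 1]`; 0 returns
#'   `params_a`, 1 returns `params_b`.
#' @return An [nft_params()] object.
#' @export
interpolate_stage <- function(params_a, params_b, fraction) {
  validate_nft_params(params_a); validate_nft_params(params_b)
  stopifnot(is.numeric(fraction), length(fraction) == 1,
            fraction >= 0, fraction <= 1)
  fixed <- setdiff(names(unclass(params_a)), "nu")
  for (f in fixed) {
    if (!isTRUE(all.equal(params_a[[f]], params_b[[f]])))
      stop(sprintf("non-interpolated constant `%s` differs between endpoints", f),
           call. = FALSE)
  }
  out <- params_a
  out$nu <- (1 - fraction) * params_a$nu[nu_names] +
    fraction * params_b$nu[nu_names]
  validate_nft_params(out)
  out
}
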