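# Steady-state, loop-gain and linear transfer-function analysis.
#
# With all temporal and spatial derivatives set to zero the model collapses
# to one scalar fixed-point equation in the steady cortical firing rate
# phi_e0; every other population's steady value follows by back-substitution
# through the cortical balance V_e0 = (nu_ee + nu_ei) phi_e0 + nu_es phi_s0.

sigmoid_q <- function(V, params) {
  params$Q_max / (1 + exp(-(V - params$theta) / params$sigma_rho))
}

sigmoid_inv <- function(phi, params) {
  params$theta - params$sigma_rho * log(params$Q_max / phi - 1)
}

sigmoid_slope <- function(V, params) {
  q <- sigmoid_q(V, params)
  q * (1 - q / params$Q_max) / params$sigma_rho
}

#' Population firing rate from soma voltage
#'
#' The sigmoidal activation `Q(V) = Q_max / (1 + exp(-(V - theta)/sigma_rho))`,
#' a logistic approximation to the cumulative normal distribution of firing
#' thresholds across the population.
#'
#' @param V Soma voltage (V); may be a vector.
#' @param params An [nft_params()].
#' @return Firing rate(s) in s^-1, strictly inside `(0, Q_max)` for finite `V`.
#' @export
sigmoid_firing <- function(V, params) {
  validate_nft_params(params)
  if (any(!is.finite(V))) stop("`V` must be finite", call. = FALSE)
  sigmoid_q(V, params)
}

# residual (in V) of the steady-state equation as a function of phi_e0,
# with the drive phi_n0 held fixed
steady_residual <- function(phi_e0, params, phi_n0) {
  nu <- params$nu[nu_names] * 1e-3  # mV s -> V s
  Ve <- sigmoid_inv(phi_e0, params)
  lhs <- Ve - (nu[["ee"]] + nu[["ei"]]) * phi_e0   # = nu_es * phi_s0
  Vr <- nu[["re"]] * phi_e0 + (nu[["rs"]] / nu[["es"]]) * lhs
  Vs <- nu[["se"]] * phi_e0 + nu[["sr"]] * sigmoid_q(Vr, params) +
    nu[["sn"]] * phi_n0
  lhs - nu[["es"]] * sigmoid_q(Vs, params)
}

#' Steady state of the corticothalamic model
#'
#' Solves the scalar fixed-point equation for the steady cortical firing
#' rate by damped Newton iteration from the conventional initial guess of
#' 10 s^-1, then back-substitutes the remaining populations' steady
#' voltages, rates and sigmoid slopes.
#'
#' @param params An [nft_params()].
#' @param phi_n0 Steady input drive (s^-1); defaults to the value stored in
#'   `params`.
#' @param guess Initial guess for `phi_e0` (s^-1).
#' @return An object of class `nft_steady`: a list with per-population steady
#'   rates `phi_a0`, voltages `V_a0` and slopes `rho_a`, the drive `phi_n0`,
#'   and the residual at the solution.
#' @seealso [steady_state_roots()] for all roots by exhaustive bracketing.
#' @export
solve_steady_state <- function(params, phi_n0 = params$phi_n0, guess = 10) {
  validate_nft_params(params)
  stopifnot(phi_n0 >= 0)
  f <- function(x) steady_residual(x, params, phi_n0)
  x <- guess
  lo <- 1e-9
  hi <- params$Q_max - 1e-9
  converged <- FALSE
  for (it in 1:200) {
    fx <- f(x)
    if (abs(fx) < 1e-12) { converged <- TRUE; break }
    h <- max(1e-7, 1e-7 * abs(x))
    dfx <- (f(x + h) - f(x - h)) / (2 * h)
    step <- fx / dfx
    xn <- x - step
    # dampen into the admissible open interval (0, Q_max)
    while (xn <= lo || xn >= hi) { step <- step / 2; xn <- x - step }
    if (abs(xn - x) < 1e-13 * max(1, abs(x))) { x <- xn; converged <- TRUE; break }
    x <- xn
  }
  if (!converged && abs(f(x)) > 1e-9)
    stop(sprintf("steady-state solver did not converge (last residual %.3g V)",
                 f(x)), call. = FALSE)
  phi_e0 <- x
  nu <- params$nu[nu_names] * 1e-3
  V_e0 <- sigmoid_inv(phi_e0, params)
  phi_s0 <- (V_e0 - (nu[["ee"]] + nu[["ei"]]) * phi_e0) / nu[["es"]]
  V_r0 <- nu[["re"]] * phi_e0 + nu[["rs"]] * phi_s0
  phi_r0 <- sigmoid_q(V_r0, params)
  V_s0 <- nu[["se"]] * phi_e0 + nu[["sr"]] * phi_r0 + nu[["sn"]] * phi_n0
  structure(list(
    phi_e0 = phi_e0, phi_i0 = phi_e0, phi_r0 = phi_r0, phi_s0 = phi_s0,
    V_e0 = V_e0, V_i0 = V_e0, V_r0 = V_r0, V_s0 = V_s0,
    rho_e = sigmoid_slope(V_e0, params),
    rho_i = sigmoid_slope(V_e0, params),
    rho_r = sigmoid_slope(V_r0, params),
    rho_s = sigmoid_slope(V_s0, params),
    phi_n0 = phi_n0,
    residual = f(phi_e0)),
    class = "nft_steady")
}

#' @export
print.nft_steady <- function(x, ...) {
  cat("<nft_steady> steady state at phi_n0 =", x$phi_n0, "s^-1\n")
  cat(sprintf("  phi_e0 %.4f, phi_r0 %.4f, phi_s0 %.4f s^-1 (residual %.2g V)\n",
              x$phi_e0, x$phi_r0, x$phi_s0, x$residual))
  invisible(x)
}

#' All steady-state roots by exhaustive bracketing
#'
#' Scans the admissible range `(0, Q_max)` of the steady cortical rate on a
#' fine grid, brackets every sign change of the fixed-point residual and
#' polishes each bracket with [stats::uniroot()]. Diagnostic companion to
#' [solve_steady_state()], which returns the single root reached from the
#' conventional initial guess.
#'
#' @inheritParams solve_steady_state
#' @param n_grid Number of scan points.
#' @return Numeric vector of roots `phi_e0` (s^-1), increasing.
#' @export
steady_state_roots <- function(params, phi_n0 = params$phi_n0, n_grid = 2000) {
  validate_nft_params(params)
  g <- seq(1e-3, params$Q_max - 1e-3, length.out = n_grid)
  r <- vapply(g, steady_residual, numeric(1), params = params, phi_n0 = phi_n0)
  idx <- which(diff(sign(r)) != 0)
  vapply(idx, function(i) {
    stats::uniroot(steady_residual, c(g[i], g[i + 1]), params = params,
                   phi_n0 = phi_n0, tol = 1e-12)$root
  }, numeric(1))
}

#' Loop gains and the XYZ sleep-stage coordinates
#'
#' The linearised gain of connection `ab` is `G_ab = rho_a * nu_ab` with
#' `nu` in V s. The three-coordinate summary locates a brain state by its
#' intracortical (`X`), corticothalamic (`Y`) and intrathalamic (`Z`) loop
#' strengths:
#' `X = G_ee / (1 - G_ei)`,
#' `Y = (G_es G_se + G_es G_re G_sr) / ((1 - G_sr G_rs)(1 - G_ei))`,
#' `Z = -G_sr G_rs alpha beta / (alpha + beta)^2`.
#'
#' @param params An [nft_params()].
#' @param steady An `nft_steady` from [solve_steady_state()] for the same
#'   parameters; solved at `params$phi_n0` when omitted.
#' @return A one-row tibble with columns `G_ee` ... `G_sn`, `X`, `Y`, `Z`.
#' @export
gains_and_xyz <- function(params, steady = solve_steady_state(params)) {
  validate_nft_params(params)
  stopifnot(inherits(steady, "nft_steady"))
  nu <- params$nu[nu_names] * 1e-3
  rho <- c(ee = steady$rho_e, ei = steady$rho_e, es = steady$rho_e,
           re = steady$rho_r, rs = steady$rho_r,
           se = steady$rho_s, sr = steady$rho_s, sn = steady$rho_s)
  G <- rho[nu_names] * nu
  names(G) <- nu_names
  if (abs(1 - G[["ei"]]) < 1e-12 || abs(1 - G[["sr"]] * G[["rs"]]) < 1e-12)
    stop("vanishing loop denominator: |1 - G_ei| or |1 - G_sr G_rs| ~ 0",
         call. = FALSE)
  X <- G[["ee"]] / (1 - G[["ei"]])
  Y <- (G[["es"]] * G[["se"]] + G[["es"]] * G[["re"]] * G[["sr"]]) /
    ((1 - G[["sr"]] * G[["rs"]]) * (1 - G[["ei"]]))
  Z <- -G[["sr"]] * G[["rs"]] * params$alpha * params$beta /
    (params$alpha + params$beta)^2
  out <- tibble::as_tibble(as.list(stats::setNames(G, paste0("G_", nu_names))))
  out$X <- X; out$Y <- Y; out$Z <- Z
  out
}

#' Linear transfer function and model spectrum
#'
#' Evaluates the closed-form linearised transfer function from the input
#' drive to the cortical field at spatial mode `k` (default `k = 0`, the
#' uniform mode that survives spatial averaging of the output), with
#' `L(omega) = 1 / ((1 - i omega/alpha)(1 - i omega/beta))` the dendritic
#' low-pass response and the one-way corticothalamic delay `t0/2` entering
#' as explicit phase factors. The returned power column is the one-sided
#' output power spectral density `|T|^2 * 2 * noise_sd^2 * dt / n_nodes`:
#' per-node noise of variance `noise_sd^2` drawn once per integration step
#' `dt` has one-sided density `2 noise_sd^2 dt`, and spatial averaging over
#' `n_nodes` independent nodes divides the uniform-mode drive variance by
#' `n_nodes`. This matches a Welch estimate of the simulated output
#' directly, with no free scale.
#'
#' @param params An [nft_params()].
#' @param freqs Frequencies (Hz) at which to evaluate; positive (negative
#'   frequencies follow by conjugate symmetry).
#' @param steady Steady state (defaults to solving at `params$phi_n0`).
#' @param k Spatial wavenumber (rad/m).
#' @param n_nodes Number of nodes over which the output is averaged (scales
#'   the noise floor of the uniform mode); default 256.
#' @param dt Integration step (s) of the simulation being matched.
#' @return A tibble with columns `freq` (Hz), `transfer` (complex) and
#'   `power` (arbitrary units, (s^-1)^2/Hz scale).
#' @export
transfer_spectrum <- function(params, freqs,
                              steady = solve_steady_state(params), k = 0,
                              n_nodes = 256, dt = 1e-4) {
  validate_nft_params(params)
  g <- gains_and_xyz(params, steady)
  w <- 2 * pi * freqs
  L <- 1 / ((1 - 1i * w / params$alpha) * (1 - 1i * w / params$beta))
  den_ei <- 1 - L * g$G_ei
  den_sr <- 1 - L^2 * g$G_sr * g$G_rs
  delta <- (1 - 1i * w / params$gamma_e)^2 -
    (1 / den_ei) * (g$G_ee * L +
      (g$G_es * g$G_se * L^2 + g$G_es * g$G_re * g$G_sr * L^3) *
        exp(1i * w * params$t0) / den_sr)
  tr <- L^2 * g$G_es * g$G_sn * exp(1i * w * params$t0 / 2) /
    (den_ei * den_sr * (delta + k^2 * params$r_e^2))
  if (any(!is.finite(tr)))
    stop("transfer function evaluated at a pole", call. = FALSE)
  tibble::tibble(freq = freqs, transfer = tr,
                 power = Mod(tr)^2 * 2 * params$noise_sd^2 * dt / n_nodes)
}
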