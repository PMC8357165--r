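# Additional broom-style and plotting methods.

#' @export
tidy.nft_steady <- function(x, ...) {
  tibble::tibble(
    population = c("e", "i", "r", "s"),
    phi_0 = c(x$phi_e0, x$phi_i0, x$phi_r0, x$phi_s0),
    V_0 = c(x$V_e0, x$V_i0, x$V_r0, x$V_s0),
    rho = c(x$rho_e, x$rho_i, x$rho_r, x$rho_s))
}

#' @export
glance.nft_steady <- function(x, ...) {
  tibble::tibble(phi_e0 = x$phi_e0, phi_n0 = x$phi_n0,
                 residual = x$residual)
}

#' @export
autoplot.nft_summary <- function(object, band = c("SO", "SP"), ...) {
  band <- match.arg(band)
  df <- object$per_seed
  if (band == "SO") {
    df <- dplyr::transmute(df, seed = .data$seed, index = .data$i_so,
                           rate = .data$n_so_per_min)
    labs <- c("power difference index I(SO)", "slow oscillations / min")
  } else {
    df <- dplyr::transmute(df, seed = .data$seed, index = .data$i_sp,
                           rate = .data$n_sp_per_min)
    labs <- c("power difference index I(SP)", "spindles / min")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$rate)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = labs[1], y = labs[2],
                  title = sprintf("%s condition, per seed", toupper(object$mode)))
}

#' Spectrum comparison plot: simulated Welch estimate vs linear prediction
#'
#' @param sim An `nft_sim` (a SHAM run).
#' @param params The [nft_params()] used for the run.
#' @param segment_length Welch segment length (samples).
#' @return A ggplot object on log-log axes.
#' @export
plot_spectrum_check <- function(sim, params = sim$params,
                                segment_length = 1024) {
  ps <- welch_psd(sim$trace, sim$grid$store_rate, segment_length)
  sel <- ps$freq >= 0.1 & ps$freq <= 30
  tf <- transfer_spectrum(params, ps$freq[sel],
                          n_nodes = sim$grid$nx * sim$grid$ny,
                          dt = sim$grid$dt)
  df <- dplyr::bind_rows(
    tibble::tibble(freq = ps$freq[sel], power = ps$power[sel],
                   source = "simulated (Welch)"),
    tibble::tibble(freq = tf$freq, power = tf$power,
                   source = "linearised model"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$power,
                                   colour = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "power spectral density",
                  colour = NULL)
}
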