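# Morlet scalograms and the band power-difference index.

#' Morlet continuous wavelet scalogram
#'
#' Continuous wavelet transform with the complex Morlet mother wavelet
#' `Psi(t) = exp(-t^2 / 2) exp(i omega0 t)` (unit width, central frequency
#' `omega0 = 15` by default), evaluated by frequency-domain convolution on
#' 300 logarithmically spaced scales whose pseudo-frequencies
#' `f = omega0 / (2 pi s)` span 0.1-30 Hz endpoint to endpoint. The L2
#' normalisation `s^(-1/2) Psi(t/s)` is used; the band power-difference
#' index is invariant to this choice.
#'
#' @param x Numeric trace, data frame with column `x`, or `nft_sim` object.
#' @param rate Sampling rate (Hz); taken from the object when available.
#' @param n_scales Number of scales.
#' @param f_range Length-2 pseudo-frequency range (Hz).
#' @param omega0 Morlet central frequency (rad, mother-wavelet time).
#' @return An object of class `nft_scalogram`: list with `magnitude`
#'   (`n_scales` x `n_time` matrix `|S|`), `freqs` (pseudo-frequency per
#'   scale, Hz, decreasing with scale), `scales` (s), `t` (s) and `rate`.
#' @export
morlet_scalogram <- function(x, rate = NULL, n_scales = 300,
                             f_range = c(0.1, 30), omega0 = 15) {
  if (inherits(x, "nft_sim")) { rate <- x$grid$store_rate; x <- x$trace$x }
  if (is.data.frame(x)) x <- x$x
  stopifnot(is.numeric(x), is.numeric(rate), length(f_range) == 2)
  if (f_range[2] >= rate / 2)
    stop("top frequency must be below the Nyquist rate", call. = FALSE)
  n <- length(x)
  if (n < 2 * rate / f_range[1])
    stop("trace too short for the lowest requested frequency", call. = FALSE)
  freqs <- exp(seq(log(f_range[2]), log(f_range[1]), length.out = n_scales))
  scales <- omega0 / (2 * pi * freqs)
  X <- stats::fft(x)
  w <- 2 * pi * c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) *
    rate / n
  mag <- matrix(0, n_scales, n)
  for (i in seq_len(n_scales)) {
    s <- scales[i]
    psi_hat <- sqrt(2 * pi * s) * exp(-0.5 * (s * w - omega0)^2)
    mag[i, ] <- Mod(stats::fft(X * psi_hat, inverse = TRUE) / n)
  }
  structure(list(magnitude = mag, freqs = freqs, scales = scales,
                 t = (seq_len(n) - 1) / rate, rate = rate, omega0 = omega0),
            class = "nft_scalogram")
}

#' @export
print.nft_scalogram <- function(x, ...) {
  cat(sprintf("<nft_scalogram> %d scales (%.3g-%.3g Hz) x %d samples at %g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs), ncol(x$magnitude),
              x$rate))
  invisible(x)
}

#' @export
autoplot.nft_scalogram <- function(object, ...) {
  df <- tibble::tibble(
    t = rep(object$t, each = length(object$freqs)),
    freq = rep(object$freqs, times = length(object$t)),
    mag = as.vector(object$magnitude))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$freq,
                                   fill = .data$mag)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = "|S|") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)")
}

band_scale_idx <- function(scal, band) {
  which(scal$freqs >= band[1] & scal$freqs <= band[2])
}

#' Scalogram band power-difference index
#'
#' Normalised difference of band-summed scalogram magnitude between a
#' stimulated run and its noise-paired SHAM baseline:
#' `I = (sum|S_x| - sum|S_b|) / (sum|S_x| + sum|S_b|)`, the sums running
#' over the scales whose pseudo-frequencies fall in the band (slow
#' oscillations 0.5-1.25 Hz, spindles 9-16 Hz) and over all times. Bounded
#' in `[-1, 1]`, antisymmetric under swapping the inputs, and invariant to
#' a common positive rescaling.
#'
#' @param s_x Scalogram of the stimulated trace ([morlet_scalogram()]).
#' @param s_b Scalogram of the paired SHAM trace, on identical scales and
#'   time grid.
#' @param band `"SO"`, `"SP"`, or a numeric length-2 band (Hz).
#' @return The index, a single number in `[-1, 1]`.
#' @export
power_difference_index <- function(s_x, s_b, band = c("SO", "SP")) {
  stopifnot(inherits(s_x, "nft_scalogram"), inherits(s_b, "nft_scalogram"))
  if (!isTRUE(all.equal(s_x$freqs, s_b$freqs)) ||
      ncol(s_x$magnitude) != ncol(s_b$magnitude))
    stop("scalograms must share scales and length", call. = FALSE)
  if (is.character(band)) {
    band <- match.arg(band)
    band <- if (band == "SO") so_band else sp_band
  }
  idx <- band_scale_idx(s_x, band)
  a <- sum(s_x$magnitude[idx, ])
  b <- sum(s_b$magnitude[idx, ])
  if (a + b == 0)
    stop("zero band power in both scalograms: index undefined", call. = FALSE)
  (a - b) / (a + b)
}

#' Time-averaged wavelet spectrum
#'
#' @param scal An [morlet_scalogram()].
#' @return A tibble with `freq` (Hz) and `power` (time-mean of `|S|`).
#' @export
wavelet_spectrum <- function(scal) {
  stopifnot(inherits(scal, "nft_scalogram"))
  tibble::tibble(freq = scal$freqs, power = rowMeans(scal$magnitude))
}
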