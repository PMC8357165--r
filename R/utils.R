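# Spectral estimation helpers.

#' Welch power spectral density
#'
#' Averaged modified periodogram with a Hann window and 50 percent overlap.
#' Used to compare simulated output spectra against the linearised transfer
#' function.
#'
#' @param x Numeric signal or data frame with column `x`.
#' @param rate Sampling rate (Hz).
#' @param segment_length Samples per segment (power of two recommended).
#' @param demean Subtract the mean of each segment before windowing.
#' @return A tibble with `freq` (Hz, positive frequencies) and `power`
#'   (one-sided PSD, signal^2 per Hz).
#' @export
welch_psd <- function(x, rate, segment_length = 1024, demean = TRUE) {
  if (is.data.frame(x)) x <- x$x
  stopifnot(is.numeric(x), segment_length > 8,
            length(x) >= segment_length)
  n <- segment_length
  step <- n %/% 2
  starts <- seq(1, length(x) - n + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  u <- sum(w^2)
  acc <- numeric(n %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + n - 1)]
    if (demean) seg <- seg - mean(seg)
    X <- stats::fft(seg * w)
    p <- Mod(X[1:(n %/% 2 + 1)])^2 / (u * rate)
    p[2:(n %/% 2)] <- 2 * p[2:(n %/% 2)]
    acc <- acc + p
  }
  tibble::tibble(freq = seq(0, n %/% 2) * rate / n,
                 power = acc / length(starts))
}
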