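# Detection of slow oscillations (SO) and sleep spindles (SP) from the
# EEG-like trace, against a noise-paired SHAM baseline.

so_band <- c(0.5, 1.25)
sp_band <- c(9, 16)

#' Zero-phase Chebyshev band-pass filter
#'
#' Order-4 Chebyshev type-I design with 1e-6 dB passband ripple, applied
#' forward and backward so the net phase response is zero (effective order
#' 8 in magnitude).
#'
#' @param x Numeric signal or data frame with column `x`.
#' @param band Length-2 passband (Hz).
#' @param rate Sampling rate (Hz).
#' @return Filtered numeric vector, same length as the input.
#' @export
zero_phase_bandpass <- function(x, band, rate) {
  if (is.data.frame(x)) x <- x$x
  stopifnot(is.numeric(x), length(band) == 2)
  if (band[1] <= 0 || band[2] >= rate / 2 || band[1] >= band[2])
    stop("`band` must lie strictly inside (0, rate/2)", call. = FALSE)
  fl <- signal::cheby1(4, 1e-6, band / (rate / 2), type = "pass")
  as.numeric(signal::filtfilt(fl, x))
}

# moving RMS over a window of `n` samples followed by Hamming smoothing of
# the same length; centred, edges padded by shrinking windows
smoothed_rms <- function(x, n) {
  csum <- cumsum(c(0, x^2))
  half <- floor(n / 2)
  i <- seq_along(x)
  lo <- pmax(i - half, 1)
  hi <- pmin(i - half + n - 1, length(x))
  rms <- sqrt((csum[hi + 1] - csum[lo]) / (hi - lo + 1))
  w <- signal::hamming(n)
  w <- w / sum(w)
  sm <- as.numeric(stats::filter(rms, w, sides = 2, circular = FALSE))
  sm[is.na(sm)] <- rms[is.na(sm)]
  sm
}

#' Baseline statistics from a noise-paired SHAM trace
#'
#' Summarises the SHAM (no stimulation) trace `b(t)` that shares the
#' stimulated run's noise seed: its mean and SD (used to z-score the
#' stimulated trace), the mean candidate slow-oscillation peak-to-peak
#' amplitude of `b` (the SO detection threshold is 1.25 times this), and
#' the mean and SD of the smoothed spindle-band RMS of `b` z-scored by its
#' own statistics (the SP threshold is this mean plus 1.25 of this SD).
#'
#' @param b SHAM trace: numeric vector, data frame with column `x`, or an
#'   `nft_sim` object.
#' @param rate Sampling rate (Hz); taken from the object when available.
#' @param rms_window Spindle RMS window length (s).
#' @return An object of class `nft_baseline`.
#' @export
baseline_stats <- function(b, rate = NULL, rms_window = 0.2) {
  if (inherits(b, "nft_sim")) { rate <- b$grid$store_rate; b <- b$trace$x }
  if (is.data.frame(b)) b <- b$x
  stopifnot(is.numeric(b), is.numeric(rate))
  mu <- mean(b); sdv <- stats::sd(b)
  cand <- so_candidates(zero_phase_bandpass(b, so_band, rate), rate)
  cand <- cand[cand$down_peak_value < -1e-6, , drop = FALSE]
  bz <- (b - mu) / sdv
  bf <- zero_phase_bandpass(bz, sp_band, rate)
  rms <- smoothed_rms(bf, round(rms_window * rate))
  structure(list(mean = mu, sd = sdv,
                 so_p2p_mean = if (nrow(cand)) mean(cand$peak_to_peak) else NA_real_,
                 sp_rms_mean = mean(rms),
                 sp_rms_sd = stats::sd(rms),
                 rate = rate, rms_window = rms_window),
            class = "nft_baseline")
}

#' @export
print.nft_baseline <- function(x, ...) {
  cat(sprintf("<nft_baseline> mean %.4g, sd %.4g; SO p2p mean %.4g; SP rms %.4g +/- %.4g\n",
              x$mean, x$sd, x$so_p2p_mean, x$sp_rms_mean, x$sp_rms_sd))
  invisible(x)
}

# candidate single oscillations: spans between consecutive positive-to-
# negative zero crossings of the z-scored band-filtered signal, each holding
# one down peak; peak-to-peak measured inside the span on the filtered trace
so_candidates <- function(xf, rate) {
  z <- (xf - mean(xf)) / stats::sd(xf)
  if (!is.finite(stats::sd(xf)) || stats::sd(xf) == 0)
    return(tibble::tibble(t_start = numeric(0), t_end = numeric(0),
                          down_peak_time = numeric(0),
                          down_peak_value = numeric(0),
                          peak_to_peak = numeric(0)))
  pn <- which(z[-length(z)] > 0 & z[-1] <= 0)
  if (length(pn) < 2)
    return(tibble::tibble(t_start = numeric(0), t_end = numeric(0),
                          down_peak_time = numeric(0),
                          down_peak_value = numeric(0),
                          peak_to_peak = numeric(0)))
  purrr::map_dfr(seq_len(length(pn) - 1), function(i) {
    a <- pn[i]; b <- pn[i + 1]
    seg <- xf[a:b]
    k <- which.min(seg)
    tibble::tibble(t_start = (a - 1) / rate, t_end = (b - 1) / rate,
                   down_peak_time = (a + k - 2) / rate,
                   down_peak_value = seg[k],
                   peak_to_peak = max(seg) - min(seg))
  })
}

#' Detect slow oscillations
#'
#' Band-passes the trace to 0.5-1.25 Hz, delimits candidate single
#' oscillations between consecutive positive-to-negative zero crossings of
#' the z-scored filtered signal, and keeps candidates whose filtered-signal
#' negative peak falls below -1e-6 s^-1, whose peak-to-peak amplitude
#' exceeds 1.25 times the baseline's mean candidate peak-to-peak, and whose
#' duration lies in the 0.8-2 s slow-oscillation range.
#'
#' @param x Stimulated trace: numeric vector, data frame with column `x`, or
#'   an `nft_sim` object.
#' @param baseline An [baseline_stats()] object from the paired SHAM run.
#' @param rate Sampling rate (Hz); taken from the object when available.
#' @param p2p_factor Peak-to-peak threshold multiplier.
#' @param duration_range Admissible event duration (s).
#' @return A tibble of events: `kind`, `t_start`, `t_end`, `down_peak_time`,
#'   `down_peak_value`, `peak_to_peak`.
#' @export
detect_slow_oscillations <- function(x, baseline, rate = NULL,
                                     p2p_factor = 1.25,
                                     duration_range = c(0.8, 2)) {
  if (inherits(x, "nft_sim")) { rate <- x$grid$store_rate; x <- x$trace$x }
  if (is.data.frame(x)) x <- x$x
  stopifnot(inherits(baseline, "nft_baseline"), is.numeric(rate))
  if (length(x) < 5 * rate)
    stop("trace shorter than 5 s: filter transients dominate", call. = FALSE)
  xf <- zero_phase_bandpass(x, so_band, rate)
  cand <- so_candidates(xf, rate)
  thr <- p2p_factor * baseline$so_p2p_mean
  keep <- cand$down_peak_value < -1e-6 &
    !is.na(thr) & cand$peak_to_peak > thr &
    (cand$t_end - cand$t_start) >= duration_range[1] &
    (cand$t_end - cand$t_start) <= duration_range[2]
  out <- cand[keep, , drop = FALSE]
  dplyr::bind_cols(tibble::tibble(kind = rep("SO", nrow(out))), out)
}

#' Detect sleep spindles
#'
#' Z-scores the trace by the paired baseline's mean and SD, band-passes to
#' 9-16 Hz, computes the moving RMS over a 0.2 s window smoothed with a
#' Hamming window of the same length, and marks an event wherever the
#' smoothed RMS stays above the baseline's smoothed spindle-band RMS mean
#' by more than 1.25 baseline RMS standard deviations for at least
#' `min_duration`.
#'
#' @inheritParams detect_slow_oscillations
#' @param threshold_factor RMS threshold multiplier.
#' @param min_duration Minimum event duration (s).
#' @return A tibble of events: `kind`, `t_start`, `t_end`, `center_time`,
#'   `peak_rms`.
#' @export
detect_spindles <- function(x, baseline, rate = NULL, threshold_factor = 1.25,
                            min_duration = 0.5) {
  if (inherits(x, "nft_sim")) { rate <- x$grid$store_rate; x <- x$trace$x }
  if (is.data.frame(x)) x <- x$x
  stopifnot(inherits(baseline, "nft_baseline"), is.numeric(rate))
  if (length(x) < 5 * rate)
    stop("trace shorter than 5 s: filter transients dominate", call. = FALSE)
  z <- (x - baseline$mean) / baseline$sd
  zf <- zero_phase_bandpass(z, sp_band, rate)
  rms <- smoothed_rms(zf, round(baseline$rms_window * rate))
  thr <- baseline$sp_rms_mean + threshold_factor * baseline$sp_rms_sd
  above <- rms > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= round(min_duration * rate)
  if (!any(keep))
    return(tibble::tibble(kind = character(0), t_start = numeric(0),
                          t_end = numeric(0), center_time = numeric(0),
                          peak_rms = numeric(0)))
  purrr::map_dfr(which(keep), function(i) {
    a <- starts[i]; b <- ends[i]
    tibble::tibble(kind = "SP", t_start = (a - 1) / rate,
                   t_end = (b - 1) / rate,
                   center_time = ((a - 1) + (b - 1)) / (2 * rate),
                   peak_rms = max(rms[a:b]))
  })
}

#' Match co-occurring slow oscillations and spindles
#'
#' Greedy chronological matching: spindles are visited in temporal order
#' and paired with the unmatched slow oscillation that overlaps them the
#' most, provided the overlap is at least `min_overlap`; ties go to the
#' earlier slow oscillation. Every event participates in at most one match,
#' so the number of matches never exceeds the smaller event count.
#'
#' @param so,sp Event tibbles from [detect_slow_oscillations()] and
#'   [detect_spindles()].
#' @param min_overlap Minimum temporal overlap (s).
#' @return A tibble of matches: `so_index`, `sp_index`, `overlap`, `delay`
#'   (spindle centre minus SO down-peak, s).
#' @export
match_cooccurrences <- function(so, sp, min_overlap = 0.25) {
  if (nrow(so) == 0 || nrow(sp) == 0)
    return(tibble::tibble(so_index = integer(0), sp_index = integer(0),
                          overlap = numeric(0), delay = numeric(0)))
  so_used <- rep(FALSE, nrow(so))
  ord <- order(sp$t_start)
  res <- list()
  for (j in ord) {
    ov <- pmin(so$t_end, sp$t_end[j]) - pmax(so$t_start, sp$t_start[j])
    ov[so_used] <- -Inf
    i <- which.max(ov)           # ties resolve to the earlier SO
    if (ov[i] >= min_overlap) {
      so_used[i] <- TRUE
      res[[length(res) + 1]] <- tibble::tibble(
        so_index = i, sp_index = j, overlap = ov[i],
        delay = sp$center_time[j] - so$down_peak_time[i])
    }
  }
  if (!length(res))
    return(tibble::tibble(so_index = integer(0), sp_index = integer(0),
                          overlap = numeric(0), delay = numeric(0)))
  dplyr::arrange(dplyr::bind_rows(res), .data$so_index)
}

#' Spindle-centre timing relative to the slow-oscillation down-peak
#'
#' @param matches Output of [match_cooccurrences()].
#' @param window Symmetric histogram window (s).
#' @param bin_width Histogram bin width (s).
#' @return A list with `delays` (numeric, s) and `histogram` (tibble
#'   `bin_mid`, `count`).
#' @export
spindle_timing <- function(matches, window = 1.5, bin_width = 0.1) {
  delays <- matches$delay
  breaks <- seq(-window, window, by = bin_width)
  d <- delays[delays >= -window & delays <= window]
  h <- if (length(d)) {
    cut_idx <- findInterval(d, breaks, rightmost.closed = TRUE)
    counts <- tabulate(cut_idx, nbins = length(breaks) - 1)
    tibble::tibble(bin_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
                   count = counts)
  } else {
    tibble::tibble(bin_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
                   count = rep(0L, length(breaks) - 1))
  }
  list(delays = delays, histogram = h)
}
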