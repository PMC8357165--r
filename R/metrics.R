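# Per-condition summaries and statistical comparisons between stimulation
# protocols.

#' Summarise a stimulation condition from paired STIM/SHAM runs
#'
#' For each seed-paired run: detects slow oscillations and spindles in the
#' stimulated trace against the paired SHAM baseline, matches
#' co-occurrences, and computes the scalogram power-difference indices.
#' Rates are normalised by the analysed duration, which excludes the
#' stimulation-free head and tail margins. `P_SO` is the fraction of the
#' analysed time covered by slow oscillations and `P_C_given_SP` the
#' probability that a detected spindle co-occurs with a slow oscillation;
#' co-occurrence above chance is exactly `P_C_given_SP > P_SO`.
#'
#' @param stim_runs,sham_runs Lists of `nft_sim` objects, paired by seed
#'   (same order, identical seeds).
#' @param exclude_margin Head/tail margin excluded from rate normalisation
#'   (s); use the protocol's stimulation-free margin.
#' @return An object of class `nft_summary`: a list with `per_seed` (tibble,
#'   one row per seed) and the event/match tables. `tidy()` returns the
#'   per-seed tibble, `glance()` the across-seed means.
#' @export
summarize_condition <- function(stim_runs, sham_runs, exclude_margin = 5) {
  if (inherits(stim_runs, "nft_sim")) stim_runs <- list(stim_runs)
  if (inherits(sham_runs, "nft_sim")) sham_runs <- list(sham_runs)
  stopifnot(length(stim_runs) == length(sham_runs))
  seeds_a <- vapply(stim_runs, function(r) r$seed, integer(1))
  seeds_b <- vapply(sham_runs, function(r) r$seed, integer(1))
  if (!identical(seeds_a, seeds_b))
    stop("STIM and SHAM runs must be paired by seed", call. = FALSE)

  rows <- purrr::map2_dfr(stim_runs, sham_runs, function(stim, sham) {
    rate <- stim$grid$store_rate
    dur <- stim$duration - 2 * exclude_margin
    bl <- baseline_stats(sham)
    so <- detect_slow_oscillations(stim, bl)
    sp <- detect_spindles(stim, bl)
    mt <- match_cooccurrences(so, sp)
    s_x <- morlet_scalogram(stim)
    s_b <- morlet_scalogram(sham)
    tibble::tibble(
      seed = stim$seed,
      n_so = nrow(so), n_sp = nrow(sp), n_c = nrow(mt),
      n_so_per_min = nrow(so) / (dur / 60),
      n_sp_per_min = nrow(sp) / (dur / 60),
      p_so = sum(pmin(so$t_end, stim$duration - exclude_margin) -
                   pmax(so$t_start, exclude_margin)) / dur,
      p_c_given_sp = if (nrow(sp)) nrow(mt) / nrow(sp) else NA_real_,
      i_so = power_difference_index(s_x, s_b, "SO"),
      i_sp = power_difference_index(s_x, s_b, "SP"))
  })
  structure(list(per_seed = rows,
                 mode = stim_runs[[1]]$protocol$mode,
                 exclude_margin = exclude_margin),
            class = "nft_summary")
}

#' @export
print.nft_summary <- function(x, ...) {
  cat("<nft_summary>", toupper(x$mode), "condition,",
      nrow(x$per_seed), "seed(s)\n")
  print(x$per_seed)
  invisible(x)
}

#' @export
tidy.nft_summary <- function(x, ...) x$per_seed

#' @export
glance.nft_summary <- function(x, ...) {
  dplyr::summarise(x$per_seed,
                   n_seeds = dplyr::n(),
                   dplyr::across(c("n_so_per_min", "n_sp_per_min", "p_so",
                                   "p_c_given_sp", "i_so", "i_sp"),
                                 ~ mean(.x, na.rm = TRUE)))
}

#' Compare two stimulation conditions
#'
#' Scalar summaries (indices, rates, probabilities) are compared after
#' Shapiro-Wilk normality screening of both groups: if neither group
#' rejects normality at `alpha`, Welch's unequal-variance t-test is used;
#' otherwise a Wilcoxon test (signed-rank when the groups are paired by
#' seed, rank-sum otherwise). Timing-delay distributions are compared with
#' the two-sample Kolmogorov-Smirnov test.
#'
#' @param a,b Numeric samples (one value per seed for `kind = "scalar"`, the
#'   pooled delay samples for `kind = "distribution"`).
#' @param kind `"scalar"` or `"distribution"`.
#' @param paired Are scalar samples paired by seed?
#' @param alpha Normality screening level.
#' @return A one-row tibble: `test`, `statistic`, `p_value`.
#' @export
compare_conditions <- function(a, b, kind = c("scalar", "distribution"),
                               paired = FALSE, alpha = 0.05) {
  kind <- match.arg(kind)
  a <- as.numeric(a); b <- as.numeric(b)
  if (kind == "distribution") {
    if (length(a) < 1 || length(b) < 1)
      stop("need at least one delay per group", call. = FALSE)
    ks <- suppressWarnings(stats::ks.test(a, b))
    return(tibble::tibble(test = "kolmogorov-smirnov",
                          statistic = unname(ks$statistic),
                          p_value = ks$p.value))
  }
  if (length(a) < 3 || length(b) < 3)
    stop("need at least three values per group for scalar comparison",
         call. = FALSE)
  normal <- function(x) {
    if (stats::sd(x) == 0) return(FALSE)
    stats::shapiro.test(x)$p.value >= alpha
  }
  if (normal(a) && normal(b)) {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    tibble::tibble(test = "welch", statistic = unname(tt$statistic),
                   p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                              exact = FALSE))
    tibble::tibble(test = if (paired) "wilcoxon-signed-rank"
                          else "wilcoxon-rank-sum",
                   statistic = unname(wt$statistic), p_value = wt$p.value)
  }
}

#' Pairwise comparison matrix across conditions
#'
#' @param samples Named list of numeric vectors, one per condition.
#' @param kind Passed to [compare_conditions()].
#' @param paired Passed to [compare_conditions()].
#' @return A tibble with one row per unordered condition pair.
#' @export
compare_all_conditions <- function(samples, kind = "scalar", paired = FALSE) {
  nm <- names(samples)
  stopifnot(!is.null(nm), length(nm) >= 2)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    res <- compare_conditions(samples[[p[1]]], samples[[p[2]]], kind = kind,
                              paired = paired)
    dplyr::bind_cols(tibble::tibble(condition_a = p[1], condition_b = p[2]),
                     res)
  })
}
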