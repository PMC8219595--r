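#' Bin final posterior odds into a calibration curve
#'
#' Builds the observed-versus-nominal posterior-odds diagnostic: the final
#' odds of H0- and H1-generated replicates are histogrammed on the log-odds
#' scale with bins of width `bin_width` (0.1 in natural log by default), and
#' the *observed* posterior odds in a bin is the ratio of the H1 count to the
#' H0 count.  If the reported odds are calibrated, a bin whose *nominal*
#' odds (its geometric centre) are 3.5 should hold about 3.5 times as many
#' H1 replicates as H0 replicates.  Bins in which either histogram holds
#' fewer than `min_count` replicates are masked: a ratio with a very small
#' numerator or denominator is too unstable to read, and conditioning on a
#' nonzero denominator biases sparse-bin ratios downward.
#'
#' @param odds_h0,odds_h1 Final posterior odds of the replicates generated
#'   under H0 and under H1: numeric vectors of odds, vectors of log odds via
#'   `log = TRUE`, or lists of [odds_value] objects.  The two should hold
#'   equally many replicates.
#' @param bin_width Bin width on the natural-log-odds scale.
#' @param min_count Mask bins in which either hypothesis has fewer
#'   replicates than this.
#' @param log Set to `TRUE` if the inputs are already natural-log odds.
#' @return A `calibration_curve`: a data frame with columns `bin_lo`,
#'   `bin_hi` (log-odds edges), `nominal` (odds at the geometric bin centre),
#'   `counts_h0`, `counts_h1`, `observed`, `masked`, with the replicate
#'   counts in attributes `reps_h0`, `reps_h1`.
#' @examples
#' curve <- build_curve(exp(rnorm(500)), exp(rnorm(500, 1)))
#' @export
build_curve <- function(odds_h0, odds_h1, bin_width = 0.1, min_count = 10L,
                        log = FALSE) {
  l0 <- if (log) odds_h0 else log_odds(odds_h0)
  l1 <- if (log) odds_h1 else log_odds(odds_h1)
  if (length(l0) == 0L || length(l1) == 0L)
    stop_invalid("empty odds input")
  if (min_count < 1) stop_invalid("'min_count' must be >= 1")
  if (bin_width <= 0) stop_invalid("'bin_width' must be positive")
  all_l <- c(l0, l1)
  k_lo <- floor(min(all_l) / bin_width)
  k_hi <- floor(max(all_l) / bin_width)
  edges <- (k_lo:(k_hi + 1L)) * bin_width
  c0 <- tabulate(findInterval(l0, edges, rightmost.closed = TRUE),
                 nbins = length(edges) - 1L)
  c1 <- tabulate(findInterval(l1, edges, rightmost.closed = TRUE),
                 nbins = length(edges) - 1L)
  keep <- c0 + c1 > 0L
  lo <- edges[-length(edges)][keep]
  hi <- edges[-1L][keep]
  c0 <- c0[keep]
  c1 <- c1[keep]
  out <- data.frame(bin_lo = lo, bin_hi = hi,
                    nominal = exp((lo + hi) / 2),
                    counts_h0 = c0, counts_h1 = c1,
                    observed = ifelse(c0 > 0L, c1 / c0, NA_real_),
                    masked = pmin(c0, c1) < min_count)
  attr(out, "reps_h0") <- length(l0)
  attr(out, "reps_h1") <- length(l1)
  attr(out, "bin_width") <- bin_width
  class(out) <- c("calibration_curve", "data.frame")
  out
}

#' Summarise a calibration curve by slope and deviation
#'
#' Fits a least-squares line of log observed on log nominal odds over the
#' unmasked bins, weighting each bin by the inverse variance of its log
#' count ratio (`1 / (1/counts_h1 + 1/counts_h0)`), and reports the slope
#' together with the largest absolute log deviation from the identity line.
#' Perfect calibration gives slope 1 and deviation 0; under optional stopping
#' with fixed-parameter alternatives the observed odds fall systematically
#' below the nominal odds and the slope drops below 1.
#'
#' @param curve A `calibration_curve`.
#' @return List with `slope`, `max_abs_log_deviation`, and `n_bins` used.
#' @export
calibration_slope <- function(curve) {
  use <- !curve$masked & curve$counts_h0 > 0L & curve$counts_h1 > 0L
  if (sum(use) < 3L)
    stop_invalid("insufficient data: need at least 3 usable bins")
  lx <- log(curve$nominal[use])
  ly <- log(curve$observed[use])
  w <- 1 / (1 / curve$counts_h1[use] + 1 / curve$counts_h0[use])
  slope <- unname(stats::coef(stats::lm(ly ~ lx, weights = w))[2L])
  list(slope = slope,
       max_abs_log_deviation = max(abs(ly - lx)),
       n_bins = sum(use))
}

#' Per-bin log deviation of observed from nominal odds
#'
#' @param curve A `calibration_curve`.
#' @param nominal_min Restrict to bins with nominal odds at least this value.
#' @param weighted If `TRUE` (default) the mean deviation is weighted by the
#'   total bin count.
#' @return List with `mean_log_deviation`, per-bin `log_deviation`, and the
#'   propagated binomial standard error `se` of each bin's log ratio
#'   (`sqrt(1/counts_h1 + 1/counts_h0)`).
#' @export
curve_log_deviation <- function(curve, nominal_min = 0, weighted = TRUE) {
  use <- !curve$masked & curve$counts_h0 > 0L & curve$counts_h1 > 0L &
    curve$nominal >= nominal_min
  if (!any(use)) stop_invalid("no usable bins at nominal >= ", nominal_min)
  dev <- log(curve$observed[use]) - log(curve$nominal[use])
  w <- if (weighted) curve$counts_h0[use] + curve$counts_h1[use] else
    rep(1, sum(use))
  list(mean_log_deviation = sum(w * dev) / sum(w),
       log_deviation = dev,
       se = sqrt(1 / curve$counts_h1[use] + 1 / curve$counts_h0[use]),
       nominal = curve$nominal[use])
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Calibration curve: ", nrow(x), " occupied bins (",
      sum(!x$masked), " unmasked), ", attr(x, "reps_h0"), " + ",
      attr(x, "reps_h1"), " replicates\n", sep = "")
  NextMethod()
}

#' Plot a calibration curve
#'
#' Observed versus nominal posterior odds on log-log axes with the identity
#' line; masked bins are drawn hollow.
#'
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.calibration_curve <- function(x, ...) {
  df <- x[!is.na(x$observed) & x$observed > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = nominal, y = observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(shape = masked)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "nominal posterior odds",
                  y = "observed posterior odds")
}

#' Paired histograms of posterior odds under the two hypotheses
#'
#' @param odds_h0,odds_h1 As in [build_curve()].
#' @param bin_width Bin width on the natural-log scale.
#' @param log Set to `TRUE` if inputs are natural-log odds.
#' @return A ggplot object.
#' @export
plot_odds_histograms <- function(odds_h0, odds_h1, bin_width = 0.1,
                                 log = FALSE) {
  l0 <- if (log) odds_h0 else log_odds(odds_h0)
  l1 <- if (log) odds_h1 else log_odds(odds_h1)
  df <- data.frame(log_odds = c(l0, l1),
                   hypothesis = rep(c("H0", "H1"), c(length(l0), length(l1))))
  ggplot2::ggplot(df, ggplot2::aes(x = log_odds,
                                   fill = hypothesis)) +
    ggplot2::geom_histogram(binwidth = bin_width, alpha = 0.6,
                            position = "identity") +
    ggplot2::labs(x = "log posterior odds", y = "replicates")
}

run_calibration <- function(family, h1_source, fixed_params, reps, rule,
                            n_fixed, seed, spec, sigma, bin_width, min_count) {
  seeds <- substream_seeds(seed, 2L)
  h0 <- simulate_final_odds(family, "H0", reps = reps, seed = seeds[1L],
                            rule = rule, n_fixed = n_fixed, spec = spec,
                            sigma = sigma)
  h1 <- simulate_final_odds(family, "H1", parameter_source = h1_source,
                            fixed_params = fixed_params, reps = reps,
                            seed = seeds[2L], rule = rule, n_fixed = n_fixed,
                            spec = spec, sigma = sigma)
  curve <- build_curve(h0$log_odds, h1$log_odds, bin_width = bin_width,
                       min_count = min_count, log = TRUE)
  sl <- calibration_slope(curve)
  structure(list(curve = curve, slope = sl$slope,
                 max_abs_log_deviation = sl$max_abs_log_deviation,
                 n_bins = sl$n_bins, runs_h0 = h0, runs_h1 = h1,
                 family = family, reps = reps, seed = seed),
            class = "calibration_check")
}

#' @export
print.calibration_check <- function(x, ...) {
  cat("Calibration check (", x$family, ", ", x$reps,
      " replicates per hypothesis)\n", sep = "")
  cat("  slope of log observed on log nominal: ",
      format(x$slope, digits = 4), "\n", sep = "")
  cat("  max |log observed - log nominal|:     ",
      format(x$max_abs_log_deviation, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Prior calibration check
#'
#' Simulates `reps` replicates under each hypothesis with the H1 parameter
#' drawn from its prior, computes the final posterior odds at a fixed sample
#' size or under a stopping rule, and summarises the calibration curve.
#' With proper priors on the tested parameter the observed odds match the
#' nominal odds (slope 1) for *any* stopping rule; this function is the
#' executable form of that claim.
#'
#' @param family One of the closed-form families (see
#'   [simulate_final_odds()]).
#' @param reps Replicates per hypothesis.
#' @param rule A [stopping_rule], or `NULL` with `n_fixed` set.
#' @param n_fixed Fixed sample size.
#' @param seed Integer seed.
#' @param spec A [model_spec].
#' @param sigma Sampling standard deviation for the unknown-variance families.
#' @param bin_width,min_count Passed to [build_curve()].
#' @return A `calibration_check`: the curve, its slope and maximum absolute
#'   log deviation, and the per-replicate run tables.
#' @examples
#' check_prior_calibration("normal_known_var", reps = 2000, n_fixed = 10,
#'                         seed = 1)
#' @export
check_prior_calibration <- function(family, reps = 5000, rule = NULL,
                                    n_fixed = NULL, seed = 1,
                                    spec = model_spec(family), sigma = 1,
                                    bin_width = 0.1, min_count = 10L) {
  run_calibration(family, "from_prior", list(), reps, rule, n_fixed, seed,
                  spec, sigma, bin_width, min_count)
}

#' Strong calibration check
#'
#' As [check_prior_calibration()], but the H1 parameter of interest is held
#' at a fixed value instead of drawn from its prior (pick one in a region of
#' large prior density).  For scale parameters under the Jeffreys prior this
#' leaves calibration intact for any fixed `sigma`; for the parameter of
#' interest under a default prior it degrades mildly at fixed `n` and
#' severely under optional stopping.
#'
#' @inheritParams check_prior_calibration
#' @param fixed_params Named list of fixed H1 parameters (`mu`, `delta`, or
#'   `theta`; plus `sigma` via the `sigma` argument).
#' @return A `calibration_check`.
#' @export
check_strong_calibration <- function(family, fixed_params, reps = 5000,
                                     rule = NULL, n_fixed = NULL, seed = 1,
                                     spec = model_spec(family), sigma = 1,
                                     bin_width = 0.1, min_count = 10L) {
  if (!is.null(fixed_params$sigma)) sigma <- fixed_params$sigma
  run_calibration(family, "fixed", fixed_params, reps, rule, n_fixed, seed,
                  spec, sigma, bin_width, min_count)
}

#' Export a calibration curve to CSV
#'
#' @param curve A `calibration_curve`.
#' @param file Output path.
#' @return The curve, invisibly.
#' @export
export_curve <- function(curve, file) {
  utils::write.csv(as.data.frame(curve), file, row.names = FALSE)
  invisible(curve)
}
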