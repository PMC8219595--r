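#' Threshold stopping rule for sequential posterior odds
#'
#' Sampling continues until the running posterior odds reach `threshold`
#' (or drop to `1/threshold`, unless `one_sided`), with monitoring after every
#' observation from `n_min` on and a hard maximum of `n_max` observations.
#' An unbounded rule (`n_max = Inf`) is capped by the engine's `cap`
#' argument, and runs that hit the cap are flagged, never dropped.
#'
#' @param threshold Odds threshold `a > 1` (e.g. 10 for 10-to-1).
#' @param n_min First sample size at which the odds are evaluated.
#' @param n_max Maximum sample size (may be `Inf`).
#' @param one_sided If `TRUE`, stop only when odds favour H1 at `threshold`;
#'   the lower boundary `1/threshold` is not used.
#' @return An object of class `stopping_rule`.
#' @examples
#' stopping_rule(threshold = 10, n_max = 25)
#' @export
stopping_rule <- function(threshold = 10, n_min = 1L, n_max = 25L,
                          one_sided = FALSE) {
  if (threshold <= 1) stop_invalid("'threshold' must exceed 1")
  if (n_min < 1) stop_invalid("'n_min' must be >= 1")
  if (n_max < n_min) stop_invalid("'n_max' must be >= 'n_min'")
  structure(list(threshold = threshold, n_min = as.integer(n_min),
                 n_max = n_max, one_sided = isTRUE(one_sided)),
            class = "stopping_rule")
}

#' @export
print.stopping_rule <- function(x, ...) {
  cat("Stopping rule: stop when odds >= ", x$threshold,
      if (!x$one_sided) paste0(" or <= 1/", x$threshold),
      "; monitor n = ", x$n_min, "..", x$n_max, "\n", sep = "")
  invisible(x)
}

new_sequential_run <- function(tau, log_traj, stop_reason, rule,
                               skipped_looks = integer(0)) {
  structure(list(tau = tau,
                 final_odds = odds_value(log_traj[length(log_traj)]),
                 log_trajectory = log_traj,
                 stop_reason = stop_reason,
                 n_min = rule$n_min,
                 skipped_looks = skipped_looks),
            class = "sequential_run")
}

#' @export
print.sequential_run <- function(x, ...) {
  cat("Sequential run: stopped at n = ", x$tau, " (", x$stop_reason,
      "), final odds ", format(x$final_odds$value, digits = 5), "\n", sep = "")
  invisible(x)
}

stop_check <- function(log_o, rule) {
  la <- log(rule$threshold)
  if (log_o >= la) return("upper")
  if (!rule$one_sided && log_o <= -la) return("lower")
  NA_character_
}

#' Run a Bayes-factor engine under optional stopping
#'
#' Feeds a replicate stream into a posterior-odds engine one observation at a
#' time, evaluating the odds after every observation from `rule$n_min` on and
#' stopping the first time the rule fires or `n_max` (or the hard `cap` for
#' unbounded rules) is reached.  The full trajectory of log odds over the
#' monitored sample sizes is returned.
#'
#' @param stream A `replicate_stream` yielding numeric observations.
#' @param engine Function mapping a data prefix (numeric vector) to an
#'   [odds_value] (or a number interpretable as odds).
#' @param rule A [stopping_rule].
#' @param cap Hard cap on the sample size for unbounded rules.
#' @return A `sequential_run` with fields `tau`, `final_odds`,
#'   `log_trajectory` (named by sample size), `stop_reason` (one of
#'   `"upper"`, `"lower"`, `"n_max"`, `"cap"`).
#' @examples
#' s <- gen_normal(sampling_regime("H0"), model_spec("normal_known_var"), seed = 1)
#' run_sequential(s, function(x) odds_normal_known_var(length(x), mean(x)),
#'                stopping_rule(10, n_max = 25))
#' @export
run_sequential <- function(stream, engine, rule, cap = 10000L) {
  n_stop <- min(rule$n_max, cap)
  x <- numeric(0)
  log_traj <- numeric(0)
  ns <- integer(0)
  n <- 0L
  repeat {
    n <- n + 1L
    x <- c(x, stream_next(stream, 1L))
    if (n < rule$n_min) next
    log_o <- log_odds(engine(x))
    log_traj <- c(log_traj, log_o)
    ns <- c(ns, n)
    reason <- stop_check(log_o, rule)
    if (!is.na(reason)) break
    if (n >= rule$n_max) { reason <- "n_max"; break }
    if (n >= cap) { reason <- "cap"; break }
  }
  names(log_traj) <- ns
  new_sequential_run(n, log_traj, reason, rule)
}

#' Optional stopping for g-prior regression with an explicit prior convention
#'
#' Runs the g-prior regression engine sequentially on a stream of `(x, y)`
#' pairs.  Because the g-prior is scaled by the design, it is not clear which
#' design should scale it when the sample size is data-dependent; both named
#' conventions are implemented and must be chosen explicitly:
#' \describe{
#'   \item{`current_n`}{the prior is rebuilt from the realized design at each
#'     look;}
#'   \item{`max_n`}{the prior is held at the initially planned design
#'     (`planned_X`) throughout.}
#' }
#' Looks at which the centered realized design is still singular (e.g. all
#' covariate values equal) are skipped and recorded in `skipped_looks`.
#'
#' @param stream A regression `replicate_stream` (see [gen_regression()]).
#' @param rule A [stopping_rule] (use `n_min >= 3`).
#' @param prior_convention `"current_n"` or `"max_n"`.
#' @param planned_X Planned design; required for `max_n`.
#' @param spec A [model_spec] with family `gprior_regression`.
#' @param cap Hard cap for unbounded rules.
#' @return A `sequential_run`.
#' @export
run_sequential_gprior <- function(stream, rule,
                                  prior_convention = c("current_n", "max_n"),
                                  planned_X = NULL,
                                  spec = model_spec("gprior_regression"),
                                  cap = 10000L) {
  prior_convention <- match.arg(prior_convention)
  if (prior_convention == "max_n" && is.null(planned_X))
    stop_invalid("'planned_X' is required for the max_n convention")
  if (rule$n_min < 3L)
    stop_invalid("'n_min' must be >= 3 for the regression engine")
  n_stop <- min(rule$n_max, cap)
  xs <- numeric(0)
  ys <- numeric(0)
  log_traj <- numeric(0)
  ns <- integer(0)
  skipped <- integer(0)
  n <- 0L
  reason <- NA_character_
  repeat {
    n <- n + 1L
    obs <- stream_next(stream, 1L)
    xs <- c(xs, obs$x)
    ys <- c(ys, obs$y)
    at_end <- n >= rule$n_max || n >= cap
    if (n >= rule$n_min) {
      if (sum((xs - mean(xs))^2) < 1e-12) {
        skipped <- c(skipped, n)
      } else {
        pX <- if (prior_convention == "current_n") xs else planned_X
        o <- bf_gprior_regression(ys, xs, prior_X = pX, spec = spec)
        log_traj <- c(log_traj, o$log_value)
        ns <- c(ns, n)
        reason <- stop_check(o$log_value, rule)
        if (!is.na(reason)) break
      }
    }
    if (at_end) {
      reason <- if (n >= rule$n_max) "n_max" else "cap"
      if (length(log_traj) == 0L)
        stop_invalid("design remained singular over the whole run")
      break
    }
  }
  names(log_traj) <- ns
  new_sequential_run(n, log_traj, reason, rule, skipped_looks = skipped)
}

#' Tabulate sequential runs
#'
#' @param runs List of `sequential_run` objects.
#' @param file Optional CSV path to write the table to.
#' @return Data frame with columns `replicate_id`, `tau`, `log_final_odds`,
#'   `stop_reason`.
#' @export
runs_to_table <- function(runs, file = NULL) {
  out <- data.frame(
    replicate_id = seq_along(runs),
    tau = vapply(runs, `[[`, numeric(1), "tau"),
    log_final_odds = vapply(runs, function(r) r$final_odds$log_value, numeric(1)),
    stop_reason = vapply(runs, `[[`, character(1), "stop_reason"))
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
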