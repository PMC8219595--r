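# Vectorised replicate-level simulation drivers.
#
# The closed-form engines depend on the data only through running sufficient
# statistics, so whole experiments (20,000 replicates in the headline
# protocol) are simulated as matrices with one row per replicate.  The
# stream-based run_sequential() path is the reference implementation; tests
# cross-check the two against each other.

.jzs_cache <- new.env(parent = emptyenv())

# The JZS Bayes factor is increasing in |t| at fixed n, so a threshold rule
# on the odds is equivalent to per-n boundaries on |t|.  Boundaries are
# root-found once per (n, threshold, rscale) and memoised.
jzs_t_boundaries <- function(n, threshold, rscale = 1) {
  key <- paste(n, threshold, rscale, sep = "|")
  hit <- get0(key, envir = .jzs_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  lb <- log(threshold)
  f <- function(t) log(jzs_bf_t(t, n, rscale, rel_tol = 1e-10))
  # upper boundary: BF = threshold; bracket by doubling
  hi <- 2
  while (f(hi) < lb && hi < 1e6) hi <- hi * 2
  t_hi <- if (f(hi) < lb) Inf else
    stats::uniroot(function(t) f(t) - lb, c(0, hi), tol = 1e-9)$root
  # lower boundary: BF = 1/threshold; attainable only if BF at t = 0 is below
  t_lo <- if (f(0) <= -lb) {
    stats::uniroot(function(t) f(t) + lb, c(0, max(t_hi, 1)), tol = 1e-9)$root
  } else NA_real_
  out <- c(lower = t_lo, upper = t_hi)
  assign(key, out, envir = .jzs_cache)
  out
}

# First threshold crossing per row of a score matrix.
# score: reps x length(n_seq); upper/lower: per-column bounds (use -Inf for
# an inactive lower bound).  Returns tau, the column index stopped at, and
# the stop reason ("n_max" when no bound was hit).
first_crossing <- function(score, upper, lower, n_seq) {
  up <- sweep(score, 2L, upper, ">=")
  dn <- sweep(score, 2L, lower, "<=")
  hit <- up | dn
  any_hit <- rowSums(hit) > 0L
  col <- max.col(hit, ties.method = "first")
  col[!any_hit] <- ncol(score)
  reason <- ifelse(any_hit,
                   ifelse(up[cbind(seq_len(nrow(score)), col)], "upper", "lower"),
                   "n_max")
  list(tau = n_seq[col], col = col, reason = reason)
}

# Draw per-replicate parameters for a family/regime (vectorised over reps).
draw_replicate_params <- function(family, hypothesis, parameter_source,
                                  fixed_params, reps, spec, sigma) {
  fp <- fixed_params
  switch(family,
    normal_known_var = {
      mu <- if (hypothesis == "H0") rep(0, reps)
        else if (parameter_source == "from_prior") stats::rnorm(reps)
        else rep(fp$mu %||% stop_invalid("fixed regime requires 'mu'"), reps)
      list(mu = mu, sigma = rep(1, reps))
    },
    normal_jeffreys_var = {
      mu <- if (hypothesis == "H0") rep(0, reps)
        else if (parameter_source == "from_prior") stats::rnorm(reps, 0, sigma)
        else rep(fp$mu %||% stop_invalid("fixed regime requires 'mu'"), reps)
      list(mu = mu, sigma = rep(sigma, reps))
    },
    jzs_ttest = {
      delta <- if (hypothesis == "H0") rep(0, reps)
        else if (parameter_source == "from_prior")
          stats::rcauchy(reps, 0, spec$cauchy_scale)
        else if (!is.null(fp$delta)) rep(fp$delta, reps)
        else if (!is.null(fp$mu)) rep((fp$mu - spec$mu0) / sigma, reps)
        else stop_invalid("fixed regime requires 'delta' or 'mu'")
      list(mu = spec$mu0 + delta * sigma, sigma = rep(sigma, reps))
    },
    bernoulli_jeffreys = {
      theta <- if (hypothesis == "H0") rep(0.5, reps)
        else if (parameter_source == "from_prior") stats::rbeta(reps, 0.5, 0.5)
        else rep(fp$theta %||% stop_invalid("fixed regime requires 'theta'"), reps)
      list(theta = theta)
    },
    stop_invalid("no vectorised driver for family ", family))
}

#' Simulate final posterior odds over many replicates
#'
#' Fast matrix-based simulation of the final posterior odds of `reps`
#' replicates for the closed-form families, either at a fixed sample size or
#' under a threshold [stopping_rule].  Each replicate draws its parameter
#' once (from the prior or fixed), then observations accrue; this is the
#' engine behind the calibration and operating-characteristic experiments.
#'
#' @param family One of `"normal_known_var"`, `"normal_jeffreys_var"`,
#'   `"jzs_ttest"`, `"bernoulli_jeffreys"`.
#' @param hypothesis `"H0"` or `"H1"`.
#' @param parameter_source `"from_prior"` or `"fixed"` (H1 only).
#' @param fixed_params Named list (`mu`, `delta`, `theta`) for fixed regimes.
#' @param reps Number of replicates.
#' @param seed Integer seed.
#' @param rule A [stopping_rule], or `NULL` for a fixed sample size.
#' @param n_fixed Fixed sample size when `rule` is `NULL`.
#' @param spec A [model_spec] for the family.
#' @param sigma Sampling standard deviation for the unknown-variance families
#'   (the improper prior on `sigma` cannot be sampled, so a value must be
#'   picked; the calibration results do not depend on it).
#' @return Data frame with one row per replicate: `tau`, `log_odds`,
#'   `stop_reason`.
#' @export
simulate_final_odds <- function(family, hypothesis = "H0",
                                parameter_source = "from_prior",
                                fixed_params = list(), reps, seed,
                                rule = NULL, n_fixed = NULL,
                                spec = model_spec(family), sigma = 1) {
  if (reps < 1) stop_invalid("'reps' must be >= 1")
  if (is.null(rule) && is.null(n_fixed))
    stop_invalid("supply either 'rule' or 'n_fixed'")
  if (!is.null(rule) && !is.finite(rule$n_max))
    stop_invalid("vectorised driver requires a finite 'n_max'; use ",
                 "run_sequential() for unbounded rules")
  n_top <- if (is.null(rule)) n_fixed else rule$n_max
  n_lo <- if (is.null(rule)) n_fixed else
    max(rule$n_min, if (family %in% c("normal_jeffreys_var", "jzs_ttest")) 2L else 1L)
  set.seed(seed)
  par <- draw_replicate_params(family, hypothesis, parameter_source,
                               fixed_params, reps, spec, sigma)

  if (family == "bernoulli_jeffreys") {
    m <- matrix(stats::rbinom(reps * n_top, 1L, par$theta), nrow = reps)
  } else {
    m <- matrix(stats::rnorm(reps * n_top, mean = par$mu, sd = par$sigma),
                nrow = reps)
  }
  n_seq <- n_lo:n_top
  s1 <- row_cumsum(m)[, n_seq, drop = FALSE]

  if (family == "jzs_ttest") {
    s2 <- row_cumsum(m^2)[, n_seq, drop = FALSE]
    nn <- matrix(n_seq, nrow = reps, ncol = length(n_seq), byrow = TRUE)
    y1 <- s1 - nn * spec$mu0              # sum of (x - mu0)
    y2 <- s2 - 2 * spec$mu0 * s1 + nn * spec$mu0^2
    varn <- pmax((y2 - y1^2 / nn) / (nn - 1), 1e-300)
    tmat <- (y1 / nn) / sqrt(varn / nn)
    if (is.null(rule)) {
      k <- length(n_seq)
      lo <- vapply(tmat[, k], function(t)
        log(jzs_bf_t(t, n_fixed, spec$cauchy_scale)), numeric(1))
      return(data.frame(tau = n_fixed, log_odds = lo, stop_reason = "fixed_n"))
    }
    bounds <- vapply(n_seq, jzs_t_boundaries, numeric(2),
                     threshold = rule$threshold, rscale = spec$cauchy_scale)
    lower <- if (rule$one_sided) rep(-Inf, length(n_seq)) else {
      lb <- bounds["lower", ]
      lb[is.na(lb)] <- -Inf
      lb
    }
    cross <- first_crossing(abs(tmat), bounds["upper", ], lower, n_seq)
    t_at_stop <- tmat[cbind(seq_len(reps), cross$col)]
    lo <- mapply(function(t, n) log(jzs_bf_t(t, n, spec$cauchy_scale)),
                 t_at_stop, cross$tau)
    return(data.frame(tau = cross$tau, log_odds = lo,
                      stop_reason = cross$reason))
  }

  logodds <- switch(family,
    normal_known_var = {
      nn <- matrix(n_seq, nrow = reps, ncol = length(n_seq), byrow = TRUE)
      s1^2 / (2 * (nn + 1)) - 0.5 * log(nn + 1)
    },
    normal_jeffreys_var = {
      s2 <- row_cumsum(m^2)[, n_seq, drop = FALSE]
      nn <- matrix(n_seq, nrow = reps, ncol = length(n_seq), byrow = TRUE)
      log_odds_normal_jeffreys_var(nn, s1, s2)
    },
    bernoulli_jeffreys = {
      nn <- matrix(n_seq, nrow = reps, ncol = length(n_seq), byrow = TRUE)
      log_odds_bernoulli(s1, nn - s1)
    })

  if (is.null(rule)) {
    return(data.frame(tau = n_fixed, log_odds = logodds[, length(n_seq)],
                      stop_reason = "fixed_n"))
  }
  la <- log(rule$threshold)
  lower <- if (rule$one_sided) rep(-Inf, length(n_seq)) else rep(-la, length(n_seq))
  cross <- first_crossing(logodds, rep(la, length(n_seq)), lower, n_seq)
  data.frame(tau = cross$tau,
             log_odds = logodds[cbind(seq_len(reps), cross$col)],
             stop_reason = cross$reason)
}
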