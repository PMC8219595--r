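#' Posterior odds for a normal mean with known unit variance
#'
#' Tests H0: `mu = 0` against H1: `mu ~ N(0, 1)` for i.i.d. `N(mu, 1)` data,
#' at prior odds 1-to-1.  The marginal-likelihood ratio has the closed form
#' `exp(n^2 xbar^2 / (2 (n + 1))) / sqrt(n + 1)`, which depends on the data
#' only through the sample mean.  Computation is done in the log domain, so
#' the log odds never overflow even for extreme `xbar` and `n`.
#'
#' @param n Sample size (integer, at least 1).
#' @param xbar Sample mean.
#' @param prior_odds Prior odds of H1 versus H0 (default 1).
#' @return An [odds_value].
#' @examples
#' odds_normal_known_var(10, 0.5)
#' @export
odds_normal_known_var <- function(n, xbar, prior_odds = 1) {
  if (length(n) != 1L || is.na(n) || n < 1 || n != round(n))
    stop_invalid("'n' must be a single integer >= 1")
  lv <- log_odds_normal_known_var(n, xbar) + log(prior_odds)
  odds_value(lv)
}

# Vectorised log-odds kernel shared with the simulation drivers.
log_odds_normal_known_var <- function(n, xbar) {
  n^2 * xbar^2 / (2 * (n + 1)) - 0.5 * log(n + 1)
}

#' Posterior odds for a normal mean with Jeffreys prior on the scale
#'
#' Tests H0: `mu = 0` against H1: `mu | sigma ~ N(0, sigma^2)` for i.i.d.
#' `N(mu, sigma^2)` data with unknown `sigma`, which carries the improper
#' Jeffreys prior `1/sigma` in both hypotheses.  The improper prior enters
#' only as a ratio of integrals, which is well defined and has the closed form
#' `(1/sqrt(n+1)) * (1 - (sum(x)/(n+1))^2 / (sum(x^2)/(n+1)))^(-n/2)`.
#' The odds are invariant under rescaling `x -> c x`.
#'
#' @param x Numeric data vector, length at least 2, not all zero.
#' @param prior_odds Prior odds of H1 versus H0 (default 1).
#' @return An [odds_value].
#' @examples
#' odds_normal_jeffreys_var(c(1, 2, 3))
#' @export
odds_normal_jeffreys_var <- function(x, prior_odds = 1) {
  if (length(x) < 2L) stop_invalid("need at least 2 observations")
  if (all(x == 0)) stop_invalid("degenerate input: all observations are zero")
  lv <- log_odds_normal_jeffreys_var(length(x), sum(x), sum(x^2)) +
    log(prior_odds)
  odds_value(lv)
}

# Log-odds kernel in terms of the sufficient statistics (vectorised).
log_odds_normal_jeffreys_var <- function(n, s1, s2) {
  # by Cauchy-Schwarz s1^2 <= n s2, so the log1p argument stays in (-1, 0]
  a <- s1^2 / ((n + 1) * s2)
  -0.5 * log(n + 1) - (n / 2) * log1p(-a)
}

#' JZS Bayes factor for the one-sample t test
#'
#' Tests H0: `mu = mu0` against H1: `(mu - mu0)/sigma ~ Cauchy(0, r)` for
#' i.i.d. `N(mu, sigma^2)` data, with the Jeffreys prior `1/sigma` on the
#' scale in both hypotheses.  After integrating `sigma` out analytically the
#' Bayes factor depends on the data only through the t statistic and reduces
#' to a one-dimensional integral of noncentral-t density ratios against the
#' Cauchy effect-size prior; the heavy Cauchy tails are handled by the
#' substitution `delta = r tan(u)`, with adaptive quadrature split at
#' `delta = 0`.  The odds are invariant under joint rescaling of `x - mu0`.
#'
#' @param x Numeric data vector, length at least 2, with positive sample
#'   variance.
#' @param spec A [model_spec] (family `jzs_ttest`) supplying `mu0`,
#'   `cauchy_scale` and `prior_odds`; alternatively pass `mu0` and
#'   `cauchy_scale` directly.
#' @param mu0,cauchy_scale,prior_odds Used when `spec` is not given.
#' @param rel_tol Relative quadrature tolerance.
#' @return An [odds_value].
#' @examples
#' bf_jzs_ttest(c(1.2, 1.5, 0.9, 1.8, 1.4), mu0 = 1)
#' @export
bf_jzs_ttest <- function(x, spec = NULL, mu0 = 0, cauchy_scale = 1,
                         prior_odds = 1, rel_tol = 1e-8) {
  if (!is.null(spec)) {
    mu0 <- spec$mu0
    cauchy_scale <- spec$cauchy_scale
    prior_odds <- spec$prior_odds
  }
  n <- length(x)
  if (n < 2L) stop_invalid("need at least 2 observations")
  v <- stats::var(x)
  if (!is.finite(v) || v <= 0)
    stop_invalid("degenerate input: zero sample variance")
  tstat <- sqrt(n) * (mean(x) - mu0) / sqrt(v)
  bf <- jzs_bf_t(tstat, n, rscale = cauchy_scale, rel_tol = rel_tol)
  odds_value(log(bf) + log(prior_odds))
}

#' JZS Bayes factor from a t statistic
#'
#' Workhorse behind [bf_jzs_ttest()]: the Bayes factor of the one-sample JZS
#' test as a function of the observed t statistic and the sample size.
#'
#' @param tstat Observed one-sample t statistic.
#' @param n Sample size (>= 2).
#' @param rscale Cauchy prior scale (default 1).
#' @param rel_tol Relative quadrature tolerance.
#' @return The Bayes factor (numeric, H1 vs H0).
#' @export
jzs_bf_t <- function(tstat, n, rscale = 1, rel_tol = 1e-8) {
  if (n < 2) stop_invalid("'n' must be >= 2")
  nu <- n - 1
  ldt0 <- stats::dt(tstat, nu, log = TRUE)
  # integrand on u in (-pi/2, pi/2): density ratio under effect size
  # delta = rscale * tan(u); the Cauchy weight times the Jacobian is 1/pi
  f <- function(u) {
    ncp <- sqrt(n) * rscale * tan(u)
    exp(suppressWarnings(stats::dt(tstat, nu, ncp = ncp, log = TRUE)) - ldt0) / pi
  }
  # the integrand peaks near the effect size matching the observed t; for
  # large n it is sharp, so the range is split there as well as at zero
  u_peak <- atan(abs(tstat) / (sqrt(n) * rscale))
  brk <- sort(unique(c(-pi / 2, -u_peak, 0, u_peak, pi / 2)))
  total <- 0
  for (i in seq_len(length(brk) - 1L)) {
    piece <- tryCatch(stats::integrate(f, brk[i], brk[i + 1L],
                                       rel.tol = rel_tol,
                                       subdivisions = 200L)$value,
                      error = function(e) e)
    if (inherits(piece, "error")) {
      # adaptive rule gives up when a piece underflows over most of its
      # range; fall back to a fixed fine Simpson rule, which is ample for
      # this smooth integrand
      piece <- simpson(f, brk[i], brk[i + 1L], 4001L)
    }
    total <- total + piece
  }
  total
}

#' Posterior odds for g-prior linear regression
#'
#' Tests H0: `beta = 0` against H1 with the mixture-of-normals g-prior
#' `beta | g ~ N(0, g sigma^2 n_p (Xp' Xp)^{-1})`, `g ~ IG(g_shape, g_scale)`,
#' in the fixed-design model `y ~ N(mu + X beta, sigma^2)`.  The common
#' intercept `mu` and scale `sigma` carry the Jeffreys prior `1/sigma` in both
#' hypotheses; they are integrated out analytically by centering `y` and `X`.
#' The prior on `beta` is scaled by a *prior design* `prior_X` (with `n_p`
#' rows, uncentered cross-product), which need not equal the realized design:
#' under optional stopping the two conventions named in
#' [run_sequential_gprior()] differ precisely in this argument, and the
#' engine therefore takes it explicitly rather than defaulting silently.
#' Conditional on `g` the marginal-likelihood ratio is closed-form; the
#' mixture is evaluated by one-dimensional quadrature over `g`.
#'
#' @param y Numeric response vector.
#' @param X Realized design: numeric matrix (or vector for one covariate) with
#'   `length(y)` rows.
#' @param prior_X Design used to scale the g-prior (defaults to `X`).
#' @param spec A [model_spec] (family `gprior_regression`); alternatively pass
#'   the hyperparameters directly.
#' @param g_shape,g_scale,prior_odds Used when `spec` is not given.
#' @param rel_tol Relative quadrature tolerance.
#' @return An [odds_value].
#' @examples
#' x <- example3_design(20)
#' y <- 1 + 0.5 * x + rnorm(20, sd = 0.5)
#' bf_gprior_regression(y, x)
#' @export
bf_gprior_regression <- function(y, X, prior_X = X, spec = NULL,
                                 g_shape = 1 / 2, g_scale = sqrt(2) / 8,
                                 prior_odds = 1, rel_tol = 1e-8) {
  if (!is.null(spec)) {
    g_shape <- spec$g_shape
    g_scale <- spec$g_scale
    prior_odds <- spec$prior_odds
  }
  X <- as.matrix(X)
  prior_X <- as.matrix(prior_X)
  n <- length(y)
  if (nrow(X) != n) stop_invalid("nrow(X) must equal length(y)")
  if (ncol(prior_X) != ncol(X))
    stop_invalid("'prior_X' must have the same number of columns as 'X'")
  if (nrow(prior_X) < 1L) stop_invalid("'prior_X' must have rows")
  if (n < 3L) stop_invalid("need at least 3 observations")
  Sp <- crossprod(prior_X)                       # prior scaling (Eq.-10 convention)
  if (!is.finite(rcond_sym(Sp)) || rcond_sym(Sp) < 1e-12)
    stop_invalid("singular prior design: prior_X'prior_X is not invertible")
  np <- nrow(prior_X)
  yc <- y - mean(y)
  Xc <- sweep(X, 2L, colMeans(X))
  Sxx <- crossprod(Xc)
  if (rcond_sym(Sxx) < 1e-12)
    stop_invalid("singular design: centered X'X is not invertible")
  b <- crossprod(Xc, yc)
  q0 <- sum(yc^2)
  if (q0 <= 0) stop_invalid("degenerate input: response is constant")
  p <- ncol(X)
  f <- function(g) exp(log_bf_gprior(g, n, np, Sp, Sxx, b, q0) +
                         dinvgamma(g, g_shape, g_scale, log = TRUE))
  int <- tryCatch(stats::integrate(f, 0, Inf, rel.tol = rel_tol,
                                   subdivisions = 400L),
                  error = function(e) e)
  if (inherits(int, "error"))
    stop_invalid("quadrature over g failed: ", conditionMessage(int))
  odds_value(log(int$value) + log(prior_odds))
}

# Closed-form log Bayes factor conditional on the mixing value g, after the
# intercept and scale are integrated out analytically (centered data).
log_bf_gprior <- function(g, n, np, Sp, Sxx, b, q0) {
  A <- np * solve(Sp) %*% Sxx
  ev <- Re(eigen(A, only.values = TRUE)$values)
  vapply(g, function(gg) {
    ld <- 0.5 * sum(log1p(gg * ev))
    # yc'(I + Xc W Xc')^{-1} yc = q0 - b'(W^{-1} + Sxx)^{-1} b,  W = g np Sp^{-1}
    q1 <- q0 - drop(crossprod(b, solve(Sp / (gg * np) + Sxx, b)))
    -ld - ((n - 1) / 2) * (log(q1) - log(q0))
  }, numeric(1))
}

#' Conditional g-prior Bayes factor at a fixed mixing value
#'
#' The Bayes factor of [bf_gprior_regression()] conditional on `g`, i.e.
#' with `beta | g ~ N(0, g sigma^2 n_p (Xp'Xp)^{-1})` and no mixing over
#' `g`.  The mixture engine integrates exactly this quantity against the
#' inverse-gamma density.
#'
#' @inheritParams bf_gprior_regression
#' @param g Positive mixing value.
#' @return An [odds_value].
#' @export
gprior_bf_conditional <- function(y, X, g, prior_X = X, prior_odds = 1) {
  if (g <= 0) stop_invalid("'g' must be positive")
  X <- as.matrix(X)
  prior_X <- as.matrix(prior_X)
  n <- length(y)
  if (nrow(X) != n) stop_invalid("nrow(X) must equal length(y)")
  yc <- y - mean(y)
  Xc <- sweep(X, 2L, colMeans(X))
  odds_value(log_bf_gprior(g, n, nrow(prior_X), crossprod(prior_X),
                           crossprod(Xc), crossprod(Xc, yc), sum(yc^2)) +
               log(prior_odds))
}

rcond_sym <- function(m) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) return(0)
  min(ev) / max(ev)
}

#' Posterior odds for the Bernoulli model with Jeffreys prior
#'
#' Tests H0: `theta = 1/2` against H1: `theta ~ Beta(1/2, 1/2)` (the Jeffreys
#' prior, normalized by `1/pi`) for a sequence of `n1` ones and `n0` zeros.
#' The odds are `B(n1 + 1/2, n0 + 1/2) / B(1/2, 1/2) / (1/2)^(n1 + n0)`.
#'
#' @param n1,n0 Counts of ones and zeros (non-negative, `n1 + n0 >= 1`).
#' @param prior_odds Prior odds of H1 versus H0 (default 1).
#' @return An [odds_value].
#' @examples
#' bf_bernoulli_jeffreys(2, 0)  # odds 1.5
#' @export
bf_bernoulli_jeffreys <- function(n1, n0, prior_odds = 1) {
  if (n1 < 0 || n0 < 0 || n1 + n0 < 1 ||
      n1 != round(n1) || n0 != round(n0))
    stop_invalid("'n1' and 'n0' must be non-negative counts with n1 + n0 >= 1")
  lv <- log_odds_bernoulli(n1, n0) + log(prior_odds)
  odds_value(lv)
}

# Vectorised log-odds kernel.
log_odds_bernoulli <- function(n1, n0) {
  lbeta(n1 + 0.5, n0 + 0.5) - lbeta(0.5, 0.5) + (n1 + n0) * log(2)
}

#' Marginal g-prior density of a scalar regression coefficient
#'
#' The prior on a scalar coefficient implied by the g-prior is
#' `beta | g ~ N(0, g sigma^2 n / (x'x))`.  With `g` fixed this is the
#' conditional normal; with `g = NULL` the conditional is integrated over
#' `g ~ IG(g_shape, g_scale)` by quadrature.  Because the scaling `n/(x'x)`
#' depends on the design, adding rows to the design changes the prior itself;
#' evaluating this density at several design sizes makes that visible.
#'
#' @param beta Numeric vector of coefficient values at which to evaluate.
#' @param X Design (vector or one-column matrix).
#' @param sigma Error standard deviation entering the prior variance.
#' @param g Fixed mixing value, or `NULL` to integrate over the inverse-gamma
#'   mixing distribution.
#' @param g_shape,g_scale Inverse-gamma hyperparameters.
#' @return Numeric vector of density values.
#' @examples
#' gprior_marginal_density(0, example3_design(20), sigma = 1)
#' @export
gprior_marginal_density <- function(beta, X, sigma = 1, g = NULL,
                                    g_shape = 1 / 2, g_scale = sqrt(2) / 8) {
  X <- as.matrix(X)
  if (ncol(X) != 1L)
    stop_invalid("unsupported dimension: a single covariate column is required")
  if (sigma <= 0) stop_invalid("'sigma' must be positive")
  n <- nrow(X)
  scale2 <- sigma^2 * n / sum(X^2)
  if (!is.null(g)) {
    if (g <= 0) stop_invalid("'g' must be positive")
    return(stats::dnorm(beta, 0, sqrt(g * scale2)))
  }
  vapply(beta, function(b) {
    lf <- function(u) {
      gg <- exp(u)
      stats::dnorm(b, 0, sqrt(gg * scale2), log = TRUE) +
        dinvgamma(gg, g_shape, g_scale, log = TRUE) + u
    }
    # the mixing integrand peaks near g ~ beta^2/scale2 for large |beta|;
    # locate it and integrate on the log-g scale around it
    u0 <- stats::optimize(function(u) -lf(u), c(-50, 50))$minimum
    stats::integrate(function(u) exp(lf(u)), u0 - 40, u0 + 40,
                     rel.tol = 1e-10, subdivisions = 400L)$value
  }, numeric(1))
}
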