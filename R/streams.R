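#' Describe how replicate data are generated
#'
#' A sampling regime fixes the generating hypothesis and whether the relevant
#' parameter is drawn from its prior (once per replicate, then held fixed
#' while observations accrue) or set to a fixed value.  Drawing from the
#' prior is only possible for parameters with proper priors — the mean in the
#' known-variance model, the effect size in the t-test model, `beta` and `g`
#' in the regression model, `theta` in the Bernoulli model.  The scale
#' parameter under the improper Jeffreys prior can never be sampled; strong
#' calibration runs instead fix it (`sigma` in `fixed_params`).
#'
#' @param hypothesis `"H0"` or `"H1"`.
#' @param parameter_source `"from_prior"` or `"fixed"`.
#' @param fixed_params Named list; recognised entries are `mu`, `sigma`,
#'   `delta` (effect size), `beta`, `theta`.
#' @return An object of class `sampling_regime`.
#' @examples
#' sampling_regime("H1", "fixed", list(mu = 1.3, sigma = 1))
#' @export
sampling_regime <- function(hypothesis = c("H0", "H1"),
                            parameter_source = c("from_prior", "fixed"),
                            fixed_params = list()) {
  hypothesis <- match.arg(hypothesis)
  parameter_source <- match.arg(parameter_source)
  stopifnot(is.list(fixed_params))
  if (!is.null(fixed_params$sigma) && fixed_params$sigma <= 0)
    stop_invalid("'sigma' must be positive")
  structure(list(hypothesis = hypothesis,
                 parameter_source = parameter_source,
                 fixed_params = fixed_params),
            class = "sampling_regime")
}

# Internal stream constructor.  A stream owns its RNG state: parameters are
# drawn once at creation, and each stream_next() call resumes the stream's
# private state, so interleaving streams in any order cannot change results.
new_stream <- function(seed, draw_params, gen_obs) {
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  e$params <- draw_params()
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  e$seed <- seed
  e$count <- 0L
  e$gen_obs <- gen_obs
  class(e) <- "replicate_stream"
  e
}

#' Draw further observations from a replicate stream
#'
#' Returns the next `k` observations of the stream's replicate.  The
#' underlying parameter draw is fixed for the stream's lifetime; only the
#' observation noise advances.
#'
#' @param stream A `replicate_stream`.
#' @param k Number of observations to draw.
#' @return A numeric vector, or for regression streams a data frame with
#'   columns `x` and `y`.
#' @export
stream_next <- function(stream, k = 1L) {
  stopifnot(inherits(stream, "replicate_stream"), k >= 1L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  out <- stream$gen_obs(stream$params, stream$count, as.integer(k))
  stream$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  stream$count <- stream$count + as.integer(k)
  out
}

#' Inspect the parameter draw underlying a stream
#'
#' @param stream A `replicate_stream`.
#' @return Named list of the replicate's (fixed) parameters.
#' @export
stream_params <- function(stream) stream$params

#' @export
print.replicate_stream <- function(x, ...) {
  cat("Replicate stream (seed ", x$seed, ", ", x$count,
      " observations drawn)\n", sep = "")
  p <- x$params
  cat("  parameters:", paste(names(p), vapply(p, function(v)
    paste(format(v, digits = 4), collapse = ","), character(1)),
    sep = " = ", collapse = "; "), "\n")
  invisible(x)
}

#' Replicate stream of normal observations
#'
#' Under H0 observations are `N(mu0, sigma^2)`; under H1 the mean is drawn
#' from its prior or fixed, then observations are i.i.d. normal around it.
#' For the known-variance family the H1 prior is `mu ~ N(0, 1)` with
#' `sigma = 1`; for the Jeffreys-variance family it is `mu ~ N(0, sigma^2)`
#' with `sigma` fixed by the regime (the improper prior on `sigma` cannot be
#' sampled).
#'
#' @param regime A [sampling_regime].
#' @param spec A [model_spec] with family `normal_known_var` or
#'   `normal_jeffreys_var`.
#' @param seed Integer seed for this replicate.
#' @return A `replicate_stream` yielding numeric observations.
#' @export
gen_normal <- function(regime, spec = model_spec("normal_known_var"), seed) {
  known <- spec$family == "normal_known_var"
  fp <- regime$fixed_params
  sigma <- if (known) spec$sigma_known %||% 1 else fp$sigma %||% spec$sigma_known
  if (is.null(sigma))
    stop_invalid("illegal regime: sigma has an improper Jeffreys prior and ",
                 "cannot be sampled; supply a fixed 'sigma'")
  draw <- function() {
    mu <- if (regime$hypothesis == "H0") {
      spec$mu0
    } else if (regime$parameter_source == "from_prior") {
      # effect-size prior is standard normal, so mu ~ N(0, sigma^2)
      stats::rnorm(1, 0, sigma)
    } else {
      fp$mu %||% stop_invalid("fixed regime requires 'mu'")
    }
    list(mu = mu, sigma = sigma)
  }
  new_stream(seed, draw, function(p, from, k) stats::rnorm(k, p$mu, p$sigma))
}

#' Replicate stream for the one-sample t-test model
#'
#' Under H1 the standardized effect size `delta = (mu - mu0)/sigma` is drawn
#' from `Cauchy(0, cauchy_scale)` or fixed; observations are
#' `N(mu0 + delta sigma, sigma^2)`.  Under H0 they are `N(mu0, sigma^2)`.
#'
#' @inheritParams gen_normal
#' @param spec A [model_spec] with family `jzs_ttest`.
#' @return A `replicate_stream` yielding numeric observations.
#' @export
gen_ttest_effect <- function(regime, spec = model_spec("jzs_ttest"), seed) {
  fp <- regime$fixed_params
  sigma <- fp$sigma %||% spec$sigma_known %||% 1
  draw <- function() {
    delta <- if (regime$hypothesis == "H0") {
      0
    } else if (regime$parameter_source == "from_prior") {
      stats::rcauchy(1, 0, spec$cauchy_scale)
    } else {
      if (!is.null(fp$delta)) fp$delta
      else if (!is.null(fp$mu)) (fp$mu - spec$mu0) / sigma
      else stop_invalid("fixed regime requires 'delta' or 'mu'")
    }
    list(delta = delta, mu = spec$mu0 + delta * sigma, sigma = sigma)
  }
  new_stream(seed, draw, function(p, from, k) stats::rnorm(k, p$mu, p$sigma))
}

#' Replicate stream for fixed-design g-prior regression
#'
#' Per replicate: `g ~ IG(g_shape, g_scale)` and
#' `beta | g ~ N(0, g sigma^2 n (X'X)^{-1})` (or `beta` fixed; `beta = 0`
#' under H0), then `y_i = mu + x_i' beta + N(0, sigma^2)` with the covariate
#' rows served in the design order of `X`.  Requests beyond `nrow(X)` recycle
#' the design cyclically, matching a sequential extension in which another
#' full round of doses is appended.
#'
#' @inheritParams gen_normal
#' @param X Design matrix (or vector for one covariate) fixed in advance.
#' @param spec A [model_spec] with family `gprior_regression`.
#' @return A `replicate_stream`; `stream_next()` returns a data frame with
#'   columns `x` (first covariate) and `y`.
#' @export
gen_regression <- function(regime, X, spec = model_spec("gprior_regression"),
                           seed) {
  X <- as.matrix(X)
  fp <- regime$fixed_params
  sigma <- fp$sigma %||% spec$sigma_known %||% 1
  mu <- fp$mu %||% 0
  n <- nrow(X)
  Sp_inv <- solve(crossprod(X))
  draw <- function() {
    if (regime$hypothesis == "H0") {
      list(beta = rep(0, ncol(X)), g = NA_real_, mu = mu, sigma = sigma)
    } else if (regime$parameter_source == "from_prior") {
      g <- rinvgamma(1, spec$g_shape, spec$g_scale)
      cov <- g * sigma^2 * n * Sp_inv
      L <- chol(cov)
      beta <- drop(t(L) %*% stats::rnorm(ncol(X)))
      list(beta = beta, g = g, mu = mu, sigma = sigma)
    } else {
      beta <- fp$beta %||% stop_invalid("fixed regime requires 'beta'")
      list(beta = rep_len(beta, ncol(X)), g = NA_real_, mu = mu, sigma = sigma)
    }
  }
  gen <- function(p, from, k) {
    idx <- ((from + seq_len(k) - 1L) %% n) + 1L
    xi <- X[idx, , drop = FALSE]
    data.frame(x = xi[, 1L],
               y = p$mu + drop(xi %*% p$beta) + stats::rnorm(k, 0, p$sigma))
  }
  new_stream(seed, draw, gen)
}

#' Replicate stream of Bernoulli observations
#'
#' Under H0 `theta = 1/2`; under H1 `theta ~ Beta(1/2, 1/2)` (Jeffreys prior)
#' or fixed.
#'
#' @inheritParams gen_normal
#' @param spec A [model_spec] with family `bernoulli_jeffreys`.
#' @return A `replicate_stream` yielding 0/1 observations.
#' @export
gen_bernoulli <- function(regime, spec = model_spec("bernoulli_jeffreys"),
                          seed) {
  fp <- regime$fixed_params
  draw <- function() {
    theta <- if (regime$hypothesis == "H0") {
      0.5
    } else if (regime$parameter_source == "from_prior") {
      stats::rbeta(1, 0.5, 0.5)
    } else {
      fp$theta %||% stop_invalid("fixed regime requires 'theta'")
    }
    list(theta = theta)
  }
  new_stream(seed, draw, function(p, from, k) stats::rbinom(k, 1L, p$theta))
}

#' Sequential design of the fertilizer regression example
#'
#' Doses 0.1, 0.2, ..., 2.0 for the first twenty pots; further pots repeat
#' the dose cycle from 0.1 (so rows 21-23 carry doses 0.1, 0.2, 0.3, and a
#' planned 40-pot design is two full rounds).
#'
#' @param n Number of rows.
#' @return Numeric vector of doses, length `n`.
#' @examples
#' example3_design(23)[21:23]
#' @export
example3_design <- function(n) {
  rep_len(seq(0.1, 2, by = 0.1), n)
}

#' Export replicate datasets to CSV for audit
#'
#' @param streams List of `replicate_stream` objects.
#' @param n_obs Observations to draw from each stream.
#' @param file Output CSV path.
#' @return The written data frame, invisibly (columns `replicate_id`,
#'   `obs_index`, `x` where present, `y`).
#' @export
export_streams <- function(streams, n_obs, file) {
  rows <- lapply(seq_along(streams), function(i) {
    obs <- stream_next(streams[[i]], n_obs)
    if (is.data.frame(obs)) {
      data.frame(replicate_id = i, obs_index = seq_len(n_obs),
                 x = obs$x, y = obs$y)
    } else {
      data.frame(replicate_id = i, obs_index = seq_len(n_obs), y = obs)
    }
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}
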