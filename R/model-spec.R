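#' Specify a hypothesis pair and its prior hyperparameters
#'
#' A `model_spec` bundles the model family with the hyperparameters of the
#' priors used by the posterior-odds engines.  All engines test a point null
#' against a composite alternative at prior odds `prior_odds` (default 1-to-1,
#' so the posterior odds equal the Bayes factor).
#'
#' Families:
#' \describe{
#'   \item{`normal_known_var`}{Data `N(mu, 1)`; H0: `mu = 0`, H1: `mu ~ N(0, 1)`.}
#'   \item{`normal_jeffreys_var`}{Data `N(mu, sigma^2)` with unknown `sigma`
#'     carrying the improper Jeffreys prior `1/sigma` in both hypotheses;
#'     H0: `mu = 0`, H1: `mu | sigma ~ N(0, sigma^2)` (standard-normal effect
#'     size).}
#'   \item{`jzs_ttest`}{One-sample Bayesian t test: Jeffreys prior on `sigma`
#'     in both hypotheses; H0: `mu = mu0`, H1: effect size
#'     `(mu - mu0)/sigma ~ Cauchy(0, cauchy_scale)`.}
#'   \item{`gprior_regression`}{Fixed-design linear regression with Jeffreys
#'     prior on the intercept and scale and a Zellner-Siow-style g-prior on the
#'     coefficients: `beta | g ~ N(0, g sigma^2 n (X'X)^{-1})`,
#'     `g ~ IG(g_shape, g_scale)`; H0: `beta = 0`.}
#'   \item{`bernoulli_jeffreys`}{Bernoulli sequences; H0: `theta = 1/2`,
#'     H1: `theta ~ Beta(1/2, 1/2)` (Jeffreys prior).}
#' }
#'
#' @param family Model family, one of the five listed above.
#' @param mu0 Null-hypothesis mean (used by the t-test family; e.g. 1 for a
#'   crop whose mean height is one meter under the old treatment).
#' @param sigma_known Known standard deviation, or `NULL` where the scale is
#'   unknown (then it is handled by the Jeffreys prior, never sampled).
#' @param cauchy_scale Scale of the Cauchy effect-size prior (default 1, the
#'   standard Cauchy).
#' @param g_shape,g_scale Inverse-gamma hyperparameters of the g-prior mixing
#'   distribution; defaults `1/2` and `sqrt(2)/8`.
#' @param prior_odds Prior odds of H1 versus H0 (default 1).
#'
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("jzs_ttest", mu0 = 1)
#' @export
model_spec <- function(family = c("normal_known_var", "normal_jeffreys_var",
                                  "jzs_ttest", "gprior_regression",
                                  "bernoulli_jeffreys"),
                       mu0 = 0, sigma_known = NULL, cauchy_scale = 1,
                       g_shape = 1 / 2, g_scale = sqrt(2) / 8,
                       prior_odds = 1) {
  family <- match.arg(family)
  if (!is.null(sigma_known) && sigma_known <= 0)
    stop_invalid("'sigma_known' must be positive")
  if (cauchy_scale <= 0) stop_invalid("'cauchy_scale' must be positive")
  if (g_shape <= 0 || g_scale <= 0)
    stop_invalid("g-prior hyperparameters must be positive")
  if (prior_odds <= 0) stop_invalid("'prior_odds' must be positive")
  structure(list(family = family, mu0 = mu0, sigma_known = sigma_known,
                 cauchy_scale = cauchy_scale, g_shape = g_shape,
                 g_scale = g_scale, prior_odds = prior_odds),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model specification (", x$family, ")\n", sep = "")
  cat("  null mean mu0:     ", x$mu0, "\n")
  if (!is.null(x$sigma_known)) cat("  known sigma:       ", x$sigma_known, "\n")
  if (x$family == "jzs_ttest")
    cat("  Cauchy scale:      ", x$cauchy_scale, "\n")
  if (x$family == "gprior_regression")
    cat("  g ~ IG(", x$g_shape, ", ", format(x$g_scale), ")\n", sep = "")
  cat("  prior odds H1:H0:  ", x$prior_odds, "\n")
  invisible(x)
}

#' Posterior-odds value
#'
#' Container pairing posterior odds with their natural logarithm.  Engines
#' compute in the log domain, so `log_value` is always finite for finite
#' inputs even when `value` overflows to `Inf`.
#'
#' @param log_value Natural log of the posterior odds of H1 versus H0.
#' @return An object of class `odds_value` with fields `value` and `log_value`.
#' @export
odds_value <- function(log_value) {
  stopifnot(is.numeric(log_value), length(log_value) == 1L, !is.na(log_value))
  structure(list(value = exp(log_value), log_value = log_value),
            class = "odds_value")
}

#' @export
print.odds_value <- function(x, ...) {
  cat("Posterior odds (H1 vs H0): ", format(x$value, digits = 6),
      "   [log = ", format(x$log_value, digits = 6), "]\n", sep = "")
  invisible(x)
}

#' @export
as.numeric.odds_value <- function(x, ...) x$value

#' Extract log posterior odds
#'
#' @param x An `odds_value`, a list of them, or a numeric vector of odds.
#' @return Numeric vector of natural-log odds.
#' @export
log_odds <- function(x) {
  if (inherits(x, "odds_value")) return(x$log_value)
  if (is.list(x)) return(vapply(x, log_odds, numeric(1)))
  if (is.numeric(x)) return(log(x))
  stop_invalid("cannot extract log odds from object of class ",
               paste(class(x), collapse = "/"))
}
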