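# Closed-form posterior-odds engines against their defining integrals.

test_that("known-variance odds match the closed form and its oracle", {
  expect_equal(odds_normal_known_var(3, 0)$value, 0.5)
  # frozen from the 1-d quadrature oracle over mu ~ N(0,1)
  expect_equal(odds_normal_known_var(10, 0.5)$value, 0.93933, tolerance = 1e-4)

  set.seed(41)
  for (i in 1:20) {
    x <- rnorm(sample(2:12, 1), mean = runif(1, -1.5, 1.5))
    got <- odds_normal_known_var(length(x), mean(x))$value
    expect_equal(got, oracle_normal_known_var(x), tolerance = 1e-6)
  }
})

test_that("known-variance odds are monotone in |xbar| and exceed 10 eventually", {
  xb <- seq(0, 4, by = 0.25)
  vals <- sapply(xb, function(v) odds_normal_known_var(10, v)$value)
  expect_true(all(diff(vals) > 0))
  expect_gt(max(vals), 10)
  vals_neg <- sapply(-xb, function(v) odds_normal_known_var(10, v)$value)
  expect_equal(vals, vals_neg)
})

test_that("log odds never overflow for extreme inputs", {
  o <- odds_normal_known_var(1e6, 1e6)
  expect_true(is.finite(o$log_value))
  expect_identical(o$value, Inf)  # the odds themselves overflow, by design
  expect_true(is.finite(odds_normal_known_var(1e6, -1e6)$log_value))
})

test_that("Jeffreys-variance odds match the closed form and the 2-d oracle", {
  expect_equal(odds_normal_jeffreys_var(c(1, -1))$value, 1 / sqrt(3))
  # frozen from the (mu, sigma) quadrature oracle with widened cutoffs
  expect_equal(odds_normal_jeffreys_var(c(1, 2, 3))$value, 2.34265,
               tolerance = 1e-5)

  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(sample(2:10, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 2))
    got <- odds_normal_jeffreys_var(x)$value
    ora <- oracle_normal_jeffreys_var(x)
    ora_wide <- oracle_normal_jeffreys_var(x, widen = 3)
    expect_equal(ora, ora_wide, tolerance = 1e-7)  # cutoffs stabilised
    expect_equal(got, ora, tolerance = 1e-6)
  }
})

test_that("Jeffreys-variance odds are exactly scale invariant", {
  set.seed(43)
  x <- rnorm(8, 1, 2)
  base <- odds_normal_jeffreys_var(x)$log_value
  for (c_ in c(0.1, 1, 7)) {
    expect_equal(odds_normal_jeffreys_var(c_ * x)$log_value, base,
                 tolerance = 1e-12)
  }
  expect_equal(odds_normal_jeffreys_var(c(2, 4, 6))$value,
               odds_normal_jeffreys_var(c(1, 2, 3))$value)
})

test_that("engine preconditions are enforced", {
  expect_error(odds_normal_known_var(0, 1), "must be a single integer")
  expect_error(odds_normal_jeffreys_var(c(0, 0, 0)), "degenerate")
  expect_error(odds_normal_jeffreys_var(1), "at least 2")
  expect_error(bf_jzs_ttest(c(1, 1, 1)), "zero sample variance")
  expect_error(bf_jzs_ttest(2), "at least 2")
  expect_error(bf_bernoulli_jeffreys(0, 0), "n1 \\+ n0 >= 1")
  expect_error(bf_bernoulli_jeffreys(-1, 2), "non-negative")
})

test_that("JZS odds agree with the independent (delta, sigma) quadrature", {
  set.seed(44)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    x <- rnorm(n, mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
    got <- bf_jzs_ttest(x)$value
    expect_equal(got, oracle_jzs_2d(x), tolerance = 1e-6)
  }
  # non-unit Cauchy scale and shifted null
  x <- rnorm(8, 1.4, 0.8)
  expect_equal(bf_jzs_ttest(x, mu0 = 1, cauchy_scale = 0.7)$value,
               oracle_jzs_2d(x, mu0 = 1, rscale = 0.7), tolerance = 1e-6)
})

test_that("JZS odds are invariant under effect-scale and location changes", {
  set.seed(45)
  x <- rnorm(10, 1.2, 1)
  base <- bf_jzs_ttest(x, mu0 = 1)$log_value
  for (c_ in c(0.1, 1, 7)) {
    expect_equal(bf_jzs_ttest(1 + c_ * (x - 1), mu0 = 1)$log_value, base,
                 tolerance = 1e-9)
  }
  # shifting data and null together changes nothing
  expect_equal(bf_jzs_ttest(x + 5, mu0 = 6)$log_value, base, tolerance = 1e-9)
})

test_that("JZS odds favour the null when the sample mean sits on it", {
  x <- c(-1.3, -0.8, -0.2, 0.2, 0.8, 1.3, -0.5, 0.5, -1, 1)
  o <- bf_jzs_ttest(x, mu0 = 0)
  expect_lt(o$value, 1)
  expect_equal(o$value, oracle_jzs_2d(x), tolerance = 1e-6)
})

test_that("Bernoulli odds match Jeffreys marginal likelihoods", {
  expect_equal(bf_bernoulli_jeffreys(1, 0)$value, 1)
  expect_equal(bf_bernoulli_jeffreys(2, 0)$value, 1.5)
  set.seed(46)
  for (i in 1:20) {
    n1 <- sample(0:15, 1)
    n0 <- sample(0:15, 1)
    if (n1 + n0 == 0) n1 <- 1
    expect_equal(bf_bernoulli_jeffreys(n1, n0)$value, oracle_bernoulli(n1, n0),
                 tolerance = 1e-8)
  }
})

test_that("Bernoulli odds vanish for balanced counts as n grows", {
  vals <- sapply(c(5, 10, 20), function(k) bf_bernoulli_jeffreys(k, k)$value)
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[3], 0.3)
})

test_that("g-prior regression matches the conditional-on-g oracle", {
  set.seed(47)
  x <- example3_design(8)
  y <- 1 + 0.6 * x + rnorm(8, sd = 0.8)
  # closed conditional form vs full (mu, beta, sigma) quadrature at fixed g
  for (g in c(0.3, 1, 4)) {
    expect_equal(gprior_bf_conditional(y, x, g)$value,
                 oracle_gprior_conditional(y, x, g, x), tolerance = 1e-4)
  }
  # a different prior design moves the conditional too
  expect_equal(gprior_bf_conditional(y, x, 1,
                                     prior_X = example3_design(23))$value,
               oracle_gprior_conditional(y, x, 1, example3_design(23)),
               tolerance = 1e-4)
})

test_that("g-prior regression agrees with Monte-Carlo averaging over g", {
  set.seed(48)
  x <- example3_design(12)
  y <- 1 + 0.4 * x + rnorm(12, sd = 1)
  got <- bf_gprior_regression(y, x)$value
  # sampling oracle: average the closed conditional BF over g draws
  gs <- 1 / rgamma(1e6, 0.5, rate = sqrt(2) / 8)
  n <- length(y); np <- length(x)
  yc <- y - mean(y); xc <- x - mean(x)
  spx <- sum(x^2); sxx <- sum(xc^2); sxy <- sum(xc * yc); q0 <- sum(yc^2)
  w <- gs * np / spx
  bf_g <- (1 + w * sxx)^(-0.5) *
    ((q0 - w / (1 + w * sxx) * sxy^2) / q0)^(-(n - 1) / 2)
  mc <- mean(bf_g)
  mc_se <- sd(bf_g) / sqrt(length(gs))
  expect_lt(abs(got - mc), 3 * mc_se)
})

test_that("the g-prior depends on the prior design, with a cyclic exception", {
  set.seed(49)
  x <- example3_design(20)
  y <- 1 + 0.5 * x + rnorm(20, sd = 0.7)
  base <- bf_gprior_regression(y, x)$value
  # 23-pot design rescales n (X'X)^{-1}, so the odds move
  expect_false(isTRUE(all.equal(
    base, bf_gprior_regression(y, x, prior_X = example3_design(23))$value,
    tolerance = 1e-6)))
  # a full second round doubles n and X'X alike, leaving the prior unchanged
  expect_equal(base,
               bf_gprior_regression(y, x, prior_X = example3_design(40))$value,
               tolerance = 1e-10)
})

test_that("null-generated regression data favour the null on median", {
  set.seed(50)
  x <- example3_design(20)
  odds <- replicate(300, {
    y <- rnorm(20)
    bf_gprior_regression(y, x)$value
  })
  expect_lt(median(odds), 1)
})

test_that("g-prior regression rejects degenerate designs", {
  y <- rnorm(5)
  expect_error(bf_gprior_regression(y, rep(1, 5)), "singular")
  expect_error(bf_gprior_regression(y, 1:4), "nrow")
})

test_that("marginal g-prior density normalises, is symmetric, and widens with the design", {
  x20 <- example3_design(20)
  total <- integrate(function(b) gprior_marginal_density(b, x20),
                     -Inf, Inf, rel.tol = 1e-6)$value
  expect_equal(total, 1, tolerance = 1e-4)
  # the IG(1/2) mixture of normals is exactly a Cauchy: independent check
  grid <- seq(-3, 3, by = 0.5)
  gam <- sqrt(2 * (sqrt(2) / 8) * 20 / sum(x20^2))
  expect_equal(gprior_marginal_density(grid, x20), dcauchy(grid, 0, gam),
               tolerance = 1e-7)
  expect_equal(gprior_marginal_density(1.3, x20),
               gprior_marginal_density(-1.3, x20))
  # adding pots at low doses makes the prior wider and less peaked
  d20 <- gprior_marginal_density(0, x20)
  d23 <- gprior_marginal_density(0, example3_design(23))
  d34 <- gprior_marginal_density(0, example3_design(34))
  expect_gt(d20, d23)
  expect_gt(d23, d34)
  # fixed-g conditional is the plain normal density
  expect_equal(gprior_marginal_density(0.4, x20, sigma = 2, g = 0.3),
               dnorm(0.4, 0, sqrt(0.3 * 4 * 20 / sum(x20^2))))
  expect_error(gprior_marginal_density(0, cbind(x20, x20)), "dimension")
})

test_that("prior-predictive expectation of the odds is one (martingale property)", {
  # known-variance family: integrate odds(xbar) against the H0 law of xbar
  for (n in c(3, 10, 25)) {
    ev <- integrate(function(xb)
      exp(seqbf:::log_odds_normal_known_var(n, xb) +
            dnorm(xb, 0, 1 / sqrt(n), log = TRUE)),
      -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(ev, 1, tolerance = 1e-8)
  }
  # Bernoulli family: exact enumeration over all H0 sequences
  for (n in c(4, 8)) {
    k <- 0:n
    ev <- sum(choose(n, k) * 0.5^n *
                vapply(k, function(k1)
                  bf_bernoulli_jeffreys(k1, n - k1)$value, numeric(1)))
    expect_equal(ev, 1, tolerance = 1e-12)
  }
})
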