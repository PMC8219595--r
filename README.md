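# seqbf — sequential Bayes factors and posterior-odds calibration under optional stopping

Bayes factor hypothesis tests report the posterior odds of an alternative
H1 against a null H0 (with prior odds 1-to-1, the posterior odds *are* the
Bayes factor `P(D|H1)/P(D|H0)`).  A recurring claim is that such reports
remain interpretable under *optional stopping* — sampling until the running
odds cross a threshold.  Whether that is true depends on the prior:

* **prior calibration** — among replicates whose reported odds are `a`,
  with H1 parameters drawn from their prior, H1 really was `a` times as
  likely to have generated the data.  This holds for any stopping rule
  whenever the tested parameter has a proper prior.
* **strong calibration** — the same property when data are generated from a
  *fixed* parameter value rather than from the prior.  It survives optional
  stopping only for special group-invariant nuisance priors (the Jeffreys
  scale prior `1/sigma`); for default priors on the parameter of interest
  (e.g. the Cauchy effect-size prior of the Bayesian t test) it fails badly
  under stopping, and for design-dependent priors (the g-prior for
  regression, Jeffreys' Bernoulli prior) it is not even well defined which
  prior one should use.

`seqbf` is a simulation laboratory for these questions, for statisticians
and methodologists who want the claims reproduced rather than asserted.  It
provides:

* closed-form / quadrature posterior-odds engines for five hypothesis
  pairs: normal mean with known variance
  (`exp(n^2 xbar^2 / (2(n+1))) / sqrt(n+1)`), normal mean with Jeffreys
  scale prior, the JZS one-sample t test (Cauchy effect-size prior;
  `bf_jzs_ttest`, `jzs_bf_t`), Zellner–Siow-style g-prior regression with
  `g ~ IG(1/2, sqrt(2)/8)` and an explicit prior design
  (`bf_gprior_regression`), and the Bernoulli model with Jeffreys'
  Beta(1/2,1/2) prior;
* seeded replicate streams (`gen_normal`, `gen_ttest_effect`,
  `gen_regression`, `gen_bernoulli`) drawing each replicate's parameter
  once from its prior or holding it fixed;
* an optional-stopping engine (`run_sequential`, `stopping_rule`,
  `run_sequential_gprior`) with full trajectories and stop accounting;
* the calibration diagnostic (`build_curve`, `calibration_slope`,
  `check_prior_calibration`, `check_strong_calibration`): histogram the
  final log odds of H0- and H1-replicates in 0.1-wide bins, take the
  count ratio per bin as the *observed* odds and compare with the bin's
  *nominal* odds;
* frequentist operating characteristics (`type1_under_stopping` for the
  universal bound under a simple null; `type2_schonbrodt` for the
  sequential t-test design rule), plus experiment orchestration
  (`run_experiment`, `summary_matrix`, `bernoulli_prior_checks`) and a thin
  CLI at `inst/scripts/bfoptstop.R`.

## A worked example

Ten plants given a new fertilizer, null mean height 1 m (the old
fertilizer), Bayesian t test:

```r
library(seqbf)
set.seed(7)
x <- rnorm(10, mean = 1.25, sd = 0.9)
bf_jzs_ttest(x, mu0 = 1)
#> Posterior odds (H1 vs H0): 0.350963   [log = -1.04708]
```

Odds of about 0.35-to-1: this noisy sample mildly favours the null.  Now
optional stopping — keep measuring plants (true mean 1.3 m) until the odds
reach 10-to-1 either way or 25 observations:

```r
s <- gen_ttest_effect(sampling_regime("H1", "fixed", list(mu = 1.3, sigma = 1)),
                      model_spec("jzs_ttest", mu0 = 1), seed = 42)
run <- run_sequential(s, function(v) bf_jzs_ttest(v, mu0 = 1),
                      stopping_rule(10, n_min = 2, n_max = 25))
run
#> Sequential run: stopped at n = 11 (upper), final odds 12.52
round(run$log_trajectory, 3)
#>      2      3      4      5      6      7      8      9     10     11
#> -0.591 -0.416  0.011  0.471  0.551  1.126  1.204  1.671  1.758  2.527
```

The run drifted up and crossed `log(10) = 2.303` at the eleventh plant.
Is the *reported* 12.5-to-1 trustworthy on average?  For prior-sampled
alternatives, yes — the calibration check reproduces the identity line
(slope 1) even under this stopping rule:

```r
check_prior_calibration("normal_known_var", reps = 5000,
                        rule = stopping_rule(10, n_max = 25), seed = 1)
#> Calibration check (normal_known_var, 5000 replicates per hypothesis)
#>   slope of log observed on log nominal: 0.9803
#>   max |log observed - log nominal|:     0.4569
```

A slope near 1 means bins that claim odds `a` really contain about `a`
times as many H1 as H0 replicates.  Repeating the check with the t-test
mean *fixed* at 1.3 (`check_strong_calibration`) drops the slope to about
0.6 and leaves every bin claiming odds of 10 or more overconfident by a
factor of three or more — the same contrast `summary_matrix()` tabulates
across engines.  And `bernoulli_prior_checks()` shows why one might not
*believe* a default prior in the first place: Jeffreys' Bernoulli prior
puts 10.0 times more mass on parameters within 0.01 of the boundary than
on the equally wide band around 1/2.

See the vignette (`vignettes/optional-stopping-calibration.Rmd`) for the
models, the numerical choices, and the limits of what these simulations
show.

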