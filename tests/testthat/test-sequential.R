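# Optional-stopping engine: rule semantics, trajectory consistency, and
# agreement between the stream-based path and the vectorised drivers.

engine_ex0 <- function(x) odds_normal_known_var(length(x), mean(x))

test_that("a threshold just above 1 stops at n_min", {
  for (seed in 1:5) {
    s <- gen_normal(sampling_regime("H0"), seed = seed)
    run <- run_sequential(s, engine_ex0, stopping_rule(1 + 1e-9, n_min = 1,
                                                       n_max = 50))
    expect_equal(run$tau, 1)
  }
})

test_that("runs respect n_max and never cross a threshold early", {
  rule <- stopping_rule(10, n_min = 1, n_max = 25)
  la <- log(10)
  for (seed in 1:30) {
    s <- gen_normal(sampling_regime("H0"), seed = 100 + seed)
    run <- run_sequential(s, engine_ex0, rule)
    expect_lte(run$tau, 25)
    traj <- run$log_trajectory
    before <- traj[-length(traj)]
    expect_true(all(before < la & before > -la))
    if (run$stop_reason == "upper") expect_gte(run$final_odds$log_value, la)
    if (run$stop_reason == "lower") expect_lte(run$final_odds$log_value, -la)
    if (run$stop_reason == "n_max") {
      expect_equal(run$tau, 25)
      expect_lt(abs(run$final_odds$log_value), la)
    }
  }
})

test_that("one-sided rules ignore the lower boundary", {
  rule <- stopping_rule(2, n_min = 1, n_max = 40, one_sided = TRUE)
  for (seed in 1:10) {
    s <- gen_normal(sampling_regime("H0"), seed = 200 + seed)
    run <- run_sequential(s, engine_ex0, rule)
    expect_false(run$stop_reason == "lower")
    if (run$stop_reason == "n_max")
      expect_true(any(run$log_trajectory < -log(2)) ||
                    all(run$log_trajectory < log(2)))
  }
})

test_that("no looks happen before n_min", {
  s <- gen_normal(sampling_regime("H0"), seed = 1)
  run <- run_sequential(s, engine_ex0, stopping_rule(10, n_min = 5,
                                                     n_max = 20))
  expect_equal(as.integer(names(run$log_trajectory)[1]), 5)
})

test_that("trajectory entries reproduce the engine on each prefix", {
  s <- gen_normal(sampling_regime("H1", "from_prior"), seed = 77)
  run <- run_sequential(s, engine_ex0, stopping_rule(10, n_max = 25))
  s2 <- gen_normal(sampling_regime("H1", "from_prior"), seed = 77)
  x <- stream_next(s2, run$tau)
  for (k in seq_along(run$log_trajectory)) {
    n <- as.integer(names(run$log_trajectory)[k])
    expect_equal(run$log_trajectory[[k]],
                 engine_ex0(x[seq_len(n)])$log_value)
  }
})

test_that("unbounded rules hit the cap and say so", {
  s <- gen_normal(sampling_regime("H0"), seed = 4)
  run <- run_sequential(s, engine_ex0,
                        stopping_rule(1e8, n_min = 1, n_max = Inf), cap = 30)
  expect_equal(run$stop_reason, "cap")
  expect_equal(run$tau, 30)
})

test_that("stream path and vectorised driver stop identically on shared data", {
  # the two implementations are independent codepaths over the same formula;
  # feed both the exact same observations
  rule <- stopping_rule(10, n_min = 1, n_max = 25)
  sim <- simulate_final_odds("normal_known_var", "H0", reps = 50, seed = 31,
                             rule = rule)
  set.seed(31)  # H0 draws no parameters, then the driver fills the matrix
  m <- matrix(rnorm(50 * 25), nrow = 50)
  for (i in 1:50) {
    ref <- oracle_sequential_loop(m[i, ],
                                  function(x) engine_ex0(x)$log_value,
                                  10, 1, 25)
    expect_equal(sim$tau[i], ref$tau)
    expect_equal(sim$log_odds[i], ref$log_odds)
    expect_equal(sim$stop_reason[i], ref$reason)
  }
})

test_that("stopping fractions agree between independent implementations", {
  rule <- stopping_rule(10, n_min = 1, n_max = 25)
  sim <- simulate_final_odds("normal_known_var", "H0", reps = 5000, seed = 8,
                             rule = rule)
  frac_fast <- mean(sim$tau < 25)
  frac_slow <- mean(vapply(1:800, function(i) {
    s <- gen_normal(sampling_regime("H0"), seed = 600000 + i)
    run_sequential(s, engine_ex0, rule)$tau < 25
  }, logical(1)))
  se <- sqrt(frac_slow * (1 - frac_slow) * (1 / 5000 + 1 / 800))
  expect_lt(abs(frac_fast - frac_slow), 3 * se)
})

test_that("JZS driver agrees with direct sequential monitoring", {
  rule <- stopping_rule(10, n_min = 2, n_max = 25)
  spec <- model_spec("jzs_ttest", mu0 = 1)
  sim <- simulate_final_odds("jzs_ttest", "H1", "fixed",
                             fixed_params = list(mu = 1.3), reps = 40,
                             seed = 21, rule = rule, spec = spec)
  set.seed(21)
  m <- matrix(rnorm(40 * 25, mean = 1.3), nrow = 40)
  for (i in 1:40) {
    ref <- oracle_sequential_loop(m[i, ], function(x)
      bf_jzs_ttest(x, spec = spec)$log_value, 10, 2, 25)
    expect_equal(sim$tau[i], ref$tau)
    expect_equal(sim$log_odds[i], ref$log_odds, tolerance = 1e-7)
    expect_equal(sim$stop_reason[i], ref$reason)
  }
})

test_that("gprior conventions coincide when the planned design is realized", {
  # a threshold far out of reach forces both conventions to the full design,
  # where the realized prefix equals the planned design and they coincide
  rule <- stopping_rule(1e6, n_min = 5, n_max = 20, one_sided = TRUE)
  X <- example3_design(20)
  for (seed in c(3, 4)) {
    s1 <- gen_regression(sampling_regime("H1", "from_prior"), X, seed = seed)
    s2 <- gen_regression(sampling_regime("H1", "from_prior"), X, seed = seed)
    r_cur <- run_sequential_gprior(s1, rule, "current_n")
    r_max <- run_sequential_gprior(s2, rule, "max_n", planned_X = X)
    expect_equal(r_cur$tau, 20)
    expect_equal(r_max$tau, 20)
    expect_equal(r_cur$final_odds$log_value, r_max$final_odds$log_value,
                 tolerance = 1e-10)
  }
})

test_that("gprior conventions generally differ before the planned size", {
  rule <- stopping_rule(10, n_min = 5, n_max = 23)
  planned <- example3_design(40)
  s1 <- gen_regression(sampling_regime("H1", "from_prior"),
                       example3_design(23), seed = 11)
  s2 <- gen_regression(sampling_regime("H1", "from_prior"),
                       example3_design(23), seed = 11)
  r_cur <- run_sequential_gprior(s1, rule, "current_n")
  r_max <- run_sequential_gprior(s2, rule, "max_n", planned_X = planned)
  differ <- r_cur$tau != r_max$tau ||
    abs(r_cur$final_odds$log_value - r_max$final_odds$log_value) > 1e-8
  expect_true(differ)
})

test_that("gprior runs are reproducible under reseeding", {
  rule <- stopping_rule(10, n_min = 5, n_max = 30)
  one <- function() {
    runs <- lapply(1:10, function(i) {
      s <- gen_regression(sampling_regime("H0"), example3_design(30),
                          seed = 900 + i)
      run_sequential_gprior(s, rule, "current_n")
    })
    runs_to_table(runs)
  }
  expect_identical(one(), one())
})

test_that("stopping-rule validation rejects nonsense", {
  expect_error(stopping_rule(1), "exceed 1")
  expect_error(stopping_rule(10, n_min = 5, n_max = 4), "n_max")
  expect_error(run_sequential_gprior(NULL, stopping_rule(10, n_min = 1)),
               "n_min")
})
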