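test_that("parameter validation catches bad inputs", {
  expect_error(sim_params(u = -0.1), "non-negative")
  expect_error(sim_params(day_fractions = c(0.5, 0.4, 0.4)), "simplex")
  expect_error(sim_params(p_nonreproducer = 1.5), "probability")
  expect_error(effect_equal(1.2))
  expect_error(effect_gamma(shape = -1))
})

test_that("a fixed seed gives a bit-identical experiment", {
  p <- sim_params(n_lines = 2, n_sublines = 5, n_pseudolines = 4)
  s1 <- simulate_experiment(p, seed = 99)
  s2 <- simulate_experiment(p, seed = 99)
  expect_identical(tibble::as_tibble(s1$table), tibble::as_tibble(s2$table))
  expect_identical(s1$truth$sublines$g, s2$truth$sublines$g)
  s3 <- simulate_experiment(p, seed = 100)
  expect_false(identical(tibble::as_tibble(s1$table),
                         tibble::as_tibble(s3$table)))
})

test_that("u = 0 is a clean null: no mutations, no mean decline", {
  sim <- simulate_experiment(
    sim_params(u = 0, n_lines = 2, n_sublines = 20, n_pseudolines = 10),
    seed = 13)
  expect_true(all(sim$truth$sublines$g == 1))
  expect_true(all(sim$truth$sublines$n_mut == 0))
  rec <- relative_fitness(sim$table)
  for (l in unique(rec$line_id)) {
    d <- rec[rec$line_id == l, ]
    wM <- tapply(d$w[d$treatment == "ma"], d$subline_id[d$treatment == "ma"],
                 mean)
    dm <- delta_M(mean(wM), 150)
    se <- sd(wM) / sqrt(length(wM)) / 150
    expect_lt(abs(dm), 3 * se + 1e-4)
  }
})

test_that("mean genotypic fitness matches the compound-Poisson expectation", {
  # additive action: E[g] = 1 - (u t / 4) * 4a = 1 - u t a (up to the floor)
  p <- sim_params(u = 0.02, effect = effect_equal(0.05), n_lines = 10,
                  n_sublines = 40, n_replicates = 1)
  sim <- simulate_experiment(p, seed = 17)
  g <- sim$truth$sublines$g[sim$truth$sublines$treatment == "ma"]
  expect_equal(mean(g), 1 - 0.02 * 150 * 0.05,
               tolerance = 3 * sd(g) / sqrt(length(g)) / 0.85)
  # controls carry g = 1
  expect_true(all(sim$truth$sublines$g[
    sim$truth$sublines$treatment == "control"] == 1))
})

test_that("expected_moments gives the closed forms", {
  em <- expected_moments(sim_params(u = 0.02, effect = effect_equal(0.05)))
  expect_equal(em$delta_m, -0.02 * 0.05)
  expect_equal(em$v_m, 2 * 0.02 * 0.05^2)

  # gamma(shape, mean): E[a^2] = mean^2 (1 + 1/shape)
  emg <- expected_moments(sim_params(u = 0.01,
                                     effect = effect_gamma(2, 0.04)))
  expect_equal(emg$delta_m, -0.01 * 0.04)
  expect_equal(emg$v_m, 2 * 0.01 * 0.04^2 * 1.5)

  em0 <- expected_moments(sim_params(u = 0))
  expect_equal(c(em0$delta_m, em0$v_m), c(0, 0))
})

test_that("gamma effect-model moments match brute-force sampling", {
  set.seed(19)
  eff <- effect_gamma(shape = 1, mean = 0.05)
  draws <- eff$draw(1e6)
  expect_equal(mean(draws), 0.05, tolerance = 5e-3)
  expect_equal(mean(draws^2), eff$mean_sq, tolerance = 2e-2)
})

test_that("an infinite neutrality threshold reproduces the unthinned model", {
  p1 <- sim_params(n_lines = 2, n_sublines = 6, neutrality_threshold = Inf)
  p2 <- sim_params(n_lines = 2, n_sublines = 6)
  s1 <- simulate_experiment(p1, seed = 23)
  s2 <- simulate_experiment(p2, seed = 23)
  expect_identical(tibble::as_tibble(s1$table), tibble::as_tibble(s2$table))

  # a tight threshold discards large-effect mutations
  p3 <- sim_params(n_lines = 2, n_sublines = 30,
                   effect = effect_gamma(1, 0.05),
                   neutrality_threshold = 0.1)
  s3 <- simulate_experiment(p3, seed = 23)
  effs <- unlist(s3$truth$sublines$effects)
  expect_true(all(effs <= 0.1))
})

test_that("more environmental noise raises V_E* and lowers h2_M", {
  run_once <- function(v_e, seed) {
    sim <- simulate_experiment(
      sim_params(n_lines = 1, n_sublines = 24, n_pseudolines = 10,
                 v_e = v_e), seed = seed)
    rec <- relative_fitness(sim$table)
    b <- bootstrap_line(rec, settings = bootstrap_settings(100, seed = seed))
    e <- tidy(b)
    c(ve = e$estimate[e$quantity == "v_e_star_ma"],
      h2 = e$estimate[e$quantity == "h2_m"])
  }
  lo <- colMeans(t(vapply(1:6, function(s) run_once(0.1, s), c(ve = 0, h2 = 0))))
  hi <- colMeans(t(vapply(1:6, function(s) run_once(1.2, s), c(ve = 0, h2 = 0))))
  expect_gt(hi["ve"], lo["ve"])
  expect_lt(hi["h2"], lo["h2"])
})

test_that("the pipeline recovers the generator's expected moments at scale", {
  # large design (100 sublines x 10 replicates) so the moment estimators are
  # tight; 40 experiments
  set.seed(29)
  p <- sim_params(n_lines = 1, n_sublines = 100, n_pseudolines = 40,
                  n_replicates = 10)
  em <- expected_moments(p)
  seeds <- sample.int(1e6, 40)
  res <- vapply(seeds, function(s) {
    sim <- simulate_experiment(p, seed = s)
    rec <- relative_fitness(sim$table)
    wM <- tapply(rec$w[rec$treatment == "ma"],
                 rec$subline_id[rec$treatment == "ma"], mean)
    vcM <- fit_oneway_components(rec[rec$treatment == "ma", ], w, subline_id)
    vc0 <- fit_oneway_components(rec[rec$treatment == "control", ], w, subline_id)
    c(dm = delta_M(mean(wM), 150),
      vm = as.numeric(v_m(vcM$v_subline, vc0$v_subline, 150)))
  }, c(dm = 0, vm = 0))
  dm <- res["dm", ]; vmv <- res["vm", ]
  expect_lt(abs(mean(dm) - em$delta_m), 2 * sd(dm) / sqrt(length(dm)))
  # V_M carries a small, known downward bias from truncating the control
  # component at zero before differencing; allow for it alongside the
  # Monte-Carlo error
  expect_lt(abs(mean(vmv) - em$v_m),
            2 * sd(vmv) / sqrt(length(vmv)) + 0.2 * em$v_m)
})
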