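test_that("delta_M reproduces the worked per-line values", {
  # line 508: MA mean 0.58 after 150 generations -> -2.80 x 10^-3 / gen
  expect_equal(delta_M(0.58, 150) * 1e3, -2.80, tolerance = 1e-8)
  # a line that increased (1.47) gives +3.13 x 10^-3 (printed 3.10 from
  # unrounded inputs; one printed unit of slack)
  expect_equal(delta_M(1.47, 150) * 1e3, 3.13, tolerance = 0.01)
  expect_equal(delta_M(1, 150), 0)
  expect_error(delta_M(0.58, 0), "positive")
})

test_that("v_m applies the (V_L,MA - V_L,0) / 2t formula with a floor at 0", {
  expect_equal(as.numeric(v_m(0.06, 0, 150)), 2e-4)
  expect_equal(as.numeric(v_m(0.05, 0.05, 150)), 0)
  expect_equal(as.numeric(v_m(0.01, 0.05, 150)), 0)   # floor rule
  expect_error(v_m(-0.01, 0, 150), "truncated")
  expect_equal(attr(v_m(0.06, 0, 150, scale = "ma_mean"), "scale"), "ma_mean")
})

test_that("v_m is monotone in its components", {
  vl <- seq(0, 0.1, by = 0.01)
  up <- vapply(vl, function(v) as.numeric(v_m(v, 0.03, 150)), 0)
  expect_true(all(diff(up) >= 0))
  down <- vapply(vl, function(v) as.numeric(v_m(0.03, v, 150)), 0)
  expect_true(all(diff(down) <= 0))
})

test_that("Bateman-Mukai point estimates match the published table arithmetic", {
  # (line, delta_M x 1e3, V_M x 1e4, U_MIN, E[a]_MAX) rows of the B-M table
  cases <- tibble::tribble(
    ~dm,    ~vm,   ~u,    ~e,
    -2.84,  1.84,  0.09,  NA,     # U rounds to 0.09
    -2.22,  1.10,  0.09,  -0.02,
    -0.83,  0.63,  0.02,  -0.04,
    -1.43,  1.81,  0.02,  -0.06
  )
  bm <- bateman_mukai(cases$dm * 1e-3, cases$vm * 1e-4)
  expect_true(all(bm$defined))
  expect_equal(round(bm$u_min, 2), cases$u)
  expect_equal(round(bm$e_a_max, 2)[-1], cases$e[-1])
})

test_that("non-declining lines give flagged-undefined B-M estimates", {
  bm <- bateman_mukai(3.10e-3, 0.31e-4)
  expect_false(bm$defined)
  expect_true(is.na(bm$u_min) && is.na(bm$e_a_max))
  expect_match(bm$note, "delta_m >= 0")

  bm0 <- bateman_mukai(-1e-3, 0)
  expect_false(bm0$defined)
  expect_match(bm0$note, "v_m = 0")

  # a huge V_M against a tiny decline: returned but flagged nonsensical
  big <- bateman_mukai(-0.18e-3, 6.44e-4)
  expect_true(big$defined)
  expect_equal(big$e_a_max, -1.789, tolerance = 0.001)
  expect_match(big$note, "nonsensical")
})

test_that("the B-M identities hold: u*e = delta_M and u*e^2 = V_M / 2", {
  set.seed(12)
  dm <- -runif(50, 1e-4, 5e-3)
  vm <- runif(50, 1e-6, 1e-3)
  bm <- bateman_mukai(dm, vm)
  expect_equal(bm$u_min * bm$e_a_max, dm, tolerance = 1e-12)
  expect_equal(bm$u_min * bm$e_a_max^2, vm / 2, tolerance = 1e-12)
})

test_that("mutational heritability divides by the average environmental variance", {
  expect_equal(mutational_heritability(4.76e-4, 0.28, 0.39) * 1e3, 1.42,
               tolerance = 0.01)
  expect_equal(mutational_heritability(0, 0.3, 0.5), 0)
  expect_equal(mutational_heritability(2e-4, 0.4, 0.4), 2e-4 / 0.4)
  expect_error(mutational_heritability(1e-4, 0, 0), "positive")
})

test_that("group summaries apply the unweighted re-assay merge rule", {
  # per-line delta_M values (x 10^3) with one line assayed twice
  est <- tibble::tibble(
    assay_id = c(rep("a1", 10), "a2"),
    line_id = c("504", "508", "547", "550", "579",
                "522", "537", "566", "583", "587", "579"),
    fitness_class = rep(c("low", "high", "low"), c(5, 5, 1)),
    delta_m = c(-2.84, -2.80, -2.22, -0.83, 3.10,
                -1.43, -1.33, -0.46, -0.08, -1.00, -0.18) * 1e-3)
  gs <- group_summary(est, delta_m)
  expect_equal(gs$mean[gs$group == "low"] * 1e3, -1.44, tolerance = 0.01)
  expect_equal(gs$mean[gs$group == "high"] * 1e3, -0.86, tolerance = 0.005)
  expect_equal(gs$mean[gs$group == "all"] * 1e3, -1.15, tolerance = 0.01)
  expect_equal(gs$n_lines[gs$group == "all"], 10L)
  expect_equal(gs$n_lines[gs$group == "low"], 5L)
})

test_that("undefined per-assay values drop out of the merge, as in the tables", {
  est <- tibble::tibble(
    assay_id = c("a1", "a2", "a1"),
    line_id = c("579", "579", "550"),
    fitness_class = "low",
    u_min = c(NA, 0.004, 0.02))
  # high group must exist for the summary; add one high line
  est <- dplyr::bind_rows(est, tibble::tibble(
    assay_id = "a1", line_id = "522", fitness_class = "high", u_min = 0.02))
  gs <- group_summary(est, u_min)
  low <- gs[gs$group == "low", ]
  expect_equal(low$mean, mean(c(0.004, 0.02)))
  expect_equal(low$n_lines, 2L)
})

test_that("exact rank probability matches enumeration over all subsets", {
  expect_equal(exact_rank_probability(5, 5, 3), 10 / 120)
  expect_equal(round(exact_rank_probability(5, 5, 3), 4), 0.0833)
  expect_equal(exact_rank_probability(5, 5, 6), 0)
  expect_equal(exact_rank_probability(5, 5, 1), 0.5)

  # brute force: enumerate every k-subset of 10 labelled lines and count the
  # subsets drawn entirely from the 5 low-fitness lines
  lines <- c(rep("low", 5), rep("high", 5))
  for (k in 1:6) {
    subsets <- utils::combn(10, k)
    frac <- mean(apply(subsets, 2, function(s) all(lines[s] == "low")))
    expect_equal(exact_rank_probability(5, 5, k), frac)
  }
  expect_error(exact_rank_probability(5, 5, 11), "exceed")
})
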