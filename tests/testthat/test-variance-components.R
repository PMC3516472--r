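test_that("moments components match the hand ANOVA on four toy datasets", {
  # (1) frozen by hand: 2 sublines x 2 reps, (0,0) vs (2,2):
  #     MS_among = 4, MS_within = 0, k0 = 2 -> v_subline = 2, v_residual = 0
  d1 <- data.frame(g = rep(c("a", "b"), each = 2), y = c(0, 0, 2, 2))
  vc <- fit_oneway_components(d1, y, g)
  expect_equal(vc$v_subline, 2)
  expect_equal(vc$v_residual, 0)

  toys <- list(
    data.frame(g = rep(letters[1:3], each = 4),
               y = c(1, 2, 3, 4, 2, 4, 6, 8, 0, 1, 0, 1)),
    data.frame(g = rep(letters[1:4], each = 3),
               y = c(5, 6, 7, 5, 5, 5, 9, 8, 10, 1, 2, 3)),
    data.frame(g = rep(letters[1:5], each = 2),
               y = c(0.1, 0.2, 0.4, 0.3, 0.9, 1.1, 0.5, 0.5, 0.2, 0.6)),
    data.frame(g = rep(letters[1:3], each = 5), y = sin(1:15))
  )
  ks <- c(4, 3, 2, 5)
  for (i in seq_along(toys)) {
    vc <- fit_oneway_components(toys[[i]], y, g)
    oracle <- aov_components_oracle(toys[[i]]$y, toys[[i]]$g, ks[i])
    expect_equal(vc$v_subline, unname(oracle["v_subline"]), tolerance = 1e-12)
    expect_equal(vc$v_residual, unname(oracle["v_residual"]), tolerance = 1e-12)
  }
})

test_that("moments handles unbalanced groups with the k0 coefficient", {
  d <- data.frame(g = rep(c("a", "b", "c"), times = c(2, 3, 5)),
                  y = c(1, 2, 4, 5, 6, 1.5, 2.5, 2, 1, 3))
  vc <- fit_oneway_components(d, y, g)
  # independent route: REML on the same data, then compare orders of magnitude
  # is not exact for unbalanced data, so check the defining moment equations
  ni <- c(2, 3, 5); N <- 10; a <- 3
  m <- tapply(d$y, d$g, mean); gm <- mean(d$y)
  msa <- sum(ni * (m - gm)^2) / (a - 1)
  msw <- sum((d$y - m[d$g])^2) / (N - a)
  k0 <- (N - sum(ni^2) / N) / (a - 1)
  expect_equal(vc$v_subline, max(0, (msa - msw) / k0))
  expect_equal(vc$v_residual, msw)
})

test_that("moments and REML agree on balanced data with interior estimates", {
  set.seed(31)
  g <- rep(sprintf("s%02d", 1:12), each = 5)
  y <- rnorm(12, sd = 2)[match(g, unique(g))] + rnorm(60)
  d <- data.frame(g = g, y = y)
  mo <- fit_oneway_components(d, y, g, method = "moments")
  re <- fit_oneway_components(d, y, g, method = "reml")
  expect_gt(mo$v_subline, 0)
  expect_equal(re$v_subline, mo$v_subline, tolerance = 1e-6)
  expect_equal(re$v_residual, mo$v_residual, tolerance = 1e-6)
  expect_false(is.na(re$loglik))
})

test_that("degenerate inputs: identical values warn, single subline errors", {
  d <- data.frame(g = rep(c("a", "b"), each = 3), y = rep(1, 6))
  expect_warning(vc <- fit_oneway_components(d, y, g), "[Zz]ero")
  expect_equal(c(vc$v_subline, vc$v_residual), c(0, 0))
  expect_error(fit_oneway_components(data.frame(g = "a", y = 1:3), y, g),
               "two sublines")
})

test_that("REML among-pseudoline variance is 0 in at least half of null sims", {
  # genetically homogeneous pseudolines: the true among-group component is 0,
  # so the REML boundary estimate lands exactly on 0 about half the time
  # 5 pseudolines x 20 replicates: the boundary-zero probability is
  # P(F(4, 95) <= 1) ~ 0.59, so >= half of 200 simulations is all but certain
  set.seed(77)
  zeros <- 0L
  n_sim <- 200
  for (i in seq_len(n_sim)) {
    d <- data.frame(g = rep(sprintf("p%02d", 1:5), each = 20),
                    y = rnorm(100))
    vc <- fit_oneway_components(d, y, g, method = "reml")
    zeros <- zeros + (vc$v_subline < 1e-10)
  }
  expect_gte(zeros, n_sim / 2)
})

test_that("LRT of identical models gives chi2 = 0 and p ~ 1", {
  set.seed(5)
  d <- data.frame(g = rep(letters[1:6], each = 4), y = rnorm(24))
  res <- lrt_variance(d, y ~ 1 + (1 | g), y ~ 1 + (1 | g))
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1, tolerance = 1e-6)
})

test_that("LRT chi2 equals twice the log-likelihood gap of independent refits", {
  set.seed(6)
  d <- data.frame(g = rep(sprintf("s%02d", 1:10), each = 4))
  d$y <- rnorm(10, sd = 1.5)[match(d$g, unique(d$g))] + rnorm(40)
  res <- lrt_variance(d, y ~ 1 + (1 | g), y ~ 1)
  llf <- as.numeric(logLik(lme4::lmer(y ~ 1 + (1 | g), d, REML = TRUE)))
  llr <- as.numeric(logLik(lm(y ~ 1, d), REML = TRUE))
  expect_equal(res$chi2, 2 * (llf - llr), tolerance = 1e-8)
  expect_equal(res$df, 1)
  expect_error(lrt_variance(d, y ~ 1 + (1 | g), y ~ g),
               "[Nn]on-nested")
})

test_that("LRT detects a strong among-subline component (power simulation)", {
  # 20 sublines x 5 reps, v_subline = 10 x v_residual: should be significant
  # essentially always; 60 simulations keep the check fast
  set.seed(8)
  hits <- 0L
  n_sim <- 60
  for (i in seq_len(n_sim)) {
    g <- rep(sprintf("s%02d", 1:20), each = 5)
    y <- rnorm(20, sd = sqrt(10))[match(g, unique(g))] + rnorm(100)
    p <- lrt_variance(data.frame(g = g, y = y), y ~ 1 + (1 | g), y ~ 1)$p
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / n_sim, 0.95)
})
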