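#' Mutational effect distributions
#'
#' Effect models for the synthetic MA experiment, on the Bateman-Mukai scale
#' (the scale on which `u` and the mean effect are defined; see
#' [sim_params()]). `effect_equal()` gives every mutation the same effect
#' `a`; `effect_gamma()` draws effects from a gamma distribution with the
#' given shape and mean, the classic model of a skewed deleterious-effect
#' distribution.
#'
#' @param a,mean Mean effect on relative fitness, in (0, 1).
#' @param shape Gamma shape parameter (> 0); `shape = 1` is exponential.
#' @return A list of class `effect_model` with elements `model`, `mean`,
#'   `mean_sq` (E\[a^2\]) and `draw(n)`.
#' @export
#' @examples
#' effect_equal(0.05)
#' effect_gamma(shape = 1, mean = 0.05)
effect_equal <- function(a = 0.05) {
  stopifnot(a > 0, a < 1)
  structure(list(model = "equal", mean = a, mean_sq = a^2,
                 draw = function(n) rep.int(a, n)),
            class = "effect_model")
}

#' @rdname effect_equal
#' @export
effect_gamma <- function(shape = 1, mean = 0.05) {
  stopifnot(shape > 0, mean > 0, mean < 1)
  structure(list(model = "gamma", shape = shape, mean = mean,
                 mean_sq = mean^2 * (1 + 1 / shape),
                 draw = function(n) rgamma(n, shape = shape,
                                           scale = mean / shape)),
            class = "effect_model")
}

#' Parameters of the synthetic MA experiment
#'
#' Defines a nested second-order MA design: `n_lines` first-order lines (half
#' labelled high-, half low-fitness), each with `n_pseudolines` ancestral
#' control pseudolines and `n_sublines` MA sublines, every subline assayed
#' with `n_replicates` worms.
#'
#' `u` and the effect model are expressed in the convention of the
#' Bateman-Mukai estimators: `u` is the genomic (diploid) rate and the effect
#' model describes the per-mutation effect the estimator pair
#' \eqn{(2\Delta M^2/V_M,\; V_M/2\Delta M)} converges to. Internally the
#' generator realizes fixed mutational events per subline as
#' Poisson(`u` t / 4) with genotypic effect 4x the drawn effect -- the unique
#' compound-Poisson moment matching for which the estimator pipeline is
#' consistent for (`u`, mean effect) under equal effects (see the methods
#' vignette for the bookkeeping).
#'
#' @param u Genomic mutation rate for fitness, per generation (>= 0).
#' @param effect An [effect_equal()] or [effect_gamma()] model.
#' @param action `"additive"` (genotypic fitness `1 - sum(effects)`, floored
#'   at 0; keeps the Bateman-Mukai identities exact) or `"multiplicative"`
#'   (`prod(1 - effects)`, floored at 0).
#' @param t Generations of MA (default 150).
#' @param n_lines,n_pseudolines,n_sublines,n_replicates Design sizes
#'   (defaults 10, 10, 22, 5).
#' @param ancestral_W Mean lifetime reproductive output of the unmutated
#'   ancestor (default 148.5 offspring).
#' @param ages Assay reproduction-day ages.
#' @param day_fractions Fraction of lifetime output laid on each day (sums
#'   to 1); default `c(0.55, 0.35, 0.10)`, an early-peaked schedule.
#' @param p_nonreproducer Probability a replicate leaves no offspring at all
#'   (independent of genotype by default).
#' @param genotype_linked_zero If `TRUE`, the non-reproducer probability for
#'   a worm with genotypic fitness g is `p_nonreproducer / g` (capped at 1),
#'   linking zero-inflation to mutation load.
#' @param v_e Environmental variance of relative fitness (variance of the
#'   mean-1 environmental multiplier).
#' @param env_model `"lognormal"` multiplier (default) or `"normal"`
#'   additive deviation of genotypic fitness, truncated at 0.
#' @param overdispersion `NULL` for Poisson daily counts, or a positive
#'   negative-binomial size parameter (smaller = more overdispersed).
#' @param neutrality_threshold Mutations with genotypic effect above this
#'   value are discarded (a crude stand-in for selection during MA, where
#'   only effectively neutral mutations, 4 Ne s < 1, accumulate freely).
#'   Default `Inf` (off).
#' @param seed Optional integer seed stored with the parameters.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(u = 0.02, effect = effect_equal(0.05),
                       action = c("additive", "multiplicative"),
                       t = 150L, n_lines = 10L, n_pseudolines = 10L,
                       n_sublines = 22L, n_replicates = 5L,
                       ancestral_W = 148.5, ages = c(4.75, 5.75, 6.75),
                       day_fractions = c(0.55, 0.35, 0.10),
                       p_nonreproducer = 0.05, genotype_linked_zero = FALSE,
                       v_e = 0.4, env_model = c("lognormal", "normal"),
                       overdispersion = NULL, neutrality_threshold = Inf,
                       seed = NULL) {
  action <- match.arg(action)
  env_model <- match.arg(env_model)
  if (u < 0) abort("`u` must be non-negative.")
  if (!inherits(effect, "effect_model")) abort("`effect` must be an effect_model.")
  if (abs(sum(day_fractions) - 1) > 1e-8 || any(day_fractions < 0)) {
    abort("`day_fractions` must be a simplex (non-negative, summing to 1).")
  }
  if (length(day_fractions) != length(ages)) {
    abort("`day_fractions` must have one entry per assay day.")
  }
  if (p_nonreproducer < 0 || p_nonreproducer > 1) {
    abort("`p_nonreproducer` must be a probability.")
  }
  if (v_e < 0 || ancestral_W <= 0 || t <= 0) {
    abort("`v_e` must be >= 0, `ancestral_W` and `t` positive.")
  }
  structure(
    list(u = u, effect = effect, action = action, t = as.integer(t),
         n_lines = as.integer(n_lines),
         n_pseudolines = as.integer(n_pseudolines),
         n_sublines = as.integer(n_sublines),
         n_replicates = as.integer(n_replicates),
         ancestral_W = ancestral_W, ages = ages,
         day_fractions = day_fractions,
         p_nonreproducer = p_nonreproducer,
         genotype_linked_zero = genotype_linked_zero,
         v_e = v_e, env_model = env_model,
         overdispersion = overdispersion,
         neutrality_threshold = neutrality_threshold, seed = seed),
    class = "sim_params")
}

#' Simulate a second-order MA fitness assay
#'
#' Generates an [assay_table()] under the nested design of [sim_params()],
#' together with a truth record. Per MA subline, fixed mutational events are
#' Poisson with mean `u * t / 4`, each with genotypic effect 4x a draw from
#' the effect model (see [sim_params()] for why), optionally thinned by the
#' neutrality threshold; genotypic fitness combines the effects additively
#' or multiplicatively. Control pseudolines carry genotypic fitness 1. Each
#' replicate worm gets an environmental multiplier (mean 1, variance `v_e`),
#' is a total non-reproducer with probability `p_nonreproducer`, and lays
#' integer daily counts (Poisson, or negative binomial when
#' `overdispersion` is set) around `ancestral_W * g * env * day_fraction`.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed (overrides `params$seed`). The same seed and
#'   parameters give a bit-identical table.
#' @return A list of class `ma_sim`: `table` (an [assay_table()]) and
#'   `truth` (list: `sublines` tibble with per-subline mutation count,
#'   effects and genotypic fitness; `params`; `expected`, see
#'   [expected_moments()]; `seed`).
#' @export
#' @examples
#' sim <- simulate_experiment(sim_params(n_lines = 2, n_sublines = 6), seed = 1)
#' summarize_design(sim$table)
simulate_experiment <- function(params, seed = params$seed) {
  if (!is.null(seed)) {
    return(withr::with_seed(as.integer(seed),
                            simulate_experiment(params, seed = NULL)))
  }
  p <- params
  half <- ceiling(p$n_lines / 2)
  lines <- tibble(
    line_id = sprintf("L%02d", seq_len(p$n_lines)),
    fitness_class = rep(c("high", "low"), c(half, p$n_lines - half))
  )

  sub_rows <- list()
  truth_rows <- list()
  for (i in seq_len(p$n_lines)) {
    # controls: genetically homogeneous pseudolines of the line's ancestor
    ctrl <- tibble(
      line_id = lines$line_id[i], fitness_class = lines$fitness_class[i],
      treatment = "control",
      subline_id = sprintf("P%02d", seq_len(p$n_pseudolines)),
      gmax = 0L, n_mut = 0L, g = 1,
      effects = replicate(p$n_pseudolines, numeric(0), simplify = FALSE)
    )
    lambda <- p$u * p$t / 4
    n_mut <- rpois(p$n_sublines, lambda)
    effects <- lapply(n_mut, function(n) {
      e <- 4 * p$effect$draw(n)
      e[e <= p$neutrality_threshold]
    })
    g <- vapply(effects, function(e) {
      # an effect >= 1 is lethal under either action
      if (p$action == "additive") max(0, 1 - sum(e)) else prod(1 - pmin(e, 1))
    }, 0)
    ma <- tibble(
      line_id = lines$line_id[i], fitness_class = lines$fitness_class[i],
      treatment = "ma",
      subline_id = sprintf("S%02d", seq_len(p$n_sublines)),
      gmax = p$t, n_mut = lengths(effects), g = g, effects = effects
    )
    sub <- dplyr::bind_rows(ctrl, ma)
    truth_rows[[i]] <- sub
    sub_rows[[i]] <- sub
  }
  sublines <- dplyr::bind_rows(sub_rows)

  worms <- sublines[rep(seq_len(nrow(sublines)), each = p$n_replicates),
                    c("line_id", "fitness_class", "treatment", "subline_id",
                      "gmax", "g")]
  worms$replicate_id <- sprintf("R%d", rep_len(seq_len(p$n_replicates),
                                               nrow(worms)))
  n <- nrow(worms)
  env <- if (p$env_model == "lognormal") {
    sdlog <- sqrt(log1p(p$v_e))
    rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    1 + rnorm(n, 0, sqrt(p$v_e))
  }
  mu <- pmax(0, p$ancestral_W * worms$g * env)
  p_zero <- if (p$genotype_linked_zero) {
    pmin(1, p$p_nonreproducer / pmax(worms$g, 1e-12))
  } else {
    rep_len(p$p_nonreproducer, n)
  }
  zero <- runif(n) < p_zero
  counts <- matrix(0L, n, length(p$ages))
  for (j in seq_along(p$ages)) {
    mj <- mu * p$day_fractions[j]
    counts[, j] <- if (is.null(p$overdispersion)) {
      rpois(n, mj)
    } else {
      rnbinom(n, size = p$overdispersion, mu = mj)
    }
  }
  counts[zero, ] <- 0L
  tab <- worms[c("line_id", "fitness_class", "treatment", "subline_id",
                 "replicate_id", "gmax")]
  for (j in seq_along(p$ages)) tab[[paste0("d", j)]] <- counts[, j]
  table <- assay_table(tab, ages = p$ages, t = p$t, assay_id = "sim")

  structure(list(
    table = table,
    truth = list(sublines = dplyr::bind_rows(truth_rows),
                 params = p, expected = expected_moments(p), seed = seed)
  ), class = "ma_sim")
}

#' Expected per-generation moments of the synthetic experiment
#'
#' The values the estimation pipeline's \eqn{\Delta M_w} and \eqn{V_M}
#' converge to under the generator: \eqn{-u\,E[a]} and \eqn{2\,u\,E[a^2]}
#' per generation for additive gene action (exact up to the fitness floor at
#' zero). For multiplicative action the mean decays geometrically and the
#' returned values are the realized secant slope
#' \eqn{(e^{-u E[a] t} - 1)/t} and the exact compound-Poisson among-line
#' variance over \eqn{2t}; `approx_error` bounds the relative gap to the
#' additive (log-scale first-order) values.
#'
#' @param params A [sim_params()] object.
#' @return A list: `delta_m`, `v_m`, `e_a` (mean effect), `e_a_sq`,
#'   `approx_error`.
#' @export
#' @examples
#' expected_moments(sim_params(u = 0.02, effect = effect_equal(0.05)))
expected_moments <- function(params) {
  p <- params
  ea <- p$effect$mean
  ea2 <- p$effect$mean_sq
  if (p$u == 0) {
    return(list(delta_m = 0, v_m = 0, e_a = ea, e_a_sq = ea2,
                approx_error = 0))
  }
  if (p$action == "additive") {
    list(delta_m = -p$u * ea, v_m = 2 * p$u * ea2, e_a = ea, e_a_sq = ea2,
         approx_error = 0)
  } else {
    lambda <- p$u * p$t / 4
    # compound-Poisson moments of g = prod(1 - 4a_i), ignoring the floor at 0
    m1 <- exp(-lambda * 4 * ea)
    m2 <- exp(-lambda * (8 * ea - 16 * ea2))
    dm <- (m1 - 1) / p$t
    vm <- (m2 - m1^2) / (2 * p$t)
    list(delta_m = dm, v_m = vm, e_a = ea, e_a_sq = ea2,
         approx_error = abs(dm + p$u * ea) / (p$u * ea))
  }
}
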