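# Shared fixtures and independent oracles, all built in code.

# A tiny deterministic assay: 1 line, 2 pseudolines + 2 MA sublines, 2 reps.
make_toy_table <- function(t = 150L) {
  d <- tibble::tibble(
    line_id = "504",
    fitness_class = "low",
    treatment = rep(c("control", "ma"), each = 4),
    subline_id = rep(c("P1", "P1", "P2", "P2", "S1", "S1", "S2", "S2")),
    replicate_id = rep(c("r1", "r2"), 4),
    gmax = rep(c(0L, t), each = 4),
    d1 = c(30L, 28L, 32L, 30L, 20L, 18L, 25L, 23L),
    d2 = c(10L, 12L, 8L, 10L, 6L, 8L, 7L, 9L),
    d3 = c(2L, 0L, 1L, 3L, 1L, 0L, 2L, 1L)
  )
  assay_table(d, t = t)
}

# fitness records with explicit w values (bypassing the demographic step)
make_records <- function(w_ctrl, w_ma, line_id = "L1", assay_id = "a1",
                         fitness_class = "low") {
  stopifnot(is.list(w_ctrl), is.list(w_ma))
  mk <- function(wl, treat, prefix) {
    g <- if (treat == "control") 0L else 150L
    purrr::imap_dfr(wl, function(w, i) {
      tibble::tibble(
        assay_id = assay_id, line_id = line_id,
        fitness_class = fitness_class, treatment = treat,
        subline_id = paste0(prefix, i),
        replicate_id = paste0("r", seq_along(w)),
        gmax = g, w = w)
    })
  }
  dplyr::bind_rows(mk(w_ctrl, "control", "P"), mk(w_ma, "ma", "S"))
}

# Independent one-way ANOVA oracle via aov(): mean squares read off the
# aov table, components from the textbook balanced formulas.
aov_components_oracle <- function(y, g, k) {
  # k = replicates per group (balanced designs only)
  fit <- stats::aov(y ~ factor(g))
  ms <- summary(fit)[[1]][["Mean Sq"]]
  c(v_subline = max(0, (ms[1] - ms[2]) / k), v_residual = ms[2])
}

# Brute-force bisection on a fine grid for the Euler-Lotka root.
bisect_r0_oracle <- function(lxmx, ages, lo = -10, hi = 10, tol = 1e-12) {
  f <- function(r) sum(exp(-r * ages) * lxmx) - 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
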