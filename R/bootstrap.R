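#' Bootstrap settings
#'
#' @param n_reps Number of bootstrap resamples (default 1000).
#' @param seed Optional integer seed; a given seed makes the bootstrap
#'   bit-reproducible.
#' @param ci_level Confidence level for percentile intervals (default 0.95).
#' @return A list of class `bootstrap_settings`. The resampling unit is fixed
#'   at the subline: all replicates of a drawn subline enter the resample
#'   together.
#' @export
bootstrap_settings <- function(n_reps = 1000L, seed = NULL, ci_level = 0.95) {
  stopifnot(n_reps >= 1, ci_level > 0, ci_level < 1)
  structure(list(n_reps = as.integer(n_reps), seed = seed,
                 ci_level = ci_level, resample_unit = "subline"),
            class = "bootstrap_settings")
}

#' Subline-level bootstrap of one line's mutational parameters
#'
#' Resamples sublines with replacement, separately within the control and MA
#' strata of one first-order line (all replicates of a drawn subline are kept
#' together). Per resample: the control and MA means are recomputed from the
#' unweighted subline means; one-way variance components are refitted per
#' stratum; \eqn{\Delta M_w = (\bar w_{MA}-\bar w_0)/(\bar w_0 t)}; and
#' \eqn{V_M = (V_{L,MA}-V_{L,0})/2t} floored at zero, on both the ancestral
#' (raw `w`) scale and the own-group-mean (`w*`) scale. Point estimates are
#' the means over resamples; confidence intervals are the middle
#' `ci_level` percentile interval. The Bateman-Mukai estimates are computed
#' from the bootstrap-mean \eqn{\Delta M} and ancestor-scale \eqn{V_M}
#' (a ratio of means, not a mean of per-resample ratios, which is how the
#' method is defined and is far better behaved).
#'
#' @param records Fitness records for one line in one assay: a data frame
#'   with columns `treatment`, `subline_id`, `w` (e.g. one line's rows of a
#'   [relative_fitness()] table).
#' @param t Generations of MA; taken from the records' attribute if present.
#' @param settings A [bootstrap_settings()].
#' @param components_method `"moments"` (closed form, default) or `"reml"`
#'   for the per-resample variance components.
#'
#' @return An object of class `ma_line_boot`: list with `estimates`
#'   (tibble: quantity, estimate, ci_lo, ci_hi), `bm` (the Bateman-Mukai
#'   tibble), `draws` (one row per resample), `settings`, `t`, `line_id`.
#'   `tidy()` returns the estimates table.
#' @export
bootstrap_line <- function(records, t = NULL,
                           settings = bootstrap_settings(),
                           components_method = c("moments", "reml")) {
  components_method <- match.arg(components_method)
  t <- t %||% attr(records, "t")
  if (is.null(t)) abort("`t` (generations of MA) is required.")
  line_id <- unique(as.character(records$line_id %||% "line"))
  if (length(line_id) > 1) {
    abort("`records` must contain a single line; see estimate_lines().")
  }
  ctrl <- records[records$treatment == "control", ]
  ma <- records[records$treatment == "ma", ]
  subs0 <- split(ctrl$w, ctrl$subline_id)
  subsM <- split(ma$w, ma$subline_id)
  if (length(subs0) < 2 || length(subsM) < 2) {
    abort("Need at least two control pseudolines and two MA sublines.")
  }

  one_rep <- function() {
    i0 <- sample.int(length(subs0), replace = TRUE)
    iM <- sample.int(length(subsM), replace = TRUE)
    y0 <- subs0[i0]
    yM <- subsM[iM]
    wbar0 <- mean(vapply(y0, mean, 0))
    wbarM <- mean(vapply(yM, mean, 0))
    g0 <- rep(seq_along(i0), lengths(y0))
    gM <- rep(seq_along(iM), lengths(yM))
    vc0 <- vc_fit_(unlist(y0, use.names = FALSE), g0, components_method)
    vcM <- vc_fit_(unlist(yM, use.names = FALSE), gM, components_method)
    dm <- (wbarM - wbar0) / wbar0 / t
    c(delta_m = dm,
      v_l_0 = vc0[[1]], v_l_ma = vcM[[1]],
      v_e_0 = vc0[[2]], v_e_ma = vcM[[2]],
      v_m = max(0, (vcM[[1]] - vc0[[1]]) / (2 * t)),
      v_m_star = max(0, (vcM[[1]] / wbarM^2 - vc0[[1]] / wbar0^2) / (2 * t)),
      v_e_star_0 = vc0[[2]] / wbar0^2,
      v_e_star_ma = vcM[[2]] / wbarM^2,
      wbar_0 = wbar0, wbar_ma = wbarM)
  }

  run <- function() {
    draws <- matrix(NA_real_, settings$n_reps, 11)
    for (r in seq_len(settings$n_reps)) draws[r, ] <- one_rep()
    draws
  }
  draws <- if (is.null(settings$seed)) run() else {
    withr::with_seed(settings$seed, run())
  }
  colnames(draws) <- c("delta_m", "v_l_0", "v_l_ma", "v_e_0", "v_e_ma",
                       "v_m", "v_m_star", "v_e_star_0", "v_e_star_ma",
                       "wbar_0", "wbar_ma")
  draws <- as_tibble(draws)
  denom <- (draws$v_e_star_0 + draws$v_e_star_ma) / 2
  draws$h2_m <- ifelse(denom > 0, draws$v_m_star / denom, NA_real_)

  alpha <- (1 - settings$ci_level) / 2
  est <- purrr::map_dfr(names(draws), function(q) {
    x <- draws[[q]][!is.na(draws[[q]])]
    if (!length(x)) {
      return(tibble(quantity = q, estimate = NA_real_,
                    ci_lo = NA_real_, ci_hi = NA_real_))
    }
    tibble(quantity = q, estimate = mean(x),
           ci_lo = unname(quantile(x, alpha)),
           ci_hi = unname(quantile(x, 1 - alpha)))
  })
  bm <- bateman_mukai(mean(draws$delta_m), mean(draws$v_m))
  structure(list(estimates = est, bm = bm, draws = draws,
                 settings = settings, t = t, line_id = line_id,
                 n_boot = settings$n_reps),
            class = "ma_line_boot")
}

vc_fit_ <- function(y, g, method) {
  if (var(y) == 0) return(c(0, 0))
  if (method == "moments") {
    vc_moments_(y, g)
  } else {
    fit <- suppressMessages(lme4::lmer(
      y ~ 1 + (1 | g), REML = TRUE, data = data.frame(y = y, g = g),
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore")))
    vc <- as.data.frame(lme4::VarCorr(fit))
    c(vc$vcov[vc$grp == "g"], vc$vcov[vc$grp == "Residual"])
  }
}

#' @export
print.ma_line_boot <- function(x, ...) {
  cat(sprintf("Line %s: %d bootstrap resamples (subline level), t = %d\n\n",
              x$line_id, x$n_boot, x$t))
  print(x$estimates)
  cat("\nBateman-Mukai (from bootstrap means):\n")
  print(x$bm)
  invisible(x)
}

#' @rdname bootstrap_line
#' @param x An `ma_line_boot` object.
#' @param ... Unused.
#' @method tidy ma_line_boot
#' @export
tidy.ma_line_boot <- function(x, ...) x$estimates

#' Per-line mutational parameter estimates across an experiment
#'
#' Runs [bootstrap_line()] for every line x assay in a fitness-record table
#' and assembles the per-line estimates (the per-line analogue of the
#' summary tables of an MA study).
#'
#' @param records Fitness records ([relative_fitness()] output, possibly
#'   row-bound over assays; must contain `assay_id`, `line_id`,
#'   `fitness_class`, `treatment`, `subline_id`, `w`).
#' @param t Generations of MA.
#' @inheritParams bootstrap_line
#' @return A tibble with one row per line x assay: means of control and MA
#'   fitness, `delta_m` with CI, `v_m` (ancestor scale), `v_m_star`,
#'   `v_e_star_0`, `v_e_star_ma`, `h2_m`, `u_min`, `e_a_max`, `bm_note`.
#'   Per-line `ma_line_boot` objects are attached as attribute `boots`.
#' @export
estimate_lines <- function(records, t = NULL,
                           settings = bootstrap_settings(),
                           components_method = "moments") {
  t <- t %||% attr(records, "t")
  if (!"assay_id" %in% names(records)) records$assay_id <- "assay1"
  keys <- dplyr::distinct(as_tibble(records), .data$assay_id, .data$line_id,
                          .data$fitness_class)
  boots <- purrr::pmap(keys, function(assay_id, line_id, fitness_class) {
    d <- records[records$assay_id == assay_id & records$line_id == line_id, ]
    bootstrap_line(d, t = t, settings = settings,
                   components_method = components_method)
  })
  grab <- function(b, q) {
    e <- b$estimates[b$estimates$quantity == q, ]
    c(e$estimate, e$ci_lo, e$ci_hi)
  }
  out <- keys
  for (q in c("delta_m", "v_m", "v_m_star", "h2_m", "wbar_0", "wbar_ma")) {
    m <- vapply(boots, grab, numeric(3), q = q)  # 3 x n_lines
    out[[q]] <- m[1, ]
    if (q %in% c("delta_m", "v_m_star")) {
      out[[paste0(q, "_lo")]] <- m[2, ]
      out[[paste0(q, "_hi")]] <- m[3, ]
    }
  }
  out$v_e_star_0 <- vapply(boots, function(b) grab(b, "v_e_star_0")[1], 0)
  out$v_e_star_ma <- vapply(boots, function(b) grab(b, "v_e_star_ma")[1], 0)
  out$u_min <- vapply(boots, function(b) b$bm$u_min, 0)
  out$e_a_max <- vapply(boots, function(b) b$bm$e_a_max, 0)
  out$bm_note <- vapply(boots, function(b) {
    if (is.na(b$bm$note)) NA_character_ else b$bm$note
  }, "")
  structure(out, boots = boots, t = t,
            class = c("ma_line_estimates", class(tibble())))
}
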