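#' One-way variance components (among-subline / residual)
#'
#' Estimates the among-group and within-group variance components of the
#' linear model `value = group + residual`, the decomposition underlying the
#' among-subline ("line") and environmental components of fitness variance.
#'
#' The `"moments"` method uses the one-way ANOVA estimator with the standard
#' unbalanced coefficient
#' \eqn{k_0 = (N - \sum n_i^2 / N) / (a - 1)}:
#' \eqn{\hat\sigma^2_A = (MS_A - MS_W)/k_0}, truncated at zero. The `"reml"`
#' method maximizes the restricted normal likelihood (via [lme4::lmer()]);
#' on balanced data the two agree exactly whenever the untruncated moments
#' estimate is non-negative.
#'
#' @param data A data frame.
#' @param value,group Columns (unquoted) holding the response and the
#'   grouping factor (e.g. `w_star` and `subline_id`).
#' @param method `"moments"` (closed form) or `"reml"`.
#'
#' @return A one-row tibble: `v_subline` (among-group component, >= 0),
#'   `v_residual`, `method`, `n_sublines`, `n_total`, `loglik` (REML only,
#'   `NA` for moments).
#' @export
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 2), y = c(0, 0, 2, 2))
#' fit_oneway_components(d, y, g)
fit_oneway_components <- function(data, value, group,
                                  method = c("moments", "reml")) {
  method <- match.arg(method)
  y <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  if (anyNA(y)) abort("`value` contains missing values.")
  a <- length(unique(g))
  if (a < 2) abort("Need at least two sublines to separate components.")
  if (var(y) == 0) {
    warn("Zero total variance: both components are 0.")
    return(tibble(v_subline = 0, v_residual = 0, method = method,
                  n_sublines = a, n_total = length(y), loglik = NA_real_))
  }
  if (method == "moments") {
    vc <- vc_moments_(y, g)
    tibble(v_subline = vc[["v_subline"]], v_residual = vc[["v_residual"]],
           method = method, n_sublines = a, n_total = length(y),
           loglik = NA_real_)
  } else {
    fit <- lme4::lmer(y ~ 1 + (1 | g), REML = TRUE,
                      data = data.frame(y = y, g = g),
                      control = lme4::lmerControl(
                        calc.derivs = FALSE,
                        check.conv.singular = "ignore"))
    vc <- as.data.frame(lme4::VarCorr(fit))
    tibble(v_subline = vc$vcov[vc$grp == "g"],
           v_residual = vc$vcov[vc$grp == "Residual"],
           method = method, n_sublines = a, n_total = length(y),
           loglik = as.numeric(logLik(fit)))
  }
}

# closed-form one-way components on bare vectors (hot path for the bootstrap)
vc_moments_ <- function(y, g) {
  ni <- tabulate(factor(g))
  N <- length(y)
  a <- length(ni)
  m <- rowsum(y, g) / ni
  gm <- sum(y) / N
  ss_among <- sum(ni * (m - gm)^2)
  ss_within <- sum((y - m[match(g, sort(unique(g)))])^2)
  ms_among <- ss_among / (a - 1)
  ms_within <- ss_within / (N - a)
  k0 <- (N - sum(ni^2) / N) / (a - 1)
  c(v_subline = max(0, (ms_among - ms_within) / k0), v_residual = ms_within)
}

n_ranef_terms <- function(formula) {
  length(lme4::findbars(formula))
}

fit_mixed_or_lm <- function(formula, data, REML = TRUE) {
  if (n_ranef_terms(formula) > 0) {
    lme4::lmer(formula, data = data, REML = REML,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore"))
  } else {
    stats::lm(formula, data = data)
  }
}

loglik_reml <- function(fit) {
  if (inherits(fit, "lm")) as.numeric(logLik(fit, REML = TRUE))
  else as.numeric(logLik(fit))
}

#' Likelihood-ratio test for variance components
#'
#' Fits a full and a nested reduced mixed model (both by REML; the fixed
#' effects must be identical so the restricted likelihoods are comparable)
#' and compares twice the log-likelihood difference to a chi-square with
#' degrees of freedom equal to the difference in the number of variance
#' parameters. Because a variance component sits on the boundary of its
#' parameter space under the null, a 50:50 chi-square mixture reference is
#' available via `boundary = "mixture"`; the plain chi-square is the default.
#'
#' @param data A data frame.
#' @param full,reduced Model formulas in `lme4` syntax; `reduced` must drop
#'   one or more random-effect terms of `full` and keep the same fixed part.
#'   A reduced model with no random effects is fitted by `lm()` (restricted
#'   likelihood).
#' @param boundary `"chisq"` or `"mixture"`.
#'
#' @return A one-row tibble: `chi2`, `df`, `p`.
#' @export
lrt_variance <- function(data, full, reduced, boundary = c("chisq", "mixture")) {
  boundary <- match.arg(boundary)
  fx_full <- lme4::nobars(full)
  fx_red <- lme4::nobars(reduced)
  if (!identical(deparse(fx_full), deparse(fx_red))) {
    abort("Non-nested specs: fixed effects of `full` and `reduced` differ.")
  }
  re_full <- vapply(lme4::findbars(full), deparse, "")
  re_red <- vapply(lme4::findbars(reduced), deparse, "")
  if (!all(re_red %in% re_full)) {
    abort("Non-nested specs: `reduced` has random terms not in `full`.")
  }
  df <- length(re_full) - length(re_red)
  ll_full <- loglik_reml(fit_mixed_or_lm(full, data))
  ll_red <- loglik_reml(fit_mixed_or_lm(reduced, data))
  chi2 <- max(0, 2 * (ll_full - ll_red))
  p <- if (df == 0) {
    1  # identical specs: no restriction is being tested
  } else if (boundary == "chisq") {
    pchisq(chi2, df, lower.tail = FALSE)
  } else if (df == 1) {
    0.5 * pchisq(chi2, 1, lower.tail = FALSE) + 0.5 * (chi2 <= 0)
  } else {
    0.5 * pchisq(chi2, df, lower.tail = FALSE) +
      0.5 * pchisq(chi2, df - 1, lower.tail = FALSE)
  }
  tibble(chi2 = chi2, df = df, p = p)
}

#' Hierarchical model comparing mutational decay between fitness groups
#'
#' Fits the assay-wide mixed model of relative fitness on generations of MA:
#' fixed effects `Gmax` (the common per-generation decay, whose slope is
#' \eqn{\Delta M_w}) and `Gmax x Fitness` (the decay difference between
#' high- and low-fitness lines); random effects for first-order line (MA
#' stratum only) and subline, with a separate among-subline variance per
#' Fitness x Treatment stratum. Scaling each line's control mean to 1 is
#' equivalent to omitting the Fitness main effect and constraining the
#' among-line variance of the controls to zero, which is how the model is
#' parameterized here. Fixed-effect tests use Satterthwaite degrees of
#' freedom (via \pkg{lmerTest}).
#'
#' The default engine (`"lmer"`) pools the residual variance across strata;
#' `engine = "glmmTMB"` additionally estimates a separate residual variance
#' per stratum (`dispformula = ~ stratum`) with Wald z tests for the fixed
#' effects. Note that when a variance component is estimated on the boundary
#' (zero) the glmmTMB Hessian is singular and the Wald standard errors come
#' back `NA`; point estimates and variance components remain valid, but for
#' tests prefer the default engine, whose Satterthwaite machinery tolerates
#' boundary fits.
#'
#' @param records Fitness records ([relative_fitness()] output, possibly
#'   row-bound over assays) containing both fitness groups and both
#'   treatments. Rows with `fitness_class == "ancestor"` are dropped.
#' @param engine `"lmer"` (default) or `"glmmTMB"`.
#'
#' @return An object of class `ma_hier_fit` with [tidy()] and [glance()]
#'   methods; `tidy(fit)` gives the fixed-effect tests, and
#'   `tidy(fit, effects = "ran_pars")` the per-stratum variance components.
#' @export
fit_hierarchical_model <- function(records, engine = c("lmer", "glmmTMB")) {
  engine <- match.arg(engine)
  d <- dplyr::filter(as_tibble(records), .data$fitness_class != "ancestor")
  d$fitness_class <- factor(d$fitness_class, levels = c("high", "low"))
  need <- tidyr::expand_grid(fitness_class = c("high", "low"),
                             treatment = c("control", "ma"))
  have <- dplyr::distinct(d, .data$fitness_class, .data$treatment)
  miss <- dplyr::anti_join(
    need, dplyr::mutate(have, fitness_class = as.character(.data$fitness_class)),
    by = c("fitness_class", "treatment"))
  if (nrow(miss)) {
    abort(paste0("Missing stratum(s): ",
                 paste(miss$fitness_class, miss$treatment, sep = ":",
                       collapse = ", ")))
  }
  aid <- if ("assay_id" %in% names(d)) d$assay_id else "a1"
  d$stratum <- paste(d$fitness_class, d$treatment, sep = "_")
  d$line_key <- paste(aid, d$line_id)
  d$subline_key <- paste(aid, d$line_id, d$treatment, d$subline_id)
  for (s in unique(d$stratum)) d[[paste0("in_", s)]] <- as.numeric(d$stratum == s)

  sub_terms <- paste0("(0 + in_", unique(d$stratum), " | subline_key)")
  line_terms <- c("(0 + in_high_ma | line_key)", "(0 + in_low_ma | line_key)")
  rhs <- paste(c("gmax", "gmax:fitness_class", line_terms, sub_terms),
               collapse = " + ")
  form <- as.formula(paste("w ~", rhs))

  if (engine == "lmer") {
    fit <- lmerTest::lmer(form, data = d, REML = TRUE,
                          control = lme4::lmerControl(
                            calc.derivs = FALSE,
                            check.conv.singular = "ignore"))
  } else {
    if (!requireNamespace("glmmTMB", quietly = TRUE)) {
      abort("engine = 'glmmTMB' requires the glmmTMB package.")
    }
    fit <- glmmTMB::glmmTMB(form, data = d, dispformula = ~ 0 + stratum,
                            REML = TRUE)
  }
  structure(list(fit = fit, engine = engine, data = d), class = "ma_hier_fit")
}

#' @export
print.ma_hier_fit <- function(x, ...) {
  cat("Hierarchical MA fitness model (", x$engine, ")\n\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_hierarchical_model
#' @param x An `ma_hier_fit` object.
#' @method tidy ma_hier_fit
#' @param effects `"fixed"` for the Gmax slope and Gmax x Fitness tests,
#'   `"ran_pars"` for per-stratum variance components.
#' @param ... Unused.
#' @export
tidy.ma_hier_fit <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects)
  relabel <- function(unit, dummy) {
    unit <- ifelse(grepl("^subline_key", unit), "subline",
                   ifelse(grepl("^line_key", unit), "line", unit))
    paste0(unit, ":", sub("^in_", "", dummy))
  }
  if (effects == "fixed") {
    if (x$engine == "lmer") {
      s <- coef(summary(x$fit))  # matrix; keeps the spaced column names
      tibble(term = rownames(s), estimate = s[, "Estimate"],
             std_error = s[, "Std. Error"], df = s[, "df"],
             statistic = s[, "t value"], p_value = s[, "Pr(>|t|)"])
    } else {
      s <- coef(summary(x$fit))$cond
      tibble(term = rownames(s), estimate = s[, "Estimate"],
             std_error = s[, "Std. Error"], df = NA_real_,
             statistic = s[, "z value"], p_value = s[, "Pr(>|z|)"])
    }
  } else {
    if (x$engine == "lmer") {
      vc <- as.data.frame(lme4::VarCorr(x$fit))
      tibble(term = ifelse(is.na(vc$var1), vc$grp,
                           relabel(vc$grp, vc$var1)),
             variance = vc$vcov)
    } else {
      vc <- glmmTMB::VarCorr(x$fit)$cond
      out <- tibble(
        term = relabel(names(vc),
                       vapply(vc, function(m) rownames(m)[1], "")),
        variance = vapply(vc, function(m) m[1, 1], 0))
      # gaussian dispformula coefficients are per-stratum log residual
      # variances
      disp <- glmmTMB::fixef(x$fit)$disp
      dplyr::bind_rows(out, tibble(
        term = paste0("residual:", sub("^stratum", "", names(disp))),
        variance = exp(unname(disp))))
    }
  }
}

#' @rdname fit_hierarchical_model
#' @method glance ma_hier_fit
#' @export
glance.ma_hier_fit <- function(x, ...) {
  ll <- logLik(x$fit)
  tibble(logLik = as.numeric(ll), df = attr(ll, "df"),
         nobs = nrow(x$data), engine = x$engine)
}
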