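#' Per-generation change in mean relative fitness
#'
#' \eqn{\Delta M_w = (\bar w_{MA} - \bar w_0) / (\bar w_0 \, t)}: the
#' per-generation mutational decay of mean relative fitness, negative when
#' fitness declines. With the control mean defined equal to 1 this is
#' \eqn{(\bar w_{MA} - 1)/t}.
#'
#' @param w_ma_mean Mean relative fitness of the MA sublines (vectorized).
#' @param t Generations of MA (> 0).
#' @param w_control_mean Mean control fitness; 1 by definition.
#' @return \eqn{\Delta M_w}, per generation.
#' @export
#' @examples
#' delta_M(0.58, 150)  # -2.80e-3: a ~0.3% fitness loss per generation
delta_M <- function(w_ma_mean, t, w_control_mean = 1) {
  if (any(t <= 0)) abort("`t` must be a positive number of generations.")
  ((w_ma_mean - w_control_mean) / w_control_mean) / t
}

#' Per-generation mutational variance
#'
#' \eqn{V_M = \max(0, (V_{L,MA} - V_{L,0}) / (2t))}: half the per-generation
#' excess of the among-MA-subline variance component over the among-control
#' (pseudoline) component. Negative excess is floored at zero -- sampling can
#' put the MA component below the control component, which carries no
#' information about mutational input. Both input components must already be
#' truncated at zero (as [fit_oneway_components()] guarantees).
#'
#' @param v_l_ma,v_l_0 Among-subline variance components of the MA and control
#'   groups (non-negative; vectorized).
#' @param t Generations of MA (> 0).
#' @param scale Which mean standardization the input components carry:
#'   `"control_mean"` (ancestor scale; the scale on which Bateman-Mukai
#'   estimates are consistent) or `"ma_mean"` (own-group scale, the
#'   opportunity-for-selection form). Recorded as an attribute.
#' @return Non-negative \eqn{V_M}, with attribute `scale`.
#' @export
v_m <- function(v_l_ma, v_l_0, t, scale = c("control_mean", "ma_mean")) {
  scale <- match.arg(scale)
  if (any(t <= 0)) abort("`t` must be a positive number of generations.")
  if (any(v_l_ma < 0) || any(v_l_0 < 0)) {
    abort("Variance components must be pre-truncated at zero.")
  }
  structure(pmax(0, (v_l_ma - v_l_0) / (2 * t)), scale = scale)
}

#' Bateman-Mukai bounds on the genomic mutation rate and mean effect
#'
#' Under the equal-effects assumption, \eqn{U_{MIN} = 2\Delta M^2 / V_M} is a
#' downwardly biased estimate of the genomic (diploid) mutation rate for the
#' trait and \eqn{E[a]_{MAX} = V_M / (2\Delta M)} an upwardly biased estimate
#' of the average mutational effect. Both require \eqn{V_M} on the scale of
#' the common ancestor. When \eqn{\Delta M \ge 0} (no decline) or
#' \eqn{V_M = 0} no meaningful estimate exists and the pair is returned as
#' flagged missing rather than a numeric sentinel. An estimate with
#' \eqn{|E[a]_{MAX}| > 1} is returned but flagged: an average effect on
#' relative fitness cannot exceed 1 in magnitude.
#'
#' @param delta_m \eqn{\Delta M} per generation (vectorized).
#' @param v_m_control_scale \eqn{V_M} on the ancestral-mean scale.
#' @return A tibble: `delta_m`, `v_m`, `u_min`, `e_a_max`, `defined`, `note`.
#' @export
#' @examples
#' bateman_mukai(-2.84e-3, 1.84e-4)  # U >= 0.09, |a| <= 0.04
bateman_mukai <- function(delta_m, v_m_control_scale) {
  vm <- as.numeric(v_m_control_scale)
  n <- max(length(delta_m), length(vm))
  delta_m <- rep_len(delta_m, n)
  vm <- rep_len(vm, n)
  if (any(vm < 0, na.rm = TRUE)) abort("`v_m_control_scale` must be >= 0.")
  ok <- !is.na(delta_m) & !is.na(vm) & delta_m < 0 & vm > 0
  u <- ifelse(ok, 2 * delta_m^2 / vm, NA_real_)
  e <- ifelse(ok, vm / (2 * delta_m), NA_real_)
  note <- dplyr::case_when(
    is.na(delta_m) | is.na(vm) ~ "missing input",
    delta_m >= 0 ~ "delta_m >= 0: no deleterious-effect estimate",
    vm == 0 ~ "v_m = 0: mutation rate unbounded below",
    abs(e) > 1 ~ "nonsensical: |e_a_max| > 1",
    .default = NA_character_
  )
  tibble(delta_m = delta_m, v_m = vm, u_min = u, e_a_max = e,
         defined = ok, note = note)
}

#' Mutational heritability
#'
#' \eqn{h^2_M = V_{M*} / \bar V_{E*}}, with the environmental variance taken
#' as the average of the control and MA within-subline components.
#'
#' @param v_m_star Own-group-mean-standardized mutational variance.
#' @param v_e_control,v_e_ma Within-subline (environmental) components of the
#'   control and MA groups, same standardization.
#' @return \eqn{h^2_M}, per generation.
#' @export
#' @examples
#' mutational_heritability(4.76e-4, 0.28, 0.39)  # 1.42e-3
mutational_heritability <- function(v_m_star, v_e_control, v_e_ma) {
  denom <- (v_e_control + v_e_ma) / 2
  if (any(denom <= 0)) abort("Environmental variance must be positive.")
  v_m_star / denom
}

#' Exact probability that the k most extreme lines are all low-fitness
#'
#' Under exchangeability of line ranks between the two fitness groups, the
#' probability that the `k` most extreme ranks (e.g. the fastest-declining
#' lines) all fall in the low-fitness group is
#' \eqn{\binom{n_{low}}{k} / \binom{n_{low}+n_{high}}{k}}.
#'
#' @param n_low,n_high Group sizes.
#' @param k Number of extreme ranks considered (`k <= n_low + n_high`).
#' @return A probability; 0 when `k > n_low`.
#' @export
#' @examples
#' exact_rank_probability(5, 5, 3)  # 10/120 = 0.0833
exact_rank_probability <- function(n_low, n_high, k) {
  if (k > n_low + n_high) abort("`k` cannot exceed the number of lines.")
  if (k > n_low) return(0)
  choose(n_low, k) / choose(n_low + n_high, k)
}

#' Group summaries of per-line estimates
#'
#' Collapses per-assay line estimates to per-line values (a line assayed
#' more than once contributes the unweighted mean of its per-assay values,
#' undefined values dropped), then summarizes each fitness group and all
#' lines together by the unweighted mean and median of the line values.
#'
#' @param estimates A data frame with one row per line x assay.
#' @param ... Value columns to summarize (tidy-select).
#' @param line,group Columns identifying the line and its fitness group.
#' @return A tibble with one row per group (`"high"`, `"low"`, `"all"`) per
#'   value column: `group`, `quantity`, `mean`, `median`, `n_lines`.
#' @export
group_summary <- function(estimates, ..., line = line_id, group = fitness_class) {
  vals <- names(dplyr::select(dplyr::as_tibble(estimates), ...))
  if (!length(vals)) abort("No value columns selected.")
  per_line <- estimates |>
    dplyr::group_by(line = {{ line }}, group = {{ group }}) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(vals),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(vals),
                                ~ ifelse(is.nan(.x), NA_real_, .x)))
  if (any(!per_line$group %in% c("high", "low"))) {
    abort("Fitness groups must be 'high' or 'low'.")
  }
  if (!all(c("high", "low") %in% per_line$group)) {
    abort("Empty fitness group: need lines in both 'high' and 'low'.")
  }
  long <- tidyr::pivot_longer(per_line, dplyr::all_of(vals),
                              names_to = "quantity")
  one <- function(d, label) {
    d |>
      dplyr::group_by(quantity = .data$quantity) |>
      dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                       median = median(.data$value, na.rm = TRUE),
                       n_lines = sum(!is.na(.data$value)), .groups = "drop") |>
      dplyr::mutate(group = label, .before = 1)
  }
  out <- dplyr::bind_rows(
    one(dplyr::filter(long, .data$group == "high"), "high"),
    one(dplyr::filter(long, .data$group == "low"), "low"),
    one(long, "all")
  )
  # a quantity undefined for every line of a group (e.g. u_min when no line
  # declined) summarizes to NA, not an error
  out$mean[out$n_lines == 0] <- NA_real_
  out$median[out$n_lines == 0] <- NA_real_
  out$quantity <- factor(out$quantity, levels = vals)
  dplyr::arrange(out, .data$quantity, .data$group) |>
    dplyr::mutate(quantity = as.character(.data$quantity))
}
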