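#' Mean control reproduction schedule
#'
#' Averages the day-structured reproductive output (the survivorship x
#' fecundity products \eqn{l_x m_x}) over control individuals. The mean
#' schedule is the input to the Euler-Lotka solve for the control intrinsic
#' rate of increase.
#'
#' @param x An [assay_table()].
#' @param weight_by_line If `TRUE`, average per-line mean schedules (each
#'   control line weighted equally); default averages over individuals.
#'
#' @return A tibble with columns `age` and `lxmx`.
#' @export
mean_control_schedule <- function(x, weight_by_line = FALSE) {
  ages <- attr(x, "ages")
  ctrl <- as_tibble(x)[x$treatment == "control", ]
  if (nrow(ctrl) == 0) abort("No control individuals in the assay table.")
  d <- as.matrix(ctrl[offspring_cols(x)])
  if (weight_by_line) {
    per_line <- rowsum(d, ctrl$line_id) / as.vector(table(ctrl$line_id))
    lxmx <- colMeans(per_line)
  } else {
    lxmx <- colMeans(d)
  }
  tibble(age = ages, lxmx = as.numeric(lxmx))
}

#' Solve for the control intrinsic rate of increase
#'
#' Finds the rate \eqn{r_0} at which the discounted mean control schedule sums
#' to one: \eqn{\sum_x e^{-r_0 x} \bar l_x \bar m_x = 1}. The left-hand side
#' is strictly decreasing in \eqn{r_0} (for a non-negative schedule with at
#' least one positive entry), so the root is unique. The root is bracketed in
#' `bracket` and refined by bisection, then polished by Newton steps to
#' residual tolerance `tol`.
#'
#' @param schedule A tibble from [mean_control_schedule()] (columns `age`,
#'   `lxmx`) or a numeric vector of \eqn{\bar l_x \bar m_x} values.
#' @param ages Ages, required when `schedule` is a bare numeric vector.
#' @param tol Absolute residual tolerance at the solution.
#' @param bracket Initial search interval for \eqn{r_0}, in day\eqn{^{-1}}.
#'
#' @return A list of class `control_rate` with elements `r0`, `converged`,
#'   and `residual` (the value of the discounted sum minus 1 at `r0`).
#' @export
#' @examples
#' solve_r0(c(0, 2, 0), ages = c(4.75, 5.75, 6.75))
solve_r0 <- function(schedule, ages = NULL, tol = 1e-10, bracket = c(-10, 10)) {
  if (is.data.frame(schedule)) {
    ages <- schedule$age
    lxmx <- schedule$lxmx
  } else {
    lxmx <- as.numeric(schedule)
    if (is.null(ages)) abort("`ages` is required for a bare numeric schedule.")
  }
  if (length(ages) != length(lxmx)) abort("schedule/ages length mismatch.")
  if (any(lxmx < 0)) abort("Schedule entries must be non-negative.")
  if (all(lxmx == 0)) abort("All-zero schedule: no root for r0 exists.")
  if (tol <= 0) abort("`tol` must be positive.")

  f <- function(r) sum(exp(-r * ages) * lxmx) - 1
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo); fhi <- f(hi)
  if (flo < 0 || fhi > 0) {
    abort(sprintf(
      "Root not bracketed in [%g, %g]: f(lo) = %.3g, f(hi) = %.3g.",
      lo, hi, flo, fhi))
  }
  root <- uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75)$root
  # Newton polish on the residual (f' = -sum(x * e^{-rx} lxmx), nonzero)
  for (i in 1:50) {
    res <- f(root)
    if (abs(res) <= tol) break
    root <- root + res / sum(ages * exp(-root * ages) * lxmx)
  }
  res <- f(root)
  structure(list(r0 = root, converged = abs(res) <= tol, residual = res),
            class = "control_rate")
}

#' @export
print.control_rate <- function(x, ...) {
  cat(sprintf("<control_rate r0 = %.8g /day, converged: %s, residual %.2e>\n",
              x$r0, x$converged, x$residual))
  invisible(x)
}

#' Demographic relative fitness per individual
#'
#' Computes absolute fitness `W` (lifetime reproductive output) and
#' demographic relative fitness
#' \eqn{w = \sum_x e^{-r_0 x} l_x m_x} for every worm in an assay, using a
#' single control-derived \eqn{r_0} for control and MA individuals alike. An
#' individual with no offspring has `w = 0` exactly. By construction the mean
#' `w` over the control individuals that defined \eqn{r_0} equals 1 (to
#' solver tolerance).
#'
#' @param x An [assay_table()].
#' @param r0 A [solve_r0()] result; computed from the table's controls when
#'   `NULL`.
#' @param weight_by_line Passed to [mean_control_schedule()] when `r0` is
#'   computed here.
#'
#' @return A tibble of fitness records: the design key columns plus `W` and
#'   `w`, with the assay's `r0`, `ages`, `t` and `assay_id` as attributes.
#' @export
relative_fitness <- function(x, r0 = NULL, weight_by_line = FALSE) {
  ages <- attr(x, "ages")
  if (is.null(r0)) {
    r0 <- solve_r0(mean_control_schedule(x, weight_by_line = weight_by_line))
  }
  if (!isTRUE(r0$converged)) abort("`r0` did not converge.")
  d <- as.matrix(as_tibble(x)[offspring_cols(x)])
  if (ncol(d) != length(ages)) abort("Count/ages length mismatch.")
  wts <- exp(-r0$r0 * ages)
  out <- as_tibble(x)[c("line_id", "fitness_class", "treatment", "subline_id",
                        "replicate_id", "gmax")]
  out$W <- as.integer(rowSums(d))
  out$w <- as.numeric(d %*% wts)
  out <- dplyr::mutate(out, assay_id = attr(x, "assay_id"), .before = 1)
  structure(out, r0 = r0, ages = ages, t = attr(x, "t"),
            assay_id = attr(x, "assay_id"),
            class = class(tibble()))
}

#' Rescale fitness to its own group mean
#'
#' Divides each individual's relative fitness by the mean of its group
#' (by default line x treatment), so every rescaled group mean equals 1.
#' The variance of the rescaled values is the variance of the raw values
#' divided by the squared mean -- the "opportunity for selection" scaling
#' appropriate for comparing variances between groups whose means differ.
#'
#' @param records A fitness-record tibble from [relative_fitness()] (or any
#'   data frame with a `w` column).
#' @param ... Grouping columns (tidy-select); default
#'   `assay_id, line_id, treatment` when present.
#'
#' @return `records` with an added `w_star` column.
#' @export
rescale_within_group <- function(records, ...) {
  grp <- sapply(rlang::enquos(...), as_name)
  if (!length(grp)) {
    grp <- intersect(c("assay_id", "line_id", "treatment"), names(records))
  }
  out <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(.gm = mean(.data$w)) |>
    dplyr::ungroup()
  if (any(out$.gm <= 0)) {
    abort("Degenerate group: a group mean of w is zero (or negative).")
  }
  out$w_star <- out$w / out$.gm
  out$.gm <- NULL
  out
}
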