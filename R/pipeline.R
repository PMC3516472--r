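#' Run the full MA estimation pipeline
#'
#' Orchestrates the analysis of one or more fitness assays: relative fitness
#' per assay (each assay gets its own control \eqn{r_0}), per-line bootstrap
#' estimates of \eqn{\Delta M_w}, \eqn{V_M}, \eqn{V_{M*}}, \eqn{h^2_M} and
#' the Bateman-Mukai parameters, group summaries with the unweighted-mean
#' rule for re-assayed lines, and (optionally) the hierarchical mixed model
#' comparing decay between fitness groups. A line assayed twice appears once
#' per assay in the per-line table and contributes the unweighted mean of
#' its per-assay estimates to the group summaries.
#'
#' @param tables An [assay_table()] or a (possibly named) list of them; list
#'   names override each table's `assay_id`.
#' @param settings A [bootstrap_settings()]; when `seed` is given it seeds
#'   the whole run (per-line bootstrap streams are drawn from it, so a rerun
#'   with the same config is bit-identical).
#' @param components_method `"moments"` or `"reml"` for the per-resample
#'   variance components.
#' @param hierarchical Fit the Gmax x Fitness mixed model (requires both
#'   fitness groups; skipped with a message otherwise).
#' @param seed Convenience override for `settings$seed`.
#' @param out_dir Optional directory; when given, writes `fitness.csv`,
#'   `line_estimates.csv`, `group_summary.csv`, and `results.json`
#'   (machine-readable summary including `r0` per assay and run metadata).
#'
#' @return A list of class `ma_pipeline_result`: `fitness` (per-worm
#'   records), `r0` (per assay), `line_estimates`, `group_summary`,
#'   `hierarchical` (`ma_hier_fit` or `NULL`), `config`.
#' @export
run_ma_pipeline <- function(tables, settings = bootstrap_settings(),
                            components_method = c("moments", "reml"),
                            hierarchical = TRUE, seed = NULL,
                            out_dir = NULL) {
  components_method <- match.arg(components_method)
  if (inherits(tables, "assay_table")) tables <- list(tables)
  if (!is.null(names(tables))) {
    for (i in seq_along(tables)) attr(tables[[i]], "assay_id") <- names(tables)[i]
  }
  if (!is.null(seed)) settings$seed <- seed

  # stage seeds drawn from one stream so stages are independently rerunnable
  stage_seeds <- if (!is.null(settings$seed)) {
    withr::with_seed(as.integer(settings$seed),
                     sample.int(.Machine$integer.max - 1L, 2L))
  } else NULL

  fitness <- purrr::map(tables, function(tab) {
    rec <- relative_fitness(tab)
    rec
  })
  r0s <- tibble(
    assay_id = vapply(fitness, function(f) attr(f, "assay_id"), ""),
    r0 = vapply(fitness, function(f) attr(f, "r0")$r0, 0),
    residual = vapply(fitness, function(f) attr(f, "r0")$residual, 0)
  )
  t_gen <- attr(tables[[1]], "t")
  records <- dplyr::bind_rows(fitness)

  line_settings <- settings
  if (!is.null(stage_seeds)) line_settings$seed <- NULL
  est <- if (!is.null(stage_seeds)) {
    withr::with_seed(stage_seeds[1],
                     estimate_lines(records, t = t_gen,
                                    settings = line_settings,
                                    components_method = components_method))
  } else {
    estimate_lines(records, t = t_gen, settings = line_settings,
                   components_method = components_method)
  }

  grp <- tryCatch(
    group_summary(dplyr::filter(est, .data$fitness_class != "ancestor"),
                  dplyr::all_of(c("delta_m", "v_m", "v_m_star", "h2_m",
                                  "u_min", "e_a_max"))),
    error = function(e) {
      inform(paste0("Group summary skipped: ", conditionMessage(e)))
      NULL
    })

  hier <- NULL
  if (hierarchical) {
    hier <- tryCatch(fit_hierarchical_model(records), error = function(e) {
      inform(paste0("Hierarchical model skipped: ", conditionMessage(e)))
      NULL
    })
  }

  res <- structure(list(
    fitness = records, r0 = r0s, line_estimates = est, group_summary = grp,
    hierarchical = hier,
    config = list(seed = settings$seed, n_boot = settings$n_reps,
                  ci_level = settings$ci_level,
                  components_method = components_method, t = t_gen,
                  n_assays = length(tables))
  ), class = "ma_pipeline_result")

  if (!is.null(out_dir)) write_pipeline_results(res, out_dir)
  res
}

#' @rdname run_ma_pipeline
#' @param res An `ma_pipeline_result`.
#' @export
write_pipeline_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(res$fitness, file.path(out_dir, "fitness.csv"))
  readr::write_csv(dplyr::select(res$line_estimates, -dplyr::any_of("boots")),
                   file.path(out_dir, "line_estimates.csv"))
  if (!is.null(res$group_summary)) {
    readr::write_csv(res$group_summary, file.path(out_dir, "group_summary.csv"))
  }
  out <- list(
    config = res$config,
    r0 = res$r0,
    line_estimates = dplyr::select(res$line_estimates, -dplyr::any_of("boots")),
    group_summary = res$group_summary,
    hierarchical = if (!is.null(res$hierarchical)) {
      list(fixed = tidy(res$hierarchical),
           varcomp = tidy(res$hierarchical, effects = "ran_pars"))
    },
    bm_flags = dplyr::filter(
      dplyr::select(res$line_estimates, dplyr::all_of(
        c("assay_id", "line_id", "bm_note"))), !is.na(.data$bm_note))
  )
  jsonlite::write_json(out, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}

#' @export
print.ma_pipeline_result <- function(x, ...) {
  cat(sprintf("MA pipeline: %d assay(s), %d worms, t = %d, %d bootstrap reps\n",
              x$config$n_assays, nrow(x$fitness), x$config$t, x$config$n_boot))
  cat("\nr0 per assay:\n"); print(x$r0)
  cat("\nPer-line estimates:\n")
  print(dplyr::select(x$line_estimates, dplyr::all_of(
    c("assay_id", "line_id", "fitness_class", "wbar_ma", "delta_m",
      "v_m_star", "u_min", "e_a_max"))))
  if (!is.null(x$group_summary)) {
    cat("\nGroup summary:\n"); print(x$group_summary, n = Inf)
  }
  invisible(x)
}
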