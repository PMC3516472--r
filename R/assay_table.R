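#' Column-name mapping for assay tables
#'
#' Delimited assay files have no standard header; `assay_cols()` records which
#' input columns hold each field of the nested design. The defaults define the
#' package's own documented header.
#'
#' @param line,fitness,treatment,subline,replicate,gmax Column names (length-1
#'   character) for the first-order line, fitness class, treatment, subline,
#'   replicate identifier, and generations of MA.
#' @param offspring Character vector of columns holding the offspring count for
#'   each reproduction day, in age order.
#' @param survived Optional character vector of per-day survival indicator
#'   columns (same length as `offspring`). When `NULL`, worms are assumed to
#'   have survived all reproduction days.
#'
#' @return A named list of class `assay_cols`.
#' @export
#' @examples
#' assay_cols()
#' assay_cols(replicate = "rep_id", offspring = c("day1", "day2", "day3"))
assay_cols <- function(line = "line", fitness = "fitness",
                       treatment = "treatment", subline = "subline",
                       replicate = "rep", offspring = c("d1", "d2", "d3"),
                       survived = NULL, gmax = "gmax") {
  if (!is.null(survived) && length(survived) != length(offspring)) {
    abort("`survived` must name one column per offspring day.")
  }
  structure(
    list(line = line, fitness = fitness, treatment = treatment,
         subline = subline, replicate = replicate, offspring = offspring,
         survived = survived, gmax = gmax),
    class = "assay_cols"
  )
}

offspring_cols <- function(x) {
  n <- length(attr(x, "ages"))
  paste0("d", seq_len(n))
}

survived_cols <- function(x) {
  n <- length(attr(x, "ages"))
  paste0("s", seq_len(n))
}

#' Construct an assay table
#'
#' An assay table holds one fitness assay: one row per worm, with its position
#' in the nested design (line / treatment / subline / replicate) and its
#' offspring counts on each reproduction day. Ages of the reproduction days
#' and the number of generations of MA separating MA sublines from their
#' ancestral controls are carried as attributes.
#'
#' @param x A data frame with columns `line_id`, `fitness_class`
#'   (`"high"`, `"low"` or `"ancestor"`), `treatment` (`"control"` or `"ma"`),
#'   `subline_id`, `replicate_id`, `gmax`, offspring-count columns
#'   `d1 ... dJ` and (optionally) survival columns `s1 ... sJ`.
#' @param ages Strictly increasing ages (days) of the reproduction days.
#'   Default `c(4.75, 5.75, 6.75)`.
#' @param t Generations of MA separating MA sublines from controls.
#' @param assay_id Identifier of the assay (re-assays of a line are separate
#'   assay tables with distinct `assay_id`s).
#' @param validate Validate invariants (default `TRUE`).
#'
#' @return A tibble of class `assay_table`.
#' @export
assay_table <- function(x, ages = c(4.75, 5.75, 6.75), t = 150L,
                        assay_id = "assay1", validate = TRUE) {
  x <- as_tibble(x)
  if (!all(diff(ages) > 0) || any(ages <= 0)) {
    abort("`ages` must be positive and strictly increasing.")
  }
  scols <- paste0("s", seq_along(ages))
  for (sc in scols) {
    if (!sc %in% names(x)) x[[sc]] <- TRUE
  }
  id_cols <- c("line_id", "fitness_class", "treatment", "subline_id",
               "replicate_id", "gmax")
  x <- x[, c(id_cols, paste0("d", seq_along(ages)), scols)]
  x$line_id <- as.character(x$line_id)
  x$subline_id <- as.character(x$subline_id)
  x$replicate_id <- as.character(x$replicate_id)
  x$gmax <- as.integer(x$gmax)
  out <- structure(x,
    ages = as.numeric(ages), t = as.integer(t), assay_id = assay_id,
    class = c("assay_table", class(tibble())))
  if (validate) validate_assay_table(out)
  out
}

#' Validate an assay table
#'
#' Checks the structural invariants of the nested design. Problems are
#' collected per row and reported together, so a bad file produces one
#' message naming every offending row rather than failing piecemeal.
#'
#' @param x An [assay_table()].
#' @param on_invalid `"error"` aborts with all problems listed; `"report"`
#'   returns the valid rows with a `problems` attribute (a tibble with
#'   `row` and `problem` columns). No row is ever silently dropped:
#'   `nrow(input) == nrow(accepted) + nrow(problems)`.
#'
#' @return `x` invisibly (or the accepted subset for `on_invalid = "report"`).
#' @export
validate_assay_table <- function(x, on_invalid = c("error", "report")) {
  on_invalid <- match.arg(on_invalid)
  ages <- attr(x, "ages")
  tt <- attr(x, "t")
  dcols <- offspring_cols(x)
  scols <- survived_cols(x)
  missing_cols <- setdiff(
    c("line_id", "fitness_class", "treatment", "subline_id", "replicate_id",
      "gmax", dcols), names(x))
  if (length(missing_cols)) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }

  probs <- list()
  note <- function(rows, what) {
    if (length(rows)) probs[[length(probs) + 1L]] <<-
        tibble(row = as.integer(rows), problem = what)
  }

  d <- as.matrix(x[dcols])
  s <- as.matrix(x[scols])
  note(which(apply(d, 1, function(z) any(!is.na(z) & z < 0))),
       "negative offspring count")
  note(which(apply(d, 1, function(z) any(!is.na(z) & z != floor(z)))),
       "non-integer offspring count")
  # a missing count on a day the worm survived is an error; a dead worm has
  # count 0 and survived FALSE for that day
  note(which(rowSums(is.na(d) & s) > 0),
       "missing offspring count on a survived day")
  note(which(rowSums(!s & !is.na(d) & d > 0) > 0),
       "positive offspring count on a non-survived day")
  note(which(!x$treatment %in% c("control", "ma")),
       "treatment must be 'control' or 'ma'")
  note(which(x$treatment == "control" & x$gmax != 0L),
       "control rows must have gmax = 0")
  note(which(x$treatment == "ma" & x$gmax != tt),
       sprintf("ma rows must have gmax = t = %d", tt))
  note(which(!x$fitness_class %in% c("high", "low", "ancestor")),
       "fitness_class must be 'high', 'low' or 'ancestor'")
  key <- paste(x$line_id, x$treatment, x$subline_id, x$replicate_id, sep = "\r")
  note(which(duplicated(key) | duplicated(key, fromLast = TRUE)),
       "duplicate (line, treatment, subline, replicate) key")

  if (!length(probs)) return(invisible(x))
  probs <- dplyr::arrange(dplyr::bind_rows(probs), .data$row)
  if (on_invalid == "error") {
    msg <- paste0("row ", probs$row, ": ", probs$problem)
    abort(c("Invalid assay table:", setNames(head(msg, 20), rep("x", min(20, length(msg))))))
  }
  bad <- unique(probs$row)
  accepted <- assay_table(as_tibble(x)[-bad, ], ages = ages, t = tt,
                          assay_id = attr(x, "assay_id"), validate = FALSE)
  attr(accepted, "problems") <- probs
  invisible(accepted)
}

#' Read an assay table from delimited text
#'
#' @param path Path to a CSV/TSV file.
#' @param col_map An [assay_cols()] mapping of file columns to fields.
#' @param delim Field delimiter; `NULL` (default) picks `","` for `.csv` and
#'   `"\t"` for `.tsv`/`.txt`, otherwise lets `readr` guess.
#' @param on_invalid Passed to [validate_assay_table()].
#' @inheritParams assay_table
#'
#' @return An [assay_table()].
#' @export
read_assay_table <- function(path, col_map = assay_cols(), delim = NULL,
                             ages = c(4.75, 5.75, 6.75), t = 150L,
                             assay_id = NULL, on_invalid = "error") {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (is.null(delim)) {
    delim <- switch(tolower(tools::file_ext(path)),
                    csv = ",", tsv = "\t", txt = "\t", ",")
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  needed <- c(col_map$line, col_map$fitness, col_map$treatment, col_map$subline,
              col_map$replicate, col_map$gmax, col_map$offspring, col_map$survived)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    abort(paste0("Configuration error: input lacks mapped column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- tibble(
    line_id = as.character(raw[[col_map$line]]),
    fitness_class = as.character(raw[[col_map$fitness]]),
    treatment = as.character(raw[[col_map$treatment]]),
    subline_id = as.character(raw[[col_map$subline]]),
    replicate_id = as.character(raw[[col_map$replicate]]),
    gmax = raw[[col_map$gmax]]
  )
  for (j in seq_along(col_map$offspring)) {
    out[[paste0("d", j)]] <- raw[[col_map$offspring[j]]]
  }
  if (!is.null(col_map$survived)) {
    for (j in seq_along(col_map$survived)) {
      out[[paste0("s", j)]] <- as.logical(raw[[col_map$survived[j]]])
    }
  }
  x <- assay_table(out, ages = ages, t = t,
                   assay_id = assay_id %||% basename(path), validate = FALSE)
  res <- validate_assay_table(x, on_invalid = on_invalid)
  if (on_invalid == "report") res else x
}

#' Write an assay table to delimited text
#'
#' Writes with the package's default header, so the file round-trips through
#' [read_assay_table()] unchanged.
#'
#' @param x An [assay_table()].
#' @param path Output path; `.tsv` extension writes tab-separated.
#' @return `path`, invisibly.
#' @export
write_assay_table <- function(x, path) {
  out <- as_tibble(x)
  names(out)[match(c("line_id", "fitness_class", "treatment", "subline_id",
                     "replicate_id"), names(out))] <-
    c("line", "fitness", "treatment", "subline", "rep")
  delim <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Summarize the nested design of an assay
#'
#' Counts, per first-order line, the control pseudolines and MA sublines and
#' the replication within sublines. Unbalanced designs are reported, not
#' rejected.
#'
#' @param x An [assay_table()].
#' @return A tibble with one row per line: `line_id`, `fitness_class`,
#'   `n_pseudolines`, `n_ma_sublines`, `reps_per_subline` (mean), `balanced`.
#' @export
summarize_design <- function(x) {
  if (nrow(x) == 0) {
    return(tibble(line_id = character(), fitness_class = character(),
                  n_pseudolines = integer(), n_ma_sublines = integer(),
                  reps_per_subline = numeric(), balanced = logical()))
  }
  as_tibble(x) |>
    dplyr::group_by(.data$line_id, .data$fitness_class) |>
    dplyr::summarise(
      n_pseudolines = dplyr::n_distinct(.data$subline_id[.data$treatment == "control"]),
      n_ma_sublines = dplyr::n_distinct(.data$subline_id[.data$treatment == "ma"]),
      reps_per_subline = nrow(dplyr::pick(dplyr::everything())) /
        dplyr::n_distinct(paste(.data$treatment, .data$subline_id)),
      balanced = length(unique(table(paste(.data$treatment, .data$subline_id)))) == 1L,
      .groups = "drop"
    )
}

#' @export
print.assay_table <- function(x, ...) {
  cat(sprintf("<assay_table '%s': %d worms, ages [%s] d, t = %d>\n",
              attr(x, "assay_id"), nrow(x),
              paste(attr(x, "ages"), collapse = ", "), attr(x, "t")))
  NextMethod()
}
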