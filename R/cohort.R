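#' Cohort table: per-subject clinical records
#'
#' Columns: `id` (unique string), `side` ("left"/"right"), `ms_subtype`
#' ("relapsing-remitting", "primary-progressive", "secondary-progressive"),
#' `initial_target` ("VIM"/"VOp"), `baseline_trs_motor` (Tremor Rating Scale
#' motor subscore, points, >= 0) and percent improvement from baseline at 3
#' and 6 months (`improvement_3m`, `improvement_6m`; negative = worsening).
#' Optional demographic columns `age` (years) and `sex` are used by
#' [summarize_cohort()] when present.
#'
#' @name cohort_table
NULL

cohort_required_cols <- c("id", "side", "ms_subtype", "initial_target",
                          "baseline_trs_motor", "improvement_3m",
                          "improvement_6m")
cohort_sides <- c("left", "right")
cohort_subtypes <- c("relapsing-remitting", "primary-progressive",
                     "secondary-progressive")

#' Read a cohort CSV
#'
#' UTF-8 CSV with a header row and '.' decimal separator. Improvement
#' columns may be empty (only allowed when the stages using them are
#' skipped).
#'
#' @param path CSV path.
#' @return A validated `cohort_table` data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(cohort_required_cols, names(raw))
  if (length(missing_cols) > 0)
    stop("validation error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  as_cohort_table(raw)
}

parse_numeric_col <- function(x, col) {
  x[!nzchar(trimws(x))] <- NA_character_
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(v))
  if (length(bad) > 0)
    stop("validation error: unparseable numeric in column '", col,
         "' at row(s) ", paste(bad, collapse = ", "), call. = FALSE)
  v
}

#' Validate and type a cohort data frame
#' @param df Data frame with the required cohort columns.
#' @return A `cohort_table` data frame.
#' @export
as_cohort_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  dup <- which(duplicated(df$id))
  if (length(dup) > 0)
    stop("validation error: duplicate id at row(s) ",
         paste(dup, collapse = ", "), call. = FALSE)
  for (col in intersect(c("baseline_trs_motor", "improvement_3m",
                          "improvement_6m", "age"), names(df)))
    df[[col]] <- parse_numeric_col(as.character(df[[col]]), col)
  bad_side <- which(!df$side %in% cohort_sides)
  if (length(bad_side) > 0)
    stop("validation error: side must be left/right at row(s) ",
         paste(bad_side, collapse = ", "), call. = FALSE)
  bad_sub <- which(!df$ms_subtype %in% cohort_subtypes)
  if (length(bad_sub) > 0)
    stop("validation error: unknown ms_subtype at row(s) ",
         paste(bad_sub, collapse = ", "), call. = FALSE)
  if (any(df$baseline_trs_motor < 0, na.rm = TRUE))
    stop("validation error: baseline_trs_motor must be >= 0", call. = FALSE)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a table of rows to CSV
#' @param rows Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Path to the bundled reference cohort table
#'
#' Demographics and baseline clinical characteristics of the 11-subject
#' dual-lead DBS cohort (no per-subject improvements are published, so the
#' improvement columns are empty).
#' @return File path.
#' @export
reference_cohort_path <- function() {
  system.file("extdata", "table1_cohort.csv", package = "tremormap",
              mustWork = TRUE)
}

#' Cohort descriptive statistics
#'
#' Means and standard deviations of age, baseline TRS motor score and
#' 6-month percent improvement, plus subtype and side counts. Standard
#' deviations default to the population (divisor n) formula; display
#' rounding is age to integer years, TRS to one decimal.
#'
#' @param cohort A `cohort_table`.
#' @param sd_type "population" (divisor n, default) or "sample" (divisor
#'   n - 1).
#' @return A `cohort_summary` list.
#' @export
summarize_cohort <- function(cohort, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  sdev <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) <= 1L) return(0)
    if (sd_type == "population") sqrt(mean((x - mean(x))^2)) else stats::sd(x)
  }
  mn <- function(x) if (any(is.finite(x))) mean(x[is.finite(x)]) else NA_real_
  age <- if ("age" %in% names(cohort)) cohort$age else rep(NA_real_, nrow(cohort))
  out <- list(
    n = nrow(cohort),
    mean_age = mn(age), sd_age = sdev(age),
    mean_baseline_trs = mn(cohort$baseline_trs_motor),
    sd_baseline_trs = sdev(cohort$baseline_trs_motor),
    mean_improvement_6m = mn(cohort$improvement_6m),
    sd_improvement_6m = sdev(cohort$improvement_6m),
    subtype_counts = table(factor(cohort$ms_subtype, levels = cohort_subtypes)),
    side_counts = table(factor(cohort$side, levels = cohort_sides)),
    sd_type = sd_type
  )
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d subjects\n", x$n))
  if (is.finite(x$mean_age))
    cat(sprintf("  age: %d (+/- %d) years\n", round(x$mean_age), round(x$sd_age)))
  cat(sprintf("  baseline TRS motor: %.1f (+/- %.1f)\n",
              x$mean_baseline_trs, x$sd_baseline_trs))
  if (is.finite(x$mean_improvement_6m))
    cat(sprintf("  6-month improvement: %.0f%% (+/- %.0f%%)\n",
                x$mean_improvement_6m, x$sd_improvement_6m))
  cat("  subtypes:", paste(names(x$subtype_counts), as.integer(x$subtype_counts),
                           sep = "=", collapse = ", "), "\n")
  cat("  sides:", paste(names(x$side_counts), as.integer(x$side_counts),
                        sep = "=", collapse = ", "), "\n")
  invisible(x)
}
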