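# Count-table I/O and schema validation.

count_columns <- c("animal_id", "region", "stage", "n_gfp_pos", "n_gfp_neg")

# Validate a records data.frame. context = "read" checks the schema (types,
# non-negative integer counts, naming offending fields and data-file line
# numbers); context = "estimation" additionally requires every record to have
# at least one counted cell.
validate_count_records <- function(records, context = c("read", "estimation"),
                                   line_offset = 1L) {
  context <- match.arg(context)
  if (!is.data.frame(records)) {
    stop("count records must be a data.frame", call. = FALSE)
  }
  missing_cols <- setdiff(count_columns, names(records))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"cohort" %in% names(records)) {
    if (nrow(records) == 0L) {
      records$cohort <- character(0)
    } else {
      records <- cbind(cohort = "unspecified", records, stringsAsFactors = FALSE)
    }
  }
  if (nrow(records) == 0L) {
    # header-only input: normalise the column types and return
    for (col in c("n_gfp_pos", "n_gfp_neg")) records[[col]] <- integer(0)
    for (col in c("cohort", "animal_id", "region", "stage")) {
      records[[col]] <- character(0)
    }
    return(records)
  }
  for (col in c("n_gfp_pos", "n_gfp_neg")) {
    v <- records[[col]]
    if (!is.numeric(v)) {
      stop("schema error: column ", col, " must be numeric", call. = FALSE)
    }
    bad <- which(!is_count(v))
    if (length(bad) > 0L) {
      stop("schema error: column ", col,
           " must contain non-negative integers; offending line(s): ",
           paste(utils::head(bad + line_offset, 5L), collapse = ", "),
           call. = FALSE)
    }
    records[[col]] <- as.integer(round(v))
  }
  for (col in c("cohort", "animal_id", "region", "stage")) {
    records[[col]] <- as.character(records[[col]])
  }
  if (context == "estimation" && nrow(records) > 0L) {
    bad <- which(records$n_gfp_pos + records$n_gfp_neg < 1L)
    if (length(bad) > 0L) {
      stop("record(s) with zero counted cells cannot enter estimation; ",
           "offending line(s): ",
           paste(utils::head(bad + line_offset, 5L), collapse = ", "),
           call. = FALSE)
    }
  }
  records
}

#' Read a cell-count table
#'
#' Reads a delimited count table (the schema written by
#' [simulate_cohort()]/[write_count_table()], also suitable for hand-made
#' tables of real counts): one row per (animal, region, stage) with columns
#' `animal_id`, `region`, `stage`, `n_gfp_pos`, `n_gfp_neg` and optionally
#' `cohort`. Validation is strict — missing columns, negative or
#' non-integer counts raise errors naming the offending field and data-file
#' line numbers.
#'
#' @param path path to a CSV file with a header row.
#' @return validated data.frame of count records.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_count_records(records, context = "read")
}

#' Write a cell-count table
#'
#' @param records data.frame of count records.
#' @param path output CSV path (UTF-8, header row).
#' @return `path`, invisibly.
#' @export
write_count_table <- function(records, path) {
  records <- validate_count_records(records, context = "read")
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a per-group survival estimate table
#'
#' Writes the [survival_by_group()] summary as CSV, with percentage columns
#' rounded to one decimal place (the display precision used for GFP
#' positivity) and survival quantities to four decimals.
#'
#' @param estimates an `"xci_survival"` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  stopifnot(inherits(estimates, "xci_survival"))
  df <- as.data.frame(estimates)
  for (col in c("mean_gfp_pct", "sem_gfp_pct")) {
    df[[col]] <- round(df[[col]], 1)
  }
  for (col in c("p_survival_mean", "p_survival_sem", "ci_low", "ci_high")) {
    df[[col]] <- round(df[[col]], 4)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
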