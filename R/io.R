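# CSV exchange format. One row per blood draw; pg/mL is the only accepted
# input unit (conversion to pmol/L is internal). Unknown columns are
# preserved and passed through.

SAMPLE_REQUIRED_COLS <- c("sample_id", "sflt1_pg_ml", "free_plgf_pg_ml")
SAMPLE_NUMERIC_COLS <- c("sflt1_pg_ml", "free_plgf_pg_ml", "total_plgf_pg_ml",
                         "ga_weeks")
SAMPLE_GROUPS <- c("no_pe", "pe", "hellp", "aflp", "liver_failure", "healthy")

#' Read a sample table from CSV
#'
#' Expected columns: `sample_id` (required), `sflt1_pg_ml` and
#' `free_plgf_pg_ml` (required, non-negative), and optionally `group`,
#' `timepoint` (`antepartum`/`postpartum`, default antepartum),
#' `day_postpartum`, `ga_weeks`, `total_plgf_pg_ml`. Empty cells become
#' `NA`; unknown columns are kept. Rows failing validation abort the read
#' with a message listing every offending row number.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return Validated sample data frame.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop_plgf(paste("file not found:", path), "input_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  validate_samples(df)
}

#' Validate a sample data frame against the exchange schema
#'
#' @param df Data frame to validate (e.g. from [read_samples()] or built in
#'   code).
#' @return The validated data frame with defaults filled in.
#' @export
validate_samples <- function(df) {
  miss <- setdiff(SAMPLE_REQUIRED_COLS, names(df))
  if (length(miss)) {
    stop_plgf(paste("missing required column(s):", paste(miss, collapse = ", ")),
              "schema_error")
  }
  if (nrow(df) == 0L) stop_plgf("sample table has no rows", "schema_error")
  problems <- character(0)
  for (col in intersect(SAMPLE_NUMERIC_COLS, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which((!is.na(df[[col]]) & is.na(v)) | (!is.na(v) & v < 0))
    if (length(bad)) {
      problems <- c(problems, sprintf("column %s: row(s) %s not a non-negative number",
                                      col, paste(bad, collapse = ",")))
    }
    df[[col]] <- v
  }
  if (!"timepoint" %in% names(df)) df$timepoint <- "antepartum"
  df$timepoint[is.na(df$timepoint)] <- "antepartum"
  bad_tp <- which(!df$timepoint %in% c("antepartum", "postpartum"))
  if (length(bad_tp)) {
    problems <- c(problems, sprintf("column timepoint: row(s) %s not antepartum/postpartum",
                                    paste(bad_tp, collapse = ",")))
  }
  if ("group" %in% names(df)) {
    bad_g <- which(!is.na(df$group) & !df$group %in% SAMPLE_GROUPS)
    if (length(bad_g)) {
      problems <- c(problems, sprintf("column group: row(s) %s not one of %s",
                                      paste(bad_g, collapse = ","),
                                      paste(SAMPLE_GROUPS, collapse = "/")))
    }
  }
  if ("day_postpartum" %in% names(df)) {
    mism <- which((df$timepoint == "postpartum") != !is.na(df$day_postpartum))
    if (length(mism)) {
      problems <- c(problems, sprintf("day_postpartum must be present iff timepoint is postpartum: row(s) %s",
                                      paste(mism, collapse = ",")))
    }
  } else if (any(df$timepoint == "postpartum")) {
    problems <- c(problems, "postpartum rows require a day_postpartum column")
  }
  if (length(problems)) {
    stop_plgf(paste0("invalid sample table:\n  ",
                     paste(problems, collapse = "\n  ")), "row_error")
  }
  df
}

#' Write a sample table to CSV
#'
#' Writes atomically (temp file in the destination directory, then rename),
#' so a failed write never leaves a partial file. Full precision is kept:
#' a read/write round trip preserves all values.
#'
#' @param df Sample data frame.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(df, path) {
  write_atomic(df, path)
}

write_atomic <- function(df, path, writer = NULL) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  if (is.null(writer)) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], format, digits = 17, trim = TRUE,
                      scientific = FALSE)
    utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE, na = "")
  } else {
    writer(tmp)
  }
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
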