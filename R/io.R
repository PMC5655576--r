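# Reading and writing the package's file formats.

#' Read a long-format rating table from CSV
#'
#' Expects columns `rater_id`, `scenario_id`, `rating` with rating
#' tokens `S`, `M-DA`, `S-DA` (case-sensitive). The survey's
#' colour-coded aliases green/yellow/red are accepted only when
#' `allow_colors = TRUE`, keeping default files unambiguous.
#'
#' @param path CSV file path.
#' @param allow_colors Translate `green`/`yellow`/`red` to
#'   `S`/`M-DA`/`S-DA` before validation.
#' @return Validated rating data frame (see [validate_ratings()]).
#' @export
read_ratings <- function(path, allow_colors = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (isTRUE(allow_colors) && "rating" %in% names(df)) {
    map <- c(green = "S", yellow = "M-DA", red = "S-DA")
    hit <- df$rating %in% names(map)
    df$rating[hit] <- map[df$rating[hit]]
  }
  validate_ratings(df)
}

#' Write a rating table to CSV
#'
#' Columns and row order are preserved so that a write/read round trip
#' is the identity.
#'
#' @param ratings Rating data frame.
#' @param path Output CSV path.
#' @export
write_ratings <- function(ratings, path) {
  ratings <- validate_ratings(ratings)
  ratings$rating <- as.character(ratings$rating)
  utils::write.csv(ratings[c("rater_id", "scenario_id", "rating")],
                   path, row.names = FALSE, quote = FALSE)
}

#' Read patient records from CSV
#'
#' One row per patient with the full scoring inputs: `igf_value`,
#' `igf_lln`, `igf_uln`, `tumor_visible` (logical), `tumor_change_pct`
#' (may be empty/NA), `tumor_invasive`, `vision_worse` (logical),
#' `diabetes`, `sleep_apnea`, `cardiac` (category codes, see
#' [classify_comorbidity()]), `sss_1`..`sss_5`, `qol_1`..`qol_22`.
#'
#' @param path CSV file path.
#' @return Data frame ready for [assess_patients()].
#' @export
read_patients <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PATIENT_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    abort_invalid(paste0(
      "patient file is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  for (col in c("tumor_visible", "tumor_invasive", "vision_worse")) {
    df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' Write an analysis report deterministically
#'
#' Writes a data frame as CSV or a list/data frame as JSON with a fixed
#' column order and stable number formatting, so identical inputs give
#' byte-identical files.
#'
#' @param results Data frame (csv) or any jsonlite-encodable object
#'   (json).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @export
write_report <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!is.data.frame(results)) {
      abort_invalid("csv reports require a data frame")
    }
    num <- vapply(results, is.double, logical(1))
    results[num] <- lapply(results[num], signif, digits = 6L)
    utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = 6L,
                         pretty = TRUE)
  }
  invisible(path)
}
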