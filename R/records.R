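#' @details
#' A seed bank record table is a plain `data.frame` (class
#' `"seedbank_records"`) with one row per survey observation and the columns
#' of the canonical CSV schema:
#' `record_id, latitude, longitude, biome, measure, value, sample_area_m2,
#' depth_upper_cm, depth_lower_cm, sampling_month, season`.
#'
#' Conventions:
#' * Coordinates are decimal degrees (WGS84 implied); southern latitudes are
#'   negative.
#' * `measure` is `"diversity"` (species per sample) or `"density"`.
#'   Density values are raw seed counts for the stated `sample_area_m2`;
#'   sources reporting seeds per m2 directly are encoded with
#'   `sample_area_m2 = 1`, so the per-m2 conversion (count / area) is the
#'   identity for them.
#' * Missing values are empty cells in files and `NA` in memory — never a
#'   sentinel number.
#' * Standardization progress is tracked in logical flag columns
#'   `flag_density_unit`, `flag_season`, `flag_area`, `flag_depth`, added by
#'   the standardization steps (in-memory only, not part of the CSV schema).
#' @keywords internal
#' @name seedbank_records
NULL

record_columns <- function() {
  c("record_id", "latitude", "longitude", "biome", "measure", "value",
    "sample_area_m2", "depth_upper_cm", "depth_lower_cm",
    "sampling_month", "season")
}

flag_columns <- function() {
  c("flag_density_unit", "flag_season", "flag_area", "flag_depth")
}

season_levels <- function() c("spring", "summer", "autumn", "winter")

# Ensure the in-memory flag columns exist (FALSE when absent).
ensure_flags <- function(records) {
  for (fc in flag_columns()) {
    if (is.null(records[[fc]])) records[[fc]] <- rep(FALSE, nrow(records))
  }
  records
}

as_seedbank_records <- function(df) {
  df <- ensure_flags(df)
  class(df) <- c("seedbank_records", "data.frame")
  df
}

# Row-level invariant checks. Returns a character vector (one message per
# violated invariant) for a single row, empty when valid.
row_violations <- function(row) {
  v <- character(0)
  if (is.na(row$latitude) || row$latitude < -90 || row$latitude > 90)
    v <- c(v, "latitude in [-90, 90]")
  if (is.na(row$longitude) || row$longitude < -180 || row$longitude > 180)
    v <- c(v, "longitude in [-180, 180]")
  if (is.na(row$biome) || !(row$biome %in% biome_codes()))
    v <- c(v, "biome is a TEOW code")
  if (is.na(row$measure) || !(row$measure %in% c("diversity", "density")))
    v <- c(v, "measure in {diversity, density}")
  if (is.na(row$value) || row$value < 0)
    v <- c(v, "value >= 0")
  if (is.na(row$sample_area_m2) || row$sample_area_m2 <= 0)
    v <- c(v, "sample_area_m2 > 0")
  if (is.na(row$depth_upper_cm) || row$depth_upper_cm < 0 ||
      is.na(row$depth_lower_cm) || row$depth_lower_cm <= row$depth_upper_cm)
    v <- c(v, "depth_lower_cm > depth_upper_cm >= 0")
  if (!is.na(row$sampling_month) &&
      (row$sampling_month < 1 || row$sampling_month > 12 ||
       row$sampling_month != round(row$sampling_month)))
    v <- c(v, "sampling_month integer in 1..12")
  if (!is.na(row$season) && !(row$season %in% season_levels()))
    v <- c(v, "season in {spring, summer, autumn, winter}")
  v
}

#' Read seed bank records from CSV
#'
#' Parses the canonical records schema. Rows violating a record invariant
#' (e.g. `depth_lower_cm <= depth_upper_cm`, negative value) are rejected,
#' not silently kept; the rejection report is attached so that
#' `parsed + rejected = rows`.
#'
#' @param path Path to a UTF-8 CSV file with header
#'   `record_id,latitude,longitude,biome,measure,value,sample_area_m2,depth_upper_cm,depth_lower_cm,sampling_month,season`.
#' @return A `seedbank_records` data frame of the accepted rows, with
#'   attribute `"rejections"`: a data frame (`row`, `record_id`, `reason`)
#'   describing every rejected input row.
#' @seealso [write_records()], [validate_dataset()]
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("records file does not exist: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(record_id = "character"),
                         na.strings = "")
  missing_cols <- setdiff(record_columns(), names(raw))
  if (length(missing_cols) > 0) {
    stop("records file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- raw[record_columns()]
  for (col in c("latitude", "longitude", "value", "sample_area_m2",
                "depth_upper_cm", "depth_lower_cm", "sampling_month")) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  raw$season <- as.character(raw$season)
  raw$biome <- as.character(raw$biome)
  raw$measure <- as.character(raw$measure)

  keep <- logical(nrow(raw))
  rej <- list()
  for (i in seq_len(nrow(raw))) {
    v <- row_violations(raw[i, ])
    if (length(v) == 0) {
      keep[i] <- TRUE
    } else {
      rej[[length(rej) + 1]] <- data.frame(
        row = i, record_id = raw$record_id[i],
        reason = paste(v, collapse = "; "), stringsAsFactors = FALSE)
    }
  }
  rejections <- if (length(rej) > 0) do.call(rbind, rej) else
    data.frame(row = integer(0), record_id = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  out <- as_seedbank_records(raw[keep, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "rejections") <- rejections
  out
}

#' Write seed bank records to CSV
#'
#' Writes the canonical schema columns in their fixed order; in-memory flag
#' columns are not written. Missing values become empty cells (not the text
#' "NA"), so `read_records(write_records(x))` is the identity on the schema
#' fields.
#'
#' @param records A `seedbank_records` data frame (or compatible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  missing_cols <- setdiff(record_columns(), names(records))
  if (length(missing_cols) > 0) {
    stop("records are missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(records[record_columns()], path, row.names = FALSE,
                   na = "", quote = TRUE)
  invisible(path)
}

#' Validate a record table
#'
#' Scans every record against the schema invariants and tallies violations
#' per invariant, plus per-biome record counts for each measure.
#'
#' @param records A `seedbank_records` data frame.
#' @return A list of class `"seedbank_validation"` with elements
#'   `n_records`, `n_valid`, `violations` (data frame `invariant`, `count`),
#'   `by_biome` (biome x measure contingency table as a data frame).
#' @export
validate_dataset <- function(records) {
  all_v <- character(0)
  valid <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    v <- row_violations(records[i, ])
    valid[i] <- length(v) == 0
    all_v <- c(all_v, v)
  }
  viol <- if (length(all_v) > 0) {
    tab <- table(all_v)
    data.frame(invariant = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(invariant = character(0), count = integer(0),
               stringsAsFactors = FALSE)
  }
  by_biome <- as.data.frame(table(biome = records$biome,
                                  measure = records$measure),
                            stringsAsFactors = FALSE)
  names(by_biome)[3] <- "count"
  out <- list(n_records = nrow(records), n_valid = sum(valid),
              violations = viol, by_biome = by_biome)
  class(out) <- "seedbank_validation"
  out
}

#' @export
print.seedbank_validation <- function(x, ...) {
  cat("Seed bank dataset validation\n")
  cat("  records:", x$n_records, " valid:", x$n_valid, "\n")
  if (nrow(x$violations) == 0) {
    cat("  no invariant violations\n")
  } else {
    cat("  violations:\n")
    for (i in seq_len(nrow(x$violations))) {
      cat(sprintf("    %-45s %d\n", x$violations$invariant[i],
                  x$violations$count[i]))
    }
  }
  invisible(x)
}

#' @export
print.seedbank_records <- function(x, ...) {
  cat("Seed bank records:", nrow(x), "observations",
      sprintf("(%d diversity, %d density)\n",
              sum(x$measure == "diversity"), sum(x$measure == "density")))
  NextMethod()
}
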