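# Reading, validating and writing the survey and count-panel tables.

.stratifier_domains <- function() {
  list(
    region = .mdsr_regions,
    facility_level = .mdsr_levels,
    location = .mdsr_locations,
    region_type = .mdsr_region_types,
    agro_zone = .mdsr_agro_zones,
    years_implementing = .mdsr_years
  )
}

# yes/no tokens accepted case-insensitively; anything else errors (never imputed)
.normalize_binary <- function(x, column) {
  tok <- tolower(trimws(as.character(x)))
  out <- rep(NA_integer_, length(tok))
  out[tok %in% c("yes", "1", "true")] <- 1L
  out[tok %in% c("no", "0", "false")] <- 0L
  bad <- which(is.na(out))
  if (length(bad)) {
    stop(sprintf("non-binary value %s in column '%s' at row %d",
                 dQuote(x[bad[1]]), column, bad[1]), call. = FALSE)
  }
  out
}

#' Read and validate a facility survey table
#'
#' Reads a CSV with one row per surveyed facility: the stratifier columns
#' (`facility_id`, `region`, `facility_level`, `location`, `region_type`,
#' `agro_zone`, `years_implementing`), the two eligibility counts
#' (`notified_last_year`, `reviewed_last_year`) and the 54 binary item
#' columns named per [dimension_specs()]. Yes/no tokens (`yes/no/1/0/
#' true/false`, case-insensitive) are normalised to integer 1/0; any other
#' token is an error, never imputed.
#'
#' @param path CSV file path.
#' @param config an [evaluation_config()]; its dimension specs define the
#'   expected item columns.
#' @return a validated `data.frame`, row order preserved.
#' @export
read_facility_table <- function(path, config = evaluation_config()) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_facility_table(df, config)
}

#' Validate an in-memory facility survey table
#'
#' @param df data frame in the layout of [read_facility_table()].
#' @inheritParams read_facility_table
#' @return the validated data frame with normalised item columns.
#' @export
validate_facility_table <- function(df, config = evaluation_config()) {
  items <- item_columns(config$dimension_specs)
  required <- c("facility_id", names(.stratifier_domains()),
                "notified_last_year", "reviewed_last_year", items)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("facility table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in names(.stratifier_domains())) {
    dom <- .stratifier_domains()[[col]]
    bad <- which(!(as.character(df[[col]]) %in% dom))
    if (length(bad)) {
      stop(sprintf("row %d: value %s not a valid level of '%s'",
                   bad[1], dQuote(df[[col]][bad[1]]), col), call. = FALSE)
    }
    df[[col]] <- as.character(df[[col]])
  }
  for (col in c("notified_last_year", "reviewed_last_year")) {
    v <- df[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v != floor(v))) {
      stop("column '", col, "' must hold non-negative integer counts",
           call. = FALSE)
    }
    df[[col]] <- as.integer(v)
  }
  for (col in items) df[[col]] <- .normalize_binary(df[[col]], col)
  df
}

#' Write a facility survey table to CSV
#' @param df validated facility table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_facility_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Restrict a survey to MDSR-implementing facilities
#'
#' A facility counts as implementing the system when it both notified and
#' reviewed at least one maternal death in the year before the survey.
#' The numbers kept and dropped are attached as attributes and reported
#' via [message()].
#'
#' @param df validated facility table.
#' @param quiet suppress the message.
#' @return the filtered table with attributes `n_kept` and `n_dropped`.
#' @export
filter_implementing <- function(df, quiet = FALSE) {
  keep <- df$notified_last_year >= 1L & df$reviewed_last_year >= 1L
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  if (!quiet) {
    message(sprintf("filter_implementing: kept %d of %d facilities (%d dropped)",
                    sum(keep), length(keep), sum(!keep)))
  }
  out
}

#' Read and validate a regional count panel
#'
#' The panel holds, per region, the six death-count aggregates of the
#' surveillance cascade: expected (estimated) deaths E(d), identified
#' deaths, notified deaths, reviewed deaths, and the community/facility
#' split of reviewed deaths. Counts must be non-negative integers and the
#' community + facility split must sum to the reviewed total.
#'
#' @param path CSV with columns `region, expected, identified, notified,
#'   reviewed, reviewed_community, reviewed_facility`.
#' @return a validated `data.frame`, one row per region.
#' @export
read_count_panel <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_count_panel(df)
}

#' Validate an in-memory count panel
#' @param df data frame in the layout of [read_count_panel()].
#' @return the validated data frame.
#' @export
validate_count_panel <- function(df) {
  cols <- c("region", "expected", "identified", "notified", "reviewed",
            "reviewed_community", "reviewed_facility")
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("count panel is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) return(df[cols])
  for (col in cols[-1]) {
    v <- df[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v != floor(v))) {
      stop("column '", col, "' must hold non-negative integer counts",
           call. = FALSE)
    }
    df[[col]] <- as.integer(v)
  }
  bad <- which(df$reviewed_community + df$reviewed_facility != df$reviewed)
  if (length(bad)) {
    stop(sprintf(paste0("region '%s': reviewed_community (%d) + ",
                        "reviewed_facility (%d) != reviewed (%d)"),
                 df$region[bad[1]], df$reviewed_community[bad[1]],
                 df$reviewed_facility[bad[1]], df$reviewed[bad[1]]),
         call. = FALSE)
  }
  df[cols]
}

#' Write a count panel to CSV
#' @param df validated count panel.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_count_panel <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' The Ethiopian 2014-2020 regional count panel
#'
#' The published per-region death-count aggregates for Ethiopia's MDSR
#' system over 2014-2020 (11 regions), shipped as a packaged CSV fixture.
#' The published national total of expected deaths (60686) differs from the
#' sum of the per-region values (60639); the printed national total is
#' attached as attribute `expected_total_printed` and is the default used
#' by national aggregation.
#'
#' @return the validated panel with attribute `expected_total_printed`.
#' @export
#' @examples
#' panel <- ethiopia_mdsr_counts()
#' sum(panel$notified)  # 5696
ethiopia_mdsr_counts <- function() {
  path <- system.file("extdata", "ethiopia_mdsr_counts_2014_2020.csv",
                      package = "mdsrpi", mustWork = TRUE)
  panel <- read_count_panel(path)
  attr(panel, "expected_total_printed") <- 60686L
  panel
}

#' Published national readiness summary, Ethiopia 2020
#'
#' National mean scores (with standard errors) of the four readiness
#' dimensions and the overall composite from the 2020 Ethiopian MDSR
#' evaluation (n = 400 implementing facilities), shipped as a fixture for
#' desk-level checks that need only published summary statistics.
#'
#' @return data frame with columns `dimension, n, mean_pct, se_pct`.
#' @export
ethiopia_readiness_national <- function() {
  path <- system.file("extdata", "ethiopia_readiness_national_2020.csv",
                      package = "mdsrpi", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
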