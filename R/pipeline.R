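# End-to-end evaluation wiring and report rendering.

# Polynomial rolling hash over the deparsed object: a stable content
# fingerprint for run manifests (not cryptographic).
.content_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full MDSR evaluation pipeline
#'
#' Wires the stages together: validates and filters the facility survey to
#' implementing facilities, scores readiness per facility, summarises and
#' compares every stratifier, computes the per-region and national MDSRPI
#' from the count panel, and runs the trend analysis on the yearly series.
#' Deterministic given inputs and config. Any stage failure aborts with
#' the stage name.
#'
#' @param facilities facility table (data frame) or CSV path.
#' @param panel count panel (data frame) or CSV path; defaults to the
#'   packaged [ethiopia_mdsr_counts()].
#' @param trend_series data frame with `year`/`value` columns (or 2-column
#'   CSV path), or `NULL` to skip the trend stage.
#' @param config an [evaluation_config()].
#' @return list of class `mdsr_evaluation` with elements `readiness`,
#'   `group_comparisons` (one [compare_groups()] result per stratifier),
#'   `performance` (an `mdsrpi` table), `trend` (or `NULL`), `manifest`.
#' @export
run_full_evaluation <- function(facilities,
                                panel = ethiopia_mdsr_counts(),
                                trend_series = NULL,
                                config = evaluation_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  facilities <- stage("readiness", {
    if (is.character(facilities)) {
      facilities <- read_facility_table(facilities, config)
    } else {
      facilities <- validate_facility_table(facilities, config)
    }
    filter_implementing(facilities, quiet = TRUE)
  })
  readiness <- stage("readiness", facility_readiness(facilities, config))
  comparisons <- stage("compare", {
    strat <- names(.stratifier_domains())
    stats::setNames(lapply(strat, function(s) {
      compare_groups(readiness, s, alpha = config$alpha)
    }), strat)
  })
  performance <- stage("mdsrpi", {
    if (is.character(panel)) panel <- read_count_panel(panel)
    mdsr_performance(panel, weights = config$mdsrpi_weights)
  })
  trend <- if (!is.null(trend_series)) {
    stage("trend", {
      if (is.character(trend_series)) {
        trend_series <- utils::read.csv(trend_series)
      }
      trend_analysis(trend_series[[2]], trend_series[[1]],
                     conf_level = 1 - config$alpha)
    })
  }
  manifest <- list(
    software = paste0("mdsrpi ",
                      as.character(utils::packageVersion("mdsrpi"))),
    config_hash = .content_hash(config),
    n_facilities_implementing = nrow(readiness),
    n_facilities_dropped = attr(facilities, "n_dropped") %||% 0L,
    n_regions = nrow(performance) - 1L,
    trend_years = if (is.null(trend)) 0L else trend$n
  )
  structure(list(readiness = readiness, group_comparisons = comparisons,
                 performance = performance, trend = trend,
                 manifest = manifest),
            class = "mdsr_evaluation")
}

#' @export
print.mdsr_evaluation <- function(x, ...) {
  cat("MDSR system evaluation\n")
  cat("  implementing facilities scored: ",
      x$manifest$n_facilities_implementing, "\n", sep = "")
  nat_r <- mean(x$readiness$overall_pct)
  cat("  national readiness: ", round_half_up(nat_r, 1), "% (",
      as.character(classify_ephi(nat_r)), ")\n", sep = "")
  nat <- x$performance[x$performance$region == "Total", ]
  cat("  national MDSRPI: ", round_half_up(nat$mdsrpi_pct, 1), "% (",
      nat$performance_class, " performing)\n", sep = "")
  if (!is.null(x$trend)) {
    cat(sprintf("  trend: Sen's slope %.3g per year, p = %.3g\n",
                x$trend$sen_slope, x$trend$p_value))
  }
  invisible(x)
}

.markdown_table <- function(df) {
  fmt <- function(v) ifelse(is.na(v), "NA", as.character(v))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) {
    paste0("| ", paste(fmt(r), collapse = " | "), " |")
  })
  c(header, sep, rows)
}

#' Render an evaluation bundle to files
#'
#' Writes the result bundle under `dir`: per-facility readiness and the
#' regional-plus-national performance table as CSV and/or markdown with
#' one-decimal display rounding, the full-precision bundle as JSON, and a
#' `manifest.json` listing every emitted file. JSON keeps full precision;
#' display formats round half away from zero.
#'
#' @param bundle an `mdsr_evaluation` object.
#' @param dir output directory (created if needed).
#' @param format subset of `c("csv", "json", "markdown")`.
#' @return character vector of files written, invisibly.
#' @export
render_report <- function(bundle, dir,
                          format = c("csv", "json", "markdown")) {
  if (!inherits(bundle, "mdsr_evaluation")) {
    stop("bundle must be an mdsr_evaluation object", call. = FALSE)
  }
  bad <- setdiff(format, c("csv", "json", "markdown"))
  if (length(bad)) stop("unknown format: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  perf <- as.data.frame(bundle$performance)
  perf_disp <- perf
  for (cl in c(.mdsr_indicators, "mdsrpi_pct")) {
    perf_disp[[cl]] <- round_half_up(perf_disp[[cl]], 1)
  }
  if ("csv" %in% format) {
    f1 <- file.path(dir, "readiness.csv")
    utils::write.csv(as.data.frame(bundle$readiness), f1, row.names = FALSE)
    f2 <- file.path(dir, "performance.csv")
    utils::write.csv(perf_disp, f2, row.names = FALSE)
    files <- c(files, f1, f2)
  }
  if ("markdown" %in% format) {
    f <- file.path(dir, "performance.md")
    writeLines(.markdown_table(perf_disp[, c("region", .mdsr_indicators,
                                             "mdsrpi_pct",
                                             "performance_class")]), f)
    files <- c(files, f)
  }
  if ("json" %in% format) {
    f <- file.path(dir, "results.json")
    payload <- list(
      readiness = as.data.frame(bundle$readiness),
      performance = perf,
      trend = if (!is.null(bundle$trend)) unclass(bundle$trend),
      manifest = bundle$manifest
    )
    jsonlite::write_json(payload, f, auto_unbox = TRUE, digits = NA,
                         na = "null")
    files <- c(files, f)
  }
  manifest <- c(bundle$manifest,
                list(files = basename(files),
                     timestamp = format(Sys.time(), tz = "UTC")))
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, mf))
}
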