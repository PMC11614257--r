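# Facility readiness scoring: per-dimension percentages, the weighted
# overall composite, EPHI functionality ratings and group summaries.

.ephi_labels <- c("not functioning", "less functioning", "fairly functioning",
                  "effectively functioning", "very effectively functioning")

#' Score one dimension for one facility
#'
#' The dimension score is the percentage of "yes" answers among the
#' dimension's items: `100 * (# yes) / (# items)`. The weighted score is
#' the dimension weight times that percentage.
#'
#' @param responses named integer vector (or one-row data frame) of 0/1
#'   item responses; must contain every item of `spec`.
#' @param spec one element of [dimension_specs()].
#' @return list with `dimension`, `raw_total`, `score_pct`, `weighted_pct`.
#' @export
#' @examples
#' spec <- dimension_specs()$structure
#' r <- setNames(c(1, 1, 1, 1, 0, 0, 0), spec$item_ids)
#' score_dimension(r, spec)$score_pct  # 57.14...
score_dimension <- function(responses, spec) {
  if (is.data.frame(responses)) responses <- unlist(responses[1, , drop = TRUE])
  missing <- setdiff(spec$item_ids, names(responses))
  if (length(missing)) {
    stop("missing response for item(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  v <- as.numeric(responses[spec$item_ids])
  if (any(is.na(v)) || !all(v %in% c(0, 1))) {
    stop("responses must be binary 0/1 with no missing values", call. = FALSE)
  }
  raw <- sum(v)
  pct <- 100 * raw / length(spec$item_ids)
  list(dimension = spec$name, raw_total = raw, score_pct = pct,
       weighted_pct = spec$weight * pct)
}

#' Combine dimension scores into the overall readiness percentage
#'
#' The overall readiness score is the weight-sum of the four dimension
#' percentages; with the default equal weights it is their arithmetic mean.
#'
#' @param scores numeric vector of the four dimension percentages, in the
#'   order structure, core, supportive, attributes (names optional).
#' @param weights weights summing to 1 (tolerance 1e-9).
#' @return the composite percentage (unrounded).
#' @export
#' @examples
#' overall_readiness(c(51.7, 20.0, 38.4, 69.6))  # 44.925
overall_readiness <- function(scores, weights = rep(0.25, 4)) {
  if (length(scores) != length(weights)) {
    stop("scores and weights must have equal length", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("weights must sum to 1 (got ", sum(weights), ")", call. = FALSE)
  }
  sum(as.numeric(scores) * as.numeric(weights))
}

#' EPHI functionality rating for a percentage score
#'
#' The Ethiopian Public Health Institute mid-term evaluation bands, made
#' total on \[0, 100\] with closed upper bounds: score <= 20 is "not
#' functioning"; (20, 50\] "less functioning"; (50, 75\] "fairly
#' functioning"; (75, 90\] "effectively functioning"; (90, 100\] "very
#' effectively functioning".
#'
#' @param score_pct numeric vector of scores in \[0, 100\].
#' @return ordered factor of ratings.
#' @export
#' @examples
#' classify_ephi(c(20, 44.9, 69.6, 80, 95))
classify_ephi <- function(score_pct) {
  if (any(is.na(score_pct)) || any(score_pct < 0 | score_pct > 100)) {
    stop("scores must lie in [0, 100]", call. = FALSE)
  }
  cut(score_pct, breaks = c(-Inf, 20, 50, 75, 90, 100),
      labels = .ephi_labels, ordered_result = TRUE)
}

#' Score every facility of a survey table
#'
#' Computes, for each facility, the four dimension percentages (and the
#' five attribute subcategory percentages), the weighted overall composite
#' and its EPHI rating. The attributes dimension pools all 26 items; the
#' subcategory percentages are reported alongside but do not enter the
#' dimension score.
#'
#' @param df validated facility table (see [read_facility_table()]).
#' @param config an [evaluation_config()].
#' @return a `data.frame` of class `mdsr_readiness` with one row per
#'   facility: the stratifiers, `structure_pct`, `core_pct`,
#'   `supportive_pct`, `attributes_pct`, the subcategory percentages,
#'   `overall_pct` and `rating`.
#' @export
facility_readiness <- function(df, config = evaluation_config()) {
  specs <- config$dimension_specs
  out <- df[, c("facility_id", names(.stratifier_domains())), drop = FALSE]
  w <- vapply(specs, `[[`, numeric(1), "weight")
  for (d in names(specs)) {
    ids <- specs[[d]]$item_ids
    m <- as.matrix(df[, ids, drop = FALSE])
    out[[paste0(d, "_pct")]] <- 100 * rowSums(m) / length(ids)
  }
  for (sc in names(specs$attributes$subcategories)) {
    ids <- specs$attributes$subcategories[[sc]]
    m <- as.matrix(df[, ids, drop = FALSE])
    out[[paste0(sc, "_pct")]] <- 100 * rowSums(m) / length(ids)
  }
  dim_cols <- paste0(names(specs), "_pct")
  out$overall_pct <- as.vector(as.matrix(out[, dim_cols]) %*% w)
  out$rating <- classify_ephi(out$overall_pct)
  class(out) <- c("mdsr_readiness", "data.frame")
  out
}

#' @export
print.mdsr_readiness <- function(x, ...) {
  cat("Facility readiness scores (", nrow(x), " facilities)\n", sep = "")
  cat("overall: mean ", round_half_up(mean(x$overall_pct), 1),
      "%, rating of the mean: ",
      as.character(classify_ephi(mean(x$overall_pct))), "\n\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}

#' @export
summary.mdsr_readiness <- function(object, ...) {
  dims <- c("structure_pct", "core_pct", "supportive_pct", "attributes_pct",
            "overall_pct")
  rows <- lapply(dims, function(cl) {
    s <- summarize_group(object[[cl]], sub("_pct$", "", cl))
    as.data.frame(s, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rating <- as.character(classify_ephi(out$mean_pct))
  out
}

#' Summarise a group of percentage scores
#'
#' Mean, standard error (sample SD / sqrt(n)) and the normal-approximation
#' 95% interval `mean +/- 1.96 * SE`, as published alongside the readiness
#' tables. With fewer than two observations the SE and interval are `NA`.
#'
#' @param scores numeric vector of percentages, n >= 1.
#' @param group_label label carried through to the output.
#' @param conf_z normal quantile for the interval (default 1.96).
#' @return list with `group`, `n`, `mean_pct`, `se_pct`, `ci_low_pct`,
#'   `ci_high_pct`.
#' @export
summarize_group <- function(scores, group_label = "", conf_z = 1.96) {
  scores <- as.numeric(scores)
  if (length(scores) < 1 || any(is.na(scores))) {
    stop("scores must be a non-empty numeric vector without NA", call. = FALSE)
  }
  n <- length(scores)
  m <- mean(scores)
  if (n < 2) {
    se <- NA_real_; lo <- NA_real_; hi <- NA_real_
  } else {
    se <- stats::sd(scores) / sqrt(n)
    lo <- m - conf_z * se
    hi <- m + conf_z * se
  }
  list(group = group_label, n = n, mean_pct = m, se_pct = se,
       ci_low_pct = lo, ci_high_pct = hi)
}

#' Group summaries of a readiness column by a stratifier
#'
#' @param readiness an `mdsr_readiness` table.
#' @param by stratifier column name (e.g. `"region"`, `"location"`).
#' @param measure score column to summarise (default `"overall_pct"`).
#' @return data frame with one row per group plus a `national` row.
#' @export
readiness_summary <- function(readiness, by, measure = "overall_pct") {
  if (!by %in% names(.stratifier_domains())) {
    stop("unknown stratifier: ", by, call. = FALSE)
  }
  groups <- split(readiness[[measure]], readiness[[by]])
  rows <- lapply(names(groups), function(g) {
    as.data.frame(summarize_group(groups[[g]], g), stringsAsFactors = FALSE)
  })
  rows[[length(rows) + 1L]] <-
    as.data.frame(summarize_group(readiness[[measure]], "national"),
                  stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out$rating <- as.character(classify_ephi(out$mean_pct))
  out
}
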