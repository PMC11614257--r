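# The five MDSR performance indicators and the weighted MDSRPI composite.

#' Compute the five performance indicators from one set of counts
#'
#' Given the death-count aggregates of a region (or the national sums),
#' computes, on the percent scale and unrounded:
#' \describe{
#'   \item{Rn}{notification rate, `100 * notified / identified`; below 80
#'     signals incomplete notification.}
#'   \item{CRn}{notification coverage rate, `100 * notified / expected`.}
#'   \item{Rr}{review rate, `100 * reviewed / notified`; may exceed 100
#'     when committees review deaths never notified weekly, and is never
#'     capped.}
#'   \item{CRr}{review coverage rate, `100 * reviewed / expected`.}
#'   \item{CRDp}{proportion of reviewed deaths that occurred at community
#'     level, `100 * reviewed_community / reviewed`.}
#' }
#' A zero denominator leaves the affected indicator `NA` (undefined), never
#' 0 or infinite.
#'
#' @param counts a list or one-row data frame with `expected, identified,
#'   notified, reviewed, reviewed_community`.
#' @return named numeric vector `c(Rn, CRn, CRr, Rr, CRDp)`.
#' @export
#' @examples
#' compute_indicators(list(expected = 2715, identified = 598, notified = 265,
#'                         reviewed = 566, reviewed_community = 444))
compute_indicators <- function(counts) {
  if (is.data.frame(counts)) counts <- as.list(counts[1, , drop = TRUE])
  need <- c("expected", "identified", "notified", "reviewed",
            "reviewed_community")
  missing <- setdiff(need, names(counts))
  if (length(missing)) {
    stop("counts is missing: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  c(Rn = rate(counts$notified, counts$identified),
    CRn = rate(counts$notified, counts$expected),
    CRr = rate(counts$reviewed, counts$expected),
    Rr = rate(counts$reviewed, counts$notified),
    CRDp = rate(counts$reviewed_community, counts$reviewed))
}

#' Aggregate a regional count panel to the national level
#'
#' National indicators are computed from nationally summed numerators and
#' denominators, not from averaging regional rates. Because published
#' national totals of expected deaths can differ from the sum of the
#' regional values, `expected_total` (when supplied, e.g. the attribute of
#' [ethiopia_mdsr_counts()]) overrides the regional sum.
#'
#' @param panel validated count panel.
#' @param expected_total optional national expected-deaths total to use in
#'   place of `sum(panel$expected)`.
#' @return one-row data frame of national counts with `region = "Total"`.
#' @export
aggregate_national <- function(panel, expected_total = NULL) {
  if (nrow(panel) == 0) stop("empty count panel", call. = FALSE)
  out <- data.frame(
    region = "Total",
    expected = if (is.null(expected_total)) sum(panel$expected)
               else as.integer(expected_total),
    identified = sum(panel$identified),
    notified = sum(panel$notified),
    reviewed = sum(panel$reviewed),
    reviewed_community = sum(panel$reviewed_community),
    reviewed_facility = sum(panel$reviewed_facility),
    stringsAsFactors = FALSE
  )
  out
}

#' Weighted MDSRPI composite from a set of indicators
#'
#' The Maternal Death Surveillance and Response Performance Index is the
#' weight-sum of the five indicators on the percent scale. Default weights
#' put 0.3 on each coverage rate, 0.2 on the review rate and 0.1 on the
#' notification rate and community proportion. Indicators enter the
#' composite unrounded and uncapped (a review rate above 100 contributes
#' its full weighted value).
#'
#' @param indicators named vector as returned by [compute_indicators()];
#'   all five must be defined (non-`NA`).
#' @param weights named weights over `Rn, CRn, CRr, Rr, CRDp` summing to 1.
#' @return list with `mdsrpi_pct` (unrounded) and `performance_class`.
#' @export
#' @examples
#' ind <- c(Rn = 64.7, CRn = 3.5, CRr = 4.4, Rr = 126.9, CRDp = 30.8)
#' compute_mdsrpi(ind)$mdsrpi_pct  # ~37.3
compute_mdsrpi <- function(indicators,
                           weights = c(Rn = 0.1, CRn = 0.3, CRr = 0.3,
                                       Rr = 0.2, CRDp = 0.1)) {
  missing <- setdiff(.mdsr_indicators, names(indicators))
  if (length(missing)) {
    stop("indicators is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  undef <- .mdsr_indicators[is.na(indicators[.mdsr_indicators])]
  if (length(undef)) {
    stop("undefined indicator(s): ", paste(undef, collapse = ", "),
         call. = FALSE)
  }
  missing_w <- setdiff(.mdsr_indicators, names(weights))
  if (length(missing_w)) {
    stop("weights is missing: ", paste(missing_w, collapse = ", "),
         call. = FALSE)
  }
  if (abs(sum(weights[.mdsr_indicators]) - 1) > 1e-9) {
    stop("weights must sum to 1 (got ", sum(weights[.mdsr_indicators]), ")",
         call. = FALSE)
  }
  score <- sum(indicators[.mdsr_indicators] * weights[.mdsr_indicators])
  list(mdsrpi_pct = unname(score),
       performance_class = classify_mdsrpi(score))
}

#' Performance class of an MDSRPI score
#'
#' On the fraction scale (score / 100): below 0.4 is "low", 0.4 to 0.6
#' inclusive "moderate", above 0.6 "good".
#'
#' @param mdsrpi_pct numeric vector of composite scores on the percent
#'   scale; must be non-negative.
#' @return character vector of classes.
#' @export
#' @examples
#' classify_mdsrpi(c(33.9, 40, 64.2))
classify_mdsrpi <- function(mdsrpi_pct) {
  if (any(is.na(mdsrpi_pct)) || any(mdsrpi_pct < 0)) {
    stop("MDSRPI scores must be non-negative", call. = FALSE)
  }
  f <- mdsrpi_pct / 100
  ifelse(f < 0.4, "low", ifelse(f <= 0.6, "moderate", "good"))
}

#' Full MDSRPI analysis of a regional count panel
#'
#' Computes, for every region and for the national aggregate, the five
#' performance indicators, the weighted MDSRPI composite and its
#' performance class.
#'
#' @param panel validated count panel (e.g. [ethiopia_mdsr_counts()]).
#' @param weights MDSRPI weights, see [compute_mdsrpi()].
#' @param expected_total optional national expected-deaths override; when
#'   `NULL` and the panel carries an `expected_total_printed` attribute,
#'   that attribute is used.
#' @return a `data.frame` of class `mdsrpi`: counts, unrounded indicators,
#'   `mdsrpi_pct` and `performance_class`, regions first and the national
#'   `Total` row last.
#' @export
#' @examples
#' perf <- mdsr_performance(ethiopia_mdsr_counts())
#' perf[perf$region == "Total", c("Rn", "Rr", "mdsrpi_pct")]
mdsr_performance <- function(panel,
                             weights = c(Rn = 0.1, CRn = 0.3, CRr = 0.3,
                                         Rr = 0.2, CRDp = 0.1),
                             expected_total = NULL) {
  panel <- validate_count_panel(as.data.frame(panel))
  if (nrow(panel) == 0) stop("empty count panel", call. = FALSE)
  if (is.null(expected_total)) {
    expected_total <- attr(panel, "expected_total_printed")
  }
  rows <- rbind(panel, aggregate_national(panel, expected_total))
  ind <- t(vapply(seq_len(nrow(rows)),
                  function(i) compute_indicators(rows[i, ]),
                  numeric(5)))
  out <- cbind(rows, as.data.frame(ind))
  comp <- lapply(seq_len(nrow(out)), function(i) {
    compute_mdsrpi(ind[i, ], weights)
  })
  out$mdsrpi_pct <- vapply(comp, `[[`, numeric(1), "mdsrpi_pct")
  out$performance_class <- vapply(comp, `[[`, character(1),
                                  "performance_class")
  attr(out, "weights") <- weights
  class(out) <- c("mdsrpi", "data.frame")
  out
}

#' @export
print.mdsrpi <- function(x, digits = 1, ...) {
  cat("MDSR Performance Index (", nrow(x) - 1L, " regions + national)\n\n",
      sep = "")
  disp <- as.data.frame(x)
  for (cl in c(.mdsr_indicators, "mdsrpi_pct")) {
    disp[[cl]] <- round_half_up(disp[[cl]], digits)
  }
  print.data.frame(disp[, c("region", "notified", "reviewed",
                            .mdsr_indicators, "mdsrpi_pct",
                            "performance_class")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.mdsrpi <- function(object, ...) {
  nat <- object[object$region == "Total", , drop = FALSE]
  cat("National MDSRPI: ", round_half_up(nat$mdsrpi_pct, 1), "% (",
      nat$performance_class, " performing)\n", sep = "")
  cls <- table(object$performance_class[object$region != "Total"])
  cat("Regional classes: ",
      paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n",
      sep = "")
  invisible(object)
}
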