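# Mann-Kendall trend test and Sen's slope for short yearly series.

.check_series <- function(years, values, min_n = 3) {
  years <- as.numeric(years); values <- as.numeric(values)
  if (length(years) != length(values)) {
    stop("years and values must have equal length", call. = FALSE)
  }
  if (any(is.na(years)) || any(is.na(values))) {
    stop("series must not contain NA", call. = FALSE)
  }
  if (any(diff(years) <= 0)) {
    stop("years must be strictly increasing", call. = FALSE)
  }
  if (length(values) < min_n) {
    stop("need at least ", min_n, " observations", call. = FALSE)
  }
  list(years = years, values = values)
}

#' Mann-Kendall trend test
#'
#' Nonparametric monotone-trend test for a yearly series. The score is
#' `S = sum over i < j of sign(x_j - x_i)`; its variance uses the standard
#' tie-group correction
#' `var(S) = (n(n-1)(2n+5) - sum_t t(t-1)(2t+5)) / 18`
#' with `t` running over the sizes of tied groups. The normalised statistic
#' applies the +/-1 continuity correction (`z = (S - 1)/sqrt(var S)` for
#' S > 0, 0 for S = 0, `(S + 1)/sqrt(var S)` for S < 0; switchable), and
#' the p-value is two-sided normal. Kendall's tau is `S / (n(n-1)/2)`.
#'
#' @param values series values (percentages or proportions).
#' @param years observation years, strictly increasing; defaults to
#'   `seq_along(values)`.
#' @param continuity apply the continuity correction (default TRUE).
#' @return object of class `mdsr_trend`: `S`, `var_S`, `z`, `p_value`,
#'   `tau`, `n`.
#' @export
#' @examples
#' mann_kendall(c(100, 83, 75, 66, 58, 50, 45, 41.7), years = 2013:2020)
mann_kendall <- function(values, years = seq_along(values),
                         continuity = TRUE) {
  s <- .check_series(years, values, min_n = 3)
  x <- s$values
  n <- length(x)
  d <- outer(x, x, "-")
  S <- sum(sign(d[lower.tri(d)]))  # lower.tri: rows j > cols i, x_j - x_i
  ties <- table(x)
  ties <- ties[ties > 1]
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (var_S <= 0) {  # all values tied
    z <- 0
  } else if (continuity) {
    z <- if (S > 0) (S - 1) / sqrt(var_S)
         else if (S < 0) (S + 1) / sqrt(var_S)
         else 0
  } else {
    z <- S / sqrt(var_S)
  }
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(S = S, var_S = var_S, z = z, p_value = p,
                 tau = S / (n * (n - 1) / 2), n = n,
                 continuity = continuity),
            class = "mdsr_trend")
}

#' @export
print.mdsr_trend <- function(x, ...) {
  cat("Mann-Kendall trend test (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  S = %d, var(S) = %.2f, z = %.3f, tau = %.3f, p = %.4g\n",
              x$S, x$var_S, x$z, x$tau, x$p_value))
  if (!is.null(x$sen_slope)) {
    cat(sprintf("  Sen's slope = %.4g per year (%.0f%% CI %.4g to %.4g)\n",
                x$sen_slope, 100 * (x$conf_level %||% 0.95),
                x$slope_ci_low, x$slope_ci_high))
  }
  invisible(x)
}

#' Sen's slope estimator with rank-based confidence interval
#'
#' The slope is the median of all pairwise slopes
#' `(x_j - x_i) / (year_j - year_i)`, i < j. The confidence interval uses
#' the rank method tied to the Mann-Kendall variance: with
#' `C = z_{1-alpha/2} * sqrt(var S)` and N pairwise slopes sorted
#' ascending, the bounds sit at ranks `(N - C)/2` and `(N + C)/2`, linearly
#' interpolated between adjacent order statistics and clamped to `[1, N]`.
#'
#' @inheritParams mann_kendall
#' @param conf_level confidence level for the interval.
#' @return list with `slope` (units of `values` per year), `ci_low`,
#'   `ci_high`, `n_pairs`.
#' @export
#' @examples
#' sen_slope(c(3, 5, 7, 9, 11), years = 2013:2017)$slope  # exactly 2
sen_slope <- function(values, years = seq_along(values), conf_level = 0.95) {
  s <- .check_series(years, values, min_n = 3)
  x <- s$values; yr <- s$years
  n <- length(x)
  pairs <- utils::combn(n, 2)
  slopes <- (x[pairs[2, ]] - x[pairs[1, ]]) / (yr[pairs[2, ]] - yr[pairs[1, ]])
  slopes <- sort(slopes)
  N <- length(slopes)
  mk <- mann_kendall(x, yr)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  C <- zq * sqrt(mk$var_S)
  rank_at <- function(r) {
    r <- min(max(r, 1), N)
    lo <- floor(r); hi <- ceiling(r)
    if (lo == hi) slopes[lo]
    else slopes[lo] + (r - lo) * (slopes[hi] - slopes[lo])
  }
  list(slope = stats::median(slopes),
       ci_low = rank_at((N - C) / 2),
       ci_high = rank_at((N + C) / 2),
       n_pairs = N, conf_level = conf_level)
}

#' Combined trend analysis of a yearly series
#'
#' Runs [mann_kendall()] and [sen_slope()] on one series and merges the
#' results into a single `mdsr_trend` object.
#'
#' @inheritParams sen_slope
#' @param continuity apply the Mann-Kendall continuity correction.
#' @return `mdsr_trend` object including `sen_slope`, `slope_ci_low`,
#'   `slope_ci_high`.
#' @export
trend_analysis <- function(values, years = seq_along(values),
                           conf_level = 0.95, continuity = TRUE) {
  mk <- mann_kendall(values, years, continuity = continuity)
  ss <- sen_slope(values, years, conf_level = conf_level)
  mk$sen_slope <- ss$slope
  mk$slope_ci_low <- ss$ci_low
  mk$slope_ci_high <- ss$ci_high
  mk$conf_level <- conf_level
  mk
}
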