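# Comparison machinery behind the readiness tables: normality gate,
# pooled two-group t-test, one-way ANOVA, Bonferroni pairwise contrasts,
# and a normal approximation working from published summary statistics.

#' Shapiro-Wilk normality gate
#'
#' Wraps [stats::shapiro.test()] and turns it into an advisory gate: the
#' data "pass" (are treated as compatible with normality) when p >= alpha.
#' Parametric comparisons downstream proceed either way; a failed gate is
#' reported via a warning, never a hard stop.
#'
#' @param scores numeric vector, 3 <= n <= 5000, non-constant.
#' @param alpha significance level of the gate.
#' @return list with `W`, `p_value`, `pass`.
#' @export
shapiro_wilk_gate <- function(scores, alpha = 0.05) {
  scores <- as.numeric(scores)
  if (length(scores) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(scores) == 0) {
    stop("Shapiro-Wilk test undefined for constant data", call. = FALSE)
  }
  ht <- stats::shapiro.test(scores)
  pass <- ht$p.value >= alpha
  if (!pass) {
    warning("normality gate failed (Shapiro-Wilk p = ",
            signif(ht$p.value, 3), "); parametric tests proceed regardless",
            call. = FALSE)
  }
  list(W = unname(ht$statistic), p_value = ht$p.value, pass = pass)
}

.comparison_result <- function(label, diff, stat, df, p, adj_p = NA_real_,
                               alpha = 0.05) {
  p_eff <- if (!is.na(adj_p)) adj_p else p
  list(contrast = label, absolute_difference_pct = abs(diff),
       statistic = stat, df = df, p_value = p, adjusted_p_value = adj_p,
       significant = p_eff < alpha)
}

#' Pooled-variance two-group t-test
#'
#' Student's independent-samples t-test with pooled variance (the classical
#' default, consistent with the ANOVA F = t^2 identity); a Welch switch is
#' available.
#'
#' @param a,b numeric vectors, each n >= 2.
#' @param label contrast label.
#' @param alpha significance level.
#' @param welch use the Welch (unequal-variance) test instead.
#' @return a comparison result: `contrast`, `absolute_difference_pct`,
#'   `statistic` (t), `df`, `p_value`, `significant`.
#' @export
two_group_test <- function(a, b, label = "a vs b", alpha = 0.05,
                           welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  .comparison_result(label, mean(a) - mean(b), unname(ht$statistic),
                     unname(ht$parameter), ht$p.value, alpha = alpha)
}

#' One-way analysis of variance
#'
#' Classical F-test from the between/within decomposition of sums of
#' squares. Data with zero total variance return F = 0, p = 1 rather than
#' erroring, so that fully tied groups are handled.
#'
#' @param groups named list of numeric vectors (>= 2 groups, total n >
#'   number of groups).
#' @return list with `F`, `df_between`, `df_within`, `p_value`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups) %||% seq_along(groups),
                       lengths(groups)))
  if (length(values) <= length(groups)) {
    stop("total n must exceed the number of groups", call. = FALSE)
  }
  if (stats::var(values) == 0) {
    return(list(F = 0, df_between = length(groups) - 1L,
                df_within = length(values) - length(groups), p_value = 1))
  }
  fit <- stats::aov(values ~ labels)
  tab <- summary(fit)[[1]]
  list(F = tab[["F value"]][1],
       df_between = tab[["Df"]][1],
       df_within = tab[["Df"]][2],
       p_value = tab[["Pr(>F)"]][1])
}

#' Bonferroni-adjusted pairwise contrasts
#'
#' All k(k-1)/2 pairwise pooled-variance t-tests among the groups, with
#' p-values multiplied by the number of comparisons and capped at 1. The
#' family is all pairwise contrasts within the one characteristic being
#' compared. By convention the contrasts are only run after a significant
#' omnibus ANOVA; `force = TRUE` overrides that guard.
#'
#' @param groups named list of numeric vectors.
#' @param alpha significance level for the omnibus guard and the flags.
#' @param force run the contrasts even when the ANOVA is not significant.
#' @return list of comparison results (one per pair), with attribute
#'   `family_size`.
#' @export
bonferroni_pairwise <- function(groups, alpha = 0.05, force = FALSE) {
  an <- one_way_anova(groups)
  if (an$p_value >= alpha && !force) {
    stop("omnibus ANOVA not significant (p = ", signif(an$p_value, 3),
         "); use force = TRUE to run pairwise contrasts anyway",
         call. = FALSE)
  }
  nm <- names(groups) %||% as.character(seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2)
  m <- ncol(pairs)
  out <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    r <- two_group_test(groups[[i1]], groups[[i2]],
                        label = paste(nm[i1], "vs", nm[i2]), alpha = alpha)
    r$adjusted_p_value <- min(1, r$p_value * m)
    r$significant <- r$adjusted_p_value < alpha
    r
  })
  attr(out, "family_size") <- m
  out
}

#' Approximate comparison from published summary statistics
#'
#' When only group means and standard errors are available (as in published
#' tables), compares two groups with the normal approximation
#' `z = (mean1 - mean2) / sqrt(se1^2 + se2^2)` and a two-sided normal
#' p-value. Labelled approximate: it ignores the t-distribution and any
#' covariance.
#'
#' @param mean1,se1,n1 first group's mean, standard error and size.
#' @param mean2,se2,n2 second group's mean, standard error and size.
#' @param label contrast label.
#' @param alpha significance level.
#' @return a comparison result with `statistic` = z and `df` = NA.
#' @export
#' @examples
#' compare_from_summaries(55.3, 1.26, 162, 49.3, 1.17, 238,
#'                        label = "urban vs rural")
compare_from_summaries <- function(mean1, se1, n1, mean2, se2, n2,
                                   label = "group1 vs group2", alpha = 0.05) {
  if (se1 < 0 || se2 < 0) stop("standard errors must be >= 0", call. = FALSE)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (se1 == 0 && se2 == 0) {
    stop("both standard errors are zero; comparison undefined", call. = FALSE)
  }
  z <- (mean1 - mean2) / sqrt(se1^2 + se2^2)
  p <- 2 * stats::pnorm(-abs(z))
  r <- .comparison_result(label, mean1 - mean2, z, NA_real_, p, alpha = alpha)
  r$approximate <- TRUE
  r
}

#' Compare a readiness measure across the levels of a stratifier
#'
#' Reproduces the published comparison workflow for one characteristic:
#' group summaries, then a pooled t-test when the stratifier has two
#' levels with n >= 2 each, or a one-way ANOVA followed (when significant)
#' by Bonferroni pairwise contrasts. Groups with fewer than 2 observations
#' are summarised but excluded from testing.
#'
#' @param readiness an `mdsr_readiness` table.
#' @param by stratifier column name.
#' @param measure score column (default `"overall_pct"`).
#' @param alpha significance level.
#' @return list with `summaries` (see [readiness_summary()]), `omnibus`
#'   (t-test or ANOVA result or `NULL`), and `contrasts` (possibly empty
#'   list of significant pairwise results).
#' @export
compare_groups <- function(readiness, by, measure = "overall_pct",
                           alpha = 0.05) {
  summaries <- readiness_summary(readiness, by, measure)
  groups <- split(readiness[[measure]], readiness[[by]])
  testable <- groups[lengths(groups) >= 2]
  omnibus <- NULL
  contrasts <- list()
  if (length(testable) == 2) {
    omnibus <- two_group_test(testable[[1]], testable[[2]],
                              label = paste(names(testable)[1], "vs",
                                            names(testable)[2]),
                              alpha = alpha)
    if (omnibus$significant) contrasts <- list(omnibus)
  } else if (length(testable) > 2) {
    omnibus <- one_way_anova(testable)
    if (omnibus$p_value < alpha) {
      all_pairs <- bonferroni_pairwise(testable, alpha = alpha)
      contrasts <- Filter(function(r) r$significant, all_pairs)
    }
  }
  list(by = by, measure = measure, summaries = summaries,
       omnibus = omnibus, contrasts = contrasts)
}
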