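# Multi-stage survey-design arithmetic: design effect, finite-population
# corrected stratum sizes, and PPS allocation across regions.

#' Design effect for cluster sampling
#'
#' `deff = 1 + (m - 1) * rho`, the variance inflation from sampling
#' clusters of mean size `m` with intra-cluster correlation `rho`.
#'
#' @param m mean cluster size, >= 1 (may be fractional).
#' @param rho intra-cluster correlation in \[0, 1\]; 0.33 is a common
#'   conservative choice.
#' @return the design effect.
#' @export
#' @examples
#' design_effect(1.6, 0.33)  # 1.198, ~1.2
design_effect <- function(m, rho) {
  if (any(m < 1)) stop("mean cluster size m must be >= 1", call. = FALSE)
  if (any(rho < 0 | rho > 1)) stop("rho must lie in [0, 1]", call. = FALSE)
  1 + (m - 1) * rho
}

#' Stratum sample size with finite-population correction
#'
#' The initial size is `n0 = z^2 * sigma2 / epsilon^2`; the stratum size
#' applies the finite-population correction `n0 * N / (n0 + N - 1)`, is
#' inflated by the design effect, rounded up, and capped at the stratum
#' population `N`. By default the design effect multiplies the corrected
#' size; `deff_before_fpc = TRUE` inflates `n0` before the correction.
#'
#' @param N stratum population size, >= 1.
#' @param sigma2 pooled variance of the performance measure, > 0.
#' @param epsilon margin of error, > 0 (same units as the measure).
#' @param z critical value of the standard normal (default 1.96).
#' @param deff design effect multiplier (default 1).
#' @param deff_before_fpc apply the design effect to `n0` before the
#'   finite-population correction.
#' @return integer sample size for the stratum.
#' @export
#' @examples
#' # n0 = 1000 via z = 1, sigma2 = 1000, epsilon = 1
#' stratum_sample_size(N = 302, sigma2 = 1000, epsilon = 1, z = 1)  # 233
stratum_sample_size <- function(N, sigma2, epsilon, z = 1.96, deff = 1,
                                deff_before_fpc = FALSE) {
  if (N < 1 || N != floor(N)) stop("N must be a positive integer", call. = FALSE)
  if (sigma2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  if (z <= 0) stop("z must be > 0", call. = FALSE)
  if (deff < 1) stop("deff must be >= 1", call. = FALSE)
  n0 <- z^2 * sigma2 / epsilon^2
  if (deff_before_fpc) n0 <- deff * n0
  ni <- n0 * N / (n0 + N - 1)
  if (!deff_before_fpc) ni <- deff * ni
  min(as.integer(ceiling(ni)), N)
}

#' Probability-proportional-to-size allocation
#'
#' Distributes a total sample of `n` across regions proportionally to
#' their population sizes: ideal shares `n * N_r / N` are integerised by
#' the largest-remainder method so the allocation sums to `n` exactly.
#'
#' @param n total sample size, >= 0.
#' @param region_sizes named numeric vector of region population sizes,
#'   all >= 0 with a positive sum.
#' @return named integer vector of allocated sizes summing to `n`.
#' @export
#' @examples
#' pps_allocate(629, c(a = 100, b = 200, c = 700))
pps_allocate <- function(n, region_sizes) {
  if (length(region_sizes) == 0) stop("empty region map", call. = FALSE)
  if (n < 0 || n != floor(n)) stop("n must be a non-negative integer", call. = FALSE)
  if (any(region_sizes < 0) || sum(region_sizes) <= 0) {
    stop("region sizes must be non-negative with a positive total", call. = FALSE)
  }
  share <- n * region_sizes / sum(region_sizes)
  base <- floor(share)
  rem <- n - sum(base)
  if (rem > 0) {
    # break remainder ties deterministically by region order
    extra <- order(share - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(region_sizes))
}

#' Build a full sampling plan
#'
#' Combines the design-effect, stratum-size and PPS-allocation arithmetic:
#' computes per-stratum sizes (e.g. health centres and hospitals), their
#' total, and a per-region allocation of the total by PPS.
#'
#' @param N_strata named vector of stratum population sizes.
#' @param sigma2,epsilon,z as in [stratum_sample_size()].
#' @param m,rho cluster parameters for [design_effect()].
#' @param region_sizes optional named vector of region sizes for the PPS
#'   allocation of the total sample.
#' @param deff_before_fpc see [stratum_sample_size()].
#' @return list of class `mdsr_sampling_plan`: `deff`, `n0`, `n_strata`,
#'   `n_total`, `allocation` (or `NULL`).
#' @export
sampling_plan <- function(N_strata, sigma2, epsilon, z = 1.96,
                          m = 1, rho = 0, region_sizes = NULL,
                          deff_before_fpc = FALSE) {
  deff <- design_effect(m, rho)
  n_strata <- vapply(N_strata, function(N) {
    stratum_sample_size(N, sigma2, epsilon, z, deff, deff_before_fpc)
  }, numeric(1))
  n_total <- sum(n_strata)
  allocation <- if (!is.null(region_sizes)) pps_allocate(n_total, region_sizes)
  structure(list(deff = deff, n0 = z^2 * sigma2 / epsilon^2,
                 n_strata = n_strata, n_total = n_total,
                 allocation = allocation),
            class = "mdsr_sampling_plan")
}

#' @export
print.mdsr_sampling_plan <- function(x, ...) {
  cat("Multi-stage sampling plan\n")
  cat(sprintf("  design effect %.3f, initial size n0 = %.1f\n", x$deff, x$n0))
  cat("  stratum sizes: ",
      paste(sprintf("%s=%d", names(x$n_strata), as.integer(x$n_strata)),
            collapse = ", "),
      " (total ", as.integer(x$n_total), ")\n", sep = "")
  if (!is.null(x$allocation)) {
    cat("  PPS allocation:\n")
    print(x$allocation)
  }
  invisible(x)
}
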