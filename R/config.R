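#' @keywords internal
"_PACKAGE"

# Canonical categorical domains for the facility survey table.
.mdsr_regions <- c(
  "Addis Ababa", "Afar", "Amhara", "Benishangul-Gumuz", "Dire Dawa",
  "Gambella", "Harari", "Oromia", "SNNPR", "Somali", "Tigray"
)
.mdsr_levels <- c("primary", "secondary", "tertiary")
.mdsr_locations <- c("rural", "urban")
.mdsr_region_types <- c("agrarian", "pastoralist", "city_administration")
.mdsr_agro_zones <- c("desert", "lowland", "midland", "highland", "upper_highland")
.mdsr_years <- c("lt2", "ge2")

.mdsr_indicators <- c("Rn", "CRn", "CRr", "Rr", "CRDp")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Display rounding used throughout published tables: half away from zero.
# base::round() rounds half to even, which would turn 44.925 into 44.92.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Dimension specifications for the facility readiness instrument
#'
#' The readiness questionnaire has four dimensions of yes/no items:
#' structure (7 items), core function (11), supportive function (10) and
#' system attributes (26 items partitioned into five subcategories:
#' simplicity 7, flexibility 2, acceptability 5, usefulness 8, stability 4).
#' Item identity is positional; columns are named `structure_1..7`,
#' `core_1..11`, `supportive_1..10` and `attr_<subcategory>_<k>`.
#'
#' @param weights named numeric vector of dimension weights summing to 1;
#'   default equal weights (0.25 each).
#' @return a named list of four dimension specs, each a list with elements
#'   `name`, `item_ids`, `weight` and (attributes only) `subcategories`.
#' @export
#' @examples
#' specs <- dimension_specs()
#' lengths(lapply(specs, `[[`, "item_ids"))
dimension_specs <- function(weights = c(structure = 0.25, core = 0.25,
                                        supportive = 0.25, attributes = 0.25)) {
  nm <- c("structure", "core", "supportive", "attributes")
  if (!all(nm %in% names(weights))) {
    stop("weights must be named for all four dimensions: ",
         paste(setdiff(nm, names(weights)), collapse = ", "))
  }
  weights <- weights[nm]
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("dimension weights must sum to 1 (got ", sum(weights), ")")
  }
  subcats <- list(
    simplicity    = paste0("attr_simplicity_", 1:7),
    flexibility   = paste0("attr_flexibility_", 1:2),
    acceptability = paste0("attr_acceptability_", 1:5),
    usefulness    = paste0("attr_usefulness_", 1:8),
    stability     = paste0("attr_stability_", 1:4)
  )
  list(
    structure = list(name = "structure", item_ids = paste0("structure_", 1:7),
                     weight = unname(weights["structure"])),
    core = list(name = "core", item_ids = paste0("core_", 1:11),
                weight = unname(weights["core"])),
    supportive = list(name = "supportive", item_ids = paste0("supportive_", 1:10),
                      weight = unname(weights["supportive"])),
    attributes = list(name = "attributes",
                      item_ids = unlist(subcats, use.names = FALSE),
                      subcategories = subcats,
                      weight = unname(weights["attributes"]))
  )
}

#' Evaluation configuration
#'
#' Bundles the tunable parameters of the evaluation pipeline: the dimension
#' specifications, the MDSRPI indicator weights, display rounding, the
#' significance level and the master random seed for stochastic modules.
#'
#' Default MDSRPI weights follow the national technical working group's
#' choice: the two coverage rates (representativeness) carry 0.3 each, the
#' review rate 0.2, and the notification rate and community proportion 0.1
#' each.
#'
#' @param dimension_weights passed to [dimension_specs()].
#' @param mdsrpi_weights named vector over `Rn, CRn, CRr, Rr, CRDp`, summing
#'   to 1.
#' @param rounding_decimals decimals used for display rounding.
#' @param alpha two-sided significance level.
#' @param seed integer master seed.
#' @return an object of class `mdsr_config`.
#' @export
evaluation_config <- function(dimension_weights = c(structure = 0.25, core = 0.25,
                                                    supportive = 0.25, attributes = 0.25),
                              mdsrpi_weights = c(Rn = 0.1, CRn = 0.3, CRr = 0.3,
                                                 Rr = 0.2, CRDp = 0.1),
                              rounding_decimals = 1,
                              alpha = 0.05,
                              seed = 20200101L) {
  if (!all(.mdsr_indicators %in% names(mdsrpi_weights))) {
    stop("mdsrpi_weights must be named for all of: ",
         paste(.mdsr_indicators, collapse = ", "))
  }
  mdsrpi_weights <- mdsrpi_weights[.mdsr_indicators]
  if (abs(sum(mdsrpi_weights) - 1) > 1e-9) {
    stop("mdsrpi_weights must sum to 1 (got ", sum(mdsrpi_weights), ")")
  }
  stopifnot(alpha > 0, alpha < 1, rounding_decimals >= 0)
  structure(
    list(
      dimension_specs = dimension_specs(dimension_weights),
      mdsrpi_weights = mdsrpi_weights,
      rounding_decimals = as.integer(rounding_decimals),
      alpha = alpha,
      seed = as.integer(seed)
    ),
    class = "mdsr_config"
  )
}

#' Read an evaluation configuration from a YAML file
#'
#' Recognised top-level keys: `dimension_weights`, `mdsrpi_weights`,
#' `rounding_decimals`, `alpha`, `seed`. Missing keys fall back to the
#' defaults of [evaluation_config()].
#'
#' @param path YAML file path.
#' @return an `mdsr_config` object.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$dimension_weights)) args$dimension_weights <- unlist(y$dimension_weights)
  if (!is.null(y$mdsrpi_weights)) args$mdsrpi_weights <- unlist(y$mdsrpi_weights)
  for (k in c("rounding_decimals", "alpha", "seed")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(evaluation_config, args)
}

#' @export
print.mdsr_config <- function(x, ...) {
  cat("MDSR evaluation configuration\n")
  cat("  dimension weights: ",
      paste(sprintf("%s=%.2f", names(x$dimension_specs),
                    vapply(x$dimension_specs, `[[`, numeric(1), "weight")),
            collapse = ", "), "\n", sep = "")
  cat("  MDSRPI weights:    ",
      paste(sprintf("%s=%.2f", names(x$mdsrpi_weights), x$mdsrpi_weights),
            collapse = ", "), "\n", sep = "")
  cat("  alpha: ", x$alpha, "; rounding: ", x$rounding_decimals,
      " dp; seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

#' All item column names of the facility survey table
#' @param specs dimension specs as returned by [dimension_specs()].
#' @return character vector of 54 item column names.
#' @export
item_columns <- function(specs = dimension_specs()) {
  unlist(lapply(specs, `[[`, "item_ids"), use.names = FALSE)
}
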