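# Synthetic survey, count-panel and trend-series generators. These emulate
# the statistical structure the pipeline assumes (exchangeable Bernoulli
# items within dimensions, a binomial surveillance cascade per region, a
# linear-plus-noise yearly share) so every stage is testable without raw
# survey data, and so parameter-recovery checks are possible.

# ethiopia2020 calibration profile: regional facility counts and
# categorical mixes of the 400 implementing facilities, national dimension
# means as yes-probabilities, and the national cascade ratios.
.ethiopia2020_region_counts <- c(
  "Addis Ababa" = 17, "Afar" = 2, "Amhara" = 112, "Benishangul-Gumuz" = 10,
  "Dire Dawa" = 4, "Gambella" = 4, "Harari" = 2, "Oromia" = 170,
  "SNNPR" = 52, "Somali" = 2, "Tigray" = 25
)

.ethiopia2020_region_type <- c(
  "Addis Ababa" = "city_administration", "Dire Dawa" = "city_administration",
  "Harari" = "city_administration",
  "Afar" = "pastoralist", "Somali" = "pastoralist",
  "Gambella" = "pastoralist", "Benishangul-Gumuz" = "pastoralist",
  "Amhara" = "agrarian", "Oromia" = "agrarian", "SNNPR" = "agrarian",
  "Tigray" = "agrarian"
)

#' Configuration for the synthetic-data generators
#'
#' Defaults are the "ethiopia2020" calibration profile: regional facility
#' counts and categorical mixes matching the 400 implementing facilities
#' of the 2020 Ethiopian evaluation; per-dimension yes-probabilities equal
#' to the published national dimension means (0.517, 0.200, 0.384, 0.696);
#' an implementing (inclusion) probability of 0.77 (400/519); cascade
#' probabilities equal to the national count ratios of
#' [ethiopia_mdsr_counts()]; and a community-review share declining
#' linearly from 100 over 2013-2020.
#'
#' @param seed master integer seed; every generator is reproducible from it.
#' @param region_counts named integer vector: facilities per region.
#' @param dimension_probs named vector of per-dimension yes-probabilities.
#' @param region_effects named vector of additive per-region offsets on the
#'   yes-probabilities (defaults to 0); results are clamped to \[0, 1\].
#' @param level_probs,location_probs,agro_zone_probs,years_probs
#'   categorical mixes for the remaining stratifiers.
#' @param inclusion_prob probability that a facility is MDSR-implementing.
#' @param panel_params data frame with `region, expected, p_identify,
#'   p_notify, p_review, p_community`.
#' @param years year range of the trend series.
#' @param trend list with `intercept`, `slope_per_year`, `noise_sd` (all on
#'   the percent scale).
#' @return list of class `mdsr_synth_config`.
#' @export
synth_config <- function(seed = 20200101L,
                         region_counts = .ethiopia2020_region_counts,
                         dimension_probs = c(structure = 0.517, core = 0.200,
                                             supportive = 0.384,
                                             attributes = 0.696),
                         region_effects = NULL,
                         level_probs = c(primary = 0.893, secondary = 0.073,
                                         tertiary = 0.035),
                         location_probs = c(rural = 0.595, urban = 0.405),
                         agro_zone_probs = c(desert = 0.015, lowland = 0.1425,
                                             midland = 0.5175,
                                             highland = 0.3175,
                                             upper_highland = 0.0075),
                         years_probs = c(lt2 = 0.215, ge2 = 0.785),
                         inclusion_prob = 0.77,
                         panel_params = NULL,
                         years = 2013:2020,
                         trend = list(intercept = 100,
                                      slope_per_year = -8.33,
                                      noise_sd = 5)) {
  if (is.null(panel_params)) {
    panel_params <- data.frame(
      region = names(region_counts),
      expected = c("Addis Ababa" = 2268, "Afar" = 1273, "Amhara" = 10552,
                   "Benishangul-Gumuz" = 857, "Dire Dawa" = 371,
                   "Gambella" = 381, "Harari" = 190, "Oromia" = 25183,
                   "SNNPR" = 12648, "Somali" = 4201,
                   "Tigray" = 2715)[names(region_counts)],
      p_identify = 0.123, p_notify = 0.763, p_review = 0.606,
      p_community = 0.535,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  probs <- c(dimension_probs, inclusion_prob, level_probs, location_probs,
             agro_zone_probs, years_probs,
             unlist(panel_params[c("p_identify", "p_notify", "p_review",
                                   "p_community")]))
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(region_counts < 1) || any(panel_params$expected < 1)) {
    stop("facility counts and expected deaths must be >= 1", call. = FALSE)
  }
  if (length(years) == 0) stop("empty year range", call. = FALSE)
  if (is.null(region_effects)) {
    region_effects <- stats::setNames(rep(0, length(region_counts)),
                                      names(region_counts))
  }
  structure(list(seed = as.integer(seed), region_counts = region_counts,
                 dimension_probs = dimension_probs,
                 region_effects = region_effects,
                 level_probs = level_probs, location_probs = location_probs,
                 agro_zone_probs = agro_zone_probs, years_probs = years_probs,
                 inclusion_prob = inclusion_prob,
                 panel_params = panel_params, years = years, trend = trend),
            class = "mdsr_synth_config")
}

.sample_cat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic facility survey table
#'
#' Each facility draws its stratifiers from the configured categorical
#' mixes (region membership follows the fixed per-region counts; region
#' type is the fixed region-to-type map), and each of the 54 binary items
#' independently from Bernoulli(dimension probability + region effect).
#' Whether a facility is implementing (notified and reviewed >= 1 in the
#' last year) is Bernoulli(`inclusion_prob`); the eligibility counts are
#' drawn accordingly. Fully reproducible from the config seed.
#'
#' @param config an [synth_config()] object.
#' @return a validated facility table (see [read_facility_table()]).
#' @export
gen_facility_survey <- function(config = synth_config()) {
  set.seed(config$seed)
  specs <- dimension_specs()
  region <- rep(names(config$region_counts), config$region_counts)
  n <- length(region)
  df <- data.frame(
    facility_id = sprintf("F%04d", seq_len(n)),
    region = region,
    facility_level = .sample_cat(n, config$level_probs),
    location = .sample_cat(n, config$location_probs),
    region_type = unname(.ethiopia2020_region_type[region]),
    agro_zone = .sample_cat(n, config$agro_zone_probs),
    years_implementing = .sample_cat(n, config$years_probs),
    stringsAsFactors = FALSE
  )
  implementing <- stats::rbinom(n, 1, config$inclusion_prob) == 1
  notified <- integer(n); reviewed <- integer(n)
  notified[implementing] <- 1L + stats::rpois(sum(implementing), 0.8)
  reviewed[implementing] <- 1L + stats::rpois(sum(implementing), 0.5)
  # non-implementing facilities fail at least one leg of the criterion
  ni <- which(!implementing)
  mode <- sample(3, length(ni), replace = TRUE)
  notified[ni[mode == 2]] <- 1L + stats::rpois(sum(mode == 2), 0.5)
  reviewed[ni[mode == 3]] <- 1L + stats::rpois(sum(mode == 3), 0.5)
  df$notified_last_year <- notified
  df$reviewed_last_year <- reviewed
  eff <- config$region_effects[region]
  eff[is.na(eff)] <- 0
  for (d in names(specs)) {
    p <- pmin(pmax(config$dimension_probs[[d]] + eff, 0), 1)
    for (id in specs[[d]]$item_ids) {
      df[[id]] <- stats::rbinom(n, 1, p)
    }
  }
  validate_facility_table(df)
}

#' Generate a synthetic regional count panel
#'
#' Per region the surveillance cascade is binomial: identified ~
#' Binomial(expected, p_identify); notified ~ Binomial(identified,
#' p_notify); reviewed ~ Binomial(identified, p_review) — drawn from
#' identified rather than notified, so that review rates above 100% are
#' reachable, as observed in practice; reviewed_community ~
#' Binomial(reviewed, p_community), with the facility count as the
#' remainder.
#'
#' @param config an [synth_config()] object.
#' @param seed_offset added to the config seed, so replicate panels can be
#'   drawn from one config.
#' @return a validated count panel.
#' @export
gen_count_panel <- function(config = synth_config(), seed_offset = 0L) {
  set.seed(config$seed + seed_offset)
  pp <- config$panel_params
  identified <- stats::rbinom(nrow(pp), pp$expected, pp$p_identify)
  notified <- stats::rbinom(nrow(pp), identified, pp$p_notify)
  reviewed <- stats::rbinom(nrow(pp), identified, pp$p_review)
  community <- stats::rbinom(nrow(pp), reviewed, pp$p_community)
  validate_count_panel(data.frame(
    region = pp$region, expected = pp$expected, identified = identified,
    notified = notified, reviewed = reviewed,
    reviewed_community = community,
    reviewed_facility = reviewed - community,
    stringsAsFactors = FALSE
  ))
}

#' Generate a synthetic yearly trend series
#'
#' `value(year) = intercept + slope_per_year * (year - first year) +
#' N(0, noise_sd)`, clipped to \[0, 100\]. With the default profile this
#' emulates a community-review share declining from 100% toward ~42% over
#' 2013-2020.
#'
#' @param config an [synth_config()] object.
#' @param seed_offset added to the config seed for replicate series.
#' @return data frame with columns `year`, `value`.
#' @export
gen_trend_series <- function(config = synth_config(), seed_offset = 0L) {
  if (length(config$years) == 0) stop("empty year range", call. = FALSE)
  set.seed(config$seed + seed_offset)
  t0 <- config$years[1]
  mu <- config$trend$intercept +
    config$trend$slope_per_year * (config$years - t0)
  v <- mu + stats::rnorm(length(config$years), 0, config$trend$noise_sd)
  data.frame(year = config$years, value = pmin(pmax(v, 0), 100))
}
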