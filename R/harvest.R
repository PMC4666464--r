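#' Fishing mortality at maximum sustainable yield
#'
#' The life-history-invariant approximation \eqn{F_{MSY} = 0.87 M}.
#'
#' @param m Natural mortality (1/yr), >= 0. Vectorized.
#' @return F_MSY (1/yr).
#' @examples
#' fmsy_from_m(0.37) # 0.3219
#' @export
fmsy_from_m <- function(m) {
  if (any(m < 0)) stop("m must be >= 0", call. = FALSE)
  0.87 * m
}

#' Stock biomass from areal density and habitat area
#'
#' @param density_kg_ha Biomass density (kg per hectare), e.g. from a
#'   hydroacoustic survey.
#' @param area Habitat area, in hectares by default.
#' @param area_unit `"ha"` or `"km2"` (converted at 100 ha per km^2).
#' @return Stock biomass (kg).
#' @examples
#' stock_biomass(4.4, 276000) # 1,214,400 kg
#' @export
stock_biomass <- function(density_kg_ha, area, area_unit = c("ha", "km2")) {
  area_unit <- match.arg(area_unit)
  check_nonneg(density_kg_ha, "density_kg_ha")
  check_positive(area, "area")
  if (area_unit == "km2") area <- area * 100
  density_kg_ha * area
}

#' Maximum sustainable yield from F_MSY and biomass
#'
#' \eqn{MSY = (1 - e^{-F_{MSY}})\, B}: the annual removal implied by fishing
#' the stock at rate F_MSY. Bounded above by the biomass itself.
#'
#' @param f_msy Fishing mortality at MSY (1/yr), >= 0. Vectorized.
#' @param biomass Stock biomass (kg), >= 0.
#' @return MSY (kg per year).
#' @examples
#' msy(0.25, 1e6) # 221,199 kg
#' @export
msy <- function(f_msy, biomass) {
  if (any(f_msy < 0)) stop("f_msy must be >= 0", call. = FALSE)
  if (any(biomass < 0)) stop("biomass must be >= 0", call. = FALSE)
  (1 - exp(-f_msy)) * biomass
}

#' Assessment input vector
#'
#' The constants that turn an MSY into effort scenarios: how much a night of
#' fishing catches, how often a fisher fishes, and how many families live
#' around the fishery. Defaults describe a subsistence gillnet fishery where
#' a fisher deploys 50 m of optimal-mesh gillnet per night.
#'
#' @param z Total mortality (1/yr).
#' @param biomass_density_kg_ha Areal biomass density (kg/ha).
#' @param area_ha Habitat area (ha).
#' @param catch_per_night_kg Catch per fisher-night (kg).
#' @param nights_per_fisher_yr Nights fished per fisher per year.
#' @param population Resident population (people).
#' @param household_size People per family.
#' @return An object of class `assessment_inputs`.
#' @export
assessment_inputs <- function(z = 0.42,
                              biomass_density_kg_ha = 4.4,
                              area_ha = 276000,
                              catch_per_night_kg = 15,
                              nights_per_fisher_yr = 100,
                              population = 5440,
                              household_size = 3.6) {
  check_nonneg(z, "z")
  check_positive(biomass_density_kg_ha, "biomass_density_kg_ha")
  check_positive(area_ha, "area_ha")
  check_positive(catch_per_night_kg, "catch_per_night_kg")
  check_positive(nights_per_fisher_yr, "nights_per_fisher_yr")
  check_positive(population, "population")
  check_positive(household_size, "household_size")
  structure(
    list(z = z, biomass_density_kg_ha = biomass_density_kg_ha,
         area_ha = area_ha, catch_per_night_kg = catch_per_night_kg,
         nights_per_fisher_yr = nights_per_fisher_yr,
         population = population, household_size = household_size),
    class = "assessment_inputs"
  )
}

#' Effort required to take a given yield
#'
#' Converts an annual yield into the fishing effort needed to realize it:
#' nights of gillnetting, full-time-equivalent fishers, and the share of
#' resident families those fishers represent. All quantities are linear in
#' `msy_kg`; `percent_families` equals
#' \eqn{100\,\mathrm{nights}/(\mathrm{nights\ per\ fisher}\times\mathrm{families})}.
#'
#' @param msy_kg Annual yield to realize (kg/yr), >= 0.
#' @param inputs An [assessment_inputs] object.
#' @return A one-row tibble: `msy_kg`, `nights`, `fishers`, `families`,
#'   `percent_families`, `nights_per_family`. Full precision; use
#'   [format_assessment()] for display rounding.
#' @examples
#' effort_requirements(330869, assessment_inputs())
#' @export
effort_requirements <- function(msy_kg, inputs = assessment_inputs()) {
  if (!inherits(inputs, "assessment_inputs")) {
    stop("`inputs` must be an assessment_inputs object", call. = FALSE)
  }
  if (any(msy_kg < 0)) stop("msy_kg must be >= 0", call. = FALSE)
  nights <- msy_kg / inputs$catch_per_night_kg
  fishers <- nights / inputs$nights_per_fisher_yr
  families <- inputs$population / inputs$household_size  # kept unrounded
  tibble::tibble(
    msy_kg = msy_kg,
    nights = nights,
    fishers = fishers,
    families = families,
    percent_families = 100 * fishers / families,
    nights_per_family = nights / families
  )
}

#' Data-poor assessment table: from natural mortality to effort scenarios
#'
#' Runs the full chain per estimator: M (from life history, or supplied
#' directly) -> F = Z - M -> F_MSY = 0.87 M -> MSY = (1 - e^{-F_MSY}) B ->
#' nights / fishers / percent of families. Every column is carried at full
#' precision; [format_assessment()] produces the display-precision twin.
#'
#' @param life A [life_history], used to compute M per method; ignored when
#'   `m` is given.
#' @param m Optional named numeric vector of natural mortality rates (1/yr),
#'   names taken as method labels, bypassing the life-history estimators.
#' @param inputs An [assessment_inputs]; its `z` feeds F = Z - M and its
#'   density and area give the biomass.
#' @param methods Methods to run when deriving M from `life` (default all
#'   available).
#' @return A tibble with one row per method: `method`, `m`, `f`, `f_msy`,
#'   `biomass_kg`, `msy_kg`, `nights`, `fishers`, `percent_families`,
#'   `nights_per_family`, `f_negative`.
#' @examples
#' assessment_table(grayling_life_history())
#' assessment_table(m = c(hoenig_nls = 0.37, pauly_nls_t = 0.27,
#'                        gunderson = 0.30))
#' @export
assessment_table <- function(life = NULL, m = NULL,
                             inputs = assessment_inputs(),
                             methods = "all") {
  if (is.null(m)) {
    if (is.null(life)) stop("supply either `life` or `m`", call. = FALSE)
    est <- natural_mortality(life, method = methods)
    m <- setNames(est$m, est$method)
  }
  if (is.null(names(m)) || any(!nzchar(names(m)))) {
    stop("`m` must be a named vector (method labels)", call. = FALSE)
  }
  biomass <- stock_biomass(inputs$biomass_density_kg_ha, inputs$area_ha)
  f <- inputs$z - m
  f_msy <- fmsy_from_m(m)
  yield <- unname(msy(f_msy, biomass))
  eff <- effort_requirements(yield, inputs)
  tibble::tibble(
    method = names(m),
    m = unname(m),
    f = unname(f),
    f_negative = unname(f < 0),
    f_msy = unname(f_msy),
    biomass_kg = biomass,
    msy_kg = eff$msy_kg,
    nights = eff$nights,
    fishers = eff$fishers,
    percent_families = eff$percent_families,
    nights_per_family = eff$nights_per_family
  )
}

#' Display-precision view of an assessment table
#'
#' Rounds half away from zero to the conventions of published data-poor
#' assessment tables: mortality rates to 2 decimals; MSY and nights to whole
#' numbers; fishers, percent of families and nights per family to 1 decimal.
#'
#' @param tbl A tibble from [assessment_table()] or [effort_requirements()].
#' @return The tibble with display rounding applied.
#' @export
format_assessment <- function(tbl) {
  two <- intersect(c("m", "f", "f_msy"), names(tbl))
  whole <- intersect(c("biomass_kg", "msy_kg", "nights"), names(tbl))
  one <- intersect(c("fishers", "percent_families", "nights_per_family"),
                   names(tbl))
  for (cl in two) tbl[[cl]] <- round_half_up(tbl[[cl]], 2)
  for (cl in whole) tbl[[cl]] <- round_half_up(tbl[[cl]], 0)
  for (cl in one) tbl[[cl]] <- round_half_up(tbl[[cl]], 1)
  tbl
}

#' Annual removals implied by a reported spawning-run fishery
#'
#' Rangers or observers often describe a migration fishery as a set of
#' periods, each with a day count and a low-high range of fish removed per
#' day. This calculator sums days x daily removals over periods at a chosen
#' point of the range and reports the full low-high envelope alongside.
#'
#' @param periods A data frame with columns `days`, `low`, `high` (daily
#'   removals; `low <= high`), one row per period.
#' @param rule Which point of each period's range to use: `"low"`, `"mid"`
#'   (default), or `"high"`.
#' @return A list: `removals` (fish/yr at the chosen point), `low`, `high`
#'   (the envelope), and `periods` echoed.
#' @examples
#' runs <- data.frame(days = c(6, 20), low = c(3600, 1000),
#'                    high = c(3600, 1500))
#' spawning_run_removal(runs) # envelope 41,600 - 51,600
#' @export
spawning_run_removal <- function(periods, rule = c("mid", "low", "high")) {
  rule <- match.arg(rule)
  if (is.null(periods) || nrow(periods) == 0L) {
    stop("at least one period is required", call. = FALSE)
  }
  check_cols(periods, c("days", "low", "high"), "spawning-run report")
  if (any(periods$days < 0)) stop("days must be >= 0", call. = FALSE)
  if (any(periods$low > periods$high)) {
    stop("each period needs low <= high", call. = FALSE)
  }
  pt <- switch(rule,
               low = periods$low,
               high = periods$high,
               mid = (periods$low + periods$high) / 2)
  list(
    removals = sum(periods$days * pt),
    low = sum(periods$days * periods$low),
    high = sum(periods$days * periods$high),
    rule = rule,
    periods = tibble::as_tibble(periods)
  )
}
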