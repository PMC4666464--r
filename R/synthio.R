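#' Configuration for the age-structured population simulator
#'
#' Describes a closed population at steady state under a constant total
#' mortality rate Z, with von Bertalanffy mean growth and multiplicative
#' length-at-age variability.
#'
#' @param life A [life_history]; its `t_max` bounds the age distribution.
#' @param z Total mortality rate (1/yr), >= 0.
#' @param n_fish Number of fish to draw, >= 1.
#' @param recruit_age Youngest age present in the sample (yr); must be less
#'   than `t_max`. Default 2, a typical age at full recruitment to the gear.
#' @param length_cv Coefficient of variation of length at age (lognormal
#'   multiplicative noise); in `[0, 0.5)`. Default 0.08.
#' @param seed Random seed (explicit, never global state), or `NULL`.
#' @return An object of class `population_sim_config`.
#' @export
population_sim_config <- function(life, z, n_fish, recruit_age = 2,
                                  length_cv = 0.08, seed = NULL) {
  if (!inherits(life, "life_history")) {
    stop("invalid `life`: must be a life_history object", call. = FALSE)
  }
  check_nonneg(z, "z")
  check_that(is.numeric(n_fish) && length(n_fish) == 1L && n_fish >= 1,
             "n_fish", "must be >= 1")
  check_that(is.numeric(length_cv) && length_cv >= 0 && length_cv < 0.5,
             "length_cv", "must lie in [0, 0.5)")
  check_that(is.na(life$t_max) || recruit_age < life$t_max,
             "recruit_age", "must be less than t_max")
  check_nonneg(recruit_age, "recruit_age")
  structure(
    list(life = life, z = z, n_fish = as.integer(n_fish),
         recruit_age = recruit_age, length_cv = length_cv, seed = seed),
    class = "population_sim_config"
  )
}

#' Simulate a length-and-age sample from a steady-state population
#'
#' Ages are drawn from the truncated exponential with density proportional to
#' \eqn{e^{-Z a}} on `[recruit_age, t_max]` (uniform when Z = 0) — the age
#' structure of a cohort declining at constant total mortality. Lengths are
#' the von Bertalanffy mean at age times lognormal noise with coefficient of
#' variation `length_cv` (exactly on the curve when `length_cv = 0`).
#'
#' @param cfg A [population_sim_config].
#' @return A tibble with `age_yr` and `length_mm` (fish lengths are carried
#'   in mm; the growth curve's Linf is cm).
#' @examples
#' pop <- simulate_population(population_sim_config(
#'   grayling_life_history(), z = 0.42, n_fish = 1000, seed = 7))
#' head(pop)
#' @export
simulate_population <- function(cfg) {
  if (!inherits(cfg, "population_sim_config")) {
    stop("invalid `cfg`: must be a population_sim_config", call. = FALSE)
  }
  life <- cfg$life
  if (is.na(life$t_max)) stop("invalid `life$t_max`: required", call. = FALSE)
  a0 <- cfg$recruit_age; a1 <- life$t_max
  with_seed_or_not(cfg$seed, {
    u <- runif(cfg$n_fish)
    ages <- if (cfg$z == 0) {
      a0 + u * (a1 - a0)
    } else {
      # inverse CDF of the exponential truncated to [a0, a1]
      -log(exp(-cfg$z * a0) - u * (exp(-cfg$z * a0) - exp(-cfg$z * a1))) / cfg$z
    }
    mean_len_mm <- 10 * vb_length(ages, life)
    len <- if (cfg$length_cv == 0) {
      mean_len_mm
    } else {
      sdlog <- sqrt(log(1 + cfg$length_cv^2))
      mean_len_mm * rlnorm(cfg$n_fish, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    tibble::tibble(age_yr = ages, length_mm = len)
  })
}

#' Gillnet monitoring survey design
#'
#' Defaults mirror a sequential-mesh monitoring design: 2 nets at each of 7
#' sites over 4 survey years, each net carrying five 4-m panels of
#' 2.54/3.81/5.08/6.35/7.62 cm bar mesh, fished for one night per set.
#'
#' @param sites Character vector of site identifiers.
#' @param years Integer vector of survey years.
#' @param nets_per_site Nets set per site per year.
#' @param panel_meshes Bar mesh sizes (cm), distinct and positive.
#' @param panel_length_m Length of each panel (m).
#' @param panel_depth_m Depth of each panel (m).
#' @param soak_nights Nights per set (the effort unit; overnight soaks of
#'   8.5-10.5 hr all count as one night).
#' @return An object of class `survey_design`.
#' @export
survey_design <- function(sites = paste0("S", 1:7),
                          years = c(2009, 2011, 2012, 2013),
                          nets_per_site = 2,
                          panel_meshes = c(2.54, 3.81, 5.08, 6.35, 7.62),
                          panel_length_m = 4,
                          panel_depth_m = 2,
                          soak_nights = 1) {
  check_that(length(sites) >= 0 && !anyDuplicated(sites), "sites",
             "must be unique identifiers")
  check_that(all(panel_meshes > 0) && !anyDuplicated(panel_meshes),
             "panel_meshes", "must be distinct positive mesh sizes")
  check_positive(panel_length_m, "panel_length_m")
  check_positive(panel_depth_m, "panel_depth_m")
  check_that(nets_per_site >= 1, "nets_per_site", "must be >= 1")
  check_that(soak_nights >= 1, "soak_nights", "must be >= 1")
  structure(
    list(sites = sites, years = years, nets_per_site = nets_per_site,
         panel_meshes = panel_meshes, panel_length_m = panel_length_m,
         panel_depth_m = panel_depth_m, soak_nights = soak_nights),
    class = "survey_design"
  )
}

#' Per-species generative parameters for the catch-survey simulator
#'
#' Expected catches follow a log-linear model: the log of the expected
#' set-level count is `log_cpue0 + year_slope * (year - first year) +`
#' a site random intercept with SD `site_sd`; counts are Poisson (or
#' negative-binomial) and are allocated across mesh panels in proportion to a
#' lognormal selectivity curve evaluated at the species' modal length.
#' Individual lengths are lognormal around `sel_mult * mesh` (the optimal
#' length for the capturing mesh), shifted by `size_slope` per year on the
#' log scale; weights follow the allometry `w = a l^b` times optional
#' lognormal noise.
#'
#' @param species Species label.
#' @param log_cpue0 Log expected count per net-night in the first year.
#' @param year_slope Year effect on log expected count (1/yr).
#' @param site_sd SD of the site random intercept (log scale), >= 0.
#' @param family `"poisson"` (default) or `"nbinom"` for overdispersed
#'   counts.
#' @param dispersion Negative-binomial size parameter, > 0 (ignored for
#'   Poisson).
#' @param lw_a,lw_b Length-weight coefficients, `w_g = lw_a * l_mm^lw_b`;
#'   `lw_b` in `[2.5, 3.5]` for realism.
#' @param sel_mult Optimal length (mm) per cm of bar mesh.
#' @param sel_spread Relative spread of the selectivity curve (sdlog of the
#'   lognormal in length), > 0.
#' @param modal_length_mm Modal length of the vulnerable population (mm),
#'   used to weight catch across panels.
#' @param size_slope Year effect on log mean length (1/yr); negative values
#'   emulate shrinking body size.
#' @param weight_sigma SD of lognormal weight noise (log scale); 0 means
#'   weights sit exactly on the allometric curve.
#' @return An object of class `species_config`.
#' @export
species_config <- function(species = "grayling",
                           log_cpue0 = log(15),
                           year_slope = 0,
                           site_sd = 0.3,
                           family = c("poisson", "nbinom"),
                           dispersion = 5,
                           lw_a = 1e-5, lw_b = 3,
                           sel_mult = 110,
                           sel_spread = 0.15,
                           modal_length_mm = 280,
                           size_slope = 0,
                           weight_sigma = 0) {
  family <- match.arg(family)
  check_nonneg(site_sd, "site_sd")
  if (family == "nbinom") check_positive(dispersion, "dispersion")
  check_positive(lw_a, "lw_a")
  check_that(lw_b >= 2.5 && lw_b <= 3.5, "lw_b",
             "must lie in [2.5, 3.5] for a plausible allometry")
  check_positive(sel_mult, "sel_mult")
  check_positive(sel_spread, "sel_spread")
  check_positive(modal_length_mm, "modal_length_mm")
  check_nonneg(weight_sigma, "weight_sigma")
  structure(
    list(species = species, log_cpue0 = log_cpue0, year_slope = year_slope,
         site_sd = site_sd, family = family, dispersion = dispersion,
         lw_a = lw_a, lw_b = lw_b, sel_mult = sel_mult,
         sel_spread = sel_spread, modal_length_mm = modal_length_mm,
         size_slope = size_slope, weight_sigma = weight_sigma),
    class = "species_config"
  )
}

#' Simulate a multi-mesh gillnet monitoring survey
#'
#' Draws a full catch-and-effort dataset under [survey_design] and a list of
#' [species_config]s: a `sets` table (one row per site x year x net), a
#' `panels` table (one row per set x mesh), and a `catch` table (one row per
#' captured fish, with panel mesh, length and weight).
#'
#' @param design A [survey_design].
#' @param community A [species_config] or list of them.
#' @param seed Random seed, or `NULL`.
#' @return A list of tibbles: `sets`, `panels`, `catch`.
#' @examples
#' sim <- simulate_catch_survey(survey_design(),
#'                              species_config(year_slope = -0.1), seed = 1)
#' nrow(sim$catch)
#' @export
simulate_catch_survey <- function(design, community, seed = NULL) {
  if (!inherits(design, "survey_design")) {
    stop("invalid `design`: must be a survey_design", call. = FALSE)
  }
  if (inherits(community, "species_config")) community <- list(community)
  if (length(design$sites) == 0L || length(design$years) == 0L) {
    stop("survey design needs at least one site and one year", call. = FALSE)
  }

  sets <- tidyr::expand_grid(site = design$sites, year = design$years,
                             net = seq_len(design$nets_per_site))
  sets$set_id <- sprintf("%s_%d_n%d", sets$site, sets$year, sets$net)
  year0 <- min(design$years)

  with_seed_or_not(seed, {
    sets$soak_hr <- round(runif(nrow(sets), 8.5, 10.5), 1)
    sets$nights <- design$soak_nights
    panels <- tidyr::expand_grid(set_id = sets$set_id,
                                 mesh_cm = design$panel_meshes)
    panels$length_m <- design$panel_length_m

    catch <- lapply(community, function(sp) {
      site_eff <- setNames(rnorm(length(design$sites), 0, sp$site_sd),
                           design$sites)
      # share of the set-level expectation taken by each mesh panel:
      # selectivity at the species' modal length, normalized
      share <- stats::dlnorm(sp$modal_length_mm,
                             meanlog = log(sp$sel_mult * design$panel_meshes),
                             sdlog = sp$sel_spread)
      if (sum(share) == 0) share <- rep(1, length(share))
      share <- share / sum(share)

      rows <- Map(function(set_id, site, year) {
        lambda_set <- exp(sp$log_cpue0 + sp$year_slope * (year - year0) +
                            site_eff[[site]]) * sets$nights[1]
        lam <- lambda_set * share
        n <- if (sp$family == "poisson") {
          rpois(length(lam), lam)
        } else {
          rnbinom(length(lam), mu = lam, size = sp$dispersion)
        }
        if (sum(n) == 0L) return(NULL)
        mesh <- rep(design$panel_meshes, n)
        len <- rlnorm(sum(n),
                      meanlog = log(sp$sel_mult * mesh) +
                        sp$size_slope * (year - year0),
                      sdlog = sp$sel_spread)
        w <- sp$lw_a * len^sp$lw_b
        if (sp$weight_sigma > 0) {
          w <- w * rlnorm(sum(n), -sp$weight_sigma^2 / 2, sp$weight_sigma)
        }
        tibble::tibble(set_id = set_id, mesh_cm = mesh, species = sp$species,
                       length_mm = len, weight_g = w)
      }, sets$set_id, sets$site, sets$year)
      dplyr::bind_rows(rows)
    })
    catch <- dplyr::bind_rows(catch)
    if (nrow(catch) == 0L) {
      catch <- tibble::tibble(set_id = character(), mesh_cm = numeric(),
                              species = character(), length_mm = numeric(),
                              weight_g = numeric())
    }
    list(
      sets = tibble::as_tibble(sets[, c("set_id", "site", "year", "net",
                                        "soak_hr", "nights")]),
      panels = tibble::as_tibble(panels),
      catch = catch
    )
  })
}

#' Simulate a derelict-gear transect survey
#'
#' Item counts per transect and category are Poisson with mean
#' `density x transect length`; item weights are lognormal around the
#' category mean; net-bearing items (`whole_net`, `net_fragment`) are
#' assigned a mesh size from `mesh_mix`.
#'
#' @param transects Data frame with `transect_id` and `length_km` (> 0);
#'   `site`/`year` columns, if present, are carried through.
#' @param densities Named numeric vector: mean items per km for each
#'   category, >= 0.
#' @param mean_weights_g Named numeric vector of mean item weights (g), >= 0;
#'   categories missing from it default to 50 g.
#' @param mesh_mix Named numeric vector: probability of each mesh size (cm,
#'   names coercible to numeric) for net-bearing items; must sum to 1.
#' @param weight_cv Coefficient of variation of item weights (default 0.3;
#'   0 gives every item exactly the category mean).
#' @param seed Random seed, or `NULL`.
#' @return A tibble of items: `transect_id`, `category`, `weight_g`,
#'   `mesh_cm` (`NA` for non-net items).
#' @examples
#' tr <- data.frame(transect_id = "T1", length_km = 2)
#' simulate_debris(tr, densities = c(foam_float = 3, net_fragment = 1),
#'                 seed = 1)
#' @export
simulate_debris <- function(transects,
                            densities,
                            mean_weights_g = c(whole_net = 400,
                                               net_fragment = 120,
                                               float_line = 60, lead_line = 150,
                                               foam_float = 8, bottle_float = 25,
                                               rod = 200, monofilament = 10,
                                               lure = 15, bobber = 12),
                            mesh_mix = c("3.5" = 0.7, "5" = 0.3),
                            weight_cv = 0.3,
                            seed = NULL) {
  check_cols(transects, c("transect_id", "length_km"), "transects table")
  if (any(transects$length_km <= 0)) {
    stop("invalid `length_km`: transect lengths must be > 0", call. = FALSE)
  }
  if (any(densities < 0)) {
    stop("invalid `densities`: must be >= 0", call. = FALSE)
  }
  if (is.null(names(densities))) {
    stop("`densities` must be named by category", call. = FALSE)
  }
  if (abs(sum(mesh_mix) - 1) > 1e-8) {
    stop("invalid `mesh_mix`: weights must sum to 1", call. = FALSE)
  }
  check_nonneg(weight_cv, "weight_cv")
  meshes <- as.numeric(names(mesh_mix))

  with_seed_or_not(seed, {
    rows <- lapply(seq_len(nrow(transects)), function(i) {
      counts <- rpois(length(densities),
                      densities * transects$length_km[i])
      if (sum(counts) == 0L) return(NULL)
      cat_col <- rep(names(densities), counts)
      mu <- unname(mean_weights_g[cat_col])
      mu[is.na(mu)] <- 50
      w <- if (weight_cv == 0) mu else {
        sdlog <- sqrt(log(1 + weight_cv^2))
        mu * rlnorm(length(mu), -sdlog^2 / 2, sdlog)
      }
      mesh <- rep(NA_real_, length(cat_col))
      netty <- cat_col %in% c("whole_net", "net_fragment")
      if (any(netty)) {
        mesh[netty] <- sample(meshes, sum(netty), replace = TRUE,
                              prob = mesh_mix)
      }
      tibble::tibble(transect_id = transects$transect_id[i],
                     category = cat_col, weight_g = w, mesh_cm = mesh)
    })
    out <- dplyr::bind_rows(rows)
    if (nrow(out) == 0L) {
      out <- tibble::tibble(transect_id = character(), category = character(),
                            weight_g = numeric(), mesh_cm = numeric())
    }
    out
  })
}
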