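#' Fit a length-weight allometry
#'
#' Least-squares fit of `log(weight)` on `log(length)`, back-transformed to
#' the power law \eqn{w = a\, l^b}. By package convention lengths are mm and
#' weights g, so `a` carries units g mm^-b.
#'
#' @param records Tibble with `length_mm` and `weight_g`; rows without a
#'   measured weight are ignored, and at least 3 weighted rows are required.
#' @return An object of class `lw_params`: `a`, `b`, `n`, `sigma_log`
#'   (residual SD on the log scale).
#' @examples
#' d <- data.frame(length_mm = c(200, 250, 300, 350),
#'                 weight_g = 1e-5 * c(200, 250, 300, 350)^3)
#' fit_length_weight(d)
#' @export
fit_length_weight <- function(records) {
  check_cols(records, c("length_mm", "weight_g"), "catch records")
  ok <- is.finite(records$length_mm) & records$length_mm > 0 &
    is.finite(records$weight_g) & records$weight_g > 0
  d <- records[ok, ]
  if (nrow(d) < 3L) {
    stop(sprintf("need at least 3 records with measured weight (have %d)",
                 nrow(d)), call. = FALSE)
  }
  fit <- lm(log(weight_g) ~ log(length_mm), data = d)
  structure(
    list(a = exp(unname(coef(fit)[1])), b = unname(coef(fit)[2]),
         n = nrow(d), sigma_log = sigma(fit)),
    class = "lw_params"
  )
}

#' @export
print.lw_params <- function(x, ...) {
  cat(sprintf("Length-weight: w = %.4g * l^%.4g (n = %d, log-scale SD %.3g)\n",
              x$a, x$b, x$n, x$sigma_log))
  invisible(x)
}

#' Fill in missing weights from the allometric fit
#'
#' Missing weights are replaced by \eqn{a\, l^b}; measured weights are never
#' altered. An `imputed` flag records which rows were filled so downstream
#' body-size analyses can exclude them (the fit would otherwise feed back
#' into itself).
#'
#' @param records Catch tibble with `species`, `length_mm`, `weight_g`.
#' @param lw Either a single `lw_params` (applied to all rows) or a named
#'   list of them keyed by species.
#' @return `records` with complete `weight_g` and a logical `imputed` column.
#' @export
impute_weights <- function(records, lw) {
  check_cols(records, c("length_mm", "weight_g"), "catch records")
  records <- tibble::as_tibble(records)
  records$imputed <- !is.finite(records$weight_g)
  if (!any(records$imputed)) return(records)
  miss <- which(records$imputed)
  if (inherits(lw, "lw_params")) {
    records$weight_g[miss] <-
      lw$a * records$length_mm[miss]^lw$b
  } else {
    sp <- records$species[miss]
    bad <- setdiff(unique(sp), names(lw))
    if (length(bad) > 0L) {
      stop(sprintf("no length-weight parameters for species: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    records$weight_g[miss] <- vapply(miss, function(i) {
      p <- lw[[records$species[i]]]
      p$a * records$length_mm[i]^p$b
    }, numeric(1))
  }
  records
}

#' Panel-level catch per unit effort
#'
#' CPUE standardized to 10 m of net per night: count CPUE is
#' `n * (10 / panel_length) / nights` and biomass CPUE the same with the
#' summed weight in kg. Effort is counted in nights, not hours: any
#' overnight soak is one night.
#'
#' @param records Catch records from one panel (needs `weight_g` for the
#'   biomass component; missing weights contribute 0 with a message).
#' @param panel_length_m Panel length (m), > 0.
#' @param nights Soak nights, >= 1.
#' @return One-row tibble: `n_fish`, `cpue_n` (fish / 10 m / night),
#'   `cpue_kg` (kg / 10 m / night).
#' @examples
#' d <- data.frame(weight_g = c(400, 400, 400))
#' panel_cpue(d, panel_length_m = 4) # 7.5 fish and 3 kg per 10 m-night
#' @export
panel_cpue <- function(records, panel_length_m = 4, nights = 1) {
  check_positive(panel_length_m, "panel_length_m")
  check_that(nights >= 1, "nights", "must be >= 1")
  if (!"weight_g" %in% names(records)) records$weight_g <- NA_real_
  if (anyNA(records$weight_g) && nrow(records) > 0) {
    message(sprintf("%d record(s) without weight omitted from biomass CPUE",
                    sum(is.na(records$weight_g))))
  }
  scale <- 10 / panel_length_m / nights
  tibble::tibble(
    n_fish = nrow(records),
    cpue_n = nrow(records) * scale,
    cpue_kg = sum(records$weight_g, na.rm = TRUE) / 1000 * scale
  )
}

#' Set-level catch per unit effort
#'
#' Totals across all panels of a net divided by soak nights: fish per
#' net-night and kg per net-night.
#'
#' @param records Catch records from one gillnet set.
#' @param nights Soak nights, >= 1.
#' @return One-row tibble: `n_fish`, `cpue_n` (fish / net-night), `cpue_kg`
#'   (kg / net-night).
#' @export
set_cpue <- function(records, nights = 1) {
  check_that(nights >= 1, "nights", "must be >= 1")
  if (!"weight_g" %in% names(records)) records$weight_g <- NA_real_
  tibble::tibble(
    n_fish = nrow(records),
    cpue_n = nrow(records) / nights,
    cpue_kg = sum(records$weight_g, na.rm = TRUE) / 1000 / nights
  )
}

#' CPUE of every panel in a survey
#'
#' Builds the full set x mesh grid from the panels table so that empty panels
#' appear as zero-CPUE rows (dropping them would bias mesh comparisons and
#' trends), then computes [panel_cpue()] within each cell, by species when
#' requested.
#'
#' @param catch Catch tibble (`set_id`, `mesh_cm`, `species`, `length_mm`,
#'   `weight_g`).
#' @param panels Panels tibble (`set_id`, `mesh_cm`, `length_m`).
#' @param sets Sets tibble (`set_id`, `site`, `year`, `nights`).
#' @param by_species Split by species (`TRUE`) or pool all species per panel
#'   (`FALSE`, default).
#' @return Tibble with one row per set x mesh (x species): metadata plus
#'   `n_fish`, `cpue_n`, `cpue_kg`.
#' @export
panel_cpue_table <- function(catch, panels, sets, by_species = FALSE) {
  check_cols(panels, c("set_id", "mesh_cm", "length_m"), "panels table")
  check_cols(sets, c("set_id", "nights"), "sets table")
  grid <- dplyr::left_join(panels, sets, by = "set_id")
  if (by_species) {
    grid <- tidyr::expand_grid(grid, species = unique(catch$species))
  }
  per_row <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sub <- catch[catch$set_id == g$set_id & catch$mesh_cm == g$mesh_cm, ,
                 drop = FALSE]
    if (by_species) sub <- sub[sub$species == g$species, , drop = FALSE]
    suppressMessages(panel_cpue(sub, g$length_m, g$nights))
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(per_row))
}

#' CPUE of every gillnet set in a survey
#'
#' One row per set (optionally per species), with zero-catch sets retained
#' as zeros. This is the abundance response for trend testing.
#'
#' @inheritParams panel_cpue_table
#' @return Tibble with set metadata plus `n_fish`, `cpue_n`, `cpue_kg`.
#' @export
set_cpue_table <- function(catch, sets, by_species = FALSE) {
  check_cols(sets, c("set_id", "nights"), "sets table")
  grid <- sets
  if (by_species) {
    grid <- tidyr::expand_grid(sets, species = unique(catch$species))
  }
  per_row <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sub <- catch[catch$set_id == g$set_id, , drop = FALSE]
    if (by_species) sub <- sub[sub$species == g$species, , drop = FALSE]
    set_cpue(sub, g$nights)
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(per_row))
}

#' Mesh size maximizing mean CPUE
#'
#' Averages panel CPUE by mesh size and returns the mesh with the highest
#' mean under the chosen criterion; exact ties go to the smaller mesh (the
#' cheaper, more commonly used net).
#'
#' @param panel_table Output of [panel_cpue_table()].
#' @param species Optional species filter (requires a `species` column).
#' @param criterion `"count"` (fish per 10 m-night) or `"biomass"`
#'   (kg per 10 m-night).
#' @return The optimal mesh size (cm), with the per-mesh means attached as
#'   attribute `"means"`.
#' @export
optimal_mesh <- function(panel_table, species = NULL,
                         criterion = c("count", "biomass")) {
  criterion <- match.arg(criterion)
  if (!is.null(species)) {
    check_cols(panel_table, "species", "panel CPUE table")
    panel_table <- panel_table[panel_table$species %in% species, ,
                               drop = FALSE]
  }
  if (length(unique(panel_table$mesh_cm)) < 2L) {
    stop("need CPUE for at least 2 mesh sizes", call. = FALSE)
  }
  col <- if (criterion == "count") "cpue_n" else "cpue_kg"
  means <- panel_table |>
    dplyr::group_by(.data$mesh_cm) |>
    dplyr::summarise(mean_cpue = mean(.data[[col]]), .groups = "drop") |>
    dplyr::arrange(.data$mesh_cm)
  best <- means$mesh_cm[which.max(means$mean_cpue)]  # first max = smaller mesh
  structure(best, means = means)
}

#' Year-trend test with site random intercepts
#'
#' Fits `response ~ year + (1 | site)` by maximum likelihood and compares it
#' against the intercept-only model `response ~ 1 + (1 | site)` with a
#' likelihood-ratio test (1 df chi-square). The same machinery serves
#' abundance trends (set CPUE as response) and body-size trends (individual
#' lengths or weights as response). Year is centred at the first survey year
#' before fitting, which changes the intercept but not the slope or p-value.
#'
#' @param data Data frame holding the response and grouping columns.
#' @param response Name of the response column.
#' @param year Name of the year column (default `"year"`); must vary.
#' @param site Name of the site column (default `"site"`). With a single
#'   site the model degrades to a fixed-intercept linear fit, with a
#'   warning.
#' @param log1p_response Model `log(1 + response)` instead of the raw scale
#'   (robustness option for skewed CPUE). Default `FALSE`: CPUE and body
#'   size are modelled on the scale on which they are plotted.
#' @return An object of class `trend_result`: `response`, `slope`, `se`,
#'   `site_sd`, `resid_sd`, `lr_stat`, `p_value`, `n_obs`, `n_sites`.
#' @examples
#' sim <- simulate_catch_survey(survey_design(),
#'                              species_config(year_slope = -0.2), seed = 2)
#' cpue <- set_cpue_table(sim$catch, sim$sets)
#' trend_test(cpue, "cpue_n")
#' @export
trend_test <- function(data, response, year = "year", site = "site",
                       log1p_response = FALSE) {
  check_cols(data, c(response, year, site), "trend data")
  d <- data.frame(
    resp = data[[response]],
    year_c = data[[year]] - min(data[[year]]),
    site = factor(data[[site]])
  )
  d <- d[stats::complete.cases(d), ]
  if (log1p_response) d$resp <- log1p(d$resp)
  if (length(unique(d$year_c)) < 2L) {
    stop("year column is constant: no trend is estimable", call. = FALSE)
  }

  result <- function(slope, se, site_sd, resid_sd, lr, p) {
    structure(
      list(response = response, slope = slope, se = se, site_sd = site_sd,
           resid_sd = resid_sd, lr_stat = lr, p_value = p,
           n_obs = nrow(d), n_sites = nlevels(d$site)),
      class = "trend_result"
    )
  }

  if (var(d$resp) == 0) {
    # degenerate flat response: the year effect is exactly zero
    return(result(0, NA_real_, 0, 0, 0, 1))
  }

  if (nlevels(d$site) < 2L) {
    warning("single site: fitting fixed-intercept models without a random effect")
    full <- lm(resp ~ year_c, data = d)
    null <- lm(resp ~ 1, data = d)
    lr <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(null))))
    return(result(unname(coef(full)["year_c"]),
                  unname(sqrt(diag(stats::vcov(full)))["year_c"]),
                  NA_real_, sigma(full), lr,
                  pchisq(lr, df = 1, lower.tail = FALSE)))
  }

  full <- lme4::lmer(resp ~ year_c + (1 | site), data = d, REML = FALSE)
  null <- lme4::lmer(resp ~ 1 + (1 | site), data = d, REML = FALSE)
  lr <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(null))))
  vc <- as.data.frame(lme4::VarCorr(full))
  result(
    slope = unname(lme4::fixef(full)["year_c"]),
    se = unname(sqrt(diag(as.matrix(stats::vcov(full))))["year_c"]),
    site_sd = vc$sdcor[vc$grp == "site"],
    resid_sd = vc$sdcor[vc$grp == "Residual"],
    lr = lr,
    p = pchisq(lr, df = 1, lower.tail = FALSE)
  )
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Trend in %s: slope %.4g /yr (SE %.3g), LR = %.3g, p = %.4g\n",
              x$response, x$slope, x$se, x$lr_stat, x$p_value))
  cat(sprintf("  %d obs, %d site(s); site SD %.3g, residual SD %.3g\n",
              x$n_obs, x$n_sites, x$site_sd, x$resid_sd))
  invisible(x)
}
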