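test_that("length-weight fit recovers an exact power law", {
  l <- c(150, 200, 250, 300, 350, 400)
  d <- data.frame(length_mm = l, weight_g = 1e-5 * l^3)
  fit <- fit_length_weight(d)
  expect_equal(fit$b, 3, tolerance = 1e-10)
  expect_equal(fit$a, 1e-5, tolerance = 1e-10)
  expect_equal(fit$n, 6)

  expect_error(fit_length_weight(d[1:2, ]), "at least 3")
  # unweighed rows don't count towards the minimum
  d$weight_g[3:6] <- NA
  expect_error(fit_length_weight(d), "at least 3")
})

test_that("length-weight fit is accurate under lognormal noise", {
  reps <- 200
  hits <- vapply(1:reps, function(s) {
    withr::with_seed(400 + s, {
      l <- exp(runif(500, log(150), log(400)))
      w <- 2e-5 * l^3.1 * rlnorm(500, 0, 0.1)
      abs(fit_length_weight(data.frame(length_mm = l, weight_g = w))$b - 3.1) <= 0.05
    })
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("weight imputation fills only the gaps, positively", {
  lw <- structure(list(a = 1e-5, b = 3, n = 10, sigma_log = 0),
                  class = "lw_params")
  d <- tibble::tibble(species = "grayling",
                      length_mm = c(300, 250, 410),
                      weight_g = c(NA, 180, NA))
  out <- impute_weights(d, lw)
  expect_equal(out$weight_g[1], 270)         # 1e-5 * 300^3
  expect_equal(out$weight_g[2], 180)         # measured value untouched
  expect_equal(out$imputed, c(TRUE, FALSE, TRUE))
  expect_true(all(out$weight_g > 0))

  # complete data pass through unchanged
  full <- impute_weights(out[, c("species", "length_mm", "weight_g")], lw)
  expect_equal(full$weight_g, out$weight_g)
  expect_false(any(full$imputed))

  expect_error(impute_weights(d, list(lenok = lw)), "grayling")
})

test_that("panel CPUE standardizes to 10 m-nights", {
  d <- data.frame(weight_g = c(400, 400, 400))
  p <- panel_cpue(d, panel_length_m = 4, nights = 1)
  expect_equal(p$cpue_n, 7.5)
  expect_equal(p$cpue_kg, 3.0)

  empty <- panel_cpue(d[0, , drop = FALSE], 4, 1)
  expect_equal(c(empty$cpue_n, empty$cpue_kg), c(0, 0))

  two_nights <- panel_cpue(d, 4, nights = 2)
  expect_equal(two_nights$cpue_n, 3.75)
  expect_error(panel_cpue(d, 0), "panel_length_m")
})

test_that("CPUE is linear in catch and set CPUE aggregates panels", {
  sim <- fixture_survey(seed = 50)
  one_set <- sim$sets$set_id[1]
  rec <- sim$catch[sim$catch$set_id == one_set, ]
  s1 <- set_cpue(rec)
  s2 <- set_cpue(rbind(rec, rec))
  expect_equal(s2$cpue_n, 2 * s1$cpue_n)
  expect_equal(s2$cpue_kg, 2 * s1$cpue_kg)

  # set CPUE equals the panel-length-weighted sum of panel CPUE
  pt <- panel_cpue_table(sim$catch, sim$panels, sim$sets)
  st <- set_cpue_table(sim$catch, sim$sets)
  agg <- tapply(pt$cpue_n * pt$length_m / 10, pt$set_id, sum)
  expect_equal(as.numeric(agg[st$set_id]), st$cpue_n)
  agg_kg <- tapply(pt$cpue_kg * pt$length_m / 10, pt$set_id, sum)
  expect_equal(as.numeric(agg_kg[st$set_id]), st$cpue_kg)
})

test_that("zero-catch sets appear as zero CPUE rows", {
  sim <- fixture_survey(seed = 51)
  st <- set_cpue_table(sim$catch[0, ], sim$sets)
  expect_equal(nrow(st), nrow(sim$sets))
  expect_true(all(st$cpue_n == 0))
})

test_that("optimal mesh follows the selectivity peak and tie rule", {
  # small-bodied species loaded on the smallest mesh
  sim <- fixture_survey(seed = 52)
  pt <- panel_cpue_table(sim$catch, sim$panels, sim$sets)
  expect_equal(as.numeric(optimal_mesh(pt, criterion = "count")), 2.54)

  # larger-bodied species shifts the biomass optimum to mid meshes
  big <- simulate_catch_survey(
    survey_design(),
    species_config(species = "lenok", modal_length_mm = 460,
                   sel_mult = 110, log_cpue0 = log(8)),
    seed = 53)
  ptb <- panel_cpue_table(big$catch, big$panels, big$sets)
  expect_true(as.numeric(optimal_mesh(ptb, criterion = "biomass")) %in%
                c(3.81, 5.08))

  # exact tie resolves to the smaller mesh
  tied <- tibble::tibble(mesh_cm = c(2.54, 3.81), cpue_n = c(5, 5),
                         cpue_kg = c(1, 1))
  expect_equal(as.numeric(optimal_mesh(tied)), 2.54)
  expect_error(optimal_mesh(tied[1, ]), "2 mesh")
})

test_that("trend test handles degenerate inputs per contract", {
  d <- data.frame(y = rep(3, 20), year = rep(2009:2012, 5),
                  site = rep(c("A", "B"), 10))
  res <- trend_test(d, "y")
  expect_equal(res$slope, 0)
  expect_equal(res$lr_stat, 0)
  expect_equal(res$p_value, 1)

  d2 <- d; d2$year <- 2009
  expect_error(trend_test(d2, "y"), "constant")

  d3 <- data.frame(y = rnorm(20), year = rep(2009:2012, 5), site = "A")
  expect_warning(res3 <- trend_test(d3, "y"), "single site")
  expect_true(res3$p_value >= 0 && res3$p_value <= 1)
})

test_that("trend slope and p-value are invariant to recentring year", {
  set.seed(60)
  d <- data.frame(year = rep(c(2009, 2011:2013), each = 14),
                  site = rep(paste0("S", 1:7), 8))
  d$y <- 5 - 0.2 * (d$year - 2009) + rnorm(56, 0, 0.5) +
    rep(rnorm(7, 0, 0.3), 8)[as.integer(factor(d$site))]
  r1 <- trend_test(d, "y")
  d_shift <- d; d_shift$year <- d$year + 1000
  r2 <- trend_test(d_shift, "y")
  expect_equal(r1$slope, r2$slope, tolerance = 1e-8)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-8)
})

test_that("trend test recovers a known slope with ~95% CI coverage", {
  reps <- 200
  covered <- vapply(1:reps, function(s) {
    withr::with_seed(700 + s, {
      d <- data.frame(year = rep(c(2009, 2011:2013), each = 14),
                      site = rep(paste0("S", 1:7), 8))
      site_eff <- rnorm(7, 0, 0.2)
      d$y <- 2 - 0.10 * (d$year - 2009) +
        site_eff[as.integer(factor(d$site))] + rnorm(56, 0, 0.3)
      r <- trend_test(d, "y")
      abs(r$slope - (-0.10)) <= 1.96 * r$se
    })
  }, logical(1))
  expect_equal(mean(covered), 0.95, tolerance = 0.05 / 0.95)
})

test_that("a negative body-size slope in the generator is detected", {
  sim <- fixture_survey(seed = 61, size_slope = -0.05, nets_per_site = 4)
  body <- dplyr::left_join(sim$catch,
                           sim$sets[, c("set_id", "site", "year")],
                           by = "set_id")
  res <- trend_test(body, "length_mm")
  expect_lt(res$slope, 0)
  expect_lt(res$p_value, 0.01)
})
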