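test_that("population config validation names the offending field", {
  lh <- default_life()
  expect_error(population_sim_config(lh, z = -1, n_fish = 10), "`z`")
  expect_error(population_sim_config(lh, z = 0.3, n_fish = 0), "`n_fish`")
  expect_error(population_sim_config(lh, z = 0.3, n_fish = 10,
                                     length_cv = 0.7), "`length_cv`")
  expect_error(population_sim_config(lh, z = 0.3, n_fish = 10,
                                     recruit_age = 20), "`recruit_age`")
  expect_error(simulate_population(list()), "population_sim_config")
})

test_that("zero mortality gives a uniform age distribution", {
  lh <- life_history(linf = 40, k = 0.2, t_max = 10)
  pop <- simulate_population(population_sim_config(
    lh, z = 0, n_fish = 1e5, recruit_age = 0, seed = 1))
  h <- hist(pop$age_yr, breaks = 0:10, plot = FALSE)$counts
  expect_true(all(abs(h - 1e4) < 4 * sqrt(1e4 * 0.9)))  # ~4 sigma MC band
  ks <- suppressWarnings(ks.test(pop$age_yr, "punif", 0, 10))
  expect_gt(ks$p.value, 1e-4)
})

test_that("binned log age counts decay at slope -z", {
  lh <- life_history(linf = 40, k = 0.2, t_max = 12)
  pop <- simulate_population(population_sim_config(
    lh, z = 0.5, n_fish = 1e5, recruit_age = 0, seed = 2))
  counts <- hist(pop$age_yr, breaks = 0:12, plot = FALSE)$counts
  mid <- 0:11 + 0.5
  keep <- counts > 0 & mid < 10   # avoid the noisy truncated tail
  slope <- coef(lm(log(counts[keep]) ~ mid[keep]))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.02 / 0.5)
})

test_that("age marginal matches the truncated exponential law", {
  lh <- default_life()
  cfg <- population_sim_config(lh, z = 0.42, n_fish = 2e4, seed = 3)
  pop <- simulate_population(cfg)
  a0 <- 2; a1 <- lh$t_max; z <- 0.42
  cdf <- function(a) (exp(-z * a0) - exp(-z * a)) /
    (exp(-z * a0) - exp(-z * a1))
  ks <- suppressWarnings(ks.test(pop$age_yr, cdf))
  expect_gt(ks$p.value, 1e-4)
  expect_true(all(pop$age_yr >= a0 & pop$age_yr <= a1))
})

test_that("zero length noise puts every fish exactly on the growth curve", {
  lh <- default_life()
  pop <- simulate_population(population_sim_config(
    lh, z = 0.3, n_fish = 500, length_cv = 0, seed = 4))
  expect_equal(pop$length_mm, 10 * vb_length(pop$age_yr, lh))
})

test_that("fixed seeds make every simulator fully reproducible", {
  lh <- default_life()
  cfg <- population_sim_config(lh, z = 0.4, n_fish = 200, seed = 11)
  expect_identical(simulate_population(cfg), simulate_population(cfg))

  s1 <- fixture_survey(seed = 5)
  s2 <- fixture_survey(seed = 5)
  expect_identical(s1, s2)
  expect_false(identical(s1$catch, fixture_survey(seed = 6)$catch))

  tr <- data.frame(transect_id = c("A", "B"), length_km = c(2, 3))
  d1 <- simulate_debris(tr, densities = c(foam_float = 4), seed = 9)
  expect_identical(d1, simulate_debris(tr, densities = c(foam_float = 4),
                                       seed = 9))
})

test_that("catch survey validates its design and community", {
  expect_error(simulate_catch_survey(survey_design(sites = character()),
                                     species_config(), seed = 1),
               "at least one site")
  expect_error(survey_design(panel_meshes = c(2, 2, 3)), "panel_meshes")
  expect_error(species_config(lw_b = 4), "lw_b")
  expect_error(species_config(site_sd = -1), "site_sd")
})

test_that("catch survey emits consistent set, panel and catch tables", {
  sim <- fixture_survey(seed = 7)
  expect_equal(nrow(sim$sets), 7 * 4 * 2)
  expect_equal(nrow(sim$panels), nrow(sim$sets) * 5)
  expect_true(all(sim$catch$set_id %in% sim$sets$set_id))
  expect_true(all(sim$catch$mesh_cm %in% c(2.54, 3.81, 5.08, 6.35, 7.62)))
  expect_true(all(sim$catch$length_mm > 0 & sim$catch$weight_g > 0))
})

test_that("weights sit exactly on the allometry when weight noise is zero", {
  sim <- fixture_survey(seed = 8)
  expect_equal(sim$catch$weight_g, 1e-5 * sim$catch$length_mm^3)
})

test_that("intercept-only surveys have mean set CPUE near exp(intercept)", {
  sp <- species_config(log_cpue0 = log(15), year_slope = 0, site_sd = 0)
  means <- vapply(1:40, function(s) {
    sim <- simulate_catch_survey(survey_design(), sp, seed = 100 + s)
    mean(set_cpue_table(sim$catch, sim$sets)$cpue_n)
  }, numeric(1))
  # MC standard error of the grand mean over 40 x 56 Poisson(15) sets
  expect_equal(mean(means), 15, tolerance = 0.01)
})

test_that("debris counts are Poisson with mean density x length", {
  tr <- data.frame(transect_id = sprintf("T%04d", 1:10000), length_km = 2)
  items <- simulate_debris(tr, densities = c(net_fragment = 5), seed = 10)
  counts <- table(factor(items$transect_id, levels = tr$transect_id))
  expect_equal(mean(counts), 10, tolerance = 0.1 / 10)
  expect_equal(var(as.numeric(counts)), 10, tolerance = 0.1)
})

test_that("debris simulator recovers the mesh mixture and rejects bad input", {
  tr <- data.frame(transect_id = "T1", length_km = 400)
  items <- simulate_debris(tr, densities = c(net_fragment = 10),
                           mesh_mix = c("3" = 0.7, "5" = 0.3), seed = 12)
  p3 <- mean(items$mesh_cm == 3)
  expect_equal(p3, 0.7, tolerance = 3 * sqrt(0.7 * 0.3 / nrow(items)) / 0.7)
  expect_true(all(!is.na(items$mesh_cm)))

  expect_error(simulate_debris(tr, densities = c(net_fragment = -1)),
               "densities")
  expect_error(simulate_debris(tr, densities = c(net_fragment = 1),
                               mesh_mix = c("3" = 0.5, "5" = 0.3)),
               "mesh_mix")
  zero <- simulate_debris(tr, densities = c(net_fragment = 0), seed = 1)
  expect_equal(nrow(zero), 0)
})
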