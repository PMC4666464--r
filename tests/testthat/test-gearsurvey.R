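test_that("gear classification applies the attachment rules", {
  # bare ambiguous debris is not fishing gear
  expect_equal(classify_gear("bottle"), "non_gear")
  expect_equal(classify_gear("string_rope"), "non_gear")
  expect_equal(classify_gear("stake"), "non_gear")
  # attachments convert it
  expect_equal(classify_gear("bottle", has_line = TRUE), "bottle_float")
  expect_equal(classify_gear("string_rope", has_weights = TRUE), "lead_line")
  expect_equal(classify_gear("string_rope", has_floats = TRUE), "float_line")
  expect_equal(classify_gear("bottle", has_mesh = TRUE), "net_fragment")
  # named categories pass through
  expect_equal(classify_gear("foam_float"), "foam_float")
  expect_equal(classify_gear("rod"), "rod")
  expect_equal(classify_gear(c("lure", "bobber", "whole_net")),
               c("lure", "bobber", "whole_net"))
  expect_error(classify_gear("tyre"), "Permitted labels")
})

test_that("transect density is count/length and weight/length", {
  tr <- data.frame(transect_id = "T1", length_km = 2)
  items <- data.frame(transect_id = "T1",
                      category = rep("net_fragment", 10),
                      weight_g = rep(25, 10))
  d <- transect_density(items, tr)
  expect_equal(d$count_per_km, 5.0)
  expect_equal(d$g_per_km, 125.0)
  expect_equal(d$count_per_km * tr$length_km, d$n_items)

  empty <- transect_density(items[0, ], data.frame(transect_id = "T2",
                                                   length_km = 3))
  expect_equal(c(empty$count_per_km, empty$g_per_km), c(0, 0))

  expect_error(transect_density(items, data.frame(transect_id = "T1",
                                                  length_km = 0)),
               "positive")
  expect_error(transect_density(items, data.frame(transect_id = "T9",
                                                  length_km = 1)),
               "reference")
})

test_that("items without weight count for density but not weight density", {
  tr <- data.frame(transect_id = "T1", length_km = 1)
  items <- data.frame(transect_id = "T1", category = rep("foam_float", 4),
                      weight_g = c(10, NA, NA, 10))
  expect_message(d <- transect_density(items, tr), "2 item")
  expect_equal(d$count_per_km, 4)
  expect_equal(d$g_per_km, 20)
})

test_that("per-category densities sum to the all-gear density", {
  tr <- data.frame(transect_id = "T1", length_km = 3.7)
  items <- simulate_debris(tr, densities = c(foam_float = 5, net_fragment = 3,
                                             rod = 1, lead_line = 2),
                           seed = 21)
  all_gear <- transect_density(items, tr, scope = "all")
  by_cat <- transect_density(items, tr, scope = "by_category")
  expect_equal(sum(by_cat$count_per_km), all_gear$count_per_km)
  expect_equal(sum(by_cat$g_per_km), all_gear$g_per_km)
  gn <- transect_density(items, tr, scope = "gillnet")
  hl <- transect_density(items, tr, scope = "hookline")
  expect_equal(gn$count_per_km + hl$count_per_km, all_gear$count_per_km)
})

test_that("pooled density weights by transect length", {
  tr <- data.frame(transect_id = c("A", "B"), length_km = c(2, 8))
  recs <- data.frame(transect_id = c("A", "B"), count_per_km = c(4, 1),
                     g_per_km = c(0, 0))
  expect_equal(pooled_density(recs, tr)$count_per_km, 1.6)  # (8 + 8) / 10

  # equal lengths reduce to the arithmetic mean
  tr_eq <- data.frame(transect_id = c("A", "B"), length_km = c(3, 3))
  expect_equal(pooled_density(recs, tr_eq)$count_per_km, 2.5)

  # single transect is the identity
  expect_equal(pooled_density(recs[1, ], tr[1, ])$count_per_km, 4)

  expect_error(pooled_density(recs, tr[1, ]), "same transect set")
})

test_that("pooled density equals total items over total shoreline", {
  # a census totalling 220 items over 54.9 km pools to 220/54.9 per km
  lengths <- c(8.5, 6.2, 5.5, 5.0, 4.8, 4.5, 4.4, 4.0, 3.9, 3.1, 2.5, 2.1, 0.4)
  expect_equal(sum(lengths), 54.9)
  set.seed(31)
  counts <- c(rmultinom(1, 220, prob = lengths / sum(lengths)))
  tr <- data.frame(transect_id = sprintf("T%02d", seq_along(lengths)),
                   length_km = lengths)
  items <- data.frame(
    transect_id = rep(tr$transect_id, counts),
    category = "net_fragment", weight_g = 26.27)
  recs <- density_table(items, tr, scope = "all")
  pooled <- pooled_density(recs, tr)
  expect_equal(pooled$count_per_km, 220 / 54.9)  # = 4.007 per km
  expect_equal(pooled$total_items, 220)
})

test_that("mesh composition bins by half-open intervals, count and weight", {
  items <- data.frame(transect_id = "T", category = "net_fragment",
                      mesh_cm = c(3, 3, 4, 6), weight_g = c(10, 20, 5, 5))
  h <- mesh_composition(items, edges = 2:8)
  expect_equal(h$n_items, c(0L, 2L, 1L, 0L, 1L, 0L))
  expect_equal(h$weight_g, c(0, 30, 5, 0, 5, 0))
  expect_equal(which.max(h$n_items), which(h$bin_lo == 3))
  expect_equal(sum(h$n_items), sum(!is.na(items$mesh_cm)))  # conservation

  expect_error(mesh_composition(items, edges = c(2, 4, 3)), "increasing")
  none <- mesh_composition(data.frame(mesh_cm = numeric(),
                                      weight_g = numeric()))
  expect_true(all(none$n_items == 0))
})

test_that("a 3-4 cm dominated mixture is modal by count and weight", {
  tr <- data.frame(transect_id = "T1", length_km = 50)
  items <- simulate_debris(tr, densities = c(net_fragment = 8),
                           mesh_mix = c("3.5" = 0.6, "2.5" = 0.15,
                                        "5.5" = 0.15, "6.5" = 0.1),
                           seed = 33)
  h <- mesh_composition(items, edges = 2:8)
  expect_equal(h$bin_lo[which.max(h$n_items)], 3)
  expect_equal(h$bin_lo[which.max(h$weight_g)], 3)
})

test_that("re-accumulation compares shared sites and flags zero baselines", {
  a <- data.frame(site = c("S1", "S2", "S3"), count_per_km = c(2, 0, 1))
  b <- data.frame(site = c("S1", "S2", "S3"), count_per_km = c(3, 2, 0.5))
  ch <- accumulation_change(a, b)
  s1 <- ch$by_site[ch$by_site$site == "S1", ]
  expect_equal(s1$diff, 1.0)
  expect_equal(s1$ratio, 1.5)
  expect_true(ch$by_site$ratio_undefined[ch$by_site$site == "S2"])
  expect_true(is.na(ch$by_site$ratio[ch$by_site$site == "S2"]))
  # increasing at all but one site
  expect_equal(ch$n_increasing, ch$n_sites - 1L)

  same <- accumulation_change(a, a)
  expect_true(all(same$by_site$diff == 0))
  expect_true(all(same$by_site$ratio[!same$by_site$ratio_undefined] == 1))

  expect_error(accumulation_change(a, data.frame(site = "S9",
                                                 count_per_km = 1)),
               "no sites")
})
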