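# Shared fixtures, built in code at test time.

default_life <- function() grayling_life_history()

# A small but non-trivial simulated survey reused across files.
fixture_survey <- function(seed = 42, year_slope = 0, size_slope = 0,
                           nets_per_site = 2) {
  simulate_catch_survey(
    survey_design(nets_per_site = nets_per_site),
    species_config(year_slope = year_slope, size_slope = size_slope),
    seed = seed
  )
}

# Exactly exponential pre-binned length frequencies with unit age spans:
# bin edges placed on the growth curve at integer ages, counts 1000 e^{-Z a}
# at each bin's midpoint relative age.
exact_catch_curve_bins <- function(z, growth, ages = 0:12) {
  edges_mm <- 10 * vb_length(ages, growth)
  mid_mm <- (edges_mm[-1] + edges_mm[-length(edges_mm)]) / 2
  age_mid <- length_to_relative_age(mid_mm / 10, growth)
  data.frame(bin_lo = edges_mm[-length(edges_mm)],
             bin_hi = edges_mm[-1],
             count = 1000 * exp(-z * age_mid))
}
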