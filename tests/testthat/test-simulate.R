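test_that("the default run reproduces the study grid: 30 experiments x 48 seasons", {
  rec <- simulate_tillage_data(sim_config())
  expect_equal(nrow(rec), 1440)
  expect_length(unique(rec$experiment), 30)
  expect_true(all(table(rec$experiment) == 48))
  expect_equal(sort(unique(rec$year)), 1975:2022)
  # experiment ids follow the NT.OC-7%PDPG8 naming pattern
  expect_true("NT.OC-7%PDPG8" %in% rec$experiment)
  expect_true("CT.OC-2.6%PDPG6" %in% rec$experiment)
  # all physical quantities non-negative
  for (v in c("rainfall", "csom", "aws", "interception", "biomass",
              "yield", "runoff", "ghg"))
    expect_true(all(rec[[v]] >= 0), label = sprintf("%s >= 0", v))
})

test_that("identical seeds give identical datasets; different seeds differ", {
  a <- simulate_tillage_data(sim_config(years = 1975:1984, seed = 33))
  b <- simulate_tillage_data(sim_config(years = 1975:1984, seed = 33))
  expect_identical(a, b)
  c <- simulate_tillage_data(sim_config(years = 1975:1984, seed = 34))
  expect_false(identical(a$rainfall, c$rainfall))
})

test_that("the weather series is seed-reproducible with the configured moments", {
  cfg <- sim_config(seed = 12)
  w1 <- weather_series(cfg)
  w2 <- weather_series(cfg)
  expect_identical(w1, w2)
  expect_equal(nrow(w1), 48)
  expect_true(all(w1$rainfall >= 0))
  se_rain <- cfg$rainfall_sd / sqrt(48)
  expect_lt(abs(mean(w1$rainfall) - cfg$rainfall_mean), 3 * se_rain)
  se_temp <- cfg$temp_sd / sqrt(48)
  expect_lt(abs(mean(w1$temperature) - cfg$temp_mean), 3 * se_temp)
})

test_that("paired seasons are ordered by tillage: CT never less runoff or emissions", {
  cfg <- sim_config(seed = 5)
  soilrows <- soil_profiles()
  w <- weather_series(cfg, seed = 5)
  for (i in c(1, 8, 15)) {
    soil <- soilrows[i, , drop = FALSE]
    carry <- list(csom = soil$csom_init)
    nt <- simulate_season(soil, "NT", w[1, ], carry, cfg, noise = FALSE)
    ct <- simulate_season(soil, "CT", w[1, ], carry, cfg, noise = FALSE)
    expect_lte(nt$record$runoff, ct$record$runoff)
    expect_lte(nt$record$ghg, ct$record$ghg)
    expect_gte(nt$carry$csom, ct$carry$csom)
  }
})

test_that("a rainless season produces zero runoff", {
  cfg <- sim_config()
  soil <- soil_profiles()[1, , drop = FALSE]
  dry <- data.frame(year = 1975L, rainfall = 0, temperature = 10)
  res <- simulate_season(soil, "CT", dry, list(csom = soil$csom_init), cfg,
                         noise = FALSE)
  expect_equal(res$record$runoff, 0)
})

test_that("noise-free yield and biomass increase monotonically across carbon levels", {
  cfg <- sim_config(seed = 21)
  rec <- simulate_tillage_data(cfg, noise = FALSE)
  modeled <- rec[rec$oc_percent %in% c(1, 3, 5, 7), ]
  agg <- aggregate(cbind(yield, biomass) ~ soilscape + tillage + oc_percent,
                   modeled, mean)
  for (s in unique(agg$soilscape)) for (t in c("NT", "CT")) {
    sub <- agg[agg$soilscape == s & agg$tillage == t, ]
    sub <- sub[order(sub$oc_percent), ]
    expect_true(all(diff(sub$yield) > 0), label = paste(s, t, "yield"))
    expect_true(all(diff(sub$biomass) > 0), label = paste(s, t, "biomass"))
  }
})

test_that("tillage contrasts exceed two pooled standard errors at default settings", {
  rec <- simulate_tillage_data(sim_config())
  contrast <- function(v) {
    nt <- rec[[v]][rec$tillage == "NT"]; ct <- rec[[v]][rec$tillage == "CT"]
    (mean(ct) - mean(nt)) / sqrt(var(nt) / length(nt) + var(ct) / length(ct))
  }
  expect_gt(contrast("runoff"), 2)
  expect_gt(contrast("ghg"), 2)
})

test_that("the carbon stock never increases under conventional till", {
  rec <- simulate_tillage_data(sim_config(years = 1975:1990, seed = 2))
  for (e in unique(rec$experiment[rec$tillage == "CT"])) {
    series <- rec$csom[rec$experiment == e]
    expect_true(all(diff(series) <= 0), label = e)
  }
})

test_that("the calibration report matches the published layout and magnitude envelope", {
  rec <- simulate_tillage_data(sim_config())
  cal <- calibration_report(rec)
  expect_equal(ncol(cal$yield), 30)
  expect_equal(ncol(cal$runoff), 30)
  expect_equal(rownames(cal$yield),
               c("Minimum", "Maximum", "Average", "Standard deviation"))
  means <- as.numeric(cal$yield["Average", ])
  expect_true(all(means > 2000 & means < 6100))
  # CT mean runoff exceeds NT within every soilscape
  agg <- aggregate(runoff ~ soilscape + tillage, rec, mean)
  for (s in unique(agg$soilscape))
    expect_gt(agg$runoff[agg$soilscape == s & agg$tillage == "CT"],
              agg$runoff[agg$soilscape == s & agg$tillage == "NT"])
})

test_that("non-positive coefficients are rejected as configuration errors", {
  expect_error(sim_config(coefficients = list(runoff_coef = -1)),
               class = "bbn_config_error")
  expect_error(sim_config(coefficients = list(ghg_tillage = c(NT = 0, CT = 1))),
               class = "bbn_config_error")
  expect_error(sim_config(rainfall_sd = -5), class = "bbn_config_error")
})
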