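# Seeded stochastic emulator of the crop-soil-climate simulations that
# parameterize the tillage network. It is a statistical emulator, not a
# crop model: structural equations are chosen for sign fidelity to the
# agronomic assumptions behind the network (rainfall drives biomass and
# runoff; soil carbon raises fertility and water space; biomass
# intercepts precipitation and suppresses runoff; conventional tillage
# accelerates carbon turnover, runoff and emissions), with magnitudes
# loosely anchored to the published seasonal summaries.

#' The 15 default soil profiles
#'
#' Three soilscapes, each at its native topsoil organic-carbon percentage
#' plus modeled 1/3/5/7% variants. The initial C-SOM stock scales with
#' the organic-carbon percentage; the water-capacity baseline is a
#' soilscape property.
#'
#' @param csom_per_oc C-SOM stock (kg/ha) per percent organic carbon.
#' @param aws_baseline named numeric, water-capacity baseline per
#'   soilscape (same units as the available-water-space variable).
#' @return data.frame with columns `soil`, `soilscape`, `oc_percent`,
#'   `aws_baseline`, `csom_init`.
#' @export
soil_profiles <- function(csom_per_oc = 38000,
                          aws_baseline = c(PDPG6 = 105, PDPG7 = 120,
                                           PDPG8 = 112)) {
  rows <- lapply(SOILSCAPES, function(s) {
    oc <- c(NATIVE_OC[[s]], MODELED_OC)
    data.frame(soil = paste0(s, ".OC", oc), soilscape = s, oc_percent = oc,
               aws_baseline = unname(aws_baseline[s]),
               csom_init = oc * csom_per_oc, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Configuration of the seasonal-data generator
#'
#' Bundles the study grid (years, soils, tillage systems), the seasonal
#' weather distributions, the structural-equation coefficients and the
#' random seed. The defaults reproduce the study conditions: 48 seasons
#' (1975-2022) for each of 30 experiments (15 soils x no-till /
#' conventional till) = 1,440 seasonal cases.
#'
#' @param years integer vector of simulation years.
#' @param soils data.frame of soil profiles (see [soil_profiles()]).
#' @param tillage_systems character vector of tillage labels.
#' @param rainfall_mean,rainfall_sd seasonal rainfall distribution (mm);
#'   drawn from a gamma (right-skewed, non-negative).
#' @param temp_mean,temp_sd seasonal mean temperature (deg C); normal.
#' @param coefficients named list of structural-equation coefficients;
#'   see [default_coefficients()]. Entries supplied here override the
#'   defaults individually.
#' @param seed integer random seed; the whole dataset is reproducible
#'   from it.
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(years = 1975:2022,
                       soils = soil_profiles(),
                       tillage_systems = c("NT", "CT"),
                       rainfall_mean = 650, rainfall_sd = 130,
                       temp_mean = 10.5, temp_sd = 0.8,
                       coefficients = list(),
                       seed = 1975L) {
  if (rainfall_sd < 0 || temp_sd < 0)
    stop_bbn("weather standard deviations must be >= 0", "bbn_config_error")
  co <- utils::modifyList(default_coefficients(), coefficients)
  pos <- c("csom_per_oc", "aws_oc_slope", "biomass_max", "rain_half_sat",
           "temp_width", "fertility_exp", "interception_half_sat",
           "runoff_coef", "runoff_aws_ref", "harvest_index",
           "ghg_base", "ghg_turnover")
  for (nm in pos) if (any(co[[nm]] <= 0))
    stop_bbn(sprintf("coefficient '%s' must be positive", nm),
             "bbn_config_error")
  for (nm in c("csom_decay", "aws_tillage", "runoff_tillage", "ghg_tillage"))
    if (any(co[[nm]] <= 0))
      stop_bbn(sprintf("multipliers '%s' must be positive", nm),
               "bbn_config_error")
  if (co$noise_cv < 0)
    stop_bbn("'noise_cv' must be >= 0", "bbn_config_error")
  structure(list(years = as.integer(years), soils = soils,
                 tillage_systems = tillage_systems,
                 rainfall_mean = rainfall_mean, rainfall_sd = rainfall_sd,
                 temp_mean = temp_mean, temp_sd = temp_sd,
                 coefficients = co, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default structural-equation coefficients of the generator
#'
#' Units and roles are documented in the methods vignette. Highlights:
#' `csom_decay` is the per-season fractional loss of the C-SOM stock
#' (conventional till turns carbon over an order of magnitude faster
#' than no-till); `runoff_tillage` and `ghg_tillage` are the
#' conventional-till multipliers on the runoff coefficient and the
#' emission rate; `noise_cv` is the coefficient of variation of the
#' multiplicative lognormal noise applied to biomass, runoff and
#' emissions (mean-one, so expectations are noise-free).
#'
#' @return named list of coefficients.
#' @export
default_coefficients <- function() {
  list(
    csom_decay = c(NT = 0.001, CT = 0.01),     # fraction of stock per season
    csom_per_oc = 38000,                        # kg/ha per % organic carbon
    aws_oc_slope = 52,                          # AWS units per effective % OC
    aws_tillage = c(NT = 1.00, CT = 0.97),      # compaction under CT
    biomass_max = 14500,                        # kg/ha potential biomass
    rain_half_sat = 280,                        # mm, half-saturation of rain response
    temp_opt = 11, temp_width = 4,              # deg C, suitability bell
    soilscape_fertility = c(PDPG6 = 0.84, PDPG7 = 1.00, PDPG8 = 1.18),
    fertility_exp = 0.27, fertility_ref = 4,    # OC fertility power law
    interception_base = 0.10, interception_gain = 0.50,
    interception_half_sat = 9000,               # kg/ha biomass
    runoff_coef = 0.010,                        # baseline fraction of rainfall
    runoff_tillage = c(NT = 1.0, CT = 2.2),
    runoff_aws_ref = 300,                       # AWS units
    runoff_interception = 0.8,                  # interception damping strength
    extreme_quantile = 0.9,                     # seasonal rainfall threshold
    extreme_runoff_mult = 3.5,
    extreme_yield_penalty = 0.6,                # yield multiplier, wet + low OC
    extreme_oc_threshold = 3,                   # % OC below which penalty applies
    harvest_index = 0.46,
    runoff_stress = 0.5, runoff_stress_ref = 40,  # mm
    ghg_base = 4000,                            # kgCO2eq/ha baseline respiration
    ghg_turnover = 0.5,                         # kgCO2eq per kg C-SOM turned over
    ghg_tillage = c(NT = 1.0, CT = 1.8),
    ghg_temp_slope = 0.05,                      # per deg C above 10
    noise_cv = 0.25)
}

#' Draw the shared seasonal weather series
#'
#' One rainfall/temperature pair per year; all experiments of a run share
#' the same weather (a single-site study). Rainfall is gamma distributed
#' (right-skewed, non-negative), temperature normal. Uses the current RNG
#' state unless `seed` is given.
#'
#' @param config a [sim_config()].
#' @param seed optional integer; when non-NULL the series is drawn after
#'   [set.seed()] and is therefore fully reproducible on its own.
#' @return data.frame with columns `year`, `rainfall`, `temperature`.
#' @export
weather_series <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(config$years)
  rain <- if (config$rainfall_sd == 0) rep(config$rainfall_mean, n)
  else stats::rgamma(n,
                     shape = (config$rainfall_mean / config$rainfall_sd)^2,
                     rate = config$rainfall_mean / config$rainfall_sd^2)
  temp <- stats::rnorm(n, config$temp_mean, config$temp_sd)
  data.frame(year = config$years, rainfall = rain, temperature = temp)
}

# Rainfall level above which a season counts as extreme; a property of
# the configured climate, not of a particular draw.
#' @keywords internal
extreme_rainfall_threshold <- function(config) {
  if (config$rainfall_sd == 0) return(Inf)
  stats::qgamma(config$coefficients$extreme_quantile,
                shape = (config$rainfall_mean / config$rainfall_sd)^2,
                rate = config$rainfall_mean / config$rainfall_sd^2)
}

#' Simulate one cropping season
#'
#' Deterministic structural equations plus mean-one multiplicative
#' lognormal noise on biomass, runoff and emissions, applied in causal
#' order: carbon stock decay (faster under conventional till), available
#' water space (increasing in the carbon stock), biomass (saturating
#' rainfall response x temperature suitability x organic-carbon
#' fertility), precipitation interception (increasing in biomass),
#' surface runoff (proportional to rainfall; damped by water space and
#' interception; amplified under conventional till and in extreme-rain
#' seasons), yield (harvest index x biomass, penalized by runoff stress
#' and by extreme rain on low-carbon soils) and emissions (baseline +
#' carbon turnover, scaled by tillage and temperature). All outputs are
#' non-negative. Draws 3 lognormal deviates from the current RNG stream
#' (none when `noise = FALSE`).
#'
#' @param soil one row of [soil_profiles()].
#' @param tillage `"NT"` or `"CT"`.
#' @param weather one row of [weather_series()].
#' @param carry carry state: list with current `csom` stock (kg/ha).
#' @param config a [sim_config()].
#' @param noise logical; FALSE evaluates the noise-free structural core.
#' @return list with `record` (one-row data.frame) and `carry` (updated).
#' @export
simulate_season <- function(soil, tillage, weather, carry, config,
                            noise = TRUE) {
  co <- config$coefficients
  rain <- weather$rainfall
  temp <- weather$temperature
  eps <- if (noise && co$noise_cv > 0) {
    sdl <- sqrt(log(1 + co$noise_cv^2))
    stats::rlnorm(3L, meanlog = -sdl^2 / 2, sdlog = sdl)
  } else rep(1, 3L)

  # (1) carbon stock decays, faster under conventional till
  decay <- co$csom_decay[[tillage]]
  turnover <- carry$csom * decay
  csom <- carry$csom - turnover

  # (2) available water space increases in the carbon stock
  oc_eff <- soil$oc_percent * csom / soil$csom_init
  aws <- (soil$aws_baseline + co$aws_oc_slope * oc_eff) *
    co$aws_tillage[[tillage]]

  # (3) biomass: saturating rain response x temperature bell x fertility
  fert <- (pmax(oc_eff, 0.05) / co$fertility_ref)^co$fertility_exp
  biomass <- co$biomass_max *
    co$soilscape_fertility[[soil$soilscape]] * fert *
    rain / (rain + co$rain_half_sat) *
    exp(-((temp - co$temp_opt) / co$temp_width)^2) * eps[1L]

  # (4) interception fraction increases in biomass
  interception <- co$interception_base +
    co$interception_gain * biomass / (biomass + co$interception_half_sat)

  # (5) runoff, amplified in extreme-rainfall seasons
  extreme <- rain > extreme_rainfall_threshold(config)
  runoff <- pmax(0, rain * co$runoff_coef * co$runoff_tillage[[tillage]] *
                   (if (extreme) co$extreme_runoff_mult else 1) *
                   co$runoff_aws_ref / (aws + co$runoff_aws_ref) *
                   (1 - co$runoff_interception * interception) * eps[2L])

  # (6) yield, with runoff stress and a wet-season penalty on poor soils
  stress <- co$runoff_stress * pmin(1, runoff / co$runoff_stress_ref)
  yield <- co$harvest_index * biomass * (1 - stress)
  if (extreme && soil$oc_percent < co$extreme_oc_threshold)
    yield <- yield * co$extreme_yield_penalty

  # (7) emissions: baseline + carbon turnover, tillage and warmth scaled
  ghg <- (co$ghg_base + co$ghg_turnover * turnover) *
    co$ghg_tillage[[tillage]] * (1 + co$ghg_temp_slope * (temp - 10)) *
    eps[3L]

  record <- data.frame(
    experiment = experiment_id(tillage, soil),
    year = weather$year, tillage = tillage, soil = soil$soil,
    soilscape = soil$soilscape, oc_percent = soil$oc_percent,
    rainfall = rain, temperature = temp,
    csom = csom, aws = aws, interception = interception, biomass = biomass,
    yield = max(0, yield), runoff = runoff, ghg = max(0, ghg),
    stringsAsFactors = FALSE)
  list(record = record, carry = list(csom = csom))
}

#' @keywords internal
experiment_id <- function(tillage, soil) {
  sprintf("%s.OC-%s%%%s", tillage, format(soil$oc_percent), soil$soilscape)
}

#' Simulate the full seasonal dataset
#'
#' Iterates the experiment grid (soils x tillage systems) over the
#' configured years with a per-experiment carry state for the carbon
#' stock. The default configuration yields 30 experiments x 48 seasons =
#' 1,440 case records; the run is fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param noise logical; FALSE evaluates the noise-free structural core
#'   (useful for directional checks).
#' @return data.frame of seasonal case records.
#' @export
simulate_tillage_data <- function(config = sim_config(), noise = TRUE) {
  set.seed(config$seed)
  weather <- weather_series(config, seed = NULL)
  out <- vector("list",
                nrow(config$soils) * length(config$tillage_systems))
  k <- 0L
  for (scape in unique(config$soils$soilscape)) {
    for (till in config$tillage_systems) {
      block <- config$soils[config$soils$soilscape == scape, , drop = FALSE]
      for (i in seq_len(nrow(block))) {
        soil <- block[i, , drop = FALSE]
        carry <- list(csom = soil$csom_init)
        recs <- vector("list", nrow(weather))
        for (y in seq_len(nrow(weather))) {
          res <- simulate_season(soil, till, weather[y, , drop = FALSE],
                                 carry, config, noise = noise)
          recs[[y]] <- res$record
          carry <- res$carry
        }
        k <- k + 1L
        out[[k]] <- do.call(rbind, recs)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-experiment summary of yield and runoff
#'
#' Minimum, maximum, mean and standard deviation of crop yield and of
#' surface runoff for each experiment, in the wide layout of the study's
#' seasonal summary tables (statistics as rows, one column per
#' experiment). Intended for qualitative side-by-side comparison with the
#' published magnitudes, not for equality checks.
#'
#' @param records data.frame from [simulate_tillage_data()].
#' @return list with elements `yield` and `runoff`, each a data.frame
#'   with rows Minimum/Maximum/Average/`Standard deviation`.
#' @export
calibration_report <- function(records) {
  stats_for <- function(v) {
    sp <- split(records[[v]], records$experiment)
    sp <- sp[unique(records$experiment)]  # keep grid order
    as.data.frame(lapply(sp, function(x)
      c(Minimum = min(x), Maximum = max(x), Average = mean(x),
        `Standard deviation` = stats::sd(x))),
      check.names = FALSE)
  }
  list(yield = stats_for("yield"), runoff = stats_for("runoff"))
}
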