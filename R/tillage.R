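# The 11-node tillage-wheat network: four inputs (tillage system,
# soilscape, seasonal rainfall, seasonal temperature), four intermediaries
# (carbon in soil organic matter, available water space, precipitation
# interception, crop biomass) and three outputs (crop yield, surface
# runoff, GHG-CO2 emissions).

TILLAGE_STATES <- c("NT", "CT")
SOILSCAPES <- c("PDPG6", "PDPG7", "PDPG8")
NATIVE_OC <- c(PDPG6 = 2.6, PDPG7 = 4.4, PDPG8 = 3.9)
MODELED_OC <- c(1, 3, 5, 7)

#' Soil state labels of the combined soilscape x organic-carbon node
#' @return character vector of the 15 soil labels (3 soilscapes, each with
#'   its native organic-carbon level plus modeled 1/3/5/7% variants).
#' @export
soil_states <- function() {
  unlist(lapply(SOILSCAPES, function(s)
    paste0(s, ".OC", c(NATIVE_OC[[s]], MODELED_OC))), use.names = FALSE)
}

#' @keywords internal
continuous_vars <- function() {
  c("rainfall", "temperature", "csom", "aws", "interception",
    "biomass", "yield", "runoff", "ghg")
}

#' The default tillage-wheat network structure
#'
#' Eleven nodes and seventeen directed links. Tillage and soil act on the
#' soil-state intermediaries (C-SOM stock, available water space); weather
#' drives biomass, runoff and emissions; biomass intercepts precipitation
#' and, with the carbon stock, determines yield. Available water space
#' carries the most links of any node. Input nodes are parentless and the
#' three output nodes (yield, runoff, ghg) are childless.
#'
#' Continuous nodes are declared with `n_bands` ordered band states
#' (outputs always use the five canonical `Very low ... Very high` bands);
#' the actual cut points come from binning schemes fitted to training
#' data, see [fit_bins()] and [cases_to_states()]. The soil node is a
#' single 15-state categorical (soilscape x organic-carbon level) by
#' default; `soil_encoding = "split"` instead uses a 3-state soilscape
#' node, with organic-carbon level folded into the soilscape fertility
#' (the combined encoding is the default because the study grid crosses
#' every soilscape with every carbon level).
#'
#' @param n_bands number of bands for continuous non-output nodes
#'   (default 5).
#' @param soil_encoding `"combined"` (15-state soil node) or `"split"`
#'   (3-state soilscape node).
#' @param links optional replacement edge list (2-column matrix,
#'   parent/child) if an alternative topology is wanted; it is validated
#'   like any other structure.
#' @return a [network_spec()].
#' @examples
#' spec <- tillage_network()
#' length(spec$nodes)   # 11
#' nrow(spec$links)     # 17
#' @export
tillage_network <- function(n_bands = 5L,
                            soil_encoding = c("combined", "split"),
                            links = NULL) {
  soil_encoding <- match.arg(soil_encoding)
  bands <- band_labels(n_bands)
  out_bands <- band_labels(5L)
  soil_levels <- if (soil_encoding == "combined") soil_states() else SOILSCAPES
  nodes <- list(
    node_spec("tillage", TILLAGE_STATES, "input"),
    node_spec("soil", soil_levels, "input"),
    node_spec("rainfall", bands, "input"),
    node_spec("temperature", bands, "input"),
    node_spec("csom", bands, "intermediary"),
    node_spec("aws", bands, "intermediary"),
    node_spec("interception", bands, "intermediary"),
    node_spec("biomass", bands, "intermediary"),
    node_spec("yield", out_bands, "output"),
    node_spec("runoff", out_bands, "output"),
    node_spec("ghg", out_bands, "output"))
  if (is.null(links)) {
    links <- rbind(
      c("tillage", "csom"),
      c("tillage", "aws"),
      c("soil", "csom"),
      c("soil", "aws"),
      c("rainfall", "biomass"),
      c("rainfall", "runoff"),
      c("rainfall", "aws"),
      c("temperature", "biomass"),
      c("temperature", "ghg"),
      c("csom", "yield"),
      c("csom", "aws"),
      c("csom", "ghg"),
      c("aws", "biomass"),
      c("aws", "runoff"),
      c("biomass", "interception"),
      c("interception", "runoff"),
      c("biomass", "yield"))
  }
  network_spec(nodes, links)
}

#' Fit banding schemes for every continuous variable of the tillage model
#'
#' One [scheme_for_output()]-style quantile scheme per continuous
#' variable, fitted on (training) case records only — fitting on the full
#' data before splitting would leak test information into the model.
#'
#' @param records data.frame of raw seasonal case records (see
#'   [simulate_tillage_data()] for the column roster).
#' @param n_bands bands for non-output variables (outputs always get 5).
#' @return named list of `bin_scheme` objects.
#' @export
fit_tillage_schemes <- function(records, n_bands = 5L) {
  out_vars <- c("yield", "runoff", "ghg")
  schemes <- lapply(continuous_vars(), function(v) {
    if (!v %in% names(records))
      stop_bbn(sprintf("records lack column '%s'", v), "bbn_data_error")
    nb <- if (v %in% out_vars) 5L else n_bands
    fit_bins(records[[v]], n_bins = nb, method = "quantile", variable = v)
  })
  stats::setNames(schemes, continuous_vars())
}

#' Discretize seasonal case records into network states
#'
#' Categorical variables (tillage, soil) pass through unchanged;
#' continuous variables are banded with the supplied schemes (fitted on
#' training data only). `year` and `experiment` are preserved so that
#' chronological splitting remains possible downstream.
#'
#' @param records data.frame of raw case records.
#' @param schemes named list of `bin_scheme` objects, one per continuous
#'   variable (e.g. from [fit_tillage_schemes()]).
#' @return data.frame of factors over node states, plus `year` and
#'   `experiment` columns.
#' @export
cases_to_states <- function(records, schemes) {
  need <- c("experiment", "year", "tillage", "soil", continuous_vars())
  for (v in need) {
    if (!v %in% names(records))
      stop_bbn(sprintf("records lack column '%s'", v), "bbn_data_error")
    bad <- which(is.na(records[[v]]))
    if (length(bad))
      stop_bbn(sprintf("row %d: missing value in column '%s'", bad[1L], v),
               "bbn_data_error")
  }
  out <- data.frame(
    experiment = as.character(records$experiment),
    year = as.integer(records$year),
    tillage = factor(as.character(records$tillage), levels = TILLAGE_STATES),
    soil = factor(as.character(records$soil), levels = soil_states()),
    stringsAsFactors = FALSE)
  if (anyNA(out$tillage))
    stop_bbn("unknown tillage label in records", "bbn_data_error")
  if (anyNA(out$soil))
    stop_bbn("unknown soil label in records", "bbn_data_error")
  for (v in continuous_vars()) {
    if (!v %in% names(schemes))
      stop_bbn(sprintf("no banding scheme supplied for '%s'", v),
               "bbn_data_error")
    out[[v]] <- apply_bins(records[[v]], schemes[[v]])
  }
  out
}

#' Named evidence presets for scenario analysis
#'
#' The two single-finding tillage scenarios plus a favorable
#' (no-till, high-carbon soil, moderate rainfall) and an unfavorable
#' (conventional till, low-carbon soil, extreme rainfall) composite,
#' the "good-to-best / bad-to-worst" pattern of influence analysis.
#'
#' @return named list of evidence sets (named character vectors).
#' @export
scenario_presets <- function() {
  list(
    NT = c(tillage = "NT"),
    CT = c(tillage = "CT"),
    favorable = c(tillage = "NT", soil = "PDPG8.OC7", rainfall = "Medium"),
    unfavorable = c(tillage = "CT", soil = "PDPG6.OC1",
                    rainfall = "Very high"))
}
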