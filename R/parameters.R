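#' Default evaluative multimedia environment
#'
#' Parameterization of the closed three-compartment (air / surface water /
#' surface soil) evaluative environment used by the fate metrics. The values
#' describe a generic continental-scale region; because all hazard scores are
#' percentile ranks computed with the same environment for the screened and
#' the reference chemicals, the ranking is insensitive to the exact values.
#'
#' @param total_area Horizontal area of the region (m^2).
#' @param fraction_water,fraction_soil Area fractions of water and soil; must
#'   sum to 1.
#' @param air_height,water_depth,soil_depth Compartment depths (m).
#' @param wind_speed Mean wind speed (m/s), the advective velocity used for
#'   `ctd_air` and for the inter-regional air flow of the transfer-efficiency
#'   calculation.
#' @param water_current Mean water current (m/s), the advective velocity used
#'   for `ctd_water`.
#' @param aerosol_tsp Total suspended particle concentration in air (ug/m^3).
#' @param aerosol_om_fraction Organic-matter mass fraction of the aerosol.
#' @param rain_rate Rain rate (m/h).
#' @param particle_dep_velocity Dry deposition velocity of aerosol particles
#'   (m/h).
#' @param wet_scavenging_ratio Dimensionless washout ratio for particle-bound
#'   chemical.
#' @param mtc_air_side,mtc_water_side Air-side and water-side mass transfer
#'   coefficients of the two-film air-water exchange model (m/h).
#' @param mtc_air_soil Effective soil-side mass transfer coefficient for
#'   air-soil diffusive exchange (m/h).
#' @param soil_oc_fraction Organic-carbon mass fraction of soil solids.
#' @param water_ss_conc Suspended-solids concentration in water (kg/m^3).
#' @param ss_oc_fraction Organic-carbon mass fraction of suspended solids.
#' @param koc_from_kow_factor Proportionality constant relating Koc (L/kg) to
#'   Kow.
#' @param soil_runoff_rate_water,soil_runoff_rate_solids Water and solids
#'   runoff rates from soil to water (m/h).
#' @param region_length_scale Length of the region in the direction of air
#'   flow (m); defaults to `sqrt(total_area)`.
#'
#' @return A named list of class `"environment_parameters"`.
#' @export
#' @examples
#' env <- default_environment()
#' env$wind_speed
default_environment <- function(total_area = 1e13,
                                fraction_water = 0.7,
                                fraction_soil = 0.3,
                                air_height = 6000,
                                water_depth = 100,
                                soil_depth = 0.1,
                                wind_speed = 4,
                                water_current = 0.02,
                                aerosol_tsp = 30,
                                aerosol_om_fraction = 0.1,
                                rain_rate = 9.7e-5,
                                particle_dep_velocity = 10.8,
                                wet_scavenging_ratio = 2e5,
                                mtc_air_side = 3,
                                mtc_water_side = 0.03,
                                mtc_air_soil = 0.02,
                                soil_oc_fraction = 0.02,
                                water_ss_conc = 0.005,
                                ss_oc_fraction = 0.2,
                                koc_from_kow_factor = 0.41,
                                soil_runoff_rate_water = 3.9e-5,
                                soil_runoff_rate_solids = 2.3e-8,
                                region_length_scale = NULL) {
  env <- list(
    total_area = total_area,
    fraction_water = fraction_water,
    fraction_soil = fraction_soil,
    air_height = air_height,
    water_depth = water_depth,
    soil_depth = soil_depth,
    wind_speed = wind_speed,
    water_current = water_current,
    aerosol_tsp = aerosol_tsp,
    aerosol_om_fraction = aerosol_om_fraction,
    rain_rate = rain_rate,
    particle_dep_velocity = particle_dep_velocity,
    wet_scavenging_ratio = wet_scavenging_ratio,
    mtc_air_side = mtc_air_side,
    mtc_water_side = mtc_water_side,
    mtc_air_soil = mtc_air_soil,
    soil_oc_fraction = soil_oc_fraction,
    water_ss_conc = water_ss_conc,
    ss_oc_fraction = ss_oc_fraction,
    koc_from_kow_factor = koc_from_kow_factor,
    soil_runoff_rate_water = soil_runoff_rate_water,
    soil_runoff_rate_solids = soil_runoff_rate_solids,
    region_length_scale = if (is.null(region_length_scale)) sqrt(total_area) else region_length_scale
  )
  validate_environment(env)
  class(env) <- "environment_parameters"
  env
}

validate_environment <- function(env) {
  numeric_fields <- setdiff(names(env), c("fraction_water", "fraction_soil"))
  for (f in numeric_fields) {
    v <- env[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("environment parameter '", f, "' must be a single positive finite number", call. = FALSE)
    }
  }
  if (abs(env$fraction_water + env$fraction_soil - 1) > 1e-10) {
    stop("fraction_water + fraction_soil must equal 1", call. = FALSE)
  }
  if (env$fraction_water <= 0 || env$fraction_soil <= 0) {
    stop("area fractions must be strictly positive", call. = FALSE)
  }
  invisible(env)
}

#' Default fish parameterization for the bioaccumulation factor model
#'
#' A single mid-trophic-level fish used by [compute_baf()]. Allometric
#' constants follow common bioaccumulation mass-balance practice: gill
#' ventilation scales as `coefficient * W^exponent / dissolved_oxygen` (L/d)
#' and feeding as `feeding_rate_coefficient * W^0.85` (kg/d).
#'
#' @param body_mass Wet body mass W (kg).
#' @param lipid_fraction Whole-body lipid content (kg/kg).
#' @param diet_lipid_fraction Lipid content of the diet (kg/kg); the diet is
#'   assumed to be in lipid-phase equilibrium with the water.
#' @param gill_ventilation_coefficient,gill_ventilation_exponent Allometric
#'   constants of the gill ventilation rate.
#' @param dissolved_oxygen Dissolved oxygen concentration (mg/L).
#' @param feeding_rate_coefficient Allometric coefficient of the feeding rate
#'   (kg food / kg^0.85 / d).
#' @param growth_rate Growth dilution rate kG (1/d).
#' @param egestion_factor Fecal egestion rate as a fraction of the dietary
#'   uptake rate constant.
#'
#' @return A named list of class `"fish_parameters"`.
#' @export
default_fish_parameters <- function(body_mass = 0.184,
                                    lipid_fraction = 0.0685,
                                    diet_lipid_fraction = 0.02,
                                    gill_ventilation_coefficient = 1400,
                                    gill_ventilation_exponent = 0.65,
                                    dissolved_oxygen = 8,
                                    feeding_rate_coefficient = 0.022,
                                    growth_rate = 0.002,
                                    egestion_factor = 0.125) {
  fish <- list(
    body_mass = body_mass,
    lipid_fraction = lipid_fraction,
    diet_lipid_fraction = diet_lipid_fraction,
    gill_ventilation_coefficient = gill_ventilation_coefficient,
    gill_ventilation_exponent = gill_ventilation_exponent,
    dissolved_oxygen = dissolved_oxygen,
    feeding_rate_coefficient = feeding_rate_coefficient,
    growth_rate = growth_rate,
    egestion_factor = egestion_factor
  )
  for (f in names(fish)) {
    v <- fish[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("fish parameter '", f, "' must be a single positive finite number", call. = FALSE)
    }
  }
  if (fish$lipid_fraction >= 1 || fish$diet_lipid_fraction >= 1) {
    stop("lipid fractions must lie in (0, 1)", call. = FALSE)
  }
  class(fish) <- "fish_parameters"
  fish
}

#' Parameterization fingerprint
#'
#' A short deterministic fingerprint of the environment and fish
#' parameterization. Reference sets store the fingerprint they were built
#' with; scoring a batch against a reference set built under a different
#' parameterization is refused, because percentile ranks are only meaningful
#' when screened and reference chemicals share one model parameterization.
#'
#' @param env Environment parameters, see [default_environment()].
#' @param fish Fish parameters, see [default_fish_parameters()].
#' @return A character scalar.
#' @export
parameter_fingerprint <- function(env = default_environment(),
                                  fish = default_fish_parameters()) {
  vals <- c(unlist(env[sort(names(env))]), unlist(fish[sort(names(fish))]))
  txt <- paste(names(vals), formatC(vals, format = "g", digits = 15), sep = "=", collapse = ";")
  # polynomial rolling hash in double precision (exact: intermediates < 2^53)
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2^45
  sprintf("hs1-%014.0f", h)
}
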