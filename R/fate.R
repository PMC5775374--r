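#' Multimedia fate metrics
#'
#' An evaluative three-compartment (air, surface water, surface soil)
#' steady-state multimedia model in the tradition of screening-level
#' long-range transport potential tools. A unit emission into a single
#' compartment is balanced against first-order degradation in all
#' compartments and intermedia transfer (two-film air-water diffusion, rain
#' dissolution, wet and dry aerosol deposition, air-soil diffusion and
#' deposition, soil-to-water runoff of water and solids). The system is
#' closed (no advective loss), so at steady state the emission equals the
#' total degradation loss; overall persistence is the mass-weighted
#' residence time with respect to degradation.
#'
#' @name fate-model
#' @keywords internal
NULL

.compartments <- c("air", "water", "soil")

# soil matrix composition (volume fractions) and particle densities (kg/L);
# fixed internal constants of the evaluative soil, not exposed in the
# environment parameter list
.soil_vf_air <- 0.2
.soil_vf_water <- 0.3
.soil_vf_solid <- 0.5
.solid_density <- 2.4

check_record <- function(record) {
  need <- c("log_kow", "log_kaw", "t_half_air_h", "t_half_water_h", "t_half_soil_h")
  for (f in need) {
    v <- record[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("chemical record field '", f, "' must be a single finite number", call. = FALSE)
    }
  }
  if (record$t_half_air_h <= 0 || record$t_half_water_h <= 0 || record$t_half_soil_h <= 0) {
    stop("degradation half-lives must be strictly positive", call. = FALSE)
  }
  invisible(record)
}

# Aquivalence capacities (Z values) relative to pure water (Z_water = 1).
# phi is the particle-bound fraction in air from the Koa organic-matter
# absorption model: log Kp = log Koa + log f_om - 11.91, Kp in m^3/ug.
z_values <- function(record, env) {
  kow <- 10^record$log_kow
  kaw <- 10^record$log_kaw
  koa <- kow / kaw
  kp <- 10^(log10(koa) + log10(env$aerosol_om_fraction) - 11.91)
  kptsp <- kp * env$aerosol_tsp
  phi <- kptsp / (1 + kptsp)

  z_gas <- kaw
  z_air_bulk <- kaw * (1 + kptsp) # = z_gas / (1 - phi), no cancellation

  koc <- env$koc_from_kow_factor * kow # L/kg
  ss_kg_per_l <- env$water_ss_conc / 1000
  f_dissolved <- 1 / (1 + koc * env$ss_oc_fraction * ss_kg_per_l)
  z_water_bulk <- 1 / f_dissolved

  z_soil_solid <- koc * env$soil_oc_fraction * .solid_density
  z_soil_bulk <- .soil_vf_air * z_gas + .soil_vf_water * 1 + .soil_vf_solid * z_soil_solid

  list(
    gas = z_gas, air_bulk = z_air_bulk, aerosol_volumetric = z_gas * kptsp,
    water_bulk = z_water_bulk, f_dissolved = f_dissolved,
    soil_solid = z_soil_solid, soil_bulk = z_soil_bulk, phi = phi
  )
}

#' Phase fractions within each compartment
#'
#' Splits each bulk compartment into its phases: gas and aerosol-bound in
#' air; freely dissolved and sorbed to suspended solids in water; solid-bound,
#' pore-water and pore-air in soil. The aerosol-bound fraction uses the
#' octanol-air absorption model `log Kp = log Koa + log f_om - 11.91`
#' (Kp in m^3/ug) with `phi = Kp * TSP / (1 + Kp * TSP)`; the dissolved water
#' fraction is `1 / (1 + Koc * f_oc * SS)` with `Koc = koc_from_kow_factor * Kow`.
#'
#' @param record A chemical record (named list or one-row data frame) with at
#'   least `log_kow`, `log_kaw` and the three half-life columns.
#' @param env Environment parameters, see [default_environment()].
#' @return A list with elements `air`, `water` and `soil`, each a named
#'   numeric vector of phase fractions summing to 1.
#' @export
#' @examples
#' partitioning_fractions(
#'   list(log_kow = 4, log_kaw = -2, t_half_air_h = 100,
#'        t_half_water_h = 500, t_half_soil_h = 1000),
#'   default_environment()
#' )
partitioning_fractions <- function(record, env = default_environment()) {
  check_record(record)
  z <- z_values(record, env)
  air <- c(gas = 1 - z$phi, aerosol = z$phi)
  water <- c(dissolved = z$f_dissolved, sorbed = 1 - z$f_dissolved)
  soil_parts <- c(
    solid = .soil_vf_solid * z$soil_solid,
    pore_water = .soil_vf_water * 1,
    pore_air = .soil_vf_air * z$gas
  )
  soil <- soil_parts / sum(soil_parts)
  list(air = air, water = water, soil = soil)
}

#' First-order rate matrix of the evaluative environment
#'
#' Builds the intermedia transfer rate coefficients (1/h) between air, water
#' and soil for one chemical, together with the per-compartment degradation
#' rate vector `ln(2) / t_half`. Transfer coefficients are derived from
#' conductance (D) values divided by the source compartment's bulk capacity
#' `V * Z`, so the exchange-only matrix conserves mass: each of its columns
#' sums to zero.
#'
#' @inheritParams partitioning_fractions
#' @return A list with `exchange` (3x3 matrix, source in columns, destination
#'   in rows, negative column totals on the diagonal), `k_deg` (named vector,
#'   1/h), and `volumes_z` (bulk `V * Z` per compartment, used internally).
#' @export
build_rate_matrix <- function(record, env = default_environment()) {
  check_record(record)
  z <- z_values(record, env)

  a_w <- env$total_area * env$fraction_water
  a_s <- env$total_area * env$fraction_soil
  v_air <- env$total_area * env$air_height
  v_water <- a_w * env$water_depth
  v_soil <- a_s * env$soil_depth

  vz <- c(
    air = v_air * z$air_bulk,
    water = v_water * z$water_bulk,
    soil = v_soil * z$soil_bulk
  )

  # D values (conductances, m^3/h times Z): flux = D * aquivalence
  d_diff_aw <- a_w / (1 / (env$mtc_air_side * z$gas) + 1 / env$mtc_water_side)
  d_rain_w <- a_w * env$rain_rate
  d_wet_w <- a_w * env$rain_rate * env$wet_scavenging_ratio * z$aerosol_volumetric
  d_dry_w <- a_w * env$particle_dep_velocity * z$aerosol_volumetric

  d_diff_as <- a_s / (1 / (env$mtc_air_side * z$gas) + 1 / (env$mtc_air_soil * z$soil_bulk))
  d_rain_s <- a_s * env$rain_rate
  d_wet_s <- a_s * env$rain_rate * env$wet_scavenging_ratio * z$aerosol_volumetric
  d_dry_s <- a_s * env$particle_dep_velocity * z$aerosol_volumetric

  d_runoff <- a_s * (env$soil_runoff_rate_water * 1 +
    env$soil_runoff_rate_solids * z$soil_solid)

  d <- matrix(0, 3, 3, dimnames = list(.compartments, .compartments))
  d["water", "air"] <- d_diff_aw + d_rain_w + d_wet_w + d_dry_w
  d["soil", "air"] <- d_diff_as + d_rain_s + d_wet_s + d_dry_s
  d["air", "water"] <- d_diff_aw
  d["air", "soil"] <- d_diff_as
  d["water", "soil"] <- d_runoff

  exchange <- d / rep(vz, each = 3) # k[j, i] = D[j, i] / (V_i * Z_i)
  diag(exchange) <- -colSums(exchange)

  k_deg <- log(2) / c(
    air = record$t_half_air_h,
    water = record$t_half_water_h,
    soil = record$t_half_soil_h
  )

  if (all(abs(exchange) == 0) && all(k_deg == 0)) {
    stop("degenerate chemical: all transfer and degradation rates are zero", call. = FALSE)
  }

  list(exchange = exchange, k_deg = k_deg, volumes_z = vz)
}

#' Steady-state mass distribution for a single emission mode
#'
#' Solves the linear steady-state mass balance `(exchange - diag(k_deg)) m +
#' e = 0` for a constant emission into one compartment of the closed
#' evaluative environment. At steady state the emission rate equals the sum
#' of all degradation losses.
#'
#' @inheritParams partitioning_fractions
#' @param emission_mode One of `"air"`, `"water"`, `"soil"`.
#' @param emission_rate Emission rate (mol/h); results are linear in it.
#' @return A list of class `"steady_state"` with `masses` (mol),
#'   `degradation_losses` (mol/h), `intermedia_fluxes` (mol/h, source in
#'   columns), `k_deg`, `emission_mode`, `emission_rate` and the relative
#'   mass-balance error `balance_rel_error`.
#' @export
solve_steady_state <- function(record, env = default_environment(),
                               emission_mode = c("air", "water", "soil"),
                               emission_rate = 1) {
  emission_mode <- match.arg(emission_mode)
  stopifnot(is.numeric(emission_rate), length(emission_rate) == 1L, emission_rate > 0)
  rm <- build_rate_matrix(record, env)
  solve_steady_state_from_matrix(rm, emission_mode, emission_rate)
}

solve_steady_state_from_matrix <- function(rm, emission_mode, emission_rate,
                                           extra_loss = NULL, emission_vector = NULL) {
  a <- rm$exchange
  diag(a) <- diag(a) - rm$k_deg
  if (!is.null(extra_loss)) diag(a) <- diag(a) - extra_loss
  e <- if (is.null(emission_vector)) {
    stats::setNames(as.numeric(.compartments == emission_mode), .compartments) * emission_rate
  } else {
    emission_vector
  }
  m <- tryCatch(solve(a, -e), error = function(err) {
    stop("steady-state solve failed (singular system): ", conditionMessage(err), call. = FALSE)
  })
  m <- stats::setNames(pmax(m, 0), .compartments)
  losses <- rm$k_deg * m
  extra <- if (is.null(extra_loss)) 0 else sum(extra_loss * m)
  rel_err <- abs(sum(e) - sum(losses) - extra) / sum(e)
  fluxes <- rm$exchange * rep(m, each = 3)
  diag(fluxes) <- 0
  structure(
    list(
      emission_mode = if (is.null(emission_vector)) emission_mode else "custom",
      emission_rate = sum(e),
      masses = m,
      degradation_losses = losses,
      intermedia_fluxes = fluxes,
      k_deg = rm$k_deg,
      balance_rel_error = rel_err
    ),
    class = "steady_state"
  )
}

#' Overall persistence from a steady state
#'
#' `Pov = sum(m) / sum(k_deg * m)`, the mass-weighted residence time with
#' respect to degradation, converted from hours to days. Pov is bracketed by
#' the shortest and longest compartment half-life divided by ln 2.
#'
#' @param state A `"steady_state"` object from [solve_steady_state()].
#' @return Overall persistence in days (`Inf` with a warning when all
#'   degradation rates are zero).
#' @export
compute_pov <- function(state) {
  stopifnot(inherits(state, "steady_state"))
  total_loss <- sum(state$degradation_losses)
  if (total_loss == 0) {
    warning("all degradation losses are zero; overall persistence is infinite")
    return(Inf)
  }
  (sum(state$masses) / total_loss) / 24
}

#' Characteristic travel distance in a mobile medium
#'
#' `CTD = u * (m_medium / sum(m)) * tau_ov`, the distance travelled in the
#' mobile medium (air or water) before the chemical's mass declines to 1/e,
#' evaluated at the steady state for emission into that medium. `u` is the
#' medium's advective velocity and `tau_ov` the overall residence time of
#' that steady state.
#'
#' @inheritParams partitioning_fractions
#' @param medium `"air"` or `"water"`.
#' @param state Optional pre-computed steady state for emission into
#'   `medium`; solved internally when omitted.
#' @return Characteristic travel distance in km.
#' @export
compute_ctd <- function(record, env = default_environment(),
                        medium = c("air", "water"), state = NULL) {
  medium <- match.arg(medium)
  if (is.null(state)) state <- solve_steady_state(record, env, emission_mode = medium)
  stopifnot(inherits(state, "steady_state"))
  total_loss <- sum(state$degradation_losses)
  if (total_loss == 0) {
    warning("infinite residence time; characteristic travel distance is infinite")
    return(Inf)
  }
  tau_h <- sum(state$masses) / total_loss
  mobile_fraction <- state$masses[[medium]] / sum(state$masses)
  u_m_per_h <- switch(medium, air = env$wind_speed, water = env$water_current) * 3600
  u_m_per_h * mobile_fraction * tau_h / 1000
}

#' Atmospheric transfer efficiency
#'
#' Percentage of a unit emission to air in a source region that is deposited
#' (net) to the surface media of an identical remote region. The source
#' region's air compartment loses mass by advection at rate
#' `wind_speed / region_length_scale`; that outflow is the sole input to the
#' remote region, whose air is flushed at the same rate. At steady state the
#' net deposition to the remote surface equals the degradation loss in the
#' remote water and soil compartments, which is how it is evaluated here.
#'
#' @inheritParams partitioning_fractions
#' @return Transfer efficiency in percent, in `[0, 100]`.
#' @export
compute_te <- function(record, env = default_environment()) {
  rm <- build_rate_matrix(record, env)
  k_adv <- (env$wind_speed * 3600) / env$region_length_scale
  adv_loss <- c(air = k_adv, water = 0, soil = 0)
  emission <- 1
  source_ss <- solve_steady_state_from_matrix(rm, "air", emission, extra_loss = adv_loss)
  outflow <- k_adv * source_ss$masses[["air"]]
  if (outflow <= 0) {
    return(0)
  }
  remote_e <- c(air = outflow, water = 0, soil = 0)
  remote_ss <- solve_steady_state_from_matrix(rm, "air", outflow,
    extra_loss = adv_loss, emission_vector = remote_e
  )
  te <- 100 * (remote_ss$degradation_losses[["water"]] +
    remote_ss$degradation_losses[["soil"]]) / emission
  min(max(te, 0), 100)
}

#' Fate metrics for one chemical
#'
#' Runs the evaluative model for the three single-compartment emission modes
#' and assembles the screening fate metrics: overall persistence `pov_days`
#' (the maximum over the three emission modes, a conservative screening
#' convention), `ctd_air_km` (air-emission scenario), `ctd_water_km`
#' (water-emission scenario) and `te_percent` (two-region air-emission
#' construction).
#'
#' @inheritParams partitioning_fractions
#' @return A list of class `"fate_metrics"` with fields `pov_days`,
#'   `ctd_air_km`, `ctd_water_km`, `te_percent`.
#' @export
#' @examples
#' rec <- list(log_kow = 6, log_kaw = -4, t_half_air_h = 1000,
#'             t_half_water_h = 1000, t_half_soil_h = 1000)
#' compute_fate_metrics(rec)
compute_fate_metrics <- function(record, env = default_environment()) {
  check_record(record)
  states <- lapply(.compartments, function(mode) {
    solve_steady_state(record, env, emission_mode = mode)
  })
  names(states) <- .compartments
  pov_by_mode <- vapply(states, compute_pov, numeric(1))
  structure(
    list(
      pov_days = max(pov_by_mode),
      ctd_air_km = compute_ctd(record, env, "air", state = states$air),
      ctd_water_km = compute_ctd(record, env, "water", state = states$water),
      te_percent = compute_te(record, env)
    ),
    class = "fate_metrics"
  )
}

#' Fate metrics for a table of chemicals
#'
#' Applies [compute_fate_metrics()] row-wise. Per-chemical failures do not
#' abort the batch: failing rows get `NA` metrics, a `fate_error` message and
#' a warning.
#'
#' @param records Data frame of chemical records (see
#'   [read_chemical_table()] for the column contract).
#' @param env Environment parameters.
#' @return `records` with columns `pov_days`, `ctd_air_km`, `ctd_water_km`,
#'   `te_percent` and `fate_error` appended.
#' @export
fate_metrics_table <- function(records, env = default_environment()) {
  n <- nrow(records)
  out <- data.frame(
    pov_days = rep(NA_real_, n), ctd_air_km = rep(NA_real_, n),
    ctd_water_km = rep(NA_real_, n), te_percent = rep(NA_real_, n),
    fate_error = rep(NA_character_, n), stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    res <- tryCatch(
      compute_fate_metrics(as.list(records[i, , drop = FALSE]), env),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      out$fate_error[i] <- conditionMessage(res)
    } else {
      out$pov_days[i] <- res$pov_days
      out$ctd_air_km[i] <- res$ctd_air_km
      out$ctd_water_km[i] <- res$ctd_water_km
      out$te_percent[i] <- res$te_percent
    }
  }
  failed <- sum(!is.na(out$fate_error))
  if (failed > 0) {
    warning(failed, " record(s) failed fate-metric computation; see 'fate_error' column")
  }
  cbind(records, out)
}
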