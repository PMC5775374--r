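# fixtures built in code; no data files

make_record <- function(log_kow = 4, log_kaw = -3,
                        t_air = 200, t_water = 1000, t_soil = 2000, ...) {
  c(
    list(
      chem_id = "TEST-001", log_kow = log_kow, log_kaw = log_kaw,
      t_half_air_h = t_air, t_half_water_h = t_water, t_half_soil_h = t_soil
    ),
    list(...)
  )
}

# random records on the curated property domain with bounded half-lives
# (keeps dynamic-integration oracles cheap)
random_records <- function(n, seed) {
  set.seed(seed)
  data.frame(
    chem_id = sprintf("RND-%04d", seq_len(n)),
    log_kow = runif(n, -4, 10),
    log_kaw = runif(n, -12, 3),
    t_half_air_h = 10^runif(n, 1, 5),
    t_half_water_h = 10^runif(n, 1, 5),
    t_half_soil_h = 10^runif(n, 1, 5),
    stringsAsFactors = FALSE
  )
}

# independent dynamic-integration oracle: integrates dm/dt = A m + e with
# deSolve and returns the state at a time long enough for steady state
integrate_to_steady <- function(exchange, k_deg, emission,
                                extra_loss = 0, rel_horizon = 40) {
  a <- exchange
  diag(a) <- diag(a) - k_deg - extra_loss
  rates <- function(t, m, parms) list(a %*% m + emission)
  slowest <- min(k_deg + extra_loss)
  t_end <- rel_horizon / slowest
  times <- c(0, t_end / 2, t_end)
  out <- deSolve::lsoda(rep(0, length(k_deg)), times, rates, NULL,
    rtol = 1e-10, atol = 1e-12
  )
  m_half <- out[2, -1]
  m_end <- out[3, -1]
  stopifnot(max(abs(m_end - m_half) / max(m_end)) < 1e-8) # converged
  unname(m_end)
}
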