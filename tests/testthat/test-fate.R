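env <- default_environment()

test_that("phase fractions are normalized and follow the partitioning models", {
  # small Koa and Koc: gas and dissolved phases dominate
  rec <- make_record(log_kow = 0, log_kaw = 0)
  pf <- partitioning_fractions(rec, env)
  expect_lt(pf$air[["aerosol"]], 1e-6)
  expect_gt(pf$water[["dissolved"]], 0.999)

  # every compartment's fractions sum to 1
  for (seed_rec in split(random_records(20, seed = 11), seq_len(20))) {
    pf <- partitioning_fractions(as.list(seed_rec), env)
    for (comp in pf) expect_equal(sum(comp), 1, tolerance = 1e-12)
  }

  # aerosol fraction reproduces the Koa absorption closed form:
  # Kp = 10^(log Koa + log f_om - 11.91), phi = Kp TSP / (1 + Kp TSP)
  rec <- make_record(log_kow = 8, log_kaw = -2) # Koa = 1e10
  kp <- 10^(10 + log10(0.1) - 11.91)
  phi_expected <- kp * 30 / (1 + kp * 30)
  pf <- partitioning_fractions(rec, env)
  expect_equal(pf$air[["aerosol"]], phi_expected, tolerance = 1e-12)
})

test_that("rate matrix conserves mass in transfer and encodes half-lives", {
  rec <- make_record(t_air = 1e15, t_water = 1e15, t_soil = 1e15)
  rm <- build_rate_matrix(rec, env)
  expect_true(all(rm$k_deg < 1e-14))
  expect_lt(max(abs(colSums(rm$exchange))) / max(abs(rm$exchange)), 1e-12)

  rec <- make_record()
  rm <- build_rate_matrix(rec, env)
  expect_equal(
    unname(rm$k_deg),
    log(2) / c(rec$t_half_air_h, rec$t_half_water_h, rec$t_half_soil_h)
  )
  # off-diagonals non-negative
  off <- rm$exchange
  diag(off) <- 0
  expect_true(all(off >= 0))

  # at the Kaw floor, volatilization from water is negligible compared to
  # air-to-water transfer
  rec <- make_record(log_kaw = -12)
  rm <- build_rate_matrix(rec, env)
  expect_lt(rm$exchange["air", "water"], rm$exchange["water", "air"] * 1e-6)
})

test_that("zero-degradation dynamics conserve total mass (oracle)", {
  skip_if_not_installed("deSolve")
  set.seed(21)
  recs <- random_records(5, seed = 21)
  for (i in seq_len(nrow(recs))) {
    rm <- build_rate_matrix(as.list(recs[i, ]), env)
    rates <- function(t, m, parms) list(rm$exchange %*% m)
    m0 <- runif(3, 0.5, 2)
    out <- deSolve::lsoda(m0, c(0, 1e4, 1e6), rates, NULL, rtol = 1e-11, atol = 1e-13)
    totals <- rowSums(out[, -1])
    expect_lt(max(abs(totals - sum(m0))) / sum(m0), 1e-9)
  }
})

test_that("steady state closes the mass balance and is linear in emission", {
  rec <- make_record()
  ss1 <- solve_steady_state(rec, env, "air", emission_rate = 1)
  ss2 <- solve_steady_state(rec, env, "air", emission_rate = 2)
  expect_lt(ss1$balance_rel_error, 1e-9)
  expect_equal(unname(ss2$masses), unname(2 * ss1$masses), tolerance = 1e-12)
  expect_true(all(ss1$masses >= 0))
})

test_that("steady state matches long-time dynamic integration", {
  skip_if_not_installed("deSolve")
  recs <- random_records(12, seed = 31)
  modes <- rep(c("air", "water", "soil"), length.out = nrow(recs))
  for (i in seq_len(nrow(recs))) {
    rec <- as.list(recs[i, ])
    rm <- build_rate_matrix(rec, env)
    ss <- solve_steady_state(rec, env, modes[i])
    e <- as.numeric(c("air", "water", "soil") == modes[i])
    m_oracle <- integrate_to_steady(rm$exchange, rm$k_deg, e)
    expect_equal(unname(ss$masses), m_oracle, tolerance = 1e-6)
  }
})

test_that("overall persistence behaves as a mass-weighted residence time", {
  # equal half-lives: Pov = t / ln 2 regardless of partitioning
  for (t_half in c(50, 1000, 1e4)) {
    rec <- make_record(t_air = t_half, t_water = t_half, t_soil = t_half)
    for (mode in c("air", "water", "soil")) {
      ss <- solve_steady_state(rec, env, mode)
      expect_equal(compute_pov(ss), t_half / log(2) / 24, tolerance = 1e-12)
    }
  }

  # single-compartment limit: volatile, only air degrades appreciably
  rec <- make_record(log_kaw = 3, t_air = 100, t_water = 1e12, t_soil = 1e12)
  ss <- solve_steady_state(rec, env, "air")
  expect_gt(ss$masses[["air"]] / sum(ss$masses), 0.999)
  expect_equal(compute_pov(ss), 100 / log(2) / 24, tolerance = 1e-3)

  # bracketing on random records
  recs <- random_records(200, seed = 41)
  for (i in seq_len(nrow(recs))) {
    rec <- as.list(recs[i, ])
    ss <- solve_steady_state(rec, env, "air")
    pov <- compute_pov(ss)
    t3 <- c(rec$t_half_air_h, rec$t_half_water_h, rec$t_half_soil_h) / 24
    expect_gte(pov, min(t3) / log(2) * (1 - 1e-12))
    expect_lte(pov, max(t3) / log(2) * (1 + 1e-12))
  }

  # infinite-persistence sentinel
  rec <- make_record(t_air = 1e12, t_water = 1e12, t_soil = 1e12)
  ss <- solve_steady_state(rec, env, "air")
  ss$degradation_losses[] <- 0
  expect_warning(pov <- compute_pov(ss), "infinite")
  expect_identical(pov, Inf)
})

test_that("characteristic travel distance follows the mobile-fraction closed form", {
  # fully airborne chemical: CTD_air = wind speed x residence time
  rec <- make_record(log_kaw = 3, t_air = 100, t_water = 1e12, t_soil = 1e12)
  ss <- solve_steady_state(rec, env, "air")
  ctd <- compute_ctd(rec, env, "air", state = ss)
  tau_h <- sum(ss$masses) / sum(ss$degradation_losses)
  expect_equal(ctd, env$wind_speed * 3600 * tau_h / 1000, tolerance = 1e-3)

  # chemical strongly retained in surface media after emission to air: the
  # airborne mass fraction collapses and CTD_air falls far below the
  # fully-mobile limit wind_speed x residence time
  rec <- make_record(log_kow = 8, log_kaw = -10, t_air = 100, t_water = 1e6, t_soil = 1e6)
  ss <- solve_steady_state(rec, env, "air")
  frac_air <- ss$masses[["air"]] / sum(ss$masses)
  expect_lt(frac_air, 1e-3)
  tau_h <- sum(ss$masses) / sum(ss$degradation_losses)
  mobile_limit_km <- env$wind_speed * 3600 * tau_h / 1000
  expect_lt(compute_ctd(rec, env, "air", state = ss), 1e-3 * mobile_limit_km)

  # monotone in air half-life
  sweep <- 10^seq(1, 4, length.out = 20)
  ctds <- vapply(sweep, function(t_air) {
    compute_ctd(make_record(t_air = t_air), env, "air")
  }, numeric(1))
  expect_true(all(diff(ctds) >= 0))
})

test_that("transfer efficiency is bounded and matches a two-region dynamic oracle", {
  # destroyed in air before transport
  expect_lt(compute_te(make_record(t_air = 1e-3), env), 1e-6)

  # volatile and hydrophobic: no deposition pathway
  expect_lt(compute_te(make_record(log_kow = 2, log_kaw = 3), env), 0.05)

  # mid-space chemical against an independent 6-state dynamic simulation
  skip_if_not_installed("deSolve")
  rec <- make_record(log_kow = 6, log_kaw = -4, t_air = 1000, t_water = 1000, t_soil = 1000)
  te <- compute_te(rec, env)
  rm <- build_rate_matrix(rec, env)
  k_adv <- env$wind_speed * 3600 / env$region_length_scale
  a_region <- rm$exchange
  diag(a_region) <- diag(a_region) - rm$k_deg - c(k_adv, 0, 0)
  a_full <- matrix(0, 6, 6)
  a_full[1:3, 1:3] <- a_region
  a_full[4:6, 4:6] <- a_region
  a_full[4, 1] <- k_adv # region-1 air outflow feeds region-2 air
  rates <- function(t, m, parms) list(a_full %*% m + c(1, 0, 0, 0, 0, 0))
  t_end <- 40 / min(rm$k_deg)
  out <- deSolve::lsoda(rep(0, 6), c(0, t_end / 2, t_end), rates, NULL,
    rtol = 1e-10, atol = 1e-14
  )
  m2_water <- unname(out[3, 6])
  m2_soil <- unname(out[3, 7])
  te_oracle <- 100 * (rm$k_deg[["water"]] * m2_water + rm$k_deg[["soil"]] * m2_soil)
  expect_equal(te, te_oracle, tolerance = 1e-5)
  expect_gte(te, 0)
  expect_lte(te, 100)
})

test_that("fate metric bundle is conservative, batch-consistent and clip-insensitive", {
  rec <- make_record()
  fm <- compute_fate_metrics(rec, env)
  pov_modes <- vapply(c("air", "water", "soil"), function(mode) {
    compute_pov(solve_steady_state(rec, env, mode))
  }, numeric(1))
  expect_equal(fm$pov_days, max(pov_modes))
  expect_true(all(fm$pov_days >= pov_modes))

  # persistent volatile chemical scores high on all four metrics
  hi <- compute_fate_metrics(
    make_record(log_kow = 5, log_kaw = 0, t_air = 5e4, t_water = 5e4, t_soil = 5e4), env
  )
  lo <- compute_fate_metrics(
    make_record(log_kow = 2, log_kaw = -4, t_air = 20, t_water = 100, t_soil = 100), env
  )
  expect_gt(hi$pov_days, 50 * lo$pov_days)
  expect_gt(hi$ctd_air_km, lo$ctd_air_km)
  expect_gt(hi$ctd_water_km, lo$ctd_water_km)

  # batch equals scalar
  recs <- random_records(30, seed = 51)
  batch <- fate_metrics_table(recs, env)
  for (i in c(1, 13, 30)) {
    fm <- compute_fate_metrics(as.list(recs[i, ]), env)
    expect_equal(batch$pov_days[i], fm$pov_days)
    expect_equal(batch$ctd_air_km[i], fm$ctd_air_km)
    expect_equal(batch$ctd_water_km[i], fm$ctd_water_km)
    expect_equal(batch$te_percent[i], fm$te_percent)
  }

  # moving inputs beyond the domain bounds changes nothing after curation
  beyond <- data.frame(
    chem_id = c("a", "b"), log_kow = c(12, 4), log_kaw = c(0, 5),
    t_half_air_h = 500, t_half_water_h = 500, t_half_soil_h = 500
  )
  at_bound <- data.frame(
    chem_id = c("a", "b"), log_kow = c(10, 4), log_kaw = c(0, 3),
    t_half_air_h = 500, t_half_water_h = 500, t_half_soil_h = 500
  )
  m1 <- fate_metrics_table(clip_partition_ratios(beyond)$records, env)
  m2 <- fate_metrics_table(clip_partition_ratios(at_bound)$records, env)
  for (col in c("pov_days", "ctd_air_km", "ctd_water_km", "te_percent")) {
    expect_equal(m1[[col]], m2[[col]], tolerance = 1e-12)
  }
})

test_that("invalid records are rejected and batch failures are contained", {
  expect_error(compute_fate_metrics(make_record(log_kow = NaN)), "log_kow")
  expect_error(compute_fate_metrics(make_record(t_air = -5)), "positive")
  bad_batch <- random_records(3, seed = 61)
  bad_batch$t_half_water_h[2] <- -1
  expect_warning(out <- fate_metrics_table(bad_batch, env), "failed")
  expect_true(is.na(out$pov_days[2]) && !is.na(out$fate_error[2]))
  expect_false(anyNA(out$pov_days[c(1, 3)]))
})
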