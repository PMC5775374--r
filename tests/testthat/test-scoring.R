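test_that("raw profile scores are the stated metric products", {
  raw <- raw_hazard_scores(
    pov_days = 100, log_baf = 4, te_percent = 2,
    ctd_air_km = 500, ctd_water_km = 50
  )
  expect_equal(raw$raw_pop, 2e6)
  expect_equal(raw$raw_vpvb, 1e6)
  expect_equal(raw$raw_apc, 5e4)
  expect_equal(raw$raw_wpc, 5e3)

  # doubling TE doubles the POP score and leaves vPvB unchanged
  raw2 <- raw_hazard_scores(100, 4, 4, 500, 50)
  expect_equal(raw2$raw_pop, 2 * raw$raw_pop)
  expect_equal(raw2$raw_vpvb, raw$raw_vpvb)

  # TE = 0 zeroes POP but not APC
  raw0 <- raw_hazard_scores(100, 4, 0, 500, 50)
  expect_equal(raw0$raw_pop, 0)
  expect_gt(raw0$raw_apc, 0)

  expect_error(raw_hazard_scores(-1, 4, 2, 500, 50), "negative")
})

test_that("percentile ranks count reference values strictly below", {
  ref <- c(1, 2, 3, 4)
  expect_equal(percentile_score(2.5, ref), 50)
  expect_equal(percentile_score(0.5, ref), 0)
  expect_equal(percentile_score(9, ref), 100)
  expect_equal(percentile_score(2, ref), 25) # tie counts as not exceeding

  # brute-force double-loop oracle on a random batch
  set.seed(13)
  reference <- rlnorm(148, 5, 3)
  raws <- c(rlnorm(50, 5, 3), sample(reference, 10)) # include exact ties
  got <- percentile_score(raws, reference)
  oracle <- vapply(raws, function(r) 100 * sum(reference < r) / length(reference), numeric(1))
  expect_equal(got, oracle)

  expect_error(percentile_score(1, numeric(0)), "empty")
})

test_that("scoring is rank-invariant and self-benchmarking lies on the uniform grid", {
  set.seed(17)
  n_ref <- 148
  ref_raw <- data.frame(
    raw_pop = rlnorm(n_ref, 8, 4), raw_vpvb = rlnorm(n_ref, 6, 3),
    raw_apc = rlnorm(n_ref, 7, 2), raw_wpc = rlnorm(n_ref, 5, 2)
  )
  ref <- reference_set(ref_raw, provenance = "unit test")

  batch <- data.frame(
    pov_days = rlnorm(50, 3, 1), log_baf = runif(50, 0, 8),
    te_percent = runif(50, 0, 30), ctd_air_km = rlnorm(50, 6, 1),
    ctd_water_km = rlnorm(50, 4, 1)
  )
  scored <- score_table(batch, ref)

  # joint monotone rescaling of raw and reference leaves percentiles unchanged
  scale <- 7.3
  ref_scaled <- reference_set(ref_raw * scale)
  rescored <- score_table(batch, ref_scaled)
  # scale raw scores by scaling the metrics feeding them
  batch_scaled <- batch
  batch_scaled$pov_days <- batch$pov_days * scale
  rescored2 <- score_table(batch_scaled, ref_scaled)
  for (col in c("s_pop", "s_vpvb", "s_apc", "s_wpc")) {
    expect_equal(rescored2[[col]], scored[[col]])
  }

  # percentiles computed on log-transformed raw scores agree (rank invariance)
  log_ref <- ref_raw
  log_ref[] <- lapply(log_ref, log)
  expect_equal(
    percentile_score(log(scored$raw_pop), sort(log(ref_raw$raw_pop))),
    scored$s_pop
  )

  # attainable values form the grid {0, 100/148, ..., 100}
  expect_true(all(scored$s_pop %in% (100 * (0:n_ref) / n_ref)))

  # self-benchmarking: each reference chemical's score is its strict rank
  self <- data.frame(
    pov_days = ref_raw$raw_vpvb, log_baf = 0, te_percent = 1,
    ctd_air_km = 1, ctd_water_km = 1
  )
  self_scored <- score_table(self, ref)
  expect_equal(self_scored$s_vpvb, 100 * (rank(ref_raw$raw_vpvb) - 1) / n_ref)
  expect_setequal(self_scored$s_vpvb, 100 * (0:(n_ref - 1)) / n_ref)
})

test_that("fingerprint mismatches between batch and reference are refused", {
  ref_raw <- data.frame(
    raw_pop = 1:10, raw_vpvb = 1:10, raw_apc = 1:10, raw_wpc = 1:10
  )
  ref <- reference_set(ref_raw, fingerprint = "hs1-aaa")
  batch <- data.frame(
    pov_days = 1, log_baf = 1, te_percent = 1, ctd_air_km = 1, ctd_water_km = 1
  )
  expect_error(score_table(batch, ref, fingerprint = "hs1-bbb"), "fingerprint mismatch")
  expect_silent(score_table(batch, ref, fingerprint = "hs1-aaa"))
  expect_silent(score_table(batch, ref)) # unknown batch fingerprint tolerated
})

test_that("priority flags use strict thresholds and the spatial-class precedence", {
  sc <- data.frame(
    s_pop = c(95, 10, 90, 5, 95), s_vpvb = c(95, 20, 90, 5, 50),
    s_apc = c(50, 95, 90, 5, 50), s_wpc = c(50, 50, 90, 5, 50)
  )
  fl <- priority_flags(sc)
  expect_equal(
    as.character(fl$spatial_class),
    c("near_field", "global", "none", "none", "far_field")
  )
  # scores exactly at the threshold do not flag (strict >)
  expect_false(any(unlist(fl[3, grep("^over90", names(fl))])))
  expect_true(all(unlist(fl[4, grep("^under10", names(fl))])))
})

test_that("priority summaries reconcile with brute-force set algebra", {
  # constructed overlap case: one row over in POP and APC only
  sc <- data.frame(s_pop = 95, s_vpvb = 50, s_apc = 95, s_wpc = 50)
  s <- priority_summary(priority_flags(sc))
  expect_equal(s$over90_any, 1L)
  expect_equal(sum(s$over90_exclusive), 0L)

  # all-zero rows
  sc0 <- data.frame(s_pop = 0, s_vpvb = 0, s_apc = 0, s_wpc = 0)[rep(1, 5), ]
  s0 <- priority_summary(priority_flags(sc0))
  expect_equal(s0$over90_any, 0L)
  expect_equal(s0$all_zero, 5L)
  expect_equal(s0$under10_all, 5L)

  # random batch vs direct set algebra
  set.seed(23)
  n <- 200
  sc_rand <- data.frame(
    s_pop = sample(seq(0, 100, 100 / 148), n, TRUE),
    s_vpvb = sample(seq(0, 100, 100 / 148), n, TRUE),
    s_apc = sample(seq(0, 100, 100 / 148), n, TRUE),
    s_wpc = sample(seq(0, 100, 100 / 148), n, TRUE)
  )
  s_rand <- priority_summary(priority_flags(sc_rand))
  over <- sc_rand > 90
  expect_equal(s_rand$over90_per_profile, unname(colSums(over)))
  expect_equal(s_rand$over90_any, sum(rowSums(over) > 0))
  expect_equal(
    s_rand$over90_exclusive,
    unname(vapply(1:4, function(j) sum(over[, j] & rowSums(over) == 1), numeric(1)))
  )
  expect_equal(s_rand$under10_all, sum(rowSums(sc_rand < 10) == 4))
  expect_equal(s_rand$spatial_pop90_not_vpvb90, sum(over[, 1] & !over[, 2]))
  expect_equal(s_rand$spatial_apc90_not_pop90, sum(over[, 3] & !over[, 1]))
  expect_equal(s_rand$spatial_wpc90_not_pop90, sum(over[, 4] & !over[, 1]))
  # exclusive <= per-profile <= any-profile total
  expect_true(all(s_rand$over90_exclusive <= s_rand$over90_per_profile))
  expect_true(all(s_rand$over90_per_profile <= s_rand$over90_any | s_rand$over90_per_profile == 0))
})

test_that("reference sets round-trip through the file format", {
  set.seed(29)
  raw <- data.frame(
    chem_id = sprintf("R%03d", 1:20),
    raw_pop = rlnorm(20), raw_vpvb = rlnorm(20),
    raw_apc = rlnorm(20), raw_wpc = rlnorm(20)
  )
  ref <- reference_set(raw, provenance = "roundtrip test", fingerprint = "hs1-xyz")
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference_set(ref, raw, path)
  back <- read_reference_set(path)
  expect_equal(back$scores, ref$scores)
  expect_equal(back$fingerprint, "hs1-xyz")
  expect_equal(back$provenance, "roundtrip test")
})
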