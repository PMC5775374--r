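#' Configuration of the synthetic chemical-property generator
#'
#' The generator emulates the statistical structure of a large
#' commerce-scale screening database of neutral organics with
#' property-estimation-derived inputs: partition ratios spanning the
#' property-model domain (log Kow in \[-4, 10\], log Kaw in \[-12, 3\]),
#' right-skewed (log-normal) degradation half-lives, a minority fraction of
#' ionizable records, and element compositions with commerce-like
#' prevalences (e.g. ~13% of structures chlorinated, ~4% fluorinated, ~3%
#' brominated) and halogenation-level distributions peaking at three
#' fluorines and two chlorines.
#'
#' @param n_chemicals Number of records to generate.
#' @param seed Integer seed; the output is fully determined by
#'   `(config, seed)`.
#' @param log_kow_range,log_kaw_range Clip ranges of the partition ratios.
#' @param log_kow_mean,log_kow_sd,log_kaw_mean,log_kaw_sd Normal draw
#'   parameters before clipping.
#' @param half_life_log_mean Named vector (`air`, `water`, `soil`) of log
#'   median half-lives, `log(hours)`.
#' @param half_life_log_sd Named vector of log standard deviations.
#' @param ionizable_fraction Fraction of records assigned `pka < 5` or
#'   `pkb > 8`.
#' @param element_prevalence Named per-element probability that a structure
#'   contains the element.
#' @param halogen_count_weights Named list of unnormalized integer-count
#'   weights (index = atom count) for F, Cl, Br, I.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_chemicals = 1000,
                             seed = 1,
                             log_kow_range = c(-4, 10),
                             log_kaw_range = c(-12, 3),
                             log_kow_mean = 3, log_kow_sd = 2.2,
                             log_kaw_mean = -4, log_kaw_sd = 3,
                             half_life_log_mean = c(air = log(100), water = log(900), soil = log(1800)),
                             half_life_log_sd = c(air = 1.2, water = 1.0, soil = 1.0),
                             ionizable_fraction = 0.31,
                             element_prevalence = c(
                               F = 0.038, Cl = 0.131, Br = 0.029, I = 0.003,
                               N = 0.363, S = 0.101, P = 0.030, O = 0.816,
                               Si = 0.028, B = 0.003
                             ),
                             halogen_count_weights = list(
                               F = c(20, 12, 35, 8, 10, 6, 4, 2, 1, 2),
                               Cl = c(18, 40, 8, 20, 4, 6, 1, 2),
                               Br = c(50, 25, 10, 8, 4, 3),
                               I = c(70, 15, 10, 5)
                             )) {
  cfg <- list(
    n_chemicals = n_chemicals, seed = seed,
    log_kow_range = log_kow_range, log_kaw_range = log_kaw_range,
    log_kow_mean = log_kow_mean, log_kow_sd = log_kow_sd,
    log_kaw_mean = log_kaw_mean, log_kaw_sd = log_kaw_sd,
    half_life_log_mean = half_life_log_mean,
    half_life_log_sd = half_life_log_sd,
    ionizable_fraction = ionizable_fraction,
    element_prevalence = element_prevalence,
    halogen_count_weights = halogen_count_weights
  )
  if (!is.numeric(n_chemicals) || n_chemicals < 1) {
    stop("n_chemicals must be a positive count", call. = FALSE)
  }
  if (diff(log_kow_range) <= 0 || diff(log_kaw_range) <= 0) {
    stop("clip ranges must be ordered", call. = FALSE)
  }
  if (ionizable_fraction < 0 || ionizable_fraction > 1) {
    stop("ionizable_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(element_prevalence < 0 | element_prevalence > 1)) {
    stop("element prevalences must lie in [0, 1]", call. = FALSE)
  }
  class(cfg) <- "synthetic_config"
  cfg
}

sample_count <- function(n, weights) {
  sample.int(length(weights), n, replace = TRUE, prob = weights / sum(weights))
}

assemble_formula <- function(counts) {
  # Hill order: C, H, then remaining symbols alphabetically
  symbols <- c("C", "H", sort(setdiff(names(counts), c("C", "H"))))
  parts <- vapply(symbols, function(el) {
    k <- counts[[el]]
    if (is.null(k) || is.na(k) || k == 0) "" else if (k == 1) el else paste0(el, k)
  }, character(1))
  paste0(parts, collapse = "")
}

#' Generate a synthetic screening table
#'
#' Draws `n_chemicals` synthetic chemical records under the configured
#' marginal distributions (properties are sampled independently; real
#' property databases carry correlations that this generator deliberately
#' does not emulate). Ionizable records receive `pka` uniform on
#' (2, 4.9) or `pkb` uniform on (8.1, 12); the remainder receive a safe
#' constant or `NA` (unknown) in equal parts, so downstream handling of
#' missing ionization data is exercised.
#'
#' @param config A [synthetic_config()].
#' @return A data frame of chemical records with the standard column
#'   contract (see [read_chemical_table()]).
#' @export
#' @examples
#' head(generate_screening_set(synthetic_config(n_chemicals = 5, seed = 42)))
generate_screening_set <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_chemicals
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    })
    set.seed(config$seed)
    expr
  }
  withr_seed({
    log_kow <- pmin(pmax(
      stats::rnorm(n, config$log_kow_mean, config$log_kow_sd),
      config$log_kow_range[1]
    ), config$log_kow_range[2])
    log_kaw <- pmin(pmax(
      stats::rnorm(n, config$log_kaw_mean, config$log_kaw_sd),
      config$log_kaw_range[1]
    ), config$log_kaw_range[2])
    t_air <- stats::rlnorm(n, config$half_life_log_mean[["air"]], config$half_life_log_sd[["air"]])
    t_water <- stats::rlnorm(n, config$half_life_log_mean[["water"]], config$half_life_log_sd[["water"]])
    t_soil <- stats::rlnorm(n, config$half_life_log_mean[["soil"]], config$half_life_log_sd[["soil"]])

    ionizable <- stats::runif(n) < config$ionizable_fraction
    acid <- stats::runif(n) < 0.5
    pka <- rep(NA_real_, n)
    pkb <- rep(NA_real_, n)
    pka[ionizable & acid] <- stats::runif(sum(ionizable & acid), 2, 4.9)
    pkb[ionizable & !acid] <- stats::runif(sum(ionizable & !acid), 8.1, 12)
    known_neutral <- !ionizable & stats::runif(n) < 0.5
    pka[known_neutral] <- stats::runif(sum(known_neutral), 6, 12)
    pkb[known_neutral] <- stats::runif(sum(known_neutral), 1, 7.5)

    prev <- config$element_prevalence
    c_count <- pmax(1L, stats::rpois(n, 9))
    counts <- list(C = c_count)
    for (el in names(prev)) {
      present <- stats::runif(n) < prev[[el]]
      k <- integer(n)
      if (el %in% names(config$halogen_count_weights)) {
        k[present] <- sample_count(sum(present), config$halogen_count_weights[[el]])
      } else if (el == "O") {
        k[present] <- sample_count(sum(present), c(30, 25, 18, 10, 8, 5, 3, 1))
      } else if (el == "N") {
        k[present] <- sample_count(sum(present), c(45, 30, 15, 7, 3))
      } else {
        k[present] <- sample_count(sum(present), c(70, 20, 7, 3))
      }
      counts[[el]] <- k
    }
    # crude but valence-plausible hydrogen count
    h_count <- pmax(0L, 2L * c_count + 2L -
      (counts$F + counts$Cl + counts$Br + counts$I) -
      as.integer(round(0.5 * (counts$N + counts$O + counts$S))))
    counts$H <- h_count

    formula <- vapply(seq_len(n), function(i) {
      assemble_formula(lapply(counts, `[`, i))
    }, character(1))

    data.frame(
      chem_id = sprintf("SYN-%06d", seq_len(n)),
      name = sprintf("synthetic chemical %d", seq_len(n)),
      formula = formula,
      smiles = NA_character_,
      log_kow = log_kow,
      log_kaw = log_kaw,
      t_half_air_h = t_air,
      t_half_water_h = t_water,
      t_half_soil_h = t_soil,
      pka = pka,
      pkb = pkb,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a synthetic reference fixture
#'
#' Builds a synthetic stand-in for the reference set of well-characterized
#' contaminants: `n` records spanning the reference chemical space
#' (log Kaw in (-10, 2), log Kow in (-2, 10)), biased toward persistent and
#' bioaccumulative property combinations so the raw reference scores cover
#' several orders of magnitude, then runs the full metric pipeline on them
#' to obtain the per-profile raw score arrays.
#'
#' @param n Number of reference chemicals (default 148).
#' @param seed Integer seed.
#' @param env,fish Model parameterization used to compute the reference
#'   metrics (must match the batch to be scored).
#' @return A list with `reference` (a `"reference_set"` whose fingerprint is
#'   `parameter_fingerprint(env, fish)`) and `records` (the underlying
#'   chemical table including metrics and raw scores).
#' @export
generate_reference_fixture <- function(n = 148, seed = 1,
                                       env = default_environment(),
                                       fish = default_fish_parameters()) {
  stopifnot(n >= 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  records <- data.frame(
    chem_id = sprintf("REF-%03d", seq_len(n)),
    name = sprintf("synthetic reference chemical %d", seq_len(n)),
    formula = NA_character_,
    smiles = NA_character_,
    log_kow = stats::runif(n, -2, 10),
    log_kaw = stats::runif(n, -10, 2),
    t_half_air_h = stats::rlnorm(n, log(500), 1.5),
    t_half_water_h = stats::rlnorm(n, log(3000), 1.5),
    t_half_soil_h = stats::rlnorm(n, log(8000), 1.5),
    pka = NA_real_,
    pkb = NA_real_,
    stringsAsFactors = FALSE
  )
  with_metrics <- fate_metrics_table(records, env)
  with_metrics <- apply_baf_column(with_metrics, fish)
  raw <- raw_hazard_scores(
    with_metrics$pov_days, with_metrics$log_baf, with_metrics$te_percent,
    with_metrics$ctd_air_km, with_metrics$ctd_water_km
  )
  # raw POP scores can be zero when TE underflows; floor at the smallest
  # positive double so reference arrays stay > 0 without affecting ranks
  raw[raw == 0] <- .Machine$double.xmin
  out <- cbind(with_metrics, raw)
  ref <- reference_set(raw,
    provenance = paste0("synthetic fixture (n = ", n, ", seed = ", seed, ")"),
    fingerprint = parameter_fingerprint(env, fish)
  )
  list(reference = ref, records = out)
}
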