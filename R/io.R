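#' Read and write chemical property tables
#'
#' The file contract is delimited text (comma-separated, UTF-8, header row)
#' with required columns `chem_id`, `log_kow`, `log_kaw`, `t_half_air_h`,
#' `t_half_water_h`, `t_half_soil_h` (half-lives in hours, partition ratios
#' on the log10 scale) and optional columns `name`, `formula`, `smiles`,
#' `pka`, `pkb`, `log_baf` (external override, log10 L/kg) and `km_per_day`
#' (whole-body biotransformation rate, 1/d). Unknown columns are preserved
#' as passthrough. Rows with unparseable numbers in required columns are
#' flagged in an `input_error` column and reported with a warning.
#'
#' @param path File path.
#' @param records Data frame to write.
#' @return `read_chemical_table` returns a data frame of typed records.
#' @export
read_chemical_table <- function(path) {
  tbl <- utils::read.csv(path,
    stringsAsFactors = FALSE, check.names = FALSE, fileEncoding = "UTF-8"
  )
  required <- c(
    "chem_id", "log_kow", "log_kaw",
    "t_half_air_h", "t_half_water_h", "t_half_soil_h"
  )
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    stop("input table is missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  numeric_cols <- intersect(
    c(
      "log_kow", "log_kaw", "t_half_air_h", "t_half_water_h", "t_half_soil_h",
      "pka", "pkb", "log_baf", "km_per_day"
    ),
    names(tbl)
  )
  bad_rows <- rep(FALSE, nrow(tbl))
  for (col in numeric_cols) {
    raw <- tbl[[col]]
    if (is.numeric(raw)) next
    raw <- as.character(raw)
    parsed <- suppressWarnings(as.numeric(raw))
    newly_bad <- !is.na(raw) & nzchar(trimws(raw)) & is.na(parsed)
    bad_rows <- bad_rows | newly_bad
    tbl[[col]] <- parsed
  }
  if (any(bad_rows)) {
    warning(
      sum(bad_rows), " row(s) with unparseable numeric values flagged in 'input_error'"
    )
  }
  tbl$input_error <- bad_rows
  tbl
}

#' @rdname read_chemical_table
#' @export
write_chemical_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Run the full screening pipeline
#'
#' Executes the stages in order: curation (ionizability filter, domain
#' clipping) -> multimedia fate metrics -> bioaccumulation factor -> raw
#' profile scores and percentile benchmarking -> priority flags and
#' summaries. The reference set either comes from the caller (built or read
#' with a matching parameterization fingerprint) or is generated as the
#' synthetic fixture under `reference_seed`.
#'
#' @param records Data frame of chemical records (see
#'   [read_chemical_table()]), or a path to such a file.
#' @param env,fish Model parameterization.
#' @param reference A `"reference_set"`, or `NULL` to generate the synthetic
#'   fixture.
#' @param reference_seed Seed for the synthetic reference fixture when
#'   `reference` is `NULL`.
#' @param pka_threshold,pkb_threshold,kow_range,kaw_range Curation settings.
#' @return A list of class `"pipeline_result"` with `scored` (the scored and
#'   flagged table), `curation` (the curation report), `summary` (priority
#'   counts), `reference`, and `manifest` (stage row counts, fingerprint,
#'   package version).
#' @export
run_pipeline <- function(records,
                         env = default_environment(),
                         fish = default_fish_parameters(),
                         reference = NULL,
                         reference_seed = 1,
                         pka_threshold = 5, pkb_threshold = 8,
                         kow_range = c(-4, 10), kaw_range = c(-12, 3)) {
  if (is.character(records) && length(records) == 1L) {
    records <- read_chemical_table(records)
  }
  fingerprint <- parameter_fingerprint(env, fish)
  if (is.null(reference)) {
    reference <- generate_reference_fixture(
      n = 148, seed = reference_seed,
      env = env, fish = fish
    )$reference
  }
  stopifnot(inherits(reference, "reference_set"))

  cur <- curate_records(records, pka_threshold, pkb_threshold, kow_range, kaw_range)
  with_metrics <- fate_metrics_table(cur$records, env)
  with_baf <- apply_baf_column(with_metrics, fish)
  scored <- score_table(with_baf, reference, fingerprint = fingerprint)
  flagged <- priority_flags(scored)
  summary <- priority_summary(flagged)

  manifest <- list(
    package_version = as.character(utils::packageVersion("hazscreen")),
    fingerprint = fingerprint,
    reference_provenance = reference$provenance,
    n_reference = reference$n,
    stages = list(
      input = cur$report$n_input,
      curated = cur$report$n_output,
      metrics = sum(is.na(flagged$fate_error)),
      scored = nrow(flagged)
    )
  )
  structure(
    list(
      scored = flagged, curation = cur$report, summary = summary,
      reference = reference, manifest = manifest
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Screening pipeline result\n")
  cat(
    "  input:", x$manifest$stages$input, "-> curated:", x$manifest$stages$curated,
    "-> scored:", x$manifest$stages$scored, "\n"
  )
  cat("  reference:", x$manifest$reference_provenance, "\n")
  cat("  over-90 in any profile:", x$summary$over90_any, "\n")
  invisible(x)
}

#' Write a pipeline manifest
#'
#' @param result A `"pipeline_result"`.
#' @param path Output path (JSON).
#' @export
write_manifest <- function(result, path) {
  stopifnot(inherits(result, "pipeline_result"))
  jsonlite::write_json(result$manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
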