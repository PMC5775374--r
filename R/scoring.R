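#' Raw multiplicative hazard scores
#'
#' Each exposure-based hazard profile is a product of the metrics it names
#' (legislative "persistent AND bioaccumulative" language translated as a
#' logical AND, hence multiplication on the linear scale):
#'
#' * `raw_pop  = Pov * BAF * TE`    (persistence, bioaccumulation, transfer efficiency)
#' * `raw_vpvb = Pov * BAF`          (no long-range transport term)
#' * `raw_apc  = Pov * CTD_air`      (persistence and mobility in air)
#' * `raw_wpc  = Pov * CTD_water`    (persistence and mobility in water)
#'
#' Units: Pov in days, BAF in L/kg, TE in percent, CTDs in km. The absolute
#' units are immaterial because scores are converted to percentile ranks,
#' which are invariant under any joint monotone rescaling.
#'
#' @param pov_days,log_baf,te_percent,ctd_air_km,ctd_water_km Numeric
#'   vectors of equal length (metrics on the scales above; `log_baf` on the
#'   log10 scale, exponentiated internally).
#' @return A data frame with columns `raw_pop`, `raw_vpvb`, `raw_apc`,
#'   `raw_wpc`.
#' @export
#' @examples
#' raw_hazard_scores(100, 4, 2, 500, 50)
raw_hazard_scores <- function(pov_days, log_baf, te_percent, ctd_air_km, ctd_water_km) {
  args <- list(pov_days, log_baf, te_percent, ctd_air_km, ctd_water_km)
  n <- unique(lengths(args))
  if (length(n) != 1L) stop("metric vectors must have equal length", call. = FALSE)
  ok <- is.na(pov_days) | is.na(te_percent) | is.na(ctd_air_km) | is.na(ctd_water_km) |
    (pov_days >= 0 & te_percent >= 0 & ctd_air_km >= 0 & ctd_water_km >= 0)
  if (!all(ok)) stop("negative metric values are invalid", call. = FALSE)
  baf <- 10^log_baf
  data.frame(
    raw_pop = pov_days * baf * te_percent,
    raw_vpvb = pov_days * baf,
    raw_apc = pov_days * ctd_air_km,
    raw_wpc = pov_days * ctd_water_km
  )
}

#' Percentile rank against a reference score vector
#'
#' `score = 100 * (# reference values strictly below raw) / N_ref`. With
#' `N_ref` reference chemicals there are `N_ref + 1` attainable scores: 0
#' (below every reference chemical) through 100 (above every reference
#' chemical). Ties with a reference value count as not exceeding it (the
#' conservative choice).
#'
#' @param raw Numeric vector of raw scores to benchmark.
#' @param reference Numeric vector of reference raw scores (any order).
#' @return Percentile scores on `[0, 100]`, same length as `raw`.
#' @export
#' @examples
#' percentile_score(2.5, c(1, 2, 3, 4)) # 50
percentile_score <- function(raw, reference) {
  if (length(reference) == 0L) {
    stop("reference set is empty; cannot benchmark", call. = FALSE)
  }
  if (any(!is.finite(reference))) stop("reference scores must be finite", call. = FALSE)
  ref_sorted <- sort(reference)
  n_ref <- length(ref_sorted)
  below <- findInterval(raw, ref_sorted, left.open = TRUE)
  out <- 100 * below / n_ref
  out[is.na(raw)] <- NA_real_
  out
}

#' Construct a reference set
#'
#' Bundles per-profile sorted raw scores of the benchmark chemicals with a
#' provenance label and the parameterization fingerprint they were computed
#' under. [score_table()] refuses to benchmark a batch against a reference
#' set carrying a different fingerprint.
#'
#' @param raw_scores Data frame with columns `raw_pop`, `raw_vpvb`,
#'   `raw_apc`, `raw_wpc` (one row per reference chemical, all finite, > 0).
#' @param provenance Character label describing the origin of the set.
#' @param fingerprint Parameterization fingerprint
#'   (see [parameter_fingerprint()]), or `NULL` for externally supplied sets
#'   of unknown provenance.
#' @return An object of class `"reference_set"`.
#' @export
reference_set <- function(raw_scores, provenance = "unspecified", fingerprint = NULL) {
  profiles <- c("raw_pop", "raw_vpvb", "raw_apc", "raw_wpc")
  missing_cols <- setdiff(profiles, names(raw_scores))
  if (length(missing_cols) > 0) {
    stop("reference raw scores missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(raw_scores) < 2) stop("reference set needs at least 2 chemicals", call. = FALSE)
  scores <- lapply(raw_scores[profiles], function(v) {
    if (any(!is.finite(v)) || any(v <= 0)) {
      stop("reference raw scores must be finite and > 0", call. = FALSE)
    }
    sort(as.numeric(v))
  })
  names(scores) <- sub("^raw_", "", profiles)
  structure(
    list(
      scores = scores, n = nrow(raw_scores),
      provenance = provenance, fingerprint = fingerprint
    ),
    class = "reference_set"
  )
}

#' @export
print.reference_set <- function(x, ...) {
  cat("Reference set:", x$n, "chemicals (", x$provenance, ")\n")
  if (!is.null(x$fingerprint)) cat("  fingerprint:", x$fingerprint, "\n")
  invisible(x)
}

#' Score a chemical table against a reference set
#'
#' Computes the four raw profile scores row-wise and converts each to a
#' percentile rank against the reference set, appending columns `raw_pop`,
#' `raw_vpvb`, `raw_apc`, `raw_wpc`, `s_pop`, `s_vpvb`, `s_apc`, `s_wpc`.
#'
#' @param records Data frame carrying the metric columns `pov_days`,
#'   `log_baf`, `te_percent`, `ctd_air_km`, `ctd_water_km`.
#' @param reference A `"reference_set"`.
#' @param fingerprint Parameterization fingerprint of the batch; checked
#'   against the reference set's fingerprint when both are non-`NULL`.
#' @return `records` with the eight score columns appended.
#' @export
score_table <- function(records, reference, fingerprint = NULL) {
  stopifnot(inherits(reference, "reference_set"))
  if (!is.null(fingerprint) && !is.null(reference$fingerprint) &&
    !identical(fingerprint, reference$fingerprint)) {
    stop("parameterization fingerprint mismatch between batch (", fingerprint,
      ") and reference set (", reference$fingerprint,
      "); rebuild the reference set with the same environment and fish parameters",
      call. = FALSE
    )
  }
  raw <- raw_hazard_scores(
    records$pov_days, records$log_baf, records$te_percent,
    records$ctd_air_km, records$ctd_water_km
  )
  records$raw_pop <- raw$raw_pop
  records$raw_vpvb <- raw$raw_vpvb
  records$raw_apc <- raw$raw_apc
  records$raw_wpc <- raw$raw_wpc
  records$s_pop <- percentile_score(raw$raw_pop, reference$scores$pop)
  records$s_vpvb <- percentile_score(raw$raw_vpvb, reference$scores$vpvb)
  records$s_apc <- percentile_score(raw$raw_apc, reference$scores$apc)
  records$s_wpc <- percentile_score(raw$raw_wpc, reference$scores$wpc)
  records
}

#' Priority flags and spatial-coverage class
#'
#' Flags chemicals scoring above `hi` (default 90) or below `lo` (default
#' 10) in each profile (strict inequalities) and assigns a
#' spatial-coverage class describing where regulatory attention is most
#' relevant: `near_field` when the vPvB profile exceeds `hi` (national
#' scale), else `far_field` when the POP profile exceeds `hi`
#' (national-to-supranational), else `global` when APC or WPC exceeds `hi`
#' (supranational-to-global), else `none`.
#'
#' @param scores Data frame with columns `s_pop`, `s_vpvb`, `s_apc`, `s_wpc`
#'   on `[0, 100]`.
#' @param hi,lo High and low score thresholds.
#' @return `scores` with logical columns `over90_pop`, `over90_vpvb`,
#'   `over90_apc`, `over90_wpc`, `under10_pop`, `under10_vpvb`,
#'   `under10_apc`, `under10_wpc` and a `spatial_class` factor appended.
#' @export
priority_flags <- function(scores, hi = 90, lo = 10) {
  for (col in c("s_pop", "s_vpvb", "s_apc", "s_wpc")) {
    if (!col %in% names(scores)) stop("missing score column: ", col, call. = FALSE)
  }
  scores$over90_pop <- scores$s_pop > hi
  scores$over90_vpvb <- scores$s_vpvb > hi
  scores$over90_apc <- scores$s_apc > hi
  scores$over90_wpc <- scores$s_wpc > hi
  scores$under10_pop <- scores$s_pop < lo
  scores$under10_vpvb <- scores$s_vpvb < lo
  scores$under10_apc <- scores$s_apc < lo
  scores$under10_wpc <- scores$s_wpc < lo
  scores$spatial_class <- factor(
    ifelse(scores$over90_vpvb, "near_field",
      ifelse(scores$over90_pop, "far_field",
        ifelse(scores$over90_apc | scores$over90_wpc, "global", "none")
      )
    ),
    levels = c("near_field", "far_field", "global", "none")
  )
  scores
}

#' Summaries of the priority flags
#'
#' Counts used to characterize a screen: per-profile high scorers, exclusive
#' high scorers (over the threshold in exactly one profile), chemicals over
#' the threshold in at least one profile, chemicals under the low threshold
#' in every profile, chemicals scoring zero in every profile, and the
#' spatial-coverage combinations (vPvB-high; POP-high but not vPvB-high;
#' APC-high but not POP-high; WPC-high but not POP-high).
#'
#' @param flags Data frame from [priority_flags()].
#' @return A list of named integer counts.
#' @export
priority_summary <- function(flags) {
  over <- cbind(
    pop = flags$over90_pop, vpvb = flags$over90_vpvb,
    apc = flags$over90_apc, wpc = flags$over90_wpc
  )
  under <- cbind(
    pop = flags$under10_pop, vpvb = flags$under10_vpvb,
    apc = flags$under10_apc, wpc = flags$under10_wpc
  )
  n_over_each <- colSums(over, na.rm = TRUE)
  row_over <- rowSums(over)
  exclusive <- vapply(seq_len(ncol(over)), function(j) {
    sum(over[, j] & row_over == 1, na.rm = TRUE)
  }, numeric(1))
  names(exclusive) <- colnames(over)
  zero <- with(flags, s_pop == 0 & s_vpvb == 0 & s_apc == 0 & s_wpc == 0)
  list(
    n = nrow(flags),
    over90_per_profile = as.integer(n_over_each),
    over90_exclusive = as.integer(exclusive),
    over90_any = sum(row_over > 0, na.rm = TRUE),
    under10_all = sum(rowSums(under) == ncol(under), na.rm = TRUE),
    all_zero = sum(zero, na.rm = TRUE),
    spatial_vpvb90 = sum(over[, "vpvb"], na.rm = TRUE),
    spatial_pop90_not_vpvb90 = sum(over[, "pop"] & !over[, "vpvb"], na.rm = TRUE),
    spatial_apc90_not_pop90 = sum(over[, "apc"] & !over[, "pop"], na.rm = TRUE),
    spatial_wpc90_not_pop90 = sum(over[, "wpc"] & !over[, "pop"], na.rm = TRUE)
  )
}

#' Read / write a reference set file
#'
#' The on-disk format is delimited text with columns `chem_id`, `raw_pop`,
#' `raw_vpvb`, `raw_apc`, `raw_wpc`, preceded by comment header lines
#' carrying the provenance and the parameterization fingerprint, e.g.
#' `# fingerprint: hs1-...`.
#'
#' @param x A `"reference_set"` (for writing).
#' @param path File path.
#' @param raw_scores Data frame with `chem_id` and the four raw-score
#'   columns, used when writing.
#' @return `read_reference_set` returns a `"reference_set"`.
#' @export
read_reference_set <- function(path) {
  header <- readLines(path, n = 10L)
  meta <- grep("^#", header, value = TRUE)
  get_meta <- function(key) {
    line <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(line) == 0) {
      return(NULL)
    }
    trimws(sub(paste0("^#\\s*", key, ":"), "", line[1]))
  }
  tbl <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  reference_set(tbl,
    provenance = get_meta("provenance") %||% "file",
    fingerprint = get_meta("fingerprint")
  )
}

#' @rdname read_reference_set
#' @export
write_reference_set <- function(x, raw_scores, path) {
  stopifnot(inherits(x, "reference_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# provenance: ", x$provenance), con)
  if (!is.null(x$fingerprint)) {
    writeLines(paste0("# fingerprint: ", x$fingerprint), con)
  }
  utils::write.csv(
    raw_scores[, c("chem_id", "raw_pop", "raw_vpvb", "raw_apc", "raw_wpc")],
    con,
    row.names = FALSE
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
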