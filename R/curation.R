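#' Remove chemicals likely ionized at environmentally relevant pH
#'
#' Screening-level fate and bioaccumulation estimates for neutral organics
#' are unreliable for substances that are substantially ionized in the
#' environment, so records with `pka < pka_threshold` or
#' `pkb > pkb_threshold` are removed (strict inequalities: a record at
#' exactly the threshold is kept). Records carrying neither constant are
#' kept and flagged `ionization_unknown`.
#'
#' @param records Data frame of chemical records; optional numeric columns
#'   `pka` and `pkb` (`NA` = not available).
#' @param pka_threshold,pkb_threshold Exclusion thresholds (defaults 5 and 8).
#' @return A list with `records` (kept rows, plus a logical
#'   `ionization_unknown` column) and `report` (a `curation_report`).
#' @export
#' @examples
#' tbl <- data.frame(chem_id = c("a", "b", "c"), pka = c(4.2, 5, NA),
#'                   pkb = NA_real_)
#' filter_ionizable(tbl)$report$n_removed_ionizable
filter_ionizable <- function(records, pka_threshold = 5, pkb_threshold = 8) {
  stopifnot(is.finite(pka_threshold), is.finite(pkb_threshold))
  n <- nrow(records)
  pka <- if ("pka" %in% names(records)) records$pka else rep(NA_real_, n)
  pkb <- if ("pkb" %in% names(records)) records$pkb else rep(NA_real_, n)
  ionized <- (!is.na(pka) & pka < pka_threshold) | (!is.na(pkb) & pkb > pkb_threshold)
  kept <- records[!ionized, , drop = FALSE]
  kept$ionization_unknown <- is.na(pka[!ionized]) & is.na(pkb[!ionized])
  report <- curation_report(
    n_input = n,
    n_removed_ionizable = sum(ionized),
    n_clipped_kow = 0L, n_clipped_kaw = 0L,
    n_output = nrow(kept),
    removed_ids = if ("chem_id" %in% names(records)) records$chem_id[ionized] else character(0)
  )
  list(records = kept, report = report)
}

#' Clip partition ratios to the property-estimation model domain
#'
#' Predicted partition ratios outside the range of the measured values that
#' trained the property-estimation models are clamped to the domain
#' boundary: `log_kow` to `[-4, 10]` and `log_kaw` to `[-12, 3]`. The fate
#' model's outputs are insensitive to changes of the partition ratios beyond
#' these bounds, so clipping changes no ranking while keeping inputs inside
#' the models' applicability domain. Non-finite partition ratios invalidate
#' the record (excluded, warned, identifiers reported).
#'
#' @param records Data frame of chemical records with `log_kow`, `log_kaw`.
#' @param kow_range,kaw_range Length-2 numeric clip bounds.
#' @return A list with `records` (clipped, plus logical `kow_clipped` /
#'   `kaw_clipped` columns) and `report` (a `curation_report`; invalid rows
#'   are listed in `removed_ids`).
#' @export
clip_partition_ratios <- function(records, kow_range = c(-4, 10), kaw_range = c(-12, 3)) {
  stopifnot(length(kow_range) == 2L, length(kaw_range) == 2L,
            kow_range[1] < kow_range[2], kaw_range[1] < kaw_range[2])
  n <- nrow(records)
  bad <- !is.finite(records$log_kow) | !is.finite(records$log_kaw)
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-finite partition ratios excluded")
  }
  out <- records[!bad, , drop = FALSE]
  kow_clipped <- out$log_kow < kow_range[1] | out$log_kow > kow_range[2]
  kaw_clipped <- out$log_kaw < kaw_range[1] | out$log_kaw > kaw_range[2]
  out$log_kow <- pmin(pmax(out$log_kow, kow_range[1]), kow_range[2])
  out$log_kaw <- pmin(pmax(out$log_kaw, kaw_range[1]), kaw_range[2])
  out$kow_clipped <- kow_clipped
  out$kaw_clipped <- kaw_clipped
  report <- curation_report(
    n_input = n,
    n_removed_ionizable = 0L,
    n_clipped_kow = sum(kow_clipped),
    n_clipped_kaw = sum(kaw_clipped),
    n_output = nrow(out),
    removed_ids = if ("chem_id" %in% names(records)) records$chem_id[bad] else character(0)
  )
  list(records = out, report = report)
}

#' Full curation step: ionizability filter then domain clipping
#'
#' @inheritParams filter_ionizable
#' @inheritParams clip_partition_ratios
#' @return A list with `records` and a combined `report`.
#' @export
curate_records <- function(records, pka_threshold = 5, pkb_threshold = 8,
                           kow_range = c(-4, 10), kaw_range = c(-12, 3)) {
  f <- filter_ionizable(records, pka_threshold, pkb_threshold)
  cl <- clip_partition_ratios(f$records, kow_range, kaw_range)
  report <- curation_report(
    n_input = f$report$n_input,
    n_removed_ionizable = f$report$n_removed_ionizable,
    n_clipped_kow = cl$report$n_clipped_kow,
    n_clipped_kaw = cl$report$n_clipped_kaw,
    n_output = nrow(cl$records),
    removed_ids = c(f$report$removed_ids, cl$report$removed_ids)
  )
  list(records = cl$records, report = report)
}

curation_report <- function(n_input, n_removed_ionizable, n_clipped_kow,
                            n_clipped_kaw, n_output, removed_ids) {
  stopifnot(n_input >= 0, n_removed_ionizable >= 0, n_output >= 0)
  structure(
    list(
      n_input = as.integer(n_input),
      n_removed_ionizable = as.integer(n_removed_ionizable),
      n_clipped_kow = as.integer(n_clipped_kow),
      n_clipped_kaw = as.integer(n_clipped_kaw),
      n_output = as.integer(n_output),
      removed_ids = removed_ids
    ),
    class = "curation_report"
  )
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report\n")
  cat("  input records:        ", x$n_input, "\n")
  cat("  removed (ionizable):  ", x$n_removed_ionizable, "\n")
  cat("  clipped log Kow:      ", x$n_clipped_kow, "\n")
  cat("  clipped log Kaw:      ", x$n_clipped_kaw, "\n")
  cat("  output records:       ", x$n_output, "\n")
  invisible(x)
}
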