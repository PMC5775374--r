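#' Parse a molecular formula into element counts
#'
#' Tokenizes a Hill-notation molecular formula (element symbols followed by
#' optional multi-digit counts; no charges, isotopes or parenthesized
#' groups). The twelve elements tracked by the composition analytics
#' (C, H, F, Cl, Br, I, N, S, P, O, Si, B) are returned as a named count
#' vector; any other valid element symbols are collected in an `other` map.
#'
#' @param formula A molecular formula string, e.g. `"C7H3Br5"`.
#' @return A list of class `"element_counts"` with `counts` (named integer
#'   vector over the tracked elements) and `other` (named integer vector,
#'   possibly empty).
#' @export
#' @examples
#' parse_formula("CH2Cl2")$counts[c("C", "H", "Cl")]
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
    !nzchar(formula)) {
    stop("formula must be a single non-empty string", call. = FALSE)
  }
  tokens <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  matched <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE))[[1]]
  covered <- sum(attr(tokens, "match.length"))
  if (covered != nchar(formula) || length(matched) == 0) {
    # locate first position not covered by a token
    pos <- rep(FALSE, nchar(formula))
    for (i in seq_along(matched)) {
      s <- tokens[i]
      pos[s:(s + attr(tokens, "match.length")[i] - 1)] <- TRUE
    }
    bad <- which(!pos)[1]
    stop("malformed formula '", formula, "' at position ", bad, call. = FALSE)
  }
  elements <- sub("[0-9]*$", "", matched)
  counts_chr <- sub("^[A-Za-z]+", "", matched)
  counts <- ifelse(nzchar(counts_chr), suppressWarnings(as.integer(counts_chr)), 1L)
  if (any(is.na(counts))) stop("malformed count in formula '", formula, "'", call. = FALSE)

  tracked <- stats::setNames(integer(length(.tracked_elements)), .tracked_elements)
  other <- integer(0)
  for (i in seq_along(elements)) {
    el <- elements[i]
    if (el %in% .tracked_elements) {
      tracked[el] <- tracked[el] + counts[i]
    } else {
      other[el] <- (if (el %in% names(other)) other[[el]] else 0L) + counts[i]
    }
  }
  structure(list(counts = tracked, other = other), class = "element_counts")
}

.tracked_elements <- c("C", "H", "F", "Cl", "Br", "I", "N", "S", "P", "O", "Si", "B")

# standard atomic masses (g/mol), CIAAW abridged values
.atomic_masses <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.95,
  K = 39.098, Ca = 40.078, Ti = 47.867, Cr = 51.996, Mn = 54.938, Fe = 55.845,
  Ni = 58.693, Cu = 63.546, Zn = 65.38, As = 74.922, Se = 78.971, Br = 79.904,
  Sn = 118.71, Sb = 121.76, I = 126.90, Hg = 200.59, Pb = 207.2
)

element_counts_matrix <- function(formulas) {
  n <- length(formulas)
  m <- matrix(NA_integer_, n, length(.tracked_elements),
    dimnames = list(NULL, .tracked_elements)
  )
  mw <- rep(NA_real_, n)
  ok <- rep(FALSE, n)
  for (i in seq_len(n)) {
    f <- formulas[i]
    if (is.na(f) || !nzchar(f)) next
    parsed <- tryCatch(parse_formula(f), error = function(e) NULL)
    if (is.null(parsed)) next
    m[i, ] <- parsed$counts
    all_counts <- c(parsed$counts[parsed$counts > 0], parsed$other)
    masses <- .atomic_masses[names(all_counts)]
    mw[i] <- if (any(is.na(masses))) NA_real_ else sum(masses * all_counts)
    ok[i] <- TRUE
  }
  list(counts = m, mw = mw, parseable = ok)
}

#' Element presence and molecular-weight summary of a chemical table
#'
#' For each tracked element beyond C and H, the percentage and count of
#' parseable structures containing at least one atom of it, plus min / max /
#' median / mean molecular weight (standard atomic masses). Rows without a
#' parseable formula are excluded with a warning.
#'
#' @param records Data frame with a `formula` column.
#' @return A list with `elements` (data frame: `element`, `n_containing`,
#'   `percent`), `molecular_weight` (named numeric), `n_parseable`,
#'   `n_total`.
#' @export
presence_summary <- function(records) {
  formulas <- if ("formula" %in% names(records)) records$formula else rep(NA_character_, nrow(records))
  ec <- element_counts_matrix(formulas)
  n_bad <- sum(!ec$parseable)
  if (n_bad > 0 && nrow(records) > 0) {
    warning(n_bad, " record(s) without parseable formula excluded from composition summary")
  }
  counts <- ec$counts[ec$parseable, , drop = FALSE]
  n <- nrow(counts)
  elements <- setdiff(.tracked_elements, c("C", "H"))
  containing <- vapply(elements, function(el) sum(counts[, el] > 0), numeric(1))
  mw <- ec$mw[ec$parseable]
  mw <- mw[!is.na(mw)]
  list(
    elements = data.frame(
      element = elements,
      n_containing = as.integer(containing),
      percent = if (n > 0) 100 * containing / n else rep(0, length(elements)),
      row.names = NULL
    ),
    molecular_weight = c(
      min = if (length(mw)) min(mw) else NA_real_,
      max = if (length(mw)) max(mw) else NA_real_,
      median = if (length(mw)) stats::median(mw) else NA_real_,
      mean = if (length(mw)) mean(mw) else NA_real_
    ),
    n_parseable = n,
    n_total = nrow(records)
  )
}

#' Frequency distribution of per-structure atom counts for one element
#'
#' Restricted to parseable structures containing at least one atom of the
#' element; the histogram total therefore equals the containing-structure
#' count of [presence_summary()].
#'
#' @param records Data frame with a `formula` column.
#' @param element One of the tracked element symbols.
#' @return A data frame with integer columns `atoms` and `n_structures`.
#' @export
atom_count_histogram <- function(records, element) {
  if (!element %in% .tracked_elements) {
    stop("unknown element symbol: ", element, call. = FALSE)
  }
  ec <- element_counts_matrix(records$formula)
  counts <- ec$counts[ec$parseable, element]
  counts <- counts[counts > 0]
  if (length(counts) == 0) {
    return(data.frame(atoms = integer(0), n_structures = integer(0)))
  }
  tab <- table(counts)
  data.frame(
    atoms = as.integer(names(tab)),
    n_structures = as.integer(tab),
    row.names = NULL
  )
}

#' Mean atoms-per-structure of an element across hazard-score bins
#'
#' Bins structures by their percentile score for one profile (default 10
#' equal-width bins over `[0, 100]`) and reports the mean atom count of the
#' element per bin, averaging over all structures in the bin including those
#' containing none of the element. Empty bins are reported as `NA`.
#'
#' @param records Data frame with a `formula` column.
#' @param scores Numeric vector of percentile scores on `[0, 100]`, one per
#'   record.
#' @param element A tracked element symbol.
#' @param n_bins Number of equal-width score bins (>= 2).
#' @return A data frame with `bin_lo`, `bin_hi`, `n_structures`,
#'   `mean_atoms`.
#' @export
element_score_association <- function(records, scores, element, n_bins = 10) {
  if (!element %in% .tracked_elements) {
    stop("unknown element symbol: ", element, call. = FALSE)
  }
  stopifnot(n_bins >= 2, length(scores) == nrow(records))
  if (any(!is.na(scores) & (scores < 0 | scores > 100))) {
    stop("scores must lie on [0, 100]", call. = FALSE)
  }
  ec <- element_counts_matrix(records$formula)
  keep <- ec$parseable & !is.na(scores)
  atom <- ec$counts[keep, element]
  sc <- scores[keep]
  breaks <- seq(0, 100, length.out = n_bins + 1)
  bin <- findInterval(sc, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  n_in <- tabulate(bin, nbins = n_bins)
  mean_atoms <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    if (n_in[b] > 0) mean_atoms[b] <- mean(atom[bin == b])
  }
  data.frame(
    bin_lo = breaks[-length(breaks)],
    bin_hi = breaks[-1],
    n_structures = n_in,
    mean_atoms = mean_atoms
  )
}
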