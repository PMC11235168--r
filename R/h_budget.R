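#' Carbon-bound hydrogen atoms of glucose or an unbranched n-alkane
#'
#' Glucose carries seven carbon-bound hydrogen atoms (the ones the
#' nonexchangeable-delta methods see); an unbranched saturated n-alkane of
#' `n` carbons carries `2n + 2`.
#'
#' @param compound `"glucose"`, a chain label such as `"C29"`, or a numeric
#'   alkane chain length (>= 1).
#' @return Integer count of carbon-bound hydrogen atoms.
#' @examples
#' carbon_bound_h_count("glucose")  # 7
#' carbon_bound_h_count("C29")      # 60
#' @export
carbon_bound_h_count <- function(compound) {
  if (is.numeric(compound)) {
    n <- compound
  } else if (identical(tolower(compound), "glucose")) {
    return(7L)
  } else if (grepl("^[Cc][0-9]+$", compound)) {
    n <- as.integer(sub("^[Cc]", "", compound))
  } else {
    stop(sprintf("unsupported compound '%s': expected 'glucose', 'C<n>' or a chain length",
                 compound), call. = FALSE)
  }
  if (length(n) != 1 || !is.finite(n) || n < 1 || n != round(n)) {
    stop("alkane chain length must be a positive integer", call. = FALSE)
  }
  as.integer(2 * n + 2)
}

#' Biochemical hydrogen-source partition of a compound
#'
#' Accounting of where a compound's carbon-bound hydrogen comes from:
#' NADPH, water (direct incorporation), or carbon precursors (triose
#' phosphate / photorespiratory products for glucose; acetyl-CoA for
#' alkanes). For glucose the partition is exact integer counts, 1 : 3 : 3
#' of its 7 hydrogens. For n-alkanes the class-level percentages
#' (47 / 24 / 29, established for the C29 chain) are stored as given
#' fractions, since 47% of 60 atoms is not an integer count.
#'
#' @param compound `"glucose"` or a chain label such as `"C29"`.
#' @return List of class `h_source_partition` with elements `compound`,
#'   `total_H` and `fractions` (named numeric: `NADPH`, `water`,
#'   `precursor`, summing to 1 within 0.01).
#' @export
h_source_partition <- function(compound) {
  if (identical(tolower(compound), "glucose")) {
    part <- list(compound = "glucose", total_H = 7L,
                 fractions = c(NADPH = 1 / 7, water = 3 / 7, precursor = 3 / 7))
  } else {
    total <- carbon_bound_h_count(compound)
    part <- list(compound = toupper(compound), total_H = total,
                 fractions = c(NADPH = 0.47, water = 0.24, precursor = 0.29))
  }
  class(part) <- "h_source_partition"
  part
}

#' @export
print.h_source_partition <- function(x, ...) {
  cat(sprintf("%s: %d carbon-bound H atoms\n", x$compound, x$total_H))
  pct <- source_percentages(x)
  for (s in names(pct)) cat(sprintf("  %-9s %3d%%\n", s, pct[[s]]))
  invisible(x)
}

# round half away from zero (matching how the printed whole-percent
# partitions are obtained; base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Whole-percent hydrogen source shares
#'
#' Converts a partition's fractions to whole-number percentages, rounding
#' halves away from zero. The glucose default (1:3:3 over 7 atoms) yields
#' 14 / 43 / 43; the alkane class partition yields 47 / 24 / 29.
#'
#' @param p An [h_source_partition()] object.
#' @return Named integer vector of percentages (NADPH, water, precursor).
#' @export
source_percentages <- function(p) {
  stopifnot(inherits(p, "h_source_partition"))
  fr <- p$fractions
  if (abs(sum(fr) - 1) > 0.01) {
    stop("partition fractions must sum to 1 within 0.01", call. = FALSE)
  }
  out <- vapply(fr * 100, round_half_away, numeric(1))
  storage.mode(out) <- "integer"
  out
}

#' Isotope mass balance over a hydrogen-source partition
#'
#' Predicts a compound's delta-2H as the partition-weighted mean of its
#' hydrogen sources, each shifted by a source-specific fractionation:
#' `sum(fraction_s * (delta_s + eps_s))`. A linear mixing model for
#' scenario exploration, not a fitted quantity.
#'
#' @param p An [h_source_partition()] object.
#' @param source_deltas Named numeric, delta-2H of each source (per mil);
#'   must cover `NADPH`, `water`, `precursor`.
#' @param source_eps Named numeric, fractionation applied to each source
#'   (per mil); same names. Defaults to zero for all sources.
#' @return Mixed delta-2H (per mil).
#' @examples
#' mix_delta(h_source_partition("glucose"),
#'           c(NADPH = -300, water = -50, precursor = -100))
#' @export
mix_delta <- function(p, source_deltas,
                      source_eps = c(NADPH = 0, water = 0, precursor = 0)) {
  stopifnot(inherits(p, "h_source_partition"))
  need <- names(p$fractions)
  for (arg in list(source_deltas, source_eps)) {
    miss <- setdiff(need, names(arg))
    if (length(miss) > 0) {
      stop("missing source(s): ", paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  sum(p$fractions[need] * (source_deltas[need] + source_eps[need]))
}
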