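#' Default constants of the dual water-vapor equilibration method
#'
#' The equilibration reduction uses two water vapors of known isotopic
#' composition and an equilibrium fractionation factor between exchangeable
#' compound hydrogen and water. The defaults are the method's standard
#' operating values: vapors at -160 and -428 per mil VSMOW and
#' `alpha_ew = 1.082` (determined for cellulose and taken as representative
#' for the other carbohydrate classes).
#'
#' @return Named list with `delta_w1`, `delta_w2` (per mil VSMOW) and
#'   `alpha_ew` (dimensionless).
#' @export
equilibration_defaults <- function() {
  list(delta_w1 = -160, delta_w2 = -428, alpha_ew = 1.082)
}

# shared sanity checks for delta values: finite and above the physical
# lower bound of the delta scale (-1000 per mil = no heavy isotope at all)
check_delta <- function(x, name) {
  if (!is.numeric(x)) {
    stop(sprintf("`%s` must be numeric", name), call. = FALSE)
  }
  bad <- !is.finite(x) | x <= -1000
  if (any(bad)) {
    stop(sprintf("`%s` must be finite and > -1000 per mil (offending index %d)",
                 name, which(bad)[1]), call. = FALSE)
  }
  invisible(x)
}

#' Fraction of hydrogen exchanged during dual equilibration
#'
#' Computes the exchangeable-hydrogen fraction `x_e` of a carbohydrate sample
#' from its two equilibrated delta-2H values and the two equilibration water
#' vapors:
#'
#' \deqn{x_e = \frac{\delta_{e1} - \delta_{e2}}
#'                  {\alpha_{e-w} (\delta_{w1} - \delta_{w2})}}
#'
#' The value is deliberately not clamped to \[0, 1\]: out-of-range values are
#' diagnostic of measurement problems and are flagged downstream by
#' [process_equilibration_batch()] rather than hidden.
#'
#' @param delta_e1,delta_e2 Equilibrated delta-2H of the sample after
#'   equilibration with water vapor 1 and 2 (per mil VSMOW).
#' @param delta_w1,delta_w2 delta-2H of the two equilibration water vapors
#'   (per mil VSMOW). Must differ.
#' @param alpha_ew Equilibrium fractionation factor between exchangeable
#'   compound hydrogen and water (dimensionless, > 0).
#' @return Numeric vector of exchange fractions (dimensionless).
#' @examples
#' compute_exchange_fraction(-83.892, -185.3836)  # 0.35
#' compute_exchange_fraction(-100, -100)          # 0: no exchangeable H
#' @export
compute_exchange_fraction <- function(delta_e1, delta_e2,
                                      delta_w1 = -160, delta_w2 = -428,
                                      alpha_ew = 1.082) {
  check_delta(delta_e1, "delta_e1")
  check_delta(delta_e2, "delta_e2")
  check_delta(delta_w1, "delta_w1")
  check_delta(delta_w2, "delta_w2")
  if (any(!is.finite(alpha_ew) | alpha_ew <= 0)) {
    stop("`alpha_ew` must be finite and > 0", call. = FALSE)
  }
  if (any(delta_w1 == delta_w2)) {
    stop("degenerate water pair: `delta_w1` and `delta_w2` must differ",
         call. = FALSE)
  }
  (delta_e1 - delta_e2) / (alpha_ew * (delta_w1 - delta_w2))
}

#' Nonexchangeable delta-2H from one equilibration
#'
#' Removes the exchanged-hydrogen signal from a single equilibrated
#' measurement, given the exchange fraction `x_e`:
#'
#' \deqn{\delta_{ne} = \frac{\delta_e - x_e \alpha_{e-w} \delta_w
#'        - 1000\, x_e (\alpha_{e-w} - 1)}{1 - x_e}}
#'
#' The formula is implemented exactly in delta notation, including the
#' `1000 (alpha - 1)` term. By construction the result is identical whether
#' pair 1 `(delta_e1, delta_w1)` or pair 2 `(delta_e2, delta_w2)` is used,
#' when `x_e` comes from [compute_exchange_fraction()] on the same pair.
#'
#' @param delta_e Equilibrated delta-2H of the sample (per mil VSMOW).
#' @param x_e Exchange fraction (dimensionless, must not equal 1).
#' @param delta_w delta-2H of the equilibration water used (per mil VSMOW).
#' @param alpha_ew Equilibrium fractionation factor (dimensionless).
#' @return Nonexchangeable delta-2H (per mil VSMOW).
#' @examples
#' compute_delta_ne(-83.892, 0.35, -160)  # -80
#' @export
compute_delta_ne <- function(delta_e, x_e, delta_w, alpha_ew = 1.082) {
  check_delta(delta_e, "delta_e")
  check_delta(delta_w, "delta_w")
  if (any(x_e == 1)) {
    stop("`x_e` = 1: all hydrogen exchangeable, nonexchangeable delta undefined",
         call. = FALSE)
  }
  (delta_e - x_e * alpha_ew * delta_w - 1000 * x_e * (alpha_ew - 1)) / (1 - x_e)
}

#' Forward model of one water-vapor equilibration
#'
#' The algebraic inverse of [compute_delta_ne()]: predicts the equilibrated
#' delta-2H a sample with nonexchangeable composition `delta_ne` and exchange
#' fraction `x_e` would show after equilibration with water `delta_w`. Used
#' by the synthetic-data generator and by round-trip tests.
#'
#' @param delta_ne True nonexchangeable delta-2H (per mil VSMOW).
#' @param x_e Exchange fraction in \[0, 1\].
#' @param delta_w delta-2H of the equilibration water (per mil VSMOW).
#' @param alpha_ew Equilibrium fractionation factor (dimensionless).
#' @return Equilibrated delta-2H (per mil VSMOW).
#' @examples
#' forward_equilibrate(-80, 0.35, -160)  # -83.892
#' @export
forward_equilibrate <- function(delta_ne, x_e, delta_w, alpha_ew = 1.082) {
  check_delta(delta_ne, "delta_ne")
  check_delta(delta_w, "delta_w")
  if (any(x_e < 0 | x_e > 1)) {
    stop("`x_e` must lie in [0, 1] for the forward model", call. = FALSE)
  }
  (1 - x_e) * delta_ne + x_e * alpha_ew * delta_w + 1000 * x_e * (alpha_ew - 1)
}

#' Additive offset correction against a drift standard
#'
#' Shifts all raw deltas by the difference between the known and the measured
#' value of a reference material with no exchangeable hydrogen (IAEA-CH-7
#' polyethylene foil in the standard protocol), correcting instrumental
#' offset while preserving all differences between samples.
#'
#' @param raw_deltas Numeric vector of raw delta-2H values (per mil).
#' @param standard_measured Measured delta-2H of the standard (per mil).
#' @param standard_known Accepted delta-2H of the standard (per mil).
#' @return Offset-corrected deltas (per mil).
#' @export
offset_correct <- function(raw_deltas, standard_measured, standard_known) {
  check_delta(raw_deltas, "raw_deltas")
  check_delta(standard_measured, "standard_measured")
  check_delta(standard_known, "standard_known")
  raw_deltas + (standard_known - standard_measured)
}

#' Two-point (or least-squares) calibration to the VSMOW scale
#'
#' Maps nonexchangeable delta-2H values to the international VSMOW scale via
#' an affine fit of known against measured values of calibration standards
#' (in-house sucrose and cellulose standards in the reference protocol).
#' With exactly two standards this is the classical two-point line; with
#' more, an ordinary least-squares fit.
#'
#' @param delta_ne_values Numeric vector of values to calibrate (per mil).
#' @param standards Data frame with columns `measured_delta` and
#'   `known_delta` (per mil); at least two rows with distinct
#'   `measured_delta`.
#' @return Calibrated deltas (per mil VSMOW).
#' @examples
#' std <- data.frame(measured_delta = c(-90, -45), known_delta = c(-80, -40))
#' calibrate_to_vsmow(-70, std)  # -62.22
#' @export
calibrate_to_vsmow <- function(delta_ne_values, standards) {
  stopifnot(is.data.frame(standards),
            all(c("measured_delta", "known_delta") %in% names(standards)))
  if (nrow(standards) < 2) {
    stop("need at least two calibration standards", call. = FALSE)
  }
  if (length(unique(standards$measured_delta)) < 2) {
    stop("calibration standards must have distinct measured values",
         call. = FALSE)
  }
  check_delta(delta_ne_values, "delta_ne_values")
  fit <- stats::lm(known_delta ~ measured_delta, data = standards)
  unname(stats::coef(fit)[1] + stats::coef(fit)[2] * delta_ne_values)
}

#' Reduce a batch of dual-equilibration measurements
#'
#' Runs the full reduction in the protocol's order: optional offset
#' correction of the raw equilibrated deltas, exchange-fraction computation,
#' nonexchangeable delta from pair 1, and optional VSMOW scaling. Records
#' that violate their invariants are reported in the `error` column and do
#' not abort the batch; quality flags mark out-of-range exchange fractions
#' (`X_E_OUT_OF_RANGE`) and pairs whose two reductions disagree
#' (`PAIR_INCONSISTENT`, numerically impossible for internally computed
#' `x_e` and hence a corruption guard).
#'
#' @param measurements Data frame with columns `sample_id`, `delta_e1`,
#'   `delta_e2` and optionally `delta_w1`, `delta_w2`, `alpha_ew` (defaults
#'   from [equilibration_defaults()]).
#' @param offset_standard Optional list/row with `measured_delta` and
#'   `known_delta` of a non-exchangeable drift standard (PEF); `NULL` skips
#'   offset correction.
#' @param vsmow_standards Optional data frame for [calibrate_to_vsmow()];
#'   `NULL` skips scaling.
#' @param pair_tolerance Numerical tolerance (per mil) above which the
#'   pair-1 versus pair-2 reductions are flagged inconsistent.
#' @return Tibble with one row per input record: `sample_id`, `x_e`,
#'   `delta_ne`, `pair_residual`, `qc_flags` (";"-separated, `""` if clean)
#'   and `error` (`NA` if the record processed).
#' @export
process_equilibration_batch <- function(measurements,
                                        offset_standard = NULL,
                                        vsmow_standards = NULL,
                                        pair_tolerance = 1e-6) {
  stopifnot(is.data.frame(measurements),
            all(c("sample_id", "delta_e1", "delta_e2") %in% names(measurements)))
  defs <- equilibration_defaults()
  m <- tibble::as_tibble(measurements)
  for (col in c("delta_w1", "delta_w2", "alpha_ew")) {
    if (is.null(m[[col]])) m[[col]] <- defs[[col]]
  }

  one <- function(row) {
    tryCatch({
      e1 <- row$delta_e1
      e2 <- row$delta_e2
      if (!is.null(offset_standard)) {
        shift_src <- offset_correct(c(e1, e2),
                                    offset_standard$measured_delta,
                                    offset_standard$known_delta)
        e1 <- shift_src[1]
        e2 <- shift_src[2]
      }
      x_e <- compute_exchange_fraction(e1, e2, row$delta_w1, row$delta_w2,
                                       row$alpha_ew)
      ne1 <- compute_delta_ne(e1, x_e, row$delta_w1, row$alpha_ew)
      ne2 <- compute_delta_ne(e2, x_e, row$delta_w2, row$alpha_ew)
      resid <- abs(ne1 - ne2)
      flags <- character(0)
      if (x_e < 0 || x_e > 1) flags <- c(flags, "X_E_OUT_OF_RANGE")
      if (resid > pair_tolerance) flags <- c(flags, "PAIR_INCONSISTENT")
      tibble::tibble(sample_id = row$sample_id, x_e = x_e, delta_ne = ne1,
                     pair_residual = resid,
                     qc_flags = paste(flags, collapse = ";"),
                     error = NA_character_)
    }, error = function(e) {
      tibble::tibble(sample_id = row$sample_id, x_e = NA_real_,
                     delta_ne = NA_real_, pair_residual = NA_real_,
                     qc_flags = "", error = conditionMessage(e))
    })
  }

  out <- dplyr::bind_rows(lapply(seq_len(nrow(m)), function(i) one(m[i, ])))
  if (!is.null(vsmow_standards)) {
    ok <- !is.na(out$delta_ne)
    out$delta_ne[ok] <- calibrate_to_vsmow(out$delta_ne[ok], vsmow_standards)
  }
  out
}
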