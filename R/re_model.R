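#' Parameters of the two-pool cellulose isotope model
#'
#' Bundle of the Roden-Ehleringer model constants: the theoretical
#' autotrophic fractionation `eps_a_star` (-171 per mil), the theoretical
#' heterotrophic fractionation `eps_h_star` (+158 per mil), and the fraction
#' `f` of cellulose hydrogen that exchanged with source water during
#' synthesis (0.36). The defaults are the model's literature constants.
#'
#' @param eps_a_star Autotrophic fractionation (per mil).
#' @param eps_h_star Heterotrophic fractionation (per mil).
#' @param f Exchange fraction (dimensionless; values outside \[0, 1\] are
#'   permitted for inversion studies).
#' @return Named list of class `re_params`.
#' @export
re_params <- function(eps_a_star = -171, eps_h_star = 158, f = 0.36) {
  stopifnot(is.finite(eps_a_star), is.finite(eps_h_star), is.finite(f))
  structure(list(eps_a_star = eps_a_star, eps_h_star = eps_h_star, f = f),
            class = "re_params")
}

#' @export
print.re_params <- function(x, ...) {
  cat(sprintf(
    "Two-pool cellulose model parameters: eps_a* = %g, eps_h* = %g, f = %g\n",
    x$eps_a_star, x$eps_h_star, x$f))
  invisible(x)
}

#' Forward two-pool cellulose model
#'
#' Predicts cellulose delta-2H as a mixture of two hydrogen pools:
#' assimilates carrying the leaf-water signal plus autotrophic
#' fractionation, and hydrogen exchanged with source water plus
#' heterotrophic fractionation:
#'
#' \deqn{\delta_{cell} = (1 - f)(\delta_{leaf} + \epsilon_a^*) +
#'                        f(\delta_{source} + \epsilon_h^*)}
#'
#' @param leaf_water delta-2H of leaf water (per mil VSMOW).
#' @param source_water delta-2H of source water, approximated by root or
#'   soil water (per mil VSMOW).
#' @param params An [re_params()] object.
#' @return Modeled cellulose delta-2H (per mil VSMOW).
#' @examples
#' re_forward(-50, -79.3)  # -113.108 with default constants
#' @export
re_forward <- function(leaf_water, source_water, params = re_params()) {
  check_delta(leaf_water, "leaf_water")
  check_delta(source_water, "source_water")
  (1 - params$f) * (leaf_water + params$eps_a_star) +
    params$f * (source_water + params$eps_h_star)
}

#' Observed-minus-modeled cellulose residual
#'
#' Sign convention: observations above the model prediction give positive
#' residuals.
#'
#' @param observed,modeled delta-2H values (per mil VSMOW).
#' @return Residual (per mil).
#' @export
re_residual <- function(observed, modeled) {
  check_delta(observed, "observed")
  check_delta(modeled, "modeled")
  observed - modeled
}

#' Invert the two-pool model for the exchange fraction f
#'
#' Rearranges the forward model for `f` given an observed cellulose value
#' and a choice of autotrophic fractionation (the theoretical constant or a
#' measured, "dynamic" value):
#'
#' \deqn{f = \frac{\delta_{obs} - (\delta_{leaf} + \epsilon_a)}
#'                 {(\delta_{source} + \epsilon_h^*) -
#'                  (\delta_{leaf} + \epsilon_a)}}
#'
#' Values outside \[0, 1\] are physically out of range but are returned
#' unclamped with an `out_of_range` attribute: negative apparent `f` is a
#' real, interpretable outcome of dynamic-fractionation inversions.
#'
#' @param observed_cellulose Observed cellulose delta-2H (per mil VSMOW).
#' @param leaf_water,source_water Water delta-2H values (per mil VSMOW).
#' @param eps_a_used Autotrophic fractionation applied (per mil); the
#'   constant -171 or a measured sugar/starch epsilon_a.
#' @param eps_h_star Heterotrophic fractionation (per mil).
#' @return Numeric vector of `f` values with logical attribute
#'   `out_of_range` marking entries outside \[0, 1\].
#' @examples
#' invert_f(-100, -50, -79.3)  # 0.4037...
#' @export
invert_f <- function(observed_cellulose, leaf_water, source_water,
                     eps_a_used = -171, eps_h_star = 158) {
  check_delta(observed_cellulose, "observed_cellulose")
  check_delta(leaf_water, "leaf_water")
  check_delta(source_water, "source_water")
  denom <- (source_water + eps_h_star) - (leaf_water + eps_a_used)
  if (any(denom == 0)) {
    stop("degenerate inversion: the two pool end-members coincide",
         call. = FALSE)
  }
  f <- (observed_cellulose - (leaf_water + eps_a_used)) / denom
  attr(f, "out_of_range") <- f < 0 | f > 1
  f
}

#' Invert the two-pool model for the heterotrophic fractionation
#'
#' Rearranges the forward model for `eps_h_star` at a given exchange
#' fraction `f`:
#'
#' \deqn{\epsilon_h^* = \frac{\delta_{obs} -
#'        (1 - f)(\delta_{leaf} + \epsilon_a)}{f} - \delta_{source}}
#'
#' Small `f` amplifies the inferred fractionation; `f = 0` is a singularity
#' (no exchanged pool to attribute the fractionation to).
#'
#' @inheritParams invert_f
#' @param f Exchange fraction (must be nonzero).
#' @return Inferred heterotrophic fractionation (per mil).
#' @export
invert_eps_h <- function(observed_cellulose, leaf_water, source_water,
                         f, eps_a_used = -171) {
  check_delta(observed_cellulose, "observed_cellulose")
  check_delta(leaf_water, "leaf_water")
  check_delta(source_water, "source_water")
  if (any(f == 0)) {
    stop("`f` = 0: heterotrophic fractionation is unidentifiable",
         call. = FALSE)
  }
  (observed_cellulose - (1 - f) * (leaf_water + eps_a_used)) / f - source_water
}

#' Shift in modeled cellulose when soil water replaces root water
#'
#' Both root and soil water are proxies for source water; cryogenic
#' extraction can deplete root water relative to soil water, so the choice
#' matters. Because the model is affine, the swap shifts every prediction
#' by exactly `f * (soil - root)`, which this function returns.
#'
#' @param leaf_water,root_water,soil_water delta-2H values (per mil VSMOW).
#' @param params An [re_params()] object.
#' @return Signed prediction shift, soil-based minus root-based (per mil).
#' @export
source_sensitivity <- function(leaf_water, root_water, soil_water,
                               params = re_params()) {
  re_forward(leaf_water, soil_water, params) -
    re_forward(leaf_water, root_water, params)
}

# treatment x replicate wide table of the waters and cellulose needed by the
# model, from a long per-sample record table
re_inputs <- function(records, source = c("root", "soil")) {
  source <- match.arg(source)
  check_samples(records)
  rec <- tibble::as_tibble(records)
  pick <- function(cmp, tis, nm) {
    d <- rec[rec$compound == cmp & rec$tissue == tis,
             c("treatment", "replicate", "delta2H")]
    names(d)[3] <- nm
    d
  }
  wide <- pick("cellulose", "leaf", "cellulose")
  wide <- dplyr::inner_join(wide, pick("water", "leaf", "leaf_water"),
                            by = c("treatment", "replicate"))
  src <- if (source == "root") pick("water", "root", "source_water")
         else pick("water", "soil", "source_water")
  if (nrow(src) == 0) {
    stop(sprintf("no %s-water records available as source water", source),
         call. = FALSE)
  }
  if (source == "soil" && length(unique(src$replicate)) == 1) {
    # a single soil profile per treatment is shared across replicates
    wide$source_water <- src$source_water[match(wide$treatment, src$treatment)]
    wide
  } else {
    dplyr::inner_join(wide, src, by = c("treatment", "replicate"))
  }
}

#' Model predictions and residuals for a sample set
#'
#' Builds the per-sample model input table (observed leaf cellulose, leaf
#' water and the chosen source water, matched by treatment and replicate),
#' runs the forward model and returns observations, predictions and
#' residuals.
#'
#' @param records Per-sample table (schema of [tissue_offset()]).
#' @param params An [re_params()] object.
#' @param source Which water to use as source water: `"root"` (default)
#'   or `"soil"`.
#' @return Tibble with `treatment`, `replicate`, `observed`, `modeled`,
#'   `residual`, `source_water_used`.
#' @export
re_predict_table <- function(records, params = re_params(),
                             source = c("root", "soil")) {
  source <- match.arg(source)
  w <- re_inputs(records, source)
  modeled <- re_forward(w$leaf_water, w$source_water, params)
  tibble::tibble(treatment = w$treatment, replicate = w$replicate,
                 observed = w$cellulose, modeled = modeled,
                 residual = re_residual(w$cellulose, modeled),
                 source_water_used = source)
}

#' Per-treatment single-parameter inversions of the two-pool model
#'
#' For each treatment, inverts the model once for `f` (holding
#' `eps_h_star` fixed) and once for `eps_h_star` (holding `f` fixed), using
#' treatment-mean inputs by default or per-replicate inputs on request. The
#' autotrophic fractionation can be the theoretical constant or the
#' measured, treatment-specific epsilon_a of sugars or starch ("dynamic"
#' mode), which is computed from the same record table.
#'
#' @param records Per-sample table (schema of [tissue_offset()]).
#' @param eps_a_mode `"constant"` (use `params$eps_a_star`), `"sugars"` or
#'   `"starch"` (use the measured leaf epsilon_a of that carbohydrate,
#'   averaged per treatment).
#' @param params An [re_params()] object supplying the held-fixed values.
#' @param source Source water: `"root"` or `"soil"`.
#' @param by `"treatment"` (default; treatment-mean inputs) or
#'   `"replicate"`.
#' @return Tibble with `treatment` (and `replicate` if `by = "replicate"`),
#'   `eps_a_used`, `f_hat`, `f_out_of_range`, `eps_h_star_hat`.
#' @export
re_inversion_table <- function(records,
                               eps_a_mode = c("constant", "sugars", "starch"),
                               params = re_params(),
                               source = c("root", "soil"),
                               by = c("treatment", "replicate")) {
  eps_a_mode <- match.arg(eps_a_mode)
  source <- match.arg(source)
  by <- match.arg(by)
  w <- re_inputs(records, source)

  if (eps_a_mode == "constant") {
    w$eps_a_used <- params$eps_a_star
  } else {
    rec <- tibble::as_tibble(records)
    cmp <- rec[rec$compound == eps_a_mode & rec$tissue == "leaf", ]
    lw <- rec[rec$compound == "water" & rec$tissue == "leaf", ]
    if (nrow(cmp) == 0) {
      stop(sprintf("no leaf %s records for dynamic epsilon_a", eps_a_mode),
           call. = FALSE)
    }
    ea <- dplyr::inner_join(cmp[, c("treatment", "replicate", "delta2H")],
                            lw[, c("treatment", "replicate", "delta2H")],
                            by = c("treatment", "replicate"),
                            suffix = c("_cmp", "_lw"))
    ea <- dplyr::summarise(
      dplyr::group_by(ea, .data$treatment),
      eps_a_used = mean(epsilon_a(.data$delta2H_cmp, .data$delta2H_lw)),
      .groups = "drop")
    w <- dplyr::inner_join(w, ea, by = "treatment")
  }

  if (by == "treatment") {
    w <- dplyr::summarise(
      dplyr::group_by(w, .data$treatment),
      cellulose = mean(.data$cellulose),
      leaf_water = mean(.data$leaf_water),
      source_water = mean(.data$source_water),
      eps_a_used = mean(.data$eps_a_used),
      .groups = "drop")
  }

  f_hat <- invert_f(w$cellulose, w$leaf_water, w$source_water,
                    eps_a_used = w$eps_a_used,
                    eps_h_star = params$eps_h_star)
  eh_hat <- invert_eps_h(w$cellulose, w$leaf_water, w$source_water,
                         f = params$f, eps_a_used = w$eps_a_used)
  out <- tibble::tibble(treatment = w$treatment,
                        eps_a_used = w$eps_a_used,
                        f_hat = as.numeric(f_hat),
                        f_out_of_range = attr(f_hat, "out_of_range"),
                        eps_h_star_hat = eh_hat)
  if (by == "replicate") out <- tibble::add_column(out,
                                                   replicate = w$replicate,
                                                   .after = "treatment")
  out
}
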