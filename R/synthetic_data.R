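#' Configuration of the synthetic experiment generator
#'
#' Collects every knob of the synthetic-data generators in one validated
#' list. The defaults encode the study conditions the generators emulate: a
#' nitrogen-fertilization gradient (nitrate/ammonium ratios 100/0 down to
#' 0/100, five replicates, leaf and root tissue) and a wild-type versus
#' starch-deficient (*pgm*) genotype contrast, with the experiments'
#' reported effect sizes as the generator's truth.
#'
#' @param treatments Ordered nitrate percentages of the fertilization
#'   gradient.
#' @param n_replicates Plants per treatment.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param irrigation_water delta-2H of irrigation (source) water, per mil.
#' @param vapor_water delta-2H of chamber water vapor, per mil (recorded
#'   for completeness; the simplified leaf-water model does not mix it in).
#' @param leaf_root_water_offset Evaporative leaf-over-root water
#'   enrichment, per mil.
#' @param root_soil_water_depletion Apparent root-below-soil water
#'   depletion introduced by cryogenic extraction, per mil.
#' @param root_minus_leaf_offsets Named per-compound root-minus-leaf
#'   delta-2H offsets, per mil.
#' @param base_eps_a Named per-compound autotrophic fractionation under
#'   nitrate-dominated conditions, per mil (the lower end of each
#'   compound's treatment range).
#' @param alkane_eps_a Autotrophic fractionation of leaf n-alkanes, per
#'   mil; flat across treatments.
#' @param treatment_breakpoint Nitrate percentage below which compound
#'   delta-2H starts rising (the gradient's turning point).
#' @param treatment_amplitudes Named per-compound maximum leaf delta-2H
#'   range along the gradient, per mil.
#' @param noise_sd Measurement noise standard deviation, per mil;
#'   independent Gaussian per record.
#' @param pgm_offsets Named per-compound *pgm*-minus-wild-type offsets, per
#'   mil (alkane 0: no genotype effect).
#' @param wt_baseline Named per-compound wild-type leaf delta-2H, per mil.
#' @param missingness If `TRUE`, cellulose and alkane records are truncated
#'   to three replicates under the two most ammonium-dominated treatments,
#'   mirroring limited sample availability there.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(treatments = c(100, 90, 75, 50, 25, 10, 0),
                             n_replicates = 5,
                             seed = 42,
                             irrigation_water = -79.3,
                             vapor_water = -140.0,
                             leaf_root_water_offset = 29.6,
                             root_soil_water_depletion = 6.7,
                             root_minus_leaf_offsets = c(sugars = 17.3,
                                                         starch = 104.5,
                                                         cellulose = 12.3),
                             base_eps_a = c(sugars = -161.8,
                                            starch = -203.8,
                                            cellulose = -73.5),
                             alkane_eps_a = -128.8,
                             treatment_breakpoint = 25,
                             treatment_amplitudes = c(sugars = 128.8,
                                                      starch = 77.6,
                                                      cellulose = 35.4),
                             noise_sd = 3,
                             pgm_offsets = c(starch = 152.7, sugars = 75.0,
                                             cellulose = 38.7, alkane = 0),
                             wt_baseline = c(sugars = -150, starch = -210,
                                             cellulose = -85, alkane = -140),
                             missingness = TRUE) {
  stopifnot(n_replicates >= 1, noise_sd >= 0,
            all(treatment_amplitudes >= 0),
            length(seed) == 1, is.finite(seed))
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  cfg
}

alkane_chains <- c("alkane_C27", "alkane_C29", "alkane_C31", "alkane_C33")

# flat-then-rising treatment effect: zero while nitrate dominates, rising
# linearly below the breakpoint so the full amplitude is reached at 0% nitrate
treatment_effect <- function(no3_percent, breakpoint, amplitude) {
  amplitude * pmax(0, (breakpoint - no3_percent) / breakpoint)
}

new_record <- function(compound, tissue, treatment, replicate, delta2H) {
  tibble::tibble(
    sample_id = paste(compound, tissue, treatment, replicate, sep = "_"),
    compound = compound, tissue = tissue, treatment = treatment,
    replicate = as.integer(replicate), delta2H = delta2H)
}

#' Generate a synthetic nitrogen-fertilization experiment
#'
#' Produces one per-sample record table with the structure of the
#' fertilization-gradient experiment: soil, root and leaf water; leaf and
#' root sugars, starch and cellulose; and leaf n-alkanes (C27 to C33).
#' Soil water sits at the irrigation value, root water below it by the
#' extraction artifact, leaf water above root water by the evaporative
#' offset. Leaf carbohydrates are leaf water plus a compound-specific
#' autotrophic fractionation plus a flat-then-rising treatment effect with
#' its break at the configured turning point; root carbohydrates add the
#' configured tissue offsets; alkanes track leaf water at a constant
#' fractionation. Independent Gaussian noise is added per record.
#'
#' At `noise_sd = 0` every configured offset is recovered exactly by the
#' fractionation summaries, which is the generator's defining round-trip
#' property.
#'
#' @param config A [synthetic_config()].
#' @return Tibble of per-sample records (`sample_id`, `compound`, `tissue`,
#'   `treatment`, `replicate`, `delta2H`).
#' @export
generate_n_experiment <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    recs <- list()
    for (tr in config$treatments) {
      soil_w <- config$irrigation_water
      root_w <- soil_w - config$root_soil_water_depletion
      leaf_w <- root_w + config$leaf_root_water_offset
      reps <- seq_len(config$n_replicates)

      recs[[length(recs) + 1]] <- new_record("water", "soil", tr, reps, soil_w)
      recs[[length(recs) + 1]] <- new_record("water", "root", tr, reps, root_w)
      recs[[length(recs) + 1]] <- new_record("water", "leaf", tr, reps, leaf_w)

      for (cmp in c("sugars", "starch", "cellulose")) {
        eff <- treatment_effect(tr, config$treatment_breakpoint,
                                config$treatment_amplitudes[[cmp]])
        leaf_val <- leaf_w + config$base_eps_a[[cmp]] + eff
        cmp_reps <- reps
        if (cmp == "cellulose" && config$missingness &&
            tr %in% utils::tail(config$treatments, 2)) {
          cmp_reps <- reps[reps <= 3]
        }
        recs[[length(recs) + 1]] <- new_record(cmp, "leaf", tr, cmp_reps,
                                               leaf_val)
        recs[[length(recs) + 1]] <- new_record(
          cmp, "root", tr, cmp_reps,
          leaf_val + config$root_minus_leaf_offsets[[cmp]])
      }

      alk_reps <- reps
      if (config$missingness && tr %in% utils::tail(config$treatments, 2)) {
        alk_reps <- reps[reps <= 3]
      }
      for (chain in alkane_chains) {
        recs[[length(recs) + 1]] <- new_record(chain, "leaf", tr, alk_reps,
                                               leaf_w + config$alkane_eps_a)
      }
    }
    out <- dplyr::bind_rows(recs)
    out$delta2H <- out$delta2H + stats::rnorm(nrow(out), 0, config$noise_sd)
    out
  })
}

#' Generate a synthetic wild-type versus pgm experiment
#'
#' Leaf-only records for two genotypes, `"WT"` and `"pgm"`: wild-type
#' compounds at their configured baselines, the starch-deficient mutant
#' shifted by the configured per-compound enrichments (largest for starch,
#' none for alkanes). Gaussian noise as in [generate_n_experiment()].
#'
#' @param config A [synthetic_config()].
#' @return Tibble of per-sample records; `treatment` holds the genotype.
#' @export
generate_pgm_experiment <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    recs <- list()
    reps <- seq_len(config$n_replicates)
    for (gt in c("WT", "pgm")) {
      for (cmp in c("sugars", "starch", "cellulose")) {
        val <- config$wt_baseline[[cmp]] +
          (gt == "pgm") * config$pgm_offsets[[cmp]]
        recs[[length(recs) + 1]] <- new_record(cmp, "leaf", gt, reps, val)
      }
      alk_val <- config$wt_baseline[["alkane"]] +
        (gt == "pgm") * config$pgm_offsets[["alkane"]]
      for (chain in alkane_chains) {
        recs[[length(recs) + 1]] <- new_record(chain, "leaf", gt, reps,
                                               alk_val)
      }
    }
    out <- dplyr::bind_rows(recs)
    out$delta2H <- out$delta2H + stats::rnorm(nrow(out), 0, config$noise_sd)
    out
  })
}

#' Simulate raw dual-equilibration measurements
#'
#' Forward-models the dual water-vapor equilibration for samples of known
#' nonexchangeable composition and exchange fraction, adding independent
#' Gaussian noise to each equilibrated value. The output feeds
#' [process_equilibration_batch()], whose reduction must recover the truth
#' exactly at zero noise.
#'
#' @param true_delta_ne Numeric vector of true nonexchangeable delta-2H
#'   values (per mil VSMOW).
#' @param true_x_e Numeric vector of true exchange fractions in \[0, 1\];
#'   recycled against `true_delta_ne` if scalar.
#' @param config A [synthetic_config()] (supplies `noise_sd` and `seed`).
#' @param delta_w1,delta_w2,alpha_ew Equilibration constants.
#' @return Tibble of measurements: `sample_id`, `delta_e1`, `delta_e2`,
#'   `delta_w1`, `delta_w2`, `alpha_ew`.
#' @export
generate_equilibration_raw <- function(true_delta_ne, true_x_e,
                                       config = synthetic_config(),
                                       delta_w1 = -160, delta_w2 = -428,
                                       alpha_ew = 1.082) {
  stopifnot(inherits(config, "synthetic_config"))
  if (length(true_x_e) == 1) true_x_e <- rep(true_x_e, length(true_delta_ne))
  stopifnot(length(true_delta_ne) == length(true_x_e),
            all(true_x_e >= 0 & true_x_e <= 1))
  withr::with_seed(config$seed, {
    n <- length(true_delta_ne)
    e1 <- forward_equilibrate(true_delta_ne, true_x_e, delta_w1, alpha_ew) +
      stats::rnorm(n, 0, config$noise_sd)
    e2 <- forward_equilibrate(true_delta_ne, true_x_e, delta_w2, alpha_ew) +
      stats::rnorm(n, 0, config$noise_sd)
    tibble::tibble(sample_id = sprintf("sim%04d", seq_len(n)),
                   delta_e1 = e1, delta_e2 = e2,
                   delta_w1 = delta_w1, delta_w2 = delta_w2,
                   alpha_ew = alpha_ew)
  })
}

#' Simulate observations for inversion of the two-pool cellulose model
#'
#' Generates cellulose observations from the forward two-pool model at a
#' known exchange fraction, plus Gaussian observation noise, paired with
#' their leaf and source waters — a testbed for [invert_f()] and
#' [invert_eps_h()] parameter recovery.
#'
#' @param true_f True exchange fraction (may lie outside \[0, 1\]).
#' @param eps_a,eps_h_star Fractionation factors used in generation (per
#'   mil).
#' @param leaf_water,source_water Water delta-2H values (per mil VSMOW).
#' @param noise_sd Observation noise standard deviation (per mil).
#' @param n Number of observations.
#' @param seed Integer seed.
#' @return Tibble with `sample_id`, `leaf_water`, `source_water`,
#'   `observed`.
#' @export
generate_re_scenario <- function(true_f, eps_a = -171, eps_h_star = 158,
                                 leaf_water = -50, source_water = -79.3,
                                 noise_sd = 3, n = 100, seed = 42) {
  stopifnot(n >= 1)
  params <- re_params(eps_a_star = eps_a, eps_h_star = eps_h_star, f = true_f)
  withr::with_seed(seed, {
    lw <- rep_len(leaf_water, n)
    sw <- rep_len(source_water, n)
    obs <- re_forward(lw, sw, params) + stats::rnorm(n, 0, noise_sd)
    tibble::tibble(sample_id = sprintf("re%04d", seq_len(n)),
                   leaf_water = lw, source_water = sw, observed = obs)
  })
}
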