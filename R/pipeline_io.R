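valid_compounds <- c("water", "sugars", "starch", "cellulose",
                     "alkane_C27", "alkane_C29", "alkane_C31", "alkane_C33",
                     "bulk")
valid_tissues <- c("leaf", "root", "soil")

#' Read and validate a per-sample record table
#'
#' Reads `samples.csv` (columns `sample_id`, `compound`, `tissue`,
#' `treatment`, `replicate`, `delta2H`) and enforces the record invariants:
#' known compounds and tissues, finite delta-2H above the physical -1000
#' per mil bound, and uniqueness of (compound, tissue, treatment,
#' replicate). Violations are reported with row numbers.
#'
#' @param path CSV file path, or a data frame to validate in place.
#' @return Validated tibble of sample records.
#' @export
read_samples <- function(path) {
  rec <- if (is.data.frame(path)) tibble::as_tibble(path)
         else readr::read_csv(path, show_col_types = FALSE)
  check_samples(rec)
  bad_cmp <- which(!rec$compound %in% valid_compounds)
  if (length(bad_cmp) > 0) {
    stop(sprintf("unknown compound '%s' (row %d)",
                 rec$compound[bad_cmp[1]], bad_cmp[1]), call. = FALSE)
  }
  bad_tis <- which(!rec$tissue %in% valid_tissues)
  if (length(bad_tis) > 0) {
    stop(sprintf("unknown tissue '%s' (row %d)",
                 rec$tissue[bad_tis[1]], bad_tis[1]), call. = FALSE)
  }
  bad_d <- which(!is.finite(rec$delta2H) | rec$delta2H <= -1000)
  if (length(bad_d) > 0) {
    stop(sprintf("delta2H out of physical range (row %d: %s)",
                 bad_d[1], rec$delta2H[bad_d[1]]), call. = FALSE)
  }
  key <- paste(rec$compound, rec$tissue, rec$treatment, rec$replicate,
               sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate record key (compound|tissue|treatment|replicate): ",
         key[which(duplicated(key))[1]], call. = FALSE)
  }
  rec
}

#' Read a raw dual-equilibration measurement table
#'
#' @param path CSV path or data frame with at least `sample_id`,
#'   `delta_e1`, `delta_e2`; optional `delta_w1`, `delta_w2`, `alpha_ew`.
#' @return Tibble of measurements.
#' @export
read_equilibration <- function(path) {
  m <- if (is.data.frame(path)) tibble::as_tibble(path)
       else readr::read_csv(path, show_col_types = FALSE)
  need <- c("sample_id", "delta_e1", "delta_e2")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0) {
    stop("equilibration table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  m
}

#' Pipeline configuration
#'
#' Assembles stage inputs and analysis settings for [run_pipeline()]. All
#' constants default to the standard values used throughout the package
#' (two-pool model constants, equilibration waters and alpha).
#'
#' @param samples Sample table: a CSV path, a data frame, or `NULL` when
#'   `simulate` is set.
#' @param simulate `NULL`, `"n-gradient"` or `"pgm"`: generate the sample
#'   table with the synthetic module instead of reading it.
#' @param equilibration Optional raw equilibration CSV path or data frame;
#'   when given, the reduction stage runs and writes `delta_ne.csv`.
#' @param offset_standard,vsmow_standards Passed to
#'   [process_equilibration_batch()].
#' @param params An [re_params()] object.
#' @param eps_a_mode,source_water Passed to the model stage (see
#'   [re_inversion_table()]).
#' @param synthetic A [synthetic_config()] used when `simulate` is set.
#' @param out_dir Output directory for stage CSVs and the JSON report;
#'   `NULL` disables writing.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(samples = NULL, simulate = NULL,
                            equilibration = NULL, offset_standard = NULL,
                            vsmow_standards = NULL, params = re_params(),
                            eps_a_mode = "constant",
                            source_water = "root",
                            synthetic = synthetic_config(),
                            out_dir = NULL) {
  if (is.null(samples) && is.null(simulate)) {
    stop("either `samples` or `simulate` must be given", call. = FALSE)
  }
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

write_stage <- function(tab, out_dir, name) {
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(tab, file.path(out_dir, name))
  }
  invisible(tab)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in their methodological order — equilibration
#' reduction (if raw measurements are supplied), fractionation tables, and
#' the two-pool cellulose model with its per-treatment inversions — and
#' returns a run report with per-stage record counts, quality-flag tallies
#' and treatment-level summaries. Stage outputs and a JSON report are
#' written to `config$out_dir` when set. A failing stage halts downstream
#' stages; the report is still produced and records the failure.
#'
#' @param config A [pipeline_config()].
#' @return List of class `hydrofrac_report`: `stages` (status and counts),
#'   `tables` (the computed tibbles), `summaries` (treatment means),
#'   `config_echo`, `version`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- list()
  tables <- list()
  halted <- FALSE

  run_stage <- function(name, fn) {
    if (halted) {
      stages[[name]] <<- list(status = "skipped", n = 0L)
      return(NULL)
    }
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      stages[[name]] <<- list(status = "failed", n = 0L,
                              message = conditionMessage(res))
      halted <<- TRUE
      NULL
    } else {
      stages[[name]] <<- list(status = "ok",
                              n = if (is.data.frame(res)) nrow(res) else 0L)
      res
    }
  }

  samples <- run_stage("input", function() {
    if (!is.null(config$simulate)) {
      switch(config$simulate,
             "n-gradient" = generate_n_experiment(config$synthetic),
             "pgm" = generate_pgm_experiment(config$synthetic),
             stop("unknown simulate mode: ", config$simulate))
    } else {
      read_samples(config$samples)
    }
  })
  if (!is.null(samples)) {
    tables$samples <- write_stage(samples, config$out_dir, "samples.csv")
  }

  if (!is.null(config$equilibration)) {
    eq <- run_stage("equilibration", function() {
      process_equilibration_batch(read_equilibration(config$equilibration),
                                  offset_standard = config$offset_standard,
                                  vsmow_standards = config$vsmow_standards)
    })
    if (!is.null(eq)) {
      tables$delta_ne <- write_stage(eq, config$out_dir, "delta_ne.csv")
    }
  }

  frac <- run_stage("fractionation", function() fractionation_table(samples))
  if (!is.null(frac)) {
    tables$epsilon_a <- write_stage(frac[frac$kind == "epsilon_a", ],
                                    config$out_dir, "epsilon_a.csv")
    tables$epsilon_h <- write_stage(frac[frac$kind == "epsilon_h", ],
                                    config$out_dir, "epsilon_h.csv")
  }

  has_model_inputs <- !is.null(samples) &&
    all(c("cellulose", "water") %in% samples$compound) &&
    any(samples$tissue == config$source_water | samples$tissue == "root")
  if (has_model_inputs) {
    pred <- run_stage("re_model", function() {
      re_predict_table(samples, params = config$params,
                       source = config$source_water)
    })
    if (!is.null(pred)) {
      tables$re_predictions <- write_stage(pred, config$out_dir,
                                           "re_predictions.csv")
    }
    inv <- run_stage("re_inversion", function() {
      re_inversion_table(samples, eps_a_mode = config$eps_a_mode,
                         params = config$params,
                         source = config$source_water)
    })
    if (!is.null(inv)) {
      tables$re_inversion <- write_stage(inv, config$out_dir,
                                         "re_inversion.csv")
    }
  }

  summaries <- list()
  if (!is.null(samples)) {
    summaries$delta2H <- dplyr::summarise(
      dplyr::group_by(samples, .data$compound, .data$tissue, .data$treatment),
      mean_delta2H = mean(.data$delta2H), n = dplyr::n(), .groups = "drop")
  }
  if (!is.null(frac) && nrow(frac) > 0) {
    summaries$fractionation <- dplyr::summarise(
      dplyr::group_by(frac, .data$kind, .data$compound_a, .data$compound_b,
                      .data$context, .data$treatment),
      mean_value = mean(.data$value), n = dplyr::n(), .groups = "drop")
  }

  report <- structure(list(
    stages = stages,
    tables = tables,
    summaries = summaries,
    config_echo = list(simulate = config$simulate,
                       eps_a_mode = config$eps_a_mode,
                       source_water = config$source_water,
                       seed = config$synthetic$seed,
                       params = unclass(config$params)),
    version = as.character(utils::packageVersion("hydrofrac"))),
    class = "hydrofrac_report")

  if (!is.null(config$out_dir)) {
    json <- list(stages = stages, config = report$config_echo,
                 version = report$version)
    jsonlite::write_json(json, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  report
}

#' @export
print.hydrofrac_report <- function(x, ...) {
  cat("hydrofrac pipeline run (version", x$version, ")\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-14s %-8s %s\n", nm, st$status,
                if (st$status == "ok") paste(st$n, "records")
                else st$message %||% ""))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
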