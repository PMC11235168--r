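#' Apparent autotrophic hydrogen isotope fractionation
#'
#' The apparent autotrophic fractionation factor of a leaf compound is the
#' delta-2H difference between the compound and leaf water,
#' `epsilon_a = delta_compound - delta_leaf_water`. It normalizes compound
#' delta-2H for leaf-water isotope variation so treatments can be compared.
#' Implemented as the plain difference (the conventional definition for
#' these factors); see [epsilon_ratio()] for the ratio-based alternative.
#'
#' @param delta_compound delta-2H of the leaf compound (per mil VSMOW).
#' @param delta_leaf_water delta-2H of leaf water (per mil VSMOW).
#' @return epsilon_a (per mil).
#' @export
epsilon_a <- function(delta_compound, delta_leaf_water) {
  check_delta(delta_compound, "delta_compound")
  check_delta(delta_leaf_water, "delta_leaf_water")
  delta_compound - delta_leaf_water
}

#' Apparent heterotrophic hydrogen isotope fractionation
#'
#' The delta-2H difference between two carbohydrates (within or between
#' tissues), `epsilon_h = delta_a - delta_b`. Antisymmetric in its
#' arguments and additive along chains of contrasts:
#' `epsilon_h(C, St) = epsilon_h(C, S) + epsilon_h(S, St)`.
#'
#' @param delta_a,delta_b delta-2H of the two carbohydrates (per mil VSMOW).
#' @return epsilon_h (per mil).
#' @export
epsilon_h <- function(delta_a, delta_b) {
  check_delta(delta_a, "delta_a")
  check_delta(delta_b, "delta_b")
  delta_a - delta_b
}

#' Ratio-based isotope fractionation between two pools
#'
#' The exact (ratio-space) counterpart of the difference-based
#' [epsilon_a()] / [epsilon_h()]:
#' `1000 * ((1000 + delta_a) / (1000 + delta_b) - 1)`. Provided as a
#' separate optional output; the difference form is the one used throughout
#' the pipeline.
#'
#' @inheritParams epsilon_h
#' @return Ratio-based epsilon (per mil).
#' @export
epsilon_ratio <- function(delta_a, delta_b) {
  check_delta(delta_a, "delta_a")
  check_delta(delta_b, "delta_b")
  1000 * ((1000 + delta_a) / (1000 + delta_b) - 1)
}

#' Abundance-weighted mean n-alkane delta-2H
#'
#' Combines compound-specific delta-2H values of the odd-chain n-alkanes
#' (C27 to C33) into one proportion-normalized value: abundances are
#' renormalized to sum exactly to one, then the weighted mean
#' `sum(abundance * delta)` is returned. Abundance sums outside
#' \[0.98, 1.02\] before renormalization are rejected as a data error.
#'
#' @param profile Data frame with columns `abundance` (fractions, >= 0) and
#'   `delta2H` (per mil VSMOW); typically one row per chain length.
#' @return Weighted mean delta-2H (per mil VSMOW).
#' @examples
#' weighted_alkane_mean(data.frame(abundance = c(0.1, 0.4, 0.4, 0.1),
#'                                 delta2H = c(-160, -150, -140, -130)))
#' @export
weighted_alkane_mean <- function(profile) {
  stopifnot(is.data.frame(profile),
            all(c("abundance", "delta2H") %in% names(profile)))
  ab <- profile$abundance
  if (any(ab < 0)) stop("negative alkane abundance", call. = FALSE)
  s <- sum(ab)
  if (s < 0.98 || s > 1.02) {
    stop(sprintf("alkane abundances sum to %.4f, outside [0.98, 1.02]", s),
         call. = FALSE)
  }
  check_delta(profile$delta2H, "delta2H")
  sum(ab / s * profile$delta2H)
}

# canonical column check for a per-sample record table
check_samples <- function(records) {
  need <- c("compound", "tissue", "treatment", "replicate", "delta2H")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("sample table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(records)
}

#' Mean delta-2H offset between two tissues for one compound
#'
#' Pairs replicates by index within each treatment, averages the
#' `tissue_a - tissue_b` differences per treatment, and returns the mean of
#' the treatment means (treatments weighted equally, matching how
#' treatment-level summaries are reported even when replicate counts are
#' unbalanced).
#'
#' @param records Per-sample table with columns `compound`, `tissue`,
#'   `treatment`, `replicate`, `delta2H`.
#' @param compound Compound to summarize (e.g. `"water"`, `"sugars"`).
#' @param tissue_a,tissue_b The two tissues; the offset is a minus b.
#' @return Mean offset (per mil), with attribute `by_treatment`, a tibble of
#'   per-treatment means and paired-replicate counts.
#' @export
tissue_offset <- function(records, compound, tissue_a, tissue_b) {
  check_samples(records)
  sub <- records[records$compound == compound &
                   records$tissue %in% c(tissue_a, tissue_b), , drop = FALSE]
  for (tis in c(tissue_a, tissue_b)) {
    if (!any(sub$tissue == tis)) {
      stop(sprintf("no records for compound '%s' in tissue '%s'",
                   compound, tis), call. = FALSE)
    }
  }
  by_tr <- lapply(split(sub, sub$treatment), function(d) {
    a <- d[d$tissue == tissue_a, ]
    b <- d[d$tissue == tissue_b, ]
    a <- a[order(a$replicate), ]
    b <- b[order(b$replicate), ]
    n <- min(nrow(a), nrow(b))
    if (n == 0) return(NULL)
    tibble::tibble(treatment = d$treatment[1],
                   mean_offset = mean(a$delta2H[seq_len(n)] -
                                        b$delta2H[seq_len(n)]),
                   n_pairs = n)
  })
  tab <- dplyr::bind_rows(by_tr)
  if (nrow(tab) == 0) {
    stop(sprintf("no treatment with both tissues for compound '%s'", compound),
         call. = FALSE)
  }
  out <- mean(tab$mean_offset)
  attr(out, "by_treatment") <- tab
  out
}

# the named heterotrophic contrasts: cellulose-sugars, cellulose-starch,
# starch-sugars, each within leaves (L), within roots (R), and root vs leaf (R-L)
eps_h_contrasts <- function() {
  tibble::tibble(
    compound_a = rep(c("cellulose", "cellulose", "starch"), times = 3),
    compound_b = rep(c("sugars", "starch", "sugars"), times = 3),
    tissue_a   = rep(c("leaf", "root", "root"), each = 3),
    tissue_b   = rep(c("leaf", "root", "leaf"), each = 3),
    context    = rep(c("L", "R", "R-L"), each = 3)
  )
}

#' Table of apparent fractionation factors for a sample set
#'
#' Evaluates the autotrophic factor (compound minus leaf water) for every
#' leaf compound other than water, and the heterotrophic factor for the
#' named carbohydrate contrasts (cellulose-sugars, cellulose-starch,
#' starch-sugars) within leaves, within roots, and between roots and leaves.
#' One row is produced per contrast, treatment and paired replicate; missing
#' compounds simply yield no rows.
#'
#' @param records Per-sample table (see [tissue_offset()] for the schema).
#' @return Tibble with columns `kind` (`"epsilon_a"` or `"epsilon_h"`),
#'   `compound_a`, `compound_b`, `tissue_a`, `tissue_b`, `context`,
#'   `treatment`, `replicate`, `value` (per mil).
#' @export
fractionation_table <- function(records) {
  check_samples(records)
  rec <- tibble::as_tibble(records)

  pair_up <- function(a, b) {
    # replicate-index pairing within treatment
    k <- intersect(a$replicate, b$replicate)
    if (length(k) == 0) return(NULL)
    a <- a[match(k, a$replicate), ]
    b <- b[match(k, b$replicate), ]
    list(a = a, b = b, replicate = k)
  }

  out <- list()

  lw <- rec[rec$compound == "water" & rec$tissue == "leaf", ]
  leaf_cmp <- rec[rec$tissue == "leaf" & rec$compound != "water", ]
  if (nrow(lw) > 0 && nrow(leaf_cmp) > 0) {
    for (cmp in unique(leaf_cmp$compound)) {
      for (tr in unique(leaf_cmp$treatment[leaf_cmp$compound == cmp])) {
        a <- leaf_cmp[leaf_cmp$compound == cmp & leaf_cmp$treatment == tr, ]
        b <- lw[lw$treatment == tr, ]
        p <- pair_up(a, b)
        if (is.null(p)) next
        out[[length(out) + 1]] <- tibble::tibble(
          kind = "epsilon_a", compound_a = cmp, compound_b = "water",
          tissue_a = "leaf", tissue_b = "leaf", context = "L",
          treatment = tr, replicate = p$replicate,
          value = epsilon_a(p$a$delta2H, p$b$delta2H))
      }
    }
  }

  cons <- eps_h_contrasts()
  for (i in seq_len(nrow(cons))) {
    cn <- cons[i, ]
    a_all <- rec[rec$compound == cn$compound_a & rec$tissue == cn$tissue_a, ]
    b_all <- rec[rec$compound == cn$compound_b & rec$tissue == cn$tissue_b, ]
    if (nrow(a_all) == 0 || nrow(b_all) == 0) next
    for (tr in intersect(unique(a_all$treatment), unique(b_all$treatment))) {
      p <- pair_up(a_all[a_all$treatment == tr, ],
                   b_all[b_all$treatment == tr, ])
      if (is.null(p)) next
      out[[length(out) + 1]] <- tibble::tibble(
        kind = "epsilon_h", compound_a = cn$compound_a,
        compound_b = cn$compound_b, tissue_a = cn$tissue_a,
        tissue_b = cn$tissue_b, context = cn$context,
        treatment = tr, replicate = p$replicate,
        value = epsilon_h(p$a$delta2H, p$b$delta2H))
    }
  }

  if (length(out) == 0) {
    return(tibble::tibble(kind = character(), compound_a = character(),
                          compound_b = character(), tissue_a = character(),
                          tissue_b = character(), context = character(),
                          treatment = character(), replicate = integer(),
                          value = numeric()))
  }
  dplyr::bind_rows(out)
}
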