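# End-to-end drivers. These are the programmatic entry points the analysis
# scripts, tests and acceptance script call; each returns every table it
# writes, so results are inspectable without touching disk.

#' Run the cohort analysis pipeline
#'
#' Eligibility filtering -> patient-level classification -> binned medians ->
#' AIC knot-count selection and spline fit (linear and restricted cubic) ->
#' per-measurement uACR-threshold ROC table -> patient-level discriminator
#' table with paired AUC comparisons -> subgroup cutoffs -> distribution
#' cross-tab -> delta regressions. When `out_dir` is given, every table is
#' written as CSV plus a JSON summary carrying the run configuration.
#'
#' @param cohort Per-visit tibble (from [read_cohort_csv()] or
#'   [generate_cohort()]).
#' @param knot_candidates Candidate knot counts for AIC selection.
#' @param uacr_thresholds Thresholds for the per-measurement table.
#' @param subgroup_axes Axes for [subgroup_cutoffs()].
#' @param bin_max_g Upper uPCR bound (g/gCr) of bins entering the log-log
#'   fit (bins with label 0 are always excluded: ln 0 is undefined).
#' @param out_dir Optional output directory for the report bundle.
#' @return List of results (see Details in the vignette).
#' @export
run_cohort_pipeline <- function(cohort,
                                knot_candidates = c(3, 4, 5),
                                uacr_thresholds = c(seq(10, 150, 10), 300),
                                subgroup_axes = c("age", "sex", "gfr"),
                                bin_max_g = 0.50,
                                out_dir = NULL) {
  elig <- apply_eligibility(cohort)
  kept <- elig$kept
  patients <- build_discriminators(summarise_patients(kept))
  records <- dplyr::semi_join(kept, patients, by = "patient_id")
  records$gfr_category <- patients$gfr_category[
    match(records$patient_id, patients$patient_id)]

  bins <- bin_summaries(records$upcr, records$uacr)
  fit_bins <- bins[bins$upcr_g > 0 & bins$upcr_g <= bin_max_g, ]
  x <- log(fit_bins$upcr_g * 1000)   # ln uPCR, mg/gCr
  y <- log(fit_bins$median_uacr)
  raw_mg <- records$upcr[records$upcr > 0] * 1000
  sel <- select_knot_count(x, y, raw_mg, kind = "linear",
                           candidates = knot_candidates)
  spline_fit <- sel$fits[[paste0("k", sel$best_k)]]
  rcs_fit <- fit_restricted_cubic_spline(
    x, y, standard_knots(raw_mg, sel$best_k))
  slope_changes <- slope_change_tests(spline_fit)

  threshold_table <- uacr_threshold_table(records, uacr_thresholds)
  discrimination <- microalbuminuria_discrimination(patients)
  subgroups <- dplyr::bind_rows(lapply(subgroup_axes, function(ax)
    subgroup_cutoffs(patients, ax)))
  crosstab <- distribution_crosstab(records)
  deltas <- delta_regression(patients, on_insufficient = "skip")

  out <- list(
    excluded = elig$excluded,
    patients = patients,
    records = records,
    bins = bins,
    knot_selection = sel$aic_table,
    best_k = sel$best_k,
    spline = spline_fit,
    spline_rcs = rcs_fit,
    slope_changes = slope_changes,
    threshold_table = threshold_table,
    discrimination = discrimination$table,
    discrimination_pairwise = discrimination$pairwise,
    subgroups = subgroups,
    crosstab = crosstab,
    deltas = deltas
  )
  if (!is.null(out_dir)) {
    .write_cohort_reports(out, out_dir, knot_candidates, uacr_thresholds,
                          subgroup_axes, bin_max_g)
  }
  out
}

.write_cohort_reports <- function(res, out_dir, knot_candidates,
                                  uacr_thresholds, subgroup_axes, bin_max_g) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(
    as.data.frame(df), file.path(out_dir, name), row.names = FALSE)
  w(res$excluded, "exclusions.csv")
  w(res$bins, "binned_medians.csv")
  w(res$spline$segments, "spline_segments.csv")
  w(res$slope_changes, "slope_changes.csv")
  w(res$threshold_table, "uacr_threshold_table.csv")
  w(res$discrimination, "discriminators.csv")
  w(res$discrimination_pairwise, "discriminators_pairwise.csv")
  w(res$subgroups, "subgroups.csv")
  w(res$crosstab, "crosstab.csv")
  w(res$deltas, "delta_regression.csv")
  summary <- list(
    config = list(knot_candidates = knot_candidates,
                  uacr_thresholds = uacr_thresholds,
                  subgroup_axes = subgroup_axes, bin_max_g = bin_max_g),
    n_patients = nrow(res$patients),
    n_excluded = nrow(res$excluded),
    best_k = res$best_k,
    knots_mg = res$spline$knots_mg,
    aic = res$spline$aic,
    adj_r2 = res$spline$adj_r2,
    segments = res$spline$segments
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Run the stability-substudy pipeline
#'
#' Stratified agreement tables for every analyte and occasion pair
#' (intraday pairs 1-2 and 3-4; interday pairs 1-3, 1-4, 2-3, 2-4) plus the
#' per-occasion Youden cutoffs.
#'
#' @param samples Long stability tibble (from [read_stability_csv()] or
#'   [generate_stability_study()]).
#' @param out_dir Optional output directory.
#' @return List with `agreement` (tibble over analytes, pairs, strata) and
#'   `cutoffs` (see [stability_cutoffs()]).
#' @export
run_stability_pipeline <- function(samples, out_dir = NULL) {
  wide <- stability_wide(samples)
  pairs <- list(c(1, 2), c(3, 4), c(1, 3), c(1, 4), c(2, 3), c(2, 4))
  analytes <- c("up", "ualb", "ucr", "upcr", "uacr")
  agreement <- dplyr::bind_rows(lapply(analytes, function(an)
    dplyr::bind_rows(lapply(pairs, function(pr)
      stability_agreement_table(wide, an, pr)))))
  cutoffs <- stability_cutoffs(wide)
  out <- list(wide = wide, agreement = agreement, cutoffs = cutoffs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(agreement),
                     file.path(out_dir, "stability_agreement.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(cutoffs$per_occasion),
                     file.path(out_dir, "stability_cutoffs.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(cutoffs$mean_of_four),
                     file.path(out_dir, "stability_cutoffs_mean4.csv"),
                     row.names = FALSE)
  }
  out
}
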