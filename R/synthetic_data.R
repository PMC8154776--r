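# Seeded generators for (a) cohorts with the joint uPCR-uACR structure the
# analysis assumes and (b) stability-substudy samples with condition- and
# concentration-dependent measurement error. The generators' defaults are
# the study conditions: cohort sizes, GFR mix, diabetes split and visit
# intervals follow the published cohort description; the uPCR distribution
# is lognormal with percentiles 5/35/65/95 at 20/60/120/350 mg/gCr (the
# published knot locations); the median uACR|uPCR curve is the published
# piecewise log-linear calibration per stratum.

# deterministic per-unit seed derived from the run seed, kept below 2^31
.unit_seed <- function(seed, i) {
  (as.double(seed %% 100000L) * 19373L + as.double(i) * 7919L) %% 2147483647
}

#' Ground-truth configuration for the synthetic cohort generator
#'
#' All scale parameters act on the natural-log scale unless noted.
#'
#' @param n_non_diabetic,n_diabetic Patients per stratum.
#' @param visits Urine measurements per patient.
#' @param ln_upcr_mean,ln_upcr_sd_between,ln_upcr_sd_within Population mean
#'   and between/within-patient sds of ln uPCR (mg/gCr).
#' @param uacr_sd_patient,uacr_sd_visit Split of the ln uACR residual about
#'   the median curve into a patient effect and visit noise (total sd
#'   sqrt(0.45^2 + 0.40^2) ~ 0.6).
#' @param ln_ucr_mean,ln_ucr_sd Lognormal urinary creatinine concentration
#'   (mg/dl).
#' @param detection_limit_up,detection_limit_ualb Assay detection limits
#'   (mg/dl protein, mg/l albumin); concentrations below are censored to 0.
#' @param visit_gap_means,visit_gap_sd Mean day gaps between visits 1-2 and
#'   2-3 and their sd (normal, truncated at 14 days).
#' @param gfr_mix_non_diabetic,gfr_mix_diabetic Named G1..G4 mixing
#'   proportions (normalised internally).
#' @param male_fraction_non_diabetic,male_fraction_diabetic Sex mix.
#' @param age_mean_non_diabetic,age_sd_non_diabetic,age_mean_diabetic,age_sd_diabetic
#'   Age distributions, truncated to 18-100 years.
#' @param curve_non_diabetic,curve_diabetic `uacr_spline` models used as the
#'   median uACR|uPCR truth per stratum (defaults: the bundled published
#'   calibrations).
#' @param egfr_visit_cv Within-patient coefficient of variation of eGFR
#'   across visits.
#' @param assay_digits Decimal places at which concentrations are reported
#'   (default 1, the assay reporting precision; raise it to study the
#'   generator's noiseless limit without quantisation).
#' @return A validated list of class `cohort_truth`.
#' @export
cohort_truth <- function(n_non_diabetic = 197, n_diabetic = 106,
                         visits = 3,
                         ln_upcr_mean = 4.44,
                         ln_upcr_sd_between = 0.70,
                         ln_upcr_sd_within = 0.55,
                         uacr_sd_patient = 0.45,
                         uacr_sd_visit = 0.40,
                         ln_ucr_mean = log(65), ln_ucr_sd = 0.55,
                         detection_limit_up = 1.0,
                         detection_limit_ualb = 1.0,
                         visit_gap_means = c(84, 75), visit_gap_sd = 35,
                         gfr_mix_non_diabetic = c(G1 = 5, G2 = 47, G3a = 73,
                                                  G3b = 44, G4 = 28),
                         gfr_mix_diabetic = c(G1 = 12, G2 = 45, G3a = 26,
                                              G3b = 16, G4 = 7),
                         male_fraction_non_diabetic = 124 / 197,
                         male_fraction_diabetic = 70 / 106,
                         age_mean_non_diabetic = 68.9, age_sd_non_diabetic = 14.8,
                         age_mean_diabetic = 67.1, age_sd_diabetic = 11.6,
                         curve_non_diabetic = NULL, curve_diabetic = NULL,
                         egfr_visit_cv = 0.03,
                         assay_digits = 1) {
  truth <- as.list(environment())
  if (is.null(truth$curve_non_diabetic)) {
    truth$curve_non_diabetic <- load_calibration("non_diabetic")
  }
  if (is.null(truth$curve_diabetic)) {
    truth$curve_diabetic <- load_calibration("diabetic")
  }
  sds <- c(truth$ln_upcr_sd_between, truth$ln_upcr_sd_within,
           truth$uacr_sd_patient, truth$uacr_sd_visit, truth$ln_ucr_sd)
  if (any(sds < 0)) stop("cohort_truth(): sds must be non-negative")
  if (truth$n_non_diabetic < 0 || truth$n_diabetic < 0) {
    stop("cohort_truth(): negative cohort size")
  }
  structure(truth, class = "cohort_truth")
}

.sample_truncnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lo | x > hi
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lo | x > hi
  }
  x
}

.gfr_band <- list(G1 = c(90, 110), G2 = c(60, 90), G3a = c(45, 60),
                  G3b = c(30, 45), G4 = c(15, 30))

#' Generate a synthetic per-visit cohort
#'
#' Per patient i and visit j: ln uPCR_ij = mu_i + e_ij; ln uACR_ij =
#' f(ln uPCR_ij; stratum curve) + b_i + eps_ij; concentrations are
#' back-computed through a drawn urinary creatinine (uP = uPCR x uCr,
#' uAlb = uACR x uCr / 100), censored below the detection limits, and
#' rounded to assay reporting precision (0.1 units). Serum creatinine is
#' made consistent with the assigned GFR category by inverting the eGFR
#' equation at a target eGFR drawn within the category band. Randomness is
#' split per patient so patient k's data do not change when n changes.
#'
#' @param truth A [cohort_truth()] configuration.
#' @param seed Integer seed.
#' @return Per-visit tibble in the cohort CSV layout with derived `upcr`,
#'   `uacr`, `egfr` columns (as [read_cohort_csv()] would return).
#' @export
generate_cohort <- function(truth = cohort_truth(), seed = 1) {
  stopifnot(inherits(truth, "cohort_truth"))
  n_tot <- truth$n_non_diabetic + truth$n_diabetic
  rows <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    set.seed(.unit_seed(seed, i))
    diabetic <- i > truth$n_non_diabetic
    mix <- if (diabetic) truth$gfr_mix_diabetic else truth$gfr_mix_non_diabetic
    gcat <- sample(names(mix), 1, prob = mix / sum(mix))
    age <- round(.sample_truncnorm(
      1,
      if (diabetic) truth$age_mean_diabetic else truth$age_mean_non_diabetic,
      if (diabetic) truth$age_sd_diabetic else truth$age_sd_non_diabetic,
      18, 100))
    male_frac <- if (diabetic) truth$male_fraction_diabetic else
      truth$male_fraction_non_diabetic
    sex <- if (stats::runif(1) < male_frac) "M" else "F"
    nv <- truth$visits
    gaps <- pmax(14, stats::rnorm(
      nv - 1,
      mean = truth$visit_gap_means[pmin(seq_len(nv - 1),
                                        length(truth$visit_gap_means))],
      sd = truth$visit_gap_sd))
    days <- c(0, cumsum(round(gaps)))
    mu_i <- truth$ln_upcr_mean + stats::rnorm(1, 0, truth$ln_upcr_sd_between)
    ln_upcr <- mu_i + stats::rnorm(nv, 0, truth$ln_upcr_sd_within)
    curve <- if (diabetic) truth$curve_diabetic else truth$curve_non_diabetic
    b_i <- stats::rnorm(1, 0, truth$uacr_sd_patient)
    ln_uacr <- .predict_ln_uacr(curve, ln_upcr, extrapolate = TRUE) +
      b_i + stats::rnorm(nv, 0, truth$uacr_sd_visit)
    ucr <- exp(stats::rnorm(nv, truth$ln_ucr_mean, truth$ln_ucr_sd))
    up <- exp(ln_upcr) / 1000 * ucr          # mg/dl
    ualb <- exp(ln_uacr) * ucr / 100          # mg/l
    up_cens <- up < truth$detection_limit_up
    ualb_cens <- ualb < truth$detection_limit_ualb
    band <- .gfr_band[[gcat]]
    target_egfr <- stats::runif(1, band[1], band[2])
    egfr_visit <- target_egfr *
      exp(stats::rnorm(nv, 0, truth$egfr_visit_cv))
    scr <- (194 * age^(-0.287) / ifelse(sex == "F", egfr_visit / 0.739,
                                        egfr_visit))^(1 / 1.094)
    rows[[i]] <- tibble::tibble(
      patient_id = sprintf("P%04d", i),
      age = age, sex = sex, diabetes = diabetic,
      day = days,
      serum_cr_mgdl = round(scr, max(2, truth$assay_digits)),
      up_mgdl = ifelse(up_cens, 0, round(up, truth$assay_digits)),
      ualb_mgl = ifelse(ualb_cens, 0, round(ualb, truth$assay_digits)),
      ucr_mgdl = round(ucr, truth$assay_digits),
      up_censored = up_cens, ualb_censored = ualb_cens
    )
  }
  out <- dplyr::bind_rows(rows)
  out <- derive_ratios(out)
  out$egfr <- compute_egfr(out$serum_cr_mgdl, out$age, out$sex)
  out
}

#' Write a cohort in the cohort CSV layout
#'
#' @param cohort Per-visit tibble (derived columns are dropped on write).
#' @param path Output CSV path.
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- c("patient_id", "age", "sex", "diabetes", "day", "serum_cr_mgdl",
            "up_mgdl", "ualb_mgl", "ucr_mgdl", "up_censored", "ualb_censored")
  x <- as.data.frame(cohort[, cols])
  x$diabetes <- as.integer(x$diabetes)
  x$up_censored <- as.integer(x$up_censored)
  x$ualb_censored <- as.integer(x$ualb_censored)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Ground-truth configuration for the stability-substudy generator
#'
#' Measurement error is multiplicative lognormal per condition. Occasions:
#' 1 fresh; 2 after 3-4 h refrigerated; 3 and 4 consecutively after
#' freeze-thaw on day 3-4 (these two share one per-sample degradation
#' factor, so they stay mutually consistent even when storage has degraded
#' the sample). Protein noise under storage is inflated for low-protein
#' samples, emulating the instability of trace protein in stored specimens.
#'
#' @param n_samples Number of samples.
#' @param ln_upcr_mean,ln_upcr_sd True ln uPCR (mg/gCr) distribution.
#' @param ln_ucr_mean,ln_ucr_sd True urinary creatinine (mg/dl).
#' @param uacr_sd Residual sd of ln uACR about the median curve.
#' @param curve `uacr_spline` truth curve (default bundled non-diabetic).
#' @param ln_scr_mean,ln_scr_sd Serum creatinine (mg/dl) distribution.
#' @param sd_assay Per-measurement analytic noise (ln scale) for protein,
#'   albumin, creatinine.
#' @param sd_storage Refrigeration (occasion 2) noise per analyte.
#' @param sd_freezethaw Freeze-thaw (shared by occasions 3-4) noise per
#'   analyte.
#' @param low_protein_threshold True protein concentration (mg/dl) below
#'   which storage noise is inflated.
#' @param low_protein_inflation Multiplier applied to protein storage and
#'   freeze-thaw sds for low-protein samples.
#' @return A validated list of class `stability_truth`.
#' @export
stability_truth <- function(n_samples = 88,
                            ln_upcr_mean = 4.25, ln_upcr_sd = 1.0,
                            ln_ucr_mean = log(65), ln_ucr_sd = 0.55,
                            uacr_sd = 0.5,
                            curve = NULL,
                            ln_scr_mean = log(1.1), ln_scr_sd = 0.25,
                            sd_assay = c(up = 0.05, ualb = 0.04, ucr = 0.01),
                            sd_storage = c(up = 0.10, ualb = 0.05, ucr = 0.01),
                            sd_freezethaw = c(up = 0.10, ualb = 0.15, ucr = 0.02),
                            low_protein_threshold = 3,
                            low_protein_inflation = 6) {
  truth <- as.list(environment())
  if (is.null(truth$curve)) truth$curve <- load_calibration("non_diabetic")
  if (any(c(truth$sd_assay, truth$sd_storage, truth$sd_freezethaw) < 0)) {
    stop("stability_truth(): noise sds must be non-negative")
  }
  structure(truth, class = "stability_truth")
}

#' Generate a synthetic stability substudy
#'
#' Four occasion measurements per sample equal the true concentration times
#' multiplicative noise for the occasion's condition; occasions 3 and 4
#' share one freeze-thaw degradation factor per sample plus independent
#' analytic noise. Low-protein samples receive inflated protein noise for
#' the stored occasions.
#'
#' @param truth A [stability_truth()] configuration.
#' @param seed Integer seed.
#' @return Long tibble in the stability CSV layout (ratios derived).
#' @export
generate_stability_study <- function(truth = stability_truth(), seed = 1) {
  stopifnot(inherits(truth, "stability_truth"))
  conditions <- c("fresh", "refrigerated_3-4h", "freezethaw_rep1",
                  "freezethaw_rep2")
  rows <- vector("list", truth$n_samples)
  for (i in seq_len(truth$n_samples)) {
    set.seed(.unit_seed(seed + 500000L, i))
    ln_upcr <- stats::rnorm(1, truth$ln_upcr_mean, truth$ln_upcr_sd)
    ucr_true <- exp(stats::rnorm(1, truth$ln_ucr_mean, truth$ln_ucr_sd))
    ln_uacr <- .predict_ln_uacr(truth$curve, ln_upcr, extrapolate = TRUE) +
      stats::rnorm(1, 0, truth$uacr_sd)
    up_true <- exp(ln_upcr) / 1000 * ucr_true
    ualb_true <- exp(ln_uacr) * ucr_true / 100
    scr <- exp(stats::rnorm(1, truth$ln_scr_mean, truth$ln_scr_sd))
    infl <- if (up_true < truth$low_protein_threshold)
      truth$low_protein_inflation else 1
    noise <- function(sd) exp(stats::rnorm(1, 0, sd))
    # per-sample shared freeze-thaw degradation (occasions 3 and 4)
    ft <- c(up = noise(truth$sd_freezethaw[["up"]] * infl),
            ualb = noise(truth$sd_freezethaw[["ualb"]]),
            ucr = noise(truth$sd_freezethaw[["ucr"]]))
    meas <- function(occ) {
      st <- switch(occ,
        `1` = c(up = 1, ualb = 1, ucr = 1),
        `2` = c(up = noise(truth$sd_storage[["up"]] * infl),
                ualb = noise(truth$sd_storage[["ualb"]]),
                ucr = noise(truth$sd_storage[["ucr"]])),
        `3` = ft, `4` = ft)
      c(up = up_true * st[["up"]] * noise(truth$sd_assay[["up"]]),
        ualb = ualb_true * st[["ualb"]] * noise(truth$sd_assay[["ualb"]]),
        ucr = ucr_true * st[["ucr"]] * noise(truth$sd_assay[["ucr"]]))
    }
    m <- vapply(as.character(1:4), meas, numeric(3))
    rows[[i]] <- tibble::tibble(
      sample_id = sprintf("S%04d", i),
      occasion = 1:4,
      condition = conditions,
      up_mgdl = round(unname(m["up", ]), 1),
      ualb_mgl = round(unname(m["ualb", ]), 1),
      ucr_mgdl = round(unname(m["ucr", ]), 1),
      serum_cr_mgdl = round(scr, 2)
    )
  }
  derive_ratios(dplyr::bind_rows(rows))
}

#' Write a stability study in the stability CSV layout
#'
#' @param samples Long tibble from [generate_stability_study()].
#' @param path Output CSV path.
#' @export
write_stability_csv <- function(samples, path) {
  cols <- c("sample_id", "occasion", "condition", "up_mgdl", "ualb_mgl",
            "ucr_mgdl", "serum_cr_mgdl")
  utils::write.csv(as.data.frame(samples[, cols]), path, row.names = FALSE)
  invisible(path)
}
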