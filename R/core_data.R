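#' Derive uPCR and uACR from a urine assay triplet
#'
#' Computes the urinary protein-to-creatinine ratio (uPCR, g/gCr) and the
#' urinary albumin-to-creatinine ratio (uACR, mg/gCr) from spot-urine
#' concentrations. Protein and creatinine are both reported in mg/dl, so
#' their ratio is already g protein per g creatinine; albumin is reported in
#' mg/l (= 0.1 mg/dl), hence the factor 100 in the uACR.
#'
#' Concentrations flagged as below the assay detection limit are carried as
#' numeric 0 and yield a ratio of 0 with the censoring flag preserved, the
#' convention used for all downstream analyses.
#'
#' @param measurements A data frame with columns `up_mgdl`, `ualb_mgl`,
#'   `ucr_mgdl` and optionally `up_censored`, `ualb_censored` (0/1 or
#'   logical; default uncensored).
#' @return The input as a tibble with numeric columns `upcr` (g/gCr) and
#'   `uacr` (mg/gCr) added, and censoring flags normalised to logical.
#' @examples
#' derive_ratios(data.frame(up_mgdl = 15, ualb_mgl = 30, ucr_mgdl = 100))
#' @export
derive_ratios <- function(measurements) {
  m <- tibble::as_tibble(measurements)
  req <- c("up_mgdl", "ualb_mgl", "ucr_mgdl")
  missing_cols <- setdiff(req, names(m))
  if (length(missing_cols) > 0) {
    stop("derive_ratios(): missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"up_censored" %in% names(m)) m$up_censored <- FALSE
  if (!"ualb_censored" %in% names(m)) m$ualb_censored <- FALSE
  m$up_censored <- as.logical(m$up_censored)
  m$ualb_censored <- as.logical(m$ualb_censored)
  if (any(m$up_mgdl < 0 | m$ualb_mgl < 0, na.rm = TRUE)) {
    stop("derive_ratios(): negative concentrations are invalid")
  }
  if (any(!is.finite(m$ucr_mgdl) | m$ucr_mgdl <= 0)) {
    stop("derive_ratios(): urinary creatinine must be positive to form a ratio")
  }
  # mg/dl over mg/dl is g/g; albumin mg/l -> mg/dl needs /10, and g/gCr ->
  # mg/gCr needs *1000, net *100 relative to ualb_mgl/ucr_mgdl
  m$upcr <- ifelse(m$up_censored, 0, m$up_mgdl / m$ucr_mgdl)
  m$uacr <- ifelse(m$ualb_censored, 0, m$ualb_mgl * 100 / m$ucr_mgdl)
  m
}

#' Estimated GFR from serum creatinine, age and sex
#'
#' The Japanese Society of Nephrology equation for adults:
#' eGFR = 194 * sCr^-1.094 * age^-0.287 (ml/min/1.73 m^2), multiplied by
#' 0.739 for women. The coefficients are pluggable for other populations.
#'
#' @param serum_cr Serum creatinine, mg/dl (positive).
#' @param age Age in years (>= 18).
#' @param sex `"M"` or `"F"` (vectorised).
#' @param coef Named list of equation constants
#'   (`a * sCr^b * age^c`, `female` multiplier).
#' @return eGFR in ml/min/1.73 m^2.
#' @examples
#' compute_egfr(1.0, 60, "M")
#' @export
compute_egfr <- function(serum_cr, age, sex,
                         coef = list(a = 194, b = -1.094, c = -0.287,
                                     female = 0.739)) {
  if (any(!is.finite(serum_cr) | serum_cr <= 0)) {
    stop("compute_egfr(): serum creatinine must be positive")
  }
  if (any(!is.finite(age) | age < 18)) {
    stop("compute_egfr(): age must be >= 18 years")
  }
  sex <- toupper(as.character(sex))
  if (!all(sex %in% c("M", "F"))) stop("compute_egfr(): sex must be 'M' or 'F'")
  e <- coef$a * serum_cr^coef$b * age^coef$c
  ifelse(sex == "F", e * coef$female, e)
}

#' KDIGO GFR category from an eGFR series
#'
#' The mean eGFR over all provided values determines the category, using the
#' standard half-open KDIGO bands: G1 >= 90, G2 60-89, G3a 45-59, G3b 30-44,
#' G4 15-29, G5 < 15.
#'
#' @param egfr_series Numeric vector of eGFR values (nonempty).
#' @return A factor level among `G1, G2, G3a, G3b, G4, G5`.
#' @export
gfr_category_from_series <- function(egfr_series) {
  egfr_series <- egfr_series[is.finite(egfr_series)]
  if (length(egfr_series) == 0) stop("gfr_category_from_series(): empty eGFR series")
  gfr_category(mean(egfr_series))
}

#' @rdname gfr_category_from_series
#' @param egfr A single (or vector of) eGFR value(s).
#' @export
gfr_category <- function(egfr) {
  cut(egfr, breaks = c(-Inf, 15, 30, 45, 60, 90, Inf), right = FALSE,
      labels = c("G5", "G4", "G3b", "G3a", "G2", "G1")) |>
    factor(levels = c("G1", "G2", "G3a", "G3b", "G4", "G5"))
}

#' Albuminuria category of a single uACR value
#'
#' Normoalbuminuria is uACR < 30 mg/gCr, microalbuminuria 30-299 mg/gCr, and
#' macroalbuminuria >= 300 mg/gCr.
#'
#' @param uacr uACR in mg/gCr (non-negative, vectorised).
#' @return Factor with levels `normo`, `micro`, `macro`.
#' @export
classify_albuminuria_measurement <- function(uacr) {
  if (any(!is.finite(uacr) | uacr < 0)) {
    stop("classify_albuminuria_measurement(): uACR must be non-negative")
  }
  cut(uacr, breaks = c(-Inf, 30, 300, Inf), right = FALSE,
      labels = c("normo", "micro", "macro"))
}

#' Patient-level albuminuria category from three repeated uACR values
#'
#' A category held on at least two of the three measurements defines the
#' patient; when the three measurements fall in normo, micro and macro once
#' each, the patient is classified as microalbuminuria.
#'
#' @param uacr_triplet Exactly three non-negative uACR values (mg/gCr).
#' @return One of `"normo"`, `"micro"`, `"macro"`.
#' @export
classify_albuminuria_patient <- function(uacr_triplet) {
  if (length(uacr_triplet) != 3) {
    stop("classify_albuminuria_patient(): exactly 3 uACR values are required")
  }
  cats <- classify_albuminuria_measurement(uacr_triplet)
  counts <- table(cats)
  if (max(counts) >= 2) {
    return(names(counts)[which.max(counts)])
  }
  "micro"  # one of each category
}

#' Apply the cohort eligibility rules
#'
#' Keeps patients whose first-visit uPCR is below 0.5 g/gCr and first eGFR
#' is at least 15 ml/min/1.73 m^2, then removes any patient whose eGFR
#' dropped by 30% or more between two measurements at most `window_days`
#' apart. A uPCR that rises to 0.5 g/gCr or more on a later visit never
#' excludes. Patients lacking
#' first-visit data are excluded with reason `"incomplete"`.
#'
#' @param cohort Per-visit tibble with columns `patient_id`, `day`, `upcr`
#'   and an eGFR series given as columns `day`, `egfr` (one row per visit).
#' @param upcr_limit First-visit uPCR bound, g/gCr.
#' @param egfr_min First-visit eGFR bound.
#' @param drop_fraction Relative eGFR drop that excludes (default 0.30).
#' @param window_days "within 3 months" window, in days (default 92).
#' @return A list with elements `kept` (per-visit tibble) and `excluded`
#'   (tibble `patient_id`, `reason`).
#' @export
apply_eligibility <- function(cohort, upcr_limit = 0.5, egfr_min = 15,
                              drop_fraction = 0.30, window_days = 92) {
  cohort <- tibble::as_tibble(cohort)
  stopifnot(all(c("patient_id", "day", "upcr", "egfr") %in% names(cohort)))
  ids <- unique(cohort$patient_id)
  reasons <- character(0)
  excluded_ids <- character(0)
  for (id in ids) {
    p <- cohort[cohort$patient_id == id, ]
    p <- p[order(p$day), ]
    first <- p[1, ]
    if (!is.finite(first$upcr) || !is.finite(first$egfr)) {
      excluded_ids <- c(excluded_ids, id); reasons <- c(reasons, "incomplete")
      next
    }
    if (first$upcr >= upcr_limit) {
      excluded_ids <- c(excluded_ids, id)
      reasons <- c(reasons, "first_upcr_ge_limit")
      next
    }
    if (first$egfr < egfr_min) {
      excluded_ids <- c(excluded_ids, id)
      reasons <- c(reasons, "first_egfr_below_min")
      next
    }
    if (.egfr_unstable(p$day, p$egfr, drop_fraction, window_days)) {
      excluded_ids <- c(excluded_ids, id)
      reasons <- c(reasons, "egfr_drop_ge_30pct_within_3mo")
    }
  }
  list(
    kept = cohort[!cohort$patient_id %in% excluded_ids, ],
    excluded = tibble::tibble(patient_id = excluded_ids, reason = reasons)
  )
}

# >= drop_fraction relative eGFR decrease between any two measurements at
# most window_days apart (later vs earlier)
.egfr_unstable <- function(day, egfr, drop_fraction, window_days) {
  n <- length(day)
  if (n < 2) return(FALSE)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (day[j] - day[i] <= window_days && egfr[i] > 0) {
        if ((egfr[i] - egfr[j]) / egfr[i] >= drop_fraction) return(TRUE)
      }
    }
  }
  FALSE
}

#' Read a per-visit cohort CSV
#'
#' Expected columns: `patient_id, age, sex, diabetes, day, serum_cr_mgdl,
#' up_mgdl, ualb_mgl, ucr_mgdl, up_censored, ualb_censored` (UTF-8, header
#' required). Ratios and eGFR are derived on read.
#'
#' @param path CSV file path.
#' @return Per-visit tibble with `upcr`, `uacr` and `egfr` columns added.
#' @export
read_cohort_csv <- function(path) {
  req <- c("patient_id", "age", "sex", "diabetes", "day", "serum_cr_mgdl",
           "up_mgdl", "ualb_mgl", "ucr_mgdl", "up_censored", "ualb_censored")
  x <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    stop("read_cohort_csv(): ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  x <- derive_ratios(x)
  x$egfr <- compute_egfr(x$serum_cr_mgdl, x$age, x$sex)
  x$diabetes <- as.logical(as.integer(x$diabetes))
  x
}

#' Summarise a per-visit cohort to one row per patient
#'
#' Requires exactly three classified visits per patient; patients with fewer
#' are dropped (they cannot receive a repeated-measurement label). Adds the
#' patient-level albuminuria category, the GFR category from the mean eGFR,
#' and visit-order uPCR/uACR columns.
#'
#' @param cohort Per-visit tibble from [read_cohort_csv()] or
#'   [generate_cohort()] (needs `patient_id`, `day`, `upcr`, `uacr`, `egfr`,
#'   `age`, `sex`, `diabetes`).
#' @return One-row-per-patient tibble.
#' @export
summarise_patients <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  cohort |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::filter(dplyr::n() >= 3) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::summarise(
      age = .data$age[1], sex = .data$sex[1], diabetes = .data$diabetes[1],
      upcr1 = .data$upcr[1], upcr2 = .data$upcr[2], upcr3 = .data$upcr[3],
      uacr1 = .data$uacr[1], uacr2 = .data$uacr[2], uacr3 = .data$uacr[3],
      mean_egfr = mean(.data$egfr),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      gfr_category = gfr_category(.data$mean_egfr),
      albuminuria = vapply(
        seq_len(dplyr::n()),
        function(i) classify_albuminuria_patient(
          c(.data$uacr1[i], .data$uacr2[i], .data$uacr3[i])),
        character(1))
    )
}
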