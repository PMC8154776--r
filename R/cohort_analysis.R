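# Assembly of the discriminators and the study-style result tables:
# per-measurement uACR-threshold discrimination, patient-level single/summed
# uPCR discrimination with paired AUC comparisons, subgroup cutoffs,
# distribution cross-tabs and delta regressions.

#' Build single and summed uPCR/uACR discriminators per patient
#'
#' From a per-patient summary (three ordered visits) constructs the ten
#' discriminators: the three single uPCRs, the three pairwise sums, the
#' triple sum, and the three single uACRs, together with the patient-level
#' label (micro- or macroalbuminuria vs normoalbuminuria by the
#' repeated-measurement rule).
#'
#' @param patients One-row-per-patient tibble from [summarise_patients()].
#' @return The input with columns `upcr12`, `upcr23`, `upcr13`, `upcr123`
#'   and logical `label` added.
#' @export
build_discriminators <- function(patients) {
  patients <- tibble::as_tibble(patients)
  need <- c("upcr1", "upcr2", "upcr3", "uacr1", "uacr2", "uacr3", "albuminuria")
  stopifnot(all(need %in% names(patients)))
  dplyr::mutate(
    patients,
    upcr12 = .data$upcr1 + .data$upcr2,
    upcr23 = .data$upcr2 + .data$upcr3,
    upcr13 = .data$upcr1 + .data$upcr3,
    upcr123 = .data$upcr1 + .data$upcr2 + .data$upcr3,
    label = .data$albuminuria %in% c("micro", "macro")
  )
}

.discriminator_columns <- c(
  "1uPCR" = "upcr1", "2uPCR" = "upcr2", "3uPCR" = "upcr3",
  "1.2uPCR" = "upcr12", "2.3uPCR" = "upcr23", "1.3uPCR" = "upcr13",
  "1.2.3uPCR" = "upcr123",
  "1uACR" = "uacr1", "2uACR" = "uacr2", "3uACR" = "uacr3"
)

# one ROC + Youden row; NA-filled flagged row when only one class is present
.roc_row <- function(scores, labels) {
  if (length(unique(labels)) < 2) {
    return(tibble::tibble(n = length(scores), n_pos = sum(labels),
                          auc = NA_real_, se = NA_real_, p = NA_real_,
                          cutoff = NA_real_, sensitivity = NA_real_,
                          specificity = NA_real_, youden = NA_real_,
                          flagged = TRUE))
  }
  roc <- roc_points(scores, labels)
  co <- youden_cutoff(roc)
  tibble::tibble(n = length(scores), n_pos = roc$n_pos,
                 auc = roc$auc, se = roc$se, p = roc$p,
                 cutoff = co$cutoff, sensitivity = co$sensitivity,
                 specificity = co$specificity, youden = co$youden,
                 flagged = FALSE)
}

#' Per-measurement discrimination of uACR above each threshold
#'
#' Pools every visit as an independent record and, for each uACR threshold
#' X, derives the ROC of uPCR against the label uACR >= X with the
#' Youden-optimal cutoff (the structure of the per-measurement threshold
#' tables).
#'
#' @param records Per-visit tibble with `upcr` and `uacr`.
#' @param thresholds uACR thresholds, mg/gCr.
#' @return Tibble, one row per threshold; single-class thresholds are
#'   flagged rather than computed.
#' @export
uacr_threshold_table <- function(records, thresholds = c(seq(10, 150, 10), 300)) {
  records <- tibble::as_tibble(records)
  dplyr::bind_rows(lapply(thresholds, function(X) {
    dplyr::bind_cols(tibble::tibble(uacr_threshold = X),
                     .roc_row(records$upcr, records$uacr >= X))
  }))
}

#' Patient-level microalbuminuria discrimination by all ten discriminators
#'
#' Evaluates each single/summed uPCR and each single uACR as a discriminator
#' of the patient-level label (micro- and macroalbuminuria vs
#' normoalbuminuria): AUC with DeLong SE, p vs 0.5, Youden cutoff, and all
#' pairwise DeLong comparisons of the correlated AUCs.
#'
#' @param ds Discriminator tibble from [build_discriminators()].
#' @return List with `table` (one row per discriminator) and `pairwise`
#'   (tibble of paired DeLong tests).
#' @export
microalbuminuria_discrimination <- function(ds) {
  ds <- tibble::as_tibble(ds)
  if (length(unique(ds$label)) < 2) {
    stop("microalbuminuria_discrimination(): both classes are required")
  }
  cols <- .discriminator_columns
  tab <- dplyr::bind_rows(lapply(names(cols), function(nm) {
    dplyr::bind_cols(tibble::tibble(discriminator = nm),
                     .roc_row(ds[[cols[nm]]], ds$label))
  }))
  pairs <- utils::combn(names(cols), 2)
  pw <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    dplyr::bind_cols(tibble::tibble(a = a, b = b),
                     paired_auc_test(ds[[cols[a]]], ds[[cols[b]]], ds$label))
  }))
  list(table = tab, pairwise = pw)
}

#' Subgroup partitions of a discriminator set
#'
#' Age bands are closed-open: 18-<65, 65-<80, >=80. The GFR axis contrasts
#' G1-3a with G3b-4 (G5 patients, excluded upstream by eligibility, would
#' fall outside both).
#'
#' @param ds Discriminator tibble (needs `age`, `sex`, `gfr_category`,
#'   `diabetes` as applicable).
#' @param axis One of `"age"`, `"sex"`, `"gfr"`, `"diabetes"`.
#' @return Factor of subgroup membership aligned with `ds` rows.
#' @export
subgroup_membership <- function(ds, axis = c("age", "sex", "gfr", "diabetes")) {
  axis <- match.arg(axis)
  switch(axis,
    age = cut(ds$age, breaks = c(18, 65, 80, Inf), right = FALSE,
              labels = c("<65", "65-<80", ">=80")),
    sex = factor(ds$sex, levels = c("M", "F")),
    gfr = factor(ifelse(ds$gfr_category %in% c("G1", "G2", "G3a"),
                        "G1-3a", "G3b-4"),
                 levels = c("G1-3a", "G3b-4")),
    diabetes = factor(ifelse(ds$diabetes, "diabetic", "non_diabetic"),
                      levels = c("non_diabetic", "diabetic"))
  )
}

#' Youden cutoffs within subgroups
#'
#' Repeats the parent-table computation (ROC of a chosen discriminator
#' against a chosen label) restricted to each subgroup of the axis.
#'
#' @param ds Discriminator tibble from [build_discriminators()].
#' @param axis Subgroup axis, see [subgroup_membership()].
#' @param score_col Column of `ds` used as the score (default `"upcr2"`).
#' @param label Logical vector; defaults to the patient-level label.
#' @return Tibble, one row per subgroup (single-class subgroups flagged).
#' @export
subgroup_cutoffs <- function(ds, axis, score_col = "upcr2", label = ds$label) {
  grp <- subgroup_membership(ds, axis)
  dplyr::bind_rows(lapply(levels(grp), function(g) {
    sel <- !is.na(grp) & grp == g
    dplyr::bind_cols(tibble::tibble(axis = axis, subgroup = g),
                     .roc_row(ds[[score_col]][sel], label[sel]))
  }))
}

#' Cross-tabulation of uACR by uPCR band and GFR stratum
#'
#' Contingency counts of per-measurement records in fixed uPCR bands by
#' uACR bands, within each GFR stratum (G1-3a vs G3b-4); marginals are
#' conserved by construction.
#'
#' @param records Per-visit tibble with `upcr`, `uacr`, `gfr_category`.
#' @param upcr_breaks uPCR band edges in g/gCr (left-closed).
#' @param uacr_breaks uACR band edges in mg/gCr (left-closed).
#' @return Tibble of counts: `gfr_stratum`, `uacr_band`, `upcr_band`, `n`.
#' @export
distribution_crosstab <- function(records,
                                  upcr_breaks = c(0, 0.07, 0.09, 0.15, 0.50, Inf),
                                  uacr_breaks = c(0, 10, 20, 30, 60, 100, 150, 200, 300, Inf)) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("upcr", "uacr", "gfr_category") %in% names(records)))
  stratum <- factor(ifelse(records$gfr_category %in% c("G1", "G2", "G3a"),
                           "G1-3a", "G3b-4"), levels = c("G1-3a", "G3b-4"))
  upcr_band <- cut(records$upcr, breaks = upcr_breaks, right = FALSE)
  uacr_band <- cut(records$uacr, breaks = uacr_breaks, right = FALSE)
  as.data.frame(table(gfr_stratum = stratum, uacr_band = uacr_band,
                      upcr_band = upcr_band),
                responseName = "n") |>
    tibble::as_tibble()
}

#' False-positive audit at a uPCR cutoff
#'
#' Among records called positive at the cutoff (uPCR >= cutoff) but with
#' uACR below the disease threshold, the fraction whose uACR still reaches
#' `floor_uacr` (borderline rather than clearly normal albuminuria).
#'
#' @param records Per-visit tibble with `upcr`, `uacr`.
#' @param cutoff uPCR cutoff, g/gCr.
#' @param disease_uacr Disease threshold (default 30 mg/gCr).
#' @param floor_uacr Borderline floor (default 10 mg/gCr).
#' @return List: `n_false_positive`, `n_ge_floor`, `fraction`.
#' @export
false_positive_audit <- function(records, cutoff, disease_uacr = 30,
                                 floor_uacr = 10) {
  fp <- records$upcr >= cutoff & records$uacr < disease_uacr
  n_fp <- sum(fp)
  n_ge <- sum(fp & records$uacr >= floor_uacr)
  list(n_false_positive = n_fp, n_ge_floor = n_ge,
       fraction = if (n_fp > 0) n_ge / n_fp else NA_real_)
}

#' Regression of visit-to-visit changes in uACR on changes in uPCR
#'
#' For each visit pair (2-1 and 3-2) and each split of the cohort on the
#' first uPCR (< vs >= `split_at` g/gCr), ordinary least squares of
#' delta-uACR (mg/gCr) on delta-uPCR (g/gCr) with the Pearson correlation
#' and its two-sided p value.
#'
#' @param patients One-row-per-patient tibble (needs `upcr1..3`, `uacr1..3`).
#' @param split_at First-uPCR split point, g/gCr (default 0.15).
#' @param on_insufficient What to do with a split of fewer than 3 patients:
#'   `"error"` (default) or `"skip"` (drop the split from the output).
#' @return Tibble: `pair`, `split`, `n`, `slope`, `intercept`, `r`, `p`.
#' @export
delta_regression <- function(patients, split_at = 0.15,
                             on_insufficient = c("error", "skip")) {
  on_insufficient <- match.arg(on_insufficient)
  patients <- tibble::as_tibble(patients)
  res <- list()
  pairs <- list("2-1" = c("upcr2", "upcr1", "uacr2", "uacr1"),
                "3-2" = c("upcr3", "upcr2", "uacr3", "uacr2"))
  split <- ifelse(patients$upcr1 < split_at,
                  sprintf("<%.2f", split_at), sprintf(">=%.2f", split_at))
  for (pname in names(pairs)) {
    v <- pairs[[pname]]
    dx <- patients[[v[1]]] - patients[[v[2]]]
    dy <- patients[[v[3]]] - patients[[v[4]]]
    for (s in unique(split)) {
      sel <- split == s
      if (sum(sel) < 3) {
        if (on_insufficient == "skip") next
        stop("delta_regression(): fewer than 3 patients in split ", s)
      }
      if (stats::var(dx[sel]) == 0) {
        stop("delta_regression(): zero variance in delta-uPCR for split ", s)
      }
      fit <- stats::lm(dy[sel] ~ dx[sel])
      ct <- stats::cor.test(dx[sel], dy[sel])
      res[[length(res) + 1]] <- tibble::tibble(
        pair = pname, split = s, n = sum(sel),
        slope = unname(stats::coef(fit)[2]),
        intercept = unname(stats::coef(fit)[1]),
        r = unname(ct$estimate), p = ct$p.value
      )
    }
  }
  dplyr::bind_rows(res) |> dplyr::arrange(.data$pair, .data$split)
}
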