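# Intra/interday same-sample substudy: each sample is assayed four times
# (fresh; after 3-4 h refrigerated; twice consecutively after freeze-thaw on
# day 3-4). Agreement between occasion pairs is summarised per
# concentration stratum, and per-occasion Youden cutoffs are derived.

# fixed concentration bands from the substudy design; strata are assigned by
# the mean of the two measurements being compared
.stability_bands <- list(
  up = c(3, 8),       # mg/dl
  ualb = c(15, 40),   # mg/l
  ucr = c(50, 90),    # mg/dl
  upcr = 0.15,        # g/gCr
  uacr = 0.15         # uACR rows are stratified by the mean uPCR, g/gCr
)

#' Reshape a long stability table to one row per sample
#'
#' @param samples Long tibble: `sample_id`, `occasion` (1..4), `condition`,
#'   `up_mgdl`, `ualb_mgl`, `ucr_mgdl`, `serum_cr_mgdl`.
#' @return Wide tibble with per-occasion columns `up1..4`, `ualb1..4`,
#'   `ucr1..4`, `upcr1..4`, `uacr1..4` and `serum_cr_mgdl`.
#' @export
stability_wide <- function(samples) {
  samples <- tibble::as_tibble(samples)
  need <- c("sample_id", "occasion", "up_mgdl", "ualb_mgl", "ucr_mgdl",
            "serum_cr_mgdl")
  stopifnot(all(need %in% names(samples)))
  samples <- derive_ratios(samples)
  wide <- samples |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::arrange(.data$occasion, .by_group = TRUE) |>
    dplyr::summarise(
      serum_cr_mgdl = .data$serum_cr_mgdl[1],
      n_occ = dplyr::n(),
      up = list(.data$up_mgdl), ualb = list(.data$ualb_mgl),
      ucr = list(.data$ucr_mgdl), upcr = list(.data$upcr),
      uacr = list(.data$uacr),
      .groups = "drop"
    )
  if (any(wide$n_occ != 4)) {
    stop("stability_wide(): every sample needs exactly 4 occasions")
  }
  for (an in c("up", "ualb", "ucr", "upcr", "uacr")) {
    m <- do.call(rbind, wide[[an]])
    for (o in 1:4) wide[[paste0(an, o)]] <- m[, o]
    wide[[an]] <- NULL
  }
  wide$n_occ <- NULL
  wide
}

#' Assign concentration strata for an occasion pair
#'
#' The stratum is determined by the mean of the two measurements being
#' compared, using the substudy's fixed bands: urinary protein 3 and 8
#' mg/dl; albumin 15 and 40 mg/l; creatinine 50 and 90 mg/dl (three bands
#' each); uPCR (and uACR rows) split at mean uPCR 0.15
#' g/gCr. Band edges are configurable.
#'
#' @param wide Wide stability tibble from [stability_wide()].
#' @param analyte One of `"up"`, `"ualb"`, `"ucr"`, `"upcr"`, `"uacr"`.
#' @param pair Integer pair of occasions, e.g. `c(1, 2)`.
#' @param bands Optional numeric band edges overriding the defaults.
#' @return Tibble: `sample_id`, `earlier`, `later`, `pair_mean`, `stratum`.
#' @export
stratify_pairs <- function(wide, analyte, pair, bands = NULL) {
  analyte <- match.arg(analyte, names(.stability_bands))
  if (is.null(bands)) bands <- .stability_bands[[analyte]]
  earlier <- wide[[paste0(analyte, pair[1])]]
  later <- wide[[paste0(analyte, pair[2])]]
  # uACR agreement rows are stratified by the mean uPCR of the same pair
  strat_var <- if (analyte == "uacr") "upcr" else analyte
  sm <- (wide[[paste0(strat_var, pair[1])]] +
           wide[[paste0(strat_var, pair[2])]]) / 2
  lab <- if (length(bands) == 1) c("low", "high") else c("low", "medium", "high")
  stratum <- cut(sm, breaks = c(-Inf, bands, Inf), right = FALSE, labels = lab)
  tibble::tibble(sample_id = wide$sample_id, earlier = earlier, later = later,
                 pair_mean = (earlier + later) / 2, stratum = stratum)
}

#' Agreement between two repeated measurements in one stratum
#'
#' Ordinary least-squares regression of the later on the earlier
#' measurement, the Pearson correlation with its two-sided p value, and the
#' median and IQR of the bias (later minus earlier; type-7 interpolated
#' quartiles).
#'
#' @param earlier,later Paired measurements (n >= 3, earlier not constant).
#' @return Tibble row: `n`, `slope`, `intercept`, `r`, `p`, `bias_median`,
#'   `bias_q1`, `bias_q3`.
#' @export
pair_agreement <- function(earlier, later) {
  keep <- is.finite(earlier) & is.finite(later)
  earlier <- earlier[keep]; later <- later[keep]
  if (length(earlier) < 3) stop("pair_agreement(): need at least 3 pairs")
  if (stats::var(earlier) == 0 || stats::var(later) == 0) {
    stop("pair_agreement(): degenerate variance")
  }
  fit <- stats::lm(later ~ earlier)
  ct <- stats::cor.test(earlier, later)
  bias <- later - earlier
  tibble::tibble(
    n = length(earlier),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = unname(ct$estimate), p = ct$p.value,
    bias_median = stats::median(bias),
    bias_q1 = unname(stats::quantile(bias, 0.25, type = 7)),
    bias_q3 = unname(stats::quantile(bias, 0.75, type = 7))
  )
}

#' Stratified agreement table for one analyte and occasion pair
#'
#' @inheritParams stratify_pairs
#' @return Tibble with one row per stratum (plus descriptive pair means).
#' @export
stability_agreement_table <- function(wide, analyte, pair, bands = NULL) {
  strat <- stratify_pairs(wide, analyte, pair, bands)
  dplyr::bind_rows(lapply(levels(strat$stratum), function(s) {
    sel <- strat$stratum == s
    if (sum(sel) < 3) {
      return(tibble::tibble(analyte = analyte,
                            pair = paste(pair, collapse = "-"),
                            stratum = s, n = sum(sel)))
    }
    dplyr::bind_cols(
      tibble::tibble(analyte = analyte, pair = paste(pair, collapse = "-"),
                     stratum = s),
      pair_agreement(strat$earlier[sel], strat$later[sel])
    )
  }))
}

#' Per-occasion Youden cutoffs in the stability substudy
#'
#' For each of the four measurement occasions: the cutoff of the urinary
#' protein concentration and of the uPCR discriminating samples with
#' uACR >= 30 mg/gCr at that occasion, with the paired DeLong comparison of
#' the two correlated AUCs; and the cutoff of each occasion's uPCR
#' discriminating samples whose mean of the four uACR values is >= 30
#' mg/gCr.
#'
#' @param wide Wide stability tibble from [stability_wide()].
#' @param uacr_threshold Disease threshold, mg/gCr (default 30).
#' @return List with tibbles `per_occasion` (uP and uPCR rows with
#'   `p_up_vs_upcr`) and `mean_of_four` (uPCR rows).
#' @export
stability_cutoffs <- function(wide, uacr_threshold = 30) {
  per_occ <- list(); mean4 <- list()
  mean_uacr <- (wide$uacr1 + wide$uacr2 + wide$uacr3 + wide$uacr4) / 4
  for (o in 1:4) {
    lab <- wide[[paste0("uacr", o)]] >= uacr_threshold
    up <- wide[[paste0("up", o)]]
    upcr <- wide[[paste0("upcr", o)]]
    if (length(unique(lab)) < 2) {
      per_occ[[o]] <- tibble::tibble(occasion = o, flagged = TRUE)
    } else {
      row_up <- dplyr::bind_cols(
        tibble::tibble(occasion = o, score = "uP"), .roc_row(up, lab))
      row_upcr <- dplyr::bind_cols(
        tibble::tibble(occasion = o, score = "uPCR"), .roc_row(upcr, lab))
      cmp <- paired_auc_test(upcr, up, lab)
      row_up$p_up_vs_upcr <- cmp$p
      row_upcr$p_up_vs_upcr <- cmp$p
      per_occ[[o]] <- dplyr::bind_rows(row_up, row_upcr)
    }
    lab4 <- mean_uacr >= uacr_threshold
    mean4[[o]] <- if (length(unique(lab4)) < 2) {
      tibble::tibble(occasion = o, flagged = TRUE)
    } else {
      dplyr::bind_cols(tibble::tibble(occasion = o, score = "uPCR"),
                       .roc_row(upcr, lab4))
    }
  }
  list(per_occasion = dplyr::bind_rows(per_occ),
       mean_of_four = dplyr::bind_rows(mean4))
}

#' Read a stability-substudy CSV
#'
#' Expected columns: `sample_id, occasion, condition, up_mgdl, ualb_mgl,
#' ucr_mgdl, serum_cr_mgdl`.
#'
#' @param path CSV file path.
#' @return Long tibble (ratios derived).
#' @export
read_stability_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("sample_id", "occasion", "condition", "up_mgdl", "ualb_mgl",
            "ucr_mgdl", "serum_cr_mgdl")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("read_stability_csv(): ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  derive_ratios(tibble::as_tibble(x))
}
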