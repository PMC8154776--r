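#' Binned median uACR summaries along the uPCR axis
#'
#' Groups (uPCR, uACR) pairs into uPCR bins of fixed width (default 0.01
#' g/gCr; a pair belongs to the bin whose label is its uPCR rounded to the
#' nearest bin width) and reports the median uACR and IQR per occupied bin.
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile`, type 7).
#'
#' @param upcr_g uPCR values, g/gCr (non-negative).
#' @param uacr uACR values, mg/gCr.
#' @param bin_width Bin width in g/gCr (default 0.01).
#' @return Tibble with `upcr_g` (bin label), `n`, `median_uacr`, `q1`, `q3`.
#' @export
bin_summaries <- function(upcr_g, uacr, bin_width = 0.01) {
  if (length(upcr_g) == 0) stop("bin_summaries(): empty input")
  if (length(upcr_g) != length(uacr)) stop("bin_summaries(): length mismatch")
  if (any(upcr_g < 0)) stop("bin_summaries(): uPCR must be non-negative")
  label <- round(upcr_g / bin_width) * bin_width
  tibble::tibble(label = label, uacr = uacr) |>
    dplyr::group_by(upcr_g = .data$label) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_uacr = stats::median(.data$uacr),
      q1 = unname(stats::quantile(.data$uacr, 0.25, type = 7)),
      q3 = unname(stats::quantile(.data$uacr, 0.75, type = 7)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$upcr_g)
}

#' Standard percentile knot locations
#'
#' Places k knots at the standard percentiles of the raw predictor
#' distribution: k = 3 at 10/50/90, k = 4 at 5/35/65/95, k = 5 at
#' 5/27.5/50/72.5/95 (type-7 quantiles).
#'
#' @param values Raw measurements (uPCR, mg/gCr).
#' @param k Number of knots, one of 3, 4, 5.
#' @return Strictly increasing numeric knot vector.
#' @export
standard_knots <- function(values, k) {
  probs <- switch(as.character(k),
    "3" = c(0.10, 0.50, 0.90),
    "4" = c(0.05, 0.35, 0.65, 0.95),
    "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
    stop("standard_knots(): k must be 3, 4 or 5")
  )
  kn <- unname(stats::quantile(values, probs, type = 7))
  if (any(diff(kn) <= 0)) {
    stop("standard_knots(): knots are not strictly increasing; ",
         "too few distinct values - try fewer knots")
  }
  kn
}

# mkspline-style continuous piecewise-linear basis: column j has unit slope
# inside segment j and is flat elsewhere, so coefficient j IS segment j's
# slope. knots on the same scale as x.
.linear_spline_basis <- function(x, knots) {
  m <- length(knots)
  B <- matrix(0, nrow = length(x), ncol = m + 1)
  B[, 1] <- pmin(x, knots[1])
  if (m > 1) {
    for (j in 2:m) {
      B[, j] <- pmin(pmax(x - knots[j - 1], 0), knots[j] - knots[j - 1])
    }
  }
  B[, m + 1] <- pmax(x - knots[m], 0)
  colnames(B) <- paste0("s", seq_len(m + 1))
  B
}

# Restricted cubic (natural) spline basis, truncated-power form: linear
# beyond the boundary knots; k knots give k-1 columns (incl. the linear term).
.rcs_basis <- function(x, knots) {
  k <- length(knots)
  if (k < 3) stop("restricted cubic spline requires at least 3 knots")
  tk <- knots[k]; tk1 <- knots[k - 1]; t1 <- knots[1]
  norm2 <- (tk - t1)^2
  pos3 <- function(u) pmax(u, 0)^3
  B <- matrix(0, nrow = length(x), ncol = k - 1)
  B[, 1] <- x
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    B[, j + 1] <- (pos3(x - tj) -
                     pos3(x - tk1) * (tk - tj) / (tk - tk1) +
                     pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / norm2
  }
  colnames(B) <- c("x", paste0("c", seq_len(k - 2)))
  B
}

# Gaussian OLS AIC used for every spline kind so comparisons are like for
# like: n*ln(RSS/n) + 2*(p+1), p = number of mean parameters.
.ols_aic <- function(rss, n, p) n * log(rss / n) + 2 * (p + 1)

.spline_fit_stats <- function(fit, n, p) {
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((stats::model.response(stats::model.frame(fit)) -
                mean(stats::model.response(stats::model.frame(fit))))^2)
  list(
    rss = rss,
    aic = .ols_aic(rss, n, p),
    adj_r2 = 1 - (rss / (n - p)) / (tss / (n - 1))
  )
}

#' Fit a continuous piecewise log-linear (linear spline) calibration
#'
#' Ordinary least squares on the mkspline-style basis, so the fitted curve is
#' continuous at every knot and each basis coefficient is the slope of one
#' segment. Inputs are on the natural-log scale (`x` = ln uPCR in mg/gCr,
#' `y` = ln median uACR in mg/gCr); knots are given in mg/gCr.
#'
#' @param x,y Log-scale observations.
#' @param knots_mg Knot locations, uPCR in mg/gCr (strictly increasing).
#' @return An object of class `uacr_spline`.
#' @export
fit_linear_spline <- function(x, y, knots_mg) {
  if (any(diff(knots_mg) <= 0)) stop("fit_linear_spline(): knots must increase")
  lnk <- log(knots_mg)
  seg_idx <- findInterval(x, lnk) + 1L  # 1..m+1
  empty <- setdiff(seq_len(length(knots_mg) + 1L), unique(seg_idx))
  if (length(empty) > 0) {
    stop("fit_linear_spline(): no data in segment(s) ",
         paste(empty, collapse = ", "), "; design is rank deficient")
  }
  if (length(x) < length(knots_mg) + 2L) {
    stop("fit_linear_spline(): need at least #segments + 1 points")
  }
  B <- .linear_spline_basis(x, lnk)
  fit <- stats::lm(y ~ B)
  p <- length(stats::coef(fit))
  st <- .spline_fit_stats(fit, length(x), p)
  slopes <- unname(stats::coef(fit)[-1])
  # continuity cumulation: a_{j+1} = a_j + (b_j - b_{j+1}) * ln(knot_j)
  intercepts <- numeric(length(slopes))
  intercepts[1] <- unname(stats::coef(fit)[1])
  for (j in seq_along(lnk)) {
    intercepts[j + 1] <- intercepts[j] + (slopes[j] - slopes[j + 1]) * lnk[j]
  }
  bounds <- c(0, knots_mg, Inf)
  segments <- tibble::tibble(
    lo = bounds[-length(bounds)], hi = bounds[-1],
    intercept = intercepts, slope = slopes
  )
  structure(list(
    kind = "linear",
    knots_mg = knots_mg,
    segments = segments,
    coef = stats::coef(fit),
    vcov = stats::vcov(fit),
    df_residual = fit$df.residual,
    n = length(x), p = p,
    rss = st$rss, aic = st$aic, adj_r2 = st$adj_r2,
    domain_mg = range(exp(x)),
    population = "fitted"
  ), class = "uacr_spline")
}

#' Fit a restricted cubic spline calibration
#'
#' Truncated-power natural cubic spline (linear beyond the boundary knots)
#' fitted by ordinary least squares on the log-log scale, with the same AIC
#' convention as [fit_linear_spline()] so knot-count comparisons across kinds
#' are meaningful.
#'
#' @inheritParams fit_linear_spline
#' @return An object of class `uacr_spline` (kind `"restricted_cubic"`).
#' @export
fit_restricted_cubic_spline <- function(x, y, knots_mg) {
  if (length(knots_mg) < 3) {
    stop("fit_restricted_cubic_spline(): at least 3 knots are required")
  }
  lnk <- log(knots_mg)
  B <- .rcs_basis(x, lnk)
  fit <- stats::lm(y ~ B)
  p <- length(stats::coef(fit))
  st <- .spline_fit_stats(fit, length(x), p)
  structure(list(
    kind = "restricted_cubic",
    knots_mg = knots_mg,
    basis_coefficients = stats::coef(fit),
    vcov = stats::vcov(fit),
    df_residual = fit$df.residual,
    n = length(x), p = p,
    rss = st$rss, aic = st$aic, adj_r2 = st$adj_r2,
    domain_mg = range(exp(x)),
    population = "fitted"
  ), class = "uacr_spline")
}

#' @export
print.uacr_spline <- function(x, ...) {
  cat("uACR~uPCR calibration spline (", x$kind, "), ",
      length(x$knots_mg), " knots at ",
      paste(signif(x$knots_mg, 4), collapse = ", "), " mg/gCr\n", sep = "")
  if (!is.null(x$aic)) {
    cat(sprintf("  n = %d, AIC = %.1f, adjusted R^2 = %.3f\n",
                x$n, x$aic, x$adj_r2))
  }
  if (x$kind == "linear") print(x$segments)
  invisible(x)
}

#' Choose the number of knots by AIC
#'
#' Fits the requested spline kind for each candidate knot count (knots at
#' standard percentile locations of `raw_values`) and returns the count
#' minimising the Gaussian OLS AIC; ties go to the smaller count.
#'
#' @param x,y Log-scale observations to fit.
#' @param raw_values Raw uPCR measurements (mg/gCr) whose percentiles place
#'   the knots.
#' @param kind `"linear"` or `"restricted_cubic"`.
#' @param candidates Candidate knot counts (default 3:5).
#' @return List with `best_k`, `aic_table` (tibble k, aic) and `fits`.
#' @export
select_knot_count <- function(x, y, raw_values, kind = c("linear", "restricted_cubic"),
                              candidates = c(3, 4, 5)) {
  kind <- match.arg(kind)
  fits <- lapply(candidates, function(k) {
    kn <- standard_knots(raw_values, k)
    if (kind == "linear") fit_linear_spline(x, y, kn)
    else fit_restricted_cubic_spline(x, y, kn)
  })
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  best <- candidates[which.min(aic)]  # which.min takes the first tie -> smaller k
  list(best_k = best,
       aic_table = tibble::tibble(k = candidates, aic = aic),
       fits = stats::setNames(fits, paste0("k", candidates)))
}

#' Slope changes at the knots of a fitted linear spline
#'
#' For each adjacent segment pair reports the slope difference
#' (right minus left), its standard error from the coefficient covariance,
#' the t statistic, two-sided p value (t distribution on the residual
#' degrees of freedom) and 95% confidence interval.
#'
#' @param model A `uacr_spline` of kind `"linear"` fitted by
#'   [fit_linear_spline()] (a coefficient covariance is required).
#' @return Tibble with one row per knot.
#' @export
slope_change_tests <- function(model) {
  stopifnot(inherits(model, "uacr_spline"))
  if (model$kind != "linear") stop("slope_change_tests(): linear spline only")
  if (is.null(model$vcov)) {
    stop("slope_change_tests(): model has no coefficient covariance ",
         "(registry fixtures carry point coefficients only)")
  }
  nseg <- nrow(model$segments)
  df <- model$df_residual
  out <- vector("list", nseg - 1)
  for (j in seq_len(nseg - 1)) {
    # basis coefficient j+1 is slope of segment j (coef 1 is the intercept)
    cvec <- rep(0, length(model$coef))
    cvec[j + 1] <- -1
    cvec[j + 2] <- 1
    diff <- sum(cvec * model$coef)
    se <- sqrt(drop(t(cvec) %*% model$vcov %*% cvec))
    if (se < 1e-10 && abs(diff) < 1e-8) {
      # numerically exact fit with equal slopes: no evidence of change
      diff <- 0; tstat <- 0; p <- 1
    } else {
      tstat <- if (se > 0) diff / se else sign(diff) * Inf
      p <- 2 * stats::pt(-abs(tstat), df)
    }
    ci <- diff + c(-1, 1) * stats::qt(0.975, df) * se
    out[[j]] <- tibble::tibble(
      pair = sprintf("%dR vs %dR", j, j + 1),
      difference = diff, se = se, t = tstat, p = p,
      ci_lo = ci[1], ci_hi = ci[2]
    )
  }
  dplyr::bind_rows(out)
}

#' Load published calibration coefficient sets
#'
#' Reads a JSON registry of piecewise log-linear models
#' (`population`, `kind`, `segments` with `lo`/`hi` in mg/gCr and
#' `intercept`/`slope` on the ln scale). The registry bundled with the
#' package carries the published 4-knot calibrations for the combined,
#' non-diabetic and diabetic populations; other coefficient sets (e.g.
#' externally published conversion equations) can be supplied through the
#' same format.
#'
#' @param path Registry JSON path; default the bundled registry.
#' @param population Entry to load (`"all"`, `"non_diabetic"`, `"diabetic"`,
#'   or any population named in the file).
#' @return A `uacr_spline` (kind `"linear"`, no covariance).
#' @export
load_calibration <- function(population = c("all", "non_diabetic", "diabetic"),
                             path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "uacr_upcr_registry.json",
                        package = "microalb", mustWork = TRUE)
  }
  reg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  population <- if (is.character(population)) population[1] else population
  idx <- which(reg$models$population == population)
  if (length(idx) != 1) {
    stop("load_calibration(): population '", population, "' not in registry")
  }
  segs <- tibble::as_tibble(reg$models$segments[[idx]])
  knots <- segs$hi[-nrow(segs)]
  structure(list(
    kind = reg$models$kind[idx],
    knots_mg = knots,
    segments = segs,
    coef = NULL, vcov = NULL,
    n = NA_integer_, p = NA_integer_,
    rss = NULL, aic = NULL, adj_r2 = NULL,
    domain_mg = reg$domain_mg_per_gcr %||% c(min(segs$lo[segs$lo > 0], 1), max(segs$hi)),
    population = population
  ), class = "uacr_spline")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ln(median uACR) at ln-uPCR lnx for a linear-kind model; extrapolate=TRUE
# extends the first/last segment equations beyond the stated domain (used by
# the synthetic generator as its ground truth).
.predict_ln_uacr <- function(model, lnx, extrapolate = FALSE) {
  segs <- model$segments
  upcr <- exp(lnx)
  idx <- findInterval(upcr, segs$lo, rightmost.closed = FALSE)
  idx[upcr >= segs$hi[nrow(segs)]] <- nrow(segs)  # domain top is inclusive
  idx[idx < 1] <- 1
  if (!extrapolate) {
    dom <- model$domain_mg
    if (any(upcr < dom[1] | upcr > dom[2])) {
      stop("prediction outside the model domain [", dom[1], ", ", dom[2],
           "] mg/gCr; no extrapolation by default")
    }
  }
  segs$intercept[idx] + segs$slope[idx] * lnx
}

#' Predict the median uACR from uPCR
#'
#' Evaluates the piecewise log-linear calibration:
#' `exp(intercept + slope * ln(uPCR))` in the segment covering the query.
#' The query must lie in the model's stated domain; there is no
#' extrapolation.
#'
#' @param model A linear-kind `uacr_spline`.
#' @param upcr_mg uPCR in mg/gCr (positive, vectorised).
#' @return Predicted median uACR, mg/gCr.
#' @examples
#' m <- load_calibration("all")
#' predict_median_uacr(m, 150)  # ~78 mg/gCr
#' @export
predict_median_uacr <- function(model, upcr_mg) {
  stopifnot(inherits(model, "uacr_spline"))
  if (model$kind != "linear") {
    stop("predict_median_uacr(): segment-wise prediction requires a linear-kind model")
  }
  if (any(upcr_mg <= 0)) stop("predict_median_uacr(): uPCR must be positive")
  exp(.predict_ln_uacr(model, log(upcr_mg)))
}

#' Invert the calibration: uPCR at a target median uACR
#'
#' Solves `predict_median_uacr(model, x) = target` in closed form
#' segment-by-segment. The model must be piecewise monotone increasing
#' (every slope positive) and the target inside the predicted range.
#'
#' @param model A linear-kind `uacr_spline`.
#' @param target_uacr Target median uACR, mg/gCr.
#' @return uPCR in mg/gCr.
#' @examples
#' invert_median_uacr(load_calibration("all"), 30) / 1000  # ~0.077 g/gCr
#' @export
invert_median_uacr <- function(model, target_uacr) {
  stopifnot(inherits(model, "uacr_spline"), length(target_uacr) == 1)
  if (model$kind != "linear") stop("invert_median_uacr(): linear-kind model required")
  segs <- model$segments
  if (any(segs$slope <= 0)) {
    stop("invert_median_uacr(): model not monotone increasing in segment(s) ",
         paste(which(segs$slope <= 0), collapse = ", "))
  }
  dom <- model$domain_mg
  lo_val <- exp(.predict_ln_uacr(model, log(dom[1])))
  hi_val <- exp(.predict_ln_uacr(model, log(dom[2])))
  if (target_uacr < lo_val || target_uacr > hi_val) {
    stop(sprintf(
      "invert_median_uacr(): target %.3g outside predicted range [%.3g, %.3g]",
      target_uacr, lo_val, hi_val))
  }
  lnt <- log(target_uacr)
  for (j in seq_len(nrow(segs))) {
    x <- exp((lnt - segs$intercept[j]) / segs$slope[j])
    seg_lo <- max(segs$lo[j], dom[1])
    seg_hi <- min(segs$hi[j], dom[2])
    if (x >= seg_lo - 1e-9 && x <= seg_hi + 1e-9) return(x)
  }
  stop("invert_median_uacr(): no segment solved the target (discontinuous model?)")
}
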