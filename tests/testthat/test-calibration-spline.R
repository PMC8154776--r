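test_that("bin summaries use nearest-label bins and interpolated quartiles", {
  b <- bin_summaries(rep(0.09, 3), c(10, 20, 30))
  expect_equal(nrow(b), 1)
  expect_equal(b$median_uacr, 20)
  expect_equal(c(b$q1, b$q3), c(15, 25))  # type-7 on 3 points

  single <- bin_summaries(0.05, 30)
  expect_equal(c(single$median_uacr, single$q1, single$q3), c(30, 30, 30))

  # membership by rounding to the nearest 0.01
  b2 <- bin_summaries(c(0.054, 0.056), c(1, 2))
  expect_equal(b2$upcr_g, c(0.05, 0.06))
  expect_error(bin_summaries(numeric(0), numeric(0)), "empty")
})

test_that("standard knots sit at the documented percentiles", {
  v <- 1:100
  expect_equal(standard_knots(v, 3),
               unname(stats::quantile(v, c(.10, .50, .90), type = 7)))
  expect_equal(standard_knots(v, 4),
               unname(stats::quantile(v, c(.05, .35, .65, .95), type = 7)))
  expect_equal(standard_knots(v, 5),
               unname(stats::quantile(v, c(.05, .275, .50, .725, .95), type = 7)))
  expect_error(standard_knots(rep(1, 50), 3), "increasing")
})

test_that("linear spline interpolates exact broken lines and matches the OLS oracle", {
  # exact 2-segment broken line: slopes 0.5 then 2, knot at x = e^3
  kn <- exp(3)
  f <- function(x) ifelse(x <= 3, 1 + 0.5 * x, 1 + 0.5 * 3 + 2 * (x - 3))
  x <- seq(1, 5, by = 0.25)
  fit <- suppressWarnings(fit_linear_spline(x, f(x), kn))  # exact fit
  expect_equal(fit$segments$slope, c(0.5, 2), tolerance = 1e-8)
  expect_lt(fit$rss, 1e-16)

  # noisy set, 1 knot: coefficients equal the normal-equation solution
  set.seed(42)
  xn <- stats::runif(30, 0, 6)
  yn <- f(xn) + stats::rnorm(30, 0, 0.3)
  fit2 <- fit_linear_spline(xn, yn, kn)
  X <- cbind(1, pmin(xn, 3), pmax(xn - 3, 0))
  expect_equal(unname(fit2$coef), unname(oracle_ols(X, yn)), tolerance = 1e-8)

  # continuity at every knot for a refit model
  set.seed(43)
  xr <- log(exp(stats::runif(200, log(5), log(480))))
  yr <- 0.5 + 0.9 * xr + stats::rnorm(200, 0, 0.2)
  fitr <- fit_linear_spline(xr, yr, c(20, 60, 120, 350))
  segs <- fitr$segments
  for (j in seq_len(nrow(segs) - 1)) {
    lnk <- log(segs$hi[j])
    expect_equal(segs$intercept[j] + segs$slope[j] * lnk,
                 segs$intercept[j + 1] + segs$slope[j + 1] * lnk,
                 tolerance = 1e-8)
  }
  expect_error(fit_linear_spline(c(1, 2), c(1, 2), exp(c(3, 4))), "segment")
})

test_that("restricted cubic spline nests the straight line and matches its basis formula", {
  x <- seq(0, 10, by = 0.5)
  y <- 2 + 0.7 * x
  kn_mg <- exp(c(2, 5, 8))
  fit <- suppressWarnings(fit_restricted_cubic_spline(x, y, kn_mg))  # exact fit
  expect_lt(fit$rss, 1e-16)
  expect_equal(unname(fit$basis_coefficients[2]), 0.7, tolerance = 1e-8)
  expect_equal(unname(fit$basis_coefficients[3]), 0, tolerance = 1e-8)

  # truncated-power basis value checked by hand at a point beyond all knots
  kn <- c(2, 5, 8)
  xx <- 9.5
  hand <- ((xx - 2)^3 - (xx - 5)^3 * (8 - 2) / (8 - 5) +
             (xx - 8)^3 * (5 - 2) / (8 - 5)) / (8 - 2)^2
  B <- microalb:::.rcs_basis(xx, kn)
  expect_equal(unname(B[1, 2]), hand, tolerance = 1e-12)
  expect_error(fit_restricted_cubic_spline(x, y, exp(c(2, 5))), "3 knots")
})

test_that("AIC follows the Gaussian OLS definition and straight-line data picks the smallest k", {
  set.seed(12)
  raw <- exp(stats::rnorm(400, 4.4, 0.9))
  x <- log(raw)
  y <- 1 + 0.8 * x + stats::rnorm(400, 0, 0.1)
  sel <- select_knot_count(x, y, raw, kind = "linear")
  expect_equal(sel$best_k, 3)
  for (k in c(3, 4, 5)) {
    f <- sel$fits[[paste0("k", k)]]
    expect_equal(f$aic, length(x) * log(f$rss / length(x)) + 2 * (f$p + 1))
  }
})

test_that("slope-change inference matches a contrast-vector computation", {
  set.seed(5)
  x <- stats::runif(80, 0, 10)
  kn <- exp(c(3, 6))
  y <- 1 + 0.5 * pmin(x, 3) + 1.5 * pmin(pmax(x - 3, 0), 3) +
    0.8 * pmax(x - 6, 0) + stats::rnorm(80, 0, 0.4)
  fit <- fit_linear_spline(x, y, kn)
  sc <- slope_change_tests(fit)
  expect_equal(nrow(sc), 2)
  expect_equal(sc$difference,
               diff(fit$segments$slope)[1:2], tolerance = 1e-12)
  # independent GLS-style contrast on the lm fit
  X <- cbind(1, pmin(x, 3), pmin(pmax(x - 3, 0), 3), pmax(x - 6, 0))
  lmfit <- stats::lm(y ~ X - 1)
  V <- stats::vcov(lmfit)
  cv <- c(0, -1, 1, 0)
  expect_equal(sc$se[1], sqrt(drop(t(cv) %*% V %*% cv)), tolerance = 1e-8)
  expect_equal(sc$t[1], sc$difference[1] / sc$se[1])
  # equal slopes give difference 0, p 1
  y0 <- 2 + 0.7 * x
  fit0 <- suppressWarnings(fit_linear_spline(x, y0, kn))
  sc0 <- slope_change_tests(fit0)
  expect_equal(sc0$difference, c(0, 0), tolerance = 1e-8)
  expect_true(all(sc0$p > 0.99))
})

test_that("the published calibrations evaluate and invert to the printed values", {
  all_m <- load_calibration("all")
  nd <- load_calibration("non_diabetic")
  dm <- load_calibration("diabetic")
  expect_equal(round(predict_median_uacr(all_m, 150)), 78)
  expect_equal(round(predict_median_uacr(all_m, 500)), 297)
  expect_equal(round(predict_median_uacr(nd, 500)), 313)
  expect_equal(round(predict_median_uacr(dm, 150)), 67)
  expect_equal(round(predict_median_uacr(dm, 500)), 306)
  expect_equal(round(invert_median_uacr(all_m, 30) / 1000, 3), 0.077)
  expect_equal(round(invert_median_uacr(nd, 30) / 1000, 3), 0.075)
  expect_equal(round(invert_median_uacr(dm, 30) / 1000, 3), 0.075)
  # printed segment equations agree at the knot on the ln scale
  s <- all_m$segments
  expect_equal(s$intercept[2] + s$slope[2] * log(60), 3.021, tolerance = 5e-4)
  expect_equal(s$intercept[3] + s$slope[3] * log(60), 3.021, tolerance = 5e-4)
  # slope-change arithmetic from the printed coefficients
  expect_equal(round(s$slope[3] - s$slope[2], 2), 0.93)
  expect_error(predict_median_uacr(all_m, 600), "domain")
  expect_error(invert_median_uacr(all_m, 1e5), "range")
})

test_that("prediction and inversion are exact inverses on monotone models", {
  m <- load_calibration("non_diabetic")
  for (x in c(2, 15, 20, 45, 60, 99, 120, 300, 350, 480)) {
    expect_equal(invert_median_uacr(m, predict_median_uacr(m, x)), x,
                 tolerance = 1e-8)
  }
  # identity model: one segment, intercept 0, slope 1
  ident <- structure(list(
    kind = "linear", knots_mg = numeric(0),
    segments = tibble::tibble(lo = 0, hi = Inf, intercept = 0, slope = 1),
    vcov = NULL, domain_mg = c(1, 1e6), population = "identity"),
    class = "uacr_spline")
  expect_equal(predict_median_uacr(ident, 123.4), 123.4)
})
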