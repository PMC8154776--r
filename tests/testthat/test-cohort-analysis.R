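test_that("discriminator sums and labels are assembled correctly", {
  upcr <- rbind(c(0.05, 0.08, 0.10), c(0.30, 0.25, 0.28))
  uacr <- rbind(c(12, 45, 38), c(5, 8, 11))
  ds <- build_discriminators(make_patients(upcr, uacr))
  expect_equal(ds$upcr123[1], 0.23)
  expect_equal(ds$upcr12[2], 0.55)
  expect_equal(ds$label, c(TRUE, FALSE))  # (12,45,38) is micro
  # permuting visit order changes the single uPCRs but not sum or label
  perm <- build_discriminators(make_patients(upcr[, c(2, 3, 1)],
                                             uacr[, c(2, 3, 1)]))
  expect_equal(perm$upcr123, ds$upcr123)
  expect_equal(perm$label, ds$label)
  expect_false(isTRUE(all.equal(perm$upcr1, ds$upcr1)))
})

test_that("uACR threshold table is exact under a deterministic relation", {
  # uACR = 500 * uPCR exactly: the cutoff solves 500 * CO = X and AUC is 1
  upcr <- (1:40) / 100
  records <- tibble::tibble(upcr = upcr, uacr = 500 * upcr)
  tab <- uacr_threshold_table(records, thresholds = c(50, 100, 150))
  expect_equal(tab$auc, rep(1, 3))
  expect_equal(tab$cutoff, c(50, 100, 150) / 500)
  # n(>= X) is non-increasing in X
  expect_true(all(diff(tab$n_pos) <= 0))
  # single-class threshold rows are flagged, not computed
  tab2 <- uacr_threshold_table(records, thresholds = c(50, 1000))
  expect_true(tab2$flagged[2])
  expect_true(is.na(tab2$auc[2]))
})

test_that("cutoffs rise with the uACR threshold under a monotone truth", {
  set.seed(12)
  n <- 600
  upcr <- exp(stats::rnorm(n, -2.6, 0.8))
  uacr <- 500 * upcr * exp(stats::rnorm(n, 0, 0.5))
  tab <- uacr_threshold_table(tibble::tibble(upcr = upcr, uacr = uacr),
                              thresholds = seq(10, 150, 10))
  fit <- stats::lm(tab$cutoff ~ tab$uacr_threshold)
  expect_gt(unname(stats::coef(fit)[2]), 0)  # trend is upward
  expect_true(all(diff(tab$n_pos) <= 0))
})

test_that("microalbuminuria discrimination covers all ten discriminators", {
  set.seed(23)
  n <- 60
  # dominant patient-level signal so any single visit nearly determines the
  # repeated-measurement label (the label-leakage situation of the uACR rows)
  mu <- stats::rnorm(n, -2.6, 0.7)
  upcr <- exp(matrix(mu, n, 3) + matrix(stats::rnorm(3 * n, 0, 0.25), n, 3))
  uacr <- 450 * exp(matrix(mu, n, 3)) *
    matrix(exp(stats::rnorm(3 * n, 0, 0.15)), n, 3)
  ds <- build_discriminators(make_patients(upcr, uacr))
  res <- microalbuminuria_discrimination(ds)
  expect_equal(nrow(res$table), 10)
  expect_equal(nrow(res$pairwise), choose(10, 2))
  # uACR discriminators of a uACR-defined label approach AUC 1
  expect_gt(res$table$auc[res$table$discriminator == "2uACR"], 0.95)
  # the triple sum averages visit noise: at least as good as the worst single
  singles <- res$table$auc[res$table$discriminator %in%
                             c("1uPCR", "2uPCR", "3uPCR")]
  sum3 <- res$table$auc[res$table$discriminator == "1.2.3uPCR"]
  expect_gte(sum3, min(singles))
})

test_that("summed uPCR beats single uPCR under exchangeable visit noise", {
  # property over seeds: with a common patient signal and iid visit noise,
  # the triple sum's AUC is at least each single visit's AUC
  wins <- 0
  for (s in 1:5) {
    set.seed(100 + s)
    n <- 120
    mu <- stats::rnorm(n, -2.6, 0.6)
    upcr <- exp(matrix(mu, n, 3) + matrix(stats::rnorm(3 * n, 0, 0.45), n, 3))
    uacr <- 450 * exp(matrix(mu, n, 3)) *
      matrix(exp(stats::rnorm(3 * n, 0, 0.35)), n, 3)
    ds <- build_discriminators(make_patients(upcr, uacr))
    res <- microalbuminuria_discrimination(ds)$table
    singles <- res$auc[res$discriminator %in% c("1uPCR", "2uPCR", "3uPCR")]
    if (res$auc[res$discriminator == "1.2.3uPCR"] >= max(singles)) {
      wins <- wins + 1
    }
  }
  expect_gte(wins, 4)
})

test_that("subgroups partition the cohort and match the unstratified result", {
  set.seed(40)
  n <- 80
  upcr <- matrix(exp(stats::rnorm(3 * n, -2.6, 0.7)), ncol = 3)
  uacr <- 450 * upcr * matrix(exp(stats::rnorm(3 * n, 0, 0.4)), ncol = 3)
  ds <- build_discriminators(make_patients(
    upcr, uacr,
    age = sample(c(45, 70, 85), n, replace = TRUE),
    sex = sample(c("M", "F"), n, replace = TRUE),
    gfr = sample(c("G2", "G3b"), n, replace = TRUE)))
  for (ax in c("age", "sex", "gfr")) {
    sub <- subgroup_cutoffs(ds, ax)
    expect_equal(sum(sub$n), n)  # partition
  }
  # degenerate single-axis subgroup equals the whole cohort
  ds$sex <- "M"
  sub <- subgroup_cutoffs(ds, "sex")
  whole <- microalbuminuria_discrimination(ds)$table
  expect_equal(sub$auc[sub$subgroup == "M"],
               whole$auc[whole$discriminator == "2uPCR"])
  expect_true(is.na(sub$auc[sub$subgroup == "F"]) || sub$n[2] == 0)
})

test_that("GFR-dependent calibration shift raises the recovered cutoff", {
  # patients whose uACR|uPCR curve sits lower (later GFR stages) need a
  # higher uPCR to reach uACR 30, so the recovered cutoff is higher
  set.seed(55)
  n <- 150
  mk <- function(gain, gfr) {
    upcr <- matrix(exp(stats::rnorm(3 * n, -2.55, 0.6)), ncol = 3)
    uacr <- gain * upcr * matrix(exp(stats::rnorm(3 * n, 0, 0.45)), ncol = 3)
    make_patients(upcr, uacr, gfr = gfr)
  }
  ds <- build_discriminators(dplyr::bind_rows(mk(500, "G2"), mk(250, "G3b")))
  ds$patient_id <- sprintf("Q%04d", seq_len(nrow(ds)))
  sub <- subgroup_cutoffs(ds, "gfr")
  expect_gt(sub$cutoff[sub$subgroup == "G3b-4"],
            sub$cutoff[sub$subgroup == "G1-3a"])
})

test_that("distribution crosstab conserves marginals and supports the FP audit", {
  records <- tibble::tibble(
    upcr = c(0.10, 0.05, 0.20, 0.60, 0.08),
    uacr = c(50, 5, 250, 400, 15),
    gfr_category = c("G1", "G2", "G3b", "G4", "G3a"))
  ct <- distribution_crosstab(records)
  expect_equal(sum(ct$n), nrow(records))
  one <- ct[ct$gfr_stratum == "G1-3a" & ct$n > 0 &
              ct$uacr_band == "[30,60)", ]
  expect_equal(sum(one$n), 1)

  audit <- false_positive_audit(records, cutoff = 0.07)
  # positives at 0.07: rows 1,3,4,5; FP (uacr < 30): row 5 only, uacr 15 >= 10
  expect_equal(audit$n_false_positive, 1)
  expect_equal(audit$fraction, 1)
})

test_that("delta regression matches closed forms and handles exact lines", {
  n <- 20
  set.seed(61)
  upcr <- matrix(exp(stats::rnorm(3 * n, -2.8, 0.5)), ncol = 3)
  uacr <- cbind(500 * upcr[, 1], 500 * upcr[, 2], 500 * upcr[, 3])
  p <- make_patients(upcr, uacr)
  res <- delta_regression(p, split_at = 10)  # everyone in one split
  on_line <- res[res$pair == "2-1", ][1, ]
  expect_equal(on_line$slope, 500, tolerance = 1e-8)
  expect_equal(on_line$r, 1, tolerance = 1e-8)

  # noisy case against the closed-form oracle
  uacr2 <- uacr * matrix(exp(stats::rnorm(3 * n, 0, 0.2)), ncol = 3)
  p2 <- make_patients(upcr, uacr2)
  res2 <- delta_regression(p2, split_at = 10)  # everyone in one split
  dx <- p2$upcr2 - p2$upcr1
  dy <- p2$uacr2 - p2$uacr1
  want <- oracle_simple_regression(dx, dy)
  got <- res2[res2$pair == "2-1", ]
  expect_equal(got$slope, want$slope, tolerance = 1e-10)
  expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
  expect_equal(got$r, want$r, tolerance = 1e-10)
})
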