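test_that("ROC points match exhaustive confusion-matrix enumeration", {
  roc <- roc_points(toy_scores, toy_labels)
  for (i in seq_len(nrow(roc$points))) {
    t <- roc$points$threshold[i]
    expect_equal(roc$points$sensitivity[i],
                 mean(toy_scores[toy_labels] >= t))
    expect_equal(roc$points$specificity[i],
                 mean(toy_scores[!toy_labels] < t))
  }
  # a threshold at or below the minimum score gives Se 1, Sp 0
  low <- metrics_at_threshold(toy_scores, toy_labels, min(toy_scores))
  expect_equal(c(low$sensitivity, low$specificity, low$youden), c(1, 0, 0))
  # the sentinel above the max gives Se 0, Sp 1
  n <- nrow(roc$points)
  expect_equal(c(roc$points$sensitivity[n], roc$points$specificity[n]),
               c(0, 1))
  expect_error(roc_points(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC equals pair counting, trapezoidal area, and is tie/transform stable", {
  expect_equal(auc_mann_whitney(toy_scores, toy_labels)$auc, 5 / 6)
  expect_equal(auc_mann_whitney(rep(2, 6), c(1, 1, 0, 0, 0, 1))$auc, 0.5)
  expect_equal(auc_mann_whitney(toy_scores, !toy_labels)$auc, 1 - 5 / 6)

  set.seed(31)
  for (i in 1:20) {
    n <- sample(8:25, 1)
    scores <- sample(seq_len(12), n, replace = TRUE)  # ties likely
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    a <- auc_mann_whitney(scores, labels)$auc
    expect_equal(a, oracle_auc_pairs(scores, labels))
    expect_equal(roc_points(scores, labels)$auc, a)
    if (!any(duplicated(scores))) {
      expect_equal(a, oracle_auc_trapezoid(scores, labels))
    }
    # monotone transform invariance
    a2 <- auc_mann_whitney(exp(scores / 3), labels)$auc
    expect_equal(a2, a)
  }
})

test_that("AUC and DeLong variance agree with pROC on random instances", {
  skip_if_not_installed("pROC")
  set.seed(99)
  for (i in 1:10) {
    n <- 40
    labels <- c(rep(TRUE, 15), rep(FALSE, 25))
    scores <- stats::rnorm(n) + labels
    a <- auc_mann_whitney(scores, labels)
    pr <- suppressMessages(pROC::roc(labels, scores, direction = "<"))
    expect_equal(a$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
    expect_equal(a$se^2, as.numeric(pROC::var(pr)), tolerance = 1e-10)
  }
})

test_that("Youden cutoff equals the exhaustive scan with the larger-Sn tie-break", {
  # perfectly separated: J = 1 at the smallest positive score
  sep_scores <- c(1, 2, 3, 10, 11)
  sep_labels <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
  co <- youden_cutoff(roc_points(sep_scores, sep_labels))
  expect_equal(co$cutoff, 10)
  expect_equal(co$youden, 1)

  # engineered tie: two thresholds share J, the larger-Sn one wins
  tie_scores <- c(1, 2, 3, 4)
  tie_labels <- c(FALSE, TRUE, FALSE, TRUE)
  ct <- youden_cutoff(roc_points(tie_scores, tie_labels))
  or <- oracle_youden_scan(tie_scores, tie_labels)
  expect_equal(ct$cutoff, or$t)
  expect_equal(ct$sensitivity, or$sn)

  set.seed(17)
  for (i in 1:20) {
    n <- sample(10:30, 1)
    scores <- round(stats::rnorm(n), 1)
    labels <- stats::runif(n) < 0.4
    if (length(unique(labels)) < 2) next
    got <- youden_cutoff(roc_points(scores, labels))
    want <- oracle_youden_scan(scores, labels)
    expect_equal(got$cutoff, want$t)
    expect_equal(got$youden, want$j)
  }
})

test_that("fixed-threshold metrics satisfy the Youden identity", {
  set.seed(3)
  scores <- stats::rnorm(50); labels <- stats::runif(50) < 0.5
  for (t in c(-1, 0, 0.5)) {
    m <- metrics_at_threshold(scores, labels, t)
    expect_equal(m$youden, m$sensitivity + m$specificity - 1)
  }
})

test_that("paired DeLong test behaves under identity, symmetry, and matches pROC", {
  set.seed(8)
  labels <- c(rep(TRUE, 20), rep(FALSE, 30))
  a <- stats::rnorm(50) + labels
  b <- a * 0.5 + stats::rnorm(50, 0, 0.5) + labels

  self <- paired_auc_test(a, a, labels)
  expect_equal(self$delta, 0)
  expect_equal(self$p, 1)

  ab <- paired_auc_test(a, b, labels)
  ba <- paired_auc_test(b, a, labels)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$p, ba$p)
  expect_error(paired_auc_test(a[-1], b, labels), "length")

  skip_if_not_installed("pROC")
  pr <- suppressMessages(pROC::roc.test(
    pROC::roc(labels, a, direction = "<", quiet = TRUE),
    pROC::roc(labels, b, direction = "<", quiet = TRUE),
    method = "delong", paired = TRUE))
  expect_equal(ab$p, as.numeric(pr$p.value), tolerance = 1e-10)
})

test_that("paired DeLong variance is consistent with a seeded bootstrap", {
  set.seed(21)
  labels <- c(rep(TRUE, 25), rep(FALSE, 35))
  a <- stats::rnorm(60) + 1.2 * labels
  b <- stats::rnorm(60) + 0.8 * labels
  got <- paired_auc_test(a, b, labels)
  boot <- replicate(4000, {
    idx_p <- sample(which(labels), replace = TRUE)
    idx_n <- sample(which(!labels), replace = TRUE)
    idx <- c(idx_p, idx_n)
    auc_mann_whitney(a[idx], labels[idx])$auc -
      auc_mann_whitney(b[idx], labels[idx])$auc
  })
  expect_equal(stats::var(boot), got$se^2, tolerance = 0.10)
})
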