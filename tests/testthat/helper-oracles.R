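# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: brute-force enumeration for ROC quantities,
# explicit normal equations for least squares, closed forms for
# correlation/regression.

# AUC by exhaustive pair counting over all positive-negative pairs
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# trapezoidal area under the empirical ROC polygon
oracle_auc_trapezoid <- function(scores, labels) {
  thr <- c(sort(unique(scores)), max(scores) + 1)
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  se <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  o <- order(fpr, se)
  fpr <- c(0, fpr[o], 1); se <- c(0, se[o], 1)
  sum(diff(fpr) * (utils::head(se, -1) + utils::tail(se, -1)) / 2)
}

# exhaustive Youden scan over all candidate thresholds with the
# larger-sensitivity (lower-threshold) tie-break
oracle_youden_scan <- function(scores, labels) {
  labels <- as.logical(labels)
  thr <- c(sort(unique(scores)), max(scores) + 1)
  best <- NULL
  for (t in thr) {
    sn <- mean(scores[labels] >= t)
    sp <- mean(scores[!labels] < t)
    j <- sn + sp - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && sn > best$sn)) {
      best <- list(t = t, sn = sn, sp = sp, j = j)
    }
  }
  best
}

# OLS coefficients by explicit normal equations on a design matrix
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# closed-form simple regression slope/intercept and Pearson r
oracle_simple_regression <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  list(slope = slope,
       intercept = mean(y) - slope * mean(x),
       r = sum((x - mean(x)) * (y - mean(y))) /
         sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))
}

# small labelled score set used in several ROC tests
toy_scores <- c(3, 5, 1, 2, 4)
toy_labels <- c(TRUE, TRUE, FALSE, FALSE, FALSE)

# minimal three-visit cohort builder for classification tests: one row per
# visit, uACR/uPCR supplied directly
make_patients <- function(upcr, uacr, age = 60, sex = "M", diabetes = FALSE,
                          gfr = "G2") {
  n <- nrow(upcr)
  tibble::tibble(
    patient_id = sprintf("T%03d", seq_len(n)),
    age = age, sex = sex, diabetes = diabetes,
    upcr1 = upcr[, 1], upcr2 = upcr[, 2], upcr3 = upcr[, 3],
    uacr1 = uacr[, 1], uacr2 = uacr[, 2], uacr3 = uacr[, 3],
    mean_egfr = 70,
    gfr_category = gfr,
    albuminuria = vapply(seq_len(n), function(i)
      classify_albuminuria_patient(uacr[i, ]), character(1))
  )
}
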