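# Empirical ROC machinery. Convention throughout: a subject is called
# positive when its score is >= the threshold, so lower thresholds give
# higher sensitivity; among Youden ties the lower threshold (larger Sn) wins.

.check_labels <- function(labels) {
  labels <- as.logical(labels)
  if (any(is.na(labels))) stop("labels must be interpretable as logical")
  if (length(unique(labels)) < 2) {
    stop("both classes must be present to build an ROC curve")
  }
  labels
}

# DeLong structural components: V10[i] over positives, V01[j] over negatives
.delong_components <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  v10 <- vapply(pos, function(s) mean((s > neg) + 0.5 * (s == neg)), numeric(1))
  v01 <- vapply(neg, function(s) mean((pos > s) + 0.5 * (pos == s)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Mann-Whitney AUC with DeLong standard error
#'
#' AUC = P(score_pos > score_neg) + 0.5 P(tie) over all positive-negative
#' pairs, computed from ranks; the standard error uses the DeLong structural
#' components (the Hanley-McNeil estimator is available as an option).
#'
#' @param scores Numeric scores (higher = more disease-like).
#' @param labels Logical/0-1 class labels (TRUE = positive).
#' @param se_method `"delong"` (default) or `"hanley_mcneil"`.
#' @return List with `auc`, `se`, `n_pos`, `n_neg`.
#' @export
auc_mann_whitney <- function(scores, labels, se_method = c("delong", "hanley_mcneil")) {
  se_method <- match.arg(se_method)
  labels <- .check_labels(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  r <- rank(scores)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  if (se_method == "delong") {
    comp <- .delong_components(scores, labels)
    v10 <- if (n_pos > 1) stats::var(comp$v10) else 0
    v01 <- if (n_neg > 1) stats::var(comp$v01) else 0
    se <- sqrt(v10 / n_pos + v01 / n_neg)
  } else {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                  (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  }
  list(auc = auc, se = se, n_pos = n_pos, n_neg = n_neg)
}

#' Empirical ROC curve
#'
#' Thresholds are the unique observed scores plus a sentinel above the
#' maximum (sensitivity 0, specificity 1). Sensitivity and specificity are
#' computed at each threshold under the score >= threshold positive call.
#' The AUC, its DeLong standard error, a normal-approximation 95% CI and the
#' two-sided p value against AUC = 0.5 are attached.
#'
#' @inheritParams auc_mann_whitney
#' @return An object of class `microalb_roc`: list with `points` (tibble
#'   `threshold`, `sensitivity`, `specificity`, `youden`), `auc`, `se`,
#'   `ci`, `p`, `n_pos`, `n_neg`.
#' @export
roc_points <- function(scores, labels) {
  labels <- .check_labels(labels)
  if (any(!is.finite(scores))) stop("roc_points(): scores must be finite")
  thr <- c(sort(unique(scores)), max(scores) + 1)
  pos <- scores[labels]; neg <- scores[!labels]
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  a <- auc_mann_whitney(scores, labels)
  z <- if (a$se > 0) (a$auc - 0.5) / a$se else Inf * sign(a$auc - 0.5)
  structure(list(
    points = tibble::tibble(threshold = thr, sensitivity = sens,
                            specificity = spec,
                            youden = sens + spec - 1),
    auc = a$auc, se = a$se,
    ci = c(max(0, a$auc - 1.96 * a$se), min(1, a$auc + 1.96 * a$se)),
    p = 2 * stats::pnorm(-abs(z)),
    n_pos = a$n_pos, n_neg = a$n_neg
  ), class = "microalb_roc")
}

#' @export
print.microalb_roc <- function(x, ...) {
  cat(sprintf("Empirical ROC: %d pos / %d neg, AUC %.3f (SE %.3f, 95%% CI %.3f-%.3f)\n",
              x$n_pos, x$n_neg, x$auc, x$se, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Youden-index optimal cutoff
#'
#' Returns the threshold maximising J = sensitivity + specificity - 1.
#' When several thresholds tie on J, the one with the larger sensitivity
#' (i.e. the lowest threshold) is adopted.
#'
#' @param roc A `microalb_roc` from [roc_points()].
#' @return Tibble row: `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "microalb_roc"))
  pts <- roc$points
  jmax <- max(pts$youden)
  cand <- pts[pts$youden >= jmax - 1e-12, ]
  best <- cand[which.max(cand$sensitivity), ]  # ties: larger Sn = lower threshold
  tibble::tibble(cutoff = best$threshold, sensitivity = best$sensitivity,
                 specificity = best$specificity, youden = best$youden)
}

#' Sensitivity, specificity and Youden index at a fixed threshold
#'
#' @inheritParams auc_mann_whitney
#' @param threshold The fixed threshold (positive call: score >= threshold).
#' @return Tibble row: `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @export
metrics_at_threshold <- function(scores, labels, threshold) {
  labels <- .check_labels(labels)
  sn <- mean(scores[labels] >= threshold)
  sp <- mean(scores[!labels] < threshold)
  tibble::tibble(cutoff = threshold, sensitivity = sn, specificity = sp,
                 youden = sn + sp - 1)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors measured on the same subjects
#' (paired design) using the covariance of the DeLong structural
#' components; two-sided normal p value.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Common class labels.
#' @return Tibble row: `auc_a`, `auc_b`, `delta`, `se`, `z`, `p`.
#' @export
paired_auc_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) {
    stop("paired_auc_test(): score vectors must have the same length")
  }
  labels <- .check_labels(labels)
  ca <- .delong_components(scores_a, labels)
  cb <- .delong_components(scores_b, labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  d10 <- ca$v10 - cb$v10
  d01 <- ca$v01 - cb$v01
  v <- (if (n_pos > 1) stats::var(d10) else 0) / n_pos +
    (if (n_neg > 1) stats::var(d01) else 0) / n_neg
  delta <- ca$auc - cb$auc
  z <- if (v > 0) delta / sqrt(v) else 0
  p <- if (v > 0) 2 * stats::pnorm(-abs(z)) else 1
  tibble::tibble(auc_a = ca$auc, auc_b = cb$auc, delta = delta,
                 se = sqrt(v), z = z, p = p)
}

#' Write an ROC table to CSV
#'
#' Columns: threshold, sensitivity, specificity, youden.
#'
#' @param roc A `microalb_roc`.
#' @param path Output CSV path.
#' @export
write_roc_csv <- function(roc, path) {
  stopifnot(inherits(roc, "microalb_roc"))
  utils::write.csv(roc$points, path, row.names = FALSE)
  invisible(path)
}
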