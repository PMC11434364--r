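# ROC cutoff analysis for visceral-obesity biomarkers.

# DeLong variance of the empirical AUC via placement values.
delong_ci <- function(pos, neg, auc, level = 0.95) {
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)),
                numeric(1))
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)),
                numeric(1))
  var_auc <- stats::var(v10) / length(pos) + stats::var(v01) / length(neg)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(max(var_auc, 0))
  c(max(0, auc - z * se), min(1, auc + z * se))
}

#' ROC curve, AUC with DeLong interval, and Youden-optimal cutoff
#'
#' Builds the empirical ROC over all observed thresholds (predicting
#' positive when the value is at or above the threshold; higher values
#' indicate the positive class), computes the trapezoidal AUC (identical to
#' the Mann-Whitney `U/(n1*n2)` with midrank ties), a DeLong confidence
#' interval, and the cutoff maximizing Youden's
#' `J = sensitivity + specificity - 1` (ties resolved toward the lower
#' threshold). Sensitivity, specificity and the predictive values at the
#' sample prevalence are reported in percent.
#'
#' @param values numeric marker values, one per subject.
#' @param labels logical (or 0/1) vector; `TRUE` marks the positive class.
#' @param level confidence level of the AUC interval.
#' @return an object of class `roc_result`: `auc`, `auc_ci`, `cutoff`,
#'   `sensitivity`, `specificity`, `ppv`, `npv` (percent), `curve`
#'   (data.frame of `fpr`, `tpr`, `threshold`), `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(values, labels, level = 0.95) {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]
  labels <- as.logical(labels[ok])
  if (!any(labels) || all(labels)) {
    abort("both classes must be present", "urinmr_validation_error")
  }
  pos <- values[labels]
  neg <- values[!labels]
  n1 <- length(pos)
  n0 <- length(neg)

  thr <- sort(unique(values), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                      threshold = c(Inf, thr))
  if (curve$fpr[nrow(curve)] < 1 || curve$tpr[nrow(curve)] < 1) {
    curve <- rbind(curve, data.frame(fpr = 1, tpr = 1, threshold = -Inf))
  }
  auc <- sum(diff(curve$fpr) * (curve$tpr[-1] + curve$tpr[-nrow(curve)]) / 2)

  j <- tpr - fpr
  best <- which(j == max(j))
  best <- best[length(best)] # lowest threshold among ties
  cutoff <- thr[best]
  tp <- sum(pos >= cutoff); fn <- n1 - tp
  fp <- sum(neg >= cutoff); tn <- n0 - fp
  structure(
    list(auc = auc, auc_ci = delong_ci(pos, neg, auc, level), cutoff = cutoff,
         sensitivity = 100 * tp / n1, specificity = 100 * tn / n0,
         ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
         npv = if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_,
         curve = curve, n_pos = n1, n_neg = n0),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%.3f, %.3f), cutoff %.4g: sens %.0f%%, spec %.0f%%, PPV %.0f%%, NPV %.0f%%\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$cutoff,
              x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

#' Predictive values from sensitivity, specificity and group sizes
#'
#' Reconstructs the confusion table implied by a reported sensitivity and
#' specificity at the study's group sizes -- `TP = round(sens * n_pos)`,
#' `FP = round((1 - spec) * n_neg)` (conventional rounding, half away from
#' zero) -- and returns the positive and negative predictive values at the
#' sample prevalence, rounded to the nearest percent. When no subject tests
#' positive the PPV is undefined (`NA` with a flag).
#'
#' @param sensitivity,specificity percentages in `[0, 100]`.
#' @param n_pos,n_neg positive/negative class sizes (>= 1).
#' @return list with `ppv`, `npv` (percent), the implied `tp`, `fp`, `fn`,
#'   `tn`, and `ppv_defined`.
#' @examples
#' ppv_npv_from_accuracy(65, 69, 52, 23)  # PPV 83, NPV 47
#' @export
ppv_npv_from_accuracy <- function(sensitivity, specificity, n_pos, n_neg) {
  if (!is_number(sensitivity) || sensitivity < 0 || sensitivity > 100 ||
      !is_number(specificity) || specificity < 0 || specificity > 100) {
    abort("sensitivity and specificity must lie in [0, 100]",
          "urinmr_validation_error")
  }
  if (!is_count(n_pos) || !is_count(n_neg) || n_pos < 1 || n_neg < 1) {
    abort("group sizes must be integers >= 1", "urinmr_validation_error")
  }
  tp <- round_half_up(sensitivity / 100 * n_pos)
  fp <- round_half_up((1 - specificity / 100) * n_neg)
  fn <- n_pos - tp
  tn <- n_neg - fp
  ppv_defined <- (tp + fp) > 0
  list(
    ppv = if (ppv_defined) round_half_up(100 * tp / (tp + fp)) else NA_real_,
    npv = if (tn + fn > 0) round_half_up(100 * tn / (tn + fn)) else NA_real_,
    tp = tp, fp = fp, fn = fn, tn = tn, ppv_defined = ppv_defined
  )
}

#' Reference operating points of the urinary visceral-obesity markers
#'
#' Published accuracy metrics for the three urinary markers discriminating
#' visceral fat above 16 kg (52 subjects) from 9-16 kg (23 subjects):
#' AUC with confidence limits, the mg/mL cutoff, and sensitivity/specificity
#' at that cutoff. Bundled as worked-example inputs for
#' [ppv_npv_from_accuracy()].
#'
#' @return data.frame with one row per marker.
#' @export
reference_accuracy <- function() {
  data.frame(
    metabolite = c("Sarcosine", "Trigonelline", "Phenylalanine"),
    auc = c(0.654, 0.644, 0.644),
    ci_low = c(0.524, 0.518, 0.513),
    ci_high = c(0.783, 0.770, 0.775),
    cutoff_mg_ml = c(0.043, 0.068, 0.204),
    sensitivity = c(65, 46, 31),
    specificity = c(69, 87, 100),
    n_pos = 52L, n_neg = 23L,
    stringsAsFactors = FALSE
  )
}
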