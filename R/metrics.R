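#' One-vs-rest confusion counts for a category
#'
#' Treating each word token as one observation, counts tokens where the
#' category appears in both the reference and predicted sets (TP), only in
#' the predicted set (FP), only in the reference set (FN), or in neither
#' (TN). The four cells always sum to the total token count.
#'
#' @param aligned A [align()] result.
#' @param category Category id.
#' @return A list of class `textdx_confusion`: `category`, `tp`, `fp`,
#'   `fn`, `tn`, `n`.
#' @export
confusion <- function(aligned, category) {
  if (!category %in% colnames(aligned$ref)) {
    tdx_error(paste0("unknown category '", category, "'"),
              "textdx_data_error")
  }
  r <- aligned$ref[, category]
  p <- aligned$pred[, category]
  structure(
    list(category = category,
         tp = sum(r & p), fp = sum(!r & p),
         fn = sum(r & !p), tn = sum(!r & !p),
         n = length(r)),
    class = "textdx_confusion"
  )
}

#' @export
print.textdx_confusion <- function(x, ...) {
  cat("<textdx_confusion>", x$category,
      sprintf("tp=%d fp=%d fn=%d tn=%d (n=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$n))
  invisible(x)
}

confusion_counts <- function(category, tp, fp, fn, tn) {
  structure(list(category = category, tp = tp, fp = fp, fn = fn, tn = tn,
                 n = tp + fp + fn + tn),
            class = "textdx_confusion")
}

#' Binomial proportion with confidence interval
#'
#' Wilson score interval by default (well behaved for proportions near 0
#' or 1, e.g. specificity around 0.999); a Wald option is available.
#'
#' @param x Success count.
#' @param n Denominator (> 0).
#' @param method "wilson" or "wald".
#' @param conf Confidence level.
#' @return A list of class `textdx_proportion`: `value`, `ci_low`,
#'   `ci_high`, `n`, `method`.
#' @export
proportion_estimate <- function(x, n, method = c("wilson", "wald"),
                                conf = 0.95) {
  method <- match.arg(method)
  if (n <= 0L) {
    tdx_error("proportion undefined: zero denominator",
              "textdx_metric_error")
  }
  x <- as.numeric(x)  # avoid integer overflow in x * (n - x) at large n
  n <- as.numeric(n)
  p <- x / n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (method == "wilson") {
    centre <- (x + z^2 / 2) / (n + z^2)
    half <- z * sqrt(x * (n - x) / n + z^2 / 4) / (n + z^2)
    lo <- centre - half; hi <- centre + half
  } else {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- max(0, p - half); hi <- min(1, p + half)
  }
  structure(list(value = p, ci_low = lo, ci_high = hi, n = as.integer(n),
                 method = method, conf = conf),
            class = "textdx_proportion")
}

#' @export
print.textdx_proportion <- function(x, ...) {
  cat(sprintf("%.3f (%.3f-%.3f), n=%d [%s]\n",
              x$value, x$ci_low, x$ci_high, x$n, x$method))
  invisible(x)
}

metric_from_counts <- function(counts, num, denom, what, ...) {
  if (denom == 0L) {
    tdx_error(paste0(what, " undefined: zero denominator for category '",
                     counts$category, "'"), "textdx_metric_error")
  }
  proportion_estimate(num, denom, ...)
}

#' Diagnostic accuracy metrics from confusion counts
#'
#' Sensitivity (recall) tp/(tp+fn): the fraction of human-coded emotion
#' words the tagger also flags. Specificity tn/(tn+fp): the fraction of
#' non-emotion words left unflagged. PPV (precision) tp/(tp+fp): the
#' fraction of flagged words that human coders agree with. NPV
#' tn/(tn+fn): the fraction of unflagged words that are truly
#' non-emotion.
#'
#' @param counts A [confusion()] result.
#' @param ... Passed to [proportion_estimate()] (`method`, `conf`).
#' @return A `textdx_proportion`.
#' @export
sensitivity <- function(counts, ...) {
  metric_from_counts(counts, counts$tp, counts$tp + counts$fn,
                     "sensitivity", ...)
}

#' @rdname sensitivity
#' @export
specificity <- function(counts, ...) {
  metric_from_counts(counts, counts$tn, counts$tn + counts$fp,
                     "specificity", ...)
}

#' @rdname sensitivity
#' @export
ppv <- function(counts, ...) {
  metric_from_counts(counts, counts$tp, counts$tp + counts$fp, "PPV", ...)
}

#' @rdname sensitivity
#' @export
npv <- function(counts, ...) {
  metric_from_counts(counts, counts$tn, counts$tn + counts$fn, "NPV", ...)
}

#' F score (harmonic mean of precision and recall)
#'
#' `2 * ppv * sens / (ppv + sens)`; balances over-identification (poor
#' precision) against under-identification (poor recall).
#'
#' @param ppv Precision, in \[0, 1\] (a `textdx_proportion` is accepted).
#' @param sens Recall, in \[0, 1\].
#' @return A list of class `textdx_fscore`: `value`, `ppv`, `sensitivity`.
#' @export
#' @examples
#' f_score(0.326, 0.858)
f_score <- function(ppv, sens) {
  if (inherits(ppv, "textdx_proportion")) ppv <- ppv$value
  if (inherits(sens, "textdx_proportion")) sens <- sens$value
  if (ppv + sens <= 0) {
    tdx_error("F score undefined: PPV + sensitivity is 0",
              "textdx_metric_error")
  }
  structure(list(value = 2 * ppv * sens / (ppv + sens),
                 ppv = ppv, sensitivity = sens),
            class = "textdx_fscore")
}

#' @export
print.textdx_fscore <- function(x, ...) {
  cat(sprintf("F = %.3f (PPV %.3f, sensitivity %.3f)\n",
              x$value, x$ppv, x$sensitivity))
  invisible(x)
}

#' Pooled two-proportion z test
#'
#' z = (p1 - p2) / sqrt(phat (1 - phat) (1/n1 + 1/n2)) with phat the pooled
#' proportion; two-sided p-value from the standard normal.
#'
#' @param p1,p2 Proportions in \[0, 1\].
#' @param n1,n2 Denominators (> 0).
#' @param alpha Family-wise significance level.
#' @param m Number of comparisons in the Bonferroni family (1 = none).
#' @return A list of class `textdx_comparison`: `p1`, `p2`, `n1`, `n2`,
#'   `z`, `p_value`, `alpha_corrected`, `significant`.
#' @export
two_proportion_test <- function(p1, n1, p2, n2, alpha = 0.05, m = 1L) {
  stopifnot(n1 > 0, n2 > 0, p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  pooled <- (p1 * n1 + p2 * n2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1) {
    tdx_error("degenerate two-proportion test: pooled proportion is 0 or 1",
              "textdx_metric_error")
  }
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  p_value <- 2 * stats::pnorm(-abs(z))
  thr <- bonferroni(alpha, m)
  structure(list(p1 = p1, p2 = p2, n1 = n1, n2 = n2, z = z,
                 p_value = p_value, alpha_corrected = thr,
                 significant = p_value < thr),
            class = "textdx_comparison")
}

#' @export
print.textdx_comparison <- function(x, ...) {
  cat(sprintf("z = %.3f, p = %.4g (threshold %.4g)%s\n",
              x$z, x$p_value, x$alpha_corrected,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni(0.05, 6)   # .0083
#' bonferroni(0.05, 24)  # .0021
bonferroni <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Pearson correlations between two percentage tables
#'
#' Correlates per-participant category percentages across two sources
#' (e.g. a dictionary version against human coders), category pair by
#' category pair.
#'
#' @param tab_a,tab_b Long percentage tibbles (from
#'   [category_percentages()] or [reference_percentages()]) indexed by the
#'   same participants.
#' @return A matrix with rows = categories of `tab_a`, columns = categories
#'   of `tab_b`.
#' @export
pearson_correlation <- function(tab_a, tab_b) {
  wa <- tidyr::pivot_wider(tab_a[, c("participant_id", "category", "percentage")],
                           names_from = "category", values_from = "percentage")
  wb <- tidyr::pivot_wider(tab_b[, c("participant_id", "category", "percentage")],
                           names_from = "category", values_from = "percentage")
  if (!identical(sort(wa$participant_id), sort(wb$participant_id))) {
    tdx_error("percentage tables cover different participants",
              "textdx_data_error")
  }
  if (nrow(wa) < 3L) {
    tdx_error("need at least 3 participants for correlations",
              "textdx_data_error")
  }
  wb <- wb[match(wa$participant_id, wb$participant_id), ]
  ma <- as.matrix(wa[, -1, drop = FALSE])
  mb <- as.matrix(wb[, -1, drop = FALSE])
  const <- c(colnames(ma)[apply(ma, 2, stats::sd) == 0],
             colnames(mb)[apply(mb, 2, stats::sd) == 0])
  if (length(const) > 0L) {
    tdx_error(paste0("correlation undefined: constant column(s) ",
                     paste(unique(const), collapse = ", ")),
              "textdx_metric_error")
  }
  stats::cor(ma, mb)
}

#' Expected PPV from an operating point and prevalence
#'
#' Bayes' rule: PPV = sens * pi / (sens * pi + (1 - spec) (1 - pi)) with
#' pi the prevalence. Sensitivity and specificity are properties of the
#' tagger alone, but PPV depends on how common emotion words are in the
#' corpus being tagged — the same tagger yields lower precision on a less
#' emotionally expressive population.
#'
#' @param sens,spec,prevalence Values in \[0, 1\].
#' @return Expected PPV in \[0, 1\].
#' @export
#' @examples
#' ppv_from_prevalence(0.858, 0.967, 0.018)
ppv_from_prevalence <- function(sens, spec, prevalence) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1,
            prevalence >= 0, prevalence <= 1)
  denom <- sens * prevalence + (1 - spec) * (1 - prevalence)
  if (denom <= 0) {
    if (prevalence == 0) return(0)
    tdx_error("PPV undefined: no positive predictions expected",
              "textdx_metric_error")
  }
  sens * prevalence / denom
}
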