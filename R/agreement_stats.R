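# Chance-corrected agreement (Krippendorff's alpha, PABAK), confusion-matrix
# test performance and the temporal scenario (A-D) framework.

#' Krippendorff's alpha
#'
#' Coincidence-matrix form: for each unit with `m >= 2` pairable values, every
#' ordered value pair contributes `1/(m - 1)` to the coincidence matrix `o`;
#' with category marginals `n_c` and metric difference `d2`,
#' `alpha = 1 - (n - 1) * sum_{c<k} o_ck d2_ck / sum_{c<k} n_c n_k d2_ck`.
#' Nominal `d2` is 0/1; ordinal `d2_ck = (sum_{g=c..k} n_g - (n_c+n_k)/2)^2`
#' with categories in their sorted (ordinal) order. Missing cells simply
#' reduce `m`; units with fewer than two values contribute nothing.
#'
#' @param data units x raters matrix (or data frame) of categorical values,
#'   `NA` for missing cells. For the ordinal metric values must sort into
#'   their substantive order (e.g. integer codes).
#' @param metric `"nominal"` or `"ordinal"`.
#' @return alpha in `(-Inf, 1]`, or `NA` with a warning when the expected
#'   disagreement is zero (all pairable values in one category).
#' @examples
#' m <- cbind(r1 = c(1, 1, 2, 2), r2 = c(1, 2, 2, 2))
#' krippendorff_alpha(m, "nominal")
#' @export
krippendorff_alpha <- function(data, metric = c("nominal", "ordinal")) {
  metric <- match.arg(metric)
  m <- as.matrix(data)
  vals <- m[!is.na(m)]
  if (!length(vals)) {
    warning("alpha undefined: no values")
    return(NA_real_)
  }
  cats <- sort(unique(vals))
  k <- length(cats)
  ci <- matrix(match(m, cats), nrow = nrow(m))
  o <- matrix(0, k, k)
  for (u in seq_len(nrow(ci))) {
    vs <- ci[u, ]
    vs <- vs[!is.na(vs)]
    mu <- length(vs)
    if (mu < 2L) next
    w <- 1 / (mu - 1)
    tab <- tabulate(vs, nbins = k)
    # ordered pairs within the unit: counts tab[c]*tab[k] (minus self-pairs)
    o <- o + w * (outer(tab, tab) - diag(tab, nrow = k))
  }
  nc <- rowSums(o)
  n <- sum(nc)
  d2 <- switch(metric,
    nominal = 1 - diag(k),
    ordinal = {
      d <- matrix(0, k, k)
      for (a in seq_len(k)) for (b in seq_len(k)) {
        if (a != b) {
          lo <- min(a, b); hi <- max(a, b)
          d[a, b] <- (sum(nc[lo:hi]) - (nc[lo] + nc[hi]) / 2)^2
        }
      }
      d
    })
  upper <- upper.tri(d2)
  den <- sum(outer(nc, nc)[upper] * d2[upper])
  if (den <= 0) {
    warning("alpha undefined: zero expected disagreement")
    return(NA_real_)
  }
  1 - (n - 1) * sum(o[upper] * d2[upper]) / den
}

#' Bootstrap confidence interval for alpha
#'
#' Nonparametric percentile interval from resampling units (rows) with
#' replacement. Resamples on which alpha is undefined (degenerate category
#' distribution) are skipped and counted.
#'
#' @inheritParams krippendorff_alpha
#' @param n_boot number of resamples (default 2000).
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @return numeric `c(lo, hi)` with attributes `n_used` and `n_skipped`.
#' @export
alpha_bootstrap_ci <- function(data, metric = c("nominal", "ordinal"),
                               n_boot = 2000, seed = 1, level = 0.95) {
  metric <- match.arg(metric)
  m <- as.matrix(data)
  point <- krippendorff_alpha(m, metric)
  if (is.na(point)) stop("alpha undefined on the full data; no interval")
  set.seed(seed)
  n <- nrow(m)
  vals <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    vals[b] <- suppressWarnings(krippendorff_alpha(m[idx, , drop = FALSE], metric))
  }
  used <- vals[!is.na(vals)]
  if (!length(used)) stop("all bootstrap resamples degenerate")
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- unname(stats::quantile(used, probs, type = 7))
  attr(ci, "n_used") <- length(used)
  attr(ci, "n_skipped") <- n_boot - length(used)
  ci
}

#' Prevalence-adjusted bias-adjusted kappa
#'
#' `(k * Po - 1) / (k - 1)` for percent agreement `Po` over `k` categories.
#'
#' @param po observed percent agreement in `[0, 1]`.
#' @param k_categories number of categories (>= 2).
#' @return PABAK value.
#' @examples
#' pabak(0.75, 2) # 0.5
#' @export
pabak <- function(po, k_categories = 2) {
  if (k_categories < 2) stop("PABAK needs at least 2 categories")
  if (any(po < 0 | po > 1)) stop("Po must be in [0, 1]")
  (k_categories * po - 1) / (k_categories - 1)
}

#' Temporal agreement scenario of one encounter
#'
#' Compares the criteria-detected onset with the first expert sepsis label:
#' \describe{
#'   \item{A}{criteria not met and no sepsis label (agreement)}
#'   \item{B}{criteria onset within the `tau` hours before (or exactly at)
#'     the first sepsis label (timely agreement)}
#'   \item{C}{criteria overdue: lagging behind the label regardless of the
#'     time elapsed, or absent while a label exists}
#'   \item{D}{criteria untimely: preceding the label by more than `tau`
#'     hours, or met in the absence of any sepsis label}
#' }
#' The tolerance interval is closed at both ends.
#'
#' @param criteria_onset POSIXct or `NA`/`NULL` when criteria never met.
#' @param label_onset POSIXct or `NA`/`NULL` when no sepsis label.
#' @param tau_hours tolerance (default 24).
#' @return one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @export
classify_temporal_scenario <- function(criteria_onset, label_onset,
                                       tau_hours = 24) {
  has_c <- !is.null(criteria_onset) && !is.na(criteria_onset)
  has_l <- !is.null(label_onset) && !is.na(label_onset)
  if (!has_c && !has_l) return("A")
  if (!has_c) return("C")
  if (!has_l) return("D")
  co <- as.numeric(.as_ts(criteria_onset))
  lo <- as.numeric(.as_ts(label_onset))
  if (co > lo) return("C")
  if (co >= lo - tau_hours * 3600) return("B")
  "D"
}

#' 2x2 confusion table with derived test performance
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @return list of class `confusion_table` with the counts, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `po` (percent agreement); metrics are `NA`
#'   when their denominator is zero.
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  total <- tp + fp + fn + tn
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn, total = total,
    sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    ppv = safe(tp, tp + fp),
    npv = safe(tn, tn + fn),
    po = safe(tp + tn, total)
  ), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("tp %d  fp %d  fn %d  tn %d | sens %.3f spec %.3f ppv %.3f npv %.3f Po %.3f\n",
              x$tp, x$fp, x$fn, x$tn, x$sensitivity, x$specificity,
              x$ppv, x$npv, x$po))
  invisible(x)
}

#' Temporal confusion table from scenario assignments
#'
#' Maps scenarios to the 2x2 table: `tp = #B`, `tn = #A`, `fn = #C`,
#' `fp = #D` (untimely detections count as false positives even in
#' label-positive encounters, which makes the sensitivity `B/(B+C)` exceed
#' the positive class agreement `B/(all label-positive)`; the alternative
#' mapping that sends label-positive D to `fn` is available via
#' `untimely_positive`). Class agreements use the label-positive and
#' label-negative encounter counts as denominators.
#'
#' @param scenario character vector of `"A"`/`"B"`/`"C"`/`"D"` per encounter.
#' @param label_present logical vector: encounter has a sepsis label.
#' @param untimely_positive `"fp"` (default) or `"fn"`: where label-positive
#'   scenario-D encounters are counted.
#' @return list with `counts` (named A--D), the `confusion_table`,
#'   `positive_class_agreement`, `negative_class_agreement`.
#' @export
temporal_confusion <- function(scenario, label_present,
                               untimely_positive = c("fp", "fn")) {
  untimely_positive <- match.arg(untimely_positive)
  stopifnot(length(scenario) == length(label_present))
  if (!length(scenario)) stop("empty cohort: temporal agreement undefined")
  stopifnot(all(scenario %in% c("A", "B", "C", "D")))
  counts <- c(A = sum(scenario == "A"), B = sum(scenario == "B"),
              C = sum(scenario == "C"), D = sum(scenario == "D"))
  d_pos <- sum(scenario == "D" & label_present)
  fn_extra <- if (untimely_positive == "fn") d_pos else 0L
  ct <- confusion_table(tp = counts[["B"]],
                        fp = counts[["D"]] - fn_extra,
                        fn = counts[["C"]] + fn_extra,
                        tn = counts[["A"]])
  n_pos <- sum(label_present); n_neg <- sum(!label_present)
  list(counts = counts, table = ct, d_label_positive = d_pos,
       positive_class_agreement = if (n_pos > 0) counts[["B"]] / n_pos else NA_real_,
       negative_class_agreement = if (n_neg > 0) counts[["A"]] / n_neg else NA_real_)
}

#' Dichotomous encounter-level agreement
#'
#' Treats "criteria ever met" and "sepsis label ever present" as two ratings
#' of each encounter: standard 2x2 tabulation plus nominal Krippendorff's
#' alpha between the two.
#'
#' @param criteria_met,label_present logical vectors, one element per
#'   encounter.
#' @return list with the `confusion_table` and `alpha`.
#' @export
dichotomous_confusion <- function(criteria_met, label_present) {
  stopifnot(length(criteria_met) == length(label_present))
  ct <- confusion_table(
    tp = sum(criteria_met & label_present),
    fp = sum(criteria_met & !label_present),
    fn = sum(!criteria_met & label_present),
    tn = sum(!criteria_met & !label_present))
  a <- suppressWarnings(
    krippendorff_alpha(cbind(as.integer(criteria_met),
                             as.integer(label_present)), "nominal"))
  list(table = ct, alpha = a)
}
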