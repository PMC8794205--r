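# Detection/quantification thresholds, tiered pass/fail criteria,
# precision (RSD) and Bland-Altman comparability statistics.

#' Detection and quantification thresholds
#'
#' Defaults: relative-abundance detection threshold 0.1%, quantification
#' threshold 1%, minimum chromatographic S/N 3, minimum signal intensity
#' 50 counts.
#'
#' @param detection_pct,quantification_pct Relative-abundance thresholds
#'   in percent; detection must be below quantification.
#' @param min_sn,min_intensity Peak-level detection gates.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(detection_pct = 0.1, quantification_pct = 1.0,
                          min_sn = 3, min_intensity = 50) {
  if (detection_pct >= quantification_pct) {
    stop("detection threshold must be below quantification threshold")
  }
  structure(list(detection_pct = detection_pct,
                 quantification_pct = quantification_pct,
                 min_sn = min_sn, min_intensity = min_intensity),
            class = "qc_thresholds")
}

#' Tiered variation criteria
#'
#' Allowed variation is a multiple of the reference standard deviation,
#' tiered by the reference relative abundance: 2x SD below 5%, 1.5x SD
#' between 5 and 15% (closed interval), 1x SD above 15%.
#'
#' @param boundaries Tier boundaries in percent (default `c(5, 15)`).
#' @param multipliers SD multipliers for the low/mid/high tiers (default
#'   `c(2, 1.5, 1)`), decreasing with abundance.
#' @return A `tier_criteria` list.
#' @export
tier_criteria <- function(boundaries = c(5, 15), multipliers = c(2, 1.5, 1)) {
  stopifnot(length(boundaries) == 2, length(multipliers) == 3,
            boundaries[1] < boundaries[2])
  if (is.unsorted(rev(multipliers))) {
    stop("multipliers must decrease with abundance tier")
  }
  structure(list(boundaries = boundaries, multipliers = multipliers),
            class = "tier_criteria")
}

#' Classify a relative abundance
#'
#' @param abundance Relative abundance in percent (>= 0).
#' @param thresholds A [qc_thresholds()].
#' @return `"not_detected"` (< detection), `"detected"` (detectable but not
#'   quantifiable) or `"quantifiable"`.
#' @export
classify_abundance <- function(abundance, thresholds = qc_thresholds()) {
  stopifnot(all(abundance >= 0))
  ifelse(abundance < thresholds$detection_pct, "not_detected",
         ifelse(abundance < thresholds$quantification_pct, "detected",
                "quantifiable"))
}

#' Tier multiplier for a reference abundance
#'
#' @param ref_abundance Reference relative abundance in percent.
#' @param tiers A [tier_criteria()].
#' @return The SD multiplier of the tier containing `ref_abundance`.
#' @export
tier_multiplier <- function(ref_abundance, tiers = tier_criteria()) {
  stopifnot(all(ref_abundance >= 0))
  ifelse(ref_abundance > tiers$boundaries[2], tiers$multipliers[3],
         ifelse(ref_abundance >= tiers$boundaries[1], tiers$multipliers[2],
                tiers$multipliers[1]))
}

#' Tiered pass/fail verdict
#'
#' A measurement passes when it lies within `tier_multiplier(mean) * sd`
#' of the reference mean.
#'
#' @param value Measured relative abundance (%).
#' @param ref_mean,ref_sd Reference mean and standard deviation (%).
#' @param tiers A [tier_criteria()].
#' @return List with `verdict` ("pass"/"fail"), `lower`, `upper`,
#'   `multiplier`.
#' @export
pass_fail <- function(value, ref_mean, ref_sd, tiers = tier_criteria()) {
  stopifnot(ref_sd >= 0)
  m <- tier_multiplier(ref_mean, tiers)
  if (ref_sd == 0) {
    warning("reference SD is zero; pass requires exact equality")
  }
  lower <- ref_mean - m * ref_sd
  upper <- ref_mean + m * ref_sd
  list(verdict = if (abs(value - ref_mean) <= m * ref_sd) "pass" else "fail",
       lower = lower, upper = upper, multiplier = m)
}

#' Relative standard deviation report
#'
#' @param values Numeric vector of replicate measurements (n >= 2), or a
#'   data.frame/matrix with one column per attribute.
#' @return RSD in percent (100 x SD/mean); `NA` with a warning when the
#'   mean is zero. For tabular input, a named vector per column.
#' @export
rsd_report <- function(values) {
  if (is.data.frame(values) || is.matrix(values)) {
    return(apply(as.matrix(values), 2, rsd_report))
  }
  if (length(values) < 2) stop("RSD requires at least 2 replicates")
  m <- mean(values)
  if (m == 0) {
    warning("mean is zero; RSD undefined")
    return(NA_real_)
  }
  100 * stats::sd(values) / m
}

#' Bland-Altman agreement analysis
#'
#' For paired measurements of the same attributes by two laboratories,
#' computes the mean bias (lab1 - lab2) and the 95% limits of agreement,
#' bias +/- 1.96 x SD of the paired differences (sample SD, n - 1).
#'
#' @param lab1,lab2 Paired numeric vectors (n >= 2).
#' @return A `bland_altman` object: `n`, `mean_bias`, `loa_low`,
#'   `loa_high`, and a per-pair `table` of (mean, diff) for plotting.
#'   Bias sign convention: lab1 - lab2.
#' @export
bland_altman <- function(lab1, lab2) {
  stopifnot(length(lab1) == length(lab2))
  if (length(lab1) < 2) stop("Bland-Altman requires at least 2 pairs")
  d <- lab1 - lab2
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(n = length(d), mean_bias = bias,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 table = data.frame(mean = (lab1 + lab2) / 2, diff = d),
                 sign_convention = "lab1 - lab2"),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<Bland-Altman (n=%d): bias %0.4f, limits of agreement [%0.4f, %0.4f]>\n",
    x$n, x$mean_bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  plot(x$table$mean, x$table$diff, xlab = "Mean of methods",
       ylab = "Difference (lab1 - lab2)", ...)
  graphics::abline(h = x$mean_bias, lty = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 3)
  invisible(x)
}

#' Kruskal-Wallis convenience report
#'
#' Thin wrapper over [stats::kruskal.test()] with pairwise Wilcoxon
#' post-hoc comparisons, for comparing attribute levels across process
#' steps.
#'
#' @param values Numeric measurements.
#' @param groups Grouping factor.
#' @return List with the Kruskal-Wallis p-value and the pairwise p-value
#'   matrix (Holm-adjusted).
#' @export
group_comparison_report <- function(values, groups) {
  kw <- stats::kruskal.test(values, as.factor(groups))
  pw <- stats::pairwise.wilcox.test(values, as.factor(groups),
                                    p.adjust.method = "holm", exact = FALSE)
  list(kruskal_p = kw$p.value, pairwise_p = pw$p.value)
}
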