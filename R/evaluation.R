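# Performance metrics, ROC/AUC with DeLong variance, paired DeLong
# comparison, cohort-characteristics statistics, and the size-histogram
# overlap statistic.

#' Confusion counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @param cohort Optional cohort tag.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fp, tn, fn, cohort = NA_character_) {
  v <- c(tp, fp, tn, fn)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, cohort = cohort),
            class = "confusion_counts")
}

#' Accuracy / sensitivity / specificity from confusion counts
#'
#' All three reported in percent, rounded to 2 decimals. A zero
#' denominator yields `NA` for the affected metric.
#'
#' @param counts A [confusion_counts()] object.
#' @return Named numeric vector: accuracy, sensitivity, specificity (%).
#' @export
confusion_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  pos <- counts$tp + counts$fn
  neg <- counts$tn + counts$fp
  total <- pos + neg
  acc <- if (total > 0) (counts$tp + counts$tn) / total * 100 else NA_real_
  sens <- if (pos > 0) counts$tp / pos * 100 else NA_real_
  spec <- if (neg > 0) counts$tn / neg * 100 else NA_real_
  round(c(accuracy = acc, sensitivity = sens, specificity = spec), 2)
}

# round half away from zero (printed-rate convention)
round_half_up <- function(x) floor(x + 0.5)

#' Reconstruct confusion counts from printed rates
#'
#' Inverse of [confusion_metrics()]: TP and TN are recovered from the
#' printed sensitivity/specificity and the class sizes by
#' round-half-away-from-zero; the round trip reproduces the input rates
#' to 2 decimals.
#'
#' @param n_pos,n_neg Class sizes.
#' @param sensitivity,specificity Printed rates in percent.
#' @param cohort Optional cohort tag.
#' @return A [confusion_counts()] object.
#' @export
counts_from_rates <- function(n_pos, sensitivity, n_neg, specificity,
                              cohort = NA_character_) {
  if (sensitivity < 0 || sensitivity > 100 ||
      specificity < 0 || specificity > 100)
    stop("rates must be within [0, 100]")
  tp <- unname(round_half_up(sensitivity * n_pos / 100))
  tn <- unname(round_half_up(specificity * n_neg / 100))
  confusion_counts(tp = tp, fp = n_neg - tn, tn = tn, fn = n_pos - tp,
                   cohort = cohort)
}

# DeLong structural components: for each positive case the mean of
# psi(pos, neg) over negatives, and vice versa (psi = 1, 1/2, 0).
delong_components <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) stop("both classes must be present")
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi),
       v10 = rowMeans(psi),   # per positive
       v01 = colMeans(psi),   # per negative
       m = m, n = n)
}

#' AUC with DeLong variance and 95% CI
#'
#' AUC is the Mann-Whitney statistic (ties counted one-half); the
#' variance is DeLong's structural-components estimator and the CI is
#' the normal approximation `auc +/- 1.96 sqrt(var)`, clipped to
#' \[0, 1\]. A logit-scale CI is available via `ci_scale`.
#'
#' @param scores Continuous classifier scores (larger favors class 1).
#' @param labels 0/1 labels.
#' @param ci_scale `"auc"` (default, symmetric) or `"logit"`.
#' @return An `auc_result`: list with `auc`, `variance`, `ci95`.
#' @export
roc_auc <- function(scores, labels, ci_scale = c("auc", "logit")) {
  ci_scale <- match.arg(ci_scale)
  cmp <- delong_components(scores, labels)
  s10 <- if (cmp$m > 1) var(cmp$v10) else 0
  s01 <- if (cmp$n > 1) var(cmp$v01) else 0
  v <- s10 / cmp$m + s01 / cmp$n
  if (ci_scale == "auc") {
    half <- 1.96 * sqrt(v)
    ci <- c(max(0, cmp$auc - half), min(1, cmp$auc + half))
  } else {
    a <- min(max(cmp$auc, 1e-12), 1 - 1e-12)
    lg <- log(a / (1 - a))
    se_lg <- sqrt(v) / (a * (1 - a))
    ci <- 1 / (1 + exp(-(lg + c(-1.96, 1.96) * se_lg)))
  }
  structure(list(auc = cmp$auc, variance = v, ci95 = ci),
            class = "auc_result")
}

#' Paired DeLong test for two correlated AUCs
#'
#' Both score vectors must refer to the same cases. The covariance of
#' the paired AUCs is estimated from the DeLong structural components;
#' z = dAUC / sqrt(varA + varB - 2 cov), with a two-sided normal p. A
#' zero-variance difference is reported as p = 1 with `degenerate =
#' TRUE`.
#'
#' @param scores_a,scores_b Scores of models A and B on the same cases.
#' @param labels 0/1 labels.
#' @return A `comparison_result`: list with `delta_auc`, `z`, `p`,
#'   `auc_a`, `auc_b`, `degenerate`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors must cover the same cases")
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  va <- (if (ca$m > 1) var(ca$v10) else 0) / ca$m +
        (if (ca$n > 1) var(ca$v01) else 0) / ca$n
  vb <- (if (cb$m > 1) var(cb$v10) else 0) / cb$m +
        (if (cb$n > 1) var(cb$v01) else 0) / cb$n
  cv <- (if (ca$m > 1) stats::cov(ca$v10, cb$v10) else 0) / ca$m +
        (if (ca$n > 1) stats::cov(ca$v01, cb$v01) else 0) / ca$n
  dauc <- ca$auc - cb$auc
  vd <- va + vb - 2 * cv
  if (vd <= 1e-16) {
    return(structure(list(delta_auc = dauc, z = 0, p = 1,
                          auc_a = ca$auc, auc_b = cb$auc,
                          degenerate = TRUE),
                     class = "comparison_result"))
  }
  z <- dauc / sqrt(vd)
  structure(list(delta_auc = dauc, z = z, p = 2 * pnorm(-abs(z)),
                 auc_a = ca$auc, auc_b = cb$auc, degenerate = FALSE),
            class = "comparison_result")
}

#' Cohort characteristics table
#'
#' Numeric variables: per-class mean +/- SD and Wilcoxon rank-sum p.
#' Categorical variables: per-class percentages of each level and a
#' binomial test of the metastatic-class proportion against the
#' normal-class proportion. p < 0.05 is flagged.
#'
#' @param cohort Data frame (e.g. [cohort_table()]) with a `label`
#'   column.
#' @param variables Variables to summarize (default: all but case_id and
#'   label).
#' @return Data frame: variable, type, summaries per class, p, flag.
#' @export
cohort_stats <- function(cohort,
                         variables = setdiff(names(cohort),
                                             c("case_id", "label"))) {
  if (nrow(cohort) == 0) stop("empty cohort")
  lab <- cohort$label
  rows <- lapply(variables, function(nm) {
    v <- cohort[[nm]]
    if (is.numeric(v)) {
      g0 <- v[lab == 0]; g1 <- v[lab == 1]
      p <- if (length(g0) >= 2 && length(g1) >= 2)
        suppressWarnings(wilcox.test(g0, g1)$p.value) else NA_real_
      data.frame(variable = nm, type = "numeric",
                 normal = sprintf("%.2f ± %.2f", mean(g0), sd(g0)),
                 metastatic = sprintf("%.2f ± %.2f", mean(g1), sd(g1)),
                 p = p,
                 significant = !is.na(p) && p < 0.05,
                 stringsAsFactors = FALSE)
    } else {
      v <- as.character(v)
      lev <- sort(unique(v))[1]
      p0 <- mean(v[lab == 0] == lev)
      p1 <- mean(v[lab == 1] == lev)
      n1 <- sum(lab == 1)
      p <- if (n1 > 0 && p0 > 0 && p0 < 1)
        binom.test(sum(v[lab == 1] == lev), n1, p = p0)$p.value
      else NA_real_
      data.frame(variable = nm, type = "categorical",
                 normal = sprintf("%s: %.1f%%", lev, 100 * p0),
                 metastatic = sprintf("%s: %.1f%%", lev, 100 * p1),
                 p = p,
                 significant = !is.na(p) && p < 0.05,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Size-histogram class overlap
#'
#' Bins the pooled long-axis diameters into fixed-width bins anchored at
#' the pooled minimum and reports the percentage of nodes falling in
#' bins occupied by both classes.
#'
#' @param long_axes Long-axis diameters (mm).
#' @param labels 0/1 labels.
#' @param bin_width Bin width in mm (default 0.25).
#' @return Overlap percentage (scalar).
#' @export
diameter_histogram_overlap <- function(long_axes, labels,
                                       bin_width = 0.25) {
  if (length(long_axes) == 0) stop("empty input")
  if (bin_width <= 0) stop("bin_width must be > 0")
  bins <- floor((long_axes - min(long_axes)) / bin_width)
  b0 <- unique(bins[labels == 0])
  b1 <- unique(bins[labels == 1])
  shared <- intersect(b0, b1)
  100 * sum(bins %in% shared) / length(long_axes)
}

#' Evaluate a model on one cohort
#'
#' @param scores Continuous scores.
#' @param classes 0/1 predicted classes.
#' @param labels 0/1 true labels.
#' @param cohort Cohort tag.
#' @return List with `counts`, `metrics` (%), `auc` (an `auc_result`).
#' @export
evaluate_predictions <- function(scores, classes, labels,
                                 cohort = NA_character_) {
  counts <- confusion_counts(tp = sum(classes == 1 & labels == 1),
                             fp = sum(classes == 1 & labels == 0),
                             tn = sum(classes == 0 & labels == 0),
                             fn = sum(classes == 0 & labels == 1),
                             cohort = cohort)
  list(counts = counts,
       metrics = confusion_metrics(counts),
       auc = roc_auc(scores, labels))
}
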