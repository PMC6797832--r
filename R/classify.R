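## Tertiary torsadogenic risk stratification: logistic threshold fitting,
## interval classification, confusion summaries over the embedded
## 28-compound reference table, and metric correlations.

#' Interval conventions for the reference metrics
#'
#' Classification presets for the five reference classifiers: thresholds,
#' orientation and boundary ownership (see [partition_by_metric()]).  The
#' EAD-threshold metrics use riskier-side boundary ownership (a compound at
#' exactly the lower threshold counts as high risk); qNet and APD90 use the
#' safer side; peakCa is a single-threshold low/intermediate split.
#'
#' @param metric One of `"qNet"`, `"ThEAD"`, `"APD90"`, `"peakCa"`.
#' @return List with `th1`, `th2`, `orientation`, `boundary`.
#' @export
tertiary_rules <- function(metric = c("qNet", "ThEAD", "APD90", "peakCa")) {
  metric <- match.arg(metric)
  switch(metric,
    qNet = list(th1 = 57, th2 = 70, orientation = "low_is_high_risk",
                boundary = "safe"),
    ThEAD = list(th1 = 90, th2 = 95, orientation = "low_is_high_risk",
                 boundary = "risky"),
    APD90 = list(th1 = 307, th2 = 367, orientation = "high_is_high_risk",
                 boundary = "safe"),
    peakCa = list(th1 = 204, th2 = NA, orientation = "high_is_high_risk",
                  boundary = "risky"))
}

## midpoint of the gap between the risky-side and safe-side values
.gap_midpoint <- function(values, inside, orientation) {
  if (orientation == "low_is_high_risk")
    (max(values[inside]) + min(values[!inside])) / 2
  else
    (min(values[inside]) + max(values[!inside])) / 2
}

.ovr_threshold <- function(values, binary, orientation) {
  ## perfect separation: every in-class value on the risky side of every
  ## out-of-class value
  sep <- if (orientation == "low_is_high_risk")
    max(values[binary]) < min(values[!binary])
  else
    min(values[binary]) > max(values[!binary])
  if (sep) {
    return(list(threshold = .gap_midpoint(values, binary, orientation),
                separated = TRUE, converged = TRUE))
  }
  fit <- suppressWarnings(stats::glm(binary ~ values,
                                     family = stats::binomial()))
  b <- stats::coef(fit)
  list(threshold = -b[[1]] / b[[2]], separated = FALSE,
       converged = fit$converged)
}

#' Fit tertiary classification thresholds by logistic regression
#'
#' Two one-vs-rest binary logistic fits — high-vs-rest on the risky side of
#' the metric and low-vs-rest on the safe side — each yielding the metric
#' value where the fitted probability crosses 0.5.  Perfectly separated
#' fits fall back to the midpoint of the separating gap.
#'
#' @param values Metric values (`NA` = no-EAD sentinel, mapped to 100 for
#'   fitting per the averaging policy).
#' @param labels Tertiary risk labels (high/intermediate/low), all three
#'   present.
#' @param orientation See [partition_by_metric()].
#' @return List of class `tertiary_thresholds`: `th1 < th2`, `orientation`,
#'   and per-side fit diagnostics.
#' @export
fit_tertiary_thresholds <- function(values, labels,
                                    orientation = c("low_is_high_risk",
                                                    "high_is_high_risk")) {
  orientation <- match.arg(orientation)
  labels <- as.character(labels)
  missing <- setdiff(c("high", "intermediate", "low"), unique(labels))
  if (length(missing))
    stop("absent risk category: ", paste(missing, collapse = ", "))
  values[is.na(values)] <- 100
  hi <- .ovr_threshold(values, labels == "high", orientation)
  lo_or <- if (orientation == "low_is_high_risk") "high_is_high_risk"
           else "low_is_high_risk"
  lo <- .ovr_threshold(values, labels == "low", lo_or)
  ths <- sort(c(hi$threshold, lo$threshold))
  structure(list(th1 = ths[1], th2 = ths[2], orientation = orientation,
                 diagnostics = list(high_vs_rest = hi, low_vs_rest = lo)),
            class = "tertiary_thresholds")
}

#' Classify compounds and tally correct counts per risk category
#'
#' Assigns tertiary labels by half-open intervals (no-EAD sentinels fall on
#' the low-risk side) and tallies per-category correct counts, split by
#' training/validation membership when provided.
#'
#' @param values Metric values (`NA` = no-EAD sentinel).
#' @param thresholds Numeric `c(th1, th2)` (or `c(th1, NA)`), a
#'   `tertiary_thresholds` object, or a [tertiary_rules()] preset list.
#' @param labels True risk labels.
#' @param orientation,boundary See [partition_by_metric()]; ignored when
#'   `thresholds` carries its own.
#' @param split Optional training/validation factor.
#' @return List of class `classification_report`: `predicted`, `correct`
#'   (logical), `by_category` (correct and total per category, with
#'   training/validation columns), `total_correct`, `n`.
#' @export
classify_tertiary <- function(values, thresholds, labels,
                              orientation = "low_is_high_risk",
                              boundary = "safe", split = NULL) {
  if (inherits(thresholds, "tertiary_thresholds")) {
    orientation <- thresholds$orientation
    thresholds <- c(thresholds$th1, thresholds$th2)
  } else if (is.list(thresholds)) {
    orientation <- thresholds$orientation
    boundary <- thresholds$boundary
    thresholds <- c(thresholds$th1, thresholds$th2)
  }
  pred <- partition_by_metric(values, thresholds[1], thresholds[2],
                              orientation = orientation,
                              boundary = boundary)
  truth <- factor(as.character(labels),
                  levels = c("high", "intermediate", "low"))
  correct <- as.character(pred) == as.character(truth)
  cats <- levels(truth)
  tally <- function(sel) {
    vapply(cats, function(cat)
      sum(correct[sel & truth == cat]), numeric(1))
  }
  by_cat <- data.frame(category = cats,
                       correct = tally(rep(TRUE, length(correct))),
                       total = as.numeric(table(truth)[cats]))
  if (!is.null(split)) {
    by_cat$training <- tally(split == "training")
    by_cat$validation <- tally(split == "validation")
  }
  structure(list(predicted = pred, correct = correct, by_category = by_cat,
                 total_correct = sum(correct), n = length(correct)),
            class = "classification_report")
}

#' Recompute the reference-table classification summary
#'
#' Runs all five reference classifiers (Th_EAD full drug action, Th_EAD
#' sbIKr+bICaL-only ablation, qNet, APD90, peakCa) over the embedded
#' 28-compound table with their published thresholds and returns the
#' per-classifier correct counts.
#'
#' @return data.frame with one row per classifier: total and per-category
#'   correct counts.
#' @export
verify_table5 <- function() {
  t5 <- table5()
  specs <- list(
    th_ead_c1 = list(values = t5$th_ead_c1, rules = tertiary_rules("ThEAD")),
    th_ead_c2 = list(values = t5$th_ead_c2, rules = tertiary_rules("ThEAD")),
    qnet = list(values = t5$qnet, rules = tertiary_rules("qNet")),
    apd90 = list(values = t5$apd90, rules = tertiary_rules("APD90")),
    peakca = list(values = t5$peakca, rules = tertiary_rules("peakCa")))
  rows <- lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    rep <- classify_tertiary(sp$values, sp$rules, t5$risk, split = t5$split)
    bc <- rep$by_category
    data.frame(classifier = nm, total_correct = rep$total_correct,
               high = bc$correct[bc$category == "high"],
               intermediate = bc$correct[bc$category == "intermediate"],
               low = bc$correct[bc$category == "low"],
               training = sum(bc$training), validation = sum(bc$validation))
  })
  do.call(rbind, rows)
}

#' Pairwise Pearson correlations between metrics
#'
#' Pairwise-complete Pearson correlations over a metric table.  No-EAD
#' sentinels (`NA` in threshold columns flagged by `noead_*` columns) may
#' be coerced to 100 first via `noead_as`; the coercion is recorded in the
#' `"noead_coerced"` attribute.  Zero-variance columns give `NA` entries.
#'
#' @param metrics data.frame of metric columns (numeric).
#' @param noead_as Value substituted for no-EAD sentinels (`NULL` leaves
#'   them missing).
#' @return Correlation matrix with attribute `noead_coerced`.
#' @export
metric_correlations <- function(metrics, noead_as = NULL) {
  m <- as.data.frame(metrics)
  coerced <- 0
  if (!is.null(noead_as)) {
    for (col in names(m)) {
      nas <- is.na(m[[col]])
      coerced <- coerced + sum(nas)
      m[[col]][nas] <- noead_as
    }
  }
  cc <- suppressWarnings(stats::cor(as.matrix(m),
                                    use = "pairwise.complete.obs"))
  zero_var <- vapply(m, function(x) stats::sd(x, na.rm = TRUE) == 0,
                     logical(1))
  cc[zero_var, ] <- NA
  cc[, zero_var] <- NA
  diag(cc) <- 1
  attr(cc, "noead_coerced") <- coerced
  cc
}
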