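## Monte Carlo filtering: partition a virtual-drug population by output
## behaviour and rank parameters by the two-sample Kolmogorov-Smirnov
## distance between subset distributions.

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The exact supremum distance between the two empirical CDFs, evaluated at
#' the union of sample points (ties handled exactly), with an asymptotic
#' p-value from the Kolmogorov distribution; `exact = TRUE` computes the
#' exact small-sample p-value instead (available for `n1 * n2 <= 1e4`).
#'
#' @param x1,x2 Non-empty numeric samples.
#' @param exact Use the exact p-value (delegated to [stats::ks.test()]).
#' @return List with `D` in `[0, 1]`, `p`, `n1`, `n2`.
#' @export
ks_two_sample <- function(x1, x2, exact = FALSE) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty")
  pts <- sort(unique(c(x1, x2)))
  F1 <- vapply(pts, function(q) mean(x1 <= q), numeric(1))
  F2 <- vapply(pts, function(q) mean(x2 <= q), numeric(1))
  D <- max(abs(F1 - F2))
  if (exact) {
    if (n1 * n2 > 1e4)
      stop("exact p-value limited to n1 * n2 <= 1e4")
    p <- suppressWarnings(stats::ks.test(x1, x2, exact = TRUE)$p.value)
  } else {
    ne <- n1 * n2 / (n1 + n2)
    lam <- sqrt(ne) * D
    j <- seq_len(100)
    p <- min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lam^2))))
  }
  list(D = D, p = p, n1 = n1, n2 = n2)
}

#' Partition a metric into tertiary risk labels
#'
#' Half-open interval classification with two thresholds.  With orientation
#' `"low_is_high_risk"` (qNet, Th_EAD: small values risky) the intervals
#' are high / intermediate / low in ascending metric order; orientation
#' `"high_is_high_risk"` (APD90) mirrors them.  `boundary` decides which
#' side owns a value equal to a threshold: `"safe"` assigns it to the
#' adjacent safer interval (the qNet convention: `qNet = th2` is low risk),
#' `"risky"` to the riskier one (the Th_EAD convention: `Th = th1` is high
#' risk).  `NA` values (the no-EAD sentinel) are assigned to the low-risk
#' side and flagged via the `"n_sentinel"` attribute.
#'
#' @param values Metric values.
#' @param th1,th2 Thresholds, `th1 < th2`.  `th2 = NA` gives a two-class
#'   low/intermediate split at `th1` (no high assigned).
#' @param orientation `"low_is_high_risk"` or `"high_is_high_risk"`.
#' @param boundary `"safe"` or `"risky"`.
#' @return Factor with levels high, intermediate, low.
#' @export
partition_by_metric <- function(values, th1, th2 = NA,
                                orientation = c("low_is_high_risk",
                                                "high_is_high_risk"),
                                boundary = c("safe", "risky")) {
  orientation <- match.arg(orientation)
  boundary <- match.arg(boundary)
  if (!is.na(th2) && th1 >= th2) stop("th1 must be below th2")
  v <- values
  if (orientation == "high_is_high_risk") {
    ## mirror so that small transformed values are risky; boundary
    ## ownership (safer vs riskier side) carries over unchanged
    v <- -v
    t1 <- -th2; t2 <- -th1
    if (is.na(th2)) { t1 <- -th1; t2 <- NA }
    th1 <- t1; th2 <- t2
  }
  lab <- character(length(v))
  if (is.na(th2)) {
    ## single threshold: two-class split, the risky side is labelled
    ## intermediate (no high assigned)
    if (boundary == "safe") {
      lab[v < th1] <- "intermediate"; lab[v >= th1] <- "low"
    } else {
      lab[v <= th1] <- "intermediate"; lab[v > th1] <- "low"
    }
  } else if (boundary == "safe") {
    lab[v < th1] <- "high"
    lab[v >= th1] <- "intermediate"
    lab[v >= th2] <- "low"
  } else {
    lab[v <= th1] <- "high"
    lab[v > th1] <- "intermediate"
    lab[v > th2] <- "low"
  }
  n_sent <- sum(is.na(v))
  lab[is.na(v)] <- "low"
  out <- factor(lab, levels = c("high", "intermediate", "low"))
  if (n_sent > 0) attr(out, "n_sentinel") <- n_sent
  out
}

#' Monte Carlo filtering parameter ranking
#'
#' For each input parameter and each label contrast, the two-sample KS
#' distance between the parameter's values in the two subsets.  Behavioural
#' / non-behavioural EAD filtering is the same machinery with binary labels
#' from [detect_ead()].
#'
#' @param pop A `sample_matrix`, or a plain data.frame/matrix of parameter
#'   values.
#' @param labels Labels aligned to the rows.
#' @param contrasts List of label pairs, e.g.
#'   `list(c("low", "intermediate"), c("high", "intermediate"))`.
#' @param exact Passed to [ks_two_sample()].
#' @return data.frame of class `mcf_result` with columns `parameter`,
#'   `contrast`, `D`, `p`, `n1`, `n2`.
#' @export
mcf_rank <- function(pop, labels,
                     contrasts = list(c("low", "intermediate"),
                                      c("high", "intermediate")),
                     exact = FALSE) {
  X <- if (inherits(pop, "sample_matrix")) pop$samples else as.data.frame(pop)
  stopifnot(nrow(X) == length(labels))
  rows <- list()
  for (ct in contrasts) {
    i1 <- labels == ct[1]; i2 <- labels == ct[2]
    if (!any(i1) || !any(i2)) {
      warning("contrast ", paste(ct, collapse = " vs "),
              " has an empty subset; skipped")
      next
    }
    for (par in colnames(X)) {
      ks <- ks_two_sample(X[i1, par], X[i2, par], exact = exact)
      rows[[length(rows) + 1]] <- data.frame(
        parameter = par, contrast = paste(ct, collapse = ":"),
        D = ks$D, p = ks$p, n1 = ks$n1, n2 = ks$n2)
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  class(out) <- c("mcf_result", class(out))
  out
}
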