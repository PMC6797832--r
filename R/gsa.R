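## Variance-based (Sobol) sensitivity indices, multivariate-linear-regression
## R^2, and permutation importance (mean decrease accuracy) over
## (parameter matrix -> metric) datasets.

.saltelli_blocks <- function(pop, y) {
  k <- pop$k; n <- pop$n
  per <- if (pop$second_order) 2 * k + 2 else k + 2
  if (length(y) != n * per)
    stop("y length ", length(y), " does not match the Saltelli layout (",
         n, " x ", per, ")")
  off <- (seq_len(n) - 1) * per
  yA <- y[off + 1]
  yB <- y[off + per]
  yAB <- vapply(seq_len(k), function(j) y[off + 1 + j], numeric(n))
  yBA <- if (pop$second_order)
    vapply(seq_len(k), function(j) y[off + 1 + k + j], numeric(n))
  else NULL
  list(yA = yA, yB = yB, yAB = yAB, yBA = yBA, n = n, k = k)
}

.sobol_point <- function(b, idx = seq_len(b$n), second_order = FALSE) {
  yA <- b$yA[idx]; yB <- b$yB[idx]
  yAB <- b$yAB[idx, , drop = FALSE]
  V <- stats::var(c(yA, yB))
  S1 <- vapply(seq_len(b$k), function(j)
    mean(yB * (yAB[, j] - yA)) / V, numeric(1))
  ST <- vapply(seq_len(b$k), function(j)
    0.5 * mean((yA - yAB[, j])^2) / V, numeric(1))
  S2 <- NULL
  if (second_order && !is.null(b$yBA)) {
    yBA <- b$yBA[idx, , drop = FALSE]
    S2 <- matrix(NA_real_, b$k, b$k)
    for (i in seq_len(b$k - 1)) {
      for (j in seq(i + 1, b$k)) {
        Vij <- mean(yBA[, i] * yAB[, j] - yA * yB) / V
        S2[i, j] <- Vij - S1[i] - S1[j]
      }
    }
  }
  list(S1 = S1, ST = ST, S2 = S2)
}

#' Sobol sensitivity indices from a Saltelli sample
#'
#' First-order indices via the Saltelli (2010) estimator, total-effect
#' indices via the Jansen estimator, and (when the population carries the
#' second-order layout) closed second-order indices, with bootstrap
#' confidence half-widths over resampled base rows.  Rows whose model
#' evaluation failed (`NA` in `y`) are imputed with the population median,
#' keeping the block structure intact; the count is reported.
#'
#' @param pop A `sample_matrix` with `scheme = "saltelli"`.
#' @param y Metric values aligned to `pop$samples` rows.
#' @param n_boot Bootstrap resamples (0 to skip).
#' @param conf Confidence level for the half-widths.
#' @param seed RNG seed for the bootstrap.
#' @return List of class `sobol_result`: `S1`, `ST` (named), `S1_conf`,
#'   `ST_conf`, optional `S2`/`S2_conf`, `n`, `k`, `n_imputed`.
#' @export
sobol_indices <- function(pop, y, n_boot = 100, conf = 0.95, seed = 1) {
  if (!identical(pop$scheme, "saltelli"))
    stop("sobol_indices requires a Saltelli sample matrix")
  n_imp <- sum(is.na(y))
  if (n_imp > 0) y[is.na(y)] <- stats::median(y, na.rm = TRUE)
  b <- .saltelli_blocks(pop, y)
  pt <- .sobol_point(b, second_order = pop$second_order)
  names(pt$S1) <- names(pt$ST) <- colnames(pop$samples)

  S1_conf <- ST_conf <- rep(NA_real_, b$k)
  S2_conf <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    bs1 <- matrix(NA_real_, n_boot, b$k)
    bst <- matrix(NA_real_, n_boot, b$k)
    bs2 <- if (pop$second_order)
      array(NA_real_, c(n_boot, b$k, b$k)) else NULL
    for (r in seq_len(n_boot)) {
      idx <- sample.int(b$n, b$n, replace = TRUE)
      p <- .sobol_point(b, idx, second_order = pop$second_order)
      bs1[r, ] <- p$S1; bst[r, ] <- p$ST
      if (!is.null(bs2)) bs2[r, , ] <- p$S2
    }
    zf <- stats::qnorm(0.5 + conf / 2)
    S1_conf <- zf * apply(bs1, 2, stats::sd)
    ST_conf <- zf * apply(bst, 2, stats::sd)
    if (!is.null(bs2)) S2_conf <- zf * apply(bs2, c(2, 3), stats::sd)
  }
  structure(list(S1 = pt$S1, ST = pt$ST, S2 = pt$S2,
                 S1_conf = stats::setNames(S1_conf, names(pt$S1)),
                 ST_conf = stats::setNames(ST_conf, names(pt$ST)),
                 S2_conf = S2_conf, n = b$n, k = b$k, n_imputed = n_imp,
                 estimator = c(S1 = "saltelli2010", ST = "jansen")),
            class = "sobol_result")
}

#' Multivariate linear regression R^2 and coefficients
#'
#' Ordinary least squares of the metric on the standardized inputs: the
#' R^2 is the proportion of metric variance explained by first-order
#' (linear) terms; the standardized coefficients serve as a simple
#' regression-based sensitivity measure.
#'
#' @param X Parameter matrix or data.frame.
#' @param y Metric values.
#' @return List with `r2`, `coefficients` (named, standardized scale) and
#'   the `lm` fit.
#' @export
linear_r2 <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) < ncol(X) + 2)
    stop("need at least ncol(X) + 2 rows")
  Xs <- scale(X)
  if (qr(Xs)$rank < ncol(Xs)) stop("rank-deficient input matrix")
  fit <- stats::lm(y ~ Xs)
  list(r2 = summary(fit)$r.squared,
       coefficients = stats::setNames(stats::coef(fit)[-1], colnames(X)),
       fit = fit)
}

.fit_surrogate <- function(X, y, surrogate, seed) {
  df <- data.frame(X, .y = y)
  switch(surrogate,
    linear = {
      fit <- stats::lm(.y ~ ., data = df)
      list(score = function(X2, y2) {
        p <- stats::predict(fit, data.frame(X2))
        1 - sum((y2 - p)^2) / sum((y2 - mean(y2))^2)
      })
    },
    rf_regressor = {
      fit <- ranger::ranger(.y ~ ., data = df, num.trees = 100,
                            max.depth = 12, seed = seed)
      list(score = function(X2, y2) {
        p <- stats::predict(fit, data.frame(X2))$predictions
        1 - sum((y2 - p)^2) / sum((y2 - mean(y2))^2)
      })
    },
    logistic = {
      fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE)
      list(score = function(X2, y2) {
        p <- stats::predict(fit, data.frame(X2))
        mean(p == y2)
      })
    },
    rf_classifier = {
      fit <- ranger::ranger(.y ~ ., data = df, num.trees = 100,
                            max.depth = 12, seed = seed)
      list(score = function(X2, y2) {
        p <- stats::predict(fit, data.frame(X2))$predictions
        mean(p == y2)
      })
    },
    stop("unknown surrogate: ", surrogate))
}

#' Permutation importance (mean decrease accuracy)
#'
#' Fits a surrogate of the metric (regression) or of the class label
#' (classification) and measures, for each input column, the mean drop in
#' score (R^2 or accuracy) after randomly shuffling that column, over
#' `repeats` permutations.  The random-forest surrogates use 100 trees of
#' maximum depth 12.  Scoring is in-sample by default (the surrogate is
#' fixed after training); `holdout` scores on a held-out fraction instead.
#'
#' @param X Parameter matrix or data.frame.
#' @param y Metric values (numeric) or class labels (factor/character).
#' @param surrogate One of `"linear"`, `"rf_regressor"`, `"logistic"`,
#'   `"rf_classifier"`.
#' @param repeats Permutation repeats per column.
#' @param seed RNG seed.
#' @param holdout Fraction held out for scoring (0 = in-sample).
#' @return List of class `mda_result`: `baseline` score, `drops` (named
#'   means), `drops_sd` (repeat-level spread), `surrogate`.
#' @export
mda_importance <- function(X, y, surrogate = c("rf_regressor", "linear",
                                               "logistic", "rf_classifier"),
                           repeats = 10, seed = 1, holdout = 0) {
  surrogate <- match.arg(surrogate)
  X <- as.data.frame(X)
  classif <- surrogate %in% c("logistic", "rf_classifier")
  if (classif) y <- factor(y)
  else if (stats::sd(y) == 0) stop("degenerate (constant) metric")
  set.seed(seed)
  if (holdout > 0) {
    n_te <- max(1, round(holdout * nrow(X)))
    te <- sample.int(nrow(X), n_te)
    X_tr <- X[-te, , drop = FALSE]; y_tr <- y[-te]
    X_te <- X[te, , drop = FALSE]; y_te <- y[te]
  } else {
    X_tr <- X_te <- X; y_tr <- y_te <- y
  }
  sur <- .fit_surrogate(X_tr, y_tr, surrogate, seed)
  base <- sur$score(X_te, y_te)
  drops <- matrix(NA_real_, repeats, ncol(X),
                  dimnames = list(NULL, colnames(X)))
  for (r in seq_len(repeats)) {
    for (j in seq_len(ncol(X))) {
      Xp <- X_te
      Xp[[j]] <- sample(Xp[[j]])
      drops[r, j] <- base - sur$score(Xp, y_te)
    }
  }
  structure(list(baseline = base, drops = colMeans(drops),
                 drops_sd = apply(drops, 2, stats::sd),
                 surrogate = surrogate, repeats = repeats,
                 holdout = holdout),
            class = "mda_result")
}

## minimal ridge-logistic fallback used when a one-vs-rest fit separates
.ridge_logistic <- function(X, y, lambda = 1e-2, iter = 50) {
  X1 <- cbind(1, X)
  beta <- rep(0, ncol(X1))
  pen <- c(0, rep(lambda, ncol(X)))
  for (i in seq_len(iter)) {
    eta <- drop(X1 %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-6)
    z <- eta + (y - p) / w
    H <- crossprod(X1, X1 * w) + diag(pen * nrow(X))
    beta_new <- solve(H, crossprod(X1, w * z))
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  drop(beta)
}

#' Logistic-regression sensitivity of a tertiary label
#'
#' One-vs-rest logistic fits of each class on standardized inputs; the
#' sensitivity of a parameter for a contrast is the absolute value of its
#' standardized coefficient.  Perfectly separated contrasts are flagged and
#' refit with a ridge penalty.
#'
#' @param X Parameter matrix or data.frame.
#' @param labels Class labels (>= 2 classes present).
#' @return List of class `logistic_sensitivity`: `coef_abs` (parameters x
#'   classes), `separated` (logical per class).
#' @export
logistic_sensitivity <- function(X, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  Xs <- scale(as.matrix(X))
  classes <- levels(labels)
  coefs <- matrix(NA_real_, ncol(Xs), length(classes),
                  dimnames = list(colnames(X), classes))
  separated <- stats::setNames(logical(length(classes)), classes)
  for (cl in classes) {
    yb <- as.numeric(labels == cl)
    fit <- suppressWarnings(stats::glm(yb ~ Xs, family = stats::binomial()))
    sep <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 50)
    if (is.na(sep) || sep) {
      separated[cl] <- TRUE
      beta <- .ridge_logistic(Xs, yb)
      coefs[, cl] <- abs(beta[-1])
    } else {
      coefs[, cl] <- abs(stats::coef(fit)[-1])
    }
  }
  structure(list(coef_abs = coefs, separated = separated),
            class = "logistic_sensitivity")
}
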