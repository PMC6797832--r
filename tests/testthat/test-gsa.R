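## unit square ranges used for analytic sensitivity checks
unit_ranges <- function(k) {
  m <- matrix(rep(c(0, 1), each = k), ncol = 2,
              dimnames = list(paste0("X", seq_len(k)), c("min", "max")))
  m
}

test_that("a single-factor response loads entirely on that factor", {
  pop <- saltelli_population(unit_ranges(9), n = 1024, seed = 2)
  y <- pop$samples$X1
  res <- sobol_indices(pop, y, n_boot = 50, seed = 1)
  expect_equal(unname(res$S1[["X1"]]), 1, tolerance = 0.02)
  expect_equal(unname(res$ST[["X1"]]), 1, tolerance = 0.02)
  expect_true(all(abs(res$S1[-1]) < 0.02))
  expect_true(all(res$ST[-1] < 0.02))
})

test_that("additive responses recover the closed-form variance shares", {
  a <- c(4, 3, 2, 1, 0.5)
  share <- a^2 / sum(a^2)
  pop <- saltelli_population(unit_ranges(5), n = 1024, k = 5, seed = 3)
  y <- as.matrix(pop$samples) %*% a
  res <- sobol_indices(pop, drop(y), n_boot = 100, seed = 1)
  for (j in seq_along(a)) {
    ci <- max(res$S1_conf[j], 0.01)
    expect_lt(abs(res$S1[j] - share[j]), 3 * ci)
    ## additive: total effects equal first-order effects
    expect_lt(abs(res$ST[j] - res$S1[j]), 0.03)
  }
  expect_lt(sum(res$S1), 1 + 3 * max(res$S1_conf))
})

test_that("interaction responses match the brute-force double-loop oracle", {
  fn <- function(X) X[, 1] + 2 * X[, 2] * X[, 3]
  oracle <- sobol_oracle(fn, k = 3, n_outer = 300, n_inner = 300)
  pop <- saltelli_population(unit_ranges(3), n = 2048, k = 3, seed = 4)
  y <- fn(as.matrix(pop$samples))
  res <- sobol_indices(pop, y, n_boot = 100, seed = 1)
  for (j in 1:3) {
    expect_lt(abs(res$S1[j] - oracle$S1[j]), 0.05)
    expect_lt(abs(res$ST[j] - oracle$ST[j]), 0.05)
  }
  ## the X2:X3 interaction appears in S2 and in ST - S1
  expect_gt(res$S2[2, 3], 0.05)
  expect_gt(res$ST[2] - res$S1[2], 0.03)
  ## X1 is purely additive
  expect_lt(res$ST[1] - res$S1[1], 0.03)
})

test_that("failed rows are imputed without breaking the block structure", {
  pop <- saltelli_population(unit_ranges(3), n = 256, k = 3, seed = 5)
  y <- pop$samples$X1
  y[sample(length(y), 10)] <- NA
  res <- sobol_indices(pop, y, n_boot = 0)
  expect_equal(res$n_imputed, 10)
  expect_equal(unname(res$S1[["X1"]]), 1, tolerance = 0.06)
})

test_that("linear regression R^2 separates signal from noise", {
  set.seed(10)
  X <- matrix(runif(2000 * 5), ncol = 5)
  beta <- c(1, -2, 0.5, 0, 3)
  y_lin <- drop(X %*% beta)
  fit <- suppressWarnings(linear_r2(X, y_lin))
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  ## independent response
  expect_lt(linear_r2(X, rnorm(2000))$r2, 0.02)
  ## constructed 80/20 signal-to-noise split
  sd_sig <- sd(y_lin)
  y_noisy <- y_lin + rnorm(2000, sd = sd_sig * sqrt(0.25))
  expect_equal(linear_r2(X, y_noisy)$r2, 0.8, tolerance = 0.03)
  expect_error(linear_r2(cbind(X[, 1], X[, 1]), y_lin[1:2000]),
               "rank")
})

test_that("permutation importance isolates informative columns", {
  set.seed(11)
  X <- as.data.frame(matrix(runif(600 * 4), ncol = 4))
  y <- X[[3]]
  res <- mda_importance(X, y, surrogate = "linear", repeats = 10, seed = 2)
  expect_gt(res$drops[[3]], 0.5)
  expect_true(all(abs(res$drops[-3]) < 0.02))
  expect_equal(unname(which.max(res$drops)), 3L)
  expect_error(mda_importance(X, rep(1, 600), surrogate = "linear"),
               "degenerate")
})

test_that("MDA ranking matches the Sobol total-order ranking when additive", {
  a <- c(3, 1, 2, 0.25)
  pop <- saltelli_population(unit_ranges(4), n = 512, k = 4, seed = 6)
  y <- drop(as.matrix(pop$samples) %*% a)
  sob <- sobol_indices(pop, y, n_boot = 0)
  mda <- mda_importance(pop$samples, y, surrogate = "rf_regressor",
                        repeats = 5, seed = 3)
  expect_equal(order(mda$drops, decreasing = TRUE),
               order(sob$ST, decreasing = TRUE))
})

test_that("logistic sensitivity ranks boundary-defining parameters first", {
  set.seed(12)
  X <- matrix(runif(500 * 4), ncol = 4,
              dimnames = list(NULL, paste0("X", 1:4)))
  lab <- ifelse(X[, 2] > 0.5, "pos", "neg")
  res <- logistic_sensitivity(X, lab)
  expect_equal(unname(which.max(res$coef_abs[, "pos"])), 2L)
  expect_true(any(res$separated))  # sharp threshold separates perfectly
  ## labels independent of X: all coefficients small
  lab2 <- sample(c("a", "b"), 500, replace = TRUE)
  res2 <- logistic_sensitivity(X, lab2)
  expect_true(all(res2$coef_abs < 0.5))
  expect_error(logistic_sensitivity(X, rep("a", 500)), "2 classes")
})

test_that("logistic and MCF rankings agree on a linear boundary", {
  set.seed(13)
  X <- matrix(runif(800 * 3), ncol = 3,
              dimnames = list(NULL, paste0("X", 1:3)))
  score <- 2 * X[, 1] + 0.5 * X[, 2] + rnorm(800, sd = 0.2)
  lab <- ifelse(score > median(score), "pos", "neg")
  lg <- logistic_sensitivity(X, lab)
  mc <- mcf_rank(as.data.frame(X), lab, contrasts = list(c("pos", "neg")))
  expect_equal(order(lg$coef_abs[, "pos"], decreasing = TRUE),
               order(mc$D, decreasing = TRUE))
})
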