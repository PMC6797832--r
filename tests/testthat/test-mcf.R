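test_that("the KS statistic matches hand-checkable cases", {
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$D, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(2, 3, 4))$D, 1 / 3)
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("the KS statistic equals the brute-force oracle on random data", {
  set.seed(20)
  for (rep in 1:100) {
    n1 <- sample(2:50, 1); n2 <- sample(2:50, 1)
    ## mix continuous and tied integer samples
    if (rep %% 2 == 0) {
      x1 <- rnorm(n1); x2 <- rnorm(n2, mean = runif(1, -1, 1))
    } else {
      x1 <- sample(0:8, n1, replace = TRUE)
      x2 <- sample(2:10, n2, replace = TRUE)
    }
    D <- ks_two_sample(x1, x2)$D
    expect_equal(D, ks_oracle(x1, x2))
    ## cross-check against the stats implementation
    expect_equal(D, unname(suppressWarnings(
      stats::ks.test(x1, x2)$statistic)))
  }
})

test_that("D is invariant under strictly monotone transforms", {
  set.seed(21)
  x1 <- rexp(40); x2 <- rexp(30, rate = 2)
  D0 <- ks_two_sample(x1, x2)$D
  expect_equal(ks_two_sample(log(x1), log(x2))$D, D0)
  expect_equal(ks_two_sample(x1^3, x2^3)$D, D0)
})

test_that("asymptotic and exact p-values behave sensibly", {
  set.seed(22)
  x1 <- rnorm(100); x2 <- rnorm(120)
  p_same <- ks_two_sample(x1, x2)$p
  p_diff <- ks_two_sample(x1, rnorm(120, mean = 1))$p
  expect_gt(p_same, 0.01)
  expect_lt(p_diff, 1e-6)
  ## exact small-sample option agrees with stats::ks.test
  a <- rnorm(12); b <- rnorm(15)
  expect_equal(ks_two_sample(a, b, exact = TRUE)$p,
               stats::ks.test(a, b, exact = TRUE)$p.value)
  expect_error(ks_two_sample(rnorm(200), rnorm(200), exact = TRUE),
               "exact")
})

test_that("tertiary partition follows the interval conventions", {
  ## qNet-style: high below th1, boundary values to the safer side
  lab <- partition_by_metric(c(50, 60, 80), 57, 70)
  expect_equal(as.character(lab), c("high", "intermediate", "low"))
  expect_equal(as.character(partition_by_metric(70, 57, 70)), "low")
  expect_equal(as.character(partition_by_metric(57, 57, 70)), "intermediate")
  ## Th_EAD-style: boundary values to the riskier side
  labr <- partition_by_metric(c(90, 95), 90, 95, boundary = "risky")
  expect_equal(as.character(labr), c("high", "intermediate"))
  ## mirrored orientation for APD90
  lab_apd <- partition_by_metric(c(250, 350, 400), 307, 367,
                                 orientation = "high_is_high_risk")
  expect_equal(as.character(lab_apd), c("low", "intermediate", "high"))
  ## no-EAD sentinel goes to the low-risk side, flagged
  labna <- partition_by_metric(c(80, NA), 90, 95, boundary = "risky")
  expect_equal(as.character(labna), c("high", "low"))
  expect_equal(attr(labna, "n_sentinel"), 1)
  expect_error(partition_by_metric(1, 5, 2), "below")
})

test_that("the reference EAD-threshold column reproduces its printed counts", {
  t5 <- table5()
  lab <- partition_by_metric(t5$th_ead_c1, 90, 95, boundary = "risky")
  correct <- as.character(lab) == t5$risk
  expect_equal(sum(correct), 21)
  expect_equal(as.numeric(tapply(correct, factor(t5$risk,
    c("high", "intermediate", "low")), sum)), c(7, 9, 5))
})

test_that("MCF ranks a threshold-defining parameter at D = 1", {
  set.seed(23)
  X <- as.data.frame(matrix(runif(400 * 5), ncol = 5))
  names(X) <- paste0("X", 1:5)
  lab <- ifelse(X$X4 > 0.6, "pos", "neg")
  res <- mcf_rank(X, lab, contrasts = list(c("pos", "neg")))
  expect_equal(res$D[res$parameter == "X4"], 1)
  ## independent parameters stay below the permutation null at this n
  null95 <- quantile(replicate(200, {
    sh <- sample(lab)
    ks_two_sample(X$X1[sh == "pos"], X$X1[sh == "neg"])$D
  }), 0.95)
  others <- res$D[res$parameter != "X4"]
  expect_true(all(others <= null95 + 1e-9))
})

test_that("empty contrast subsets are skipped with a warning", {
  X <- data.frame(a = runif(10), b = runif(10))
  lab <- rep("one", 10)
  expect_warning(res <- mcf_rank(X, lab,
                                 contrasts = list(c("one", "two"))),
                 "empty")
  expect_null(res)
})
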