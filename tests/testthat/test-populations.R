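test_that("the Saltelli arrangement has the prescribed row counts", {
  expect_warning(pop <- saltelli_population(n = 500, second_order = TRUE,
                                            seed = 1),
                 "power of 2")
  expect_equal(nrow(pop$samples), 500 * (2 * 9 + 2))
  r1 <- parameter_ranges()[1, , drop = FALSE]
  p1 <- saltelli_population(r1, n = 1, k = 1, second_order = TRUE, seed = 1)
  expect_equal(nrow(p1$samples), 4)
  pf <- saltelli_population(n = 8, second_order = FALSE, seed = 1)
  expect_equal(nrow(pf$samples), 8 * (9 + 2))
  expect_error(saltelli_population(parameter_ranges(), n = 4, k = 3),
               "does not match")
})

test_that("sampled rows respect the sampling bounds exactly", {
  pop <- saltelli_population(n = 16, seed = 5)
  r <- parameter_ranges()
  for (j in rownames(r)) {
    expect_true(all(pop$samples[[j]] >= r[j, "min"]))
    expect_true(all(pop$samples[[j]] <= r[j, "max"]))
  }
})

test_that("population generation is seed-deterministic", {
  a <- saltelli_population(n = 16, seed = 7)
  b <- saltelli_population(n = 16, seed = 7)
  c <- saltelli_population(n = 16, seed = 8)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, c$samples))
  pts <- matrix(runif(45), ncol = 9,
                dimnames = list(NULL, rownames(parameter_ranges())))
  k1 <- kde_population(pts, 200, seed = 3)
  k2 <- kde_population(pts, 200, seed = 3)
  expect_identical(k1$samples, k2$samples)
})

test_that("Sobol marginals are near-uniform", {
  u <- sobol_sequence(512, 9, seed = 2)
  for (j in 1:9) {
    D <- suppressWarnings(stats::ks.test(u[, j], "punif")$statistic)
    expect_lt(D, 0.05)
  }
})

test_that("the A/B/AB/BA block layout is positionally consistent", {
  ## AB_i differs from A in exactly column i (and BA_i from B likewise)
  pop <- saltelli_population(n = 4, second_order = TRUE, seed = 9)
  k <- 9; per <- 2 * k + 2
  X <- as.matrix(pop$samples)
  for (i in 1:4) {
    off <- (i - 1) * per
    A <- X[off + 1, ]; B <- X[off + per, ]
    for (j in seq_len(k)) {
      ab <- X[off + 1 + j, ]
      expect_equal(sum(ab != A), 1)
      expect_equal(unname(ab[j]), unname(B[j]))
      ba <- X[off + 1 + k + j, ]
      expect_equal(sum(ba != B), 1)
      expect_equal(unname(ba[j]), unname(A[j]))
    }
  }
})

test_that("KDE resampling collapses onto seed points as bandwidth -> 0", {
  set.seed(4)
  pts <- matrix(runif(27, 10, 20), ncol = 9,
                dimnames = list(NULL, rownames(parameter_ranges())))
  pop <- kde_population(pts, 50, bandwidth = 1e-9, seed = 1)
  d <- apply(as.matrix(pop$samples), 1, function(row)
    min(apply(pts, 1, function(s) max(abs(row - s)))))
  expect_lt(max(d), 1e-6)
})

test_that("accepted KDE rows stay inside the componentwise seed hull", {
  set.seed(5)
  pts <- matrix(runif(90), ncol = 9,
                dimnames = list(NULL, rownames(parameter_ranges())))
  pop <- kde_population(pts, 500, bandwidth = 0.08, seed = 2)
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  X <- as.matrix(pop$samples)
  for (j in 1:9) {
    expect_true(all(X[, j] >= lo[j] - 1e-12))
    expect_true(all(X[, j] <= hi[j] + 1e-12))
  }
})

test_that("KDE marginals match the truncated-mixture oracle", {
  ## with a product kernel, the marginal CDF of accepted samples in
  ## normalized coordinates is a weighted mixture of truncated normals,
  ## the weights being each seed's acceptance probability in the OTHER
  ## coordinates
  set.seed(6)
  n_seed <- 6; bw <- 0.08
  pts <- matrix(runif(n_seed * 9), ncol = 9,
                dimnames = list(NULL, rownames(parameter_ranges())))
  pop <- kde_population(pts, 5000, bandwidth = bw, seed = 3)
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  norm <- sweep(sweep(as.matrix(pop$samples), 2, lo, "-"), 2, hi - lo, "/")
  seeds_n <- sweep(sweep(pts, 2, lo, "-"), 2, hi - lo, "/")
  acc_prob <- function(s) pnorm((1 - s) / bw) - pnorm((0 - s) / bw)
  for (j in c(1, 5, 9)) {
    w <- vapply(seq_len(n_seed), function(i)
      prod(acc_prob(seeds_n[i, -j])), numeric(1))
    mix_cdf <- function(q) {
      num <- vapply(seq_len(n_seed), function(i) {
        (pnorm((q - seeds_n[i, j]) / bw) - pnorm((0 - seeds_n[i, j]) / bw))
      }, numeric(1))
      sum(w * pmax(num, 0)) / sum(w * acc_prob(seeds_n[, j]))
    }
    qs <- seq(0.02, 0.98, by = 0.02)
    D <- max(abs(vapply(qs, function(q) mean(norm[, j] <= q) - mix_cdf(q),
                        numeric(1))))
    expect_lt(D, 0.05)
  }
})

test_that("populations round-trip through CSV", {
  pop <- saltelli_population(n = 4, seed = 1)
  tmp <- tempfile(fileext = ".csv")
  write_population(pop, tmp)
  back <- read_population(tmp, scheme = "saltelli", n = 4,
                          second_order = TRUE, seed = 1)
  expect_equal(back$samples, pop$samples, tolerance = 1e-12)
})
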