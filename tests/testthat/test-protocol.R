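test_that("APD extraction is exact on piecewise-linear synthetic APs", {
  ## triangle: linear repolarization from peak to rest over R ms
  R <- 300
  tr <- synth_ap_trace("triangle", repol_ms = R, v_rest = -85, v_peak = 35,
                       dt = 0.25)
  apd90 <- compute_apd(tr$t, tr$V, 0.9, dia = -85)
  apd50 <- compute_apd(tr$t, tr$V, 0.5, dia = -85)
  ## crossing of peak - f*amp happens f*R after the peak (upstroke at ~t=1)
  expect_equal(apd90, 0.9 * R + 0.5, tolerance = 0.01)
  expect_equal(apd50, 0.5 * R + 0.5, tolerance = 0.01)
  ## square AP of width W: APD50 = APD90 = W
  W <- 200
  sq <- synth_ap_trace("square", repol_ms = W, dt = 0.25)
  expect_equal(compute_apd(sq$t, sq$V, 0.9, dia = -85), W, tolerance = 0.3)
  expect_equal(compute_apd(sq$t, sq$V, 0.5, dia = -85), W, tolerance = 0.3)
  ## unresolved repolarization is flagged, not invented
  flat <- synth_ap_trace("square", repol_ms = 2000, cl = 1000)
  res <- compute_apd(flat$t, flat$V, 0.9, dia = -85)
  expect_true(is.na(res))
  expect_true(isTRUE(attr(res, "unresolved")))
})

test_that("qNet is the trapezoidal integral of the six-current sum", {
  z <- synth_ap_trace(cl = 2000)
  expect_equal(compute_qnet(z), 0)
  one <- synth_ap_trace(cl = 2000, currents = c(IKr = 1))
  expect_equal(compute_qnet(one), 2000)
  ## additivity over current profiles
  a <- synth_ap_trace(cl = 1000, currents = c(ICaL = -0.5))
  b <- synth_ap_trace(cl = 1000, currents = c(IKs = 0.25))
  ab <- synth_ap_trace(cl = 1000, currents = c(ICaL = -0.5, IKs = 0.25))
  expect_equal(compute_qnet(ab), compute_qnet(a) + compute_qnet(b))
  ## sampled sine matches the analytic integral within trapezoid error
  cl <- 1000; w <- 2 * pi / 500
  s <- synth_ap_trace(cl = cl, dt = 0.5)
  s$currents[, "Ito"] <- sin(w * s$t)
  analytic <- (1 - cos(w * cl)) / w
  expect_equal(compute_qnet(s), analytic, tolerance = 1e-3)
  ## INa is deliberately not part of the net-current set
  s2 <- synth_ap_trace(cl = 1000, currents = c(INa = -5))
  expect_equal(compute_qnet(s2), 0)
  ## missing current series is reported by name
  s3 <- synth_ap_trace()
  s3$currents <- s3$currents[, colnames(s3$currents) != "IKs"]
  expect_error(compute_qnet(s3), "IKs")
})

test_that("calcium-transient durations follow the exponential closed form", {
  lam <- 1 / 80
  tr <- synth_ap_trace(cl = 2000, ca = list(base = 100, amp = 400,
                                            lambda = lam), dt = 0.25)
  cm <- compute_ca_metrics(tr$t, tr$Cai, dia = 100)
  expect_equal(cm$CaTD90 - cm$CaTD50, log(5) / lam, tolerance = 0.5)
  expect_equal(cm$CaTD50, log(2) / lam, tolerance = 0.5)
  expect_equal(cm$peakCa, 500, tolerance = 1)
  ## constant calcium: zero-duration transient
  flat <- compute_ca_metrics(0:100, rep(100, 101))
  expect_equal(flat$CaTD50, 0)
  expect_equal(flat$CaTD90, 0)
  expect_equal(flat$peakCa, flat$diastolicCa)
})

test_that("paced MinCell metrics satisfy the ordering invariants", {
  m <- get_cell_model("mincell")
  mx <- derive_all(run_pacing(m, block_vector(), fast_protocol(20)))
  expect_gte(mx$APD90, mx$APD50)
  expect_gte(mx$CaTD90, mx$CaTD50)
  expect_gte(mx$peakCa, mx$diastolicCa)
})

test_that("an all-zero block vector reproduces the control trace", {
  m <- get_cell_model("mincell")
  a <- run_pacing(m, block_vector(), fast_protocol(10))
  b <- run_pacing(m, block_vector(bINa = 0, sbIKr = 0, Ku = 0), fast_protocol(10))
  expect_equal(a$V, b$V, tolerance = 1e-8)
})

test_that("strong ICaL block lowers the calcium transient", {
  m <- get_cell_model("mincell")
  ctrl <- derive_all(run_pacing(m, block_vector(), fast_protocol(20)))
  blk <- derive_all(run_pacing(m, block_vector(bICaL = 80), fast_protocol(20)))
  expect_lt(blk$peakCa, ctrl$peakCa)
})

test_that("the reduced beat count is already at quasi-steady state", {
  m <- get_cell_model("mincell")
  a50 <- derive_all(run_pacing(m, block_vector(), fast_protocol(50)))
  a1000 <- derive_all(run_pacing(m, block_vector(),
                                 pacing_protocol(n_beats = 1000)))
  expect_lt(abs(a50$APD90 - a1000$APD90), 1)
})

test_that("halving the output step changes APD90 and qNet by < 0.1%", {
  m <- get_cell_model("mincell")
  a <- derive_all(run_pacing(m, block_vector(), fast_protocol(20, dt = 1)))
  b <- derive_all(run_pacing(m, block_vector(), fast_protocol(20, dt = 0.5)))
  expect_lt(abs(a$APD90 - b$APD90) / b$APD90, 1e-3)
  expect_lt(abs(a$qNet - b$qNet) / abs(b$qNet), 1e-3)
})

test_that("peak-IKr reduction curves are ordered by trapping corner", {
  m <- get_cell_model("mincell")
  scan <- peak_ikr_scan(m, sbikr_grid = c(0, 1, 4), n_beats = 15)
  free <- scan[scan$Vhalf == -200, ]
  trap <- scan[scan$Vhalf == -1, ]
  expect_equal(free$reduction[free$sbIKr == 0], 0)
  expect_equal(trap$reduction[trap$sbIKr == 0], 0)
  expect_true(all(diff(free$reduction[order(free$sbIKr)]) >= 0))
  expect_true(all(diff(trap$reduction[order(trap$sbIKr)]) >= 0))
  ## pointwise: the free-unbinding corner reduces peak IKr least
  expect_true(all(free$reduction[order(free$sbIKr)] <=
                  trap$reduction[order(trap$sbIKr)] + 1e-9))
})
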