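test_that("ROI extraction averages boxes, tracks injected time courses, checks bounds", {
  # uniform frames give a constant series
  stack <- simulate_image_stack(c(20, 20), 0:9, data.frame()[0, ],
                                timecourse = rep(0, 10), background = 100)
  s <- extract_roi_timeseries(stack, data.frame(row = 10, col = 10))
  expect_equal(s[[1]]$F, rep(100, 10))
  # Gaussian bouton follows the injected time course
  tc <- c(rep(0, 4), seq(0, 1, length.out = 6))
  stack2 <- simulate_image_stack(c(30, 30), 0:9,
                                 data.frame(row = 15, col = 15, amp = 80),
                                 timecourse = tc, background = 50,
                                 noise_sd = 0.5, seed = 3)
  s2 <- extract_roi_timeseries(stack2, data.frame(row = 15, col = 15))
  expect_gt(stats::cor(s2[[1]]$F, tc), 0.99)
  # out-of-bounds box errors
  expect_error(extract_roi_timeseries(stack, data.frame(row = 1, col = 10)),
               "bounds")
})

test_that("iGluSnFR ROI auto-detection respects the >10 pixel rule and stays silent on noise", {
  stim <- stim_protocol(10, 2, 5)
  tc <- c(rep(0, 5), rep(1, 10))
  big <- simulate_image_stack(c(40, 40), 0:14,
                              data.frame(row = 20, col = 20, amp = 60,
                                         sigma = 2.2),
                              timecourse = tc, noise_sd = 1, seed = 2)
  rois <- detect_iglusnfr_rois(big, stim)
  expect_equal(length(rois), 1L)
  expect_gt(attr(rois, "areas")[1], 10)
  tiny <- simulate_image_stack(c(40, 40), 0:14,
                               data.frame(row = 20, col = 20, amp = 60,
                                          sigma = 0.8),
                               timecourse = tc, noise_sd = 1, seed = 2)
  expect_equal(length(detect_iglusnfr_rois(tiny, stim)), 0L)
  # stimulus-free stacks never produce ROIs
  for (s in 1:20) {
    quiet <- simulate_image_stack(c(30, 30), 0:14, data.frame()[0, ],
                                  timecourse = rep(0, 15), noise_sd = 1,
                                  seed = s)
    expect_equal(length(detect_iglusnfr_rois(quiet, stim)), 0L)
  }
})

test_that("normalization modes behave and are idempotent", {
  stim <- stim_protocol(10, 2, 5)
  tt <- 0:19
  F <- c(rep(100, 5), 100 + 10 * (1:5), rep(150, 5), rep(120, 5))
  ser <- roi_timeseries(tt, F, stim = stim)
  n1 <- normalize_response(ser, "dF_over_dFmax")
  expect_equal(max(n1$F), 1)
  n2 <- normalize_response(ser, "dF_over_F0")
  expect_equal(max(n2$F), 0.5)
  # idempotence
  expect_identical(normalize_response(n1, "dF_over_dFmax"), n1)
  expect_error(normalize_response(n1, "dF_over_F0"), "different mode")
  # flat series -> all zeros under either mode
  flat <- roi_timeseries(tt, rep(100, 20), stim = stim)
  expect_equal(normalize_response(flat, "dF_over_dFmax")$F, rep(0, 20))
  expect_equal(normalize_response(flat, "dF_over_F0")$F, rep(0, 20))
  # F0 = 0 errors for dF/F0
  zero <- roi_timeseries(tt, c(rep(0, 5), rep(10, 15)), stim = stim)
  expect_error(normalize_response(zero, "dF_over_F0"), "positive")
})

test_that("endocytic tau fit is exact on noiseless decays and flags flat series", {
  cfg <- sim_config(sampling_rate = 1, duration = 100, noise_sd = 0)
  stim <- stim_protocol(100, 20, 10)
  for (tau in c(5, 20, 60)) {
    sim <- simulate_phluorin_series(tau, stim, cfg = cfg)
    fit <- fit_endocytic_tau(normalize_response(sim$series,
                                                "dF_over_dFmax"))
    expect_equal(fit$tau, tau, tolerance = 1e-3)
    expect_false(fit$flagged)
  }
  plateau <- simulate_phluorin_series(Inf, stim, cfg = cfg)
  pf <- fit_endocytic_tau(normalize_response(plateau$series,
                                             "dF_over_dFmax"))
  expect_true(pf$flagged)
})

test_that("tau recovery is nearly unbiased on a noisy bouton cohort", {
  stim <- stim_protocol(100, 20, 10)
  taus <- vapply(1:40, function(s) {
    cfg <- sim_config(seed = s, sampling_rate = 1, duration = 100,
                      noise_sd = 10)
    sim <- simulate_phluorin_series(15, stim, cfg = cfg, dF_max = 100)
    fit_endocytic_tau(normalize_response(sim$series, "dF_over_dFmax"))$tau
  }, numeric(1))
  expect_equal(mean(taus), 15, tolerance = 0.05)
})

test_that("reacidification rate comes back as 1/tau from the acid window", {
  cfg <- sim_config(sampling_rate = 2, duration = 120, noise_sd = 0)
  stim <- stim_protocol(100, 20, 30,
                        acid_windows = list(c(10, 20), c(50, 70)))
  sim <- simulate_phluorin_series(20, stim, reacid = list(tau_reacid = 4),
                                  cfg = cfg)
  f <- fit_reacidification(sim$series, c(50, 70))
  expect_equal(f$rate, 0.25, tolerance = 1e-3)
  # non-decaying window flagged with rate ~ 0
  flat <- roi_timeseries(seq(0, 119.5, 0.5), rep(40, 240))
  ff <- fit_reacidification(flat, c(50, 70))
  expect_true(ff$flagged)
  expect_lt(abs(ff$rate), 0.01)
})

test_that("calcium peak and decay recover the generator values", {
  cfg <- sim_config(sampling_rate = 50, duration = 10, noise_sd = 0)
  stim <- stim_protocol(1, 10, 2)
  sim <- simulate_ca_series(0.8, 0.6, stim, cfg)
  ns <- normalize_response(sim$series, "dF_over_F0")
  pk <- peak_transient(ns)
  expect_equal(pk$peak, 0.8, tolerance = 1e-6)
  expect_false(pk$flagged)
  expect_equal(fit_ca_decay(ns)$tau, 0.6, tolerance = 0.01)
  flat <- roi_timeseries(seq(0, 10, 0.02), rep(100, 501), stim = stim)
  expect_equal(peak_transient(normalize_response(flat, "dF_over_F0"))$peak, 0)
})

test_that("fura ratio is elementwise, gain-invariant, and masks bad denominators", {
  F340 <- c(100, 200, 300)
  expect_equal(fura_ratio(F340, F340), rep(1, 3))
  expect_equal(fura_ratio(2 * F340, F340), rep(2, 3))
  g <- 3.7
  expect_equal(fura_ratio(g * F340, g * c(50, 60, 70)),
               fura_ratio(F340, c(50, 60, 70)))
  out <- fura_ratio(c(1, 1), c(1, 0))
  expect_true(is.na(out[2]))
})

test_that("photobleaching gate keeps <=2% decline and rejects more", {
  tt <- 0:99
  mk <- function(frac) roi_timeseries(tt, 100 * (1 - frac * tt / 99))
  expect_true(photobleach_check(mk(0.01)))
  expect_true(photobleach_check(mk(0.02)))
  expect_false(photobleach_check(mk(0.05)))
})
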