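test_that("instantaneous endocytic step is a clean omega*Cv down-step on Im only", {
  cfg <- quiet_cfg(lockin_filter_order = 0L)
  sim <- simulate_fission_trace(list(pore_event(2, "endocytic", 1e-15)), cfg)
  omega <- 2 * pi * cfg$lockin_frequency
  pre <- sim$trace$time < 2
  post <- sim$trace$time >= 2
  expect_equal(unique(sim$trace$Im[pre]), omega * 1e-15)
  expect_equal(unique(sim$trace$Im[post]), 0)
  expect_equal(max(abs(sim$trace$Re)), 0)
})

test_that("constant-Gp pore satisfies the (Re^2+Im^2)/Re identity at every sample", {
  cfg <- quiet_cfg(lockin_filter_order = 0L)
  ev <- pore_event(1, "endocytic", 1e-15, pore_duration = 0.5,
                   Gp_profile = function(s) rep(300e-12, length(s)))
  sim <- simulate_fission_trace(list(ev), cfg)
  in_pore <- sim$trace$time >= 1 & sim$trace$time < 1.5
  gp <- (sim$trace$Re[in_pore]^2 + sim$trace$Im[in_pore]^2) /
    sim$trace$Re[in_pore]
  expect_equal(gp, rep(300e-12, sum(in_pore)), tolerance = 1e-12)
})

test_that("event-free noiseless trace is a constant baseline", {
  cfg <- quiet_cfg()
  sim <- simulate_fission_trace(list(), cfg, re_baseline = 1e-12,
                                im_baseline = 5e-12)
  expect_equal(unique(sim$trace$Re), 1e-12)
  expect_equal(unique(sim$trace$Im), 5e-12)
})

test_that("overlapping pore events are rejected with a diagnostic", {
  cfg <- quiet_cfg()
  evs <- list(pore_event(1, "endocytic", 1e-15, pore_duration = 0.5),
              pore_event(1.2, "endocytic", 1e-15, pore_duration = 0.1))
  expect_error(simulate_fission_trace(evs, cfg), "overlapping")
})

test_that("identical seeds give bit-identical traces (determinism)", {
  mk <- function() {
    cfg <- quiet_cfg(seed = 42L, noise = 1e-12)
    simulate_fission_trace(list(pore_event(2, "endocytic", 1e-15)), cfg)
  }
  a <- mk(); b <- mk()
  expect_identical(a$trace$Im, b$trace$Im)
  expect_identical(a$trace$Re, b$trace$Re)
})

test_that("completed endocytic event changes Im by omega*Cv regardless of pore duration", {
  omega <- 2 * pi * 20000
  for (D in c(0, 0.02, 0.08)) {
    sim <- pore_trace(D)
    pre <- mean(sim$trace$Im[sim$trace$time < 1.5])
    post <- mean(sim$trace$Im[sim$trace$time > 2.5])
    expect_equal((pre - post) / omega, 1e-15, tolerance = 1e-9)
  }
})

test_that("patch-current generator obeys the delta_I = g(V)*V arithmetic and sign convention", {
  cfg <- quiet_cfg(fs = 5000, dur = 1)
  rectifying <- function(V) if (V > 0) 50e-12 else 5e-12
  up <- simulate_patch_current(0.04, rectifying, 0.5, 0, cfg)
  dn <- simulate_patch_current(-0.04, rectifying, 0.5, 0, cfg)
  expect_equal(up$truth$delta_I_pA, 2)
  expect_equal(dn$truth$delta_I_pA, -0.2)
  # upward drift of the plotted current at positive V
  expect_gt(mean(up$trace$I[up$trace$time > 0.6]),
            mean(up$trace$I[up$trace$time < 0.4]))
  # ohmic: equal magnitude, opposite sign
  ohm <- function(V) 20e-12
  a <- simulate_patch_current(0.04, ohm, 0.5, 0, cfg)$truth$delta_I_pA
  b <- simulate_patch_current(-0.04, ohm, 0.5, 0, cfg)$truth$delta_I_pA
  expect_equal(a, -b)
  # g = 0: flat trace up to the baseline slope
  flat <- simulate_patch_current(0.04, function(V) 0, 0.5, 2, cfg)
  expect_equal(max(abs(flat$trace$I - 2 * flat$trace$time)), 0)
})

test_that("amperometric charge identity: instant-rise exponential integrates to peak*tau", {
  cfg <- quiet_cfg(fs = 50000, dur = 1)
  sim <- simulate_amperometric_trace(
    data.frame(t = 0.5, peak = 50, tau_decay = 0.002), cfg)
  q <- trapz_q(sim$trace$time, sim$trace$I)
  expect_equal(q, 50 * 0.002, tolerance = 0.01)
  # foot plateau precedes the rise by construction
  simf <- simulate_amperometric_trace(
    data.frame(t = 0.5, peak = 50, tau_decay = 0.002, rise_time = 5e-4,
               foot_amp = 5, foot_duration = 0.002), cfg)
  foot_idx <- simf$trace$time >= 0.4985 & simf$trace$time < 0.4995
  expect_equal(unique(simf$trace$I[foot_idx]), 5)
  # empty spike list -> baseline only
  sim0 <- simulate_amperometric_trace(NULL, cfg)
  expect_equal(max(abs(sim0$trace$I)), 0)
})

test_that("pHluorin generator decays with tau_endo and supports plateau and acid pulses", {
  cfg <- quiet_cfg(fs = 1, dur = 100)
  stim <- stim_protocol(100, 20, 10)
  sim <- simulate_phluorin_series(20, stim, cfg = cfg, f0 = 100,
                                  dF_max = 100)
  post <- sim$series$time > stim$end
  expected <- 100 + 100 * exp(-(sim$series$time[post] - stim$end) / 20)
  expect_equal(sim$series$F[post], expected, tolerance = 1e-12)
  flatsim <- simulate_phluorin_series(Inf, stim, cfg = cfg)
  expect_equal(stats::sd(flatsim$series$F[post]), 0)
  # trapped decay in the second acid window has rate 1/tau_reacid
  cfg2 <- quiet_cfg(fs = 2, dur = 120)
  stim2 <- stim_protocol(100, 20, 30,
                         acid_windows = list(c(10, 20), c(50, 70)))
  sim2 <- simulate_phluorin_series(20, stim2, reacid = list(tau_reacid = 4),
                                   cfg = cfg2)
  w <- sim2$series$time >= 50 & sim2$series$time < 70
  y <- sim2$series$F[w]
  rate <- -stats::coef(stats::lm(log(y) ~ sim2$series$time[w]))[[2]]
  expect_equal(rate, 0.25, tolerance = 1e-9)
})

test_that("depressing-train generator hits its closed-form cases", {
  a <- simulate_depressing_train(250, 0.44, 0.9)
  expect_equal(a[1], 1)
  expect_true(all(diff(a) < 0))
  expect_equal(mean(utils::tail(a, 10)), 0.44, tolerance = 1e-6)
  expect_equal(simulate_depressing_train(10, 1, 0.5), rep(1, 10))
  expect_equal(simulate_depressing_train(5, 0.3, 0), c(1, rep(0.3, 4)))
  expect_error(simulate_depressing_train(10, 0.5, 1), "r must be < 1")
})

test_that("whole-cell admittance forward model has the right limits", {
  f <- 1000; omega <- 2 * pi * f
  # huge series access: Y ~ Gm + i omega Cm
  y <- simulate_whole_cell_admittance(5e-12, 0.5e-9, 0.5e-9 * 1e6, f)
  expect_equal(Re(y$Y), 0.5e-9, tolerance = 1e-4)
  expect_equal(Im(y$Y), omega * 5e-12, tolerance = 1e-4)
  # Cm = 0: purely real, equals Gt
  y0 <- simulate_whole_cell_admittance(0, 1e-9, 50e-9, f)
  expect_equal(Im(y0$Y), 0)
  expect_equal(Re(y0$Y), y0$Gt)
})
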