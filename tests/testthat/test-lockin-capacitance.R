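test_that("gp_from_re_im is the plug-in formula with Re<=0 masking", {
  expect_equal(gp_from_re_im(100e-12, 100e-12), 200e-12)
  # open-pore limit: Re -> 0+ gives a huge estimate
  expect_gt(gp_from_re_im(1e-18, 100e-12), 1e-3)
  out <- gp_from_re_im(c(100e-12, -1e-12, 50e-12), c(1, 1, 1) * 1e-10)
  expect_true(is.na(out[2]) && !anyNA(out[c(1, 3)]))
  expect_error(gp_from_re_im(c(-1e-12, 0), c(1e-12, 1e-12)),
               "whole segment")
})

test_that("gp_from_im matches its closed form and flags its limits", {
  omega <- 2 * pi * 20000; Cv <- 1e-15; wc <- omega * Cv
  expect_equal(gp_from_im(wc / 2, Cv, omega), wc)
  expect_true(is.infinite(gp_from_im(wc, Cv, omega)))
  expect_true(is.na(gp_from_im(0, Cv, omega)))
  expect_gt(gp_from_im(0.999 * wc, Cv, omega), 30 * wc)
})

test_that("both Gp routes agree with each other and ground truth on forward pores", {
  omega <- 2 * pi * 20000
  for (Cv in c(0.2e-15, 1e-15, 10e-15)) {
    gp_true <- 10^seq(log10(10e-12), log10(10e-9), length.out = 25)
    y <- pore_admittance(gp_true, Cv, omega)
    g1 <- gp_from_re_im(y$Re, y$Im)
    g2 <- gp_from_im(y$Im, Cv, omega)
    expect_equal(g1, gp_true, tolerance = 1e-6)
    expect_equal(g2, gp_true, tolerance = 1e-6)
    expect_equal(g1, g2, tolerance = 1e-6)
  }
})

test_that("gp_from_im is strictly increasing in Im on (0, omega*Cv)", {
  omega <- 2 * pi * 20000; Cv <- 1e-15; wc <- omega * Cv
  im <- seq(0.01, 0.99, by = 0.01) * wc
  expect_true(all(diff(gp_from_im(im, Cv, omega)) > 0))
})

test_that("step detector finds suprathreshold steps and never subthreshold ones", {
  sim <- pore_trace(0, Cv = 1e-15)
  ev <- detect_capacitance_steps(sim$trace)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$direction, "endocytic")
  expect_equal(ev$Cv, 1e-15, tolerance = 0.02)
  expect_equal(ev$t_step, 2, tolerance = 0.01)
  # 0.15 fF is below the 0.2 fF reliability threshold
  small <- pore_trace(0, Cv = 0.15e-15)
  expect_equal(nrow(detect_capacitance_steps(small$trace)), 0L)
  # exocytic steps are recognized by sign
  cfg <- quiet_cfg()
  ex <- simulate_fission_trace(list(pore_event(2, "exocytic", 1e-15)), cfg)
  expect_equal(detect_capacitance_steps(ex$trace)$direction, "exocytic")
})

test_that("detector recovers injected steps against ground truth at SNR >= 5", {
  cfg0 <- quiet_cfg(fs = 5000, dur = 10)
  sizes <- seq(0.3e-15, 1.5e-15, length.out = 8)
  noise <- noise_for_snr(min(sizes), 5, cfg0)
  hits <- 0; errs <- c()
  for (i in seq_along(sizes)) {
    cfg <- quiet_cfg(seed = 100L + i, fs = 5000, dur = 10, noise = noise)
    sim <- simulate_fission_trace(
      lapply(1:3, function(k) pore_event(2 * k, "endocytic", sizes[i])),
      cfg)
    ev <- detect_capacitance_steps(sim$trace)
    ev <- ev[ev$direction == "endocytic", ]
    for (k in 1:3) {
      j <- which(abs(ev$t_step - 2 * k) < 0.1)
      if (length(j) == 1) {
        hits <- hits + 1
        errs <- c(errs, abs(ev$Cv[j] - sizes[i]) / sizes[i])
      }
    }
  }
  expect_gte(hits / (3 * length(sizes)), 0.95)
  expect_lte(stats::median(errs), 0.10)
})

test_that("fission-pore duration is accurate and gated by the 15 ms validity rule", {
  # linear 40 ms closure, noiseless, through the 1 ms 4-pole filter
  sim <- pore_trace(0.04)
  ev <- measure_all_pores(sim$trace, detect_capacitance_steps(sim$trace))
  expect_equal(ev$fission_pore_duration, 0.04, tolerance = 0.05)
  expect_true(ev$kinetics_valid)
  # 8 ms pore: measurable but excluded from kinetic statistics
  sim8 <- pore_trace(0.008)
  ev8 <- measure_all_pores(sim8$trace, detect_capacitance_steps(sim8$trace))
  expect_false(ev8$kinetics_valid)
  # instantaneous step: duration ~ 0 at the sampling/filter resolution
  sim0 <- pore_trace(0)
  ev0 <- measure_all_pores(sim0$trace, detect_capacitance_steps(sim0$trace))
  expect_lt(ev0$fission_pore_duration, 0.01)
  expect_false(ev0$kinetics_valid)
})

test_that("Gp_mean of a constant-conductance pore matches the simulated value", {
  cfg <- quiet_cfg()
  ev <- pore_event(2, "endocytic", 1e-15, pore_duration = 0.06,
                   Gp_profile = function(s) rep(300e-12, length(s)))
  sim <- simulate_fission_trace(list(ev), cfg)
  det <- detect_capacitance_steps(sim$trace)
  m <- measure_fission_pore(sim$trace, det[1, ])
  expect_equal(m$Gp_mean, 300e-12, tolerance = 0.15)
})

test_that("endocytic event counting respects the 5-minute window and direction", {
  ev <- data.frame(t_step = c(10, 100, 400), direction = "endocytic")
  expect_equal(count_endocytic_events(ev), 2L)
  expect_equal(count_endocytic_events(ev[0, ]), 0L)
  mixed <- data.frame(t_step = c(seq(10, 70, 10), 80, 90, 95),
                      direction = c(rep("endocytic", 7),
                                    rep("exocytic", 3)))
  expect_equal(count_endocytic_events(mixed), 7L)
})

test_that("equivalent-circuit inversion round-trips the forward model", {
  f <- 1000; omega <- 2 * pi * f
  fwd <- simulate_whole_cell_admittance(5e-12, 0.5e-9, 50e-9, f)
  sol <- solve_equivalent_circuit(fwd$Y, fwd$Gt, omega)
  expect_equal(sol$Cm, 5e-12, tolerance = 1e-9)
  expect_equal(sol$Gm, 0.5e-9, tolerance = 1e-9)
  expect_equal(sol$Gs, 50e-9, tolerance = 1e-9)
  # grid round trip
  for (Cm in c(1e-12, 8e-12)) for (Gm in c(0.2e-9, 2e-9))
    for (Gs in c(10e-9, 100e-9)) {
      fw <- simulate_whole_cell_admittance(Cm, Gm, Gs, f)
      s <- solve_equivalent_circuit(fw$Y, fw$Gt, omega)
      expect_equal(s$Cm, Cm, tolerance = 1e-9)
      expect_equal(s$Gm, Gm, tolerance = 1e-9)
      expect_equal(s$Gs, Gs, tolerance = 1e-9)
    }
  # degenerate Cm = 0: factorisation consistent with Gt
  y0 <- simulate_whole_cell_admittance(0, 1e-9, 50e-9, f)
  s0 <- solve_equivalent_circuit(y0$Y, y0$Gt, omega)
  expect_equal(s0$Cm, 0)
  # returned factorisation (Gm = Gt, Gs -> Inf) reproduces Gt in the limit
  expect_equal(s0$Gm, y0$Gt, tolerance = 1e-9)
  expect_true(is.infinite(s0$Gs))
  # dominant series access: Cm ~ Im(Y)/omega
  yd <- simulate_whole_cell_admittance(5e-12, 0.5e-9, 1e-5, f)
  sd_ <- solve_equivalent_circuit(yd$Y, yd$Gt, omega)
  expect_equal(Im(yd$Y) / omega, 5e-12, tolerance = 1e-3)
  # non-physical input rejected
  expect_error(solve_equivalent_circuit(complex(real = 1e-9,
                                                imaginary = 1e-9),
                                        2e-9, omega), "non-physical")
})

test_that("delta-Cm uses the 40-100 ms response window against a 50 ms baseline", {
  tt <- seq(0, 1, 1e-3)
  cm <- ifelse(tt < 0.5, 5000e-15, 5010e-15)
  rec <- whole_cell_record(tt, cm)
  expect_equal(delta_cm_exocytosis(rec, 0.45, 0.5), 10e-15)
  flat <- whole_cell_record(tt, rep(5e-12, length(tt)))
  expect_equal(delta_cm_exocytosis(flat, 0.45, 0.5), 0)
  # noisy injected jump recovered within 3 SEM of the window noise
  set.seed(7)
  noisy <- whole_cell_record(tt, cm + rnorm(length(tt), 0, 5e-15))
  n_win <- 60
  sem3 <- 3 * 5e-15 * sqrt(2 / n_win)
  expect_lt(abs(delta_cm_exocytosis(noisy, 0.45, 0.5) - 10e-15), sem3)
})

test_that("leak QC discards strictly above 150 pS", {
  expect_true(qc_leak(list(leak = 100e-12)))
  expect_true(qc_leak(list(leak = 150e-12)))
  expect_false(qc_leak(list(leak = 151e-12)))
})

test_that("calcium-influx charge excludes the first 10 ms and matches analytic integrals", {
  tt <- seq(0, 0.5, 2e-4)
  I <- ifelse(tt >= 0.2 & tt <= 0.3, -100, 0)
  expect_equal(ca_influx_charge(tt, I, 0.2, 0.3), 9, tolerance = 1e-6)
  expect_equal(ca_influx_charge(tt, numeric(length(tt)), 0.2, 0.3), 0)
  # decaying current: integral of 200*exp(-(t-onset)/0.02) over [0.21, 0.3]
  I2 <- ifelse(tt >= 0.2 & tt <= 0.3, -200 * exp(-(tt - 0.2) / 0.02), 0)
  analytic <- 200 * 0.02 * (exp(-0.01 / 0.02) - exp(-0.1 / 0.02))
  expect_equal(ca_influx_charge(tt, I2, 0.2, 0.3), analytic,
               tolerance = 0.01)
  expect_error(ca_influx_charge(tt, I, 0.2, 0.205), "exclusion")
})
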