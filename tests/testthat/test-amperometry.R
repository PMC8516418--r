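amp_cfg <- function(seed = 1L, noise = 0, fs = 50000, dur = 20)
  sim_config(seed = seed, sampling_rate = fs, duration = dur,
             noise_sd = noise)

test_that("spike detection applies the >10 pA and 100-spike criteria", {
  cfg <- amp_cfg()
  one <- simulate_amperometric_trace(
    data.frame(t = 6, peak = 50, tau_decay = 0.002), cfg, stim_time = 5)
  expect_equal(nrow(detect_spikes(one$trace)), 1L)
  small <- simulate_amperometric_trace(
    data.frame(t = 6, peak = 8, tau_decay = 0.002), cfg, stim_time = 5)
  expect_equal(nrow(detect_spikes(small$trace)), 0L)
  many <- simulate_amperometric_trace(
    data.frame(t = 5.2 + (0:119) * 0.1, peak = 40, tau_decay = 0.002),
    amp_cfg(dur = 30), stim_time = 5)
  expect_equal(nrow(detect_spikes(many$trace)), 100L)
})

test_that("closed-form spike parameters: charge, halfwidth, decay tau", {
  cfg <- amp_cfg()
  sim <- simulate_amperometric_trace(
    data.frame(t = 6, peak = 50, tau_decay = 0.002), cfg, stim_time = 5)
  sp <- detect_spikes(sim$trace)
  p <- spike_params(sim$trace, sp[1, ])
  expect_equal(p$quantal_size, 0.1, tolerance = 0.005)
  expect_equal(p$halfwidth, 2 * log(2), tolerance = 0.02)
  expect_equal(p$tau_decay, 2, tolerance = 0.02)
  expect_equal(p$peak, 50, tolerance = 0.01)
})

test_that("rectangular pulse has width-equal halfwidth and area charge", {
  fs <- 50000
  tt <- seq(0, 20, 1 / fs)
  I <- ifelse(tt >= 6 & tt < 6.005, 20, 0)
  tr <- amperometric_trace(tt, I, fs, stim_time = 5)
  sp <- detect_spikes(tr)
  p <- spike_params(tr, sp[1, ])
  expect_equal(p$quantal_size, 0.1, tolerance = 0.01)
  expect_equal(p$halfwidth, 5, tolerance = 0.02)
})

test_that("foot detection measures 2 ms feet and excludes sub-0.5 ms feet", {
  cfg <- amp_cfg()
  mk <- function(fd) simulate_amperometric_trace(
    data.frame(t = 6, peak = 50, tau_decay = 0.002, rise_time = 3e-4,
               foot_amp = 5, foot_duration = fd), cfg, stim_time = 5)
  long <- mk(0.002)
  f <- detect_foot(long$trace, detect_spikes(long$trace)[1, ])
  expect_equal(f$foot_duration, 2, tolerance = 0.1)
  expect_false(f$excluded)
  expect_equal(f$foot_amp, 5, tolerance = 0.2)
  short <- mk(0.0003)
  fs_ <- detect_foot(short$trace, detect_spikes(short$trace)[1, ])
  expect_true(is.null(fs_) || fs_$excluded)
  # footless spike -> absent or excluded near-zero foot
  bare <- simulate_amperometric_trace(
    data.frame(t = 6, peak = 50, tau_decay = 0.002, rise_time = 3e-4),
    cfg, stim_time = 5)
  fb <- detect_foot(bare$trace, detect_spikes(bare$trace)[1, ])
  expect_true(is.null(fb) || fb$excluded)
})

test_that("no spike with true peak <= 10 pA survives detection across noise trials", {
  for (s in 1:20) {
    cfg <- amp_cfg(seed = s, noise = 1, fs = 10000)
    sim <- simulate_amperometric_trace(
      data.frame(t = c(6, 8, 10), peak = c(8, 9, 10), tau_decay = 0.003),
      cfg, stim_time = 5)
    sp <- detect_spikes(sim$trace)
    # allow only detections whose true underlying peak exceeds 10 pA: none here
    expect_equal(nrow(sp), 0L)
  }
})

test_that("spike frequency counts the 15 s post-stimulus window", {
  sp <- data.frame(t_peak = c(5, 10, 20))
  expect_equal(spike_frequency(sp, 0), 2L)
  expect_equal(spike_frequency(sp[0, , drop = FALSE], 0), 0L)
  cfg <- amp_cfg(dur = 40)
  sim <- simulate_amperometric_trace(
    data.frame(t = 5.5 + (0:29) * 0.45, peak = 40, tau_decay = 0.002),
    cfg, stim_time = 5)
  det <- detect_spikes(sim$trace)
  expect_equal(spike_frequency(det, 5), 30L)
})

test_that("cell medians equal brute-force medians and group stats run over cells", {
  p <- data.frame(peak = c(30, 50, 40), halfwidth = c(1, 2, 9),
                  tau_decay = c(2, 3, 4), quantal_size = c(.1, .2, .3))
  cs <- cell_summary(p, "c1")
  expect_equal(cs$halfwidth, sort(c(1, 2, 9))[2])
  expect_equal(cs$peak, 40)
  cells <- rbind(cell_summary(p, "c1"),
                 cell_summary(transform(p, halfwidth = halfwidth + 2), "c2"))
  g <- group_summary(cells)
  hw <- g[g$parameter == "halfwidth", ]
  expect_equal(hw$mean, 3)
  expect_equal(hw$sem, 1)
  expect_equal(hw$n_cells, 2)
  expect_warning(cell_summary(p[0, ], "empty"), "no included spikes")
})

test_that("noisy cohort medians recover generator parameters within 5%", {
  cfg <- amp_cfg(seed = 9, noise = 2, fs = 10000, dur = 80)
  n <- 60
  sim <- simulate_amperometric_trace(
    data.frame(t = 6 + (0:(n - 1)) * 1.2, peak = 60, tau_decay = 0.003,
               rise_time = 5e-4),
    cfg, stim_time = 5)
  det <- detect_spikes(sim$trace)
  det <- det[!det$overlapping, ]
  ps <- do.call(rbind, lapply(seq_len(nrow(det)), function(i)
    as.data.frame(spike_params(sim$trace, det[i, ]))))
  expect_equal(stats::median(ps$peak), 60, tolerance = 0.05)
  expect_equal(stats::median(ps$tau_decay), 3, tolerance = 0.05)
  # charge oracle: numerically integrate one noiseless template spike
  tmpl <- simulate_amperometric_trace(
    data.frame(t = 6, peak = 60, tau_decay = 0.003, rise_time = 5e-4),
    amp_cfg(fs = 10000, dur = 20), stim_time = 5)
  q_true <- trapz_q(tmpl$trace$time, tmpl$trace$I)
  expect_equal(stats::median(ps$quantal_size), q_true, tolerance = 0.05)
})
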