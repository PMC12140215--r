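test_that("gen_design is deterministic and respects gap constraints", {
  cfg <- design_config("exp1", n_participants = 3, seed = 7)
  t1 <- gen_design(cfg)
  t2 <- gen_design(cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # gaps inside (1, dur-1), >= 1.5 s apart within a stimulus
  expect_true(all(t1$gap_time > 1 & t1$gap_time < 19))
  sp <- tapply(t1$gap_time,
               interaction(t1$participant, t1$condition, t1$stimulus),
               function(g) if (length(g) > 1) min(diff(sort(g))) else Inf)
  expect_true(all(sp >= 1.5))
})

test_that("gen_design balances FM-phase bins and hits the design scale", {
  cfg <- design_config("exp1", n_participants = 2, seed = 3)
  tb <- gen_design(cfg)
  b <- phase_binning(9)
  # every fm_phase is a bin center
  expect_true(all(tb$fm_phase %in% b$centers))
  # near-uniform occupancy within participant x condition (counts differ <= 1)
  for (p in unique(tb$participant)) for (cc in unique(tb$condition)) {
    n <- tabulate(bin_phase(tb$fm_phase[tb$participant == p &
                                          tb$condition == cc], b), 9)
    expect_lte(diff(range(n)), 1)
  }
  # 5 blocks x 32 stimuli x 3-5 gaps: ~136 gaps per block
  per_block <- tapply(tb$gap_time,
                      interaction(tb$participant, tb$condition, tb$block),
                      length)
  expect_true(all(per_block >= 96 & per_block <= 160))
  # tACS lag varies across active trials
  expect_gt(diff(range(tb$tacs_lag[tb$stim == "tacs"])), pi)
  # infeasible packing errors out
  expect_error(design_config("exp1", stimulus_duration = 6,
                             gap_range = c(5, 5)), "1.5 s")
})

test_that("simulated outcomes follow the additive-cosine hit model", {
  # flat generator: rates flat across bins within binomial error
  cfg <- design_config("exp1", n_participants = 1, conditions = "11",
                       seed = 5)
  tb0 <- simulate_outcomes(gen_design(cfg),
                           behavioral_params(fm_amp = c("11" = 0)), seed = 2)
  br0 <- binned_hit_rates(tb0, phase_binning(9))
  expect_true(all(abs(br0$rate - 0.5) < 4 * sqrt(0.25 / br0$n)))
  # A = 0.2, pref = pi/2: binned rates converge to the analytic curve
  tb <- make_phase_table(9e5, n_bins = 9, base = 0.5, amp = 0.2,
                         pref = pi / 2, seed = 6)
  br <- binned_hit_rates(tb, phase_binning(9))
  expect_true(all(abs(br$rate - (0.5 + 0.2 * cos(br$center - pi / 2)))
                  < 0.01))
})

test_that("exp2 generator peaks at the latent resonance frequency", {
  cfg <- design_config("exp2", n_participants = 2, stimuli_per_block = 150,
                       seed = 8)
  pars <- behavioral_params(resonance_freq = 2, tacs_peak_amp = 0.15,
                            fm_pref_phase = 0.5, intrinsic_amp = 0.02)
  tb <- simulate_outcomes(gen_design(cfg), pars, seed = 3)
  amp_at <- function(f) {
    sub <- tb[tb$participant == 1 & tb$condition == f, ]
    entrainment_fit(sub, phase_binning(6), "tacs_phase")$amplitude
  }
  amps <- vapply(c("0.8", "2", "3.2", "4.4"), amp_at, numeric(1))
  expect_equal(names(which.max(amps)), "2")
  expect_gt(amps["2"], 0.08)
})

test_that("same seed gives identical simulated outcomes", {
  cfg <- design_config("exp3", n_participants = 2, seed = 4)
  tb <- gen_design(cfg)
  o1 <- simulate_outcomes(tb, seed = 11)
  o2 <- simulate_outcomes(tb, seed = 11)
  expect_identical(o1$accuracy, o2$accuracy)
  expect_false(identical(o1$accuracy,
                         simulate_outcomes(tb, seed = 12)$accuracy))
})

test_that("response classification applies the 100-1500 ms window", {
  # press 500 ms after the gap: hit
  r <- classify_responses(5.0, 5.5)
  expect_equal(r$accuracy, 1L)
  expect_equal(r$response_time, 0.5)
  expect_equal(r$false_alarms, 0)
  # press 50 ms after the gap: too early -> miss, press is a false alarm
  r <- classify_responses(5.0, 5.05)
  expect_equal(r$accuracy, 0L)
  expect_equal(r$false_alarms, 1)
  # press with no preceding gap: false alarm
  r <- classify_responses(c(5.0), c(2.0, 5.5))
  expect_equal(r$accuracy, 1L)
  expect_equal(r$false_alarms, 1)
  expect_equal(r$fa_times, 2.0)
  # each press credits at most one gap; first press in window wins
  r <- classify_responses(c(2.0, 2.6), c(2.8, 3.0))
  expect_equal(r$accuracy, c(1L, 1L))
  expect_equal(r$response_time, c(0.8, 0.4))
  # boundary: exactly +1.5 s is a hit, exactly +0.1 s is not
  expect_equal(classify_responses(1.0, 2.5)$accuracy, 1L)
  expect_equal(classify_responses(1.0, 1.1)$accuracy, 0L)
  expect_error(classify_responses(-1, 2), "negative")
})

test_that("press-stream simulation round-trips through the scorer", {
  gaps <- c(2, 4.5, 8, 12, 15)
  presses <- simulate_press_stream(gaps, p_hit = 1, fa_rate = 0, seed = 3)
  r <- classify_responses(gaps, presses)
  expect_equal(r$accuracy, rep(1L, 5))
  expect_equal(r$false_alarms, 0)
  presses <- simulate_press_stream(gaps, p_hit = 0, fa_rate = 0,
                                   duration = 20, seed = 3)
  r <- classify_responses(gaps, presses)
  expect_equal(sum(r$accuracy), 0)
  expect_equal(r$false_alarms, 0)
  # spontaneous presses outside every response window are false alarms
  presses <- simulate_press_stream(numeric(0), p_hit = 0, fa_rate = 1,
                                   duration = 20, seed = 4)
  r <- classify_responses(numeric(0), presses)
  expect_equal(r$false_alarms, length(presses))
})

test_that("EEG epoch simulation is phase-locked as configured", {
  ep <- simulate_eeg_epochs(n_trials = 8, freq = 2, fs = 100, duration = 5,
                            locked_amp = 1, noise_amp = 0,
                            phase_jitter_sd = 0, seed = 1)
  expect_equal(dim(ep$data), c(8, 9, 500))
  # perfectly locked, no noise: all trials identical
  expect_equal(ep$data[1, 1, ], ep$data[8, 9, ])
  expect_error(simulate_eeg_epochs(4, freq = 60, fs = 100), "fs/2")
  # determinism
  ep2 <- simulate_eeg_epochs(4, 2, fs = 100, duration = 2, noise_amp = 1,
                             seed = 5)
  ep3 <- simulate_eeg_epochs(4, 2, fs = 100, duration = 2, noise_amp = 1,
                             seed = 5)
  expect_identical(ep2$data, ep3$data)
})

test_that("trial tables and epoch sets round-trip through disk", {
  tb <- simulate_outcomes(gen_design(design_config("exp3",
                                                   n_participants = 1,
                                                   stimuli_per_block = 4,
                                                   seed = 2)), seed = 1)
  f <- file.path(tempdir(), "tt.csv")
  write_trial_table(tb, f)
  tb2 <- read_trial_table(f)
  expect_equal(tb2$accuracy, tb$accuracy)
  expect_equal(tb2$fm_phase, tb$fm_phase, tolerance = 1e-12)
  ep <- simulate_eeg_epochs(3, 2, fs = 50, duration = 2,
                            channel_labels = c("Cz", "Fz"), seed = 4)
  d <- file.path(tempdir(), "epochs")
  write_epochs(ep, d)
  ep2 <- read_epochs(d)
  expect_equal(ep2$data, ep$data, tolerance = 1e-12)
  expect_equal(ep2$channel_labels, ep$channel_labels)
  expect_equal(ep2$fs, ep$fs)
})
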