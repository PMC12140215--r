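test_that("tACS phase extraction recovers the phase of a slow oscillation", {
  fs <- 200
  t <- seq(0, 10, by = 1 / fs)
  x <- cos(2 * pi * 2 * t)
  ph <- extract_tacs_phase(x, fs)
  mid <- t > 2 & t < 8  # away from filter edges
  # phase ~0 at signal peaks
  peaks <- which(mid & abs(x - 1) < 1e-6)
  expect_true(all(abs(wrap_phase(ph[peaks])) < 0.05))
  # unwrapped slope ~ 2*pi*2 rad/s
  d <- wrap_phase(diff(ph[mid]))
  expect_equal(mean(d) * fs, 2 * pi * 2, tolerance = 0.01)
  # small additive noise: circular deviation < 0.1 rad away from edges
  set.seed(1)
  phn <- extract_tacs_phase(x + rnorm(length(x), 0, 0.05), fs)
  dev <- abs(wrap_phase(phn[mid] - 2 * pi * 2 * t[mid]))
  expect_lt(max(dev), 0.1)
  expect_error(extract_tacs_phase(rep(1, 1000), fs), "constant")
})

test_that("lag binning wraps the FM-tACS angular separation", {
  expect_equal(lag_binning(0.3, 0.3)$lag, 0)
  expect_equal(lag_binning(0, pi / 2)$lag, -pi / 2)
  lb <- lag_binning(0, pi / 2)
  expect_equal(lb$lag_bin, bin_phase(-pi / 2, phase_binning(6)))
  set.seed(2)
  lb <- lag_binning(runif(6000, -pi, pi), runif(6000, -pi, pi))
  occ <- tabulate(lb$lag_bin, 6)
  expect_true(all(occ > 800))  # near-uniform occupancy
})

test_that("lag profiles recover lag-dependent entrainment structure", {
  # lag-independent amplitude -> near-constant profile
  tb <- exp1_participant_table(30000, fm_amp = 0.15, tacs_mod = 0, seed = 3)
  prof <- profile_entrainment_by_lag(tb[tb$stim == "tacs", ])
  expect_equal(length(prof$entamp), 6)
  expect_lt(diff(range(prof$entamp)), 0.05)
  # A(lag) = A0 (1 + 0.5 cos(lag - 1.0)) -> peak near lag 1.0
  tb <- exp1_participant_table(60000, fm_amp = 0.15, tacs_mod = 0.5,
                               lag_opt = 1.0, seed = 4)
  prof <- profile_entrainment_by_lag(tb[tb$stim == "tacs", ])
  opt_bin <- bin_phase(1.0, phase_binning(6))
  expect_equal(which.max(prof$entamp), opt_bin)
  # empty cell -> error naming the cell
  tb2 <- tb[tb$stim == "tacs", ]
  drop <- bin_phase(tb2$fm_phase, phase_binning(9)) == 1 &
    bin_phase(tb2$tacs_lag, phase_binning(6)) == 2
  expect_error(profile_entrainment_by_lag(tb2[!drop, ]), "empty cell")
})

test_that("second-level fit finds the optimal lag exactly on cosine data", {
  lc <- phase_binning(6)$centers
  prof <- structure(list(lag_centers = lc,
                         entamp = 0.1 + 0.04 * cos(lc - 1.0),
                         fits = NULL, n_fm_bins = 9, n_lag_bins = 6),
                    class = "lag_profile")
  f <- second_level_fit(prof)
  expect_equal(f$phase, 1.0, tolerance = 1e-10)
  expect_equal(f$amplitude, 0.04, tolerance = 1e-10)
  # adding a constant leaves the optimal lag unchanged
  prof$entamp <- prof$entamp + 0.3
  expect_equal(second_level_fit(prof)$phase, 1.0, tolerance = 1e-10)
  # flat profile is degenerate
  prof$entamp <- rep(0.1, 6)
  expect_true(second_level_fit(prof)$degenerate)
})

test_that("realignment rotates to the nearest bin and excludes peak/trough", {
  lc <- phase_binning(6)$centers
  prof <- structure(list(lag_centers = lc, entamp = 1:6 / 10, fits = NULL,
                         n_fm_bins = 9, n_lag_bins = 6),
                    class = "lag_profile")
  # optimal exactly at bin 3's center -> rotation by 2 bins
  r <- realign_profile(prof, lc[3])
  expect_equal(r$shift, 2L)
  expect_equal(r$values, c(3:6, 1:2) / 10)
  expect_equal(sum(r$excluded), 2)
  expect_true(r$excluded[1])  # realigned zero bin
  expect_true(r$excluded[abs(abs(r$centers) - pi) < 1e-9])
  # realigning an already-aligned profile is the identity
  r0 <- realign_profile(prof, 0)
  expect_equal(r0$shift, 0L)
  expect_equal(r0$values, prof$entamp)
  # tie between two centers resolves to the lower-index bin
  rt <- realign_profile(prof, lc[1] + pi / 6)
  expect_equal(rt$shift, 0L)
})

test_that("half-cycle summary averages the retained adjacent bins", {
  lc <- phase_binning(6)$centers
  prof <- structure(list(lag_centers = lc,
                         entamp = c(9, 1, 2, 8, 3, 4) / 10, fits = NULL,
                         n_fm_bins = 9, n_lag_bins = 6),
                    class = "lag_profile")
  r <- realign_profile(prof, 0)
  h <- half_cycle_summary(r)
  # bins at +-60 deg around realigned zero; +-120 deg around pi
  expect_equal(h$tacs_plus, (0.1 + 0.4) / 2)
  expect_equal(h$tacs_minus, (0.2 + 0.3) / 2)
  # constant retained values -> plus = minus
  prof$entamp <- c(0.9, 0.5, 0.5, 0.1, 0.5, 0.5)
  h <- half_cycle_summary(realign_profile(prof, 0))
  expect_equal(h$tacs_plus, 0.5)
  expect_equal(h$tacs_minus, 0.5)
})

test_that("lag-dependent generator yields tacs_plus above tacs_minus", {
  tb <- exp1_participant_table(60000, fm_amp = 0.15, tacs_mod = 0.5,
                               lag_opt = -2.0, seed = 5)
  act <- tb[tb$stim == "tacs", ]
  prof <- profile_entrainment_by_lag(act)
  opt <- second_level_fit(prof)$phase
  expect_equal(wrap_phase(opt), -2.0, tolerance = 0.35)
  h <- half_cycle_summary(realign_profile(prof, opt))
  expect_gt(h$tacs_plus, h$tacs_minus)
})

test_that("rotating all tACS phases rotates the optimal lag, not the contrasts", {
  tb <- exp1_participant_table(40000, fm_amp = 0.15, tacs_mod = 0.6,
                               lag_opt = 0.5, seed = 6)
  act <- tb[tb$stim == "tacs", ]
  delta <- 2 * pi / 6  # a whole lag bin, so bin contents rotate exactly
  act2 <- act
  act2$tacs_phase <- wrap_phase(act$tacs_phase - delta)
  act2$tacs_lag <- wrap_phase(act$fm_phase - act2$tacs_phase)
  p1 <- profile_entrainment_by_lag(act)
  p2 <- profile_entrainment_by_lag(act2)
  o1 <- second_level_fit(p1)$phase
  o2 <- second_level_fit(p2)$phase
  expect_equal(wrap_phase(o2 - o1), delta, tolerance = 1e-6)
  h1 <- half_cycle_summary(realign_profile(p1, o1))
  h2 <- half_cycle_summary(realign_profile(p2, o2))
  expect_equal(h2$tacs_plus, h1$tacs_plus, tolerance = 1e-10)
  expect_equal(h2$tacs_minus, h1$tacs_minus, tolerance = 1e-10)
})

test_that("tACS effect z-scores assemble consistent contrasts", {
  tb <- exp1_participant_table(3000, fm_amp = 0.12, tacs_mod = 0.8,
                               lag_opt = 1, sham_frac = 0.2, seed = 7)
  eff <- tacs_effect_zscores(tb, n_perm = 100, seed = 2)
  expect_equal(eff$contrasts[["plus_minus_minus"]],
               eff$contrasts[["plus_minus_sham"]] -
                 eff$contrasts[["minus_minus_sham"]], tolerance = 1e-12)
  expect_true(all(is.finite(eff$z)))
  # determinism
  eff2 <- tacs_effect_zscores(tb, n_perm = 100, seed = 2)
  expect_identical(eff$z, eff2$z)
  # a lag permutation of the table lands inside its own null
  expect_lt(abs(eff2$z[["plus_minus_minus"]]), 30)
  expect_error(tacs_effect_zscores(tb[tb$stim == "tacs", ]), "sham")
})
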