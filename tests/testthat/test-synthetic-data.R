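test_that("wheel generator obeys arc-length arithmetic and rejects bad bout specs", {
  ## no motion: constant angle, zero implied velocity
  still <- gen_wheel_trace(60, NULL, noise_sd_cm_s = 0, seed = 1)
  expect_true(all(abs(diff(still$wheel$angle)) < 1e-12))

  ## one 5 cm/s x 10 s bout covers 50 cm of wheel surface:
  ## unwrapped angle advance = 50 / (pi * 15) * 2 * pi rad
  one <- gen_wheel_trace(60, data.frame(onset_s = 20, duration_s = 10,
                                        speed_cm_s = 5),
                         noise_sd_cm_s = 0, seed = 1)
  d <- diff(one$wheel$angle)
  d <- d - 2 * pi * round(d / (2 * pi))
  expect_equal(sum(d), 50 / (pi * 15) * 2 * pi, tolerance = 1e-6)

  expect_error(gen_wheel_trace(60, data.frame(onset_s = c(5, 8),
                                              duration_s = c(5, 5),
                                              speed_cm_s = c(3, 3))),
               "overlapping")
  expect_error(gen_wheel_trace(60, data.frame(onset_s = 58, duration_s = 5,
                                              speed_cm_s = 3)),
               "within")
})

test_that("wheel velocity distribution is bimodal at 0 and the bout speed", {
  wt <- gen_wheel_trace(600, make_bout_spec(600, 8, speed_cm_s = 8, seed = 7),
                        noise_sd_cm_s = 0.3, seed = 7)
  v <- oracle_velocity(wt$wheel$t, wt$wheel$angle, 15)
  near0 <- mean(abs(v) < 2)
  near_speed <- mean(abs(v - 8) < 3)
  expect_gt(near0, 0.8)            # quiescence dominates
  expect_gt(near_speed, 0.04)      # bout plateau mode present
  expect_lt(mean(v > 3 & v < 5), 0.02)  # trough between the modes
})

test_that("generators are seed-deterministic and conserve session time", {
  a <- gen_wheel_trace(120, make_bout_spec(120, 2, seed = 3),
                       noise_sd_cm_s = 0.3, seed = 9)
  b <- gen_wheel_trace(120, make_bout_spec(120, 2, seed = 3),
                       noise_sd_cm_s = 0.3, seed = 9)
  expect_identical(a$wheel$angle, b$wheel$angle)

  comps <- data.frame(f_lo = 40, f_hi = 55, amplitude = 1)
  l1 <- gen_state_lfp(30, 1000, comps, seed = 4)
  l2 <- gen_state_lfp(30, 1000, comps, seed = 4)
  expect_identical(l1$samples, l2$samples)

  s1 <- gen_state_spikes(5, 10, a$true_bouts, 120, seed = 5)
  s2 <- gen_state_spikes(5, 10, a$true_bouts, 120, seed = 5)
  expect_identical(s1$spike_times, s2$spike_times)

  ## bout + quiescent gaps tile the session exactly
  gaps <- diff(c(0, as.vector(t(as.matrix(a$true_bouts))), 120))
  expect_equal(sum(gaps), 120)
})

test_that("state LFP respects Nyquist, band gains and absent bands", {
  comps <- data.frame(f_lo = c(3, 40), f_hi = c(6, 55), amplitude = c(1, 1))
  expect_error(gen_state_lfp(10, 100, data.frame(f_lo = 40, f_hi = 55,
                                                 amplitude = 1)),
               "Nyquist")

  ## amplitude 0 in the gamma band -> essentially no 40-55 Hz power
  c0 <- data.frame(f_lo = c(3, 40), f_hi = c(6, 55), amplitude = c(1.5, 0))
  lfp0 <- gen_state_lfp(60, 1000, c0, noise_sd = 0.1, seed = 2)
  ps <- compute_psd(lfp0, data.frame(start = 0, end = 60))
  expect_lt(relative_band_power(ps, c(40, 55))$relative_power, 0.02)

  ## gain 1 -> same gamma power inside and outside bouts
  bouts <- intervals(c(20, 60), c(40, 80))
  lfp1 <- gen_state_lfp(100, 1000, comps, band_gain_L = 1,
                        true_bouts = bouts, noise_sd = 0.1, seed = 3)
  pL <- compute_psd(lfp1, bouts)
  pQ <- compute_psd(lfp1, intervals(c(0, 40, 80), c(20, 60, 100)))
  gL <- relative_band_power(pL, c(40, 55))$relative_power
  gQ <- relative_band_power(pQ, c(40, 55))$relative_power
  expect_equal(gL, gQ, tolerance = 0.12)
})

test_that("state spikes have Poisson counts, honor zero rates and lock to phase", {
  ## homogeneous 5 Hz over 100 s: count near 500, Poisson-dispersed
  tr <- gen_state_spikes(5, 5, intervals(), 100, seed = 11)
  expect_true(abs(length(tr$spike_times) - 500) < 4 * sqrt(500))

  ## silent in locomotion: no spikes inside any bout
  bouts <- intervals(c(100, 300), c(150, 350))
  tr0 <- gen_state_spikes(5, 0, bouts, 500, seed = 12)
  expect_equal(sum(tr0$spike_times >= 100 & tr0$spike_times < 150) +
                 sum(tr0$spike_times >= 300 & tr0$spike_times < 350), 0)

  ## von-Mises thinning concentrates spike phases at the band peak
  comps <- data.frame(f_lo = 38, f_hi = 42, amplitude = 1)
  lfp <- gen_state_lfp(120, 1000, comps, noise_sd = 0.05, seed = 6)
  locked <- gen_state_spikes(20, 20, intervals(), 120,
                             locking = list(freq_Hz = 40, kappa = 3),
                             lfp = lfp, seed = 7)
  free <- gen_state_spikes(20, 20, intervals(), 120, seed = 7)
  resultant <- function(st) {
    ph <- statephys:::band_phase(lfp$samples, lfp$fs, 40)
    idx <- pmax(1, pmin(length(ph), round(st * lfp$fs) + 1))
    abs(mean(exp(1i * ph[idx])))
  }
  expect_gt(resultant(locked$spike_times), 0.4)
  expect_lt(resultant(free$spike_times), 0.1)
})

test_that("feature clouds control separation and degenerate cases", {
  expect_error(gen_feature_clouds(8, 10, dim = 8), "exceed dim")
  overlapping <- gen_feature_clouds(60, 80, dim = 4, separation = 0, seed = 2)
  expect_lt(isolation_distance(overlapping), 20)
  no_noise <- gen_feature_clouds(30, 0, dim = 4, separation = 5, seed = 2)
  expect_identical(isolation_distance(no_noise), Inf)
})

test_that("behavior and outcome cohorts plant recoverable ground truth", {
  ## equal-time preference 0 -> scorer centered on index 0
  geom <- arena_three_chamber()
  idx0 <- vapply(1:4, function(i) {
    s0 <- gen_sociability_session(0, geom, duration_s = 400, seed = 20 + i)
    score_sociability(s0$traj, geom)$time_index
  }, numeric(1))
  expect_lt(abs(mean(idx0)), 0.25)

  ## +0.4 vs -0.4 groups: scorer recovers the planted separation
  idx_pos <- vapply(1:8, function(i) {
    s <- gen_sociability_session(0.4, geom, duration_s = 400, seed = 100 + i)
    score_sociability(s$traj, geom)$time_index
  }, numeric(1))
  idx_neg <- vapply(1:8, function(i) {
    s <- gen_sociability_session(-0.4, geom, duration_s = 400, seed = 200 + i)
    score_sociability(s$traj, geom)$time_index
  }, numeric(1))
  expect_lt(abs(mean(idx_pos) - 0.4), 0.15)
  expect_lt(abs(mean(idx_neg) + 0.4), 0.15)
  expect_gt(mean(idx_pos) - mean(idx_neg), 0.5)

  ## mortality hazard 0 -> everyone censored at 500 d
  spec <- cohort_spec(
    data.frame(label = "G", n = 6L),
    data.frame(label = "G", gamma_amp = 1, fr_mult = 1, mi_mult = 1,
               soc_pref = 0, marble_p = 0.5, mortality_hazard = 0,
               seizure_hazard = 0), control_label = "G", seed = 2)
  oc <- gen_outcome_cohort(spec)
  expect_true(all(oc$records$censored))
  expect_true(all(oc$records$death_age_d == 500))
})
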