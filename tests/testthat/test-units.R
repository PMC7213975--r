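test_that("firing rate is count over duration with half-open membership", {
  iv <- data.frame(start = 10, end = 20)
  expect_equal(firing_rate(seq(10, 19.8, length.out = 50), iv), 5)
  expect_equal(firing_rate(numeric(0), iv), 0)
  expect_error(firing_rate(1:3, iv[0, ]), "positive")

  ## half-open: a spike exactly at the end does not count
  expect_equal(firing_rate(c(10, 20), iv), 0.1)

  ## additivity over disjoint interval sets (duration-weighted)
  set.seed(2)
  st <- sort(runif(400, 0, 100))
  a <- data.frame(start = c(0, 30), end = c(10, 50))
  b <- data.frame(start = 70, end = 95)
  ra <- firing_rate(st, a); rb <- firing_rate(st, b)
  rab <- firing_rate(st, rbind(a, b))
  expect_equal(rab, (ra * 30 + rb * 25) / 55, tolerance = 1e-12)
})

test_that("ISI contamination counts refractory violations", {
  expect_equal(isi_contamination(seq(0, 1, by = 0.01)), 0)
  ## 2 violations among 2000 ISIs -> exactly 0.1%
  st <- cumsum(c(0, rep(0.01, 1998), 0.001, 0.001))
  expect_equal(isi_contamination(sort(st)), 2 / 2000)
  expect_true(is.na(isi_contamination(c(1))))

  ## Poisson closed form: P(ISI < r) = 1 - exp(-lambda * r)
  lam <- 8
  tr <- gen_state_spikes(lam, lam, intervals(), 2000, seed = 3)
  n_isi <- length(tr$spike_times) - 1
  expected <- 1 - exp(-lam * 0.0015)
  se <- sqrt(expected * (1 - expected) / n_isi)
  expect_lt(abs(isi_contamination(tr) - expected), 4 * se)
})

test_that("isolation distance matches Mahalanobis geometry and the oracle", {
  ## 1-d cluster with unit sample variance; noise at distance 2 -> ID = 4
  cl <- feature_cloud(matrix(c(-1, 1) / sqrt(2), 2, 1),
                      matrix(c(-2, 2), 2, 1))
  expect_equal(isolation_distance(cl), 4, tolerance = 1e-12)

  ## noise coincident with the cluster mean -> 0
  cl0 <- feature_cloud(matrix(c(-1, 1) / sqrt(2), 2, 1), matrix(0, 2, 1))
  expect_equal(isolation_distance(cl0), 0, tolerance = 1e-12)

  ## fewer noise than cluster points: unbounded isolation
  few <- feature_cloud(matrix(rnorm(40), 10, 4), matrix(rnorm(8), 2, 4))
  expect_identical(isolation_distance(few), Inf)

  ## random clouds: exact agreement with the brute-force oracle
  for (s in 1:5) {
    fc <- gen_feature_clouds(40, 60, dim = 8, separation = 3 * s, seed = s)
    expect_equal(isolation_distance(fc),
                 oracle_isolation_distance(fc$cluster_points,
                                           fc$noise_points),
                 tolerance = 1e-10)
  }

  ## invariance under invertible affine maps of feature space
  set.seed(6)
  fc <- gen_feature_clouds(50, 70, dim = 5, separation = 6, seed = 6)
  id0 <- isolation_distance(fc)
  for (i in 1:5) {
    A <- matrix(rnorm(25), 5, 5)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(25), 5, 5)
    b <- rnorm(5)
    shift <- function(M) sweep(M %*% t(A), 2, -b)
    fc2 <- feature_cloud(shift(fc$cluster_points), shift(fc$noise_points))
    expect_equal(isolation_distance(fc2), id0, tolerance = 1e-6)
  }
})

test_that("unit acceptance and RS/FS labels follow the QC rules", {
  wf <- function(ttp_ms, fs = 32000) {
    n_gap <- round(ttp_ms / 1000 * fs)
    spike_train(c(0, 1), waveform = list(
      samples = c(rep(0, 5), -10, rep(0, n_gap - 1), 6, rep(0, 5)), fs = fs))
  }
  ## ID 25, contamination 0.05%, width 0.6 ms -> accepted RS
  expect_identical(classify_unit(wf(0.6), unit_qc(25, 5e-4)), "accepted_RS")
  ## narrow waveform -> FS
  expect_identical(classify_unit(wf(0.25), unit_qc(25, 5e-4)), "accepted_FS")
  ## ID 15 -> rejected regardless of contamination
  expect_identical(classify_unit(wf(0.6), unit_qc(15, 0)), "rejected")
  ## missing waveform -> accepted but unclassified
  expect_identical(classify_unit(spike_train(c(0, 1)), unit_qc(25, 0)),
                   "accepted_unclassified")

  ## bimodal width population at noiseless 0.25 / 0.7 ms: perfect recovery
  widths <- rep(c(0.25, 0.7), each = 10)
  labels <- vapply(widths, function(w) classify_unit(wf(w), unit_qc(30, 0)),
                   character(1))
  expect_identical(labels, rep(c("accepted_FS", "accepted_RS"), each = 10))

  ## fixture table of hand-computed acceptance decisions
  fix <- read.csv(system.file("extdata", "unit_qc_fixture.csv",
                              package = "statephys"))
  got <- vapply(seq_len(nrow(fix)), function(i) {
    unit_qc(fix$isolation_distance[i], fix$isi_contamination[i])$accepted
  }, logical(1))
  expect_identical(got, fix$expected_accepted)
})

test_that("locomotion modulation index follows its formula and limits", {
  trials <- data.frame(onset_s = c(30, 60, 90), offset_s = c(35, 65, 95),
                       preceding_quiescence_s = 25, mean_speed_cm_s = 5,
                       run_duration_s = 5, accepted = TRUE)

  ## spikes only inside the L windows -> index exactly 1
  stL <- sort(c(seq(29.6, 30.4, by = 0.1), seq(59.6, 60.4, by = 0.1)))
  m1 <- locomotion_modulation(spike_train(stL), trials)
  expect_equal(m1$index, 1)
  expect_equal(m1$FR_Q, 0)

  ## rate-matched windows -> index 0 (regular 10-Hz train)
  m0 <- locomotion_modulation(spike_train(seq(0, 100, by = 0.1)), trials)
  expect_equal(m0$index, 0, tolerance = 1e-9)
  expect_equal(m0$FR_L, 10)

  ## antisymmetry: exchanging the rates in the two windows negates the index
  mk_rates <- function(rL, rQ) {
    st <- sort(unlist(lapply(trials$onset_s, function(on) {
      c(seq(on - 0.5, on + 0.5 - 1e-9, by = 1 / rL),
        seq(on - 5, on - 2 - 1e-9, by = 1 / rQ))
    })))
    locomotion_modulation(spike_train(st), trials)$index
  }
  expect_equal(mk_rates(12, 4), -mk_rates(4, 12), tolerance = 1e-9)

  ## trials whose [-5, -2] window leaves the session are dropped
  early <- trials
  early$onset_s[1] <- 3
  m2 <- locomotion_modulation(spike_train(seq(0, 100, by = 0.1)), early)
  expect_equal(m2$n_trials, 2L)

  ## degenerate cases carry the undefined marker
  silent <- locomotion_modulation(spike_train(numeric(0)), trials)
  expect_true(is.na(silent$index))
  none <- trials; none$accepted <- FALSE
  expect_true(is.na(locomotion_modulation(spike_train(1:10), none)$index))
})

test_that("modulation index converges to the closed form on generated sessions", {
  ## planted rate_Q 5 Hz, rate_L 10 Hz -> (10 - 5) / (10 + 5) = 1/3
  n_bouts <- 20
  spec <- data.frame(onset_s = 25 + (0:(n_bouts - 1)) * 30, duration_s = 5,
                     speed_cm_s = 8)
  bouts <- intervals(spec$onset_s, spec$onset_s + spec$duration_s)
  trials <- data.frame(onset_s = bouts$start, offset_s = bouts$end,
                       preceding_quiescence_s = 25, mean_speed_cm_s = 8,
                       run_duration_s = 5, accepted = TRUE)
  idx <- vapply(1:30, function(s) {
    tr <- gen_state_spikes(5, 10, bouts, 625, seed = 400 + s)
    locomotion_modulation(tr, trials)$index
  }, numeric(1))
  se <- sd(idx) / sqrt(length(idx))
  expect_lt(abs(mean(idx) - 1 / 3), 3 * se)
})
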