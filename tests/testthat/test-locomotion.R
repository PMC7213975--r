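make_wheel <- function(t, angle, diameter = 15) {
  w <- data.frame(t = t, angle = angle %% (2 * pi))
  attr(w, "wheel_diameter") <- diameter
  class(w) <- c("wheel_trace", "data.frame")
  w
}

test_that("angle-to-velocity conversion matches arc-length kinematics", {
  t <- seq(0, 10, by = 0.02)

  ## constant angle -> zero velocity
  v0 <- angle_to_velocity(make_wheel(t, rep(1.3, length(t))))
  expect_true(all(abs(v0$v) < 1e-12))

  ## one revolution per second on a 15-cm wheel = pi * 15 cm/s
  v1 <- angle_to_velocity(make_wheel(t, 2 * pi * t))
  expect_equal(stats::median(v1$v), pi * 15, tolerance = 1e-9)

  ## the 2*pi wrap produces no velocity transient
  v_true <- 10
  omega <- v_true / 7.5
  vw <- angle_to_velocity(make_wheel(t, omega * t), smoothing_window_s = 0)
  expect_lt(max(abs(vw$v - v_true)), 1e-9)
  vo <- oracle_velocity(t, (omega * t) %% (2 * pi), 15)
  expect_lt(max(abs(vo - v_true)), 1e-9)

  expect_error(angle_to_velocity(make_wheel(c(0, 1, 1, 2), rep(0, 4))),
               "increasing")
})

test_that("segmentation covers the session and finds a noiseless step exactly", {
  t <- seq(0, 200, by = 0.02)

  ## all-quiescent trace: one Q interval, no bouts
  seg0 <- segment_states(structure(data.frame(t = t, v = rep(0, length(t))),
                                   class = c("velocity_trace", "data.frame")))
  expect_equal(nrow(seg0$bouts), 0)
  expect_equal(nrow(seg0$quiescent), 1)
  expect_equal(seg0$quiescent$end - seg0$quiescent$start, 200)

  ## noiseless step 0 -> 5 cm/s at t = 100: change point within 0.5 s, and
  ## at the same sample as the exhaustive single-split oracle
  v <- ifelse(t < 100, 0, 5) + 0
  seg <- segment_states(structure(data.frame(t = t, v = v),
                                  class = c("velocity_trace", "data.frame")))
  expect_equal(nrow(seg$bouts), 1)
  expect_lt(abs(seg$bouts$start - 100), 0.5)
  k <- oracle_single_split(rank(abs(v)) / length(v))
  expect_lt(abs(t[k] - seg$bouts$start), 0.05)

  expect_error(segment_states(data.frame(t = numeric(0), v = numeric(0))),
               "empty")
})

test_that("segmentation recovers planted bouts with high F1 and keeps invariants", {
  wt <- gen_wheel_trace(600, make_bout_spec(600, 8, seed = 7),
                        noise_sd_cm_s = 0.3, seed = 7)
  v <- angle_to_velocity(wt$wheel)
  seg <- segment_states(v)
  expect_gte(onset_f1(seg$bouts$start, wt$true_bouts$start, tol = 0.5), 0.95)

  ## coverage: L and Q tile the span with no overlap
  all_iv <- rbind(seg$bouts, seg$quiescent)
  all_iv <- all_iv[order(all_iv$start), ]
  expect_equal(all_iv$start[-1], all_iv$end[-nrow(all_iv)], tolerance = 1e-9)
  expect_equal(min(all_iv$start), seg$span[1])
  expect_equal(max(all_iv$end), seg$span[2])

  ## monotonicity: a higher speed threshold never increases L time
  thresholds <- c(0.5, 1, 2, 4, 8)
  l_time <- vapply(thresholds, function(th) {
    s <- segment_states(v, speed_threshold_cm_s = th)
    sum(s$bouts$end - s$bouts$start)
  }, numeric(1))
  expect_true(all(diff(l_time) <= 1e-9))
})

## hand-built segmentation:
## Q(0,40) L(40,45) Q(45,66) L(66,70) Q(70,85) L(85,90) Q(90,200)
hand_seg <- function() {
  structure(list(bouts = data.frame(start = c(40, 66, 85),
                                    end = c(45, 70, 90)),
                 quiescent = data.frame(start = c(0, 45, 70, 90),
                                        end = c(40, 66, 85, 200)),
                 span = c(0, 200)),
            class = "state_segmentation")
}

test_that("quiescent-epoch selection applies the 20-s and 10-s rules", {
  seg <- hand_seg()

  ## firing: only Q intervals longer than 20 s (the 15-s one drops out)
  fire <- select_quiescent_epochs(seg, "firing")
  expect_equal(fire$start, c(0, 45, 90))

  ## lfp (trim convention): Q(0,40) followed by a bout -> (20, 30);
  ## Q(45,66) trims to (65, 56) and is dropped; Q(90,200) has no next bout
  ## so only the 20-s stationarity trim applies -> (110, 200)
  lfp <- select_quiescent_epochs(seg, "lfp")
  expect_equal(lfp, data.frame(start = c(20, 110), end = c(30, 200)))

  ## duration convention keeps the whole >20-s interval minus the pre-bout
  ## exclusion
  lfp2 <- select_quiescent_epochs(seg, "lfp",
                                  stationary_convention = "duration")
  expect_equal(lfp2, data.frame(start = c(0, 45, 90), end = c(30, 56, 200)))

  ## property: every returned interval satisfies the selection predicates
  for (s in 1:20) {
    wt <- gen_wheel_trace(300, make_bout_spec(300, 4, seed = s),
                          noise_sd_cm_s = 0.3, seed = s)
    sg <- segment_states(angle_to_velocity(wt$wheel))
    q_durs <- sg$quiescent$end - sg$quiescent$start
    ep <- select_quiescent_epochs(sg, "lfp")
    for (i in seq_len(nrow(ep))) {
      src <- which(sg$quiescent$start <= ep$start[i] &
                     sg$quiescent$end >= ep$end[i])
      expect_length(src, 1)
      expect_gt(q_durs[src], 20)
      expect_gte(ep$start[i] - sg$quiescent$start[src], 20 - 1e-9)
      nxt <- sg$bouts$start[sg$bouts$start >= ep$end[i] - 1e-9]
      if (length(nxt)) expect_gte(min(nxt) - ep$end[i], 10 - 1e-9)
    }
  }
})

test_that("locomotion-trial acceptance reproduces the three-part rule", {
  ## piecewise-constant speed: bouts with hand-chosen metadata
  ## A: prec Q 25 s, 5 cm/s, 5 s -> accepted
  ## B: prec Q 15 s, 5 cm/s, 10 s -> rejected (quiescence)
  ## C: prec Q 25 s, 5 cm/s, 1.5 s -> rejected (duration)
  ## D: prec Q 28.5 s, 0.9 cm/s, 10 s -> rejected (speed)
  seg <- structure(list(
    bouts = data.frame(start = c(25, 45, 80, 110),
                       end = c(30, 55, 81.5, 120)),
    quiescent = data.frame(start = c(0, 30, 55, 81.5, 120),
                           end = c(25, 45, 80, 110, 150)),
    span = c(0, 150)), class = "state_segmentation")
  t <- seq(0, 150, by = 0.1)
  sp <- numeric(length(t))
  sp[t >= 25 & t < 30] <- 5
  sp[t >= 45 & t < 55] <- 5
  sp[t >= 80 & t < 81.5] <- 5
  sp[t >= 110 & t < 120] <- 0.9
  v <- structure(data.frame(t = t, v = sp),
                 class = c("velocity_trace", "data.frame"))
  trials <- select_locomotion_trials(seg, v)
  expect_equal(trials$accepted, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(trials$preceding_quiescence_s, c(25, 15, 25, 28.5))

  ## generator session: decisions equal the rule applied to ground truth
  wt <- gen_wheel_trace(600, make_bout_spec(600, 8, bout_duration_s = 5,
                                            speed_cm_s = 8, seed = 5),
                        noise_sd_cm_s = 0.3, seed = 5)
  vv <- angle_to_velocity(wt$wheel)
  sg <- segment_states(vv)
  tr <- select_locomotion_trials(sg, vv)
  manual <- tr$preceding_quiescence_s > 20 & tr$mean_speed_cm_s > 1 &
    tr$run_duration_s > 2
  expect_identical(tr$accepted, manual)
  expect_true(all(tr$accepted))   # generator bouts satisfy the rule by design
})
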