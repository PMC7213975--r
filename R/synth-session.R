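## Synthetic single-session generators: wheel trace, state-modulated LFP,
## state-modulated (optionally phase-locked) spike trains, and sorting
## feature clouds. Every generator takes an explicit seed and is
## reproducible; planted ground truth is returned alongside the data and is
## consumed only by tests, never by the analysis pipeline.

#' Generate a wheel angle-sensor trace with planted locomotion bouts
#'
#' Emulates the magnetic angle sensor on a 15-cm running wheel. Bouts follow
#' an area-preserving trapezoidal speed profile (0.5 s rise and fall, plateau
#' scaled up so the distance covered equals `speed_cm_s * duration_s`), so
#' bout onsets are sharply defined while total distance matches the nominal
#' speed exactly.
#'
#' @param duration_s session length, seconds (> 0).
#' @param bout_spec data.frame with columns `onset_s`, `duration_s`,
#'   `speed_cm_s` (all >= 0); bouts must not overlap. NULL or zero rows
#'   means no locomotion.
#' @param noise_sd_cm_s standard deviation of white velocity noise, cm/s.
#' @param sample_rate_Hz wheel sampling rate, Hz.
#' @param wheel_diameter_cm wheel diameter, cm (default 15).
#' @param seed integer seed.
#' @return list with `wheel` (a `wheel_trace`: data.frame `t`, `angle` in
#'   [0, 2*pi), plus `wheel_diameter` attribute), `true_bouts` (interval
#'   table of planted (onset, offset)), and `true_velocity` (cm/s, noiseless).
#' @export
gen_wheel_trace <- function(duration_s, bout_spec = NULL, noise_sd_cm_s = 0,
                            sample_rate_Hz = 50, wheel_diameter_cm = 15,
                            seed = 1L) {
  stopifnot(duration_s > 0, sample_rate_Hz > 0, wheel_diameter_cm > 0,
            noise_sd_cm_s >= 0)
  if (is.null(bout_spec)) {
    bout_spec <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                            speed_cm_s = numeric(0))
  }
  stopifnot(all(c("onset_s", "duration_s", "speed_cm_s") %in% names(bout_spec)))
  if (any(bout_spec$speed_cm_s < 0)) stop("bout speeds must be >= 0")
  bout_spec <- bout_spec[order(bout_spec$onset_s), , drop = FALSE]
  off <- bout_spec$onset_s + bout_spec$duration_s
  if (nrow(bout_spec) > 1 &&
      any(bout_spec$onset_s[-1] < off[-nrow(bout_spec)])) {
    stop("overlapping bouts in bout_spec")
  }
  if (nrow(bout_spec) > 0 && (min(bout_spec$onset_s) < 0 ||
                              max(off) > duration_s)) {
    stop("bouts must lie within [0, duration_s]")
  }

  t <- seq(0, duration_s, by = 1 / sample_rate_Hz)
  v_true <- rep(0, length(t))
  ramp <- 0.5
  for (i in seq_len(nrow(bout_spec))) {
    on <- bout_spec$onset_s[i]; dur <- bout_spec$duration_s[i]
    sp <- bout_spec$speed_cm_s[i]
    r <- min(ramp, dur / 2)
    ## plateau scaled so the integral equals sp * dur (area-preserving)
    plateau <- if (dur > r) sp * dur / (dur - r) else 2 * sp
    rel <- t - on
    prof <- numeric(length(t))
    idx <- rel >= 0 & rel <= dur
    x <- rel[idx]
    prof[idx] <- plateau * pmin(1, pmin(x, dur - x) / r)
    v_true <- v_true + prof
  }

  v <- with_seed(seed, v_true + stats::rnorm(length(t), 0, noise_sd_cm_s))
  radius <- wheel_diameter_cm / 2
  arc <- c(0, cumsum((v[-1] + v[-length(v)]) / 2 * diff(t)))
  angle <- (arc / radius) %% (2 * pi)

  wheel <- data.frame(t = t, angle = angle)
  attr(wheel, "wheel_diameter") <- wheel_diameter_cm
  class(wheel) <- c("wheel_trace", "data.frame")
  list(wheel = wheel,
       true_bouts = intervals(bout_spec$onset_s, off),
       true_velocity = v_true)
}

#' Evenly spread bouts for a synthetic session
#'
#' Convenience builder: `n_bouts` bouts of the given duration and speed at
#' regular spacing with small seeded jitter, leaving at least
#' `min_gap_s` of quiescence between bouts.
#' @param duration_s session length (s).
#' @param n_bouts number of bouts.
#' @param bout_duration_s,speed_cm_s bout duration (s) and speed (cm/s).
#' @param min_gap_s minimum quiescent gap between bouts (s).
#' @param jitter_s maximal onset jitter (s).
#' @param seed integer seed.
#' @return bout_spec data.frame for [gen_wheel_trace()].
#' @export
make_bout_spec <- function(duration_s, n_bouts, bout_duration_s = 5,
                           speed_cm_s = 8, min_gap_s = 25, jitter_s = 3,
                           seed = 1L) {
  stopifnot(n_bouts >= 1)
  slot <- duration_s / n_bouts
  if (slot < bout_duration_s + min_gap_s) {
    stop("session too short for requested bouts and gaps")
  }
  with_seed(seed, {
    onset <- (seq_len(n_bouts) - 1) * slot + min_gap_s +
      stats::runif(n_bouts, 0, min(jitter_s, slot - bout_duration_s - min_gap_s))
    data.frame(onset_s = onset, duration_s = bout_duration_s,
               speed_cm_s = speed_cm_s)
  })
}

#' Generate a state-modulated LFP signal
#'
#' Each band component is Gaussian noise brick-wall filtered to
#' `[f_lo, f_hi]` and scaled to the requested RMS amplitude; inside
#' locomotion bouts the component is multiplied by its band gain. Broadband
#' white noise is added on top and the result is centered to zero mean.
#'
#' @param duration_s signal length (s).
#' @param fs_Hz sampling rate (Hz); must exceed twice the highest band edge.
#' @param band_components data.frame with columns `f_lo`, `f_hi`,
#'   `amplitude` (RMS, arbitrary microvolt units).
#' @param band_gain_L numeric vector (recycled) of multiplicative gains
#'   applied inside locomotion bouts, one per component.
#' @param true_bouts interval table of locomotion bouts (may be empty).
#' @param noise_sd broadband white-noise SD.
#' @param seed integer seed.
#' @return `lfp_signal`: list with `fs`, `samples`, `t0`.
#' @export
gen_state_lfp <- function(duration_s, fs_Hz = 1000, band_components,
                          band_gain_L = 1, true_bouts = intervals(),
                          noise_sd = 0.5, seed = 1L) {
  stopifnot(duration_s > 0, fs_Hz > 0)
  stopifnot(all(c("f_lo", "f_hi", "amplitude") %in% names(band_components)))
  if (any(band_components$f_hi > fs_Hz / 2)) {
    stop("band component above Nyquist frequency")
  }
  if (any(band_components$f_lo >= band_components$f_hi)) {
    stop("band f_lo must be below f_hi")
  }
  gains <- rep_len(band_gain_L, nrow(band_components))
  n <- round(duration_s * fs_Hz)
  t <- (seq_len(n) - 1) / fs_Hz
  inL <- in_intervals(t, true_bouts)

  samples <- with_seed(seed, {
    out <- stats::rnorm(n, 0, noise_sd)
    fgrid <- (seq_len(n) - 1) * fs_Hz / n
    fsym <- pmin(fgrid, fs_Hz - fgrid)   # two-sided frequency magnitude
    for (i in seq_len(nrow(band_components))) {
      w <- stats::rnorm(n)
      W <- stats::fft(w)
      keep <- fsym >= band_components$f_lo[i] & fsym <= band_components$f_hi[i]
      comp <- Re(stats::fft(W * keep, inverse = TRUE) / n)
      s <- stats::sd(comp)
      if (s > 0) comp <- comp / s * band_components$amplitude[i]
      comp[inL] <- comp[inL] * gains[i]
      out <- out + comp
    }
    out
  })
  lfp_signal(fs = fs_Hz, samples = samples - mean(samples), t0 = 0)
}

#' LFP signal container
#' @param fs sampling rate (Hz).
#' @param samples numeric vector, microvolts.
#' @param t0 time of the first sample (s).
#' @return object of class `lfp_signal`.
#' @export
lfp_signal <- function(fs, samples, t0 = 0) {
  stopifnot(fs > 0, all(is.finite(samples)))
  structure(list(fs = fs, samples = as.numeric(samples), t0 = t0),
            class = "lfp_signal")
}

#' Generate a state-modulated spike train
#'
#' Inhomogeneous Poisson process with rate `rate_Q_Hz` during quiescence and
#' `rate_L_Hz` inside locomotion bouts. The locomotion rate engages
#' `rate_lead_s` before each bout onset (default 0.5 s), emulating the
#' anticipatory firing-rate rise that precedes movement onset in
#' state-modulated cortical units; with the default lead the closed-form
#' modulation index over a [-0.5, 0.5] s onset window is exactly
#' `(rate_L - rate_Q) / (rate_L + rate_Q)`. Optional gamma phase locking is
#' implemented by thinning with a von-Mises-shaped acceptance probability on
#' the instantaneous phase of the LFP narrowband component at the locking
#' frequency, `exp(kappa * (cos(phi) - 1))`, so spikes concentrate at phase 0
#' (the band peak).
#'
#' @param rate_Q_Hz,rate_L_Hz quiescent and locomotion firing rates (Hz, >= 0).
#' @param true_bouts interval table of locomotion bouts.
#' @param duration_s session length (s).
#' @param locking NULL, or list(freq_Hz=, kappa=) with kappa >= 0.
#' @param lfp `lfp_signal` required when `locking` is given.
#' @param rate_lead_s anticipatory lead of the rate transition before bout
#'   onset (s).
#' @param seed integer seed.
#' @return `spike_train`: list with `spike_times` (sorted, s) and `unit_id`.
#' @export
gen_state_spikes <- function(rate_Q_Hz, rate_L_Hz, true_bouts = intervals(),
                             duration_s, locking = NULL, lfp = NULL,
                             rate_lead_s = 0.5, seed = 1L, unit_id = "u1") {
  stopifnot(rate_Q_Hz >= 0, rate_L_Hz >= 0, duration_s > 0)
  rate_iv <- if (nrow(true_bouts) > 0) {
    intervals(pmax(0, true_bouts$start - rate_lead_s), true_bouts$end)
  } else true_bouts
  rmax <- max(rate_Q_Hz, rate_L_Hz)
  st <- with_seed(seed, {
    if (rmax == 0) return(numeric(0))
    n_cand <- stats::rpois(1, rmax * duration_s)
    cand <- sort(stats::runif(n_cand, 0, duration_s))
    inL <- in_intervals(cand, rate_iv)
    rate <- ifelse(inL, rate_L_Hz, rate_Q_Hz)
    keep <- stats::runif(n_cand) < rate / rmax
    spikes <- cand[keep]
    if (!is.null(locking) && locking$kappa > 0) {
      if (is.null(lfp)) stop("phase locking requires an lfp signal")
      phase <- band_phase(lfp$samples, lfp$fs, locking$freq_Hz)
      idx <- pmin(length(phase),
                  pmax(1L, round((spikes - lfp$t0) * lfp$fs) + 1L))
      acc <- exp(locking$kappa * (cos(phase[idx]) - 1))
      spikes <- spikes[stats::runif(length(spikes)) < acc]
    }
    spikes
  })
  spike_train(st, unit_id = unit_id)
}

#' Spike-train container
#' @param spike_times numeric, seconds, sorted non-decreasing.
#' @param unit_id unit label.
#' @param waveform optional list(samples=, fs=) mean waveform.
#' @export
spike_train <- function(spike_times, unit_id = "u1", waveform = NULL) {
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times)) stop("spike times must be sorted")
  structure(list(unit_id = unit_id, spike_times = spike_times,
                 waveform = waveform),
            class = "spike_train")
}

#' Generate labeled cluster and noise feature clouds
#'
#' Fixture for sorting-quality metrics: `n_cluster` points drawn from a
#' standard normal in `dim` dimensions, and `n_noise` points from an
#' identity-covariance normal whose mean sits `separation` away along a
#' random direction.
#'
#' @param n_cluster cluster size (>= dim + 1 so covariance is estimable).
#' @param n_noise number of noise points.
#' @param dim feature dimensionality.
#' @param separation Euclidean offset of the noise centroid (>= 0).
#' @param seed integer seed.
#' @return `feature_cloud`: list with matrices `cluster_points`,
#'   `noise_points`.
#' @export
gen_feature_clouds <- function(n_cluster, n_noise, dim = 8, separation = 5,
                               seed = 1L) {
  if (n_cluster <= dim) stop("n_cluster must exceed dim (covariance estimable)")
  stopifnot(separation >= 0, n_noise >= 0)
  with_seed(seed, {
    cl <- matrix(stats::rnorm(n_cluster * dim), n_cluster, dim)
    dir <- stats::rnorm(dim)
    dir <- dir / sqrt(sum(dir^2))
    nz <- matrix(stats::rnorm(n_noise * dim), n_noise, dim) +
      matrix(rep(separation * dir, each = n_noise), n_noise, dim)
    feature_cloud(cl, nz)
  })
}

#' Feature-cloud container
#' @param cluster_points,noise_points numeric matrices with equal column count.
#' @export
feature_cloud <- function(cluster_points, noise_points) {
  cluster_points <- as.matrix(cluster_points)
  noise_points <- as.matrix(noise_points)
  if (nrow(noise_points) > 0 && ncol(noise_points) != ncol(cluster_points)) {
    stop("cluster and noise dimensionality differ")
  }
  structure(list(cluster_points = cluster_points, noise_points = noise_points),
            class = "feature_cloud")
}

#' Generate a full ground-truth recording session
#'
#' One head-fixed wheel session: wheel trace with planted bouts, LFP whose
#' named bands are state- and group-modulated, and spike trains with planted
#' quiescent/locomotion rates. The `truth` element is the ground-truth
#' sidecar consumed only by tests.
#'
#' @param duration_s session length (s).
#' @param n_bouts planted locomotion bouts.
#' @param gamma_amp,theta_amp RMS amplitudes of the 40-55 Hz and 3-6 Hz
#'   components.
#' @param gamma_gain_L,theta_gain_L locomotion gains for the two bands.
#' @param rate_Q_Hz,rate_L_Hz per-unit firing rates (recycled over units).
#' @param n_units number of spike trains.
#' @param locking optional phase-locking spec passed to [gen_state_spikes()].
#' @param wheel_noise_cm_s velocity noise SD (cm/s).
#' @param lfp_fs_Hz LFP sampling rate.
#' @param seed integer seed.
#' @return list with `wheel`, `lfp`, `spikes` (list of `spike_train`) and
#'   `truth` (bouts, rates, band gains, amplitudes).
#' @export
gen_session <- function(duration_s = 400, n_bouts = 8, gamma_amp = 1,
                        theta_amp = 1.5, gamma_gain_L = 0.7,
                        theta_gain_L = 1, rate_Q_Hz = 5, rate_L_Hz = 10,
                        n_units = 2, locking = NULL,
                        wheel_noise_cm_s = 0.3, lfp_fs_Hz = 1000, seed = 1L) {
  bouts <- make_bout_spec(duration_s, n_bouts, seed = seed)
  wt <- gen_wheel_trace(duration_s, bouts, noise_sd_cm_s = wheel_noise_cm_s,
                        seed = seed + 1L)
  comps <- data.frame(f_lo = c(3, 40), f_hi = c(6, 55),
                      amplitude = c(theta_amp, gamma_amp))
  lfp <- gen_state_lfp(duration_s, fs_Hz = lfp_fs_Hz, band_components = comps,
                       band_gain_L = c(theta_gain_L, gamma_gain_L),
                       true_bouts = wt$true_bouts, seed = seed + 2L)
  rq <- rep_len(rate_Q_Hz, n_units); rl <- rep_len(rate_L_Hz, n_units)
  spikes <- lapply(seq_len(n_units), function(i) {
    gen_state_spikes(rq[i], rl[i], wt$true_bouts, duration_s,
                     locking = locking, lfp = lfp, seed = seed + 10L + i,
                     unit_id = sprintf("u%02d", i))
  })
  list(wheel = wt$wheel, lfp = lfp, spikes = spikes,
       truth = list(bouts = wt$true_bouts,
                    rate_Q = rq, rate_L = rl,
                    band_gain = c(theta = theta_gain_L, gamma = gamma_gain_L),
                    band_amp = c(theta = theta_amp, gamma = gamma_amp),
                    seed = seed))
}
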