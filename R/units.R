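## Single-unit analysis: firing rates over interval sets, sorting-quality
## metrics (ISI contamination, isolation distance), unit acceptance and
## RS/FS classification, and locomotion-onset modulation.

#' Mean firing rate over a set of intervals
#'
#' Total spike count inside the intervals (half-open membership
#' `[start, end)`) divided by the total interval duration.
#'
#' @param train `spike_train` or numeric vector of spike times (s).
#' @param iv interval table.
#' @return rate in Hz.
#' @export
firing_rate <- function(train, iv) {
  st <- if (inherits(train, "spike_train")) train$spike_times else as.numeric(train)
  dur <- total_duration(iv)
  if (dur <= 0) stop("total interval duration must be positive")
  count_in_intervals(st, iv) / dur
}

#' Inter-spike-interval contamination
#'
#' Fraction of inter-spike intervals shorter than the refractory period;
#' sorting purity metric (acceptance requires <= 0.1% at 1.5 ms).
#'
#' @param train `spike_train` or numeric spike times.
#' @param refractory_s refractory period (s, default 0.0015).
#' @return fraction in [0, 1]; NA when fewer than two spikes.
#' @export
isi_contamination <- function(train, refractory_s = 0.0015) {
  st <- if (inherits(train, "spike_train")) train$spike_times else as.numeric(train)
  if (length(st) < 2L) return(undefined_marker())
  isi <- diff(st)
  mean(isi < refractory_s)
}

#' Isolation distance of a sorted cluster
#'
#' Squared Mahalanobis distance — with respect to the cluster mean and
#' covariance — of the n-th closest noise point, where n is the cluster
#' size. Larger values mean better separation from noise; units are
#' accepted above 20.
#'
#' @param cloud `feature_cloud`.
#' @return isolation distance; `Inf` when there are fewer noise points than
#'   cluster points (no n-th neighbour exists: unbounded isolation).
#' @export
isolation_distance <- function(cloud) {
  cl <- cloud$cluster_points
  nz <- cloud$noise_points
  n <- nrow(cl); d <- ncol(cl)
  if (n < d + 1L) stop("cluster too small to estimate covariance")
  S <- stats::cov(cl)
  if (!is.finite(rcond_sym(S)) || rcond_sym(S) < 1e-12) {
    stop("singular cluster covariance")
  }
  if (nrow(nz) < n) return(Inf)
  d2 <- stats::mahalanobis(nz, colMeans(cl), S)
  sort(d2)[n]
}

## reciprocal condition estimate for a symmetric matrix
rcond_sym <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) return(0)
  min(ev) / max(ev)
}

#' Unit quality-control verdict
#'
#' @param isolation_distance isolation distance (ID).
#' @param isi_contamination ISI contamination fraction.
#' @param id_threshold acceptance threshold on ID (default 20).
#' @param contamination_threshold ISI contamination ceiling (default 0.001,
#'   i.e. 0.1% at the 1.5-ms refractory period).
#' @return `unit_qc`: list with the two metrics and `accepted`.
#' @export
unit_qc <- function(isolation_distance, isi_contamination,
                    id_threshold = 20, contamination_threshold = 0.001) {
  acc <- !is.na(isolation_distance) && !is.na(isi_contamination) &&
    isolation_distance > id_threshold &&
    isi_contamination <= contamination_threshold
  structure(list(isolation_distance = isolation_distance,
                 isi_contamination = isi_contamination,
                 accepted = isTRUE(acc)),
            class = "unit_qc")
}

#' Waveform trough-to-peak duration
#'
#' Time from the waveform trough to the subsequent peak, in milliseconds;
#' the conventional RS/FS discriminator.
#' @param waveform list(samples=, fs=).
#' @return duration in ms.
#' @export
trough_to_peak_ms <- function(waveform) {
  s <- waveform$samples
  i_tr <- which.min(s)
  if (i_tr >= length(s)) return(NA_real_)
  i_pk <- i_tr - 1L + which.max(s[i_tr:length(s)])
  (i_pk - i_tr) / waveform$fs * 1000
}

#' Classify a unit as accepted RS, accepted FS, or rejected
#'
#' Rejected unless the QC verdict holds (ID > 20 and ISI contamination
#' <= 0.1% at 1.5 ms). Accepted units are labeled regular-spiking (RS,
#' putative pyramidal) when the waveform trough-to-peak duration exceeds
#' the boundary, fast-spiking (FS) otherwise; without a waveform the unit
#' is accepted but unclassified.
#'
#' @param train `spike_train` (its `waveform`, if any, is used).
#' @param qc `unit_qc`.
#' @param rs_boundary_ms RS/FS trough-to-peak boundary (ms, default 0.4).
#' @return one of `"rejected"`, `"accepted_RS"`, `"accepted_FS"`,
#'   `"accepted_unclassified"`.
#' @export
classify_unit <- function(train, qc, rs_boundary_ms = 0.4) {
  if (!qc$accepted) return("rejected")
  if (is.null(train$waveform)) return("accepted_unclassified")
  ttp <- trough_to_peak_ms(train$waveform)
  if (is.na(ttp)) return("accepted_unclassified")
  if (ttp > rs_boundary_ms) "accepted_RS" else "accepted_FS"
}

#' Locomotion-onset firing-rate modulation
#'
#' FR_L is the firing rate in the [-0.5, 0.5] s window around locomotion
#' onset and FR_Q the rate in the [-5, -2] s quiescent window before onset,
#' both pooled across accepted trials (total spikes over total window
#' time). The modulation index is (FR_L - FR_Q) / (FR_L + FR_Q), bounded in
#' [-1, 1]. Trials whose [-5, -2] window would leave the session are
#' excluded.
#'
#' @param train `spike_train`.
#' @param trials data.frame from [select_locomotion_trials()].
#' @param session_start session start time (s, default 0).
#' @param l_window,q_window windows relative to onset (s).
#' @param per_trial average per-trial rates instead of pooling (default
#'   FALSE: pooled counts are robust for sparse trains).
#' @return `modulation_result`: list with `FR_L`, `FR_Q`, `index`,
#'   `n_trials`; `index` is NA when FR_L + FR_Q = 0 or no trial qualifies.
#' @export
locomotion_modulation <- function(train, trials, session_start = 0,
                                  l_window = c(-0.5, 0.5),
                                  q_window = c(-5, -2), per_trial = FALSE) {
  acc <- trials[trials$accepted, , drop = FALSE]
  acc <- acc[acc$onset_s + min(q_window, l_window) >= session_start, , drop = FALSE]
  if (nrow(acc) == 0L) {
    return(structure(list(FR_L = undefined_marker(), FR_Q = undefined_marker(),
                          index = undefined_marker(), n_trials = 0L),
                     class = "modulation_result"))
  }
  ivL <- intervals(acc$onset_s + l_window[1], acc$onset_s + l_window[2])
  ivQ <- intervals(acc$onset_s + q_window[1], acc$onset_s + q_window[2])
  st <- train$spike_times
  if (per_trial) {
    rL <- mean(vapply(seq_len(nrow(ivL)), function(i)
      count_in_intervals(st, ivL[i, , drop = FALSE]) / (l_window[2] - l_window[1]),
      numeric(1)))
    rQ <- mean(vapply(seq_len(nrow(ivQ)), function(i)
      count_in_intervals(st, ivQ[i, , drop = FALSE]) / (q_window[2] - q_window[1]),
      numeric(1)))
  } else {
    rL <- firing_rate(st, ivL)
    rQ <- firing_rate(st, ivQ)
  }
  idx <- if (rL + rQ == 0) undefined_marker() else (rL - rQ) / (rL + rQ)
  structure(list(FR_L = rL, FR_Q = rQ, index = idx, n_trials = nrow(acc)),
            class = "modulation_result")
}
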