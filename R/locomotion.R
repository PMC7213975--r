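## Locomotion state analysis: wheel angle -> velocity, change-point
## segmentation into locomotion (L) and quiescence (Q), and the epoch- and
## trial-selection rules every downstream state-conditioned analysis uses.

#' Convert a wheel angle trace to linear velocity
#'
#' Unwraps the angle (so the 2*pi -> 0 crossing produces no spike), converts
#' to arc length on the wheel surface, differentiates with central
#' differences and applies a boxcar smoother.
#'
#' @param wheel `wheel_trace` (data.frame `t`, `angle` with a
#'   `wheel_diameter` attribute, cm) as from [gen_wheel_trace()] or
#'   [read_wheel_csv()].
#' @param smoothing_window_s boxcar width in seconds (default 0.25, below
#'   the 2-s minimum bout of interest).
#' @return `velocity_trace`: data.frame `t` (s), `v` (cm/s, signed).
#' @export
angle_to_velocity <- function(wheel, smoothing_window_s = 0.25) {
  stopifnot(nrow(wheel) >= 2)
  t <- wheel$t
  if (any(diff(t) <= 0)) stop("wheel time base must be strictly increasing")
  diameter <- attr(wheel, "wheel_diameter")
  if (is.null(diameter)) diameter <- 15
  stopifnot(diameter > 0)

  ## unwrap: remove 2*pi jumps
  d <- diff(wheel$angle)
  d <- d - 2 * pi * round(d / (2 * pi))
  arc <- c(0, cumsum(d)) * diameter / 2

  n <- length(t)
  v <- numeric(n)
  v[2:(n - 1)] <- (arc[3:n] - arc[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  v[1] <- (arc[2] - arc[1]) / (t[2] - t[1])
  v[n] <- (arc[n] - arc[n - 1]) / (t[n] - t[n - 1])

  fs <- 1 / stats::median(diff(t))
  v <- moving_average(v, round(smoothing_window_s * fs))
  out <- data.frame(t = t, v = v)
  class(out) <- c("velocity_trace", "data.frame")
  out
}

## Rank-based binary segmentation. Candidate change points minimize the
## within-segment sum of squares of the globally rank-transformed speed,
## which tracks shifts in the velocity distribution without assuming
## Gaussianity; a split is kept when its cost reduction exceeds a BIC-style
## penalty.
rank_binseg <- function(r, min_len, penalty) {
  cps <- integer(0)
  segment_cost <- function(cs, cs2, i, j) {
    s <- cs[j + 1L] - cs[i]
    q <- cs2[j + 1L] - cs2[i]
    q - s * s / (j - i + 1L)
  }
  cs <- cumsum(c(0, r)); cs2 <- cumsum(c(0, r^2))
  recurse <- function(i, j) {
    n <- j - i + 1L
    if (n < 2L * min_len) return(invisible(NULL))
    ks <- (i + min_len - 1L):(j - min_len)
    left <- (cs[ks + 1L] - cs[i])
    nl <- ks - i + 1L
    right <- (cs[j + 1L] - cs[ks + 1L])
    nr <- j - ks
    tot_q <- cs2[j + 1L] - cs2[i]
    cost_split <- tot_q - left^2 / nl - right^2 / nr
    k <- ks[which.min(cost_split)]
    gain <- segment_cost(cs, cs2, i, j) - min(cost_split)
    if (gain > penalty) {
      cps <<- c(cps, k)
      recurse(i, k)
      recurse(k + 1L, j)
    }
    invisible(NULL)
  }
  recurse(1L, length(r))
  sort(cps)
}

#' Segment a session into locomotion and quiescence states
#'
#' Change-point detection on the speed trace (binary segmentation with a
#' rank-based distribution-difference cost and a BIC-style penalty), then
#' each segment is labeled locomotion (L) when its mean speed reaches
#' `speed_threshold_cm_s`, quiescence (Q) otherwise; adjacent segments with
#' the same label are merged. L and Q intervals tile the session exactly.
#'
#' @param v `velocity_trace` from [angle_to_velocity()].
#' @param min_segment_s minimum segment length (s).
#' @param penalty_scale multiplier on the `log(n)`-scaled penalty.
#' @param speed_threshold_cm_s segment-labeling speed threshold (cm/s).
#' @return `state_segmentation`: list with interval tables `bouts` (L),
#'   `quiescent` (Q) and the session `span`.
#' @export
segment_states <- function(v, min_segment_s = 0.5, penalty_scale = 10,
                           speed_threshold_cm_s = 1) {
  if (is.null(v) || nrow(v) == 0L) stop("empty velocity trace")
  if (any(!is.finite(v$v))) stop("velocity trace must be finite")
  speed <- abs(v$v)
  n <- length(speed)
  fs <- 1 / stats::median(diff(v$t))
  min_len <- max(2L, round(min_segment_s * fs))

  r <- rank(speed) / n
  ## noise scale of the rank series from first differences (robust to jumps)
  sigma2 <- stats::var(diff(r)) / 2
  if (!is.finite(sigma2) || sigma2 == 0) sigma2 <- 1e-12
  penalty <- penalty_scale * sigma2 * log(n)
  cps <- rank_binseg(r, min_len, penalty)

  bounds <- c(0L, cps, n)
  seg_start <- bounds[-length(bounds)] + 1L
  seg_end <- bounds[-1]
  lab <- vapply(seq_along(seg_start), function(i) {
    mean(speed[seg_start[i]:seg_end[i]]) >= speed_threshold_cm_s
  }, logical(1))

  ## boundary times at sample midpoints; session span at trace edges
  edge_time <- function(k) {
    if (k == 0L) v$t[1] else if (k == n) v$t[n] else (v$t[k] + v$t[k + 1L]) / 2
  }
  starts <- vapply(bounds[-length(bounds)], edge_time, numeric(1))
  ends <- vapply(bounds[-1], edge_time, numeric(1))

  ## merge adjacent same-label segments
  keep <- c(TRUE, lab[-1] != lab[-length(lab)])
  m_start <- starts[keep]
  m_lab <- lab[keep]
  m_end <- c(m_start[-1], ends[length(ends)])

  seg <- list(bouts = intervals(m_start[m_lab], m_end[m_lab]),
              quiescent = intervals(m_start[!m_lab], m_end[!m_lab]),
              span = c(v$t[1], v$t[n]))
  class(seg) <- "state_segmentation"
  stopifnot(abs(total_duration(seg$bouts) + total_duration(seg$quiescent) -
                diff(seg$span)) < 1e-9)
  seg
}

#' Select quiescent epochs for analysis
#'
#' Firing-rate analyses use quiescent intervals longer than 20 s. LFP
#' analyses additionally require the animal to have been stationary for at
#' least 20 s before data are used (the first 20 s of each quiescent
#' interval are discarded) and exclude data within 10 s of the next
#' locomotion bout. Set `stationary_convention = "duration"` for the weaker
#' reading in which a > 20 s quiescent interval is used whole (minus the
#' 10-s pre-bout exclusion).
#'
#' @param seg `state_segmentation`.
#' @param purpose `"firing"` or `"lfp"`.
#' @param min_quiescence_s minimum quiescent duration (s, default 20).
#' @param pre_bout_exclusion_s LFP pre-bout exclusion (s, default 10).
#' @param stationary_convention `"trim"` (default: usable data start
#'   `min_quiescence_s` after quiescence onset) or `"duration"`.
#' @return interval table of selected (possibly trimmed) epochs.
#' @export
select_quiescent_epochs <- function(seg, purpose = c("firing", "lfp"),
                                    min_quiescence_s = 20,
                                    pre_bout_exclusion_s = 10,
                                    stationary_convention = c("trim", "duration")) {
  purpose <- match.arg(purpose)
  stationary_convention <- match.arg(stationary_convention)
  q <- seg$quiescent
  long_enough <- interval_durations(q) > min_quiescence_s
  q <- q[long_enough, , drop = FALSE]
  if (purpose == "firing" || nrow(q) == 0L) {
    rownames(q) <- NULL
    return(q)
  }
  start <- if (stationary_convention == "trim") q$start + min_quiescence_s else q$start
  end <- q$end
  ## trim the pre-bout window only where a bout actually follows
  if (nrow(seg$bouts) > 0L) {
    followed <- vapply(q$end, function(e) {
      any(abs(seg$bouts$start - e) < 1e-9)
    }, logical(1))
    end[followed] <- end[followed] - pre_bout_exclusion_s
  }
  keep <- end > start
  intervals(start[keep], end[keep])
}

#' Build locomotion-onset trials with acceptance flags
#'
#' One candidate trial per bout. A trial is accepted when the preceding
#' quiescent period lasted longer than 20 s, mean speed from onset to the
#' locomotion offset exceeds 1 cm/s, and the run lasted longer than 2 s.
#'
#' @param seg `state_segmentation`.
#' @param v `velocity_trace` for the same session.
#' @param min_preceding_quiescence_s,min_mean_speed_cm_s,min_run_duration_s
#'   acceptance thresholds (defaults 20 s, 1 cm/s, 2 s).
#' @return data.frame, one row per bout: `onset_s`, `offset_s`,
#'   `preceding_quiescence_s`, `mean_speed_cm_s`, `run_duration_s`,
#'   `accepted`.
#' @export
select_locomotion_trials <- function(seg, v,
                                     min_preceding_quiescence_s = 20,
                                     min_mean_speed_cm_s = 1,
                                     min_run_duration_s = 2) {
  b <- seg$bouts
  if (nrow(b) == 0L) {
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      preceding_quiescence_s = numeric(0),
                      mean_speed_cm_s = numeric(0),
                      run_duration_s = numeric(0), accepted = logical(0)))
  }
  prev_end <- c(seg$span[1], b$end[-nrow(b)])
  preceding <- b$start - prev_end
  mean_speed <- vapply(seq_len(nrow(b)), function(i) {
    idx <- v$t >= b$start[i] & v$t < b$end[i]
    if (!any(idx)) return(0)
    mean(abs(v$v[idx]))
  }, numeric(1))
  dur <- b$end - b$start
  data.frame(onset_s = b$start, offset_s = b$end,
             preceding_quiescence_s = preceding,
             mean_speed_cm_s = mean_speed,
             run_duration_s = dur,
             accepted = preceding > min_preceding_quiescence_s &
               mean_speed > min_mean_speed_cm_s &
               dur > min_run_duration_s)
}

#' @export
print.state_segmentation <- function(x, ...) {
  cat(sprintf("state segmentation: %d locomotion bout(s), %d quiescent interval(s), span %.1f-%.1f s\n",
              nrow(x$bouts), nrow(x$quiescent), x$span[1], x$span[2]))
  invisible(x)
}
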