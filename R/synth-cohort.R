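## Synthetic cohort generators: group specifications with planted effects
## on gamma power, firing rates, locomotion modulation, sociability,
## marble burying, mortality and seizures; behavior sessions and outcome
## tables with ground-truth sidecars.

#' Cohort specification with planted per-group effects
#'
#' @param groups data.frame with columns `label`, `n` (animals per group,
#'   >= 1).
#' @param effects data.frame keyed by `label` with columns
#'   `gamma_amp` (multiplier on the 40-55 Hz component amplitude, >= 0),
#'   `fr_mult` (firing-rate multiplier, >= 0),
#'   `mi_mult` (multiplier on the planted locomotion modulation index,
#'   >= 0), `soc_pref` (planted sociability time index, signed, in
#'   [-1, 1]), `marble_p` (per-marble burial probability),
#'   `mortality_hazard` and `seizure_hazard` (per-day exponential hazards,
#'   >= 0).
#' @param control_label which group is the control.
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, effects, control_label = groups$label[1],
                        seed = 1L) {
  stopifnot(all(c("label", "n") %in% names(groups)), all(groups$n >= 1))
  need <- c("label", "gamma_amp", "fr_mult", "mi_mult", "soc_pref",
            "marble_p", "mortality_hazard", "seizure_hazard")
  stopifnot(all(need %in% names(effects)))
  stopifnot(all(groups$label %in% effects$label))
  num <- effects[, c("gamma_amp", "fr_mult", "mi_mult", "marble_p",
                     "mortality_hazard", "seizure_hazard")]
  stopifnot(all(num >= 0), all(abs(effects$soc_pref) <= 1))
  structure(list(groups = groups, effects = effects,
                 control_label = control_label, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default synthetic cohort mirroring an interneuron Mecp2-mutant study
#'
#' Five groups: control (CON) and pan-interneuron (DLX), VIP-, PV- and
#' SST-specific mutants. Planted effects follow the qualitative pattern of
#' such cohorts: reduced gamma amplitude and reduced locomotion modulation
#' in DLX and VIP, elevated firing rates in DLX/VIP/SST, reversed
#' sociability preference and impaired marble burying in DLX and VIP, and
#' strongly elevated mortality/seizure hazards in DLX (intermediate in
#' SST).
#'
#' @param n per-group animal counts, named by label.
#' @param seed integer seed.
#' @export
default_cohort_spec <- function(n = c(CON = 12, DLX = 5, VIP = 6, PV = 6,
                                      SST = 8), seed = 1L) {
  groups <- data.frame(label = names(n), n = as.integer(n))
  effects <- data.frame(
    label = c("CON", "DLX", "VIP", "PV", "SST"),
    gamma_amp = c(1, 0.7, 0.7, 1, 1),
    fr_mult = c(1, 3, 3, 1, 3),
    mi_mult = c(1, 0.3, 0.3, 1, 1),
    soc_pref = c(0.35, -0.35, -0.35, 0.35, 0.35),
    marble_p = c(0.6, 0.18, 0.18, 0.6, 0.6),
    mortality_hazard = c(0.0005, 0.0103, 0.0006, 0.0004, 0.0066),
    seizure_hazard = c(0.0004, 0.03, 0.001, 0.0009, 0.0016)
  )
  effects <- effects[effects$label %in% names(n), , drop = FALSE]
  cohort_spec(groups, effects, control_label = "CON", seed = seed)
}

group_effect <- function(spec, label) {
  spec$effects[match(label, spec$effects$label), ]
}

#' Generate an electrophysiology cohort with planted group effects
#'
#' One wheel session per animal (wheel trace, state-modulated LFP, spike
#' trains). Between-animal variability is lognormal on the gamma amplitude
#' (SD 0.15 on the log scale) and on the quiescent firing rate (SD 0.2);
#' the planted locomotion modulation index is `base_mi * mi_mult`, realized
#' by setting the locomotion rate to `rate_Q * (1 + m) / (1 - m)`.
#'
#' @param spec `cohort_spec`.
#' @param duration_s,n_bouts,n_units per-session parameters.
#' @param base_rate_Q control quiescent rate (Hz).
#' @param base_mi control modulation index (default 1/3).
#' @return list of per-animal entries: `animal_id`, `group`, `session`
#'   (from [gen_session()]), `truth` (planted gamma amplitude, rates,
#'   modulation index).
#' @export
gen_ephys_cohort <- function(spec, duration_s = 400, n_bouts = 8,
                             n_units = 2, base_rate_Q = 5, base_mi = 1 / 3) {
  out <- list()
  k <- 0L
  for (gi in seq_len(nrow(spec$groups))) {
    lab <- spec$groups$label[gi]
    eff <- group_effect(spec, lab)
    for (ai in seq_len(spec$groups$n[gi])) {
      k <- k + 1L
      aseed <- spec$seed + 1000L * gi + ai
      av <- with_seed(aseed, c(stats::rlnorm(1, 0, 0.15),
                               stats::rlnorm(1, 0, 0.2)))
      gamma_amp <- eff$gamma_amp * av[1]
      rate_Q <- base_rate_Q * eff$fr_mult * av[2]
      m <- min(0.95, base_mi * eff$mi_mult)
      rate_L <- rate_Q * (1 + m) / (1 - m)
      sess <- gen_session(duration_s = duration_s, n_bouts = n_bouts,
                          gamma_amp = gamma_amp, rate_Q_Hz = rate_Q,
                          rate_L_Hz = rate_L, n_units = n_units,
                          gamma_gain_L = 1, seed = aseed + 17L)
      out[[k]] <- list(animal_id = sprintf("%s_%02d", lab, ai), group = lab,
                       session = sess,
                       truth = list(gamma_amp = gamma_amp, rate_Q = rate_Q,
                                    rate_L = rate_L, mi = m))
    }
  }
  out
}

## Reflected random walk biased toward a scheduled target zone: visits
## alternate between zones according to planted occupancy probabilities;
## within a visit the walk drifts toward the zone's anchor point and is
## reflected at the arena bounds.
biased_walk <- function(duration_s, dt, bounds, schedule_targets,
                        visit_mean_s, drift = 2.5, sigma = 6, seed = 1L) {
  with_seed(seed, {
    n <- round(duration_s / dt)
    t <- (seq_len(n) - 1) * dt
    x <- numeric(n); y <- numeric(n)
    x[1] <- mean(bounds[c(1, 3)]); y[1] <- mean(bounds[c(2, 4)])
    target <- schedule_targets()
    next_switch <- stats::rexp(1, 1 / visit_mean_s)
    for (i in 2:n) {
      if (t[i] >= next_switch) {
        target <- schedule_targets()
        next_switch <- t[i] + stats::rexp(1, 1 / visit_mean_s)
      }
      x[i] <- x[i - 1] + drift * (target[1] - x[i - 1]) * dt +
        sigma * sqrt(dt) * stats::rnorm(1)
      y[i] <- y[i - 1] + drift * (target[2] - y[i - 1]) * dt +
        sigma * sqrt(dt) * stats::rnorm(1)
      ## reflect at bounds
      x[i] <- reflect(x[i], bounds[1], bounds[3])
      y[i] <- reflect(y[i], bounds[2], bounds[4])
    }
    data.frame(t = t, x = x, y = y)
  })
}

reflect <- function(p, lo, hi) {
  span <- hi - lo
  p <- (p - lo) %% (2 * span)
  lo + ifelse(p > span, 2 * span - p, p)
}

#' Generate a three-chamber sociability session with a planted preference
#'
#' Visit schedule allocates side-chamber time so the expected time index
#' equals `planted_index`; within side-chamber visits the walk is biased
#' toward the holding cage, producing approach events with the same
#' expected preference.
#'
#' @param planted_index target (Time_C - Time_E) / (Time_C + Time_E).
#' @param geom three-chamber `arena_geometry`.
#' @param duration_s session length (default 600 s, the free-exploration
#'   phase).
#' @param dt sampling step (s).
#' @param p_center fraction of visits to the center chamber.
#' @param seed integer seed.
#' @return list: `traj`, `truth` (planted_index).
#' @export
gen_sociability_session <- function(planted_index, geom, duration_s = 600,
                                    dt = 0.1, p_center = 0.25, seed = 1L) {
  stopifnot(abs(planted_index) <= 1)
  pC <- (1 + planted_index) / 2
  sched <- local({
    s <- seed
    function() {
      u <- stats::runif(2)
      if (u[1] < p_center) {
        c(mean(geom$bounds[c(1, 3)]), mean(geom$bounds[c(2, 4)]))
      } else if (u[2] < pC) geom$cage_C else geom$cage_E
    }
  })
  traj <- biased_walk(duration_s, dt, geom$bounds, sched,
                      visit_mean_s = 8, drift = 8, sigma = 2.5, seed = seed)
  list(traj = traj, truth = list(planted_index = planted_index))
}

#' Generate an elevated-plus-maze session with planted open-arm occupancy
#'
#' @param planted_open_frac target fraction of time on the open arms.
#' @param geom EPM `arena_geometry`.
#' @param duration_s session length (default 300 s).
#' @param dt sampling step (s).
#' @param seed integer seed.
#' @return list: `traj`, `truth` (planted_open_frac).
#' @export
gen_epm_session <- function(planted_open_frac, geom, duration_s = 300,
                            dt = 0.1, seed = 1L) {
  stopifnot(planted_open_frac >= 0, planted_open_frac <= 1)
  anchors <- list(
    open = list(colMeans(geom$zones$open1), colMeans(geom$zones$open2)),
    closed = list(colMeans(geom$zones$closed1), colMeans(geom$zones$closed2))
  )
  sched <- function() {
    arm <- if (stats::runif(1) < planted_open_frac) anchors$open else anchors$closed
    arm[[sample.int(2, 1)]]
  }
  traj <- biased_walk(duration_s, dt, geom$bounds, sched,
                      visit_mean_s = 10, drift = 4, sigma = 3, seed = seed)
  list(traj = traj, truth = list(planted_open_frac = planted_open_frac))
}

#' Generate an open-field session
#'
#' Unbiased reflected walk in the box; the realized path length is recorded
#' as ground truth.
#' @param geom open-field `arena_geometry`.
#' @param duration_s session length (default 1200 s).
#' @param dt sampling step (s).
#' @param seed integer seed.
#' @export
gen_open_field_session <- function(geom, duration_s = 1200, dt = 0.1,
                                   seed = 1L) {
  center <- c(mean(geom$bounds[c(1, 3)]), mean(geom$bounds[c(2, 4)]))
  traj <- biased_walk(duration_s, dt, geom$bounds, function() center,
                      visit_mean_s = duration_s, drift = 0.3, sigma = 4,
                      seed = seed)
  list(traj = traj,
       truth = list(path_length_cm = sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))))
}

#' Generate before/after marble masks with planted burial decisions
#'
#' Twelve disc-shaped marbles on a 3 x 4 grid. Each marble is buried with
#' probability `p_bury`; buried marbles retain at most 1/6 of their exposed
#' area (often none), unburied marbles lose at most 1/4.
#'
#' @param p_bury per-marble burial probability.
#' @param n_marbles marble count (default 12).
#' @param shape mask dimensions (rows, cols) in pixels.
#' @param radius_px marble radius.
#' @param seed integer seed.
#' @return list: `before`, `after` (binary matrices), `truth`
#'   (logical `buried`, planted `percent_buried`).
#' @export
gen_marble_masks <- function(p_bury, n_marbles = 12, shape = c(72, 96),
                             radius_px = 6, seed = 1L) {
  with_seed(seed, {
    rows <- shape[1]; cols <- shape[2]
    nr <- 3; nc <- ceiling(n_marbles / nr)
    cy <- rows * (seq_len(nr) - 0.5) / nr
    cx <- cols * (seq_len(nc) - 0.5) / nc
    centers <- expand.grid(r = cy, c = cx)[seq_len(n_marbles), ]
    disc <- function(mask, cr, cc, rad, keep_frac = 1) {
      ## keep_frac < 1 keeps only the top chord of the disc
      for (r in max(1, floor(cr - rad)):min(rows, ceiling(cr + rad))) {
        for (cc2 in max(1, floor(cc - rad)):min(cols, ceiling(cc + rad))) {
          if ((r - cr)^2 + (cc2 - cc)^2 <= rad^2) {
            if (keep_frac >= 1 || (r - cr) < rad * (2 * keep_frac - 1)) {
              mask[r, cc2] <- 1L
            }
          }
        }
      }
      mask
    }
    before <- matrix(0L, rows, cols)
    after <- matrix(0L, rows, cols)
    buried <- stats::runif(n_marbles) < p_bury
    for (i in seq_len(n_marbles)) {
      before <- disc(before, centers$r[i], centers$c[i], radius_px)
      keep <- if (buried[i]) stats::runif(1, 0, 1 / 6) else stats::runif(1, 3 / 4, 1)
      if (keep > 0.02) {
        after <- disc(after, centers$r[i], centers$c[i], radius_px,
                      keep_frac = keep)
      }
    }
    list(before = before, after = after,
         truth = list(buried = buried,
                      percent_buried = 100 * mean(buried)))
  })
}

#' Generate a behavior cohort with planted group effects
#'
#' Per animal: an EPM session (open-arm occupancy 0.25 in all groups), an
#' open-field session, a sociability session at the group's planted
#' preference index (conspecific side randomized per animal), and marble
#' masks at the group's planted burial probability.
#'
#' @param spec `cohort_spec`.
#' @return list of per-animal entries with elements `animal_id`, `group`,
#'   `epm`, `open_field`, `sociability` (incl. geometry), `marbles`, and a
#'   `truth` sidecar.
#' @export
gen_behavior_cohort <- function(spec) {
  epm_geom <- arena_epm()
  of_geom <- arena_open_field()
  out <- list(); k <- 0L
  for (gi in seq_len(nrow(spec$groups))) {
    lab <- spec$groups$label[gi]
    eff <- group_effect(spec, lab)
    for (ai in seq_len(spec$groups$n[gi])) {
      k <- k + 1L
      aseed <- spec$seed + 5000L + 1000L * gi + ai
      side <- with_seed(aseed, sample(c("left", "right"), 1))
      soc_geom <- arena_three_chamber(conspecific_side = side)
      epm <- gen_epm_session(0.25, epm_geom, seed = aseed + 1L)
      of <- gen_open_field_session(of_geom, seed = aseed + 2L)
      soc <- gen_sociability_session(eff$soc_pref, soc_geom,
                                     seed = aseed + 3L)
      mb <- gen_marble_masks(eff$marble_p, seed = aseed + 4L)
      out[[k]] <- list(animal_id = sprintf("%s_%02d", lab, ai), group = lab,
                       epm = epm, epm_geom = epm_geom,
                       open_field = of, of_geom = of_geom,
                       sociability = soc, soc_geom = soc_geom,
                       marbles = mb,
                       truth = list(soc_pref = eff$soc_pref,
                                    marble_p = eff$marble_p,
                                    epm_open_frac = 0.25))
    }
  }
  out
}

#' Generate an outcome cohort (survival and seizures)
#'
#' Death ages are 21 d plus an exponential draw at the group's mortality
#' hazard, censored at 500 d; a first qualifying seizure (Racine 4 or 5) is
#' drawn the same way at the seizure hazard and kept when it precedes death
#' and censoring. Sub-threshold Racine 1-3 events are sprinkled in so the
#' level filter is exercised.
#'
#' @param spec `cohort_spec`.
#' @param censor_age_d end of daily tracking (default 500).
#' @return list: `records` (`animal_records`), `truth` (per-group planted
#'   hazards).
#' @export
gen_outcome_cohort <- function(spec, censor_age_d = 500) {
  ids <- character(0); grp <- character(0); death <- numeric(0)
  events <- list()
  for (gi in seq_len(nrow(spec$groups))) {
    lab <- spec$groups$label[gi]
    eff <- group_effect(spec, lab)
    for (ai in seq_len(spec$groups$n[gi])) {
      aseed <- spec$seed + 9000L + 1000L * gi + ai
      res <- with_seed(aseed, {
        d <- if (eff$mortality_hazard > 0) {
          21 + stats::rexp(1, eff$mortality_hazard)
        } else Inf
        d_obs <- if (d >= censor_age_d) NA_real_ else d
        horizon <- min(d, censor_age_d)
        ev <- NULL
        if (eff$seizure_hazard > 0) {
          s <- 21 + stats::rexp(1, eff$seizure_hazard)
          if (s < horizon) {
            ev <- data.frame(age_d = s, racine_level = sample(4:5, 1))
          }
        }
        n_minor <- stats::rpois(1, 1)
        if (n_minor > 0) {
          minor <- data.frame(age_d = stats::runif(n_minor, 21, horizon),
                              racine_level = sample(1:3, n_minor, replace = TRUE))
          ev <- rbind(ev, minor)
        }
        list(death = d_obs, events = ev)
      })
      ids <- c(ids, sprintf("%s_%02d", lab, ai))
      grp <- c(grp, lab)
      death <- c(death, res$death)
      events <- c(events, list(res$events))   # keeps NULL elements
    }
  }
  list(records = animal_records(ids, grp, death, events,
                                censor_age_d = censor_age_d),
       truth = spec$effects[, c("label", "mortality_hazard", "seizure_hazard")])
}
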