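## Behavioral assay scoring: elevated plus maze (percent open-arm time),
## open field (total distance), three-chamber sociability (time and
## approach preference indices), and marble burying (percent buried from
## before/after exposed-area masks).
##
## Coordinates are cm, origin at the arena corner, y up. Trajectories are
## data.frames (t, x, y); zone polygons are matrices with columns x, y.

poly_rect <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

point_in_poly <- function(x, y, poly) {
  as.logical(pracma::inpolygon(x, y, poly[, 1], poly[, 2],
                               boundary = TRUE))
}

#' Elevated-plus-maze geometry
#'
#' Plus maze centered on the origin-shifted arena: two open arms along x,
#' two closed arms along y, and a center square counted in neither arm.
#' @param arm_length,arm_width arm dimensions (cm).
#' @return `arena_geometry` with zones `open1`, `open2`, `closed1`,
#'   `closed2`, `center`.
#' @export
arena_epm <- function(arm_length = 30, arm_width = 5) {
  c0 <- arm_length + arm_width / 2   # center of the plus
  h <- arm_width / 2
  zones <- list(
    open1 = poly_rect(0, c0 - h, c0 - h, c0 + h),
    open2 = poly_rect(c0 + h, c0 - h, 2 * c0, c0 + h),
    closed1 = poly_rect(c0 - h, 0, c0 + h, c0 - h),
    closed2 = poly_rect(c0 - h, c0 + h, c0 + h, 2 * c0),
    center = poly_rect(c0 - h, c0 - h, c0 + h, c0 + h)
  )
  structure(list(kind = "epm", zones = zones,
                 bounds = c(0, 0, 2 * c0, 2 * c0)),
            class = "arena_geometry")
}

#' Open-field geometry: 30-cm square box divided into nine quadrants
#' @param side box side (cm, default 30).
#' @export
arena_open_field <- function(side = 30) {
  third <- side / 3
  zones <- list()
  for (i in 0:2) for (j in 0:2) {
    zones[[sprintf("q%d%d", i + 1, j + 1)]] <-
      poly_rect(i * third, j * third, (i + 1) * third, (j + 1) * third)
  }
  structure(list(kind = "open_field", zones = zones,
                 bounds = c(0, 0, side, side)),
            class = "arena_geometry")
}

#' Three-chamber sociability geometry
#'
#' Rectangular apparatus divided into three equal chambers along x; holding
#' cages sit at the centers of the two side chambers. Which side holds the
#' conspecific is given per trial.
#' @param width,depth apparatus dimensions (cm).
#' @param conspecific_side `"left"` or `"right"`.
#' @return `arena_geometry` with zones `chamber_C`, `chamber_E`, `center`
#'   and cage centers `cage_C`, `cage_E`.
#' @export
arena_three_chamber <- function(width = 60, depth = 20,
                                conspecific_side = "left") {
  third <- width / 3
  left <- poly_rect(0, 0, third, depth)
  mid <- poly_rect(third, 0, 2 * third, depth)
  right <- poly_rect(2 * third, 0, width, depth)
  cage_l <- c(third / 2, depth / 2)
  cage_r <- c(width - third / 2, depth / 2)
  C_left <- identical(conspecific_side, "left")
  structure(list(kind = "three_chamber",
                 zones = list(chamber_C = if (C_left) left else right,
                              chamber_E = if (C_left) right else left,
                              center = mid),
                 cage_C = if (C_left) cage_l else cage_r,
                 cage_E = if (C_left) cage_r else cage_l,
                 bounds = c(0, 0, width, depth)),
            class = "arena_geometry")
}

## per-sample dwell times with gap handling: sample i owns the time step to
## the next sample; steps longer than max_gap_s are logged and excluded.
sample_dwell <- function(traj, max_gap_s = 1) {
  dt <- diff(traj$t)
  gap <- dt > max_gap_s
  list(dt = ifelse(gap, 0, dt), n_gaps = sum(gap), gap_time = sum(dt[gap]))
}

#' Percent time in the open arms of the elevated plus maze
#'
#' Fraction of scored session time with the animal inside an open-arm
#' polygon; the center zone counts toward the denominator but neither arm.
#' Trajectory gaps longer than 1 s are excluded from the denominator.
#'
#' @param traj data.frame (t, x, y).
#' @param geom `arena_geometry` of kind `"epm"`.
#' @return list: `percent_open`, `percent_closed`, `scored_s`,
#'   `n_gaps`.
#' @export
score_epm <- function(traj, geom) {
  stopifnot(geom$kind == "epm", nrow(traj) >= 2)
  dw <- sample_dwell(traj)
  x <- traj$x[-nrow(traj)]; y <- traj$y[-nrow(traj)]
  open <- point_in_poly(x, y, geom$zones$open1) |
    point_in_poly(x, y, geom$zones$open2)
  closed <- point_in_poly(x, y, geom$zones$closed1) |
    point_in_poly(x, y, geom$zones$closed2)
  scored <- sum(dw$dt)
  if (scored <= 0) stop("no scored time")
  list(percent_open = 100 * sum(dw$dt[open]) / scored,
       percent_closed = 100 * sum(dw$dt[closed]) / scored,
       scored_s = scored, n_gaps = dw$n_gaps)
}

#' Total distance traversed in the open field
#'
#' Sum of Euclidean step lengths after median-filter despiking of the
#' coordinates (window of 5 samples; tracking glitches would otherwise
#' inflate path length).
#'
#' @param traj data.frame (t, x, y).
#' @param despike_k odd median-filter window (samples); 1 disables.
#' @return total distance (cm).
#' @export
score_open_field <- function(traj, despike_k = 5) {
  stopifnot(nrow(traj) >= 2)
  x <- traj$x; y <- traj$y
  if (despike_k > 1 && nrow(traj) > despike_k) {
    x <- stats::runmed(x, despike_k, endrule = "keep")
    y <- stats::runmed(y, despike_k, endrule = "keep")
  }
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Preference index (a - b) / (a + b)
#'
#' @param a,b non-negative quantities (times or counts).
#' @return index in [-1, 1]; NA when a + b = 0.
#' @export
preference_index <- function(a, b) {
  if (any(c(a, b) < 0)) stop("preference_index inputs must be non-negative")
  ifelse(a + b == 0, undefined_marker(), (a - b) / (a + b))
}

#' Score a three-chamber sociability session
#'
#' Chamber occupancy times for the conspecific (C) and empty (E) sides, and
#' approach counts into the 5-cm disc around each holding cage. An approach
#' is an outside-to-inside crossing of the disc; after entering, a new
#' approach is only counted once the animal has retreated beyond the
#' hysteresis radius (7 cm), so boundary jitter is not double-counted.
#'
#' @param traj data.frame (t, x, y) for the 10-min free-exploration phase.
#' @param geom `arena_geometry` of kind `"three_chamber"`.
#' @param approach_radius_cm approach disc radius (default 5).
#' @param hysteresis_radius_cm re-arm radius (default 7).
#' @return `sociability_result`: list with `Time_C`, `Time_E`, `App_C`,
#'   `App_E`, `time_index`, `approach_index`, `scored_s`.
#' @export
score_sociability <- function(traj, geom, approach_radius_cm = 5,
                              hysteresis_radius_cm = 7) {
  stopifnot(geom$kind == "three_chamber", nrow(traj) >= 2)
  dw <- sample_dwell(traj)
  x <- traj$x[-nrow(traj)]; y <- traj$y[-nrow(traj)]
  inC <- point_in_poly(x, y, geom$zones$chamber_C)
  inE <- point_in_poly(x, y, geom$zones$chamber_E) & !inC
  Time_C <- sum(dw$dt[inC]); Time_E <- sum(dw$dt[inE])

  count_approaches <- function(center) {
    d <- sqrt((traj$x - center[1])^2 + (traj$y - center[2])^2)
    armed <- TRUE; inside <- FALSE; n <- 0L
    for (i in seq_along(d)) {
      if (!inside && d[i] <= approach_radius_cm) {
        inside <- TRUE
        if (armed) { n <- n + 1L; armed <- FALSE }
      } else if (inside && d[i] > approach_radius_cm) {
        inside <- FALSE
      }
      if (!inside && d[i] > hysteresis_radius_cm) armed <- TRUE
    }
    n
  }
  App_C <- count_approaches(geom$cage_C)
  App_E <- count_approaches(geom$cage_E)
  structure(list(Time_C = Time_C, Time_E = Time_E,
                 App_C = App_C, App_E = App_E,
                 time_index = preference_index(Time_C, Time_E),
                 approach_index = preference_index(App_C, App_E),
                 scored_s = sum(dw$dt)),
            class = "sociability_result")
}

#' Score a marble-burying assay from before/after masks
#'
#' Connected components of the before mask are the exposed marbles; each is
#' matched to the nearest after-component by centroid proximity. A marble
#' counts as buried when its exposed area decreased by at least
#' `buried_threshold` (default 2/3). Percent buried is relative to the
#' number of marbles detected before (12 expected; a differing count
#' triggers a warning and scoring proceeds with the detected count).
#'
#' @param before_mask,after_mask binary matrices of equal shape (row-major
#'   rasters; nonzero = exposed marble surface).
#' @param buried_threshold fractional area reduction that counts as buried.
#' @param expected_marbles expected marble count (default 12).
#' @param match_radius_px maximum centroid displacement for matching
#'   (default 10 px).
#' @return list: `percent_buried`, `n_marbles`, `n_buried`, per-marble
#'   data.frame `marbles` (area_before, area_after, reduction, buried).
#' @export
score_marbles <- function(before_mask, after_mask, buried_threshold = 2 / 3,
                          expected_marbles = 12, match_radius_px = 10) {
  stopifnot(identical(dim(before_mask), dim(after_mask)))
  lab_b <- EBImage::bwlabel(before_mask != 0)
  lab_a <- EBImage::bwlabel(after_mask != 0)
  comp_stats <- function(lab) {
    ids <- setdiff(sort(unique(as.vector(lab))), 0)
    do.call(rbind, lapply(ids, function(id) {
      w <- which(lab == id, arr.ind = TRUE)
      data.frame(id = id, area = nrow(w),
                 cx = mean(w[, 1]), cy = mean(w[, 2]))
    }))
  }
  b <- comp_stats(lab_b)
  if (is.null(b) || nrow(b) == 0L) stop("no marbles detected in before mask")
  if (nrow(b) != expected_marbles) {
    warning(sprintf("detected %d before-marbles, expected %d; proceeding",
                    nrow(b), expected_marbles))
  }
  a <- comp_stats(lab_a)
  area_after <- vapply(seq_len(nrow(b)), function(i) {
    if (is.null(a) || nrow(a) == 0L) return(0)
    d <- sqrt((a$cx - b$cx[i])^2 + (a$cy - b$cy[i])^2)
    j <- which.min(d)
    if (d[j] <= match_radius_px) a$area[j] else 0
  }, numeric(1))
  reduction <- 1 - area_after / b$area
  buried <- reduction >= buried_threshold
  list(percent_buried = 100 * sum(buried) / nrow(b),
       n_marbles = nrow(b), n_buried = sum(buried),
       marbles = data.frame(area_before = b$area, area_after = area_after,
                            reduction = reduction, buried = buried))
}
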