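## Plain-text session container: per-stream CSV files plus a JSON manifest.
## Layout under a session directory:
##   manifest.json              stream inventory, sampling rates, units
##   wheel.csv                  t_s, angle_rad
##   lfp.csv                    sample_uV (fs and t0 in the manifest)
##   spikes_<unit>.csv          spike_s
##   truth.json                 optional ground-truth sidecar (tests only)

#' Write a session to a directory of CSV files with a JSON manifest
#'
#' @param session list as returned by [gen_session()] (elements `wheel`,
#'   `lfp`, `spikes`, optional `truth`).
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- list(format = "statephys-session", version = 1L, streams = list())
  if (!is.null(session$wheel)) {
    utils::write.csv(data.frame(t_s = session$wheel$t,
                                angle_rad = session$wheel$angle),
                     file.path(dir, "wheel.csv"), row.names = FALSE)
    man$streams$wheel <- list(file = "wheel.csv",
                              wheel_diameter_cm = attr(session$wheel, "wheel_diameter"))
  }
  if (!is.null(session$lfp)) {
    utils::write.csv(data.frame(sample_uV = session$lfp$samples),
                     file.path(dir, "lfp.csv"), row.names = FALSE)
    man$streams$lfp <- list(file = "lfp.csv", fs_Hz = session$lfp$fs,
                            t0_s = session$lfp$t0)
  }
  if (!is.null(session$spikes)) {
    man$streams$spikes <- lapply(session$spikes, function(tr) {
      f <- sprintf("spikes_%s.csv", tr$unit_id)
      utils::write.csv(data.frame(spike_s = tr$spike_times),
                       file.path(dir, f), row.names = FALSE)
      list(file = f, unit_id = tr$unit_id)
    })
  }
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(session$truth)) {
    tr <- session$truth
    tr$bouts <- as.list(tr$bouts)
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' The ground-truth sidecar, if present, is deliberately not read: the
#' pipeline never consumes planted truth.
#' @param dir session directory.
#' @return list with `wheel`, `lfp`, `spikes` (whichever streams exist).
#' @export
read_session <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  out <- list()
  if (!is.null(man$streams$wheel)) {
    d <- utils::read.csv(file.path(dir, man$streams$wheel$file))
    out$wheel <- data.frame(t = d$t_s, angle = d$angle_rad)
    attr(out$wheel, "wheel_diameter") <- man$streams$wheel$wheel_diameter_cm
    class(out$wheel) <- c("wheel_trace", "data.frame")
  }
  if (!is.null(man$streams$lfp)) {
    d <- utils::read.csv(file.path(dir, man$streams$lfp$file))
    out$lfp <- lfp_signal(fs = man$streams$lfp$fs_Hz, samples = d$sample_uV,
                          t0 = man$streams$lfp$t0_s)
  }
  if (!is.null(man$streams$spikes)) {
    out$spikes <- lapply(man$streams$spikes, function(s) {
      d <- utils::read.csv(file.path(dir, s$file))
      spike_train(d$spike_s, unit_id = s$unit_id)
    })
  }
  out
}

#' Read a wheel trace from a two-column CSV (t_s, angle_rad)
#' @param path CSV path.
#' @param wheel_diameter_cm wheel diameter (cm).
#' @export
read_wheel_csv <- function(path, wheel_diameter_cm = 15) {
  d <- utils::read.csv(path)
  stopifnot(ncol(d) >= 2)
  out <- data.frame(t = d[[1]], angle = d[[2]])
  attr(out, "wheel_diameter") <- wheel_diameter_cm
  class(out) <- c("wheel_trace", "data.frame")
  out
}

#' Write a state segmentation as a BED-like interval CSV
#'
#' Three columns: `label` (L/Q), `start_s`, `end_s`, sorted by start.
#' @param seg `state_segmentation`.
#' @param path output CSV path.
#' @export
write_segmentation_csv <- function(seg, path) {
  d <- rbind(data.frame(label = rep("L", nrow(seg$bouts)),
                        start_s = seg$bouts$start, end_s = seg$bouts$end),
             data.frame(label = rep("Q", nrow(seg$quiescent)),
                        start_s = seg$quiescent$start, end_s = seg$quiescent$end))
  d <- d[order(d$start_s), , drop = FALSE]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write an animal-record table as CSV (seizure events as a JSON column)
#' @param records `animal_records`.
#' @param path output CSV path.
#' @export
write_records_csv <- function(records, path) {
  ev_json <- vapply(records$seizure_events, function(ev) {
    if (is.null(ev) || nrow(ev) == 0) "[]"
    else as.character(jsonlite::toJSON(ev, digits = NA))
  }, character(1))
  utils::write.csv(data.frame(animal_id = records$animal_id,
                              group = records$group,
                              death_age_d = records$death_age_d,
                              censored = records$censored,
                              seizure_events = ev_json),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an animal-record table written by [write_records_csv()]
#' @param path CSV path.
#' @param censor_age_d censoring age (default 500).
#' @export
read_records_csv <- function(path, censor_age_d = 500) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  events <- lapply(d$seizure_events, function(s) {
    ev <- jsonlite::fromJSON(s)
    if (length(ev) == 0) NULL else as.data.frame(ev)
  })
  animal_records(d$animal_id, d$group,
                 ifelse(d$censored, NA_real_, d$death_age_d),
                 events, censor_age_d = censor_age_d)
}
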