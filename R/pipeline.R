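## End-to-end pipeline: per-session ephys analysis, per-animal behavior
## scoring, cohort tables and group statistics, driven by a single config
## list (YAML-loadable) whose defaults encode the analysis recipe: 20-s
## quiescence, 10-s pre-bout exclusion, 1 cm/s speed criterion, 2-s minimum
## run, 2-s Hann windows, 3-6 and 40-55 Hz bands, ID > 20, 0.1%
## contamination at 1.5 ms, 5-cm approach radius.

#' Default pipeline configuration
#'
#' All analysis thresholds appear here as named defaults so the standard
#' recipe is executable and auditable; override any element via
#' [run_pipeline()]'s `config`.
#' @return nested list of stage parameter blocks.
#' @export
default_config <- function() {
  list(
    segmentation = list(smoothing_window_s = 0.25, min_segment_s = 0.5,
                        penalty_scale = 10, speed_threshold_cm_s = 1),
    epochs = list(min_quiescence_s = 20, pre_bout_exclusion_s = 10,
                  stationary_convention = "trim"),
    trials = list(min_preceding_quiescence_s = 20, min_mean_speed_cm_s = 1,
                  min_run_duration_s = 2),
    spectral = list(window_s = 2, overlap = 0.5,
                    total_range = c(0.5, 100),
                    bands = list(theta = c(3, 6), gamma = c(40, 55))),
    qc = list(id_threshold = 20, contamination_threshold = 0.001,
              refractory_s = 0.0015, rs_boundary_ms = 0.4),
    behavior = list(approach_radius_cm = 5, hysteresis_radius_cm = 7,
                    buried_threshold = 2 / 3),
    stats = list(adjust = "bonferroni"),
    seizure = list(min_racine = 4)
  )
}

merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Analyze one recording session
#'
#' Runs the full single-session chain: velocity, state segmentation,
#' quiescent-epoch selection, LFP power spectrum and relative band powers,
#' per-unit quiescent firing rate, ISI contamination and locomotion-onset
#' modulation.
#'
#' @param session list with `wheel`, `lfp`, `spikes` (as from
#'   [gen_session()] or [read_session()]).
#' @param config configuration overrides merged over [default_config()].
#' @return list: `segmentation`, `trials`, `band_power` (named numeric),
#'   `psd`, `units` (data.frame: unit_id, rate_Q, isi_contamination, FR_L,
#'   FR_Q, mod_index, n_trials).
#' @export
analyze_session <- function(session, config = NULL) {
  cfg <- merge_config(default_config(), config)
  v <- angle_to_velocity(session$wheel, cfg$segmentation$smoothing_window_s)
  seg <- segment_states(v, min_segment_s = cfg$segmentation$min_segment_s,
                        penalty_scale = cfg$segmentation$penalty_scale,
                        speed_threshold_cm_s = cfg$segmentation$speed_threshold_cm_s)
  ep_fire <- select_quiescent_epochs(seg, "firing",
                                     cfg$epochs$min_quiescence_s,
                                     cfg$epochs$pre_bout_exclusion_s,
                                     cfg$epochs$stationary_convention)
  ep_lfp <- select_quiescent_epochs(seg, "lfp",
                                    cfg$epochs$min_quiescence_s,
                                    cfg$epochs$pre_bout_exclusion_s,
                                    cfg$epochs$stationary_convention)
  trials <- select_locomotion_trials(seg, v,
                                     cfg$trials$min_preceding_quiescence_s,
                                     cfg$trials$min_mean_speed_cm_s,
                                     cfg$trials$min_run_duration_s)

  psd <- NULL; bp <- NULL
  if (!is.null(session$lfp)) {
    psd <- compute_psd(session$lfp, ep_lfp, cfg$spectral$window_s,
                       cfg$spectral$overlap)
    bp <- vapply(cfg$spectral$bands, function(b) {
      relative_band_power(psd, b, cfg$spectral$total_range)$relative_power
    }, numeric(1))
  }

  units <- NULL
  if (!is.null(session$spikes) && length(session$spikes) > 0) {
    units <- do.call(rbind, lapply(session$spikes, function(tr) {
      rq <- if (nrow(ep_fire) > 0) firing_rate(tr, ep_fire) else NA_real_
      mod <- locomotion_modulation(tr, trials, session_start = seg$span[1])
      data.frame(unit_id = tr$unit_id, rate_Q = rq,
                 isi_contamination = isi_contamination(tr, cfg$qc$refractory_s),
                 FR_L = mod$FR_L, FR_Q = mod$FR_Q, mod_index = mod$index,
                 n_trials = mod$n_trials)
    }))
  }
  list(segmentation = seg, trials = trials, band_power = bp, psd = psd,
       units = units)
}

#' Per-animal ephys metric table for a generated cohort
#'
#' Runs [analyze_session()] on every animal and averages unit-level metrics
#' within animal (the animal is the statistical unit).
#'
#' @param cohort list from [gen_ephys_cohort()].
#' @param config configuration overrides.
#' @return data.frame: animal_id, group, gamma_rel, theta_rel, rate_Q,
#'   mod_index.
#' @export
analyze_ephys_cohort <- function(cohort, config = NULL) {
  do.call(rbind, lapply(cohort, function(an) {
    res <- analyze_session(an$session, config)
    u <- res$units
    data.frame(animal_id = an$animal_id, group = an$group,
               gamma_rel = unname(res$band_power["gamma"]),
               theta_rel = unname(res$band_power["theta"]),
               rate_Q = mean(u$rate_Q, na.rm = TRUE),
               mod_index = mean(u$mod_index, na.rm = TRUE))
  }))
}

#' Per-animal behavior score table for a generated cohort
#'
#' @param cohort list from [gen_behavior_cohort()].
#' @param config configuration overrides.
#' @return data.frame: animal_id, group, epm_percent_open, of_distance_cm,
#'   soc_time_index, soc_approach_index, marbles_percent_buried.
#' @export
analyze_behavior_cohort <- function(cohort, config = NULL) {
  cfg <- merge_config(default_config(), config)
  do.call(rbind, lapply(cohort, function(an) {
    epm <- score_epm(an$epm$traj, an$epm_geom)
    ofd <- score_open_field(an$open_field$traj)
    soc <- score_sociability(an$sociability$traj, an$soc_geom,
                             cfg$behavior$approach_radius_cm,
                             cfg$behavior$hysteresis_radius_cm)
    mb <- score_marbles(an$marbles$before, an$marbles$after,
                        cfg$behavior$buried_threshold)
    data.frame(animal_id = an$animal_id, group = an$group,
               epm_percent_open = epm$percent_open,
               of_distance_cm = ofd,
               soc_time_index = soc$time_index,
               soc_approach_index = soc$approach_index,
               marbles_percent_buried = mb$percent_buried)
  }))
}

#' Group comparisons for every metric column of a per-animal table
#'
#' @param df per-animal table with `group` plus metric columns.
#' @param control_label control group.
#' @param metrics metric column names (default: all numeric columns).
#' @param adjust Dunn p-adjustment method.
#' @return named list of `group_comparison` objects.
#' @export
compare_all_metrics <- function(df, control_label, metrics = NULL,
                                adjust = "bonferroni") {
  if (is.null(metrics)) {
    metrics <- names(df)[vapply(df, is.numeric, logical(1))]
  }
  out <- lapply(metrics, function(m) {
    compare_groups(data.frame(group = df$group, value = df[[m]]),
                   control_label, adjust = adjust)
  })
  names(out) <- metrics
  out
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates (or accepts) an ephys cohort, behavior cohort and outcome
#' table, computes every per-animal metric, runs the group statistics, and
#' writes tidy CSV tables plus a JSON provenance record (config hash, seed)
#' to `out_dir`. Deterministic given `spec` and config.
#'
#' @param spec `cohort_spec` (default: [default_cohort_spec()]).
#' @param config configuration overrides.
#' @param out_dir output directory, or NULL to skip writing.
#' @param stages character subset of `c("ephys", "behavior", "outcomes")`.
#' @param ephys_args extra arguments to [gen_ephys_cohort()].
#' @return list: `ephys` (per-animal table), `behavior`, `records`,
#'   `stats` (list of `group_comparison` per metric), `survival`,
#'   `seizures`, `failures`, `provenance`.
#' @export
run_pipeline <- function(spec = default_cohort_spec(), config = NULL,
                         out_dir = NULL,
                         stages = c("ephys", "behavior", "outcomes"),
                         ephys_args = list()) {
  cfg <- merge_config(default_config(), config)
  res <- list(failures = character(0))

  if ("ephys" %in% stages) {
    cohort <- do.call(gen_ephys_cohort, c(list(spec = spec), ephys_args))
    res$ephys <- tryCatch(analyze_ephys_cohort(cohort, cfg),
                          error = function(e) {
                            res$failures <<- c(res$failures,
                                               paste("ephys:", conditionMessage(e)))
                            NULL
                          })
  }
  if ("behavior" %in% stages) {
    bcohort <- gen_behavior_cohort(spec)
    res$behavior <- tryCatch(analyze_behavior_cohort(bcohort, cfg),
                             error = function(e) {
                               res$failures <<- c(res$failures,
                                                  paste("behavior:", conditionMessage(e)))
                               NULL
                             })
  }
  if ("outcomes" %in% stages) {
    oc <- gen_outcome_cohort(spec)
    res$records <- oc$records
    groups <- split(seq_len(nrow(oc$records)), oc$records$group)
    res$survival <- lapply(groups, function(ix) {
      survival_curve(oc$records[ix, , drop = FALSE])
    })
    res$seizures <- lapply(groups, function(ix) {
      seizure_summary(oc$records[ix, , drop = FALSE],
                      min_racine = cfg$seizure$min_racine)
    })
  }

  res$stats <- list()
  if (!is.null(res$ephys)) {
    res$stats <- c(res$stats,
                   compare_all_metrics(res$ephys, spec$control_label,
                                       c("gamma_rel", "theta_rel", "rate_Q",
                                         "mod_index"),
                                       adjust = cfg$stats$adjust))
  }
  if (!is.null(res$behavior)) {
    res$stats <- c(res$stats,
                   compare_all_metrics(res$behavior, spec$control_label,
                                       c("epm_percent_open", "of_distance_cm",
                                         "soc_time_index", "soc_approach_index",
                                         "marbles_percent_buried"),
                                       adjust = cfg$stats$adjust))
  }

  res$provenance <- list(
    seed = spec$seed,
    config_hash = config_hash(cfg),
    package_version = as.character(utils::packageVersion("statephys")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(res$ephys)) {
      utils::write.csv(res$ephys, file.path(out_dir, "ephys_per_animal.csv"),
                       row.names = FALSE)
    }
    if (!is.null(res$behavior)) {
      utils::write.csv(res$behavior,
                       file.path(out_dir, "behavior_per_animal.csv"),
                       row.names = FALSE)
    }
    if (!is.null(res$records)) {
      write_records_csv(res$records, file.path(out_dir, "animal_records.csv"))
    }
    stats_tab <- do.call(rbind, lapply(names(res$stats), function(m) {
      s <- res$stats[[m]]
      cbind(metric = m, H = s$H, p_global = s$p_global, s$posthoc)
    }))
    if (!is.null(stats_tab)) {
      utils::write.csv(stats_tab, file.path(out_dir, "group_stats.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(res$provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

## md5 of the canonical YAML rendering of the config
config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(cfg, f)
  unname(tools::md5sum(f))
}

#' Load a pipeline configuration from YAML
#'
#' The file may override any subset of [default_config()]; unknown keys are
#' rejected.
#' @param path YAML path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(default_config())
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config blocks: ", paste(bad, collapse = ", "))
  merge_config(default_config(), cfg)
}
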