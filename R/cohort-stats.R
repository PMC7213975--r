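## Cohort statistics: survival and seizure tabulation from animal records,
## and the nonparametric group-comparison machinery (Kruskal-Wallis with
## Dunn's post-test, mutant-vs-control family, Bonferroni adjustment).

#' Midrank computation with tie handling
#' @keywords internal
midranks <- function(x) rank(x, ties.method = "average")

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference (k - 1 degrees of
#' freedom). When every observation is identical the statistic is 0 and the
#' p value 1 by convention.
#'
#' @param groups named list of numeric vectors (one per group).
#' @return list: `H`, `p`, `df`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 1L) >= 1))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  N <- length(x)
  if (length(unique(x)) < 2L) {
    return(list(H = 0, p = 1, df = length(groups) - 1L, n = N))
  }
  r <- midranks(x)
  Rbar <- tapply(r, g, mean)
  n_i <- tabulate(g)
  H <- 12 / (N * (N + 1)) * sum(n_i * (Rbar - (N + 1) / 2)^2)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H / tie_corr
  df <- length(groups) - 1L
  list(H = H, p = stats::pchisq(H, df, lower.tail = FALSE), df = df, n = N)
}

#' Dunn's post-test against a control group
#'
#' Pairwise z statistics from pooled-rank means with tie-corrected variance,
#' comparing each non-control group to the control; two-sided p values
#' adjusted over the mutant-vs-control family (Bonferroni, the convention of
#' the usual "Dunn's multiple comparisons" output).
#'
#' @param groups named list of numeric vectors.
#' @param control_label name of the control group in `groups`.
#' @param adjust p-adjustment method (default `"bonferroni"`; any
#'   [stats::p.adjust()] method).
#' @return data.frame: `group`, `z` (positive when the group's mean rank
#'   exceeds the control's), `p`, `p_adjusted`.
#' @export
dunn_posthoc <- function(groups, control_label, adjust = "bonferroni") {
  if (!control_label %in% names(groups)) {
    stop("control group not present: ", control_label)
  }
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, 1L))
  N <- length(x)
  r <- midranks(x)
  Rbar <- tapply(r, g, mean)
  n_i <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var0 <- N * (N + 1) / 12 - tie_term
  others <- setdiff(names(groups), control_label)
  z <- vapply(others, function(lab) {
    se <- sqrt(var0 * (1 / n_i[[lab]] + 1 / n_i[[control_label]]))
    if (se == 0) return(0)
    (Rbar[[lab]] - Rbar[[control_label]]) / se
  }, numeric(1))
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group = others, z = unname(z), p = unname(p),
             p_adjusted = pmin(1, stats::p.adjust(p, method = adjust)),
             row.names = NULL)
}

#' Build an animal-record table
#'
#' @param animal_id character vector.
#' @param group group labels.
#' @param death_age_d death age in days, NA for animals alive at the end of
#'   tracking (censored at `censor_age_d`).
#' @param seizure_events list (one element per animal) of data.frames with
#'   columns `age_d`, `racine_level` (integer 1-5); NULL for none.
#' @param censor_age_d end of daily tracking (default 500).
#' @return data.frame of class `animal_records` with a list-column
#'   `seizure_events` and logical `censored`.
#' @export
animal_records <- function(animal_id, group, death_age_d,
                           seizure_events = NULL, censor_age_d = 500) {
  n <- length(animal_id)
  stopifnot(length(group) == n, length(death_age_d) == n)
  if (is.null(seizure_events)) seizure_events <- rep(list(NULL), n)
  stopifnot(length(seizure_events) == n)
  for (ev in seizure_events) {
    if (!is.null(ev) && nrow(ev) > 0) {
      stopifnot(all(ev$racine_level %in% 1:5), all(ev$age_d >= 0))
    }
  }
  censored <- is.na(death_age_d) | death_age_d >= censor_age_d
  if (any(death_age_d[!censored] < 21, na.rm = TRUE)) {
    stop("death ages must be >= 21 d (post-weaning tracking)")
  }
  out <- data.frame(animal_id = animal_id, group = group,
                    death_age_d = ifelse(censored, censor_age_d, death_age_d),
                    censored = censored)
  out$seizure_events <- seizure_events
  attr(out, "censor_age_d") <- censor_age_d
  class(out) <- c("animal_records", "data.frame")
  out
}

#' Empirical survival curve and mean death age
#'
#' Fraction of animals alive at each day of the tracking window; censored
#' animals count as alive through the censoring age. Mean and SEM of death
#' age are computed over uncensored animals only.
#'
#' @param records `animal_records` (single group or pre-filtered).
#' @param age_grid days at which to evaluate (default 21..censor age).
#' @return list: `age_d`, `surviving` (non-increasing, starts at 1),
#'   `mean_death_age_d`, `sem_death_age_d`, `n`, `n_uncensored`.
#' @export
survival_curve <- function(records, age_grid = NULL) {
  stopifnot(nrow(records) >= 1)
  censor <- attr(records, "censor_age_d")
  if (is.null(censor)) censor <- 500
  if (is.null(age_grid)) age_grid <- seq(21, censor)
  surv <- vapply(age_grid, function(a) {
    mean(records$censored | records$death_age_d > a)
  }, numeric(1))
  dd <- records$death_age_d[!records$censored]
  list(age_d = age_grid, surviving = surv,
       mean_death_age_d = if (length(dd)) mean(dd) else NA_real_,
       sem_death_age_d = if (length(dd) > 1) stats::sd(dd) / sqrt(length(dd)) else NA_real_,
       n = nrow(records), n_uncensored = length(dd))
}

#' Seizure incidence and onset summary
#'
#' A qualifying seizure is an event reaching Racine level 4 or 5 (rearing
#' with forelimb clonus, with or without falling). Incidence is the
#' fraction of animals with at least one qualifying event; onset age is
#' averaged over those animals' first qualifying events.
#'
#' @param records `animal_records`.
#' @param min_racine qualifying Racine level (default 4).
#' @return list: `incidence`, `n_with_seizure`, `n`,
#'   `mean_first_seizure_age_d`, `first_seizure_ages_d`.
#' @export
seizure_summary <- function(records, min_racine = 4) {
  first_age <- vapply(records$seizure_events, function(ev) {
    if (is.null(ev) || nrow(ev) == 0) return(NA_real_)
    qual <- ev$age_d[ev$racine_level >= min_racine]
    if (length(qual) == 0) NA_real_ else min(qual)
  }, numeric(1))
  has <- !is.na(first_age)
  list(incidence = mean(has), n_with_seizure = sum(has), n = nrow(records),
       mean_first_seizure_age_d = if (any(has)) mean(first_age[has]) else NA_real_,
       first_seizure_ages_d = first_age)
}

#' Five-number box-plot summary
#'
#' Minimum, first quartile, median, third quartile and maximum, using
#' linear-interpolation quantiles; the summary behind the box-and-whisker
#' plots (whiskers at the distribution extremes).
#'
#' @param values numeric vector, n >= 1 (NAs dropped).
#' @return named numeric: `min`, `q1`, `median`, `q3`, `max`.
#' @export
summarize_boxstats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values to summarize")
  q <- stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7,
                       names = FALSE)
  c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
}

#' Compare per-animal metric values across groups
#'
#' Kruskal-Wallis omnibus test followed by Dunn's post-test of every group
#' against the control. The statistical unit is the animal: callers must
#' pass one value per animal (unit- or session-level metrics averaged
#' within animal first).
#'
#' @param df data.frame with columns `group` and `value`.
#' @param control_label control group label.
#' @param adjust p-adjustment method for the Dunn family.
#' @return `group_comparison`: list with `H`, `p_global`, `posthoc`
#'   (data.frame), `boxstats` (per-group five-number summaries).
#' @export
compare_groups <- function(df, control_label, adjust = "bonferroni") {
  df <- df[!is.na(df$value), , drop = FALSE]
  groups <- split(df$value, df$group)
  kw <- kruskal_wallis(groups)
  ph <- dunn_posthoc(groups, control_label, adjust = adjust)
  bs <- t(vapply(groups, summarize_boxstats, numeric(5)))
  structure(list(H = kw$H, p_global = kw$p, posthoc = ph,
                 boxstats = as.data.frame(bs), adjust = adjust,
                 control = control_label),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.3f, p = %.4g; Dunn vs %s (%s):\n",
              x$H, x$p_global, x$control, x$adjust))
  print(x$posthoc, row.names = FALSE)
  invisible(x)
}
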