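#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules. Intervals are two-column
## data.frames (start, end) in seconds, half-open [start, end).

#' Build an interval table
#'
#' @param start,end numeric vectors of equal length, seconds.
#' @return data.frame with columns `start`, `end`.
#' @keywords internal
intervals <- function(start = numeric(0), end = numeric(0)) {
  stopifnot(length(start) == length(end))
  if (any(end < start)) stop("interval end before start")
  data.frame(start = as.numeric(start), end = as.numeric(end))
}

interval_durations <- function(iv) iv$end - iv$start

#' Total duration covered by an interval table
#' @keywords internal
total_duration <- function(iv) sum(interval_durations(iv))

#' Membership of time points in a set of half-open intervals
#'
#' @param t numeric vector of times.
#' @param iv interval table.
#' @return logical vector, TRUE where t falls in [start, end) of any interval.
#' @keywords internal
in_intervals <- function(t, iv) {
  if (nrow(iv) == 0L) return(rep(FALSE, length(t)))
  hit <- rep(FALSE, length(t))
  for (i in seq_len(nrow(iv))) {
    hit <- hit | (t >= iv$start[i] & t < iv$end[i])
  }
  hit
}

#' Count points inside half-open intervals
#' @keywords internal
count_in_intervals <- function(t, iv) {
  if (nrow(iv) == 0L) return(0L)
  ## findInterval on sorted t: spikes are sorted, use vectorized counting
  n <- 0L
  for (i in seq_len(nrow(iv))) {
    n <- n + sum(t >= iv$start[i] & t < iv$end[i])
  }
  n
}

#' Moving average with shrinking edge windows
#'
#' Boxcar smoother; near the edges the window shrinks so no samples are
#' dropped and no NA padding appears.
#' @keywords internal
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- width %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (width - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Trapezoidal integral of y(f) over [a, b] with interpolated endpoints
#'
#' Restricts the grid to the band and adds linearly interpolated values at
#' the exact band edges so narrow bands are integrated accurately.
#' @keywords internal
trapz_band <- function(f, y, a, b) {
  if (a >= b) stop("empty band")
  if (a < min(f) || b > max(f)) stop("band outside the frequency grid")
  inside <- f > a & f < b
  fs <- c(a, f[inside], b)
  ys <- c(stats::approx(f, y, xout = a)$y, y[inside],
          stats::approx(f, y, xout = b)$y)
  pracma::trapz(fs, ys)
}

#' Analytic-signal phase of a narrowband component
#'
#' FFT brick-wall bandpass around `freq` followed by the analytic signal
#' (one-sided spectrum); returns instantaneous phase in radians.
#' @keywords internal
band_phase <- function(x, fs, freq, half_bw = 2) {
  n <- length(x)
  X <- stats::fft(x)
  fgrid <- (seq_len(n) - 1) * fs / n
  ## positive-frequency band only -> analytic signal directly
  keep <- fgrid >= (freq - half_bw) & fgrid <= (freq + half_bw) & fgrid <= fs / 2
  Xa <- ifelse(keep, 2 * X, 0 + 0i)
  Xa[1] <- 0
  z <- stats::fft(Xa, inverse = TRUE) / n
  Arg(z)
}

#' Evaluate an expression with a private RNG seed
#'
#' Restores the caller's RNG state afterwards so generators never clobber
#' the session RNG.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Undefined-value marker
#'
#' Quantities that are mathematically undefined (0/0 indices, isolation
#' distance without noise points) are reported as NA rather than NaN so they
#' can be excluded from population summaries explicitly.
#' @keywords internal
undefined_marker <- function() NA_real_
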