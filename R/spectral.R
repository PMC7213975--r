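## State-conditioned LFP spectral analysis: Welch-style averaged modified
## periodogram restricted to selected quiescent epochs, relative band power,
## and spike-field coherence.

## Indices (1-based, into lfp$samples) of window start positions that fit
## wholly inside the given epochs, with the requested overlap.
window_starts <- function(lfp, epochs, nwin, step) {
  starts <- integer(0)
  n <- length(lfp$samples)
  for (i in seq_len(nrow(epochs))) {
    i0 <- ceiling((epochs$start[i] - lfp$t0) * lfp$fs) + 1L
    i1 <- floor((epochs$end[i] - lfp$t0) * lfp$fs) + 1L
    i0 <- max(1L, i0); i1 <- min(n, i1)
    if (i1 - i0 + 1L < nwin) next
    starts <- c(starts, seq(i0, i1 - nwin + 1L, by = step))
  }
  starts
}

## One-sided modified periodograms (Hann taper, per-window mean removed) for
## a set of window start indices. Returns a matrix (freq x windows) of
## spectral densities plus the frequency grid.
welch_segments <- function(x, fs, starts, nwin) {
  w <- 0.5 * (1 - cos(2 * pi * (0:(nwin - 1)) / nwin))  # periodic Hann
  U <- sum(w^2)
  nfreq <- nwin %/% 2 + 1L
  P <- matrix(0, nfreq, length(starts))
  X <- matrix(0 + 0i, nfreq, length(starts))
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + nwin - 1L)]
    seg <- (seg - mean(seg)) * w
    F <- stats::fft(seg)[1:nfreq]
    X[, j] <- F
    p <- Mod(F)^2 / (fs * U)
    p[2:(nfreq - 1L)] <- 2 * p[2:(nfreq - 1L)]
    P[, j] <- p
  }
  list(freq = (0:(nfreq - 1L)) * fs / nwin, P = P, X = X, U = U)
}

#' Averaged modified-periodogram power spectrum over quiescent epochs
#'
#' Welch estimate from 2-s Hann-tapered windows with 50% overlap, using only
#' windows wholly inside the supplied epochs (so bout-contaminated data
#' never enter the estimate). Frequency resolution with the defaults is
#' 0.5 Hz.
#'
#' @param lfp `lfp_signal`.
#' @param epochs interval table, typically from
#'   [select_quiescent_epochs()] with `purpose = "lfp"`.
#' @param window_s window length (s, default 2).
#' @param overlap fractional window overlap (default 0.5).
#' @return `power_spectrum`: list with `freq` (Hz), `power` (uV^2/Hz),
#'   `normalized` flag, `n_segments`.
#' @export
compute_psd <- function(lfp, epochs, window_s = 2, overlap = 0.5) {
  stopifnot(inherits(lfp, "lfp_signal"), overlap >= 0, overlap < 1)
  nwin <- round(window_s * lfp$fs)
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- window_starts(lfp, epochs, nwin, step)
  if (length(starts) == 0L) {
    stop("insufficient quiescence: no complete analysis window fits in the epochs")
  }
  ws <- welch_segments(lfp$samples, lfp$fs, starts, nwin)
  structure(list(freq = ws$freq, power = rowMeans(ws$P),
                 normalized = FALSE, n_segments = length(starts)),
            class = "power_spectrum")
}

#' Normalize a power spectrum to unit total power
#'
#' Divides by the trapezoidal integral over the analysis range so the
#' spectrum integrates to 1 there (the convention used for displaying
#' population spectra).
#'
#' @param ps `power_spectrum`.
#' @param total_range analysis range (Hz), default 0.5-100.
#' @export
normalize_spectrum <- function(ps, total_range = c(0.5, 100)) {
  tot <- trapz_band(ps$freq, ps$power, total_range[1], total_range[2])
  if (tot <= 0) stop("non-positive total power")
  ps$power <- ps$power / tot
  ps$normalized <- TRUE
  ps
}

#' Relative power in a frequency band
#'
#' Ratio between the trapezoidal power integral over the band and the
#' integral over the full analysis range (default 0.5-100 Hz, covering both
#' reported bands while excluding DC drift).
#'
#' @param ps `power_spectrum`.
#' @param band numeric length-2, (f_lo, f_hi) Hz.
#' @param total_range analysis range (Hz).
#' @return `band_power`: list with `band` and `relative_power` in [0, 1].
#' @export
relative_band_power <- function(ps, band, total_range = c(0.5, 100)) {
  stopifnot(length(band) == 2, band[1] < band[2])
  if (band[1] < total_range[1] || band[2] > total_range[2]) {
    stop("band outside the analysis range")
  }
  num <- trapz_band(ps$freq, ps$power, band[1], band[2])
  den <- trapz_band(ps$freq, ps$power, total_range[1], total_range[2])
  structure(list(band = band, relative_power = num / den),
            class = "band_power")
}

#' Spike-field coherence over quiescent epochs
#'
#' Magnitude-squared coherence between the spike point process (binned at
#' the LFP sampling rate) and the LFP, with the same Hann/overlap windowing
#' as [compute_psd()]. The small-sample bias of the coherence estimate is
#' corrected by `(C - 1/K) / (1 - 1/K)` with K the number of windows
#' (clipped at 0), so independent spike trains converge to 0.
#'
#' @param train `spike_train`.
#' @param lfp `lfp_signal`.
#' @param epochs interval table of analysis epochs.
#' @param window_s,overlap windowing parameters as in [compute_psd()].
#' @param min_spikes flag threshold: results based on fewer spikes inside
#'   the epochs carry `flag = "too_few_spikes"` (default 50).
#' @return `coherence_spectrum`: list with `freq`, `coherence` in [0, 1],
#'   `n_spikes`, `n_segments`, `flag`.
#' @export
spike_field_coherence <- function(train, lfp, epochs, window_s = 2,
                                  overlap = 0.5, min_spikes = 50) {
  stopifnot(inherits(train, "spike_train"), inherits(lfp, "lfp_signal"))
  nwin <- round(window_s * lfp$fs)
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- window_starts(lfp, epochs, nwin, step)
  if (length(starts) == 0L) {
    stop("insufficient quiescence: no complete analysis window fits in the epochs")
  }
  n <- length(lfp$samples)
  bins <- tabulate(pmin(n, pmax(1L, floor((train$spike_times - lfp$t0) * lfp$fs) + 1L)),
                   nbins = n)
  n_spikes <- count_in_intervals(train$spike_times, epochs)

  wx <- welch_segments(lfp$samples, lfp$fs, starts, nwin)
  wy <- welch_segments(bins, lfp$fs, starts, nwin)
  K <- length(starts)
  Sxx <- rowMeans(Mod(wx$X)^2)
  Syy <- rowMeans(Mod(wy$X)^2)
  Sxy <- rowMeans(wx$X * Conj(wy$X))
  coh <- Mod(Sxy)^2 / (Sxx * Syy)
  coh[!is.finite(coh)] <- 0
  if (K > 1) coh <- pmax(0, (coh - 1 / K) / (1 - 1 / K))
  structure(list(freq = wx$freq, coherence = pmin(1, coh),
                 n_spikes = n_spikes, n_segments = K,
                 flag = if (n_spikes < min_spikes) "too_few_spikes" else NA_character_),
            class = "coherence_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("power spectrum: %d bins, %.2f-%.1f Hz, %d window(s)%s\n",
              length(x$freq), x$freq[1], x$freq[length(x$freq)], x$n_segments,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}
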