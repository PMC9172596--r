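#' EEG frequency band set
#'
#' Default rodent EEG bands: delta 0.5-4, theta 4-8, alpha 8-11, sigma
#' 11-15, beta 15-30 Hz. Intervals are half-open `[low, high)` so shared
#' edges are assigned deterministically (4 Hz belongs to theta, 30 Hz to
#' beta: the top band is closed at its upper edge).
#'
#' @param name,low,high band names and edges in Hz; bands must be
#'   non-overlapping and ascending.
#' @return data.frame with columns `name`, `low`, `high` (class `band_set`).
#' @export
band_set <- function(name = c("delta", "theta", "alpha", "sigma", "beta"),
                     low = c(0.5, 4, 8, 11, 15),
                     high = c(4, 8, 11, 15, 30)) {
  stopifnot(length(name) == length(low), length(low) == length(high))
  if (any(low >= high)) stop("each band needs low < high", call. = FALSE)
  o <- order(low)
  name <- name[o]; low <- low[o]; high <- high[o]
  if (any(high[-length(high)] > low[-1] + 1e-12)) {
    stop("bands must be non-overlapping and ascending", call. = FALSE)
  }
  structure(data.frame(name = name, low = low, high = high),
            class = c("band_set", "data.frame"))
}

#' Single-epoch power spectrum
#'
#' @param frequencies ascending Hz grid.
#' @param power non-negative spectral power per frequency (arbitrary units,
#'   conventionally uV^2-scaled).
#' @return object of class `epoch_spectrum`.
#' @export
epoch_spectrum <- function(frequencies, power) {
  if (length(frequencies) != length(power)) {
    stop("frequencies and power must have equal length", call. = FALSE)
  }
  if (any(diff(frequencies) <= 0)) {
    stop("frequencies must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(power)) || any(power < 0)) {
    stop("power must be finite and non-negative", call. = FALSE)
  }
  structure(list(frequencies = frequencies, power = power),
            class = "epoch_spectrum")
}

#' Welch periodogram of a raw EEG segment
#'
#' Averaged periodogram with Hann-windowed segments (default 2 s) and 50%
#' overlap; one-sided density scaling so that `sum(power) * df` approximates
#' the signal's mean power.
#'
#' @param signal numeric vector of samples.
#' @param sampling_rate sampling rate in Hz.
#' @param segment_sec segment length in seconds (default 2).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return an [epoch_spectrum()] on the grid `0, 1/segment_sec, ..., fs/2`.
#' @export
periodogram <- function(signal, sampling_rate, segment_sec = 2, overlap = 0.5) {
  if (any(!is.finite(signal))) stop("signal contains non-finite samples", call. = FALSE)
  nseg <- as.integer(round(segment_sec * sampling_rate))
  if (length(signal) < nseg) {
    stop(sprintf("signal too short: %d samples < one %g-s segment (%d samples)",
                 length(signal), segment_sec, nseg), call. = FALSE)
  }
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))  # Hann
  U <- sum(w^2)
  step <- max(1L, as.integer(floor(nseg * (1 - overlap))))
  starts <- seq.int(1L, length(signal) - nseg + 1L, by = step)
  nhalf <- nseg %/% 2L
  acc <- numeric(nhalf + 1L)
  for (s0 in starts) {
    x <- signal[s0:(s0 + nseg - 1L)] * w
    X <- stats::fft(x)
    p <- (Mod(X)^2) / (sampling_rate * U)
    one <- p[seq_len(nhalf + 1L)]
    if (nhalf > 1L) one[2:nhalf] <- 2 * one[2:nhalf]  # fold negative freqs
    acc <- acc + one
  }
  epoch_spectrum(frequencies = seq(0, nhalf) * sampling_rate / nseg,
                 power = acc / length(starts))
}

#' Band powers from a spectrum
#'
#' Sums spectral values whose frequency falls in each band's `[low, high)`
#' interval (the band with the highest upper edge is closed at `high`).
#'
#' @param spectrum an [epoch_spectrum()].
#' @param bands a [band_set()].
#' @return named numeric vector, one power per band.
#' @export
band_powers <- function(spectrum, bands = band_set()) {
  stopifnot(inherits(spectrum, "epoch_spectrum"))
  f <- spectrum$frequencies
  top <- which.max(bands$high)
  out <- numeric(nrow(bands))
  names(out) <- bands$name
  for (i in seq_len(nrow(bands))) {
    if (bands$low[i] < min(f) - 1e-9 || bands$high[i] > max(f) + 1e-9) {
      stop(sprintf("band '%s' [%g, %g) not covered by the frequency grid [%g, %g]",
                   bands$name[i], bands$low[i], bands$high[i], min(f), max(f)),
           call. = FALSE)
    }
    inb <- f >= bands$low[i] & (f < bands$high[i] | (i == top & f <= bands$high[i]))
    out[i] <- sum(spectrum$power[inb])
  }
  out
}

#' Relative band power
#'
#' Each band's power divided by the total power across the named bands
#' (power outside the band set does not enter the denominator).
#'
#' @param powers named numeric vector from [band_powers()].
#' @return fractions summing to 1.
#' @export
relative_power <- function(powers) {
  if (any(powers < 0)) stop("band powers must be non-negative", call. = FALSE)
  tot <- sum(powers)
  if (tot <= 0) stop("all band powers are zero; relative power undefined", call. = FALSE)
  powers / tot
}

#' NREM relative-delta timecourse
#'
#' Per ZT-labeled time bin, the mean over NREM epochs of each epoch's
#' relative delta power. Bins with no NREM epochs are reported as `NA`.
#'
#' @param series an [epoch_series()].
#' @param power matrix of per-epoch spectra (epochs x frequencies), one row
#'   per epoch of `series`.
#' @param frequencies Hz grid for the columns of `power`.
#' @param bin_hours bin width in hours (default 3).
#' @param bands a [band_set()]; the first band is treated as delta.
#' @return data.frame with `bin`, `zt_start`, `n_nrem_epochs`,
#'   `relative_delta`.
#' @export
nrem_delta_timecourse <- function(series, power, frequencies, bin_hours = 3,
                                  bands = band_set()) {
  stopifnot(inherits(series, "epoch_series"))
  power <- as.matrix(power)
  if (nrow(power) != length(series$states)) {
    stop(sprintf("one spectrum per epoch required: %d spectra vs %d epochs",
                 nrow(power), length(series$states)), call. = FALSE)
  }
  reldelta <- vapply(seq_len(nrow(power)), function(i) {
    bp <- band_powers(epoch_spectrum(frequencies, power[i, ]), bands)
    if (sum(bp) <= 0) return(NA_real_)
    unname(relative_power(bp)[1L])
  }, numeric(1))

  epb <- as.integer(round(bin_hours * 3600 / series$epoch_length))
  nbin <- length(series$states) %/% epb
  bin_of <- rep(seq_len(nbin), each = epb)
  is_n <- series$states[seq_len(nbin * epb)] == "N"
  rd <- reldelta[seq_len(nbin * epb)]
  out <- data.frame(
    bin = seq_len(nbin),
    zt_start = (series$start_zt + (seq_len(nbin) - 1L) * bin_hours) %% 24,
    n_nrem_epochs = as.integer(tapply(is_n, bin_of, sum)),
    relative_delta = NA_real_
  )
  for (b in seq_len(nbin)) {
    sel <- bin_of == b & is_n
    if (any(sel)) out$relative_delta[b] <- mean(rd[sel], na.rm = TRUE)
  }
  out
}
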