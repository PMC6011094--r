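#' Averaged-periodogram power spectral density
#'
#' Welch-style estimate: the record is cut into Hann-tapered windows (8 s by
#' default, shorter records fall back to a single full-length window) with 50%
#' overlap; per-window periodograms are averaged. Each window is demeaned
#' before tapering so the DC bin reflects drift, not the offset. The 8 s
#' window gives a 0.125 Hz grid, fine enough to resolve the sub-1 Hz baseline
#' band used by basSQI.
#'
#' @param record An [ecg_record()] with at least 1024 samples.
#' @param window_s Window length in seconds.
#' @param overlap Fractional overlap between consecutive windows.
#' @return An object of class `power_spectrum`: list with `freqs` (Hz) and
#'   `power` (density, arbitrary units).
#' @export
estimate_spectrum <- function(record, window_s = 8, overlap = 0.5) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples
  fs <- record$fs
  if (length(x) < 1024L) {
    abort("record too short for spectral estimation (need >= 1024 samples).",
          class = "ecgsqi_error_input_too_short")
  }
  nwin <- min(length(x), as.integer(round(window_s * fs)))
  step <- max(1L, as.integer(round(nwin * (1 - overlap))))
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1))  # Hann taper
  scale <- fs * sum(w^2)
  nfreq <- nwin %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg))^2 / scale
    acc <- acc + p[seq_len(nfreq)]
  }
  pow <- acc / length(starts)
  # one-sided density: double everything except DC (and Nyquist when present)
  if (nwin %% 2L == 0L) {
    pow[2:(nfreq - 1L)] <- 2 * pow[2:(nfreq - 1L)]
  } else {
    pow[2:nfreq] <- 2 * pow[2:nfreq]
  }
  structure(list(freqs = (seq_len(nfreq) - 1L) * fs / nwin, power = pow),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, 0-%.1f Hz, resolution %.3f Hz\n",
              length(x$freqs), max(x$freqs), x$freqs[2] - x$freqs[1]))
  invisible(x)
}

#' Integrated band power
#'
#' Trapezoidal integral of the spectral density over `[f_lo, f_hi]`, with
#' linear interpolation at the band edges.
#'
#' @param spectrum A `power_spectrum`.
#' @param f_lo,f_hi Band edges in Hz.
#' @return Non-negative scalar power.
#' @export
band_power <- function(spectrum, f_lo, f_hi) {
  stopifnot(inherits(spectrum, "power_spectrum"), f_lo < f_hi)
  f <- spectrum$freqs
  p <- spectrum$power
  if (f_hi > max(f) + 1e-9) {
    abort(sprintf("spectrum covers only up to %.2f Hz (need %.2f).", max(f), f_hi),
          class = "ecgsqi_error_argument")
  }
  grid <- sort(unique(c(f_lo, f_hi, f[f > f_lo & f < f_hi])))
  pg <- approx(f, p, xout = grid, rule = 2)$y
  sum(diff(grid) * (pg[-length(pg)] + pg[-1L]) / 2)
}
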