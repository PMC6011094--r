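#' @title R-peak detection
#' @description
#' Two independent QRS detectors whose agreement defines the qSQI index:
#'
#' * `detect_rpeaks_hilbert()`: 5-20 Hz zero-phase band-pass, first
#'   difference, analytic-signal (Hilbert) envelope, then a dynamic adaptive
#'   threshold with a 0.2 s refractory period and a search-back pass at a
#'   lowered threshold when an expected beat is missed.
#' * `detect_rpeaks_dwt()`: stationary (a trous) wavelet decomposition with the
#'   quadratic-spline smoothed-derivative filter pair; R peaks are the zero
#'   crossings between paired positive/negative modulus maxima of the detail
#'   coefficients at the QRS-dominant scale, with cross-scale amplitude gating
#'   to suppress narrowband (powerline) extrema.
#'
#' Both return sample positions of detected R peaks, strictly increasing and
#' separated by at least the refractory period.
#'
#' @param record An [ecg_record()] of at least 2 s duration.
#' @param refractory_s Minimum separation between accepted beats (s).
#' @return An object of class `rpeak_set`: list with `indices` (1-based sample
#'   positions), `detector_id`, `fs`.
#' @name rpeak_detection
NULL

new_rpeak_set <- function(indices, detector_id, fs) {
  structure(list(indices = as.integer(indices), detector_id = detector_id,
                 fs = fs), class = "rpeak_set")
}

#' @export
print.rpeak_set <- function(x, ...) {
  cat(sprintf("<rpeak_set> %s: %d peaks @ %g Hz\n", x$detector_id,
              length(x$indices), x$fs))
  invisible(x)
}

#' Peak sets as a tibble
#' @param x An `rpeak_set`.
#' @param ... Unused.
#' @return A tibble with `sample_index`, `time_s`, `detector_id`.
#' @export
as_tibble.rpeak_set <- function(x, ...) {
  tibble(sample_index = x$indices, time_s = (x$indices - 1L) / x$fs,
         detector_id = x$detector_id)
}

check_min_duration <- function(record, min_s = 2) {
  if (duration_s(record) < min_s) {
    abort(sprintf("record too short: %.2f s (need >= %g s).",
                  duration_s(record), min_s),
          class = "ecgsqi_error_input_too_short")
  }
}

# analytic-signal envelope via FFT (no hilbert() in the installed stack)
envelope_hilbert <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

bandpass_qrs <- function(x, fs, low = 5, high = 20, order = 3) {
  ny <- fs / 2
  bf <- signal::butter(order, c(low, high) / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2)) |>
    (\(y) { y[is.na(y)] <- 0; y })()
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' @rdname rpeak_detection
#' @export
detect_rpeaks_hilbert <- function(record, refractory_s = 0.2) {
  stopifnot(inherits(record, "ecg_record"))
  check_min_duration(record)
  fs <- record$fs
  if (sd(record$samples) == 0) return(new_rpeak_set(integer(0), "hilbert_adaptive", fs))
  bp <- bandpass_qrs(record$samples, fs)
  d <- c(diff(bp), 0)
  env <- envelope_hilbert(d)
  env <- moving_average(env, max(1L, as.integer(round(0.1 * fs))))
  refr <- as.integer(round(refractory_s * fs))

  cand <- local_maxima(env)
  init <- 0.6 * as.numeric(quantile(env[seq_len(min(length(env), 2L * fs))], 0.98))
  if (!is.finite(init) || init <= 0) return(new_rpeak_set(integer(0), "hilbert_adaptive", fs))

  accepted <- integer(0)
  amps <- numeric(0)
  thr <- init
  for (i in cand) {
    if (length(accepted) > 0L && (i - accepted[length(accepted)]) < refr) {
      if (env[i] > amps[length(amps)]) {  # larger lobe within refractory wins
        accepted[length(accepted)] <- i
        amps[length(amps)] <- env[i]
      }
      next
    }
    if (env[i] > thr) {
      accepted <- c(accepted, i)
      amps <- c(amps, env[i])
      recent <- amps[max(1L, length(amps) - 7L):length(amps)]
      thr <- 0.3 * mean(recent)
    }
  }

  # search-back: revisit gaps longer than 1.66 x median RR at 0.4 x threshold
  if (length(accepted) >= 3L) {
    med_rr <- median(diff(accepted))
    repeat {
      gaps <- which(diff(accepted) > 1.66 * med_rr)
      if (length(gaps) == 0L) break
      inserted <- FALSE
      for (g in gaps) {
        lo <- accepted[g] + refr
        hi <- accepted[g + 1L] - refr
        if (hi <= lo) next
        seg <- cand[cand >= lo & cand <= hi]
        seg <- seg[env[seg] > 0.4 * thr]
        if (length(seg) > 0L) {
          best <- seg[which.max(env[seg])]
          accepted <- sort(c(accepted, best))
          inserted <- TRUE
          break
        }
      }
      if (!inserted) break
    }
  }

  # refine envelope peaks to the band-passed extremum (polarity-insensitive)
  half <- as.integer(round(0.075 * fs))
  refined <- vapply(accepted, function(i) {
    lo <- max(1L, i - half); hi <- min(length(bp), i + half)
    lo + which.max(abs(bp[lo:hi])) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  if (length(refined) > 1L) {  # refinement may merge neighbours
    keep <- c(TRUE, diff(refined) >= refr)
    refined <- refined[keep]
  }
  new_rpeak_set(refined, "hilbert_adaptive", fs)
}

# quadratic-spline filter pair (smoothed-derivative wavelet)
swt_lowpass <- c(1, 3, 3, 1) / 8
swt_highpass <- c(2, -2)

conv_aligned <- function(x, f, up) {
  taps <- rep(0, (length(f) - 1L) * up + 1L)
  taps[seq(1L, length(taps), by = up)] <- f
  delay <- as.integer(round((length(taps) - 1L) / 2))
  y <- stats::convolve(x, rev(taps), type = "open")
  y[(delay + 1L):(delay + length(x))]
}

# detail coefficients of the a trous SWT at `level`, aligned to the signal
swt_detail <- function(x, level) {
  a <- x
  for (j in seq_len(level - 1L)) a <- conv_aligned(a, swt_lowpass, 2L^(j - 1L))
  conv_aligned(a, swt_highpass, 2L^(level - 1L))
}

# scale whose passband best covers the QRS-dominant ~10 Hz band
qrs_swt_level <- function(fs) max(2L, min(4L, as.integer(round(log2(fs))) - 5L))

#' @rdname rpeak_detection
#' @export
detect_rpeaks_dwt <- function(record, refractory_s = 0.2) {
  stopifnot(inherits(record, "ecg_record"))
  check_min_duration(record)
  fs <- record$fs
  x <- record$samples - mean(record$samples)
  lev <- qrs_swt_level(fs)
  d <- swt_detail(x, lev)
  d1 <- swt_detail(x, 1L)
  n <- length(d)
  # two-part amplitude gate: a floor from the bulk modulus distribution plus
  # a fraction of the strongest (QRS-scale) moduli, so that P/T-wave maxima
  # stay below threshold even when QRS lobes dominate the upper percentiles
  thr <- max(0.3 * as.numeric(quantile(abs(d), 0.95)),
             0.125 * as.numeric(quantile(abs(d), 0.999)))
  if (!is.finite(thr) || thr <= 0) return(new_rpeak_set(integer(0), "dwt_modmax", fs))

  pos <- local_maxima(d); pos <- pos[d[pos] > thr]
  neg <- local_maxima(-d); neg <- neg[d[neg] < -thr]
  ext <- sort(c(pos, neg))
  if (length(ext) < 2L) return(new_rpeak_set(integer(0), "dwt_modmax", fs))

  # cross-scale gating: a genuine QRS singularity keeps its modulus at the
  # coarse scale; narrowband interference (e.g. 50/60 Hz) lives at scale 1
  half_gate <- as.integer(round(0.05 * fs))
  gate_ok <- vapply(ext, function(i) {
    lo <- max(1L, i - half_gate); hi <- min(n, i + half_gate)
    abs(d[i]) >= 0.8 * max(abs(d1[lo:hi]))
  }, logical(1))
  ext <- ext[gate_ok]
  if (length(ext) < 2L) return(new_rpeak_set(integer(0), "dwt_modmax", fs))

  pair_win <- as.integer(round(0.12 * fs))
  cand_idx <- integer(0)
  cand_str <- numeric(0)
  for (k in seq_len(length(ext) - 1L)) {
    i <- ext[k]; j <- ext[k + 1L]
    if (sign(d[i]) == sign(d[j]) || (j - i) > pair_win) next
    seg <- d[i:j]
    zc <- which(seg[-length(seg)] * seg[-1L] <= 0)
    if (length(zc) == 0L) next
    r <- i + zc[1L] - 1L
    if (abs(seg[zc[1L] + 1L]) < abs(seg[zc[1L]])) r <- r + 1L
    cand_idx <- c(cand_idx, r)
    cand_str <- c(cand_str, min(abs(d[i]), abs(d[j])))
  }
  if (length(cand_idx) == 0L) return(new_rpeak_set(integer(0), "dwt_modmax", fs))

  # strength-greedy refractory enforcement
  refr <- as.integer(round(refractory_s * fs))
  ord <- order(cand_str, decreasing = TRUE)
  accepted <- integer(0)
  for (k in ord) {
    if (all(abs(cand_idx[k] - accepted) >= refr)) {
      accepted <- c(accepted, cand_idx[k])
    }
  }
  accepted <- sort(accepted)
  accepted <- accepted[accepted >= 1L & accepted <= n]
  new_rpeak_set(accepted, "dwt_modmax", fs)
}

#' Match two R-peak sets
#'
#' One-to-one assignment between the peaks of two detectors: a pair may match
#' only if it lies within `tolerance_s`, and the number of matched pairs `N` is
#' maximised by a non-crossing dynamic program (exact for 1-D points with a
#' symmetric tolerance). Returns the counts that enter the qSQI index.
#'
#' @param a,b `rpeak_set` objects with equal sampling rate.
#' @param tolerance_s Matching window in seconds (default 0.15, the PhysioNet
#'   beat-matching convention).
#' @return An object of class `rpeak_match`: list with `n_matched`, `n_a`,
#'   `n_b`, `tolerance_s`.
#' @export
match_rpeaks <- function(a, b, tolerance_s = 0.15) {
  stopifnot(inherits(a, "rpeak_set"), inherits(b, "rpeak_set"))
  if (!isTRUE(all.equal(a$fs, b$fs))) {
    abort("peak sets have different sampling rates.", class = "ecgsqi_error_argument")
  }
  ta <- a$indices / a$fs
  tb <- b$indices / b$fs
  na <- length(ta); nb <- length(tb)
  if (na == 0L || nb == 0L) {
    return(structure(list(n_matched = 0L, n_a = na, n_b = nb,
                          tolerance_s = tolerance_s), class = "rpeak_match"))
  }
  # f[i+1, j+1] = max matches using first i of a, first j of b
  f <- matrix(0L, na + 1L, nb + 1L)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      best <- max(f[i, j + 1L], f[i + 1L, j])
      if (abs(ta[i] - tb[j]) <= tolerance_s) best <- max(best, f[i, j] + 1L)
      f[i + 1L, j + 1L] <- best
    }
  }
  structure(list(n_matched = f[na + 1L, nb + 1L], n_a = na, n_b = nb,
                 tolerance_s = tolerance_s), class = "rpeak_match")
}

#' @export
print.rpeak_match <- function(x, ...) {
  cat(sprintf("<rpeak_match> N=%d of Na=%d, Nb=%d (tol %.0f ms)\n",
              x$n_matched, x$n_a, x$n_b, 1000 * x$tolerance_s))
  invisible(x)
}
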