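#' Synthesis specification for synthetic ECG
#'
#' Describes one synthetic single-lead record: sampling rate, duration, heart
#' rate and its beat-to-beat jitter, and the relative amplitude of each of the
#' four additive noise classes (as fractions of the R-wave amplitude, which is
#' 1 by construction):
#'
#' * `baseline_wander` — sum of slow sinusoids (0.05-0.5 Hz, random
#'   frequencies and phases), scaled so its peak equals the requested
#'   amplitude;
#' * `powerline` — a 50 or 60 Hz tone at the requested peak amplitude;
#' * `emg` — white noise band-passed to 20-40 Hz (inside the analysed 0-40 Hz
#'   band) at the requested RMS;
#' * `gaussian` — white Gaussian noise at the requested standard deviation.
#'
#' @param fs Sampling rate (Hz, >= 100).
#' @param duration_s Duration (s, >= 5).
#' @param heart_rate_bpm Mean heart rate (30-220 bpm).
#' @param hr_jitter_frac Coefficient of variation of the RR intervals.
#' @param noise_amplitudes Named numeric vector over the four noise classes.
#' @param powerline_hz Mains frequency, 50 or 60.
#' @param label_bands Per-noise amplitude cut points `(to_B, to_U)` used to
#'   derive the construction-time quality label: a record is labelled `"B"`
#'   once any noise amplitude reaches its first cut and `"U"` once any
#'   reaches its second.
#' @param seed Integer seed; every random draw in the generator flows from it.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(fs = 300, duration_s = 30, heart_rate_bpm = 75,
                       hr_jitter_frac = 0.02,
                       noise_amplitudes = c(baseline_wander = 0, powerline = 0,
                                            emg = 0, gaussian = 0),
                       powerline_hz = 50,
                       label_bands = list(baseline_wander = c(0.1, 1.5),
                                          powerline = c(0.3, 2.0),
                                          emg = c(0.15, 0.5),
                                          gaussian = c(0.1, 0.5)),
                       seed = 1L) {
  amps <- c(baseline_wander = 0, powerline = 0, emg = 0, gaussian = 0)
  amps[names(noise_amplitudes)] <- noise_amplitudes
  if (fs < 100 || duration_s < 5 || heart_rate_bpm < 30 || heart_rate_bpm > 220 ||
      any(amps < 0) || hr_jitter_frac < 0) {
    abort(paste("invalid synthesis spec: need fs >= 100, duration >= 5 s,",
                "heart rate in [30, 220], non-negative amplitudes."),
          class = "ecgsqi_error_argument")
  }
  if (!powerline_hz %in% c(50, 60)) {
    abort("powerline_hz must be 50 or 60.", class = "ecgsqi_error_argument")
  }
  structure(list(fs = fs, duration_s = duration_s,
                 heart_rate_bpm = heart_rate_bpm,
                 hr_jitter_frac = hr_jitter_frac,
                 noise_amplitudes = amps, powerline_hz = powerline_hz,
                 label_bands = label_bands, seed = as.integer(seed)),
            class = "synth_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# P-QRS-T morphology as Gaussian bumps; (amplitude, offset, width) with
# offsets of the slow waves expressed as fractions of the local RR so the
# beat compresses plausibly at high heart rates
beat_components <- function(rr) {
  list(
    p = c(a = 0.15, c = -0.20 * rr, w = 0.025),
    q = c(a = -0.10, c = -0.026, w = 0.009),
    r = c(a = 1.00, c = 0.000, w = 0.010),
    s = c(a = -0.20, c = 0.028, w = 0.009),
    t = c(a = 0.35, c = 0.30 * rr, w = 0.06 + 0.01 * rr)
  )
}

label_from_amplitudes <- function(spec) {
  lab <- "E"
  for (nm in names(spec$noise_amplitudes)) {
    a <- spec$noise_amplitudes[[nm]]
    cuts <- spec$label_bands[[nm]]
    if (a >= cuts[2]) return("U")
    if (a >= cuts[1]) lab <- "B"
  }
  lab
}

#' Generate a clean synthetic ECG record
#'
#' Quasi-periodic waveform built from Gaussian-bump P/Q/R/S/T components, with
#' RR intervals `60/heart_rate * (1 + jitter)` where the jitter is i.i.d.
#' normal (truncated at three sigma) with the requested coefficient of
#' variation. Ground-truth R positions are recorded exactly. Noise amplitudes
#' in the spec are ignored here; apply [add_noise()] afterwards.
#'
#' @param spec A [synth_spec()].
#' @return A list of class `labeled_ecg`: `record` ([ecg_record()]),
#'   `true_rpeaks` (sample indices), `intended_label` (`"E"`), `spec`.
#' @export
generate_clean <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  fs <- spec$fs
  n <- as.integer(round(spec$duration_s * fs))
  t <- (seq_len(n) - 1L) / fs
  rr0 <- 60 / spec$heart_rate_bpm
  with_seed(spec$seed, {
    n_beats <- ceiling(spec$duration_s / rr0) + 3L
    jit <- pmax(-3, pmin(3, rnorm(n_beats)))
    rr <- rr0 * (1 + spec$hr_jitter_frac * jit)
    r_times <- cumsum(c(rr0 / 2, rr))  # first R half a cycle in
  })
  x <- numeric(n)
  for (i in seq_along(r_times)) {
    tr <- r_times[i]
    if (tr < -1 || tr > spec$duration_s + 1) next
    rr_loc <- if (i < length(r_times)) r_times[i + 1L] - tr else rr0
    for (cmp in beat_components(rr_loc)) {
      ctr <- tr + cmp[["c"]]
      lo <- max(1L, as.integer(floor((ctr - 5 * cmp[["w"]]) * fs)) + 1L)
      hi <- min(n, as.integer(ceiling((ctr + 5 * cmp[["w"]]) * fs)) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      x[idx] <- x[idx] + cmp[["a"]] * exp(-((t[idx] - ctr)^2) / (2 * cmp[["w"]]^2))
    }
  }
  true_r <- as.integer(round(r_times * fs)) + 1L
  true_r <- true_r[true_r >= 1L & true_r <= n]
  rec <- ecg_record(x, fs = fs, source_id = sprintf("synth-seed%d", spec$seed))
  structure(list(record = rec, true_rpeaks = true_r, intended_label = "E",
                 spec = spec), class = "labeled_ecg")
}

#' @export
print.labeled_ecg <- function(x, ...) {
  cat(sprintf("<labeled_ecg> %s: intended %s, %d true R peaks\n",
              x$record$source_id, x$intended_label, length(x$true_rpeaks)))
  invisible(x)
}

#' Add calibrated noise to a synthetic record
#'
#' Adds the four noise classes described in [synth_spec()] at the amplitudes
#' given there (all relative to the unit R amplitude). The construction-time
#' label is downgraded according to the spec's per-noise amplitude bands; when
#' the record was already noised, the worse label wins.
#'
#' @param labeled A `labeled_ecg` from [generate_clean()].
#' @param spec A [synth_spec()] carrying the noise amplitudes (defaults to the
#'   one stored in `labeled`).
#' @return A new `labeled_ecg` with noisy samples and updated label.
#' @export
add_noise <- function(labeled, spec = labeled$spec) {
  stopifnot(inherits(labeled, "labeled_ecg"), inherits(spec, "synth_spec"))
  rec <- labeled$record
  fs <- rec$fs
  n <- length(rec$samples)
  t <- (seq_len(n) - 1L) / fs
  amps <- spec$noise_amplitudes
  noise <- numeric(n)
  with_seed(spec$seed + 104729L, {  # distinct stream from the waveform's
    if (amps[["baseline_wander"]] > 0) {
      f <- runif(3, 0.05, 0.5)
      ph <- runif(3, 0, 2 * pi)
      a <- c(1, 0.6, 0.3)
      bw <- numeric(n)
      for (k in 1:3) bw <- bw + a[k] * sin(2 * pi * f[k] * t + ph[k])
      noise <- noise + amps[["baseline_wander"]] * bw / max(abs(bw))
    }
    if (amps[["powerline"]] > 0) {
      noise <- noise + amps[["powerline"]] *
        sin(2 * pi * spec$powerline_hz * t + runif(1, 0, 2 * pi))
    }
    if (amps[["emg"]] > 0) {
      w <- rnorm(n)
      bf <- signal::butter(4, c(20, 40) / (fs / 2), type = "pass")
      e <- as.numeric(signal::filtfilt(bf, w))
      noise <- noise + amps[["emg"]] * e / sd(e)
    }
    if (amps[["gaussian"]] > 0) {
      noise <- noise + amps[["gaussian"]] * rnorm(n)
    }
  })
  new_label <- label_from_amplitudes(spec)
  order_ebu <- c(E = 1L, B = 2L, U = 3L)
  worst <- names(which.max(order_ebu[c(labeled$intended_label, new_label)]))
  rec$samples <- rec$samples + noise
  structure(list(record = rec, true_rpeaks = labeled$true_rpeaks,
                 intended_label = worst, spec = spec), class = "labeled_ecg")
}

random_class_spec <- function(class, fs, duration_s, seed) {
  draw <- function(lo, hi) runif(1, lo, hi)
  with_seed(seed, {
    hr <- draw(72, 110)
    cv <- draw(0.01, 0.04)
    amps <- switch(class,
      E = c(baseline_wander = draw(0, 0.05), powerline = draw(0, 0.04),
            emg = draw(0, 0.04), gaussian = draw(0, 0.02)),
      B = c(baseline_wander = draw(0.08, 0.12), powerline = draw(0, 0.05),
            emg = draw(0, 0.05), gaussian = draw(0.25, 0.45)),
      U = if (runif(1) < 0.5) {
        # EMG-dominant composite corruption: muscle noise at the R amplitude
        # over the wideband + drift floor of motion-corrupted recordings
        c(baseline_wander = draw(0.4, 0.8), powerline = draw(0, 0.1),
          emg = draw(0.8, 1.2), gaussian = draw(0.4, 0.6))
      } else {
        # electrode-motion wander: heavy drift with its broadband component
        c(baseline_wander = draw(1.6, 2.6), powerline = draw(0, 0.1),
          emg = draw(0.7, 1.1), gaussian = draw(0.25, 0.45))
      },
      abort("class must be E, B or U.", class = "ecgsqi_error_argument")
    )
    synth_spec(fs = fs, duration_s = duration_s, heart_rate_bpm = hr,
               hr_jitter_frac = cv, noise_amplitudes = amps, seed = seed)
  })
}

#' Generate a balanced labelled dataset
#'
#' Draws `n_per_class` records for each requested quality class with
#' randomised per-record synthesis parameters (heart rate 72-110 bpm, mild RR
#' jitter) and class-specific noise mixtures: Excellent records carry only
#' trace noise; Barely-acceptable records carry moderate Gaussian noise and a
#' touch of baseline wander;
#' Unacceptable records are either EMG-dominated or show electrode-motion
#' wander (heavy drift plus broadband artifact), mirroring the two main
#' failure modes of ambulatory recordings. Deterministic for a fixed seed.
#'
#' @param n_per_class Records per class (>= 1).
#' @param seed Integer master seed.
#' @param classes Which classes to generate.
#' @param fs,duration_s Record geometry.
#' @return A list of `labeled_ecg` objects.
#' @export
generate_dataset <- function(n_per_class, seed = 1L, classes = c("E", "U"),
                             fs = 300, duration_s = 30) {
  stopifnot(n_per_class >= 1L, all(classes %in% c("E", "B", "U")))
  out <- list()
  k <- 0L
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      rec_seed <- (seed * 10007L + k * 7919L) %% .Machine$integer.max
      sp <- random_class_spec(cl, fs, duration_s, rec_seed)
      lab <- add_noise(generate_clean(sp), sp)
      lab$record$source_id <- sprintf("synth-%s-%03d", cl, i)
      # construction-time class is authoritative for the dataset
      lab$intended_label <- cl
      out[[k]] <- lab
    }
  }
  out
}
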