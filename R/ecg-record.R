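#' Construct a single-lead ECG record
#'
#' The universal input container of the package: a sampled single-lead ECG
#' trace together with its sampling rate. All quality indices computed here are
#' scale invariant (ratios, standardized moments, band-power ratios), so the
#' amplitude unit is carried for display only and never normalised.
#'
#' @param samples Numeric vector of amplitudes (mV or raw ADC units).
#' @param fs Sampling rate in Hz, must be positive.
#' @param lead_name Lead label, e.g. `"II"` or `"MLII"`.
#' @param source_id Free-text provenance identifier.
#' @param units Amplitude unit label (display only).
#' @param na_action How to treat NaN/Inf samples: `"error"` rejects the record,
#'   `"interpolate"` linearly interpolates isolated non-finite runs.
#'
#' @return An object of class `ecg_record`: a list with elements `samples`,
#'   `fs`, `lead_name`, `source_id`, `units`.
#' @examples
#' rec <- ecg_record(sin(2 * pi * 1 * seq(0, 10, by = 1 / 300)), fs = 300)
#' rec
#' @export
ecg_record <- function(samples, fs, lead_name = "I", source_id = "anonymous",
                       units = "mV", na_action = c("error", "interpolate")) {
  na_action <- match.arg(na_action)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number.", class = "ecgsqi_error_argument")
  }
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    abort("`samples` must contain at least one value.", class = "ecgsqi_error_argument")
  }
  bad <- !is.finite(samples)
  if (any(bad)) {
    if (na_action == "error") {
      abort(
        sprintf("record contains %d non-finite samples; set na_action = \"interpolate\" to repair.", sum(bad)),
        class = "ecgsqi_error_argument"
      )
    }
    if (all(bad)) {
      abort("record contains no finite samples.", class = "ecgsqi_error_argument")
    }
    idx <- seq_along(samples)
    samples <- approx(idx[!bad], samples[!bad], xout = idx, rule = 2)$y
  }
  structure(
    list(samples = samples, fs = fs, lead_name = lead_name,
         source_id = source_id, units = units),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s lead %s: %d samples @ %g Hz (%.1f s, %s)\n",
              x$source_id, x$lead_name, length(x$samples), x$fs,
              length(x$samples) / x$fs, x$units))
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$samples)

duration_s <- function(record) length(record$samples) / record$fs

#' Read a one-column CSV/TSV of ECG samples
#'
#' Accepts a single numeric column with an optional one-line header. The
#' sampling rate is not stored in the file and must be supplied.
#'
#' @param path Path to the file.
#' @param fs Sampling rate in Hz.
#' @inheritParams ecg_record
#' @return An [ecg_record()].
#' @export
read_ecg_csv <- function(path, fs, lead_name = "I",
                         source_id = basename(path), units = "mV") {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "ecgsqi_error_io")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort(sprintf("empty ECG file: %s", path), class = "ecgsqi_error_parse")
  }
  start <- 1L
  if (is.na(suppressWarnings(as.numeric(lines[1L])))) start <- 2L  # header line
  if (start > length(lines)) {
    abort(sprintf("no sample rows in %s", path), class = "ecgsqi_error_parse")
  }
  vals <- suppressWarnings(as.numeric(lines[start:length(lines)]))
  if (anyNA(vals)) {
    bad_line <- start + which(is.na(vals))[1L] - 1L
    abort(sprintf("non-numeric sample at line %d of %s", bad_line, path),
          class = "ecgsqi_error_parse")
  }
  ecg_record(vals, fs = fs, lead_name = lead_name, source_id = source_id,
             units = units)
}

#' Write an ECG record as a one-column CSV
#'
#' @param record An [ecg_record()].
#' @param path Output path.
#' @param header Whether to write a one-line `"ecg"` header.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(record, path, header = TRUE) {
  stopifnot(inherits(record, "ecg_record"))
  lines <- format(record$samples, digits = 15, trim = TRUE, scientific = FALSE)
  if (header) lines <- c("ecg", lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read a WFDB record (PhysioNet dialect)
#'
#' Minimal reader for the PhysioNet waveform-database format: a `.hea` header
#' plus a `.dat` signal file. Sample formats 16 (little-endian int16) and 212
#' (packed 12-bit pairs) are supported, which covers the CinC 2011/2017
#' distributions. When the header carries a gain, amplitudes are converted to
#' physical units via `(adc - baseline) / gain`.
#'
#' @param path Record path with or without the `.hea` extension.
#' @param lead Lead to extract: a signal description (e.g. `"II"`) or 1-based
#'   channel index. Default is the first channel.
#' @return An [ecg_record()] for the requested channel.
#' @export
read_wfdb <- function(path, lead = 1L) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) {
    abort(sprintf("WFDB header not found: %s", hea), class = "ecgsqi_error_io")
  }
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  record_name <- top[1L]
  n_sig <- as.integer(top[2L])
  fs <- if (length(top) >= 3L) as.numeric(strsplit(top[3L], "/")[[1L]][1L]) else 250
  n_samp <- if (length(top) >= 4L) as.integer(top[4L]) else NA_integer_
  if (n_sig < 1L) abort("WFDB header declares no signals.", class = "ecgsqi_error_parse")
  sig <- lines[2:(1L + n_sig)]
  parse_sig <- function(line) {
    f <- strsplit(trimws(line), "\\s+")[[1L]]
    fmt <- as.integer(sub("x.*$", "", sub("\\+.*$", "", f[2L])))
    gain_field <- f[3L]
    baseline <- 0
    if (grepl("\\(", gain_field)) {
      baseline <- as.numeric(sub("^.*\\(([-0-9.]+)\\).*$", "\\1", gain_field))
      gain_field <- sub("\\(.*$", "", gain_field)
    }
    gain <- as.numeric(sub("/.*$", "", gain_field))
    units <- if (grepl("/", f[3L])) sub("^.*/", "", f[3L]) else "adu"
    desc <- if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ") else ""
    list(file = f[1L], format = fmt, gain = gain, baseline = baseline,
         units = units, desc = desc)
  }
  sigs <- lapply(sig, parse_sig)
  ch <- if (is.numeric(lead)) as.integer(lead) else {
    hit <- which(vapply(sigs, function(s) identical(s$desc, lead), logical(1)))
    if (length(hit) == 0L) {
      abort(sprintf("lead \"%s\" not present in %s", lead, hea),
            class = "ecgsqi_error_lead")
    }
    hit[1L]
  }
  if (ch < 1L || ch > n_sig) {
    abort(sprintf("channel %d out of range (record has %d signals)", ch, n_sig),
          class = "ecgsqi_error_lead")
  }
  dat <- file.path(dirname(hea), sigs[[ch]]$file)
  if (!file.exists(dat)) {
    abort(sprintf("WFDB signal file not found: %s", dat), class = "ecgsqi_error_io")
  }
  fmts <- vapply(sigs, `[[`, integer(1), "format")
  if (!all(fmts == fmts[1L])) {
    abort("mixed per-signal formats are not supported.", class = "ecgsqi_error_parse")
  }
  raw_bytes <- readBin(dat, "raw", n = file.size(dat))
  adc <- switch(as.character(fmts[1L]),
    "16" = {
      v <- readBin(raw_bytes, "integer", n = length(raw_bytes) %/% 2L,
                   size = 2L, signed = TRUE, endian = "little")
      matrix(v, nrow = n_sig)[ch, ]
    },
    "212" = {
      v <- decode_fmt212(raw_bytes)
      matrix(v[seq_len((length(v) %/% n_sig) * n_sig)], nrow = n_sig)[ch, ]
    },
    abort(sprintf("unsupported WFDB format %d (only 16 and 212).", fmts[1L]),
          class = "ecgsqi_error_parse")
  )
  if (!is.na(n_samp) && n_samp > 0L) adc <- adc[seq_len(min(n_samp, length(adc)))]
  gain <- sigs[[ch]]$gain
  phys <- if (is.finite(gain) && gain != 0) (adc - sigs[[ch]]$baseline) / gain else adc
  units <- if (is.finite(gain) && gain != 0) sigs[[ch]]$units else "adu"
  lead_name <- if (nzchar(sigs[[ch]]$desc)) sigs[[ch]]$desc else as.character(ch)
  ecg_record(phys, fs = fs, lead_name = lead_name, source_id = record_name,
             units = units)
}

# format 212: two 12-bit samples packed into three bytes
decode_fmt212 <- function(raw_bytes) {
  n3 <- (length(raw_bytes) %/% 3L) * 3L
  b <- as.integer(raw_bytes[seq_len(n3)])
  b1 <- b[seq(1L, n3, by = 3L)]
  b2 <- b[seq(2L, n3, by = 3L)]
  b3 <- b[seq(3L, n3, by = 3L)]
  s1 <- b1 + bitwShiftL(bitwAnd(b2, 0x0FL), 8L)
  s2 <- b3 + bitwShiftL(bitwShiftR(b2, 4L), 8L)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  as.integer(rbind(s1, s2))
}

#' Write an ECG record as a WFDB format-16 record
#'
#' Companion writer used mainly to build test fixtures and to export synthetic
#' records in a form other WFDB tools can read. Amplitudes are quantised with
#' the given gain.
#'
#' @param record An [ecg_record()].
#' @param path Record path with or without the `.hea` extension.
#' @param gain ADC units per physical unit (default 200).
#' @return The header path, invisibly.
#' @export
write_wfdb <- function(record, path, gain = 200) {
  stopifnot(inherits(record, "ecg_record"))
  base <- sub("\\.hea$", "", path)
  name <- basename(base)
  adc <- as.integer(round(record$samples * gain))
  if (any(adc > 32767L | adc < -32768L)) {
    abort("amplitudes overflow int16 at this gain; lower `gain`.",
          class = "ecgsqi_error_argument")
  }
  writeBin(adc, paste0(base, ".dat"), size = 2L, endian = "little")
  hdr <- c(
    sprintf("%s 1 %g %d", name, record$fs, length(record$samples)),
    sprintf("%s.dat 16 %g(0)/%s 16 0 %d 0 0 %s",
            name, gain, record$units, adc[1L], record$lead_name)
  )
  writeLines(hdr, paste0(base, ".hea"))
  invisible(paste0(base, ".hea"))
}

#' Cut a record into fixed-length analysis windows
#'
#' Windows are consecutive and non-overlapping; a trailing remainder shorter
#' than `length` is dropped. Each window inherits the sampling rate and gets a
#' provenance id `<source_id>#<window index>`.
#'
#' @param record An [ecg_record()].
#' @param length Window length in samples (default 9000, i.e. 30 s at 300 Hz).
#' @return A list of `ecg_record` windows (possibly empty).
#' @export
segment_ecg <- function(record, length = 9000L) {
  stopifnot(inherits(record, "ecg_record"))
  length <- as.integer(length)
  if (length < 1L) abort("`length` must be >= 1.", class = "ecgsqi_error_argument")
  n_win <- base::length(record$samples) %/% length
  if (n_win == 0L) return(list())
  lapply(seq_len(n_win), function(i) {
    idx <- ((i - 1L) * length + 1L):(i * length)
    ecg_record(record$samples[idx], fs = record$fs,
               lead_name = record$lead_name,
               source_id = sprintf("%s#%d", record$source_id, i),
               units = record$units)
  })
}
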