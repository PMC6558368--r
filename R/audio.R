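# Audio rendering and WAV input/output. Battery stimuli are rendered at
# 44,100 Hz mono and stored as 16-bit PCM.

DEFAULT_RATE <- 44100L

#' Construct an audio clip
#'
#' @param samples Numeric amplitude vector, every value in \[-1, 1\].
#' @param rate Sampling rate in samples per second.
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, rate = DEFAULT_RATE) {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) rlang::abort("samples must be finite")
  if (length(samples) && max(abs(samples)) > 1 + 1e-9) {
    rlang::abort("samples exceed [-1, 1]: clip would distort",
                 class = "minimuse_clipping")
  }
  structure(list(samples = samples, rate = as.integer(rate)),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %d samples @ %d Hz (%.3f s), peak %.3f\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' @export
length.audio_clip <- function(x) length(x$samples)

#' Specify a pure tone
#'
#' The pitch-task standard is a 1000 Hz pure tone of 400 ms with 25 ms linear
#' onset and offset ramps.
#'
#' @param freq_hz Tone frequency in Hz.
#' @param dur_ms Duration in milliseconds.
#' @param ramp_ms Linear onset/offset ramp length in milliseconds; the two
#'   ramps together may not exceed the duration.
#' @return An object of class `tone_spec`.
#' @export
tone_spec <- function(freq_hz = 1000, dur_ms = 400, ramp_ms = 25) {
  if (freq_hz <= 0 || dur_ms <= 0 || ramp_ms < 0) {
    rlang::abort("freq_hz and dur_ms must be positive, ramp_ms non-negative")
  }
  if (2 * ramp_ms > dur_ms) {
    rlang::abort("ramps longer than half the tone duration")
  }
  structure(list(freq_hz = freq_hz, dur_ms = dur_ms, ramp_ms = ramp_ms),
            class = "tone_spec")
}

#' Synthesise a ramped pure tone
#'
#' A sinusoid at `spec$freq_hz` lasting `spec$dur_ms`, with linear amplitude
#' ramps of `spec$ramp_ms` at onset and offset (so the first and last samples
#' are at zero amplitude).
#'
#' @param spec A [tone_spec()].
#' @param rate Sampling rate.
#' @param amplitude Peak amplitude before ramping, in (0, 1\].
#' @return An `audio_clip` of `round(dur_ms / 1000 * rate)` samples.
#' @examples
#' synth_tone(tone_spec(1000, 400, 25))
#' @export
synth_tone <- function(spec, rate = DEFAULT_RATE, amplitude = 0.8) {
  stopifnot(inherits(spec, "tone_spec"))
  n <- round(spec$dur_ms / 1000 * rate)
  t <- (seq_len(n) - 1L) / rate
  x <- amplitude * sin(2 * pi * spec$freq_hz * t)
  nr <- round(spec$ramp_ms / 1000 * rate)
  if (nr > 0) {
    ramp <- seq(0, 1, length.out = nr)
    x[seq_len(nr)] <- x[seq_len(nr)] * ramp
    x[(n - nr + 1L):n] <- x[(n - nr + 1L):n] * rev(ramp)
  }
  audio_clip(x, rate)
}

# default note timbre: ramped sinusoid, 5 ms linear ramps
sine_timbre <- function(freq_hz, dur_s, rate) {
  n <- max(round(dur_s * rate), 1L)
  t <- (seq_len(n) - 1L) / rate
  x <- sin(2 * pi * freq_hz * t)
  nr <- min(round(0.005 * rate), floor(n / 2))
  if (nr > 0) {
    ramp <- seq(0, 1, length.out = nr)
    x[seq_len(nr)] <- x[seq_len(nr)] * ramp
    x[(n - nr + 1L):n] <- x[(n - nr + 1L):n] * rev(ramp)
  }
  x
}

midi_to_hz <- function(pitch) 440 * 2 ^ ((pitch - 69) / 12)

#' Render a melody to audio
#'
#' Note onsets fall at the cumulative beat positions times `60 / tempo_bpm`
#' seconds; each note is rendered by the `timbre` function (by default a
#' sinusoid with 5 ms ramps) for its full duration. The clip length equals
#' the closed-form prediction `round(total_beats * 60 / tempo_bpm * rate)`.
#'
#' @param m A `melody`.
#' @param rate Sampling rate.
#' @param timbre A function `(freq_hz, dur_s, rate) -> numeric samples`.
#' @param amplitude Peak scaling applied to each note.
#' @return An `audio_clip`.
#' @export
render_melody <- function(m, rate = DEFAULT_RATE, timbre = sine_timbre,
                          amplitude = 0.8) {
  validate_melody(m)
  spb <- 60 / m$tempo_bpm
  onsets_beats <- cumsum(c(0, m$durations[-length(m$durations)]))
  total <- round(sum(m$durations) * spb * rate)
  x <- numeric(total)
  for (i in seq_along(m$pitches)) {
    start <- round(onsets_beats[i] * spb * rate) + 1L
    note <- amplitude * timbre(midi_to_hz(m$pitches[i]), m$durations[i] * spb, rate)
    stop <- min(start + length(note) - 1L, total)
    idx <- start:stop
    x[idx] <- x[idx] + note[seq_along(idx)]
  }
  x <- pmax(pmin(x, 1), -1)
  audio_clip(x, rate)
}

#' Render a metronome click track
#'
#' `n_clicks` short click bursts (10 ms, 1 kHz by default) with onsets at
#' `k * 60 / bpm` seconds, `k = 0 .. n_clicks - 1`.
#'
#' @param bpm Tempo in beats per minute.
#' @param n_clicks Number of clicks.
#' @param rate Sampling rate.
#' @param click_ms Click burst length in milliseconds.
#' @param tail_s Trailing silence after the last click.
#' @return A list with `clip` (an `audio_clip`) and `onsets_s` (the exact
#'   click onset times in seconds).
#' @export
render_metronome <- function(bpm, n_clicks, rate = DEFAULT_RATE,
                             click_ms = 10, tail_s = 0.5) {
  stopifnot(bpm > 0, n_clicks >= 1)
  ioi <- 60 / bpm
  onsets <- (seq_len(n_clicks) - 1L) * ioi
  total <- round((max(onsets) + tail_s) * rate) + 1L
  x <- numeric(total)
  nb <- round(click_ms / 1000 * rate)
  burst <- 0.9 * sin(2 * pi * 1000 * (seq_len(nb) - 1L) / rate) *
    exp(-(seq_len(nb) - 1L) / (0.4 * nb))
  for (on in onsets) {
    start <- round(on * rate) + 1L
    stop <- min(start + nb - 1L, total)
    x[start:stop] <- burst[seq_len(stop - start + 1L)]
  }
  list(clip = audio_clip(x, rate), onsets_s = onsets)
}

#' Normalize a clip to a target RMS level
#'
#' Battery stimuli share a common -20 dBFS RMS level so relative loudness is
#' uniform across tasks; the absolute presentation level (75 dB SPL in the
#' original administration) is a playback calibration, not a file property.
#'
#' @param clip An `audio_clip`.
#' @param target_dbfs Target RMS level in dB full scale.
#' @return The rescaled `audio_clip` (also peak-limited to avoid clipping).
#' @export
normalize_rms <- function(clip, target_dbfs = -20) {
  stopifnot(inherits(clip, "audio_clip"))
  r <- sqrt(mean(clip$samples^2))
  if (r == 0) return(clip)
  g <- 10 ^ (target_dbfs / 20) / r
  x <- clip$samples * g
  pk <- max(abs(x))
  if (pk > 0.999) x <- x * 0.999 / pk
  audio_clip(x, clip$rate)
}

#' Frequency of the maximum-magnitude FFT bin
#'
#' @param clip An `audio_clip`.
#' @return The frequency in Hz of the peak-magnitude bin of the full-length
#'   FFT, restricted to \[0, Nyquist\].
#' @export
spectral_peak <- function(clip) {
  stopifnot(inherits(clip, "audio_clip"))
  n <- length(clip$samples)
  mag <- Mod(stats::fft(clip$samples))
  half <- seq_len(floor(n / 2) + 1L)
  freqs <- (half - 1L) * clip$rate / n
  freqs[which.max(mag[half])]
}

#' Write / read a mono 16-bit PCM WAV file
#'
#' A minimal RIFF/WAVE codec: mono, 16-bit PCM. Round-tripping a clip
#' reproduces it within one quantisation step (2^-15).
#'
#' @param clip An `audio_clip` with samples in \[-1, 1\].
#' @param path File path.
#' @return `write_wav()` returns `path` invisibly; `read_wav()` returns an
#'   `audio_clip`.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  if (length(clip$samples) && max(abs(clip$samples)) > 1 + 1e-9) {
    rlang::abort("refusing to write a clipping signal", class = "minimuse_clipping")
  }
  pcm <- as.integer(round(pmax(pmin(clip$samples, 1), -1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(clip$rate), con, size = 4, endian = "little")
  writeBin(as.integer(clip$rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 44L ||
      rawToChar(raw[1:4]) != "RIFF" || rawToChar(raw[9:12]) != "WAVE") {
    rlang::abort("not a RIFF/WAVE file", class = "minimuse_parse_error")
  }
  u16 <- function(i) sum(as.integer(raw[i:(i + 1L)]) * c(1, 256))
  u32 <- function(i) sum(as.numeric(raw[i:(i + 3L)]) * c(1, 256, 65536, 16777216))
  pos <- 13L
  fmt <- NULL
  data_off <- NULL
  data_len <- NULL
  while (pos + 8L <= length(raw) + 1L) {
    id <- rawToChar(raw[pos:(pos + 3L)])
    sz <- u32(pos + 4L)
    body <- pos + 8L
    if (id == "fmt ") {
      fmt <- list(codec = u16(body), channels = u16(body + 2L),
                  rate = u32(body + 4L), bits = u16(body + 14L))
    } else if (id == "data") {
      data_off <- body
      data_len <- sz
    }
    pos <- body + sz + (sz %% 2L)
  }
  if (is.null(fmt) || is.null(data_off)) {
    rlang::abort("missing fmt/data chunk", class = "minimuse_parse_error")
  }
  if (fmt$codec != 1L || fmt$channels != 1L || fmt$bits != 16L) {
    rlang::abort("only mono 16-bit PCM is supported", class = "minimuse_parse_error")
  }
  if (data_off + data_len - 1L > length(raw)) {
    rlang::abort("truncated data chunk", class = "minimuse_parse_error")
  }
  pcm <- readBin(raw[data_off:(data_off + data_len - 1L)], "integer",
                 n = data_len / 2L, size = 2L, endian = "little", signed = TRUE)
  audio_clip(pcm / 32767, as.integer(fmt$rate))
}
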