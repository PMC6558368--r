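# Symbolic melodies: short diatonic note sequences that every perception task
# manipulates. Pitches follow the MIDI convention (60 = middle C); durations
# are in beats (1 = quarter note).

MAJOR_SCALE_STEPS <- c(0L, 2L, 4L, 5L, 7L, 9L, 11L)

PITCH_MIN <- 36L
PITCH_MAX <- 96L

#' Construct a melody
#'
#' A melody is an ordered sequence of notes (MIDI pitch + duration in beats)
#' together with its key (tonic pitch class, major mode), nominal tempo and
#' meter. All pitches must be diatonic in the melody's major key.
#'
#' @param pitches Integer vector of MIDI pitches (60 = middle C), each in
#'   \[36, 96\] and diatonic in `(tonic, major)`.
#' @param durations Numeric vector of note durations in beats (1 = quarter
#'   note), all positive. Recycled to `length(pitches)` if scalar.
#' @param tonic Tonic pitch class, an integer 0--11 (0 = C).
#' @param tempo_bpm Nominal tempo in quarter-note beats per minute.
#' @param meter Beats per bar (the toolkit's batteries use 4/4).
#'
#' @return An object of class `melody`.
#' @examples
#' m <- melody(c(60, 64, 67), 1, tonic = 0, tempo_bpm = 140)
#' contour_signature(m)
#' @export
melody <- function(pitches, durations = 1, tonic = 0L, tempo_bpm = 140,
                   meter = 4L) {
  pitches <- as.integer(pitches)
  durations <- rep_len(as.numeric(durations), length(pitches))
  m <- structure(
    list(pitches = pitches, durations = durations, tonic = as.integer(tonic),
         mode = "major", tempo_bpm = as.numeric(tempo_bpm),
         meter = as.integer(meter)),
    class = "melody"
  )
  validate_melody(m)
  m
}

validate_melody <- function(m) {
  stopifnot(inherits(m, "melody"))
  if (length(m$pitches) < 1L) rlang::abort("melody must contain at least one note")
  if (any(m$pitches < PITCH_MIN | m$pitches > PITCH_MAX)) {
    rlang::abort(sprintf("pitches must lie in [%d, %d]", PITCH_MIN, PITCH_MAX))
  }
  if (any(m$durations <= 0)) rlang::abort("durations must be positive")
  if (m$tonic < 0L || m$tonic > 11L) rlang::abort("tonic must be a pitch class 0-11")
  if (m$tempo_bpm <= 0) rlang::abort("tempo_bpm must be positive")
  if (!all(is_diatonic(m$pitches, m$tonic))) {
    rlang::abort("all pitches must be diatonic in the melody's major key")
  }
  invisible(m)
}

#' Is a pitch diatonic in a major key?
#'
#' @param pitch Integer MIDI pitch (vectorised).
#' @param tonic Tonic pitch class 0--11.
#' @return Logical vector.
#' @export
is_diatonic <- function(pitch, tonic) {
  ((as.integer(pitch) - as.integer(tonic)) %% 12L) %in% MAJOR_SCALE_STEPS
}

#' @export
print.melody <- function(x, ...) {
  cat(sprintf("<melody> %d notes, tonic pc %d (major), %g BPM, %d/4\n",
              length(x$pitches), x$tonic, x$tempo_bpm, x$meter))
  cat("  pitches:  ", paste(x$pitches, collapse = " "), "\n")
  cat("  durations:", paste(x$durations, collapse = " "), "beats\n")
  invisible(x)
}

#' @export
length.melody <- function(x) length(x$pitches)

#' Tidy a melody into a per-note tibble
#'
#' @param x A `melody`.
#' @param ... Unused.
#' @return A tibble with one row per note: `note`, `pitch`, `duration_beats`,
#'   `onset_beats`, `onset_s`.
#' @export
tidy.melody <- function(x, ...) {
  onsets <- cumsum(c(0, x$durations[-length(x$durations)]))
  tibble::tibble(
    note = seq_along(x$pitches),
    pitch = x$pitches,
    duration_beats = x$durations,
    onset_beats = onsets,
    onset_s = onsets * 60 / x$tempo_bpm
  )
}

#' Total duration of a melody in seconds at its nominal tempo
#'
#' @param m A `melody`.
#' @return Duration in seconds.
#' @export
melody_duration_s <- function(m) sum(m$durations) * 60 / m$tempo_bpm

#' Transpose a melody to a new key
#'
#' Every pitch is shifted by the same offset: the smallest non-negative
#' semitone shift mapping the current tonic to `target_tonic`, then
#' octave-centred (shifted by whole octaves) so the mean pitch stays within
#' \[55, 84\], a child-appropriate register. Interval structure, durations and
#' tempo are untouched.
#'
#' @param m A `melody`.
#' @param target_tonic Target tonic pitch class 0--11.
#' @return The transposed `melody`.
#' @examples
#' transpose(melody(c(60, 64, 67)), 2)  # C major -> D major
#' @export
transpose <- function(m, target_tonic) {
  validate_melody(m)
  target_tonic <- as.integer(target_tonic) %% 12L
  shift <- (target_tonic - m$tonic) %% 12L
  p <- m$pitches + shift
  while (mean(p) > 84 && min(p) - 12L >= PITCH_MIN) p <- p - 12L
  while (mean(p) < 55 && max(p) + 12L <= PITCH_MAX) p <- p + 12L
  out <- m
  out$pitches <- as.integer(p)
  out$tonic <- target_tonic
  validate_melody(out)
  out
}

#' Contour signature of a melody
#'
#' The sign of each successive pitch interval: +1 ascending, -1 descending,
#' 0 repeated pitch. Two melodies share a contour iff their signatures are
#' identical; a contour-violating mutation changes the signature, a
#' contour-preserving one does not.
#'
#' @param m A `melody` with at least two notes.
#' @return Integer vector of length `length(m) - 1` with values in
#'   \{-1, 0, 1\}.
#' @export
contour_signature <- function(m) {
  validate_melody(m)
  if (length(m$pitches) < 2L) {
    rlang::abort("contour requires at least two notes")
  }
  as.integer(sign(diff(m$pitches)))
}

#' Serialize a melody to JSON / parse one back
#'
#' @param m A `melody`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `melody_to_json()`: the JSON string (invisibly, if written to
#'   `path`); `melody_from_json()`: a `melody`.
#' @export
melody_to_json <- function(m, path = NULL) {
  validate_melody(m)
  x <- list(
    notes = purrr::map2(m$pitches, m$durations,
                        ~ list(pitch = .x, duration_beats = .y)),
    tonic = m$tonic, mode = m$mode, tempo_bpm = m$tempo_bpm, meter = m$meter
  )
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname melody_to_json
#' @param json A JSON string or file path produced by `melody_to_json()`.
#' @export
melody_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  melody(pitches = x$notes$pitch, durations = x$notes$duration_beats,
         tonic = x$tonic, tempo_bpm = x$tempo_bpm, meter = x$meter)
}

#' Export a melody as a standard MIDI file (format 0)
#'
#' Writes a single-track MIDI file at 480 ticks per quarter note with the
#' melody's tempo as a tempo meta event. Notes are written back to back at
#' full duration on channel 0.
#'
#' @param m A `melody`.
#' @param path Output file path.
#' @param velocity Note-on velocity, 1--127.
#' @return `path`, invisibly.
#' @export
write_midi <- function(m, path, velocity = 96L) {
  validate_melody(m)
  tpq <- 480L
  vlq <- function(n) {
    # variable-length quantity, 7 bits per byte, high bit = continuation
    n <- as.integer(n)
    bytes <- n %% 128L
    n <- n %/% 128L
    while (n > 0L) {
      bytes <- c(n %% 128L + 128L, bytes)
      n <- n %/% 128L
    }
    as.raw(bytes)
  }
  u32 <- function(n) as.raw(c(n %/% 16777216L, n %/% 65536L %% 256L,
                              n %/% 256L %% 256L, n %% 256L))
  u16 <- function(n) as.raw(c(n %/% 256L, n %% 256L))
  uspq <- round(60e6 / m$tempo_bpm)
  ev <- c(
    vlq(0L), as.raw(c(0xFF, 0x51, 0x03)),
    as.raw(c(uspq %/% 65536, uspq %/% 256 %% 256, uspq %% 256))
  )
  for (i in seq_along(m$pitches)) {
    ticks <- as.integer(round(m$durations[i] * tpq))
    ev <- c(ev,
            vlq(0L), as.raw(c(0x90, m$pitches[i], velocity)),
            vlq(ticks), as.raw(c(0x80, m$pitches[i], 0L)))
  }
  ev <- c(ev, vlq(0L), as.raw(c(0xFF, 0x2F, 0x00)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("MThd"), con)
  writeBin(u32(6L), con); writeBin(u16(0L), con)
  writeBin(u16(1L), con); writeBin(u16(tpq), con)
  writeBin(charToRaw("MTrk"), con)
  writeBin(u32(length(ev)), con)
  writeBin(ev, con)
  invisible(path)
}
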