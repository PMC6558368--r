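# Stimulus mutation operators: the single change that turns a standard melody
# into its "different" comparison in the oddity tasks.

#' Specify a stimulus mutation
#'
#' The four comparison-stimulus manipulations used by the perception tasks:
#' a single-note pitch change that either violates or preserves the melodic
#' contour (`contour_violating`, `contour_preserving`), a duration
#' reassignment over adjacent notes (`rhythm`), or a tempo change (`tempo`).
#'
#' @param kind One of `"contour_violating"`, `"contour_preserving"`,
#'   `"rhythm"`, `"tempo"`.
#' @param delta_semitones Absolute pitch change in semitones (pitch kinds).
#'   Contour-violating changes span 8--12 semitones, contour-preserving
#'   changes 3--5.
#' @param n_changed Number of adjacent notes whose durations change (rhythm
#'   kind), 2 or 3.
#' @param beat_class `"downbeat"` (the first altered note starts a bar) or
#'   `"upbeat"` (rhythm kind).
#' @param delta_bpm Tempo change in BPM (tempo kind), 25--70.
#' @param direction `"faster"` or `"slower"` (tempo kind).
#'
#' @return An object of class `mutation_spec`.
#' @export
mutation_spec <- function(kind, delta_semitones = NULL, n_changed = NULL,
                          beat_class = NULL, delta_bpm = NULL,
                          direction = NULL) {
  kind <- rlang::arg_match(kind, c("contour_violating", "contour_preserving",
                                   "rhythm", "tempo"))
  if (kind %in% c("contour_violating", "contour_preserving")) {
    if (is.null(delta_semitones)) rlang::abort("pitch mutations need delta_semitones")
    delta_semitones <- as.integer(delta_semitones)
    rng_ok <- if (kind == "contour_violating") {
      delta_semitones >= 8L && delta_semitones <= 12L
    } else {
      delta_semitones >= 3L && delta_semitones <= 5L
    }
    if (!rng_ok) {
      rlang::abort(sprintf(
        "delta_semitones %d outside the %s range (%s)", delta_semitones, kind,
        if (kind == "contour_violating") "8-12" else "3-5"))
    }
  }
  if (kind == "rhythm") {
    if (is.null(n_changed) || !(n_changed %in% c(2L, 3L))) {
      rlang::abort("rhythm mutations need n_changed in {2, 3}")
    }
    beat_class <- rlang::arg_match(beat_class, c("downbeat", "upbeat"))
    n_changed <- as.integer(n_changed)
  }
  if (kind == "tempo") {
    if (is.null(delta_bpm) || delta_bpm < 25 || delta_bpm > 70) {
      rlang::abort("tempo mutations need delta_bpm in [25, 70]")
    }
    direction <- rlang::arg_match(direction, c("faster", "slower"))
    delta_bpm <- as.integer(delta_bpm)
  }
  structure(list(kind = kind, delta_semitones = delta_semitones,
                 n_changed = n_changed, beat_class = beat_class,
                 delta_bpm = delta_bpm, direction = direction),
            class = "mutation_spec")
}

# Run expr with a temporary RNG state seeded by `seed` (NULL = use the
# current stream). Restores the caller's .Random.seed afterwards.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Enumerate all valid single-note pitch mutations
#'
#' Exhaustively lists every diatonic substitution of one middle note that
#' moves the pitch by exactly `spec$delta_semitones` (up or down), stays in
#' range, and changes the contour signature iff the mutation kind is
#' contour-violating.
#'
#' @param m A 3- or 5-note `melody`.
#' @param spec A pitch-kind `mutation_spec`.
#' @return A tibble with columns `index`, `old_pitch`, `new_pitch`,
#'   `direction` (one row per valid candidate; zero rows when infeasible).
#' @export
pitch_mutation_candidates <- function(m, spec) {
  validate_melody(m)
  stopifnot(inherits(spec, "mutation_spec"))
  if (!spec$kind %in% c("contour_violating", "contour_preserving")) {
    rlang::abort("spec must be a pitch-kind mutation")
  }
  n <- length(m$pitches)
  if (!n %in% c(3L, 5L)) rlang::abort("pitch mutations apply to 3- or 5-note melodies")
  idx <- if (n == 3L) 2L else 2:4
  sig0 <- contour_signature(m)
  out <- purrr::map_dfr(idx, function(i) {
    purrr::map_dfr(c(-1L, 1L), function(s) {
      p_new <- m$pitches[i] + s * spec$delta_semitones
      if (p_new < PITCH_MIN || p_new > PITCH_MAX) return(NULL)
      if (!is_diatonic(p_new, m$tonic)) return(NULL)
      p <- m$pitches
      p[i] <- p_new
      sig1 <- as.integer(sign(diff(p)))
      changed <- !identical(sig1, sig0)
      want_change <- spec$kind == "contour_violating"
      if (changed != want_change) return(NULL)
      tibble::tibble(index = i, old_pitch = m$pitches[i], new_pitch = p_new,
                     direction = if (s > 0) "up" else "down")
    })
  })
  if (nrow(out) == 0) {
    tibble::tibble(index = integer(), old_pitch = integer(),
                   new_pitch = integer(), direction = character())
  } else out
}

#' Apply a single-note pitch mutation
#'
#' Changes exactly one middle note of the melody (the 2nd of a 3-note melody;
#' the 2nd, 3rd or 4th of a 5-note melody) by `spec$delta_semitones`
#' semitones, keeping the new pitch diatonic in the melody's key. The contour
#' signature changes iff `spec$kind == "contour_violating"`. When several
#' candidates exist one is drawn uniformly at random.
#'
#' @param m A 3- or 5-note `melody`.
#' @param spec A pitch-kind `mutation_spec`.
#' @param seed Optional integer seed making the draw reproducible.
#' @return The mutated `melody`, with attribute `"mutation"` recording the
#'   chosen candidate row.
#' @export
mutate_pitch <- function(m, spec, seed = NULL) {
  cand <- pitch_mutation_candidates(m, spec)
  if (nrow(cand) == 0) {
    rlang::abort(
      sprintf("no %s mutation with |delta| = %d is feasible for this melody",
              spec$kind, spec$delta_semitones),
      class = "minimuse_infeasible")
  }
  row <- with_local_seed(seed, cand[sample.int(nrow(cand), 1L), ])
  out <- m
  out$pitches[row$index] <- row$new_pitch
  validate_melody(out)
  attr(out, "mutation") <- row
  out
}

# Duration values (in beats) available to rhythm reassignments.
RHYTHM_DURATION_GRID <- c(0.5, 1, 1.5, 2)

#' Enumerate all valid rhythm mutations
#'
#' Lists every reassignment of durations over `spec$n_changed` adjacent notes
#' that conserves the total duration, changes every affected note, and whose
#' first altered note starts on a downbeat (bar-initial beat) iff
#' `spec$beat_class == "downbeat"`. Durations are drawn from the grid
#' \{0.5, 1, 1.5, 2\} beats.
#'
#' @param m A `melody` with at least `spec$n_changed` notes.
#' @param spec A rhythm-kind `mutation_spec`.
#' @return A tibble with columns `start`, `durations` (list column of the new
#'   duration run).
#' @export
rhythm_mutation_candidates <- function(m, spec) {
  validate_melody(m)
  stopifnot(inherits(spec, "mutation_spec"), spec$kind == "rhythm")
  k <- spec$n_changed
  n <- length(m$pitches)
  if (n < k) rlang::abort("melody shorter than n_changed")
  onsets <- cumsum(c(0, m$durations[-n]))
  starts <- seq_len(n - k + 1L)
  grid <- as.matrix(expand.grid(rep(list(RHYTHM_DURATION_GRID), k)))
  purrr::map_dfr(starts, function(s) {
    run <- s:(s + k - 1L)
    on_down <- (onsets[s] %% m$meter) == 0 && onsets[s] == round(onsets[s])
    if (on_down != (spec$beat_class == "downbeat")) return(NULL)
    tot <- sum(m$durations[run])
    keep <- abs(rowSums(grid) - tot) < 1e-9 &
      apply(grid, 1L, function(d) all(abs(d - m$durations[run]) > 1e-9))
    if (!any(keep)) return(NULL)
    tibble::tibble(start = s,
                   durations = lapply(which(keep), function(r) grid[r, ]))
  })
}

#' Apply a rhythm mutation
#'
#' Reassigns the durations of `spec$n_changed` adjacent notes, conserving the
#' note count and the total duration in beats (hence the rendered length),
#' leaving the pitch sequence untouched. The first altered note's onset falls
#' on a downbeat iff `spec$beat_class == "downbeat"`.
#'
#' @inheritParams mutate_pitch
#' @param spec A rhythm-kind `mutation_spec`.
#' @return The mutated `melody` with attribute `"mutation"`.
#' @export
mutate_rhythm <- function(m, spec, seed = NULL) {
  cand <- rhythm_mutation_candidates(m, spec)
  if (nrow(cand) == 0) {
    rlang::abort("no rhythm mutation satisfies the constraints for this melody",
                 class = "minimuse_infeasible")
  }
  row <- with_local_seed(seed, cand[sample.int(nrow(cand), 1L), ])
  out <- m
  run <- row$start:(row$start + spec$n_changed - 1L)
  out$durations[run] <- row$durations[[1L]]
  validate_melody(out)
  attr(out, "mutation") <- row
  out
}

#' Make a tempo-variant comparison melody
#'
#' Returns the identical note sequence at a tempo `spec$delta_bpm` BPM faster
#' or slower than the standard. Tempo-task standards run at 100 BPM, and
#' deltas span 25--70 BPM around it.
#'
#' @param m A `melody`.
#' @param spec A tempo-kind `mutation_spec`.
#' @return The tempo-shifted `melody`.
#' @export
make_tempo_variant <- function(m, spec) {
  validate_melody(m)
  stopifnot(inherits(spec, "mutation_spec"), spec$kind == "tempo")
  out <- m
  out$tempo_bpm <- m$tempo_bpm +
    if (spec$direction == "faster") spec$delta_bpm else -spec$delta_bpm
  if (out$tempo_bpm <= 0) rlang::abort("tempo variant would be non-positive")
  out
}

#' Apply any mutation spec to a melody
#'
#' Dispatches to [mutate_pitch()], [mutate_rhythm()] or
#' [make_tempo_variant()] according to `spec$kind`.
#'
#' @inheritParams mutate_pitch
#' @export
apply_mutation <- function(m, spec, seed = NULL) {
  switch(spec$kind,
         contour_violating = ,
         contour_preserving = mutate_pitch(m, spec, seed),
         rhythm = mutate_rhythm(m, spec, seed),
         tempo = make_tempo_variant(m, spec))
}

#' Compose a standard melody that admits the required mutations
#'
#' Draws diatonic melodies (random walk over scale tones in a
#' child-appropriate register, quarter-note durations) until one is found for
#' which every spec in `feasibility` has at least one valid mutation,
#' verified by exhaustive enumeration. Melodies last 1--3 s at their tempo.
#'
#' @param length Number of notes, 3--5.
#' @param tonic Tonic pitch class of the key to compose in.
#' @param tempo_bpm Nominal tempo (140 for melody/rhythm-task standards,
#'   100 for tempo-task standards).
#' @param feasibility List of `mutation_spec`s the melody must support.
#' @param seed Optional integer seed; the search is deterministic given it.
#' @param max_attempts Attempt bound before giving up.
#' @return A `melody`.
#' @export
compose_standard <- function(length, tonic = 0L, tempo_bpm = 140,
                             feasibility = list(), seed = NULL,
                             max_attempts = 1000L) {
  stopifnot(length %in% 3:5)
  with_local_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      m <- try_compose(length, tonic, tempo_bpm)
      if (is.null(m)) next
      ok <- all(purrr::map_lgl(feasibility, function(sp) {
        n_mut <- switch(sp$kind,
                        contour_violating = ,
                        contour_preserving =
                          nrow(pitch_mutation_candidates(m, sp)),
                        rhythm = nrow(rhythm_mutation_candidates(m, sp)),
                        tempo = 1L)
        n_mut > 0L
      }))
      if (ok) return(m)
    }
    rlang::abort("could not compose a feasible standard melody",
                 class = "minimuse_search_failure")
  })
}

try_compose <- function(length, tonic, tempo_bpm) {
  # diatonic pitches in the singing-adjacent register the battery uses
  scale <- sort(unlist(lapply(seq(36L, 96L, 12L),
                              function(o) o + tonic + MAJOR_SCALE_STEPS)))
  scale <- scale[scale >= 53L & scale <= 86L]
  p <- numeric(length)
  start_set <- scale[scale >= 57 & scale <= 79]
  p[1] <- start_set[sample.int(length(start_set), 1L)]
  for (i in seq_len(length - 1L)) {
    nxt <- scale[abs(scale - p[i]) <= 7 & scale != p[i]]
    if (!length(nxt)) return(NULL)
    p[i + 1L] <- nxt[sample.int(length(nxt), 1L)]
  }
  m <- melody(p, 1, tonic = tonic, tempo_bpm = tempo_bpm)
  d <- melody_duration_s(m)
  if (d < 1 || d > 3) return(NULL)
  m
}
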