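# Battery assembly: the four perception tasks as counterbalanced, seeded
# trial manifests implementing the 2+1 oddity design (standard, then a
# "same" and a "different" comparison; the child picks the matching one).

#' Default battery configuration
#'
#' Encodes the printed design constants of the four perception tasks:
#' pitch (10 trials, 1000 Hz standard, easiest comparison 120 Hz away, the
#' other nine 12--60 Hz, half lower / half higher), melody (twelve trials,
#' six 3-note and six 5-note standards at 140 BPM, one diatonic single-note
#' change each, half contour-violating with 8--12 semitone deltas, half
#' contour-preserving with 3--5), rhythm (the same twelve standards, 2--3
#' adjacent durations reassigned, half downbeat / half upbeat), and tempo
#' (ten 4-note standards at 100 BPM, comparisons 25--70 BPM faster or
#' slower, balanced).
#'
#' @return A named list of per-task settings.
#' @export
battery_config <- function() {
  list(
    pitch = list(n_trials = 10L, standard_hz = 1000, easiest_delta_hz = 120,
                 delta_range_hz = c(12, 60), dur_ms = 400, ramp_ms = 25),
    melody = list(n_per_length = 6L, lengths = c(3L, 5L), tempo_bpm = 140,
                  violating = list(`3` = c(8L, 9L, 9L), `5` = c(9L, 9L, 12L)),
                  preserving = list(`3` = c(3L, 4L, 4L), `5` = c(3L, 4L, 5L))),
    rhythm = list(n_changed = list(`3` = 2L, `5` = 3L),
                  downbeat_fraction = 0.5),
    tempo = list(n_trials = 10L, length = 4L, standard_bpm = 100,
                 deltas = seq(25L, 70L, by = 5L)),
    isi_s = 1.0,
    # seed of the fixed item bank: every participant hears the same stimuli,
    # only trial order and counterbalancing assignment vary by participant
    stimulus_seed = 2025L
  )
}

validate_config <- function(config) {
  ok <- config$pitch$n_trials == 10L &&
    2L * config$melody$n_per_length == 12L &&
    config$tempo$n_trials == 10L &&
    config$pitch$delta_range_hz[1] >= 12 &&
    config$pitch$delta_range_hz[2] <= 60 &&
    all(unlist(config$melody$violating) >= 8) &&
    all(unlist(config$melody$violating) <= 12) &&
    all(unlist(config$melody$preserving) >= 3) &&
    all(unlist(config$melody$preserving) <= 5) &&
    all(config$tempo$deltas >= 25) && all(config$tempo$deltas <= 70) &&
    config$rhythm$downbeat_fraction == 0.5 &&
    config$isi_s == 1.0
  if (!ok) {
    rlang::abort("configuration violates a battery design constraint",
                 class = "minimuse_config")
  }
  invisible(config)
}

# exact half-splits of position x order, crossed; balanced to within one
# trial per cell for counts not divisible by 4
counterbalance <- function(n) {
  combos <- tidyr::expand_grid(different_position = c("left", "right"),
                               same_order = c("first", "second"))
  base <- n %/% 4L
  extra <- n %% 4L
  counts <- rep(base, 4L)
  if (extra > 0L) {
    # distribute leftovers on complementary cells to keep both margins even
    bump <- switch(as.character(extra), "1" = 1L, "2" = c(1L, 4L),
                   "3" = c(1L, 4L, 2L))
    counts[bump] <- counts[bump] + 1L
  }
  combos[rep(seq_len(4L), counts), ]
}

#' Design a full battery manifest
#'
#' Generates the four perception tasks under the printed design: composes
#' feasibility-checked standard melodies in C major, transposes each into a
#' different major key, applies the task's mutation to produce the
#' "different" comparison, assigns comparison deltas, balances
#' lower/higher, faster/slower, downbeat/upbeat, screen position and
#' presentation order, and permutes trial order. The stimulus set is a
#' fixed item bank (seeded by `config$stimulus_seed`): two participant
#' seeds hear identical trial multisets in different orders.
#'
#' @param seed Integer per-participant seed governing counterbalancing
#'   assignment and trial order.
#' @param config A [battery_config()] list.
#' @return An object of class `battery_manifest`: `trials` (tibble, one row
#'   per oddity trial with list columns `standard` and `comparison` holding
#'   the symbolic stimuli), `practice` (4 practice trials), `seed`,
#'   `config`.
#' @export
design_battery <- function(seed = 1L, config = battery_config()) {
  validate_config(config)
  trials <- with_local_seed(config$stimulus_seed, dplyr::bind_rows(
    build_pitch_task(config),
    build_melody_rhythm_tasks(config),
    build_tempo_task(config)
  ))
  with_local_seed(seed, {
    trials <- trials |>
      dplyr::group_by(.data$task) |>
      dplyr::group_modify(function(df, key) {
        cb <- counterbalance(nrow(df))
        cb <- cb[sample.int(nrow(cb)), ]
        df <- dplyr::bind_cols(df, cb)
        df[sample.int(nrow(df)), ]
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(isi_s = config$isi_s,
                    trial_id = paste0(.data$task, "_",
                                      sprintf("%02d", dplyr::row_number())),
                    .by = "task") |>
      dplyr::relocate("trial_id")
    practice <- tibble::tibble(
      trial = 1:4,
      standard_sound = c("dog_bark", "bell", "car_horn", "cat_meow"),
      different_sound = c("bell", "car_horn", "cat_meow", "dog_bark")
    )
    structure(list(trials = trials, practice = practice, seed = seed,
                   config = config),
              class = "battery_manifest")
  })
}

build_pitch_task <- function(config) {
  pc <- config$pitch
  deltas <- c(pc$easiest_delta_hz,
              seq(pc$delta_range_hz[1], pc$delta_range_hz[2], length.out = 9))
  signs <- sample(rep(c(-1, 1), length.out = pc$n_trials))
  std <- tone_spec(pc$standard_hz, pc$dur_ms, pc$ramp_ms)
  tibble::tibble(
    task = "pitch",
    item = seq_len(pc$n_trials),
    stimulus_type = "tone",
    melody_length = NA_integer_,
    kind = "pitch",
    delta = signs * deltas,
    delta_unit = "Hz",
    n_changed = NA_integer_,
    beat_class = NA_character_,
    direction = ifelse(signs > 0, "higher", "lower"),
    standard = list(std),
    comparison = lapply(signs * deltas, function(d) {
      tone_spec(pc$standard_hz + d, pc$dur_ms, pc$ramp_ms)
    })
  )
}

build_melody_rhythm_tasks <- function(config) {
  mc <- config$melody
  rc <- config$rhythm
  keys <- sample(0:11)  # all twelve major keys, one per melody
  items <- tidyr::expand_grid(length = mc$lengths, slot = seq_len(mc$n_per_length))
  melody_rows <- list()
  rhythm_rows <- list()
  for (i in seq_len(nrow(items))) {
    L <- items$length[i]
    slot <- items$slot[i]
    viol <- mc$violating[[as.character(L)]]
    pres <- mc$preserving[[as.character(L)]]
    pitch_spec <- if (slot <= length(viol)) {
      mutation_spec("contour_violating", delta_semitones = viol[slot])
    } else {
      mutation_spec("contour_preserving",
                    delta_semitones = pres[slot - length(viol)])
    }
    beat_class <- if (slot %% 2L == 1L) "downbeat" else "upbeat"
    rhythm_spec <- mutation_spec("rhythm",
                                 n_changed = rc$n_changed[[as.character(L)]],
                                 beat_class = beat_class)
    # compose in C, transpose, and re-verify feasibility in the target key
    # (a candidate can leave the legal pitch range after transposition)
    std <- NULL
    for (attempt in 1:50) {
      std_c <- compose_standard(L, tonic = 0L, tempo_bpm = mc$tempo_bpm,
                                feasibility = list(pitch_spec, rhythm_spec))
      cand <- transpose(std_c, keys[i])
      if (nrow(pitch_mutation_candidates(cand, pitch_spec)) > 0L) {
        std <- cand
        break
      }
    }
    if (is.null(std)) {
      rlang::abort("could not compose a transposable standard melody",
                   class = "minimuse_search_failure")
    }
    comp_mel <- mutate_pitch(std, pitch_spec)
    comp_rhy <- mutate_rhythm(std, rhythm_spec)
    mut <- attr(comp_mel, "mutation")
    melody_rows[[i]] <- tibble::tibble(
      task = "melody", item = i, stimulus_type = "melody",
      melody_length = L, kind = pitch_spec$kind,
      delta = (mut$new_pitch - mut$old_pitch),
      delta_unit = "semitones",
      n_changed = NA_integer_, beat_class = NA_character_,
      direction = mut$direction,
      standard = list(std), comparison = list(comp_mel))
    rhythm_rows[[i]] <- tibble::tibble(
      task = "rhythm", item = i, stimulus_type = "melody",
      melody_length = L, kind = "rhythm",
      delta = NA_real_, delta_unit = NA_character_,
      n_changed = rhythm_spec$n_changed, beat_class = beat_class,
      direction = NA_character_,
      standard = list(std), comparison = list(comp_rhy))
  }
  dplyr::bind_rows(dplyr::bind_rows(melody_rows), dplyr::bind_rows(rhythm_rows))
}

build_tempo_task <- function(config) {
  tc <- config$tempo
  keys <- sample(0:11, tc$n_trials)
  directions <- sample(rep(c("faster", "slower"), length.out = tc$n_trials))
  deltas <- tc$deltas
  rows <- lapply(seq_len(tc$n_trials), function(i) {
    spec <- mutation_spec("tempo", delta_bpm = deltas[i],
                          direction = directions[i])
    std_c <- compose_standard(tc$length, tonic = 0L,
                              tempo_bpm = tc$standard_bpm)
    std <- transpose(std_c, keys[i])
    tibble::tibble(
      task = "tempo", item = i, stimulus_type = "melody",
      melody_length = tc$length, kind = "tempo",
      delta = ifelse(directions[i] == "faster", 1, -1) * deltas[i],
      delta_unit = "BPM",
      n_changed = NA_integer_, beat_class = NA_character_,
      direction = directions[i],
      standard = list(std), comparison = list(make_tempo_variant(std, spec)))
  })
  dplyr::bind_rows(rows)
}

#' @export
print.battery_manifest <- function(x, ...) {
  counts <- dplyr::count(x$trials, .data$task)
  cat(sprintf("<battery_manifest> seed %s; %d trials (+%d practice)\n",
              format(x$seed), nrow(x$trials), nrow(x$practice)))
  print(counts)
  invisible(x)
}

#' Tidy a battery manifest into its trial table
#'
#' @param x A `battery_manifest`.
#' @param ... Unused.
#' @return The trial tibble without the stimulus list columns.
#' @export
tidy.battery_manifest <- function(x, ...) {
  dplyr::select(x$trials, -"standard", -"comparison")
}

#' Practice-block eligibility gate
#'
#' Children first take four practice trials with easily identifiable sounds
#' and must get at least three right to enter the battery.
#'
#' @param practice_results Logical vector of exactly four results.
#' @return `TRUE` iff at least 3 of the 4 are correct.
#' @export
practice_gate <- function(practice_results) {
  practice_results <- as.logical(practice_results)
  if (length(practice_results) != 4L || anyNA(practice_results)) {
    rlang::abort("practice_results must be exactly four TRUE/FALSE values")
  }
  sum(practice_results) >= 3L
}

render_stimulus <- function(stim, rate = DEFAULT_RATE) {
  clip <- if (inherits(stim, "tone_spec")) {
    synth_tone(stim, rate)
  } else {
    render_melody(stim, rate)
  }
  normalize_rms(clip)
}

#' Render battery stimuli to WAV files
#'
#' Renders each trial's standard and comparison (RMS-normalized to a common
#' -20 dBFS level) into `dir` and writes a `manifest.csv` listing, per
#' trial, the stimulus files, the side holding the "different" comparison
#' and hence the correct ("same") side.
#'
#' @param manifest A `battery_manifest`.
#' @param dir Output directory (created if needed).
#' @param tasks Optional subset of task names to render.
#' @param rate Sampling rate.
#' @return A tibble mirroring `manifest.csv`, invisibly.
#' @export
render_battery_audio <- function(manifest, dir, tasks = NULL,
                                 rate = DEFAULT_RATE) {
  stopifnot(inherits(manifest, "battery_manifest"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trials <- manifest$trials
  if (!is.null(tasks)) trials <- dplyr::filter(trials, .data$task %in% tasks)
  rows <- purrr::pmap_dfr(
    list(trials$trial_id, trials$standard, trials$comparison,
         trials$different_position),
    function(id, std, comp, dpos) {
      f_std <- file.path(dir, paste0(id, "_standard.wav"))
      f_diff <- file.path(dir, paste0(id, "_different.wav"))
      write_wav(render_stimulus(std, rate), f_std)
      write_wav(render_stimulus(comp, rate), f_diff)
      tibble::tibble(trial_id = id, standard_file = f_std,
                     different_file = f_diff,
                     correct_side = ifelse(dpos == "left", "right", "left"))
    })
  out <- dplyr::left_join(tidy(manifest), rows, by = "trial_id") |>
    dplyr::filter(!is.na(.data$standard_file))
  utils::write.csv(out, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(out)
}
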