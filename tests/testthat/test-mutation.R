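test_that("pitch mutation matches the spec's enumeration examples", {
  m <- melody(c(60, 64, 69), tonic = 0)
  pres <- mutation_spec("contour_preserving", delta_semitones = 3)
  out <- mutate_pitch(m, pres, seed = 1)
  expect_identical(out$pitches, c(60L, 67L, 69L))
  expect_identical(contour_signature(out), contour_signature(m))

  viol <- mutation_spec("contour_violating", delta_semitones = 8)
  out <- mutate_pitch(m, viol, seed = 1)
  expect_identical(out$pitches, c(60L, 72L, 69L))
  expect_false(identical(contour_signature(out), contour_signature(m)))
})

test_that("candidate enumeration equals an exhaustive substitution oracle", {
  set.seed(21)
  checked <- 0
  for (i in 1:60) {
    m <- random_test_melody(len = sample(c(3, 5), 1))
    kind <- sample(c("contour_violating", "contour_preserving"), 1)
    delta <- if (kind == "contour_violating") sample(8:12, 1) else sample(3:5, 1)
    spec <- mutation_spec(kind, delta_semitones = delta)
    mine <- pitch_mutation_candidates(m, spec)
    oracle <- enumerate_pitch_mutations(m, kind, delta)
    if (is.null(oracle)) {
      expect_identical(nrow(mine), 0L)
      expect_error(mutate_pitch(m, spec), class = "minimuse_infeasible")
    } else {
      checked <- checked + 1
      expect_setequal(paste(mine$index, mine$new_pitch),
                      paste(oracle$index, oracle$new_pitch))
    }
  }
  expect_gt(checked, 10)
})

test_that("pitch mutation changes exactly one middle note", {
  set.seed(5)
  for (i in 1:30) {
    spec <- mutation_spec("contour_preserving", delta_semitones = sample(3:5, 1))
    m <- compose_standard(sample(c(3, 5), 1), tonic = sample(0:11, 1),
                          feasibility = list(spec))
    out <- mutate_pitch(m, spec, seed = i)
    diffidx <- which(out$pitches != m$pitches)
    expect_length(diffidx, 1)
    expect_true(diffidx >= 2 && diffidx <= length(m) - 1)
    expect_equal(abs(out$pitches[diffidx] - m$pitches[diffidx]),
                 spec$delta_semitones)
    expect_true(is_diatonic(out$pitches[diffidx], m$tonic))
    expect_identical(out$durations, m$durations)
  }
})

test_that("mutation spec ranges are enforced", {
  expect_error(mutation_spec("contour_violating", delta_semitones = 5), "8-12")
  expect_error(mutation_spec("contour_preserving", delta_semitones = 8), "3-5")
  expect_error(mutation_spec("tempo", delta_bpm = 20, direction = "faster"),
               "25")
  expect_error(mutation_spec("rhythm", n_changed = 4, beat_class = "downbeat"),
               "n_changed")
})

test_that("rhythm mutation conserves notes and total beats", {
  m <- melody(c(60, 64, 67), durations = c(1, 1, 2), tempo_bpm = 140)
  spec <- mutation_spec("rhythm", n_changed = 2, beat_class = "upbeat")
  out <- mutate_rhythm(m, spec, seed = 2)
  expect_identical(out$pitches, m$pitches)
  expect_equal(sum(out$durations), sum(m$durations))
  changed <- which(abs(out$durations - m$durations) > 1e-9)
  expect_length(changed, 2)
  expect_identical(diff(changed), 1L)
  # the altered run starts off the bar-initial beat
  onset <- cumsum(c(0, m$durations))[changed[1]]
  expect_true(onset %% m$meter != 0)
})

test_that("downbeat rhythm changes start on a bar-initial beat", {
  set.seed(9)
  for (i in 1:20) {
    n_changed <- sample(2:3, 1)
    len <- if (n_changed == 2) 3 else 5
    spec <- mutation_spec("rhythm", n_changed = n_changed,
                          beat_class = "downbeat")
    m <- compose_standard(len, tonic = sample(0:11, 1),
                          feasibility = list(spec))
    out <- mutate_rhythm(m, spec, seed = i)
    changed <- which(abs(out$durations - m$durations) > 1e-9)
    expect_length(changed, n_changed)
    onset <- cumsum(c(0, m$durations))[changed[1]]
    expect_equal(onset %% m$meter, 0)
    expect_equal(sum(out$durations), sum(m$durations))
    expect_identical(out$pitches, m$pitches)
  }
})

test_that("standard and rhythm comparison render to equal lengths", {
  spec <- mutation_spec("rhythm", n_changed = 2, beat_class = "downbeat")
  m <- compose_standard(3, feasibility = list(spec), seed = 3)
  out <- mutate_rhythm(m, spec, seed = 3)
  expect_lte(abs(length(render_melody(m)) - length(render_melody(out))), 1)
})

test_that("tempo variants change only the tempo", {
  m <- melody(c(60, 62, 64, 65), tempo_bpm = 100)
  faster <- make_tempo_variant(m, mutation_spec("tempo", delta_bpm = 40,
                                                direction = "faster"))
  expect_equal(faster$tempo_bpm, 140)
  expect_identical(faster$pitches, m$pitches)
  expect_identical(faster$durations, m$durations)
  slower <- make_tempo_variant(m, mutation_spec("tempo", delta_bpm = 70,
                                                direction = "slower"))
  expect_equal(slower$tempo_bpm, 30)
})

test_that("mutations are deterministic given a seed", {
  spec <- mutation_spec("contour_preserving", delta_semitones = 4)
  m <- compose_standard(5, feasibility = list(spec), seed = 4)
  expect_identical(mutate_pitch(m, spec, seed = 10)$pitches,
                   mutate_pitch(m, spec, seed = 10)$pitches)
  expect_identical(compose_standard(5, feasibility = list(spec), seed = 4)$pitches,
                   m$pitches)
})

test_that("composed standards satisfy feasibility and the melody invariants", {
  specs <- list(mutation_spec("contour_violating", delta_semitones = 12),
                mutation_spec("rhythm", n_changed = 2, beat_class = "upbeat"))
  for (seed in 1:10) {
    m <- compose_standard(3, tonic = 7, feasibility = specs, seed = seed)
    d <- melody_duration_s(m)
    expect_gte(d, 1)
    expect_lte(d, 3)
    expect_true(all(is_diatonic(m$pitches, 7)))
    expect_no_error(mutate_pitch(m, specs[[1]], seed = 1))
    expect_no_error(mutate_rhythm(m, specs[[2]], seed = 1))
  }
})
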