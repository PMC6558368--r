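test_that("the battery reproduces the printed task design", {
  b <- design_battery(seed = 1)
  tr <- tidy(b)
  counts <- dplyr::count(tr, task)
  expect_equal(counts$n[counts$task == "pitch"], 10)
  expect_equal(counts$n[counts$task == "melody"], 12)
  expect_equal(counts$n[counts$task == "rhythm"], 12)
  expect_equal(counts$n[counts$task == "tempo"], 10)

  pitch <- dplyr::filter(tr, task == "pitch")
  expect_equal(sum(abs(pitch$delta) == 120), 1)
  rest <- abs(pitch$delta[abs(pitch$delta) != 120])
  expect_true(all(rest >= 12 & rest <= 60))
  expect_equal(sum(pitch$delta < 0), 5)  # half lower, half higher

  rhythm <- dplyr::filter(tr, task == "rhythm")
  expect_equal(sum(rhythm$beat_class == "downbeat"), 6)
  expect_true(all(rhythm$n_changed %in% 2:3))

  tempo <- dplyr::filter(tr, task == "tempo")
  expect_true(all(abs(tempo$delta) >= 25 & abs(tempo$delta) <= 70))
  expect_equal(sum(tempo$direction == "faster"), 5)
  expect_true(all(purrr::map_dbl(
    b$trials$standard[b$trials$task == "tempo"], "tempo_bpm") == 100))

  mel <- dplyr::filter(tr, task == "melody")
  expect_equal(sum(mel$melody_length == 3), 6)
  expect_equal(sum(mel$melody_length == 5), 6)
  expect_true(all(tr$isi_s == 1.0))
})

test_that("melody comparisons reproduce the contour-type delta profile", {
  tr <- tidy(design_battery(seed = 2))
  mel <- dplyr::filter(tr, task == "melody")
  viol <- abs(mel$delta[mel$kind == "contour_violating"])
  pres <- abs(mel$delta[mel$kind == "contour_preserving"])
  expect_length(viol, 6)
  expect_length(pres, 6)
  expect_equal(round(mean(viol), 1), 9.3)
  expect_equal(round(mean(pres), 1), 3.8)
  expect_equal(range(viol), c(8, 12))
  expect_equal(range(pres), c(3, 5))
  expect_true(all(abs(mel$delta) >= 3 & abs(mel$delta) <= 12))
})

test_that("position and order are counterbalanced within each task", {
  tr <- tidy(design_battery(seed = 3))
  bal <- tr |>
    dplyr::summarise(
      left = sum(different_position == "left"),
      right = sum(different_position == "right"),
      first = sum(same_order == "first"),
      second = sum(same_order == "second"),
      .by = task)
  expect_true(all(abs(bal$left - bal$right) == 0))
  expect_true(all(abs(bal$first - bal$second) == 0))
  cells <- dplyr::count(tr, task, different_position, same_order)
  expect_true(all(tapply(cells$n, cells$task, function(x) diff(range(x))) <= 1))
})

test_that("two participant seeds share the item bank but not the order", {
  b1 <- design_battery(seed = 10)
  b2 <- design_battery(seed = 11)
  key <- function(b) {
    dplyr::arrange(dplyr::select(tidy(b), task, item, kind, delta,
                                 direction, beat_class, n_changed),
                   task, item)
  }
  expect_identical(key(b1), key(b2))
  expect_false(identical(dplyr::select(tidy(b1), task, item),
                         dplyr::select(tidy(b2), task, item)))
  expect_identical(tidy(design_battery(seed = 10)), tidy(b1))
})

test_that("the same comparison renders bit-identically to the standard", {
  b <- design_battery(seed = 4)
  row <- b$trials[b$trials$task == "melody", ][1, ]
  same <- minimuse:::render_stimulus(row$standard[[1]])
  again <- minimuse:::render_stimulus(row$standard[[1]])
  different <- minimuse:::render_stimulus(row$comparison[[1]])
  expect_identical(same$samples, again$samples)
  expect_false(identical(same$samples, different$samples))
})

test_that("battery audio export writes normalized stimuli and a manifest", {
  dir <- withr::local_tempdir()
  b <- design_battery(seed = 5)
  out <- render_battery_audio(b, dir, tasks = "pitch")
  expect_equal(nrow(out), 10)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  clip <- read_wav(out$standard_file[1])
  expect_equal(20 * log10(sqrt(mean(clip$samples^2))), -20, tolerance = 0.2)
  expect_identical(out$correct_side[1],
                   ifelse(out$different_position[1] == "left", "right", "left"))
})

test_that("invalid configurations are refused", {
  cfg <- battery_config()
  cfg$pitch$n_trials <- 8L
  expect_error(design_battery(seed = 1, config = cfg),
               class = "minimuse_config")
  cfg <- battery_config()
  cfg$tempo$deltas <- c(10L, rep(30L, 9L))
  expect_error(design_battery(seed = 1, config = cfg),
               class = "minimuse_config")
})

test_that("the practice gate requires three of four correct", {
  expect_true(practice_gate(c(TRUE, TRUE, TRUE, FALSE)))
  expect_true(practice_gate(c(TRUE, TRUE, TRUE, TRUE)))
  expect_false(practice_gate(c(TRUE, TRUE, FALSE, FALSE)))
  expect_error(practice_gate(c(TRUE, TRUE, TRUE)), "four")
})
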