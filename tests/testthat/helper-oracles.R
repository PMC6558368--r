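# Independent oracles used across tests: deliberately naive implementations
# (sample-by-sample loops, exhaustive enumeration) kept separate from the
# package's code paths.

# Brute-force onset scan: walks the squared signal one sample at a time,
# opening a candidate at each below-to-above threshold crossing and
# accepting it only when at least the refractory gap has passed.
brute_force_onsets <- function(samples, rate, k = 4, refractory_ms = 200) {
  x2 <- samples^2
  thr <- k * sd(x2)
  refr <- round(refractory_ms / 1000 * rate)
  onsets <- numeric()
  last <- -Inf
  prev_above <- FALSE
  for (i in seq_along(x2)) {
    above <- x2[i] > thr
    if (above && !prev_above && (i - last) >= refr) {
      onsets <- c(onsets, (i - 1) / rate)
      last <- i
    }
    prev_above <- above
  }
  onsets
}

# Exhaustive nearest-click assignment: for every tap find the nearest click;
# keep taps within half the click IOI; for clashes on a click keep the
# closest tap. O(n^2), no vectorisation.
brute_force_pairing <- function(taps, clicks) {
  half <- if (length(clicks) > 1) median(diff(clicks)) / 2 else Inf
  assign <- data.frame(tap = numeric(), click = integer(), dev = numeric())
  for (t in taps) {
    best <- 0
    bestd <- Inf
    for (j in seq_along(clicks)) {
      d <- abs(t - clicks[j])
      if (d < bestd) {
        bestd <- d
        best <- j
      }
    }
    if (bestd <= half) {
      assign <- rbind(assign, data.frame(tap = t, click = best, dev = t - clicks[best]))
    }
  }
  out <- numeric()
  for (j in sort(unique(assign$click))) {
    sub <- assign[assign$click == j, ]
    out <- c(out, sub$dev[which.min(abs(sub$dev))])
  }
  out * 1000
}

# Exhaustive single-note substitution oracle: every pitch in [36, 96] at a
# middle index, filtered by |delta|, diatonicity and the contour criterion.
enumerate_pitch_mutations <- function(m, kind, delta) {
  n <- length(m$pitches)
  idx <- if (n == 3) 2 else 2:4
  sig0 <- sign(diff(m$pitches))
  out <- NULL
  for (i in idx) {
    for (p_new in 36:96) {
      if (abs(p_new - m$pitches[i]) != delta) next
      if (!minimuse::is_diatonic(p_new, m$tonic)) next
      p <- m$pitches
      p[i] <- p_new
      changed <- !identical(sign(diff(p)), sig0)
      if (changed != (kind == "contour_violating")) next
      out <- rbind(out, data.frame(index = i, new_pitch = p_new))
    }
  }
  out
}

# A train of identical 5 ms sine bursts with the given onset spacing.
burst_train <- function(spacing_s, total_s = 2, rate = 44100, freq = 1000,
                        amp = 0.8, burst_s = 0.005) {
  x <- numeric(round(total_s * rate))
  nb <- round(burst_s * rate)
  burst <- amp * sin(2 * pi * freq * (seq_len(nb) - 1) / rate)
  onsets <- seq(0, total_s - burst_s, by = spacing_s)
  for (on in onsets) {
    s <- round(on * rate) + 1
    x[s:(s + nb - 1)] <- burst
  }
  minimuse::audio_clip(x, rate)
}

random_test_melody <- function(len = sample(3:5, 1), tonic = sample(0:11, 1)) {
  scale_steps <- c(0, 2, 4, 5, 7, 9, 11)
  scale <- sort(unlist(lapply(seq(36, 96, 12), function(o) o + tonic + scale_steps)))
  scale <- scale[scale >= 55 & scale <= 84]
  minimuse::melody(sample(scale, len, replace = TRUE),
                   durations = sample(c(0.5, 1, 2), len, replace = TRUE),
                   tonic = tonic, tempo_bpm = 140)
}
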