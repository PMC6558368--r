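# Tap-onset detection and synchronization scoring. A recorded (or simulated)
# tapping trial is squared sample-by-sample; samples whose energy exceeds
# k * SD(squared signal) open a candidate onset, and a refractory window
# after each accepted onset prevents one physical tap being counted twice.
# Tap-to-click asynchronies summarise to the SEA (standard error of
# asynchronies): smaller SEA = steadier synchronization.

#' Onset-detection parameters
#'
#' @param k Threshold multiplier: the energy threshold is `k` times the
#'   standard deviation of the squared trial (default 4).
#' @param refractory_ms Refractory window in ms after each accepted onset
#'   during which no new onset may be declared (default 200).
#' @return An object of class `onset_params`.
#' @export
onset_params <- function(k = 4, refractory_ms = 200) {
  if (k <= 0 || refractory_ms <= 0) rlang::abort("k and refractory_ms must be positive")
  structure(list(k = k, refractory_ms = refractory_ms), class = "onset_params")
}

onset_candidates <- function(clip, params) {
  x2 <- clip$samples^2
  if (stats::sd(x2) == 0) {
    rlang::abort("zero-variance signal: cannot set an energy threshold",
                 class = "minimuse_degenerate_signal")
  }
  threshold <- params$k * stats::sd(x2)
  above <- x2 > threshold
  starts <- which(above & !c(FALSE, above[-length(above)]))
  ends <- which(above & !c(above[-1L], FALSE))
  peak <- purrr::map2_dbl(starts, ends, ~ max(x2[.x:.y]))
  list(starts = starts, peak_energy = peak, threshold = threshold)
}

#' Detect tap onsets in an audio clip
#'
#' Each sample is squared and compared with a threshold of `k` times the
#' standard deviation of the squared trial; the first sample of each
#' supra-threshold run is a candidate onset. Candidates are accepted left to
#' right, and after each accepted onset all candidates within the refractory
#' window are suppressed, so consecutive onsets are at least
#' `refractory_ms` apart.
#'
#' @param clip An `audio_clip` with nonzero variance.
#' @param params An [onset_params()].
#' @return Ascending numeric vector of onset times in seconds (possibly
#'   empty for near-silent input).
#' @export
detect_onsets <- function(clip, params = onset_params()) {
  stopifnot(inherits(clip, "audio_clip"))
  cand <- onset_candidates(clip, params)
  refr <- round(params$refractory_ms / 1000 * clip$rate)
  accepted <- integer()
  last <- -Inf
  for (s in cand$starts) {
    if (s - last >= refr) {
      accepted <- c(accepted, s)
      last <- s
    }
  }
  (accepted - 1L) / clip$rate
}

#' Per-candidate detection diagnostics
#'
#' The detector is semi-automatic in practice: every trial's detections are
#' reviewed and the threshold multiplier / refractory window re-tuned per
#' participant when needed. This function exposes the candidate-level view
#' that review works from; re-running it with adjusted `params` reproduces
#' the manual-adjustment loop.
#'
#' @inheritParams detect_onsets
#' @return A tibble with one row per candidate: `time_s`, `peak_energy`,
#'   `accepted`, plus the threshold as attribute `"threshold"`.
#' @export
inspect_detection <- function(clip, params = onset_params()) {
  stopifnot(inherits(clip, "audio_clip"))
  cand <- onset_candidates(clip, params)
  accepted_times <- detect_onsets(clip, params)
  times <- (cand$starts - 1L) / clip$rate
  out <- tibble::tibble(
    time_s = times,
    peak_energy = cand$peak_energy,
    accepted = times %in% accepted_times
  )
  attr(out, "threshold") <- cand$threshold
  out
}

#' Pair tap onsets with metronome clicks
#'
#' Each tap is assigned to its nearest click, provided the deviation is
#' within half the click inter-onset interval; when several taps claim the
#' same click the closest wins and the others are dropped, so at most one
#' tap is paired per click.
#'
#' @param onsets_s Ascending tap onset times (s).
#' @param click_times_s Ascending metronome click times (s).
#' @return A numeric vector of signed asynchronies in ms (tap minus click),
#'   ordered by click time, with attribute `"clicks"` giving the matched
#'   click times.
#' @export
pair_asynchronies <- function(onsets_s, click_times_s) {
  if (!length(onsets_s) || !length(click_times_s)) {
    rlang::abort("onsets and clicks must be non-empty")
  }
  if (is.unsorted(onsets_s, strictly = FALSE) ||
      is.unsorted(click_times_s, strictly = FALSE)) {
    rlang::abort("onset and click times must be ascending")
  }
  half_win <- if (length(click_times_s) > 1L) {
    stats::median(diff(click_times_s)) / 2
  } else Inf
  nearest <- vapply(onsets_s, function(t) which.min(abs(click_times_s - t)), 1L)
  dev <- onsets_s - click_times_s[nearest]
  pairs <- tibble::tibble(tap = onsets_s, click_idx = nearest, dev = dev) |>
    dplyr::filter(abs(dev) <= half_win) |>
    dplyr::group_by(.data$click_idx) |>
    dplyr::slice_min(abs(.data$dev), n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$click_idx)
  out <- pairs$dev * 1000
  attr(out, "clicks") <- click_times_s[pairs$click_idx]
  out
}

#' Standard error of asynchronies (SEA)
#'
#' The SEA of a tapping trial is the standard error of the signed tap-click
#' asynchronies: sample SD divided by the square root of the number of
#' paired taps. Smaller values indicate steadier synchronization. Set
#' `type = "sd"` for the plain SD (the two differ only by the sqrt(n)
#' factor).
#'
#' @param asynchronies_ms Signed asynchronies in ms, length >= 2.
#' @param type `"se"` (default) or `"sd"`.
#' @return SEA in ms.
#' @export
sea <- function(asynchronies_ms, type = c("se", "sd")) {
  type <- rlang::arg_match(type)
  n <- length(asynchronies_ms)
  if (n < 2L) {
    rlang::abort("at least two asynchronies are needed",
                 class = "minimuse_insufficient_data")
  }
  s <- stats::sd(asynchronies_ms)
  if (type == "se") s / sqrt(n) else s
}

#' Mean SEA over the two tapping tempi
#'
#' Each child taps one trial at 100 BPM and one at 120 BPM; since a single
#' rate is unlikely to match a child's preferred tempo, the outcome score is
#' the arithmetic mean of the two trials' SEA.
#'
#' @param sea_a,sea_b SEA values (ms) of the two trials, or `sync_result`
#'   objects from [analyze_tapping()].
#' @return Mean SEA in ms.
#' @export
mean_sea <- function(sea_a, sea_b) {
  g <- function(x) if (inherits(x, "sync_result")) x$sea_ms else as.numeric(x)
  (g(sea_a) + g(sea_b)) / 2
}

#' Analyse a tapping trial end to end
#'
#' Detects tap onsets, pairs them with the metronome clicks and summarises
#' synchronization variability.
#'
#' @param clip An `audio_clip` of the recorded trial.
#' @param click_times_s Metronome click times in seconds.
#' @param params An [onset_params()].
#' @param type SEA convention passed to [sea()].
#' @return An object of class `sync_result`: `onsets_s`, `asynchronies_ms`,
#'   `matched_clicks_s`, `sea_ms`, `n_paired`.
#' @export
analyze_tapping <- function(clip, click_times_s, params = onset_params(),
                            type = "se") {
  onsets <- detect_onsets(clip, params)
  asy <- pair_asynchronies(onsets, click_times_s)
  structure(
    list(onsets_s = onsets,
         asynchronies_ms = as.numeric(asy),
         matched_clicks_s = attr(asy, "clicks"),
         sea_ms = sea(asy, type = type),
         n_paired = length(asy)),
    class = "sync_result")
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf("<sync_result> %d onsets, %d paired, SEA %.2f ms\n",
              length(x$onsets_s), x$n_paired, x$sea_ms))
  invisible(x)
}

#' Tidy a sync result into a per-pair tibble
#'
#' @param x A `sync_result`.
#' @param ... Unused.
#' @return Tibble with `click_s` and `asynchrony_ms`.
#' @export
tidy.sync_result <- function(x, ...) {
  tibble::tibble(click_s = x$matched_clicks_s,
                 asynchrony_ms = x$asynchronies_ms)
}

#' @export
glance.sync_result <- function(x, ...) {
  tibble::tibble(n_onsets = length(x$onsets_s), n_paired = x$n_paired,
                 mean_asynchrony_ms = mean(x$asynchronies_ms),
                 sd_asynchrony_ms = stats::sd(x$asynchronies_ms),
                 sea_ms = x$sea_ms)
}

#' Plot asynchronies over a trial
#'
#' @param object A `sync_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sync_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$click_s, y = .data$asynchrony_ms)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "click time (s)", y = "asynchrony (ms)",
                  title = sprintf("SEA = %.1f ms", object$sea_ms)) +
    ggplot2::theme_minimal()
}
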