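# Synthetic data: simulated child cohorts with specified marginals and
# correlation structure, simulated tapping-trial audio with known ground
# truth, and simulated oddity-task responses from a psychometric accuracy
# model. These generators make every analysis module testable end to end
# without any recorded data.

#' Default cohort marginals
#'
#' Per-variable means, SDs and legal score ranges matching the battery's
#' reference cohort of 3--4-year-olds: perception tasks scored as correct
#' trials (pitch/tempo out of 10, melody/rhythm out of 12), the two-rater
#' song composite (0--10), synchronization as mean SEA in ms units of the
#' study scale, the phonological-awareness composite (1--100 scale),
#' standardized grammar and receptive-vocabulary scores, and the two
#' cognitive covariates.
#'
#' @return A tibble with columns `variable`, `mean`, `sd`, `min`, `max`.
#' @export
cohort_defaults <- function() {
  tibble::tribble(
    ~variable,      ~mean, ~sd,   ~min, ~max,
    "pitch",         6.35, 1.60,     1,   10,
    "melody",        7.81, 1.99,     1,   12,
    "tempo",         7.18, 1.74,     1,   10,
    "rhythm",        8.60, 2.19,     1,   12,
    "song",          7.06, 2.18,     1,   10,
    "synch",         3.79, 1.63,     0,  Inf,
    "phon_aw",      51.56, 21.38,    1,  100,
    "grammar",      66.81, 19.73,   20,  160,
    "vocabulary",  107.80, 10.03,   40,  160,
    "block_design", 10.87, 1.73,     1,   19,
    "digit_span",   69.63, 20.16,   10,  140
  )
}

#' Specify a synthetic cohort
#'
#' @param n Number of children.
#' @param variables Marginal table as from [cohort_defaults()] (columns
#'   `variable`, `mean`, `sd`, `min`, `max`); rows define the simulated
#'   columns and their truncation ranges.
#' @param correlation Correlation matrix over the variables (default
#'   identity); must be symmetric positive definite.
#' @param missingness Per-variable missingness rates in \[0, 1), recycled.
#' @param seed Integer seed; the draw is reproducible given it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, variables = cohort_defaults(), correlation = NULL,
                        missingness = 0, seed = NULL) {
  p <- nrow(variables)
  if (is.null(correlation)) correlation <- diag(p)
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation))) ||
      any(eigen(correlation, symmetric = TRUE, only.values = TRUE)$values <= 1e-10)) {
    rlang::abort("correlation matrix must be symmetric positive definite",
                 class = "minimuse_not_pd")
  }
  if (nrow(correlation) != p) rlang::abort("correlation dimension mismatch")
  missingness <- rep_len(missingness, p)
  if (any(missingness < 0 | missingness >= 1)) {
    rlang::abort("missingness rates must lie in [0, 1)")
  }
  structure(list(n = as.integer(n), variables = variables,
                 correlation = correlation, missingness = missingness,
                 seed = seed),
            class = "cohort_spec")
}

#' Simulate a child cohort
#'
#' Multivariate-normal draws (Gaussian copula on the correlation scale) are
#' rescaled to the requested per-variable means and SDs, truncated to each
#' task's legal score range, and thinned by the requested missingness. Note
#' truncation slightly biases the realised moments toward the range centre.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble, one row per child (`child` id column plus one column
#'   per variable).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  v <- spec$variables
  with_local_seed(spec$seed, {
    z <- MASS::mvrnorm(spec$n, mu = rep(0, nrow(v)), Sigma = spec$correlation)
    z <- matrix(z, nrow = spec$n)
    cols <- lapply(seq_len(nrow(v)), function(j) {
      x <- v$mean[j] + v$sd[j] * z[, j]
      x <- pmin(pmax(x, v$min[j]), v$max[j])
      miss <- stats::runif(spec$n) < spec$missingness[j]
      x[miss] <- NA_real_
      x
    })
    names(cols) <- v$variable
    dplyr::bind_cols(tibble::tibble(child = seq_len(spec$n)),
                     tibble::as_tibble(cols))
  })
}

#' A demonstration correlation preset
#'
#' Encodes the qualitative sign pattern the battery is designed to probe:
#' modest positive correlations among the music perception/production
#' scores, rhythm and synchronization linked to phonological awareness
#' (synchronization negatively, since larger SEA = worse), melody linked to
#' grammar, and positive links from the cognitive covariates to the
#' language scores. The matrix is shrunk toward the identity until positive
#' definite.
#'
#' @param variables Variable table as in [cohort_defaults()].
#' @return A correlation matrix.
#' @export
demo_correlation <- function(variables = cohort_defaults()) {
  nm <- variables$variable
  p <- length(nm)
  r <- diag(p)
  dimnames(r) <- list(nm, nm)
  set_r <- function(a, b, val) {
    if (all(c(a, b) %in% nm)) {
      r[a, b] <<- val
      r[b, a] <<- val
    }
  }
  music <- intersect(c("pitch", "melody", "tempo", "rhythm", "song"), nm)
  for (i in seq_along(music)) {
    for (j in seq_len(i - 1L)) set_r(music[i], music[j], 0.25)
  }
  set_r("rhythm", "phon_aw", 0.55)
  set_r("synch", "phon_aw", -0.40)
  set_r("tempo", "phon_aw", 0.30)
  set_r("melody", "grammar", 0.40)
  set_r("rhythm", "grammar", 0.25)
  set_r("digit_span", "phon_aw", 0.45)
  set_r("digit_span", "grammar", 0.45)
  set_r("block_design", "grammar", 0.40)
  set_r("block_design", "rhythm", 0.30)
  set_r("digit_span", "pitch", 0.30)
  set_r("synch", "rhythm", -0.25)
  while (min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) < 1e-3) {
    r <- 0.9 * r + 0.1 * diag(p)
  }
  r
}

#' Specify a simulated tapping trial
#'
#' @param bpm Metronome tempo (the battery uses 100 and 120 BPM trials).
#' @param n_taps Number of taps / clicks per trial (default 20).
#' @param jitter_sd_ms SD of Gaussian timing jitter around the clicks.
#' @param mean_offset_ms Constant tap anticipation/lag in ms.
#' @param snr_db Tap-to-noise power ratio in dB.
#' @param seed Integer seed.
#' @return An object of class `tap_sim_spec`.
#' @export
tap_sim_spec <- function(bpm = 120, n_taps = 20L, jitter_sd_ms = 20,
                         mean_offset_ms = 0, snr_db = 20, seed = NULL) {
  if (n_taps < 1L || jitter_sd_ms < 0 || bpm <= 0) {
    rlang::abort("invalid tapping-simulation spec")
  }
  structure(list(bpm = bpm, n_taps = as.integer(n_taps),
                 jitter_sd_ms = jitter_sd_ms, mean_offset_ms = mean_offset_ms,
                 snr_db = snr_db, seed = seed),
            class = "tap_sim_spec")
}

# sharply-attacked damped 1 kHz transient, ~25 ms
tap_transient <- function(rate, dur_s = 0.025, amp = 0.9) {
  n <- round(dur_s * rate)
  t <- (seq_len(n) - 1L) / rate
  amp * sin(2 * pi * 1000 * t) * exp(-t / 0.005)
}

#' Simulate a tapping-trial recording with known ground truth
#'
#' Places one tap transient per metronome click at click time plus the mean
#' offset plus Gaussian jitter, over white noise at the requested SNR
#' (tap-transient power vs noise power). The exact tap and click times are
#' returned, so detector accuracy and SEA recovery can be measured against
#' truth.
#'
#' @param spec A [tap_sim_spec()].
#' @param rate Sampling rate.
#' @return A list: `clip` (`audio_clip`), `tap_times_s` (true onsets),
#'   `click_times_s`.
#' @export
simulate_tapping_audio <- function(spec, rate = DEFAULT_RATE) {
  stopifnot(inherits(spec, "tap_sim_spec"))
  with_local_seed(spec$seed, {
    ioi <- 60 / spec$bpm
    lead_in <- 0.5
    clicks <- lead_in + (seq_len(spec$n_taps) - 1L) * ioi
    taps <- clicks + spec$mean_offset_ms / 1000 +
      stats::rnorm(spec$n_taps, 0, spec$jitter_sd_ms / 1000)
    taps <- sort(pmax(taps, 0))
    burst <- tap_transient(rate)
    total <- round((max(taps) + 0.5) * rate)
    noise_sd <- sqrt(mean(burst^2) * 10 ^ (-spec$snr_db / 10))
    x <- stats::rnorm(total, 0, noise_sd)
    for (tt in taps) {
      start <- round(tt * rate) + 1L
      stop <- min(start + length(burst) - 1L, total)
      x[start:stop] <- x[start:stop] + burst[seq_len(stop - start + 1L)]
    }
    x <- pmax(pmin(x, 1), -1)
    list(clip = audio_clip(x, rate), tap_times_s = taps,
         click_times_s = clicks)
  })
}

#' Simulate oddity-task responses
#'
#' A two-alternative oddity trial has a 0.5 guessing floor, so the accuracy
#' model is `P(correct) = 0.5 + 0.5 * logistic(ability - difficulty)`:
#' chance performance for very low ability, ceiling for very high, 0.75 when
#' ability matches the trial difficulty.
#'
#' @param ability Scalar latent ability of the child.
#' @param trial_difficulties Numeric vector of per-trial difficulties.
#' @param seed Integer seed.
#' @return A tibble with `trial`, `difficulty`, `p_correct`, `correct`.
#' @export
simulate_oddity_responses <- function(ability, trial_difficulties, seed = NULL) {
  if (any(!is.finite(trial_difficulties))) {
    rlang::abort("difficulties must be finite")
  }
  p <- 0.5 + 0.5 * stats::plogis(ability - trial_difficulties)
  correct <- with_local_seed(seed,
                             stats::runif(length(p)) < p)
  tibble::tibble(trial = seq_along(p), difficulty = trial_difficulties,
                 p_correct = p, correct = correct)
}
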