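#' Default session plans for the six-session Ishihara paradigm
#'
#' Each diagnostic session shows a pair of Ishihara plates above two squares
#' flickering at 15 and 18 Hz and asks the subject to look at the plate
#' showing a stated digit. The plate pairs are chosen so that red-green CVD
#' observers systematically pick the non-target plate; in sessions 2, 4 and 6
#' the non-target plate is a hidden-digit plate (visible only to CVD
#' observers), which is what the severity score counts.
#'
#' The plate-to-frequency assignment is a display-layout choice: by default
#' the target plate's square flickers at 15 Hz in odd sessions and at 18 Hz
#' in even sessions, so both frequencies serve as targets. Override the
#' `target_frequency` column for other layouts.
#'
#' @return A tibble with one row per session: `session_id`, `question_digit`,
#'   `target_frequency`, `nontarget_frequency` (Hz),
#'   `target_plate_is_hidden_digit` (always `FALSE`),
#'   `nontarget_plate_is_hidden_digit` (`TRUE` in sessions 2, 4, 6).
#' @export
#'
#' @examples
#' default_session_plans()
default_session_plans <- function() {
  session_id <- 1:6
  target <- ifelse(session_id %% 2 == 1, 15, 18)
  tibble::tibble(
    session_id = session_id,
    question_digit = c("2", "45", "5", "5", "5", "2"),
    target_frequency = target,
    nontarget_frequency = 33 - target,
    target_plate_is_hidden_digit = FALSE,
    nontarget_plate_is_hidden_digit = session_id %in% c(2, 4, 6)
  )
}

#' Subject profile for the behavioral choice model
#'
#' @param subject_id Subject identifier.
#' @param condition `"normal"` or `"cvd"`.
#' @param severity For CVD subjects, the probability of recognising (and thus
#'   choosing) a hidden-digit plate in sessions 2/4/6; more recognised hidden
#'   digits indicates more severe CVD. Ignored for normal subjects.
#' @param lapse_rate Probability that a session's choice is a random guess
#'   between the two plates, for any subject.
#'
#' @return A list of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, condition = c("normal", "cvd"),
                            severity = 1, lapse_rate = 0) {
  condition <- match.arg(condition)
  stopifnot(severity >= 0, severity <= 1, lapse_rate >= 0, lapse_rate <= 1)
  structure(list(subject_id = as.character(subject_id),
                 condition = condition,
                 severity = severity,
                 lapse_rate = lapse_rate),
            class = "subject_profile")
}

#' Simulate one session's plate choice
#'
#' Implements the behavioral model: with probability `lapse_rate` the subject
#' guesses uniformly between the two plates. Otherwise a normal-vision
#' subject chooses the target plate; a CVD subject chooses the expected CVD
#' plate — in hidden-digit sessions the hidden (non-target) plate with
#' probability `severity` (falling back to the target plate when the hidden
#' digit goes unrecognised), and in the remaining sessions the non-target
#' plate. The attended flicker frequency of the chosen plate is returned.
#'
#' Marginally, a non-lapsing subject attends its condition-expected frequency
#' with probability `1 - lapse_rate / 2` (severity 1).
#'
#' @param profile A [subject_profile()].
#' @param plan One row of [default_session_plans()].
#' @return Attended frequency in Hz (15 or 18). Uses the current RNG stream.
#' @export
simulate_choice <- function(profile, plan) {
  stopifnot(inherits(profile, "subject_profile"))
  target <- plan$target_frequency
  nontarget <- plan$nontarget_frequency
  if (stats::runif(1) < profile$lapse_rate) {
    return(sample(c(target, nontarget), 1L))
  }
  if (profile$condition == "normal") {
    return(target)
  }
  if (plan$nontarget_plate_is_hidden_digit) {
    if (stats::runif(1) < profile$severity) nontarget else target
  } else {
    nontarget
  }
}

#' Simulation configuration
#'
#' Amplitudes are chosen to emulate the structure of occipital SSVEP
#' recordings: an entrained response at the attended frequency and its
#' harmonics, strongest over O1/O2 and weaker at Pz and Cz; an ever-present
#' ~10 Hz peak; broadband 1/f background; 60 Hz line noise; and occasional
#' high-amplitude blink-like transients.
#'
#' @param fs Sampling rate, Hz.
#' @param channel_names Channel montage (order defines `ssvep_amp` order).
#' @param trial_s,rest_s Stimulation and rest durations, s.
#' @param n_trials_per_session,n_sessions Paradigm shape.
#' @param ssvep_amp Named numeric, fundamental SSVEP amplitude per channel,
#'   microvolts.
#' @param harmonic_decay Amplitude ratio between successive harmonics.
#' @param n_harmonics_gen Number of harmonics generated (those above Nyquist
#'   are skipped).
#' @param alpha_amp Amplitude of the 10 Hz non-target component, microvolts.
#' @param noise_scale RMS of the 1/f background process, microvolts.
#' @param noise_exponent Spectral exponent of the background (power ~ 1/f^a).
#' @param line_amp Amplitude of the 60 Hz line component, microvolts.
#' @param artifact_rate Expected artifacts per minute.
#' @param artifact_amp Peak artifact amplitude, microvolts.
#' @param seed Default seed used by [simulate_cohort()] when none is given.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(fs = 250,
                       channel_names = c("O1", "O2", "Pz", "Cz"),
                       trial_s = 10, rest_s = 10,
                       n_trials_per_session = 10, n_sessions = 6,
                       ssvep_amp = c(O1 = 2.5, O2 = 2.5, Pz = 1.5, Cz = 1.0),
                       harmonic_decay = 0.5,
                       n_harmonics_gen = 3,
                       alpha_amp = 3,
                       noise_scale = 5,
                       noise_exponent = 1,
                       line_amp = 1,
                       artifact_rate = 0.5,
                       artifact_amp = 400,
                       seed = 1L) {
  stopifnot(fs > 0, trial_s > 0, rest_s > 0,
            all(ssvep_amp >= 0), alpha_amp >= 0, noise_scale >= 0,
            line_amp >= 0, artifact_rate >= 0, artifact_amp >= 0,
            harmonic_decay > 0, harmonic_decay <= 1, n_harmonics_gen >= 1)
  if (abs(trial_s * fs - round(trial_s * fs)) > 1e-9) {
    stop("trial_s * fs must be an integer number of samples", call. = FALSE)
  }
  if (length(ssvep_amp) != length(channel_names)) {
    stop("`ssvep_amp` must have one value per channel", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

# Unit-RMS 1/f^(a/2)-amplitude noise via spectral shaping of white noise.
pink_noise <- function(n, exponent = 1) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1))          # avoid DC blow-up; bin 0 treated as bin 1
  f <- pmin(f, n - f + 1)            # mirror for negative frequencies
  X <- X / f^(exponent / 2)
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y <- y - mean(y)
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

# Background activity common to trial and rest epochs.
background_matrix <- function(n, cfg) {
  t <- (seq_len(n) - 1) / cfg$fs
  n_ch <- length(cfg$channel_names)
  out <- matrix(0, n_ch, n)
  for (ch in seq_len(n_ch)) {
    bg <- cfg$noise_scale * pink_noise(n, cfg$noise_exponent)
    alpha <- cfg$alpha_amp * sin(2 * pi * 10 * t + stats::runif(1, 0, 2 * pi))
    out[ch, ] <- bg + alpha
  }
  if (cfg$line_amp > 0 && 60 < cfg$fs / 2) {
    out <- out + rep(cfg$line_amp * sin(2 * pi * 60 * t), each = n_ch)
  }
  # blink-like transients: 0.2 s raised-cosine pulses with a random
  # per-channel gradient (a spatially uniform pulse would be cancelled by
  # the average reference, which real artifacts are not)
  n_art <- stats::rpois(1, cfg$artifact_rate * n / cfg$fs / 60)
  if (n_art > 0 && cfg$artifact_amp > 0) {
    w <- max(3L, round(0.2 * cfg$fs))
    pulse <- cfg$artifact_amp * 0.5 * (1 - cos(2 * pi * seq_len(w) / (w + 1)))
    for (a in seq_len(n_art)) {
      at <- sample.int(max(1L, n - w), 1L)
      idx <- at:(at + w - 1L)
      gain <- stats::runif(n_ch, 0.3, 1)
      out[, idx] <- out[, idx] + gain %o% pulse
    }
  }
  out
}

#' Synthesize one 10-s stimulation trial
#'
#' Each channel is the sum of the SSVEP series (harmonics of the attended
#' frequency with geometrically decaying amplitude and per-harmonic phases),
#' a 10 Hz component with random phase, unit-RMS 1/f background scaled by
#' `noise_scale`, a 60 Hz line tone, and sparse high-amplitude transients.
#' Harmonics at or above Nyquist are skipped.
#'
#' @param attended_freq Attended flicker frequency, Hz.
#' @param cfg A [sim_config()].
#' @param ssvep_phases Optional phases (radians), one per generated harmonic.
#'   SSVEPs are stimulus-locked, so [simulate_cohort()] draws these once per
#'   session and reuses them across that session's trials; when `NULL` they
#'   are drawn from the current RNG stream.
#' @return Numeric matrix, channels x `trial_s * fs`, microvolts. Consumes
#'   the current RNG stream (seed it for reproducibility).
#' @export
synthesize_trial <- function(attended_freq, cfg = sim_config(),
                             ssvep_phases = NULL) {
  if (cfg$fs <= 0) stop("sampling rate must be positive", call. = FALSE)
  n <- round(cfg$trial_s * cfg$fs)
  t <- (seq_len(n) - 1) / cfg$fs
  if (is.null(ssvep_phases)) {
    ssvep_phases <- stats::runif(cfg$n_harmonics_gen, 0, 2 * pi)
  }
  ssvep <- numeric(n)
  for (h in seq_len(cfg$n_harmonics_gen)) {
    fh <- h * attended_freq
    if (fh >= cfg$fs / 2) next
    ssvep <- ssvep +
      cfg$harmonic_decay^(h - 1) * sin(2 * pi * fh * t + ssvep_phases[h])
  }
  out <- background_matrix(n, cfg)
  out + cfg$ssvep_amp %o% ssvep
}

#' Simulate a cohort of frequency-tagged EEG recordings
#'
#' One recording per subject: `n_sessions` sessions of
#' `n_trials_per_session` stimulation/rest pairs, trigger 0 during trials and
#' 1 during rest. The attended frequency of each session comes from
#' [simulate_choice()] under the subject's condition, severity and lapse
#' rate; trial content comes from [synthesize_trial()] with session-locked
#' SSVEP phases, and rest epochs contain background activity only.
#'
#' @param n_normal,n_cvd Subject counts per condition (study shape: 11 and 5).
#' @param cfg A [sim_config()].
#' @param plans Session plans, see [default_session_plans()].
#' @param severity,lapse_rate Behavioral parameters for the generated
#'   profiles (severity applies to CVD subjects only).
#' @param seed Integer seed; defaults to `cfg$seed`. All output is a pure
#'   function of the arguments and this seed.
#'
#' @return A tibble with one row per subject: `subject_id`, `condition`,
#'   `severity`, `lapse_rate`, `attended` (list column, attended frequency
#'   per session) and `recording` (list column of [eeg_recording()]s).
#' @export
#'
#' @examples
#' cohort <- simulate_cohort(1, 1, sim_config(n_trials_per_session = 1,
#'                                            n_sessions = 2))
#' cohort$recording[[1]]
simulate_cohort <- function(n_normal, n_cvd, cfg = sim_config(),
                            plans = default_session_plans(),
                            severity = 1, lapse_rate = 0,
                            seed = cfg$seed) {
  stopifnot(n_normal >= 0, n_cvd >= 0)
  plans <- plans[seq_len(min(nrow(plans), cfg$n_sessions)), , drop = FALSE]
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)

  conditions <- c(rep("normal", n_normal), rep("cvd", n_cvd))
  ids <- sprintf("S%02d", seq_along(conditions))
  n_trial <- round(cfg$trial_s * cfg$fs)
  n_rest <- round(cfg$rest_s * cfg$fs)
  n_ch <- length(cfg$channel_names)

  rows <- purrr::map(seq_along(conditions), function(i) {
    profile <- subject_profile(ids[i], conditions[i],
                               severity = severity, lapse_rate = lapse_rate)
    attended <- numeric(nrow(plans))
    blocks <- list()
    trig <- list()
    for (s in seq_len(nrow(plans))) {
      attended[s] <- simulate_choice(profile, plans[s, ])
      phases <- stats::runif(cfg$n_harmonics_gen, 0, 2 * pi)
      for (tr in seq_len(cfg$n_trials_per_session)) {
        blocks <- c(blocks, list(
          synthesize_trial(attended[s], cfg, ssvep_phases = phases),
          background_matrix(n_rest, cfg)))
        trig <- c(trig, list(integer(n_trial), rep(1L, n_rest)))
      }
    }
    rec <- eeg_recording(
      do.call(cbind, blocks),
      channel_names = cfg$channel_names,
      fs = cfg$fs,
      trigger = unlist(trig),
      meta = list(subject_id = ids[i], condition = conditions[i])
    )
    tibble::tibble(subject_id = ids[i], condition = conditions[i],
                   severity = if (conditions[i] == "cvd") severity else NA_real_,
                   lapse_rate = lapse_rate,
                   attended = list(attended), recording = list(rec))
  })
  dplyr::bind_rows(rows)
}
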