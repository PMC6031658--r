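#' Simulation configuration for the synthetic multi-subject pool
#'
#' The generator emulates the statistical structure that sensorimotor-rhythm
#' (SMR) decoding assumes: each subject carries two bilateral pairs of
#' narrow-band sources (~10-Hz mu and ~20-Hz beta, one per hemisphere) mixed
#' into the sensors by a subject-specific spatial pattern, on top of 1/f
#' background activity and white sensor noise. After cue onset (t >= 0) the
#' band power of the source contralateral to the cued hand is multiplicatively
#' suppressed (event-related desynchronization, ERD); the pre-cue baseline is
#' untouched. Motor imagery (MI) uses `erd_depth_mi`/`lateralization_mi`,
#' passive movement (PM) the (weaker, less lateralized) PM parameters, and
#' rest has no suppression at all.
#'
#' Defaults mirror the recording conditions of the study the pipeline
#' models: 18 subjects of which 5 are poor performers, 80 epochs per
#' condition (40 per class), 3-s epochs spanning -1..2 s around the cue at
#' 1 kHz, and a 64-channel MEG-like montage (28 channels for EEG-like data).
#'
#' @param n_subjects number of subjects.
#' @param n_channels sensors per subject (64 = MEG-like, 28 = EEG-like).
#' @param modality `"MEG"` or `"EEG"` tag carried by the generated sets.
#' @param sfreq sampling frequency, Hz.
#' @param epoch_window `c(start, end)` seconds relative to the cue; the cue
#'   sits at t = 0 so `start < 0 < end`.
#' @param n_epochs_per_condition epochs per subject and condition.
#' @param class_balance fraction of left-hand (+1) epochs.
#' @param mu_freq,beta_freq SMR component frequencies, Hz.
#' @param erd_depth_mi,erd_depth_pm relative post-cue band-power suppression
#'   in `[0, 1]` on the contralateral source (0 = none, 1 = silenced).
#' @param lateralization_mi,lateralization_pm degree of contralaterality in
#'   `[0, 1]`: the ipsilateral source is suppressed by
#'   `depth * (1 - lateralization)`; 1 = fully contralateral. PM is
#'   modelled as less lateralized than MI.
#' @param pattern_jitter spread of the subject-specific spatial mixing
#'   around the group-level pattern (0 = identical subjects).
#' @param evoked_amp amplitude of the cue-locked lateralized oscillatory
#'   burst (a phase-locked ~8-Hz motor-related component peaking ~0.5 s
#'   after the cue, stronger contralaterally). This is what gives the
#'   *mean* post-cue time course class information; the ERD itself is a
#'   phase-random variance effect that only variance-based features (CSP
#'   log-power) can see. Scaled by the condition's ERD depth and the
#'   subject's performer quality, so `erd_depth = 0` silences it too.
#' @param sensor_noise_sd white sensor-noise standard deviation, in units of
#'   the (unit-RMS) 1/f background.
#' @param background_exponent spectral slope of the 1/f background.
#' @param n_low_quality number of subjects flagged as poor performers
#'   (reduced ERD gain, emulating weak SMR modulation).
#' @param seed master RNG seed; all per-subject/condition seeds are derived
#'   from it deterministically.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 18L,
                       n_channels = 64L,
                       modality = c("MEG", "EEG"),
                       sfreq = 1000,
                       epoch_window = c(-1, 2),
                       n_epochs_per_condition = 80L,
                       class_balance = 0.5,
                       mu_freq = 10,
                       beta_freq = 20,
                       erd_depth_mi = 0.75,
                       erd_depth_pm = 0.5,
                       lateralization_mi = 0.9,
                       lateralization_pm = 0.35,
                       pattern_jitter = 0.4,
                       evoked_amp = 3,
                       sensor_noise_sd = 0.5,
                       background_exponent = 1,
                       n_low_quality = 5L,
                       seed = 1L) {
  modality <- match.arg(modality)
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_channels = as.integer(n_channels), modality = modality,
              sfreq = sfreq, epoch_window = epoch_window,
              n_epochs_per_condition = as.integer(n_epochs_per_condition),
              class_balance = class_balance, mu_freq = mu_freq,
              beta_freq = beta_freq, erd_depth_mi = erd_depth_mi,
              erd_depth_pm = erd_depth_pm,
              lateralization_mi = lateralization_mi,
              lateralization_pm = lateralization_pm,
              pattern_jitter = pattern_jitter,
              evoked_amp = evoked_amp,
              sensor_noise_sd = sensor_noise_sd,
              background_exponent = background_exponent,
              n_low_quality = as.integer(n_low_quality),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fr <- c("class_balance", "erd_depth_mi", "erd_depth_pm",
          "lateralization_mi", "lateralization_pm")
  for (f in fr)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("sim_config: %s must lie in [0, 1]", f))
  if (cfg$n_subjects < 1L || cfg$n_channels < 1L)
    stop("sim_config: n_subjects and n_channels must be positive")
  if (cfg$sfreq <= 2 * (cfg$beta_freq + 2))
    stop("sim_config: sfreq must exceed twice the beta band edge")
  if (!(cfg$epoch_window[1L] < 0 && cfg$epoch_window[2L] > 0))
    stop("sim_config: epoch_window must straddle the cue at t = 0")
  if (cfg$n_low_quality >= cfg$n_subjects)
    stop("sim_config: n_low_quality must be smaller than n_subjects")
  if (cfg$n_epochs_per_condition < 2L)
    stop("sim_config: need at least 2 epochs per condition")
  if (cfg$pattern_jitter < 0 || cfg$sensor_noise_sd < 0)
    stop("sim_config: spreads must be non-negative")
  invisible(cfg)
}

# Six latent sources, ordered: mu-left, mu-right, beta-left, beta-right,
# evoked-left, evoked-right (odd indices = left hemisphere).
N_SOURCES <- 6L
source_freqs <- function(cfg) c(cfg$mu_freq, cfg$mu_freq,
                                cfg$beta_freq, cfg$beta_freq, NA, NA)

# cue-locked oscillatory burst: fixed phase, ~8 Hz carrier under a Gaussian
# envelope peaking 0.5 s post-cue; zero before the cue
evoked_waveform <- function(t, freq = 8) {
  ifelse(t >= 0, sin(2 * pi * freq * t) * exp(-((t - 0.5) / 0.3)^2), 0)
}

#' Draw per-subject generative profiles
#'
#' Each profile holds the subject-specific spatial mixing matrix (unit-norm
#' columns, drawn as group pattern + `pattern_jitter` * subject deviation),
#' per-source band amplitudes, and a `performer_quality` factor in `(0, 1]`
#' that scales the effective ERD depth. `n_low_quality` subjects (chosen
#' reproducibly from the seed) get a strongly reduced quality, emulating
#' participants with insufficient SMR modulation.
#'
#' @param cfg a [sim_config()].
#' @return A list of `subject_profile` objects of length `n_subjects`.
#' @export
make_profiles <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(derive_seed(cfg$seed, 1L), {
    C <- cfg$n_channels
    base <- matrix(stats::rnorm(C * N_SOURCES), C, N_SOURCES)
    low_ids <- sample.int(cfg$n_subjects, cfg$n_low_quality)
    lapply(seq_len(cfg$n_subjects), function(s) {
      M <- base + cfg$pattern_jitter * matrix(stats::rnorm(C * N_SOURCES), C, N_SOURCES)
      M <- sweep(M, 2L, sqrt(colSums(M^2)), "/")
      quality <- if (s %in% low_ids) stats::runif(1, 0.05, 0.25)
                 else stats::runif(1, 0.75, 1)
      amps <- c(stats::runif(2, 2.2, 3.0), stats::runif(2, 1.4, 2.0),
                rep(cfg$evoked_amp, 2))
      structure(list(subject_id = s, mixing_matrix = M,
                     source_band_powers = amps,
                     erd_gains = c(MI = cfg$erd_depth_mi * quality,
                                   PM = cfg$erd_depth_pm * quality,
                                   rest = 0),
                     performer_quality = quality,
                     low_quality = s %in% low_ids),
                class = "subject_profile")
    })
  })
}

# unit-RMS narrow-band Gaussian noise centred on `center` Hz
narrowband_noise <- function(n, sfreq, center, width = 1) {
  f <- (seq_len(n) - 1L) * sfreq / n
  f <- pmin(f, sfreq - f)                       # two-sided spectrum
  w <- exp(-0.5 * ((f - center) / (width / 2))^2)
  x <- Re(stats::fft(stats::fft(stats::rnorm(n)) * w, inverse = TRUE)) / n
  x / max(stats::sd(x), .Machine$double.eps)
}

# unit-RMS 1/f^a background noise for one or more channels (columns)
background_noise <- function(n, n_ch, exponent) {
  f <- (seq_len(n) - 1L)
  f <- pmin(f, n - f)
  amp <- c(0, 1 / pmax(f[-1L], 1)^(exponent / 2))
  X <- stats::mvfft(matrix(stats::rnorm(n * n_ch), n, n_ch)) * amp
  x <- Re(stats::mvfft(X, inverse = TRUE)) / n
  sweep(x, 2L, pmax(apply(x, 2L, stats::sd), .Machine$double.eps), "/")
}

#' Simulate one subject/condition epoch block
#'
#' Generates `n_epochs_per_condition` epochs of mixed narrow-band SMR
#' sources, 1/f background and sensor noise. For labelled conditions the
#' post-cue (t >= 0) amplitude of the hemisphere contralateral to the cued
#' hand is scaled by `sqrt(1 - depth)` so that its band *power* drops by the
#' configured ERD depth; the ipsilateral hemisphere is suppressed by
#' `depth * (1 - lateralization)`. Rest epochs carry balanced (meaningless)
#' labels and no suppression.
#'
#' @param profile a `subject_profile` from [make_profiles()].
#' @param cfg the [sim_config()] used to create the profile.
#' @param condition `"MI"`, `"PM"` or `"rest"`.
#' @return An [epoch_set()].
#' @export
simulate_subject <- function(profile, cfg, condition = c("MI", "PM", "rest")) {
  condition <- match.arg(condition)
  validate_sim_config(cfg)
  n_ep <- cfg$n_epochs_per_condition
  n <- round(diff(cfg$epoch_window) * cfg$sfreq)
  C <- cfg$n_channels
  t <- cfg$epoch_window[1L] + (seq_len(n) - 1L) / cfg$sfreq
  post <- t >= 0
  freqs <- source_freqs(cfg)
  lat <- switch(condition, MI = cfg$lateralization_mi,
                PM = cfg$lateralization_pm, rest = 0)
  depth <- unname(profile$erd_gains[[condition]])

  n_left <- round(n_ep * cfg$class_balance)
  cond_idx <- match(condition, c("MI", "PM", "rest"))
  with_seed(derive_seed(cfg$seed, 2L, profile$subject_id, cond_idx), {
    labels <- sample(c(rep(1L, n_left), rep(-1L, n_ep - n_left)))
    data <- array(0, dim = c(n_ep, C, n))
    M <- profile$mixing_matrix
    ev <- evoked_waveform(t)
    for (e in seq_len(n_ep)) {
      # suppression per source pair: even indices are the right hemisphere,
      # contralateral to a left-hand (+1) cue
      d <- rep(0, 4L)
      a_ev <- c(0, 0)                       # evoked amplitude (L, R)
      if (condition != "rest" && depth > 0) {
        contra <- if (labels[e] == 1L) c(2L, 4L) else c(1L, 3L)
        d[contra] <- depth
        d[setdiff(1:4, contra)] <- depth * (1 - lat)
        hemi_contra <- if (labels[e] == 1L) 2L else 1L
        a_ev[hemi_contra] <- depth
        a_ev[3L - hemi_contra] <- depth * (1 - lat)
      }
      S <- matrix(0, N_SOURCES, n)
      for (k in 1:4) {
        env <- ifelse(post, sqrt(1 - d[k]), 1)
        S[k, ] <- profile$source_band_powers[k] *
          narrowband_noise(n, cfg$sfreq, freqs[k]) * env
      }
      for (h in 1:2)
        S[4L + h, ] <- profile$source_band_powers[4L + h] * a_ev[h] *
          exp(stats::rnorm(1, 0, 0.2)) * ev
      bg <- t(background_noise(n, C, cfg$background_exponent))
      noise <- matrix(stats::rnorm(C * n, sd = cfg$sensor_noise_sd), C, n)
      data[e, , ] <- M %*% S + bg + noise
    }
    epoch_set(data, labels, condition, cfg$modality, profile$subject_id,
              cfg$sfreq, cfg$epoch_window[1L])
  })
}

#' Simulate the full multi-subject pool
#'
#' One MI, one PM and one rest [epoch_set()] per subject, drawn from a
#' consistent per-subject profile. Seeds are derived per subject and
#' condition from the master seed, so pools are bit-reproducible and the
#' three conditions are independent draws.
#'
#' @param cfg a [sim_config()].
#' @param conditions conditions to generate (default all three).
#' @return A list with elements `profiles`, `cfg`, and `subjects`; the
#'   latter is a list (one entry per subject) of named epoch sets.
#' @export
simulate_pool <- function(cfg, conditions = c("MI", "PM", "rest")) {
  profiles <- make_profiles(cfg)
  subjects <- lapply(profiles, function(p) {
    sets <- lapply(conditions, function(cond) simulate_subject(p, cfg, cond))
    names(sets) <- conditions
    sets
  })
  names(subjects) <- paste0("S", vapply(profiles, `[[`, 1L, "subject_id"))
  list(profiles = profiles, cfg = cfg, subjects = subjects)
}
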