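# Synthetic multi-subject sEMG + kinematics cohorts.
#
# Each trial is built from a closed-form joint-velocity waveform
# (raised-cosine twist pulses of alternating sign for pronation-supination;
# bipolar strike/return pulses for dart-throwing motion), integrated
# analytically to a joint angle.  Two latent muscle drives (agonist for
# positive velocity, antagonist for negative) lead the velocity by an
# electromechanical delay and are mixed into eight channels by a
# subject-specific mixing matrix.  The raw sEMG is that latent envelope
# amplitude-modulating band-limited (20-450 Hz) carrier noise plus
# additive sensor noise, so the rectify + low-pass envelope stage of the
# pipeline is genuinely exercised.  Inter-subject domain shift is modelled
# as electrode rotation, gain jitter and mixing perturbation.

N_EMG_CHANNELS <- 8L

#' Task kinematic profile
#'
#' Defaults reflect the two task families: pronation-supination (bulb,
#' screw) with a large velocity range, and dart-throwing motion (hammer,
#' cup) with a markedly smaller one.
#'
#' @param kind `"PS"` or `"DTM"`.
#' @param n_repetitions Number of movement repetitions per trial
#'   (protocol: 10).
#' @param cycle_frequency_hz Repetition rate; one pulse lasts
#'   `1 / cycle_frequency_hz` seconds.
#' @param velocity_amplitude_deg_s Peak joint velocity (deg/s).
#' @param rest_duration_s Rest before the first and after the last
#'   repetition.
#' @return An object of class `task_profile`.
#' @export
task_profile <- function(kind = c("PS", "DTM"), n_repetitions = 10L,
                         cycle_frequency_hz = NULL,
                         velocity_amplitude_deg_s = NULL,
                         rest_duration_s = 2) {
  kind <- match.arg(kind)
  cycle_frequency_hz <- cycle_frequency_hz %||%
    (if (kind == "PS") 0.5 else 1)
  velocity_amplitude_deg_s <- velocity_amplitude_deg_s %||%
    (if (kind == "PS") 150 else 60)
  assert_scalar_num(n_repetitions, "n_repetitions")
  assert_scalar_num(cycle_frequency_hz, "cycle_frequency_hz")
  assert_scalar_num(velocity_amplitude_deg_s, "velocity_amplitude_deg_s")
  if (!is.numeric(rest_duration_s) || rest_duration_s < 0)
    wv_stop("rest_duration_s must be non-negative")
  structure(list(kind = kind, n_repetitions = as.integer(n_repetitions),
                 cycle_frequency_hz = cycle_frequency_hz,
                 velocity_amplitude_deg_s = velocity_amplitude_deg_s,
                 rest_duration_s = rest_duration_s),
            class = "task_profile")
}

#' Default task profile for a named task
#' @param task_name One of `"bulb"`, `"screw"`, `"hammer"`, `"cup"`.
#' @param ... Overrides passed to [task_profile()].
#' @return A [task_profile()].
#' @export
default_task_profile <- function(task_name = VALID_TASKS, ...) {
  task_name <- match.arg(task_name)
  kind <- if (task_name %in% c("bulb", "screw")) "PS" else "DTM"
  task_profile(kind = kind, ...)
}

#' Trial duration implied by a task profile
#' @param task A [task_profile()].
#' @return Duration in seconds (rest + repetitions + rest).
#' @export
trial_duration_s <- function(task) {
  2 * task$rest_duration_s + task$n_repetitions / task$cycle_frequency_hz
}

# Closed-form joint velocity and its exact integral at times `t`.
task_waveform <- function(task, t) {
  Tp <- 1 / task$cycle_frequency_hz
  A <- task$velocity_amplitude_deg_s
  R <- task$n_repetitions
  u_all <- t - task$rest_duration_s
  j <- floor(u_all / Tp) + 1
  u <- u_all - (j - 1) * Tp
  active <- u_all >= 0 & j <= R
  completed <- pmax(0, pmin(j - 1, R))
  v <- numeric(length(t))
  if (task$kind == "PS") {
    sgn <- ifelse(j %% 2 == 1, 1, -1)
    pulse_v <- sgn * A * 0.5 * (1 - cos(2 * pi * u / Tp))
    partial <- sgn * A / 2 * (u - Tp / (2 * pi) * sin(2 * pi * u / Tp))
    base <- (completed %% 2) * A * Tp / 2
  } else {
    pulse_v <- A * sin(2 * pi * u / Tp)
    partial <- A * Tp / (2 * pi) * (1 - cos(2 * pi * u / Tp))
    base <- numeric(length(t))
  }
  v[active] <- pulse_v[active]
  th <- base
  th[active] <- base[active] + partial[active]
  list(velocity = v, angle = th)
}

#' Subject profile: how latent muscle drives appear on the electrodes
#'
#' @param mixing 8 x 2 non-degenerate matrix mapping the agonist and
#'   antagonist drives to the channels.
#' @param channel_gains Eight positive per-channel gains.
#' @param noise_sd Additive sensor-noise standard deviation (signal
#'   units; latent envelopes are O(1)).
#' @param electrode_rotation Accumulated integer channel rotation (set by
#'   [apply_domain_shift()]).
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(mixing, channel_gains = rep(1, N_EMG_CHANNELS),
                            noise_sd = 0.05, electrode_rotation = 0L) {
  mixing <- as.matrix(mixing)
  if (!all(dim(mixing) == c(N_EMG_CHANNELS, 2L)))
    wv_stop("mixing must be ", N_EMG_CHANNELS, " x 2")
  if (qr(mixing)$rank < 2L)
    wv_stop("mixing must have full column rank")
  if (length(channel_gains) != N_EMG_CHANNELS || any(channel_gains <= 0))
    wv_stop("channel_gains must be ", N_EMG_CHANNELS, " positive values")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    wv_stop("noise_sd must be non-negative")
  structure(list(mixing = mixing, channel_gains = as.numeric(channel_gains),
                 noise_sd = noise_sd,
                 electrode_rotation = as.integer(electrode_rotation)),
            class = "subject_profile")
}

#' Population template profile
#'
#' Channels are tuned around the forearm: channel `c` at angular position
#' `2*pi*(c-1)/8` responds to the agonist drive with a rectified cosine
#' tuning curve and to the antagonist with the opposite tuning, plus a
#' small common crosstalk floor.
#'
#' @param noise_sd Sensor-noise level for the template.
#' @return A [subject_profile()].
#' @export
template_subject_profile <- function(noise_sd = 0.05) {
  alpha <- 2 * pi * (seq_len(N_EMG_CHANNELS) - 1) / N_EMG_CHANNELS
  mixing <- cbind(pmax(cos(alpha), 0), pmax(-cos(alpha), 0)) + 0.05
  subject_profile(mixing, noise_sd = noise_sd)
}

#' Perturb a subject profile to emulate domain shift
#'
#' Electrode displacement is modelled as a channel rotation of
#' `round(2 * severity)` positions plus multiplicative gain jitter and an
#' additive mixing perturbation, all scaled by `severity`.  Severity 0 is
#' the identity.
#'
#' @param subject A [subject_profile()].
#' @param severity Shift severity in [0, 1].
#' @param seed Seed making the perturbation deterministic.
#' @return A perturbed [subject_profile()].
#' @export
apply_domain_shift <- function(subject, severity, seed = 1L) {
  stopifnot(inherits(subject, "subject_profile"))
  if (!is.numeric(severity) || severity < 0 || severity > 1)
    wv_stop("severity must lie in [0, 1]")
  with_seed(seed, {
    k <- as.integer(round(2 * severity))
    rot <- ((seq_len(N_EMG_CHANNELS) - 1L + k) %% N_EMG_CHANNELS) + 1L
    mixing <- subject$mixing[rot, , drop = FALSE]
    mixing <- mixing + matrix(rnorm(length(mixing), sd = 0.3 * severity),
                              nrow = N_EMG_CHANNELS)
    gains <- subject$channel_gains[rot] *
      exp(rnorm(N_EMG_CHANNELS, sd = 0.25 * severity))
    subject_profile(mixing, gains, subject$noise_sd,
                    subject$electrode_rotation + k)
  })
}

#' Cohort configuration
#'
#' @param n_subjects Number of subjects (study cohort: 24).
#' @param n_trials Trials per subject (study protocol: 3, one per table
#'   height).
#' @param task A [task_profile()]; defaults to the profile of
#'   `task_name`.
#' @param task_name Task label used in manifests.
#' @param sampling_rate_hz sEMG rate (study protocol: 2000 Hz).
#' @param mocap_rate_hz Motion-capture rate.
#' @param shift_severity Inter-subject dispersion and the extra shift
#'   applied to "new" subjects, in [0, 1].
#' @param new_subject_start 1-based subject index from which the extra
#'   domain shift is applied (`Inf` disables it).
#' @param activation_lead_s Electromechanical lead of muscle activation
#'   relative to joint velocity, seconds.
#' @param seed Master seed; fixes the whole cohort deterministically.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects, n_trials = 3L, task = NULL,
                          task_name = "bulb", sampling_rate_hz = 2000,
                          mocap_rate_hz = 100, shift_severity = 0.5,
                          new_subject_start = Inf,
                          activation_lead_s = 0.1, seed = 1L) {
  assert_scalar_num(n_subjects, "n_subjects")
  assert_scalar_num(n_trials, "n_trials")
  task <- task %||% default_task_profile(task_name)
  stopifnot(inherits(task, "task_profile"))
  if (!task_name %in% VALID_TASKS)
    wv_stop("task_name must be one of ", paste(VALID_TASKS, collapse = ", "))
  if (shift_severity < 0 || shift_severity > 1)
    wv_stop("shift_severity must lie in [0, 1]")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials), task = task,
                 task_name = task_name,
                 sampling_rate_hz = sampling_rate_hz,
                 mocap_rate_hz = mocap_rate_hz,
                 shift_severity = shift_severity,
                 new_subject_start = new_subject_start,
                 activation_lead_s = activation_lead_s,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate one trial of one subject
#'
#' @param subject A [subject_profile()].
#' @param task A [task_profile()].
#' @param cfg A [cohort_config()] (rates and activation lead).
#' @param trial_seed Seed for this trial's stochastic components
#'   (carrier and sensor noise, amplitude jitter).
#' @return A list with `emg` ([emg_recording()]), `angle`
#'   ([angle_series()] at the mocap rate), `velocity`
#'   ([velocity_series()] at the sEMG rate — the ground-truth labels),
#'   and `latent_envelope` (the noise-free per-channel drive envelopes).
#' @export
simulate_trial <- function(subject, task, cfg, trial_seed = 1L) {
  stopifnot(inherits(subject, "subject_profile"),
            inherits(task, "task_profile"),
            inherits(cfg, "cohort_config"))
  dur <- trial_duration_s(task)
  if (dur <= 0) wv_stop("non-positive trial duration")
  fs <- cfg$sampling_rate_hz
  n_emg <- round(dur * fs) + 1L
  t_emg <- (seq_len(n_emg) - 1) / fs
  n_mo <- round(dur * cfg$mocap_rate_hz) + 1L
  t_mo <- (seq_len(n_mo) - 1) / cfg$mocap_rate_hz
  wave <- task_waveform(task, t_emg)
  wave_mo <- task_waveform(task, t_mo)
  drive <- task_waveform(task, t_emg + cfg$activation_lead_s)$velocity /
    task$velocity_amplitude_deg_s
  act <- cbind(agonist = pmax(drive, 0), antagonist = pmax(-drive, 0))
  with_seed(trial_seed, {
    amp <- exp(rnorm(1, sd = 0.05))         # trial-to-trial vigour jitter
    env <- amp * (act %*% t(subject$mixing))
    env <- sweep(env, 2L, subject$channel_gains, `*`)
    bf <- signal::butter(2L, c(20, 450) / (fs / 2), type = "pass")
    carrier <- vapply(seq_len(N_EMG_CHANNELS), function(ch) {
      x <- as.numeric(signal::filter(bf, rnorm(n_emg)))
      x / stats::sd(x)
    }, numeric(n_emg))
    raw <- env * carrier +
      subject$noise_sd * matrix(rnorm(n_emg * N_EMG_CHANNELS), n_emg)
    list(emg = emg_recording(raw, fs),
         angle = angle_series(wave_mo$angle, cfg$mocap_rate_hz, task$kind),
         velocity = velocity_series(wave$velocity, fs, task$kind),
         latent_envelope = env)
  })
}

#' Draw the subject profiles and trial seeds of a cohort
#'
#' Subjects are drawn around the population template with dispersion
#' proportional to `shift_severity`; subjects at or beyond
#' `new_subject_start` additionally receive [apply_domain_shift()] to
#' play the "new subject" role.
#'
#' @param cfg A [cohort_config()].
#' @return List with `profiles` (per subject) and `trial_seeds`
#'   (n_subjects x n_trials integer matrix).
#' @export
draw_cohort_profiles <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  with_seed(cfg$seed, {
    template <- template_subject_profile()
    sev <- cfg$shift_severity
    profiles <- lapply(seq_len(cfg$n_subjects), function(s) {
      mixing <- template$mixing +
        matrix(rnorm(16, sd = 0.1 * sev), N_EMG_CHANNELS)
      gains <- exp(rnorm(N_EMG_CHANNELS, sd = 0.1 * sev))
      prof <- subject_profile(mixing, gains, template$noise_sd)
      if (s >= cfg$new_subject_start)
        prof <- apply_domain_shift(prof, sev,
                                   seed = sample.int(2147483646L, 1L))
      prof
    })
    trial_seeds <- matrix(sample.int(2147483646L,
                                     cfg$n_subjects * cfg$n_trials),
                          cfg$n_subjects, cfg$n_trials)
    list(profiles = profiles, trial_seeds = trial_seeds)
  })
}

# Marker positions realising a given angle series (synthetic convention
# matching the shipped angle presets): forearm fixed along z, hand segment
# of 80 mm rotating by the angle, fixed radial and ulnar references.
synthesize_markers <- function(angle, kind) {
  th <- angle * pi / 180
  n <- length(th)
  wrist <- c(0, 0, 300)
  hand <- if (kind == "PS") {
    cbind(80 * cos(th), 80 * sin(th), rep(0, n))
  } else {
    cbind(80 * sin(th), rep(0, n), 80 * cos(th))
  }
  pos <- array(0, c(n, 5L, 3L))
  pos[, 2, ] <- matrix(wrist, n, 3L, byrow = TRUE)
  pos[, 3, ] <- sweep(hand, 2L, wrist, `+`)
  pos[, 4, ] <- matrix(wrist + c(80, 0, 0), n, 3L, byrow = TRUE)
  pos[, 5, ] <- matrix(wrist + c(0, -80, 0), n, 3L, byrow = TRUE)
  pos
}

SYNTH_MARKERS <- c("elbow", "wrist", "hand", "ref_rad", "ref_uln")

#' Marker trajectory realising an angle series
#'
#' Uses the synthetic five-marker convention of the shipped angle presets,
#' so `vector_pair_angle(synthetic_markers(a), angle_preset(...))`
#' recovers `a`.
#'
#' @param angle An [angle_series()].
#' @return A [marker_trajectory()].
#' @export
synthetic_markers <- function(angle) {
  stopifnot(inherits(angle, "angle_series"))
  marker_trajectory(synthesize_markers(angle$angle_deg, angle$kind),
                    angle$frame_rate_hz, SYNTH_MARKERS)
}

#' Simulate a cohort and write it to disk
#'
#' Writes per-trial sEMG and marker CSV files plus a YAML manifest
#' compatible with [load_manifest()].  The same seed always reproduces
#' identical files.
#'
#' @param cfg A [cohort_config()].
#' @param out_dir Output directory (created if needed).
#' @return The [session_manifest()], invisibly written to
#'   `out_dir/manifest.yaml`.
#' @export
simulate_cohort <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "cohort_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) wv_stop("cannot create directory ", out_dir)
  drawn <- draw_cohort_profiles(cfg)
  heights <- c(78.5, 83.5, 88.5)
  rows <- list()
  for (s in seq_len(cfg$n_subjects)) {
    for (tr in seq_len(cfg$n_trials)) {
      trial <- simulate_trial(drawn$profiles[[s]], cfg$task, cfg,
                              trial_seed = drawn$trial_seeds[s, tr])
      stem <- sprintf("s%02d_t%d_%s", s, tr, cfg$task_name)
      emg_file <- file.path(out_dir, paste0(stem, "_emg.csv"))
      mrk_file <- file.path(out_dir, paste0(stem, "_markers.csv"))
      write_emg(trial$emg, emg_file)
      write_markers(synthetic_markers(trial$angle), mrk_file)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("s%02d", s), trial = tr, task = cfg$task_name,
        emg = basename(emg_file), markers = basename(mrk_file),
        height_cm = heights[min(tr, length(heights))],
        frame_rate_hz = cfg$mocap_rate_hz, stringsAsFactors = FALSE)
    }
  }
  entries <- do.call(rbind, rows)
  manifest_path <- file.path(out_dir, "manifest.yaml")
  man <- session_manifest(entries, check_paths = FALSE)
  write_manifest(man, manifest_path)
  entries$emg <- file.path(out_dir, entries$emg)
  entries$markers <- file.path(out_dir, entries$markers)
  invisible(session_manifest(entries, check_paths = TRUE))
}
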