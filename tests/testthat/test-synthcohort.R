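fast_task <- function(kind = "PS")
  task_profile(kind, n_repetitions = 2, rest_duration_s = 0.3)

test_that("trials are deterministic given the trial seed", {
  task <- fast_task()
  cfg <- cohort_config(n_subjects = 1, task = task, seed = 1)
  subj <- template_subject_profile()
  a <- simulate_trial(subj, task, cfg, trial_seed = 77)
  b <- simulate_trial(subj, task, cfg, trial_seed = 77)
  expect_identical(a$emg$samples, b$emg$samples)
  expect_identical(a$angle$angle_deg, b$angle$angle_deg)
  c <- simulate_trial(subj, task, cfg, trial_seed = 78)
  expect_false(identical(a$emg$samples, c$emg$samples))
})

test_that("the angle series integrates the velocity waveform", {
  task <- fast_task()
  cfg <- cohort_config(n_subjects = 1, task = task, seed = 2)
  sim <- simulate_trial(template_subject_profile(), task, cfg, 3)
  v <- sim$velocity$velocity_deg_s
  fs <- sim$velocity$sampling_rate_hz
  rebuilt <- cumtrapz_oracle(v, 1 / fs)
  # compare at the mocap frames
  stride <- fs / sim$angle$frame_rate_hz
  at <- 1 + stride * (seq_along(sim$angle$angle_deg) - 1)
  expect_lt(max(abs(rebuilt[at] - sim$angle$angle_deg)), 1e-3)
})

test_that("pronation-supination spans a larger velocity range than DTM", {
  cfg <- cohort_config(n_subjects = 1, task = fast_task(), seed = 4)
  ps <- simulate_trial(template_subject_profile(), fast_task("PS"), cfg, 9)
  dtm <- simulate_trial(template_subject_profile(), fast_task("DTM"), cfg, 9)
  expect_gt(diff(range(ps$velocity$velocity_deg_s)),
            diff(range(dtm$velocity$velocity_deg_s)))
})

test_that("a linear decoder recovers velocity from noise-free envelopes", {
  task <- task_profile("PS", n_repetitions = 3, rest_duration_s = 0.5)
  cfg <- cohort_config(n_subjects = 1, task = task, seed = 6)
  subj <- template_subject_profile(noise_sd = 0)
  sim <- simulate_trial(subj, task, cfg, 13)
  env <- compute_envelope(sim$emg)
  df <- as.data.frame(env$values)
  df$y <- sim$velocity$velocity_deg_s
  fit <- lm(y ~ ., df)
  expect_gt(cor(fitted(fit), df$y), 0.95)
})

test_that("domain shift is the identity at severity zero and grows with it", {
  subj <- template_subject_profile()
  same <- apply_domain_shift(subj, 0, seed = 5)
  expect_identical(same$mixing, subj$mixing)
  expect_identical(same$channel_gains, subj$channel_gains)

  s1 <- apply_domain_shift(subj, 1, seed = 5)
  s1b <- apply_domain_shift(subj, 1, seed = 5)
  expect_identical(s1$mixing, s1b$mixing)

  frob <- function(sev) {
    mean(vapply(1:20, function(sd_) {
      sh <- apply_domain_shift(subj, sev, seed = sd_)
      sqrt(sum((sh$mixing - subj$mixing)^2))
    }, numeric(1)))
  }
  d <- vapply(c(0.2, 0.5, 1), frob, numeric(1))
  expect_true(all(diff(d) > 0))
  expect_error(apply_domain_shift(subj, 1.5), "\\[0, 1\\]")
})

test_that("shifted subjects degrade a decoder fitted on the template", {
  # the premise that makes quick training demonstrable: averaged over
  # seeds, a linear decoder fitted on template-profile data has higher
  # RMSE on severity-0.5 shifted subjects than on held-out template data
  task <- fast_task()
  deltas <- vapply(1:3, function(seed) {
    cfg <- cohort_config(n_subjects = 1, task = task, seed = seed)
    subj <- template_subject_profile()
    fit_trial <- simulate_trial(subj, task, cfg, 100 + seed)
    held_out <- simulate_trial(subj, task, cfg, 200 + seed)
    shifted_subj <- apply_domain_shift(subj, 0.5, seed = seed)
    shifted <- simulate_trial(shifted_subj, task, cfg, 300 + seed)
    df <- function(sim) {
      d <- as.data.frame(compute_envelope(sim$emg)$values)
      d$y <- sim$velocity$velocity_deg_s
      d
    }
    fit <- lm(y ~ ., df(fit_trial))
    rmse_on <- function(sim) {
      d <- df(sim)
      sqrt(mean((predict(fit, d) - d$y)^2))
    }
    rmse_on(shifted) - rmse_on(held_out)
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("cohort generation is reproducible and round-trips through IO", {
  task <- fast_task()
  cfg <- cohort_config(n_subjects = 2, n_trials = 2, task = task,
                       task_name = "hammer", shift_severity = 0.3,
                       new_subject_start = 2, seed = 42)
  d1 <- file.path(tempdir(), "cohort1")
  d2 <- file.path(tempdir(), "cohort2")
  man1 <- simulate_cohort(cfg, d1)
  man2 <- simulate_cohort(cfg, d2)
  expect_equal(nrow(man1$entries), 4L)
  expect_identical(readLines(man1$entries$emg[1]),
                   readLines(man2$entries$emg[1]))

  man <- load_manifest(file.path(d1, "manifest.yaml"))
  e <- man$entries[1, ]
  rec <- read_emg(e$emg, 2000)
  expect_equal(ncol(rec$samples), 8L)
  traj <- read_markers(e$markers, e$frame_rate_hz)
  expect_equal(dim(traj$positions)[2], 5L)
  ang <- vector_pair_angle(traj, angle_preset("dtm_default"))
  expect_true(all(is.finite(ang$angle_deg)))
})

test_that("zero dispersion yields identical cohort profiles", {
  cfg <- cohort_config(n_subjects = 3, task = fast_task(),
                       shift_severity = 0, seed = 9)
  drawn <- draw_cohort_profiles(cfg)
  expect_identical(drawn$profiles[[1]]$mixing, drawn$profiles[[2]]$mixing)
  expect_identical(drawn$profiles[[2]]$channel_gains,
                   drawn$profiles[[3]]$channel_gains)
})
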