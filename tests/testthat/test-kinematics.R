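make_traj <- function(vecs_a, vecs_b, extra = NULL) {
  # frames x markers x 3 with markers: origin, a-tip, b-tip (+ optional ref)
  n <- nrow(vecs_a)
  k <- 3L + as.integer(!is.null(extra))
  pos <- array(0, c(n, k, 3L))
  pos[, 2L, ] <- vecs_a
  pos[, 3L, ] <- vecs_b
  if (!is.null(extra)) pos[, 4L, ] <- extra
  marker_trajectory(pos, 100, c("o", "a", "b", "r")[seq_len(k)])
}

pair_spec <- function(...) vector_pair_spec(c("o", "a"), c("o", "b"), ...)

test_that("vector pair angles match closed forms", {
  one <- function(a, b) {
    traj <- make_traj(matrix(a, 1), matrix(b, 1))
    vector_pair_angle(traj, pair_spec())$angle_deg
  }
  expect_equal(one(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(one(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(one(c(1, 0, 0), c(1, 1, 0)), 45)
})

test_that("angles are invariant to translation, scaling and rotation", {
  set.seed(5)
  a <- matrix(rnorm(30), 10)
  b <- matrix(rnorm(30), 10)
  base <- vector_pair_angle(make_traj(a, b), pair_spec())$angle_deg

  shift <- matrix(rnorm(3), 10, 3, byrow = TRUE)
  traj2 <- make_traj(a + shift, b + shift)
  traj2$positions[, 1, ] <- shift
  expect_equal(vector_pair_angle(traj2, pair_spec())$angle_deg, base)

  expect_equal(vector_pair_angle(make_traj(3.7 * a, 3.7 * b),
                                 pair_spec())$angle_deg, base)

  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3)
  expect_equal(vector_pair_angle(make_traj(a %*% R, b %*% R),
                                 pair_spec())$angle_deg, base)
})

test_that("degenerate vectors and unknown markers are rejected", {
  a <- rbind(c(1, 0, 0), c(0, 0, 0))
  b <- rbind(c(0, 1, 0), c(0, 1, 0))
  expect_error(vector_pair_angle(make_traj(a, b), pair_spec()),
               "frame 2")
  expect_error(
    vector_pair_angle(make_traj(a, b),
                      vector_pair_spec(c("o", "nope"), c("o", "b"))),
    "unknown marker")
})

test_that("signed angles follow the sign reference", {
  th <- c(30, -40) * pi / 180
  a <- cbind(cos(th), sin(th), 0)
  b <- matrix(c(1, 0, 0), 2, 3, byrow = TRUE)
  ref <- matrix(c(0, 0, -1), 2, 3, byrow = TRUE)
  traj <- make_traj(a, b, extra = ref)
  got <- vector_pair_angle(traj, pair_spec(sign_reference = c("o", "r")))
  expect_equal(got$angle_deg, c(30, -40))
})

test_that("resampling interpolates linearly and preserves endpoints", {
  s <- angle_series(c(0, 10), 1, "PS")
  r <- resample_to(s, 2)
  expect_equal(r$angle_deg, c(0, 5, 10))

  ramp <- angle_series(seq(0, 20, length.out = 11), 10, "PS")
  up <- resample_to(ramp, 35)
  t_up <- (seq_along(up$angle_deg) - 1) / 35
  expect_equal(up$angle_deg, 20 * t_up, tolerance = 1e-12)
  expect_identical(resample_to(ramp, 10), ramp)
  expect_error(resample_to(angle_series(1, 10, "PS"), 5), "2 points")
})

test_that("differentiation matches closed forms", {
  fs <- 2000
  ramp <- angle_series(10 * (0:999) / fs, fs, "PS")
  v <- differentiate(ramp)
  expect_equal(v$velocity_deg_s[2:999], rep(10, 998), tolerance = 1e-9)

  const <- differentiate(angle_series(rep(3, 100), 100, "DTM"))
  expect_true(all(const$velocity_deg_s == 0))

  f <- 1; A <- 30; fr <- 1000
  t <- (0:2999) / fr
  v2 <- differentiate(angle_series(A * sin(2 * pi * f * t), fr, "PS"))
  expect_lt(abs(max(abs(v2$velocity_deg_s)) - 2 * pi * f * A) /
              (2 * pi * f * A), 0.01)
  expect_error(differentiate(angle_series(c(1, 2), 10, "PS")), "3 points")
})

test_that("integrating the computed velocity recovers the angle", {
  f <- 1; A <- 30
  err_at <- function(fr) {
    t <- seq(0, 2, by = 1 / fr)
    th <- A * sin(2 * pi * f * t)
    v <- differentiate(angle_series(th, fr, "PS"))
    rebuilt <- th[1] + cumtrapz_oracle(v$velocity_deg_s, 1 / fr)
    max(abs(rebuilt - th))
  }
  expect_lt(err_at(500), 0.05)
  expect_lt(err_at(1000), err_at(500))
})

test_that("label alignment matches the envelope timeline", {
  env <- envelope_series(matrix(0, 2001, 2), 2000)  # 1 s
  vel <- velocity_series(seq(0, 50, length.out = 101), 100, "PS")  # 1 s
  out <- align_labels(vel, env)
  expect_equal(length(out$velocity_deg_s), 2001L)
  expect_equal(out$sampling_rate_hz, 2000)
  expect_equal(out$velocity_deg_s[c(1, 2001)], c(0, 50))

  const <- align_labels(velocity_series(rep(7, 101), 100, "PS"), env)
  expect_true(all(const$velocity_deg_s == 7))

  long <- velocity_series(rep(0, 121), 100, "PS")  # 1.2 s vs 1 s
  expect_error(align_labels(long, env), "durations differ")
})

test_that("shipped presets decode the synthetic marker convention", {
  task <- task_profile("PS", n_repetitions = 2, rest_duration_s = 0.2)
  cfg <- cohort_config(n_subjects = 1, task = task, seed = 3)
  sim <- simulate_trial(template_subject_profile(), task, cfg, 5)
  traj <- synthetic_markers(sim$angle)
  got <- vector_pair_angle(traj, angle_preset("ps_default"))
  expect_equal(got$angle_deg, sim$angle$angle_deg, tolerance = 1e-8)

  task_d <- task_profile("DTM", n_repetitions = 2, rest_duration_s = 0.2)
  sim_d <- simulate_trial(template_subject_profile(), task_d,
                          cohort_config(n_subjects = 1, task = task_d,
                                        seed = 3), 5)
  got_d <- vector_pair_angle(synthetic_markers(sim_d$angle),
                             angle_preset("dtm_default"))
  expect_equal(got_d$angle_deg, sim_d$angle$angle_deg, tolerance = 1e-8)
})
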