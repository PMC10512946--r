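# Shared fixture builders; everything is generated in code at test time.

# A tiny architecture that keeps unit tests fast.
tiny_spec <- function(depth = 1L, residual_period = 3L)
  regressor_spec(depth = depth, kernel_sizes = c(4L, 3L, 2L),
                 n_filters = 2L, bottleneck_size = 2L,
                 residual_period = residual_period)

random_window_set <- function(n = 8L, len = 20L, channels = 2L, seed = 1L) {
  set.seed(seed)
  window_set(array(rnorm(n * len * channels), c(n, len, channels)),
             rnorm(n))
}

# An in-memory manifest of n subjects x 3 trials for one task; paths are
# placeholders (not validated).
fake_manifest <- function(n_subjects, task = "bulb") {
  entries <- expand.grid(trial = 1:3,
                         subject_id = sprintf("s%02d", seq_len(n_subjects)),
                         stringsAsFactors = FALSE)
  entries$task <- task
  entries$emg <- sprintf("%s_t%d_emg.csv", entries$subject_id, entries$trial)
  entries$markers <- sprintf("%s_t%d_markers.csv", entries$subject_id,
                             entries$trial)
  entries$height_cm <- c(78.5, 83.5, 88.5)[entries$trial]
  session_manifest(entries)
}

write_csv_lines <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# Trapezoidal cumulative integral (independent oracle for kinematics).
cumtrapz_oracle <- function(y, dt) {
  c(0, cumsum((utils::head(y, -1) + utils::tail(y, -1)) / 2 * dt))
}
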