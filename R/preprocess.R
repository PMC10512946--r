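# Envelope extraction and sliding-window feature generation.
#
# Raw sEMG is (optionally) full-wave rectified and low-pass filtered with a
# causal first-order Butterworth filter (1 Hz default), standardised with a
# scaler fitted on the pre-training corpus only, and cut into fixed-length
# overlapping windows (250 samples / 125 ms at 2000 Hz, overlap 240).

#' Preprocessing configuration
#'
#' @param cutoff_hz Low-pass cutoff of the envelope filter in Hz.
#' @param filter_order Butterworth filter order.
#' @param window_len Window length in samples.
#' @param overlap Overlap between consecutive windows in samples; the
#'   stride is `window_len - overlap`.
#' @param rectify Full-wave rectify before filtering.  On zero-mean raw
#'   sEMG a 1 Hz low-pass alone annihilates the signal, so rectification
#'   is the default; disable it to filter the raw signal literally.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(cutoff_hz = 1, filter_order = 1L,
                              window_len = 250L, overlap = 240L,
                              rectify = TRUE) {
  assert_scalar_num(cutoff_hz, "cutoff_hz")
  assert_scalar_num(filter_order, "filter_order")
  assert_scalar_num(window_len, "window_len")
  if (!is.numeric(overlap) || length(overlap) != 1L || overlap < 0)
    wv_stop("'overlap' must be a single non-negative number")
  window_len <- as.integer(window_len); overlap <- as.integer(overlap)
  if (overlap >= window_len)
    wv_stop("overlap (", overlap, ") must be smaller than window_len (",
            window_len, ")")
  structure(list(cutoff_hz = cutoff_hz,
                 filter_order = as.integer(filter_order),
                 window_len = window_len, overlap = overlap,
                 rectify = isTRUE(rectify)),
            class = "preprocess_config")
}

#' Window duration in milliseconds
#'
#' Under the default configuration (250-sample windows at 2000 Hz) this
#' is 125 ms.
#'
#' @param cfg A [preprocess_config()].
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return Duration of one window in milliseconds.
#' @export
window_duration_ms <- function(cfg, sampling_rate_hz) {
  assert_scalar_num(sampling_rate_hz, "sampling_rate_hz")
  cfg$window_len / sampling_rate_hz * 1000
}

#' Extract the sEMG envelope
#'
#' Per channel: optional full-wave rectification followed by a causal
#' (forward-only, zero initial state) Butterworth low-pass realised with
#' the bilinear transform.  The filter has unit DC gain and preserves the
#' input length.
#'
#' @param rec An [emg_recording()].
#' @param cfg A [preprocess_config()].
#' @return An object of class `envelope_series` with fields `values`
#'   (n_samples x n_channels, non-negative when rectifying) and
#'   `sampling_rate_hz`.
#' @export
compute_envelope <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "emg_recording"))
  fs <- rec$sampling_rate_hz
  if (cfg$cutoff_hz >= fs / 2)
    wv_stop("cutoff_hz (", cfg$cutoff_hz, ") must be below the Nyquist rate (",
            fs / 2, ")")
  x <- rec$samples
  if (nrow(x) == 0L) wv_stop("empty recording")
  if (cfg$rectify) x <- abs(x)
  bf <- signal::butter(cfg$filter_order, cfg$cutoff_hz / (fs / 2),
                       type = "low")
  out <- apply(x, 2L, function(col) signal::filter(bf, col))
  out <- matrix(as.numeric(out), nrow = nrow(x))
  envelope_series(out, fs)
}

#' Construct an envelope series
#'
#' @param values Numeric matrix (n_samples x n_channels).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return An object of class `envelope_series`.
#' @export
envelope_series <- function(values, sampling_rate_hz) {
  values <- as.matrix(values)
  assert_scalar_num(sampling_rate_hz, "sampling_rate_hz")
  structure(list(values = values, sampling_rate_hz = sampling_rate_hz),
            class = "envelope_series")
}

#' @export
print.envelope_series <- function(x, ...) {
  cat(sprintf("<envelope_series> %d samples x %d channels @ %g Hz\n",
              nrow(x$values), ncol(x$values), x$sampling_rate_hz))
  invisible(x)
}

#' Fit a per-channel standardising scaler
#'
#' Statistics (mean and standard deviation per channel) are computed over
#' the concatenation of the supplied series only — in the study protocol
#' this is the pre-training group, and the same frozen scaler is then
#' applied to the model-selection, quick-training and test groups.
#'
#' @param envs A single `envelope_series` or a list of them, all with the
#'   same channel count.
#' @return An object of class `channel_scaler` with fields `center` and
#'   `scale`.
#' @export
fit_scaler <- function(envs) {
  if (inherits(envs, "envelope_series")) envs <- list(envs)
  if (!length(envs)) wv_stop("fit_scaler: empty collection")
  ncols <- vapply(envs, function(e) ncol(e$values), integer(1))
  if (length(unique(ncols)) != 1L)
    wv_stop("fit_scaler: series have differing channel counts")
  all_values <- do.call(rbind, lapply(envs, `[[`, "values"))
  center <- colMeans(all_values)
  scale <- apply(all_values, 2L, stats::sd)
  zero <- which(scale <= .Machine$double.eps)
  if (length(zero))
    wv_stop("fit_scaler: zero-variance channel(s): ",
            paste(zero, collapse = ", "))
  structure(list(center = center, scale = scale, n_channels = ncols[1L]),
            class = "channel_scaler")
}

#' Apply a fitted scaler
#'
#' @param env An `envelope_series`.
#' @param sc A [fit_scaler()] result.
#' @param invert Undo the standardisation instead of applying it.
#' @return A standardised `envelope_series` of the same shape.
#' @export
apply_scaler <- function(env, sc, invert = FALSE) {
  stopifnot(inherits(env, "envelope_series"), inherits(sc, "channel_scaler"))
  if (ncol(env$values) != sc$n_channels)
    wv_stop("apply_scaler: scaler was fitted on ", sc$n_channels,
            " channels but the series has ", ncol(env$values))
  v <- if (invert) {
    sweep(sweep(env$values, 2L, sc$scale, `*`), 2L, sc$center, `+`)
  } else {
    sweep(sweep(env$values, 2L, sc$center, `-`), 2L, sc$scale, `/`)
  }
  envelope_series(v, env$sampling_rate_hz)
}

#' Cut an envelope series into overlapping labelled windows
#'
#' Windows are contiguous sample slices of length `window_len` taken every
#' `window_len - overlap` samples.  Each window is labelled with the joint
#' velocity at its final sample (causal convention: the controller outputs
#' the velocity for "now" from the immediately preceding 125 ms of sEMG).
#'
#' @param env An `envelope_series` (n_samples x n_channels).
#' @param labels A `velocity_series` (see [differentiate()]) or a numeric
#'   vector time-aligned to `env` at the same rate.
#' @param cfg A [preprocess_config()].
#' @param subject,trial Optional provenance recorded on the window set.
#' @return An object of class `window_set` with fields `features`
#'   (n_windows x window_len x n_channels), `labels` (deg/s) and
#'   `window_end_times_s`.
#' @export
slide_windows <- function(env, labels, cfg = preprocess_config(),
                          subject = NULL, trial = NULL) {
  stopifnot(inherits(env, "envelope_series"))
  lab <- if (inherits(labels, "velocity_series")) labels$velocity_deg_s
         else as.numeric(labels)
  n <- nrow(env$values)
  if (length(lab) != n)
    wv_stop("slide_windows: labels (", length(lab),
            ") are not aligned with the envelope (", n, " samples)")
  if (any(!is.finite(lab))) wv_stop("slide_windows: non-finite labels")
  wl <- cfg$window_len
  stride <- wl - cfg$overlap
  if (n < wl)
    wv_stop("slide_windows: series of ", n,
            " samples is shorter than one window (", wl, ")")
  n_win <- (n - wl) %/% stride + 1L
  starts <- 1L + stride * (seq_len(n_win) - 1L)
  feats <- array(0, c(n_win, wl, ncol(env$values)))
  for (w in seq_len(n_win))
    feats[w, , ] <- env$values[starts[w]:(starts[w] + wl - 1L), ]
  ends <- starts + wl - 1L
  window_set(feats, lab[ends], ends / env$sampling_rate_hz,
             subject = subject, trial = trial)
}

#' Construct a window set
#'
#' @param features Array `(n_windows, window_len, n_channels)`.
#' @param labels Numeric vector of joint velocities (deg/s), one per
#'   window.
#' @param window_end_times_s End time of each window in seconds.
#' @param subject,trial Optional per-window provenance (scalar or vector).
#' @return An object of class `window_set`.
#' @export
window_set <- function(features, labels, window_end_times_s = NULL,
                       subject = NULL, trial = NULL) {
  if (length(dim(features)) != 3L)
    wv_stop("features must be a 3-D array (windows, samples, channels)")
  n <- dim(features)[1]
  if (length(labels) != n)
    wv_stop("labels length does not match the number of windows")
  if (any(!is.finite(labels))) wv_stop("window labels must be finite")
  expand <- function(x) {
    if (is.null(x)) return(NULL)
    if (length(x) == 1L) rep(x, n) else if (length(x) == n) x
    else wv_stop("subject/trial metadata length mismatch")
  }
  structure(list(features = features, labels = as.numeric(labels),
                 window_end_times_s = window_end_times_s %||%
                   as.numeric(seq_len(n)),
                 subject = expand(subject), trial = expand(trial)),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$features)
  cat(sprintf("<window_set> %d windows of shape (%d, %d)%s\n", d[1], d[2], d[3],
              if (!is.null(x$subject))
                paste0(", subjects: ",
                       paste(unique(x$subject), collapse = ", "))
              else ""))
  invisible(x)
}

#' Number of windows in a window set
#' @param ws A [window_set()].
#' @return Integer count.
#' @export
n_windows <- function(ws) dim(ws$features)[1]

#' Concatenate window sets
#'
#' @param sets List of [window_set()] objects with identical window shape.
#' @return A single pooled `window_set` preserving per-window provenance.
#' @export
bind_window_sets <- function(sets) {
  stopifnot(length(sets) > 0L)
  if (length(sets) == 1L) return(sets[[1L]])
  d <- dim(sets[[1L]]$features)
  for (s in sets)
    if (!all(dim(s$features)[2:3] == d[2:3]))
      wv_stop("bind_window_sets: incompatible window shapes")
  total <- sum(vapply(sets, n_windows, integer(1)))
  feats <- array(0, c(total, d[2], d[3]))
  at <- 0L
  for (s in sets) {
    k <- n_windows(s)
    if (k > 0L) feats[(at + 1L):(at + k), , ] <- s$features
    at <- at + k
  }
  grab <- function(field) {
    vals <- lapply(sets, function(s) s[[field]] %||% rep(NA, n_windows(s)))
    out <- unlist(vals, use.names = FALSE)
    if (all(is.na(out))) NULL else out
  }
  window_set(feats, unlist(lapply(sets, `[[`, "labels")),
             unlist(lapply(sets, `[[`, "window_end_times_s")),
             subject = grab("subject"), trial = grab("trial"))
}

#' Persist a window set to a single-file container
#'
#' @param ws A [window_set()].
#' @param path Output path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_window_set <- function(ws, path) {
  stopifnot(inherits(ws, "window_set"))
  saveRDS(ws, path)
  invisible(path)
}

#' @rdname save_window_set
#' @export
load_window_set <- function(path) {
  if (!file.exists(path)) wv_stop("window-set file not found: ", path)
  ws <- readRDS(path)
  if (!inherits(ws, "window_set")) wv_stop(path, " is not a saved window set")
  ws
}
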