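# Joint angles from motion-capture markers, differentiation to angular
# velocity, and alignment of velocity labels to the sEMG timeline.
#
# Angles are measured between two marker-defined vectors, optionally after
# projection onto a plane; the exact marker construction is configurable
# because conventions differ between laboratories.  The shipped presets
# ("ps_default", "dtm_default") assume the synthetic marker set written by
# `simulate_cohort()` (markers: elbow, wrist, hand, ref_rad, ref_uln).

#' Specify an angle as a pair of marker vectors
#'
#' @param vector_a,vector_b Character pairs `c(from, to)` of marker names.
#' @param projection_plane_normal Optional `c(from, to)` pair; both
#'   vectors are projected onto the plane orthogonal to this direction
#'   before the angle is measured.
#' @param sign_reference Optional `c(from, to)` pair; when given, the
#'   angle is signed in (-180, 180] with sign `sign((a x b) . ref)`,
#'   otherwise unsigned in [0, 180].
#' @param kind Either `"PS"` (pronation-supination) or `"DTM"`
#'   (dart-throwing motion).
#' @return An object of class `vector_pair_spec`.
#' @export
vector_pair_spec <- function(vector_a, vector_b,
                             projection_plane_normal = NULL,
                             sign_reference = NULL,
                             kind = c("PS", "DTM")) {
  kind <- match.arg(kind)
  chk <- function(x, name) {
    if (!is.character(x) || length(x) != 2L)
      wv_stop("'", name, "' must be a character pair c(from, to)")
    x
  }
  chk(vector_a, "vector_a"); chk(vector_b, "vector_b")
  if (!is.null(projection_plane_normal))
    chk(projection_plane_normal, "projection_plane_normal")
  if (!is.null(sign_reference)) chk(sign_reference, "sign_reference")
  structure(list(vector_a = vector_a, vector_b = vector_b,
                 projection_plane_normal = projection_plane_normal,
                 sign_reference = sign_reference, kind = kind),
            class = "vector_pair_spec")
}

#' Shipped angle conventions
#'
#' `"ps_default"`: hand vector against a forearm-fixed radial reference,
#' both projected onto the plane normal to the forearm long axis, signed
#' about that axis.  `"dtm_default"`: hand long axis against the forearm
#' long axis, signed towards the ulnar reference.  These are conventions
#' for the synthetic marker set, not study facts.
#'
#' @param name Preset name.
#' @return A [vector_pair_spec()].
#' @export
angle_preset <- function(name = c("ps_default", "dtm_default")) {
  name <- match.arg(name)
  switch(name,
    ps_default = vector_pair_spec(
      vector_a = c("wrist", "hand"),
      vector_b = c("wrist", "ref_rad"),
      projection_plane_normal = c("elbow", "wrist"),
      sign_reference = c("wrist", "elbow"),
      kind = "PS"),
    dtm_default = vector_pair_spec(
      vector_a = c("wrist", "hand"),
      vector_b = c("elbow", "wrist"),
      sign_reference = c("wrist", "ref_uln"),
      kind = "DTM"))
}

marker_index <- function(traj, name) {
  i <- match(name, traj$marker_names)
  if (is.na(i)) wv_stop("unknown marker '", name, "'; trajectory has: ",
                        paste(traj$marker_names, collapse = ", "))
  i
}

marker_vec <- function(traj, pair) {
  from <- traj$positions[, marker_index(traj, pair[1L]), , drop = FALSE]
  to <- traj$positions[, marker_index(traj, pair[2L]), , drop = FALSE]
  matrix(to - from, ncol = 3L)
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Angle between two marker-defined vectors, per frame
#'
#' The angle is computed as `atan2(|a x b|, a . b)` in degrees, which is
#' numerically stable for near-parallel vectors; translation, uniform
#' scaling and whole-set rotation of the markers leave it unchanged.
#'
#' @param traj A [marker_trajectory()].
#' @param spec A [vector_pair_spec()].
#' @return An object of class `angle_series` with fields `angle_deg`,
#'   `frame_rate_hz` and `kind`.
#' @export
vector_pair_angle <- function(traj, spec) {
  stopifnot(inherits(traj, "marker_trajectory"),
            inherits(spec, "vector_pair_spec"))
  a <- marker_vec(traj, spec$vector_a)
  b <- marker_vec(traj, spec$vector_b)
  if (!is.null(spec$projection_plane_normal)) {
    nrm <- marker_vec(traj, spec$projection_plane_normal)
    nn <- sqrt(rowSums(nrm^2))
    bad <- which(nn == 0)
    if (length(bad))
      wv_stop("zero-length plane normal at frame ", bad[1L])
    nrm <- nrm / nn
    a <- a - rowSums(a * nrm) * nrm
    b <- b - rowSums(b * nrm) * nrm
  }
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  bad <- which(na == 0 | nb == 0)
  if (length(bad))
    wv_stop("zero-length vector at frame ", bad[1L],
            "; angle is undefined there")
  cr <- row_cross(a, b)
  ang <- atan2(sqrt(rowSums(cr^2)), rowSums(a * b)) * 180 / pi
  if (!is.null(spec$sign_reference)) {
    ref <- marker_vec(traj, spec$sign_reference)
    s <- sign(rowSums(cr * ref))
    s[s == 0] <- 1
    ang <- ang * s
  }
  angle_series(ang, traj$frame_rate_hz, spec$kind)
}

#' Construct an angle series
#'
#' @param angle_deg Numeric vector of joint angles in degrees.
#' @param frame_rate_hz Frame rate in Hz.
#' @param kind `"PS"` or `"DTM"`.
#' @return An object of class `angle_series`.
#' @export
angle_series <- function(angle_deg, frame_rate_hz, kind = c("PS", "DTM")) {
  kind <- match.arg(kind)
  assert_scalar_num(frame_rate_hz, "frame_rate_hz")
  if (any(!is.finite(angle_deg))) wv_stop("angle series must be finite")
  structure(list(angle_deg = as.numeric(angle_deg),
                 frame_rate_hz = frame_rate_hz, kind = kind),
            class = "angle_series")
}

#' Construct a velocity series
#'
#' @param velocity_deg_s Numeric vector of joint velocities in deg/s.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param kind `"PS"` or `"DTM"`.
#' @return An object of class `velocity_series`.
#' @export
velocity_series <- function(velocity_deg_s, sampling_rate_hz,
                            kind = c("PS", "DTM")) {
  kind <- match.arg(kind)
  assert_scalar_num(sampling_rate_hz, "sampling_rate_hz")
  if (any(!is.finite(velocity_deg_s)))
    wv_stop("velocity series must be finite")
  structure(list(velocity_deg_s = as.numeric(velocity_deg_s),
                 sampling_rate_hz = sampling_rate_hz, kind = kind),
            class = "velocity_series")
}

#' Resample an angle series by linear interpolation
#'
#' The output is a uniform timeline at `target_rate_hz` spanning the same
#' duration; both endpoints are preserved.  Linear interpolation is exact
#' on affine signals.
#'
#' @param series An [angle_series()].
#' @param target_rate_hz Target rate in Hz.
#' @return An [angle_series()] at the new rate.
#' @export
resample_to <- function(series, target_rate_hz) {
  stopifnot(inherits(series, "angle_series"))
  assert_scalar_num(target_rate_hz, "target_rate_hz")
  n <- length(series$angle_deg)
  if (n < 2L) wv_stop("resample_to: need at least 2 points")
  if (target_rate_hz == series$frame_rate_hz) return(series)
  dur <- (n - 1) / series$frame_rate_hz
  m <- round(dur * target_rate_hz) + 1L
  t_new <- seq(0, dur, length.out = m)
  t_old <- (seq_len(n) - 1) / series$frame_rate_hz
  y <- stats::approx(t_old, series$angle_deg, xout = t_new)$y
  angle_series(y, target_rate_hz, series$kind)
}

#' Differentiate an angle series to angular velocity
#'
#' Central differences in the interior, one-sided differences at the two
#' endpoints, scaled by the frame rate (deg/s).  Optionally the velocity
#' is smoothed with a causal first-order low-pass, because differencing
#' interpolated motion-capture data amplifies noise.
#'
#' @param series An [angle_series()].
#' @param smooth_cutoff_hz Optional low-pass cutoff (Hz) for the velocity;
#'   `NULL` (default) disables smoothing.
#' @return A [velocity_series()] of the same length and rate.
#' @export
differentiate <- function(series, smooth_cutoff_hz = NULL) {
  stopifnot(inherits(series, "angle_series"))
  th <- series$angle_deg
  n <- length(th)
  if (n < 3L) wv_stop("differentiate: need at least 3 points")
  fr <- series$frame_rate_hz
  v <- numeric(n)
  v[2:(n - 1)] <- (th[3:n] - th[1:(n - 2)]) * fr / 2
  v[1] <- (th[2] - th[1]) * fr
  v[n] <- (th[n] - th[n - 1]) * fr
  if (!is.null(smooth_cutoff_hz)) {
    assert_scalar_num(smooth_cutoff_hz, "smooth_cutoff_hz")
    if (smooth_cutoff_hz >= fr / 2)
      wv_stop("smooth_cutoff_hz must be below the Nyquist rate")
    bf <- signal::butter(1L, smooth_cutoff_hz / (fr / 2), type = "low")
    v <- as.numeric(signal::filter(bf, v))
  }
  velocity_series(v, fr, series$kind)
}

#' Align a velocity series to an sEMG envelope timeline
#'
#' Resamples the velocity to the envelope sampling rate and trims or
#' pads (repeating the final value) to exactly the envelope's sample
#' count, so the result can be fed to [slide_windows()].
#'
#' @param vel A [velocity_series()] (typically at the mocap rate).
#' @param env An `envelope_series` (typically at 2000 Hz).
#' @param tolerance_s Maximum allowed duration mismatch in seconds;
#'   defaults to one mocap frame.
#' @return A [velocity_series()] at the envelope rate and length.
#' @export
align_labels <- function(vel, env, tolerance_s = NULL) {
  stopifnot(inherits(vel, "velocity_series"),
            inherits(env, "envelope_series"))
  n_v <- length(vel$velocity_deg_s)
  if (n_v < 2L) wv_stop("align_labels: velocity series too short")
  dur_v <- (n_v - 1) / vel$sampling_rate_hz
  n_e <- nrow(env$values)
  dur_e <- (n_e - 1) / env$sampling_rate_hz
  tol <- tolerance_s %||% (1 / vel$sampling_rate_hz)
  if (abs(dur_v - dur_e) > tol + 1e-9)
    wv_stop(sprintf(
      "align_labels: durations differ beyond tolerance (%.4f s vs %.4f s)",
      dur_v, dur_e))
  t_old <- (seq_len(n_v) - 1) / vel$sampling_rate_hz
  t_new <- (seq_len(n_e) - 1) / env$sampling_rate_hz
  y <- stats::approx(t_old, vel$velocity_deg_s, xout = t_new, rule = 2)$y
  velocity_series(y, env$sampling_rate_hz, vel$kind)
}
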