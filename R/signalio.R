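# Reading and writing sEMG recordings, marker trajectories, and session
# manifests.  All files are plain comma-separated text with an optional
# single header row; time is implicit (row index over the sampling rate).

#' Construct an sEMG recording
#'
#' @param samples Numeric matrix, one row per sample and one column per
#'   channel (microvolt-scale arbitrary units).
#' @param sampling_rate_hz Sampling rate in Hz (the study protocol samples
#'   at 2000 Hz).
#' @param channel_names Optional channel identifiers; defaults to
#'   `c1..c<n>`.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(samples, sampling_rate_hz = 2000,
                          channel_names = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  assert_scalar_num(sampling_rate_hz, "sampling_rate_hz")
  if (nrow(samples) == 0L) wv_stop("recording has no samples")
  if (anyNA(samples) || any(!is.finite(samples)))
    wv_stop("recording contains missing or non-finite samples")
  if (is.null(channel_names))
    channel_names <- paste0("c", seq_len(ncol(samples)))
  if (length(channel_names) != ncol(samples))
    wv_stop("channel_names length does not match the number of channels")
  structure(list(samples = unname(samples),
                 sampling_rate_hz = sampling_rate_hz,
                 channel_names = as.character(channel_names)),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d samples x %d channels @ %g Hz (%.3f s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate_hz,
              nrow(x$samples) / x$sampling_rate_hz))
  invisible(x)
}

#' Construct a marker trajectory
#'
#' @param positions Numeric array `(n_frames, n_markers, 3)` of marker
#'   positions in millimetres.
#' @param frame_rate_hz Motion-capture frame rate in Hz.
#' @param marker_names Marker identifiers (length `n_markers`).
#' @return An object of class `marker_trajectory`.
#' @export
marker_trajectory <- function(positions, frame_rate_hz,
                              marker_names = NULL) {
  if (length(dim(positions)) != 3L || dim(positions)[3] != 3L)
    wv_stop("positions must be an (n_frames, n_markers, 3) array")
  assert_scalar_num(frame_rate_hz, "frame_rate_hz")
  n_markers <- dim(positions)[2]
  if (is.null(marker_names)) marker_names <- paste0("m", seq_len(n_markers))
  if (length(marker_names) != n_markers)
    wv_stop("marker_names length does not match the number of markers")
  structure(list(positions = unname(positions),
                 frame_rate_hz = frame_rate_hz,
                 marker_names = as.character(marker_names)),
            class = "marker_trajectory")
}

#' @export
print.marker_trajectory <- function(x, ...) {
  cat(sprintf("<marker_trajectory> %d frames x %d markers @ %g Hz\n",
              dim(x$positions)[1], dim(x$positions)[2], x$frame_rate_hz))
  invisible(x)
}

# Shared delimited-text scanner with per-line field-count validation.
read_delim_checked <- function(path, what) {
  if (!file.exists(path)) wv_stop(what, " file not found: ", path)
  n_fields <- utils::count.fields(path, sep = ",", blank.lines.skip = FALSE)
  if (length(n_fields) == 0L) wv_stop(what, " file is empty: ", path)
  bad <- which(n_fields != n_fields[1L])
  if (length(bad))
    wv_stop(sprintf("%s file %s: row %d has %d fields, expected %d",
                    what, path, bad[1L], n_fields[bad[1L]], n_fields[1L]))
  dt <- suppressWarnings(
    data.table::fread(path, sep = ",", header = "auto", data.table = FALSE,
                      showProgress = FALSE))
  if (nrow(dt) == 0L || ncol(dt) == 0L) wv_stop(what, " file is empty: ", path)
  has_header <- !all(grepl("^V[0-9]+$", names(dt)))
  for (j in seq_along(dt)) {
    if (!is.numeric(dt[[j]])) {
      num <- suppressWarnings(as.numeric(dt[[j]]))
      if (anyNA(num))
        wv_stop(sprintf("%s file %s: non-numeric value '%s' at row %d, column %d",
                        what, path, dt[[j]][which(is.na(num))[1L]],
                        which(is.na(num))[1L] + has_header, j))
      dt[[j]] <- num
    }
  }
  m <- as.matrix(dt)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    wv_stop(sprintf("%s file %s: missing value at row %d, column %d",
                    what, path, bad[1L, 1L] + has_header, bad[1L, 2L]))
  }
  list(values = unname(m), names = if (has_header) names(dt) else NULL)
}

#' Read an sEMG recording from delimited text
#'
#' One row per sample, one column per channel, optional header row of
#' channel names.
#'
#' @param path Path to a comma-separated text file.
#' @param sampling_rate_hz Sampling rate of the file in Hz.
#' @return An [emg_recording()].
#' @export
read_emg <- function(path, sampling_rate_hz = 2000) {
  parsed <- read_delim_checked(path, "sEMG")
  rec <- emg_recording(parsed$values, sampling_rate_hz,
                       channel_names = parsed$names)
  wv_log(sprintf("read_emg: %s -> %d samples x %d channels", path,
                 nrow(rec$samples), ncol(rec$samples)))
  rec
}

#' Write an sEMG recording to delimited text
#'
#' Values are written at full precision so that a read/write round trip
#' reproduces the samples bit-identically.
#'
#' @param rec An [emg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_emg <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  write_numeric_csv(rec$samples, rec$channel_names, path)
  invisible(path)
}

# 17 significant digits round-trip any double exactly through text.
write_numeric_csv <- function(m, col_names, path) {
  df <- as.data.frame(m)
  df[] <- lapply(df, function(col) sprintf("%.17g", col))
  names(df) <- col_names
  data.table::fwrite(df, path, quote = FALSE)
}

#' Read marker trajectories from delimited text
#'
#' One row per frame, three columns (`name_x`, `name_y`, `name_z`) per
#' marker.
#'
#' @param path Path to a comma-separated text file.
#' @param frame_rate_hz Motion-capture frame rate in Hz.
#' @return A [marker_trajectory()].
#' @export
read_markers <- function(path, frame_rate_hz) {
  parsed <- read_delim_checked(path, "marker")
  m <- parsed$values
  if (ncol(m) %% 3L != 0L)
    wv_stop(sprintf(
      "marker file %s: %d columns is not divisible by 3 (x,y,z per marker)",
      path, ncol(m)))
  n_markers <- ncol(m) %/% 3L
  marker_names <- if (!is.null(parsed$names)) {
    unique(sub("_[xyz]$", "", parsed$names))
  } else paste0("m", seq_len(n_markers))
  if (length(marker_names) != n_markers)
    wv_stop("marker file ", path, ": header does not follow the ",
            "name_x,name_y,name_z convention")
  pos <- array(0, c(nrow(m), n_markers, 3L))
  for (k in seq_len(n_markers))
    pos[, k, ] <- m[, (3L * (k - 1L) + 1L):(3L * k), drop = FALSE]
  traj <- marker_trajectory(pos, frame_rate_hz, marker_names)
  wv_log(sprintf("read_markers: %s -> %d frames x %d markers", path,
                 nrow(m), n_markers))
  traj
}

#' Write marker trajectories to delimited text
#'
#' @param traj A [marker_trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(traj, path) {
  stopifnot(inherits(traj, "marker_trajectory"))
  n_markers <- dim(traj$positions)[2]
  cols <- lapply(seq_len(n_markers), function(k) traj$positions[, k, ])
  m <- do.call(cbind, cols)
  write_numeric_csv(m, as.vector(t(outer(traj$marker_names, c("x", "y", "z"),
                                         paste, sep = "_"))), path)
  invisible(path)
}

VALID_TASKS <- c("bulb", "screw", "hammer", "cup")

#' Construct a session manifest
#'
#' A manifest lists every recorded trial of a study session: subject,
#' trial index (1-3, one per table height), task, file paths, and table
#' height.
#'
#' @param entries A data frame with columns `subject_id`, `trial`, `task`,
#'   `emg`, `markers`, `height_cm` and optionally `frame_rate_hz`.
#' @param check_paths Verify that referenced files exist.
#' @return An object of class `session_manifest`.
#' @export
session_manifest <- function(entries, check_paths = FALSE) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  required <- c("subject_id", "trial", "task", "emg", "markers", "height_cm")
  missing <- setdiff(required, names(entries))
  if (length(missing))
    wv_stop("manifest entries missing required field(s): ",
            paste(missing, collapse = ", "))
  if (nrow(entries) == 0L) wv_stop("manifest has no entries")
  entries$trial <- as.integer(entries$trial)
  if (any(!entries$trial %in% 1:3))
    wv_stop("manifest trial index must be 1, 2 or 3; got ",
            paste(unique(setdiff(entries$trial, 1:3)), collapse = ", "))
  if (any(!entries$task %in% VALID_TASKS))
    wv_stop("manifest task must be one of ",
            paste(VALID_TASKS, collapse = ", "))
  key <- paste(entries$subject_id, entries$trial, entries$task)
  if (anyDuplicated(key))
    wv_stop("duplicate manifest entry: ", key[duplicated(key)][1L])
  if (check_paths) {
    paths <- c(entries$emg, entries$markers)
    absent <- paths[!file.exists(paths)]
    if (length(absent))
      wv_stop("manifest references missing file(s): ",
              paste(utils::head(absent, 3L), collapse = ", "))
  }
  structure(list(entries = entries), class = "session_manifest")
}

#' @export
print.session_manifest <- function(x, ...) {
  cat(sprintf("<session_manifest> %d entries, %d subjects, task(s): %s\n",
              nrow(x$entries), length(unique(x$entries$subject_id)),
              paste(unique(x$entries$task), collapse = ", ")))
  invisible(x)
}

#' Load a session manifest from YAML
#'
#' The document is a list of records with keys `subject_id`, `trial`,
#' `task`, `emg`, `markers`, `height_cm` (and optionally
#' `frame_rate_hz`).  Relative paths are resolved against the manifest's
#' directory.
#'
#' @param path Path to a YAML manifest.
#' @param check_paths Verify that referenced files exist (default `TRUE`).
#' @return A [session_manifest()].
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) wv_stop("manifest file not found: ", path)
  doc <- yaml::read_yaml(path)
  recs <- if (!is.null(doc$entries)) doc$entries else doc
  if (!is.list(recs) || length(recs) == 0L)
    wv_stop("manifest ", path, " contains no entries")
  rows <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    required <- c("subject_id", "trial", "task", "emg", "markers", "height_cm")
    missing <- setdiff(required, names(r))
    if (length(missing))
      wv_stop(sprintf("manifest entry %d missing field(s): %s", i,
                      paste(missing, collapse = ", ")))
    data.frame(subject_id = as.character(r$subject_id),
               trial = as.integer(r$trial),
               task = as.character(r$task),
               emg = as.character(r$emg),
               markers = as.character(r$markers),
               height_cm = as.numeric(r$height_cm),
               frame_rate_hz = as.numeric(r$frame_rate_hz %||% NA_real_),
               stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, rows)
  base <- dirname(path)
  rel <- !grepl("^(/|[A-Za-z]:)", entries$emg)
  entries$emg[rel] <- file.path(base, entries$emg[rel])
  rel <- !grepl("^(/|[A-Za-z]:)", entries$markers)
  entries$markers[rel] <- file.path(base, entries$markers[rel])
  man <- session_manifest(entries, check_paths = check_paths)
  wv_log(sprintf("load_manifest: %s -> %d entries", path, nrow(man$entries)))
  man
}

#' Write a session manifest to YAML
#'
#' @param manifest A [session_manifest()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "session_manifest"))
  recs <- lapply(seq_len(nrow(manifest$entries)), function(i) {
    r <- manifest$entries[i, ]
    out <- list(subject_id = r$subject_id, trial = r$trial, task = r$task,
                emg = r$emg, markers = r$markers, height_cm = r$height_cm)
    if (!is.null(r$frame_rate_hz) && !is.na(r$frame_rate_hz))
      out$frame_rate_hz <- r$frame_rate_hz
    out
  })
  yaml::write_yaml(list(entries = recs), path)
  invisible(path)
}
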