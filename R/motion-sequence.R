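#' Construct a skeletal motion sequence
#'
#' An ordered trial of time-stamped skeletal frames: per-frame 3D joint
#' positions (meters, camera coordinates unless noted), per-joint unit
#' orientation quaternions `(w, x, y, z)`, and per-frame floor-plane
#' coefficients `(a, b, c, d)` of the plane `a x + b y + c z + d = 0`.
#'
#' @param timestamps Numeric vector, seconds from trial start, strictly
#'   increasing with gaps of `1/frame_rate` within 10% jitter.
#' @param positions Numeric array `n_frames x 25 x 3`; second dimension
#'   named with [kinect_joints()], third with `c("x","y","z")`.
#' @param orientations Numeric array `n_frames x 25 x 4` of unit
#'   quaternions (`qw,qx,qy,qz`); defaults to identity quaternions.
#' @param floor Numeric matrix `n_frames x 4` of floor-plane coefficients
#'   with unit normal `(a,b,c)`; if `NULL` it is estimated as the
#'   horizontal plane through the lower ankle (documented fallback).
#' @param frame_rate Nominal capture rate in Hz (default 60).
#' @param subject_id,exercise_id,trial_id Identifiers.
#' @param coords `"camera"` or `"pcs"` (personal coordinate system).
#'
#' @return A `motion_sequence` object.
#' @seealso [read_motion_csv()], [write_motion_csv()], [to_personal_coords()]
#' @export
motion_sequence <- function(timestamps, positions, orientations = NULL,
                            floor = NULL, frame_rate = 60,
                            subject_id = "s1", exercise_id = "hip_abduction",
                            trial_id = "t1", coords = "camera") {
  n <- length(timestamps)
  joints <- kinect_joints()
  if (is.null(orientations)) {
    orientations <- array(0, dim = c(n, 25L, 4L),
                          dimnames = list(NULL, joints, c("qw", "qx", "qy", "qz")))
    orientations[, , "qw"] <- 1
  }
  if (is.null(floor)) floor <- estimate_floor(positions)
  seq <- structure(
    list(timestamps = as.numeric(timestamps),
         positions = positions, orientations = orientations,
         floor = floor, frame_rate = frame_rate,
         subject_id = subject_id, exercise_id = exercise_id,
         trial_id = trial_id, coords = coords),
    class = "motion_sequence")
  validate_motion_sequence(seq)
  seq
}

# Fallback floor: horizontal plane (camera y up) through the lower ankle.
estimate_floor <- function(positions) {
  n <- dim(positions)[1L]
  y0 <- min(positions[, c("ankle_left", "ankle_right"), "y"])
  matrix(c(0, 1, 0, -y0), nrow = n, ncol = 4L, byrow = TRUE,
         dimnames = list(NULL, c("a", "b", "c", "d")))
}

validate_motion_sequence <- function(seq, tol = 1e-6) {
  n <- length(seq$timestamps)
  if (n < 2L)
    rehab_error("a motion sequence needs at least 2 frames", "rehabmm_invariant_error")
  if (!all(dim(seq$positions) == c(n, 25L, 3L)))
    rehab_error("positions must be an n x 25 x 3 array", "rehabmm_invariant_error")
  jn <- dimnames(seq$positions)[[2L]]
  missing <- setdiff(kinect_joints(), jn)
  if (length(missing))
    rehab_error(paste0("missing joint(s): ", paste(missing, collapse = ", ")),
                "rehabmm_schema_error")
  if (anyNA(seq$positions))
    rehab_error("joint positions contain missing values", "rehabmm_invariant_error")
  dt <- diff(seq$timestamps)
  if (any(dt <= 0))
    rehab_error(sprintf("timestamps not strictly increasing at frame %d",
                        which(dt <= 0)[1L] + 1L), "rehabmm_order_error")
  nominal <- 1 / seq$frame_rate
  if (any(abs(dt - nominal) > 0.1 * nominal))
    rehab_error("frame gaps deviate from 1/frame_rate by more than 10%",
                "rehabmm_invariant_error")
  qn <- sqrt(rowSums(matrix(seq$orientations, ncol = 4L)^2))
  if (any(abs(qn - 1) > tol))
    rehab_error("orientation quaternions must have unit norm", "rehabmm_invariant_error")
  fn <- sqrt(rowSums(seq$floor[, 1:3, drop = FALSE]^2))
  if (any(abs(fn - 1) > tol))
    rehab_error("floor-plane normals must have unit norm", "rehabmm_invariant_error")
  invisible(seq)
}

#' @export
print.motion_sequence <- function(x, ...) {
  cat(sprintf("<motion_sequence> %s/%s/%s: %d frames @ %g Hz (%.2f s), %s coordinates\n",
              x$subject_id, x$exercise_id, x$trial_id,
              length(x$timestamps), x$frame_rate,
              diff(range(x$timestamps)), x$coords))
  invisible(x)
}

#' @export
length.motion_sequence <- function(x) length(x$timestamps)

#' Number of frames in a motion sequence
#' @param seq A `motion_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) length(seq$timestamps)

#' Per-frame positions of one joint
#'
#' @param seq A `motion_sequence`.
#' @param joint Joint name (aliases such as `"shoulder_center"` accepted).
#' @return `n_frames x 3` matrix.
#' @export
joint_positions <- function(seq, joint) {
  seq$positions[, resolve_joint(joint), , drop = TRUE]
}

frame_csv_columns <- function() {
  c("trial_id", "frame_idx", "timestamp", "joint", "x", "y", "z",
    "qw", "qx", "qy", "qz", "floor_a", "floor_b", "floor_c", "floor_d")
}

#' Read a skeletal trial from a long-format frame CSV
#'
#' Expects one row per frame x joint with columns
#' `trial_id,frame_idx,timestamp,joint,x,y,z,qw,qx,qy,qz,floor_a,floor_b,floor_c,floor_d`
#' (UTF-8, header mandatory, `.` decimal). All 25 canonical joints must be
#' present in every frame; quaternions within `1e-3` of unit norm are
#' renormalized. Floor columns may be `NA` throughout, in which case the
#' floor is estimated as the horizontal plane through the lower ankle.
#'
#' @param path CSV file path.
#' @param frame_rate Nominal frame rate in Hz.
#' @param subject_id,exercise_id Metadata not stored in the frame schema.
#' @return A validated [motion_sequence()].
#' @export
read_motion_csv <- function(path, frame_rate = 60, subject_id = "s1",
                            exercise_id = "hip_abduction") {
  if (!file.exists(path)) rehab_error(paste0("no such file: ", path), "rehabmm_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(frame_csv_columns(), names(df))
  if (length(missing_cols))
    rehab_error(paste0("frame CSV lacks column(s): ", paste(missing_cols, collapse = ", ")),
                "rehabmm_schema_error")
  joints <- kinect_joints()
  frames <- unique(df$frame_idx)
  if (is.unsorted(frames, strictly = TRUE))
    rehab_error(sprintf("non-monotonic frame_idx first at row %d",
                        which(diff(match(df$frame_idx, frames)) < 0)[1L] + 1L),
                "rehabmm_order_error")
  n <- length(frames)
  for (j in joints) {
    if (sum(df$joint == j) != n)
      rehab_error(paste0("joint missing or duplicated in frame rows: ", j),
                  "rehabmm_schema_error")
  }
  if (nrow(df) != n * 25L)
    rehab_error(sprintf("expected %d rows (%d frames x 25 joints), found %d",
                        n * 25L, n, nrow(df)), "rehabmm_schema_error")
  # order rows as frame-major, canonical joint order
  df <- df[order(match(df$frame_idx, frames), match(df$joint, joints)), ]
  pos <- array(NA_real_, c(n, 25L, 3L), dimnames = list(NULL, joints, c("x", "y", "z")))
  ori <- array(NA_real_, c(n, 25L, 4L), dimnames = list(NULL, joints, c("qw", "qx", "qy", "qz")))
  for (k in seq_along(c("x", "y", "z")))
    pos[, , k] <- matrix(df[[c("x", "y", "z")[k]]], nrow = n, ncol = 25L, byrow = TRUE)
  for (k in seq_along(c("qw", "qx", "qy", "qz")))
    ori[, , k] <- matrix(df[[c("qw", "qx", "qy", "qz")[k]]], nrow = n, ncol = 25L, byrow = TRUE)
  qn <- sqrt(ori[, , 1]^2 + ori[, , 2]^2 + ori[, , 3]^2 + ori[, , 4]^2)
  bad <- abs(qn - 1) > 1e-3
  if (any(bad))
    rehab_error("orientation quaternion deviates from unit norm by more than 1e-3",
                "rehabmm_invariant_error")
  for (k in 1:4) ori[, , k] <- ori[, , k] / qn
  first <- df[match(frames, df$frame_idx), ]
  ts <- first$timestamp
  if (any(diff(ts) <= 0))
    rehab_error(sprintf("non-monotonic timestamps first at frame_idx %s",
                        frames[which(diff(ts) <= 0)[1L] + 1L]), "rehabmm_order_error")
  floor <- as.matrix(first[, c("floor_a", "floor_b", "floor_c", "floor_d")])
  dimnames(floor) <- list(NULL, c("a", "b", "c", "d"))
  if (anyNA(floor)) floor <- NULL
  motion_sequence(ts, pos, ori, floor, frame_rate = frame_rate,
                  subject_id = subject_id, exercise_id = exercise_id,
                  trial_id = as.character(first$trial_id[1L]))
}

#' Write a skeletal trial to the long-format frame CSV
#'
#' Inverse of [read_motion_csv()]: positions, quaternions and floor
#' coefficients survive a round trip to better than `1e-9`.
#'
#' @param seq A valid [motion_sequence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_motion_csv <- function(seq, path) {
  validate_motion_sequence(seq)
  joints <- kinect_joints()
  n <- length(seq$timestamps)
  idx <- rep(seq_len(n), each = 25L)
  fmt <- function(x) sprintf("%.12g", x)
  df <- data.frame(
    trial_id = seq$trial_id,
    frame_idx = idx,
    timestamp = fmt(seq$timestamps[idx]),
    joint = rep(joints, n),
    x = fmt(as.vector(t(seq$positions[, , "x"]))),
    y = fmt(as.vector(t(seq$positions[, , "y"]))),
    z = fmt(as.vector(t(seq$positions[, , "z"]))),
    qw = fmt(as.vector(t(seq$orientations[, , "qw"]))),
    qx = fmt(as.vector(t(seq$orientations[, , "qx"]))),
    qy = fmt(as.vector(t(seq$orientations[, , "qy"]))),
    qz = fmt(as.vector(t(seq$orientations[, , "qz"]))),
    floor_a = fmt(seq$floor[idx, "a"]), floor_b = fmt(seq$floor[idx, "b"]),
    floor_c = fmt(seq$floor[idx, "c"]), floor_d = fmt(seq$floor[idx, "d"]),
    stringsAsFactors = FALSE)
  ok <- tryCatch({ write.csv(df, path, row.names = FALSE, quote = FALSE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) rehab_error(paste0("cannot write: ", path), "rehabmm_io_error")
  invisible(path)
}

#' Read therapist labels from CSV
#'
#' Expects columns `subject_id,trial_id,aspect,rating,rater_id`. Aspects
#' are `ROM`, `coordination` or `compensation`; ratings are normalized
#' from `{G,F,B}` or `{good,fair,bad}` (case-insensitive) to the ordered
#' three-level scale used throughout.
#'
#' @param path CSV file path.
#' @return Data frame of class `therapist_labels` with `rating` an ordered
#'   factor `bad < fair < good`.
#' @export
read_labels_csv <- function(path) {
  if (!file.exists(path)) rehab_error(paste0("no such file: ", path), "rehabmm_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "trial_id", "aspect", "rating", "rater_id")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    rehab_error(paste0("label CSV lacks column(s): ", paste(missing_cols, collapse = ", ")),
                "rehabmm_schema_error")
  normalize_labels(df)
}

normalize_labels <- function(df) {
  map <- c(g = "good", f = "fair", b = "bad",
           good = "good", fair = "fair", bad = "bad")
  tok <- tolower(trimws(as.character(df$rating)))
  unknown <- which(!tok %in% names(map))
  if (length(unknown))
    rehab_error(sprintf("unknown rating token '%s' at row %d",
                        df$rating[unknown[1L]], unknown[1L]), "rehabmm_parse_error")
  df$rating <- factor(unname(map[tok]), levels = c("bad", "fair", "good"), ordered = TRUE)
  aspects <- c("ROM", "coordination", "compensation")
  bad_aspect <- which(!df$aspect %in% aspects)
  if (length(bad_aspect))
    rehab_error(sprintf("unknown aspect '%s' at row %d (expected %s)",
                        df$aspect[bad_aspect[1L]], bad_aspect[1L],
                        paste(aspects, collapse = "/")), "rehabmm_parse_error")
  class(df) <- c("therapist_labels", "data.frame")
  df
}
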