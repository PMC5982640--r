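#' Interior angle of a triangle from its side lengths
#'
#' Law of cosines: the angle `A` opposite side `a` in a triangle with
#' sides `a, b, c` is `acos((-a^2 + b^2 + c^2) / (2 b c))`.
#'
#' @param a Length of the side opposite the requested angle.
#' @param b,c Lengths of the adjacent sides.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
#' @examples
#' angle_from_sides(1, 1, 1)   # equilateral: 60
#' angle_from_sides(5, 3, 4)   # right angle: 90
angle_from_sides <- function(a, b, c) {
  if (any(c(a, b, c) <= 0))
    rehab_error("side lengths must be positive", "rehabmm_domain_error")
  cosA <- (-a^2 + b^2 + c^2) / (2 * b * c)
  if (abs(cosA) > 1 + 1e-9)
    rehab_error("side lengths violate the triangle inequality", "rehabmm_domain_error")
  acos(pmin(1, pmax(-1, cosA))) * 180 / pi
}

#' Angle at a joint between two adjacent segments
#'
#' Computes the three inter-point distances and applies the law of
#' cosines at `p_joint`; identical to the angle between the vectors
#' `p_prox - p_joint` and `p_dist - p_joint`.
#'
#' @param p_prox,p_joint,p_dist 3D points (numeric length-3).
#' @return Angle in degrees.
#' @export
angle_at_joint <- function(p_prox, p_joint, p_dist) {
  a <- sqrt(sum((p_prox - p_dist)^2))  # opposite the joint
  b <- sqrt(sum((p_prox - p_joint)^2))
  c <- sqrt(sum((p_dist - p_joint)^2))
  if (b < 1e-9 || c < 1e-9)
    rehab_error("coincident points: angle undefined", "rehabmm_domain_error")
  angle_from_sides(a, b, c)
}

#' Cross product of two 3D vectors
#'
#' @param u,v Numeric vectors of length 3.
#' @return `u x v` as a numeric vector of length 3.
#' @export
cross_product <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-9) rehab_error("cannot normalize a near-zero vector", "rehabmm_degenerate_error")
  v / n
}

#' Build the personal coordinate system for one frame
#'
#' The PCS is a body-anchored, rotation-invariant frame: the left/right
#' axis is the hip line projected onto the floor, the up axis is the
#' floor normal (oriented towards the body), the front/back axis is their
#' cross product, and the origin is the hip-midpoint's orthogonal
#' projection onto the floor (the floor point under the body center).
#'
#' @param hip_left,hip_right 3D positions of the two hip joints.
#' @param floor_plane Coefficients `(a,b,c,d)` of the floor plane with
#'   unit normal `(a,b,c)`.
#' @return A `pcs_frame`: list with `origin` and unit, mutually
#'   orthogonal, right-handed axes `axis_lr`, `axis_ud`, `axis_fb`.
#' @export
build_pcs <- function(hip_left, hip_right, floor_plane) {
  nrm <- floor_plane[1:3]
  nn <- sqrt(sum(nrm^2))
  if (nn < 1e-9) rehab_error("degenerate floor normal", "rehabmm_degenerate_error")
  nrm <- nrm / nn
  d <- floor_plane[4L] / nn
  mid <- (hip_left + hip_right) / 2
  if (sum(nrm * mid) + d < 0) {  # orient the normal towards the body
    nrm <- -nrm
    d <- -d
  }
  v <- hip_right - hip_left
  v_floor <- v - sum(v * nrm) * nrm
  if (sqrt(sum(v_floor^2)) < 1e-9)
    rehab_error("hips vertically stacked: left/right axis undefined",
                "rehabmm_degenerate_error")
  axis_lr <- unit(v_floor)
  axis_ud <- nrm
  axis_fb <- unit(cross_product(axis_lr, axis_ud))
  origin <- mid - (sum(nrm * mid) + d) * nrm
  structure(list(origin = origin, axis_lr = axis_lr,
                 axis_ud = axis_ud, axis_fb = axis_fb),
            class = "pcs_frame")
}

#' Re-express a motion sequence in personal coordinates
#'
#' Every joint position is mapped to `(left/right, up/down, front/back)`
#' components relative to that frame's personal coordinate system, making
#' the representation invariant under rigid rotations about the floor
#' normal and translations along the floor.
#'
#' @param seq A `motion_sequence` in camera coordinates with a floor plane
#'   in every frame.
#' @return A `motion_sequence` with `coords = "pcs"` whose position axes
#'   are `(lr, ud, fb)`.
#' @export
to_personal_coords <- function(seq) {
  tf <- pcs_transform(seq)
  seq$positions <- tf$positions
  seq$coords <- "pcs"
  seq
}

# Per-frame PCS transform: PCS-expressed positions plus the frame axes
# (needed to project camera-frame velocities onto body directions).
pcs_transform <- function(seq) {
  n <- length(seq$timestamps)
  out <- seq$positions
  dimnames(out)[[3L]] <- c("lr", "ud", "fb")
  axes <- array(NA_real_, c(n, 3L, 3L),
                dimnames = list(NULL, NULL, c("lr", "ud", "fb")))
  for (i in seq_len(n)) {
    pcs <- tryCatch(
      build_pcs(seq$positions[i, "hip_left", ], seq$positions[i, "hip_right", ],
                seq$floor[i, ]),
      rehabmm_degenerate_error = function(e)
        rehab_error(sprintf("degenerate personal coordinate system at frame %d: %s",
                            i, conditionMessage(e)), "rehabmm_degenerate_error"))
    A <- cbind(pcs$axis_lr, pcs$axis_ud, pcs$axis_fb)
    rel <- sweep(seq$positions[i, , ], 2L, pcs$origin)
    out[i, , ] <- rel %*% A
    axes[i, , ] <- A
  }
  list(positions = out, axes = axes)
}

#' Buffered (denoised) speed of a position series
#'
#' Per-frame displacement per unit time, averaged over a sliding buffer
#' that is updated at every frame by discarding the oldest value and
#' adding the newest. The first `buffer_len - 1` outputs are `NA` (the
#' stream becomes available once the buffer is filled). For a 3D series
#' the unsigned speed is the mean of displacement magnitudes; for a
#' scalar series with `signed = TRUE` the buffered first difference keeps
#' its sign (used e.g. for angular speed).
#'
#' @param x Numeric vector (scalar series) or `n x 3` matrix (positions).
#' @param buffer_len Buffer length in frames (default 15, about 0.25 s at
#'   60 Hz).
#' @param frame_rate Frames per second.
#' @param signed Keep the sign of scalar first differences.
#' @return Numeric vector of length `nrow(x)` with an `NA` prefix of
#'   length `buffer_len - 1`.
#' @export
buffered_speed <- function(x, buffer_len = 15, frame_rate = 60, signed = FALSE) {
  if (buffer_len < 2) rehab_error("buffer_len must be >= 2", "rehabmm_config_error")
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  if (n <= buffer_len)
    rehab_error("series shorter than the speed buffer", "rehabmm_config_error")
  d <- diff(x) * frame_rate                     # per-frame velocity, length n-1
  inst <- if (ncol(x) == 1L && signed) as.vector(d) else sqrt(rowSums(d^2))
  buffered_mean(inst, buffer_len)
}

# Sliding-buffer mean of an instantaneous per-frame series (length n - 1,
# value i belonging to the transition into frame i + 1); returns length-n
# output with an NA prefix of buffer_len - 1 frames.
buffered_mean <- function(inst, buffer_len) {
  n <- length(inst) + 1L
  out <- rep(NA_real_, n)
  cs <- cumsum(c(0, inst))
  for (i in seq(buffer_len, n)) {
    lo <- max(2L, i - buffer_len + 1L)
    out[i] <- (cs[i] - cs[lo - 1L]) / (i - lo + 1L)
  }
  out
}

quat_to_matrix <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3L, byrow = TRUE)
}

#' Intrinsic rotation angles of a joint quaternion
#'
#' Decomposes a unit quaternion, expressed relative to a parent coordinate
#' frame, into intrinsic x-y-z (pitch-yaw-roll) rotation angles. Near
#' gimbal lock (`|yaw| = 90` degrees) the pitch/roll split is not unique;
#' the canonical decomposition with pitch absorbed into roll is returned
#' and flagged.
#'
#' @param q Unit quaternion `(w, x, y, z)` (norm within `1e-6` of 1).
#' @param parent_axes 3x3 matrix whose columns are the parent frame axes
#'   (identity by default; e.g. `cbind(pcs$axis_lr, pcs$axis_ud, pcs$axis_fb)`).
#' @return Named numeric vector `(pitch, yaw, roll)` in degrees with
#'   attribute `gimbal_lock` (logical).
#' @export
quaternion_to_rotations <- function(q, parent_axes = diag(3)) {
  if (abs(sqrt(sum(q^2)) - 1) > 1e-6)
    rehab_error("quaternion must have unit norm", "rehabmm_domain_error")
  R <- quat_to_matrix(q)
  R <- t(parent_axes) %*% R %*% parent_axes  # express in the parent frame
  lock <- abs(R[1L, 3L]) > 1 - 1e-9
  if (lock) {
    yaw <- asin(pmin(1, pmax(-1, R[1L, 3L])))
    pitch <- 0
    roll <- atan2(R[2L, 1L], R[2L, 2L])
  } else {
    yaw <- asin(R[1L, 3L])
    pitch <- atan2(-R[2L, 3L], R[3L, 3L])
    roll <- atan2(-R[1L, 2L], R[1L, 1L])
  }
  out <- c(pitch = pitch, yaw = yaw, roll = roll) * 180 / pi
  attr(out, "gimbal_lock") <- lock
  out
}
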