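#' Declare a kinematic feature
#'
#' Features are computed per frame from a motion sequence in personal
#' coordinates. Supported kinds:
#' \describe{
#'   \item{`joint_angle`}{Angle in degrees at `joints[2]` between the
#'     segments to `joints[1]` and `joints[3]`, optionally projected onto
#'     a PCS plane (`plane = "frontal"`, `"sagittal"` or `"horizontal"`).}
#'   \item{`pcs_position`}{Signed PCS coordinate (`axis` = `"lr"`, `"ud"`
#'     or `"fb"`) of one joint, in meters.}
#'   \item{`buffered_speed`}{Unsigned buffered speed of one joint (m/s).}
#'   \item{`axis_speed`}{Signed buffered speed of one joint along one PCS
#'     axis (m/s); `direction_labels` names the negative/positive ends
#'     (e.g. `c("left", "right")`).}
#'   \item{`angular_speed`}{Signed buffered first difference of another
#'     feature given in `source` (degrees/s for angle sources).}
#'   \item{`excursion`}{Negated absolute deviation of one joint's PCS
#'     coordinate from its starting baseline (m); its valley marks the
#'     peak excursion of the movement.}
#'   \item{`rotation`}{One intrinsic rotation angle (`component` =
#'     `"pitch"`, `"yaw"` or `"roll"`) of a joint quaternion (degrees).}
#' }
#'
#' @param name Feature (channel) name.
#' @param kind One of the kinds above.
#' @param joints Character vector of joint names (arity depends on kind).
#' @param axis PCS axis for position-like kinds.
#' @param plane Projection plane for `joint_angle`.
#' @param source Source feature name for `angular_speed`.
#' @param component Rotation component for `rotation`.
#' @param buffer_len Speed buffer length in frames; `NA` means
#'   `round(0.25 * frame_rate)`.
#' @param direction_labels Length-2 labels for the negative/positive
#'   direction of an `axis_speed` feature.
#' @return A `feature_spec` object.
#' @export
feature_spec <- function(name, kind, joints = character(), axis = NULL,
                         plane = NULL, source = NULL, component = NULL,
                         buffer_len = NA, direction_labels = NULL) {
  kinds <- c("joint_angle", "frontal_leg_angle", "pcs_position", "buffered_speed",
             "axis_speed", "angular_speed", "excursion", "rotation")
  if (!kind %in% kinds)
    rehab_error(paste0("unknown feature kind: ", kind), "rehabmm_config_error")
  arity <- c(joint_angle = 3L, frontal_leg_angle = 2L, pcs_position = 1L,
             buffered_speed = 1L, axis_speed = 1L, angular_speed = 0L,
             excursion = 1L, rotation = 1L)
  if (length(joints) != arity[[kind]])
    rehab_error(sprintf("feature kind '%s' needs %d joint(s), got %d",
                        kind, arity[[kind]], length(joints)), "rehabmm_config_error")
  structure(list(name = name, kind = kind,
                 joints = vapply(joints, resolve_joint, character(1)),
                 axis = axis, plane = plane, source = source,
                 component = component, buffer_len = buffer_len,
                 direction_labels = direction_labels),
            class = "feature_spec")
}

#' Canonical hip-abduction feature preset
#'
#' The four-channel feature vector used by the canonical trunk and hip
#' models — `hip_center_speed` (m/s), `shoulder_center_speed` (m/s),
#' `right_hip_frontal_angular_speed` (degrees/s) and
#' `right_hip_frontal_angle` (degrees) — plus auxiliary channels for
#' clipping and error direction: the signed left/right and up/down
#' pelvis speeds and the shoulder-center sway excursion.
#'
#' @return List of [feature_spec()] objects.
#' @export
abduction_preset <- function() {
  list(
    feature_spec("hip_center_speed", "buffered_speed", "hip_center"),
    feature_spec("shoulder_center_speed", "buffered_speed", "shoulder_center"),
    feature_spec("right_hip_frontal_angular_speed", "angular_speed",
                 source = "right_hip_frontal_angle"),
    feature_spec("right_hip_frontal_angle", "frontal_leg_angle",
                 joints = c("hip_right", "knee_right"), plane = "frontal"),
    feature_spec("hip_center_lr_speed", "axis_speed", "hip_center", axis = "lr",
                 direction_labels = c("left", "right")),
    feature_spec("hip_center_ud_speed", "axis_speed", "hip_center", axis = "ud",
                 direction_labels = c("down", "up")),
    feature_spec("shoulder_center_sway", "excursion", "shoulder_center",
                 axis = "lr"))
}

axis_index <- function(axis) {
  i <- match(axis, c("lr", "ud", "fb"))
  if (is.na(i)) rehab_error(paste0("unknown PCS axis: ", axis), "rehabmm_config_error")
  i
}

plane_axes <- function(plane) {
  switch(plane,
         frontal = c(1L, 2L),     # lr-ud
         sagittal = c(3L, 2L),    # fb-ud
         horizontal = c(1L, 3L),  # lr-fb
         rehab_error(paste0("unknown plane: ", plane), "rehabmm_config_error"))
}

#' Extract a feature series from a motion sequence
#'
#' Evaluates each [feature_spec()] per frame. The sequence is converted
#' to personal coordinates first if needed. Speed-like channels carry an
#' `NA` warm-up prefix until their buffer fills; `valid_from` is the first
#' frame at which every channel is defined.
#'
#' @param seq A `motion_sequence`.
#' @param specs List of [feature_spec()]s (default [abduction_preset()]).
#' @return A `feature_series`: list with `values` (`n_frames x n_features`
#'   matrix, named columns), `frame_rate`, `valid_from`, `timestamps` and
#'   per-channel `direction_labels`.
#' @export
extract_features <- function(seq, specs = abduction_preset()) {
  if (inherits(specs, "feature_spec")) specs <- list(specs)
  n <- length(seq$timestamps)
  if (seq$coords == "camera") {
    cam <- seq$positions
    tf <- pcs_transform(seq)
    seq$positions <- tf$positions
    seq$coords <- "pcs"
    axes <- tf$axes
  } else {
    # already body-relative: treat positions as both representations,
    # with identity axes
    cam <- seq$positions
    axes <- array(rep(diag(3), each = n), c(n, 3L, 3L),
                  dimnames = list(NULL, NULL, c("lr", "ud", "fb")))
  }
  buf_default <- max(2L, round(0.25 * seq$frame_rate))
  vals <- matrix(NA_real_, n, length(specs),
                 dimnames = list(NULL, vapply(specs, `[[`, character(1), "name")))
  dir_labels <- list()
  # angle sources first so angular_speed can refer to them
  order_idx <- order(vapply(specs, function(s) s$kind == "angular_speed", logical(1)))
  for (k in order_idx) {
    sp <- specs[[k]]
    blen <- if (is.na(sp$buffer_len)) buf_default else sp$buffer_len
    vals[, k] <- switch(
      sp$kind,
      joint_angle = {
        ax <- plane_axes(sp$plane %||% "frontal")
        p1 <- seq$positions[, sp$joints[1L], ax, drop = FALSE]
        pj <- seq$positions[, sp$joints[2L], ax, drop = FALSE]
        p3 <- seq$positions[, sp$joints[3L], ax, drop = FALSE]
        vapply(seq_len(n), function(i)
          angle_at_joint(c(p1[i, 1, ], 0), c(pj[i, 1, ], 0), c(p3[i, 1, ], 0)),
          numeric(1))
      },
      frontal_leg_angle = {
        ax <- plane_axes(sp$plane %||% "frontal")
        hip <- seq$positions[, sp$joints[1L], ax, drop = FALSE]
        knee <- seq$positions[, sp$joints[2L], ax, drop = FALSE]
        # angle of the upper-leg vector from the downward body vertical,
        # via the cosine law against a virtual point straight below the hip
        vapply(seq_len(n), function(i) {
          h <- c(hip[i, 1, ], 0); k <- c(knee[i, 1, ], 0)
          if (sqrt(sum((h - k)^2)) < 1e-9) return(0)
          angle_at_joint(h + c(0, -1, 0), h, k)
        }, numeric(1))
      },
      pcs_position = seq$positions[, sp$joints[1L], axis_index(sp$axis %||% "lr")],
      # speeds use camera-frame displacements so whole-body motion (e.g.
      # a pelvis drift the PCS origin would follow) stays visible; the
      # magnitude is rotation invariant, signed components are projected
      # onto the per-frame PCS axes
      buffered_speed = buffered_speed(cam[, sp$joints[1L], ],
                                      blen, seq$frame_rate),
      axis_speed = {
        dir_labels[[sp$name]] <- sp$direction_labels
        ai <- axis_index(sp$axis)
        d <- diff(cam[, sp$joints[1L], ]) * seq$frame_rate
        inst <- rowSums(d * axes[-1L, , ai])
        buffered_mean(inst, blen)
      },
      angular_speed = {
        if (is.na(match(sp$source, colnames(vals))) || all(is.na(vals[, sp$source])))
          rehab_error(paste0("angular_speed source not computed: ", sp$source),
                      "rehabmm_config_error")
        buffered_speed(vals[, sp$source], blen, seq$frame_rate, signed = TRUE)
      },
      excursion = {
        x <- seq$positions[, sp$joints[1L], axis_index(sp$axis %||% "lr")]
        baseline <- median(x[seq_len(min(n, buf_default))])
        -abs(x - baseline)
      },
      rotation = {
        q <- seq$orientations[, sp$joints[1L], ]
        vapply(seq_len(n), function(i)
          quaternion_to_rotations(q[i, ])[[sp$component %||% "roll"]], numeric(1))
      })
  }
  valid_from <- 1L
  if (anyNA(vals)) {
    ok <- !apply(is.na(vals), 1L, any)
    valid_from <- which(ok)[1L]
    if (is.na(valid_from))
      rehab_error("no frame with all features defined", "rehabmm_config_error")
  }
  structure(list(values = vals, frame_rate = seq$frame_rate,
                 valid_from = valid_from, timestamps = seq$timestamps,
                 direction_labels = dir_labels),
            class = "feature_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %d frames @ %g Hz, %d channel(s), valid from frame %d\n",
              nrow(x$values), x$frame_rate, ncol(x$values), x$valid_from))
  cat("  channels:", paste(colnames(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' Complete-case observation matrix of a feature series
#'
#' @param fs A `feature_series`.
#' @param channels Channel names to keep (default all).
#' @return Numeric matrix of the frames from `valid_from` on, with
#'   attribute `first_frame` giving the original index of its first row.
#' @export
feature_matrix <- function(fs, channels = colnames(fs$values)) {
  missing_ch <- setdiff(channels, colnames(fs$values))
  if (length(missing_ch))
    rehab_error(paste0("unknown feature channel(s): ", paste(missing_ch, collapse = ", ")),
                "rehabmm_config_error")
  m <- fs$values[seq(fs$valid_from, nrow(fs$values)), channels, drop = FALSE]
  attr(m, "first_frame") <- fs$valid_from
  m
}

#' Write a feature series to wide CSV
#'
#' Columns `frame_idx,timestamp,<feature channels>`; warm-up frames keep
#' `NA` values.
#'
#' @param fs A `feature_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(fs, path) {
  df <- data.frame(frame_idx = seq_len(nrow(fs$values)),
                   timestamp = fs$timestamps, fs$values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
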