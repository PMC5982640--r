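#' Canonical 25-joint skeleton vocabulary
#'
#' The joint names of the Kinect-v2 skeletal layout, in canonical order.
#' All motion containers in the package carry exactly these joints.
#'
#' @return Character vector of 25 joint names.
#' @export
#' @examples
#' kinect_joints()
kinect_joints <- function() {
  c("spine_base", "spine_mid", "neck", "head",
    "shoulder_left", "elbow_left", "wrist_left", "hand_left",
    "shoulder_right", "elbow_right", "wrist_right", "hand_right",
    "hip_left", "knee_left", "ankle_left", "foot_left",
    "hip_right", "knee_right", "ankle_right", "foot_right",
    "spine_shoulder",
    "hand_tip_left", "thumb_left", "hand_tip_right", "thumb_right")
}

#' Informal-to-canonical joint name aliases
#'
#' Clinical shorthand maps onto the canonical skeleton: the "shoulder
#' center" is the spine-shoulder joint and the "hip center" is the spine
#' base (pelvis center).
#'
#' @return Named character vector mapping informal names to canonical ones.
#' @export
joint_aliases <- function() {
  c(shoulder_center = "spine_shoulder", hip_center = "spine_base")
}

#' Resolve a joint name, accepting informal aliases
#'
#' @param joint Joint name, canonical or aliased.
#' @return Canonical joint name.
#' @export
resolve_joint <- function(joint) {
  stopifnot(is.character(joint), length(joint) == 1L)
  al <- joint_aliases()
  if (joint %in% names(al)) joint <- unname(al[[joint]])
  if (!joint %in% kinect_joints())
    rehab_error(sprintf("unknown joint '%s'", joint), "rehabmm_schema_error")
  joint
}
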