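#' Sliding-window forward likelihood trace
#'
#' Scores tiled windows of a feature sequence under a trained model with
#' the forward algorithm, per-frame normalized so window values are
#' comparable across lengths. The minimum-value window is exposed as the
#' error locus: a local execution fault depresses the likelihood of the
#' window(s) containing it.
#'
#' @param model A [gaussian_hmm()].
#' @param features `feature_series` or observation matrix.
#' @param window_len Window length in frames (default 60, about 1 s).
#' @param stride Window step in frames (default 15).
#' @return A `window_trace`: list with `window_starts` (frame indices,
#'   in the coordinates of `features`), `window_len`, `stride`, `values`
#'   (per-frame normalized forward log-likelihood per window) and
#'   `min_index` (index of the minimum-value window).
#' @export
sliding_window_likelihood <- function(model, features, window_len = 60, stride = 15) {
  if (window_len < 2) rehab_error("window_len must be >= 2", "rehabmm_config_error")
  obs <- as_obs_matrix(features, model)
  first <- attr(features, "first_frame") %||%
    (if (inherits(features, "feature_series")) features$valid_from else 1L)
  n <- nrow(obs)
  if (n < window_len)
    rehab_error("sequence shorter than the window", "rehabmm_config_error")
  starts <- seq.int(1L, n - window_len + 1L, by = stride)
  values <- vapply(starts, function(s)
    forward_loglik(model, obs[s:(s + window_len - 1L), , drop = FALSE]) / window_len,
    numeric(1))
  structure(list(window_starts = as.integer(starts + first - 1L),
                 window_len = as.integer(window_len),
                 stride = as.integer(stride), values = values,
                 min_index = which.min(values)),
            class = "window_trace")
}

#' @export
print.window_trace <- function(x, ...) {
  cat(sprintf("<window_trace> %d windows of %d frames (stride %d), min %.3f at window %d\n",
              length(x$values), x$window_len, x$stride,
              min(x$values), x$min_index))
  invisible(x)
}

#' Clip one movement between rest-state terminations
#'
#' Delimits the movement using the rest state (state 0) of a decoded
#' phase path: the clip starts where the opening rest segment ends and
#' ends where the closing rest segment begins. The peak is the deepest
#' valley of a signed trunk excursion signal within the clip — the point
#' of maximum amplitude, where the movement direction inverts and speed
#' is about zero.
#'
#' @param trunk_signal Signed scalar series aligned with `path` (the
#'   shoulder-center sway excursion channel by convention; its minimum
#'   marks the movement center).
#' @param path A [viterbi_path()] over the same frames.
#' @param frame_offset Offset added to reported frame indices (use the
#'   `first_frame` of a trimmed feature matrix to report original frame
#'   numbers).
#' @param min_seg Minimum rest-segment length in frames (default 15)
#'   for a segment to count as the opening/closing rest phase; shorter
#'   rest visits are decode blips.
#' @return A `movement_clipping`: list with `start_frame`, `peak_frame`,
#'   `end_frame` (offset applied), `start < peak < end`.
#' @export
clip_movement <- function(trunk_signal, path, frame_offset = 0L, min_seg = 15L) {
  states <- path$states
  if (length(trunk_signal) != length(states))
    rehab_error("trunk signal and path lengths differ", "rehabmm_arity_error")
  if (all(states == 0L))
    rehab_error("no non-rest segment: nothing to clip", "rehabmm_no_movement_error")
  rest <- state_segments(states, 0L, min_seg)
  if (is.null(rest)) rest <- state_segments(states, 0L)
  start <- if (rest[1L, "start"] <= min_seg) rest[1L, "end"] else 1L
  end <- if (rest[nrow(rest), "end"] >= length(states) - min_seg + 1L)
    rest[nrow(rest), "start"] else length(states)
  if (end - start < 2L)
    rehab_error("movement segment too short to clip", "rehabmm_no_movement_error")
  peak <- start + which.min(trunk_signal[start:end]) - 1L
  if (peak <= start || peak >= end)
    rehab_error("degenerate clip: peak coincides with a boundary",
                "rehabmm_no_movement_error")
  structure(list(start_frame = as.integer(unname(start + frame_offset)),
                 peak_frame = as.integer(unname(peak + frame_offset)),
                 end_frame = as.integer(unname(end + frame_offset))),
            class = "movement_clipping")
}

#' @export
print.movement_clipping <- function(x, ...) {
  cat(sprintf("<movement_clipping> start %d, peak %d, end %d\n",
              x$start_frame, x$peak_frame, x$end_frame))
  invisible(x)
}

#' Symmetry ratio of a clipped movement
#'
#' Time taken to reach the maximum amplitude divided by the time taken
#' to return to the initial pose. An evenly distributed effort yields 1;
#' values below 1 mean the peak was reached faster than the return.
#'
#' @param clip A [clip_movement()] result.
#' @return Ratio (positive scalar).
#' @export
symmetry_ratio <- function(clip) {
  denom <- clip$end_frame - clip$peak_frame
  if (denom <= 0 || clip$peak_frame <= clip$start_frame)
    rehab_error("degenerate clip: zero rise or fall duration", "rehabmm_degenerate_error")
  (clip$peak_frame - clip$start_frame) / denom
}

#' Report a timing ratio with its normalized form
#'
#' Ratios above 1 are reported alongside their reciprocal so that trial
#' averages can be computed on a common `(0, 1]` scale: the normalized
#' value is `min(r, 1/r)`, rounded to 2 decimals like the display value.
#'
#' @param r Positive ratio.
#' @return List with `display` (r, 2 decimals) and `normalized`
#'   (`min(r, 1/r)`, 2 decimals).
#' @export
#' @examples
#' report_ratio(1.16)  # display 1.16, normalized 0.86
report_ratio <- function(r) {
  if (!is.finite(r) || r <= 0)
    rehab_error("ratio must be positive", "rehabmm_domain_error")
  list(display = round(r, 2), normalized = round(min(r, 1 / r), 2))
}

state_segments <- function(states, state, min_seg = 1L) {
  r <- rle(states)
  ends <- cumsum(r$lengths)
  keep <- r$values == state & r$lengths >= min_seg
  if (!any(keep)) return(NULL)
  cbind(start = (ends - r$lengths + 1L)[keep], end = ends[keep])
}

#' Synchronicity ratio between hip and trunk movement
#'
#' Timing alignment of the trunk relative to the hip movement: the
#' midpoint `m` of the hold phase (state 2) of the hip phase path is
#' compared with the lengths of the trunk clip on either side of it,
#' `ratio = (end - m) / (m - start)`. Values below 1 mean the shoulders
#' moved before the hip abduction (the clip sits early relative to the
#' hold); 1 is perfect coordination. When several hold segments exist
#' (faulted trials) the longest one is used.
#'
#' @param hip_path A [viterbi_path()] from the hip phase model (4 states,
#'   hold = state 2).
#' @param trunk_clip A [clip_movement()] from the trunk model.
#' @param frame_offset Offset of `hip_path` frame indices (as in
#'   [clip_movement()]).
#' @return Ratio (positive scalar).
#' @export
synchronicity_ratio <- function(hip_path, trunk_clip, frame_offset = 0L) {
  segs <- state_segments(hip_path$states, 2L)
  if (is.null(segs))
    rehab_error("no hold (state 2) segment in the hip path: incoordination",
                "rehabmm_incoordination_error")
  seg <- segs[which.max(segs[, "end"] - segs[, "start"]), ]
  m <- floor((seg[["start"]] + seg[["end"]]) / 2) + frame_offset
  left <- m - trunk_clip$start_frame
  right <- trunk_clip$end_frame - m
  if (left <= 0 || right <= 0)
    rehab_error("hold midpoint outside the trunk clip: incoordination",
                "rehabmm_incoordination_error")
  right / left
}

#' Reference profile of decoded state paths
#'
#' Summarizes training-set Viterbi paths per state: how often the state
#' is visited per trial and how long its segments last. Used to flag
#' extra/missing transitions and elongated/shortened states in new
#' executions.
#'
#' @param paths List of [viterbi_path()]s (at least 3).
#' @param n_states Number of model states.
#' @param min_seg Minimum segment length in frames for a state visit to
#'   count (default 15, about 0.25 s at 60 Hz): shorter segments are
#'   decode blips, not phase realizations.
#' @return A `state_profile` data frame with one row per state:
#'   `visits_min`, `visits_max`, `duration_min`, `duration_max`; the
#'   segment filter is carried in attribute `min_seg`.
#' @export
state_profile <- function(paths, n_states, min_seg = 15L) {
  if (length(paths) < 3L)
    rehab_error("reference profile needs at least 3 training paths",
                "rehabmm_config_error")
  out <- lapply(seq_len(n_states) - 1L, function(s) {
    visits <- vapply(paths, function(p) {
      segs <- state_segments(p$states, s, min_seg)
      if (is.null(segs)) 0L else nrow(segs)
    }, integer(1))
    durs <- unlist(lapply(paths, function(p) {
      segs <- state_segments(p$states, s, min_seg)
      if (is.null(segs)) NULL else segs[, "end"] - segs[, "start"] + 1L
    }))
    data.frame(state = s, visits_min = min(visits), visits_max = max(visits),
               duration_min = if (length(durs)) min(durs) else NA_integer_,
               duration_max = if (length(durs)) max(durs) else NA_integer_)
  })
  out <- do.call(rbind, out)
  class(out) <- c("state_profile", "data.frame")
  attr(out, "min_seg") <- min_seg
  out
}

#' Detect state-transition anomalies against a reference profile
#'
#' A correct execution visits each phase a characteristic number of
#' times (e.g. the trunk bump state exactly twice). A state visited more
#' often than in any training path signals an extra transition (e.g. a
#' balance-loss bump); fewer visits signal a missing transition; segment
#' durations outside the training range (widened by `duration_slack`)
#' signal elongated/shortened phases.
#'
#' @param path A [viterbi_path()].
#' @param profile A [state_profile()].
#' @param duration_slack Multiplicative widening of the training duration
#'   range before flagging (default 1.25).
#' @return Data frame of flags with columns `kind`
#'   (`extra_transition`, `missing_transition`, `elongated_state`,
#'   `shortened_state`), `state`, `index` (segment ordinal, `NA` for
#'   visit-count flags).
#' @export
detect_transition_anomalies <- function(path, profile, duration_slack = 1.25) {
  if (!inherits(profile, "state_profile") || !nrow(profile))
    rehab_error("empty reference profile", "rehabmm_config_error")
  min_seg <- attr(profile, "min_seg") %||% 1L
  flags <- list()
  for (i in seq_len(nrow(profile))) {
    s <- profile$state[i]
    segs <- state_segments(path$states, s, min_seg)
    visits <- if (is.null(segs)) 0L else nrow(segs)
    # visit counts carry phase semantics only for states visited a
    # characteristic number of times in correct executions (e.g. the
    # bump state exactly twice); ramp states with variable counts are
    # exempt
    if (profile$visits_max[i] - profile$visits_min[i] <= 1L) {
      if (visits > profile$visits_max[i])
        flags[[length(flags) + 1L]] <- data.frame(kind = "extra_transition",
                                                  state = s, index = NA_integer_)
      if (visits < profile$visits_min[i])
        flags[[length(flags) + 1L]] <- data.frame(kind = "missing_transition",
                                                  state = s, index = NA_integer_)
    }
    # a phase's duration is that of its dominant (longest) segment;
    # decode blips can split a phase and say nothing about its length
    if (!is.null(segs) && !is.na(profile$duration_min[i])) {
      durs <- segs[, "end"] - segs[, "start"] + 1L
      j <- which.max(durs)
      if (durs[j] > ceiling(profile$duration_max[i] * duration_slack))
        flags[[length(flags) + 1L]] <- data.frame(kind = "elongated_state",
                                                  state = s, index = j)
      if (durs[j] < floor(profile$duration_min[i] / duration_slack))
        flags[[length(flags) + 1L]] <- data.frame(kind = "shortened_state",
                                                  state = s, index = j)
    }
  }
  if (!length(flags))
    return(data.frame(kind = character(), state = integer(), index = integer()))
  do.call(rbind, flags)
}

#' Direction of the error in low-likelihood windows
#'
#' For each window whose per-frame normalized forward log-likelihood
#' falls below `threshold`, compares the observed mean of every signed
#' directional-speed feature with the emission mean of the
#' Viterbi-aligned (majority) state over the window, and labels the
#' window with the direction of the largest absolute deviation (e.g.
#' `"left"` for a leftward drift the model did not expect).
#'
#' @param model A [gaussian_hmm()] whose features include directional
#'   (signed axis) speeds.
#' @param trace A [sliding_window_likelihood()] trace of `features`
#'   under `model`.
#' @param features `feature_series` or matrix used for the trace.
#' @param threshold Low-likelihood threshold (per-frame normalized log
#'   units).
#' @param direction_labels Named list mapping feature name to
#'   `c(negative, positive)` labels; defaults to the `feature_series`
#'   metadata.
#' @return Data frame with `window` (index), `feature`, `direction`,
#'   `deviation` for each flagged window (zero rows if none).
#' @export
error_direction <- function(model, trace, features, threshold,
                            direction_labels = NULL) {
  if (is.null(direction_labels) && inherits(features, "feature_series"))
    direction_labels <- features$direction_labels
  direction_labels <- direction_labels[names(direction_labels) %in% model$feature_names]
  if (!length(direction_labels))
    rehab_error("model has no directional-speed features", "rehabmm_unsupported_model")
  obs <- as_obs_matrix(features, model)
  first <- attr(features, "first_frame") %||%
    (if (inherits(features, "feature_series")) features$valid_from else 1L)
  path <- viterbi_path(model, obs)
  low <- which(trace$values < threshold)
  out <- lapply(low, function(w) {
    s0 <- trace$window_starts[w] - first + 1L
    idx <- s0:(s0 + trace$window_len - 1L)
    st <- as.integer(names(which.max(table(path$states[idx])))) + 1L
    devs <- vapply(names(direction_labels), function(f) {
      j <- match(f, model$feature_names)
      mean(obs[idx, j]) - model$means[st, j]
    }, numeric(1))
    top <- which.max(abs(devs))
    lab <- direction_labels[[top]][if (devs[top] < 0) 1L else 2L]
    data.frame(window = w, feature = names(direction_labels)[top],
               direction = lab, deviation = unname(devs[top]))
  })
  if (!length(out))
    return(data.frame(window = integer(), feature = character(),
                      direction = character(), deviation = numeric()))
  do.call(rbind, out)
}

#' Aggregate window likelihoods and flags into a single outcome
#'
#' The rule mirrors how fractions of a movement are assessed and then
#' summed into one verdict: `good` when there are no fault flags and
#' every model's worst window stays at or above its good threshold;
#' `fair` when there is at most one flag and every worst window stays at
#' or above its fair threshold; otherwise `bad`. Default thresholds are
#' the 25th (good) and 5th (fair) percentiles of the training-set
#' distribution of per-trial minimum window likelihoods, stored with
#' each trained model.
#'
#' @param min_window_liks Named numeric vector: worst per-frame
#'   normalized window log-likelihood per model.
#' @param flags Data frame of fault flags (one row per flag).
#' @param thresholds List with numeric vectors `good` and `fair`, named
#'   by model id.
#' @return `"good"`, `"fair"` or `"bad"`.
#' @export
aggregate_outcome <- function(min_window_liks, flags, thresholds) {
  ids <- names(min_window_liks)
  if (is.null(thresholds) || is.null(thresholds$good) || is.null(thresholds$fair) ||
      !all(ids %in% names(thresholds$good)) || !all(ids %in% names(thresholds$fair)))
    rehab_error("missing likelihood thresholds: train models with their assessment config",
                "rehabmm_config_error")
  n_flags <- if (is.null(flags)) 0L else nrow(flags)
  if (n_flags == 0L && all(min_window_liks >= thresholds$good[ids] - 1e-12))
    return("good")
  if (n_flags <= 1L && all(min_window_liks >= thresholds$fair[ids] - 1e-12))
    return("fair")
  "bad"
}
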