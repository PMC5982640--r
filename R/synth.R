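#' Specification of a synthetic hip-abduction trial
#'
#' States the world a synthetic trial is drawn from: a standing skeleton
#' whose right upper leg follows a smooth raised-cosine abduction
#' profile through the phases rest - rise - hold - fall - rest, with the
#' trunk counter-swaying towards the stance leg. Faults are expressed as
#' spec fields and are off by default.
#'
#' @param frame_rate Capture rate in Hz.
#' @param rest_before,rise,hold,fall,rest_after Phase durations in
#'   frames (each at least the speed-buffer length).
#' @param peak_abduction Peak leg angle in degrees, in (0, 90).
#' @param trunk_coupling Lateral shoulder-center sway amplitude in
#'   meters at peak abduction (trunk lean over the stance leg, additional
#'   to the pelvis shift).
#' @param pelvis_coupling Lateral pelvis weight-shift amplitude in
#'   meters at peak abduction (the whole body above the ankles follows).
#' @param trunk_shift Signed frames by which the trunk sway leads the
#'   leg movement (incoordination fault; positive = trunk moves early).
#' @param asymmetry Fall/rise duration multiplier (symmetry fault; 1 =
#'   even).
#' @param wobble_at Frame index of a balance-loss oscillation, or `NULL`.
#' @param wobble_amp Amplitude of the balance-loss sway pulse (m).
#' @param end_drift Leftward whole-body drift at the end of the
#'   movement (m; adduction-compensation fault).
#' @param reduced_rom Multiplier on `peak_abduction` (range-of-motion
#'   fault; 1 = full range).
#' @param noise_sd Positional jitter, meters. Jitter is band-limited
#'   (smoothed over the speed-buffer span) to emulate tracker output
#'   rather than white sensor noise.
#' @param seed Integer seed.
#' @return A `synthetic_motion_spec`.
#' @export
abduction_spec <- function(frame_rate = 60, rest_before = 90, rise = 120,
                           hold = 60, fall = 120, rest_after = 90,
                           peak_abduction = 40, trunk_coupling = 0.05,
                           pelvis_coupling = 0.02,
                           trunk_shift = 0, asymmetry = 1, wobble_at = NULL,
                           wobble_amp = 0, end_drift = 0, reduced_rom = 1,
                           noise_sd = 0.002, seed = 1) {
  spec <- structure(as.list(environment()), class = "synthetic_motion_spec")
  validate_motion_spec(spec)
  spec
}

validate_motion_spec <- function(spec) {
  buf <- max(2L, round(0.25 * spec$frame_rate))
  durations <- c(spec$rest_before, spec$rise, spec$hold, spec$fall, spec$rest_after)
  if (any(durations < buf))
    rehab_error(sprintf("all phase durations must be at least the buffer length (%d frames)",
                        buf), "rehabmm_config_error")
  peak <- spec$peak_abduction * spec$reduced_rom
  if (peak <= 0 || peak >= 90)
    rehab_error("effective peak abduction must lie in (0, 90) degrees",
                "rehabmm_config_error")
  if (spec$noise_sd < 0 || spec$trunk_coupling < 0 ||
      spec$pelvis_coupling < 0 || spec$asymmetry <= 0)
    rehab_error("noise_sd/couplings must be >= 0 and asymmetry > 0",
                "rehabmm_config_error")
  invisible(spec)
}

#' Inject movement faults into a synthetic trial spec
#'
#' Supported kinds: `trunk_shift` (frames of trunk lead), `asymmetry`
#' (fall/rise multiplier), `wobble` (balance-loss sway amplitude in m,
#' placed at the hold midpoint unless `wobble_at` is already set),
#' `end_drift` (leftward end-of-movement drift in m) and `reduced_rom`
#' (peak-angle multiplier). Faults are composable.
#'
#' @param spec A [abduction_spec()].
#' @param faults Named numeric vector/list, e.g.
#'   `c(wobble = 0.05, asymmetry = 1.5)`.
#' @return The modified spec.
#' @export
inject_faults <- function(spec, faults) {
  known <- c("trunk_shift", "asymmetry", "wobble", "end_drift", "reduced_rom")
  unknown <- setdiff(names(faults), known)
  if (length(unknown) || is.null(names(faults)))
    rehab_error(paste0("unknown fault kind(s): ",
                       paste(if (length(unknown)) unknown else "<unnamed>",
                             collapse = ", ")), "rehabmm_config_error")
  for (k in names(faults)) {
    v <- as.numeric(faults[[k]])
    if (k == "wobble") {
      spec$wobble_amp <- v
      if (is.null(spec$wobble_at))
        spec$wobble_at <- spec$rest_before + spec$rise + floor(spec$hold / 2)
    } else {
      spec[[k]] <- v
    }
  }
  validate_motion_spec(spec)
  spec
}

# Static standing skeleton template (camera coords, meters, y up, subject
# facing the camera at z = 2; the subject's left side is at camera +x).
skeleton_template <- function() {
  j <- function(x, y, z = 2) c(x, y, z)
  list(spine_base = j(0, 1.00), spine_mid = j(0, 1.25), neck = j(0, 1.50),
       head = j(0, 1.65), spine_shoulder = j(0, 1.45),
       shoulder_left = j(0.20, 1.45), elbow_left = j(0.25, 1.20),
       wrist_left = j(0.27, 0.95), hand_left = j(0.28, 0.88),
       hand_tip_left = j(0.28, 0.82), thumb_left = j(0.25, 0.90),
       shoulder_right = j(-0.20, 1.45), elbow_right = j(-0.25, 1.20),
       wrist_right = j(-0.27, 0.95), hand_right = j(-0.28, 0.88),
       hand_tip_right = j(-0.28, 0.82), thumb_right = j(-0.25, 0.90),
       hip_left = j(0.10, 0.95), knee_left = j(0.10, 0.50),
       ankle_left = j(0.10, 0.08), foot_left = j(0.10, 0.02, 1.88),
       hip_right = j(-0.10, 0.95), knee_right = j(-0.10, 0.50),
       ankle_right = j(-0.10, 0.08), foot_right = j(-0.10, 0.02, 1.88))
}

# Raised-cosine abduction angle profile with a 2% settle dip so that the
# maximum amplitude is attained exactly at the hold midpoint.
angle_profile <- function(spec) {
  peak <- spec$peak_abduction * spec$reduced_rom
  peak_eff <- peak * 0.98
  fall_eff <- max(2L, round(spec$fall * spec$asymmetry))
  u_rise <- seq_len(spec$rise) / spec$rise
  u_hold <- (seq_len(spec$hold) - 0.5) / spec$hold
  u_fall <- seq_len(fall_eff) / fall_eff
  theta <- c(rep(0, spec$rest_before),
             peak_eff / 2 * (1 - cos(pi * u_rise)),
             peak_eff + (peak - peak_eff) * sin(pi * u_hold),
             peak_eff / 2 * (1 + cos(pi * u_fall)),
             rep(0, spec$rest_after))
  phases <- c(rep(0L, spec$rest_before), rep(1L, spec$rise),
              rep(2L, spec$hold), rep(3L, fall_eff), rep(0L, spec$rest_after))
  list(theta = theta, phases = phases, fall_eff = fall_eff)
}

shift_series <- function(x, shift) {
  # positive shift moves the series earlier in time
  n <- length(x)
  if (shift == 0) return(x)
  if (shift > 0) c(x[(shift + 1):n], rep(x[n], shift))
  else c(rep(x[1L], -shift), x[1:(n + shift)])
}

#' Simulate a synthetic hip-abduction trial
#'
#' Generates a standing 25-joint skeleton whose right upper leg follows
#' the spec's abduction profile; the shoulder center sways laterally
#' towards the stance leg in proportion to the (possibly time-shifted)
#' leg angle, giving the characteristic twin speed bumps on rise and
#' fall; joint positions keep fixed limb lengths; quaternions follow the
#' leg direction; band-limited Gaussian jitter is added. Deterministic
#' per seed, and faults only touch their own support: frames outside it
#' are identical to the unfaulted trial at the same seed.
#'
#' @param spec A [abduction_spec()].
#' @param subject_id,trial_id Metadata for the emitted sequence.
#' @return List with `sequence` (a [motion_sequence()]) and `truth` (a
#'   `synthetic_truth`: per-frame phase labels 0-3, true peak frame,
#'   rise/fall frame counts, injected fault kinds).
#' @export
simulate_abduction <- function(spec, subject_id = "s1", trial_id = "t1") {
  validate_motion_spec(spec)
  prof <- angle_profile(spec)
  n <- length(prof$theta)
  joints <- kinect_joints()
  theta <- prof$theta
  peak <- spec$peak_abduction * spec$reduced_rom
  theta_trunk <- shift_series(theta, round(spec$trunk_shift))
  # weight shift towards the stance (left) leg: the pelvis translates and
  # the trunk additionally leans, both towards camera +x
  pelvis <- spec$pelvis_coupling * theta_trunk / max(peak, 1e-9)
  sway <- spec$trunk_coupling * theta_trunk / max(peak, 1e-9)
  if (!is.null(spec$wobble_at) && spec$wobble_amp > 0) {
    sigma <- 0.15 * spec$frame_rate
    d2 <- (seq_len(n) - spec$wobble_at)^2
    pulse <- spec$wobble_amp * exp(-d2 / (2 * sigma^2))
    pulse[d2 > (4 * sigma)^2] <- 0  # compact support: fault stays local
    sway <- sway + pulse
  }
  drift <- rep(0, n)
  if (spec$end_drift > 0) {
    d0 <- spec$rest_before + spec$rise + spec$hold + floor(prof$fall_eff / 2)
    d1 <- spec$rest_before + spec$rise + spec$hold + prof$fall_eff +
      floor(spec$rest_after / 2)
    idx <- seq.int(d0, d1)
    drift[idx] <- spec$end_drift * 0.5 * (1 - cos(pi * (idx - d0) / (d1 - d0)))
    if (d1 < n) drift[(d1 + 1):n] <- spec$end_drift
  }
  tmpl <- skeleton_template()
  pos <- array(0, c(n, 25L, 3L), dimnames = list(NULL, joints, c("x", "y", "z")))
  for (j in joints) pos[, j, ] <- matrix(tmpl[[j]], n, 3L, byrow = TRUE)
  # the feet stay planted; everything above the ankles shifts with the
  # pelvis (weight shift + any end-of-movement drift)
  planted <- c("ankle_left", "foot_left", "ankle_right", "foot_right")
  shifted <- setdiff(joints, planted)
  for (j in shifted) pos[, j, "x"] <- pos[, j, "x"] + pelvis + drift
  # right leg rotates about the (shifted) right hip in the frontal plane
  th <- theta * pi / 180
  hip_r <- tmpl$hip_right
  for (j in c("knee_right", "ankle_right", "foot_right")) {
    off <- tmpl[[j]] - hip_r
    r <- sqrt(off[1L]^2 + off[2L]^2)
    # offsets are straight below the hip; abduction swings them to the
    # subject's right (camera -x)
    pos[, j, "x"] <- hip_r[1L] + pelvis + drift - r * sin(th)
    pos[, j, "y"] <- hip_r[2L] - r * cos(th)
    pos[, j, "z"] <- tmpl[[j]][3L]
  }
  # trunk lean: everything above the pelvis translates further laterally
  upper <- c("spine_mid", "spine_shoulder", "neck", "head",
             "shoulder_left", "elbow_left", "wrist_left", "hand_left",
             "hand_tip_left", "thumb_left",
             "shoulder_right", "elbow_right", "wrist_right", "hand_right",
             "hand_tip_right", "thumb_right")
  for (j in upper) pos[, j, "x"] <- pos[, j, "x"] + sway
  # band-limited positional jitter (consumed identically whatever the
  # faults): white noise smoothed with a Gaussian kernel of sd 0.25 s, so
  # the induced velocity noise stays well below genuine joint speeds
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed, matrix(rnorm(n * 75L), n, 75L))
    ks <- 0.25 * spec$frame_rate
    kern <- dnorm(seq(-ceiling(3 * ks), ceiling(3 * ks)), sd = ks)
    kern <- kern / sum(kern)
    sm <- apply(noise, 2L, function(x)
      stats::filter(x, kern, sides = 2L, circular = TRUE))
    sm <- sm / sd(as.vector(sm)) * spec$noise_sd
    pos <- pos + array(sm, dim(pos))
  }
  # quaternions: identity everywhere except the abducting leg chain,
  # which rotates about the camera z axis by -theta
  ori <- array(0, c(n, 25L, 4L), dimnames = list(NULL, joints, c("qw", "qx", "qy", "qz")))
  ori[, , "qw"] <- 1
  for (j in c("knee_right", "ankle_right", "foot_right")) {
    ori[, j, "qw"] <- cos(-th / 2)
    ori[, j, "qz"] <- sin(-th / 2)
    ori[, j, "qx"] <- 0; ori[, j, "qy"] <- 0
  }
  floor <- matrix(c(0, 1, 0, 0), n, 4L, byrow = TRUE,
                  dimnames = list(NULL, c("a", "b", "c", "d")))
  seqn <- motion_sequence((seq_len(n) - 1L) / spec$frame_rate, pos, ori, floor,
                          frame_rate = spec$frame_rate, subject_id = subject_id,
                          trial_id = trial_id)
  faults <- c(if (spec$trunk_shift != 0) "trunk_shift",
              if (spec$asymmetry != 1) "asymmetry",
              if (!is.null(spec$wobble_at) && spec$wobble_amp > 0) "wobble",
              if (spec$end_drift > 0) "end_drift",
              if (spec$reduced_rom != 1) "reduced_rom")
  truth <- structure(
    list(phases = prof$phases,
         peak_frame = spec$rest_before + spec$rise + ceiling(spec$hold / 2),
         rise_frames = spec$rise, fall_frames = prof$fall_eff,
         faults = faults %||% character(0)),
    class = "synthetic_truth")
  list(sequence = seqn, truth = truth)
}

default_fault_magnitude <- function(kind, u) {
  # u in [0, 1): scales within the plausible clinical range of each fault
  switch(kind,
         trunk_shift = round(18 + u * 18),       # 0.3-0.6 s trunk lead
         asymmetry = 1.4 + u * 0.5,
         wobble = 0.03 + u * 0.03,
         end_drift = 0.06 + u * 0.06,
         reduced_rom = 0.7 - u * 0.3)
}

fault_aspect <- function(kind) {
  switch(kind, reduced_rom = "ROM", trunk_shift = "coordination",
         "compensation")
}

fault_severity <- function(kind, magnitude) {
  bad <- switch(kind, trunk_shift = magnitude >= 27, asymmetry = magnitude >= 1.6,
                wobble = magnitude >= 0.045, end_drift = magnitude >= 0.09,
                reduced_rom = magnitude <= 0.55)
  if (bad) "bad" else "fair"
}

#' Generate a labelled synthetic cohort
#'
#' Emulates a multi-subject recording protocol: each subject receives
#' random kinematic idiosyncrasies (phase durations, peak angle, sway
#' amplitude, jitter level), each exercise preset is repeated
#' `trials_per_subject` times, and a fixed fraction of trials receives
#' one randomly drawn fault. Therapist-style labels are auto-generated:
#' clean trials are rated good on all aspects by every rater; a faulted
#' trial is rated fair or bad (by fault magnitude) on the aspect its
#' fault affects.
#'
#' @param n_subjects Number of subjects (at least 2).
#' @param trials_per_subject Repetitions of each preset per subject.
#' @param fault_rate Fraction of trials receiving a fault.
#' @param seed Integer seed.
#' @param exercise_presets Named list of base [abduction_spec()]s, one
#'   per exercise (default: a single hip-abduction preset).
#' @param n_raters Number of simulated raters.
#' @return A `motion_cohort`: list with `trials` (motion sequences),
#'   `truths`, `labels` (a `therapist_labels` data frame) and the
#'   generating settings.
#' @export
generate_cohort <- function(n_subjects, trials_per_subject = 8, fault_rate = 0,
                            seed = 1, exercise_presets = NULL, n_raters = 3) {
  if (n_subjects < 2) rehab_error("need at least 2 subjects", "rehabmm_config_error")
  if (is.null(exercise_presets))
    exercise_presets <- list(hip_abduction = abduction_spec())
  n_total <- n_subjects * length(exercise_presets) * trials_per_subject
  plan <- with_seed(seed, {
    faulted <- sample.int(n_total, round(fault_rate * n_total))
    kinds <- sample(c("trunk_shift", "asymmetry", "wobble", "end_drift",
                      "reduced_rom"), length(faulted), replace = TRUE)
    mags <- runif(length(faulted))
    subj <- lapply(seq_len(n_subjects), function(i)
      list(dur_scale = runif(5, 0.85, 1.15), peak = runif(1, 35, 45),
           coupling = runif(1, 0.04, 0.06), pelvis = runif(1, 0.015, 0.025),
           noise = runif(1, 0.0015, 0.0025)))
    list(faulted = faulted, kinds = kinds, mags = mags, subj = subj,
         trial_seeds = sample.int(2^30, n_total))
  })
  trials <- list(); truths <- list(); label_rows <- list()
  k <- 0L
  for (i in seq_len(n_subjects)) {
    sid <- paste0("s", i)
    idio <- plan$subj[[i]]
    t_in_subject <- 0L
    for (ex in names(exercise_presets)) {
      base <- exercise_presets[[ex]]
      for (rep_i in seq_len(trials_per_subject)) {
        k <- k + 1L
        t_in_subject <- t_in_subject + 1L
        tid <- paste0("t", t_in_subject)
        sp <- base
        ds <- idio$dur_scale
        sp$rest_before <- round(base$rest_before * ds[1L])
        sp$rise <- round(base$rise * ds[2L])
        sp$hold <- round(base$hold * ds[3L])
        sp$fall <- round(base$fall * ds[4L])
        sp$rest_after <- round(base$rest_after * ds[5L])
        sp$peak_abduction <- idio$peak
        sp$trunk_coupling <- idio$coupling
        sp$pelvis_coupling <- idio$pelvis
        sp$noise_sd <- idio$noise
        sp$seed <- plan$trial_seeds[k]
        fi <- match(k, plan$faulted)
        aspects <- c(ROM = "good", coordination = "good", compensation = "good")
        if (!is.na(fi)) {
          kind <- plan$kinds[fi]
          mag <- default_fault_magnitude(kind, plan$mags[fi])
          sp <- inject_faults(sp, stats::setNames(list(mag), kind))
          aspects[fault_aspect(kind)] <- fault_severity(kind, mag)
        }
        sim <- simulate_abduction(sp, subject_id = sid, trial_id = tid)
        sim$sequence$exercise_id <- ex
        trials[[k]] <- sim$sequence
        truths[[k]] <- sim$truth
        for (r in seq_len(n_raters))
          for (a in names(aspects))
            label_rows[[length(label_rows) + 1L]] <- data.frame(
              subject_id = sid, trial_id = tid, aspect = a,
              rating = aspects[[a]], rater_id = paste0("r", r),
              stringsAsFactors = FALSE)
      }
    }
  }
  labels <- normalize_labels(do.call(rbind, label_rows))
  structure(list(trials = trials, truths = truths, labels = labels,
                 n_subjects = n_subjects, trials_per_subject = trials_per_subject,
                 fault_rate = fault_rate, seed = seed),
            class = "motion_cohort")
}

#' @export
print.motion_cohort <- function(x, ...) {
  n_faulted <- sum(vapply(x$truths, function(t) length(t$faults) > 0, logical(1)))
  cat(sprintf("<motion_cohort> %d trials (%d subjects), %d faulted (seed %d)\n",
              length(x$trials), x$n_subjects, n_faulted, x$seed))
  invisible(x)
}

#' Write a cohort to disk (frame CSVs, labels CSV, truth JSON)
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$trials)) {
    tr <- cohort$trials[[i]]
    write_motion_csv(tr, file.path(dir, sprintf("%s_%s_%s.csv", tr$subject_id,
                                                tr$exercise_id, tr$trial_id)))
  }
  write.csv(cohort$labels, file.path(dir, "labels.csv"), row.names = FALSE)
  truth <- lapply(seq_along(cohort$truths), function(i) {
    t <- cohort$truths[[i]]
    tr <- cohort$trials[[i]]
    list(subject_id = tr$subject_id, trial_id = tr$trial_id,
         exercise_id = tr$exercise_id, peak_frame = t$peak_frame,
         rise_frames = t$rise_frames, fall_frames = t$fall_frames,
         faults = as.list(t$faults), phases = t$phases)
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
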