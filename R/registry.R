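#' Assessment configuration
#'
#' Tunables of the multi-model assessment blueprint, echoed into every
#' report for audit.
#'
#' @param window_len,stride Sliding-window geometry in frames.
#' @param good_pctl Percentile of the training-set distribution of
#'   per-trial minimum window log-likelihoods below which an execution
#'   no longer counts as good.
#' @param novelty_margin Fault-flag margin in per-frame log-likelihood
#'   units (nats/frame): a window flags as low-likelihood only when it
#'   falls below the training envelope (the worst training minimum) by
#'   more than `max(envelope spread, novelty_margin)`. Healthy
#'   held-out-subject variability stays within a couple of nats/frame
#'   of the envelope while genuine execution faults overshoot it by an
#'   order of magnitude, so the operating point is deliberately wide.
#' @param duration_slack Widening factor for training state-duration
#'   ranges before flagging.
#' @param ratio_margin Slack below the minimum training normalized ratio
#'   before a symmetry/synchronicity flag is raised.
#' @param min_good_fraction Rater fraction that must label every aspect
#'   good for a trial to count as correct in training (strict majority
#'   by default).
#' @return An `assessment_config` list.
#' @export
assessment_config <- function(window_len = 60, stride = 15,
                              good_pctl = 0.25, novelty_margin = 3,
                              duration_slack = 1.25, ratio_margin = 0.05,
                              min_good_fraction = 0.5) {
  structure(list(window_len = window_len, stride = stride,
                 good_pctl = good_pctl, novelty_margin = novelty_margin,
                 duration_slack = duration_slack, ratio_margin = ratio_margin,
                 min_good_fraction = min_good_fraction),
            class = "assessment_config")
}

# Flag threshold: the training envelope (worst training minimum) widened
# by its own spread or the configured novelty margin, whichever is larger.
flag_threshold <- function(min_liks, cfg) {
  min(min_liks) - max(median(min_liks) - min(min_liks), cfg$novelty_margin)
}

registry_entry <- function(id, name, features, n_states, role = "aux") {
  list(id = id, name = name, features = features, n_states = n_states,
       role = role, model = NULL, stats = NULL)
}

#' Canonical model registry for hip abduction
#'
#' The multi-model blueprint assigns one HMM per semantic movement
#' aspect. The canonical entries are model II "Trunk Movement"
#' (shoulder-center and hip-center speed, 3 states) and model V "Right
#' Hip Frontal" (right hip frontal angular speed and angle, 4 states).
#' A third entry "D" (pelvis drift, signed left/right and up/down
#' hip-center speeds, 3 states) supplies the directional features used
#' to label the direction of an error; further slots of the blueprint
#' can be added via `extra`.
#'
#' @param config An [assessment_config()].
#' @param extra Optional named list of additional entries.
#' @return A `model_registry`.
#' @export
abduction_registry <- function(config = assessment_config(), extra = NULL) {
  entries <- list(
    II = registry_entry("II", "Trunk Movement",
                        c("shoulder_center_speed", "hip_center_speed"),
                        n_states = 3L, role = "trunk"),
    V = registry_entry("V", "Right Hip Frontal",
                       c("right_hip_frontal_angular_speed", "right_hip_frontal_angle"),
                       n_states = 4L, role = "hip"),
    D = registry_entry("D", "Pelvis Drift",
                       c("hip_center_lr_speed", "hip_center_ud_speed"),
                       n_states = 3L, role = "direction"))
  if (!is.null(extra)) entries <- c(entries, extra)
  if (anyDuplicated(names(entries)))
    rehab_error("registry ids must be unique", "rehabmm_config_error")
  structure(list(entries = entries, config = config), class = "model_registry")
}

#' @export
print.model_registry <- function(x, ...) {
  cat(sprintf("<model_registry> %d entr%s\n", length(x$entries),
              if (length(x$entries) == 1L) "y" else "ies"))
  for (e in x$entries)
    cat(sprintf("  %-3s %-18s %d states, features: %s%s\n", e$id, e$name,
                e$n_states, paste(e$features, collapse = ", "),
                if (is.null(e$model)) " (untrained)" else ""))
  invisible(x)
}

entry_by_role <- function(registry, role) {
  for (e in registry$entries) if (identical(e$role, role)) return(e)
  NULL
}

#' Train every registry model on a set of correct trials
#'
#' Fits each entry's HMM on its bound feature channels across the
#' training trials, then stores the training statistics the assessment
#' thresholds are drawn from: the distribution of per-trial minimum
#' window log-likelihoods, the decoded state profile, and the
#' symmetry/synchronicity ratios of the training trials themselves.
#'
#' @param registry A [abduction_registry()]-style registry.
#' @param feature_list List of `feature_series`, one per correct
#'   training trial.
#' @param seed Integer seed.
#' @return The registry with trained `model` and `stats` per entry plus
#'   registry-level `ratio_stats`.
#' @export
train_registry <- function(registry, feature_list, seed = 1) {
  if (!length(feature_list))
    rehab_error("no training trials", "rehabmm_config_error")
  cfg <- registry$config
  for (i in seq_along(registry$entries)) {
    e <- registry$entries[[i]]
    fit <- baum_welch_fit(feature_list, e$n_states, seed = seed + i,
                          feature_names = e$features)
    fit$model <- relabel_states_temporal(fit$model, feature_list)
    traces <- lapply(feature_list, function(fs)
      sliding_window_likelihood(fit$model, fs, cfg$window_len, cfg$stride))
    paths <- lapply(feature_list, function(fs)
      viterbi_path(fit$model, fs))
    min_liks <- vapply(traces, function(tr) min(tr$values), numeric(1))
    e$model <- fit$model
    e$fit_report <- fit$report
    e$stats <- list(
      min_liks = min_liks,
      good_threshold = unname(quantile(min_liks, cfg$good_pctl, type = 7)),
      fair_threshold = flag_threshold(min_liks, cfg),
      profile = state_profile(paths, e$n_states))
    registry$entries[[i]] <- e
  }
  registry$ratio_stats <- training_ratio_stats(registry, feature_list)
  registry
}

# Symmetry/synchronicity ratios of the training trials under the freshly
# trained models; their normalized minima anchor the ratio anomaly bands.
training_ratio_stats <- function(registry, feature_list) {
  trunk <- entry_by_role(registry, "trunk")
  hip <- entry_by_role(registry, "hip")
  if (is.null(trunk) || is.null(hip)) return(NULL)
  sym <- num <- numeric(0)
  for (fs in feature_list) {
    res <- tryCatch({
      sway <- feature_matrix(fs, "shoulder_center_sway")
      tp <- viterbi_path(trunk$model, fs)
      clip <- clip_movement(as.vector(sway), tp, attr(sway, "first_frame") - 1L)
      hp <- viterbi_path(hip$model, fs)
      c(report_ratio(symmetry_ratio(clip))$normalized,
        report_ratio(synchronicity_ratio(hp, clip, fs$valid_from - 1L))$normalized)
    }, rehabmm_error = function(e) NULL, error = function(e) NULL)
    if (!is.null(res)) { sym <- c(sym, res[1L]); num <- c(num, res[2L]) }
  }
  if (length(sym) < 3L) return(NULL)
  list(symmetry = sym, synchronicity = num,
       symmetry_min = min(sym), synchronicity_min = min(num))
}

# Strict-majority consensus: a trial is correct when at least
# `min_good_fraction` of its raters label every aspect good.
correct_trial_ids <- function(labels, min_good_fraction = 0.5) {
  key <- interaction(labels$subject_id, labels$trial_id, drop = TRUE)
  ok <- vapply(split(labels, key), function(df) {
    all(vapply(split(df, df$aspect), function(a)
      mean(a$rating == "good") > min_good_fraction, logical(1)))
  }, logical(1))
  names(ok)[ok]
}

#' Leave-one-subject-out training
#'
#' For each subject, trains every registry model on the correct trials
#' (by therapist-label consensus) of all other subjects, mirroring how
#' per-patient reference models are built without the patient's own
#' data.
#'
#' @param trials List of `motion_sequence` trials (subject/trial ids in
#'   their metadata).
#' @param labels A `therapist_labels` data frame covering the trials.
#' @param registry Registry template (e.g. [abduction_registry()]).
#' @param seed Integer seed.
#' @param specs Feature specs used for extraction (default
#'   [abduction_preset()]).
#' @return Named list (one element per subject) of trained registries,
#'   each carrying `training_trials` bookkeeping (the subject/trial ids
#'   it was fitted on).
#' @export
loso_train <- function(trials, labels, registry = abduction_registry(),
                       seed = 1, specs = abduction_preset()) {
  subjects <- unique(vapply(trials, `[[`, character(1), "subject_id"))
  if (length(subjects) < 2L)
    rehab_error("leave-one-subject-out needs at least 2 subjects",
                "rehabmm_config_error")
  good <- correct_trial_ids(labels, registry$config$min_good_fraction)
  keys <- vapply(trials, function(tr) paste(tr$subject_id, tr$trial_id, sep = "."),
                 character(1))
  subject_of <- vapply(trials, `[[`, character(1), "subject_id")
  feats <- lapply(trials, extract_features, specs = specs)
  out <- list()
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    idx <- which(subject_of != s & keys %in% good)
    if (!length(idx))
      rehab_error(paste0("no correct training trials for held-out subject ", s),
                  "rehabmm_fold_error")
    reg <- train_registry(registry, feats[idx], seed = seed + 100L * si)
    reg$held_out <- s
    reg$training_trials <- keys[idx]
    out[[s]] <- reg
  }
  if (length(subjects) >= 3L) out <- crossfold_stats(out, feats, keys, good,
                                                     subject_of, registry$config)
  out
}

# Fitted likelihoods are optimistic: a fold's own training minima sit too
# high for an unseen subject. Every correct trial of subject u has an
# unbiased score under the registry that held u out, so thresholds,
# state profiles and ratio bands are rebuilt from those cross-fold
# scores (needs >= 3 subjects so each fold keeps >= 2 score sources).
crossfold_stats <- function(regs, feats, keys, good, subject_of, cfg) {
  idx <- which(keys %in% good)
  ids <- names(regs[[1L]]$entries)
  scores <- lapply(idx, function(i) {
    reg_u <- regs[[subject_of[i]]]
    fs <- feats[[i]]
    per <- lapply(reg_u$entries, function(e) {
      tr <- sliding_window_likelihood(e$model, fs, cfg$window_len, cfg$stride)
      list(min_lik = min(tr$values), path = viterbi_path(e$model, fs))
    })
    trunk <- entry_by_role(reg_u, "trunk")
    hip <- entry_by_role(reg_u, "hip")
    ratios <- c(symmetry = NA_real_, synchronicity = NA_real_)
    if (!is.null(trunk) && !is.null(hip)) {
      ratios <- tryCatch({
        sway <- feature_matrix(fs, "shoulder_center_sway")
        clip <- clip_movement(as.vector(sway), per[[trunk$id]]$path,
                              attr(sway, "first_frame") - 1L)
        c(symmetry = report_ratio(symmetry_ratio(clip))$normalized,
          synchronicity = report_ratio(synchronicity_ratio(
            per[[hip$id]]$path, clip, fs$valid_from - 1L))$normalized)
      }, error = function(e) c(symmetry = NA_real_, synchronicity = NA_real_))
    }
    list(subject = subject_of[i], per = per, ratios = ratios)
  })
  for (s in names(regs)) {
    use <- which(vapply(scores, `[[`, character(1), "subject") != s)
    # likelihood thresholds and ratio bands use the unbiased cross-fold
    # scores; state profiles stay in-sample, where decode labels are
    # consistent with this fold's own models (bump/ramp roles are not
    # label-stable across folds, and visit structure is not
    # optimism-prone the way likelihood levels are)
    for (id in ids) {
      min_liks <- vapply(scores[use], function(x) x$per[[id]]$min_lik, numeric(1))
      regs[[s]]$entries[[id]]$stats$min_liks <- min_liks
      regs[[s]]$entries[[id]]$stats$good_threshold <-
        unname(quantile(min_liks, cfg$good_pctl, type = 7))
      regs[[s]]$entries[[id]]$stats$fair_threshold <-
        flag_threshold(min_liks, cfg)
    }
    sym <- vapply(scores[use], function(x) x$ratios[["symmetry"]], numeric(1))
    syn <- vapply(scores[use], function(x) x$ratios[["synchronicity"]], numeric(1))
    sym <- sym[!is.na(sym)]; syn <- syn[!is.na(syn)]
    if (length(sym) >= 3L && length(syn) >= 3L)
      regs[[s]]$ratio_stats <- list(symmetry = sym, synchronicity = syn,
                                    symmetry_min = min(sym),
                                    synchronicity_min = min(syn))
  }
  regs
}

#' Assess one movement execution with a trained registry
#'
#' Runs every registered model on its bound features, then derives the
#' full assessment: sliding-window likelihood traces and Viterbi phase
#' paths per model, the trunk movement clip, symmetry and synchronicity
#' ratios, transition anomalies against the training profiles, error
#' direction labels for low-likelihood windows of the directional model,
#' and the aggregated good/fair/bad outcome.
#'
#' @param registry A trained registry (see [train_registry()] /
#'   [loso_train()]).
#' @param features A `feature_series` of the trial (covering all
#'   registered channels).
#' @return A `movement_assessment`: per-model results, `symmetry` and
#'   `synchronicity` (display + normalized), `clip`, `flags` data frame,
#'   `outcome`.
#' @export
classify_movement <- function(registry, features) {
  if (!length(registry$entries))
    rehab_error("empty model registry", "rehabmm_config_error")
  cfg <- registry$config
  per_model <- list()
  flags <- list()
  add_flag <- function(model, kind, state = NA_integer_, window = NA_integer_,
                       direction = NA_character_) {
    flags[[length(flags) + 1L]] <<- data.frame(
      model = model, kind = kind, state = state, window = window,
      direction = direction, stringsAsFactors = FALSE)
  }
  offset <- features$valid_from - 1L
  for (e in registry$entries) {
    if (is.null(e$model))
      rehab_error(paste0("registry entry ", e$id, " is untrained"),
                  "rehabmm_config_error")
    res <- tryCatch({
      tr <- sliding_window_likelihood(e$model, features, cfg$window_len, cfg$stride)
      pa <- viterbi_path(e$model, features)
      ll <- forward_loglik(e$model, features)
      # overlapping windows mean any real fault depresses several; a
      # single sub-threshold window is a threshold graze, not evidence
      if (sum(tr$values < e$stats$fair_threshold) >= 2L) {
        if (identical(e$role, "direction")) {
          dirs <- error_direction(e$model, tr, features, e$stats$fair_threshold)
          for (k in seq_len(nrow(dirs)))
            add_flag(e$id, "low_likelihood", window = dirs$window[k],
                     direction = dirs$direction[k])
        } else {
          add_flag(e$id, "low_likelihood", window = tr$min_index)
        }
      }
      if (e$role %in% c("trunk", "hip")) {
        an <- detect_transition_anomalies(pa, e$stats$profile, cfg$duration_slack)
        for (k in seq_len(nrow(an)))
          add_flag(e$id, an$kind[k], state = an$state[k])
      }
      list(id = e$id, loglik = ll, loglik_per_frame = ll / nrow(feature_matrix(features, e$features)),
           trace = tr, path = pa)
    }, rehabmm_error = function(err) {
      add_flag(e$id, "model_error")
      list(id = e$id, error = conditionMessage(err))
    })
    per_model[[e$id]] <- res
  }
  trunk <- entry_by_role(registry, "trunk")
  hip <- entry_by_role(registry, "hip")
  clip <- NULL; symmetry <- NULL; synchronicity <- NULL
  rs <- registry$ratio_stats
  if (!is.null(trunk) && is.null(per_model[[trunk$id]]$error)) {
    clip <- tryCatch({
      sway <- feature_matrix(features, "shoulder_center_sway")
      clip_movement(as.vector(sway), per_model[[trunk$id]]$path, offset)
    }, rehabmm_error = function(e) { add_flag(trunk$id, "no_movement"); NULL })
    if (!is.null(clip)) {
      symmetry <- report_ratio(symmetry_ratio(clip))
      if (!is.null(rs) && symmetry$normalized < rs$symmetry_min - cfg$ratio_margin)
        add_flag(trunk$id, "asymmetry")
      if (!is.null(hip) && is.null(per_model[[hip$id]]$error)) {
        synchronicity <- tryCatch(
          report_ratio(synchronicity_ratio(per_model[[hip$id]]$path, clip, offset)),
          rehabmm_incoordination_error = function(e) {
            add_flag(hip$id, "incoordination"); NULL
          })
        if (!is.null(synchronicity) && !is.null(rs) &&
            synchronicity$normalized < rs$synchronicity_min - cfg$ratio_margin)
          add_flag(hip$id, "incoordination")
      }
    }
  }
  flags <- if (length(flags)) do.call(rbind, flags)
           else data.frame(model = character(), kind = character(),
                           state = integer(), window = integer(),
                           direction = character(), stringsAsFactors = FALSE)
  scored <- names(per_model)[vapply(per_model, function(p) is.null(p$error), logical(1))]
  min_liks <- vapply(per_model[scored], function(p) min(p$trace$values), numeric(1))
  names(min_liks) <- scored
  thresholds <- list(
    good = vapply(registry$entries[scored], function(e) e$stats$good_threshold, numeric(1)),
    fair = vapply(registry$entries[scored], function(e) e$stats$fair_threshold, numeric(1)))
  outcome <- aggregate_outcome(min_liks, flags, thresholds)
  structure(list(per_model = per_model, clip = clip, symmetry = symmetry,
                 synchronicity = synchronicity, flags = flags,
                 outcome = outcome, config = cfg),
            class = "movement_assessment")
}

#' @export
print.movement_assessment <- function(x, ...) {
  cat(sprintf("<movement_assessment> outcome: %s, %d flag(s)\n",
              x$outcome, nrow(x$flags)))
  if (!is.null(x$symmetry))
    cat(sprintf("  symmetry: %.2f (normalized %.2f)\n",
                x$symmetry$display, x$symmetry$normalized))
  if (!is.null(x$synchronicity))
    cat(sprintf("  synchronicity: %.2f (normalized %.2f)\n",
                x$synchronicity$display, x$synchronicity$normalized))
  if (nrow(x$flags)) {
    cat("  flags:\n")
    for (i in seq_len(nrow(x$flags)))
      cat(sprintf("    [%s] %s%s%s\n", x$flags$model[i], x$flags$kind[i],
                  if (!is.na(x$flags$state[i])) paste0(" state ", x$flags$state[i]) else "",
                  if (!is.na(x$flags$direction[i])) paste0(" -> ", x$flags$direction[i]) else ""))
  }
  invisible(x)
}
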