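test_that("sliding windows tile the sequence and localize perturbations", {
  m <- rand_hmm(2, 2, seed = 61)
  obs <- sample_sequence(m, 200, seed = 6)
  tr <- sliding_window_likelihood(m, obs, window_len = 60, stride = 15)
  expect_identical(tr$window_starts, seq(1L, 141L, by = 15L))
  expect_true(all(is.finite(tr$values)))
  # self-sampled data: no window is a gross outlier
  expect_true(all(abs(tr$values - median(tr$values)) <=
                    3 * mad(tr$values) + 1e-8))

  # stride = len - window gives exactly two windows
  tr2 <- sliding_window_likelihood(m, obs, window_len = 60, stride = 140)
  expect_identical(length(tr2$values), 2L)

  # a displaced window attains the trace minimum
  obs_bad <- obs
  obs_bad[101:160, ] <- obs_bad[101:160, ] +
    10 * sqrt(max(m$variances))
  tr3 <- sliding_window_likelihood(m, obs_bad, window_len = 60, stride = 15)
  expect_true(tr3$window_starts[tr3$min_index] %in% seq(61L, 121L, by = 15L))
  expect_error(sliding_window_likelihood(m, obs, window_len = 1),
               class = "rehabmm_config_error")
})

test_that("movement clipping brackets the activity between rest terminations", {
  states <- c(rep(0L, 50), rep(1L, 40), rep(2L, 30), rep(3L, 40), rep(0L, 50))
  path <- structure(list(states = states, log_joint = 0), class = "viterbi_path")
  signal <- -c(rep(0, 50), seq(0, 1, length.out = 40), rep(1, 29), 1.05,
               seq(1, 0, length.out = 40), rep(0, 50))
  clip <- clip_movement(signal, path)
  expect_identical(clip$start_frame, 50L)
  expect_identical(clip$end_frame, 161L)
  expect_identical(clip$peak_frame, 120L)  # the deepest valley
  expect_true(clip$start_frame < clip$peak_frame &&
                clip$peak_frame < clip$end_frame)

  all_rest <- structure(list(states = rep(0L, 100), log_joint = 0),
                        class = "viterbi_path")
  expect_error(clip_movement(rep(0, 100), all_rest),
               class = "rehabmm_no_movement_error")
  expect_error(clip_movement(rep(0, 10), path), class = "rehabmm_arity_error")
})

test_that("symmetry and ratio reporting follow the reciprocal convention", {
  clip <- structure(list(start_frame = 0L, peak_frame = 60L, end_frame = 150L),
                    class = "movement_clipping")
  expect_equal(symmetry_ratio(clip), 60 / 90, tolerance = 1e-12)
  clip2 <- structure(list(start_frame = 0L, peak_frame = 90L, end_frame = 150L),
                     class = "movement_clipping")
  expect_equal(symmetry_ratio(clip2), 1.5, tolerance = 1e-12)

  expect_equal(report_ratio(1.16), list(display = 1.16, normalized = 0.86))
  expect_equal(report_ratio(1), list(display = 1, normalized = 1))
  expect_equal(report_ratio(0.74), list(display = 0.74, normalized = 0.74))
  expect_error(report_ratio(0), class = "rehabmm_domain_error")
  # normalized form is orientation invariant and lives in (0, 1]
  set.seed(3)
  for (r in exp(runif(200, -2, 2))) {
    n1 <- report_ratio(r)$normalized
    expect_identical(n1, report_ratio(1 / r)$normalized)
    expect_true(n1 > 0 && n1 <= 1)
  }
})

test_that("synchronicity uses the hold midpoint of the hip path", {
  trunk_clip <- structure(list(start_frame = 100L, peak_frame = 190L,
                               end_frame = 280L), class = "movement_clipping")
  hip_states <- c(rep(0L, 99), rep(1L, 60), rep(2L, 61), rep(3L, 60), rep(0L, 60))
  hip <- structure(list(states = hip_states, log_joint = 0), class = "viterbi_path")
  # hold spans frames 160..220, midpoint 190 = clip center
  expect_equal(synchronicity_ratio(hip, trunk_clip), 1, tolerance = 1e-12)

  # clip lengths 40 left / 50 right of the hold midpoint
  clip2 <- structure(list(start_frame = 150L, peak_frame = 195L, end_frame = 240L),
                     class = "movement_clipping")
  expect_equal(synchronicity_ratio(hip, clip2), 50 / 40, tolerance = 1e-12)
  expect_equal(report_ratio(synchronicity_ratio(hip, clip2))$normalized, 0.8)

  # monotonicity: a trunk moving earlier (advanced clip) lowers the ratio
  shifted <- structure(list(start_frame = 70L, peak_frame = 160L, end_frame = 250L),
                       class = "movement_clipping")
  expect_lt(synchronicity_ratio(hip, shifted),
            synchronicity_ratio(hip, trunk_clip))

  no_hold <- structure(list(states = c(rep(0L, 50), rep(1L, 50), rep(0L, 50)),
                            log_joint = 0), class = "viterbi_path")
  expect_error(synchronicity_ratio(no_hold, trunk_clip),
               class = "rehabmm_incoordination_error")
})

test_that("transition anomalies agree with a run-length-encoding oracle", {
  mk_path <- function(states) structure(list(states = states, log_joint = 0),
                                        class = "viterbi_path")
  ref_states <- c(rep(0L, 30), rep(1L, 30), rep(2L, 30), rep(0L, 30))
  profile <- state_profile(lapply(1:4, function(i) mk_path(ref_states)), 3,
                           min_seg = 1L)
  expect_identical(nrow(detect_transition_anomalies(mk_path(ref_states), profile)), 0L)

  # an extra hold visit is flagged on the right state
  extra <- mk_path(c(rep(0L, 30), rep(1L, 20), rep(2L, 15), rep(1L, 10),
                     rep(2L, 15), rep(0L, 30)))
  fl <- detect_transition_anomalies(extra, profile)
  expect_true(any(fl$kind == "extra_transition" & fl$state == 2L))

  # random paths: visit-count flags match the independent RLE oracle
  set.seed(17)
  for (i in 1:50) {
    p <- mk_path(sample(0:2, 120, replace = TRUE, prob = c(0.5, 0.3, 0.2)))
    fl <- detect_transition_anomalies(p, profile)
    vis <- oracle_visits(p$states, 3)
    for (s in 0:2) {
      expect_identical(any(fl$kind == "extra_transition" & fl$state == s),
                       vis[s + 1] > profile$visits_max[s + 1])
      expect_identical(any(fl$kind == "missing_transition" & fl$state == s),
                       vis[s + 1] < profile$visits_min[s + 1])
    }
  }
  expect_error(detect_transition_anomalies(mk_path(ref_states),
                                           data.frame()),
               class = "rehabmm_config_error")
})

test_that("duration anomalies use the dominant segment", {
  mk_path <- function(states) structure(list(states = states, log_joint = 0),
                                        class = "viterbi_path")
  ref <- lapply(1:3, function(i)
    mk_path(c(rep(0L, 40), rep(1L, 40), rep(0L, 40))))
  profile <- state_profile(ref, 2, min_seg = 5L)
  long <- mk_path(c(rep(0L, 40), rep(1L, 90), rep(0L, 40)))
  fl <- detect_transition_anomalies(long, profile)
  expect_true(any(fl$kind == "elongated_state" & fl$state == 1L))
  short <- mk_path(c(rep(0L, 70), rep(1L, 12), rep(0L, 70)))
  fl2 <- detect_transition_anomalies(short, profile)
  expect_true(any(fl2$kind == "shortened_state" & fl2$state == 1L))
})

test_that("error direction labels the axis and sign of the deviation", {
  dirs <- list(lr_speed = c("left", "right"), ud_speed = c("down", "up"))
  m <- gaussian_hmm(c(1, 0), matrix(c(0.95, 0.05, 0.05, 0.95), 2, byrow = TRUE),
                    matrix(c(0, 0, 0, 0), 2, 2), matrix(0.01, 2, 2),
                    feature_names = names(dirs))
  obs <- matrix(rnorm(400, 0, 0.05), 200, 2, dimnames = list(NULL, names(dirs)))
  obs[151:200, 1] <- obs[151:200, 1] - 1  # strong negative lr drift at the end
  tr <- sliding_window_likelihood(m, obs, 60, 15)
  thr <- sort(tr$values)[3] + 1e-9
  lab <- error_direction(m, tr, obs, thr, direction_labels = dirs)
  expect_true(nrow(lab) >= 1)
  expect_true(all(lab$direction == "left"))

  clean <- sliding_window_likelihood(m, matrix(rnorm(400, 0, 0.05), 200, 2), 60, 15)
  expect_identical(nrow(error_direction(m, clean,
                                        matrix(rnorm(400, 0, 0.05), 200, 2,
                                               dimnames = list(NULL, names(dirs))),
                                        min(clean$values) - 10,
                                        direction_labels = dirs)), 0L)
  expect_error(error_direction(m, tr, obs, thr, direction_labels = list()),
               class = "rehabmm_unsupported_model")
})

test_that("the outcome aggregation rule is monotone in flags and likelihoods", {
  thr <- list(good = c(II = -1, V = -1), fair = c(II = -3, V = -3))
  no_flags <- data.frame()
  one_flag <- data.frame(model = "II", kind = "extra_transition")
  two_flags <- rbind(one_flag, data.frame(model = "V", kind = "low_likelihood"))
  liks_hi <- c(II = 0, V = 0); liks_mid <- c(II = -2, V = 0); liks_lo <- c(II = -5, V = 0)
  expect_identical(aggregate_outcome(liks_hi, no_flags, thr), "good")
  expect_identical(aggregate_outcome(liks_mid, no_flags, thr), "fair")
  expect_identical(aggregate_outcome(liks_hi, one_flag, thr), "fair")
  expect_identical(aggregate_outcome(liks_lo, no_flags, thr), "bad")
  expect_identical(aggregate_outcome(liks_hi, two_flags, thr), "bad")
  # monotonicity: adding flags or lowering likelihood never improves rank
  rank <- c(bad = 0, fair = 1, good = 2)
  for (liks in list(liks_hi, liks_mid, liks_lo)) {
    o0 <- rank[[aggregate_outcome(liks, no_flags, thr)]]
    o1 <- rank[[aggregate_outcome(liks, one_flag, thr)]]
    o2 <- rank[[aggregate_outcome(liks, two_flags, thr)]]
    expect_true(o0 >= o1 && o1 >= o2)
    expect_true(rank[[aggregate_outcome(liks - 10, no_flags, thr)]] <= o0)
  }
  expect_error(aggregate_outcome(liks_hi, no_flags, list()),
               class = "rehabmm_config_error")
})

test_that("LOSO training keeps fold bookkeeping honest", {
  tl <- tiny_loso()
  regs <- tl$regs
  expect_identical(sort(names(regs)), c("s1", "s2", "s3"))
  for (s in names(regs)) {
    expect_identical(regs[[s]]$held_out, s)
    # no trial of the held-out subject in the training set
    expect_false(any(startsWith(regs[[s]]$training_trials, paste0(s, "."))))
    expect_identical(length(regs[[s]]$training_trials), 8L)
    for (e in regs[[s]]$entries) {
      expect_s3_class(e$model, "gaussian_hmm")
      expect_true(is.finite(e$stats$fair_threshold))
    }
  }
  # training sets of different folds overlap but differ
  expect_false(setequal(regs$s1$training_trials, regs$s2$training_trials))
  expect_true(length(intersect(regs$s1$training_trials,
                               regs$s2$training_trials)) > 0)
  expect_error(loso_train(tl$cohort$trials[1:4], tl$cohort$labels),
               class = "rehabmm_config_error")  # single subject
})

test_that("classification produces a coherent assessment on clean and faulted trials", {
  tl <- tiny_loso()
  tr <- tl$cohort$trials[[1]]
  reg <- tl$regs[[tr$subject_id]]
  a <- classify_movement(reg, extract_features(tr))
  expect_s3_class(a, "movement_assessment")
  expect_true(a$outcome %in% c("good", "fair", "bad"))
  expect_identical(sort(names(a$per_model)), c("D", "II", "V"))
  expect_true(a$symmetry$normalized > 0 && a$symmetry$normalized <= 1)

  wob <- simulate_abduction(
    inject_faults(short_spec(seed = 500), c(wobble = 0.06)),
    subject_id = tr$subject_id)
  aw <- classify_movement(reg, extract_features(wob$sequence))
  expect_true(nrow(aw$flags) >= 1)
  expect_true(aw$outcome %in% c("fair", "bad"))
  expect_error(classify_movement(structure(list(entries = list()),
                                           class = "model_registry"),
                                 extract_features(tr)),
               class = "rehabmm_config_error")
})
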