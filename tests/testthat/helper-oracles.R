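# Independent oracles and small fixtures. Everything here recomputes
# quantities from first principles, without touching the package's own
# forward/Viterbi/feature code paths.

# Random valid Gaussian HMM (rows renormalized explicitly).
rand_hmm <- function(n_states, d = 1, seed = 1) {
  set.seed(seed)
  pi0 <- runif(n_states); pi0 <- pi0 / sum(pi0)
  Tm <- matrix(runif(n_states^2), n_states)
  Tm <- Tm / rowSums(Tm)
  gaussian_hmm(pi0, Tm,
               matrix(rnorm(n_states * d, sd = 2), n_states, d),
               matrix(runif(n_states * d, 0.2, 1.5), n_states, d))
}

# Per-frame per-state emission log densities, recomputed directly.
oracle_logdens <- function(model, obs) {
  obs <- rbind(obs)
  t(vapply(seq_len(nrow(obs)), function(t)
    vapply(seq_len(model$n_states), function(s)
      sum(dnorm(obs[t, ], model$means[s, ], sqrt(model$variances[s, ]),
                log = TRUE)), numeric(1)),
    numeric(model$n_states)))
}

# Exhaustive path-sum of the factorized joint probability: the forward
# oracle. Only feasible for n_states^n_frames up to ~1e5.
oracle_loglik <- function(model, obs) {
  obs <- rbind(obs)
  ld <- oracle_logdens(model, obs)
  n <- nrow(obs); S <- model$n_states
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), n)))
  lp <- log(model$initial[paths[, 1L]]) + ld[cbind(1L, paths[, 1L])]
  if (n > 1L)
    for (t in 2:n)
      lp <- lp + log(model$transition[cbind(paths[, t - 1L], paths[, t])]) +
        ld[cbind(t, paths[, t])]
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

# Exhaustive best path (first maximum = lowest state indices in
# expand.grid order for the first time step; ties deeper in the path are
# asserted away by using continuous observations).
oracle_best_path <- function(model, obs) {
  obs <- rbind(obs)
  ld <- oracle_logdens(model, obs)
  n <- nrow(obs); S <- model$n_states
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), n)))
  lp <- log(model$initial[paths[, 1L]]) + ld[cbind(1L, paths[, 1L])]
  if (n > 1L)
    for (t in 2:n)
      lp <- lp + log(model$transition[cbind(paths[, t - 1L], paths[, t])]) +
        ld[cbind(t, paths[, t])]
  list(states = unname(paths[which.max(lp), ]) - 1L, log_joint = max(lp))
}

# Naive re-computation of the buffered speed convention: loop over
# frames, average the instantaneous speeds in the trailing buffer.
oracle_buffered_speed <- function(x, buffer_len, frame_rate) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  inst <- rep(NA_real_, n)
  for (i in 2:n) inst[i] <- sqrt(sum((x[i, ] - x[i - 1L, ])^2)) * frame_rate
  out <- rep(NA_real_, n)
  for (i in seq(buffer_len, n)) {
    w <- inst[max(2L, i - buffer_len + 1L):i]
    out[i] <- mean(w)
  }
  out
}

# Run-length-encoding re-derivation of per-state visit counts (segments
# of at least min_seg frames) for the anomaly-flag oracle.
oracle_visits <- function(states, n_states, min_seg = 1L) {
  r <- rle(states)
  vapply(seq_len(n_states) - 1L, function(s)
    sum(r$values == s & r$lengths >= min_seg), integer(1))
}

validate_ok <- function(model) {
  tryCatch({ rehabmm:::validate_gaussian_hmm(model); TRUE },
           error = function(e) FALSE)
}

# Short, fast synthetic trial (about 3.5 s at 60 Hz); any field of
# abduction_spec() can be overridden.
short_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(rest_before = 40, rise = 55, hold = 25, fall = 55,
         rest_after = 40, seed = seed), list(...))
  do.call(abduction_spec, args)
}

# Tiny cohort + trained LOSO registries, cached across tests in a session.
tiny_loso <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- generate_cohort(
        3, 4, fault_rate = 0, seed = 11,
        exercise_presets = list(hip_abduction = short_spec()))
      regs <- loso_train(cohort$trials, cohort$labels, seed = 11)
      cache <<- list(cohort = cohort, regs = regs)
    }
    cache
  }
})
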