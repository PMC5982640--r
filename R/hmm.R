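#' Construct a Gaussian-emission hidden Markov model
#'
#' States carry diagonal-covariance Gaussian emissions; the model is
#' parameterized by an initial state distribution, a row-stochastic
#' transition matrix and per-state mean/variance vectors. State labels
#' are 0-based throughout the package, matching the exercise-phase
#' convention (rest = state 0).
#'
#' @param initial Probability vector over states (sums to 1).
#' @param transition Row-stochastic `n x n` transition matrix.
#' @param means `n_states x d` matrix of emission means.
#' @param variances `n_states x d` matrix of emission variances
#'   (floored at `1e-6`).
#' @param feature_names Character vector binding the `d` observation
#'   dimensions to feature channels.
#' @return A `gaussian_hmm` object.
#' @export
gaussian_hmm <- function(initial, transition, means, variances,
                         feature_names = colnames(means)) {
  means <- rbind(means)
  variances <- rbind(variances)
  if (is.null(feature_names))
    feature_names <- paste0("f", seq_len(ncol(means)))
  model <- structure(
    list(n_states = length(initial), initial = as.numeric(initial),
         transition = as.matrix(transition), means = unname(means),
         variances = unname(pmax(variances, 1e-6)),
         feature_names = as.character(feature_names)),
    class = "gaussian_hmm")
  validate_gaussian_hmm(model)
  model
}

validate_gaussian_hmm <- function(model, tol = 1e-9) {
  n <- model$n_states
  if (n < 1L) rehab_error("model needs at least one state", "rehabmm_invariant_error")
  p <- c(model$initial, model$transition)
  if (any(p < -tol | p > 1 + tol))
    rehab_error("probabilities must lie in [0, 1]", "rehabmm_invariant_error")
  if (abs(sum(model$initial) - 1) > tol)
    rehab_error("initial distribution must sum to 1", "rehabmm_invariant_error")
  if (!all(dim(model$transition) == c(n, n)))
    rehab_error("transition matrix must be n_states x n_states", "rehabmm_invariant_error")
  if (any(abs(rowSums(model$transition) - 1) > tol))
    rehab_error("transition rows must sum to 1", "rehabmm_invariant_error")
  if (!all(dim(model$means) == dim(model$variances)) ||
      nrow(model$means) != n)
    rehab_error("means/variances must be n_states x d", "rehabmm_invariant_error")
  if (any(model$variances < 1e-6 - 1e-12))
    rehab_error("variances below the 1e-6 floor", "rehabmm_invariant_error")
  if (length(model$feature_names) != ncol(model$means))
    rehab_error("feature_names must match emission dimension", "rehabmm_invariant_error")
  invisible(model)
}

#' @export
print.gaussian_hmm <- function(x, ...) {
  cat(sprintf("<gaussian_hmm> %d states, %d feature(s): %s\n",
              x$n_states, ncol(x$means), paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

as_obs_matrix <- function(obs, model) {
  if (inherits(obs, "feature_series")) obs <- feature_matrix(obs, model$feature_names)
  obs <- rbind(obs)
  if (ncol(obs) != ncol(model$means))
    rehab_error(sprintf("observation arity %d does not match model arity %d",
                        ncol(obs), ncol(model$means)), "rehabmm_arity_error")
  if (anyNA(obs))
    rehab_error("observations contain missing values", "rehabmm_arity_error")
  unname(obs)
}

# T x S matrix of per-frame per-state emission log-densities
emission_logdens <- function(model, obs) {
  S <- model$n_states
  out <- matrix(0, nrow(obs), S)
  for (s in seq_len(S)) {
    ld <- dnorm(obs, rep(model$means[s, ], each = nrow(obs)),
                rep(sqrt(model$variances[s, ]), each = nrow(obs)), log = TRUE)
    out[, s] <- rowSums(rbind(ld))
  }
  out
}

log_clamp <- function(p) log(pmax(p, 1e-300))

#' Forward log-likelihood of an observation sequence
#'
#' Computes `log p(o_1..o_n)` marginalized over all hidden-state paths
#' with the forward algorithm in log space (no underflow up to at least
#' 1e5 frames).
#'
#' @param model A [gaussian_hmm()].
#' @param obs Observation matrix (`T x d`) or a `feature_series` (its
#'   model-bound channels are used).
#' @return Log-likelihood (scalar).
#' @export
forward_loglik <- function(model, obs) {
  obs <- as_obs_matrix(obs, model)
  hmm_forward_cpp(log_clamp(model$initial), log_clamp(model$transition),
                  emission_logdens(model, obs))
}

#' Most probable hidden-state path (Viterbi)
#'
#' Ties are broken towards the lower state index at each backtracking
#' step, so decoding is deterministic.
#'
#' @inheritParams forward_loglik
#' @return A `viterbi_path`: list with `states` (0-based integers, one
#'   per frame) and `log_joint` (log probability of the joint
#'   observation/state factorization along the path).
#' @export
viterbi_path <- function(model, obs) {
  obs <- as_obs_matrix(obs, model)
  res <- hmm_viterbi_cpp(log_clamp(model$initial), log_clamp(model$transition),
                         emission_logdens(model, obs))
  structure(list(states = as.integer(res$states), log_joint = res$log_joint),
            class = "viterbi_path")
}

#' @export
print.viterbi_path <- function(x, ...) {
  r <- rle(x$states)
  cat(sprintf("<viterbi_path> %d frames, log joint %.3f\n  segments: %s\n",
              length(x$states), x$log_joint,
              paste(sprintf("%d x%d", r$values, r$lengths), collapse = " -> ")))
  invisible(x)
}

# Temporal quantile-slicing initialization: states are exercise phases,
# so state l starts from the l-th temporal segment of each sequence.
init_hmm <- function(obs_list, n_states, feature_names) {
  d <- ncol(obs_list[[1L]])
  means <- matrix(0, n_states, d)
  vars <- matrix(0, n_states, d)
  pooled <- var_pooled(obs_list)
  for (l in seq_len(n_states)) {
    block <- do.call(rbind, lapply(obs_list, function(o) {
      n <- nrow(o)
      idx <- seq.int(floor((l - 1) * n / n_states) + 1L, floor(l * n / n_states))
      o[idx, , drop = FALSE]
    }))
    means[l, ] <- colMeans(block)
    v <- apply(block, 2L, var)
    v[!is.finite(v)] <- pooled[!is.finite(v)]
    vars[l, ] <- pmax(v, 1e-6)
  }
  initial <- rep(0.1 / max(1, n_states - 1), n_states)
  initial[1L] <- if (n_states == 1L) 1 else 0.9
  transition <- matrix(0.1 / max(1, n_states - 1), n_states, n_states)
  diag(transition) <- if (n_states == 1L) 1 else 0.9
  gaussian_hmm(initial, transition, means, vars, feature_names)
}

var_pooled <- function(obs_list) {
  all_obs <- do.call(rbind, obs_list)
  pmax(apply(all_obs, 2L, var), 1e-6)
}

#' Fit a Gaussian HMM with the Baum-Welch (EM) algorithm
#'
#' Multi-sequence expectation-maximization: sufficient statistics are
#' summed over sequences in the E-step; the M-step re-estimates the
#' initial distribution, transition matrix and diagonal Gaussian
#' emissions (variance floor `1e-6`). Iterations stop when the total
#' log-likelihood gain falls below `tol` or after `max_iter` iterations.
#' Deterministic for a given `seed` (randomness is used only to re-seed
#' collapsed states at a random data point).
#'
#' @param observations A matrix, `feature_series`, or list thereof.
#' @param n_states Number of hidden states.
#' @param max_iter Maximum EM iterations.
#' @param tol Minimum log-likelihood gain to continue.
#' @param seed Integer seed.
#' @param feature_names Optional channel binding (required to fit a
#'   `feature_series` subset; defaults to its column names).
#' @return List with `model` (a [gaussian_hmm()]) and `report` (a
#'   `fit_report`: per-iteration log-likelihood trace, iteration count,
#'   convergence flag, seed, collapse count).
#' @export
baum_welch_fit <- function(observations, n_states, max_iter = 200, tol = 1e-4,
                           seed = 1, feature_names = NULL) {
  obs_list <- as_obs_list(observations, feature_names)
  if (!length(obs_list))
    rehab_error("empty observation set", "rehabmm_config_error")
  feature_names <- attr(obs_list, "feature_names")
  total_frames <- sum(vapply(obs_list, nrow, integer(1)))
  if (total_frames < 10 * n_states)
    rehab_error("need at least 10 frames per state to fit", "rehabmm_config_error")
  with_seed(seed, {
    model <- init_hmm(obs_list, n_states, feature_names)
    pooled <- var_pooled(obs_list)
    trace <- numeric(0)
    converged <- FALSE
    n_collapsed <- 0L
    for (iter in seq_len(max_iter)) {
      lp <- log_clamp(model$initial); lT <- log_clamp(model$transition)
      ll <- 0
      g1 <- numeric(n_states)
      xis <- matrix(0, n_states, n_states)
      gsum <- numeric(n_states)
      m_num <- matrix(0, n_states, length(feature_names))
      v_num <- matrix(0, n_states, length(feature_names))
      for (o in obs_list) {
        fb <- hmm_fb_cpp(lp, lT, emission_logdens(model, o))
        ll <- ll + fb$loglik
        g <- fb$gamma
        g1 <- g1 + g[1L, ]
        xis <- xis + fb$xisum
        gsum <- gsum + colSums(g)
        m_num <- m_num + t(g) %*% o
        v_num <- v_num + t(g) %*% (o^2)
      }
      trace <- c(trace, ll)
      if (iter > 1L && (ll - trace[iter - 1L]) < tol) {
        converged <- (ll - trace[iter - 1L]) >= -1e-8
        break
      }
      initial <- g1 / sum(g1)
      rs <- rowSums(xis)
      transition <- model$transition
      ok <- rs > 0
      transition[ok, ] <- xis[ok, , drop = FALSE] / rs[ok]
      means <- m_num / gsum
      vars <- v_num / gsum - means^2
      collapsed <- which(gsum < 1)
      if (length(collapsed)) {
        n_collapsed <- n_collapsed + length(collapsed)
        all_obs <- do.call(rbind, obs_list)
        for (s in collapsed) {
          means[s, ] <- all_obs[sample.int(nrow(all_obs), 1L), ]
          vars[s, ] <- pooled
        }
      }
      vars <- pmax(vars, 1e-6)
      model <- gaussian_hmm(initial, transition, means, vars, feature_names)
    }
    report <- structure(list(log_likelihood_trace = trace,
                             n_iterations = length(trace),
                             converged = converged, seed = seed,
                             n_collapsed = n_collapsed),
                        class = "fit_report")
    list(model = model, report = report)
  })
}

as_obs_list <- function(observations, feature_names = NULL) {
  if (inherits(observations, "feature_series") || is.matrix(observations) ||
      is.numeric(observations))
    observations <- list(observations)
  out <- lapply(observations, function(o) {
    if (inherits(o, "feature_series")) {
      if (is.null(feature_names)) feature_names <<- colnames(o$values)
      feature_matrix(o, feature_names)
    } else {
      o <- rbind(o)
      if (is.null(feature_names))
        feature_names <<- colnames(o) %||% paste0("f", seq_len(ncol(o)))
      unname(o)
    }
  })
  out <- lapply(out, unname)
  attr(out, "feature_names") <- feature_names
  out
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> %d iteration(s), final log-lik %.4f, %s (seed %d)\n",
              x$n_iterations, tail(x$log_likelihood_trace, 1L),
              if (x$converged) "converged" else "not converged", x$seed))
  invisible(x)
}

#' BIC scan over hidden-state counts
#'
#' For each candidate state count, fits the model on training folds and
#' scores `BIC = k ln(N) - 2 lnL` on the held-out fold, with
#' `k = (n - 1) + n (n - 1) + 2 n d` free parameters for an `n`-state,
#' `d`-dimensional diagonal-Gaussian HMM and `N` the held-out frame
#' count; fold scores are averaged. With `n_folds = 1` the scan reduces
#' to direct BIC on the full set.
#'
#' @param observations As in [baum_welch_fit()].
#' @param state_range Integer vector of candidate state counts; counts
#'   outside 2..10 are allowed but warned about (a useful phase model has
#'   at least 2 states).
#' @param n_folds Number of cross-validation folds.
#' @param seed Integer seed (fold assignment and fits).
#' @param ... Passed to [baum_welch_fit()].
#' @return A `bic_scan` data frame (`n_states`, `bic`, `loglik`, `k`)
#'   with attribute `best` = argmin state count.
#' @export
bic_scan <- function(observations, state_range = 2:10, n_folds = 3, seed = 1, ...) {
  obs_list <- as_obs_list(observations)
  if (!length(obs_list)) rehab_error("empty observation set", "rehabmm_config_error")
  if (any(state_range < 2) || any(state_range > 10))
    warning("state counts outside 2..10: a phase HMM normally has 2-10 states")
  if (length(obs_list) < n_folds)
    rehab_error("fewer sequences than folds", "rehabmm_config_error")
  d <- ncol(obs_list[[1L]])
  fold_of <- with_seed(seed, {
    idx <- sample.int(length(obs_list))
    out <- integer(length(obs_list))
    out[idx] <- rep_len(seq_len(n_folds), length(obs_list))
    out
  })
  rows <- lapply(seq_along(state_range), function(si) {
    n <- state_range[si]
    k <- hmm_free_parameters(n, d)
    scores <- numeric(n_folds); lls <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      train <- obs_list[if (n_folds == 1L) TRUE else fold_of != f]
      held <- obs_list[if (n_folds == 1L) TRUE else fold_of == f]
      fit <- baum_welch_fit(train, n, seed = seed + 1000L * si + f, ...)
      ll <- sum(vapply(held, function(o) forward_loglik(fit$model, o), numeric(1)))
      N <- sum(vapply(held, nrow, integer(1)))
      lls[f] <- ll
      scores[f] <- k * log(N) - 2 * ll
    }
    data.frame(n_states = n, bic = mean(scores), loglik = mean(lls), k = k)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bic_scan", "data.frame")
  attr(out, "best") <- out$n_states[which.min(out$bic)]
  out
}

#' Free-parameter count of a diagonal-Gaussian HMM
#'
#' `(n - 1)` initial + `n (n - 1)` transition + `2 n d` emission
#' parameters.
#'
#' @param n_states,n_features Model dimensions.
#' @return Integer parameter count.
#' @export
hmm_free_parameters <- function(n_states, n_features) {
  (n_states - 1L) + n_states * (n_states - 1L) + 2L * n_states * n_features
}

#' Relabel HMM states in temporal order of appearance
#'
#' Baum-Welch is label-symmetric, but exercise-phase models carry a
#' temporal convention (rest = state 0, then successive phases). This
#' permutes the states of a fitted model so that state labels follow the
#' average order of first appearance in the Viterbi paths of the
#' training sequences; states that never appear keep their relative
#' order at the end.
#'
#' @param model A [gaussian_hmm()].
#' @param observations As in [baum_welch_fit()].
#' @return The relabeled model.
#' @export
relabel_states_temporal <- function(model, observations) {
  obs_list <- as_obs_list(observations, model$feature_names)
  S <- model$n_states
  first <- matrix(NA_real_, length(obs_list), S)
  for (i in seq_along(obs_list)) {
    st <- viterbi_path(model, obs_list[[i]])$states
    for (s in seq_len(S))
      first[i, s] <- match(s - 1L, st)
  }
  avg_first <- colMeans(first, na.rm = TRUE)
  avg_first[is.nan(avg_first)] <- Inf
  perm <- order(avg_first)
  gaussian_hmm(model$initial[perm], model$transition[perm, perm, drop = FALSE],
               model$means[perm, , drop = FALSE],
               model$variances[perm, , drop = FALSE], model$feature_names)
}

#' Sample an observation sequence from a Gaussian HMM
#'
#' Draws `h_1` from the initial distribution, successive states from the
#' transition rows, and observations from the state emissions;
#' deterministic per seed.
#'
#' @param model A [gaussian_hmm()].
#' @param length Number of frames to draw.
#' @param seed Integer seed.
#' @return Observation matrix (`length x d`, columns named) with
#'   attribute `states` (0-based generating states).
#' @export
sample_sequence <- function(model, length, seed = 1) {
  stopifnot(length >= 1)
  with_seed(seed, {
    S <- model$n_states
    d <- ncol(model$means)
    states <- integer(length)
    states[1L] <- sample.int(S, 1L, prob = model$initial)
    if (length > 1L)
      for (i in 2:length)
        states[i] <- sample.int(S, 1L, prob = model$transition[states[i - 1L], ])
    obs <- model$means[states, , drop = FALSE] +
      matrix(rnorm(length * d), length, d) * sqrt(model$variances)[states, , drop = FALSE]
    colnames(obs) <- model$feature_names
    attr(obs, "states") <- states - 1L
    obs
  })
}
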