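test_that("model construction enforces stochasticity and floors", {
  expect_error(gaussian_hmm(c(0.5, 0.4), diag(2), matrix(0, 2, 1), matrix(1, 2, 1)),
               "sum to 1", class = "rehabmm_invariant_error")
  expect_error(gaussian_hmm(c(0.5, 0.5), matrix(c(0.9, 0.3, 0.2, 0.7), 2),
                            matrix(0, 2, 1), matrix(1, 2, 1)),
               class = "rehabmm_invariant_error")
  m <- gaussian_hmm(c(0.5, 0.5), matrix(0.5, 2, 2), matrix(0, 2, 1),
                    matrix(1e-12, 2, 1))
  expect_true(all(m$variances >= 1e-6))  # variance floor applied
})

test_that("forward log-likelihood matches closed form and exhaustive enumeration", {
  # 1-state model: sum of per-frame emission log densities
  m1 <- gaussian_hmm(1, matrix(1, 1, 1), matrix(0.3, 1, 2), matrix(c(0.5, 2), 1, 2))
  obs <- matrix(rnorm(10), 5, 2)
  expect_equal(forward_loglik(m1, obs),
               sum(dnorm(obs[, 1], 0.3, sqrt(0.5), log = TRUE)) +
                 sum(dnorm(obs[, 2], 0.3, sqrt(2), log = TRUE)), tolerance = 1e-10)

  # 2-state, 4-frame: exhaustive sum over all 2^4 paths
  m2 <- rand_hmm(2, 2, seed = 21)
  obs2 <- sample_sequence(m2, 4, seed = 1)
  expect_equal(forward_loglik(m2, obs2), oracle_loglik(m2, obs2), tolerance = 1e-10)

  # label-permutation symmetry
  perm <- c(2, 1)
  m2p <- gaussian_hmm(m2$initial[perm], m2$transition[perm, perm],
                      m2$means[perm, ], m2$variances[perm, ], m2$feature_names)
  expect_equal(forward_loglik(m2p, obs2), forward_loglik(m2, obs2), tolerance = 1e-10)
})

test_that("forward stays finite on very long sequences (no underflow)", {
  m <- rand_hmm(3, 1, seed = 33)
  obs <- sample_sequence(m, 1e5, seed = 2)
  ll <- forward_loglik(m, obs)
  expect_true(is.finite(ll))
  expect_lt(ll, 0)
})

test_that("Viterbi decoding matches exhaustive search and the generating states", {
  m1 <- gaussian_hmm(1, matrix(1, 1, 1), matrix(0, 1, 1), matrix(1, 1, 1))
  p1 <- viterbi_path(m1, matrix(rnorm(6), 6, 1))
  expect_identical(p1$states, rep(0L, 6))

  m3 <- rand_hmm(3, 1, seed = 31)
  obs <- sample_sequence(m3, 6, seed = 3)
  got <- viterbi_path(m3, obs)
  want <- oracle_best_path(m3, obs)
  expect_identical(got$states, want$states)
  expect_equal(got$log_joint, want$log_joint, tolerance = 1e-10)
  # the best single path never beats the marginal over all paths
  expect_lte(got$log_joint, forward_loglik(m3, obs) + 1e-10)

  # observations at the means of a well-separated sticky model decode to
  # the generating states
  sep <- gaussian_hmm(c(1, 0, 0),
                      matrix(c(0.98, 0.02, 0, 0, 0.98, 0.02, 0.02, 0, 0.98),
                             3, byrow = TRUE),
                      matrix(c(0, 10, 20), 3, 1), matrix(0.1, 3, 1))
  states <- rep(c(0L, 1L, 2L), each = 30)
  obs_exact <- matrix(c(0, 10, 20)[states + 1L], ncol = 1)
  expect_identical(viterbi_path(sep, obs_exact)$states, states)
})

test_that("Baum-Welch reduces to the pooled closed form with one state", {
  obs <- list(matrix(rnorm(60, 3, 2), ncol = 2), matrix(rnorm(40, 3, 2), ncol = 2))
  fit <- baum_welch_fit(obs, 1, seed = 5)
  pooled <- rbind(obs[[1]], obs[[2]])
  expect_equal(as.vector(fit$model$means), colMeans(pooled), tolerance = 1e-8)
  expect_equal(as.vector(fit$model$variances),
               apply(pooled, 2, function(x) mean((x - mean(x))^2)), tolerance = 1e-8)
})

test_that("Baum-Welch is monotone, deterministic and preserves invariants", {
  m <- gaussian_hmm(c(0.8, 0.15, 0.05),
                    matrix(c(0.9, 0.08, 0.02, 0.05, 0.9, 0.05, 0.02, 0.08, 0.9),
                           3, byrow = TRUE),
                    matrix(c(-4, 0, 4), 3, 1), matrix(c(0.6, 0.8, 0.5), 3, 1))
  obs <- lapply(1:5, function(i) sample_sequence(m, 60, seed = i))
  fit1 <- baum_welch_fit(obs, 3, seed = 9)
  fit2 <- baum_welch_fit(obs, 3, seed = 9)
  expect_identical(fit1$model, fit2$model)  # bit-identical per seed
  tr <- fit1$report$log_likelihood_trace
  expect_true(all(diff(tr) >= -1e-8))
  expect_true(validate_ok(fit1$model))
  expect_error(baum_welch_fit(list(), 2), class = "rehabmm_config_error")
  expect_error(baum_welch_fit(obs[[1]][1:10, , drop = FALSE], 3),
               class = "rehabmm_config_error")  # too few frames per state
})

test_that("parameters of a well-separated generator are recovered", {
  gen <- gaussian_hmm(c(0.9, 0.08, 0.02),
                      matrix(c(0.95, 0.04, 0.01, 0.02, 0.95, 0.03, 0.03, 0.02, 0.95),
                             3, byrow = TRUE),
                      matrix(c(-5, 0, 6, 2, -3, 4), 3, 2),
                      matrix(0.5, 3, 2))
  obs <- lapply(1:40, function(i) sample_sequence(gen, 80, seed = 100 + i))
  fit <- baum_welch_fit(obs, 3, seed = 13)
  # optimal state matching by nearest mean
  perm <- apply(fit$model$means, 1, function(mu)
    which.min(colSums((t(gen$means) - mu)^2)))
  expect_identical(sort(perm), 1:3)
  for (s in 1:3)
    expect_equal(fit$model$means[s, ], gen$means[perm[s], ], tolerance = 0.6)
})

test_that("state relabeling follows temporal order without changing the law", {
  gen <- gaussian_hmm(c(0.05, 0.9, 0.05),
                      matrix(c(0.97, 0.02, 0.01, 0.03, 0.95, 0.02, 0.01, 0.02, 0.97),
                             3, byrow = TRUE),
                      matrix(c(8, 0, -8), 3, 1), matrix(0.4, 3, 1))
  obs <- lapply(1:6, function(i) sample_sequence(gen, 100, seed = i))
  fit <- baum_welch_fit(obs, 3, seed = 3)
  rel <- relabel_states_temporal(fit$model, obs)
  expect_equal(forward_loglik(rel, obs[[1]]), forward_loglik(fit$model, obs[[1]]),
               tolerance = 1e-9)
  # average first-occurrence time is nondecreasing in the new state labels
  first_occ <- sapply(obs, function(o) match(0:2, viterbi_path(rel, o)$states))
  avg <- rowMeans(first_occ, na.rm = TRUE)
  expect_false(is.unsorted(avg))
})

test_that("BIC free-parameter count and degenerate single fold behave as defined", {
  expect_identical(hmm_free_parameters(3L, 2L), 20L)  # 2 + 6 + 12
  m <- gaussian_hmm(c(0.7, 0.3), matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE),
                    matrix(c(-2, 2), 2, 1), matrix(0.5, 2, 1))
  obs <- lapply(1:6, function(i) sample_sequence(m, 50, seed = i))
  one_fold <- bic_scan(obs, state_range = 2:3, n_folds = 1, seed = 4)
  fit2 <- baum_welch_fit(obs, 2, seed = 4 + 1000L + 1L)
  ll <- sum(vapply(obs, function(o) forward_loglik(fit2$model, o), numeric(1)))
  N <- sum(vapply(obs, nrow, integer(1)))
  expect_equal(one_fold$bic[one_fold$n_states == 2],
               hmm_free_parameters(2L, 1L) * log(N) - 2 * ll, tolerance = 1e-8)
  expect_warning(bic_scan(obs, state_range = 1:2, n_folds = 2, seed = 1),
                 "2-10")
})

test_that("sampling is seeded and follows the transition law", {
  m <- rand_hmm(3, 2, seed = 55)
  s1 <- sample_sequence(m, 50, seed = 8)
  s2 <- sample_sequence(m, 50, seed = 8)
  expect_identical(s1, s2)
  big <- sample_sequence(m, 2e4, seed = 9)
  st <- attr(big, "states") + 1L
  emp <- prop.table(table(factor(st[-length(st)], 1:3),
                          factor(st[-1], 1:3)), margin = 1)
  expect_equal(unclass(emp), unclass(m$transition), tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("JSON model serialization round-trips bit-exactly", {
  m <- rand_hmm(4, 3, seed = 77)
  path <- withr::local_tempfile(fileext = ".json")
  write_hmm_json(m, path)
  m2 <- read_hmm_json(path)
  expect_identical(m2$initial, m$initial)
  expect_identical(m2$transition, m$transition)
  expect_identical(m2$means, m$means)
  expect_identical(m2$variances, m$variances)
  expect_identical(m2$feature_names, m$feature_names)
  expect_error(read_hmm_json(file.path(tempdir(), "absent.json")),
               class = "rehabmm_io_error")
})
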