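hyper_default <- observer_hyperparams(sigma2_u = 2e-3, kappa = 5, lambda0 = 7)

test_that("category grid covers the stimulus range with semitones", {
  b <- init_beliefs(hyper_default, c(500, 800))
  expect_length(b$nu, 10L)
  expect_equal(b$category_hz[1], 493.8833, tolerance = 1e-4) # B4
  expect_equal(b$nu[1], log(440 * 2^(2 / 12)))
  expect_equal(b$category_hz[10], 830.6094, tolerance = 1e-4) # Ab5
  # minimality: dropping either end note uncovers part of the range
  expect_lt(b$category_hz[1], 500)
  expect_gt(b$category_hz[2], 500)
  expect_gt(b$category_hz[10], 800)
  expect_lt(b$category_hz[9], 800)
  # transition matrix: zero diagonal, off-diagonal rows sum to 1
  expect_equal(diag(b$B), rep(0, 10))
  expect_equal(rowSums(b$B), rep(1, 10))
  expect_equal(b$n_nu, rep(5, 10))
  expect_error(init_beliefs(hyper_default, c(800, 500)), "low < high")
})

test_that("hyperparameter validation enforces the stated ranges", {
  expect_error(observer_hyperparams(0, 1, 5), "sigma2_u")
  expect_error(observer_hyperparams(1e-3, 0, 5), "kappa")
  expect_error(observer_hyperparams(1e-3, 1, 1), "lambda0")
})

test_that("predictive distribution implements the run-length hazard", {
  b <- init_beliefs(hyper_default, c(500, 800))
  # before any tone: uniform over the 10 categories
  p0 <- predictive_distribution(b)
  expect_equal(p0$p_pred, rep(0.1, 10))

  b$c_prev <- 3L
  b$r <- 2L
  geo <- predictive_distribution(b, hazard = "geometric")
  expect_equal(geo$change_hazard, 1 / b$lambda_hat)
  # geometric hazard is constant in the run length
  b$r <- 9L
  expect_equal(predictive_distribution(b, hazard = "geometric")$change_hazard,
               1 / b$lambda_hat)

  # stay probability does not depend on B's values
  p1 <- predictive_distribution(b)
  b2 <- b
  b2$B[3L, ] <- c(0, 0.5, 0, 0.5, rep(0, 6))
  p2 <- predictive_distribution(b2)
  expect_equal(p1$p_pred[3L], p2$p_pred[3L])
  expect_equal(sum(p1$p_pred), 1)
  expect_equal(sum(p2$p_pred), 1)

  # Poisson hazard grows with the run length when lambda > 1
  hs <- vapply(0:9, function(r) {
    b$r <- r
    predictive_distribution(b, hazard = "poisson")$change_hazard
  }, numeric(1))
  expect_true(all(diff(hs) > 0))
})

test_that("a perfectly predicted tone causes no surprise and no learning", {
  hyper <- observer_hyperparams(2e-3, kappa = 1e6, lambda0 = 7)
  b <- init_beliefs(hyper, c(500, 800))
  b$c_prev <- 4L
  b$r <- 1L
  res <- update_beliefs(b, b$nu[4L])
  expect_equal(res$record$c_hat, 4L)
  expect_equal(res$record$d_nu, 0, tolerance = 1e-9)
  expect_false(res$record$is_change)
  # sensory prediction error vanishes only up to the hazard-weighted
  # contribution of other categories; category mean update is exactly ~0
  expect_equal(res$belief$nu[4L], b$nu[4L], tolerance = 1e-9)
  expect_error(update_beliefs(b, NaN), "non-finite")
})

test_that("MAP categorization matches brute-force enumeration", {
  set.seed(31)
  hyper <- observer_hyperparams(1e-3, 2, 5)
  b <- init_beliefs(hyper, c(500, 800))
  for (i in 1:1000) {
    u <- runif(1, log(480), log(850))
    pred <- predictive_distribution(b)
    oracle <- which.max(vapply(seq_along(b$nu), function(j) {
      log(pred$p_pred[j]) - (u - b$nu[j])^2 / (2 * hyper$sigma2_u)
    }, numeric(1)))
    res <- update_beliefs(b, u)
    expect_identical(res$record$c_hat, as.integer(oracle))
    b <- res$belief
  }
})

test_that("repeated identical input drives the conjugate posterior mean", {
  hyper <- observer_hyperparams(1e-4, kappa = 3, lambda0 = 7)
  b0 <- init_beliefs(hyper, c(500, 800))
  j <- 6L
  u <- b0$nu[j] + 0.01 # within the category's basin
  b <- b0
  n <- 50L
  for (i in seq_len(n)) b <- update_beliefs(b, u)$belief
  expect_equal(b$nu[j], (3 * b0$nu[j] + n * u) / (3 + n), tolerance = 1e-12)
  expect_equal(b$n_nu[j], 3 + n)
})

test_that("rigid priors freeze the beliefs", {
  hyper <- observer_hyperparams(2e-3, kappa = 1e6, lambda0 = 7)
  s <- generate_roving_sequence(stimulus_design(n_tones = 300L), 4)
  traj <- run_observer(s, hyper)
  expect_lt(max(abs(traj$d_nu)), 1e-6)
  expect_lt(max(abs(traj$d_lambda)), 1e-4)
  expect_lt(max(traj$d_B_l1), 1e-4)
})

test_that("observer trajectories are deterministic and self-consistent", {
  s <- generate_roving_sequence(stimulus_design(n_tones = 400L), 9)
  t1 <- run_observer(s, hyper_default)
  t2 <- run_observer(s, hyper_default)
  expect_identical(t1, t2)
  # surprisals are nonnegative; records exist for every tone
  expect_true(all(t1$surprisal_input >= 0))
  expect_true(all(t1$surprisal_category >= 0))
  expect_equal(nrow(t1), 400L)
  # run_observer agrees with folding update_beliefs step by step
  b <- init_beliefs(hyper_default, range(s$design$frequency_set))
  recs <- vector("list", 20L)
  for (t in 1:20) {
    st <- update_beliefs(b, s$log_frequencies[t])
    b <- st$belief
    recs[[t]] <- st$record
  }
  manual <- do.call(rbind, recs)
  expect_equal(manual$c_hat, t1$c_hat[1:20])
  expect_equal(manual$surprisal_category, t1$surprisal_category[1:20])
  expect_equal(manual$d_nu, t1$d_nu[1:20])
})

test_that("internal energy is minimized at the chosen category", {
  s <- generate_roving_sequence(stimulus_design(n_tones = 200L), 12)
  hyper <- hyper_default
  b <- init_beliefs(hyper, range(s$design$frequency_set))
  for (t in seq_len(200L)) {
    u <- s$log_frequencies[t]
    pred <- predictive_distribution(b)
    energies <- -(log(pred$p_pred) - (u - b$nu)^2 / (2 * hyper$sigma2_u) -
                    0.5 * log(2 * pi * hyper$sigma2_u))
    st <- update_beliefs(b, u)
    expect_equal(st$record$internal_energy, min(energies))
    expect_lte(st$record$internal_energy,
               min(energies[-st$record$c_hat]) + 1e-12)
    b <- st$belief
  }
})

test_that("transition-matrix rows remain probability vectors under long input", {
  set.seed(77)
  u <- runif(1e5, log(480), log(850))
  s <- tone_sequence(exp(u))
  traj <- run_observer(s, observer_hyperparams(5e-3, 1, 4),
                       stimulus_range_hz = c(500, 800))
  b <- attr(traj, "final_belief")
  expect_equal(rowSums(b$B), rep(1, 10), tolerance = 1e-10)
  expect_equal(diag(b$B), rep(0, 10))
  expect_true(all(b$B >= 0))
  expect_gt(b$lambda_hat, 1)
})

test_that("with tiny perceptual noise on-grid tones map to their category", {
  hyper <- observer_hyperparams(1e-8, 1, 5)
  b <- init_beliefs(hyper, c(500, 800))
  set.seed(5)
  cats <- sample.int(10L, 500, replace = TRUE)
  s <- tone_sequence(b$category_hz[cats])
  traj <- run_observer(s, hyper, stimulus_range_hz = c(500, 800))
  expect_equal(traj$c_hat, cats)
})

test_that("evidence-maximizing grid search returns a consistent optimum", {
  sub <- toy_subject("M6", n_tones = 500, seed = 21)
  grid <- default_fep_grid()[c(5, 14, 23), ]
  fit <- fit_hyperparameters(sub$amplitudes, sub$seq, sub$trials, "M6",
                             grid = grid)
  expect_true(nrow(merge(as.data.frame(fit$params), grid)) == 1L)
  # reported evidence equals evidence recomputed independently at the optimum
  hyper <- observer_hyperparams(fit$params$sigma2_u, fit$params$kappa,
                                fit$params$lambda0)
  traj <- run_observer(sub$seq, hyper)
  X <- build_design_matrix(compute_predictor("M6", sub$trials, sub$seq, traj))
  expect_equal(fit$log_evidence,
               subject_log_evidence(sub$amplitudes$values, X))
  # single-point grid returns that point
  fit1 <- fit_hyperparameters(sub$amplitudes, sub$seq, sub$trials, "M6",
                              grid = grid[2, ])
  expect_equal(as.numeric(fit1$params), as.numeric(grid[2, ]))
  expect_error(
    fit_hyperparameters(sub$amplitudes, sub$seq, sub$trials, "M6",
                        grid = grid[0, ]),
    "empty"
  )
})
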