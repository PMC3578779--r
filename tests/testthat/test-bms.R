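test_that("identical evidences give the symmetric fixed point", {
  L <- matrix(-100, 8, 13, dimnames = list(NULL, paste0("M", 1:13)))
  fit <- rfx_bms(L, prior_counts = 1)
  expect_true(fit$converged)
  expect_equal(unname(fit$alpha), rep(1 + 8 / 13, 13), tolerance = 1e-6)
  expect_equal(unname(fit$expected_probs), rep(1 / 13, 13), tolerance = 1e-8)
})

test_that("per-subject additive constants leave the result unchanged", {
  set.seed(10)
  L <- matrix(rnorm(8 * 5, sd = 3), 8, 5,
              dimnames = list(NULL, paste0("M", 1:5)))
  f1 <- rfx_bms(L)
  L2 <- L
  L2[3, ] <- L2[3, ] + 100
  f2 <- rfx_bms(L2)
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-8)
  expect_error(rfx_bms(matrix(c(1, NA), 1)), "finite")
  expect_error(rfx_bms(L, prior_counts = 0), "> 0")
})

test_that("two-model problems match the exhaustive-integration oracle", {
  # strong unanimous preference: expected probability is high
  L <- cbind(M1 = rep(10, 8), M2 = rep(0, 8))
  fit <- rfx_bms(L)
  expect_gt(fit$expected_probs["M1"], 0.85)
  # across a grid of evidence differences (unanimous and split cohorts),
  # the variational posterior tracks exact numerical integration
  for (d in c(0, 2, 5, 10, 20)) {
    for (split in c(8, 6)) {
      l1 <- c(rep(d, split), rep(0, 8 - split))
      L <- cbind(M1 = l1, M2 = rep(0, 8))
      fit <- rfx_bms(L)
      oracle <- exhaustive_rfx_k2(L)
      expect_lt(max(abs(unname(fit$expected_probs) - oracle)), 0.02)
    }
  }
  # for near-equivocal evidence (< ~2 nats) the variational posterior is
  # overconfident in the favored model relative to the exact posterior; the
  # bias has a known direction even where its size exceeds the band above
  for (d in c(0.5, 1)) {
    L <- cbind(M1 = rep(d, 8), M2 = rep(0, 8))
    fit <- rfx_bms(L)
    oracle <- exhaustive_rfx_k2(L)
    expect_gte(unname(fit$expected_probs[1]), oracle[1])
    expect_lt(unname(fit$expected_probs[1]) - oracle[1], 0.1)
  }
})

test_that("exceedance probabilities follow the Dirichlet posterior", {
  xp_sym <- exceedance_probabilities(rep(2, 5), n_samples = 2e5, seed = 3)
  se <- sqrt(0.2 * 0.8 / 2e5)
  expect_true(all(abs(xp_sym - 0.2) < 3 * se))
  expect_equal(sum(xp_sym), 1)

  # K = 2: exceedance is the Beta tail probability P(r1 > 1/2)
  alpha <- c(6.5, 3.5)
  xp <- exceedance_probabilities(alpha, n_samples = 5e5, seed = 4)
  beta_oracle <- stats::pbeta(0.5, alpha[1], alpha[2], lower.tail = FALSE)
  expect_equal(unname(xp[1]), beta_oracle, tolerance = 5e-3)

  xp_extreme <- exceedance_probabilities(c(100, 1), n_samples = 2e5, seed = 5)
  expect_gt(xp_extreme[1], 0.999)
  expect_error(exceedance_probabilities(c(1, 1), n_samples = 10), ">= 1e5")
})

test_that("family inference aggregates the model-level posterior", {
  set.seed(21)
  L <- matrix(rnorm(6 * 3), 6, 3, dimnames = list(NULL, c("A", "B", "C")))

  # single family containing everything: probability 1
  f_all <- family_bms(L, list(all = c("A", "B", "C")), n_samples = 1e5 * 2,
                      seed = 1)
  expect_equal(unname(f_all$expected_probs), 1)
  expect_equal(unname(f_all$exceedance_probs), 1)

  # equal evidence, two equal-size families: 50/50
  Lf <- matrix(0, 6, 4, dimnames = list(NULL, c("A", "B", "C", "D")))
  f_eq <- family_bms(Lf, list(f1 = c("A", "B"), f2 = c("C", "D")),
                     n_samples = 2e5, seed = 2)
  expect_equal(unname(f_eq$expected_probs), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(unname(f_eq$exceedance_probs), c(0.5, 0.5), tolerance = 0.01)

  # prior counts of 1/family-size imply a flat prior over families
  part <- list(solo = "A", pair = c("B", "C"))
  counts <- c(solo = 1, B = 0.5, C = 0.5)
  expect_equal(sum(counts["solo"]), sum(counts[c("B", "C")]))
  prior_family_probs <- c(1, 0.5 + 0.5) / 2
  expect_equal(prior_family_probs, c(0.5, 0.5))

  expect_error(family_bms(L, list(f1 = c("A", "B"))), "partition")
  expect_error(family_bms(L, list(f1 = c("A", "B"), f2 = c("B", "C"))),
               "partition")
})

test_that("family BMS recovers a dominant family", {
  set.seed(33)
  L <- matrix(rnorm(8 * 13), 8, 13, dimnames = list(NULL, paste0("M", 1:13)))
  L[, 9:13] <- L[, 9:13] + 6 # model-adjustment family dominates
  f <- family_bms(L, predefined_partitions()$theories, n_samples = 2e5,
                  seed = 9)
  expect_equal(names(which.max(f$exceedance_probs)), "model_adjustment")
  expect_gt(f$exceedance_probs["model_adjustment"], 0.9)
  expect_equal(sum(f$expected_probs), 1)
  expect_equal(sum(f$exceedance_probs), 1)
})
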