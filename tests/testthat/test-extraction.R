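# hand-built epoch arrays for unit-level checks
make_epochs <- function(data, sampling_rate_hz = 500, t0_ms = -100) {
  step <- 1000 / sampling_rate_hz
  structure(
    list(data = data,
         times_ms = seq(t0_ms, by = step, length.out = dim(data)[3]),
         sampling_rate_hz = sampling_rate_hz, t0_ms = t0_ms),
    class = "epoch_array"
  )
}

test_that("standard ERPs average the sixth-presentation trials per frequency", {
  st <- toy_sequence(c(rep(500, 6), rep(800, 6), 500))
  n_t <- 210L
  data <- array(0, dim = c(13, 2, n_t))
  template <- matrix(rnorm(2 * n_t), 2, n_t)
  data[6, , ] <- template       # standard-6 of 500 Hz
  data[12, , ] <- -template     # standard-6 of 800 Hz
  ep <- make_epochs(data)
  erps <- compute_standard_erps(ep, st$trials)
  expect_equal(erps[["500.000000"]], template)
  expect_equal(erps[["800.000000"]], -template)

  # averaging of v and -v cancels: give 500 Hz two standard-6 trials
  st2 <- toy_sequence(c(rep(500, 6), rep(800, 6), rep(500, 6), 800))
  data2 <- array(0, dim = c(19, 2, n_t))
  data2[6, , ] <- template
  data2[18, , ] <- -template
  erps2 <- compute_standard_erps(make_epochs(data2), st2$trials)
  expect_equal(erps2[["500.000000"]], matrix(0, 2, n_t))

  # a deviant frequency without any standard-6 trial is an error
  st3 <- toy_sequence(c(rep(500, 6), 800, 500))
  expect_error(
    compute_standard_erps(make_epochs(array(0, c(8, 2, n_t))), st3$trials),
    "800"
  )
})

test_that("ERP estimate converges to the template under zero-mean noise", {
  n_std <- 1000L
  n_t <- 180L
  template <- sin(seq(0, 6, length.out = n_t))
  freqs <- c(rep(c(rep(500, 6), 800), n_std), rep(800, 6))
  st <- toy_sequence(freqs)
  sd_noise <- 0.8
  set.seed(404)
  data <- array(rnorm(length(freqs) * 1 * n_t, sd = sd_noise),
                dim = c(length(freqs), 1, n_t))
  std6 <- which(st$trials$is_standard6)
  for (i in std6) data[i, 1, ] <- data[i, 1, ] + template
  erp <- compute_standard_erps(make_epochs(data), st$trials)[["500.000000"]]
  se <- sd_noise / sqrt(n_std)
  expect_true(all(abs(erp[1, ] - template) < 4.5 * se))
})

test_that("deviance potentials subtract the standard ERP and the baseline", {
  st <- toy_sequence(c(rep(500, 6), rep(800, 6), 500))
  n_t <- 210L
  times <- seq(-100, by = 2, length.out = n_t)
  erp500 <- matrix(rnorm(n_t), 1, n_t)
  erp800 <- matrix(rnorm(n_t), 1, n_t)
  data <- array(0, dim = c(13, 1, n_t))
  data[6, 1, ] <- erp500
  data[12, 1, ] <- erp800
  # deviants: trial 7 (800 Hz) and trial 13 (500 Hz)
  data[7, 1, ] <- erp800                   # identical to its standard ERP
  bump <- -2 * exp(-(times - 150)^2 / 800) # post-stimulus bump, zero baseline
  data[13, 1, ] <- erp500 + bump + 3.7     # plus a DC offset
  diffs <- deviance_potentials(make_epochs(data), st$trials,
                               compute_standard_erps(make_epochs(data),
                                                     st$trials))
  expect_equal(dim(diffs$data), c(2L, 1L, n_t))
  expect_equal(diffs$data[1, 1, ], rep(0, n_t)) # deviant == standard ERP
  # DC offsets are removed; what remains is the bump minus its baseline mean
  base <- which(times >= -100 & times < 0)
  expect_equal(diffs$data[2, 1, ], bump - mean(bump[base]), tolerance = 1e-12)
})

test_that("peak latency takes the earliest minimum in the 100-200 ms band", {
  n_t <- 210L
  times <- seq(-100, by = 2, length.out = n_t)
  mk <- function(wave) {
    arr <- array(rep(wave, each = 1), dim = c(1, 1, n_t))
    structure(list(data = arr, deviant_trial_indices = 1L, times_ms = times),
              class = "deviance_potentials")
  }
  gauss <- -exp(-(times - 150)^2 / (2 * 20^2))
  expect_equal(estimate_peak_latency(mk(gauss)), 150)
  # monotonically decreasing wave: boundary case at 200 ms
  expect_equal(estimate_peak_latency(mk(-times)), 200)
  # exact tie between 120 and 180 ms: earlier sample wins
  tie <- rep(0, n_t)
  tie[times == 120] <- -1
  tie[times == 180] <- -1
  expect_equal(estimate_peak_latency(mk(tie)), 120)
})

test_that("windowed means recover constant deviance potentials", {
  n_t <- 210L
  times <- seq(-100, by = 2, length.out = n_t)
  arr <- array(0, dim = c(2, 2, n_t))
  arr[1, 1, ] <- 3.25 # constant over the whole epoch
  diffs <- structure(
    list(data = arr, deviant_trial_indices = c(4L, 9L), times_ms = times),
    class = "deviance_potentials"
  )
  amps <- extract_amplitudes(diffs, peak_latency_ms = 150, window_ms = 50)
  expect_equal(amps$values, rbind(c(3.25, 0), c(0, 0)))
  expect_equal(amps$peak_latency_ms, 150)
  expect_error(extract_amplitudes(diffs, 310, 50), "exceeds")
})

test_that("Sidak electrode selection separates signal from noise channels", {
  expect_equal(sidak_alpha(0.05, 10), 1 - 0.95^0.1)
  expect_equal(sidak_alpha(0.05, 10), 0.005116, tolerance = 1e-4)

  n_dev <- 500L
  n_t <- 210L
  times <- seq(-100, by = 2, length.out = n_t)
  bump <- -exp(-(times - 150)^2 / (2 * 20^2))
  set.seed(606)
  arr <- array(rnorm(n_dev * 3 * n_t, sd = 1), dim = c(n_dev, 3, n_t))
  # electrode 1: large MMN bump on every deviant; 2: pure noise; 3: flat zero
  for (i in seq_len(n_dev)) arr[i, 1, ] <- arr[i, 1, ] + 6 * bump
  arr[, 3, ] <- 0
  diffs <- structure(
    list(data = arr, deviant_trial_indices = seq_len(n_dev), times_ms = times),
    class = "deviance_potentials"
  )
  sel <- suppressWarnings(
    select_electrodes(diffs, peak_latency_ms = 150, window_ms = 50,
                      fwe_level = 0.05)
  )
  expect_equal(sel, 1L)
  expect_warning(
    select_electrodes(diffs, 150, 50, candidate_electrodes = 3L),
    "degenerate"
  )
})

test_that("the full pipeline is exact on noiseless epochs and honours order", {
  design <- stimulus_design(n_tones = 200L)
  s <- generate_roving_sequence(design, 51)
  tr <- annotate_trials(s)
  truth <- subject_ground_truth("M2", list(), outer(c(-3, -1), c(1, 1.3)),
                                1, 61)
  amps <- simulate_amplitudes(s, tr, truth)
  cfg <- epoch_config(bump_shape = "flat", flat_halfwidth_ms = 75,
                      sensor_noise_sd = 0)
  ep <- simulate_epochs(s, tr, amps, cfg)
  ex <- extract_mmn(ep, tr, window_ms = 50, fwe_level = NULL)
  expect_lt(max(abs(ex$amplitudes$values - amps$values)), 1e-9)

  # invariant to a per-epoch DC offset
  ep_dc <- ep
  ep_dc$data <- ep$data + 12.5
  ex_dc <- extract_mmn(ep_dc, tr, window_ms = 50, fwe_level = NULL)
  expect_equal(ex_dc$amplitudes$values, ex$amplitudes$values,
               tolerance = 1e-10)

  # a subject with no MMN at all is flagged, not dropped
  amps0 <- amps
  amps0$values[] <- 0
  ep0 <- simulate_epochs(s, tr, amps0,
                         epoch_config(bump_shape = "flat",
                                      sensor_noise_sd = 0.5))
  ex0 <- suppressWarnings(extract_mmn(ep0, tr, window_ms = 50,
                                      fwe_level = 0.05))
  expect_true(ex0$flagged)
  expect_length(ex0$selected_electrodes, 0L)
})
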