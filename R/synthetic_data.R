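#' Ground truth for one synthetic subject
#'
#' Describes how a synthetic subject's trial-wise MMN amplitudes are
#' generated: which of the 13 response models drives them, that model's
#' parameters (observer hyperparameters for the free-energy models,
#' adaptation time constants for M4), the per-electrode regression weights
#' applied to the model's z-scored design matrix, and the per-electrode
#' Gaussian noise SD. Negative weights encode the negativity of the MMN.
#'
#' @param generating_model_id One of "M1".."M13".
#' @param model_params List: for M4 `tau_a`, `tau_r`; for M5-M13 an
#'   [observer_hyperparams()] under `hyper`; ignored for M1-M3.
#' @param electrode_weights Numeric matrix, design columns x electrodes
#'   (arbitrary units mapping predictors to microvolts).
#' @param noise_sd Per-electrode noise SD (microvolts), recycled.
#' @param seed Integer seed for the subject's noise.
#' @return An object of class `subject_ground_truth`.
#' @export
subject_ground_truth <- function(generating_model_id, model_params = list(),
                                 electrode_weights, noise_sd, seed) {
  if (!generating_model_id %in% model_registry()$model_id) {
    stop("unknown generating model: ", generating_model_id, call. = FALSE)
  }
  electrode_weights <- as.matrix(electrode_weights)
  noise_sd <- rep(noise_sd, length.out = ncol(electrode_weights))
  if (any(!is.finite(electrode_weights))) {
    stop("electrode weights must be finite", call. = FALSE)
  }
  if (any(noise_sd <= 0)) stop("noise_sd must be > 0", call. = FALSE)
  structure(
    list(
      generating_model_id = generating_model_id,
      model_params = model_params,
      electrode_weights = electrode_weights,
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "subject_ground_truth"
  )
}

# Design matrix of a ground truth's generating model for a sequence.
truth_design_matrix <- function(seq, trials, truth, hazard = "poisson") {
  reg <- model_registry()
  mid <- truth$generating_model_id
  trajectory <- NULL
  if (reg$framework[reg$model_id == mid] == "FEP") {
    hyper <- truth$model_params$hyper
    if (is.null(hyper)) stop("FEP generating model needs model_params$hyper",
                             call. = FALSE)
    trajectory <- run_observer(seq, hyper, hazard = hazard)
  }
  series <- compute_predictor(mid, trials, seq, trajectory, truth$model_params)
  build_design_matrix(series, reg$includes_intercept[reg$model_id == mid],
                      label = mid)
}

#' Simulate trial-wise MMN amplitudes from a generating model
#'
#' Draws the deviant x electrode amplitude matrix as
#' `y_k = X w_k + eps_k`, where `X` is the generating model's z-scored
#' design matrix (intercept included except for M1) and `eps_k` is i.i.d.
#' Gaussian with the electrode's noise SD.
#'
#' @param seq A `tone_sequence`.
#' @param trials Its `trial_table`.
#' @param truth A [subject_ground_truth()]; `electrode_weights` must have
#'   one row per design column.
#' @return List of class `amplitude_matrix`: `values` (deviants x
#'   electrodes, microvolts), `deviant_trial_indices`, plus the design
#'   matrix as attribute `design`.
#' @export
simulate_amplitudes <- function(seq, trials, truth) {
  X <- truth_design_matrix(seq, trials, truth)
  W <- truth$electrode_weights
  if (nrow(W) != ncol(X)) {
    stop("electrode_weights rows (", nrow(W), ") != design columns (",
         ncol(X), ")", call. = FALSE)
  }
  rng <- local_rng(truth$seed)
  on.exit(rng$restore())
  mean_part <- X %*% W
  noise <- matrix(stats::rnorm(length(mean_part)), nrow(mean_part)) *
    rep(truth$noise_sd, each = nrow(mean_part))
  out <- list(
    values = mean_part + noise,
    deviant_trial_indices = which(trials$is_deviant),
    peak_latency_ms = NA_real_,
    window_ms = NA_real_
  )
  attr(out, "design") <- X
  class(out) <- "amplitude_matrix"
  out
}

#' Epoch-level simulation settings
#'
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param t0_ms Time of the first sample relative to tone onset (<= -100).
#' @param t_end_ms Time of the last sample (>= 300 to cover the MMN band
#'   plus the post-window used in electrode selection).
#' @param bump_center_ms,bump_sd_ms Center and SD of the Gaussian
#'   deviance-specific bump (defaults 150 and 20 ms, mid-way through the
#'   100-200 ms latency search band).
#' @param bump_shape `"gaussian"`, or `"flat"` for a unit plateau over
#'   `flat_halfwidth_ms` around the center (exactly invertible by the
#'   windowed-mean extraction).
#' @param flat_halfwidth_ms Plateau half-width for `bump_shape = "flat"`.
#' @param electrode_gains Per-electrode gain on the deviance-specific
#'   signal (recycled to the electrode count at simulation time).
#' @param sensor_noise_sd Additive white Gaussian sensor noise SD
#'   (microvolts); 0 for noiseless epochs.
#' @return List of class `epoch_config`.
#' @export
epoch_config <- function(sampling_rate_hz = 500, t0_ms = -100, t_end_ms = 300,
                         bump_center_ms = 150, bump_sd_ms = 20,
                         bump_shape = c("gaussian", "flat"),
                         flat_halfwidth_ms = 25,
                         electrode_gains = 1, sensor_noise_sd = 0) {
  bump_shape <- match.arg(bump_shape)
  if (t0_ms > -100) stop("epoch must start at or before -100 ms", call. = FALSE)
  if (t_end_ms < 300) stop("epoch must extend to at least 300 ms", call. = FALSE)
  structure(
    list(sampling_rate_hz = sampling_rate_hz, t0_ms = t0_ms,
         t_end_ms = t_end_ms, bump_center_ms = bump_center_ms,
         bump_sd_ms = bump_sd_ms, bump_shape = bump_shape,
         flat_halfwidth_ms = flat_halfwidth_ms,
         electrode_gains = electrode_gains,
         sensor_noise_sd = sensor_noise_sd),
    class = "epoch_config"
  )
}

# Unit deviance-bump time course on a sample grid (positive; the sign of
# the MMN enters through negative amplitudes).
bump_waveform <- function(times_ms, config) {
  if (config$bump_shape == "flat") {
    as.numeric(abs(times_ms - config$bump_center_ms) <=
                 config$flat_halfwidth_ms + 1e-9)
  } else {
    exp(-(times_ms - config$bump_center_ms)^2 / (2 * config$bump_sd_ms^2))
  }
}

# Deterministic per-frequency standard template: an N1-like deflection
# whose gain depends on the tone, zero over the baseline segment.
standard_template <- function(times_ms, freq_index, n_electrodes) {
  shape <- -(1 + 0.15 * freq_index) *
    exp(-(times_ms - 100)^2 / (2 * 30^2)) * (times_ms >= 0)
  matrix(rep(shape, each = n_electrodes), n_electrodes, length(times_ms))
}

#' Simulate peristimulus epochs embedding known trial-wise amplitudes
#'
#' Builds one epoch per tone: the tone's standard template, plus (on
#' deviant trials) the deviance bump scaled by the trial's generated
#' amplitude and the electrode gain, plus optional white sensor noise.
#' Because standard trials of a tone contain exactly its template, the
#' windowed-mean extraction applied to these epochs recovers the generated
#' amplitudes (exactly, for a flat bump covering the extraction window and
#' zero sensor noise).
#'
#' @inheritParams simulate_amplitudes
#' @param amplitudes An `amplitude_matrix` from [simulate_amplitudes()]
#'   giving the deviance-specific amplitude per deviant and electrode.
#' @param config An [epoch_config()].
#' @return List of class `epoch_array`: `data` (trials x electrodes x
#'   samples, microvolts), `times_ms`, `sampling_rate_hz`, `t0_ms`.
#' @export
simulate_epochs <- function(seq, trials, amplitudes, config = epoch_config()) {
  stopifnot(inherits(config, "epoch_config"))
  n_trials <- nrow(trials)
  n_elec <- ncol(amplitudes$values)
  gains <- rep(config$electrode_gains, length.out = n_elec)
  step <- 1000 / config$sampling_rate_hz
  times <- seq(config$t0_ms, config$t_end_ms, by = step)
  if (config$bump_center_ms < 100 || config$bump_center_ms > 200) {
    stop("bump center must lie in the 100-200 ms MMN search band", call. = FALSE)
  }
  n_t <- length(times)
  freq_index <- match(round(seq$frequencies_hz, 9),
                      round(seq$design$frequency_set, 9))
  bump <- bump_waveform(times, config)

  rng <- local_rng(derive_seed(amplitudes_seed(amplitudes, seq), 77L))
  on.exit(rng$restore())
  data <- array(0, dim = c(n_trials, n_elec, n_t))
  templates <- lapply(sort(unique(freq_index)), function(fi) {
    standard_template(times, fi, n_elec)
  })
  names(templates) <- as.character(sort(unique(freq_index)))
  dev_row <- 0L
  dev_idx <- amplitudes$deviant_trial_indices
  for (t in seq_len(n_trials)) {
    ep <- templates[[as.character(freq_index[t])]]
    if (t %in% dev_idx) {
      dev_row <- dev_row + 1L
      ep <- ep + (amplitudes$values[dev_row, ] * gains) %o% bump
    }
    if (config$sensor_noise_sd > 0) {
      ep <- ep + matrix(stats::rnorm(n_elec * n_t, sd = config$sensor_noise_sd),
                        n_elec, n_t)
    }
    data[t, , ] <- ep
  }
  structure(
    list(data = data, times_ms = times,
         sampling_rate_hz = config$sampling_rate_hz, t0_ms = config$t0_ms),
    class = "epoch_array"
  )
}

amplitudes_seed <- function(amplitudes, seq) {
  # epochs get their own reproducible noise stream tied to the sequence seed
  seq$seed %||% 1L
}

#' Simulate a multi-subject synthetic cohort
#'
#' Generates `n_subjects` independent subjects: each gets its own roving
#' sequence, trial table and amplitude matrix (plus, optionally, full
#' epochs), with per-subject seeds derived deterministically from the
#' master seed. Defaults mirror the modelled study: 8 subjects, 1600
#' tones, 7 log-spaced frequencies in 500-800 Hz, 10 electrodes.
#'
#' @param generating_model_id Model driving the amplitudes ("M1".."M13").
#' @param n_subjects Number of subjects.
#' @param n_electrodes Number of electrodes.
#' @param design A [stimulus_design()].
#' @param model_params As in [subject_ground_truth()]; defaults supply
#'   mid-grid observer hyperparameters for free-energy models and
#'   `tau_a = 8`, `tau_r = 16` for M4.
#' @param electrode_weights Design-columns x electrodes weight matrix;
#'   default: intercept -2 microvolts and slope -1 microvolt, scaled by
#'   distinct electrode gains between 0.6 and 1.4.
#' @param noise_sd Per-electrode noise SD (default 2 microvolts).
#' @param master_seed Master seed; subject seeds derive from it.
#' @param epochs If `TRUE` also simulate epoch arrays per subject.
#' @param epoch_cfg An [epoch_config()] when `epochs = TRUE`.
#' @return List of class `synthetic_cohort` with `subjects` (each holding
#'   `seq`, `trials`, `amplitudes`, optional `epochs`, `truth`),
#'   `generating_model_id`, `n_electrodes`, `master_seed`.
#' @export
make_cohort <- function(generating_model_id = "M6",
                        n_subjects = 8L,
                        n_electrodes = 10L,
                        design = stimulus_design(),
                        model_params = NULL,
                        electrode_weights = NULL,
                        noise_sd = 2,
                        master_seed = 1L,
                        epochs = FALSE,
                        epoch_cfg = epoch_config()) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  reg <- model_registry()
  if (is.null(model_params)) {
    model_params <- default_model_params(generating_model_id)
  }
  has_intercept <- reg$includes_intercept[reg$model_id == generating_model_id]
  if (is.null(electrode_weights)) {
    gains <- seq(0.6, 1.4, length.out = n_electrodes)
    base <- if (has_intercept) c(-2, -1) else -2
    electrode_weights <- outer(base, gains)
  }
  subjects <- lapply(seq_len(n_subjects), function(i) {
    seq_i <- generate_roving_sequence(design, derive_seed(master_seed, i))
    trials_i <- annotate_trials(seq_i)
    truth_i <- subject_ground_truth(
      generating_model_id, model_params, electrode_weights, noise_sd,
      seed = derive_seed(master_seed, 1000L + i)
    )
    amps_i <- simulate_amplitudes(seq_i, trials_i, truth_i)
    out <- list(seq = seq_i, trials = trials_i, amplitudes = amps_i,
                truth = truth_i)
    if (epochs) out$epochs <- simulate_epochs(seq_i, trials_i, amps_i, epoch_cfg)
    out
  })
  structure(
    list(subjects = subjects, generating_model_id = generating_model_id,
         n_electrodes = as.integer(n_electrodes),
         master_seed = as.integer(master_seed)),
    class = "synthetic_cohort"
  )
}

#' @rdname make_cohort
#' @export
default_model_params <- function(generating_model_id) {
  reg <- model_registry()
  fw <- reg$framework[reg$model_id == generating_model_id]
  if (fw == "FEP") {
    list(hyper = observer_hyperparams(sigma2_u = 2e-3, kappa = 5, lambda0 = 7))
  } else if (generating_model_id == "M4") {
    list(tau_a = 8, tau_r = 16)
  } else {
    list()
  }
}
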