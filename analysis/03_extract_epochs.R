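#!/usr/bin/env Rscript
# Stage 3: epoch-level round trip for two subjects.
#
# Simulates full peristimulus waveforms (500 Hz sampling, -100..300 ms,
# Gaussian deviance bump at 150 ms, 0.5 uV sensor noise) embedding the
# stage-2 amplitudes, then re-estimates trial-wise MMN amplitudes with the
# four-step procedure (standard ERP subtraction, baseline correction, peak
# latency in 100-200 ms, windowed mean) plus Sidak electrode selection.
#
# Finds: the estimated peak latency lands on the simulated bump center and
# extracted amplitudes correlate strongly with the embedded ground truth
# despite the sensor noise.

suppressPackageStartupMessages(library(mmnlearn))
out_dir <- "results/extraction"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

master_seed <- 101L
cohort <- make_cohort("M6", n_subjects = 2L, n_electrodes = 10L,
                      master_seed = master_seed)
cfg <- epoch_config(bump_shape = "gaussian", bump_center_ms = 150,
                    sensor_noise_sd = 0.5)

summaries <- list()
for (i in seq_along(cohort$subjects)) {
  s <- cohort$subjects[[i]]
  epochs <- simulate_epochs(s$seq, s$trials, s$amplitudes, cfg)
  ex <- extract_mmn(epochs, s$trials, window_ms = 50, fwe_level = 0.05)
  truth_vals <- s$amplitudes$values[, ex$selected_electrodes, drop = FALSE]
  r <- cor(as.vector(ex$amplitudes$values), as.vector(truth_vals))
  summaries[[i]] <- list(subject = i,
                         peak_latency_ms = ex$peak_latency_ms,
                         n_selected_electrodes = length(ex$selected_electrodes),
                         flagged = ex$flagged,
                         cor_with_truth = r)
  write_amplitude_matrix(
    ex$amplitudes,
    file.path(out_dir, sprintf("subject%02d_extracted_amplitudes.tsv", i))
  )
  cat(sprintf(
    "subject %d: latency %g ms, %d/%d electrodes selected, cor(truth) = %.3f\n",
    i, ex$peak_latency_ms, length(ex$selected_electrodes),
    cohort$n_electrodes, r
  ))
}
jsonlite::write_json(summaries, file.path(out_dir, "extraction_summary.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
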