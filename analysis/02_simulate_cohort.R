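#!/usr/bin/env Rscript
# Stage 2: simulate the synthetic study cohort.
#
# Eight subjects, each with their own 1600-tone roving sequence and a
# deviants x 10-electrode matrix of trial-wise MMN amplitudes generated
# under the category-level prediction-error model (M6): amplitudes are a
# linear mixture of the model's z-scored predictor (negative weights, as
# befits a negativity) plus 2 microvolts of Gaussian trial noise.
# Ground truth is written alongside so later stages can score recovery.

suppressPackageStartupMessages(library(mmnlearn))
out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

master_seed <- 101L
cohort <- make_cohort("M6", n_subjects = 8L, n_electrodes = 10L,
                      master_seed = master_seed)

for (i in seq_along(cohort$subjects)) {
  s <- cohort$subjects[[i]]
  write_trial_table(s$trials,
                    file.path(out_dir, sprintf("subject%02d_trials.tsv", i)))
  write_amplitude_matrix(
    s$amplitudes, file.path(out_dir, sprintf("subject%02d_amplitudes.tsv", i))
  )
}

truth <- cohort$subjects[[1]]$truth
jsonlite::write_json(
  list(generating_model_id = cohort$generating_model_id,
       master_seed = master_seed,
       n_subjects = length(cohort$subjects),
       n_electrodes = cohort$n_electrodes,
       observer_hyperparams = truth$model_params$hyper[c("sigma2_u", "kappa",
                                                         "lambda0")],
       electrode_weights = truth$electrode_weights,
       noise_sd = truth$noise_sd),
  file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE
)

n_dev <- vapply(cohort$subjects, function(s) sum(s$trials$is_deviant),
                integer(1))
cat("cohort written to", out_dir, "\n")
cat("generating model:", cohort$generating_model_id, "\n")
cat("deviants per subject:", paste(n_dev, collapse = ", "), "\n")
cat("mean amplitude (uV), subject 1:",
    round(mean(cohort$subjects[[1]]$amplitudes$values), 3), "\n")
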