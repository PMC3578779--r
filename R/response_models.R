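#' Registry of the 13 trial-wise MMN response models
#'
#' The model space is organized hierarchically: five families under two
#' frameworks.
#' \itemize{
#'   \item change detection (phenomenological): M1 categorical change, M2
#'     absolute change in log-frequency, M3 signed change;
#'   \item adaptation (phenomenological): M4 responsiveness of the
#'     deviant-driven population;
#'   \item prediction error (free energy): M5 precision-weighted sensory
#'     prediction error, M6 precision-weighted category prediction error;
#'   \item novelty (free energy): M7 surprisal of the sensory input, M8
#'     surprisal of the tone category;
#'   \item model adjustment (free energy): M9 signed change in the MAP
#'     category's mean, M10 signed change in expected train length, M11 L1
#'     change in the change-conditional transition matrix, M12 = |M9|,
#'     M13 = |M10|.
#' }
#' All models except M1 get an intercept column appended to their z-scored
#' predictor; M1 is a constant-only (null) model predicting no
#' trial-by-trial variation and takes no extra intercept.
#'
#' @return A `data.frame` with columns `model_id`, `family`, `framework`,
#'   `includes_intercept`, `description` (13 rows, M1..M13).
#' @export
model_registry <- function() {
  data.frame(
    model_id = paste0("M", 1:13),
    family = c(rep("change_detection", 3), "adaptation",
               rep("prediction_error", 2), rep("novelty", 2),
               rep("model_adjustment", 5)),
    framework = c(rep("phenomenological", 4), rep("FEP", 9)),
    includes_intercept = c(FALSE, rep(TRUE, 12)),
    description = c(
      "categorical response: change or no change",
      "absolute change in log-frequency",
      "signed change in log-frequency",
      "responsiveness of adapted neurons selective to the deviant",
      "precision-weighted prediction error on the sensory input",
      "precision-weighted prediction error on the tone category",
      "surprisal of the sensory input",
      "surprisal of the tone category",
      "signed change in the category's mean log-frequency",
      "signed change in expected train length",
      "L1 change in change-conditional transition probabilities",
      "absolute change in the category's mean log-frequency",
      "absolute change in expected train length"
    ),
    stringsAsFactors = FALSE
  )
}

#' Per-deviant predictor series for one model
#'
#' Evaluates the model's response function at every deviant trial. The
#' free-energy models read quantities from an observer trajectory computed
#' with [run_observer()] (values come from that trial's predictive
#' distribution and same-trial belief update); the phenomenological models
#' are computed directly from the sequence (M1-M3) or from the adaptation
#' state iteration (M4, which needs `params = list(tau_a, tau_r)`).
#'
#' @param model_id One of "M1".."M13".
#' @param trials `trial_table` for the sequence.
#' @param seq The `tone_sequence`.
#' @param trajectory `observer_trajectory` (required for M5-M13).
#' @param params List of parameters for M4 (`tau_a`, `tau_r`).
#' @return Numeric vector, one value per deviant trial.
#' @export
compute_predictor <- function(model_id, trials, seq, trajectory = NULL,
                              params = NULL) {
  dev <- which(trials$is_deviant)
  fep_field <- c(
    M5 = "pe_sensory", M6 = "pe_category", M7 = "surprisal_input",
    M8 = "surprisal_category", M9 = "d_nu", M10 = "d_lambda",
    M11 = "d_B_l1", M12 = "d_nu", M13 = "d_lambda"
  )
  if (model_id %in% c("M1", "M2", "M3")) {
    variant <- c(M1 = "categorical", M2 = "absolute", M3 = "signed")[[model_id]]
    change_detection_predictor(trials, seq, variant)
  } else if (model_id == "M4") {
    if (is.null(params$tau_a) || is.null(params$tau_r)) {
      stop("M4 requires params$tau_a and params$tau_r", call. = FALSE)
    }
    adaptation_predictor(seq, trials, params$tau_a, params$tau_r)
  } else if (model_id %in% names(fep_field)) {
    if (is.null(trajectory)) {
      stop(model_id, " requires an observer trajectory", call. = FALSE)
    }
    x <- trajectory[[fep_field[[model_id]]]][dev]
    if (model_id %in% c("M12", "M13")) abs(x) else x
  } else {
    stop("unknown model_id: ", model_id, call. = FALSE)
  }
}

#' Assemble a design matrix from a predictor series
#'
#' Non-constant predictors are z-scored (sample standard deviation, n - 1
#' denominator) and an intercept column of ones is appended; a
#' constant-only model (M1) yields the single all-ones column with no
#' additional intercept.
#'
#' @param series Per-deviant predictor values.
#' @param includes_intercept Whether to z-score `series` and append an
#'   intercept (`TRUE` for all models but M1).
#' @param label Column label for the predictor.
#' @return Numeric matrix (deviants x 1 or 2) with column names.
#' @export
build_design_matrix <- function(series, includes_intercept = TRUE,
                                label = "predictor") {
  n <- length(series)
  if (n < 3L) stop("need at least 3 deviant trials", call. = FALSE)
  if (!includes_intercept) {
    return(matrix(1, n, 1, dimnames = list(NULL, "constant")))
  }
  s <- stats::sd(series)
  if (!is.finite(s) || s == 0) {
    stop("zero-variance predictor for ", label, call. = FALSE)
  }
  z <- (series - mean(series)) / s
  X <- cbind(rep(1, n), z)
  colnames(X) <- c("intercept", label)
  X
}

#' The three predefined partitions of the model space
#'
#' \enumerate{
#'   \item `theories`: the five families (change detection, adaptation,
#'     prediction error, novelty, model adjustment; sizes 3/1/2/2/5).
#'   \item `frameworks`: phenomenological (M1-M4) vs free-energy (M5-M13).
#'   \item `representation`: models tied to low-level sound frequency
#'     (M1-M5, M7, M9, M12) vs abstract temporal structure / tone-category
#'     sequence (M6, M8, M10, M11, M13).
#' }
#'
#' @return Named list of three partitions; each partition is a named list
#'   of character vectors of model ids covering M1..M13 exactly once.
#' @export
predefined_partitions <- function() {
  list(
    theories = list(
      change_detection = paste0("M", 1:3),
      adaptation = "M4",
      prediction_error = paste0("M", 5:6),
      novelty = paste0("M", 7:8),
      model_adjustment = paste0("M", 9:13)
    ),
    frameworks = list(
      phenomenological = paste0("M", 1:4),
      free_energy = paste0("M", 5:13)
    ),
    representation = list(
      low_level = paste0("M", c(1:5, 7, 9, 12)),
      high_level = paste0("M", c(6, 8, 10, 11, 13))
    )
  )
}
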