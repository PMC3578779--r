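#' Default hyperparameter grids
#'
#' `default_fep_grid()` spans perceptual uncertainty from well below to
#' above one semitone (the category spacing is ln(2)/12 ~ 0.058 log-Hz),
#' prior strengths from weak to firm, and prior train lengths bracketing
#' the design's mean of ~7.3 tones. `default_adaptation_grid()` covers
#' adaptation/recovery time constants on a doubling grid over 1-50 trials.
#'
#' @return A `data.frame`, one row per grid point.
#' @export
default_fep_grid <- function() {
  expand.grid(
    sigma2_u = c(5e-4, 2e-3, 8e-3),
    kappa = c(1, 5, 20),
    lambda0 = c(3, 7, 11)
  )
}

#' @rdname default_fep_grid
#' @export
default_adaptation_grid <- function() {
  taus <- c(1, 2, 4, 8, 16, 32, 50)
  expand.grid(tau_a = taus, tau_r = taus)
}

#' Evidence-maximizing hyperparameter fit for one model
#'
#' Grid search: for each grid point the observer (or adaptation state) is
#' run over the subject's tone sequence, the model's design matrix is
#' assembled, and the subject log evidence is computed; the grid point
#' with the highest evidence is returned together with that evidence,
#' which is the model evidence reported for the subject.
#'
#' @param amplitudes `amplitude_matrix` (or bare deviants x electrodes
#'   matrix) for the subject.
#' @param seq,trials The subject's tone sequence and trial table.
#' @param model_id One of "M1".."M13".
#' @param grid `data.frame` of parameter combinations: columns
#'   `sigma2_u`, `kappa`, `lambda0` for M5-M13; `tau_a`, `tau_r` for M4;
#'   ignored for M1-M3.
#' @param prior A [regression_prior()].
#' @param hazard Hazard family passed to [run_observer()].
#' @return List: `params` (best row as a list; empty for M1-M3),
#'   `log_evidence`, `grid_evidence` (evidence at every grid point).
#' @export
fit_hyperparameters <- function(amplitudes, seq, trials, model_id,
                                grid = NULL, prior = regression_prior(),
                                hazard = "poisson") {
  fits <- fit_subject(amplitudes, seq, trials, models = model_id,
                      fep_grid = grid, adaptation_grid = grid,
                      prior = prior, hazard = hazard)
  fits[[model_id]]
}

#' Fit all (or some) of the 13 models to one subject
#'
#' Shares work across models: each observer run (one per free-energy grid
#' point) serves all nine free-energy models, and each adaptation sweep
#' serves M4. Returns, per model, the maximized log evidence and the
#' maximizing parameters.
#'
#' @inheritParams fit_hyperparameters
#' @param models Character vector of model ids (default: all 13).
#' @param fep_grid Grid for the observer hyperparameters
#'   (default [default_fep_grid()]).
#' @param adaptation_grid Grid for `tau_a`, `tau_r`
#'   (default [default_adaptation_grid()]).
#' @return Named list (per model) of lists `params`, `log_evidence`,
#'   `grid_evidence`.
#' @export
fit_subject <- function(amplitudes, seq, trials,
                        models = model_registry()$model_id,
                        fep_grid = NULL, adaptation_grid = NULL,
                        prior = regression_prior(), hazard = "poisson") {
  if (inherits(amplitudes, "amplitude_matrix")) {
    Y <- amplitudes$values
  } else {
    Y <- as.matrix(amplitudes)
  }
  if (nrow(Y) != sum(trials$is_deviant)) {
    stop("amplitude rows must equal the number of deviants", call. = FALSE)
  }
  reg <- model_registry()
  unknown <- setdiff(models, reg$model_id)
  if (length(unknown) > 0L) {
    stop("unknown model ids: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- list()

  evidence_for <- function(series, model_id) {
    X <- build_design_matrix(
      series, reg$includes_intercept[reg$model_id == model_id], model_id
    )
    subject_log_evidence(Y, X, prior)
  }

  for (mid in intersect(models, c("M1", "M2", "M3"))) {
    series <- compute_predictor(mid, trials, seq)
    out[[mid]] <- list(params = list(),
                       log_evidence = evidence_for(series, mid),
                       grid_evidence = NULL)
  }

  if ("M4" %in% models) {
    g <- adaptation_grid
    if (is.null(g) || is.null(g$tau_a)) g <- default_adaptation_grid()
    ev <- vapply(seq_len(nrow(g)), function(i) {
      series <- adaptation_predictor(seq, trials, g$tau_a[i], g$tau_r[i])
      evidence_for(series, "M4")
    }, numeric(1))
    best <- which.max(ev)
    out[["M4"]] <- list(params = as.list(g[best, , drop = FALSE]),
                        log_evidence = unname(ev[best]), grid_evidence = ev)
  }

  fep_models <- intersect(models, paste0("M", 5:13))
  if (length(fep_models) > 0L) {
    g <- fep_grid
    if (is.null(g) || is.null(g$sigma2_u)) g <- default_fep_grid()
    if (nrow(g) == 0L) stop("empty hyperparameter grid", call. = FALSE)
    ev <- matrix(NA_real_, nrow(g), length(fep_models),
                 dimnames = list(NULL, fep_models))
    for (i in seq_len(nrow(g))) {
      hyper <- observer_hyperparams(g$sigma2_u[i], g$kappa[i], g$lambda0[i])
      traj <- run_observer(seq, hyper, hazard = hazard)
      for (mid in fep_models) {
        series <- compute_predictor(mid, trials, seq, trajectory = traj)
        ev[i, mid] <- evidence_for(series, mid)
      }
    }
    for (mid in fep_models) {
      best <- which.max(ev[, mid])
      out[[mid]] <- list(params = as.list(g[best, , drop = FALSE]),
                         log_evidence = unname(ev[best, mid]),
                         grid_evidence = ev[, mid])
    }
  }
  out[models]
}

#' Subjects x models log-evidence table for a cohort
#'
#' @param cohort A `synthetic_cohort` (or a list of subjects each holding
#'   `amplitudes`, `seq`, `trials`).
#' @inheritParams fit_subject
#' @return Numeric matrix (subjects x models) of maximized log evidences,
#'   with model ids as column names; per-subject best-fit parameters in
#'   attribute `best_params`.
#' @export
evidence_table <- function(cohort, models = model_registry()$model_id,
                           fep_grid = NULL, adaptation_grid = NULL,
                           prior = regression_prior(), hazard = "poisson") {
  subjects <- if (inherits(cohort, "synthetic_cohort")) cohort$subjects else cohort
  tab <- matrix(NA_real_, length(subjects), length(models),
                dimnames = list(paste0("S", seq_along(subjects)), models))
  best <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    fits <- fit_subject(s$amplitudes, s$seq, s$trials, models,
                        fep_grid, adaptation_grid, prior, hazard)
    tab[i, ] <- vapply(fits, `[[`, numeric(1), "log_evidence")
    best[[i]] <- lapply(fits, `[[`, "params")
  }
  attr(tab, "best_params") <- best
  tab
}
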