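#' Hyperparameters of the free-energy Bayesian observer
#'
#' Three subject-level quantities govern the observer: the perceptual
#' uncertainty `sigma2_u` (variance of the log-frequency representation, in
#' log-Hz squared), the prior strength `kappa` (virtual prior observations;
#' acts as the initial effective count for category means, expected
#' sequence length and transition rows alike), and the prior expectation of
#' tone-train length `lambda0` (tones, > 1). They are properties of the
#' observer, inferred from data by grid search ([fit_hyperparameters()]),
#' not learned by the observer itself.
#'
#' @param sigma2_u Perceptual uncertainty, > 0 (log-Hz squared).
#' @param kappa Prior strength, > 0 (virtual observations).
#' @param lambda0 Prior expected train length, > 1 (tones).
#' @return An object of class `observer_hyperparams`.
#' @export
observer_hyperparams <- function(sigma2_u, kappa, lambda0) {
  if (!is.finite(sigma2_u) || sigma2_u <= 0) stop("sigma2_u must be > 0", call. = FALSE)
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  if (!is.finite(lambda0) || lambda0 <= 1) stop("lambda0 must be > 1", call. = FALSE)
  structure(
    list(sigma2_u = sigma2_u, kappa = kappa, lambda0 = lambda0),
    class = "observer_hyperparams"
  )
}

# Equal-tempered semitone frequency for index k relative to A4 = 440 Hz.
semitone_hz <- function(k) 440 * 2^(k / 12)

#' Initialize the observer's belief state
#'
#' The observer's mental model of the tone sequence holds a fixed grid of
#' tone categories, one per equal-tempered semitone (A4 = 440 Hz
#' reference): the minimal contiguous run of semitones covering the
#' stimulus frequency range. For the 500-800 Hz range used here this gives
#' 10 categories, from B4 (493.88 Hz) to Ab5 (830.61 Hz). Each category
#' carries a point-estimate belief about its characteristic log-frequency
#' (initialized at the semitone), the observer holds a belief about the
#' expected train length (`lambda0`) and a change-conditional transition
#' matrix (uniform off-diagonal), and every belief carries an effective
#' count initialized at `kappa`.
#'
#' @param hyper An [observer_hyperparams()].
#' @param stimulus_range_hz Length-2 numeric `(low, high)`, 0 < low < high.
#' @return An object of class `belief_state`: `nu` (category log-frequency
#'   means), `n_nu`, `lambda_hat`, `n_lambda`, `B` (change-conditional
#'   transition matrix, zero diagonal, off-diagonal rows summing to 1),
#'   `n_B`, `c_prev` (NA before the first tone), `r` (current run length),
#'   `F_trace`, plus `hyper` and `category_hz`.
#' @export
init_beliefs <- function(hyper, stimulus_range_hz) {
  stopifnot(inherits(hyper, "observer_hyperparams"))
  low <- stimulus_range_hz[1L]
  high <- stimulus_range_hz[2L]
  if (!is.finite(low) || !is.finite(high) || low <= 0 || low >= high) {
    stop("stimulus range must satisfy 0 < low < high", call. = FALSE)
  }
  # minimal contiguous semitone run covering [low, high]
  k_lo <- floor(12 * log2(low / 440))
  if (semitone_hz(k_lo + 1) <= low) k_lo <- k_lo + 1L
  k_hi <- ceiling(12 * log2(high / 440))
  if (semitone_hz(k_hi - 1) >= high) k_hi <- k_hi - 1L
  ks <- seq(k_lo, k_hi)
  n_cat <- length(ks)
  if (n_cat < 2L) stop("stimulus range not coverable by >= 2 categories", call. = FALSE)
  category_hz <- semitone_hz(ks)

  B <- matrix(1 / (n_cat - 1L), n_cat, n_cat)
  diag(B) <- 0
  structure(
    list(
      nu = log(category_hz),
      n_nu = rep(hyper$kappa, n_cat),
      lambda_hat = hyper$lambda0,
      n_lambda = hyper$kappa,
      B = B,
      n_B = rep(hyper$kappa, n_cat),
      c_prev = NA_integer_,
      r = 0L,
      F_trace = NA_real_,
      hyper = hyper,
      category_hz = category_hz
    ),
    class = "belief_state"
  )
}

# Hazard of a change after r repetitions of the current tone, under a
# run-length (train length, in tones) distribution with mean lambda.
#  - "poisson": L = 1 + Poisson(lambda - 1); hazard increases with r.
#  - "geometric": L ~ Geometric with mean lambda; constant hazard 1/lambda.
change_hazard <- function(r, lambda, hazard = c("poisson", "geometric")) {
  hazard <- match.arg(hazard)
  if (hazard == "geometric") {
    h <- 1 / lambda
  } else {
    mu <- lambda - 1
    # P(L = r + 1 | L > r) with L - 1 ~ Poisson(mu)
    num <- stats::dpois(r, mu)
    den <- if (r == 0L) 1 else stats::ppois(r - 1L, mu, lower.tail = FALSE)
    h <- if (den > 0) num / den else 1
  }
  min(max(h, 1e-12), 1 - 1e-12)
}

#' Predictive distribution over the next tone's category
#'
#' The effective transition row of the observer's run-length-dependent
#' hidden Markov model: with probability `1 - h(r)` the current category
#' repeats; with probability `h(r)` a change occurs and the next category
#' follows the change-conditional transition row `B[c_prev, ]`. The hazard
#' `h(r)` depends on how often the current tone has been repeated (`r`) and
#' on the believed mean train length. Before the first tone the prediction
#' is uniform over categories.
#'
#' @param belief A `belief_state`.
#' @param hazard Run-length distribution family for the hazard:
#'   `"poisson"` (default; hazard grows with run length) or `"geometric"`
#'   (constant hazard `1/lambda`).
#' @return List with `p_pred` (probability vector over categories) and
#'   `change_hazard`.
#' @export
predictive_distribution <- function(belief, hazard = c("poisson", "geometric")) {
  hazard <- match.arg(hazard)
  n_cat <- length(belief$nu)
  if (is.na(belief$c_prev)) {
    return(list(p_pred = rep(1 / n_cat, n_cat), change_hazard = NA_real_))
  }
  h <- change_hazard(belief$r, belief$lambda_hat, hazard)
  p <- h * belief$B[belief$c_prev, ]
  p[belief$c_prev] <- 1 - h
  list(p_pred = p, change_hazard = h)
}

#' Assimilate one tone: perception and learning by MAP inference
#'
#' One application of the observer's evolution function. With point-mass
#' (delta) posterior beliefs, free-energy minimization reduces to
#' maximum-a-posteriori inference on the expected internal energy:
#' the tone is assigned to the category maximizing
#' `ln p_pred(j) - (u_t - nu_j)^2 / (2 sigma2_u)` (ties broken toward the
#' lower index). Learning then updates the conjugate sufficient statistics:
#' the MAP category's mean moves toward `u_t` with its effective count; if
#' a change is inferred, the previous category's transition row is
#' incremented on the new category, the expected train length is updated as
#' the count-weighted running mean of the completed train's length, and the
#' run length resets.
#'
#' @param belief A `belief_state`.
#' @param u_t Log-frequency of the presented tone.
#' @inheritParams predictive_distribution
#' @return List with `belief` (updated state) and `record`, a one-row
#'   `data.frame` holding the trial's predictor source quantities:
#'   `c_hat`, `mu_pred`, `s2_pred`, `pe_sensory`, `pe_category`,
#'   `surprisal_input`, `surprisal_category`, `d_nu`, `d_lambda`,
#'   `d_B_l1`, `internal_energy`, `change_hazard`, `is_change`.
#' @export
update_beliefs <- function(belief, u_t, hazard = c("poisson", "geometric")) {
  hazard <- match.arg(hazard)
  if (!is.finite(u_t)) stop("non-finite sensory input", call. = FALSE)
  step <- update_beliefs_fast(belief, u_t, hazard)
  rec <- step$rec
  names(rec) <- observer_record_fields()
  record <- as.data.frame(as.list(rec))
  record$c_hat <- as.integer(record$c_hat)
  record$is_change <- as.logical(record$is_change)
  list(belief = step$belief, record = record)
}

observer_record_fields <- function() {
  c("c_hat", "mu_pred", "s2_pred", "pe_sensory", "pe_category",
    "surprisal_input", "surprisal_category", "d_nu", "d_lambda",
    "d_B_l1", "internal_energy", "change_hazard", "is_change")
}

#' Run the observer over a whole tone sequence
#'
#' Folds [update_beliefs()] over the sequence's log-frequencies in
#' presentation order. Deterministic given its inputs.
#'
#' @param seq A `tone_sequence` (or any object with a `log_frequencies`
#'   field).
#' @param hyper An [observer_hyperparams()].
#' @param stimulus_range_hz Stimulus range used to build the category grid;
#'   defaults to the range of the design's frequency set.
#' @inheritParams predictive_distribution
#' @return An object of class `observer_trajectory`: a `data.frame` with
#'   one row per tone (all [update_beliefs()] record fields), with the
#'   final `belief_state` attached as attribute `final_belief`.
#' @export
run_observer <- function(seq, hyper,
                         stimulus_range_hz = NULL,
                         hazard = c("poisson", "geometric")) {
  hazard <- match.arg(hazard)
  u <- seq$log_frequencies
  n <- length(u)
  if (n == 0L) stop("empty tone sequence", call. = FALSE)
  if (is.null(stimulus_range_hz)) {
    stimulus_range_hz <- range(seq$design$frequency_set)
  }
  belief <- init_beliefs(hyper, stimulus_range_hz)

  cols <- observer_record_fields()
  out <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  for (t in seq_len(n)) {
    step <- update_beliefs_fast(belief, u[t], hazard)
    belief <- step$belief
    out[t, ] <- step$rec
  }
  traj <- as.data.frame(out)
  traj$c_hat <- as.integer(traj$c_hat)
  traj$is_change <- as.logical(traj$is_change)
  traj$trial <- seq_len(n)
  attr(traj, "final_belief") <- belief
  class(traj) <- c("observer_trajectory", "data.frame")
  traj
}

# Same update as update_beliefs() but returning a bare numeric vector, to
# keep long runs cheap; update_beliefs() wraps it with a data.frame record.
update_beliefs_fast <- function(belief, u_t, hazard) {
  s2u <- belief$hyper$sigma2_u
  nu <- belief$nu
  n_cat <- length(nu)

  if (is.na(belief$c_prev)) {
    p_pred <- rep(1 / n_cat, n_cat)
    h <- NA_real_
  } else {
    h <- change_hazard(belief$r, belief$lambda_hat, hazard)
    p_pred <- h * belief$B[belief$c_prev, ]
    p_pred[belief$c_prev] <- 1 - h
  }

  objective <- log(p_pred) - (u_t - nu)^2 / (2 * s2u)
  c_hat <- which.max(objective)

  mu_pred <- sum(p_pred * nu)
  s2_pred <- sum(p_pred * (nu - mu_pred)^2)

  d_lambda <- 0
  d_B_l1 <- 0
  nu_old <- nu[c_hat]
  belief$nu[c_hat] <- (belief$n_nu[c_hat] * nu_old + u_t) / (belief$n_nu[c_hat] + 1)
  belief$n_nu[c_hat] <- belief$n_nu[c_hat] + 1
  d_nu <- belief$nu[c_hat] - nu_old

  is_change <- !is.na(belief$c_prev) && c_hat != belief$c_prev
  if (is_change) {
    cp <- belief$c_prev
    row_old <- belief$B[cp, ]
    e <- numeric(n_cat)
    e[c_hat] <- 1
    belief$B[cp, ] <- (belief$n_B[cp] * row_old + e) / (belief$n_B[cp] + 1)
    belief$n_B[cp] <- belief$n_B[cp] + 1
    d_B_l1 <- sum(abs(belief$B[cp, ] - row_old))
    lam_old <- belief$lambda_hat
    belief$lambda_hat <- (belief$n_lambda * lam_old + belief$r + 1) /
      (belief$n_lambda + 1)
    belief$n_lambda <- belief$n_lambda + 1
    d_lambda <- belief$lambda_hat - lam_old
    belief$r <- 0L
  } else if (!is.na(belief$c_prev)) {
    belief$r <- belief$r + 1L
  }
  belief$c_prev <- c_hat
  ie <- -(objective[c_hat] - 0.5 * log(2 * pi * s2u))
  belief$F_trace <- ie

  list(
    belief = belief,
    rec = c(c_hat, mu_pred, s2_pred, (u_t - mu_pred) / s2u,
            (nu[c_hat] - mu_pred) / s2_pred, (u_t - mu_pred)^2 / (2 * s2u),
            -log(p_pred[c_hat]), d_nu, d_lambda, d_B_l1, ie, h, is_change)
  )
}
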