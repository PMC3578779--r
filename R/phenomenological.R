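#' Change-detection predictors (models M1-M3)
#'
#' The change-detection family assumes a one-dimensional memory trace
#' holding the previous tone's log-frequency. The three variants predict
#' the MMN amplitude at each deviant as:
#' \describe{
#'   \item{`categorical`}{1 for every deviant (M1): a constant response to
#'     any change, the family's null model of no trial-by-trial variation.}
#'   \item{`absolute`}{`|u_t - u_{t-1}|`, the unsigned change in
#'     log-frequency (M2).}
#'   \item{`signed`}{`u_t - u_{t-1}`, the signed change (M3).}
#' }
#'
#' @param trials A `trial_table` from [annotate_trials()].
#' @param seq The matching `tone_sequence`.
#' @param variant One of `"categorical"`, `"absolute"`, `"signed"`.
#' @return Numeric vector with one element per deviant trial, in trial
#'   order.
#' @export
change_detection_predictor <- function(trials, seq,
                                       variant = c("categorical", "absolute",
                                                   "signed")) {
  variant <- match.arg(variant)
  dev <- which(trials$is_deviant)
  u <- seq$log_frequencies
  if (variant == "categorical") return(rep(1, length(dev)))
  delta <- u[dev] - u[dev - 1L] # every deviant has a predecessor
  if (variant == "absolute") abs(delta) else delta
}

#' Frequency-selective adaptation state (model M4)
#'
#' Seven neural populations, each selective for one of the stimulus
#' frequencies, start fully responsive (responsiveness 1). On each tone the
#' driven population adapts by a multiplicative factor `exp(-1 / tau_a)`
#' while every other population recovers exponentially toward 1 with time
#' constant `tau_r` (both in units of trials).
#'
#' @param tau_a,tau_r Positive adaptation and recovery time constants
#'   (trials).
#' @param n_populations Number of frequency-selective populations.
#' @return An object of class `adaptation_state` with fields `a`
#'   (responsiveness vector in (0, 1]), `tau_a`, `tau_r`.
#' @export
adaptation_state <- function(tau_a, tau_r, n_populations = 7L) {
  if (!is.finite(tau_a) || !is.finite(tau_r) || tau_a <= 0 || tau_r <= 0) {
    stop("tau_a and tau_r must be positive and finite", call. = FALSE)
  }
  structure(
    list(a = rep(1, n_populations), tau_a = tau_a, tau_r = tau_r),
    class = "adaptation_state"
  )
}

#' Advance the adaptation state by one tone
#'
#' @param state An [adaptation_state()].
#' @param tone_index Index of the population driven by the presented tone.
#' @return Updated `adaptation_state`.
#' @export
adaptation_step <- function(state, tone_index) {
  a <- state$a
  if (tone_index < 1L || tone_index > length(a)) {
    stop("tone_index outside population map", call. = FALSE)
  }
  decay <- exp(-1 / state$tau_a)
  recover <- exp(-1 / state$tau_r)
  a_new <- 1 - (1 - a) * recover
  a_new[tone_index] <- a[tone_index] * decay
  state$a <- a_new
  state
}

#' Adaptation predictor for deviant trials (model M4)
#'
#' Iterates [adaptation_step()] over the whole tone sequence and reads out,
#' at every deviant, the responsiveness of the deviant frequency's
#' population *before* that trial's own adaptation step (the state at
#' stimulus arrival).
#'
#' @param seq A `tone_sequence`; every frequency must be one of the
#'   design's frequency set (the population map).
#' @param trials The matching `trial_table`.
#' @inheritParams adaptation_state
#' @return Numeric vector, one value in (0, 1] per deviant trial.
#' @export
adaptation_predictor <- function(seq, trials, tau_a, tau_r) {
  freqs <- seq$design$frequency_set
  pop <- match(round(seq$frequencies_hz, 9), round(freqs, 9))
  if (anyNA(pop)) stop("frequency not in population map", call. = FALSE)
  n_pop <- length(freqs)
  if (!is.finite(tau_a) || !is.finite(tau_r) || tau_a <= 0 || tau_r <= 0) {
    stop("tau_a and tau_r must be positive and finite", call. = FALSE)
  }
  decay <- exp(-1 / tau_a)
  recover <- exp(-1 / tau_r)
  a <- rep(1, n_pop)
  is_dev <- trials$is_deviant
  out <- numeric(sum(is_dev))
  j <- 0L
  for (t in seq_along(pop)) {
    i <- pop[t]
    if (is_dev[t]) {
      j <- j + 1L
      out[j] <- a[i]
    }
    a_i <- a[i] * decay
    a <- 1 - (1 - a) * recover
    a[i] <- a_i
  }
  out
}
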