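# Shared fixtures and independent oracles for the test suite.

# short two-frequency alternating sequence with annotated trials
toy_sequence <- function(pattern = c(500, 500, 500, 800, 800, 500),
                         design = NULL) {
  s <- tone_sequence(pattern, design)
  list(seq = s, trials = annotate_trials(s))
}

# small simulated subject with a known generating model
toy_subject <- function(model_id = "M3", n_tones = 400, n_electrodes = 2,
                        noise_sd = 1, seed = 11,
                        weights = NULL) {
  design <- stimulus_design(n_tones = n_tones)
  s <- generate_roving_sequence(design, seed)
  tr <- annotate_trials(s)
  reg <- model_registry()
  p <- if (reg$includes_intercept[reg$model_id == model_id]) 2L else 1L
  if (is.null(weights)) {
    weights <- outer(c(-2, -1)[seq_len(p)], seq(0.8, 1.2,
                                                length.out = n_electrodes))
  }
  truth <- subject_ground_truth(model_id, default_model_params(model_id),
                                weights, noise_sd, seed = seed + 1000L)
  amps <- simulate_amplitudes(s, tr, truth)
  list(seq = s, trials = tr, truth = truth, amplitudes = amps)
}

# Independent oracle: log marginal likelihood of the conjugate regression
# by nested numerical quadrature over (beta, sigma^2). Only practical for
# a single coefficient.
quadrature_log_evidence <- function(y, x, tau, a0, b0) {
  n <- length(y)
  lik_given_sigma2 <- function(s2) {
    inner <- function(beta) {
      vapply(beta, function(b) {
        exp(sum(stats::dnorm(y, x * b, sqrt(s2), log = TRUE)) +
              stats::dnorm(b, 0, sqrt(s2) * tau, log = TRUE))
      }, numeric(1))
    }
    stats::integrate(inner, -Inf, Inf, rel.tol = 1e-12)$value
  }
  outer_fn <- function(s2) {
    vapply(s2, function(v) {
      dens <- b0^a0 / gamma(a0) * v^(-a0 - 1) * exp(-b0 / v)
      dens * lik_given_sigma2(v)
    }, numeric(1))
  }
  log(stats::integrate(outer_fn, 0, Inf, rel.tol = 1e-10)$value)
}

# Independent oracle: exact RFX posterior for K = 2 models by numerical
# integration over the population frequency r1 with a flat Dirichlet(1,1)
# prior: posterior density ~ prod_n (r1 e^{l_n1} + (1 - r1) e^{l_n2}).
exhaustive_rfx_k2 <- function(log_evidence) {
  stopifnot(ncol(log_evidence) == 2L)
  # per-subject normalization for numerical stability (cancels in posterior)
  L <- log_evidence - apply(log_evidence, 1L, max)
  post_unnorm <- function(r1) {
    vapply(r1, function(r) {
      exp(sum(log(r * exp(L[, 1L]) + (1 - r) * exp(L[, 2L]))))
    }, numeric(1))
  }
  z <- stats::integrate(post_unnorm, 0, 1, rel.tol = 1e-10)$value
  m1 <- stats::integrate(function(r) r * post_unnorm(r), 0, 1,
                         rel.tol = 1e-10)$value
  c(m1 / z, 1 - m1 / z)
}
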