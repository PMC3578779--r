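#' Prior for the Bayesian linear regression of trial-wise amplitudes
#'
#' Conjugate Normal-Inverse-Gamma prior: regression coefficients
#' `beta | sigma^2 ~ N(0, sigma^2 tau^2 I)` and error precision
#' `1/sigma^2 ~ Gamma(a0, b0)` (shape/rate). The defaults
#' (`tau = 10`, `a0 = b0 = 1e-3`) are weakly informative on the scale of
#' microvolt amplitudes and z-scored predictors.
#'
#' @param tau Prior coefficient scale (multiplier on the residual SD), > 0.
#' @param a0,b0 Shape and rate of the Gamma prior on the error precision,
#'   both > 0.
#' @return An object of class `regression_prior`.
#' @export
regression_prior <- function(tau = 10, a0 = 1e-3, b0 = 1e-3) {
  if (any(!is.finite(c(tau, a0, b0))) || any(c(tau, a0, b0) <= 0)) {
    stop("tau, a0, b0 must all be positive and finite", call. = FALSE)
  }
  structure(list(tau = tau, a0 = a0, b0 = b0), class = "regression_prior")
}

#' Exact log marginal likelihood of the conjugate regression
#'
#' Closed-form log evidence of `y = X beta + eps` under the
#' Normal-Inverse-Gamma prior of [regression_prior()] (the marginal of `y`
#' is multivariate t). Serves as the analytic reference for
#' [log_evidence_mc()].
#'
#' @param y Response vector (one electrode's amplitudes, microvolts).
#' @param X Design matrix (full column rank, more rows than columns).
#' @param prior A [regression_prior()].
#' @return Log marginal likelihood (nats).
#' @export
log_evidence_closed_form <- function(y, X, prior = regression_prior()) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("length(y) != nrow(X)", call. = FALSE)
  if (n < p + 1L) stop("need at least ncol(X) + 1 observations", call. = FALSE)
  if (qr(X)$rank < p) stop("design matrix is rank deficient", call. = FALSE)

  Lambda0 <- diag(1 / prior$tau^2, p)
  Lambda_n <- crossprod(X) + Lambda0
  mu_n <- solve(Lambda_n, crossprod(X, y))
  a_n <- prior$a0 + n / 2
  b_n <- prior$b0 + 0.5 * (sum(y^2) - drop(crossprod(mu_n, Lambda_n %*% mu_n)))

  as.numeric(
    -0.5 * n * log(2 * pi) +
      0.5 * (determinant(Lambda0, logarithm = TRUE)$modulus -
               determinant(Lambda_n, logarithm = TRUE)$modulus) +
      prior$a0 * log(prior$b0) - a_n * log(b_n) +
      lgamma(a_n) - lgamma(prior$a0)
  )
}

#' Monte-Carlo log marginal likelihood
#'
#' Estimates the log evidence as the log of the prior-sample average of
#' the likelihood: draw `(beta, sigma^2)` from the prior, average
#' `p(y | beta, sigma^2)` with log-sum-exp stabilization. Deterministic
#' given `seed`. Converges to [log_evidence_closed_form()] as `n_samples`
#' grows; kept as the sampling-based route and as a cross-check of the
#' closed form.
#'
#' @inheritParams log_evidence_closed_form
#' @param n_samples Number of prior draws (>= 1000).
#' @param seed Integer seed.
#' @return Log marginal likelihood estimate (nats).
#' @export
log_evidence_mc <- function(y, X, prior = regression_prior(),
                            n_samples = 1e5, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("length(y) != nrow(X)", call. = FALSE)
  if (n_samples < 1e3) stop("n_samples must be >= 1000", call. = FALSE)
  rng <- local_rng(seed)
  on.exit(rng$restore())

  n_samples <- as.integer(n_samples)
  prec <- stats::rgamma(n_samples, shape = prior$a0, rate = prior$b0)
  sigma <- 1 / sqrt(prec)
  # beta ~ N(0, sigma^2 tau^2 I): p x S matrix of draws
  B <- matrix(stats::rnorm(p * n_samples), p, n_samples) *
    rep(sigma * prior$tau, each = p)
  E <- X %*% B                        # n x S predicted means
  rss <- colSums((y - E)^2)
  loglik <- -0.5 * n * log(2 * pi) - n * log(sigma) - rss / (2 * sigma^2)
  log_mean_exp(loglik)
}

#' Per-subject log evidence across electrodes
#'
#' Electrodes are conditionally independent given the design, so the
#' subject's log evidence for a model is the sum of per-electrode log
#' evidences under the shared design matrix.
#'
#' @param amplitudes Numeric matrix, deviant trials x electrodes
#'   (microvolts).
#' @param X Design matrix for the model (same row count).
#' @param prior A [regression_prior()].
#' @param method `"closed_form"` (default) or `"mc"`.
#' @param n_samples,seed Monte-Carlo settings when `method = "mc"`.
#' @return Subject log evidence (nats).
#' @export
subject_log_evidence <- function(amplitudes, X, prior = regression_prior(),
                                 method = c("closed_form", "mc"),
                                 n_samples = 1e5, seed = 1L) {
  method <- match.arg(method)
  amplitudes <- as.matrix(amplitudes)
  if (ncol(amplitudes) < 1L) stop("need at least one electrode", call. = FALSE)
  per_elec <- vapply(seq_len(ncol(amplitudes)), function(k) {
    if (method == "closed_form") {
      log_evidence_closed_form(amplitudes[, k], X, prior)
    } else {
      log_evidence_mc(amplitudes[, k], X, prior, n_samples,
                      seed = derive_seed(seed, k))
    }
  }, numeric(1))
  sum(per_elec)
}
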