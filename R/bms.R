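#' Random-effects Bayesian model selection at the group level
#'
#' Treats the model generating each subject's data as a random effect with
#' population frequencies `r ~ Dirichlet(alpha)`, and fits the variational
#' posterior over `alpha` from per-subject log evidences: per subject,
#' responsibilities `u_nk` proportional to
#' `exp(l_nk + psi(alpha_k) - psi(sum(alpha)))`, normalized over models;
#' then `alpha = alpha0 + sum_n u_n`. Iterated until `max |delta alpha|`
#' drops below `tol`. Per-subject additive constants in the log evidences
#' cancel in the normalization.
#'
#' @param log_evidence Numeric matrix, subjects x models, with model ids as
#'   column names.
#' @param prior_counts Dirichlet prior counts `alpha0`: scalar or one value
#'   per model (default 1, a uniform prior over models).
#' @param tol Convergence tolerance on `max |delta alpha|`.
#' @param max_iter Iteration cap; non-convergence is an error.
#' @return An object of class `bms_result`: `alpha`, `expected_probs`
#'   (`alpha / sum(alpha)`), `responsibilities`, `iterations`, `converged`.
#'   Exceedance probabilities are added by [exceedance_probabilities()].
#' @export
rfx_bms <- function(log_evidence, prior_counts = 1, tol = 1e-6,
                    max_iter = 500L) {
  L <- as.matrix(log_evidence)
  if (any(!is.finite(L))) stop("log evidences must be finite", call. = FALSE)
  n_sub <- nrow(L)
  n_mod <- ncol(L)
  alpha0 <- rep(prior_counts, length.out = n_mod)
  if (any(alpha0 <= 0)) stop("prior counts must be > 0", call. = FALSE)

  alpha <- alpha0 + n_sub / n_mod
  u <- matrix(0, n_sub, n_mod)
  for (it in seq_len(max_iter)) {
    w <- sweep(L, 2L, digamma(alpha) - digamma(sum(alpha)), `+`)
    w <- w - apply(w, 1L, max)
    u <- exp(w)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    if (delta < tol) {
      res <- list(
        alpha = stats::setNames(alpha, colnames(L)),
        expected_probs = stats::setNames(alpha / sum(alpha), colnames(L)),
        responsibilities = u,
        iterations = it,
        converged = TRUE
      )
      class(res) <- "bms_result"
      return(res)
    }
  }
  stop("RFX BMS did not converge in ", max_iter,
       " iterations (last delta = ", format(delta), ")", call. = FALSE)
}

#' Exceedance probabilities under a Dirichlet posterior
#'
#' Monte-Carlo estimate of `P(r_k > r_j for all j != k)` under
#' `r ~ Dirichlet(alpha)`: the posterior probability that model `k` is the
#' most frequent in the population. Deterministic given `seed`; the
#' estimates sum to 1 up to Monte-Carlo error.
#'
#' @param alpha Dirichlet parameter vector.
#' @param n_samples Number of Dirichlet draws (>= 1e5).
#' @param seed Integer seed.
#' @return Named numeric vector of exceedance probabilities.
#' @export
exceedance_probabilities <- function(alpha, n_samples = 1e6, seed = 1L) {
  if (n_samples < 1e5) stop("n_samples must be >= 1e5", call. = FALSE)
  k <- length(alpha)
  rng <- local_rng(seed)
  on.exit(rng$restore())
  n_samples <- as.integer(n_samples)
  # Dirichlet draws via normalized Gammas; only the argmax is needed
  G <- matrix(stats::rgamma(n_samples * k, shape = rep(alpha, each = n_samples)),
              n_samples, k)
  winners <- max.col(G, ties.method = "first")
  stats::setNames(tabulate(winners, k) / n_samples, names(alpha))
}

#' Family-level Bayesian model selection
#'
#' Runs [rfx_bms()] with per-model prior counts of 1 over the family size
#' (so the implied prior over families is flat regardless of how many
#' models each family contains), then aggregates: the expected family
#' probability is the summed expected frequency of its members, and family
#' exceedance probabilities are computed by Dirichlet sampling of the
#' model-level posterior with within-family summation of the sampled
#' frequencies.
#'
#' @inheritParams rfx_bms
#' @param partition Named list of character vectors of model ids forming a
#'   disjoint, exhaustive partition of the columns of `log_evidence`.
#' @param n_samples,seed Dirichlet sampling settings.
#' @return An object of class `family_bms_result`: `model_bms` (the
#'   underlying [rfx_bms()] fit), `family_alpha` (summed Dirichlet
#'   parameters), `expected_probs` and `exceedance_probs` per family.
#' @export
family_bms <- function(log_evidence, partition, n_samples = 1e6, seed = 1L) {
  L <- as.matrix(log_evidence)
  ids <- colnames(L)
  members <- unlist(partition, use.names = FALSE)
  if (is.null(ids) || length(members) != ncol(L) || anyDuplicated(members) ||
      !setequal(members, ids)) {
    stop("partition must cover the evidence table's models exactly once",
         call. = FALSE)
  }
  fam_size <- vapply(partition, length, integer(1))
  prior_counts <- numeric(ncol(L))
  for (f in names(partition)) {
    prior_counts[match(partition[[f]], ids)] <- 1 / fam_size[[f]]
  }
  fit <- rfx_bms(L, prior_counts = prior_counts)

  k <- ncol(L)
  rng <- local_rng(seed)
  on.exit(rng$restore())
  n_samples <- as.integer(n_samples)
  G <- matrix(stats::rgamma(n_samples * k, shape = rep(fit$alpha, each = n_samples)),
              n_samples, k)
  fam_draws <- vapply(partition, function(m) {
    cols <- match(m, ids)
    if (length(cols) == 1L) G[, cols] else rowSums(G[, cols, drop = FALSE])
  }, numeric(n_samples))
  winners <- max.col(fam_draws, ties.method = "first")
  exceed <- stats::setNames(tabulate(winners, length(partition)) / n_samples,
                            names(partition))

  fam_alpha <- vapply(partition, function(m) sum(fit$alpha[match(m, ids)]),
                      numeric(1))
  res <- list(
    model_bms = fit,
    family_alpha = fam_alpha,
    expected_probs = fam_alpha / sum(fam_alpha),
    exceedance_probs = exceed
  )
  class(res) <- "family_bms_result"
  res
}
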