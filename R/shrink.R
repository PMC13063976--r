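#' Empirical-Bayes shrinkage and local false sign rates
#'
#' Condition-by-condition adaptive shrinkage of effect estimates under a
#' normal-means model: the effect prior is a mixture of a point mass at zero
#' and zero-mean normals on a fixed geometric grid of scales (from
#' `min(se)/10` to `2 * max(|betahat|)`), with mixture weights estimated by
#' EM on the marginal likelihood. For each effect the local false sign rate
#' is the smaller of the posterior probabilities that the effect is
#' non-positive / non-negative (the point mass counts towards both), i.e.
#' the posterior probability that the estimated sign is wrong or the effect
#' is zero.
#'
#' @param betahat effect estimates.
#' @param se standard errors (all > 0).
#' @param n_grid number of non-null mixture scales.
#' @param max_iter EM iteration cap (a warning is raised and the last
#'   iterate returned if it is hit without convergence).
#' @param tol EM convergence tolerance on the log-likelihood.
#' @return A tibble: betahat, se, posterior_mean, lfsr, plus attributes
#'   `mixture` (tibble of scales and weights) and `loglik`.
#' @export
shrink_lfsr <- function(betahat, se, n_grid = 20, max_iter = 2000, tol = 1e-7) {
  stopifnot(length(betahat) == length(se))
  if (any(!is.finite(se)) || any(se <= 0)) rlang::abort("se must be positive")
  n <- length(betahat)
  lo <- min(se) / 10
  hi <- max(2 * max(abs(betahat)), lo * 2)
  scales <- c(0, exp(seq(log(lo), log(hi), length.out = n_grid)))
  K <- length(scales)
  # marginal likelihood of each observation under each component
  Lik <- vapply(scales, function(s) {
    stats::dnorm(betahat, mean = 0, sd = sqrt(se^2 + s^2))
  }, numeric(n))
  Lik <- pmax(Lik, 1e-300)
  pi_k <- rep(1 / K, K)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    num <- sweep(Lik, 2, pi_k, "*")
    marg <- rowSums(num)
    ll <- sum(log(marg))
    resp <- num / marg
    pi_k <- colMeans(resp)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged) rlang::warn("EM did not converge; returning last iterate")
  num <- sweep(Lik, 2, pi_k, "*")
  resp <- num / rowSums(num)
  # component posteriors: N(mu_k, tau_k^2) given data, for each scale
  post_mean <- numeric(n)
  p_neg <- resp[, 1] * 0  # strictly-negative mass
  p_pos <- p_neg
  for (k in 2:K) {
    s2 <- scales[k]^2
    shrink <- s2 / (s2 + se^2)
    mu_k <- shrink * betahat
    tau_k <- sqrt(shrink * se^2)
    post_mean <- post_mean + resp[, k] * mu_k
    p_neg <- p_neg + resp[, k] * stats::pnorm(0, mean = mu_k, sd = tau_k)
    p_pos <- p_pos + resp[, k] * stats::pnorm(0, mean = mu_k, sd = tau_k,
                                              lower.tail = FALSE)
  }
  p0 <- resp[, 1]
  lfsr <- pmin(p0 + p_neg, p0 + p_pos)
  out <- tibble::tibble(betahat = betahat, se = se,
                        posterior_mean = post_mean, lfsr = lfsr)
  attr(out, "mixture") <- tibble::tibble(scale = scales, weight = pi_k)
  attr(out, "loglik") <- ll_old
  out
}
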