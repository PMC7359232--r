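#' Prior configuration
#'
#' Priors: independent mean-zero normals on the branch intercepts
#' (`sigma2_alpha`) and on active coefficients (the slab, `sigma2_beta`);
#' and one of two priors on the inclusion indicators `zeta`:
#' \describe{
#'   \item{`"beta_binomial"`}{a common Bernoulli inclusion probability is
#'     integrated against a Beta(`a`, `b`) distribution, yielding the
#'     marginalized prior `Beta(a + k, b + M - k) / Beta(a, b)` for a
#'     configuration with `k` of `M = B * P` indicators active.  `a = b = 1`
#'     is non-informative (every single indicator has prior inclusion
#'     probability 1/2).}
#'   \item{`"mrf"`}{a Markov random field over each branch's covariate
#'     indicator vector, `d * sum(zeta) + f * zeta_b' G zeta_b` summed over
#'     branches, unnormalized.  `G` is a shared symmetric 0/1 covariate
#'     adjacency with zero diagonal; `d` controls sparsity (more negative =
#'     sparser), `f >= 0` rewards joint inclusion of covariates linked in
#'     `G`.  The quadratic form counts each edge twice (both triangles of the
#'     symmetric `G`); defaults `d = -2.2` (about logit 0.1) and `f = 0.5`
#'     are deliberately conservative given the known phase-transition
#'     sensitivity of MRF priors.}
#' }
#'
#' @param prior `"beta_binomial"` or `"mrf"`.
#' @param a,b Beta-Binomial hyperparameters (positive).
#' @param sigma2_alpha,sigma2_beta prior variances of intercepts and slab.
#' @param d,f MRF sparsity and smoothing scalars.
#' @param G covariate adjacency matrix (required for the MRF prior).
#' @return object of class `dtm_prior`.
#' @export
prior_config <- function(prior = c("beta_binomial", "mrf"),
                         a = 1, b = 1,
                         sigma2_alpha = 10, sigma2_beta = 10,
                         d = -2.2, f = 0.5, G = NULL) {
  prior <- match.arg(prior)
  if (a <= 0 || b <= 0) stop("a and b must be positive")
  if (sigma2_alpha <= 0 || sigma2_beta <= 0)
    stop("prior variances must be positive")
  if (f < 0) stop("f must be nonnegative")
  if (prior == "mrf") {
    if (is.null(G)) stop("the MRF prior requires an adjacency matrix G")
    G <- validate_graph(G)
  }
  structure(list(prior = prior, a = a, b = b,
                 sigma2_alpha = sigma2_alpha, sigma2_beta = sigma2_beta,
                 d = d, f = f, G = G),
            class = "dtm_prior")
}

#' Log-prior of the branch intercepts
#' @param alpha numeric vector of intercepts.
#' @param prior a [prior_config].
#' @return log-density (numeric scalar).
#' @export
log_prior_alpha <- function(alpha, prior) {
  sum(stats::dnorm(alpha, 0, sqrt(prior$sigma2_alpha), log = TRUE))
}

#' Log-prior of the coefficients under the spike-and-slab
#'
#' Active entries (`zeta == 1`) contribute a mean-zero normal slab density;
#' inactive entries sit on the point mass at zero and contribute nothing.
#'
#' @param beta,zeta B x P matrices (coefficients and indicators).
#' @param prior a [prior_config].
#' @return log-density (numeric scalar).
#' @export
log_prior_beta <- function(beta, zeta, prior) {
  act <- beta[zeta == 1]
  if (!all(is.finite(act))) stop("nonfinite active beta")
  sum(stats::dnorm(act, 0, sqrt(prior$sigma2_beta), log = TRUE))
}

#' Log-prior of the inclusion indicators
#'
#' Dispatches on `prior$prior`: the marginalized Beta-Binomial (normalized)
#' or the MRF (unnormalized; the sampler only uses ratios).
#'
#' @param zeta binary B x P matrix.
#' @param prior a [prior_config].
#' @return log-density (Beta-Binomial) or unnormalized log-mass (MRF).
#' @export
log_prior_zeta <- function(zeta, prior) {
  switch(prior$prior,
         beta_binomial = log_prior_zeta_bb(zeta, prior),
         mrf = log_prior_zeta_mrf(zeta, prior))
}

#' @rdname log_prior_zeta
#' @export
log_prior_zeta_bb <- function(zeta, prior) {
  M <- length(zeta)
  k <- sum(zeta)
  lbeta(prior$a + k, prior$b + M - k) - lbeta(prior$a, prior$b)
}

#' @rdname log_prior_zeta
#' @export
log_prior_zeta_mrf <- function(zeta, prior) {
  zeta <- as.matrix(zeta)
  G <- prior$G
  if (is.null(G)) stop("MRF prior evaluated without an adjacency matrix")
  if (ncol(zeta) != nrow(G))
    stop("zeta has ", ncol(zeta), " covariates but G is ", nrow(G), " x ",
         ncol(G))
  quad <- sum(vapply(seq_len(nrow(zeta)),
                     function(b) drop(zeta[b, ] %*% G %*% zeta[b, ]),
                     numeric(1)))
  prior$d * sum(zeta) + prior$f * quad
}

# log prior ratio for toggling zeta[b, p] from 0 to 1, given current zeta.
# O(1) for Beta-Binomial (the add-one identity (a+k)/(b+M-k-1)), O(P) for MRF.
log_prior_zeta_add_ratio <- function(zeta, b, p, prior) {
  if (prior$prior == "beta_binomial") {
    M <- length(zeta); k <- sum(zeta)
    log(prior$a + k) - log(prior$b + M - k - 1)
  } else {
    prior$d + 2 * prior$f * sum(prior$G[p, ] * zeta[b, ])
  }
}
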