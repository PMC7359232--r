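#' Model state for DTM regression with spike-and-slab selection
#'
#' The model has, per branch `b`, an intercept `alpha[b]`, and per
#' branch-covariate pair `(b, p)`, a log-linear coefficient `beta[b, p]`
#' gated by a binary inclusion indicator `zeta[b, p]`.  The spike-and-slab
#' constraint `zeta == 0  =>  beta == 0` is enforced on construction.
#'
#' @param alpha numeric vector of length B.
#' @param beta numeric B x P matrix.
#' @param zeta binary B x P matrix.
#' @return object of class `dtm_state`.
#' @export
dtm_state <- function(alpha, beta, zeta) {
  beta <- as.matrix(beta); zeta <- as.matrix(zeta)
  if (length(alpha) != nrow(beta) || !all(dim(beta) == dim(zeta)))
    stop("dimension mismatch between alpha, beta, zeta")
  if (!all(zeta %in% c(0, 1))) stop("zeta must be binary")
  if (any(beta[zeta == 0] != 0))
    stop("spike-and-slab violation: beta must be 0 wherever zeta is 0")
  if (!all(is.finite(alpha)) || !all(is.finite(beta)))
    stop("alpha and beta must be finite")
  structure(list(alpha = as.numeric(alpha), beta = beta,
                 zeta = zeta), class = "dtm_state")
}

#' Per-subject, per-branch Dirichlet-multinomial concentrations
#'
#' The log-linear link: `gamma[i, b] = exp(alpha[b] +
#' sum_p zeta[b, p] * beta[b, p] * x[i, p])`.  Concentrations are strictly
#' positive; overflow to `Inf` aborts with a hint to standardize covariates.
#'
#' @param state a [dtm_state].
#' @param X subjects x covariates matrix.
#' @return n x B positive matrix of concentrations.
#' @export
link_concentrations <- function(state, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(state$beta))
    stop("X has ", ncol(X), " covariates but state has ", ncol(state$beta))
  eta <- X %*% t(state$beta * state$zeta)
  gamma <- exp(sweep(eta, 2L, state$alpha, `+`))
  if (!all(is.finite(gamma)))
    stop("concentration overflow (gamma not finite); ",
         "consider standardizing covariates or shrinking coefficients")
  gamma
}

#' Dirichlet-multinomial log-likelihood of one node's child counts
#'
#' For counts `y` with total `N = sum(y)` and concentrations `gamma`, the DM
#' log-density (up to the multinomial coefficient) is
#' `lgamma(sum(gamma)) - lgamma(sum(gamma) + N) +
#'  sum(lgamma(gamma + y) - lgamma(gamma))`.
#' Everything is computed through `lgamma`; ratios of Gamma functions are
#' never formed directly, so counts in the hundreds or thousands are safe.
#' With `include_coef = TRUE` the multinomial coefficient
#' `lgamma(N + 1) - sum(lgamma(y + 1))` is added, giving the exact log pmf;
#' the sampler omits it because it is constant in all parameters.
#'
#' `y` and `gamma` may also be matrices (subjects x children), in which case
#' the returned value is the sum of per-subject log-likelihoods.
#'
#' @param y nonnegative integer counts (vector, or subjects x children
#'   matrix).
#' @param gamma positive concentrations, same shape as `y` (or a vector
#'   recycled across subjects when `y` is a matrix).
#' @param include_coef add the multinomial coefficient?
#' @return a single numeric log-likelihood.
#' @export
dm_node_loglik <- function(y, gamma, include_coef = FALSE) {
  if (is.matrix(y)) {
    if (!is.matrix(gamma))
      gamma <- matrix(gamma, nrow(y), ncol(y), byrow = TRUE)
    if (!all(dim(y) == dim(gamma))) stop("y/gamma dimension mismatch")
    if (any(y < 0)) stop("negative count")
    if (any(gamma <= 0)) stop("nonpositive gamma")
    sg <- rowSums(gamma); sy <- rowSums(y)
    ll <- sum(lgamma(sg) - lgamma(sg + sy)) +
      sum(lgamma(gamma + y) - lgamma(gamma))
    if (include_coef) ll <- ll + sum(lgamma(sy + 1)) - sum(lgamma(y + 1))
    return(ll)
  }
  if (length(y) != length(gamma)) stop("y/gamma length mismatch")
  if (any(y < 0)) stop("negative count")
  if (any(gamma <= 0)) stop("nonpositive gamma")
  sg <- sum(gamma); sy <- sum(y)
  ll <- lgamma(sg) - lgamma(sg + sy) + sum(lgamma(gamma + y) - lgamma(gamma))
  if (include_coef) ll <- ll + lgamma(sy + 1) - sum(lgamma(y + 1))
  ll
}

#' Dirichlet-tree multinomial log-likelihood
#'
#' The DTM likelihood is the product over internal nodes of DM kernels on the
#' node-local child counts, with concentrations given by
#' [link_concentrations] restricted to each node's child branches.  The
#' multinomial coefficients are omitted (constant in all parameters).  On a
#' star tree this is exactly the DM regression log-likelihood on the full
#' count matrix.
#'
#' @param node_counts a `dtm_node_counts` from [decompose_counts], or a
#'   [dtm_data] object.
#' @param state a [dtm_state].
#' @param X subjects x covariates matrix (ignored when `node_counts` is a
#'   `dtm_data`, which carries its own).
#' @return the log-likelihood (a single numeric).
#' @export
dtm_loglik <- function(node_counts, state, X = NULL) {
  if (inherits(node_counts, "dtm_data")) {
    X <- node_counts$X
    node_counts <- node_counts$node_counts
  }
  tree <- node_counts$tree
  if (length(state$alpha) != tree$B)
    stop("state has ", length(state$alpha), " branches but tree has ", tree$B)
  gamma <- link_concentrations(state, X)
  ll <- 0
  for (k in seq_along(tree$node_ids)) {
    bs <- tree$node_branches[[k]]
    ll <- ll + dm_node_loglik(node_counts$node_y[[k]],
                              gamma[, bs, drop = FALSE])
  }
  ll
}
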