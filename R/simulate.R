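#' Simulate a random rooted bifurcating tree
#'
#' Sequential random leaf attachment: starting from a two-leaf cherry, each
#' new taxon replaces a uniformly chosen existing leaf position with a cherry
#' containing it.  The result is a rooted bifurcating topology with
#' `B = 2J - 2` branches.
#'
#' @param J number of leaves (>= 2).
#' @param seed optional integer seed (draws from the current RNG stream when
#'   `NULL`).
#' @param labels leaf labels (default `t1 ... tJ`).
#' @return a [dtm_tree].
#' @export
simulate_tree <- function(J, seed = NULL, labels = paste0("t", seq_len(J))) {
  if (J < 2L) stop("a tree needs at least 2 leaves")
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(labels) == J, !anyDuplicated(labels))
  # newick fragments per current leaf slot
  slots <- c(labels[1L], labels[2L])
  for (j in seq_len(J)[-(1:2)]) {
    i <- sample.int(length(slots), 1L)
    slots[i] <- paste0("(", slots[i], ",", labels[j], ")")
  }
  parse_newick(text = paste0("(", slots[1L], ",", slots[2L], ");"))
}

#' Simulate covariates
#'
#' Rows are drawn from a mean-zero multivariate normal with unit variances
#' and exchangeable correlation `rho` (or a user-supplied correlation
#' matrix), then columns are z-scored, matching the standardization the
#' fitting pipeline expects.
#'
#' @param n subjects.
#' @param P covariates.
#' @param rho exchangeable pairwise correlation, `|rho| < 1` (ignored when
#'   `P == 1` or when `Sigma` is given).
#' @param Sigma optional P x P correlation matrix overriding `rho`.
#' @param seed optional integer seed.
#' @return n x P standardized matrix with columns `x1 ... xP`.
#' @export
simulate_covariates <- function(n, P, rho = 0, Sigma = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(Sigma)) {
    if (abs(rho) >= 1) stop("|rho| must be < 1")
    Sigma <- matrix(rho, P, P); diag(Sigma) <- 1
  }
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("correlation matrix is not positive definite")
  X <- MASS::mvrnorm(n, mu = rep(0, P), Sigma = Sigma)
  X <- matrix(X, n, P)
  colnames(X) <- paste0("x", seq_len(P))
  standardize_covariates(X)
}

#' Draw a generating truth
#'
#' Chooses `n_active` distinct branch-covariate pairs uniformly over the
#' `B x P` grid (internal branches eligible), assigns coefficients
#' `+/- effect` with random signs, and draws intercepts uniformly on
#' `intercept_range`.
#'
#' @param tree a [dtm_tree].
#' @param P number of covariates.
#' @param n_active number of true pairs (`<= B * P`).
#' @param effect absolute effect size of active coefficients.
#' @param intercept_range range of the per-branch intercepts.
#' @param seed optional integer seed.
#' @return a [dtm_state] holding the truth.
#' @export
make_truth <- function(tree, P, n_active, effect = 1.0,
                       intercept_range = c(-0.5, 0.5), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  B <- tree$B
  if (n_active > B * P) stop("n_active exceeds B * P = ", B * P)
  zeta <- matrix(0L, B, P)
  beta <- matrix(0, B, P)
  if (n_active > 0) {
    idx <- sample.int(B * P, n_active)
    zeta[idx] <- 1L
    beta[idx] <- effect * sample(c(-1, 1), n_active, replace = TRUE)
  }
  alpha <- stats::runif(B, intercept_range[1L], intercept_range[2L])
  dtm_state(alpha, beta, zeta)
}

#' Simulate counts through the DTM forward model
#'
#' Top-down per subject: the root total is the sequencing depth; at each
#' internal node, child proportions are drawn from a Dirichlet with the
#' node's concentrations (from [link_concentrations] at the generating
#' truth) and the node total is allocated multinomially among the children.
#' Counts are generated through the exact likelihood the model fits -- not a
#' logit approximation -- so simulator and likelihood test each other.
#' Conservation (child counts summing to node totals, root totals equal to
#' depths) holds by construction.
#'
#' @param tree a [dtm_tree].
#' @param truth a [dtm_state] (the generating parameters).
#' @param X subjects x covariates matrix.
#' @param depths per-subject sequencing depth: a scalar, an n-vector, or a
#'   length-2 range sampled uniformly (integers).
#' @param seed optional integer seed.
#' @return subjects x taxa count matrix (columns in tree leaf order).
#' @export
simulate_counts <- function(tree, truth, X, depths = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(depths) == 1L) {
    depths <- rep(depths, n)
  } else if (length(depths) == n) {
    # per-subject depths as given
  } else if (length(depths) == 2L) {
    depths <- sample(seq.int(depths[1L], depths[2L]), n, replace = TRUE)
  } else {
    stop("depths must be a scalar, an n-vector, or a length-2 range")
  }
  if (any(depths < 1)) stop("sequencing depths must be >= 1")
  gamma <- link_concentrations(truth, X)

  ntip <- length(tree$leaf_labels)
  # node totals filled parents-first (node_ids is a preorder)
  totals <- vector("list", length(tree$node_ids))
  totals[[1L]] <- as.numeric(depths)
  counts <- matrix(0, n, ntip, dimnames = list(rownames(X), tree$leaf_labels))
  for (k in seq_along(tree$node_ids)) {
    bs <- tree$node_branches[[k]]
    C <- length(bs)
    g <- gamma[, bs, drop = FALSE]
    # Dirichlet draw per subject via normalized gammas
    w <- matrix(stats::rgamma(n * C, shape = g), n, C)
    # guard against all-zero rows from tiny shapes (numerically underflowed)
    zero <- rowSums(w) == 0
    if (any(zero)) w[zero, ] <- g[zero, , drop = FALSE]
    pr <- w / rowSums(w)
    alloc <- matrix(0, n, C)
    tot <- totals[[k]]
    pos <- tot > 0
    for (i in which(pos))
      alloc[i, ] <- stats::rmultinom(1L, tot[i], pr[i, ])
    for (j in seq_len(C)) {
      child <- tree$branch_child[bs[j]]
      if (child <= ntip) {
        counts[, child] <- alloc[, j]
      } else {
        totals[[match(child, tree$node_ids)]] <- alloc[, j]
      }
    }
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Simulate a complete study scenario
#'
#' Bundles tree, covariates, truth and counts into a ready-to-fit data set.
#' The defaults describe the package's reference recovery scenario: 200
#' subjects, a random 4-leaf tree (6 branches), 10 uncorrelated covariates,
#' 3 active branch-covariate pairs with `|beta| = 1`, and 10,000 reads per
#' subject (a typical 16S sequencing depth).
#'
#' @param n subjects.
#' @param J leaves of the random tree (ignored when `tree` is supplied).
#' @param P covariates.
#' @param rho exchangeable covariate correlation.
#' @param n_active true branch-covariate pairs.
#' @param effect absolute effect size.
#' @param depths sequencing depth specification (see [simulate_counts]).
#' @param intercept_range intercept range (see [make_truth]).
#' @param tree optional [dtm_tree] to use instead of a random one.
#' @param seed integer seed (required; governs every random draw).
#' @return list with `data` (a [dtm_data]), `truth` (a [dtm_state]), `tree`,
#'   `counts`, `covariates`, and the scenario settings.
#' @export
simulate_scenario <- function(n = 200, J = 4, P = 10, rho = 0,
                              n_active = 3, effect = 1.0, depths = 10000,
                              intercept_range = c(-0.5, 0.5),
                              tree = NULL, seed) {
  if (missing(seed)) stop("`seed` is required")
  set.seed(seed)
  if (is.null(tree)) tree <- simulate_tree(J)
  X <- simulate_covariates(n, P, rho)
  truth <- make_truth(tree, P, n_active, effect, intercept_range)
  counts <- simulate_counts(tree, truth, X, depths)
  data <- dtm_data(counts, X, tree, standardize = FALSE)
  list(data = data, truth = truth, tree = tree, counts = counts,
       covariates = X,
       settings = list(n = n, J = length(tree$leaf_labels), P = P, rho = rho,
                       n_active = n_active, effect = effect,
                       depths = depths, seed = seed))
}
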