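# Small deterministic fixtures, built in code at test time.

fixture_three_leaf <- function() {
  tree <- parse_newick("((A,B),C);")
  counts <- matrix(c(2, 4, 0,
                     1, 3, 0,
                     3, 2, 7), 3, 3, byrow = TRUE,
                   dimnames = list(paste0("s", 1:3), c("A", "B", "C")))
  list(tree = tree, counts = counts)
}

# a modest simulated data set for sampler-level tests
fixture_small_scenario <- function(seed = 9, n = 60, J = 3, P = 3,
                                   n_active = 1, depths = 500) {
  simulate_scenario(n = n, J = J, P = P, rho = 0, n_active = n_active,
                    effect = 1, depths = depths, seed = seed)
}

# assemble a dtm_samples object by hand (for inference-level unit tests)
fixture_samples <- function(zeta_draws, B, P, thin = 1L, burn_in = 0L,
                            lp = NULL, n_active = NULL) {
  nd <- nrow(zeta_draws)
  structure(list(
    alpha = matrix(0, nd, B), beta = zeta_draws * 0.5, zeta = zeta_draws,
    log_posterior = lp %||% rnorm(nd),
    n_active = n_active %||% rowSums(zeta_draws),
    B = B, P = P,
    branch_labels = paste0("br", seq_len(B)),
    covariate_names = paste0("x", seq_len(P)),
    iterations = nd * thin, burn_in = burn_in, thin = thin, seed = 1L,
    prior = prior_config(), control = NULL, prior_only = FALSE,
    acceptance = NULL), class = "dtm_samples")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
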