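test_that("the log-linear link maps states to concentrations", {
  tr <- star_tree(c("A", "B"))
  X <- matrix(0.5, 1, 1, dimnames = list(NULL, "x1"))
  # alpha = 0, beta = 0 -> gamma identically 1
  st0 <- dtm_state(c(0, 0), matrix(0, 2, 1), matrix(0, 2, 1))
  expect_equal(unname(link_concentrations(st0, X)), matrix(1, 1, 2))
  # alpha = log 2, one active covariate beta = 1 at x = 0.5 -> 2 * e^0.5
  st1 <- dtm_state(c(log(2), 0), matrix(c(1, 0), 2, 1),
                   matrix(c(1, 0), 2, 1))
  expect_equal(link_concentrations(st1, X)[1, 1], 2 * exp(0.5),
               tolerance = 1e-12)
})

test_that("inactive coefficients are gated out of the likelihood", {
  # assemble states bypassing the constructor so beta can be nonzero where
  # zeta = 0; the link must ignore those entries entirely
  tr <- star_tree(c("A", "B", "C"))
  set.seed(1)
  X <- matrix(rnorm(12), 4, 3)
  counts <- matrix(rpois(12, 20), 4, 3, dimnames = list(NULL, tr$leaf_labels))
  nc <- decompose_counts(counts, tr)
  zeta <- matrix(0, 3, 3); zeta[1, 2] <- 1
  beta0 <- matrix(0, 3, 3); beta0[1, 2] <- 0.7
  beta_pert <- beta0; beta_pert[zeta == 0] <- rnorm(8)
  mk <- function(b) structure(list(alpha = c(0.1, -0.2, 0), beta = b,
                                   zeta = zeta), class = "dtm_state")
  expect_equal(dtm_loglik(nc, mk(beta0), X), dtm_loglik(nc, mk(beta_pert), X),
               tolerance = 1e-12)
})

test_that("concentration overflow is caught with a standardization hint", {
  st <- dtm_state(c(0, 0), matrix(c(50, 0), 2, 1), matrix(c(1, 0), 2, 1))
  X <- matrix(100, 1, 1)
  expect_error(link_concentrations(st, X), "standardiz")
})

test_that("the DM node kernel matches exhaustive Polya-urn enumeration", {
  expect_equal(dm_node_loglik(c(0, 0, 0), c(1, 2, 3)), 0)
  # Dirichlet(1,1) makes the first count uniform on 0..3: pmf(2,1) = 1/4
  expect_equal(dm_node_loglik(c(2, 1), c(1, 1), include_coef = TRUE),
               log(0.25), tolerance = 1e-12)
  expect_equal(dm_node_loglik(c(3, 2, 1), c(0.5, 1.0, 2.0),
                              include_coef = TRUE),
               polya_urn_logpmf(c(3, 2, 1), c(0.5, 1.0, 2.0)),
               tolerance = 1e-10)
  expect_error(dm_node_loglik(c(1, 2), c(1, 1, 1)), "mismatch")
  expect_error(dm_node_loglik(c(-1, 2), c(1, 1)), "negative")
  expect_error(dm_node_loglik(c(1, 2), c(0, 1)), "nonpositive")
})

test_that("the DM pmf sums to one over all allocations of a fixed total", {
  gamma <- c(0.7, 1.3, 2.1)
  N <- 4
  total <- 0
  for (y1 in 0:N) for (y2 in 0:(N - y1)) {
    y <- c(y1, y2, N - y1 - y2)
    total <- total + exp(dm_node_loglik(y, gamma, include_coef = TRUE))
  }
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("the DTM factorizes over nodes (manual two-node sum)", {
  fx <- fixture_three_leaf()
  set.seed(2)
  X <- matrix(rnorm(6), 3, 2)
  nc <- decompose_counts(fx$counts, fx$tree)
  zeta <- matrix(rbinom(8, 1, 0.5), 4, 2)
  beta <- matrix(rnorm(8, 0, 0.5), 4, 2) * zeta
  st <- dtm_state(rnorm(4, 0, 0.3), beta, zeta)
  gamma <- link_concentrations(st, X)
  # branch order is depth-first: root's children are branches 1 (inner clade)
  # and 4 (leaf C); the inner node's children are branches 2 and 3
  manual <- dm_node_loglik(nc$node_y[[1]], gamma[, c(1, 4)]) +
    dm_node_loglik(nc$node_y[[2]], gamma[, c(2, 3)])
  expect_equal(dtm_loglik(nc, st, X), manual, tolerance = 1e-12)
})

test_that("on a star tree the DTM equals DM regression", {
  set.seed(3)
  J <- 4; n <- 6; P <- 2
  tr <- star_tree(paste0("t", 1:J))
  X <- matrix(rnorm(n * P), n, P)
  counts <- matrix(rpois(n * J, 15), n, J, dimnames = list(NULL, tr$leaf_labels))
  nc <- decompose_counts(counts, tr)
  zeta <- matrix(rbinom(J * P, 1, 0.5), J, P)
  beta <- matrix(rnorm(J * P, 0, 0.4), J, P) * zeta
  st <- dtm_state(rnorm(J, 0, 0.5), beta, zeta)
  expect_equal(dtm_loglik(nc, st, X),
               dm_regression_loglik_ref(counts, X, st$alpha, st$beta),
               tolerance = 1e-10)
})

test_that("as concentrations grow the DTM approaches the multinomial limit", {
  fx <- fixture_three_leaf()
  nc <- decompose_counts(fx$counts, fx$tree)
  X <- matrix(0, 3, 1)
  pr <- c(0.5, 0.2, 0.3) # leaf probabilities for A, B, C
  scale <- 1e6
  alpha <- numeric(4)
  alpha[c(1, 4)] <- log(scale * c(pr[1] + pr[2], pr[3]))      # root node
  alpha[c(2, 3)] <- log(scale * c(pr[1], pr[2]) / (pr[1] + pr[2])) # inner
  st <- dtm_state(alpha, matrix(0, 4, 1), matrix(0, 4, 1))
  # multinomial log-likelihood with leaf probabilities pr (no coefficient)
  mult <- sum(t(fx$counts) * log(pr))
  expect_equal(dtm_loglik(nc, st, X), mult, tolerance = 1e-3)
})
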