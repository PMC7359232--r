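test_that("sampler configuration enforces its invariants", {
  expect_error(sampler_config(iterations = 100, burn_in = 100, seed = 1),
               "burn_in")
  expect_error(sampler_config(seed = 1, rw_sd_alpha = 0), "positive")
  expect_error(sampler_config(seed = 1, swap_prob = 1), "swap_prob")
  expect_error(sampler_config(iterations = 10, burn_in = 5), "seed")
  cfg <- sampler_config(iterations = 150000, burn_in = 75000, seed = 1)
  expect_equal(cfg$iterations, 150000L)
  expect_equal(cfg$burn_in, 75000L)
})

test_that("log-posterior is the sum of likelihood and prior terms", {
  scen <- fixture_small_scenario()
  pr <- prior_config()
  st <- make_truth(scen$tree, scen$data$P, n_active = 2, seed = 4)
  lp <- log_posterior(st, scen$data, pr)
  manual <- dtm_loglik(scen$data, st) +
    log_prior_alpha(st$alpha, pr) +
    log_prior_beta(st$beta, st$zeta, pr) +
    log_prior_zeta(st$zeta, pr)
  expect_equal(lp, manual, tolerance = 1e-12)

  # two states differing in one active beta: difference decomposes into
  # likelihood difference plus slab density difference
  idx <- which(st$zeta == 1)[1]
  st2 <- st; st2$beta[idx] <- st$beta[idx] + 0.3
  expect_equal(log_posterior(st2, scen$data, pr) - lp,
               dtm_loglik(scen$data, st2) - dtm_loglik(scen$data, st) +
                 dnorm(st2$beta[idx], 0, sqrt(pr$sigma2_beta), log = TRUE) -
                 dnorm(st$beta[idx], 0, sqrt(pr$sigma2_beta), log = TRUE),
               tolerance = 1e-10)
})

test_that("identical seed and inputs give bit-identical samples", {
  scen <- fixture_small_scenario()
  ctrl <- sampler_config(iterations = 300, burn_in = 100, seed = 77)
  s1 <- run_mcmc(scen$data, prior_config(), ctrl)
  s2 <- run_mcmc(scen$data, prior_config(), ctrl)
  expect_identical(s1$alpha, s2$alpha)
  expect_identical(s1$beta, s2$beta)
  expect_identical(s1$zeta, s2$zeta)
  expect_identical(s1$log_posterior, s2$log_posterior)
})

test_that("stored draws respect the gating and active-count invariants", {
  scen <- fixture_small_scenario()
  ctrl <- sampler_config(iterations = 400, burn_in = 100, seed = 5,
                         debug = TRUE)
  sm <- run_mcmc(scen$data, prior_config(), ctrl)
  expect_true(all(sm$beta[sm$zeta == 0L] == 0))
  expect_identical(sm$n_active, as.integer(rowSums(sm$zeta)))
  expect_true(all(is.finite(sm$log_posterior)))
})

test_that("with the likelihood disabled the sampler recovers its prior", {
  tr <- star_tree(c("A", "B", "C"))
  counts <- matrix(5L, 2, 3, dimnames = list(NULL, tr$leaf_labels))
  X <- matrix(rnorm(4), 2, 2, dimnames = list(NULL, c("x1", "x2")))
  d <- dtm_data(counts, X, tr, standardize = FALSE)
  ctrl <- sampler_config(iterations = 20000, burn_in = 1000, seed = 11,
                         rw_sd_alpha = 2.5)
  sm <- run_mcmc(d, prior_config(), ctrl, prior_only = TRUE)
  keep <- 1001:20000
  # marginal inclusion of each indicator: a / (a + b) = 1/2
  zbar <- rowMeans(sm$zeta[keep, ])
  se <- batch_means_se(zbar)
  expect_lt(abs(mean(zbar) - 0.5), 3 * se)
  # alpha marginals match N(0, sigma2_alpha)
  a1 <- sm$alpha[keep, 1]
  expect_lt(abs(sd(a1) / sqrt(10) - 1), 0.05)
  expect_lt(abs(mean(a1)) / (sd(a1) / sqrt(200)), 5) # generous, correlated
})

test_that("thinning stores every k-th draw and moves_per_iter scales", {
  scen <- fixture_small_scenario()
  ctrl <- sampler_config(iterations = 200, burn_in = 50, seed = 3, thin = 4)
  sm <- run_mcmc(scen$data, prior_config(), ctrl)
  expect_equal(nrow(sm$alpha), 50)
  mp <- compute_mppi(sm, burn_in = 100)
  expect_equal(dim(mp), c(scen$data$B, scen$data$P))
})

test_that("a fitted chain concentrates on the generating pairs", {
  scen <- fixture_small_scenario(seed = 21, n = 80, depths = 1000)
  ctrl <- sampler_config(iterations = 3000, burn_in = 1500, seed = 22)
  sm <- run_mcmc(scen$data, prior_config(), ctrl)
  mp <- compute_mppi(sm)
  ti <- which(scen$truth$zeta == 1)
  expect_gt(min(mp[ti]), 0.5)
  expect_lt(mean(mp[-ti]), 0.2)
  # alpha acceptance lands in a sane random-walk band (logged, not tuned)
  expect_gt(sm$acceptance["alpha"], 0.05)
  expect_lt(sm$acceptance["alpha"], 0.8)
})

test_that("the MRF prior steers selection toward linked covariates", {
  scen <- fixture_small_scenario(seed = 31, n = 50, P = 4, depths = 500)
  G <- matrix(0, 4, 4); G[1, 2] <- G[2, 1] <- 1
  pr <- prior_config("mrf", d = -2, f = 0.5, G = G)
  ctrl <- sampler_config(iterations = 1500, burn_in = 500, seed = 32)
  sm <- run_mcmc(scen$data, pr, ctrl)
  expect_true(all(is.finite(sm$log_posterior)))
  expect_true(all(sm$beta[sm$zeta == 0L] == 0))
})
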