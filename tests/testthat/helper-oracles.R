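# Independent reference implementations used as oracles.  Each is written
# naively (enumeration, per-subject loops, brute-force search) and must stay
# independent of the package code paths it checks.

# Exhaustive Polya-urn enumeration of the Dirichlet-multinomial pmf: sum,
# over every distinct ordering of the draws, of the sequential urn
# probabilities (gamma_c + #previous draws of c) / (sum(gamma) + t).
polya_urn_logpmf <- function(y, gamma) {
  rec <- function(rem, drawn, t) {
    if (sum(rem) == 0) return(1)
    tot <- 0
    for (cc in which(rem > 0)) {
      pc <- (gamma[cc] + drawn[cc]) / (sum(gamma) + t)
      rem2 <- rem; rem2[cc] <- rem2[cc] - 1
      drawn2 <- drawn; drawn2[cc] <- drawn2[cc] + 1
      tot <- tot + pc * rec(rem2, drawn2, t + 1)
    }
    tot
  }
  log(rec(y, rep(0, length(y)), 0))
}

# Independently coded Dirichlet-multinomial regression log-likelihood
# (the star-tree special case), per-subject loop, no caching.
dm_regression_loglik_ref <- function(counts, X, alpha, beta) {
  ll <- 0
  for (i in seq_len(nrow(counts))) {
    g <- exp(alpha + as.numeric(beta %*% X[i, ]))
    y <- counts[i, ]
    ll <- ll + lgamma(sum(g)) - lgamma(sum(g) + sum(y)) +
      sum(lgamma(g + y) - lgamma(g))
  }
  ll
}

# Brute-force search over all prefix cutoffs for the Bayesian-FDR rule:
# for each prefix of the descending-MPPI ranking, recompute the expected
# FDR from scratch and keep the largest qualifying prefix.
bfdr_threshold_bruteforce <- function(mppi, alpha) {
  v <- sort(as.numeric(mppi), decreasing = TRUE)
  best <- NA_real_
  for (k in seq_along(v)) {
    if (mean(1 - v[seq_len(k)]) <= alpha) best <- v[k]
  }
  best
}

# Brute-force count decomposition: per subject and node, sum leaf counts by
# explicit reachability over the raw phylo edge matrix (independent of the
# package's precomputed leaf sets).
decompose_bruteforce <- function(counts, tree) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  tips_under <- function(v) {
    if (v <= ntip) return(v)
    kids <- phy$edge[phy$edge[, 1] == v, 2]
    sort(unlist(lapply(kids, tips_under)))
  }
  out <- vector("list", length(tree$node_ids))
  for (k in seq_along(tree$node_ids)) {
    kids <- phy$edge[phy$edge[, 1] == tree$node_ids[k], 2]
    out[[k]] <- sapply(kids, function(ch) {
      tl <- phy$tip.label[tips_under(ch)]
      rowSums(counts[, tl, drop = FALSE])
    })
    if (nrow(counts) == 1L) out[[k]] <- matrix(out[[k]], nrow = 1L)
  }
  out
}

# Batch-means Monte-Carlo standard error of the mean of a (possibly
# autocorrelated) chain.
batch_means_se <- function(x, n_batches = 50) {
  n <- length(x)
  bs <- n %/% n_batches
  m <- tapply(x[seq_len(bs * n_batches)],
              rep(seq_len(n_batches), each = bs), mean)
  stats::sd(m) / sqrt(n_batches)
}

# Grid-quadrature posterior model probabilities for the 2-leaf star tree
# with one covariate: mode-centered trapezoid integration of the
# unnormalized posterior for each of the 4 inclusion configurations,
# combined with the Beta-Binomial model prior.  Independent of the sampler.
tiny_model_posterior <- function(counts, X, s2a = 10, s2b = 10,
                                 a = 1, b = 1, npts = 31, span = 6) {
  y1 <- counts[, 1]; y2 <- counts[, 2]; x <- X[, 1]; N <- y1 + y2
  llgrid <- function(a1, a2, b1, b2) {
    n <- length(x)
    g1 <- exp(outer(a1, rep(1, n)) + outer(b1, x))
    g2 <- exp(outer(a2, rep(1, n)) + outer(b2, x))
    sg <- g1 + g2
    rowSums(lgamma(sg) - lgamma(sweep(sg, 2, N, `+`))) +
      rowSums(lgamma(sweep(g1, 2, y1, `+`)) - lgamma(g1)) +
      rowSums(lgamma(sweep(g2, 2, y2, `+`)) - lgamma(g2))
  }
  log_marg <- function(zeta) {
    np <- 2 + sum(zeta)
    negpost <- function(th) {
      bb <- c(0, 0); bb[zeta == 1] <- th[-(1:2)]
      -(llgrid(th[1], th[2], bb[1], bb[2]) +
          sum(dnorm(th[1:2], 0, sqrt(s2a), log = TRUE)) +
          sum(dnorm(th[-(1:2)], 0, sqrt(s2b), log = TRUE)))
    }
    opt <- stats::optim(rep(0, np), negpost, method = "BFGS", hessian = TRUE)
    sds <- sqrt(diag(solve(opt$hessian)))
    grids <- lapply(seq_len(np), function(j)
      seq(opt$par[j] - span * sds[j], opt$par[j] + span * sds[j],
          length.out = npts))
    h <- vapply(grids, function(g) g[2] - g[1], 1)
    gr <- as.matrix(expand.grid(grids))
    vals <- numeric(nrow(gr))
    chunk <- 50000L
    for (s in seq(1, nrow(gr), by = chunk)) {
      e <- min(s + chunk - 1L, nrow(gr))
      nb <- e - s + 1L
      bb1 <- if (zeta[1]) gr[s:e, 3] else rep(0, nb)
      bb2 <- if (zeta[2]) gr[s:e, 2 + sum(zeta)] else rep(0, nb)
      vals[s:e] <- llgrid(gr[s:e, 1], gr[s:e, 2], bb1, bb2) +
        dnorm(gr[s:e, 1], 0, sqrt(s2a), log = TRUE) +
        dnorm(gr[s:e, 2], 0, sqrt(s2a), log = TRUE) +
        (if (np > 2)
          rowSums(matrix(dnorm(gr[s:e, -(1:2), drop = FALSE],
                               0, sqrt(s2b), log = TRUE), nb)) else 0)
    }
    m <- max(vals)
    m + log(sum(exp(vals - m))) + sum(log(h))
  }
  models <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  lm_ <- vapply(models, log_marg, 1)
  lpz <- vapply(models, function(z)
    lbeta(a + sum(z), b + 2 - sum(z)) - lbeta(a, b), 1)
  w <- lm_ + lpz
  p <- exp(w - max(w))
  p / sum(p)
}
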