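#' Sampler configuration
#'
#' Controls the Metropolis-Hastings-within-Gibbs sampler.  Each iteration
#' performs `moves_per_iter` between-model proposals (add/delete/swap on the
#' branch-by-covariate inclusion grid, with jointly proposed coefficients)
#' followed by one within-model sweep (random-walk updates of every intercept
#' and every active coefficient).  Defaults of 150,000 iterations with a
#' 75,000 burn-in are the scale at which the method is typically applied;
#' small simulated problems mix far faster and can be run much shorter.
#'
#' @param iterations total MCMC iterations.
#' @param burn_in iterations discarded before posterior summaries
#'   (`< iterations`).
#' @param seed integer RNG seed; required, to make runs bit-reproducible.
#' @param rw_sd_alpha,rw_sd_beta random-walk proposal standard deviations
#'   for intercepts and coefficients (also the spread of the coefficient
#'   proposal attached to add/swap moves).
#' @param moves_per_iter between-model proposals per iteration; default
#'   `max(1, ceiling(B * P / 10))`, scaling with model size so per-iteration
#'   mixing is roughly constant.
#' @param swap_prob probability a between-model proposal is a within-branch
#'   swap rather than an add/delete (in `[0, 1)`).
#' @param thin store every `thin`-th iteration.
#' @param tune Robbins-Monro adaptation of the random-walk scales during
#'   burn-in only (kernels are fixed after burn-in, preserving the target).
#' @param debug assert the spike-and-slab gating invariant after every
#'   iteration (slow; for development).
#' @return object of class `dtm_control`.
#' @export
sampler_config <- function(iterations = 150000L, burn_in = 75000L, seed,
                           rw_sd_alpha = 0.5, rw_sd_beta = 0.5,
                           moves_per_iter = NULL, swap_prob = 0.5,
                           thin = 1L, tune = FALSE, debug = FALSE) {
  if (missing(seed)) stop("`seed` is required for reproducibility")
  iterations <- as.integer(iterations); burn_in <- as.integer(burn_in)
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations")
  if (rw_sd_alpha <= 0 || rw_sd_beta <= 0)
    stop("random-walk proposal sds must be positive")
  if (swap_prob < 0 || swap_prob >= 1) stop("swap_prob must be in [0, 1)")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(iterations = iterations, burn_in = burn_in,
                 seed = as.integer(seed),
                 rw_sd_alpha = rw_sd_alpha, rw_sd_beta = rw_sd_beta,
                 moves_per_iter = moves_per_iter, swap_prob = swap_prob,
                 thin = as.integer(thin), tune = isTRUE(tune),
                 debug = isTRUE(debug)),
            class = "dtm_control")
}

#' Log-posterior of a model state
#'
#' `dtm_loglik + log_prior_alpha + log_prior_beta + log_prior_zeta` (the
#' MRF variant is unnormalized, so the value is then a relative
#' log-posterior).  Errors identify which term went nonfinite.
#'
#' @param state a [dtm_state].
#' @param data a [dtm_data].
#' @param prior a [prior_config].
#' @param prior_only drop the likelihood term (used to validate the sampler
#'   against its prior).
#' @return numeric scalar.
#' @export
log_posterior <- function(state, data, prior, prior_only = FALSE) {
  terms <- c(
    loglik = if (prior_only) 0 else dtm_loglik(data, state),
    alpha = log_prior_alpha(state$alpha, prior),
    beta = log_prior_beta(state$beta, state$zeta, prior),
    zeta = log_prior_zeta(state$zeta, prior))
  if (!all(is.finite(terms)))
    stop("nonfinite log-posterior term(s): ",
         paste(names(terms)[!is.finite(terms)], collapse = ", "),
         "; consider standardizing covariates or reviewing hyperparameters")
  sum(terms)
}

#' Run the MCMC sampler
#'
#' Add/delete/swap Metropolis-Hastings over the inclusion indicators with
#' jointly proposed coefficients, interleaved with random-walk updates of
#' intercepts and active coefficients.  Every proposal perturbs a single
#' branch's concentration column, so each Metropolis step costs one
#' node-local Dirichlet-multinomial evaluation; per-node caches make the
#' sweep linear in the data touched.
#'
#' Between-model moves are exactly reversible: when a swap lands on a branch
#' with no active (or no inactive) entry it degenerates to an add (or
#' delete), and the Metropolis-Hastings ratio accounts for both proposal
#' paths (the plain add/delete kernel and the degenerate swap) that can
#' produce the same toggle, so detailed balance holds in every state.
#' Coefficients attached to add/swap proposals are drawn from
#' `N(0, rw_sd_beta^2)` with the proposal density included in the ratio,
#' which keeps acceptance stable when the slab is diffuse.
#'
#' Initialization: the empty model (`zeta = 0`, `beta = 0`) with
#' `alpha[b] = log(pooled child proportion at b + 0.01)`, matching the
#' sparsity assumption and guarding empty branches.
#'
#' @param data a [dtm_data].
#' @param prior a [prior_config].
#' @param control a [sampler_config]; `seed` is required.
#' @param prior_only drop the likelihood term and sample from the prior
#'   (diagnostic mode).
#' @param init optional [dtm_state] to start from.
#' @param verbose print progress (current active count and log-posterior)
#'   every 1000 iterations.
#' @return object of class `dtm_samples`: matrices `alpha`
#'   (draws x B), `beta` and `zeta` (draws x B*P, flattened column-major so
#'   entry `(b, p)` is column `(p-1)*B + b`), vectors `log_posterior` and
#'   `n_active`, plus the configuration and labels needed for inference.
#'   Identical seed, data and configuration give bit-identical output.
#' @export
run_mcmc <- function(data, prior = prior_config(), control,
                     prior_only = FALSE, init = NULL, verbose = FALSE) {
  stopifnot(inherits(data, "dtm_data"), inherits(prior, "dtm_prior"),
            inherits(control, "dtm_control"))
  if (prior$prior == "mrf" && nrow(prior$G) != data$P)
    stop("G is ", nrow(prior$G), " x ", ncol(prior$G), " but there are ",
         data$P, " covariates")
  set.seed(control$seed)

  tree <- data$tree
  B <- data$B; P <- data$P; n <- data$n; M <- B * P
  X <- unclass(data$X); attributes(X)[c("center", "scale", "standardized")] <- NULL
  Y <- data$node_counts$node_y
  ysum <- data$node_counts$node_total
  node_of <- tree$branch_parent
  pos_of <- tree$branch_child_pos
  nodes <- seq_along(tree$node_ids)

  s <- control$swap_prob
  rw_a <- control$rw_sd_alpha; rw_b <- control$rw_sd_beta
  sd_slab <- sqrt(prior$sigma2_beta); sd_a <- sqrt(prior$sigma2_alpha)
  mpi <- control$moves_per_iter
  if (is.null(mpi)) mpi <- max(1L, ceiling(M / 10))

  # --- initial state ---------------------------------------------------
  if (is.null(init)) {
    if (prior_only) {
      alpha <- numeric(B)
    } else {
      alpha <- numeric(B)
      for (k in nodes) {
        bs <- tree$node_branches[[k]]
        tot <- sum(ysum[[k]])
        pooled <- if (tot > 0) colSums(Y[[k]]) / tot else
          rep(1 / length(bs), length(bs))
        alpha[bs] <- log(pooled + 0.01)
      }
    }
    beta <- matrix(0, B, P)
    zeta <- matrix(0L, B, P)
  } else {
    stopifnot(inherits(init, "dtm_state"))
    alpha <- init$alpha; beta <- init$beta; zeta <- init$zeta
    storage.mode(zeta) <- "integer"
  }
  k_act <- sum(zeta)

  # --- likelihood caches ----------------------------------------------
  # eta[, b] = X %*% (beta[b, ] * zeta[b, ]); gcols[, b] = exp(alpha_b + eta_b)
  # per node k: sg = rowSums of its gamma columns; colterm[j] = the
  # count-vs-concentration term of child j; llk = the node's total loglik
  if (!prior_only) {
    eta <- X %*% t(beta * zeta)
    gcols <- exp(sweep(eta, 2L, alpha, `+`))
    if (!all(is.finite(gcols)))
      stop("nonfinite concentrations at initialization; ",
           "standardize covariates or review the initial state")
    sg <- vector("list", length(nodes))
    colterm <- vector("list", length(nodes))
    llnode <- numeric(length(nodes))
    for (k in nodes) {
      bs <- tree$node_branches[[k]]
      g <- gcols[, bs, drop = FALSE]
      sg[[k]] <- rowSums(g)
      colterm[[k]] <- vapply(seq_along(bs), function(j)
        sum(lgamma(g[, j] + Y[[k]][, j]) - lgamma(g[, j])), numeric(1))
      llnode[k] <- sum(lgamma(sg[[k]]) - lgamma(sg[[k]] + ysum[[k]])) +
        sum(colterm[[k]])
    }
    cur_ll <- sum(llnode)
    if (!is.finite(cur_ll)) stop("nonfinite log-likelihood at initialization")
  } else {
    eta <- NULL; cur_ll <- 0
  }

  # pending single-column update, committed on acceptance
  pend <- new.env(parent = emptyenv())
  eval_col <- function(b, newcol) {
    if (any(!is.finite(newcol))) return(-Inf)
    k <- node_of[b]; j <- pos_of[b]
    new_sg <- sg[[k]] - gcols[, b] + newcol
    new_term <- sum(lgamma(newcol + Y[[k]][, j]) - lgamma(newcol))
    new_ll <- sum(lgamma(new_sg) - lgamma(new_sg + ysum[[k]])) +
      sum(colterm[[k]]) - colterm[[k]][j] + new_term
    if (!is.finite(new_ll)) return(-Inf)
    pend$b <- b; pend$k <- k; pend$j <- j
    pend$col <- newcol; pend$sg <- new_sg; pend$term <- new_term
    pend$ll <- new_ll
    new_ll - llnode[k]
  }
  commit_col <- function() {
    k <- pend$k
    gcols[, pend$b] <<- pend$col
    sg[[k]] <<- pend$sg
    colterm[[k]][pend$j] <<- pend$term
    cur_ll <<- cur_ll + pend$ll - llnode[k]
    llnode[k] <<- pend$ll
  }

  # per-path proposal mass of toggling one entry: the add/delete kernel
  # contributes (1-s)/M always; the swap kernel contributes s/M only when it
  # degenerates on that branch (no active entry for an add, none inactive
  # for a delete)
  log_w <- function(degenerate) log((1 - s) / M + (s / M) * degenerate)

  acc <- c(add = 0, delete = 0, swap = 0, alpha = 0, beta = 0)
  att <- c(add = 0, delete = 0, swap = 0, alpha = 0, beta = 0)

  do_add <- function(b, p) {
    att["add"] <<- att["add"] + 1
    bprop <- stats::rnorm(1, 0, rw_b)
    delta_ll <- if (prior_only) 0 else {
      eta_new <- eta[, b] + bprop * X[, p]
      eval_col(b, exp(alpha[b] + eta_new))
    }
    nb_act <- sum(zeta[b, ])
    logr <- delta_ll +
      stats::dnorm(bprop, 0, sd_slab, log = TRUE) +
      log_prior_zeta_add_ratio(zeta, b, p, prior) +
      log_w(nb_act + 1L == P) -        # reverse delete: branch all-active
      log_w(nb_act == 0L) -            # forward add: branch all-inactive
      stats::dnorm(bprop, 0, rw_b, log = TRUE)
    if (is.finite(logr) && log(stats::runif(1)) < logr) {
      zeta[b, p] <<- 1L; beta[b, p] <<- bprop; k_act <<- k_act + 1L
      if (!prior_only) { eta[, b] <<- eta[, b] + bprop * X[, p]; commit_col() }
      acc["add"] <<- acc["add"] + 1
    }
  }

  do_delete <- function(b, p) {
    att["delete"] <<- att["delete"] + 1
    bcur <- beta[b, p]
    delta_ll <- if (prior_only) 0 else {
      eta_new <- eta[, b] - bcur * X[, p]
      eval_col(b, exp(alpha[b] + eta_new))
    }
    nb_act <- sum(zeta[b, ])
    logr <- delta_ll -
      stats::dnorm(bcur, 0, sd_slab, log = TRUE) -
      log_prior_zeta_add_ratio_post_delete(zeta, b, p, prior) +
      log_w(nb_act == 1L) -            # reverse add: branch all-inactive after
      log_w(nb_act == P) +             # forward delete: branch all-active
      stats::dnorm(bcur, 0, rw_b, log = TRUE)
    if (is.finite(logr) && log(stats::runif(1)) < logr) {
      zeta[b, p] <<- 0L; beta[b, p] <<- 0; k_act <<- k_act - 1L
      if (!prior_only) { eta[, b] <<- eta[, b] - bcur * X[, p]; commit_col() }
      acc["delete"] <<- acc["delete"] + 1
    }
  }

  do_exchange <- function(b, p0, p1) {
    # p0 active -> out; p1 inactive -> in; selection probabilities are
    # symmetric (same branch, same active/inactive counts after the move)
    att["swap"] <<- att["swap"] + 1
    b0 <- beta[b, p0]
    bprop <- stats::rnorm(1, 0, rw_b)
    delta_ll <- if (prior_only) 0 else {
      eta_new <- eta[, b] - b0 * X[, p0] + bprop * X[, p1]
      eval_col(b, exp(alpha[b] + eta_new))
    }
    dzeta <- if (prior$prior == "beta_binomial") 0 else {
      zo <- zeta[b, ]; zn <- zo; zn[p0] <- 0L; zn[p1] <- 1L
      prior$f * (drop(zn %*% prior$G %*% zn) - drop(zo %*% prior$G %*% zo))
    }
    logr <- delta_ll + dzeta +
      stats::dnorm(bprop, 0, sd_slab, log = TRUE) -
      stats::dnorm(b0, 0, sd_slab, log = TRUE) +
      stats::dnorm(b0, 0, rw_b, log = TRUE) -
      stats::dnorm(bprop, 0, rw_b, log = TRUE)
    if (is.finite(logr) && log(stats::runif(1)) < logr) {
      zeta[b, p0] <<- 0L; zeta[b, p1] <<- 1L
      beta[b, p0] <<- 0; beta[b, p1] <<- bprop
      if (!prior_only) {
        eta[, b] <<- eta[, b] - b0 * X[, p0] + bprop * X[, p1]
        commit_col()
      }
      acc["swap"] <<- acc["swap"] + 1
    }
  }

  between_step <- function() {
    if (stats::runif(1) < 1 - s) {
      m <- sample.int(M, 1L)
      b <- (m - 1L) %% B + 1L
      p <- (m - 1L) %/% B + 1L
      if (zeta[b, p] == 0L) do_add(b, p) else do_delete(b, p)
    } else {
      b <- sample.int(B, 1L)
      nb <- sum(zeta[b, ])
      if (nb == 0L) {
        do_add(b, sample.int(P, 1L))
      } else if (nb == P) {
        do_delete(b, sample.int(P, 1L))
      } else {
        act <- which(zeta[b, ] == 1L); inact <- which(zeta[b, ] == 0L)
        p0 <- if (length(act) == 1L) act else act[sample.int(length(act), 1L)]
        p1 <- if (length(inact) == 1L) inact else
          inact[sample.int(length(inact), 1L)]
        do_exchange(b, p0, p1)
      }
    }
  }

  within_step <- function() {
    for (b in seq_len(B)) {
      att["alpha"] <<- att["alpha"] + 1
      anew <- alpha[b] + stats::rnorm(1, 0, rw_a)
      delta_ll <- if (prior_only) 0 else eval_col(b, exp(anew + eta[, b]))
      logr <- delta_ll +
        stats::dnorm(anew, 0, sd_a, log = TRUE) -
        stats::dnorm(alpha[b], 0, sd_a, log = TRUE)
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        alpha[b] <<- anew
        if (!prior_only) commit_col()
        acc["alpha"] <<- acc["alpha"] + 1
      }
    }
    act <- which(zeta == 1L)
    for (m in act) {
      att["beta"] <<- att["beta"] + 1
      b <- (m - 1L) %% B + 1L
      p <- (m - 1L) %/% B + 1L
      bcur <- beta[m]
      bnew <- bcur + stats::rnorm(1, 0, rw_b)
      delta_ll <- if (prior_only) 0 else {
        eta_new <- eta[, b] + (bnew - bcur) * X[, p]
        eval_col(b, exp(alpha[b] + eta_new))
      }
      logr <- delta_ll +
        stats::dnorm(bnew, 0, sd_slab, log = TRUE) -
        stats::dnorm(bcur, 0, sd_slab, log = TRUE)
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        beta[m] <<- bnew
        if (!prior_only) {
          eta[, b] <<- eta[, b] + (bnew - bcur) * X[, p]
          commit_col()
        }
        acc["beta"] <<- acc["beta"] + 1
      }
    }
  }

  # --- main loop -------------------------------------------------------
  nstore <- control$iterations %/% control$thin
  pair_names <- paste(rep(tree$branch_labels, times = P),
                      rep(colnames(X), each = B), sep = ":")
  out_alpha <- matrix(NA_real_, nstore, B,
                      dimnames = list(NULL, tree$branch_labels))
  out_beta <- matrix(NA_real_, nstore, M, dimnames = list(NULL, pair_names))
  out_zeta <- matrix(NA_integer_, nstore, M,
                     dimnames = list(NULL, pair_names))
  out_lp <- numeric(nstore); out_na <- integer(nstore)

  tune_win <- 50L
  tune_batch <- 0L
  acc0 <- acc; att0 <- att

  si <- 0L
  for (it in seq_len(control$iterations)) {
    for (mv in seq_len(mpi)) between_step()
    within_step()

    if (control$tune && it <= control$burn_in && it %% tune_win == 0L) {
      tune_batch <- tune_batch + 1L
      da <- (acc["alpha"] - acc0["alpha"]) / max(1, att["alpha"] - att0["alpha"])
      db <- (acc["beta"] - acc0["beta"]) / max(1, att["beta"] - att0["beta"])
      step <- 1 / sqrt(tune_batch)
      rw_a <- rw_a * exp(step * (da - 0.44))
      if (att["beta"] > att0["beta"]) rw_b <- rw_b * exp(step * (db - 0.44))
      acc0 <- acc; att0 <- att
    }

    if (control$debug && any(beta[zeta == 0L] != 0))
      stop("gating invariant violated at iteration ", it)

    if (it %% control$thin == 0L) {
      si <- si + 1L
      out_alpha[si, ] <- alpha
      out_beta[si, ] <- beta
      out_zeta[si, ] <- zeta
      out_na[si] <- k_act
      out_lp[si] <- cur_ll +
        log_prior_alpha(alpha, prior) +
        log_prior_beta(beta, zeta, prior) +
        log_prior_zeta(zeta, prior)
    }
    if (verbose && it %% 1000L == 0L)
      message(sprintf("iter %d: n_active = %d, log-posterior = %.2f",
                      it, k_act, out_lp[max(1L, si)]))
  }

  if (!prior_only) {
    # cache-consistency audit against a from-scratch evaluation
    check <- dtm_loglik(data, dtm_state(alpha, beta, zeta))
    if (abs(check - cur_ll) > 1e-6 * max(1, abs(check)))
      stop("internal error: cached log-likelihood drifted (",
           cur_ll, " vs ", check, ")")
  }

  structure(list(alpha = out_alpha, beta = out_beta, zeta = out_zeta,
                 log_posterior = out_lp, n_active = out_na,
                 B = B, P = P,
                 branch_labels = tree$branch_labels,
                 covariate_names = colnames(X),
                 iterations = control$iterations, burn_in = control$burn_in,
                 thin = control$thin, seed = control$seed,
                 prior = prior, control = control, prior_only = prior_only,
                 acceptance = ifelse(att > 0, acc / att, NA_real_)),
            class = "dtm_samples")
}

# log prior ratio of re-adding zeta[b, p] after deleting it (used to form
# the delete ratio as the negative of the corresponding add ratio)
log_prior_zeta_add_ratio_post_delete <- function(zeta, b, p, prior) {
  if (prior$prior == "beta_binomial") {
    M <- length(zeta); k <- sum(zeta) - 1L
    log(prior$a + k) - log(prior$b + M - k - 1)
  } else {
    # G has zero diagonal, so zeta[b, p] = 1 does not contribute
    prior$d + 2 * prior$f * sum(prior$G[p, ] * zeta[b, ]) -
      2 * prior$f * prior$G[p, p]
  }
}

#' @export
print.dtm_samples <- function(x, ...) {
  cat("dtm_samples:", nrow(x$alpha), "stored draws,", x$B, "branches x",
      x$P, "covariates\n")
  cat("  burn-in:", x$burn_in, "of", x$iterations, "iterations; seed",
      x$seed, "\n")
  ar <- paste(sprintf("%s %.2f", names(x$acceptance), x$acceptance),
              collapse = ", ")
  cat("  acceptance rates:", ar, "\n")
  invisible(x)
}
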