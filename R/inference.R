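#' Marginal posterior probabilities of inclusion
#'
#' The MPPI of a branch-covariate pair is the average of its inclusion
#' indicator's post-burn-in MCMC samples.
#'
#' @param samples a `dtm_samples` from [run_mcmc].
#' @param burn_in iterations to discard (defaults to the value stored at run
#'   time); interpreted on the iteration scale and mapped through the
#'   thinning interval.
#' @return B x P matrix of MPPIs in `[0, 1]`, rows labeled by branch, columns
#'   by covariate.
#' @export
compute_mppi <- function(samples, burn_in = NULL) {
  if (is.null(burn_in)) burn_in <- samples$burn_in
  keep <- which(seq_len(nrow(samples$zeta)) * samples$thin > burn_in)
  if (!length(keep))
    stop("burn_in (", burn_in, ") leaves no stored draws")
  m <- colMeans(samples$zeta[keep, , drop = FALSE])
  matrix(m, samples$B, samples$P,
         dimnames = list(samples$branch_labels, samples$covariate_names))
}

#' Bayesian false discovery rate threshold
#'
#' Selecting all pairs with MPPI at or above a cutoff incurs an expected
#' (Bayesian) FDR equal to the mean of `1 - MPPI` over the selected set.
#' Candidates are ranked by descending MPPI; the largest prefix whose
#' expected FDR is at or below `alpha` determines the cutoff (the smallest
#' MPPI in that prefix).  If no prefix qualifies, `NA` is returned, meaning
#' "select nothing".  Because the cumulative mean of `1 - MPPI` is
#' nondecreasing along the ranking, the selected set is monotone in `alpha`.
#'
#' @param mppi numeric vector (or matrix, flattened) of MPPIs in `[0, 1]`.
#' @param alpha target Bayesian FDR in `(0, 1)`.
#' @return the MPPI cutoff, or `NA_real_` if nothing can be selected.
#' @export
bfdr_threshold <- function(mppi, alpha) {
  v <- as.numeric(mppi)
  if (!length(v)) stop("empty MPPI input")
  if (any(v < 0 | v > 1)) stop("MPPI values must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  v <- sort(v, decreasing = TRUE)
  efdr <- cumsum(1 - v) / seq_along(v)
  ok <- which(efdr <= alpha)
  if (!length(ok)) return(NA_real_)
  v[max(ok)]
}

#' Select branch-covariate pairs
#'
#' Either the fixed-threshold rule (MPPI >= 0.5 by convention; the median
#' probability model) or the Bayesian-FDR rule via [bfdr_threshold].  Ties at
#' the cutoff are all included (a `>=` comparison throughout).
#'
#' @param mppi B x P MPPI matrix from [compute_mppi].
#' @param rule `"mppi"` (fixed cutoff) or `"bfdr"`.
#' @param cutoff MPPI cutoff for `rule = "mppi"`.
#' @param alpha target rate for `rule = "bfdr"`.
#' @return object of class `dtm_selection`: the `mppi` matrix, the `rule`,
#'   the implied `threshold`, and `selected`, a data frame with one row per
#'   selected pair (branch index, covariate index, labels, MPPI).
#' @export
select_pairs <- function(mppi, rule = c("mppi", "bfdr"), cutoff = 0.5,
                         alpha = 0.01) {
  rule <- match.arg(rule)
  mppi <- as.matrix(mppi)
  thr <- switch(rule,
                mppi = cutoff,
                bfdr = bfdr_threshold(mppi, alpha))
  if (is.na(thr)) {
    idx <- integer(0)
  } else {
    idx <- which(mppi >= thr)
  }
  b <- (idx - 1L) %% nrow(mppi) + 1L
  p <- (idx - 1L) %/% nrow(mppi) + 1L
  sel <- data.frame(
    branch = b, covariate = p,
    branch_label = rownames(mppi)[b],
    covariate_name = colnames(mppi)[p],
    mppi = mppi[idx],
    stringsAsFactors = FALSE)
  sel <- sel[order(-sel$mppi, sel$branch, sel$covariate), , drop = FALSE]
  rownames(sel) <- NULL
  structure(list(mppi = mppi, rule = rule,
                 alpha = if (rule == "bfdr") alpha else NA_real_,
                 threshold = thr, selected = sel),
            class = "dtm_selection")
}

#' @export
print.dtm_selection <- function(x, ...) {
  cat("dtm_selection: ", nrow(x$selected), " pair(s) selected by rule '",
      x$rule, "' (threshold ", format(x$threshold, digits = 3), ")\n",
      sep = "")
  if (nrow(x$selected)) print(utils::head(x$selected, 20L))
  invisible(x)
}

#' Association-network edge list
#'
#' Each selected branch-covariate pair becomes an edge between the branch's
#' child label (a taxon name for leaf branches, a synthesized stable
#' `node_k` label for internal branches) and the covariate.  With `taxa`
#' given, edges are restricted to branches lying on the root-to-leaf paths of
#' the named taxa -- the lineage view used to summarize results for a taxon
#' of interest.
#'
#' @param selection a `dtm_selection`.
#' @param tree the [dtm_tree] the model was fit on.
#' @param taxa optional character vector of leaf labels to restrict to.
#' @return data frame with columns `node`, `covariate`, `mppi`.
#' @export
network_edges <- function(selection, tree, taxa = NULL) {
  sel <- selection$selected
  if (!is.null(taxa)) {
    keep_b <- unique(unlist(lapply(taxa, leaf_path_branches, tree = tree)))
    sel <- sel[sel$branch %in% keep_b, , drop = FALSE]
  }
  data.frame(node = sel$branch_label, covariate = sel$covariate_name,
             mppi = sel$mppi, stringsAsFactors = FALSE)
}

#' Convergence traces and Geweke diagnostic
#'
#' Returns the per-draw number of active covariates and log-posterior
#' series (the two traces routinely inspected for convergence), together
#' with a Geweke z-score on the post-burn-in log-posterior: the difference
#' between the means of the first 10% and last 50% of the chain, scaled by
#' spectral-density-at-zero standard errors.  A degenerate (constant) chain
#' yields `geweke_applicable = FALSE` and `NA` for the score.
#'
#' @param samples a `dtm_samples`.
#' @param burn_in iterations to discard before the Geweke computation
#'   (default: the stored burn-in).
#' @return list with `n_active`, `log_posterior`, `geweke_z`,
#'   `geweke_applicable`.
#' @export
convergence_traces <- function(samples, burn_in = NULL) {
  if (is.null(burn_in)) burn_in <- samples$burn_in
  keep <- which(seq_len(nrow(samples$zeta)) * samples$thin > burn_in)
  lp <- samples$log_posterior[keep]
  z <- geweke_z(lp)
  list(n_active = samples$n_active,
       log_posterior = samples$log_posterior,
       geweke_z = z, geweke_applicable = is.finite(z))
}

#' Geweke z-score of a chain segment
#'
#' Compares the mean of the first `frac1` of the series with the mean of the
#' last `frac2`, with variances estimated as spectral density at frequency
#' zero from AIC-selected autoregressive fits (robust to autocorrelation).
#'
#' @param x numeric chain.
#' @param frac1,frac2 fractions of the series to compare (defaults 0.1 and
#'   0.5).
#' @return the z-score, or `NA` for degenerate input.
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  if (n < 20L || stats::sd(x) == 0) return(NA_real_)
  x1 <- x[seq_len(max(2L, floor(frac1 * n)))]
  x2 <- x[seq.int(n - max(2L, floor(frac2 * n)) + 1L, n)]
  v1 <- spectrum0_ar(x1) / length(x1)
  v2 <- spectrum0_ar(x2) / length(x2)
  if (!is.finite(v1) || !is.finite(v2) || v1 + v2 <= 0) return(NA_real_)
  (mean(x1) - mean(x2)) / sqrt(v1 + v2)
}

# spectral density at frequency zero via an AIC-selected AR fit
spectrum0_ar <- function(x) {
  if (stats::sd(x) == 0) return(0)
  fit <- tryCatch(stats::ar(x, aic = TRUE,
                            order.max = min(30L, length(x) %/% 4L)),
                  error = function(e) NULL)
  if (is.null(fit)) return(stats::var(x))
  if (fit$order == 0L) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Score a selection against a known truth
#'
#' For simulation studies: compares the selected branch-covariate pairs with
#' a generating truth and reports the usual confusion summaries.
#'
#' @param selection a `dtm_selection`, or a binary B x P matrix of selected
#'   pairs.
#' @param truth binary B x P matrix of true inclusions (e.g. the `zeta` of a
#'   generating [dtm_state]).
#' @return list with `tpr`, `fpr`, `mcc`, `f1`, and the confusion counts.
#' @export
score_selection <- function(selection, truth) {
  truth <- as.matrix(truth)
  if (inherits(selection, "dtm_selection")) {
    sel <- matrix(0, nrow(selection$mppi), ncol(selection$mppi))
    if (nrow(selection$selected))
      sel[cbind(selection$selected$branch, selection$selected$covariate)] <- 1
  } else {
    sel <- as.matrix(selection)
  }
  if (!all(dim(sel) == dim(truth)))
    stop("selection is ", nrow(sel), " x ", ncol(sel), " but truth is ",
         nrow(truth), " x ", ncol(truth))
  tp <- sum(sel == 1 & truth == 1); fp <- sum(sel == 1 & truth == 0)
  fn <- sum(sel == 0 & truth == 1); tn <- sum(sel == 0 & truth == 0)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fpr <- if (fp + tn > 0) fp / (fp + tn) else NA_real_
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  list(tpr = tpr, fpr = fpr, mcc = mcc, f1 = f1,
       tp = tp, fp = fp, fn = fn, tn = tn)
}
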