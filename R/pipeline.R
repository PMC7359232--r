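#' Fit the DTM variable-selection model (high-level wrapper)
#'
#' Runs the sampler and summarizes the posterior in one call: MPPIs,
#' selection under the requested rule, and convergence traces.
#'
#' @param data a [dtm_data] (see also [simulate_scenario]).
#' @param prior a [prior_config].
#' @param control a [sampler_config] (`seed` required).
#' @param rule `"mppi"` or `"bfdr"` (see [select_pairs]).
#' @param cutoff MPPI cutoff for the `"mppi"` rule.
#' @param alpha target rate for the `"bfdr"` rule.
#' @param verbose print sampler progress.
#' @return object of class `dtm_fit`: `samples`, `mppi`, `selection`,
#'   `traces`.
#' @export
dtm_fit <- function(data, prior = prior_config(), control,
                    rule = c("mppi", "bfdr"), cutoff = 0.5, alpha = 0.01,
                    verbose = FALSE) {
  rule <- match.arg(rule)
  samples <- run_mcmc(data, prior, control, verbose = verbose)
  mppi <- compute_mppi(samples)
  selection <- select_pairs(mppi, rule = rule, cutoff = cutoff, alpha = alpha)
  traces <- convergence_traces(samples)
  structure(list(samples = samples, mppi = mppi, selection = selection,
                 traces = traces, data = data),
            class = "dtm_fit")
}

#' @export
print.dtm_fit <- function(x, ...) {
  print(x$samples)
  print(x$selection)
  if (isTRUE(x$traces$geweke_applicable))
    cat("Geweke z on log-posterior:", format(x$traces$geweke_z, digits = 3),
        "\n")
  invisible(x)
}

write_matrix_tsv <- function(m, path, row_label = "row") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- row_label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Persist MCMC samples as plain matrices
#'
#' Writes `alpha.csv`, `beta.csv`, `zeta.csv`, and `scalars.csv`
#' (log-posterior and active-count traces) plus `config.json` into a
#' directory.  The CSV matrices have one row per stored draw and are
#' directly loadable by external MCMC-diagnostic tooling (e.g. coda via
#' `as.mcmc(read.csv(...))`).
#'
#' @param samples a `dtm_samples`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_samples <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(samples$alpha, file.path(dir, "alpha.csv"),
                   row.names = FALSE)
  utils::write.csv(samples$beta, file.path(dir, "beta.csv"),
                   row.names = FALSE)
  utils::write.csv(samples$zeta, file.path(dir, "zeta.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(log_posterior = samples$log_posterior,
                              n_active = samples$n_active),
                   file.path(dir, "scalars.csv"), row.names = FALSE)
  cfg <- list(iterations = samples$iterations, burn_in = samples$burn_in,
              thin = samples$thin, seed = samples$seed,
              B = samples$B, P = samples$P,
              prior = samples$prior[setdiff(names(samples$prior), "G")],
              control = unclass(samples$control))
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}

#' File-based fit pipeline
#'
#' Reads counts, covariates, and tree from disk, fits the model, and writes
#' the full set of run artifacts: `mppi.tsv`, `selection.tsv`, `edges.tsv`,
#' `traces.csv`, a `samples/` directory ([write_samples]), and
#' `manifest.json` recording configuration, package version and seed --
#' enough to re-run bit-identically.
#'
#' @param counts_file,covariates_file TSV/CSV tables (header row of labels,
#'   first column subject ids).
#' @param tree_file Newick file; omit with `dm = TRUE` for the star-tree
#'   (Dirichlet-multinomial) fallback.
#' @param out_dir output directory.
#' @param dm use a star tree over the count columns instead of a tree file.
#' @param graph_file optional covariate adjacency TSV (switches the
#'   inclusion prior to the MRF unless `prior` is given explicitly).
#' @param indicator_cols covariate columns exempt from standardization.
#' @param prior a [prior_config]; default Beta-Binomial `a = b = 1`, or MRF
#'   when `graph_file` is given.
#' @param control a [sampler_config] (`seed` required).
#' @param rule,cutoff,alpha selection rule parameters (see [select_pairs]).
#' @param verbose print progress.
#' @return the `dtm_fit`, invisibly.
#' @export
run_fit <- function(counts_file, covariates_file, tree_file = NULL,
                    out_dir, dm = is.null(tree_file), graph_file = NULL,
                    indicator_cols = character(),
                    prior = NULL, control,
                    rule = c("mppi", "bfdr"), cutoff = 0.5, alpha = 0.01,
                    verbose = FALSE) {
  rule <- match.arg(rule)
  for (f in c(counts_file, covariates_file, tree_file, graph_file))
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  counts <- read_counts(counts_file)
  X <- read_covariates(covariates_file)
  tree <- if (dm || is.null(tree_file)) star_tree(colnames(counts)) else
    parse_newick(file = tree_file)
  if (is.null(prior)) {
    prior <- if (is.null(graph_file)) prior_config() else
      prior_config("mrf", G = read_graph(graph_file))
  }
  data <- dtm_data(counts, X, tree, indicator_cols = indicator_cols)
  fit <- dtm_fit(data, prior, control, rule = rule, cutoff = cutoff,
                 alpha = alpha, verbose = verbose)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(fit$mppi, file.path(out_dir, "mppi.tsv"), "branch")
  utils::write.table(fit$selection$selected,
                     file.path(out_dir, "selection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(network_edges(fit$selection, tree),
                     file.path(out_dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(data.frame(n_active = fit$traces$n_active,
                              log_posterior = fit$traces$log_posterior),
                   file.path(out_dir, "traces.csv"), row.names = FALSE)
  write_samples(fit$samples, file.path(out_dir, "samples"))
  manifest <- list(
    package = "dtmbvs",
    version = as.character(utils::packageVersion("dtmbvs")),
    inputs = list(counts = counts_file, covariates = covariates_file,
                  tree = tree_file, graph = graph_file, dm = dm),
    prior = fit$samples$prior[setdiff(names(fit$samples$prior), "G")],
    control = unclass(fit$samples$control),
    selection = list(rule = rule, cutoff = cutoff, alpha = alpha,
                     threshold = fit$selection$threshold,
                     n_selected = nrow(fit$selection$selected)),
    geweke_z = fit$traces$geweke_z)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA,
                       pretty = TRUE)
  invisible(fit)
}

#' Write a simulated scenario to disk
#'
#' Produces the same TSV/Newick formats the fitting pipeline reads, plus a
#' truth table (`branch`, `covariate`, `beta`, `zeta`) for scoring.
#'
#' @param out_dir output directory.
#' @param ... scenario settings passed to [simulate_scenario] (`seed`
#'   required).
#' @return the scenario list, invisibly.
#' @export
run_simulate <- function(out_dir, ...) {
  scen <- simulate_scenario(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- scen$counts
  rownames(counts) <- rownames(counts) %||% paste0("s", seq_len(nrow(counts)))
  write_matrix_tsv(counts, file.path(out_dir, "counts.tsv"), "subject")
  X <- scen$covariates
  rownames(X) <- rownames(counts)
  write_matrix_tsv(X, file.path(out_dir, "covariates.tsv"), "subject")
  ape::write.tree(scen$tree$phylo, file.path(out_dir, "tree.nwk"))
  truth <- scen$truth
  idx <- which(truth$zeta == 1L)
  b <- (idx - 1L) %% nrow(truth$zeta) + 1L
  p <- (idx - 1L) %/% nrow(truth$zeta) + 1L
  utils::write.table(
    data.frame(branch = b, covariate = p, beta = truth$beta[idx], zeta = 1L),
    file.path(out_dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(scen)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
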