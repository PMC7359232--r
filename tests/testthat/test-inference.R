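test_that("MPPI is the post-burn-in average of inclusion draws", {
  z <- matrix(0L, 10, 2)
  z[1:7, 1] <- 1L
  sm <- fixture_samples(z, B = 2, P = 1)
  mp <- compute_mppi(sm, burn_in = 0)
  expect_equal(unname(mp[1, 1]), 0.7)
  expect_equal(unname(mp[2, 1]), 0)

  zall <- matrix(1L, 5, 4)
  expect_true(all(compute_mppi(fixture_samples(zall, 2, 2), burn_in = 0) == 1))

  zalt <- matrix(rep(c(0L, 1L), 500), 1000, 1)
  expect_equal(unname(compute_mppi(fixture_samples(zalt, 1, 1),
                                   burn_in = 0)[1, 1]), 0.5)

  expect_error(compute_mppi(fixture_samples(z, 2, 1), burn_in = 10),
               "no stored draws")
})

test_that("BFDR threshold follows the cumulative expected-FDR rule", {
  expect_equal(bfdr_threshold(c(0.99, 0.98, 0.60, 0.10), 0.05), 0.98)
  expect_equal(bfdr_threshold(rep(1, 5), 0.01), 1)
  # nothing selectable -> sentinel
  expect_true(is.na(bfdr_threshold(c(0.3, 0.2), 0.05)))
  expect_error(bfdr_threshold(numeric(0), 0.05), "empty")
  expect_error(bfdr_threshold(c(0.5, 1.2), 0.05), "\\[0, 1\\]")
})

test_that("BFDR threshold matches brute-force prefix search on random inputs", {
  set.seed(14)
  for (rep in 1:20) {
    v <- runif(sample(3:40, 1))
    alpha <- runif(1, 0.01, 0.3)
    expect_equal(bfdr_threshold(v, alpha), bfdr_threshold_bruteforce(v, alpha))
  }
})

test_that("selection is monotone in alpha and inclusive at ties", {
  mp <- matrix(c(0.99, 0.95, 0.50, 0.50, 0.20, 0.05), 3, 2,
               dimnames = list(paste0("b", 1:3), c("x1", "x2")))
  # fixed-threshold rule: a pair at exactly 0.5 is included
  s5 <- select_pairs(mp, rule = "mppi", cutoff = 0.5)
  expect_true(all(c("b3:x1", "b1:x2") %in%
                    paste(s5$selected$branch_label, s5$selected$covariate_name,
                          sep = ":")))
  expect_equal(nrow(s5$selected), 4)
  # BFDR: growing alpha never shrinks the selected set
  sizes <- sapply(c(0.01, 0.05, 0.1, 0.2, 0.4), function(a)
    nrow(select_pairs(mp, rule = "bfdr", alpha = a)$selected))
  expect_true(all(diff(sizes) >= 0))
  # sentinel selects nothing without error
  low <- matrix(c(0.1, 0.2), 1, 2)
  s0 <- select_pairs(low, rule = "bfdr", alpha = 0.01)
  expect_equal(nrow(s0$selected), 0)
})

test_that("MPPI-rule and BFDR-rule selections coincide at the implied cutoff", {
  set.seed(15)
  mp <- matrix(runif(24), 6, 4,
               dimnames = list(paste0("b", 1:6), paste0("x", 1:4)))
  sb <- select_pairs(mp, rule = "bfdr", alpha = 0.3)
  if (!is.na(sb$threshold)) {
    sm <- select_pairs(mp, rule = "mppi", cutoff = sb$threshold)
    expect_equal(sm$selected[order(sm$selected$branch, sm$selected$covariate),
                             c("branch", "covariate")],
                 sb$selected[order(sb$selected$branch, sb$selected$covariate),
                             c("branch", "covariate")],
                 ignore_attr = TRUE)
  }
})

test_that("network edges map branches to taxa or stable node labels", {
  tr <- star_tree(c("A", "B", "C"))
  mp <- matrix(c(0.9, 0.1, 0.8), 3, 1,
               dimnames = list(tr$branch_labels, "diet"))
  sel <- select_pairs(mp, rule = "mppi", cutoff = 0.5)
  ed <- network_edges(sel, tr)
  # star tree: branches are leaves, so edges are taxon <-> covariate
  expect_setequal(ed$node, c("A", "C"))

  tr2 <- parse_newick("((A,B),C);")
  path <- leaf_path_branches(tr2, "A")
  expect_equal(tr2$branch_labels[path], c("node_2", "A"))
  expect_error(leaf_path_branches(tr2, "Z"), "unknown taxon")

  mp2 <- matrix(c(0.9, 0.8, 0.1, 0.95), 4, 1,
                dimnames = list(tr2$branch_labels, "diet"))
  sel2 <- select_pairs(mp2, rule = "mppi", cutoff = 0.5)
  edA <- network_edges(sel2, tr2, taxa = "A")
  expect_setequal(edA$node, c("node_2", "A")) # C's branch filtered out

  # edge lists round-trip through a TSV file
  tf <- tempfile(fileext = ".tsv")
  write.table(edA, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read.delim(tf, stringsAsFactors = FALSE)
  expect_equal(back$node, edA$node)
  expect_equal(back$mppi, edA$mppi, tolerance = 1e-12)
})

test_that("convergence traces report Geweke and flag degenerate chains", {
  z <- matrix(rbinom(600, 1, 0.5), 300, 2)
  lp <- rnorm(300)
  sm <- fixture_samples(z, B = 2, P = 1, lp = lp)
  tr <- convergence_traces(sm, burn_in = 0)
  expect_length(tr$n_active, 300)
  expect_true(is.finite(tr$geweke_z))

  smc <- fixture_samples(z, B = 2, P = 1, lp = rep(1.5, 300))
  trc <- convergence_traces(smc, burn_in = 0)
  expect_false(trc$geweke_applicable)
  expect_true(is.na(trc$geweke_z))
})

test_that("Geweke scores on white noise are standard normal", {
  set.seed(16)
  z <- replicate(100, geweke_z(rnorm(600)))
  expect_gt(mean(abs(z) < 3), 0.95)
  expect_lt(abs(mean(z)), 0.4)
})

test_that("selection scoring reproduces confusion-matrix formulas", {
  truth <- matrix(c(1, 0, 0, 1), 2, 2)
  perfect <- score_selection(truth, truth)
  expect_equal(perfect$tpr, 1)
  expect_equal(perfect$fpr, 0)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$f1, 1)

  none <- score_selection(matrix(0, 2, 2), truth)
  expect_equal(none$tpr, 0)

  sel <- matrix(c(1, 1, 0, 0), 2, 2)
  sc <- score_selection(sel, truth)
  tp <- 1; fp <- 1; fn <- 1; tn <- 1
  expect_equal(sc$mcc, (tp * tn - fp * fn) /
                 sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
  expect_equal(sc$f1, 2 * tp / (2 * tp + fp + fn))
  expect_error(score_selection(matrix(0, 3, 2), truth), "truth")
})
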