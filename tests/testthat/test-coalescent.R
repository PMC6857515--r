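test_that("theta identity and validation", {
  expect_equal(theta_from_lengths(0.005, 2.5), 0.002)
  expect_equal(theta_from_lengths(0, 1), 0)
  expect_error(theta_from_lengths(0.1, 0), "tau")
  expect_error(theta_from_lengths(-0.1, 1), "muT")
  # algebraic round trip
  expect_equal(theta_from_lengths(0.002 * 2.5, 2.5), 0.002)
})

test_that("expected triplet probabilities follow the closed form", {
  expect_equal(unlist(expected_triplet_probs(0)[c("major", "minor")]),
               c(major = 1 / 3, minor = 1 / 3))
  expect_equal(expected_triplet_probs(50)$major, 1, tolerance = 1e-12)
  p <- expected_triplet_probs(0.1)
  expect_equal(p$major, 0.39678, tolerance = 1e-4)
  expect_equal(p$minor, 0.30161, tolerance = 1e-4)
  tt <- seq(0, 5, by = 0.25)
  pp <- expected_triplet_probs(tt)
  expect_equal(pp$major + 2 * pp$minor, rep(1, length(tt)))
  expect_true(all(diff(pp$major) > 0))
  expect_true(all(pp$major >= 1 / 3))
  expect_error(expected_triplet_probs(-0.1), ">= 0")
})

test_that("branch length inverts the major-triplet frequency", {
  expect_equal(branch_length_from_major_freq(0.3967751), 0.1,
               tolerance = 1e-5)
  for (t in c(0.01, 0.1, 1, 3)) {
    p <- expected_triplet_probs(t)$major
    expect_equal(branch_length_from_major_freq(p), t, tolerance = 1e-12)
  }
  expect_error(branch_length_from_major_freq(1 / 3), "between")
  expect_error(branch_length_from_major_freq(1), "between")
})

test_that("a(x) matches its closed form, monotonicity, and zero crossing", {
  expect_equal(a_of_x(0.1), 0.3267, tolerance = 1e-4)
  expect_lt(a_of_x(10), 0)
  expect_equal(a_of_x(50), log(2 / 3), tolerance = 1e-8)
  xx <- seq(0.01, 5, by = 0.01)
  expect_true(all(diff(a_of_x(xx)) < 0))
  expect_gt(a_of_x(0.001), 2)  # divergence near zero
  # single sign change, bracketed numerically
  root <- uniroot(a_of_x, c(0.1, 1))$root
  expect_equal(root, 0.2655, tolerance = 1e-3)
  expect_error(a_of_x(0), "> 0")
})

test_that("anomaly scan flags exactly the pairs with y < a(x)", {
  safe <- caterpillar_model(ab = 5, abc = 5, abcd = 5)
  expect_false(any(anomaly_scan(safe)$anomalous))

  risky <- caterpillar_model(ab = 0.01, abc = 0.05, abcd = 5)
  scan <- anomaly_scan(risky)
  flagged <- scan[scan$anomalous, ]
  expect_equal(nrow(flagged), 1L)
  expect_equal(flagged$x, 0.05)
  expect_equal(flagged$y, 0.01)
  expect_gt(flagged$a_x, 0.01)

  # missing tau on an internal edge errors naming the clade
  bad <- parse_newick("(((A,B),C),D);")
  expect_error(anomaly_scan(bad), "tau")
})

test_that("batch anomaly scan reports flag fractions across replicates", {
  risky <- caterpillar_model(ab = 0.01, abc = 0.05, abcd = 5)
  safe <- caterpillar_model(ab = 5, abc = 5, abcd = 5)
  rep <- anomaly_scan_replicates(list(risky, risky, safe))
  ab_row <- rep[rep$child_clade == "A,B", ]
  expect_equal(ab_row$n_replicates, 3L)
  expect_equal(ab_row$frac_anomalous, 2 / 3)
})

test_that("gene-tree simulation is seeded-deterministic and respects limits", {
  model <- trio_model(1)
  g1 <- simulate_gene_trees(model, 5, seed = 7)
  g2 <- simulate_gene_trees(model, 5, seed = 7)
  g3 <- simulate_gene_trees(model, 5, seed = 8)
  nwk <- function(g) vapply(g$trees, write_newick, character(1))
  expect_identical(nwk(g1), nwk(g2))
  expect_false(identical(nwk(g1), nwk(g3)))

  # tau -> infinity: every tree topologically equals the species tree
  deep <- caterpillar_model(ab = 30, abc = 30, abcd = 30)
  gs <- simulate_gene_trees(deep, 200, seed = 3)
  keys <- vapply(gs$trees, topology_key, character(1))
  expect_true(all(keys == topology_key(deep$tree)))

  # all branch lengths are non-negative
  expect_true(all(vapply(gs$trees, function(tr)
    all(tr$edge.length >= 0), logical(1))))
})

test_that("simulated trio concordance matches the analytic oracle", {
  n <- 4000
  for (t in c(0.1, 1)) {
    gs <- simulate_gene_trees(trio_model(t), n, seed = 100 + round(100 * t))
    conc <- mean(vapply(gs$trees, function(tr)
      decompose_triplet(tr, c("A", "B", "C")) == "C", logical(1)))
    p <- expected_triplet_probs(t)$major
    expect_lt(abs(conc - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("heterogeneity ratio is ~1 under self-consistency and <1 with error", {
  model <- caterpillar_model(ab = 0.3, abc = 0.5, abcd = 2)
  emp <- simulate_gene_trees(model, 800, seed = 41)
  hr <- heterogeneity_ratio(emp, model, n_sim = 2000, metric = "rf",
                            seed = 42)
  se_ratio <- hr$ratio * sqrt(((hr$ci_sim[2] - hr$mean_sim) / 1.96 /
                                 hr$mean_sim)^2 +
                              ((hr$ci_emp[2] - hr$mean_emp) / 1.96 /
                                 hr$mean_emp)^2)
  expect_lt(abs(hr$ratio - 1), 3 * se_ratio)

  # NNI-perturbed "empirical" trees inflate the empirical mean
  sets <- generate_gene_tree_sets(model, data.frame(
    class = "X", n_loci = 800, error_rate = 1, nni_k = 1), seed = 43)
  hr2 <- heterogeneity_ratio(sets$X, model, n_sim = 2000, metric = "rf",
                             seed = 44)
  expect_lt(hr2$ratio, 1)

  # matching metric runs and stays on the same side
  hr3 <- heterogeneity_ratio(sets$X, model, n_sim = 400,
                             metric = "matching", seed = 45)
  expect_lt(hr3$ratio, 1)

  # degenerate: empirical trees identical to the species tree
  ident <- gene_tree_set(rep(list(model$tree), 10))
  hr4 <- heterogeneity_ratio(ident, model, n_sim = 100, seed = 46)
  expect_true(hr4$undefined)
  expect_true(is.na(hr4$ratio))
})

test_that("triplet goodness of fit behaves at both extremes and calibrates", {
  t <- branch_length_from_major_freq(0.4)
  expect_equal(triplet_gof(c(40, 30, 30), t), 1)
  expect_lt(triplet_gof(c(100, 0, 0), 0), 1e-6)
  expect_lt(triplet_gof(c(10, 0, 0), 0), 0.05)
  expect_error(triplet_gof(c(0, 0, 0), 1), "zero total")

  # counts simulated at the matching t should rarely reject
  t <- 0.3
  p_maj <- expected_triplet_probs(t)$major
  pvals <- vapply(1:6, function(s) {
    set.seed(500 + s)
    draws <- sample(1:3, 400, replace = TRUE,
                    prob = c(p_maj, (1 - p_maj) / 2, (1 - p_maj) / 2))
    triplet_gof(tabulate(draws, 3), t)
  }, numeric(1))
  expect_gte(sum(pvals > 0.05), 5)
})

test_that("species tree model enforces the theta = muT/tau identity", {
  tr <- parse_newick("((A:1,B:1):0.5,C:1.5);")
  m <- species_tree_model(tr, theta = 0.002)
  internal <- tr$edge[, 2] > 3
  expect_equal(m$muT[internal], 0.002 * 0.5)
  expect_equal(m$theta[!internal], rep(1, sum(!internal)))

  expect_error(species_tree_model(tr, muT = rep(0.01, 4),
                                  theta = rep(0.5, 4)),
               "theta = muT / tau")
  expect_error(suppressWarnings(species_tree_model(
    parse_newick("((A:1,B:1):0,C:1);"))), "tau")
})
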