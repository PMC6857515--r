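test_that("topology binning counts, flags the species tree, and separates bins", {
  a <- parse_newick("((((A,B),C),D),E);")
  b <- parse_newick("((((A,C),B),D),E);")
  set <- gene_tree_set(c(rep(list(a), 5), rep(list(b), 3)))
  bins <- bin_topologies(set, species_tree = b)
  expect_equal(bins$count, c(5L, 3L))
  expect_equal(bins$is_species_tree, c(FALSE, TRUE))
  expect_equal(sum(bins$count), attr(bins, "total"))
  reps <- attr(bins, "representatives")
  expect_equal(rf_cluster_distance(reps[[1]], a), 0L)
  expect_gt(rf_cluster_distance(reps[[1]], reps[[2]]), 0L)
})

test_that("polytomies bin only with identical polytomies", {
  res <- parse_newick("(((A,B),C),D);")
  poly <- parse_newick("((A,B,C),D);")
  set <- gene_tree_set(list(res, poly, poly))
  bins <- bin_topologies(set)
  expect_equal(sort(bins$count), c(1L, 2L))
})

test_that("long internal branches concentrate trees on the species tree", {
  model <- caterpillar_model(ab = 5, abc = 5, abcd = 5)
  gs <- simulate_gene_trees(model, 1000, seed = 101)
  bins <- bin_topologies(gs, species_tree = model$tree)
  expect_true(bins$is_species_tree[1])
  expect_gt(bins$freq[1], 0.9)
  for (key in cluster_keys(model$tree)) {
    expect_gt(gene_support_frequency(gs, strsplit(key, ",")[[1]]), 90)
  }
})

test_that("gene support frequency is the percent of trees with the clade", {
  a <- parse_newick("(((A,B),C),D);")
  b <- parse_newick("(((A,C),B),D);")
  set <- gene_tree_set(list(a, a, b))
  expect_equal(gene_support_frequency(set, c("A", "B")), 100 * 2 / 3)
  expect_equal(gene_support_frequency(set, c("A", "B", "C")), 100)
  expect_error(gene_support_frequency(set, c("A", "Z")), "outside")
})

test_that("simulated pair support tracks the analytic triplet expectation", {
  t <- 0.5
  n <- 4000
  model <- trio_model(t)
  gs <- simulate_gene_trees(model, n, seed = 7)
  p_hat <- gene_support_frequency(gs, c("A", "B")) / 100
  p <- expected_triplet_probs(t)$major
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("internode certainty follows its entropy definition and sign rule", {
  sp <- parse_newick("(((A,B),C),D);")
  conc <- sp
  confl <- parse_newick("(((A,C),B),D);")

  all_same <- gene_tree_set(rep(list(conc), 10))
  ica <- internode_certainty_all(all_same, sp)
  expect_equal(ica$ica, rep(1, nrow(ica)))
  expect_equal(ica$gsf, rep(100, nrow(ica)))

  # 50/50 two-way conflict: certainty collapses to zero
  half <- gene_tree_set(c(rep(list(conc), 5), rep(list(confl), 5)))
  ica2 <- internode_certainty_all(half, sp)
  expect_equal(ica2$ica[ica2$cluster == "A,B"], 0, tolerance = 1e-12)

  # focal at 25% vs conflict at 75%: negative, magnitude from the formula
  quarter <- gene_tree_set(c(rep(list(conc), 2), rep(list(confl), 6)))
  ica3 <- internode_certainty_all(quarter, sp)
  val <- ica3$ica[ica3$cluster == "A,B"]
  p <- c(0.25, 0.75)
  expected <- -(1 + sum(p * log(p, base = 2)))
  expect_lt(val, 0)
  expect_equal(val, expected, tolerance = 1e-12)

  # conflicts below the frequency threshold are ignored
  rare <- gene_tree_set(c(rep(list(conc), 99), list(confl)))
  ica4 <- internode_certainty_all(rare, sp, freq_threshold = 0.05)
  expect_equal(ica4$ica[ica4$cluster == "A,B"], 1)
})

test_that("triplet decomposition resolves trios and flags polytomies", {
  tr <- parse_newick("((((A,B),C),D),Out);")
  expect_equal(decompose_triplet(tr, c("A", "B", "C")), "C")
  expect_equal(decompose_triplet(tr, c("B", "C", "D")), "D")
  star <- parse_newick("(A,B,C,D);")
  expect_equal(decompose_triplet(star, c("A", "B", "C")), "unresolved")
  expect_error(decompose_triplet(tr, c("A", "B", "Z")), "not in tree")

  set.seed(13)
  big <- random_rooted_tree(12)
  trios <- utils::combn(big$tip.label, 3, simplify = FALSE)
  res <- vapply(trios, function(tr3) decompose_triplet(big, tr3), character(1))
  expect_false(any(res == "unresolved"))
  expect_true(all(vapply(seq_along(trios), function(i)
    res[i] %in% trios[[i]], logical(1))))
})

test_that("lineage triplet tally reduces to per-gene triplets and omits ties", {
  lm <- c(a1 = "L1", a2 = "L1", b = "L2", c = "L3")

  # one taxon per lineage: no ties possible
  g1 <- parse_newick("((a1,b),c);")
  set1 <- gene_tree_set(list(g1, g1))
  tc1 <- lineage_triplet_tally(set1, lm[c("a1", "b", "c")],
                               c("L1", "L2", "L3"))
  expect_equal(unname(tc1$counts[["L3"]]), 2L)
  expect_equal(tc1$n_tied_omitted, 0L)

  # cross-lineage votes split 1/1: the gene is omitted
  g2 <- parse_newick("((a1,b),(a2,c));")
  tc2 <- lineage_triplet_tally(gene_tree_set(list(g2)), lm,
                               c("L1", "L2", "L3"))
  expect_equal(tc2$n_tied_omitted, 1L)
  expect_equal(sum(tc2$counts), 0L)

  expect_error(lineage_triplet_tally(set1, lm, c("L1", "L2", "L9")),
               "no member taxa")
})

test_that("MSC triplet tallies match coalescent expectations at t = 0.1", {
  t <- 0.1
  n <- 4000
  model <- trio_model(t)
  gs <- simulate_gene_trees(model, n, seed = 29)
  lm <- c(A = "LA", B = "LB", C = "LC")
  tc <- lineage_triplet_tally(gs, lm, c("LA", "LB", "LC"))
  ex <- expected_triplet_probs(t)
  se <- sqrt(ex$major * (1 - ex$major) / n)
  expect_lt(abs(tc$counts[["LC"]] / n - ex$major), 3 * se)
  expect_equal(tc$major, "LC")

  # the two minor counts are statistically symmetric
  p <- binom.test(tc$counts[["LA"]], tc$counts[["LA"]] + tc$counts[["LB"]],
                  0.5)$p.value
  expect_gt(p, 0.01)
})
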