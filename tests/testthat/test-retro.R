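toy_matrix <- function() {
  m <- rbind(
    inf_ab   = c(1, 1, 0, 0, 0, 0),
    sympl    = c(1, 1, 1, 1, 1, 1),
    auto_c   = c(0, 0, 1, 0, 0, 0),
    miss_lin = c(1, 1, 0, 0, NA, NA),
    inf_cd   = c(0, 0, 1, 1, 0, 0)
  )
  colnames(m) <- c("A", "B", "C", "D", "E", "F")
  insertion_matrix(m)
}

toy_lineages <- c(A = "L1", B = "L1", C = "L2", D = "L2", E = "L3", F = "L3")

test_that("insertion matrix validates states and scorability", {
  expect_error(insertion_matrix(matrix(2, 1, 2,
                                       dimnames = list("l", c("A", "B")))),
               "states")
  expect_error(insertion_matrix(matrix(NA_integer_, 1, 2,
                                       dimnames = list("l", c("A", "B")))),
               "non-omitted")
  expect_error(insertion_matrix(matrix(1, 1, 2)), "taxon names")
})

test_that("insertion matrix TSV round trip preserves all three states", {
  m <- toy_matrix()
  path <- tempfile(fileext = ".tsv")
  write_insertion_matrix(m, path)
  txt <- readLines(path)
  expect_true(grepl("\\?", txt[5]))  # omitted cells written as ?
  m2 <- read_insertion_matrix(path)
  expect_equal(unclass(m2), unclass(m), ignore_attr = TRUE)
  expect_equal(rownames(m2), rownames(m))
})

test_that("pattern classification applies the lineage-coverage rules", {
  cl <- classify_patterns(toy_matrix(), toy_lineages)
  expect_equal(cl$class,
               c("informative", "symplesiomorphy", "autapomorphy",
                 "missing-lineage-omitted", "informative"))
  expect_equal(cl$cluster[1], "A,B")
  expect_equal(cl$cluster[5], "C,D")
  # classification partitions the loci
  expect_equal(sum(table(cl$class)), nrow(toy_matrix()))
  expect_error(classify_patterns(toy_matrix(), toy_lineages[-1]), "missing")
})

test_that("generator mechanism: stem -> symplesiomorphy, terminal -> autapomorphy", {
  model <- caterpillar_model(ab = 0.3, abc = 0.5, abcd = 2)
  ins <- generate_insertion_dataset(model, 400, seed = 9, omission_rate = 0)
  meta <- attr(ins, "metadata")
  lm <- setNames(rep("only", 5), c("A", "B", "C", "D", "E"))
  cl <- classify_patterns(ins, lm)
  expect_equal(sum(cl$class == "symplesiomorphy"),
               sum(meta$edge_type == "stem"))
  expect_equal(sum(cl$class == "autapomorphy"),
               sum(meta$edge_type == "terminal"))
  expect_equal(sum(cl$class == "informative"),
               sum(meta$edge_type == "internal"))
})

test_that("trio support tally reproduces engineered counts", {
  taxa <- c("E1", "K1", "T1", "X1")
  lm <- c(E1 = "EC", K1 = "kiwi", T1 = "tinamous", X1 = "other")
  build <- function(present, n) {
    m <- matrix(0L, n, length(taxa), dimnames = list(NULL, taxa))
    m[, present] <- 1L
    m
  }
  m <- rbind(build(c("E1", "K1"), 12),        # EC+kiwi, tinamou absent
             build(c("E1", "T1"), 1),
             build(c("K1", "T1"), 1))
  rownames(m) <- paste0("L", seq_len(nrow(m)))
  cl <- classify_patterns(insertion_matrix(m), lm)
  tal <- tally_trio_support(cl, lm, c("EC", "kiwi", "tinamous"))
  expect_equal(c(tal$n1, tal$n2, tal$n3), c(12L, 1L, 1L))
  expect_equal(signif(kksc_tree_test(tal$n1, tal$n2, tal$n3)$p_value, 2),
               8.2e-05)

  empty <- classify_patterns(insertion_matrix(build("E1", 2)), lm)
  tal0 <- tally_trio_support(empty, lm, c("EC", "kiwi", "tinamous"))
  expect_equal(c(tal0$n1, tal0$n2, tal0$n3), c(0L, 0L, 0L))
})

test_that("insertion tree test matches printed values and the trinomial oracle", {
  expect_equal(signif(kksc_tree_test(12, 1, 1)$p_value, 2), 8.2e-05)
  expect_equal(signif(kksc_tree_test(12, 6, 5)$p_value, 2), 0.048)
  expect_equal(kksc_tree_test(0, 0, 0)$p_value, 1)
  expect_equal(kksc_tree_test(5, 5, 5)$p_value, 0.596, tolerance = 1e-3)
  expect_error(kksc_tree_test(-1, 0, 0), ">= 0")

  # closed form for unopposed counts
  for (n1 in c(1, 3, 7)) {
    expect_equal(kksc_tree_test(n1, 0, 0)$p_value, (1 / 3)^n1,
                 tolerance = 1e-12)
  }
  # strictly decreasing in n1 at fixed total of alternatives
  ps <- vapply(1:9, function(n1) kksc_tree_test(n1, 5, 4)$p_value,
               numeric(1))
  expect_true(all(diff(ps) < 0))
  # exhaustive trinomial enumeration oracle for all totals <= 12
  for (total in c(3, 7, 12)) {
    for (n1 in 0:total) {
      expect_equal(kksc_tree_test(n1, total - n1, 0)$p_value,
                   oracle_trinomial_tail(n1, total), tolerance = 1e-10)
    }
  }
})

test_that("log-space tail agrees with direct summation for totals <= 30", {
  for (total in c(5, 18, 30)) {
    for (n1 in c(0, 1, total %/% 2, total)) {
      direct <- sum(dbinom(n1:total, total, 1 / 3))
      p <- kksc_tree_test(n1, total - n1, 0)$p_value
      expect_equal(p, min(1, direct), tolerance = 1e-10)
      expect_true(p > 0 && p <= 1)
    }
  }
})

test_that("minor-pattern symmetry test is exact two-sided binomial", {
  expect_equal(minor_symmetry_test(6, 5), 1)
  expect_equal(minor_symmetry_test(10, 0), 2 * 0.5^10, tolerance = 1e-12)
  for (k in c(1, 4, 9)) expect_equal(minor_symmetry_test(k, k), 1)
  expect_error(minor_symmetry_test(0, 0), "both counts zero")
})

test_that("species-tree consistency report counts conflicts", {
  sp <- parse_newick("(((A,B),(C,D)),E);")
  lm <- setNames(LETTERS[1:5], LETTERS[1:5])
  consistent <- rbind(matrix(rep(c(1, 1, 0, 0, 0), 8), 8, byrow = TRUE))
  conflicting <- matrix(rep(c(1, 0, 1, 0, 0), 2), 2, byrow = TRUE)
  m <- rbind(consistent, conflicting)
  colnames(m) <- LETTERS[1:5]
  rownames(m) <- paste0("L", 1:10)
  cl <- classify_patterns(insertion_matrix(m), lm)
  rep <- species_tree_consistency_report(cl, sp)
  expect_equal(rep$n_informative, 10L)
  expect_equal(rep$n_consistent, 8L)
  expect_equal(rep$percent_consistent, 80)
  expect_equal(rep$per_edge$n_supporting[rep$per_edge$cluster == "A,B"], 8L)
})

test_that("hemiplasy with long branches yields <1% conflicting patterns", {
  model <- caterpillar_model(ab = 5, abc = 5, abcd = 5)
  ins <- generate_insertion_dataset(model, 800, seed = 77, omission_rate = 0)
  lm <- setNames(c("A", "B", "C", "D", "E"), c("A", "B", "C", "D", "E"))
  cl <- classify_patterns(ins, lm)
  rep <- species_tree_consistency_report(cl, model$tree)
  expect_gt(rep$percent_consistent, 99)
})

test_that("hemiplasy pattern frequencies respect the trio expectation", {
  t <- 0.2
  model <- trio_model(t, tip_len = 2)
  ins <- generate_insertion_dataset(model, 1500, seed = 55, omission_rate = 0)
  lm <- c(A = "LA", B = "LB", C = "LC")
  cl <- classify_patterns(ins, lm)
  tal <- tally_trio_support(cl, lm, c("LA", "LB", "LC"))
  total <- tal$n1 + tal$n2 + tal$n3
  minor_p <- expected_triplet_probs(t)$minor
  # neither discordant pattern occurs significantly more often than the
  # coalescent minor-triplet expectation (one-sided binomial, alpha = 0.01)
  expect_gt(binom.test(tal$n2, total, minor_p, "greater")$p.value, 0.01)
  expect_gt(binom.test(tal$n3, total, minor_p, "greater")$p.value, 0.01)
  # and the two discordant patterns are symmetric
  expect_gt(minor_symmetry_test(tal$n2, tal$n3), 0.01)
})

test_that("omission noise rescores cells but never a whole locus", {
  model <- trio_model(0.5)
  ins <- generate_insertion_dataset(model, 300, seed = 12,
                                    omission_rate = 0.3)
  expect_gt(sum(is.na(ins)), 0)
  expect_true(all(rowSums(!is.na(unclass(ins))) >= 1))
})
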