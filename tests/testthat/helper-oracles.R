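# Independent oracles and small fixture builders used across the suite.

# Random rooted binary tree on n leaves labelled t1..tn (ape::rtree is rooted).
random_rooted_tree <- function(n, labels = paste0("t", seq_len(n))) {
  tr <- ape::rtree(n)
  tr$tip.label <- sample(labels)
  tr
}

# All permutations of a vector (tiny n only).
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
  }
  out
}

# Independent cluster extraction: a leaf subset S is a cluster of a rooted
# tree iff the tips below MRCA(S) are exactly S. Enumerates all subsets, so
# it shares no code path with tree_clusters().
oracle_clusters <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  out <- list()
  for (k in 2:(n - 1L)) {
    for (idx in utils::combn(n, k, simplify = FALSE)) {
      s <- labs[idx]
      mr <- ape::getMRCA(tree, s)
      below <- if (mr <= n) labs[mr] else ape::extract.clade(tree, mr)$tip.label
      if (setequal(below, s)) out <- c(out, list(sort(s)))
    }
  }
  out
}

oracle_rf <- function(t1, t2) {
  k1 <- vapply(oracle_clusters(t1), paste, character(1), collapse = ",")
  k2 <- vapply(oracle_clusters(t2), paste, character(1), collapse = ",")
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

# Exhaustive-matching oracle for the matching cluster distance.
oracle_mcd <- function(t1, t2) {
  c1 <- oracle_clusters(t1)
  c2 <- oracle_clusters(t2)
  m <- max(length(c1), length(c2))
  if (m == 0L) return(0)
  length(c1) <- m
  length(c2) <- m
  best <- Inf
  for (p in perms(seq_len(m))) {
    cost <- sum(vapply(seq_len(m), function(i) {
      a <- c1[[i]]
      b <- c2[[p[i]]]
      length(setdiff(a, b)) + length(setdiff(b, a))
    }, numeric(1)))
    best <- min(best, cost)
  }
  best
}

# Exhaustive trinomial oracle for the insertion tree test: enumerate all
# multinomial(total; 1/3,1/3,1/3) outcomes and sum the probability of those
# with first count >= n1.
oracle_trinomial_tail <- function(n1, total) {
  if (n1 <= 0) return(1)
  p <- 0
  for (k1 in 0:total) {
    for (k2 in 0:(total - k1)) {
      k3 <- total - k1 - k2
      if (k1 >= n1) {
        p <- p + exp(lgamma(total + 1) - lgamma(k1 + 1) - lgamma(k2 + 1) -
                       lgamma(k3 + 1) + total * log(1 / 3))
      }
    }
  }
  p
}

# Independent count of rooted binary leaf-labelled topologies by the
# add-a-leaf recursion (each new leaf attaches at any node of the smaller
# tree, including above the root).
oracle_count_rooted <- function(n) {
  if (n <= 2L) return(1)
  (2 * n - 3) * oracle_count_rooted(n - 1L)
}

# A small species-tree model for a rooted trio (A,B) against C with internal
# branch t; all theta = 1 so mutational and coalescent lengths coincide.
trio_model <- function(t, tip_len = 5) {
  nwk <- sprintf("((A:%g,B:%g):%g,C:%g);", tip_len, tip_len, t, tip_len + t)
  species_tree_model(parse_newick(nwk))
}

# 5-taxon caterpillar model with named internal branch lengths.
caterpillar_model <- function(ab, abc, abcd = 3, tip = 6) {
  nwk <- sprintf("((((A:1,B:1):%g,C:2):%g,D:3):%g,E:%g);",
                 ab, abc, abcd, tip)
  species_tree_model(parse_newick(nwk))
}

scenario_lineage_map <- function(scenario) {
  c(scenario$spec$lineage_map, setNames("outgroup", scenario$spec$outgroup))
}
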