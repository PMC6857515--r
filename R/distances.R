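# Rooted-tree topology distances on cluster sets.

check_same_leaves <- function(t1, t2) {
  a <- sort(t1$tip.label)
  b <- sort(t2$tip.label)
  if (!identical(a, b)) {
    only1 <- setdiff(a, b)
    only2 <- setdiff(b, a)
    stop("leaf sets differ; only in first: {",
         paste(only1, collapse = ", "), "}; only in second: {",
         paste(only2, collapse = ", "), "}")
  }
  invisible(TRUE)
}

#' Robinson-Foulds cluster distance between rooted trees
#'
#' The size of the symmetric difference between the two trees' sets of
#' nontrivial clusters (rooted-tree analogue of the RF bipartition distance).
#' Zero if and only if the topologies are identical, including any polytomies.
#'
#' @param t1,t2 Rooted `phylo` objects on identical leaf sets.
#' @return A non-negative integer.
#' @export
rf_cluster_distance <- function(t1, t2) {
  check_same_leaves(t1, t2)
  k1 <- cluster_keys(t1)
  k2 <- cluster_keys(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Matching cluster distance between rooted trees
#'
#' Minimum total cost over perfect matchings between the two trees' cluster
#' multisets (the smaller side padded with empty clusters), where the cost of
#' pairing two clusters is the cardinality of the symmetric difference of their
#' leaf sets. Less sensitive than RF to the displacement of a single taxon.
#'
#' @param t1,t2 Rooted `phylo` objects on identical leaf sets.
#' @return A non-negative integer; zero iff the topologies are identical.
#' @export
matching_cluster_distance <- function(t1, t2) {
  check_same_leaves(t1, t2)
  c1 <- tree_clusters(t1)
  c2 <- tree_clusters(t2)
  m <- max(length(c1), length(c2))
  if (m == 0L) return(0L)
  length(c1) <- m  # pad with NULL = empty cluster
  length(c2) <- m
  cost <- matrix(0L, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      cost[i, j] <- length(symdiff_chr(c1[[i]], c2[[j]]))
    }
  }
  as.integer(min_cost_assignment(cost))
}

symdiff_chr <- function(a, b) c(setdiff(a, b), setdiff(b, a))

# Minimum-cost perfect matching on a square cost matrix, via maximum-weight
# bipartite matching (igraph). Weights are shifted so every maximum-weight
# matching is perfect.
min_cost_assignment <- function(cost) {
  m <- nrow(cost)
  if (m == 1L) return(cost[1L, 1L])
  big <- max(cost) + 1
  w <- big - cost
  g <- igraph::make_full_bipartite_graph(m, m)
  el <- igraph::as_edgelist(g)
  weights <- w[cbind(el[, 1L], el[, 2L] - m)]
  mt <- igraph::max_bipartite_match(g, weights = weights)
  m * big - mt$matching_weight
}
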