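# Gene-tree heterogeneity statistics: topology distributions, per-clade
# support (GSF, internode certainty), and rooted-triplet tallies.

#' Bin gene trees into identical-topology classes
#'
#' Partitions a gene-tree set into bins of pairwise RF cluster distance zero
#' (exact topology equality; a polytomy bins only with identical polytomies),
#' sorted by descending count. When a species tree is supplied, the bin
#' matching its topology is flagged.
#'
#' @param set A filtered `gene_tree_set` (identical taxa across trees).
#' @param species_tree Optional rooted `phylo` to flag among the bins.
#' @param top Optional cap on the number of bins reported (e.g. 50); a
#'   reporting convenience only, counts are computed from all trees.
#' @return An object of class `topology_distribution`: a data frame with
#'   columns `rank`, `count`, `freq`, `is_species_tree`, plus attributes
#'   `representatives` (one `phylo` per bin) and `total`.
#' @export
bin_topologies <- function(set, species_tree = NULL, top = NULL) {
  stopifnot(inherits(set, "gene_tree_set"), length(set$trees) >= 1L)
  keys <- vapply(set$trees, topology_key, character(1))
  tab <- sort(table(keys), decreasing = TRUE)
  bin_keys <- names(tab)
  reps <- set$trees[match(bin_keys, keys)]
  sp_key <- if (!is.null(species_tree)) topology_key(species_tree) else NA
  res <- data.frame(
    rank = seq_along(tab),
    count = as.integer(tab),
    freq = as.integer(tab) / length(keys),
    is_species_tree = if (is.na(sp_key)) NA else bin_keys == sp_key,
    stringsAsFactors = FALSE
  )
  if (!is.null(top) && nrow(res) > top) {
    res <- res[seq_len(top), ]
    reps <- reps[seq_len(top)]
  }
  structure(res, representatives = reps, total = length(keys),
            class = c("topology_distribution", "data.frame"))
}

#' @export
print.topology_distribution <- function(x, ...) {
  cat("Topology distribution:", attr(x, "total"), "trees in",
      nrow(x), "bins\n")
  print.data.frame(head(x, 10), row.names = FALSE)
  if (nrow(x) > 10) cat("  ... and", nrow(x) - 10, "more bins\n")
  invisible(x)
}

#' Gene support frequency of a clade
#'
#' The percentage of gene trees containing the given cluster.
#'
#' @param set A `gene_tree_set`.
#' @param cluster Character vector of taxa (a subset of the taxon universe).
#' @return A percent in \[0, 100\].
#' @export
gene_support_frequency <- function(set, cluster) {
  stopifnot(inherits(set, "gene_tree_set"))
  if (!all(cluster %in% set$taxa)) {
    stop("cluster contains taxa outside the set's taxon universe: ",
         paste(setdiff(cluster, set$taxa), collapse = ", "))
  }
  key <- cluster_key(cluster)
  hits <- vapply(set$trees, function(tr) key %in% cluster_keys(tr),
                 logical(1))
  100 * mean(hits)
}

# Two clusters (on a shared universe) conflict iff they overlap but neither
# nests inside the other.
clusters_conflict <- function(a, b) {
  i <- length(intersect(a, b))
  i > 0L && i < length(a) && i < length(b)
}

#' Internode certainty "all" and gene support frequency per species-tree clade
#'
#' For each nontrivial cluster of the species tree, collects the cluster's
#' relative frequency in the gene-tree set together with the frequencies of
#' all observed clusters that conflict with it and occur at relative frequency
#' at least `freq_threshold`. The selected frequencies are normalized to sum
#' to one and scored as `ICA = 1 + sum(p_i * log(p_i, base = n))` with `n` the
#' number of clusters considered. The score is 1 when no conflicting cluster
#' passes the threshold, and its sign is negated when the focal cluster is not
#' the most frequent of its conflict set.
#'
#' @param set A filtered `gene_tree_set`.
#' @param species_tree A rooted binary `phylo` on the set's taxa.
#' @param freq_threshold Minimum relative frequency for a conflicting cluster
#'   to enter the calculation (default 0.05).
#' @return A data frame with columns `cluster` (comma-joined taxa), `size`,
#'   `gsf` (percent), and `ica`.
#' @export
internode_certainty_all <- function(set, species_tree, freq_threshold = 0.05) {
  stopifnot(inherits(set, "gene_tree_set"), inherits(species_tree, "phylo"))
  n_tr <- length(set$trees)
  all_keys <- unlist(lapply(set$trees, cluster_keys))
  freq_tab <- table(all_keys) / n_tr
  obs_keys <- names(freq_tab)
  obs_sets <- strsplit(obs_keys, ",", fixed = TRUE)
  focal <- tree_clusters(species_tree)
  out <- lapply(focal, function(cl) {
    fkey <- cluster_key(cl)
    f_freq <- if (fkey %in% obs_keys) as.numeric(freq_tab[[fkey]]) else 0
    confl <- vapply(obs_sets, clusters_conflict, logical(1), b = cl)
    confl_freqs <- as.numeric(freq_tab[confl])
    confl_freqs <- confl_freqs[confl_freqs >= freq_threshold]
    if (!length(confl_freqs)) {
      ica <- 1
    } else {
      sel <- c(f_freq, confl_freqs)
      p <- sel / sum(sel)
      n <- length(sel)
      ica <- 1 + sum(p * log(p, base = n))
      if (f_freq < max(confl_freqs)) ica <- -ica
    }
    data.frame(cluster = fkey, size = length(cl), gsf = 100 * f_freq,
               ica = ica, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# ---------------------------------------------------------------------------
# Rooted triplets
# ---------------------------------------------------------------------------

#' Resolve the rooted triplet induced by three taxa
#'
#' Restricts the rooted tree to a trio of leaves and reports which taxon lies
#' outside the cherry, or `"unresolved"` when a polytomy spans the trio.
#'
#' @param tree A rooted `phylo`.
#' @param trio Character vector of three leaf labels.
#' @return A length-1 character: the outlier taxon name, or `"unresolved"`.
#' @export
decompose_triplet <- function(tree, trio) {
  stopifnot(inherits(tree, "phylo"), length(trio) == 3L)
  if (!all(trio %in% tree$tip.label)) {
    stop("trio taxa not in tree: ",
         paste(setdiff(trio, tree$tip.label), collapse = ", "))
  }
  dep <- node_depths(tree)
  tips <- match(trio, tree$tip.label)
  m12 <- ape::getMRCA(tree, tips[c(1L, 2L)])
  m13 <- ape::getMRCA(tree, tips[c(1L, 3L)])
  m23 <- ape::getMRCA(tree, tips[c(2L, 3L)])
  d <- dep[c(m12, m13, m23)]
  if (max(d) == min(d)) return("unresolved")
  # deepest pairwise MRCA identifies the cherry; outlier is the excluded taxon
  trio[c(3L, 2L, 1L)][which.max(d)]
}

# Depth (edges from root) for every node.
node_depths <- function(tree) {
  tr <- reorder(tree)  # cladewise: parents precede children
  n_all <- length(tree$tip.label) + tree$Nnode
  dep <- integer(n_all)
  for (k in seq_len(nrow(tr$edge))) {
    dep[tr$edge[k, 2L]] <- dep[tr$edge[k, 1L]] + 1L
  }
  dep
}

# Resolution codes for many trios at once, one tree.
# trios: 3-row character matrix of taxon names (columns = trios).
# Returns integer vector: 1/2/3 = index of the outlier within the trio, 0 =
# unresolved.
triplet_codes_one_tree <- function(tree, trios) {
  dep <- node_depths(tree)
  mr <- ape::mrca(tree)  # tip x tip matrix, labelled
  labs <- tree$tip.label
  i1 <- match(trios[1L, ], labs)
  i2 <- match(trios[2L, ], labs)
  i3 <- match(trios[3L, ], labs)
  d12 <- dep[mr[cbind(i1, i2)]]
  d13 <- dep[mr[cbind(i1, i3)]]
  d23 <- dep[mr[cbind(i2, i3)]]
  dm <- cbind(d12, d13, d23)
  mx <- pmax(d12, d13, d23)
  mn <- pmin(d12, d13, d23)
  code <- max.col(dm, ties.method = "first")
  code <- c(3L, 2L, 1L)[code]  # deepest of (12),(13),(23) -> outlier 3,2,1
  code[mx == mn] <- 0L
  code
}

# Per-gene x per-trio resolution table for a gene-tree set.
triplet_code_table <- function(set, trios) {
  res <- vapply(set$trees, triplet_codes_one_tree, integer(ncol(trios)),
                trios = trios)
  if (is.null(dim(res))) matrix(res, ncol = 1L) else t(res)
}

#' Tally rooted-triplet resolutions for three lineages across genes
#'
#' For each gene, evaluates every cross-lineage trio (one member taxon from
#' each of the three lineages), takes the modal resolution for that gene, and
#' omits the gene when the mode is tied. Unresolved trios do not vote; genes
#' with no resolved trio are counted as unresolved. Counts are then summed
#' across genes.
#'
#' @param set A filtered `gene_tree_set`.
#' @param lineage_map Named character vector mapping taxon -> lineage (or a
#'   two-column data frame `taxon`, `lineage`).
#' @param lineages Character vector of three lineage names.
#' @return An object of class `triplet_counts`: a list with `lineages`,
#'   `counts` (named by outlier lineage), `n_unresolved`, `n_tied_omitted`,
#'   `major` (the most frequent resolution; ties flagged via `major_tied`).
#' @export
lineage_triplet_tally <- function(set, lineage_map, lineages) {
  stopifnot(inherits(set, "gene_tree_set"), length(lineages) == 3L)
  lineage_map <- as_lineage_map(lineage_map)
  members <- lapply(lineages, function(l) {
    m <- intersect(names(lineage_map)[lineage_map == l], set$taxa)
    if (!length(m)) stop("lineage '", l, "' has no member taxa in the set")
    m
  })
  trios <- as.matrix(expand.grid(members[[1L]], members[[2L]], members[[3L]],
                                 stringsAsFactors = FALSE))
  trios <- t(trios)
  codes <- triplet_code_table(set, trios)
  counts <- setNames(integer(3L), lineages)
  n_unres <- 0L
  n_tied <- 0L
  for (g in seq_len(nrow(codes))) {
    votes <- tabulate(codes[g, ], nbins = 3L)
    if (sum(votes) == 0L) {
      n_unres <- n_unres + 1L
      next
    }
    top <- max(votes)
    if (sum(votes == top) > 1L) {
      n_tied <- n_tied + 1L
      next
    }
    w <- which.max(votes)
    counts[w] <- counts[w] + 1L
  }
  major <- names(counts)[which.max(counts)]
  structure(list(lineages = lineages, counts = counts,
                 n_unresolved = n_unres, n_tied_omitted = n_tied,
                 major = major,
                 major_tied = sum(counts == max(counts)) > 1L),
            class = "triplet_counts")
}

#' @export
print.triplet_counts <- function(x, ...) {
  cat("Rooted-triplet tally for lineages:",
      paste(x$lineages, collapse = ", "), "\n")
  for (l in names(x$counts)) {
    pair <- setdiff(x$lineages, l)
    cat(sprintf("  (%s,%s)|%s : %d\n", pair[1], pair[2], l, x$counts[[l]]))
  }
  cat("  unresolved genes:", x$n_unresolved,
      " tie-omitted genes:", x$n_tied_omitted, "\n")
  cat("  major resolution: outlier =", x$major,
      if (x$major_tied) "(tied)" else "", "\n")
  invisible(x)
}

as_lineage_map <- function(lineage_map) {
  if (is.data.frame(lineage_map)) {
    stopifnot(all(c("taxon", "lineage") %in% names(lineage_map)))
    lineage_map <- setNames(as.character(lineage_map$lineage),
                            as.character(lineage_map$taxon))
  }
  stopifnot(is.character(lineage_map), !is.null(names(lineage_map)))
  lineage_map
}
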