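# Phylogenomic subsampling (gene-level double resampling) with a
# rooted-triplet (R*) species-tree estimator and hypothesis-support
# summarization.

#' Subsampling design
#'
#' Locus subset sizes, replicates per size, and gene-wise bootstraps per
#' replicate.
#'
#' @param sizes Strictly increasing vector of subset sizes.
#' @param replicates Replicates per size.
#' @param bootstraps Bootstrap resamples per replicate.
#' @return An object of class `subsample_design` with `n_datasets` =
#'   `length(sizes) * replicates` and the total work-unit count
#'   `sum(sizes) * replicates * bootstraps`.
#' @examples
#' d <- subsample_design(c(50, 100, 200, 300, 400, 500, 1000, 1500, 2000,
#'                         2500, 3000), replicates = 10)
#' d$n_datasets  # 110
#' @export
subsample_design <- function(sizes, replicates = 10, bootstraps = 200) {
  stopifnot(length(sizes) >= 1L, all(diff(sizes) > 0), all(sizes >= 1),
            replicates >= 1, bootstraps >= 1)
  structure(list(sizes = as.integer(sizes),
                 replicates = as.integer(replicates),
                 bootstraps = as.integer(bootstraps),
                 n_datasets = length(sizes) * as.integer(replicates),
                 work_units = sum(sizes) * replicates * bootstraps),
            class = "subsample_design")
}

#' @export
print.subsample_design <- function(x, ...) {
  cat("Subsampling design:", length(x$sizes), "sizes x", x$replicates,
      "replicates =", x$n_datasets, "data sets;",
      x$bootstraps, "bootstraps each\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# R* consensus: modal rooted triplets assembled by the BUILD construction.
# ---------------------------------------------------------------------------

# Aho BUILD on a set of rooted triples. `trips` is a data.frame with columns
# a, b (the cherry) and out. Returns a Newick string (polytomies where the
# triples underdetermine the tree) or NULL if the triples are inconsistent.
build_from_triplets <- function(trips, taxa) {
  if (length(taxa) == 1L) return(taxa)
  if (length(taxa) == 2L) return(paste0("(", taxa[1L], ",", taxa[2L], ")"))
  idx <- trips$a %in% taxa & trips$b %in% taxa & trips$out %in% taxa
  sub <- trips[idx, , drop = FALSE]
  # union-find over taxa, joining the cherry of every applicable triple
  parent <- seq_along(taxa)
  names(parent) <- taxa
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(sub))) {
    ra <- find(match(sub$a[k], taxa))
    rb <- find(match(sub$b[k], taxa))
    if (ra != rb) parent[rb] <- ra
  }
  comp <- vapply(seq_along(taxa), find, integer(1))
  groups <- split(taxa, comp)
  if (length(groups) == 1L) return(NULL)  # inconsistent triples
  parts <- character(length(groups))
  for (i in seq_along(groups)) {
    p <- build_from_triplets(sub, groups[[i]])
    if (is.null(p)) return(NULL)
    parts[i] <- p
  }
  if (length(parts) == 1L) return(parts)
  paste0("(", paste(parts, collapse = ","), ")")
}

# Modal triplet per trio from a code table (genes x trios; codes 1..3 =
# outlier index within the trio, 0 = unresolved), optionally restricted to a
# subset of gene rows (with multiplicity). Returns a data.frame of accepted
# modal triples with their support margins; ties leave the trio out.
modal_triplets <- function(codes, trios, gene_idx = NULL) {
  if (!is.null(gene_idx)) codes <- codes[gene_idx, , drop = FALSE]
  out <- vector("list", ncol(codes))
  for (j in seq_len(ncol(codes))) {
    votes <- tabulate(codes[, j], nbins = 3L)
    top <- max(votes)
    if (top == 0L || sum(votes == top) > 1L) next
    w <- which.max(votes)
    trio <- trios[, j]
    pair <- trio[-w]
    out[[j]] <- data.frame(a = pair[1L], b = pair[2L], out = trio[w],
                           margin = top - max(votes[-w]),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(a = character(0), b = character(0),
                      out = character(0), margin = numeric(0))
  }
  res[order(-res$margin), , drop = FALSE]
}

# Greedy compatibility filter: accept modal triples in decreasing margin
# order, skipping any triple inconsistent (by BUILD) with those accepted.
greedy_compatible_build <- function(trips, taxa) {
  accepted <- trips[0, , drop = FALSE]
  for (k in seq_len(nrow(trips))) {
    cand <- rbind(accepted, trips[k, , drop = FALSE])
    if (!is.null(build_from_triplets(cand, taxa))) accepted <- cand
  }
  nwk <- build_from_triplets(accepted, taxa)
  parse_newick(paste0(nwk, ";"))
}

#' R* consensus species tree from rooted gene trees
#'
#' Computes the modal resolution of every taxon trio across the gene trees
#' and assembles the modal triples into a rooted tree with the standard
#' rooted-triple BUILD construction, inserting triples greedily in decreasing
#' order of support margin and skipping any triple incompatible with those
#' already accepted. Tied trios are left unconstrained, so the output may
#' contain polytomies. The estimator is statistically consistent under the
#' multispecies coalescent (no three-taxon anomaly exists), gene-order
#' invariant, and—unlike a democratic vote over whole topologies—recovers the
#' species tree even inside the anomaly zone.
#'
#' @param set A filtered `gene_tree_set` of rooted trees.
#' @param outgroup Optional outgroup taxon: each gene tree is rooted on it
#'   first, trios are taken over the ingroup, and the outgroup is re-attached
#'   at the root of the estimate.
#' @return A rooted `phylo`.
#' @export
rstar_species_tree <- function(set, outgroup = NULL) {
  stopifnot(inherits(set, "gene_tree_set"))
  if (!length(set$trees)) stop("empty gene-tree set")
  taxa <- set$taxa
  if (!is.null(outgroup)) {
    set <- gene_tree_set(lapply(set$trees, outgroup_root, outgroup = outgroup),
                         marker_class = set$marker_class, taxa = taxa)
    taxa <- setdiff(taxa, outgroup)
  }
  if (length(taxa) < 3L) stop("need at least three ingroup taxa")
  trios <- combn(sort(taxa), 3L)
  codes <- triplet_code_table(set, trios)
  trips <- modal_triplets(codes, trios)
  est <- greedy_compatible_build(trips, sort(taxa))
  if (!is.null(outgroup)) {
    est <- parse_newick(paste0("(", sub(";$", "", write_newick(
      drop_lengths(est))), ",", outgroup, ");"))
  }
  est
}

# ---------------------------------------------------------------------------
# Hypotheses on lineage-collapsed trees
# ---------------------------------------------------------------------------

#' Default alternative hypotheses for the sister group of the rheas
#'
#' Five mutually exclusive statements about the placement of the rhea lineage
#' among the nonostrich palaeognath lineages, each encoded as the set of
#' lineage-level clusters that must be present in the (binary) collapsed
#' species tree. Configurable: supply your own named list of cluster lists to
#' [run_subsample()].
#'
#' @param lineages Lineage names used by the synthetic palaeognath scenario.
#' @return A named list (`H1`..`H5`) of lists of character vectors.
#' @export
default_hypotheses <- function(lineages = c("ostrich", "rheas",
                                            "emu_cassowary", "kiwi",
                                            "tinamous")) {
  ec <- "emu_cassowary"
  list(
    H1 = list(c(ec, "kiwi"), c("rheas", ec, "kiwi")),      # rheas sister to EC+kiwi
    H2 = list(c(ec, "kiwi", "tinamous")),                  # rheas sister to rest
    H3 = list(c("rheas", "tinamous")),                     # rheas sister to moa+tinamous
    H4 = list(c("rheas", ec)),                             # rheas sister to EC
    H5 = list(c("rheas", "kiwi"))                          # rheas sister to kiwi
  )
}

#' Collapse a taxon-level tree to lineages
#'
#' Checks that every lineage with two or more member taxa is monophyletic in
#' the tree, then prunes each lineage to a single representative relabelled
#' with the lineage name.
#'
#' @param tree A rooted `phylo`.
#' @param lineage_map Named character vector taxon -> lineage.
#' @return A `phylo` on lineage names, or `NULL` if some lineage is not
#'   monophyletic.
#' @export
collapse_to_lineages <- function(tree, lineage_map) {
  lineage_map <- as_lineage_map(lineage_map)
  tips <- tree$tip.label
  lin <- lineage_map[tips]
  keys <- cluster_keys(tree)
  for (l in unique(lin)) {
    mem <- tips[lin == l]
    if (length(mem) < 2L) next
    if (length(mem) == length(tips)) next
    if (!cluster_key(mem) %in% keys) return(NULL)
  }
  keep <- tips[!duplicated(lin)]
  drop <- setdiff(tips, keep)
  out <- if (length(drop)) ape::drop.tip(tree, drop, collapse.singles = TRUE)
    else tree
  out$tip.label <- unname(lineage_map[out$tip.label])
  out
}

# Which hypothesis does a lineage tree satisfy? Returns its name or "other".
score_hypotheses <- function(lineage_tree, hypotheses) {
  if (is.null(lineage_tree)) return("other")
  keys <- c(cluster_keys(lineage_tree),
            cluster_key(lineage_tree$tip.label))
  for (h in names(hypotheses)) {
    need <- vapply(hypotheses[[h]], cluster_key, character(1))
    if (all(need %in% keys)) return(h)
  }
  "other"
}

#' Run a phylogenomic subsampling experiment
#'
#' For each subset size and replicate, loci are drawn with replacement from
#' the gene-tree set; within each replicate, each bootstrap redraws loci with
#' replacement (gene-wise bootstrap), estimates a species tree with the R*
#' triplet consensus, collapses it to lineages, and scores which hypothesis
#' it satisfies. Reported are per-replicate bootstrap support percentages and
#' their per-size means. Trees satisfying no listed hypothesis fall into the
#' residual category `"other"`. Deterministic given `seed`.
#'
#' @param set A filtered `gene_tree_set`.
#' @param design A `subsample_design`.
#' @param hypotheses Named list of hypotheses (lists of lineage clusters);
#'   see [default_hypotheses()].
#' @param lineage_map Named character vector taxon -> lineage.
#' @param outgroup Optional outgroup taxon passed to the R* estimator.
#' @param seed Integer seed.
#' @return An object of class `subsample_result`: list with `per_replicate`
#'   (data frame: `size`, `replicate`, one support-percent column per
#'   hypothesis plus `other`), `per_size` (means across replicates),
#'   `design`, and `work_units`.
#' @export
run_subsample <- function(set, design, hypotheses = default_hypotheses(),
                          lineage_map, outgroup = NULL, seed = 1L) {
  stopifnot(inherits(set, "gene_tree_set"),
            inherits(design, "subsample_design"), length(set$trees) >= 1L)
  lineage_map <- as_lineage_map(lineage_map)
  taxa <- set$taxa
  if (!is.null(outgroup)) {
    set <- gene_tree_set(lapply(set$trees, outgroup_root, outgroup = outgroup),
                         marker_class = set$marker_class, taxa = taxa)
    taxa <- setdiff(taxa, outgroup)
  }
  trios <- combn(sort(taxa), 3L)
  codes <- triplet_code_table(set, trios)
  n_genes <- nrow(codes)
  hyp_names <- c(names(hypotheses), "other")
  rows <- list()
  with_seed(seed, {
    for (s in design$sizes) {
      for (r in seq_len(design$replicates)) {
        replicate_idx <- sample.int(n_genes, s, replace = TRUE)
        hits <- setNames(numeric(length(hyp_names)), hyp_names)
        for (b in seq_len(design$bootstraps)) {
          boot_idx <- replicate_idx[sample.int(s, s, replace = TRUE)]
          trips <- modal_triplets(codes, trios, gene_idx = boot_idx)
          est <- greedy_compatible_build(trips, sort(taxa))
          lt <- collapse_to_lineages(est, lineage_map)
          h <- score_hypotheses(lt, hypotheses)
          hits[h] <- hits[h] + 1
        }
        rows[[length(rows) + 1L]] <- c(size = s, replicate = r,
                                       100 * hits / design$bootstraps)
      }
    }
  })
  per_rep <- as.data.frame(do.call(rbind, rows))
  per_size <- aggregate(per_rep[, hyp_names, drop = FALSE],
                        by = list(size = per_rep$size), FUN = mean)
  structure(list(per_replicate = per_rep, per_size = per_size,
                 design = design, hypotheses = hyp_names,
                 work_units = design$work_units, seed = seed),
            class = "subsample_result")
}

#' @export
print.subsample_result <- function(x, ...) {
  cat("Subsampling result:", nrow(x$per_replicate), "data sets;",
      x$work_units, "work units\n")
  cat("Mean bootstrap support (%) by size:\n")
  print(x$per_size, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Count replicates exceeding bootstrap-support thresholds
#'
#' For each subset size, hypothesis, and threshold, counts how many
#' replicates reached at least that bootstrap support percentage (the
#' heatmap summary of a subsampling experiment).
#'
#' @param results A `subsample_result`.
#' @param thresholds Percent thresholds (default `c(70, 90)`).
#' @return A data frame with columns `size`, `hypothesis`, `threshold`,
#'   `n_replicates`.
#' @export
threshold_heatmap_counts <- function(results, thresholds = c(70, 90)) {
  stopifnot(inherits(results, "subsample_result"))
  pr <- results$per_replicate
  hyps <- results$hypotheses
  out <- list()
  for (th in thresholds) {
    for (h in hyps) {
      cnt <- aggregate(pr[[h]] >= th, by = list(size = pr$size), FUN = sum)
      out[[length(out) + 1L]] <- data.frame(size = cnt$size, hypothesis = h,
                                            threshold = th,
                                            n_replicates = cnt$x,
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
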