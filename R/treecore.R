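#' @importFrom stats setNames rexp runif pbinom dbinom binom.test
#'   fisher.test sd reorder aggregate
#' @importFrom utils combn head read.delim write.table
NULL

# ---------------------------------------------------------------------------
# Rooted-tree data model.  Trees are ape "phylo" objects throughout; this file
# provides validated Newick I/O, cluster extraction, outgroup rooting,
# gene-tree set filtering, and rooted-topology enumeration.
# ---------------------------------------------------------------------------

#' Parse a single Newick string into a validated rooted tree
#'
#' Accepts one well-formed Newick statement (terminated by `;`), with optional
#' branch lengths after `:`, quoted labels, internal-node labels (read as plain
#' strings; mainstream ML tools write bootstrap support there), and comments in
#' square brackets (ignored). Polytomies are preserved; unbranched (degree-2)
#' internal nodes are collapsed, merging branch lengths by addition.
#'
#' @param text A length-1 character vector holding one Newick statement.
#' @return An object of class `phylo` (rooted; polytomies allowed).
#' @examples
#' tr <- parse_newick("((A:1,B:2)90:0.5,C:3);")
#' tr$node.label
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_syntax(text)
  text <- gsub("\\[[^]]*\\]", "", text)  # strip bracketed comments
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick string")
  if (inherits(tr, "multiPhylo")) {
    stop("expected a single Newick statement, found ", length(tr))
  }
  validate_rooted_tree(tr)
}

# Pre-scan for balanced parentheses/quotes so malformed input fails with the
# character offset instead of an opaque downstream error.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_quote <- FALSE
  in_comment <- FALSE
  quote_start <- NA_integer_
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (in_quote) {
      if (ch == "'") in_quote <- FALSE
      next
    }
    if (in_comment) {
      if (ch == "]") in_comment <- FALSE
      next
    }
    if (ch == "'") {
      in_quote <- TRUE
      quote_start <- i
    } else if (ch == "[") {
      in_comment <- TRUE
    } else if (ch == "(") {
      depth <- depth + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("malformed Newick: unmatched ')' at character ", i)
      }
    }
  }
  if (in_quote) stop("malformed Newick: unclosed quote opened at character ",
                     quote_start)
  if (depth > 0L) stop("malformed Newick: ", depth,
                       " unclosed '(' at end of input")
  if (!grepl(";\\s*$", text)) stop("malformed Newick: missing terminal ';'")
  invisible(TRUE)
}

validate_rooted_tree <- function(tr) {
  tr <- ape::collapse.singles(tr)
  labs <- tr$tip.label
  if (any(labs == "" | is.na(labs))) stop("empty or missing leaf label")
  if (anyDuplicated(labs)) {
    stop("duplicate leaf label(s): ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0, na.rm = TRUE)) {
    stop("negative branch length")
  }
  tr
}

#' Serialize a rooted tree to Newick
#'
#' Round-trips with [parse_newick()]: the re-parsed tree has identical clusters
#' and branch lengths to within the printed precision.
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits used for branch lengths.
#' @return A length-1 character vector (Newick, `;`-terminated).
#' @export
write_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = digits)
}

#' Nontrivial clusters of a rooted tree
#'
#' A cluster is the set of leaf labels descending from one internal edge.
#' Trivial clusters (singletons and the full leaf set) are excluded, so a star
#' tree has none and a rooted binary tree on n leaves has n - 2.
#'
#' @param tree A `phylo` object.
#' @return A list of character vectors, each sorted; one per internal edge.
#' @export
tree_clusters <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 3L || tree$Nnode < 2L) return(list())
  tr <- stats::reorder(tree, "postorder")
  nodes <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) nodes[[i]] <- tree$tip.label[i]
  parents <- tr$edge[, 1L]
  children <- tr$edge[, 2L]
  for (k in seq_along(parents)) {
    p <- parents[k]
    nodes[[p]] <- c(nodes[[p]], nodes[[children[k]]])
  }
  root <- n + 1L
  internal <- setdiff(unique(parents), root)
  out <- lapply(internal, function(v) sort(nodes[[v]]))
  out[lengths(out) >= 2L & lengths(out) < n]
}

#' Canonical string keys for clusters and topologies
#'
#' `cluster_key` joins a sorted taxon set with commas; `cluster_keys` applies
#' it to every nontrivial cluster of a tree; `topology_key` joins a tree's
#' sorted cluster keys with semicolons, so two rooted trees have equal keys
#' exactly when their RF cluster distance is zero.
#'
#' @param x Character vector of taxa.
#' @return A character scalar (or vector, for `cluster_keys`).
#' @export
cluster_key <- function(x) paste(sort(x), collapse = ",")

#' @rdname cluster_key
#' @param tree A `phylo` object.
#' @export
cluster_keys <- function(tree) {
  vapply(tree_clusters(tree), cluster_key, character(1))
}

#' @rdname cluster_key
#' @export
topology_key <- function(tree) paste(sort(cluster_keys(tree)), collapse = ";")

#' Root a tree on an outgroup taxon
#'
#' Re-roots so that the outgroup leaf attaches directly at the root; the
#' ingroup topology (its cluster set) is unchanged. Idempotent when the tree is
#' already rooted on the outgroup.
#'
#' @param tree A `phylo` object.
#' @param outgroup A leaf label present in the tree.
#' @return A rooted `phylo` with the outgroup as one child of the root.
#' @export
outgroup_root <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"), is.character(outgroup),
            length(outgroup) == 1L)
  if (!outgroup %in% tree$tip.label) {
    stop("outgroup '", outgroup, "' is not a leaf of the tree")
  }
  tip <- match(outgroup, tree$tip.label)
  root <- length(tree$tip.label) + 1L
  parent <- tree$edge[tree$edge[, 2L] == tip, 1L]
  n_root_children <- sum(tree$edge[, 1L] == root)
  if (parent == root && n_root_children == 2L) return(tree)
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

# ---------------------------------------------------------------------------
# Gene-tree sets
# ---------------------------------------------------------------------------

#' Construct a gene-tree set
#'
#' An ordered collection of rooted gene trees on a shared taxon universe,
#' tagged with a marker class (e.g. `"CNEE"`).
#'
#' @param trees A `multiPhylo` object or list of `phylo` objects.
#' @param marker_class Free-text tag for the marker class.
#' @param taxa Taxon universe; defaults to the union of tip labels.
#' @return An object of class `gene_tree_set`.
#' @export
gene_tree_set <- function(trees, marker_class = "", taxa = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  stopifnot(length(trees) >= 1L,
            all(vapply(trees, inherits, logical(1), "phylo")))
  class(trees) <- "multiPhylo"
  if (is.null(taxa)) {
    taxa <- sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))
  }
  structure(list(trees = trees, marker_class = marker_class,
                 taxa = sort(taxa)),
            class = "gene_tree_set")
}

#' @export
print.gene_tree_set <- function(x, ...) {
  cat("Gene-tree set", if (nzchar(x$marker_class))
    paste0("[", x$marker_class, "]") else "", "\n")
  cat("  trees:", length(x$trees), "\n")
  cat("  taxa: ", length(x$taxa), "(",
      paste(head(x$taxa, 6), collapse = ", "),
      if (length(x$taxa) > 6) ", ..." else "", ")\n")
  rep <- attr(x, "filter_report")
  if (!is.null(rep)) {
    cat("  filter: retained", rep$retained, "of", rep$input, "\n")
  }
  invisible(x)
}

#' Number of trees in a gene-tree set
#' @param x A `gene_tree_set`.
#' @return Integer count.
#' @export
n_trees <- function(x) length(x$trees)

#' Prune and filter a gene-tree set to a common taxon sample
#'
#' Drops the taxa in `drop_taxa` from every tree (suppressing the resulting
#' degree-2 nodes, merging branch lengths by addition), then retains only trees
#' whose leaf set contains all of `required_taxa`; retained trees are pruned to
#' exactly `required_taxa`. A report of retained/omitted counts is attached as
#' attribute `"filter_report"`.
#'
#' @param set A `gene_tree_set`.
#' @param drop_taxa Taxa to prune from all trees (may be `NULL`).
#' @param required_taxa Taxa that every retained tree must contain; defaults to
#'   all set taxa minus `drop_taxa`.
#' @return A filtered `gene_tree_set` (warning, not error, when empty).
#' @export
filter_gene_trees <- function(set, drop_taxa = NULL, required_taxa = NULL) {
  stopifnot(inherits(set, "gene_tree_set"))
  if (is.null(required_taxa)) required_taxa <- setdiff(set$taxa, drop_taxa)
  required_taxa <- sort(setdiff(required_taxa, drop_taxa))
  keep <- logical(length(set$trees))
  out <- vector("list", length(set$trees))
  for (i in seq_along(set$trees)) {
    tr <- set$trees[[i]]
    labs <- tr$tip.label
    if (!all(required_taxa %in% labs)) next
    extra <- setdiff(labs, required_taxa)
    if (length(extra)) {
      if (length(labs) - length(extra) < 2L) next
      tr <- ape::drop.tip(tr, extra, collapse.singles = TRUE)
    }
    keep[i] <- TRUE
    out[[i]] <- tr
  }
  retained <- out[keep]
  if (!length(retained)) {
    warning("no gene trees retained after filtering")
    res <- structure(list(trees = structure(list(), class = "multiPhylo"),
                          marker_class = set$marker_class,
                          taxa = required_taxa),
                     class = "gene_tree_set")
  } else {
    res <- gene_tree_set(retained, marker_class = set$marker_class,
                         taxa = required_taxa)
  }
  attr(res, "filter_report") <- list(input = length(set$trees),
                                     retained = sum(keep),
                                     omitted = sum(!keep))
  res
}

# ---------------------------------------------------------------------------
# Rooted-topology enumeration
# ---------------------------------------------------------------------------

#' Double factorial
#' @param n Non-negative integer.
#' @return `n!!` (defined as 1 for `n <= 0`).
#' @export
double_factorial <- function(n) {
  if (n <= 0) return(1)
  prod(seq(n, 1, by = -2))
}

# Recursive enumeration over nested-list tree representations.
enum_rep <- function(leaves) {
  if (length(leaves) == 1L) return(list(leaves))
  smaller <- enum_rep(leaves[-length(leaves)])
  leaf <- leaves[length(leaves)]
  out <- list()
  for (tr in smaller) out <- c(out, insert_all(tr, leaf))
  out
}

# All trees obtained by attaching `leaf` at every node (subtree) of `tr`.
insert_all <- function(tr, leaf) {
  out <- list(list(tr, leaf))
  if (is.list(tr)) {
    for (t2 in insert_all(tr[[1L]], leaf)) out <- c(out, list(list(t2, tr[[2L]])))
    for (t2 in insert_all(tr[[2L]], leaf)) out <- c(out, list(list(tr[[1L]], t2)))
  }
  out
}

rep_to_newick <- function(tr) {
  if (!is.list(tr)) return(tr)
  paste0("(", rep_to_newick(tr[[1L]]), ",", rep_to_newick(tr[[2L]]), ")")
}

#' Enumerate all rooted binary leaf-labeled topologies
#'
#' Free enumeration on n leaves yields `(2n - 3)!!` topologies. With
#' `constraint` (a subset of the leaves forced to be monophyletic), the
#' constrained clade's internal resolutions are enumerated independently and
#' grafted onto every arrangement of the remaining lineages, giving
#' `(2(n - k + 1) - 3)!! * (2k - 3)!!` topologies for a constrained subclade of
#' size k.
#'
#' @param leaves Character vector of leaf labels (2 to 9 free lineages).
#' @param constraint Optional character vector: a subset of `leaves` (size
#'   >= 2) constrained to be monophyletic.
#' @return A `multiPhylo` of distinct rooted binary topologies.
#' @examples
#' length(enumerate_rooted_topologies(paste0("L", 1:5)))  # 105
#' @export
enumerate_rooted_topologies <- function(leaves, constraint = NULL) {
  stopifnot(is.character(leaves), length(leaves) >= 2L,
            !anyDuplicated(leaves))
  guard <- function(k, what) {
    if (k > 9L) {
      stop(what, " has ", k, " lineages; enumeration would produce ",
           format(double_factorial(2 * k - 3), big.mark = ","),
           " topologies (guard limit is 9 lineages)")
    }
  }
  if (is.null(constraint)) {
    guard(length(leaves), "leaf set")
    strs <- vapply(enum_rep(leaves), rep_to_newick, character(1))
  } else {
    stopifnot(is.character(constraint), length(constraint) >= 2L,
              all(constraint %in% leaves))
    free <- setdiff(leaves, constraint)
    placeholder <- "__constrained_clade__"
    guard(length(free) + 1L, "free leaf set (with constrained clade)")
    guard(length(constraint), "constrained clade")
    outer <- vapply(enum_rep(c(free, placeholder)), rep_to_newick, character(1))
    inner <- vapply(enum_rep(constraint), rep_to_newick, character(1))
    strs <- as.vector(vapply(inner, function(sub) {
      sub("__constrained_clade__", sub, outer, fixed = TRUE)
    }, character(length(outer))))
  }
  trees <- ape::read.tree(text = paste0(strs, ";", collapse = "\n"))
  if (inherits(trees, "phylo")) trees <- structure(list(trees),
                                                   class = "multiPhylo")
  trees
}
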