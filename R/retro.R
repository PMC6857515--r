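# Retroelement presence/absence analytics: pattern classification against a
# species tree, insertion significance tests, minor-pattern symmetry, and a
# hemiplasy (ILS) insertion simulator.

#' Construct an insertion presence/absence matrix
#'
#' Loci x taxa matrix with states present (1), absent (0), or omitted (`NA`,
#' written as `?` on disk — e.g. when an alignment gap spans the insertion
#' site). Every locus must have at least one non-omitted state.
#'
#' @param x A matrix (or data frame) of 0/1/`NA`, rows = loci, columns = taxa.
#' @param metadata Optional per-locus data frame (e.g. element subtype,
#'   orientation), carried through for provenance.
#' @return An object of class `insertion_matrix`.
#' @export
insertion_matrix <- function(x, metadata = NULL) {
  x <- as.matrix(x)
  mode(x) <- "integer"
  if (!all(x %in% c(0L, 1L, NA_integer_))) {
    stop("states must be present (1), absent (0), or omitted (NA)")
  }
  if (is.null(colnames(x))) stop("taxon names required as column names")
  if (is.null(rownames(x))) rownames(x) <- paste0("locus", seq_len(nrow(x)))
  if (any(rowSums(!is.na(x)) == 0L)) {
    stop("every locus must have at least one non-omitted state")
  }
  if (!is.null(metadata)) stopifnot(nrow(metadata) == nrow(x))
  structure(x, metadata = metadata, class = c("insertion_matrix", "matrix"))
}

#' @export
print.insertion_matrix <- function(x, ...) {
  cat("Insertion matrix:", nrow(x), "loci x", ncol(x), "taxa\n")
  cat("  present:", sum(x == 1L, na.rm = TRUE),
      " absent:", sum(x == 0L, na.rm = TRUE),
      " omitted:", sum(is.na(x)), "\n")
  invisible(x)
}

#' Read / write insertion matrices as TSV
#'
#' Plain-text interchange format: tab-separated, header row of taxon names,
#' first column of locus identifiers, cells in `{1, 0, ?}`.
#'
#' @param path File path.
#' @return `read_insertion_matrix` returns an `insertion_matrix`.
#' @export
read_insertion_matrix <- function(path) {
  d <- read.delim(path, row.names = 1L, check.names = FALSE,
                  na.strings = "?", colClasses = "character")
  m <- as.matrix(d)
  mode(m) <- "integer"
  insertion_matrix(m)
}

#' @rdname read_insertion_matrix
#' @param x An `insertion_matrix`.
#' @export
write_insertion_matrix <- function(x, path) {
  stopifnot(inherits(x, "insertion_matrix"))
  out <- matrix(as.character(unclass(x)), nrow(x), ncol(x),
                dimnames = dimnames(x))
  out[is.na(out)] <- "?"
  df <- data.frame(locus = rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify insertion loci by phylogenetic information content
#'
#' Per-locus labels: `missing-lineage-omitted` when at least one lineage has
#' no scored (non-omitted) taxon; `symplesiomorphy` when the element is
#' present in every scored taxon; `autapomorphy` when present in exactly one;
#' `uninformative-absent` when present in none (possible once omission noise
#' masks the only carrier); otherwise `informative`, with the presence set as
#' the supported cluster.
#'
#' @param x An `insertion_matrix`.
#' @param lineage_map Named character vector taxon -> lineage (or two-column
#'   data frame `taxon`, `lineage`) covering all matrix taxa.
#' @return A data frame with columns `locus`, `class`, `cluster` (comma-joined
#'   presence set, `NA` unless informative), and list-columns `presence` and
#'   `scored` holding the taxa involved.
#' @export
classify_patterns <- function(x, lineage_map) {
  stopifnot(inherits(x, "insertion_matrix"))
  lineage_map <- as_lineage_map(lineage_map)
  taxa <- colnames(x)
  unmapped <- setdiff(taxa, names(lineage_map))
  if (length(unmapped)) {
    stop("taxa missing from lineage map: ", paste(unmapped, collapse = ", "))
  }
  lineages <- unique(lineage_map[taxa])
  res <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    row <- x[i, ]
    scored <- taxa[!is.na(row)]
    present <- taxa[!is.na(row) & row == 1L]
    scored_lin <- unique(lineage_map[scored])
    cls <- if (length(setdiff(lineages, scored_lin)) > 0L) {
      "missing-lineage-omitted"
    } else if (length(present) == length(scored)) {
      "symplesiomorphy"
    } else if (length(present) == 1L) {
      "autapomorphy"
    } else if (length(present) == 0L) {
      "uninformative-absent"
    } else {
      "informative"
    }
    res[[i]] <- list(class = cls,
                     cluster = if (cls == "informative")
                       cluster_key(present) else NA_character_,
                     presence = present, scored = scored)
  }
  out <- data.frame(locus = rownames(x),
                    class = vapply(res, `[[`, character(1), "class"),
                    cluster = vapply(res, `[[`, character(1), "cluster"),
                    stringsAsFactors = FALSE)
  out$presence <- lapply(res, `[[`, "presence")
  out$scored <- lapply(res, `[[`, "scored")
  out
}

#' Tally insertion support for the three resolutions of a lineage trio
#'
#' Counts informative loci whose presence set unites (at least one member
#' taxon of) exactly two of the three lineages while every scored member of
#' the third lacks the insertion. A locus contributes only if each trio
#' lineage has at least one scored (non-omitted) taxon; taxa outside the trio
#' do not affect the tally.
#'
#' @param classes Output of [classify_patterns()].
#' @param lineage_map Named character vector taxon -> lineage.
#' @param trio Character vector of three lineage names; the tested resolution
#'   is the pairing of the first two lineages to the exclusion of the third,
#'   whose count is reported as `n1`.
#' @return A list of class `pattern_tally` with `n1`, `n2`, `n3` (`n2` =
#'   first+third pairing, `n3` = second+third), the trio, and the tested
#'   resolution label.
#' @export
tally_trio_support <- function(classes, lineage_map, trio) {
  stopifnot(length(trio) == 3L)
  lineage_map <- as_lineage_map(lineage_map)
  counts <- c(0L, 0L, 0L)  # outlier = trio[3], trio[2], trio[1]
  inf <- classes[classes$class == "informative", , drop = FALSE]
  for (i in seq_len(nrow(inf))) {
    present <- inf$presence[[i]]
    scored <- inf$scored[[i]]
    pres_lin <- lineage_map[present]
    scor_lin <- lineage_map[scored]
    if (!all(trio %in% scor_lin)) next
    has <- trio %in% pres_lin
    # absence must hold for every scored member of the excluded lineage
    clean_absent <- vapply(trio, function(l) {
      mem <- scored[scor_lin == l]
      !any(mem %in% present)
    }, logical(1))
    if (has[1L] && has[2L] && clean_absent[3L]) {
      counts[1L] <- counts[1L] + 1L
    } else if (has[1L] && has[3L] && clean_absent[2L]) {
      counts[2L] <- counts[2L] + 1L
    } else if (has[2L] && has[3L] && clean_absent[1L]) {
      counts[3L] <- counts[3L] + 1L
    }
  }
  structure(list(n1 = counts[1L], n2 = counts[2L], n3 = counts[3L],
                 trio = trio,
                 tested = paste0("(", trio[1L], ",", trio[2L], ")|",
                                 trio[3L])),
            class = "pattern_tally")
}

#' @export
print.pattern_tally <- function(x, ...) {
  cat("Insertion pattern tally for trio:", paste(x$trio, collapse = ", "),
      "\n")
  cat("  tested resolution", x$tested, ": n1 =", x$n1, "\n")
  cat("  alternatives: n2 =", x$n2, ", n3 =", x$n3, "\n")
  invisible(x)
}

#' Insertion significance test for a lineage trio (tree test)
#'
#' Tests whether the insertions supporting one resolution of a lineage trio
#' (`n1`) exceed what a hard polytomy would produce, under which each of the
#' three resolutions is equally likely. The p-value is the exact trinomial
#' tail `P(X >= n1)` with `X ~ Binomial(n1 + n2 + n3, 1/3)`, accumulated in
#' log space.
#'
#' @param n1 Count supporting the tested resolution.
#' @param n2,n3 Counts supporting the two alternative resolutions.
#' @return An object of class `kksc_result`: list with `n1`, `n2`, `n3`,
#'   `p_value`. `p_value = 1` when all counts are zero.
#' @examples
#' kksc_tree_test(12, 1, 1)$p_value   # 8.2e-05
#' kksc_tree_test(12, 6, 5)$p_value   # 0.048
#' @export
kksc_tree_test <- function(n1, n2, n3) {
  if (any(c(n1, n2, n3) < 0)) stop("counts must be >= 0")
  total <- n1 + n2 + n3
  p <- if (total == 0L) 1 else binom_upper_tail_log(n1, total, 1 / 3)
  structure(list(n1 = n1, n2 = n2, n3 = n3, p_value = p),
            class = "kksc_result")
}

# P(X >= k) for X ~ Binomial(n, p), summed in log space for stability.
binom_upper_tail_log <- function(k, n, p) {
  if (k <= 0) return(1)
  lp <- dbinom(k:n, n, p, log = TRUE)
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))
}

#' @export
print.kksc_result <- function(x, ...) {
  cat("Insertion tree test: counts (", x$n1, ",", x$n2, ",", x$n3, ")\n")
  cat("  P(X >=", x$n1, "| trinomial polytomy null) =",
      format(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' Symmetry test for the two minor insertion patterns
#'
#' Under ILS the two conflicting (minor) resolutions of a trio are equally
#' probable, whereas ancestral hybridization skews them. Exact two-sided
#' binomial test of `n2` successes in `n2 + n3` trials against probability
#' 1/2.
#'
#' @param n2,n3 Minor-pattern counts; at least one must be positive.
#' @return The two-sided p-value.
#' @export
minor_symmetry_test <- function(n2, n3) {
  if (n2 < 0 || n3 < 0) stop("counts must be >= 0")
  if (n2 + n3 == 0) stop("no minor patterns to compare (both counts zero)")
  binom.test(n2, n2 + n3, p = 0.5, alternative = "two.sided")$p.value
}

#' Consistency of informative insertion patterns with a species tree
#'
#' Flags each informative locus as consistent when its presence set, restricted
#' to the locus's scored taxa, is a cluster (or a trivial subset) of the
#' species tree pruned to those taxa, and as conflicting otherwise. Reports
#' aggregate counts and per-edge supporting counts.
#'
#' @param classes Output of [classify_patterns()].
#' @param species_tree Rooted `phylo` on the matrix taxa.
#' @return A list of class `consistency_report`: `n_informative`,
#'   `n_consistent`, `n_conflicting`, `percent_consistent`, `per_edge`
#'   (data frame of species-tree clusters with supporting locus counts), and
#'   the per-locus logical vector `consistent`.
#' @export
species_tree_consistency_report <- function(classes, species_tree) {
  stopifnot(inherits(species_tree, "phylo"))
  inf <- classes[classes$class == "informative", , drop = FALSE]
  sp_keys <- cluster_keys(species_tree)
  support <- setNames(integer(length(sp_keys)), sp_keys)
  consistent <- logical(nrow(inf))
  for (i in seq_len(nrow(inf))) {
    present <- inf$presence[[i]]
    scored <- intersect(inf$scored[[i]], species_tree$tip.label)
    drop <- setdiff(species_tree$tip.label, scored)
    sub <- if (length(drop)) {
      if (length(scored) < 3L) NULL
      else ape::drop.tip(species_tree, drop, collapse.singles = TRUE)
    } else species_tree
    key <- cluster_key(intersect(present, scored))
    if (is.null(sub)) {
      consistent[i] <- TRUE  # too few scored taxa to conflict
      next
    }
    sub_keys <- cluster_keys(sub)
    if (length(intersect(present, scored)) < 2L ||
        length(intersect(present, scored)) >= length(scored)) {
      consistent[i] <- TRUE  # trivial after restriction
    } else if (key %in% sub_keys) {
      consistent[i] <- TRUE
      full_key <- cluster_key(present)
      if (full_key %in% names(support)) {
        support[full_key] <- support[full_key] + 1L
      }
    }
  }
  structure(list(
    n_informative = nrow(inf),
    n_consistent = sum(consistent),
    n_conflicting = sum(!consistent),
    percent_consistent = if (nrow(inf)) 100 * mean(consistent) else NA_real_,
    per_edge = data.frame(cluster = names(support),
                          n_supporting = as.integer(support),
                          stringsAsFactors = FALSE),
    consistent = consistent,
    loci = inf$locus
  ), class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat("Species-tree consistency of informative insertions\n")
  cat(sprintf("  %d of %d consistent (%.1f%%)\n", x$n_consistent,
              x$n_informative, x$percent_consistent))
  invisible(x)
}

#' Simulate a retroelement insertion matrix under the coalescent (hemiplasy)
#'
#' For each locus, simulates one gene tree under the multispecies coalescent
#' and drops a single insertion onto one branch chosen with probability
#' proportional to its mutational length (including a stem branch above the
#' gene-tree root of length `root_stem_mut`, which produces
#' symplesiomorphies). Presence is inherited by all leaves below the insertion
#' point, so discordant presence patterns arise purely through incomplete
#' lineage sorting of the insertion, never through homoplasy. Optional
#' omission noise independently rescores cells as omitted.
#'
#' @param model A `species_tree_model`.
#' @param n_loci Number of insertion loci.
#' @param seed Optional integer seed.
#' @param omission_rate Per-cell probability of rescoring as omitted.
#' @param root_stem_mut Mutational length of the stem above the gene-tree
#'   root; defaults to the model's `root_theta` (one coalescent unit in the
#'   root population).
#' @return An `insertion_matrix` with per-locus metadata column `edge_type`
#'   (`"stem"`, `"terminal"`, or `"internal"`).
#' @export
generate_insertion_dataset <- function(model, n_loci, seed = NULL,
                                       omission_rate = 0,
                                       root_stem_mut = NULL) {
  stopifnot(inherits(model, "species_tree_model"), n_loci >= 1L)
  if (is.null(root_stem_mut)) root_stem_mut <- model$root_theta
  taxa <- model$taxa
  gs <- simulate_gene_trees(model, n_loci, seed = seed)
  seed2 <- if (is.null(seed)) NULL else seed + 1L
  mat <- matrix(0L, n_loci, length(taxa),
                dimnames = list(paste0("locus", seq_len(n_loci)), taxa))
  edge_type <- character(n_loci)
  with_seed(seed2, {
    for (i in seq_len(n_loci)) {
      tr <- gs$trees[[i]]
      n_tip <- length(tr$tip.label)
      lens <- c(tr$edge.length, root_stem_mut)
      pick <- sample.int(length(lens), 1L, prob = lens)
      if (pick > nrow(tr$edge)) {
        present <- tr$tip.label
        edge_type[i] <- "stem"
      } else {
        child <- tr$edge[pick, 2L]
        present <- if (child <= n_tip) tr$tip.label[child] else
          ape::extract.clade(tr, child)$tip.label
        edge_type[i] <- if (child <= n_tip) "terminal" else "internal"
      }
      mat[i, present] <- 1L
      if (omission_rate > 0) {
        om <- runif(length(taxa)) < omission_rate
        # keep the locus scoreable: never omit every taxon
        if (all(om)) om[sample.int(length(taxa), 1L)] <- FALSE
        mat[i, om] <- NA_integer_
      }
    }
  })
  insertion_matrix(mat, metadata = data.frame(
    locus = rownames(mat), edge_type = edge_type, stringsAsFactors = FALSE))
}
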