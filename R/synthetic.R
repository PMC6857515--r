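# Synthetic study scenarios: a palaeognath-like 13-taxon species-tree model
# with two successive short internal branches inside the anomaly zone,
# gene-tree sets with controlled topology-estimation error, and insertion
# matrices. Everything is generated in code; no external data are required.

#' Reference marker-panel locus counts
#'
#' The three noncoding marker classes emulated by the synthetic scenario, at
#' full study scale: 12,676 conserved nonexonic elements, 5,016 introns, and
#' 3,158 ultraconserved elements (20,850 loci in total).
#'
#' @return A data frame with columns `class` and `n_loci`.
#' @export
palaeognath_panel <- function() {
  data.frame(class = c("CNEE", "intron", "UCE"),
             n_loci = c(12676L, 5016L, 3158L),
             stringsAsFactors = FALSE)
}

default_taxa <- function() {
  list(
    outgroup = "chicken",
    lineage_map = c(
      ostrich = "ostrich",
      rhea_greater = "rheas", rhea_lesser = "rheas",
      emu = "emu_cassowary", cassowary = "emu_cassowary",
      kiwi_little_spotted = "kiwi", kiwi_great_spotted = "kiwi",
      kiwi_okarito_brown = "kiwi",
      tinamou_chilean = "tinamous", tinamou_elegant = "tinamous",
      tinamou_thicket = "tinamous", tinamou_whitethroated = "tinamous")
  )
}

# Default internal branch lengths (coalescent units). The two successive
# short branches x (rheas+kiwi+emu/cassowary) and y (kiwi+emu/cassowary)
# satisfy y < a(x) twice over: 0.1 < a(0.12) = 0.253 and 0.05 < a(0.1) =
# 0.327, so the anomaly scan flags exactly those two parent-child pairs.
default_internal_tau <- function() {
  c(palaeognaths = 5, nonostrich = 0.12, rhea_kiwi_ec = 0.1, kiwi_ec = 0.05,
    emu_cassowary = 3, kiwi = 1, kiwi_spotted = 1, rheas = 3,
    tinamous = 3, tinamou_cd = 1, tinamou_tw = 1)
}

scenario_newick <- function(tau) {
  kiwi <- sprintf("((kiwi_little_spotted,kiwi_great_spotted)%s,kiwi_okarito_brown)%s",
                  lab("kiwi_spotted", tau), lab("kiwi", tau))
  ke <- sprintf("(%s,(emu,cassowary)%s)%s",
                kiwi, lab("emu_cassowary", tau), lab("kiwi_ec", tau))
  rke <- sprintf("((rhea_greater,rhea_lesser)%s,%s)%s",
                 lab("rheas", tau), ke, lab("rhea_kiwi_ec", tau))
  tin <- sprintf("((tinamou_chilean,tinamou_elegant)%s,(tinamou_thicket,tinamou_whitethroated)%s)%s",
                 lab("tinamou_cd", tau), lab("tinamou_tw", tau),
                 lab("tinamous", tau))
  sprintf("(chicken,(ostrich,(%s,%s)%s)%s);",
          tin, rke, lab("nonostrich", tau), lab("palaeognaths", tau))
}

lab <- function(name, tau) sprintf(":%g", tau[[name]])

#' Build a palaeognath-like synthetic study scenario
#'
#' Constructs a 12-ingroup-taxon (plus outgroup) species-tree model whose two
#' successive short internal branches satisfy the anomaly-zone condition
#' `y < a(x)`, together with marker-class profiles and insertion-locus
#' settings. The default branch lengths are this package's own choices
#' (verified at construction via [a_of_x()]), not estimates from any
#' particular data set.
#'
#' @param overrides Named list overriding documented keys: `internal_tau`
#'   (full or partial named vector, see `default_internal_tau()`),
#'   `theta_internal` (scalar theta for internal branches), `terminal_mut`
#'   (extra mutational length padding to the tips), `scale` (fraction of the
#'   full panel's locus counts), `error_rates` (named per-class NNI
#'   perturbation probabilities), `nni_k` (NNI moves per perturbed tree),
#'   `n_insertion_loci`, `omission_rate`, and `require_anomaly` (verify the
#'   two designed anomaly pairs; default TRUE when `internal_tau` is not
#'   overridden).
#' @param seed Integer seed stored in the scenario and used by the
#'   generators.
#' @return A list of class `scenario` with the parameter set (`spec`) and the
#'   `species_tree_model` (`model`).
#' @export
make_scenario <- function(overrides = list(), seed = 1L) {
  allowed <- c("internal_tau", "theta_internal", "terminal_mut", "scale",
               "error_rates", "nni_k", "n_insertion_loci", "omission_rate",
               "require_anomaly")
  bad <- setdiff(names(overrides), allowed)
  if (length(bad)) stop("unknown override key(s): ", paste(bad, collapse = ", "))
  tau <- default_internal_tau()
  if (!is.null(overrides$internal_tau)) {
    ov <- overrides$internal_tau
    stopifnot(!is.null(names(ov)), all(names(ov) %in% names(tau)))
    if (any(ov <= 0)) stop("internal tau must be > 0")
    tau[names(ov)] <- ov
  }
  theta_internal <- overrides$theta_internal %||% 0.002
  terminal_mut <- overrides$terminal_mut %||% 0.01
  scale <- overrides$scale %||% 0.1
  error_rates <- overrides$error_rates %||%
    c(CNEE = 0.3, intron = 0.1, UCE = 0.1)
  nni_k <- overrides$nni_k %||% 1L
  n_insertion_loci <- overrides$n_insertion_loci %||% 2000L
  omission_rate <- overrides$omission_rate %||% 0.007
  require_anomaly <- overrides$require_anomaly %||%
    is.null(overrides$internal_tau)

  tx <- default_taxa()
  tree <- parse_newick(scenario_newick(tau))
  model <- scenario_model(tree, theta_internal, terminal_mut)
  if (require_anomaly) {
    scan <- anomaly_scan(model)
    flagged <- scan[scan$anomalous, ]
    want_child <- c(
      cluster_key(names(tx$lineage_map)[tx$lineage_map %in%
        c("rheas", "kiwi", "emu_cassowary")]),
      cluster_key(names(tx$lineage_map)[tx$lineage_map %in%
        c("kiwi", "emu_cassowary")]))
    if (nrow(flagged) != 2L || !setequal(flagged$child_clade, want_child)) {
      stop("requested anomaly-zone placement violated: the two designed ",
           "short-branch pairs must satisfy y < a(x); check internal_tau")
    }
  }
  panel <- palaeognath_panel()
  profiles <- data.frame(
    class = panel$class,
    n_loci = pmax(1L, as.integer(round(panel$n_loci * scale))),
    error_rate = unname(error_rates[panel$class]),
    nni_k = nni_k,
    stringsAsFactors = FALSE)
  structure(list(
    spec = list(taxa = names(tx$lineage_map), outgroup = tx$outgroup,
                lineage_map = tx$lineage_map, internal_tau = tau,
                theta_internal = theta_internal,
                terminal_mut = terminal_mut, scale = scale,
                profiles = profiles, n_insertion_loci = n_insertion_loci,
                omission_rate = omission_rate, seed = as.integer(seed)),
    model = model), class = "scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Assemble the species_tree_model: internal muT = theta * tau; terminal muT
# chosen to make the mutational tree ultrametric (strict clock), with
# terminal theta fixed at 1.
scenario_model <- function(tree, theta_internal, terminal_mut) {
  n_tip <- length(tree$tip.label)
  internal <- tree$edge[, 2L] > n_tip
  muT <- numeric(nrow(tree$edge))
  muT[internal] <- theta_internal * tree$edge.length[internal]
  depth <- node_depths_num(tree, muT)
  height <- max(depth[tree$edge[internal, 2L]], depth[n_tip + 1L]) +
    terminal_mut
  term <- which(!internal)
  muT[term] <- height - depth[tree$edge[term, 1L]]
  tau <- tree$edge.length
  tau[!internal] <- muT[!internal]  # terminal theta = 1 convention
  species_tree_model(tree, tau = tau, muT = muT)
}

node_depths_num <- function(tree, edge_len) {
  tr <- reorder(tree)
  n_all <- length(tree$tip.label) + tree$Nnode
  dep <- numeric(n_all)
  m <- match(paste(tr$edge[, 1], tr$edge[, 2]),
             paste(tree$edge[, 1], tree$edge[, 2]))
  for (k in seq_len(nrow(tr$edge))) {
    dep[tr$edge[k, 2L]] <- dep[tr$edge[k, 1L]] + edge_len[m[k]]
  }
  dep
}

#' @export
print.scenario <- function(x, ...) {
  cat("Synthetic palaeognath-like scenario (seed", x$spec$seed, ")\n")
  cat("  taxa:", length(x$spec$taxa), "ingroup + outgroup",
      x$spec$outgroup, "\n")
  cat("  anomaly-zone branches: x =", x$spec$internal_tau[["rhea_kiwi_ec"]],
      ", y =", x$spec$internal_tau[["kiwi_ec"]], "\n")
  cat("  marker profiles:\n")
  print(x$spec$profiles, row.names = FALSE)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Gene-tree sets with estimation error
# ---------------------------------------------------------------------------

# One rooted NNI move: pick an internal edge (u, v) with v internal, swap a
# random child subtree of v with a random other child of u. Changes exactly
# one cluster (RF cluster distance 2 from the input).
rooted_nni <- function(tree, k = 1L) {
  for (rep in seq_len(k)) {
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    cand <- which(tree$edge[, 2L] > n_tip)
    if (!length(cand)) return(tree)
    e <- cand[sample.int(length(cand), 1L)]
    u <- tree$edge[e, 1L]
    v <- tree$edge[e, 2L]
    v_children <- which(tree$edge[, 1L] == v)
    siblings <- setdiff(which(tree$edge[, 1L] == u), e)
    if (!length(siblings) || !length(v_children)) next
    ce <- v_children[sample.int(length(v_children), 1L)]
    se <- siblings[sample.int(length(siblings), 1L)]
    tree$edge[ce, 1L] <- u
    tree$edge[se, 1L] <- v
    tree <- reorder(stats::reorder(tree, "postorder"))
  }
  tree
}

#' Generate gene-tree sets for each marker class
#'
#' Simulates each class's loci under the multispecies coalescent
#' ([simulate_gene_trees()]), then perturbs each tree with probability equal
#' to the class error rate by `nni_k` random rooted NNI moves — a minimal,
#' quantifiable stand-in for gene-tree estimation error (one NNI changes
#' exactly one cluster). A truth manifest recording the pre-error topology
#' and the perturbation flag is attached as attribute `"manifest"`.
#'
#' @param model A `species_tree_model`.
#' @param profiles Data frame with columns `class`, `n_loci`, `error_rate`,
#'   `nni_k` (as built by [make_scenario()]).
#' @param seed Integer seed.
#' @return Named list of `gene_tree_set` objects, one per class.
#' @export
generate_gene_tree_sets <- function(model, profiles, seed = 1L) {
  stopifnot(nrow(profiles) >= 1L)
  out <- list()
  for (i in seq_len(nrow(profiles))) {
    cls <- profiles$class[i]
    n <- profiles$n_loci[i]
    class_seed <- seed + i
    gs <- simulate_gene_trees(model, n, seed = class_seed)
    pre_keys <- vapply(gs$trees, topology_key, character(1))
    perturbed <- logical(n)
    with_seed(class_seed + 10000L, {
      perturbed <- runif(n) < profiles$error_rate[i]
      for (j in which(perturbed)) {
        gs$trees[[j]] <- rooted_nni(gs$trees[[j]], k = profiles$nni_k[i])
      }
    })
    gs$marker_class <- cls
    attr(gs, "manifest") <- data.frame(
      class = cls, locus = paste0(cls, "_", seq_len(n)),
      pre_error_topology = pre_keys, perturbed = perturbed,
      stringsAsFactors = FALSE)
    out[[cls]] <- gs
  }
  out
}

# ---------------------------------------------------------------------------
# Fixture bundle
# ---------------------------------------------------------------------------

#' Write a complete, reproducible fixture bundle to disk
#'
#' Generates every input needed to exercise the analysis end to end from a
#' scenario: the species tree in coalescent units (Newick), a mutational
#' branch-length sidecar TSV (clade key, muT), one multi-tree Newick file per
#' marker class, an insertion-matrix TSV, a taxon-to-lineage map TSV, and a
#' JSON manifest with the seed, parameters, and MD5 checksums. Byte-identical
#' for a given scenario seed.
#'
#' @param scenario A `scenario` from [make_scenario()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_fixture_bundle <- function(scenario, out_dir) {
  stopifnot(inherits(scenario, "scenario"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2L) != 0L) stop("directory not writable: ", out_dir)
  sp <- scenario$spec
  model <- scenario$model
  files <- character(0)

  f_tree <- file.path(out_dir, "species_tree_tau.nwk")
  writeLines(write_newick(model$tree), f_tree)
  files <- c(files, f_tree)

  f_mut <- file.path(out_dir, "species_tree_muT.tsv")
  edge_ids <- vapply(seq_len(nrow(model$tree$edge)), function(e)
    edge_clade_key(model$tree, e), character(1))
  write.table(data.frame(clade = edge_ids, muT = model$muT),
              f_mut, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f_mut)

  f_map <- file.path(out_dir, "lineage_map.tsv")
  write.table(data.frame(taxon = c(names(sp$lineage_map), sp$outgroup),
                         lineage = c(unname(sp$lineage_map), "outgroup")),
              f_map, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f_map)

  sets <- generate_gene_tree_sets(model, sp$profiles, seed = sp$seed)
  manifests <- list()
  for (cls in names(sets)) {
    f <- file.path(out_dir, paste0("gene_trees_", cls, ".nwk"))
    writeLines(vapply(sets[[cls]]$trees, write_newick, character(1)), f)
    files <- c(files, f)
    manifests[[cls]] <- attr(sets[[cls]], "manifest")
  }
  f_manifest_tsv <- file.path(out_dir, "gene_tree_truth.tsv")
  write.table(do.call(rbind, manifests), f_manifest_tsv, sep = "\t",
              quote = FALSE, row.names = FALSE)
  files <- c(files, f_manifest_tsv)

  ins <- generate_insertion_dataset(model, sp$n_insertion_loci,
                                    seed = sp$seed + 100L,
                                    omission_rate = sp$omission_rate)
  f_ins <- file.path(out_dir, "insertions.tsv")
  write_insertion_matrix(ins, f_ins)
  files <- c(files, f_ins)

  manifest <- list(
    seed = sp$seed,
    internal_tau = as.list(sp$internal_tau),
    theta_internal = sp$theta_internal,
    scale = sp$scale,
    profiles = sp$profiles,
    n_insertion_loci = sp$n_insertion_loci,
    omission_rate = sp$omission_rate,
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a multi-tree Newick file as a gene-tree set
#'
#' @param path Newick file, one tree per line (or any multi-tree Newick).
#' @param marker_class Marker-class tag for the set.
#' @return A `gene_tree_set`.
#' @export
read_gene_trees <- function(path, marker_class = "") {
  trees <- ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- structure(list(trees),
                                                   class = "multiPhylo")
  gene_tree_set(trees, marker_class = marker_class)
}

#' Read a taxon-to-lineage map from a two-column TSV
#'
#' @param path TSV with columns `taxon` and `lineage`.
#' @return A named character vector taxon -> lineage.
#' @export
read_lineage_map <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  as_lineage_map(d)
}
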