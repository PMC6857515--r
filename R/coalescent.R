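# Multispecies-coalescent analytics and simulation.
#
# Unit conventions (stated on every public surface):
#   tau — branch length in coalescent units (T / 4Ne); one lineage pair
#         coalesces at rate 1 per coalescent unit.
#   muT — branch length in expected substitutions (mutation rate x time).
#   theta — population mutation parameter; theta = muT / tau on internal
#         branches, fixed at 1 on terminal branches (inert when one allele
#         per species is simulated).

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Population parameter theta from mutational and coalescent branch lengths
#'
#' `theta = muT / tau`, the identity linking a branch's length in expected
#' substitutions (`muT`) to its length in coalescent units (`tau`).
#'
#' @param muT Mutational branch length(s), >= 0.
#' @param tau Coalescent branch length(s), > 0.
#' @return theta, vectorized over the inputs.
#' @export
theta_from_lengths <- function(muT, tau) {
  if (any(tau <= 0)) stop("tau must be > 0")
  if (any(muT < 0)) stop("muT must be >= 0")
  muT / tau
}

#' Expected rooted-triplet frequencies under the coalescent
#'
#' For a species-tree triplet whose internal branch has length `t` coalescent
#' units, the major (species-tree) resolution has probability
#' `1 - (2/3) exp(-t)` and each minor resolution `(1/3) exp(-t)`.
#'
#' @param t Internal branch length(s) in coalescent units, >= 0.
#' @return A data frame with columns `t`, `major`, `minor`.
#' @export
expected_triplet_probs <- function(t) {
  if (any(t < 0)) stop("t must be >= 0")
  data.frame(t = t, major = 1 - (2 / 3) * exp(-t),
             minor = (1 / 3) * exp(-t))
}

#' Invert the major-triplet frequency to a branch length
#'
#' Solves `p_major = 1 - (2/3) exp(-t)` for `t`, in coalescent units.
#'
#' @param p_major Major-triplet frequency, strictly between 1/3 and 1.
#' @return `t = -log(3 (1 - p_major) / 2)`.
#' @export
branch_length_from_major_freq <- function(p_major) {
  if (any(p_major <= 1 / 3) || any(p_major >= 1)) {
    stop("p_major must lie strictly between 1/3 and 1")
  }
  -log(3 * (1 - p_major) / 2)
}

#' Anomaly-zone boundary a(x)
#'
#' For a parent internal branch of length `x` coalescent units, anomalous gene
#' trees are possible on the descendant internal branch `y` exactly when
#' `y < a(x)`, with
#' `a(x) = log(2/3 + (3 exp(2x) - 2) / (18 (exp(3x) - exp(2x))))`.
#' The function is strictly decreasing, diverges as `x -> 0+`, and tends to
#' `log(2/3) < 0` (no anomaly zone possible) for large `x`; its single zero is
#' at `x ~ 0.2655`.
#'
#' @param x Parent branch length(s) in coalescent units, > 0.
#' @return `a(x)`, vectorized; may be negative.
#' @export
a_of_x <- function(x) {
  if (any(x <= 0)) stop("x must be > 0 (a(x) is singular at 0)")
  log(2 / 3 + (3 * exp(2 * x) - 2) / (18 * (exp(3 * x) - exp(2 * x))))
}

# ---------------------------------------------------------------------------
# Species-tree model
# ---------------------------------------------------------------------------

#' Construct a species-tree model with coalescent and mutational lengths
#'
#' Wraps a rooted species-tree topology with per-branch coalescent lengths
#' `tau`, mutational lengths `muT`, and population parameters `theta`,
#' enforcing `theta = muT / tau` on internal branches. Terminal-branch theta
#' is fixed at the conventional constant 1 (inert for one-allele-per-species
#' simulation). Supply any of `muT`/`theta`; missing quantities are derived
#' from the identity, and `theta = 1` everywhere (so `muT = tau`) when neither
#' is given.
#'
#' @param tree A rooted `phylo`; branch lengths, if present, are taken as
#'   `tau` unless `tau` is supplied.
#' @param tau Per-edge coalescent lengths (ordered as `tree$edge`).
#' @param muT Per-edge mutational lengths, or a single value recycled.
#' @param theta Per-edge theta for internal branches, or a single value.
#' @param root_theta Theta governing coalescence in the (infinite) root
#'   branch; default 1.
#' @param tol Relative tolerance for the `theta = muT / tau` consistency
#'   check when both `muT` and `theta` are supplied.
#' @return An object of class `species_tree_model`.
#' @export
species_tree_model <- function(tree, tau = NULL, muT = NULL, theta = NULL,
                               root_theta = 1, tol = 1e-8) {
  stopifnot(inherits(tree, "phylo"))
  ne <- nrow(tree$edge)
  if (is.null(tau)) tau <- tree$edge.length
  if (is.null(tau)) stop("no tau: supply branch lengths in coalescent units")
  stopifnot(length(tau) == ne)
  n_tip <- length(tree$tip.label)
  internal <- tree$edge[, 2L] > n_tip
  if (any(!is.finite(tau[internal])) || any(tau[internal] <= 0)) {
    bad <- which(internal & (!is.finite(tau) | tau <= 0))[1L]
    stop("internal edge above clade {",
         edge_clade_key(tree, bad), "} lacks a positive tau")
  }
  if (!is.null(theta) && length(theta) == 1L) theta <- rep(theta, ne)
  if (!is.null(muT) && length(muT) == 1L) muT <- rep(muT, ne)
  if (is.null(muT) && is.null(theta)) theta <- rep(1, ne)
  if (is.null(muT)) {
    muT <- theta * tau
  } else if (is.null(theta)) {
    theta <- muT / tau
  } else {
    dev <- abs(theta[internal] - muT[internal] / tau[internal])
    rel <- dev / pmax(abs(theta[internal]), 1e-12)
    if (any(rel > tol)) {
      stop("inconsistent branch parameters: theta = muT / tau must hold ",
           "on internal branches")
    }
  }
  theta[!internal] <- 1  # terminal-branch convention
  if (any(muT[internal] <= 0)) {
    stop("internal muT must be > 0")
  }
  tr <- tree
  tr$edge.length <- tau
  structure(list(tree = tr, tau = tau, muT = muT, theta = theta,
                 root_theta = root_theta, taxa = sort(tree$tip.label)),
            class = "species_tree_model")
}

edge_clade_key <- function(tree, edge_idx) {
  child <- tree$edge[edge_idx, 2L]
  n <- length(tree$tip.label)
  if (child <= n) return(tree$tip.label[child])
  cluster_key(ape::extract.clade(tree, child)$tip.label)
}

#' @export
print.species_tree_model <- function(x, ...) {
  n_tip <- length(x$tree$tip.label)
  internal <- x$tree$edge[, 2L] > n_tip
  cat("Species-tree model on", n_tip, "taxa\n")
  cat("  internal tau range: [",
      signif(min(x$tau[internal]), 4), ",",
      signif(max(x$tau[internal]), 4), "]\n")
  cat("  internal theta range: [",
      signif(min(x$theta[internal]), 4), ",",
      signif(max(x$theta[internal]), 4), "]\n")
  cat("  topology:", write_newick(drop_lengths(x$tree)), "\n")
  invisible(x)
}

drop_lengths <- function(tree) {
  tree$edge.length <- NULL
  tree
}

#' Scan a species-tree model for anomaly-zone branch pairs
#'
#' Evaluates `y < a(x)` for every adjacent pair of internal edges (parent
#' branch `x`, descendant internal branch `y`), the condition under which
#' anomalous gene trees are expected.
#'
#' @param model A `species_tree_model` (or a rooted `phylo` whose branch
#'   lengths are coalescent units).
#' @return A data frame with one row per parent-child internal-edge pair:
#'   `parent_clade`, `child_clade` (comma-joined taxa), `x`, `y`, `a_x`, and
#'   logical `anomalous`.
#' @seealso [anomaly_scan_replicates()] for batch evaluation over bootstrap
#'   species trees.
#' @export
anomaly_scan <- function(model) {
  if (inherits(model, "phylo")) model <- species_tree_model(model)
  stopifnot(inherits(model, "species_tree_model"))
  tree <- model$tree
  n_tip <- length(tree$tip.label)
  edge <- tree$edge
  internal_edge <- which(edge[, 2L] > n_tip)
  if (!length(internal_edge)) {
    return(data.frame(parent_clade = character(0), child_clade = character(0),
                      x = numeric(0), y = numeric(0), a_x = numeric(0),
                      anomalous = logical(0)))
  }
  rows <- list()
  for (e in internal_edge) {
    v <- edge[e, 2L]
    children <- internal_edge[edge[internal_edge, 1L] == v]
    for (f in children) {
      x <- model$tau[e]
      y <- model$tau[f]
      ax <- a_of_x(x)
      rows[[length(rows) + 1L]] <- data.frame(
        parent_clade = edge_clade_key(tree, e),
        child_clade = edge_clade_key(tree, f),
        x = x, y = y, a_x = ax, anomalous = y < ax,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Anomaly-zone scan over bootstrap replicate species trees
#'
#' Runs [anomaly_scan()] on each replicate and reports, for every
#' parent/child clade pair observed, the fraction of replicates in which the
#' pair was flagged as anomalous.
#'
#' @param models A list of `species_tree_model` objects or rooted `phylo`
#'   trees with coalescent-unit branch lengths.
#' @return A data frame with `parent_clade`, `child_clade`, `n_replicates`
#'   (replicates containing the pair), and `frac_anomalous`.
#' @export
anomaly_scan_replicates <- function(models) {
  stopifnot(length(models) >= 1L)
  scans <- lapply(models, anomaly_scan)
  all <- do.call(rbind, scans)
  key <- paste(all$parent_clade, all$child_clade, sep = " -> ")
  agg <- lapply(split(all, key), function(d) {
    data.frame(parent_clade = d$parent_clade[1L],
               child_clade = d$child_clade[1L],
               n_replicates = nrow(d),
               frac_anomalous = mean(d$anomalous),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(-out$frac_anomalous), ]
}

# ---------------------------------------------------------------------------
# MSC gene-tree simulation
# ---------------------------------------------------------------------------

#' Simulate gene trees under the multispecies coalescent
#'
#' Standard MSC simulation with one sampled allele per extant species. Within
#' each species-tree branch of length `tau` coalescent units, every pair of
#' lineages coalesces at rate 1 per coalescent unit; surviving lineages are
#' passed to the ancestral branch, and the root branch is extended until
#' complete coalescence (using `root_theta`). Gene-tree node heights are
#' emitted in mutational units by scaling each within-branch waiting time by
#' that branch's theta (`muT = theta * tau`).
#'
#' @param model A `species_tree_model`.
#' @param n Number of gene trees, >= 1.
#' @param seed Optional integer seed; a given seed yields an identical tree
#'   list.
#' @return A `gene_tree_set` of `n` rooted binary trees on the model's taxa.
#' @export
simulate_gene_trees <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "species_tree_model"), n >= 1L)
  tree <- reorder(model$tree, "postorder")
  tau <- model$tau[match_edges(model$tree, tree)]
  theta <- model$theta[match_edges(model$tree, tree)]
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  # heights of species-tree nodes in mutational units
  h_mut <- species_node_heights(tree, model)
  # per-node: index of the edge above it (in `tree` postorder edge order)
  edge_above <- integer(n_tip + tree$Nnode)
  edge_above[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  children_of <- split(tree$edge[, 2L], tree$edge[, 1L])
  node_order <- unique(tree$edge[, 1L])  # postorder: children before parents
  strs <- character(n)
  with_seed(seed, {
    for (g in seq_len(n)) {
      lin_str <- as.list(tree$tip.label)
      lin_h <- as.list(h_mut[seq_len(n_tip)])
      pools <- vector("list", n_tip + tree$Nnode)
      for (i in seq_len(n_tip)) pools[[i]] <- i
      lid <- n_tip
      for (v in node_order) {
        pool <- unlist(pools[children_of[[as.character(v)]]])
        if (v == root) {
          tau_len <- Inf
          th <- model$root_theta
        } else {
          e <- edge_above[v]
          tau_len <- tau[e]
          th <- theta[e]
        }
        elapsed <- 0
        k <- length(pool)
        while (k >= 2L) {
          dt <- rexp(1L, rate = k * (k - 1L) / 2)
          if (elapsed + dt > tau_len) break
          elapsed <- elapsed + dt
          pick <- sample.int(k, 2L)
          i <- pool[pick[1L]]
          j <- pool[pick[2L]]
          h <- h_mut[v] + elapsed * th
          lid <- lid + 1L
          lin_str[[lid]] <- paste0("(", lin_str[[i]], ":",
                                   format(h - lin_h[[i]], digits = 10),
                                   ",", lin_str[[j]], ":",
                                   format(h - lin_h[[j]], digits = 10), ")")
          lin_h[[lid]] <- h
          pool <- c(pool[-pick], lid)
          k <- k - 1L
        }
        pools[[v]] <- pool
      }
      strs[g] <- paste0(lin_str[[pools[[root]][1L]]], ";")
    }
  })
  trees <- ape::read.tree(text = paste(strs, collapse = "\n"))
  if (inherits(trees, "phylo")) trees <- structure(list(trees),
                                                   class = "multiPhylo")
  gene_tree_set(trees, marker_class = "simulated", taxa = model$taxa)
}

# Map edges of `orig` onto the edge order of a reordered copy.
match_edges <- function(orig, reord) {
  a <- paste(orig$edge[, 1L], orig$edge[, 2L])
  b <- paste(reord$edge[, 1L], reord$edge[, 2L])
  match(b, a)
}

# Node heights in mutational units, measured up from the tips. Tips sit at
# height zero (strict-clock, ultrametric convention); internal-node heights
# accumulate muT along the path to any descendant tip (the maximum is taken
# if the muT lengths are not exactly ultrametric).
species_node_heights <- function(tree_post, model) {
  muT <- model$muT[match_edges(model$tree, tree_post)]
  n_tip <- length(tree_post$tip.label)
  h <- numeric(n_tip + tree_post$Nnode)
  for (k in seq_len(nrow(tree_post$edge))) {  # postorder: child done first
    p <- tree_post$edge[k, 1L]
    c <- tree_post$edge[k, 2L]
    h[p] <- max(h[p], h[c] + muT[k])
  }
  h
}

# ---------------------------------------------------------------------------
# Heterogeneity ratio and triplet goodness of fit
# ---------------------------------------------------------------------------

#' Fraction of gene-tree heterogeneity attributable to the coalescent
#'
#' Simulates `n_sim` gene trees from the species-tree model and returns the
#' ratio of the mean simulated gene-tree-to-species-tree distance to the mean
#' distance for the empirical gene trees. A ratio near 1 means coalescent
#' variation alone accounts for the observed heterogeneity; below 1, the
#' empirical trees are more heterogeneous than the coalescent predicts (e.g.
#' through gene-tree estimation error).
#'
#' @param empirical A filtered `gene_tree_set` on the model's taxa.
#' @param model A `species_tree_model`.
#' @param n_sim Number of simulated gene trees.
#' @param metric `"rf"` (RF cluster distance) or `"matching"` (matching
#'   cluster distance).
#' @param seed Optional integer seed for the simulation.
#' @return An object of class `heterogeneity_ratio`: list with `ratio`
#'   (`NA` with a note when the empirical mean distance is zero), `mean_sim`,
#'   `mean_emp`, 95% confidence intervals for both means, `metric`, `n_sim`,
#'   and `seed`.
#' @export
heterogeneity_ratio <- function(empirical, model, n_sim = 10000,
                                metric = c("rf", "matching"), seed = NULL) {
  stopifnot(inherits(empirical, "gene_tree_set"),
            inherits(model, "species_tree_model"))
  metric <- match.arg(metric)
  dist_fun <- if (metric == "rf") rf_cluster_distance else
    matching_cluster_distance
  sp <- model$tree
  sim <- simulate_gene_trees(model, n_sim, seed = seed)
  d_sim <- vapply(sim$trees, dist_fun, numeric(1), t2 = sp)
  d_emp <- vapply(empirical$trees, dist_fun, numeric(1), t2 = sp)
  ci <- function(d) {
    m <- mean(d)
    se <- sd(d) / sqrt(length(d))
    c(m - 1.96 * se, m + 1.96 * se)
  }
  mean_emp <- mean(d_emp)
  ratio <- if (mean_emp == 0) NA_real_ else mean(d_sim) / mean_emp
  structure(list(ratio = ratio,
                 undefined = mean_emp == 0,
                 mean_sim = mean(d_sim), ci_sim = ci(d_sim),
                 mean_emp = mean_emp, ci_emp = ci(d_emp),
                 metric = metric, n_sim = n_sim, seed = seed),
            class = "heterogeneity_ratio")
}

#' @export
print.heterogeneity_ratio <- function(x, ...) {
  cat("Gene-tree heterogeneity ratio (", x$metric, " distance)\n", sep = "")
  cat(sprintf("  mean simulated distance: %.3f [%.3f, %.3f]\n",
              x$mean_sim, x$ci_sim[1], x$ci_sim[2]))
  cat(sprintf("  mean empirical distance: %.3f [%.3f, %.3f]\n",
              x$mean_emp, x$ci_emp[1], x$ci_emp[2]))
  if (x$undefined) {
    cat("  ratio: undefined (empirical mean distance is zero)\n")
  } else {
    cat(sprintf("  ratio (simulated / empirical): %.3f\n", x$ratio))
  }
  invisible(x)
}

# Round expected counts to integers preserving the total (largest-remainder).
largest_remainder <- function(probs, total) {
  raw <- probs * total
  base <- floor(raw)
  short <- total - sum(base)
  if (short > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Goodness of fit of observed triplet counts to coalescent expectations
#'
#' Fisher's exact test comparing the observed counts of the three triplet
#' resolutions to the counts expected under the coalescent for an internal
#' branch of `t` coalescent units (expected counts are the expected
#' probabilities times the observed total, rounded by largest remainder to
#' preserve the total). The first observed count must correspond to the major
#' (species-tree) resolution. Exact 2x3 network computation is used up to
#' `max_exact` total counts; beyond that, a Monte Carlo approximation with
#' `B` replicates is used.
#'
#' @param observed A `triplet_counts` object (major first is arranged
#'   automatically) or a numeric vector of three counts, major first.
#' @param t Internal branch length in coalescent units, >= 0.
#' @param max_exact Size guard for the exact computation (per table).
#' @param B Monte Carlo replicates used above the guard.
#' @return The p-value.
#' @export
triplet_gof <- function(observed, t, max_exact = 1000, B = 10000) {
  if (inherits(observed, "triplet_counts")) {
    cnt <- observed$counts
    observed <- c(max(cnt), cnt[-which.max(cnt)])
  }
  stopifnot(length(observed) == 3L, all(observed >= 0))
  if (t < 0) stop("t must be >= 0")
  total <- sum(observed)
  if (total == 0) stop("zero total triplet count")
  ex <- expected_triplet_probs(t)
  expected <- largest_remainder(c(ex$major, ex$minor, ex$minor), total)
  tbl <- rbind(observed = as.integer(observed), expected = expected)
  keep <- colSums(tbl) > 0
  tbl <- tbl[, keep, drop = FALSE]
  if (ncol(tbl) < 2L) return(1)
  if (sum(tbl) <= 2 * max_exact) {
    fisher.test(tbl)$p.value
  } else {
    fisher.test(tbl, simulate.p.value = TRUE, B = B)$p.value
  }
}
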