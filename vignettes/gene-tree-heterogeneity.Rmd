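---
title: "Quantifying gene-tree heterogeneity and the anomaly zone with coalhet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gene-tree heterogeneity and the anomaly zone with coalhet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalhet)
```

## The problem

When internal branches of a species tree are short relative to the effective
population size, ancestral polymorphism fails to sort between successive
speciations (incomplete lineage sorting, ILS) and individual gene genealogies
conflict with the species tree and with each other. In the extreme — the
*anomaly zone* — the single most probable gene-tree topology is not the
species-tree topology, so any method that takes a democratic vote over whole
gene-tree topologies is positively misleading. Rapid ancient radiations such
as that of the palaeognath birds (ostrich, rheas, kiwi, emu and cassowary,
tinamous) are prime candidates for this regime.

`coalhet` implements the computational core of such an analysis:

* rooted-tree cluster distances (Robinson–Foulds and matching cluster) and
  gene-tree topology distributions;
* per-clade support statistics (gene support frequency, internode certainty
  "all");
* rooted-triplet tallies with their analytic coalescent expectations;
* anomaly-zone detection from coalescent branch lengths;
* multispecies-coalescent (MSC) gene-tree simulation and heterogeneity
  ratios;
* retroelement presence/absence pattern analytics with insertion
  significance tests and a hemiplasy simulator;
* an R\* rooted-triplet consensus species-tree estimator and phylogenomic
  subsampling;
* a synthetic-data generator emulating a palaeognath-like radiation, so the
  whole pipeline runs without any external data.

## Units and the coalescent model

Throughout, branch lengths come in two currencies. Coalescent lengths
$\tau$ are dimensionless and govern gene-tree topology probabilities: within
a branch of length $\tau$, each pair of lineages coalesces at rate 1 per
coalescent unit (the convention is $\tau = T/4N_e$). Mutational lengths
$\mu T$ are expected substitutions. They are linked per branch by the
population parameter
$$\Theta = \mu T / \tau,$$
exposed as `theta_from_lengths()` and enforced by the
`species_tree_model()` constructor. Terminal-branch $\Theta$ is fixed at the
conventional constant 1; with one sampled allele per species no coalescence
can occur in a terminal branch, so the value is inert. Coalescence above the
root uses `root_theta` (default 1) on an indefinitely extended root branch —
the standard convention of coalescent simulators.

For a species-tree triplet whose internal branch is $t$ coalescent units,
the concordant ("major") rooted-triplet topology has probability
$1 - \tfrac{2}{3}e^{-t}$ and each discordant ("minor") topology
$\tfrac{1}{3}e^{-t}$ (`expected_triplet_probs()`, inverted by
`branch_length_from_major_freq()`). Anomalous gene trees arise on a
descendant internal branch $y$ below a parent internal branch $x$ exactly
when $y < a(x)$ with
$$a(x) = \log\!\left[\tfrac{2}{3} +
  \frac{3e^{2x} - 2}{18\,(e^{3x} - e^{2x})}\right],$$
computed by `a_of_x()`: it is strictly decreasing, diverges as
$x \to 0^+$, crosses zero at $x \approx 0.2655$, and tends to
$\log(2/3) < 0$, so no anomaly zone exists below a parent branch longer than
about 0.2655 coalescent units. `anomaly_scan()` evaluates this condition for
every parent–child pair of internal edges; `anomaly_scan_replicates()`
summarizes the flag fraction over bootstrap species trees.

```{r anomaly}
a_of_x(c(0.05, 0.1, 0.2655, 1))
model <- species_tree_model(parse_newick(
  "((((A:1,B:1):0.02,C:2):0.05,D:3):3,E:6);"))
anomaly_scan(model)[, c("child_clade", "x", "y", "a_x", "anomalous")]
```

## Simulation and the heterogeneity ratio

`simulate_gene_trees()` is a standard MSC simulator with one allele per
species: lineages entering a branch coalesce pairwise at rate 1 per
coalescent unit, survivors pass to the ancestral branch, and node heights
are emitted in mutational units by scaling each waiting time by the branch's
$\Theta$. Gene-tree topologies depend only on the $\tau$ lengths, so the
$\tau = T/4N_e$ convention does not affect topological results. The
simulator is exercised against the analytic triplet expectations (within
three binomial standard errors at $n = 10{,}000$) in the test suite.

`heterogeneity_ratio()` asks how much of the observed gene-tree
heterogeneity the coalescent alone explains: it is the mean simulated
gene-tree-to-species-tree distance divided by the mean empirical distance
(RF or matching cluster metric). Trees drawn from the generating model give
a ratio near 1; gene-tree estimation error inflates the empirical mean and
pushes the ratio below 1. When the empirical mean distance is zero the
ratio is reported as undefined rather than infinite.

`triplet_gof()` compares observed triplet counts to their coalescent
expectation with Fisher's exact test on a 2×3 table. Expected counts are the
expected probabilities times the observed total, rounded by the
largest-remainder method so the total is preserved; this construction is a
documented choice (the rounding rule behind the printed comparison it
mirrors is not stated anywhere authoritative), and exact p-values may shift
slightly under a different rounding rule. Above 2,000 total counts the
p-value is Monte Carlo approximated.

## Support statistics

Gene support frequency (`gene_support_frequency()`) is simply the percent
of gene trees containing a clade. Internode certainty "all"
(`internode_certainty_all()`) scores each species-tree cluster against all
observed clusters that conflict with it at relative frequency at least
`freq_threshold` (default 0.05, exposed because the statistic's published
definition considers "commonly occurring" conflicts without fixing a
universal cutoff): the selected frequencies are renormalized and scored as
$1 + \sum_i p_i \log_n p_i$, which is 1 with no admissible conflict, 0 for
an even two-way split, and is negated when the focal cluster is rarer than
its best-supported conflict.

Rooted-triplet analytics come in two granularities. `decompose_triplet()`
restricts one tree to one trio (returning the taxon outside the cherry, or
"unresolved" across a polytomy). `lineage_triplet_tally()` aggregates to
lineage trios: per gene it evaluates every cross-lineage trio, takes the
modal resolution, and omits the gene when the mode is tied — the standard
guard against pseudo-replicating non-independent trios within a gene.
Unresolved trios do not vote and genes with no resolved trio are reported
separately rather than entering the denominator.

## Retroelement presence/absence analytics

A retroelement insertion is a near-homoplasy-free character: presence in a
set of taxa marks the gene-tree branch on which the element inserted.
Conflict between an insertion's presence set and the species tree therefore
signals *hemiplasy* — ILS of a single insertion — rather than convergent
insertion. `classify_patterns()` sorts loci into informative patterns,
symplesiomorphies, autapomorphies, and loci unscoreable for a whole lineage;
a fifth label (`uninformative-absent`) covers the corner case of a locus
whose only carrier was rescored as omitted. A lineage counts as present at a
locus when any scored member carries the insertion, and a locus enters a
trio tally only when all three lineages have at least one scored member.

`kksc_tree_test()` is the insertion significance test for a lineage trio in
its trinomial-tail form: under a hard-polytomy null all three resolutions
are equally likely, so the p-value is $P(X \ge n_1)$ with
$X \sim \mathrm{Binomial}(n_1+n_2+n_3, 1/3)$, accumulated in log space.
The cited test family also includes polytomy and hybridization variants;
the count-based interface here is deliberately minimal so those can be added
later. `minor_symmetry_test()` is the exact two-sided binomial test of the
two minor counts against probability one half: symmetry is the ILS
signature, asymmetry suggests introgression.

```{r kksc}
kksc_tree_test(12, 6, 5)
minor_symmetry_test(6, 5)
```

`generate_insertion_dataset()` simulates hemiplasy mechanically: one MSC
gene tree per locus, one insertion dropped on a branch chosen with
probability proportional to its mutational length (a stem above the root
yields symplesiomorphies), presence inherited by all descendant leaves.
Because each locus carries exactly one insertion event, any conflict in the
output is pure hemiplasy by construction.

## R* consensus and phylogenomic subsampling

`rstar_species_tree()` estimates the species tree from the modal resolution
of every taxon trio, assembled by the rooted-triple BUILD construction with
greedy insertion in decreasing order of support margin; tied trios leave the
corresponding node unconstrained (a polytomy). Because no three-taxon
anomaly exists under the MSC, the modal triplet is always the species-tree
triplet in expectation, making the estimator statistically consistent even
inside the anomaly zone — the property that motivates using it as the
package's internal estimator in subsampling experiments. The margin matters
in practice: for an internal branch of $t$ coalescent units the
major–minor probability gap is $1 - e^{-t}$ ($\approx 4.9\%$ at $t = 0.05$),
so resolving such a branch reliably needs on the order of
$(3\sigma)^2 \approx 2{,}500$ or more gene trees; the synthetic scenario's
default locus counts are chosen accordingly.

`run_subsample()` implements gene-level double resampling: loci are drawn
with replacement into subsets of increasing size (replicated), and each
replicate is bootstrapped by redrawing loci; every bootstrap estimate is
collapsed to lineages and scored against a configurable set of mutually
exclusive topological hypotheses (see `default_hypotheses()` for the five
classical alternatives for the rhea attachment). In the study design this
package mirrors, the inner bootstrap resamples alignment sites within loci;
without alignments the inner level here resamples genes instead — the
two-level design, size grid, and summarization are preserved, and this
substitution is a documented deviation. `threshold_heatmap_counts()`
summarizes how many replicates exceed given support thresholds.

## The synthetic scenario: what it emulates, and what it does not

`make_scenario()` builds a 12-ingroup-taxon palaeognath-like species-tree
model (ostrich; two rheas; emu and cassowary; three kiwi; four tinamous;
chicken outgroup) whose two successive short internal branches —
$x = 0.1$ above the rheas/kiwi/emu–cassowary ancestor and $y = 0.05$ above
kiwi/emu–cassowary, beneath a $0.12$ branch — satisfy $y < a(x)$ twice
over, so `anomaly_scan()` flags exactly those two pairs (verified at
construction). These lengths are this package's own design choices made to
sit inside the anomaly zone with realistic magnitudes; they are not
estimates from any particular data set. All other internal branches are 1–5
coalescent units, internal $\Theta$ defaults to 0.002 (a bird-like nuclear
value), and terminal mutational lengths are padded so the mutational tree is
ultrametric (a strict molecular clock, inheriting the usual simplification
that substitutions accrued through ancestral coalescent variance are
ignored).

Marker classes emulate the relative sizes of the reference panel (12,676 /
5,016 / 3,158 loci) scaled by `scale`, default 0.1 (1,268 / 502 / 316
loci) — large enough, per the margin analysis above together with
cross-trio aggregation, for the R\* estimator to resolve the designed
$y = 0.05$ branch. Gene-tree estimation error is emulated by applying one
random rooted NNI move per tree with a class-specific probability (default
0.3 for the CNEE-like class, 0.1 for the intron- and UCE-like classes,
reflecting that short, low-variability loci yield noisier gene trees): a
single NNI changes exactly one cluster, so realized error is exactly
quantifiable from the truth manifest. `write_fixture_bundle()` materializes
a byte-reproducible directory of all inputs with MD5 checksums.

What the generator does *not* emulate: sequence-level evolution (alignment
lengths, substitution-model misspecification, alignment error), within-locus
site resampling, gene flow or hybridization, multiple alleles per species,
and the upstream wet-informatics of retroelement calling (orthology
screening, target-site duplications). Passing tests on synthetic data
therefore demonstrate the correctness of the coalescent computations and the
end-to-end plumbing, not robustness to those real-data complications.

## Numerical choices and degenerate inputs

* Newick parsing validates parenthesis/quote balance (reporting the
  character offset), collapses degree-2 nodes merging lengths by addition,
  preserves polytomies and internal labels, ignores bracketed comments, and
  rejects duplicate or empty leaf labels; taxon matching is exact and
  case-sensitive.
* Topology identity is exact cluster-set equality (RF cluster distance 0);
  a consensus polytomy bins only with identical polytomies, and binning
  caps (e.g. "top 50") are reporting parameters only.
* The matching cluster distance solves the assignment problem by
  maximum-weight bipartite matching on a shifted weight matrix; it is
  checked against an exhaustive-permutation oracle in the tests.
* Enumeration of rooted topologies is guarded at 9 free lineages (the count
  is the double factorial $(2n-3)!!$; the error message reports the would-be
  count).
* p-values are computed in log space where underflow is possible and are
  clamped to $(0, 1]$.
* Empty inputs: filtering to an empty gene-tree set warns rather than
  errors; a zero empirical mean distance yields an explicitly undefined
  heterogeneity ratio; a zero-total trio errors in `triplet_gof()` and
  returns $p = 1$ in `kksc_tree_test()`.
* All stochastic operations take an explicit seed, restore the caller's RNG
  state, and record the seed in their outputs; problem sizes used in the
  test suite (e.g. $10{,}000$ trees for triplet calibration, $20{,}000$ for
  the anomaly-zone demonstration, desk-scale loci counts elsewhere) are the
  package's chosen trade-off between statistical resolution and runtime.

## Known limitations

RF distances are reported as raw integers (ratios built from them are
scale-invariant). The subsampling engine's species-tree estimator is R\*
rather than a pseudo-likelihood or quartet method, and its inner bootstrap
is gene-wise; both are documented stand-ins chosen so the package is
self-contained. The insertion significance test implements the
tree-significance variant only. Lineage-level presence uses the "any scored
member" rule; alternative rules (all members, majority) would tighten or
loosen trio tallies for deeply sampled lineages.
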