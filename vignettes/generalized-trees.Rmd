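---
title: "Generalized trees: shared and multifurcating divergences from biallelic characters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized trees: shared and multifurcating divergences from biallelic characters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phygen)
```

## The model

Classical rooted phylogenetics estimates, for `N` tips, a bifurcating
topology with `N - 1` free divergence times and assumes those divergences
are independent. Many processes — landscape fragmentation affecting
codistributed taxa, superspreading events in transmission trees, segmental
duplications in gene families — violate this by triggering several
divergences at once, or by splitting one lineage into more than two
descendants. `phygen` treats such trees as first-class citizens.

A *generalized tree* is a rooted, potentially multifurcating topology
whose internal nodes are mapped onto `n_tau` *height classes*, with
`1 <= n_tau <= N - 1`. All nodes in a class diverge at the same instant (a
shared divergence); a node with three or more children is a
multifurcation. The two familiar extremes are the "comb" (every tip
radiating from one event, `n_tau = 1`) and the conventional independent
bifurcating tree (`n_tau = N - 1`, each node its own class). The discrete
model space — topology plus height-sharing pattern — is enumerable for
small `N` (`count_tree_models(4)` is 29, `count_tree_models(5)` is 336),
which the samplers are validated against.

### Prior

* Every generalized topology (topology + sharing pattern) is equally
  probable a priori.
* The root age follows a parametric prior: gamma, parameterized by shape
  and mean (default shape 10, mean 0.2 expected substitutions per site),
  or exponential by mean.
* Conditional on all older classes, each non-root class height is
  beta(`alpha_tau`, 1)-distributed on `(0, U_k)`, where `U_k` is the
  height of the youngest parent of any node in the class. The second beta
  parameter is fixed at one; with the default `alpha_tau = 1` both
  readings coincide and the heights are nested uniforms.
* One mutation-scaled diploid effective population size `neu` is shared
  by all branches, with a gamma prior (default shape 20, mean 0.001 — a
  mean heterozygosity of about 0.004, typical of genomic data from many
  vertebrate populations).

The joint height density is evaluated root-downward, so every `U_k` is
well defined and the density is proper; `vignette` tests integrate it to
one by quadrature on two- and three-tip trees.

## Likelihood

The data are `m` biallelic ("red"/"green") characters summarized per
species as allele counts `(n, r)`; missing data is a species with
`n = 0`. The likelihood of a generalized species tree integrates
analytically over all gene trees (a multispecies coalescent with pairwise
coalescence rate `1 / (2 neu)` in substitution-time units) and all
two-state mutational histories (relative rates `u`, `v`; stationary green
frequency `pi = u / (u + v)`; with `u = v` the chain is the two-state
analogue of JC69).

The computation follows the classical partial-likelihood scheme for
allele-count data: tables indexed by `(k, r)` (k ancestral lineages, r
red) are initialized at the tips, pulled down branches by exponentiating
the sparse generator that couples pairwise coalescence with per-lineage
color flips, and merged at nodes with hypergeometric allocation weights.
Multifurcations are merged by folding the children pairwise in arbitrary
order; the result is provably identical to expanding the polytomy into
zero-length bifurcations, and the test suite checks this identity to
1e-10. At the root, rather than truncating an infinitely long root
branch, we use the conserved left null functional of the generator, whose
`k = 1` entries are the stationary color law — this terminates the
recursion exactly.

Two implementations coexist deliberately: a plain-R reference path
(`character_probability()`) and a compiled engine used by the samplers,
which caches pulled and combined tables by content hashes of the subtree
(structure, branch durations, population size) and reuses per-`(K, neu)`
eigendecompositions of the generator. The two paths agree to 1e-10 in the
tests, and both agree with an independent Monte-Carlo oracle: empirical
pattern frequencies from the coalescent simulator match the analytic
probabilities within three binomial standard errors at `10^5` characters.

When only variable characters are analyzed, each character's probability
is divided by one minus the probability of a constant character with that
character's sample sizes (ascertainment correction), computed per
missing-data profile.

## Posterior sampling

`run_chain()` samples the joint posterior of tree, heights and `neu` by
Metropolis-Hastings with reversible jump across the number of height
classes. Per generation it attempts `N` moves (the tip count) drawn by
weight:

* `height_slide` (weight 3): a non-root class height is either redrawn
  uniformly on its legal interval or slid within a +/- 0.02 window.
* `height_multiplier` (2), `root_scale` (2), `tree_scale` (1),
  `ne_multiplier` (2): standard multiplier proposals with log-scale
  Jacobians (scales 0.7, 0.4, 0.3 and 1.0; the population-size scale was
  chosen for sampling efficiency — it roughly doubles that parameter's
  effective sample size per move relative to narrower kernels).
* `topology` (3): a constrained child exchange — a child `x` of an
  internal node `c` swaps places with a younger sibling `y` of `c` —
  chosen uniformly among valid triples, with the count ratio as the
  Hastings term. This generalizes nearest-neighbor interchange to
  multifurcating, class-constrained trees.
* `rj_merge`/`rj_split` (3, shared): the dimension-changing pair. A merge
  picks one of the pairs of classes adjacent in height order, raises the
  younger class to the older height, and deletes any node that collides
  with its parent (creating a multifurcation). A split chooses a class
  with at least one valid allocation, a uniform allocation (each member
  node stays, moves to the new younger class, or — for polytomies —
  detaches disjoint child subsets of size two or more onto new nodes),
  and a new height on the interval between the older height and the
  nearest constraint below (structural or neighboring class), drawn from
  an equal mixture of a uniform density and a truncated-exponential
  density concentrated just below the older height (scale one twentieth
  of the interval). The concentrated component is what makes splits of
  nearly simultaneous divergences reachable; the mixture density enters
  the Hastings ratio exactly, with unit Jacobian, and an accepted merge
  or split chains one immediate height-slide refinement. The Hastings
  ratio counts forward and backward choices exactly.

The move internals were derived from scratch for this package. Their
correctness argument is empirical and strong: chains run with the
likelihood fixed at one recover the prior — uniform over all 4 (N = 3)
and 29 (N = 4) enumerated topology classes by chi-square, gamma root
heights by Kolmogorov-Smirnov, and the analytic class-size split of the
divergence-count marginal (1/29, 13/29, 15/29 at N = 4). A further check
matches MCMC posterior means against full-grid quadrature on a three-tip
problem. Disabling the reversible-jump pair (`model = "MIB"`) yields the
conventional independent-bifurcating sampler, which the tests confine to
bifurcating states with `n_tau = N - 1`.

Split proposals enumerate allocation options per polytomy; collections of
disjoint child subsets are memoized by child count, and polytomies with
more than ten children are rejected by the split move (a practical bound;
at desk scale the chains never approach it).

Prior draws of generalized trees (`sample_tree_from_prior`) assemble a
uniform random bifurcating topology by stepwise addition, mix it with
1,000 generations of prior-only moves (N per generation), and then redraw
all heights from the prior root-downward. Uniformity over topology
classes is tested against enumeration rather than assumed. Because
heights are redrawn at the end, the mixing phase only needs to mix the
topology marginal, which is uniform conditional on any height state.

## Simulator

`simulate_matrix()` is the generative counterpart used both for study
data and as the likelihood's independent oracle. Gene trees branch
backward in time within the species tree (all children of a
multifurcation enter the ancestral population simultaneously); characters
evolve along them by the two-state CTMC from a stationary root state.
Defaults mirror the study conditions: two gene copies (one diploid) per
species, all characters retained (constant included), `neu` drawn from
its gamma prior and reused as the analysis prior. Linked characters are
simulated by reusing one gene tree per locus; `one_variable_per_locus()`
implements the thinning design that retains at most one variable site per
locus and flags the result for the ascertainment correction.

What the simulator does *not* emulate: sequencing error, allele dropout,
assembly artifacts, rate variation across lineages or sites, and
population structure within species. Passing tests therefore validate the
inferential machinery under the model's own assumptions, not robustness
to the full messiness of empirical RADseq data.

## Summaries and diagnostics

`map_summary()` reports posterior means and equal-tailed 95% credible
intervals for root age, tree length, `neu` and the number of divergence
times; frequencies of splits, of *nodes* (a split together with its set
of child splits, so a polytomy and its resolutions are distinct records),
of shared-divergence events (sets of node records mapped to one class),
and of topologies; and the MAP topology annotated with conditional mean
heights. Ties for the MAP topology break toward the lexicographically
smallest canonical key (reported as such). `branch_score_distance()`
implements the square root of the sum of squared branch-length
differences over the union of splits; terminal branches are included by
default (the Kuhner-Felsenstein convention, cross-checked against
phangorn on binary trees) and can be excluded.
`merged_divergence_probabilities()` scores, for every neighbor merge of a
reference tree, the fraction of posterior samples containing that
divergence scenario — all node records created by the merge present and
mapped to one class.

Convergence diagnostics follow the field's standards: the ASDSF across
chains over splits reaching 10% frequency in at least one chain; the
Brooks-Gelman potential scale reduction factor in square-root form; and
an initial-positive-sequence autocorrelation ESS (white-noise chains give
ESS near the chain length, AR(1) chains the known deflation — both
tested). `rescale_to_calibration()` multiplies every sampled tree by one
global factor so the posterior mean root age matches a secondary
calibration.

## Numerical choices and problem sizes

* Ultrametricity and class-height consistency are checked at parse time
  to 1e-9; heights are stored once per class and branch lengths derived.
* "Neighboring" divergence times are classes adjacent in the sorted
  height order; this makes the merge set unique and matches the
  summarizer's counting.
* Parent-child merges delete nodes (rather than keeping zero-length
  branches) so `n_t` and `n_tau` stay consistent with the model; the
  zero-length expansion exists separately as a likelihood cross-check.
* Generator exponentials use eigendecompositions guarded by a
  reconstruction-error check (fallback: scaling-and-squaring), both to
  1e-10 or better; combine weights are exact binomial ratios.
* The built-in studies run at desk scale, chosen once: 20 datasets per
  true model, six species, 2,000 unlinked characters, four chains of
  1,300 generations sampled every generation with the first third
  discarded, and prior trees separated by a minimum height gap of 0.001
  substitutions per site. At 25 times fewer characters than the
  full-scale experiments, posterior uncertainty about nearly simultaneous
  divergences is genuinely larger: pairs of true divergence times up to a
  few hundredths of a substitution apart can receive posterior merge
  probabilities above one half (we verified on the worst case that this
  support persists in chains four times longer and started at the true
  tree, so it is the posterior speaking, not the sampler), and for such
  datasets the across-chain dispersion of split frequencies (ASDSF)
  reflects that real uncertainty rather than non-convergence — with 867
  retained samples per chain, a split at posterior probability one half
  has an across-chain frequency standard deviation of at least
  `sqrt(0.25/867) = 0.017` even for perfectly independent samples. The
  PSRF and ESS targets hold with margin at these sizes; false-merge
  proportions and worst-case ASDSF are intrinsically larger than at the
  full experimental scale.

## A worked example

```{r example, eval = FALSE}
set.seed(7)
true_tree <- parse_gtree(
  "((A:0.03,B:0.03)[&hc=1]:0.07,(C:0.03,D:0.03)[&hc=1]:0.07)[&hc=2];")
dat <- simulate_matrix(true_tree, model_params(neu = 0.001), m = 2000)
chains <- lapply(1:4, function(i)
  run_chain(dat, prior_config(), generations = 1500, sample_freq = 3,
            seed = i, chain_id = i))
convergence_diagnostics(lapply(chains, discard_burnin))
map_summary(chains)
```

## Limitations

The clock is strict and `mu` fixed; `pi`, `u`, `v` and `alpha_tau` are
not estimated (all paper-style analyses fix them). A single shared `neu`
is estimated; per-branch population sizes are internal-only. Tips are
contemporaneous. The uniform-topology prior is a mathematical
convenience, not a process model; a generalized birth-death prior would
be the natural next step.
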