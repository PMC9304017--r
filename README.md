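# phygen

Bayesian inference of rooted phylogenies in a *generalized* tree space in
which divergences may be shared (two or more internal nodes mapped to one
divergence time) or multifurcating (a node with three or more children).
The package is for phylogeneticists and phylogeographers who want to test
for simultaneous divergences — e.g. codistributed taxa fragmented by the
same sea-level rise, superspreading events in transmission trees — rather
than assume the conventional model of `N - 1` independent bifurcations.

## What it implements

* **Generalized trees.** A rooted multifurcating topology over `N` tips
  whose internal nodes map onto `1..N-1` height classes; classes can be
  merged and split, the discrete model space enumerated
  (`count_tree_models`), and trees round-trip through an annotated newick
  dialect (`[&hc=<class>]` node comments).
* **Prior.** Uniform over generalized topologies; gamma (or exponential)
  root age; each non-root divergence time beta(`alpha_tau`, 1) between
  zero and the youngest parent of its class,

      p(T, tau) = p(tau_root) * prod_k  Beta(h_k / U_k; alpha_tau, 1) / U_k ;

  one gamma-distributed mutation-scaled population size `neu` shared
  across branches.
* **Likelihood.** The multispecies-coalescent likelihood of biallelic
  (SNP-like) characters, integrating analytically over gene trees and
  two-state mutational histories:

      p(D | T, tau, neu, mu, pi) = prod_i p(n_i, r_i | T, tau, neu, mu, pi)

  with allele-count partial tables pulled down branches by matrix
  exponentials of the coalescent-plus-mutation generator, hypergeometric
  sibling merges, multifurcations folded exactly, and an optional
  ascertainment correction for variable-only data. A compiled engine with
  subtree caching backs the samplers; a plain-R reference path and a
  Monte-Carlo simulator serve as independent cross-checks.
* **Sampling.** Metropolis-Hastings plus reversible-jump merge/split
  moves over the number of divergence times (`run_chain`); disabling the
  rj pair gives the conventional independent-bifurcating model (`MIB`).
  Prior-recovery against exhaustive enumeration validates every Hastings
  ratio.
* **Simulation.** Gene trees within generalized species trees, two-state
  characters along them, linked-locus designs and variable-only filters
  (`simulate_matrix`, `one_variable_per_locus`), plus an end-to-end study
  driver (`run_simulation_study`).
* **Summaries.** Split/node/shared-divergence/topology frequencies, MAP
  tree with credible intervals, merged-neighbor divergence probabilities
  against a reference tree, branch-score tree distances, ASDSF/PSRF/ESS
  diagnostics, and secondary-calibration rescaling.

A thin command-line front end (`inst/cli/phygen`) exposes
`simulate` / `infer` / `summarize` over YAML configurations and
NEXUS/newick/TSV files.

## A worked example

```r
library(phygen)
set.seed(7)

## truth: two cherries diverging at the same moment (one shared class)
truth <- parse_gtree(
  "((A:0.03,B:0.03)[&hc=1]:0.07,(C:0.03,D:0.03)[&hc=1]:0.07)[&hc=2];")
dat <- simulate_matrix(truth, model_params(neu = 0.001), m = 2000)

trace <- run_chain(dat, prior_config(), generations = 800,
                   sample_freq = 2, seed = 4)
map_summary(trace)
#> phygen_summary over 267 samples
#>   root age: 0.1016 [0.09213, 0.113]
#>   MAP topology (pp = 0.831): ((A,B),(C,D))|((A,B),(C,D));(A,B)+(C,D)
```

The MAP topology key reads: topology `((A,B),(C,D))` with the two cherry
nodes sharing one height class (`(A,B)+(C,D)`) — the shared divergence is
recovered with posterior probability 0.83 from 2,000 characters, and the
root age interval covers the true 0.1.

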