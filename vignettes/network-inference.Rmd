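---
title: "Bayesian phylogenetic networks from bi-allelic markers: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian phylogenetic networks from bi-allelic markers: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markernet)
```

## The inference problem

Unlinked bi-allelic markers — SNPs typed far apart in the genome, or AFLP
band presence/absence — carry genome-wide signal about species
relationships without any within-locus recombination concerns.  When the
history of the sampled species includes hybridization, that history is a
rooted phylogenetic *network*: a binary rooted DAG whose in-degree-2 nodes
(reticulations) represent hybridization events.  `markernet` computes the
exact likelihood of such a network given bi-allelic markers, integrating
analytically over all gene trees, and samples the posterior over networks
and their parameters by reversible-jump MCMC.

Each marker is modelled by two processes:

* **The multispecies network coalescent (MSNC).**  Gene lineages sampled
  at the leaves coalesce backward in time inside the network's branches.
  Each branch carries a population mutation rate $\theta_b = 4N_b\mu$; a
  branch of length $\tau$ (in expected mutations per site) spans
  $2\tau/\theta_b$ coalescent units, so a pair of lineages coalesces at
  rate $2/\theta_b$ per unit of mutational time.  At a reticulation node a
  lineage follows one parent branch with the inheritance probability
  $\gamma$ of that branch (the two $\gamma$s of a reticulation sum to 1).
  The branch above the root is infinitely long, with its own $\theta$, so
  all lineages eventually coalesce.
* **Two-state mutation.**  Each site has two states, "red" and "green",
  mutating forward in time at rates $u$ (red to green) and $v$ (green to
  red); the root state is drawn from the stationary distribution
  $(v/(u+v),\, u/(u+v))$.  The convenience parameter `pi0` sets
  $u = 1/(2\pi_0)$, $v = 1/(2(1-\pi_0))$; $\pi_0 = 0.5$ gives the
  symmetric $u = v = 1$ model in which one time unit equals one expected
  mutation per site.

The likelihood of a network $\Psi$ given $m$ independent sites is
$L(\Psi \mid S) = \prod_i \int_G p(S_i \mid g)\, p(g \mid \Psi)\, dg$,
and the whole point of the likelihood engine is that this gene-tree
integral is evaluated exactly, in polynomial time for trees and with a
controlled combinatorial cost for networks.

## Exact likelihood via labeled partial likelihoods

For a branch $x$, the partial likelihood $F_x(n, r)$ is the joint
probability of the observed data below $x$ and of there being $n$ ancestral
lineages, $r$ of them red, at that point of the branch.  With $M$ sampled
lineages in total, the state space is $\{(n,r): 0 \le r \le n \le M\}$
(including a $(0,0)$ placeholder), of size $l = (M+1)(M+2)/2$; any fixed
bijection of these states to vector indices works, and a triangular ranking
is used.

The traversal is bottom-up:

* **Leaves.**  For co-dominant data (haploid 0/1 or diploid 0/1/2 red
  allele counts) the leaf vector is an indicator at the observed
  $(n_x, r_x)$.  For dominant markers (AFLP bands, red dominant) on $n_x$
  diploid individuals with $r_x$ band-present individuals, the vector is
  supported on $n = 2n_x$, $r_x \le r \le 2r_x$, with
  $$F(2n_x, r) = \frac{n_x!}{(r-r_x)!\,(2r_x-r)!\,(n_x-r_x)!}\,
    \frac{2^{\,2r_x-r}}{\binom{2n_x}{r}},$$
  the probability that $r$ red alleles dropped on the $2n_x$ paired
  lineages produce exactly $r_x$ band-present individuals
  ($r - r_x$ homozygous red, $2r_x - r$ heterozygous, $n_x - r_x$
  homozygous green).  This form is validated in the test suite against
  exhaustive enumeration of all allele placements for every
  $n_x \le 3$; an alternative typographic reading that puts $n = 2n_x$
  into the numerator factorials double-counts and disagrees with the
  enumeration, so the pairing-consistent form above is used.
  Missing entries (`?`) are handled, behind a flag, by summing the leaf
  indicator over every red count consistent with the observed individuals.
* **Along a branch.**  $F \mapsto F e^{Qt}$, where $Q$ is the generator
  over $(n,r)$ states: mutation moves $r$ at rates $(n-r+1)v$ and
  $(r+1)u$, coalescence moves $(n,r) \to (n-1, r)$ at rate $(n-1-r)n/\theta$
  and $(n,r) \to (n-1,r-1)$ at $(r-1)n/\theta$, with diagonal
  $-n(n-1)/\theta - (n-r)v - ru$.  The matrix exponential is the dense
  scaling-and-squaring routine of the linear algebra backend; the
  quadratic-time approximate exponential used by species-tree
  implementations is deliberately not used — correctness first, and the
  matrices here are small ($l \le 120$ for $M = 14$).
* **Reticulation nodes.**  The lineage set is bipartitioned in every
  possible way between the two parent branches.  Each single-support
  component $(n_i, r_i)$ of an arriving vector splits over all
  $(n_y, r_y)$ with $0 \le n_y \le n_i$ and
  $\max(0, r_i - (n_i-n_y)) \le r_y \le \min(r_i, n_y)$ (bipartitions that
  would need more red lineages than a side can hold are skipped, which is
  also required for pattern probabilities to sum to one); the $\gamma$-side
  carries $F(n_i,r_i)\binom{n_i}{n_y}\gamma^{n_y}(1-\gamma)^{n_i-n_y}$, the
  other side a bare indicator.  Because the two halves of a split are only
  allowed to recombine with each other, each partial likelihood carries an
  integer label vector (one coordinate per reticulation); both halves of a
  split receive the same fresh counter value at that coordinate.  Two
  labeled vectors are *compatible* when every coordinate is equal or one
  side is zero.
* **Tree nodes.**  Compatible pairs from the two child branches combine by
  the hypergeometric convolution
  $$F_x(n,r) = \sum_{n_y, r_y} F_y(n_y,r_y) F_z(n-n_y, r-r_y)\,
    \frac{\binom{r}{r_y}\binom{n-r}{n_y-r_y}}{\binom{n}{n_y}},$$
  merging labels coordinatewise (take the nonzero value).
* **Root.**  All vectors at the bottom of the root branch are summed and
  dotted with the stationary vector $x$, the normalized null vector of the
  root-branch generator restricted to $n \ge 1$ with
  $x(1,0) + x(1,1) = 1$, so that $x(n,r) = \Pr[R = r \mid N = n]$ for a
  stationary single population.

**Collapsing label bookkeeping.**  At a *lowest articulation node* — a
node whose removal disconnects all of its descendants from the root side,
having at least one child that is neither such a node nor a leaf — every
split initiated below has been resolved, and the whole LPL set collapses to
the sum of its vectors with a cleared label.  Note the qualifier "all of
its descendants": a node that merely cuts off a pendant leaf inside a
reticulation cycle is a cut vertex of the undirected graph, but collapsing
there is provably wrong (pattern probabilities stop summing to one),
because splits from a reticulation below it still need to resolve above.
The engine additionally applies this collapse per label coordinate: once an
edge dominates both parents of reticulation $j$ (every path from either
parent to the root passes through it), coordinate $j$ is zeroed and vectors
with equal labels are summed.  Both collapses are exact — every downstream
operation is linear in $F$ at fixed labels — and the test suite verifies
that enabling or disabling them never changes a likelihood.

Site patterns are deduplicated before computation and weighted by their
multiplicities, and per-pattern results are reduced in a fixed sorted
order, so results are independent of site order and of the `threads`
argument (the reduction order is fixed; the argument is accepted for
interface compatibility).  Each per-site computation carries a scalar
log-scale factor, extracted whenever the largest vector entry falls below
1e-100, so very long branches or many lineages do not underflow.

For data ascertained to contain only polymorphic sites, the likelihood can
be conditioned on polymorphism by dividing each site likelihood by
$1 - \Pr[\text{all red}] - \Pr[\text{all green}]$.  The conditioning is
flag-gated (`polymorphic_correction`) and defaults to the marker matrix's
own `polymorphic_only` flag; whether ascertainment should affect the
likelihood or only the simulation is left to the user because conventions
differ between tools.

The engine exists twice by design: a readable R composition of the exported
per-operation functions (`leaf_partials()`, `propagate_top()`,
`split_at_reticulation()`, `merge_at_tree_node()`,
`merge_at_articulation()`, `root_stationary()`) and a compiled
RcppArmadillo implementation used by `dataset_loglik()` and the sampler.  A
test asserts agreement to 1e-12 on random networks; independent oracles (a
label-free species-tree implementation, gene-tree Monte-Carlo integration
via `site_likelihood_mc()`, and exhaustive pattern enumeration) check both.

## Priors and the reversible-jump sampler

The prior on a network factorizes into: a Poisson($\nu$) prior on the
number of reticulations $k$, normalized by the number of network
topologies with $k$ reticulations; an exponential($\eta$) density on each
reticulation's *diameter* (the total branch length of the undirected cycle
through it); a divergence-time prior; a Gamma$(2, \zeta)$ density (mean
$2\zeta$) on every branch's $\theta$ including the root branch; and a
Beta$(\alpha,\beta)$ density on each inheritance probability
($\alpha=\beta=1$ is the uniform default).  Any candidate graph that
violates the network definition — a cycle, wrong degrees, a $\gamma$ pair
not summing to one, inconsistent divergence times — has prior 0, which is
how illegal proposals are rejected; proposals are allowed to construct
such graphs, keeping the Hastings ratios simple, but divergence-time
consistency itself is maintained by construction.

Two choices deserve emphasis:

* **Topology-count normalization.**  The number of $k$-reticulation
  topologies has no closed form, so the package uses a sequential-
  attachment surrogate: a $k$-reticulation network arises from a tree by
  $k$ successive attachments, the $j$-th choosing an ordered pair among
  the $E_j = 2n - 2 + 3j$ edges then present, with (on average) two
  attachment representations per resulting network, giving
  $N(k) \propto \prod_{j<k} E_j(E_j-1)/2$.  Without this term the prior
  over $k$ is dominated by the sheer growth in the number of topologies:
  reticulations of tiny diameter are invisible to the likelihood, so the
  sampler accumulates them and pushes $k$ to its cap even for
  tree-generated data.  With the term, prior-only sampling gives a
  $k$-distribution close to the intended Poisson shape, and data simulated
  on a tree yield $k=0$ in the overwhelming majority of posterior samples.
* **Divergence-time prior.**  The default is an exponential($\delta$)
  density on the root height with node times uniform given the height;
  an i.i.d.-exponential variant is available (`time_prior =
  "iid-exponential"`).  Node heights (leaves at 0) are the sampler's
  primary coordinates; branch lengths are kept in sync.

The proposal kernel mixes eight moves, chosen from a fixed menu so that
selection probabilities cancel from all ratios: a uniform window on one
node's height (confined to its feasible interval), a scaler of all heights
(Jacobian $c^{\#\text{nodes}}$), a log-scale window on one branch's
$\theta$ (root branch included), a reflected window on one reticulation's
$\gamma$, a rooted nearest-neighbour interchange on tree edges, a rooted
subtree-prune-and-regraft relocation (which detaches an ordinary internal
node with one child subtree — or a reticulation-edge tail — and re-inserts
it on a random edge at a uniform feasible time, carrying its parameters;
this is what repairs a wrong backbone or a wrong attachment without a
trans-dimensional detour), and the
dimension-changing pair: *add-reticulation* picks an ordered pair of
distinct edges, places the reticulation head uniformly on the first and
the attachment tail uniformly on the feasible part of the second, and
draws the three new $\theta$s and the new $\gamma$ from their priors
(dimension-matched with unit Jacobian); *delete-reticulation* removes one
incoming edge of a random reticulation and suppresses the two degree-2
nodes, keeping the lower segments' parameters — the exact inverse of add.
Attachments to the infinite root branch are excluded so the pair is
self-inverse on the reachable space.  A move that cannot produce a valid
proposal (for example, delete at $k=0$, or an add whose intervals are
empty) counts as a rejected proposal.

Correctness of the reversible-jump bookkeeping is established by
prior-only sampling (`likelihood = "none"`): the sampled $\theta$ and
$\gamma$ marginals are compared to their exact Gamma and Beta laws by
Kolmogorov–Smirnov tests, and the sampled reticulation-count distribution
is compared against an independent importance-sampling evaluation of the
same prior over a fully enumerated three-taxon space.  The importance
sampler is the independent oracle of choice here because the prior is
deliberately unnormalized across reticulation counts (diameter terms and
the $N(k)$ surrogate reweight it), so the $k$-marginal is not the bare
Poisson pmf and must itself be computed, not assumed.  One subtlety is
worth recording: a network whose reticulation has two ordinary internal
nodes as parents corresponds to *two* tree-plus-attachment decompositions,
and the importance density must count both.

`run_mc3_preburnin()` implements the Metropolis-coupled pre-burn-in: a few
chains with likelihood heated by $1/T$, periodic adjacent swaps, and the
highest-likelihood network visited is handed to the main chain as its
start; a separate reticulation cap can be applied during this phase.

Posterior summaries group sampled networks into topology classes by
leaf-label-preserving isomorphism; `summary()` reports the
maximum-a-posteriori topology class with its frequency, the
reticulation-count posterior, and an autocorrelation-based effective
sample size (Geyer initial positive sequence) of the log posterior.
`match_reference_topology()` maps samples onto a reference network and
extracts the inheritance probability of the edge corresponding to the
reference's minor reticulation edge.

## The simulator

`simulate_bimarkers()` generates data under exactly the model above: one
gene tree per block of `sites_per_genetree` sites (1 = unlinked) by the
MSNC — Kingman coalescence within branches at pairwise rate $2/\theta_b$,
$\gamma$-routing at reticulations, final coalescence on the root branch —
then two-state mutation down the gene tree from a stationary root draw.
Under `polymorphic_only`, a block containing any monomorphic site is
discarded, gene tree and markers jointly, and redrawn.  Diploid individuals
are two lineages with a fixed pairing across sites; co-dominant encoding
is the red-allele count, dominant encoding is band presence.

Rate variation, used to probe robustness to model violations, draws
multipliers from an invariant-plus-discrete-Gamma scheme: zero with
probability $i$, otherwise one of $g$ equal-probability category means of
a mean-one Gamma with shape $a$ (the standard equal-frequency
discretization).  "Across markers" draws one multiplier per site;
"across lineages" one per gene-tree branch (the per-gene-tree-branch
reading was chosen; a per-species-branch reading is also defensible but
is not implemented).  Variable-site multipliers average one among the
variable class; the likelihood model itself remains constant-rate, which
is the point of the exercise.

What the simulator does *not* emulate about real data: genotyping or
band-scoring error, ascertainment schemes other than the polymorphism
filter, within-locus recombination, gene flow that is continuous rather
than pulse-like, and linkage beyond the shared-gene-tree blocks.  Passing
tests therefore demonstrate correctness of the implementation under its
own generative model, not robustness to everything field data can do.

On the bundled five-taxon, one-reticulation model network (`
example_network("net5_1ret")`, $u=v=1$, $\theta = 0.006$ on external
branches and the root branch, $0.005$ internally, one haploid per taxon),
the exact engine puts the polymorphic-site probability at 0.2091, and
simulated 10,000-site data sets land within binomial noise of it — the
package's reproduction of the published 19–21% observation.

## Numerical and interface choices

* Tolerances: $\gamma$ pairs must sum to 1 within 1e-9; pattern-probability
  normalization is checked to 1e-8; engine-vs-reference agreement to
  1e-12; degenerate reductions ($\gamma \to 1$ edge deletion, single-
  lineage mixtures) to 1e-10.
* The backbone tree (delete each reticulation's smaller-$\gamma$ edge,
  suppress degree-2 nodes, summing lengths) errors on an exact 0.5/0.5 tie
  by default; a deterministic post-order tie-break is available.  Merged
  branches keep the child-side $\theta$: averaging would silently change
  the model, and backbone output is meant for topology-level comparison.
* Parsed networks are validated structurally; divergence-time consistency
  is a separate check (`check_times`) because the likelihood is well
  defined from branch lengths alone while the simulator and sampler
  require consistent heights.  One of the bundled example networks
  (`net5_2ret`) is, as printed in its source, time-inconsistent at one
  reticulation by 0.007 expected mutations; it is kept verbatim and is
  fine for likelihood work.
* Problem sizes in the test suite are chosen to keep the full run at
  desk scale: random networks up to 8 leaves and 3 reticulations for
  structural properties, up to 4 leaves, 2 reticulations and 2 lineages
  per leaf for exhaustive-normalization checks, $10^6$ gene trees per
  Monte-Carlo oracle case, a $10^6$-iteration prior-only chain, and one
  $2\times10^5$-iteration inference run on 10,000 sites (scaled down
  from the published $1.5\times10^6$-iteration analyses, which are
  cluster-scale).

## Known limitations

* The likelihood cost grows combinatorially with the number of lineages
  below reticulations and with overlapping reticulation cycles; the label
  collapses above keep the bundled examples fast, but many individuals
  under several nested reticulations will be slow — this is intrinsic to
  the exact algorithm.
* The topology-count normalization $N(k)$ is a surrogate, not an exact
  count; it changes the meaning of $\nu$ slightly (the prior over $k$ is
  Poisson-like, not exactly Poisson).
* The sampler targets networks with consistent divergence times and
  reticulation attachments strictly below the root branch.
* No FFT-accelerated propagation, no per-site rate heterogeneity in the
  likelihood (simulation only), and no network-to-network topological
  distance beyond leaf-labeled isomorphism; tree comparisons use the
  Robinson–Foulds metric.
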