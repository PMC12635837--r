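---
title: "Core-periphery analysis of directed connectomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core-periphery analysis of directed connectomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectocore)
```

## The problem

A connectome is a directed graph: neurons are nodes, chemical synapses are
directed edges, and an edge weight counts synapses between an ordered pair
of neurons. Comparing two such graphs — say, a dense larval insect brain
(~3,000 neurons, density ~0.01) against a sparse adult brain (~125,000
neurons, density ~0.0002) — raises recurring methodological questions: does
the degree distribution follow a stretched exponential or a power law? Is
there a densely interconnected structural core, and which cell types form
it? Do high-degree neurons interconnect more than chance (a rich club)? How
much does the network depend on its core?

`connectocore` implements this analysis battery for any pair of annotated
directed graphs, together with a synthetic generator so that every stage can
be validated without access to any particular dataset.

## Graph representation and binarization

Analyses operate on the binary adjacency A, A_ij = 1 when at least one
synapse runs from neuron i to j (`binarize()`); working with degrees rather
than weighted degrees avoids underweighting weak connections, and the strong
Spearman correlation between degree and strength (`degree_strength_spearman`)
is reported as a check that little is lost. Parallel synapse records are
aggregated at read time and self-loops are dropped by default: the density,
rich-club and type-matrix denominators all count ordered pairs i ≠ j, so
retaining loops (available via `selfloops = "kept"`) would bias those
statistics. The minimum synapse count for an edge is a parameter of
`read_edge_table()` with default 1 (any synapse makes an edge). Node ids are
opaque strings throughout and never reindexed — adult connectome exports use
64-bit integer ids that do not survive numeric coercion.

## D-cores and the frontier core

The D-core(k, l) is the unique maximal subgraph in which every node keeps
in-degree ≥ k and out-degree ≥ l inside the subgraph, computed by iterative
pruning (order-independent; tested against exhaustive subset search on small
graphs). The D-core matrix tabulates |D-core(k, l)| over the grid
0 ≤ k ≤ k_max + 1, 0 ≤ l ≤ l_max + 1, where k_max and l_max are the last
non-empty cores along each axis, so the final row and column are zero by
construction. Cores are nested in both arguments, which the implementation
exploits by pruning each cell from its predecessor instead of restarting.

The *frontier D-cores* are the last non-empty cells with respect to jointly
increasing (k, l). "Last" is formalized here as the Pareto-maximal skyline:
a non-empty cell (k, l) is frontier if no other non-empty cell (k', l') has
k' ≥ k and l' ≥ l. This choice (rather than the full visible staircase of
lower cells) reproduces a staircase of innermost cells and makes the core —
the union of frontier-cell members — as small and as densely connected as
the decomposition allows. The structural core of a graph with any edges is
never empty under this rule, since (0, 0) is always populated.

k-cores (total degree) and s-cores (total strength) are produced by one
shared peeling kernel: repeatedly delete the node(s) of minimal score,
assigning each deleted node the running maximum of the minimal score seen so
far. For integer degrees this is exactly the classical core number (verified
against `igraph::coreness`). For weights it yields the s-core level — the
largest strength threshold whose s-core still contains the node — with the
threshold sequence emerging adaptively from the peeling itself rather than
from the pre-pruning strength values; the adaptive sweep is what makes
uniform weights w give levels exactly w times the k-core numbers, which a
fixed grid of initially observed strengths does not.

## Degree-distribution fitting

Degrees are integers, so both families are fitted with discrete likelihoods
over positive support (zero-degree nodes are excluded and counted):

* **Power law** P(k) = k^(−α) / ζ(α, x_min), with the Hurwitz zeta
  normalization (direct summation plus an Euler–Maclaurin tail, accurate to
  ~1e−12). α is the conditional MLE for each candidate x_min among the
  sorted unique degrees, and the fit reported is the candidate minimizing
  the Kolmogorov–Smirnov distance between empirical and fitted tail CDFs.
  The scan is capped so the tail keeps at least 50 points: KS-minimization
  on smaller tails overfits noise. A closed-form continuous estimator
  (`powerlaw_alpha_continuous`) is exposed as an analytic cross-check; with
  the conventional half-integer shift it agrees with the discrete MLE to
  within 0.05 for x_min ≥ 6.
* **Discrete Weibull (stretched exponential)**
  P(k) ∝ k^(β−1) exp(−λ k^β) on x_min .. k_cap with finite-sum
  normalization; β = 1 is the exponential case. (λ, β) are found by
  Nelder–Mead on the log-parameters from five starts on a log-spaced β grid
  (λ starts matched via the continuous moment relation), relative tolerance
  1e−10 on the log-likelihood. The Weibull fit covers the entire degree
  range by default (x_min = smallest positive degree), matching how
  stretched-exponential behaviour shows up in dense networks: plateau at low
  k, fat but bounded tail.

**Model selection.** The two families overlap on their boundary: letting
β → 0 and λ → ∞ with λβ fixed turns the discrete Weibull mass into
k^(β−1−λβ) — a pure power law. On power-law data the fitted Weibull
therefore converges to that ridge and both KS distance and raw likelihood
are essentially tied between the families; neither discriminates. On
stretched-exponential data the situation is asymmetric (a one-parameter
power law cannot produce the low-k plateau) and every criterion agrees.
`compare_families()` consequently reports KS- and likelihood-preferences for
transparency but bases its headline `preferred` field on BIC, which charges
the Weibull for its second parameter: the penalty (log n) is negligible
against the thousands of log-likelihood units separating the families on
genuinely Weibull data, yet resolves the boundary tie toward parsimony on
power-law data. Measured on the reference synthetic conditions, BIC
selection recovers the generating family 20/20 in both directions.

## Rich-club analysis

The directed rich-club coefficient at threshold k is
RCC(k) = M_{>k} / (N_{>k}(N_{>k} − 1)): the density of directed edges among
nodes with in- (or out-) degree *strictly* greater than k. Because
high-degree nodes meet each other often by chance alone, raw coefficients
are normalized by the mean RCC of 100 degree-preserving random surrogates —
graphs rewired by directed edge swaps that keep every node's in- and
out-degree exactly (igraph's degree-sequence-preserving rewiring, 10 × E
attempted swaps per surrogate, a standard mixing heuristic recorded in the
output). Thresholds where fewer than two nodes qualify are skipped;
thresholds where the null mean is zero are reported as missing, never as 0
or infinity.

Two membership conventions are implemented: all nodes above the smallest
threshold where the normalized curve first exceeds 1
(`above_first_crossing`), and the top fraction of nodes by degree with ties
broken by eigenvector centrality (`top_fraction`; right eigenvector of the
binarized adjacency by power iteration, tolerance 1e−10). The fractions a
rich club spans are outcomes of the crossing, not inputs: the package
computes them rather than hard-coding any particular percentage.

## Topology summaries, communities and attacks

Directed clustering defaults to the Fagiolo triangle-based definition used
by the standard graph libraries; the simpler literal form
C_i = L_i / (k_i (k_i − 1)) — L_i the number of directed links among node
i's neighbors — is retained as `variant = "printed_formula"` for
auditability. Global efficiency and betweenness centrality are computed on
the largest strongly connected component, the only place directed
shortest-path averages are well defined; the betweenness ratio of a node set
is its mean betweenness over the component mean, and since any common
normalization cancels in the ratio, either library convention gives the same
number.

Community structure uses consensus Louvain: many shuffled-order runs on the
symmetrized graph, a pairwise co-occurrence matrix, a majority-rule cut
(pairs together in < 50% of runs are severed), and one final clustering of
the weighted co-occurrence graph. Modularity is reported from the directed
formula Q = Σ_c (L_c/m − γ k_c^in k_c^out / (2m²)); the 2m² null-term
denominator follows the formula as printed in the source methodology, and
the more common m² convention is available behind `variant = "standard"` —
the two differ only in the weight of the null term, not in ranking
partitions of a fixed graph, but reports name the variant so numbers are
comparable. Normalized clustering and modularity are ratios of the observed
value to the mean over degree-preserving nulls (ratio of means, not mean of
ratios).

Targeted attacks remove a node set simultaneously and report the after/
before ratio of mean clustering (entire graph) and of global efficiency
(largest SCC before and after). Note one sharp edge: removing nodes with
zero clustering shrinks the averaging denominator, so the clustering ratio
of a "harmless" removal is close to, but not exactly, 1.

## Composition profiles and diversity

Predecessors (presynaptic) and successors (postsynaptic) of a seed set are
collected with set semantics — distinct neurons, not synapse-weighted — and
second-order neighborhoods are the same step applied twice. Seeds are
excluded from their own profiles by default, since the object of interest
is the core's external interface. Cell-type profiles are normalized
frequencies over a vocabulary that defaults to every type present in the
annotation (not only types observed in the profile), so the diversity
denominator n reflects the type richness of the dataset; a fixed vocabulary
can be supplied for cross-network comparisons.

Two diversity indices are reported. Normalized Shannon entropy
H = −Σ p_i ln p_i / ln n lies in [0, 1] and is 1 exactly at the uniform
profile. For the Simpson index the raw form S = n Σ p_i² is analytically
≥ 1 and *decreases* with evenness, which contradicts reading it as a
diversity that is "higher when more diverse" on a 0–1 scale; the package
therefore defaults to the inverse form 1/(n Σ p_i²) ∈ (0, 1] — the unique
monotone-in-diversity rescaling of the same statistic — and exposes the raw
form as `form = "as_printed"`. Both indices are permutation-invariant in
the labels.

The type connectivity matrix normalizes directed type-to-type edge counts
by the number of possible connections, E_ij/(N_i N_j) off-diagonal and
E_ii/(N_i(N_i − 1)) on it (a type with one neuron gets NA there, not a
division by zero), and doubles as a weighted digraph over types on which
the s-core kernel ranks type centrality in in-, out- and total-strength
variants.

## The synthetic generator

No generative model is claimed by the analysis itself; the generator is an
artifact decision that emulates just the statistical features the pipeline
consumes:

* **Planted core** (`generate_planted_core`): every ordered pair sampled
  independently with a block probability — dense core–core, weak
  core–periphery, sparse periphery–periphery — and the core confined to a
  single cell-type label. The reference condition used across the tests is
  n = 200, core 20, p_cc = 0.6, p_cp = 0.05, p_pp = 0.01, labels
  A/B/C at 0.4/0.3/0.3: core nodes then hold interior in/out degrees
  around 11 against a periphery around 3, a separation comparable (in
  ratio) to a real core while keeping the graph small enough for seeded
  20-replicate tests in seconds. Under these conditions the frontier D-core
  recovers the planted core at mean Jaccard ≈ 0.95.
* **Degree models** (`sample_degree_sequence`): inverse-CDF sampling from
  the discrete Weibull or power-law mass on x_min .. k_cap, with
  k_cap = n − 1 by default (degrees cannot exceed N − 1) and an optional
  ±1 parity fix so in/out sequences can be paired. The reference recovery
  conditions are λ = 0.025, β = 1.3 at n = 3000 (Weibull, parameters of a
  dense-brain-like fit) and α = 2.5, x_min = 5 at n = 10000 (power law in
  the scale-free regime).
* **Configuration model** (`directed_configuration_graph`): uniform stub
  matching with self-loops and duplicate pairs dropped and counted — not
  rewired — the standard simple-graph projection; dropped counts are
  surfaced so tests can bound the loss.

What the generator does **not** emulate: joint in/out-degree correlation,
reciprocity, spatial embedding, neuropil structure, or synapse-count
distributions. Passing tests on synthetic data therefore validate the
algorithms and their contracts, not any biological claim about a particular
connectome.

## Numerical choices and degenerate inputs

* Hurwitz zeta by 1000-term summation + Euler–Maclaurin tail; Weibull
  normalization by explicit finite sum with log-sum-exp stabilization.
* Weibull optimizer: 5 Nelder–Mead starts, reltol 1e−10; an error with
  diagnostics if every start fails.
* All-equal degree data raises a degenerate-data error in both fitters
  rather than returning a meaningless fit.
* Empty graphs, edgeless graphs, single-node components, singleton types
  and never-crossing rich-club curves all return defined empty/NA results
  (with warnings where a silent empty set could mislead).
* Every stochastic routine takes an explicit seed; the pipeline derives
  per-stage seeds from the global seed by fixed offsets so toggling one
  stage never shifts another's stream.

## Problem sizes

The shipped test-suite and acceptance runs use 200-node planted-core graphs
(20 seeds), degree samples of 3,000–10,000 (20 seeds per condition), null
ensembles of 30–100 surrogates, and exhaustive oracles up to 7 nodes —
sizes chosen so a full validation cycle completes in about a minute on one
CPU while keeping every estimate's Monte-Carlo error far below the test
tolerances. The algorithms themselves have no small-size assumptions; the
D-core matrix on a 3,000-node, 90,000-edge graph computes in minutes.

## Known limitations

* Louvain runs on the symmetrized graph (directed modularity is used for
  reporting, not for the optimization itself), the common practical
  compromise; a natively directed optimizer could find slightly different
  partitions.
* The weighted rich club, bootstrap plausibility p-values for the power
  law, and log-normal/exponential alternatives are out of scope.
* The consensus co-occurrence matrix is dense (n × n); for graphs beyond a
  few tens of thousands of nodes use a single Louvain run instead, as the
  pipeline's `n_runs_louvain = 1` does.
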