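---
title: "Probabilistic domination control: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic domination control: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probdom)
```

## The control model

`probdom` analyses undirected networks whose edges carry an interaction
probability $w_{ij} \in [0, 1]$ — in the motivating application, dynamic
protein–protein interaction networks in which the weight reflects how
reliably both partners are expressed in a tissue and age group. The
complementary failure probability is $\rho_{ij} = 1 - w_{ij}$.

In the classical minimum dominating set (MDS) picture of network control, a
driver set $S$ must contain or neighbour every node. With probabilistic
edges a single neighbouring driver may not be enough: we require that every
node outside $S$ be reached through at least one functioning edge with
probability at least a threshold $\Theta$,

$$1 - \prod_{v_j \in S \cap N(v_i)} \rho_{ij} \;\ge\; \Theta
  \quad\text{or}\quad v_i \in S ,$$

treating edge failures as independent. Taking logarithms turns the product
constraint into a linear one,

$$-\ln(1-\Theta)\, x_j \;+ \sum_{(i,j) \in E} \big(-\ln \rho_{ij}\big)\, x_i
  \;\ge\; -\ln(1-\Theta), \qquad x \in \{0,1\}^V,$$

with degree-0 nodes forced into $S$ outright. A *probabilistic minimum
dominating set* (PMDS) is a minimum-cardinality feasible $S$. Because the
optimum is rarely unique, each node is classified by its role across **all**
minimum solutions:

* **critical** — in every minimum feasible driver set;
* **intermittent** — in some but not all;
* **redundant** — in none.

## The exact solver

The package ships its own exact combinatorial solver (C++, branch and
bound) for the log-space formulation. Its contract is proven optimality:
it either returns a minimum driver set, reports that the caller's fixings
admit no feasible set, or fails loudly when its search budget is exhausted
— never a silent suboptimal answer. The search combines

* *unit propagation*: a node whose entire remaining neighbourhood cannot
  reach $\Theta$ must self-select; an excluded node with insufficient
  potential coverage closes the branch;
* a *leaf exchange* reduction: a degree-1 node whose hub can cover it can
  be dropped from consideration, because any solution using the leaf can
  swap it for the hub without growing;
* *component decomposition* of the residual instance after propagation —
  on sparse networks near the percolation threshold most components are
  tiny and independent;
* a greedy incumbent and a packing lower bound from pending nodes with
  pairwise-disjoint helper sets (fewest-helpers-first).

Classification re-solves are answered in *decision mode*: to decide whether
excluding or forcing a node changes the optimum it is enough to search for
a solution no larger than the baseline, pruning everything deeper and
stopping at the first witness. Residual components untouched by the changed
fixing are shared between re-solves through a component cache.

## Reduction rules

Three sound rules classify many nodes before any search:

1. a node with **two or more degree-1 neighbours**, each coverable above
   $\Theta$ ($1-\rho_{ij} > \Theta$), is critical — a minimum solution
   omitting it would have to select both leaves, and exchanging them for
   the hub gives a strictly smaller feasible set (both leaves must be
   coverable for the exchange to work, which is why the rule demands two
   *qualifying* leaves rather than merely two leaves);
2. a node whose neighbours are **all critical** and whose full
   neighbourhood covers it above $\Theta$ is redundant — it is always
   covered, and could only help nodes that are themselves selected;
3. a node whose **entire neighbourhood cannot reach** $\Theta$
   (including isolated nodes) must self-select everywhere, hence is
   critical.

The number of rule-3/rule-1 criticals is a certified lower bound on the
PMDS size. The package iterates the three-rule sweep to a fixpoint by
default: each rule is a valid implication, so later passes can only
classify more nodes (rule-3 criticals can enable further rule-2
redundants). `single_pass = TRUE` restores the literal one-sweep order for
comparison. Classification with the rules enabled, disabled, or in
single-pass mode yields identical partitions — only the amount of exact
search changes — and this equivalence is exercised directly by the test
suite, which is the testable content behind using the rules as a
preprocessing accelerator (wall-clock speed-ups are hardware-dependent and
deliberately not asserted).

## Numerical choices

* **Threshold form.** The strict coverage inequality and its non-strict
  log-space counterpart differ only on boundary ties, which have measure
  zero for continuous weights. The solver adopts the non-strict form with
  an absolute tolerance `epsilon = 1e-9`; the reduction rules keep their
  strict inequalities with the same epsilon guard, so a rule that declines
  to fire on a tie is merely conservative and the exact stage settles the
  node.
* **Certain edges.** $\rho = 0$ makes $-\ln\rho$ infinite; the coefficient
  is capped at `log_cap = 50`. Since $e^{-50} \approx 2\times10^{-22}$,
  one capped edge satisfies any threshold $\Theta \le 1 - 10^{-21}$, so
  the semantics that a certain edge always covers its endpoint is
  preserved with finite coefficients.
* **Zero-weight edges** are admitted (they contribute nothing to
  coverage) but flagged with a warning at construction.
* **Determinism.** Nodes are canonicalised to lexicographic order and the
  search is fully deterministic, so the partition is independent of input
  order and of which optimal solution the engine happens to return.

## The benchmark generator

`generate_scale_free_weighted()` emulates the simulation conditions used
to validate the classifier: networks with a power-law degree distribution
$P(k) \propto k^{-\gamma}$ with $\gamma = 2.1$, average degree
$\langle k \rangle = 2$, realised by Havel–Hakimi construction and
randomized by degree-preserving double edge swaps, with independent
uniform $[0,1]$ edge weights interpreted as interaction probabilities.
Defaults and their rationale:

* `k_max` defaults to $\lfloor\sqrt{n}\rfloor$ and is tuned downward so
  the expected mean degree of the truncated power law matches
  `k_avg`; sampled sequences are accepted when the realised mean is
  within 10 % of the target, the sum is even and the sequence is
  graphical (Erdős–Gallai). Note that this truncation steepens the
  empirical *CCDF* below $-(\gamma-1)$; the undistorted check of the tail
  exponent is the log–log slope of the *pmf*, which recovers $-\gamma$
  and is what the test suite asserts.
* `n_swaps` defaults to $10\,|E|$ attempted swaps, a common mixing
  heuristic for edge-swap randomization.
* Uniform edge values are interpreted as success probabilities $w$ (not
  failures $\rho$); for symmetric uniform weights the two conventions give
  identical aggregate statistics, so the choice is a convention, and it
  matches the definition $\rho = 1 - w$ used everywhere else.

## Expression integration

The dynamic-network path consumes categorical presence/absence detection
calls (P/M/A per probe per sample), not raw intensities — running the
underlying detection algorithm is out of scope. For a gene with $q$ probes
and an age group with $y$ samples the expression score is the pooled
fraction of expressed cells among all $q \times y$ probe×sample cells
(e.g. 8 expressed cells out of $4 \times 3$ give $8/12 \approx 0.67$).
Two conventions are configurable because the underlying data conventions
are genuinely ambiguous:

* **marginal calls** score 0 by default (conservative);
  `marginal_as_expressed = TRUE` scores them 1;
* **edge presence** requires both endpoint scores to be nonzero by
  default; `presence_threshold = 0.5` imposes a majority rule instead.

Kept edges are weighted by the arithmetic mean of the endpoint scores
(geometric mean available; arithmetic dominates geometric edgewise by
AM–GM, with equality only for equal scores), and failure probabilities are
$1 - w$.

The synthetic generator `simulate_detection_calls()` draws each cell as an
independent Bernoulli presence call with a per-gene, per-group probability,
plus an independent marginal-downgrade rate. It reproduces the *statistical
structure* of multi-probe detection data — binomial pooling of cells,
many-to-one probe maps, group-wise sample structure — but none of the
correlation structure of real arrays (probe affinity differences,
within-sample correlation, batch effects). Passing tests therefore
demonstrate correctness of the scoring and network-construction machinery,
not robustness to those real-data artefacts.

## Enrichment statistics

For a control category $S$ within a network of $N$ nodes and a reference
gene set $A$ ($N_A$ of whose members occur in the network), the enrichment
is $E = \ln(f_{AS}/f_A)$ with $f_A = N_A/N$ and $f_{AS} = N_{AS}/N_S$.
Significance uses the exact two-tailed Fisher test — the conventional
two-sided convention, summing all tables with the observed margins whose
probability does not exceed the observed table's. The universe is the node
set of the analysed network, not the whole genome. $N_{AS} = 0$ yields
$E = -\infty$ with the p-value still defined; an optional $+0.5$
pseudo-count variant exists for plotting only. No multiple-testing
correction is applied across groups or categories; users comparing many
thresholds or tissues should correct downstream.

## Problem sizes and limitations

The test suite and the acceptance script exercise the solver at the scales
where exhaustive verification is possible: enumeration oracles up to 12
nodes, threshold sweeps at $n = 100$, and rule-neutrality checks on
$n = 500$ scale-free benchmarks, with the synthetic expression cohort at
40 genes. These sizes were chosen so every claim is verified against an
independent oracle or an exact invariant.

Known limitations:

* exact search scales with the largest residual component after
  propagation; dense or very large instances (e.g. $n \gtrsim 5000$ at
  $\Theta = 0.5$ on scale-free topologies) can exhaust the default search
  budget (`max_nodes`), which raises an explicit solver failure rather
  than returning an approximation — raise the budget, or lower it to fail
  faster;
* only undirected networks are supported; directed probabilistic
  domination is a different problem;
* the enumeration oracle is exponential and guarded at 20 nodes;
* Fisher tests are per-category; no correction across the many
  (group × category × threshold) combinations a full study produces.
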