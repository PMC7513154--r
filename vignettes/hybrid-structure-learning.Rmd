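---
title: "Hybrid Bayesian-network structure learning with explicit and vague expert knowledge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid Bayesian-network structure learning with explicit and vague expert knowledge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evbic)
```

## The problem

A discrete Bayesian network is a pair $BN = (G, \rho)$: a directed acyclic
graph $G = (V, E)$ over random variables $X_1, \dots, X_n$ together with
one conditional probability table per node, so that the joint
distribution factorizes as
$P(X_1, \dots, X_n) = \prod_i P(X_i \mid \pi(X_i))$ with $\pi(X_i)$ the
parent set.  Recovering $G$ from data alone is NP-hard, the number of
candidate DAGs is super-exponential in $n$ (`count_dags(4)` is already
543), and observational data cannot distinguish Markov-equivalent
structures.  Domain experts can break these symmetries — but real expert
statements are heterogeneous: some fix the causal state of a node pair
exactly, others only restrict it.

This package implements a two-stage hybrid learner that uses both.  For
every unordered node pair, in the canonical row-major order of
`enumerate_node_pairs()`, an expert may assert one of six kinds of
knowledge about the pair $(X, Y)$:

| code | statement | type |
|------|-----------|------|
| 1 | $X \to Y$ | explicit |
| 2 | $Y \to X$ | explicit |
| 3 | $X$ and $Y$ not adjacent | explicit |
| 4 | adjacent, direction unknown | vague |
| 5 | $X$ is not a parent of $Y$ | vague |
| 6 | $Y$ is not a parent of $X$ | vague |

Each expert carries six accuracy parameters: $\gamma_1$ (probability of
reporting the correct orientation of a true arc), $\gamma_2$ (reversed
orientation), $\gamma_3$ (correctly reporting a truly absent edge) for
explicit statements, and $\beta_1, \beta_2, \beta_3$ analogously for
vague statements.  The package ships a ten-expert panel
(`default_expert_accuracies()`) with $\gamma_1$ between 0.65 and 0.8,
$\gamma_2$ between 0.11 and 0.2, $\gamma_3$ between 0.7 and 0.82, and
$\beta_i = \gamma_i$ per expert.

## Knowledge likelihood trees

Scoring and simulation both need the likelihood of a report given the
true edge state $e \in \{\to, \leftarrow, \not\leftrightarrow\}$.  For
explicit reports: under a true arc the expert reports the correct
orientation with $\gamma_1$, the reverse with $\gamma_2$, absence with
$1 - \gamma_1 - \gamma_2$; under true absence, absence with $\gamma_3$
and each orientation with $(1 - \gamma_3)/2$.  The vague tree mirrors it:
under a true arc, "adjacent" with $\beta_1$, the exclusion that wrongly
rules out the true direction with $\beta_2$, the compatible exclusion
with $1 - \beta_1 - \beta_2$; under absence, "adjacent" with
$1 - \beta_3$ and each exclusion with $\beta_3/2$.  This is the only
parameterization that normalizes and is consistent with the credibility
assignments below; both trees are property-tested for normalization over
an accuracy grid.

## Stage 1: knowledge-modified initial structure

1. **Skeleton.** Every pair with a maximal-information-coefficient score
   above a threshold $\tau$ (default 0.1) receives an undirected edge.
   For discrete data the MIC is computed exactly: normalized mutual
   information maximized over contiguous groupings of the state codes,
   with the usual $n^{0.6}$ cell bound and the native category grid
   always admissible.  The skeleton is then pruned by G² (likelihood
   ratio) conditional-independence tests at level $\alpha = 0.05$ over
   conditioning sets of size up to 3 drawn from current neighbours;
   separating sets are recorded.
2. **Credibility and fusion.** The credibility $\theta$ of a statement
   is the probability it is true: $\theta_1 = \theta_2 = \gamma_1$,
   $\theta_3 = \gamma_3$, $\theta_4 = \beta_1 + \beta_2$,
   $\theta_5 = \theta_6 = 1 - \beta_2$.  Conflicting statements about
   one pair are resolved by roulette: credibilities are summed per kind
   and normalized into selection probabilities
   $P_l = \sum_{i \in G_l} \theta_l^i / \sum_l \sum_{i \in G_l} \theta_l^i$,
   one kind is drawn from the six subintervals of $[0,1]$, and its
   credibility is the arithmetic mean over its supporters.  Fused
   statements are routed into four sets: explicit arcs, explicit
   absences, vague adjacencies, and vague exclusions (a "Y is not a
   parent of X" statement is canonicalized to the ordered assertion
   "X is not a parent of Y" on the reversed pair).
3. **Rules.** On the undirected skeleton, vague adjacencies add edges
   and explicit absences delete them; each statement fires iff a uniform
   draw lands in the open interval $(0, \theta)$, consuming exactly one
   draw either way.  V-structures are then oriented: an unshielded
   triple $x - z - y$ becomes the collider $x \to z \leftarrow y$ when
   no separating set of $(x, y)$ contains $z$; the first orientation of
   an edge wins, and an orientation that would close a directed cycle
   among the arcs oriented so far is skipped (finite-sample test
   conflicts can otherwise produce cyclic intermediates).  On the
   resulting partial graph, vague exclusions delete the matching
   directed arc and explicit arc statements insert their arc, replacing
   an undirected edge or a reversed arc; insertions that would close a
   cycle are skipped and logged.  Vague rules run before explicit rules
   within each phase, pairs in canonical order, so a run is fully
   reproducible from its seed.

## Stage 2: BPSO search under EVBIC

The stage-1 output seeds a binary particle swarm search over adjacency
matrices.  Half the swarm starts from independent random completions of
the seed structure (undirected edges oriented at random, rejecting
cycles), half from sparse random digraphs; every position is repaired to
acyclicity by deleting, on each detected cycle, the arc with the largest
row-major pair index.  Velocities follow the standard
inertia/cognitive/social update with sigmoid transfer and clamping
(defaults $w = 0.8$, $c_1 = c_2 = 2$, $v_{\max} = 4$, 30 particles, 200
iterations — conventional binary-PSO settings, exposed via
`swarm_params()`).  The global-best trace is non-decreasing and ties
keep the first-found particle.

The objective is the EVBIC score
$$\mathrm{EVBIC}(G) = \mathrm{BIC}(D \mid G)
  + \sum_{j,i} \log P(V^{explicit}_{ij} \mid e_i(G), \gamma_j)
  + k \sum_{j,i} \log P(V^{vague}_{ij} \mid e_i(G), \beta_j),$$
with $\mathrm{BIC} = \sum m_{ijk} \ln (m_{ijk}/m_{ij}) -
\tfrac12 \ln N \sum_i q_i (r_i - 1)$.  The penalties sum over the raw
per-expert reports (fusion feeds stage 1 only), evaluated at the edge
state the candidate structure assigns to each pair.  $k \in [0, 1]$
down-weights vague reports; the default 0.5 reflects that each vague
statement leaves two causal states possible.  Reports with zero
likelihood under a candidate state contribute a finite floor
$\ln 10^{-12}$ so the search never sees infinities.  A data-only run
uses plain BIC; the BDeu-based explicit-accuracy score
(`explicit_accuracy_score()`, BDeu marginal likelihood plus the explicit
penalty) is provided as the baseline knowledge-aware score.  With one
explicit $\to$ report, EVBIC separates the Markov-equivalent two-node
structures by exactly $\ln(\gamma_1/\gamma_2)$ — the mechanism by which
knowledge breaks score equivalence.

## Simulated experts and the experiment driver

`simulate_experts()` emulates a heterogeneous panel judging a known
structure: `round(v * n_pairs)` pairs are selected uniformly (ties round
up), every expert reports on every selected pair, and each report is
drawn from the appropriate likelihood tree conditioned on the true edge
state.  Three study cases are supported: explicit-only, vague-only, and
mixed.  In the mixed case every expert contributes *both* one explicit
and one vague report per selected pair: a panel able to give both kinds
of statement carries strictly more information than either kind alone,
which is what makes the mixed case the strongest condition rather than a
dilution of the explicit one.  Explicit reports are drawn before vague
ones, so under a shared seed the mixed case is an exact superset of the
explicit case and all cases select the same pairs — a deliberate
common-random-numbers design that turns between-case contrasts into
paired comparisons.

`run_experiment()` runs the full protocol: for each knowledge case and
coverage $v$, ten (configurable) replicates each forward-sample a
dataset from the ground-truth network, simulate one knowledge set, learn
with knowledge placed in stage 1, stage 2, or both, and score the result
against the truth by the added/deleted/inverted/correct decomposition
whose sum A + D + I is the structural Hamming distance.  Replicate $r$
shares its dataset, knowledge stream and search seed across all
conditions.  Summaries report MR (means over replicates) and BR (best:
minimum SHD, maximum score).

The generator emulates the benchmark protocol, not real elicitation:
experts are conditionally independent given the truth, report on every
selected pair, and have known, stationary accuracies.  Passing tests
therefore demonstrate correct behaviour under the model's own
assumptions; correlated experts, selective silence, or mis-estimated
accuracies are outside what the simulation can show.

## Numerical and design choices

* **Benchmark CPTs.** The Asia (8 nodes / 8 arcs) and Alarm (37 / 46)
  structures ship with the package, but their published probability
  tables do not; `random_cpts()` draws CPT rows from a symmetric
  Dirichlet with concentration 0.3, chosen once to emulate the strongly
  diagnostic rows typical of the clinical benchmarks.  Users can supply
  literature CPTs through `read_network()` (BIF or the plain two-file
  format) for faithful reproduction.
* **Problem sizes.** The bundled experiments run the 8-node benchmark
  with 500-record datasets, ten replicates per condition, coverage
  $v = 0.6$, and a 20-particle, 60-iteration swarm — enough for the
  search to reach the exhaustively verified optimum on small problems
  in nearly every run while keeping a full case-and-placement sweep in
  the minutes range.  The 37-node benchmark is exercised structurally;
  swarm sizes for it should be scaled up by the user.
* **RNG.** All stochastic entry points take a `seed` argument and use
  R's global stream sequentially; every rule application consumes
  exactly one draw whether or not it fires, so runs are bit-reproducible.
* **Ties and degenerate input.** Equal swarm scores keep the first
  particle; conflicting v-structure orientations keep the first; a
  constant variable has MIC 0 and never enters the skeleton; empty
  conditioning strata contribute zero to G²; probabilities are compared
  at $10^{-9}$ absolute tolerance.
* **Open points resolved.** The vague-exclusion rule deletes only the
  matching directed arc, leaving undirected edges alone (deleting both
  would let a weak exclusion override a stronger adjacency statement).
  Whether skeleton pruning uses CI tests in addition to MIC is
  ambiguous in the underlying method description; both are implemented
  and pruning is on by default (`prune = FALSE` disables it).

## Known limitations

DAG-space search scales poorly past a few dozen nodes in pure R; the
SHD evaluation compares raw DAGs, not equivalence classes, so an
unidentifiable-but-equivalent orientation counts as an inversion; the
credibility formulas are taken as given rather than derived from a
probabilistic model of expert behaviour; and parameter learning beyond
maximum-likelihood counts (and inference beyond brute-force enumeration)
is out of scope.
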