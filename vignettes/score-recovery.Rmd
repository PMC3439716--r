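---
title: "Evaluating Bayesian network scoring functions for structure recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating Bayesian network scoring functions for structure recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnrecover)
```

## The question

Score-based structure learning for discrete Bayesian networks assigns
each candidate DAG a decomposable score and searches for a maximizer.
Several scoring families are in routine use — MDL/BIC, AIC, BDeu, and
fNML — and they generally disagree about which network is best. This
package implements a controlled simulation design for asking which of
them actually recovers a *known* generating structure: fix a gold
network, sample datasets of increasing size from it, relearn structures
under each score with a *globally optimal* learner, and measure the
structural distance back to the gold network. Using an optimal learner
matters: with heuristic search, a bad reconstruction may be the fault
of either the score or the search, and the two cannot be separated.
A greedy hill climber is included precisely to quantify that gap.

## Model and scores

A discrete Bayesian network is a pair $B = \{G, \Theta\}$: a DAG $G$
over variables $X_1,\dots,X_n$ and conditional probability tables
$\Theta$ giving $P(X_i \mid PA_i)$ for each variable's parent set
$PA_i$. The joint factorizes as $P(V) = \prod_i P(x_i \mid pa_i)$.
With complete data $D$ of size $N$, writing $N_{ijk}$ for the number
of rows with $X_i = k$ and $PA_i$ in configuration $j$, and
$N_{ij} = \sum_k N_{ijk}$, all four scores take the penalized
log-likelihood form

$$\mathrm{Score}(B \mid D) = \sum_i \Big[ LL_i - \mathrm{Pen}_i \Big],
\qquad LL_i = \sum_{j,k} N_{ijk} \log \frac{N_{ijk}}{N_{ij}},$$

with per-variable penalties (all our logarithms are natural; the
discretizer's entropies are the only base-2 quantities, and only a
constant separates the two — argmaxes are unaffected):

* **MDL/BIC**: $\frac{\log N}{2} p_i$ with $p_i = (r_i - 1) q_i$ free
  parameters ($r_i$ states, $q_i$ parent configurations). We use the
  maximizing sign convention, under which MDL and BIC coincide.
* **AIC**: $p_i$.
* **BDeu($\alpha$)**: not literally a penalty — the local score is the
  log marginal likelihood under symmetric Dirichlet priors that spread
  an equivalent sample size $\alpha$ as $\alpha/q_i$ per configuration
  and $\alpha/(r_i q_i)$ per cell,
  $$\sum_j \left[ \log\frac{\Gamma(\alpha/q_i)}{\Gamma(\alpha/q_i + N_{ij})}
  + \sum_k \log\frac{\Gamma(\alpha/(r_i q_i) + N_{ijk})}{\Gamma(\alpha/(r_i q_i))} \right].$$
* **fNML**: $\sum_j \log C^{r_i}_{N_{ij}}$, where $C^k_N$ is the
  multinomial regret (parametric complexity) — the sum of maximized
  likelihoods over all $k$-ary datasets of size $N$. We evaluate
  $C^2_N$ exactly by log-sum-exp over its binomial sum and extend to
  larger $k$ with the linear recurrence
  $C^{k+2}_N = C^{k+1}_N + (N/k)\, C^k_N$, all in log space; this is
  stable to $N = 10^5$ and beyond.

MDL, AIC, and BDeu are score equivalent (Markov-equivalent DAGs tie);
fNML is not, and the test suite exhibits a violating pair rather than
pretending otherwise.

Conventions adopted where the literature leaves slack: $0 \log 0 = 0$
everywhere; maximum-likelihood CPT rows for never-observed parent
configurations are filled with the uniform distribution (this keeps
forward sampling from fitted networks well-defined); parameter counting
uses free parameters $(r_i - 1) q_i$.

## Learners

`exact_learn()` is a subset dynamic program. Per variable, a
best-parents table over candidate sets is built from the local-score
recurrence $\mathrm{best}(C) = \max\{\mathrm{score}(C),
\max_{c \in C} \mathrm{best}(C \setminus \{c\})\}$; the network layer
then peels sinks: the best network on a subset $W$ is the best over
sinks $s \in W$ of the best network on $W \setminus \{s\}$ plus the
best parents for $s$ within $W \setminus \{s\}$. Memory grows as
$2^n$, so the learner refuses more than 16 variables by default; an
optional `max_parents` bound extends the practical range. Ties are
broken deterministically: smaller parent set, then lexicographic, and
earliest-declared sink — so two runs always return the same DAG, even
under exact score ties.

`hill_climb()` is the comparison heuristic: steepest-ascent over add /
delete / reverse operators that preserve acyclicity, accepting only
strictly improving moves, with the inverse of each accepted move held
in a fixed-length tabu list and random restarts (restart 0 from the
empty graph, later restarts from random DAGs with edge probability
$2/n$). The restart count (10), tabu length (100), and stopping rule
are our choices — the original experimental design leaves them
unspecified — and are exposed as arguments. Strict ascent means a
restart terminates the first time no improving non-tabu move exists.

`brute_force_learn()` enumerates every labeled DAG on up to 5 nodes
(25 at $n=3$, 543 at $n=4$) and is kept solely as a test oracle for
the dynamic program.

## Evaluation metrics

Confusion counts live on unordered variable pairs: a correctly
oriented shared edge is a TP, a shared absence a TN, an edge only in
the learned (gold) graph an FP (FN), and an adjacency oriented the
wrong way counts as *both* an FP and an FN. From these, accuracy,
sensitivity, and the average Hamming distance AHD = (FP+FN)/n. When a
denominator is empty (no gold edges, or a single variable) the metric
is defined as 1: no error was possible.

SHD operates on equivalence classes instead: each DAG is converted to
its CPDAG by Chickering's edge-ordering and labelling algorithm
(compelled edges stay directed, reversible edges become undirected;
v-structure edges are always compelled), and one unit is charged per
pair whose adjacency or edge type differs. Reversing $X \to Y$ into
$X \leftarrow Y$ therefore costs 0 — the two DAGs are the same model.
The reported decomposition is: **add** (adjacency only in the learned
CPDAG), **delete** (only in the gold), **rev** (both directed,
opposite orientation), and **mis** (adjacent in both, but compelled in
one and reversible in the other). The last bucket is the
compelled-status mismatch column of the study's structural-error
tables; grouping it with deletions would conflate lost adjacencies
with lost orientations.

## Preparing raw tables

The gold networks of the original design were learned from small
real-world datasets after cleaning, and that path is implemented in
full. Missing values are imputed by kNN with $k = 5$: distances are
Euclidean over min–max-scaled continuous columns plus 0/1 mismatch on
categorical ones, computed over the record's observed columns and
excluding the target; continuous targets take the neighbour mean,
categorical targets a majority vote (ties to the smallest state
index). The published description commits only to "Euclidean distance,
for example", so the mixed-type metric is our documented choice, as is
the impute-then-discretize order (imputation distances are more
meaningful on raw values).

Continuous columns are then discretized by supervised MDLP: recursive
binary splitting at the boundary minimizing the size-weighted class
entropy $E = \frac{|S_1|}{|S|}\mathrm{Ent}(S_1) +
\frac{|S_2|}{|S|}\mathrm{Ent}(S_2)$, accepted while
$\mathrm{Gain} > \log_2(|S|-1)/|S| + \Delta/|S|$ with
$\Delta = \log_2(3^k - 2) - [k\,\mathrm{Ent}(S) - k_1\,\mathrm{Ent}(S_1)
- k_2\,\mathrm{Ent}(S_2)]$. Candidate cuts are all midpoints between
consecutive distinct values; restricting to class-boundary midpoints
would find the same minima but we keep the full set so degenerate
pure-class columns still report their (rejected) best cut. Columns
earning no cut are single-state and dropped from modelling with a
warning — a variable with one state carries no structural signal.

## The synthetic generator

`benchmark_suite()` provides 13 networks whose (node, edge) counts
match the published benchmark profiles exactly (5–20 nodes, 8–46
edges); `random_gold_network()` draws DAGs to a target average
in-degree by giving each predecessor-pair an equal edge probability
$2\bar d/(n-1)$. CPT rows are symmetric Dirichlet with concentration
1.0 by default. Plain Dirichlet CPTs often encode dependencies too
weak to recover at realistic sample sizes — recoverability of a random
parameterization is simply not guaranteed — so the generator has a
*sharpening* mode that moves a fraction of each row's mass (0.85 in
the fixed `recovery_suite()`) onto a randomly chosen dominant state.
The recovery suite — six networks of 5–10 variables, average in-degree
1.5, binary/ternary arities, sharpened CPTs — is the fixed condition
set for the recovery and $\alpha$-sensitivity experiments. The
sample-size grid is 200–1000 by 200 and 2000–10000 by 1000: 14
distinct sizes (the two printed ranges share the 1000 endpoint).

What the generator does *not* emulate: real tables have deterministic
logical constraints, class-imbalanced marginals, and discretization
artifacts; synthetic CPTs have none of these, so passing recovery
tests here demonstrates correctness of the machinery and the
qualitative score ranking under identifiable conditions, not
performance on any particular real dataset.

## Experiment orchestration

`run_experiment()` crosses gold networks × sizes × replicates ×
scores × learners, deriving every per-cell seed deterministically from
the base seed, so a rerun of the same configuration reproduces every
record bit-for-bit. Per dataset, sufficient statistics are computed
once and scored under all requested specifications. Exact-learner
capability errors (too many variables) are recorded per cell rather
than aborting the run. `summarize_shd()` reduces each (network, score)
series to min/mean/max/population-SD across the grid, averaging
replicates within a size first; `detect_convergence()` reports the
smallest grid size from which a series is constant to the end — the
"adding more data no longer changes the metric" criterion. Per-size
datasets are sampled independently; nothing in the design requires
nested prefixes, and independent draws keep replicates exchangeable.

The `analysis/` scripts are the workflow's entry points (build gold
networks, sample, learn, report, and the raw-table demonstration);
because every computation lives behind package functions, no separate
command-line wrapper is needed.

## Problem sizes and defaults used in the shipped runs

The packaged experiment (`analysis/03_learn_structures.R`) uses the
six-network recovery suite at sizes {200, 600, 1000, 5000, 10000} with
two replicates and the full 12-spec score grid; the automated recovery
checks use the same suite at the grid's endpoints {200, 10000} with
ten replicates and three specs (MDL, BDeu $\alpha \in \{1, 100\}$).
These sizes keep a full run on one core in the minutes range while
still spanning two orders of magnitude of data; the qualitative
findings (MDL improves monotonically with data; extreme $\alpha$
degrades BDeu badly) are insensitive to the subset chosen.

## Known limitations

* The exact learner's $2^n$ tables cap it at 16 variables by default;
  the three largest benchmark profiles (17, 19, 20 nodes) are learnable
  only with a `max_parents` bound or the greedy climber.
* fNML's regret recurrence is evaluated per distinct $N_{ij}$ and
  cached, but a fresh session recomputes the $C^2_N$ binomial sum per
  $N$; this is linear in $N$ and negligible below $10^5$ rows.
* `detect_convergence()` uses exact value equality, as the convergence
  criterion demands; metrics on continuous scales (accuracy, AHD with
  non-integer averaging) rarely converge exactly under replicate
  averaging — SHD's integer-valued stability is precisely why it is
  the headline metric.
* The kNN imputer is $O(\text{missing} \times \text{complete})$ per
  column and intended for the small tables this design studies.
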