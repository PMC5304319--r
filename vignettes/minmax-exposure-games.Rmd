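---
title: "Minmax exposure to unfitness as a mechanism for fitness-proportional attachment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minmax exposure to unfitness as a mechanism for fitness-proportional attachment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minmaxfit)
```

## The model

Growth models for scale-free networks often posit that a newcomer attaches
to an existing node $i$ with probability proportional to some measure of
attractiveness: node degree $k_i$ (classical preferential attachment),
degree times intrinsic fitness $k_i\phi_i$, or fitness alone,
$p_i \propto \phi_i$ (lognormal fitness attachment). The proportionality
itself is usually assumed rather than derived. This package implements a
behavioural mechanism that produces it: suppose each node carries an
*unfitness* $U_j = 1/\phi_j$, and the connecting agent chooses attachment
probabilities $p$ to minimise its worst expected exposure to unfitness,

$$\min_{p \in \Delta} \; \max_j \; p_j U_j,
\qquad \Delta = \{p : p \ge 0,\ \textstyle\sum_j p_j = 1\}.$$

Because the objective is a maximum of linear functions, the optimum
equalizes all exposures: $p_j^* U_j = V^*$ for every $j$, which forces

$$p_j^* = \frac{\phi_j}{\sum_i \phi_i}, \qquad
V^* = \frac{1}{\sum_i \phi_i}.$$

Risk-averse avoidance of the weakest links is thus exactly
fitness-proportional attachment. The Lagrangian of the program has one
multiplier $q_j$ per exposure constraint and one, $\lambda$, on the simplex
constraint; at the optimum $q^* = p^*$ and $\lambda^* = V^*$ whenever all
$\phi_j > 0$ (strict positivity is enforced at construction time for
exactly this reason — see *Numerical choices*).

The dual variables have a game interpretation: a "demon" (malware, disease,
a biased influence) chooses which node's unfitness to expose, with
probability $q_j$, while the scheduler chooses where to attach. The minmax
program is the value problem of this two-player zero-sum game.

For *tiered* systems — supply chains with suppliers, manufacturers,
distributors, retailers; food webs; layered bipartite structures — a
feasible choice is a path taking one node per tier, and the same
minmax-exposure principle applies per tier. Since every feasible path
crosses every tier, the program decouples into one homogeneous problem per
tier, with per-tier values $V_k^* = 1/\sum_{j \in N_k}\phi_{jk}$.

## Three solution routes, kept deliberately separate

1. **Closed form** (`closed_form_attachment()`, `minmax_value()`,
   `per_tier_closed_form()`, `tier_minmax_values()`): the analytic optimum.
2. **Linear program** (`solve_lp_p0()`, `solve_lp_p2()`): a dense two-phase
   simplex with Bland's rule, written in-package because the target
   environment ships no LP library. Primal and dual are polished from the
   optimal basis by a clean linear solve, which brings agreement with the
   closed form to near machine precision. The LP never consults the closed
   form; it exists to confirm it.
3. **Iterative game / method of successive averages**
   (`a0_step()`/`run_a0()` homogeneous, `a1_step()`/`run_a1()` tiered):
   fictitious play between scheduler and demon. Each iteration the
   scheduler moves $p$ toward the node (or, tiered, the path) of least
   avoidance-weighted unfitness $q_jU_j$, the demon moves $q$ toward the
   node of highest expected unfitness $p_jU_j$, with step size
   $\alpha_m = 1/(m+1)$. The tiered step finds the least-unfit path by
   dynamic programming over the layered DAG, so constrained adjacency never
   requires path enumeration.

The single-step functions are plain R and define the algorithm's contract;
`run_a0()`/`run_a1()` execute the same updates in compiled code (the test
suite asserts bit-for-bit agreement between the two for the first
iterations). Example:

```{r toy}
fv <- fitness_vector(c(1, 3))
solve_lp_p0(fv)$p          # 0.25 0.75, with q = p and V = lambda = 0.25
run_a0(fv, tol = 1e-3, criterion = "error_bound")$solution$p
```

## Tunable parameters

* `tol` (default `1e-4`, dimensionless): convergence tolerance of the
  iterative solvers, interpreted by `criterion` (below).
* `max_iter` (default `1e6`): iteration cap. Reaching it flags
  non-convergence in the returned object; it does not raise, because a
  partially converged $p$ is still a valid simplex point and often useful.
* `criterion`: the stopping rule.
  * `"gap"` (default): stop when the duality gap
    $\max_j p_jU_j - \min_j q_jU_j \le$ `tol`. The two bounds bracket
    $V^*$ from above and below at every iteration, so the gap is a
    certificate on the *game value*.
  * `"error_bound"`: stop when a certified bound on both players' errors,
    $\max_j \max(|p_j - p_j^*|, |q_j - q_j^*|)$, is at most `tol`. From
    $|x_j - \phi_jV^*| = \phi_j\,|x_jU_j - V^*|$ (the same algebra for $p$
    and $q$, since $q^* = p^*$) and $V^* \in [\mathrm{lb}, \mathrm{ub}]$,
    the bound
    $\max_j \phi_j \cdot \mathrm{dist}(x_jU_j, [\mathrm{lb},\mathrm{ub}])$
    is computable without ever looking at the closed form.
  * `"both"`: gap at most `tol` *and* certified error at most `error_tol`
    simultaneously — the rule to use when a claim involves both the value
    and the distribution.
* `check_every`, `trace_every`: how often to test the stopping rule and to
  record `(m, upper, lower)` trace rows; they trade a little overshoot for
  speed on multi-million-iteration runs.

**Why two stopping rules.** The duality gap controls the error in the
*value* but only loosely controls the error in *p*: summing
$\phi_j(p_jU_j - V^*)$ to zero shows the worst case is
$\|p - p^*\|_\infty \le \mathrm{gap} \cdot \sum_i\phi_i$. With mild fitness
spread (shape parameter $\sigma = 1$) a gap of $10^{-4}$ lands $p$ well
within $10^{-3}$ of the closed form in practice. With heavy spread
($\sigma = 3$, where $\sum\phi$ can reach several hundred) it measurably
does not: we observed $\|p-p^*\|_\infty$ up to $0.06$ at gap $10^{-4}$.
Statements about the accuracy of $p$ therefore use `"error_bound"`, which
is a rigorous a-posteriori certificate at the cost of more iterations. The
default stays `"gap"` because the gap is the game-theoretically natural
quantity and cheap to reach.

**Other conventions** (nothing in the mechanism forces them; they are
package decisions): initial $p = q =$ uniform, iteration
counter starting at $m = 1$ so the first step has $\alpha_1 = 1/2$; the
demon's step uses the *post-update* $p$; argmin/argmax ties break at the
lowest node index (this matters with equal fitness and makes every
trajectory deterministic, hence testable); the tiered shortest-path stage
prefers lower-index predecessors, so under complete adjacency the chosen
path is the per-tier lowest-index argmin. The step size
$\alpha_m = 1/(m+1)$ is the canonical successive-averages choice:
decreasing, with divergent sum, which is all the convergence argument
needs.

## The growth simulator

`grow_network()` grows an undirected graph from a complete seed graph on
`m0` nodes; each arrival draws a fitness and connects to `m_edges` distinct
targets sampled without replacement (sequential renormalisation) under one
of three kernels: `degree`, `degree_fitness`, `fitness`. Seed-graph nodes
start at degree `m0 - 1`, so degree-based kernels never see a zero-weight
candidate. The minmax-exposure result derives the attachment *rule*, not
any particular emergent topology, and pins down no growth-experiment
parameters; the simulator's defaults (complete seed graph, lognormal(0, 1)
fitness) are the conventions of the preferential-attachment literature and
are flagged as such. `degree_distribution()` returns the exact histogram and CCDF;
deliberately, no power-law exponent is fitted — heavy-tail checks in the
tests are smoke tests (max degree an order of magnitude above the median),
not distributional claims.

```{r growth}
net <- grow_network(growth_config("fitness", n_final = 300, m_edges = 2,
                                  m0 = 3, seed = 1))
net
head(degree_distribution(net)$ccdf)
```

## What the synthetic data emulates — and what it does not

All experiments are synthetic, at the package's reference validation
settings: homogeneous sets of 12 and 100 nodes with
lognormal(0, 1) fitness (`fixture_homogeneous()`), and four-tier systems
(3 or 25 nodes per tier) with shapes 3, 1, 1, 0.1 from suppliers to
retailers (`fixture_tiered()`) — diminishing oligopoly upstream, near
perfect competition at retail. Lognormal fitness is itself motivated by
`compose_fitness()`: a product of many independent positive attributes is
approximately lognormal.

A green suite establishes that the three solution routes agree at stated
tolerances on these distributions and that the growth kernels sample at
their nominal rates. It does *not* establish anything about empirical
networks: no real fitness data is fitted, no power law is estimated, and
the simulator ignores directedness, rewiring, node removal, and
degree-fitness correlation beyond the kernels given.

## Numerical choices and degenerate inputs

* Fitness must be finite and strictly greater than a floor (default
  `1e-12`); offending values are rejected, never clamped, because clamping
  would silently rewrite $U = 1/\phi$ and the positivity of every $p_j^*$
  depends on it.
* The simplex uses Bland's rule (no cycling) and a two-phase start;
  redundant rows are dropped after phase 1. Final primal/dual come from a
  fresh solve against the optimal basis, so LP accuracy is limited by the
  basis condition number, not by accumulated pivots.
* LP dual weights are normalised to sum to one before being reported as
  `q` (solver sign conventions differ; the normalisation is exact at the
  optimum where $\sum_j q_j = 1$ holds analytically).
* Tie-breaking everywhere is lowest-index-wins, and every sampler takes an
  integer seed; with a seed, results are bit-reproducible, including the
  whole CLI (`mmf_main()`).
* A `tiered_system` must contain a feasible path; this is validated at
  construction by reachability, so the DP cannot fail later on a
  well-formed object.

## Known limitations

* The simplex is dense and intended for the problem sizes at hand
  (hundreds of variables); it is not a general LP package.
* Plain successive averages converges at the fictitious-play rate; heavy
  fitness spread (σ = 3) costs tens of millions of iterations for a
  certified $10^{-3}$. Acceleration schemes exist but are out of scope.
* The growth simulator is undirected and static-fitness only; the
  degree-fitness kernel is provided for comparison, not analysed further
  here.
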