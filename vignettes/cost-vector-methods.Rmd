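---
title: "Growth maximization with enzyme cost vectors: models, methods, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth maximization with enzyme cost vectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efmcost)
```

## The model class

`efmcost` studies a classical question of microbial physiology: when a cell
maximizes its growth rate, how many metabolic strategies does it use at once?
The model class is deliberately minimal and fully kinetic:

* **Stoichiometry.** A network of irreversible reactions with stoichiometric
  matrix $N$ ($m$ metabolites $\times$ $r$ reactions). Metabolites are either
  *external* (fixed by the environment, never balanced) or *internal*
  (balanced at steady state). One reaction is the *objective* — typically the
  biomass drain. Reversible inputs are handled upstream by
  `split_reversible()`, which replaces each reversible column by a forward
  and a negated backward copy, so the steady-state set
  $P = \{v : N_{\mathrm{int}} v = 0,\ v \ge 0\}$ is a pointed polyhedral
  cone.
* **Kinetics.** Every reaction is catalyzed by an enzyme with rate
  $v_j = e_j\,k_{\mathrm{cat},j}\,f_j(x)$: linear in the enzyme concentration
  $e_j$, with all metabolite dependence in a saturation function
  $f_j(x) \in [0,1]$. Three kinds are built in — fully saturated
  (`constant`), multi-substrate Michaelis–Menten, and Michaelis–Menten with
  one non-competitive product-inhibition factor $1/(1 + x_{\mathrm{inh}}/K_i)$.
  A registry hook accepts custom kinds; unregistered kinds fail validation.
  Bounding $f$ by 1 is a convention of this package: $k_{\mathrm{cat}}$ *is*
  the maximal rate.
* **Constraints.** $K$ weighted sums of enzyme concentrations,
  $\sum_j w_j^{(k)} e_j \le b_k$, model limited enzyme pools — cytosolic
  solvent capacity, membrane area, a translation budget. One enzyme may sit
  in any number of pools. Internally every computation rescales weights by
  the bounds, so feasibility always reads "usage $\le 1$ per pool"; bounds
  are kept explicit so that perturbation experiments can shrink pools without
  rewriting weights.

## Elementary Flux Modes and cost vectors

Elementary Flux Modes (EFMs) are the support-minimal nonzero elements of the
flux cone; for fully irreversible networks they are exactly its extreme rays,
and every steady-state flux is a nonnegative combination
$v = \sum_i \lambda_i\, \mathrm{EFM}^i$. EFMs that carry objective flux are
normalized so their objective entry is 1; $\lambda_i$ is then the objective
flux contributed by mode $i$.

At metabolite state $x$, producing one unit of objective flux through mode
$i$ requires enzyme $e_j^i = V_j^i / (k_{\mathrm{cat},j} f_j(x))$ on its
support. Folding in the pool weights gives the **cost vector**
$d^i(x)$, whose $k$-th entry is the fraction of pool $k$ consumed per unit
objective flux. Stacking cost vectors as columns gives the cost matrix
$D(x)$, and growth maximization at fixed $x$ becomes the inner linear
program

$$\max_{\lambda \ge 0} \textstyle\sum_i \lambda_i
  \quad\text{s.t.}\quad D(x)\,\lambda \le 1 .$$

Because an optimal solution lies at a vertex of the feasible polytope, at
most $K$ modes carry weight — the *extremum principle*: the number of
non-equivalent flux-carrying EFMs at a growth optimum never exceeds the
number of active enzyme-expression constraints. Two EFMs are *equivalent*
when their cost vectors coincide; equivalent modes are interchangeable in an
optimal mixture, and `analyze_active_sets()` collapses them before counting.
With two pools the geometry is fully visual: `rank_on_diagonal_2d()` ranks
pure modes by projecting their cost vector to the diagonal of the unit
constraint box and ranks a mixture of an above-diagonal with a
below-diagonal vector by the intersection of their connecting segment with
the diagonal; the dot closest to the origin wins and $1/\mathrm{dot}$ is the
achievable objective flux.

## The two-stage optimizer

`optimize_growth()` nests two searches:

1. **Inner LP.** A dense primal simplex with Bland's rule — deterministic,
   and guaranteed to return a basic feasible solution, which is what makes
   the support bound $|\{\lambda_i > 0\}| \le K$ a theorem rather than a
   tendency. Optimal-face ties are broken by scanning supports in (size,
   lexicographic) order for one that attains the optimum. A cost column of
   zeros (a "cost-free" objective EFM) is rejected: it would make the LP
   unbounded, and the framework assumes every mode draws on some pool.
2. **Outer concentration search.** Only internal metabolites that actually
   appear in a saturation function are searched; the others are inert.
   The search runs in $\log_{10}$ concentration space within bounds
   (default $[10^{-3}, 10^{3}]$ model units — concentrations are
   unit-agnostic): a coarse log-grid prescan (up to 4 free dimensions) seeds
   a seeded multistart Nelder–Mead (default 16 starts, 200 iterations per
   start); in one dimension a 25-point grid plus bracketed golden-section
   search replaces the simplex. The prescan matters: the map
   $x \mapsto \mu^*(x)$ is piecewise smooth with kinks where the optimal
   vertex changes, and with two or more constraints it need not be concave,
   so a purely local method can settle in the wrong basin. Multistart is a
   heuristic, not a certificate; per-start results are logged in the result's
   `starts` field.

The optimal enzyme profile is reassembled as
$e = \sum_i \lambda_i e^i(x^*)$ and reproduces the optimal fluxes through
the rate law identically — this is asserted in the tests, not assumed.

## The dynamical oracle

`steady_state_for_enzymes()` integrates
$\dot x_{\mathrm{int}} = N_{\mathrm{int}} v(e, x)$ with `deSolve::lsoda`
(budget $10^6$ time units; divergence above $10^9$; convergence when the
residual falls below $10^{-9}(1 + \max x)$). Since most allocations
equilibrate quickly, a Newton polish runs first and after each integration
chunk: it jumps to a nearby fixed point and accepts it only if it is
nonnegative, locally stable (Jacobian eigenvalues with nonpositive real
parts), and in the same region of state space as the trajectory. When Newton
fails and the residual stops decaying, the trajectory is drifting or cycling
and the sample is abandoned early.

`brute_force_optimize()` samples enzyme allocations on the boundary of the
constraint polytope (half of them sparsified, since optima sit on
low-support faces), evaluates the objective flux at the steady state each
allocation supports, and refines the best candidates by Nelder–Mead in
log-allocation space with restarts. It is a *lower-bound* oracle: it never
certifies optimality, but it must never exceed the LP route beyond numerical
tolerance, and on small instances it should come close. Two technical
points keep the comparison honest. First, the ODE route does not box the
concentrations: rejecting steady states outside the outer-search box would
make box-edge optima unreachable (the feasible allocation set would have a
measure-zero boundary exactly at the optimum), while the truncation error of
a $[10^{-6}, 10^{6}]$ search box is below $10^{-5}$ relative for the Km
ranges used. Second, trajectories whose residual imbalance is below
$10^{-4}$ of the flux scale count as steady: some instances approach their
optimum asymptotically (the fixed point sits at infinite concentration with
saturating kinetics), and an absolute convergence criterion would reject
exactly the interesting allocations.

The oracle comparison is only meaningful on instances whose dynamics can
equilibrate, and whose optimum is actually *realizable* as a stable steady
state. Three preconditions are checked, and instances failing any of them
are skipped with more drawn in their place:

* every internal metabolite saturates at least one of its consuming
  reactions — otherwise consumption cannot track production and generic
  allocations drift;
* the optimum survives expression noise
  (`optimum_noise_robustness()`): enzyme profiles drawn within ~2%
  multiplicative noise of the optimal one must include at least one that
  reaches a steady state realizing 95% of the optimal objective. Networks
  with autocatalytic amplification can place the optimum on a stability
  razor's edge — the optimal profile equilibrates but every neighbour
  diverges — and no steady-state sampler (nor a real cell with noisy
  expression) can sit there;
* at least one sampled allocation reaches a steady state at all.

On qualifying instances with $r \le 6$ the two routes agree to well under
5% (typically under 0.1%), and the sampled bound never exceeds the LP
optimum beyond tolerance on any instance.

## Case studies

**Overflow metabolism.** Four reactions, two objective EFMs: glucose enters
through a membrane transporter (Michaelis–Menten in external glucose,
kcat 10, Km 1) into an internal intermediate, converted to biomass precursor
either by respiration (1:1, kcat 2) or by an overflow reaction excreting
acetate (2:1, kcat 6); the biomass drain is the objective. Pools: cytosolic
enzyme (respiration + overflow) bounded by 1, membrane area (transporter)
bounded by 0.3. All constants are package constants — chosen, not fitted.
With them the switch is analytic: at low glucose the transporter is poorly
saturated, every cost vector has its membrane component largest, and pure
respiration with only the membrane pool active is optimal; the respiration
cost vector crosses the diagonal when
$0.3\,k_{\mathrm{tr}} f_{\mathrm{tr}}(s) = k_{\mathrm{resp}}$, i.e. at
glucose $= 2$, above which the optimum mixes in the overflow mode, both
pools are active, and respiratory flux strictly decreases — the
respirofermentative switch.

**The *L. lactis* fermentation switch.** Two pathways ferment glucose to
ATP: mixed-acid (3 ATP per glucose, high glucose affinity, strong
non-competitive ATP inhibition, $K_i = 0.65$) and homolactic (2 ATP per
glucose, low affinity, weak inhibition, $K_i = 14$); ATP drives the biomass
objective. Pools: total cytosolic enzyme (all three, bound 1) and an
uptake-machinery pool over the two pathways with *unequal* weights
(6.5 vs 0.02, bound 0.42) — the coarse-grained pathways embed different
shares of transport machinery per enzyme unit. The unequal weights are what
give the growth objective an interior maximum in ATP under the mixed
strategy; with equal weights the objective is monotone in ATP and the
optimum always collapses onto a pure-strategy vertex. The packaged constants
were tuned (by scripted scanning) until the model shows the experimentally
motivated behaviour: along a glucose sweep from 0.5 to 16 the optimal flux
fraction of the homolactic pathway rises from 0.15 through 0.5 to 0.82
while every optimal enzyme concentration changes by less than 20%
(realized: 12.3%) — flux reallocation at constant protein, driven entirely
by saturation: homolactic saturation rises steeply with glucose while
rising ATP increasingly inhibits the mixed-acid pathway.

**Perturbations.** `perturb_pool_bounds()` shrinks pools (expression of a
useless protein); `perturb_catalytic_rates()` scales kcat values (enzyme
inhibition, which lengthens cost vectors reciprocally). Two predictions are
checked end to end: a uniform shrink of all pools by $\gamma$ rescales the
optimum by exactly $\gamma$ (the LP is linear in the bounds and the optimal
concentrations are unchanged — this holds to $10^{-9}$, not approximately),
and shrinking only the pool dominated by one mode of a mixture first
*increases* the other mode's flux before eventually decreasing it.

**Proportionality diagnostic.** `fit_proportional_breakpoint()` implements
the chemostat reading of single-mode growth: if one EFM carries all flux,
every uptake rate is proportional to growth rate, so a through-origin line
fits until a second mode activates. The fit grid-searches candidate
breakpoints at the midpoints of consecutive growth rates, fits a
through-origin segment continuing with a free-slope segment, and reports no
breakpoint when the two-segment fit improves the single-line squared error
by less than 5% — a deliberately conservative rule for small chemostat
tables.

## The synthetic-instance generator

`generate_instance()` draws seeded random models of exactly the class above:
a linear backbone from one external substrate through 2–6 internal
metabolites to the objective guarantees at least one objective-producing
route; extra reactions (conversions, uptakes, exports with coefficients from
$\{1, 2\}$) add alternative modes; kinetics are sampled 70% Michaelis–Menten,
20% constant, 10% product-inhibited, with kcat and Km log-uniform in
$[0.1, 10]$; each reaction joins each of the $K$ pools with probability 0.7.
Instances violating the theory's standing assumptions — no objective EFM, a
cost-free objective EFM, or equivalent objective EFMs — are rejected and
redrawn under an advanced sub-seed (loudly, after 100 failures). The
generator emulates the *structure* the theory assumes, not real metabolism:
no thermodynamics, no realistic topology, desk-scale sizes. Passing
property tests on generated instances therefore demonstrates the
correctness of the mathematics and the code, not the fidelity of any
biological model.

## Problem sizes and numerical choices

The test and acceptance runs use sizes chosen to exercise the claims well
within a desk-scale budget: 200 random instances for the extremum-principle
sweep ($K \in \{2,3\}$), 100 single-constraint instances, 500 random cost
matrices for the LP vertex property, 25 instances for the enumeration
oracle, and at least 20 qualifying instances for the dynamical oracle. The
reduced outer-search effort in the big sweeps (4 starts) is deliberate: the
asserted counting properties hold at *any* LP vertex solution, not only at
the global outer optimum. Key tolerances: support membership $10^{-10}$
after normalization; rank tests $10^{-8}$; LP feasibility/optimality
$10^{-9}$; active-set thresholds $10^{-6}$ relative; EFM-equivalence testing
$10^{-8}$ at 20 seeded log-uniform states (a decidable surrogate for "equal
at every $x$"); steady-state convergence $10^{-9}(1+\max x)$.

## Known limitations

* Enumeration is for desk-scale networks (a 25-reaction guard rail);
  genome-scale EFM enumeration is out of scope by design.
* The outer search is heuristic; on pathological landscapes it can return a
  local optimum. It reports per-start logs rather than pretending to
  certify.
* Flux decomposition weights are not unique when modes outnumber the flux
  space rank; the deterministic nonnegative-least-squares solution is
  returned and documented as such.
* Equivalence testing by sampled states can in principle miss equivalence
  that fails only on a measure-zero set — irrelevant in practice, stated for
  honesty.
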