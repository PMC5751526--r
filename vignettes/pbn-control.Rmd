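---
title: "Finite-horizon optimal control of context-sensitive probabilistic Boolean networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite-horizon optimal control of context-sensitive probabilistic Boolean networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbnctrl)
```

## The model

A Boolean network describes a small gene regulatory system by a 0/1
expression value per gene and a Boolean predictor function per gene,
applied synchronously.  A *probabilistic* Boolean network (PBN) assigns
each gene `i` a set of candidate predictors `f_1^(i), ..., f_l(i)^(i)` with
selection probabilities `c_j^(i)` summing to one; the product over genes
yields `N = prod l(i)` constituent deterministic networks.  Two standard
refinements make the model biologically faithful:

* **Context sensitivity.**  Real regulatory regimes are sticky: the
  selected predictors (the *context*, recorded as an index vector `d`)
  persist from step to step, and only a global switch event, occurring
  with a small probability `q`, resamples them from the selection
  distribution.
* **Perturbation.**  Each gene is independently hit by an external
  disturbance with a small probability `p`; a perturbed gene flips its
  value instead of applying its predictor.  Perturbation makes the induced
  Markov chain ergodic.

With `m` binary control inputs (e.g. the presence of a drug) the network
becomes a Markov decision process: a control vector `u(t)` enters the
predictor functions.  A control policy is charged a *control cost*
`g(x(t), u(t))` at each of the `K` steps of a treatment horizon and a
*terminal cost* `g_K(x(K))` on the state reached at the end; desirable
expression states receive lower terminal cost.  The optimal finite-horizon
control problem asks for the policy minimizing the expected cumulated
cost.

## The reduction to a reachability reward

The package solves the problem by the reduction implemented in
`build_augmented_mdp()`: the full dynamic state `(x, d, s, per)` is
crossed with a step counter `t` in `[0..K+1]`.  Transitions advance `t` up
to `K+1` and then stay; the action reward charges `g(x, u)` while
`t <= K-1`; the state reward charges `g_K(x)` exactly on the `t = K`
layer; every other reward is zero.  The minimum expected reward cumulated
until the target set `{t = K+1}` is first reached is then exactly the
optimal expected cost, and the minimizing deterministic memoryless
resolution of the nondeterminism — which always exists for this class of
property — is the optimal policy.  `min_reachability_reward()` implements
the general solver (states from which the target is not almost surely
reachable receive `Inf`, found by a graph fixpoint, never by divergence);
`solve_finite_horizon()` exploits the time layering and computes the same
fixed point in a single backward sweep, which the test suite checks
against the general solver to `1e-10`.

## Timing conventions

Two details of the synchronous encoding deserve care, and both are
surfaced as explicit options rather than buried defaults.

**Switch and perturbation indicators.**  In the module encoding exported
by `emit_model()`, the SWITCH and PER modules sample fresh indicator
values on every synchronous transition, while the NODE modules read the
*current* indicators.  Consequently an indicator sampled at step `t` takes
effect at step `t+1`; the indicators are part of the dynamic state.  This
is the package's reference semantics (`semantics = "delayed"`), and the
worked example's initial condition ("switch off, no perturbation pending")
is stated in exactly these terms.  The alternative
`semantics = "immediate"` samples and applies switch and perturbation
within one transition; it is retained for sensitivity analysis.  In the
delayed convention a gene's context is resampled whenever the switch
indicator is on — also for a gene that is simultaneously perturbed:
switching governs the context, perturbation governs the value.

**Control timing.**  The exported module code necessarily realizes the
control input as a state variable: an INPUT module sets `u` by a
nondeterministic choice during each synchronous transition, so the value
chosen during the step `t` transition is the control *in effect at step
t+1*, and the control in effect at step 0 is an initial condition.  The
default solver timing (`timing = "input"`) adopts exactly this product
construction, so the native backward induction and the interpretation of
the generated model-checker code agree bit for bit (`interpret_prism()`
builds both from the same exact decimal literals and the test suite
asserts identity).  Under this timing the unconstrained optimum minimizes
over the initial control, and `solve_with_forced_first_action()` pins it —
the two-sided comparison a practitioner runs to decide whether to
intervene immediately.  The textbook construction, in which the action
chosen at step `t` is applied in the same step and a policy `mu_t`
observes the state at `t`, is available as `timing = "direct"`; it yields
values no larger than the input timing because the controller acts on one
step more of information.  Policies extracted under either timing are
reported over the full dynamic state; `extract_policy_table()` also
projects onto the gene state alone, in the decimal encoding customary for
intervention figures (MSB = first gene), and *flags* gene states whose
optimal decision differs between contexts rather than silently collapsing
them — optimal decisions may legitimately depend on the context, and on
the shipped example they do.

## Exact arithmetic

Every probability and cost of a model file is a terminating decimal, and
the backward induction only adds and multiplies such numbers, so the
entire computation can be carried out exactly.  The package includes a
small fixed-point decimal arithmetic (arbitrary-length integer mantissa
over a power of ten, no reduction ever needed) used in three places:
kernel probabilities are assembled exactly and converted to doubles once,
making the kernel bit-stable; `solve_finite_horizon(exact = TRUE)` runs
the whole sweep exactly and reports the optimum as a decimal string
(`4.13789086144` for the shipped example); and generated model-checker
literals are printed as the shortest exact decimal, making emission
byte-stable.  Exact solving costs roughly a hundredfold over floating
point and is intended for desk-scale models; the default double-precision
sweep reproduces it to `1e-12` on the examples in the suite and verifies a
Bellman residual below `1e-10` on every reachable state.

The exhaustive-oracle tests deserve a note on their design.  Enumerating
*all* deterministic policies over all reachable (time, state) pairs is
exponential in the pair count, so the study instances for the
solver-vs-enumeration equality are drawn with dyadic probabilities
(selection weights in eighths, `q, p` in `{0, 1/4, 1/2}`) and integer
costs, with horizons `K = 2`, or `K = 3` with `p = 0`; this bounds the
decision cells to at most about a dozen, and — because dyadic rationals
and their sums and products of this size are represented exactly in
binary floating point — makes the equality check exact rational equality.
Decimal-probability instances are additionally checked through the exact
decimal route at `K = 2`.

## Hard intervention budgets

Clinical interventions are often limited in number.  An upper bound `H_i`
on how often control `i` may be applied is handled by counters `ct_i`
carried in the augmented state, incremented whenever the control is in
effect during a charged step; actions that would drive a counter past its
bound are removed from the action set (the null control is always
allowed, so no state loses all actions).  In the exported model-checker
code the counters become CT modules and the property targets
`t = K+1 & ct_i <= H_i`: a resolution exceeding the budget never reaches
the target, receives infinite reward, and is discarded by the
minimization.  The constrained optimum is nonincreasing in each `H_i` and
equals the unconstrained optimum at `H_i = K`, which the suite checks on
synthetic instances.  The target uses equality `t = K+1`; a formulation
with `t <= K+1` would make the target hold already at the initial state
and trivialize the property.

## The synthetic-data generator

`random_network()` draws test instances: random Boolean expressions over
at most `max_indegree` gene variables (each with a 50% chance of
involving a control input, 30%/20% chances of leaf/subtree negation),
and selection probabilities drawn as a uniform random composition of a
denominator (10 by default, 8 for the dyadic test instances) into
positive parts — a discrete Dirichlet-like scheme whose stored decimals
sum to one exactly.  The shipped example network uses a typical
small-system parameter regime (`q = 0.3`, `p = 0.1`, unit control cost,
terminal costs 0/2/4/6 over four states, `K = 4`); random instances in
the tests stay in the same desk-scale regime (`n <= 3`, `l <= 3`,
`K <= 4`).  What the generator emulates is the *structure* of small
regulatory models — rule-based predictors, sticky contexts, rare flips;
what it does not emulate is anything inferred from expression data:
realistic indegree distributions, correlated selection probabilities, or
biologically calibrated costs.  Tests passing on these instances
establish the correctness of the machinery, not the adequacy of any
particular biological model.

## Numerical choices and edge cases

* Ties in the minimization are broken toward the lexicographically
  smallest control vector, so "no control" wins ties and policies are
  reproducible.
* Infinite values are represented by `Inf`, never by large floats, and
  only ever arise from the graph precomputation.
* `K = 0` is allowed: the value is the terminal cost of the initial
  state.
* Successor distributions aggregate duplicate successors by exact decimal
  addition before any float conversion (duplicates can arise under the
  immediate semantics when a flip coincides with the function image).
* Numeric probabilities supplied as R doubles are canonicalized at 15
  significant digits; passing strings (`"0.3"`) keeps full control over
  the stored representation.
* Problem sizes: the shipped example's augmented MDP has about a thousand
  reachable states and solves in a few seconds including construction;
  the test suite and the acceptance script use instances of at most a few
  thousand augmented states.

## Known limitations

* The exported module code encodes the delayed reference semantics only;
  requesting code generation for the immediate variant is an error.
* Policies of hard-constrained solutions depend on the intervention
  counters and are not accepted by the policy evaluator or simulator; the
  solution value and table are the supported outputs there.
* Steady-state (infinite-horizon) control and the long-run reward
  operators of general model checkers are out of scope; the bundled
  interpreter reads only the generated dialect.
* Monte-Carlo simulation and policy evaluation assume the policy covers
  every reachable state; gaps raise an error naming the state.
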