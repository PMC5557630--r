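---
title: "Enumerating fixed points and attractors in automata networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating fixed points and attractors in automata networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(andyn)
```

## The model class

An automata network is a triple (Σ, S, T): a finite set Σ of automata, each
automaton `a` carrying a finite ordered set of local states (levels)
`a_0 … a_{k-1}` with k ≥ 2; S the global states (one active level per
automaton); and T a set of local transitions `a_i --ℓ--> a_j` with
`i ≠ j` and ℓ a set of levels of *other* automata, at most one per
automaton.  A transition is *playable* in ζ when its origin and all of ℓ
are active in ζ.  The formalism subsumes Boolean networks (all k = 2) and
multi-valued Thomas-style logical models.

Two update schemes define the dynamics:

* **asynchronous** — each global step plays exactly one playable
  transition; non-determinism comes from the choice among `P_ζ`.
* **synchronous** — each global step plays exactly one playable transition
  *per automaton that has any*; empty steps are forbidden.  The only
  synchronous non-determinism comes from *in-conflict* transitions: same
  automaton, same origin, different destinations, jointly playable
  somewhere.  `in_conflict()` decides joint playability by merging the two
  conditions (equal origins given, a witness state exists iff no shared
  automaton is required at two different levels) — no state enumeration.

Because empty update sets are excluded in both schemes, no state is ever
its own successor; a state with no playable transition has *no* successor
and is a **fixed point**.  Fixed points are identical under both schemes.

## Fixed-point enumeration

`enumerate_fixed_points()` reproduces a prefilter + generate + test
pipeline:

1. *Prefilter* (`stable_candidates()`): a level that is the origin of a
   condition-free transition can never be stable, since that transition is
   playable wherever the level is active.  Such levels are dropped per
   automaton; if some automaton loses all its levels the network has no
   fixed point and enumeration short-circuits.
2. *Generate*: the Cartesian product of surviving candidate levels is
   walked with a mixed-radix counter — no materialization, so candidate
   spaces far larger than memory are acceptable in principle (runtime is
   still proportional to the candidate count; the default guard refuses
   more than 10^8 candidates).
3. *Test*: a state is kept iff no transition's requirement vector
   (origin + condition) is fully matched.

The prefilter is a pure optimization; a test asserts that filtering the
full state space gives the identical set, and a property suite checks
against the no-successor definition under both schemes on 100 seeded
random networks.

## Attractor enumeration

Non-singleton attractors are minimal trap domains: sets **A** (|A| ≥ 2)
closed under the successor relation and minimal by inclusion.  Direct
minimality search is awkward; we use the cycle characterization instead —
the traces of cycles are exactly the strongly connected sets, and the
attractors are exactly the traces of cycles that are trap domains.  For a
chosen length n, `enumerate_attractors()` performs:

1. **Cycle generation** — every path of length n with `states[0] ==
   states[n]`, by depth-first extension from every state.  A branch is
   pruned as soon as the start state is unreachable within the remaining
   budget (distances via reverse breadth-first search).  We deliberately do
   *not* prune on trap violations mid-path: whether a successor escapes can
   only be judged once the trace is complete.
2. **Trap filter** (`is_trap_cycle()`) — every successor of every trace
   state must lie in the trace.  Successor jumps between trace states that
   are not steps of the cycle are shortcuts inside the attractor and are
   allowed.
3. **Minimality filter** (`is_minimal_cycle()`) — the cycle length n must
   equal the length of the shortest closed walk covering the trace,
   computed exactly by breadth-first search over (state, visited-subset)
   pairs within the trace (capped at 16 trace states; beyond that the
   cycle enumeration itself is already impractical).

Step 3 is deliberately stronger than a symptom checklist (shorter
repetition-free covering cycle; shortcut edges; successive repeated
visits; whole-cycle repetition): each symptom implies a shorter covering
closed walk, so the single criterion subsumes all of them, and it also
removes the residual duplication a symptom-based filter leaves behind.
The price is exponential cost in the trace size, acceptable at the trace
sizes where exhaustive cycle enumeration is feasible at all.

Trace accounting uses the repetition formula: a path of length n with k
repeated steps visits n + 1 − k distinct states.  Complex attractors are
therefore found at n strictly larger than their size — the 4-state "star"
system (`star_model()`, a hub connected both ways to three satellites) has
its unique attractor found only at n = 6, visiting the hub three times:

```r
a <- enumerate_all_attractors(star_model(), 6)[[1]]
c(size = a$size, cycle_length = a$cycle_length)
```

Each attractor is reported once: traces are canonicalized (states sorted
by key) and deduplicated across starting states and traversals.
`dedupe = FALSE` restores one result per witnessing cycle for comparison
with solver-style answer multiplicities.  `enumerate_all_attractors()`
unions lengths 1..max_n and reports the smallest covering length per
attractor; it is complete once max_n reaches the largest shortest covering
walk among attractors, a quantity the oracle-backed tests compute exactly.

## The brute-force oracle

`build_stg()` materializes the explicit state-transition graph (full, or
forward-reachable from given roots; guarded at 10^6 nodes) and
`oracle_attractors()` partitions its terminal strongly connected
components — SCCs with no outgoing edge — into fixed points (singletons;
there are no self-edges, so a terminal singleton has no successor) and
attractors (the rest).  SCCs come from igraph's linear-time
implementation.  This route implements the definitions directly and is
the acceptance authority: wherever it and the enumeration path could
disagree, the oracle is presumed correct.  The suite holds the two routes
against each other on the packaged models and on the random ensemble.

## Successor providers

Everything downstream of the semantics (cycles, trap checks, covering
walks, the state-transition graph) runs on a minimal *successor provider*
contract: an enumerable set of state keys plus a successor function.
`an_provider()` backs it with a network and a scheme; `graph_provider()`
backs it with an explicit edge list.  The star system ships as an explicit
provider on purpose: no automata-network realization of it is given, and
inventing one would be unverifiable.

## The random-network generator

`random_an()` emulates desk-scale regulatory models: level counts uniform
on 2..max_levels (multi-valued components are common but shallow — real
logical models rarely exceed 3–4 levels per component), condition sizes
uniform on 0..2 (most regulations have one or two co-factors), and
structurally distinct transitions by rejection sampling.  Defaults (4
automata, 3 levels, 8 transitions) give state spaces of a few dozen
states, the scale at which both enumeration routes run in milliseconds.
The test ensemble varies 2–5 automata and 4–10 transitions
deterministically by seed.  What the generator does *not* emulate: the
scale-free regulation structure, canalizing logic, or the biological bias
toward few attractors.  A green ensemble test establishes agreement
between two independently derived computations of the same definitions,
not biological realism.

## Numerical and design choices

* Levels are 0-based consecutive integers; automaton order is declaration
  order; states serialize as `a:1 b:2 c:0 d:1`, which is also the
  canonical set-membership key, so all outputs are deterministic.
* Transition labels are contiguous from 1 in file order.  In the facts
  dialect the origin is serialized as the condition element on the
  transition's own automaton; the reader splits it back out and rejects
  transitions with zero or several own-automaton condition elements.
* A condition holding two levels of one automaton can never be satisfied;
  it is rejected at load rather than carried as dead weight.
* `n = 0` attractor requests are redirected to the fixed-point entry
  point with a usage error; the two problems have different machinery.
* The synchronous update-set construction materializes the per-automaton
  Cartesian product of playable transitions — exponential in the number of
  simultaneously non-deterministic automata, which at desk scale is small.
* Boolean networks are synchronously deterministic *in their successors*:
  two jointly playable same-origin transitions of a Boolean automaton
  necessarily share their destination, so several update sets may witness
  the same unique successor.  The tests assert determinism at the
  successor level, which is the observable claim.

## Limitations

Exhaustive cycle enumeration is exponential in n and in branching; the
intended scale is networks whose full state space fits the 10^6-node
guard, and attractors whose covering cycles stay short (tens of steps).
Large literature models (10^12+ states) are out of reach of the
explicit-graph oracle by construction; only the fixed-point enumerator,
which never builds the graph, extends toward that scale, and its runtime
remains proportional to the surviving candidate product.  Approximate or
symbolic (BDD) representations, basins of attraction, and garden-of-Eden
states are out of scope.
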