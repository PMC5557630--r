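# andyn — fixed points and attractors of multi-valued automata networks

Discrete models of biological regulation (gene networks, signaling) are
often written as **automata networks**: each component `a` is an automaton
with a small number of activity levels `a_0, a_1, …`, and a **local
transition** `a_i --ℓ--> a_j` moves `a` from level `i` to level `j` whenever
`a_i` is active and every local state in the condition `ℓ` (levels of other
automata) is active.  This generalizes Boolean networks to multi-valued
levels and covers Thomas-style logical models.

The long-term behaviors of such a model are its **fixed points** (global
states ζ with no playable transition, identical under both update schemes)
and its **attractors**: minimal trap domains, i.e. minimal sets **A** of at
least two states with no outgoing global transition.  `andyn` enumerates
both exhaustively under the two standard non-deterministic semantics:

- **asynchronous** — exactly one playable transition fires per step,
  `U_asyn(ζ) = { {τ} : τ ∈ P_ζ }`;
- **synchronous** — every automaton with a playable transition fires exactly
  one of them, empty steps forbidden.

Attractor search follows the generate-and-test characterization: attractors
are exactly the traces of cycles that are trap domains.  For a length `n`,
every cycle of length `n` is enumerated by depth-first extension with
reachability pruning, filtered to trap cycles (every successor of every
trace state stays in the trace), and filtered to *minimal* covering cycles:
`n` must equal the length of the shortest closed walk visiting the whole
trace.  A trace of a length-`n` path with `k` repeated steps has
`|trace| = n + 1 − k` states, so complex "star" attractors — whose shortest
covering cycle is strictly longer than their trace — are reported correctly.
An independent brute-force oracle builds the explicit state-transition
graph and reads fixed points and attractors off its **terminal strongly
connected components**; the test suite holds the two routes against each
other on packaged and seeded random models.

## Worked example

The packaged four-component model (`a`, `c` Boolean; `b`, `d` three-valued;
12 local transitions, 36 global states):

```r
library(andyn)
net <- toy_model()

vapply(enumerate_fixed_points(net), state_key, character(1))
#> [1] "a:0 b:0 c:0 d:1" "a:1 b:1 c:0 d:0" "a:1 b:1 c:1 d:0"

enumerate_attractors(net, 2, "asynchronous")[[1]]
#> Attractor of size 2 (asynchronous), covering cycle length 2:
#>   a:0 b:1 c:0 d:0
#>   a:0 b:1 c:0 d:2

length(enumerate_attractors(net, 4, "asynchronous"))  # the size-4 attractor
#> [1] 1
length(enumerate_attractors(net, 6, "asynchronous"))  # nothing spurious
#> [1] 0
```

The three fixed points are the multistable outcomes of the model; the
size-2 and size-4 sets are the sustained oscillations reachable under the
asynchronous semantics.  Under the synchronous scheme the same fixed points
remain and two size-2 attractors exist instead.  The 4-state "star" system
(`star_model()`) has a single attractor of trace size 4 whose shortest
covering cycle has length 6 — its hub state must be visited three times:

```r
a <- enumerate_all_attractors(star_model(), 6)[[1]]
c(a$size, a$cycle_length)
#> [1] 4 6
```

## Command line

A thin wrapper script ships in the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/an-tools.R", package="andyn"))')
Rscript $CLI fixed-points model.an
Rscript $CLI attractors model.an --scheme synchronous --length 2 --format json
Rscript $CLI stg model.an --scheme asynchronous --output stg.dot --color
Rscript $CLI facts model.an          # logic-programming facts rendering
Rscript $CLI random-model --seed 7
```

Exit codes: 0 success, 1 usage error, 2 model/validation error.

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch against the installed
package, the headline quantities of the packaged systems — the example
model's fixed-point count and per-scheme attractor inventory, the
repetition accounting of a worked length-6 path, and the star system's
trace size and shortest covering cycle — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope notes

Readers/writers cover the plain-text network format (see
`inst/extdata/toy_example.an`), the logic-programming facts dialect
(`automatonLevel/2`, `automaton/1`, `localTrans/1`, `condition/3`,
`target/3`) and a JSON export.  GINML/SBML-qual conversion is out of scope;
to analyze literature models (e.g. the T-helper or FGF networks from the
GINsim repository) export them to SBML-qual, convert to an automata-network
file with the LogicalModel toolchain, and load the result with
`read_model()`.  At that scale only the fixed-point enumerator is
practical here; the attractor search is meant for desk-scale state spaces
(the full-graph guard defaults to 10^6 states).
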