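---
title: "Epithelial dynamics from cellular logical models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epithelial dynamics from cellular logical models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epilattice)
```

## The modelling framework

`epilattice` composes two well-established formalisms. At the cellular
level, a *logical regulatory model*: discrete components with maximum levels
(Boolean components have maximum 1), where each internal component carries
an ordered list of `(level, expression)` rules and moves one level per
update toward its target — the highest rule level whose expression holds in
the current cell state, or 0. Input components carry no rule; their values
are imposed from outside the cell. At the tissue level, a *cellular
automaton* on a hexagonal grid: each cell runs its logical model, and the
cell's inputs are set either positionally (a constant per-cell map, the
discrete analogue of a morphogen gradient) or by *integration rules* that
count signal-bearing cells in a distance band of the neighbourhood.

The central semantic commitment is the **two-phase update**. One tissue
step is:

1. resolve every cell's input components from the full current grid state
   (integration rules read only *internal* components of other cells);
2. step the internal components of the updated cells, all from that shared
   snapshot;
3. re-apply perturbation clamps.

Phase separation makes the synchronous step a pure function of the grid
state — no cell iteration order can influence the result — and gives the
alpha-asynchronous step a clean meaning: the non-updated cells keep their
internal levels, nothing else.

A *stable pattern* is a grid state fixed under the full synchronous update.
Because the synchronous fixed-point test quantifies over every cell, a
stable pattern is absorbing under every updating scheme, every `alpha` and
every random stream; the simulator uses exactly this test (not "k identical
consecutive states", which on a stochastic scheme can trigger spuriously
whenever a step happens to select only already-stable cells) to declare
convergence of stochastic runs.

## Updating schemes

**Synchronous.** Every cell updates; the dynamics is deterministic. The
driver hashes the internal state history and reports the first revisit as a
cyclic attractor with its cycle length. The classic failure mode this
exposes: two-component lateral inhibition updated synchronously oscillates
globally instead of patterning (every run either cycles or exhausts its
step budget).

**Alpha-asynchronous** (after Fatès's asynchrony-rate cellular automata):
per step, a random subset of cells updates. The default draws *exactly*
`round(alpha * n_cells)` cells without replacement, reading "the proportion
of cells chosen for update" literally; per-cell Bernoulli(`alpha`) draws
are available as `sampling = "bernoulli"`. The two samplers have the same
mean and nearly identical dynamics on grids of thousands of cells; the
exact-count default is preferred because it makes `alpha = 1` reproduce the
synchronous operator *bitwise* (a property the test suite asserts on 1000
randomized instances) rather than only in distribution.

**Step counting.** The initial state (after perturbation clamping) is step
0; `steps_to_stability` counts applied tissue updates, including updates
whose random selection happened to change nothing — on a stochastic scheme
those are real time. Published convergence counts for this kind of system
are single stochastic realizations; reproducing them means checking that
they fall within the distribution over seeds, not hitting them exactly.

**Priority classes.** Within one cell update, classes are scanned in
declared order and only the *first* class containing a pending update in a
matching direction (increase/decrease) fires; its matching members step
together, everything else freezes. One scan per cell update. Other firing
disciplines exist in the literature (e.g. letting every applicable class
fire); the single-class reading is the conservative one — it reduces to the
plain synchronous cell update when all components share one class, which
the suite verifies exhaustively on small models.

## Geometry

Cells sit on a pointy-top hexagonal lattice addressed by 0-based odd-r
offset coordinates (odd rows shifted half a cell right), enumerated
row-major. Any consistent convention yields isomorphic dynamics; odd-r is
used because its neighbour offsets are simple parity lookups. Borders wrap
per axis: rectangle, horizontal or vertical cylinder, torus. Vertical
wrapping requires an even number of rows — odd-r adjacency depends on row
parity, and gluing an odd height would join rows of equal parity,
destroying adjacency symmetry; the constructor rejects it outright rather
than silently producing a non-symmetric graph.

Distances are defined *operationally* as shortest paths in the wrapped
adjacency graph and computed by breadth-first search. Closed-form hex
distance formulas on offset coordinates are notoriously easy to get wrong
once wrapping enters; BFS is immune, costs nothing at these problem sizes,
and gives one definition shared by all four wrap modes. Integration rules
with band `[dmin:dmax]` precompute a sparse cells-by-cells band matrix, so
each rule atom evaluates as one sparse matrix–vector product per step; band
matrices are cached per topology across runs. On an unbounded lattice the
band `[1:d]` holds `3d(d+1)` cells (6, 18, 36, ...); borders truncate it,
which is why the `all` quantifier over an *empty* band is defined as false
— a border cell with no neighbours receives no signal rather than a
vacuously positive one.

## Degenerate inputs and numerical choices

* Multi-level integration inputs: one rule per level, highest satisfied
  level wins, default 0 — mirroring the cellular target-level resolution,
  so one resolution order serves both layers.
* Heterogeneous tissues (several models over grid regions): an integration
  atom naming a component absent from a neighbour's model treats that
  neighbour as not satisfying the test; state matrices carry `NA` for
  absent components, and validation reports name collisions where a
  component is internal in one model and an input in another.
* Overlapping perturbation regions on the same component are rejected at
  validation instead of being silently ordered; disjoint clamps commute.
* Perturbation clamps are re-applied after input resolution and after every
  update, so a perturbed component never moves even if it is an input.
* The stochastic driver pins R's RNG (Mersenne–Twister, rejection
  sampling), so a (model, configuration, seed) triple reproduces its
  trajectory byte-for-byte across processes and platforms; project files
  make the seed mandatory for stochastic schemes.
* Default `max_steps` is 1000 — an order of magnitude above the observed
  convergence times of the built-in systems at their default settings.

## The built-in generator

`fixture_delta_notch()` builds the idealised juxtacrine lateral-inhibition
system: two Boolean markers per cell, `Green` the *integration input*
(the received signal) and internal `Red := !Green`. The formulation
deliberately has no third component between signal and response: the
neighbourhood rule writes `Green` directly, and the cell answers in one
step. Interposing an explicit receiver component (input `nb_Red`, internal
`Green := nb_Red`, `Red := !Green` — a shape the engine equally supports
and the unit tests exercise) delays every signal hop by one update and
creates transient `Green & Red` cells; measured on the 50×50 grid at
`alpha = 0.25` it slows convergence several-fold for the contact rules and
by an order of magnitude for the distance-3 threshold rule. The
two-component formulation is the one whose convergence-time distributions
bracket the published single-run counts, and its stable contact-rule
patterns have an exact combinatorial characterization the tests assert:
the Red set is a maximal independent set of the grid graph.

Defaults are the published study conditions: 50×50 grid, all-zero initial
state, `alpha = 0.25`, and the three rule variants
`Red>=1 [1:1] atleast 1`, `Red>=1 [1:1] all`, `Red>=1 [1:3] atleast 12`
(the band excludes the cell itself — signals come from *neighbouring*
cells). Problem sizes used in the automated checks: exhaustive state
enumeration on the 1×2 grid (16 joint states), 100 seeded runs per rule
variant on the 50×50 grid, 1000 randomized small instances for the
`alpha = 1` equivalence.

What the generator does *not* emulate: real epithelia have cell division,
death, rearrangement and geometry changes (out of scope here — the lattice
is static); signalling is graded and continuous in time rather than
two-valued and step-clocked; and biological "steps" have no fixed duration,
so convergence-time comparisons are meaningful only within one scheme and
`alpha`. Passing tests therefore certify the discrete semantics and its
documented invariants, not quantitative agreement with any particular
tissue.

## A two-phase (clone) workflow

Multi-phase experiments — run to a stable pattern, change a signal, run on
— use clones:

```{r, eval = FALSE}
fx <- fixture_delta_notch(50, 50, rule = "contact1")
tr <- run_simulation(fx$epithelium,
                     simulation_config("alpha", 0.25, seed = 7,
                                       max_steps = 1000), record = "last")
phase2 <- clone_epithelium(fx$epithelium, tr$states[[2]])
# e.g. silence a positional input, add a perturbation, or swap a rule here
tr2 <- run_simulation(phase2, simulation_config("alpha", 0.25, seed = 8,
                                                max_steps = 1000))
```

A clone is a deep copy with the given state as initial condition; edits to
it never touch the original. The same pattern covers gain-of-function
clones (a `perturbation()` restricted to a region) and morphogen-removal
experiments (`set_positional_input()` to zero).

## Known limitations

* No tissue-level attractor enumeration: the driver follows trajectories;
  it detects cycles only under the deterministic synchronous scheme and
  stability everywhere. Exhaustive analysis of the composed multicellular
  state space is out of scope by design.
* SBML qual support covers model structure (species, maxLevel, transitions
  with MathML over `and/or/not/geq/gt/leq/lt/eq`); layout and annotations
  are not preserved.
* The hexagonal lattice is static and regular; no irregular meshes or 3D.
* The project dialect is this package's own plain-text format; it
  interchanges cellular models with other tools via SBML qual, not project
  files.
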