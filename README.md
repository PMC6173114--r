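# epilattice

Logical modelling of epithelial dynamics on hexagonal cell grids.

`epilattice` simulates a monolayer epithelium as a cellular automaton: every
cell of a 2D hexagonal grid runs a qualitative (Boolean or multi-valued)
logical regulatory model, and cells communicate through *integration rules*
— logical expressions over neighbourhood signal counts that set the input
components of each cell — or receive constant *positional inputs* (e.g. a
morphogen gradient painted over the grid). It is aimed at systems biologists
studying pattern formation (lateral inhibition, epithelial patterning) who
already work with logical models and want to lift them to the tissue level
without leaving the qualitative framework.

## The model

A cellular model has components `x_1, ..., x_m`, each with a maximum level
(`1` for Boolean), split into **inputs** (no regulatory rule; value imposed
from outside the cell) and **internal** components. Each internal component
`x` has an ordered list of logical rules `(l_k, f_k)`; its *target level* in
a cell state `s` is

```
T(x, s) = max { l_k : f_k(s) true },  else 0
```

and one update moves `x` by a single level toward its target,
`x <- x + sign(T(x, s) - x)` (for Boolean components this equals jumping to
the target). Optional **priority classes** partition the component updates
into ordered classes; at each cell update only the first class with a
pending update in a matching direction fires.

At the tissue level, an **epithelium model** is a hexagonal grid (0-based
odd-r offset coordinates, pointy-top; borders optionally wrapped per axis
into cylinders or tori), a cellular model per cell, and a semantics for
every input component:

* **positional**: a fixed per-cell level;
* **integration**: per input level, a rule from the grammar

  ```
  expr   := term ('|' term)*
  term   := factor ('&' factor)*
  factor := '!' factor | '(' expr ')' | atom
  atom   := NAME '>=' INT '[' INT ':' INT ']' ('atleast' INT | 'all')
  ```

  where `Red>=1 [1:3] atleast 12` is true for a cell iff at least 12 cells
  at hexagonal graph distance 1–3 have `Red >= 1`; `all` requires the whole
  (non-empty) band. The input takes the highest level whose rule holds.

Every tissue update is two-phase: inputs are resolved for all cells from the
current grid state, then cells step their internal components from that
shared snapshot (so results never depend on cell iteration order), then
perturbation clamps are re-applied. Updating is either **synchronous**
(every cell; deterministic, with cycle detection) or
**alpha-asynchronous**: per step, a random subset of exactly
`round(alpha * n_cells)` cells updates; `alpha = 1` reproduces the
synchronous scheme. A *stable pattern* is a state fixed under the full
synchronous update, hence absorbing under every scheme.

Cellular models are exchanged as SBML Level 3 `qual` documents; projects
live in a plain-text YAML dialect; trajectories export to CSV; states render
to PNG.

## Worked example: lateral inhibition

The classic Delta–Notch lateral-inhibition system: each cell has a `Green`
marker (the received juxtacrine signal, an integration input) and an
internal `Red` marker induced at low Green (`Red := !Green`). A cell turning
Red silences the Red fate in the cells that sense it.

```r
library(epilattice)

fx <- fixture_delta_notch(50, 50, rule = "contact1")  # Green iff >=1 contact Red
tr <- run_simulation(fx$epithelium,
                     simulation_config("alpha", alpha = 0.25, seed = 7,
                                       max_steps = 1000),
                     record = "last")
print(tr)
#> Tissue trajectory (alpha, alpha = 0.25, seed = 7): 18 steps applied
#>   converged to a stable pattern after 18 steps

final <- tr$states[[2]]
print(final)
#> Grid state: 2500 cells x 2 components
#>   Green: level 0 x602, level 1 x1898
#>   Red: level 0 x1898, level 1 x602
```

The run reaches a *stable pattern* after 18 tissue updates (a stochastic
quantity: other seeds give other counts). In it, the 602 Red cells form a
maximal independent set of the grid graph — no two Red cells touch, and
every Green cell touches at least one Red cell — the salt-and-pepper
signature of lateral inhibition. `render_state(final, "Red", "pattern.png")`
draws it. The same machinery runs the synchronous scheme (which for this
system oscillates forever instead of stabilising), multi-level models,
morphogen-gradient positional inputs, knock-out/ectopic perturbations over
grid regions, and `clone_epithelium()` for two-phase simulations.

A command-line wrapper covers the same workflow from a shell:

```sh
Rscript inst/cli/epilattice.R fixture delta-notch --width 50 --height 50 --out dn.yaml
Rscript inst/cli/epilattice.R simulate dn.yaml --out traj.csv
Rscript inst/cli/epilattice.R render traj.csv --step 0 --component Red -o start.png
```

## Vignette

`vignettes/epithelial-logical-dynamics.Rmd` documents the model semantics,
the numerical and design choices, what the built-in generator does and does
not emulate, and known limitations.
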