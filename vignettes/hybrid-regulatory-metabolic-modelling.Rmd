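---
title: "Hybrid regulatory–metabolic modelling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid regulatory–metabolic modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolfba)
```

## The modelling problem

Stromal fibroblasts in a tumor microenvironment can reprogram their energy
metabolism: instead of oxidizing pyruvate through the TCA cycle and OXPHOS,
they ferment glucose to lactate even in the presence of oxygen and export
energy-rich fuels to neighbouring cancer cells (the reverse Warburg effect).
The hypothesis this package operationalizes is that this switch is imposed on
the metabolic network *by the regulatory layer*: signaling and gene
regulation, summarized as an asynchronous Boolean model, decide which
metabolic enzymes and metabolites can be active at all, and those decisions
become hard constraints on a constraint-based metabolic model.

`boolfba` implements that coupling as a reusable chain:

contextualize → clamp → propagate → minimal trap spaces → zero-flux
constraints → FBA → ATP/C-flux shares → knock-out/knock-in screen.

## The regulatory layer

### Boolean networks and clamping

A network is a set of nodes with Boolean update rules over `&`, `|`, `!`.
Nodes without regulators (inputs) carry the identity update `X := X`, which
makes them bistable until fixed. Initial conditions are applied by
*clamping*: the update rule of every node with a fixed initial value — input
or internal — is replaced by the constant. This is a deliberate semantic
choice: trap spaces of a Boolean network do not depend on a start state, so
the only way initial conditions can shape the asymptotic analysis is by
making them permanent. Knock-out (clamp 0) and knock-in (clamp 1) are the
same operation.

### Three-valued evaluation and value propagation

All asymptotic reasoning is built on Kleene three-valued evaluation:
`tv_eval()` returns 0/1 only when the expression takes that value under
*every* completion of the unknowns reachable by the rules `1 | unknown = 1`
and `0 & unknown = 0`, and unknown otherwise. This is sound but
conservative — a tautology such as `A | !A` evaluates to unknown — which is
exactly the right bias: propagated values must never over-claim.

`propagate_values()` computes the least fixpoint of "fix `v` at `b` whenever
its rule evaluates definitely to `b`". The result extends the clamping, is
idempotent, and every asynchronous attractor of the clamped network agrees
with it (tested against explicit terminal-SCC attractor computation on small
random networks).

### Minimal trap spaces

A trap space is a partial assignment `m` such that for every assigned node,
the update rule restricted to the subspace can never produce the opposite
value; minimal trap spaces contain no smaller trap space and approximate the
attractors of the asynchronous dynamics. Because subspace inclusion is
reverse pair-set inclusion, minimal trap spaces are exactly the trap spaces
with maximal sets of fixed (node, value) pairs.

`compute_minimal_trap_spaces()` is exact and works in two stages:

1. **Percolation reduction.** Values forced by constant rules (in particular
   all clamped nodes) are propagated first. Any trap space can be extended
   by these percolated pairs (Kleene evaluation is monotone under
   refinement), so every *minimal* trap space contains them; the search then
   only concerns the residual nodes with the percolated values substituted
   into their rules. Under disease-specific conditions that fix all inputs
   this reduction typically solves the problem outright, which is what makes
   the perturbation screen cheap.
2. **Closure from each residual state.** For a state `s`, iteratively free
   any assigned node whose rule, restricted to the current subspace (checked
   on the node's truth table), can take the opposite value. The set of trap
   spaces containing a given state is closed under intersection, and an
   induction over the freeing steps shows the iteration computes exactly
   that smallest trap space `T(s)`. Every minimal trap space `M` equals
   `T(s)` for any `s ∈ M`, so collecting `T(s)` over all `2^k` residual
   states and keeping the maximal assignments yields precisely the minimal
   trap spaces.

The enumeration is exponential in the number of *residual* nodes only; the
solver refuses (rather than truncates) problems beyond `max_free_nodes`
(default 16). An independent `3^n` brute-force oracle
(`brute_force_trap_spaces()`, cap 10 nodes) enumerates all subspaces and
checks closure on an explicit state-transition image; the test suite asserts
set equality between the two on 100 seeded random networks, and checks the
closure property of every solver output symbolically with `tv_eval()` — three
independent routes to the same object.

Output order is canonical (fewest fixed nodes first, then lexicographic), so
serialized results are byte-identical across runs.

## Contextualization

Expression contrasts arrive as a table (gene, fold change, adjusted p) with
an explicit fold-change convention; nothing is inferred from magnitudes. The
defaults follow common practice: adjusted *p* strictly below 0.05 and |FC|
strictly above 1.5. The signed linear convention reads down-regulation as
negative fold change (`FC < -1.5`), the `log2` convention compares against
`log2(threshold)`; both are strict so a gene exactly at a threshold is not
called. Gene-to-node matching is case-insensitive *exact* matching on node
identifiers and name annotations (plus an optional alias table); unmapped
genes are reported, never dropped silently, and opposite calls landing on
one node are an error rather than a coin flip. Curated literature values
fill only what the contrast left unfixed — data beats curation wherever both
speak — and conflicts are reported.

## The metabolic layer

### Constraint derivation

For each mapped component the *maximum* value across trap spaces is taken:
free counts as potentially active. Only a maximum of 0 — the component is
off in every asymptotic regime — licenses a constraint; activity says
nothing about feasibility or kinetics and contributes nothing. Linked
reactions get bounds `[0, 0]` (both directions: an inactive enzyme catalyzes
neither direction, an unproduced metabolite licenses neither). A
metabolite's producing reactions include reversible reactions that can form
it in either direction, the conservative reading. Constraints only ever
tighten: the constrained optimum can never exceed the unconstrained one,
which the tests assert numerically.

### FBA, shares, and numerical choices

The objective is the plain, unweighted flux sum of the ATP-producing
reactions, split into glycolytic and oxidative roles that partition it — so
the two ATP shares always sum to 100%. A stoichiometry-weighted variant was
considered and rejected as the default because the role split, not absolute
ATP yield, is the readout of interest; the roles file makes the choice
explicit and reviewable.

Linear programs are solved by a dense two-phase simplex with Bland's rule,
written for the moderate, frequently degenerate LPs of core metabolic
models: degeneracy (zero-width bounds from applied constraints, redundant
conservation relations) is routine here and Bland's rule guarantees
termination. Fixed variables (`lb = ub`) are eliminated before solving.
Tolerances: steady-state feasibility 1e-6, zero flux 1e-9, both
configurable. Infeasible or unbounded problems return an explicit status;
shares are undefined (an error, not NaN) when the objective is nonpositive.
FBA optima need not be unique; shares are computed from one returned vertex,
and the bundled toy model is built to have a unique optimum so its expected
values are exact. The tests also cross-check the model serialization and
optimum against an independent constraint-based implementation reading the
same SBML file.

Carbon-flux shares weight each active exchange by the carbon count parsed
from its metabolite's formula; carbon-free species (O2, H2O, protons) are
excluded and generic residue formulas (`R` groups) are rejected as
uncountable. Flux comparison uses magnitude ratios with a 2-fold default;
zero-to-nonzero is always reported ("activated"/"silenced") to avoid
division by zero masking real changes.

## The perturbation screen

Every node fixed in the initial conditions is flipped one at a time
(default scope `all-fixed`, with an `inputs`-only mode), and the whole chain
is rerun per condition. The control class comes from the *unconstrained*
FBA — the healthy reference is the metabolic model with no regulatory
constraints at all. A profile is glycolytic when its glycolytic share
strictly exceeds 50%. Per-condition failures (infeasible FBA after harsh
constraints) are recorded in the result and excluded from driver calls;
they never abort the screen. Drivers are the flips whose profile class
equals the control class, ordered by oxidative share.

## What the generated system emulates — and what it does not

`make_toy_coupled_model()` builds the study system: a regulatory core
`Hypoxia → HIF1 → PDK1 ⊣ PDH` — the canonical hypoxia-driven glycolytic
switch, in which PDK phosphorylates and inactivates pyruvate dehydrogenase —
plus decoy inputs wired to inert targets, coupled to a lumped
glycolysis/TCA/OXPHOS stoichiometric model through a single map entry
(PDH gates the TCA entry reaction). Glucose uptake is capped at 10 flux
units; with the TCA lump open the unique optimum is 140 (20 + 20
substrate-level, 100 complex V; oxidative share 5/7 ≈ 71.43%), with it
blocked all pyruvate goes to lactate (objective 40, glycolytic share 100%).
The three decoy inputs (a realistic handful for a miniature screen) take
seeded random baseline values, and the shipped contrast table plants their
values as differentially expressed genes at effect sizes (|FC| ≥ 2,
adjusted p < 0.01) comfortably beyond the calling thresholds, with null
genes designed to fail exactly one threshold each.

The toy system deliberately omits features of real models: ATP/ADP mass
balance and investment steps (the flux-sum objective makes explicit ATP
bookkeeping pure degeneracy), alternate carbon sources, hundreds of
reactions with alternate optima, many-to-one gene-to-node mappings, and
trap spaces that are not single stable states. Passing tests therefore
demonstrate correctness of the machinery — exact trap spaces, sound
propagation, correct constraint derivation and LP optimality — not that any
particular biological model is right. Real-model reproduction runs through
`reproduce_published_analysis()` on externally deposited files.

Fixture sizes and simulation counts throughout (networks of 4–10 nodes, 100
oracle comparisons, 20 screen replicates) were chosen as the smallest sizes
that exercise every code path and keep the whole suite comfortably
interactive.

## Known limitations

- Kleene percolation may be weaker than reachability-based value
  propagation; on models where the two differ, the percolated set here is a
  (sound) subset, and trap-space counts on real models should be compared
  against a reference implementation before interpretation.
- Scenario readouts are asymptotic only (values across minimal trap spaces);
  transient behaviour is out of scope.
- The trap-space solver enumerates residual states and is meant for models
  whose conditions fix most of the network; fully unconstrained large models
  exceed `max_free_nodes` by design.
- Single-node perturbations only; combinatorial screens are future work.
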