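# boolfba

Hybrid Boolean-regulatory / constraint-based metabolic modelling in R, built
to study metabolic reprogramming of stromal cells — in particular the
*reverse Warburg effect*, in which cancer-associated fibroblasts (CAFs) shift
their ATP production from oxidative phosphorylation to aerobic glycolysis and
secrete energy-rich fuels (lactate, alanine) for neighbouring tumor cells.

## What it computes

The pipeline couples two model layers:

1. **Regulatory layer.** An asynchronous Boolean network (SBML-qual, as
   produced by map-to-model tools) is contextualized with cell- and
   disease-specific initial conditions: up-/down-regulated genes from a
   differential-expression contrast (adjusted *p* < 0.05, |FC| > 1.5) set
   matching nodes to 1/0, and curated literature values fill the remaining
   inputs. Every fixed node is clamped as a constant; values are propagated
   (three-valued percolation) and the **minimal trap spaces** of the clamped
   network — partial states `m` with `f_v(x) = m_v` for every fixed node `v`
   and every state `x` in the subspace, containing no smaller such subspace —
   summarize its asymptotic behaviour.
2. **Metabolic layer.** For every mapped metabolic component (enzyme or
   metabolite) whose *maximal* value across trap spaces is 0, the linked
   reactions (catalyzed resp. producing) are constrained to zero flux in a
   stoichiometric model (SBML/fbc). Flux balance analysis then maximizes the
   ATP objective `max Σ v_i` over the ATP-producing reactions (the two
   glycolytic substrate-level phosphorylation steps and OXPHOS complex V)
   subject to `S v = 0`, `lb ≤ v ≤ ub`, and reports
   - glycolytic vs oxidative **ATP shares** (percent of the objective),
   - **carbon-flux shares** of uptake/secretion
     (`100 · C_i |v_i| / Σ C_j |v_j|` per direction),
   - reactions altered more than 2-fold between control and disease.
3. **Driver screen.** Every fixed initial condition is flipped one at a time
   (in-silico knock-out/knock-in), the whole chain is rerun per condition,
   and the flips that restore the control-like (oxidative) profile are
   reported as candidate regulatory drivers of the switch.

Trap spaces are computed exactly by a percolation-reduced closure method and
verified against a `3^n` brute-force oracle; FBA runs on a built-in
bounded-variable two-phase simplex (Bland's rule), cross-checked in the tests
against an independent LP implementation.

## Worked example

The repository is organised as an analysis workflow over the package; the
numbered scripts in `analysis/` run the whole study on a generated system —
a hypoxia→HIF→PDK→PDH regulatory core coupled to a lumped
glycolysis/TCA/OXPHOS model with a planted driver — and write their tables
under `results/`:

```sh
Rscript analysis/01_generate_system.R   # models + contrast + conditions (SBML/TSV/YAML)
Rscript analysis/02_contextualize.R     # DEG calling and discretization
Rscript analysis/03_trapspaces.R        # clamping, propagation, minimal trap spaces
Rscript analysis/04_metabolic.R         # constraints, control/disease FBA, C-flux
Rscript analysis/05_screen.R            # knock-out/knock-in driver screen
```

Step 4 prints, for the hypoxic (disease) baseline vs the unconstrained
control:

```
Constraints: 1 reaction(s) forced to zero flux [TCA]
Control FBA: objective 140.00, glycolytic 28.57%, oxidative 71.43%
Disease FBA: objective 40.00, glycolytic 100.00%, oxidative 0.00%
disease secretion C-flux:  lac 100.00%
```

i.e. blocking the PDH-gated TCA entry diverts all pyruvate to lactate — the
glycolytic switch. Step 5 screens all four fixed inputs and finds that only
the hypoxia knock-out restores the oxidative control profile:

```
       id    node flipped_to glycolytic oxidative      class
 baseline    <NA>         NA     100.00      0.00 glycolytic
       C1 Hypoxia          0      28.57     71.43  oxidative
       C2    DCY1          0     100.00      0.00 glycolytic
       ...
Driver node(s) restoring the control-like profile: Hypoxia
```

The same functions run unchanged on real deposited models (a breast-CAF
SBML-qual model plus the MitoCore metabolic network) via
`reproduce_published_analysis()`; those files are not redistributed here.

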