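---
title: "Coupling Boolean regulatory models to constraint-based metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling Boolean regulatory models to constraint-based metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxlogic)
```

## The modelling problem

Curated molecular interaction maps describe, in process-description form,
which reactions produce which species and under which catalytic or inhibitory
influences — but they are static. Constraint-based metabolic models, at the
other end, predict steady-state flux distributions but know nothing about the
signalling and gene-regulatory state of a particular cell type or disease.
`fluxlogic` joins the two: it derives a Boolean dynamical model from the map,
works out which metabolic components are *provably inactive* in the long run,
and turns exactly those into zero-flux constraints on a generic metabolic
model. Comparing the control and contextualized optima — summarised as the
fraction of ATP produced by glycolysis versus oxidative phosphorylation —
then exposes how the regulatory layer reshapes energy metabolism. The
approach needs no kinetic parameters and no omics data, which makes it
attractive precisely where those are missing.

## From map to Boolean model

Each map species becomes one Boolean variable. For a species $s$ the update
function is a disjunction over the reactions that produce it; each reaction
contributes the conjunction of its reactants and positive modifiers with
every negative modifier negated:

$$f_s \;=\; \bigvee_{r\,:\,s \in \mathrm{prod}(r)}
  \Big(\bigwedge_{x \in \mathrm{react}(r)} x
  \;\wedge \bigwedge_{m \in \mathrm{mod}^+(r)} m
  \;\wedge \bigwedge_{m \in \mathrm{mod}^-(r)} \neg m\Big).$$

Species never produced become inputs with the identity update $f_s = s$, so
both of their values remain dynamically possible. Modifier polarity follows
the conventional CellDesigner vocabulary (CATALYSIS-like classes positive,
INHIBITION-like negative) and is configurable through the `polarity`
argument of `infer_boolean()`. Two pragmatic choices deserve mention, since
process-description maps underdetermine them:

* **Degradation-only reactions contribute no negative terms.** Inhibition is
  expressed through modifiers only. This is the most conservative reading of
  a consumption arc, which in maps frequently encodes transport or complex
  formation rather than active removal.
* **Each species id is one variable; aliases are recorded, not merged.**
  Collapsing complexes and their components into shared variables requires
  curation decisions the file format does not carry.

Two options mirror how such maps are used in practice: a subnetwork can be
extracted upstream and/or downstream of seed components
(`extract_subnetwork()`), with regulators cut off at the boundary re-added
as free identity inputs rather than frozen constants; and an
initial-conditions CSV can clamp components to 0/1
(`apply_initial_conditions()`), which replaces their update functions by
constants — this is the mechanism that encodes a cell- or disease-specific
context.

## Minimal trap spaces as asymptotic behaviour

A *trap space* is a partial assignment of variables (the rest free) that no
trajectory can leave, under any update schedule: for every fixed variable
$v = b$, $f_v$ evaluates to $b$ throughout the subspace. Minimal trap spaces
over-approximate the asynchronous attractors, so a component fixed at 0 in
*every* minimal trap space is inactive in every possible long-run behaviour
— the strongest statement available without enumerating attractors.

`minimal_trap_spaces()` works on the prime implicants of each update
function. The closure condition becomes combinatorial: a subspace fixing
$v = b$ is closed for $v$ exactly when every prime implicant of $f_v$
toward $1-b$ contains a contradicted literal. Variables/values are explored
by a complete depth-first search over $\{0, 1, \mathrm{free}\}$ assignments
with unit propagation on these blocking constraints (the place/negated-place
siphon encoding of the implicants, explored as an iterative constraint
search), followed by an inclusion-minimality filter. The search is exact but
exponential in the worst case; the test suite exercises it against a
brute-force enumeration of all $3^n$ subspaces on hundreds of random
networks ($n \le 10$, in-degree $\le 3$ — sizes chosen so the brute-force
oracle itself stays exact and fast), and typical map-derived models with
tens of components are solved in milliseconds. Prime implicants are computed
by Quine–McCluskey over each function's truth table, which bounds practical
in-degree at roughly 16 regulators per function — far above what curated
maps produce.

Projection (`project_max()`) then takes, per component, the maximum value
across minimal trap spaces, with one deliberate asymmetry: **a free variable
counts as possibly active**, i.e. projects to 1. Only fixed-at-0-everywhere
components qualify as proven inactive, because the constraint rule must not
switch off a reaction whose enzyme could still be expressed in some
long-run behaviour.

## From projections to flux constraints

Regulatory components and metabolic entities are matched by exact,
case-sensitive identifier equality (`match_components()`): a variable equal
to an enzyme/gene label of a reaction maps as an enzyme; a variable equal to
a metabolite id maps to that metabolite's producing reactions. Exactness is
a feature — silent fuzzy matching across naming schemes causes quiet,
untraceable errors — and an explicit synonym table covers the genuine
bridges. For each matched component with projected value 0:

* **enzyme** — every catalyzed reaction gets bounds $(0, 0)$;
* **metabolite** — every *producing direction* is closed: the upper bound
  drops to 0 where the metabolite is a forward product, the lower bound
  rises to 0 where a reversible reaction produces it in reverse.
  Consumption is untouched, since inactivity of a metabolite speaks to its
  production, not to reactions that could drain a residual pool. A
  `metabolite_rule = "knockout"` flag selects the stricter behaviour.

Components of the metabolic model that never appear in the Boolean network
contribute nothing: absence from the map is not evidence of inactivity, so
the generic state is retained for them.

## FBA, FVA and the ATP report

`fba()` maximizes the model's declared objective (for energy metabolism, an
ATP demand reaction) subject to $S v = 0$ and the flux bounds; `fva()`
minimizes and maximizes each reaction with the objective held at a fraction
of the optimum, 1 by default — the comparisons of interest concern the
optimal face, and at fraction 1 every FVA interval must bracket the
corresponding FBA flux, which the tests verify on every fixture. The linear
programs are solved by a bounded-variable two-phase primal simplex written
for this package (R/simplex.R) with Bland's anti-cycling rule and an LP
presolve that substitutes out fixed variables — knockout-style models
otherwise produce the degenerate tableaus that trip generic implementations.
Feasibility tolerances are $10^{-9}$; reported fluxes below $10^{-9}$ are
rounded to 0 so that text outputs are reproducible.

An FBA optimum is generally degenerate, so single fluxes are
solver-dependent. All derived summaries therefore use the objective value,
class-wise ATP sums, or FVA envelopes. `atp_ratio()` counts, per reaction,
the positive part of (signed stoichiometric ATP coefficient × flux), sums
it into a total and into glycolytic/oxidative class sums, and reports the
two dimensionless ratios. When an FVA envelope is supplied, any
ATP-producing reaction with a non-point interval flags the report as
`solution_dependent`. Which reactions count as "glycolytic" versus
"oxidative" is configuration (`atp_classification()`), not biology baked
into the code; the shipped default covers the toy model's substrate-level
kinases and ATP synthase and is explicitly provisional for other models —
in particular, whether substrate-level TCA phosphorylation should count as
oxidative is a modelling decision left to the user.

## The synthetic coupled fixtures

`coupled_fixture()` writes a complete toy instance of the whole workflow:
a CellDesigner map of a nine-component signalling layer (a growth-factor
branch activating the glycolytic kinases through HIF1A, an oxidative branch
activating ATP synthase, β-oxidation and PDH through PGC1A, and a
HIF1A→PDH inhibition reproducing the Warburg-style switch), the matching
13-reaction toy of central energy metabolism (`toy_core_metabolism()`,
glucose and fatty-acid uptakes of 10 and 5 flux units, two substrate-level
ATP steps, a lumped TCA/oxphos route yielding 2.5 ATP per NADH), and a
scenario-specific initial-conditions file. Every optimum is hand-solvable:
the control optimum is 120 with glycolytic ratio 1/6; switching the
oxidative input off leaves 20 (ratio 1); switching the growth-factor input
off leaves 50 (ratio 0). The generator emits a ground-truth sidecar naming
the constraints each scenario provably induces, so end-to-end tests compare
against recorded expectations rather than re-derived ones.

The fixtures emulate the *shape* of real inputs — namespaced CellDesigner
XML, SBML-fbc with parameter-backed bounds and gene-product associations,
BiGG-style identifiers shared across the two halves — but not their scale
or their curation noise: real maps have thousands of species, heavy alias
structure, complexes, and imperfect identifier overlap. Passing tests
demonstrate correctness of the machinery, not robustness to curation
artefacts; the synonym table and the configurable polarity/classification
are the intended escape hatches for real data.

## Numerical and determinism choices

* Trap spaces, CSV outputs and BNET serialization are ordered
  lexicographically; re-running a configuration reproduces byte-identical
  files.
* The SBML-qual reader accepts both default-term conventions (`resultLevel`
  0 or 1) and treats the default as the else-branch of the ordered function
  terms; multi-level species are rejected rather than binarized.
* FVA retains a hair of slack ($10^{-9}$, scaled) on the optimality
  constraint so the optimal face remains feasible in floating point.
* `random_boolean_network()` seeds its own RNG stream and restores the
  caller's, so fixture generation cannot perturb user simulations.

## Known limitations

Multi-valued logical models, value propagation/percolation-based reduction,
attractor enumeration beyond the small-scale test oracle, parsimonious FBA
and expression-based contextualization methods are out of scope. The
trap-space search and the dense simplex both target desk-scale models
(hundreds of variables/reactions); genome-scale work should interface the
exported constraint sets with a dedicated solver stack.
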