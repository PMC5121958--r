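---
title: "Multi-phase constraint-based modelling of growth on a complex medium"
author: "phaseflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-phase constraint-based modelling of growth on a complex medium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phaseflux)
```

# The problem

A bacterium growing on a complex medium — a peptone broth, say — does not see
one carbon source but a mixture of amino acids that it consumes
hierarchically: preferred substrates first, the rest as the preferred ones run
out. Each depletion event redefines the nutritional environment, and with it
the flux distribution the metabolic network must adopt. `phaseflux` models
this as a sequence of *phases*: hour-long intervals of a fed-batch growth
curve, each with its own set of usable substrates and uptake rates, each
simulated as an independent steady state. The questions the package answers
are system-level ones: how many reactions does growth require in each phase,
how much of the network is rewired at each substrate switch, which reactions
rise and fall together, and how different do the predictions look when the
cell is assumed to minimise reprogramming rather than maximise growth.

# From growth data to uptake bounds

The parameterization stage turns a growth-curve table — time (h), optical
density, growth rate $\mu$ (h$^{-1}$), and the molar concentration of each
amino acid — into per-phase flux bounds.

**Biomass calibration.** OD is converted to biomass (g/l) with a single
anchor: a measured cell dry weight $w$ (g) at a reference OD $d$ in a culture
volume $V$ (l), giving $w/(dV)$ g·l$^{-1}$·OD$^{-1}$. The bundled default
(1.28 g, OD 3.8, 1.4 l) gives 0.2406 g·l$^{-1}$·OD$^{-1}$.

**Deltas and yield.** For phase $i$ (between time points $i-1$ and $i$) the
biomass increment $\Delta B_i$ comes from the OD difference, and each amino
acid's mass-concentration decrease
$\Delta c_{aa,i} = \max(0,\, c_{aa,i-1} - c_{aa,i})$ is clamped at zero when
the concentration *rose* over the hour (nutrient accumulation — a real
feature of fed-batch data that must not be counted as negative consumption).
Molar concentrations (mM) are converted with the molar weight:
$c = \mathrm{conc} \times MW \times 10^{-3}$ g/l. The phase yield is
$Y_i = \Delta B_i / \sum_{aa} \Delta c_{aa,i}$ (g biomass per g substrate),
so $Y_i \sum \Delta c = \Delta B_i$ holds exactly by construction — the
package asserts this closure.

**Uptake fluxes.** The uptake-flux bound of amino acid $aa$ in phase $i$ is

$$
UF_{aa}^{\,i} \;=\; \frac{c_{aa}^{\,i}}{\sum_{a \in AA} c_{a}^{\,i}}
\cdot \frac{\mu_i}{Y_i} \cdot \frac{1}{MW_{aa} \times 10^{-3}}
\quad [\text{mmol·gDW}^{-1}\text{h}^{-1}],
$$

optionally multiplied by a per-phase scale constant. Three reading choices
were genuinely open and are resolved as follows:

* $c_{aa}^{\,i}$ is the **mass** concentration at the **start** of phase $i$
  (what is available during that hour), and the denominator runs over all
  amino acids with nonzero concentration — including those merely in stock.
* An amino acid whose concentration did not fall during the phase
  ($\Delta c = 0$) gets $UF = 0$ regardless of its stock: availability alone
  is not consumption.
* The per-phase scale constants default to 1, i.e. the formula exactly as
  written. A `scale = "normalize"` mode instead picks each constant so the
  total carbon-mass uptake $\sum UF \cdot MW \cdot 10^{-3}$ equals a
  configurable reference. Normalisation is deliberately *not* the default:
  because $\sum UF \cdot MW \cdot 10^{-3} = \mu_i/Y_i$ before scaling,
  normalising would cancel the growth-rate and yield factors entirely and
  with them the declining-uptake structure that drives the downstream
  analyses (the growth-rate-adjusted "decreasing" sets, the near-zero final
  phase). It remains available for analyses that need phases on a common
  carbon footing, e.g. the flexible-reaction comparison below.

**Phase selection.** Trailing phases with neither growth nor consumption are
dropped (a 12-step curve with two dead tail steps yields 10 modelled phases);
a dead phase in the middle of the curve is retained, since only the tail is
uninformative.

# Phase-wise FBA and FVA

Each modelled phase is a flux balance analysis: maximise the biomass reaction
subject to $S v = 0$ and bounds, with each amino-acid exchange's uptake
capacity set to that phase's $UF$ magnitude (uptake is the negative direction
of an exchange written `met_e <->`; the code is sign-aware if a model encodes
exchanges the other way round). Salt, O2 and ammonium exchanges keep the
model's own (open) bounds. Flux variability analysis then fixes biomass at a
fraction of the optimum (default 1.0 — strict optimality, since the method is
about alternate *optima*) and reports each reaction's admissible range; the
span $v = f_{max}/f_{min}$ classifies reactions as *fixed* ($v = 1$) or
*flexible*. When $f_{min} = 0$ the ratio is undefined: the span is reported
as `NA` and the classification falls back on $f_{max} - f_{min}$.

Numerical choices, all configurable: a reaction "carries flux" when
$|v| > 10^{-9}$; a change in flux counts when $\bigl||v_2|-|v_1|\bigr| >
10^{-6}$ mmol·gDW$^{-1}$h$^{-1}$; steady state is asserted at
$\lVert Sv\rVert_\infty < 10^{-6}$. FBA flux vectors at degenerate optima are
solver-dependent; the package returns the simplex basic solution by default
and offers a parsimonious post-processing (`parsimonious = TRUE`: minimise
$\sum |v|$ at the fixed optimum) for users who need machine-independent
active-reaction counts — a deliberate post-processing step, not part of the
core method.

## The LP and QP kernels

No linear-programming package is assumed: the LP kernel is a two-phase
bounded-variable revised simplex written for this package (dense basis
inverse with eta updates, a Bland's-rule fallback against cycling, periodic
refactorisation), and the quadratic kernel is a primal active-set projection
onto $\{Sv = 0,\ lb \le v \le ub\}$ seeded from an LP-feasible vertex. Both
are validated in the test suite against independent oracles: brute-force
vertex enumeration built directly from the constraint matrices for the LP,
and `kernlab`'s interior-point solver plus closed-form KKT solutions for the
QP.

# Transition classification

Between consecutive phases, every reaction active in either phase is placed
in exactly one of four classes: *reversed* (sign flip with both magnitudes
above threshold), *increased*, *decreased* (by comparison of absolute
fluxes), or *unchanged*; reactions additionally *turn on* or *off* when their
activity state flips (a reaction turning on is, by construction, also an
increasing one; reversed reactions are never double-counted as
increased/decreased). Because a monotonically falling growth rate drags many
fluxes down at every single transition for purely systemic reasons, a
*growth-rate-adjusted* decreasing set is also reported: reactions that
decrease at every transition in which they are active are removed. An
alternative normalisation — dividing each phase's fluxes by its predicted
growth rate — is provided as `normalize_by_growth()`; activity sets are
invariant to it when the threshold is scaled accordingly, which the tests
assert.

# The minimal-adjustment (nutritional-MOMA) chain

Biomass maximisation assumes the cell re-optimises from scratch at every
nutrient switch. The alternative hypothesis — cells minimise the
reprogramming effort at each transition — is implemented as a chain of
quadratic projections: the flux vector of phase $P$ is the closest point (in
squared Euclidean distance over all reactions, the canonical
minimal-adjustment objective) to the previous phase's solution among all
steady-state vectors satisfying phase $P$'s bounds. Design choices:

* **Seeding.** No earlier state than the first modelled phase exists, so the
  chain starts from that phase's FBA solution and covers one transition per
  subsequent phase (nine columns for ten phases).
* **No biomass floor.** Only the nutrient bounds change between phases;
  growth is whatever emerges from minimal adjustment. Consequently the
  chain's biomass never exceeds the same phase's FBA optimum (asserted).
* **Norm.** Squared Euclidean by default; an L1 variant (`norm = "L1"`,
  solved as an LP) is available but off by default.

On the synthetic system the chain keeps more reactions active than FBA —
it drags a halo of small fluxes along instead of jumping between sparse
vertices — mirroring the qualitative behaviour expected of
minimal-adjustment solutions. `compare_methods()` quantifies this per phase
and per subsystem.

# Covariation clustering

Reactions whose fluxes rise and fall together across transitions are
candidates for functional partnership or shared regulation. For each
non-constant reaction the per-transition difference of absolute fluxes
$d_z = |f_{z+1}| - |f_z|$ forms a vector (nine entries for ten phases);
Pearson correlations between these vectors define a graph with edges at
$r > 0.7$, and clusters are its connected components (singletons dropped).
Two open points are settled explicitly: the threshold comparison is *strict*
(configurable), and components — not cliques — implement "sharing a
correlation above the threshold", the loosest construction consistent with
that phrase; a clique reading would only shrink clusters. Vectors with zero
variance (fluxes that change only by reversal) are excluded with a warning
rather than propagating `NaN` correlations. Clusters map to gene sets via
the GPR rules and export as plain-text lists plus a GMT file for external
annotation tools (association databases, motif finders), which are outside
the package's scope.

# The synthetic study system

The generator exists so the entire pipeline — and its tests — runs without
any external data. It emulates the statistical structure of a fed-batch
amino-acid experiment, with defaults chosen once to mirror that setting:

* **12 hourly phases**, growth rate declining linearly from 0.40 to
  0.08 h$^{-1}$ over the first ten and zero in the last two (no growth, no
  uptake — exercising the phase-truncation rule).
* **Six amino acids** by default (glutamate first and preferred at twice the
  consumption weight of the others): a block of three early substrates is
  exhausted simultaneously at phase 3 (the planted *major switch*, after
  which one phase runs on glutamate alone), and two late substrates enter use
  at phase 5 and run to the end. Initial concentrations are whatever the
  consumption plan requires, in mM (converted through real molar weights so
  the unit conversion path is always exercised).
* **Biomass calibration** fixed at the (1.28 g, OD 3.8, 1.4 l) anchor, and
  the OD trajectory is anchored so OD at the end of growth equals the
  reference OD — the calibration is self-consistent.
* **One planted accumulation**: one early substrate's concentration rises
  15% above its previous value for a single hour, exercising the
  $\Delta c = 0$ clamp (and producing a realistic transient shut-off of that
  substrate's uptake).
* **Planted yield 0.45 g/g**, a realistic aerobic yield on amino acids;
  consumption totals are derived from it, so parameterizing a noise-free
  curve recovers it exactly (asserted at $10^{-9}$).
* **Noise is off by default.** Multiplicative noise on concentrations makes
  merely-stocked substrates look faintly consumed (any downward wiggle is a
  positive delta), destroying the planted onset structure; since the
  scenario's purpose is to carry exact planted truth, `noise_sd = 0` is the
  default and noise is an explicit knob.

The companion toy network gives each amino acid an exchange, a transporter, a
degradation route into a common carbon pool and a biosynthesis route back
from it; a cyclic TCA-like core burns the pool to CO2 and redox equivalents,
oxidative phosphorylation converts those to energy, and biomass consumes a
small amount of every amino acid plus energy. Two constructional choices
matter downstream: degradation of earlier-listed amino acids yields more
energy (so a single-substrate screen ranks glutamate fastest), and the
biomass coefficients per amino acid are small (0.01) so that uptake exceeds
anabolic demand — surplus substrate is catabolised, degradation pathways
genuinely run while their substrate is fed, and shut down at its depletion,
which is what makes the planted major switch the transition with the most
flux changes.

**What passing tests on this system do and do not show.** The generator
plants exact, noise-free structure: depletion times are sharp, the yield is
constant, growth is exactly exponential within phases, and the network is
small enough that FBA optima are mostly unique. Real fed-batch data have
measurement noise, drifting yields, partially overlapping substrate usage and
genome-scale degeneracy; passing here validates the *machinery* (formulas,
classifications, optimisations, bookkeeping), not the biological fidelity of
any particular genome-scale prediction. Reaction counts at degenerate optima
remain solver-dependent on large models unless the parsimonious flag is used.

# Problem sizes

All shipped analyses run at desk scale: the default system has 33 reactions,
27 metabolites and 10 modelled phases; FVA solves about 660 LPs and the whole
pipeline (simulation through covariation, with manifest) completes in a few
seconds on one CPU. The same code paths accept genome-scale SBML models; the
kernels are dense, so models beyond a few hundred reactions would want a
sparse LP backend behind the same interface.

# Known limitations

* The per-phase scale constants of the uptake formula are a modelling choice
  (default 1); absolute flux magnitudes are therefore comparable across
  phases only up to that choice — ratios within a phase are not affected.
* Phases are independent steady states; there is no dynamic FBA, no substrate
  depletion feedback within an hour, and no thermodynamic or loop-law
  constraint (the toy network's paired degradation/biosynthesis routes admit
  a thermodynamically infeasible cycle, which FVA duly reports as flexible).
* The minimal-adjustment chain inherits the usual MOMA caveat: the distance
  is measured over all reactions in flux units, so large central fluxes
  dominate the objective.
* Growth rates are taken from the input table, not estimated from OD; the
  generator keeps them consistent by construction.
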