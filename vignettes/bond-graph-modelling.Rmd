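---
title: "Energy-based modelling of metabolic networks with BondGraphMet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-based modelling of metabolic networks with BondGraphMet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, message = FALSE}
library(BondGraphMet)
```

# The model

BondGraphMet treats a biochemical reaction network as an energy-routing
system. Species store energy, reactions dissipate it, and the
stoichiometric matrix $N$ is nothing but the wiring between the two. All
potentials are Faraday-scaled — molar Gibbs energies divided by Faraday's
constant, in millivolts — so the thermal potential
$\phi_N = RT/F$ (`thermalPotential()`, about 26.7 mV at the default
310 K) is the natural unit of driving force. `faradayScale()` converts
kJ/mol once at the data boundary; nothing inside the package works in
kJ/mol, and $\phi_N$ is always computed from $R$, $T$ and $F$, never
hard-coded.

Each species $A$ has the constitutive law
$$\phi_A = \phi_N \ln(K_A x_A),$$
with a single positive thermodynamic parameter $K_A$
(`cePotential()`, `speciesConstant()`). Each reaction carries the
Marcelin–de Donder flow
$$f = \kappa\left(e^{\Phi^f/\phi_N} - e^{\Phi^r/\phi_N}\right),$$
where $\Phi^f = (N^f)^T\phi$ and $\Phi^r = (N^r)^T\phi$ are the forward and
reverse reaction potentials assembled from the reactant and product parts
of $N = N^r - N^f$ (`decomposeStoichiometry()`, `reactionPotentials()`).
With constant $\kappa > 0$ this is mass action in disguise
($e^{\Phi^f/\phi_N} = \prod_i (K_i x_i)^{N^f_{ij}}$); a state-dependent
$\kappa(\Phi^f, \Phi^r)$ with three positive constants $(f_{max}, K_f,
\rho)$ gives the reversible Michaelis–Menten law (`reFlowMM()`).

Two structural identities carry the thermodynamics:

* $\phi^T\dot x + \Phi^T f = 0$ — the junction structure transmits but
  neither stores nor dissipates energy;
* $f\,\Phi \ge 0$ for each reaction — flows run downhill, for *any*
  positive $\kappa$ (or MM triple).

Positivity of the parameters is therefore the entire thermodynamic
constraint set: Wegscheider-type detailed-balance conditions and the energy
balance analysis (EBA) conditions ($K^T\Phi = 0$ over the cycle space, and
positive flux resistances $r_i = \Phi_i/f_i$) cannot be violated by
construction. `ebaCheck()` verifies both on any flux/potential pair, which
is useful precisely for data that did *not* come out of this
parameterization.

## Enzyme kinetics as a module

The Michaelis–Menten law is the steady state of the elementary two-step
mechanism (substrates + E ⇌ C, C ⇌ products + E). `expandEnzyme()`
performs that expansion with mass-action constants $\kappa_1, \kappa_2$,
and the parameter maps
$$f_{max} = \frac{e_0 K_C \kappa_1\kappa_2}{\kappa_1+\kappa_2},\qquad
\rho = \frac{\kappa_2}{\kappa_1+\kappa_2},\qquad K_f = \frac{K_C}{K_E},$$
with inverse $\bar\kappa = f_{max}/(K_C e_0)$, $\kappa_1 = \bar\kappa/\rho$,
$\kappa_2 = \bar\kappa/(1-\rho)$ (`massActionToMM()`,
`mmToMassAction()`). The printed form of this parameter map in the
literature is typographically ambiguous; the form implemented here is the
unique reading under which the ODE steady state of the expanded module
equals the lumped rate law, and the test suite verifies exactly that
equivalence by integrating the two-reaction module to steady state over
random parameter draws (an independent oracle — the mapping itself is never
used to generate the expected values). The expansion seeds the complex with
$10^{-6} e_0$ rather than zero so every potential is defined at $t = 0$;
the conserved total is still exactly $e_0$.

# Boundary conditions and pathways

A closed network relaxes to equilibrium with all flows zero. Two boundary
conditions open it:

* a **chemostat** fixes a species amount; the implied external flow is
  reported as that species' exchange flow $(Nf)_i$;
* a **flowstat** fixes a reaction flow (zero flow isolates a branch, the
  in-silico analogue of deleting the enzyme).

Both act on the dynamics through $N^{cd}$ — $N$ with chemostat rows and
flowstat columns zeroed (`applyStats()`) — so $\dot x = N^{cd} f$. Steady
flux patterns are the right null space of $N^{cd}$. `pathwayBasis()`
computes an exact integer basis $K_p$ by rational Gauss–Jordan elimination
(`integerNullspace()`): entries are kept as exact integer
numerator/denominator pairs, every column is scaled to coprime integers,
the sign is fixed so the first nonzero entry (in reaction file order) is
positive, and columns are ordered by their first participating reaction.
Null-space bases are not unique, so tests and comparisons work on column
*spans* and on the net pathway reactions $N_p = N K_p$
(`pathwayStoichiometry()`, `renderPathway()`), which are basis-independent
up to sign.

One modelling decision deserves emphasis: when a reaction is flowstatted,
the unit vector on its column is trivially in the null space of $N^{cd}$,
but it carries the *fixed* flow, not a free pathway coordinate. The basis
is therefore computed with flowstat columns deleted and re-inserted as zero
rows. Without this the flowstatted configurations would each report
spurious one-reaction "pathways".

Pathways are classified by their net reactions: type I touches primary
metabolites, type II only currency metabolites (futile cycles), type III
none (isoenzyme loops). The default currency set
(`currencyMetabolites()`: ATP/ADP, NAD(P)(H), Pi, H, H₂O, CO₂, O₂,
quinones, external protons, formate) is a package choice — the literature
distinguishes the two classes without fixing a list — and is overridable
per analysis.

## Fixtures

The packaged fixtures transcribe E. coli core subnetworks (upper
glycolysis + pentose phosphate; glycolysis; TCA cycle with pyruvate
dehydrogenase and pyruvate formate lyase; transhydrogenase; electron
transport chain; ATP synthase) as plain reaction lists, validated against
their published pathway analyses. Three transcription choices matter:

* RPI is oriented `RU5P <-> R5P` and SUCOAS
  `ADP + PI + SUCCOA <-> ATP + COA + SUCC`; with the opposite (BiGG
  database) orientations the published pathway coefficient vectors are not
  null vectors of $N^{cd}$, so the source network evidently used these
  directions. Orientation is pure bookkeeping — flows are signed — but it
  fixes the signs in $K_p$.
* Cytochrome oxidase is doubled to clear its half-integer O₂ coefficient;
  the published respiration pathway (12 CYTBD producing 12 O₂ worth of
  water) is itself only consistent with the doubled form. Net pathway
  reactions are unchanged by such column scaling.
* The standalone TCA analysis excludes the transhydrogenase: with all four
  NAD(P)(H) pools chemostatted, NADTRHD alone would be a fourth (type II)
  pathway, whereas the published analysis reports three. NADTRHD enters as
  its own module when the respiration network is composed, where the
  glucose pathway does use it.

The respiration fixture is not a file: it is `composeModules()` applied to
the five module fixtures over their shared species, exercising the
composition machinery every time it is built. Composition unifies exposed
species by name (a synonym table handles models with divergent
identifiers); species constants of shared species must agree — a conflict
is an error, never a silent overwrite.

# Parameter estimation

All estimation works on one steady state with (possibly partial)
measurements of reaction potentials $\Phi$, fluxes $f$ and concentrations
$c$, normalized per `normalizeData()` (concentrations by a reference
species, flows by a reference reaction converted to per-second; the induced
time unit is $t_0 = c_0/f_0$, computed, never hard-coded).

1. **Species potentials** (`estimatePotentials()`). With $N = [N_0\;N_1]$
   split by measured/unmeasured potentials, minimize
   $\tfrac12\phi^T(N_0N_0^T + \lambda I)\phi + (N_0\Phi_0)^T\phi$ subject
   to $-N_1^T\phi \ge \delta$: least squares on the measured potentials,
   a minimum-norm ridge ($\lambda$, default $10^{-6}$) resolving the
   (generic) rank deficiency, and the sign constraint expressing that every
   measured flow is positive. The strict inequality of the theory is
   implemented as a bound, default $\delta = 1$ mV. Active constraints are
   reported; the QP contract requires a KKT stationarity residual below
   $10^{-8}$ (checked via least-squares multipliers on the active set).
   The solver is `pracma::quadprog`.
2. **Pathway flows** (`estimatePathwayFlows()`). $(K_p^TK_p)\hat f_p =
   K_p^T f$ on the measured rows (missing rows deleted; rank checked);
   $\hat f = K_p\hat f_p$ imputes missing fluxes and $N\hat f$ gives the
   chemostat exchange flows.
3. **Reaction constants** (`estimateKappa()`). $\hat\kappa = \hat f/\hat
   f_0$ with $\hat f_0 = e^{\hat\Phi^f/\phi_N} - e^{\hat\Phi^r/\phi_N}$.
   Reactions at (numerical) equilibrium are flagged unidentifiable rather
   than divided through.
4. **Michaelis–Menten triples** (`estimateMMParams()`). The rate law
   rearranges to the linear-in-parameters form $y = X\theta$ with
   $X = (1, \hat f, -\hat f/\hat f_0)$, $y = \hat f \hat f_0^+/\hat f_0$,
   solved as a QP with $\theta$ bounded below by $10^{-9}$ (the strict
   positivity of the theory) and optional equality constraints. One steady
   state determines $f_{max}$ once $K_f$ and $\rho$ are fixed by equality
   constraint; three states determine all of $\theta$. Note the QP linear
   term is $-(X^Ty)^T\theta$, as expanding $\|y - X\theta\|^2$ requires.
   When converting fitted triples to $\kappa_1,\kappa_2$ the package uses
   the convention $e_0 = 1$, $K_E = 1$ (hence $K_C = K_f$), as the
   enzyme totals behind literature parameters are not separately
   identifiable from one steady state.
5. **Species constants** (`dynamicalConstants()`). With amounts per unit
   volume the reference state is the measured concentration, so
   $K = e^{\hat\phi/\phi_N}/c$ exactly inverts the species law at the
   steady state.

What is and is not identifiable: the QP recovers $\phi$ only up to the left
null space of $N_0^T$, so $\hat\kappa$ equals a generating $\kappa$ only
when $N^T$ has full column rank (the suite tests this on a three-reaction,
three-species network to $10^{-6}$). On rank-deficient networks — the
normal case — the guarantee is different and stronger in practice: the
estimated $(K, \hat\kappa)$ reproduce the measured steady state exactly,
because $\hat\kappa$ is defined as the ratio of the fitted flux to the
fitted thermodynamic driving force at the measured concentrations. The
suite asserts that reproduction to $10^{-4}$ on the glycolysis + pentose
phosphate fixture and checks that the error decreases monotonically as the
synthetic noise shrinks.

## The synthetic data generator

`generateDataset()` emulates a steady-state measurement campaign on a
network with known parameters: simulate to steady state, report $(\Phi, f,
c)$, then corrupt. Noise is additive Gaussian on potentials (they are
signed, in mV) and multiplicative log-normal on fluxes and concentrations
(they are positive), with one `noiseSd` controlling both scales; a
`missingFrac` masks flux/concentration entries at random and `unknownPhi`
marks designated reaction potentials unknown (emulating the typical
situation where a couple of reactions lack measured Gibbs energies). All
draws are seeded and the generator restores the caller's RNG state. What it
does not emulate: correlated measurement error, systematic bias,
compartment effects, or non-steady sampling — passing recovery tests here
demonstrates correctness of the estimation algebra, not robustness to real
measurement pathologies.

# Simulation

`simulateNetwork()` integrates $\dot x = N^{cd} f(x)$ with `deSolve::lsoda`
(stiff-capable; default relative tolerance $10^{-8}$, absolute $10^{-10}$).
Flows are evaluated in product form $\prod_i (K_i x_i)^{N_{ij}}$ — a
polynomial in the amounts for integer stoichiometry — so no logarithms are
taken inside the right-hand side and transient excursions towards zero are
harmless. Steady state is declared at $\|\dot x\|_\infty < 10^{-9}$ in
normalized units; `untilSteady = TRUE` extends the horizon in doubling
chunks up to `tMax`. Unknown initial amounts default to 1 (normalized).

The `Trajectory` object carries amounts, flows, exchange flows $Nf$,
potentials and reaction potentials. `fluxRatios()` reports the magnitude of
an exchange-flow ratio (product per substrate); at steady state it equals
the corresponding ratio of net-pathway coefficients, which is how the
simulated NADPH : G6P yield of 12 in the README arises independently of the
kinetic parameters. `energyAudit()` reports the internal power balance
$\phi^T\dot x + \Phi^T f$ (zero for closed systems) and the boundary power
absorbed by the chemostats, which are equal and opposite for open systems.

Because the two-step enzyme module and the lumped MM law agree exactly at
steady state, mass-action and MM parameterizations of the same network
reach the same steady-state fluxes and flux ratios while differing in their
transients; the suite checks this on a driven chain and on the
glycolysis + pentose phosphate configurations.

# Numerical choices and problem sizes

* Exact integer linear algebra for pathway bases (rational elimination,
  fraction-free in doubles — exact for any matrix whose intermediate
  numerators stay below $2^{53}$, far beyond these networks); the result is
  verified exactly ($N^{cd}K_p = 0$ in integer arithmetic) before it is
  returned.
* QP solutions require KKT residual $\le 10^{-8}$; $\lambda = 10^{-6}$ and
  $\delta = 1$ mV by default, both exposed.
* Fractional stoichiometries are rejected by default and scaled by the
  least common denominator (bounded, default 12) on request, because the
  bond-graph construction counts bonds per integer coefficient.
* Species and reaction order is file order, never sorted, so every matrix
  in a workflow is reproducible.
* Tie-breaks in the pathway basis (column order by first participating
  reaction, first nonzero entry positive) are deterministic.
* The test suite and examples run on desk-scale problems — networks of up
  to ~40 species / ~30 reactions, twenty-draw property checks, three noise
  levels × three seeds for the recovery curves — chosen so the whole suite
  completes in well under a minute while still exercising every code path.

# Known limitations

* Thermodynamic data enter as reaction potentials at a single condition; no
  pH/ionic-strength corrections or compartment-specific adjustments are
  applied (supply corrected ΔG values upstream).
* Shared-*reaction* composition (unifying Re components across modules) is
  not supported; composition is by shared species only.
* Michaelis–Menten fitting across three or more real conditions is
  supported by the algebra (`estimateMMParams()` accepts any number of
  states) but the pipeline wrapper targets the single-steady-state case
  with equality constraints.
* Pathway analysis returns a basis of the null space, not the full set of
  elementary flux modes; enumeration is out of scope.
* No graphical bond-graph layout; the JSON serialization is the exchange
  format.
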