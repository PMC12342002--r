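---
title: "Equilibrium analysis of mass-action signalling networks: models, mutations, and drug dosage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equilibrium analysis of mass-action signalling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crneq)
```

## The model

`crneq` treats an intracellular signalling network as a chemical reaction
network (CRN) with mass-action kinetics.  Given $n$ species with
concentrations $x(t) \in \mathbb{R}^n_{\ge 0}$ (nM) and $r$ reactions with
rate constants $k \in \mathbb{R}^r_{> 0}$, the dynamics are

$$\dot x(t) = S\,v(x(t), k), \qquad x(0) = x_0,$$

where $S$ is the $n \times r$ stoichiometric matrix and the flux of
reaction $j$ is $v_j = k_j \prod_i x_i^{a_{ij}}$, with $a_{ij}$ the
reactant coefficient of species $i$.  Time is kept in seconds internally
(rate units $\mathrm{nM}^{1-\text{order}}\,\mathrm{s}^{-1}$); the
reporting layer converts to minutes where figures conventionally use them.

Signalling networks built from binding, phosphorylation, and catalytic
cycles are *closed*: every protein moiety (e.g. total ERK across its free,
phosphorylated, and complexed forms) is conserved.  Formally, a
conservation law is a semi-positive vector $y \ge 0$ with $S^T y = 0$; the
rows of the conservation matrix $N$ span these laws, and the
*stoichiometric compatibility class* of $x_0$ is the affine slice
$\{x \ge 0 : N x = N x_0\}$ on which every trajectory stays.  For networks
of this type it is conjectured — not proven — that each compatibility
class carries a unique, globally asymptotically stable equilibrium.  The
package takes this *global stability condition* as a working assumption
and checks it empirically (multi-start agreement, cross-method agreement)
rather than relying on it silently.

The analysis pipeline then compares three equilibria: the *physiological*
equilibrium $x_e$, the *mutated* equilibrium $\tilde x_e$ after in-silico
mutation operators, and the *drug-loaded* equilibrium $x^d$ after the
network is enlarged with inhibitor binding reactions.  Perturbation
effects are summarised coordinate-wise by relative differences

$$\delta_i = \frac{\tilde x_{e,i} - x_{e,i}}{x_{e,i}}, \qquad
  d_i = \frac{x^d_i - x_{e,i}}{x_{e,i}},$$

which are well defined because the physiological equilibrium is strictly
positive in every coordinate (a property the generator guarantees and the
tests assert).  $\delta_i = -1$ means the species has been driven to zero.

## Extracting conservation laws

`find_conservation_laws()` computes the extreme rays of the cone
$\{y \ge 0 : S^T y = 0\}$ by the double-description method: start from the
non-negative orthant's rays, insert the equality constraints (columns of
$S$) one at a time, combine positive/negative pairs, and prune any
candidate whose support strictly contains another's — valid here because
for cones of this form the extreme rays are exactly the support-minimal
elements.  Arithmetic is exact: rays are integer vectors reduced by their
gcd (doubles represent them exactly well below $2^{53}$), so the invariant
$N S = 0$ holds *identically*, not to a tolerance.  A maximal linearly
independent subset of rays, preferring small supports and ordered
deterministically, forms $N$; if the left null space of $S$ has directions
with no semi-positive representative the function warns rather than fails.

A basis is *weakly elemented* when one species per law occurs in that law
alone with unit weight; those *elemental* species (lowest admissible index
per row, scanning rows in order, for determinism) make the columns of $N$
contain a $p \times p$ identity.  Network files may also declare their
conservation rows explicitly (`CONSERVATION` lines); declared rows are
verified exactly and used as-is, which keeps analyses of externally
converted networks reproducible without re-deriving their basis.

The double-description step is exponential in the worst case but cheap for
moiety-structured networks, whose rays are sparse and few; the package
targets desk-scale networks (tens of species) and verified bases for
larger converted ones.

## Computing equilibria

Two independent routes are provided, and their agreement is itself a test.

**Direct root finding** (`solve_equilibrium()`, the default).  At an
equilibrium on the class of $x_0$, $F(x) = 0$ where $F$ stacks the kinetic
conditions $S v(x)$ — minus the $p$ rows made redundant by the
conservation laws — and the class constraints $N x - N x_0$.  The deleted
rows are the elemental-species rows (`row_reduction_choice()`): each is
recoverable from its law, and the stacked Jacobian is square.  The solver
is a damped Newton iteration whose every iterate is projected onto the
non-negative orthant, with an Armijo-style acceptance test on
$\tfrac12\|F\|^2$; when no projected Newton step gives sufficient
decrease, it falls back to a backtracking gradient step on the same merit
function.  Defaults: tolerance $10^{-10}$ on $\|F\|_2/(1+\|x\|_\infty)$,
200 iterations per start, up to 10 seeded restarts.  Restart points are
drawn as positive random states at the scale of $x_0$ and then alternately
projected onto the affine class and clipped to the orthant; this stays
exactly on the compatibility class even for species shared between several
moieties (every enzyme–substrate complex), which is why a per-moiety
sampling scheme was not used — independent draws per law cannot satisfy
all laws at once.  Rank deficiency of the Jacobian at the solution yields
a warning (possible non-isolated equilibrium) instead of silence.

**Long-horizon integration** (`simulate_to_equilibrium()`).  Stiff
integration (lsoda with the analytic Jacobian; `rtol` $10^{-8}$, `atol`
$10^{-12}$ nM) over a geometrically growing horizon, declaring convergence
only when $\|S v(x)\|_\infty < \text{tol}_{eq}(1 + \|x\|_\infty)$ holds at
two successive checkpoints — one checkpoint invites mistaking a slow
transient (cascades have modes spanning seconds to days) for an
equilibrium.  Default ceiling $10^9$ s.

The root-finder is the default throughout the pipeline; integration is the
verification route.  The test suite requires them to agree within
$10^{-5}$ relative per coordinate on every fixture; observed agreement is
typically $10^{-9}$ or better.

## Mutation operators

A **loss of function** projects the initial state: the mutated protein and
every species whose composition contains it are zeroed
(`apply_lof()`).  The network is untouched; the equilibrium is simply
sought on the reduced compatibility class, where the zeroed species can
never be regenerated — hence $\delta = -1$ on all of them, exactly.
Composition metadata is therefore mandatory for LoF, and the toy generator
attaches it to every species.  Partial LoF is deliberately not offered.

A **gain of function** edits the kinetics: every reaction tagged
`deactivation:<GENE>` has its rate scaled by the level
$\lambda \in [0, 1]$ — the fraction of the physiological de-activation
rate retained — and at $\lambda = 0$ (complete mutation) the reactions are
removed outright (`apply_gof()`).  Which reactions constitute
de-activation of a protein is data, not code: the network file tags them.

`compose_mutations()` applies any set of mutations simultaneously; the
edits commute, so the result is order-independent, and the tests verify
the resulting *equilibria* agree too.

## Drug modelling

Inhibitors are modelled structurally (`add_drug()`): a free drug species
plus reversible binding to each listed target,
$\mathrm{drug} + T \rightleftharpoons \mathrm{drug}\_T$, with the bound
complex taking part in no other reaction.  Inhibition is therefore pure
sequestration — no modified catalytic rate laws are invented.  A
competitive inhibitor is given the catalytically active form(s) of its
target as binding partners; an allosteric inhibitor is given all
phosphoforms, locking them out of activation and catalysis alike.  The
caller lists targets explicitly, keeping the biology in the data layer.

Binding defaults are $k_{on} = 10^{-3}\ \mathrm{nM^{-1}s^{-1}}$,
$k_{off} = 10^{-2}\ \mathrm{s^{-1}}$ ($K_d = 10$ nM, a representative
small-molecule inhibitor affinity); both are fields of `drug_spec()` and
meant to be overridden when measured kinetics exist.  Optional first-order
decay of the free drug is available, with
`dbf_degradation_rate` $= 5.79 \times 10^{-6}\ \mathrm{s^{-1}}$ as the
literature value used for Dabrafenib.  Administration may be scheduled:
the drug then starts at zero and enters as a timed bolus
(`administration_event()`), which changes the transient — and only the
transient; the tests confirm the final equilibrium is
schedule-independent.

`drug_loaded_equilibrium()` implements the pipeline step: mutated
equilibrium in, augmented network built, free drug at $c_0$, complexes at
zero, equilibrium out.  Drugs at $c_0 = 0$ are skipped during
augmentation, so a zero dose is *exactly* inert — this makes 2-D scan
marginals at zero dose coincide bit-for-bit with 1-D scans.

## Dose optimisation

The scalar read-out is the modified geometric mean

$$G(d) = \Big(\prod_{i=1}^n (|d_i| + 10^{-6})\Big)^{1/n} - 10^{-6},$$

computed in log space.  The $10^{-6}$ offset admits zero entries; the
absolute value makes the product well defined for profiles of mixed sign,
consistent with $G$'s role as a distance of the drug-loaded equilibrium
from the physiological one ($G = 0$ iff $d = 0$).  Drug-related species
are excluded from $d$: they have no physiological reference concentration
to divide by.

`dose_scan_1d()` and `dose_scan_2d()` evaluate $G$ over dose grids and
report the grid argmin with smallest-dose (1-D) or lexicographic
smallest-dose (2-D) tie-breaking.  Optimisation is by grid only — matching
the scan-based read-out the metric was designed for — and per-dose solver
failures are recorded while the scan continues.  The optimum of a scan is
the concentration whose equilibrium best restores the healthy profile; on
the toy cascade the competitive-inhibitor curve $G(c)$ has an interior
minimum (under-dosing leaves the cascade active, over-dosing
over-suppresses it below the physiological level).

For local analysis, `activated_fraction()` divides an active form's
time course by its moiety's conserved total (from the conservation row of
an elemental species), giving values in $[0, 1]$.

## The synthetic testbed

`build_mapk_toy()` generates the desk-scale stand-in used by almost every
test: a GTPase cycle (GDP/GTP-bound Ras analog; GEF-catalysed activation,
GAP-catalysed hydrolysis tagged `deactivation:KRAS`), kinase tiers
activated by full enzymatic phosphorylation — explicit
$E + S \rightleftharpoons ES \to E + P$ cycles, not Michaelis–Menten
reductions, which would break the conservation-law structure — with a
phosphatase per tier and double phosphorylation on the MEK/ERK-like
tiers, plus a PTEN analog that weakly sequesters the terminal phosphatase
so loss-of-function is exercisable.

Defaults (totals in nM: KRAS 100, GEF 10, GAP 30, Raf 100, MEK 300,
ERK 400, phosphatases 50–100, PTEN 50; binding $10^{-3}$, unbinding
$10^{-2}$ throughout; GEF/GAP catalysis 0.05/1.0 s$^{-1}$;
kinase/phosphatase catalysis 0.5/0.15 s$^{-1}$; PTEN binding $K_d$ 10 µM)
were chosen once to put the network in the regime the model is about: a
quiescent physiological state (active-ERK fraction $\approx 1.6\%$) that
switches to strong pathway activation (fraction $\approx 0.47$) when the
GAP brake is removed, while the PTEN-analog LoF moves cascade active forms
by under 1%.  These are biologically representative orders of magnitude,
not fitted values.

What the toy *does* emulate: moiety conservation with a weakly elemented
basis, strictly positive physiological equilibrium, tagged de-activation
reactions, enzymatic double-phosphorylation cycles, and the qualitative
mutation signature (inactive forms down, active forms up, combination
dominated by the GoF).  What it does *not*: the scale (tens of species
versus hundreds), cross-talk between multiple pathways, feedback loops,
measured rate constants.  Passing tests therefore establish correctness of
the machinery and reproduction of the qualitative signalling behaviour —
not the published network's numeric values, which live in the deposited
full model and can be analysed by converting it to the interchange format
and loading it with `load_crcrn()`.

`random_mass_action_network()` provides seeded closed networks
(moiety-labelled species, reversible conversions and bindings) for
property-based testing; reversibility keeps equilibria strictly positive
so relative comparisons between the two solver routes are meaningful.
`build_reversible_pair()` is the closed-form oracle
($A \rightleftharpoons B$, equilibrium
$(\text{total}\,k_r, \text{total}\,k_f)/(k_f + k_r)$).

## Numerical choices and degenerate inputs

* Integrator: lsoda, `rtol` $10^{-8}$, `atol` $10^{-12}$ nM, analytic
  Jacobian; trajectory output clipped at zero (negatives beyond
  $-10^{-9}$ never observed on the fixtures).
* Root-finder: tolerance $10^{-10}$, damped steps halved down to
  $10^{-10}$, gradient fallback, 10 restarts; linear solves fall back to
  an SVD pseudo-inverse when the Jacobian is numerically singular.
* Ties: elemental species by lowest index; `top_variations()` ties keep
  species order; dose argmin ties take the smallest dose.
* Degenerate inputs: empty reaction sides encode sources/sinks; networks
  with $p = 0$ skip the class constraints; a zero reference concentration
  makes profiles undefined and raises an error rather than an Inf; a pure
  source (no equilibrium) is reported as non-convergence with the horizon
  reached.
* Problem sizes: the test-suite and the acceptance script use the 29-species
  toy cascade, 20 random networks of 6–12 species, dose grids of 11–21
  points, and a 6×5 combination grid — sizes chosen so the full suite
  recomputes everything from scratch in a couple of minutes.

## Known limitations

Uniqueness of equilibria is assumed (and spot-checked), not certified; the
double-description step is not meant for dense large networks;
pharmacokinetics beyond bolus-plus-first-order-decay is out of scope, as
are stochastic simulation, delays, compartments, and sensitivity analysis
with respect to kinetic parameters.  Partial loss-of-function is
deliberately unsupported.
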