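---
title: "Nested multipotential Monte Carlo with composite fragment energies"
author: "fragmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nested multipotential Monte Carlo with composite fragment energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragmc)
```

## The sampling problem

Simulating a bulk molecular liquid with a high-accuracy energy model is
expensive because every Markov-chain step nominally requires a full-system
energy.  `fragmc` implements the standard nested (multipotential) Monte
Carlo answer: a cheap classical force field generates sequences of trial
moves, and only every *P*-th configuration is assessed against the
expensive potential.  Writing $x$ for the current outer state and $y$ for
the candidate produced by an inner sequence of $P$ attempted moves
equilibrated under the low-level potential $U_\ell$ at generating
conditions $(T_g, p_g)$, the outer acceptance probability

$$
A(x \to y) = \min\!\left\{1,\ \exp\!\left[
  -\frac{\Delta U_h + p_t\,\Delta V}{R T_t}
  +\frac{\Delta U_\ell + p_g\,\Delta V}{R T_g}
\right]\right\}
$$

cancels the inner chain's bias and leaves the outer chain stationary with
respect to the *high*-level potential $U_h$ at the target conditions
$(T_t, p_t)$.  This expression assumes the inner sequence equilibrates
under $U_\ell$ at the generating conditions; it is the standard
detailed-balance result for nested chains, and it is the single most
consequential formula in the package.  Two consequences are tested
directly: when $U_h \equiv U_\ell$ and the conditions coincide the
exponent telescopes to zero (every outer proposal accepted), and on a
discretized 1-D double well the nested chain's occupancy histogram is
statistically indistinguishable from direct Metropolis on the high-level
surface.

Volume moves participate in the inner loop only (proposed uniformly in
$\ln V$ at $p_g$, with the usual $(N{+}1)\,\Delta\ln V$ Jacobian term);
the outer rule re-weights $\Delta V$ from $p_g$ to $p_t$ as shown.  The
$(N{+}1)\ln V$ factors are common to both ensembles and cancel in the
outer ratio.

## The composite many-body-expansion energy

The high-level tier is not a monolithic potential but a composite: a
medium-level full-system term plus high-minus-medium pairwise corrections
for every *proximate dimer*,

$$
E = E^{\mathrm{med}}_{\mathrm{full}}
  + \sum_{(i,j):\, d_{ij} \le r_c}
    \left[ E^{\mathrm{high}}_{\mathrm{int}}(i,j)
         - E^{\mathrm{med}}_{\mathrm{int}}(i,j) \right],
\qquad
E_{\mathrm{int}}(i,j) = E(ij) - E(i) - E(j),
$$

where $d_{ij}$ is the closest intermolecular site–site distance under the
minimum image and $r_c$ defaults to 4 Å, which selects the first
solvation shell.  Design choices behind this operator:

* **Contact metric.**  Dimers are selected and classified by their closest
  site–site contact, not by center-of-mass distance, because contact
  classes (hydrogen-bonded `O_H...H_O`, dispersion-bound `O_H...H_C`,
  repulsive `O_H...O_H`, …) are defined by the atoms that actually touch.
* **Geometry export.**  Dimer fragments are re-assembled across the
  periodic boundary (molecule 2 shifted by whole lattice vectors relative
  to molecule 1) so every exported fragment is contiguous in free space —
  a requirement for any external engine.
* **Monomer caching.**  Molecules are rigid, so a monomer's energy depends
  only on its template and conformer; monomer evaluations are cached per
  (backend, template, conformer).
* **Three-body terms.**  A `trimerHook` slot accepts an additive
  correction, but the default pipeline is pairs-only.
* **First-shell focus.**  The cutoff-restricted dimer set *is* the
  first-shell focus of this implementation; no additional importance
  reweighting is applied on top of it.

Backends are pluggable behind one contract (`fullEnergy`,
`fragmentEnergy`): the built-in classical force field, a zero potential, a
function-valued backend, and a generic external-engine adapter that writes
a fragment XYZ, runs a templated command, parses one energy, and caches
results by a geometry hash (coordinates rounded to $10^{-6}$ Å in
canonical atom order).  Surrogate "higher-level" theories for testing are
made by uniformly rescaling the force field's LJ well depths and/or
charges, which preserves every structural feature while shifting the
energy surface by a controlled amount.

## The built-in force field

The generator potential is a rigid-molecule site force field:
truncated 12-6 Lennard-Jones (Lorentz–Berthelot combining by default,
geometric selectable; optional analytic tail correction for homogeneous
liquid boxes) plus damped shifted-force (Wolf-type) Coulomb
electrostatics, zero in value and slope at the cutoff.  DSF was chosen
over Ewald because the generator tier only needs a deterministic, $O(N)$,
smoothly truncated electrostatics model; an Ewald backend can be added
behind the same contract.  Defaults: cutoff 4.5 Å (must stay below half
the smallest box edge; NpT volume moves that would violate this are
rejected), damping 0.2 Å⁻¹, tail correction off.

Units everywhere: Å, kJ/mol, K, bar;
$R = 8.31446\times10^{-3}$ kJ mol⁻¹ K⁻¹ and
$1\,\mathrm{bar\,Å^3} = 6.02214\times10^{-5}$ kJ/mol.

## Adaptive temperature scaling

Running the inner chain at conditions different from the target improves
the overlap between the low- and high-level energy distributions and
therefore the outer acceptance rate.  The controller adjusts only the
generating temperature: after every window of 50 outer proposals with
observed acceptance $a$, if $a$ lies outside the window $(0.75, 0.90)$
then $T_g \leftarrow T_g\,[1 + \kappa\,(a - a_{\mathrm{mid}})]$ with
$\kappa = 0.5$ and $a_{\mathrm{mid}} = 0.825$, clipped to
$[0.5, 2]\times T_t$.  The controller freezes after two consecutive
in-window windows (or after a hard cap of 40 windows, recorded in the run
object).  Adaptation breaks strict stationarity while active, so the
default burn-in for production estimators discards everything before the
freeze plus 10 % of the remainder.  The generating pressure is exposed
but not adapted by default.

## Observables and uncertainties

* **Density** $\rho = \sum_i M_i / (N_A V)$, streamed per outer proposal.
* **Vaporization enthalpy**
  $\Delta_{\mathrm{vap}}H = (\langle U_{\mathrm{gas}}\rangle + RT)
  - (\langle U_{\mathrm{liq}}\rangle/N + p\langle V\rangle/N)$,
  with the vapor treated as an ideal gas in a single-molecule box and the
  $pV$ term of the gas taken as $RT$ rather than simulated.
* **Thermal expansivity** $\alpha = -(1/\rho)(\partial\rho/\partial T)_p$
  and **heat-capacity difference**
  $\Delta_{\mathrm{vap}}C_p = \mathrm{d}(\Delta_{\mathrm{vap}}H)/\mathrm{d}T$
  by central differences across independent runs on a temperature grid
  (one-sided at the ends).  Finite differences across a grid were chosen
  over fluctuation formulas, which are much noisier at 30–120 molecule
  box sizes; the stencils are exact on the polynomial families they
  integrate, and uncertainties are propagated from the per-temperature
  errors.
* **Radial distribution functions**: intermolecular-only site–site
  histograms under the minimum image, normalized with exact spherical
  shell volumes $\tfrac{4}{3}\pi(r_2^3 - r_1^3)$ so that uniform random
  placements give $g \equiv 1$; the cumulative coordination number is
  reported alongside.  Default bin width 0.05 Å.
* **Uncertainties** by Flyvbjerg–Petersen block doubling: the SEM estimate
  is tracked over successive block-size doublings and read off the
  plateau — the first block size where the estimate changes by less than
  10 % over two further doublings, else the largest block size.  The
  estimator requires at least 16 post-burn-in samples; the quick-look
  summary tables fall back to the naive $\mathrm{sd}/\sqrt{n}$ below
  that, which underestimates for correlated streams.

## The pair-interaction library

Every composite-energy breakdown yields one record per (snapshot,
proximate dimer): both interaction energies, the contact distance, the
contact class, and (when geometry recording is on) the reassembled dimer
coordinates with provenance.  Libraries are written as multi-frame
extended XYZ — human-readable, streamable, and the same dialect as the
fragment-exchange format — with coordinates at $10^{-6}$ Å and energies
at $10^{-8}$ kJ/mol, formatted canonically so a read–write cycle is
byte-stable.  Near-duplicate geometries are *not* deduplicated: thermal
ensembles legitimately contain them.  Contact-class labels subscript each
contact atom with its nearest bonded neighbor's element
(`O_H...H_O` for a hydroxyl–hydroxyl hydrogen bond); tokens are sorted so
molecule order cannot change a label, and an unbonded site gets the
subscript `.`.

## What the toy systems emulate — and what they do not

The fixture generator provides four presets: a single-site LJ fluid, a
3-site hydrogen-bonding water-like liquid, a 3-site amphiphilic
methanol-like liquid (united-atom methyl + hydroxyl, with a two-member
conformer pool standing in for a presampled monomer-geometry pool), and a
3-site non-protic ether-like liquid.  Parameters are in the TIP3P/OPLS
family so the hydrogen-bond / dispersion / repulsive contact-class
phenomenology is exercised; hydrogens carry a small LJ core
($\sigma = 1$ Å, $\varepsilon = 0.1$ kJ/mol) because under truncated DSF
electrostatics a σ-less charged site could collapse onto an oppositely
charged neighbor during Monte Carlo moves.  A preset box of 100–120
3-site molecules reaches the 300–360-atom production scale; tests use
roughly 30 molecules.

These are *surrogate* stacks: passing tests demonstrate that the sampling
machinery is exact (nested-chain stationarity, ideal-gas equation of
state, subtractive identities, estimator recovery on known ground truth)
and that the pipeline is deterministic and self-consistent.  They say
nothing about the accuracy of any particular quantum-chemical tier on
real liquids, nothing about nuclear quantum effects (excluded), and the
rigid-molecule, discrete-conformer representation cannot capture
continuous intramolecular flexibility.

## Numerical choices and degenerate inputs

* Minimum-image displacements land in $[-L/2, L/2)$ per component;
  exactly-half-edge separations map to the negative face.
* Molecules wrap by center of mass; sites may protrude past box faces.
* Site distances below 0.1 Å are treated as degenerate: energy
  evaluations raise an error, while inside the MC kernel such trials are
  rejected (with a warning on energy overflow).
* Orthorhombic boxes only; all studied systems are isotropic liquids.
* One master seed spawns per-purpose L'Ecuyer-CMRG substreams (move
  selection, move proposals, acceptance draws, outer decisions), so
  changing the nesting period does not shift unrelated draws; runs are
  bit-reproducible per seed and checkpoint/resume continues identically.
* The nesting period $P$ counts *attempted* inner moves and defaults to
  a configurable 100 attempts.
* Random sequential insertion with a closest-contact floor (default
  1.5 Å) builds initial packings; an insertion failure after the attempt
  budget reports the box as too small.

## Problem sizes used by the validation suite

The shipped tests run desk-scale versions of every check: 13-state
double-well chains with $10^5$ outer proposals for the exactness test,
30–32-molecule water-like boxes for the oracle and adaptation tests, 200
synthetic seeds for estimator-recovery coverage, and AR(1) streams of
$2^{15}$ samples for the block-error inflation check.  These sizes were
chosen so the whole suite completes in minutes on one core while leaving
each statistical assertion a comfortable margin.

## Known limitations

* The inner kernel requires the built-in force field (or the zero
  potential) as generator — arbitrary function backends would force a
  full re-evaluation per move.
* No Ewald electrostatics, polarizable models, or flexible molecules.
* `ΔvapCp` and `α` inherit finite-difference truncation error from the
  temperature grid; grids should span at least three temperatures with
  spacing small against the curvature of the underlying property.
* The external-engine adapter assumes the engine is rotation- and
  translation-invariant; cached monomer energies additionally assume
  rigidity.
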