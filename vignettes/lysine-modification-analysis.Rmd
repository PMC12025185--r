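---
title: "Structure-guided lysine modification analysis: models, parameters, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-guided lysine modification analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laccmod)
```

## The problem

Covalent modification of lysine side chains — crosslinking with
glutaraldehyde or EGNHS, acylation with citraconic anhydride,
glycosylation with oxidized polysucrose — is a standard route to
stabilizing industrial enzymes such as laccases. Success depends on
structure: a lysine can only react if its epsilon-amine is accessible to
the reagent, free of competing electrostatic locks, and deprotonated
often enough at the working pH. `laccmod` turns those three conditions
into computable filters and pairs them with the kinetics used to judge
the outcome (first-order thermal inactivation, half-lives,
stabilization ratios, degree of modification).

This vignette documents the models, every tunable parameter with its
default and rationale, the synthetic-data world the tests rely on, and
the numerical decisions a maintainer should know about.

## Solvent accessibility

SASA is computed with the Shrake–Rupley method: each atom's van der
Waals sphere is inflated by the probe radius (default **1.4 Å**, a water
molecule), `n_points` quasi-uniform quadrature points are placed on the
inflated sphere, and a point counts as accessible when it lies outside
every neighbouring inflated sphere. Atom SASA is the accessible fraction
times `4*pi*(r + probe)^2`.

Numerical choices:

- **Point set.** A deterministic golden-spiral (Fibonacci) lattice, not
  random sampling, so results are exactly reproducible for a fixed
  `n_points`. Default **960** points/atom; the minimum accepted is 92.
  On test fixtures the 960 vs 3840 difference is ~0.01% of total area,
  well inside the 0.5% convergence budget, and agreement with an
  independent implementation (biotite, identical radii) is ~0.1%.
- **Radii.** Heavy atoms only, with united radii that implicitly absorb
  hydrogens: C 1.70, N 1.55, O 1.52, S 1.80 Å. Hydrogens, waters and
  HETATM records are dropped at parse time. The table is configurable
  (`default_element_radii()`); unknown elements fall back to 1.80 Å with
  a warning so burial is never overstated silently.
- **Neighbour search.** The compiled core prunes candidate occluders
  with a cheap squared-distance bound against the maximum inflated
  radius. This is an O(N²) prefilter rather than a cell-list grid: for
  the structure sizes this package targets (a laccase monomer is a few
  thousand heavy atoms) the prefilter is far below a second of work, and
  the simpler code is easier to audit. A cell list would only pay off
  beyond ~10^5 atoms.

**Relative exposure** divides residue SASA by its theoretical maximum in
an extended Gly-X-Gly tripeptide (Tien et al. 2013 theoretical scale).
A residue is **exposed** when relative SASA ≥ **0.20**. Upstream
descriptions of this threshold disagree about direction in one place
(a figure legend marks "exposed to less than 20%" residues, prose once
says the opposite); we resolve it the only physically sensible way —
*at least* 20% of the reference area means exposed — and the threshold
is a plain parameter. Residue names outside the reference table are
reported as `unscored`, never dropped. Isolated single-residue
fragments produced by the synthetic generator score well above the
threshold but below 1.0 because the fragments carry only 3–5 heavy
atoms; a complete isolated residue exceeds its tripeptide reference.

**Surface partition** assigns C and S atom areas to the hydrophobic
side, N and O to the hydrophilic side (the POPS convention; the
assignment sets are arguments). The reported ratio is
hydrophilic/hydrophobic; an all-carbon surface therefore has ratio 0,
and a zero hydrophobic area is flagged with an infinite ratio.

## Lysine reactivity

The reactivity index is the Henderson–Hasselbalch fraction-deprotonated
ratio: `LysRe = 10^(pH - pKa)`. pKa values are *inputs* (a TSV produced
by a PROPKA-class predictor); this package does not compute them.
Classes: **low** < 0.1 ≤ **semi** ≤ 1.0 < **high**, boundaries assigned
inclusively to the middle class. The modification pH is a required
argument — each agent's protocol buffer pH is tabulated
(`default_agents()`: EGNHS 7.4, CA 9.0, GA/CDI 5.5, N-HSP 8.0, PS 8.0)
but the triage never guesses a pH when neither an agent nor a pH is
given.

## Salt bridges and crosslink spans

A salt bridge is recorded when any charged-group nitrogen (Lys NZ; Arg
NH1/NH2/NE; His ND1/NE2) is within **4.0 Å** of any carboxylate oxygen
(Asp OD1/OD2; Glu OE1/OE2) — the standard Barlow–Thornton-style
criterion. The cutoff is exposed rather than tuned: published
salt-bridge counts for these laccases depend on an unstated cutoff, so
no attempt is made to reproduce them.

Crosslinker feasibility lists, for every unordered lysine pair, the
NZ–NZ and CA–CA distances and the bifunctional agents whose span window
covers the NZ–NZ distance (defaults: glutaraldehyde 4–11 Å — polymeric
forms widen this in practice — and EGNHS 4–18 Å). CDI is zero-length
amide coupling and the monofunctional agents (CA, N-HSP, PS,
saccharides) modify single amines, so none of them participate in pair
analysis.

## Integrated triage

A lysine is a **candidate** modification site iff it is exposed and not
a member of any salt bridge. Ranking is by reactivity class (high >
semi > low), then LysRe descending, then relative SASA descending, with
a deterministic (chain, residue number) tie-break. Lysines missing from
the pKa table are kept, flagged `has_pka = FALSE`, and ranked after the
scored ones by exposure; a pKa entry for a lysine that does not exist in
the structure is an input-consistency error, not a silent skip.

## Inactivation kinetics and assay statistics

Thermal inactivation follows the first-order model `A(t) = A0 *
exp(-kd t)`. The fit is unweighted OLS of `ln A` on `t` with a free
intercept (the model as printed upstream carries a sign typo — activity
decays — so the positive inactivation constant is minus the fitted
slope). Choices:

- Zero/negative readings cannot enter a log fit; they are excluded with
  a warning and `n_used` reports the points kept. Fewer than two usable
  points is an error.
- A fitted slope within floating noise of zero (|kd| ≤ 1e-12 min⁻¹) is
  flagged `no_decay` with an infinite half-life rather than reporting a
  meaningless 10^15-minute t½.
- A nonlinear least-squares route (`method = "nonlinear"`, initialized
  from the log fit) is available for sensitivity analysis; the default
  stays log-linear because that is how the published constants were
  obtained.

Half-life is `ln(2)/kd`; the stabilization ratio is `R = kd_control /
kd_modified`, identically the t½ ratio. Published tables round kd after
computing t½, so recomputed half-lives match printed ones only to about
0.1%; the regression fixture therefore uses a 0.2% band, and R is
compared at its printed single decimal.

Degree of modification is `DM% = 100 (1 - C_s/C_c)`, clamped to
[0, 100] with a flag — published tables contain exact 0.00 entries,
consistent with clamping when a sample reads at or above its control.
DM is invariant to jointly rescaling both concentrations. Profile
optima are reported on the measured condition grid (no interpolation,
matching the 0.5-unit granularity of published optima); ties resolve
toward the condition nearest the median of the grid, then the lower
label. Residual activity rescales an inhibitor series to percent of a
reference condition (typically 0 mM), which must exist and be positive.

## The synthetic world

The generator builds *stated geometry*, not folded proteins: each
residue is an ideal fragment (backbone CA plus the named charged
side-chain atoms, e.g. CA/CB/NZ for lysine) placed so that its key atom
sits exactly at the requested coordinate. Decoy shells — golden-spiral
cages of carbon atoms (default use: 80 atoms at 6 Å) — bury a chosen
residue below the exposure threshold. This gives exact ground truth for
burial, bridge distances and NZ–NZ spans, which the analysis modules
must reproduce; it deliberately does not emulate realistic packing
densities, rotamers or backbone connectivity. A green geometric test
therefore establishes operator correctness, not predictive accuracy on
real structures.

Decay series use multiplicative Gaussian noise, `A(t) = A0 exp(-kd t)
(1 + e)` with `e ~ N(0, sigma)`, reflecting percent-scale activity
assays; negative draws truncate at zero. Default simulated designs use
the published control constants (e.g. kd = 31.55e-4 min⁻¹) and sampling
grids inside the reported 5 min–24 h windows, with sigma = 5% for the
recovery studies. All generators take explicit seeds, restore the
global RNG state, and are byte-reproducible.

The shipped pKa fixture deserves a note: only three of the fourteen
bacterial-laccase lysine pKa values are public (8.92 for the one
down-shifted residue, and the 10.05/11.44 extremes of the rest). The
fixture file is explicitly labelled synthetic, pins the three published
values, and spreads placeholders uniformly inside the published range —
every conclusion drawn from it (exactly one lysine above the low class
at pH 9) is insensitive to the placeholder positions.

## Known limitations

- Printed whole-protein areas (e.g. a hydrophobic SASA of 16,789.74 Å²)
  are not reproducible here because the predicted models they were
  measured on are not deposited; the SASA engine is instead validated
  against closed forms, a brute-force oracle and an independent
  implementation.
- pKa prediction, structure prediction, sequence alignment and
  copper-center annotation are out of scope; their outputs are inputs.
- The salt-bridge and exposure criteria are single-cutoff geometric
  rules; they do not model microenvironment electrostatics or hydrogen
  bonding, which are known to modulate lysine reactivity beyond what
  LysRe captures.
- Upstream counts for the fungal enzyme (eleven lysines, seven
  bridged, yet five named candidates) do not reconcile; no test is
  built on them.
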