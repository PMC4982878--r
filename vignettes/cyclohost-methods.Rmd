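---
title: "Quantifying anhydrous cyclodextrin host-guest complexation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying anhydrous cyclodextrin host-guest complexation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclohost)
```

## The problem

beta-cyclodextrin (beta-CD) is a cyclic oligosaccharide of seven
glucopyranose units whose cone-shaped hydrophobic cavity can enclose small
organic guests. In aqueous solution the cavity competes with water and
complexation ratios stay modest; in an *anhydrous* melt — guest compounds
heated above their melting point in the presence of dehydrated beta-CD —
the full cavity volume is available and complexes with more than one guest
per host (N:1 complexes, N up to 4) become accessible.

Three experimental and computational probes are used to quantify this
regime, and `cyclohost` implements the computation behind each:

1. **Calorimetry (DSC).** A two-run protocol: the first heating run melts
   the guest and lets complexation proceed; in the second run only guest
   molecules *not* locked in a cavity melt. The deficit of the second-run
   molar melting heat relative to the pure-guest fusion enthalpy measures
   the complexed fraction, hence the complexation ratio alpha (guest moles
   per host mole) and the reaction yield for an assumed stoichiometry.
2. **IR spectroscopy.** Aromatic C-H stretching bands (2500-3200 cm^-1)
   are attenuated when the aromatic ring sits inside the cavity; the
   integrated band-attenuation ratio is a proxy for the complexation
   yield.
3. **Simulation-style trajectory analysis.** From configurations of a
   host/guest melt, the radial distribution function (RDF) of guest
   centres of mass around host centres of mass is integrated to inclusion
   numbers: alpha_min, the mean guest count within the cavity radius
   (4 Angstrom), and alpha_max, within the cavity extended by 3 Angstrom
   (7 Angstrom) to capture guests stacked at the rim. Complexes are
   classified internal/external per host. Stacked aromatic dimers —
   the building block of 2:1 complexes — are described by interplanar
   separation, long-axis twist, in-plane shifts and an RMSD from a
   perfectly eclipsed stack.

The package does **not** run molecular dynamics or quantum chemistry; it
analyses configurations, thermograms, spectra and component-energy tables,
and ships generators that produce all of these with known ground truth.

## The RDF and inclusion numbers

For shells of thickness $\delta r$ at distance $r$ from a host centre of
mass,

$$ g(r) = \frac{N(r)}{4\pi r^2 \rho\, \delta r}, $$

where $N(r)$ is the mean number of guest centres of mass per host per
frame in the shell, and $\rho$ a number density. Distances use the
minimum-image convention in orthorhombic periodic boxes.

Two density conventions are exposed because the normalising density of a
host-centred RDF is a convention, not a physical observable:

* `box_density` (default): $\rho = N_\mathrm{guest}/V_\mathrm{box}$. An
  uncorrelated (ideal-gas) system then gives $g = 1$, which is what makes
  the normalisation testable.
* `paper_sphere`: $\rho = N_\mathrm{guest} / \tfrac{4}{3}\pi r_{\max}^3$,
  a sphere-volume density that rescales $g$ by a constant.

The choice is irrelevant for inclusion numbers, which integrate the *raw*
shell counts:

$$ \alpha(r) = \sum_{\text{shells} < r} N(r') \;+\; \text{linear fraction
of the straddling shell}. $$

With $\delta r = 0.1$ Angstrom (default) the straddling-shell
interpolation error is bounded by one shell's count.

**Pair counting vs. occupancy.** `compute_rdf()` supports two assignment
modes. `all_pairs` counts every host-guest pair in a shell — the textbook
double-loop definition, and the one the brute-force test oracle checks.
`nearest_host` bins each guest once, at its distance to its nearest host,
so integrated counts cannot exceed guests/hosts even when host shells
overlap. `inclusion_numbers()` and `classify_complexes()` use
`nearest_host`: an occupancy must not double-count a guest sitting between
two hosts. On the synthetic systems, whose host lattice keeps 7-Angstrom
shells disjoint, the two modes agree exactly.

Defaults: `dr = 0.1` Angstrom, `r_max = 15` Angstrom (covers both cutoffs
with margin; must stay below half the box edge), cavity radius 4 Angstrom,
extension 3 Angstrom. The host *centre of mass* is the reference point —
for beta-CD it lies inside the cavity, so small host-guest COM distances
do mean inclusion.

## Stacking descriptors

A body-fixed frame is built on monomer A from the mass-weighted gyration
tensor: plane normal ("z") from the smallest eigenvalue, long axis ("x")
from the largest, short axis ("y") completing a right-handed frame. The
gyration tensor is preferred over the inertia tensor because, for planar
aromatics, both give the same plane and long axis while the gyration form
is directly checkable by an explicit second-moment sum. Monomer B is then
measured in A's frame:

* separation: $|(\mathrm{COM}_B-\mathrm{COM}_A)\cdot \hat n_A|$ (a
  symmetrised variant averaging both monomer normals is available);
* twist: angle between the long axes projected into A's plane, folded to
  [0, 90] degrees because long axes are headless lines;
* shift_x, shift_y: magnitudes of the in-plane COM offset. Magnitudes,
  not signed components — the deterministic axis-sign convention
  (largest-magnitude component positive) makes signs arbitrary, and
  magnitudes are what is invariant under rigid motion of the dimer;
* stack RMSD: monomer B against an eclipsed copy of A translated by the
  measured separation toward B, with *no rotational re-fit* — a re-fit
  would remove exactly the distortion (twist, slide) being measured.

Benzene-like monomers with two equal in-plane gyration eigenvalues
(within 1e-6 relative) set a `degenerate` flag; their twist is undefined
and reported as `NA`.

## DSC pipeline

`integrate_peak()` computes $\Delta h = 60\int (q - b)\,dT / \beta$ (J/g,
with $q$ in W/g, $\beta$ in degrees C per minute), trapezoidally, with a
linear baseline across the window. By default the baseline anchors on the
two raw window endpoints; `baseline_margin` instead averages the signal
over flat segments of that width just inside each edge and anchors the
line there, which is the standard way to make the baseline robust to
instrument noise when the window brackets the peak by several widths.
`dsc_complexation()` uses a 3-degree margin by default. Onset is the
intersection of the baseline with the steepest-ascent tangent of the
leading edge; the peak temperature is the maximum of the net signal.

The complexed fraction is the melting deficit
$f = (\Delta H_\mathrm{pure} - q_\mathrm{mix})/\Delta H_\mathrm{pure}$
with both heats per mole of **total** guest in the sample — the only
normalisation consistent with mixtures holding a deliberate molar excess
of guest. The complexation ratio is

$$ \alpha = f \cdot
\frac{w_\mathrm{guest}/M_\mathrm{guest}}{w_\mathrm{host}/M_\mathrm{host}},
$$

i.e. the fraction of guest excluded from melting times the mixture's
guest:host molar ratio; for 50% w/w samples this is
$f\,M_\mathrm{host}/M_\mathrm{guest}$. The proportionality constant is
reconstructed from the requirement that alpha carry units of guest moles
per host mole; alpha can never exceed the molar-ratio ceiling (asserted).
The yield under an assumed N:1 stoichiometry is $100\,\alpha/N$ percent.
A mixture melting peak shifted by more than 5 degrees C (configurable)
flags the result: a host dissolving in the guest melt (the
salicylic-acid regime, a 45-degree shift) biases the proportionality.

$f$ is clipped to [0, 1]; clipping by more than 1% warns. Negative net
peak areas warn and return the signed value.

## IR attenuation and energy bookkeeping

`band_attenuation()` is $1 - A_\mathrm{mix}/A_\mathrm{pure}$ on the
trapezoidal band area (default 2500-3200 cm^-1), not on per-peak heights:
area is robust to small peak shifts, and the attenuation of interest is a
property of the whole aromatic C-H window. Both spectra must be on the
same guest-mass basis; this is the caller's contract because scaling
metadata is not carried in the spectra. The ratio is scale-invariant by
construction.

Interaction energies are bookkeeping over user-supplied component
energies, $\Delta E_\mathrm{int} = E_\mathrm{complex} - E_\mathrm{host} -
E_\mathrm{guest\ aggregate}$, and `incremental_stabilization()` differences
a sorted N-series to per-step gains (the first gain is the N = 1 energy
itself). No quantum-chemistry output parsing is attempted — that keeps the
module honest about what this package computes.

## The synthetic generators

The generators define the study conditions; they are not tuning knobs.

* **Melt boxes** default to 100 hosts and 900 guests — a melt with a
  ninefold guest excess — in an 80-Angstrom periodic cube (host lattice
  spacing 16 Angstrom keeps the 7-Angstrom shells of neighbouring hosts
  disjoint), with metadata at 137 degrees C and 1 atm. A fraction
  `f_inside` of guests is placed uniformly inside a random host's
  4-Angstrom cavity sphere (hosts drawn with replacement: multiple
  occupancy is the phenomenon of interest), the rest uniformly at least
  8 Angstrom from every host, or in a prescribed annulus. Per-frame rigid
  Gaussian jitter (0.05 Angstrom) stands in for thermal motion;
  `independent_frames = TRUE` instead redraws placements each frame,
  giving the uncorrelated snapshots that normalisation checks assume.
  No forces, thermostats or barostats are simulated — the analysis
  operators only see configurations — so these boxes probe the
  *estimators*, not liquid-state physics: passing recovery tests shows
  the pipeline reads back what was placed, not that a real melt behaves
  this way.
* **Dimers** are built from idealized planar templates (fused 1.40-
  Angstrom hexagons; a planarized force-field dibenzofuran-like geometry)
  by rotating a copy about the plane normal and offsetting it in the
  template's own principal-axes frame, which is what makes the
  descriptor round-trip exact by construction.
* **Thermogram pairs** are Gaussian endotherms on a 0.02-degree grid:
  the pure curve with area `dH_fus` per gram of guest, the mixture curve
  with area $w_\mathrm{guest}\,\Delta H_\mathrm{fus}(1-f)$ per gram of
  sample, shifted by -2.5 degrees C by default (the small melting-point
  depression expected when a little host dissolves in the melt), plus an
  optional premelting peak. Noise is scaled to each curve's own ideal
  peak height, an instrument-like relative noise floor.

All generators are pure functions of their configuration and seed, and
return ground-truth tables sufficient for every recovery test.

## Numerical choices and degenerate inputs

* Coordinates are Angstrom and masses amu throughout; no unit detection.
* Orthorhombic boxes only; triclinic lattices are rejected explicitly.
* Molecules are never unwrapped across the periodic boundary; the
  generators guarantee whole molecules (documented contract of the
  trajectory model).
* Axis sign conventions are fixed deterministically (largest-magnitude
  component positive) so repeated runs give identical reports.
* Collinear point sets fail the plane fit with a degeneracy error;
  benzene-like axis degeneracy is flagged rather than silently resolved.
* `cumulative_count` uses linear interpolation in the straddling shell;
  tests allow exactly one shell's count of slack against direct pair
  counting.
* Empty coordinate sets, non-positive masses, non-increasing temperature
  or wavenumber grids, and windows outside the data are all rejected with
  named errors.

## Problem sizes

The test suite and the reproduction script run melt recoveries at the
full 100-host/900-guest composition with 50 frames, ideal-gas
normalisation checks at 5 hosts / 150 guests over 200 independent frames,
100-seed DSC noise sweeps, and 100 random rigid motions for descriptor
invariance — sizes chosen so the whole suite completes in well under a
minute on a laptop while keeping Monte-Carlo bands tight.

## Known limitations

* The synthetic melts have no host-host or guest-guest structure beyond
  the lattice and the exclusion rule, no orientational correlations, and
  no dynamics; results on them validate the estimators only.
* alpha from DSC assumes complexed guests are fully excluded from
  melting and free guests melt with the pure-compound enthalpy;
  premelting transitions must be excluded by the user's window choice
  (no automatic peak segmentation).
* The IR attenuation-to-yield mapping is reported raw: no quantitative
  calibration is attempted.
* Inclusion numbers average over all hosts, occupied or not, matching
  the per-host definition of alpha.
* PDB support covers MODEL/ENDMDL blocks and orthorhombic CRYST1 cells;
  binary trajectory formats are out of scope.
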