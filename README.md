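# cyclohost

Analysis toolkit for **β-cyclodextrin host–guest inclusion complexation in
anhydrous melts** — for researchers quantifying how many guest molecules a
cyclodextrin cavity holds when complexation is run above the guest's
melting point, where multiple (N:1, N up to 4) inclusion becomes possible.

The package implements, as tested library code plus a small analysis
workflow, the three quantitative probes of this regime:

* **Trajectory analysis.** The host-centred centre-of-mass radial
  distribution function

  *g*(*r*) = *N*(*r*) / (4π*r*²ρδ*r*),

  with minimum-image distances in periodic boxes, its cumulative integral,
  and the inclusion numbers α_min (mean guests per host within the
  4 Å cavity radius) and α_max (within 7 Å, the cavity extended by 3 Å),
  plus per-host internal/external/free complex classification.
* **π-stacking geometry.** Descriptors of stacked aromatic dimers — the
  building block of 2:1 complexes: interplanar separation, long-axis twist
  (folded to [0°, 90°]), in-plane shifts, and RMSD from a perfectly
  eclipsed stack (no rotational re-fit, so the distortion itself is
  measured).
* **Calorimetry and spectra.** DSC melting-peak integration for the
  two-run protocol, giving the complexed fraction
  *f* = (ΔH_pure − q_mix)/ΔH_pure, the complexation ratio
  α = *f* · (w_g/M_g)/(w_h/M_h) (guest moles per host mole), and the
  stoichiometric yield 100·α/N; IR band-attenuation ratios over the
  aromatic C–H window (2500–3200 cm⁻¹); and interaction-energy
  bookkeeping ΔE_int = E_complex − E_host − E_guests with per-step
  stabilization gains along an N-series.

Every input the pipeline consumes (multi-frame XYZ / multi-model PDB
trajectories with a molecule topology, thermogram and spectrum CSVs,
component-energy tables) can also be *generated* with known ground truth
by the `gen_*` functions, so all estimators are validated by parameter
recovery.

## Worked example

Place 30% of 900 guests inside the cavities of 100 hosts in a periodic
80 Å box, then read the occupancy back from the configurations alone:

```r
library(cyclohost)

sys <- gen_inclusion_trajectory(n_host = 100, n_guest = 900,
                                f_inside = 0.3, n_frames = 25, seed = 20260954)
rep <- inclusion_numbers(sys$trajectory)   # 4 A cavity, +3 A extension
rep
#> <inclusion_report> alpha_min (r = 4 A) = 2.6468, alpha_max (r = 7 A) = 2.7000
```

With 270 of 900 guests placed inside, the expected occupancy is
270/100 = 2.70 guests per host: α_max recovers it exactly, and α_min sits
just below because thermal jitter pushes a few boundary guests past the
4 Å cutoff.

A DSC pair built with a 20% complexed fraction, analysed with the
anthracene-like guest (M = 178.2 g/mol) against the β-CD host
(M = 1135 g/mol) at 50% w/w:

```r
tp <- gen_thermogram_pair(dH_fus = 162, T_m = 216, f_complexed = 0.20,
                          noise_sigma = 0.02, seed = 20260944)
res <- dsc_complexation(tp$pure, tp$mix, tp$truth$window_pure,
                        tp$truth$window_mix,
                        mixture_spec(w_guest = 0.5, M_guest = 178.2))
res
#> <complexation_result> dH_pure = 6.937 kcal/mol, q_mix = 5.549 kcal/mol
#>   f_complexed = 0.200, alpha = 1.274 guests/host, yield(2:1) = 63.7%
```

The melting deficit recovers the constructed fraction, and a measured
complexation ratio converts to a stoichiometric yield: α = 1.19 under an
assumed 2:1 complex gives `yield_from_alpha(1.19, 2)$percent_int` = 60%,
and α = 0.66 gives 33%.

The numbered scripts under `analysis/` run the full workflow (simulate →
RDF/occupancy → stacking → DSC → spectra/energies), printing what each
stage found and writing tables under `results/`.

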