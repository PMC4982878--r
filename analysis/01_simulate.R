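#!/usr/bin/env Rscript
# Generate every synthetic input the downstream analyses consume:
# host-guest melt trajectories at several inside fractions, stacked
# aromatic dimers at the geometries of interest, DSC thermogram pairs and
# an IR spectrum pair. Bulky coordinate files go to scratch/sim/ (they are
# regenerated on demand); small truth tables go to results/.

suppressMessages(library(cyclohost))
seed <- 20260924
dir.create("scratch/sim", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

## melt-scale inclusion systems: 100 hosts, 900 guests, 25 frames
truth_rows <- list()
for (f in c(0, 0.1, 0.3, 0.6)) {
  sys <- gen_inclusion_trajectory(n_host = 100, n_guest = 900, f_inside = f,
                                  n_frames = 25, seed = seed + round(100 * f))
  tag <- sprintf("f%02d", round(100 * f))
  write_xyz_trajectory(sys$trajectory, sprintf("scratch/sim/melt_%s.xyz", tag))
  utils::write.csv(
    data.frame(molecule_id = sys$trajectory$topology$molecule_id,
               role = sys$trajectory$topology$role,
               first_atom = vapply(sys$trajectory$topology$atom_indices,
                                   min, 1L),
               last_atom = vapply(sys$trajectory$topology$atom_indices,
                                  max, 1L)),
    sprintf("scratch/sim/melt_%s_topology.csv", tag), row.names = FALSE)
  truth_rows[[tag]] <- data.frame(system = tag, f_inside = f,
                                  n_placed_inside = sum(sys$truth$placement ==
                                                          "inside"))
  cat(sprintf("melt %s: %d guests placed inside cavities\n", tag,
              sum(sys$truth$placement == "inside")))
}
write_report(do.call(rbind, truth_rows), "results/simulated_truth.tsv",
             seed = seed)

## stacked dimers at the geometries under study
dimers <- list(
  naphthalene_isolated = list("naphthalene", 3.3, 9.6, 1.4, 1.5),
  anthracene_in_cavity = list("anthracene", 3.0, 28.6, 2.9, 1.6),
  dibenzofuran_stack   = list("dibenzofuran", 3.3, 15.0, 0.5, 0.2))
for (nm in names(dimers)) {
  d <- dimers[[nm]]
  dim <- gen_stacked_dimer(d[[1]], d[[2]], d[[3]], d[[4]], d[[5]])
  n <- nrow(dim$monA)
  both <- trajectory(list(rbind(dim$monA, dim$monB)),
                     rep(dim$elements, 2),
                     rep(dim$masses, 2),
                     topology(1:2, c("other", "other"),
                              list(1:n, n + 1:n), 2 * n))
  write_xyz_trajectory(both, sprintf("scratch/sim/dimer_%s.xyz", nm))
  cat(sprintf("dimer %s: %s, d=%.1f A, twist=%.1f deg\n",
              nm, d[[1]], d[[2]], d[[3]]))
}

## DSC thermogram pairs (anthracene-like guest) and an IR pair
for (f in c(0.2, 0.6, 0.95)) {
  tp <- gen_thermogram_pair(dH_fus = 162, T_m = 216, f_complexed = f,
                            noise_sigma = 0.02, seed = seed + round(100 * f))
  tag <- sprintf("f%02d", round(100 * f))
  write_thermogram_csv(tp$pure, sprintf("scratch/sim/dsc_pure_%s.csv", tag))
  write_thermogram_csv(tp$mix, sprintf("scratch/sim/dsc_mix_%s.csv", tag))
}
sp <- gen_ir_pair(0.85, noise_sigma = 0.002, seed = seed + 9)
utils::write.csv(data.frame(wavenumber_cm1 = sp$pure$wavenumber,
                            absorbance = sp$pure$absorbance),
                 "scratch/sim/ir_pure.csv", row.names = FALSE)
utils::write.csv(data.frame(wavenumber_cm1 = sp$mix$wavenumber,
                            absorbance = sp$mix$absorbance),
                 "scratch/sim/ir_mix.csv", row.names = FALSE)
cat("thermogram pairs (f = 0.2, 0.6, 0.95) and IR pair (attenuation 0.85) written\n")
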