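# Synthetic-data generators: every input the pipeline consumes, with known
# ground truth. No physical dynamics are simulated — jittered static
# placements emulate an equilibrated NpT box, because the analysis
# operators only see configurations, not forces.

# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# ---- planar aromatic templates -------------------------------------------

# idealized fused-hexagon lattices, bond length 1.40 A, C-H 1.08 A, all in
# the z = 0 plane with the long axis along x
.template_benzene <- function() {
  ang <- seq(0, 300, by = 60) * pi / 180
  C <- cbind(1.397 * cos(ang), 1.397 * sin(ang))
  H <- cbind(2.477 * cos(ang), 2.477 * sin(ang))
  list(elements = c(rep("C", 6), rep("H", 6)), xy = rbind(C, H))
}

.template_naphthalene <- function() {
  C <- rbind(
    c(0,  0.70), c(0, -0.70),
    c( 1.2124,  1.40), c( 2.4249,  0.70), c( 2.4249, -0.70), c( 1.2124, -1.40),
    c(-1.2124,  1.40), c(-2.4249,  0.70), c(-2.4249, -0.70), c(-1.2124, -1.40))
  centers <- rbind(c(1.2124, 0), c(-1.2124, 0))
  ch <- 3:10  # carbons bearing H (all but the two shared)
  H <- t(vapply(ch, function(i) {
    ctr <- centers[if (C[i, 1] > 0) 1 else 2, ]
    C[i, ] + (C[i, ] - ctr) / 1.40 * 1.08
  }, numeric(2)))
  list(elements = c(rep("C", 10), rep("H", 8)), xy = rbind(C, H))
}

.template_anthracene <- function() {
  C <- rbind(
    c(0,  1.40), c(0, -1.40),
    c( 1.2124,  0.70), c( 1.2124, -0.70),
    c(-1.2124,  0.70), c(-1.2124, -0.70),
    c( 2.4249,  1.40), c( 2.4249, -1.40),
    c(-2.4249,  1.40), c(-2.4249, -1.40),
    c( 3.6373,  0.70), c( 3.6373, -0.70),
    c(-3.6373,  0.70), c(-3.6373, -0.70))
  centers <- rbind(c(0, 0), c(2.4249, 0), c(-2.4249, 0))
  ch <- c(1, 2, 7:14)
  H <- t(vapply(ch, function(i) {
    ctr <- centers[which.min((centers[, 1] - C[i, 1])^2), ]
    C[i, ] + (C[i, ] - ctr) / 1.40 * 1.08
  }, numeric(2)))
  list(elements = c(rep("C", 14), rep("H", 10)), xy = rbind(C, H))
}

# planarized MMFF-optimized dibenzofuran geometry (synthetic template)
.template_dibenzofuran <- function() {
  m <- matrix(c(
    -3.4030, -0.4050, -3.0628, 0.9502, -1.7209, 1.3582, -0.7128, 0.3754,
    -1.0940, -0.9625, -2.4177, -1.3977, 0.0000, -1.7728, 1.0940, -0.9625,
    2.4177, -1.3977, 3.4030, -0.4050, 3.0628, 0.9502, 1.7209, 1.3582,
    0.7128, 0.3754, -4.4517, -0.6951, -3.8498, 1.7015, -1.4678, 2.4140,
    -2.6632, -2.4526, 2.6632, -2.4526, 4.4517, -0.6951, 3.8498, 1.7015,
    1.4679, 2.4140), ncol = 2, byrow = TRUE)
  list(elements = c(rep("C", 6), "O", rep("C", 6), rep("H", 8)), xy = m)
}

#' Planar aromatic monomer templates
#'
#' Idealized planar geometries (z = 0 plane, long axis along x) used by the
#' dimer generator and as COM/axes test molecules.
#'
#' @param name one of "benzene", "naphthalene", "anthracene",
#'   "dibenzofuran" (a planarized dibenzofuran-like geometry).
#' @return list: `coords` (n x 3 matrix, Angstrom), `elements`, `masses`.
#' @export
monomer_template <- function(name = c("benzene", "naphthalene",
                                      "anthracene", "dibenzofuran")) {
  name <- match.arg(name)
  t2 <- switch(name,
    benzene = .template_benzene(),
    naphthalene = .template_naphthalene(),
    anthracene = .template_anthracene(),
    dibenzofuran = .template_dibenzofuran())
  coords <- cbind(t2$xy, 0)
  list(coords = coords, elements = t2$elements,
       masses = element_mass(t2$elements))
}

# ---- inclusion-system trajectories ---------------------------------------

.unit_sphere <- function(n) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

#' Generate a host-guest inclusion trajectory with known ground truth
#'
#' Emulates an equilibrated melt of host macrocycles and small-molecule
#' guests: hosts on a jittered cubic lattice in a periodic box, a
#' prescribed fraction `f_inside` of guests placed uniformly within
#' `r_cavity` of a randomly chosen host (with replacement — multiply
#' occupied hosts are the point of the anhydrous regime), and the rest
#' either far from every host (beyond `r_exclude`) or, when `r_annulus` is
#' given, in a spherical shell around a random host. Per-frame rigid
#' Gaussian jitter stands in for thermal motion.
#'
#' @param n_host,n_guest molecule counts (defaults 100 and 900, the melt
#'   composition the analysis is sized for).
#' @param box_length cubic box edge (Angstrom).
#' @param f_inside fraction of guests placed inside a cavity.
#' @param r_cavity cavity radius used for inside placement (Angstrom).
#' @param r_annulus optional `c(lo, hi)` (Angstrom): place all non-inside
#'   guests in this shell around a random host instead of far away.
#' @param r_exclude minimum distance of far-placed guests from every host
#'   (Angstrom).
#' @param jitter_sigma per-frame rigid jitter s.d. per coordinate
#'   (Angstrom).
#' @param n_frames number of frames.
#' @param independent_frames if TRUE, guest placements are redrawn
#'   independently every frame (uncorrelated equilibrium snapshots, the
#'   regime RDF normalization checks assume); if FALSE (default), one
#'   placement is jittered per frame and the truth table describes every
#'   frame. With independent frames the truth table describes frame 1
#'   only.
#' @param host_style "point" (single pseudo-atom of the full host mass) or
#'   "ring7" (seven beads on a ring, exercising multi-atom COMs).
#' @param host_mass,guest_mass molecular masses (amu).
#' @param temperature_C,pressure_atm thermodynamic metadata carried into
#'   the config (not used by the placement).
#' @param seed RNG seed; identical seeds give identical trajectories.
#' @return list of class `inclusion_system`: `trajectory`, `truth` (one row
#'   per guest: intended placement and assigned host), `config`.
#' @export
gen_inclusion_trajectory <- function(n_host = 100, n_guest = 900,
                                     box_length = 80, f_inside = 0,
                                     r_cavity = 4, r_annulus = NULL,
                                     r_exclude = 8, jitter_sigma = 0.05,
                                     n_frames = 1, independent_frames = FALSE,
                                     host_style = c("point", "ring7"),
                                     host_mass = 1135, guest_mass = 178.2,
                                     temperature_C = 137, pressure_atm = 1,
                                     seed = NULL) {
  host_style <- match.arg(host_style)
  stopifnot(f_inside >= 0, f_inside <= 1, n_frames >= 1)
  m <- ceiling(n_host^(1 / 3))
  spacing <- box_length / m
  if (spacing < 2 * (r_cavity + 3)) {
    stop("box too small: host lattice spacing ", signif(spacing, 4),
         " A cannot keep ", r_cavity + 3, " A host shells disjoint")
  }
  .with_seed(seed, {
    # hosts: first n_host sites of an m^3 lattice, jittered
    grid <- as.matrix(expand.grid(seq_len(m), seq_len(m), seq_len(m)))
    hosts <- (grid[seq_len(n_host), , drop = FALSE] - 0.5) * spacing
    hosts <- hosts + matrix(stats::rnorm(3 * n_host, sd = 0.4), ncol = 3)

    n_in <- floor(f_inside * n_guest)
    place_guests <- function() {
      truth <- data.frame(guest_id = seq_len(n_guest),
                          placement = rep("far", n_guest),
                          host = NA_integer_, stringsAsFactors = FALSE)
      guests <- matrix(NA_real_, n_guest, 3)
      if (n_in > 0) {
        owner <- sample.int(n_host, n_in, replace = TRUE)
        r <- r_cavity * stats::runif(n_in)^(1 / 3)
        guests[seq_len(n_in), ] <- hosts[owner, , drop = FALSE] +
          .unit_sphere(n_in) * r
        truth$placement[seq_len(n_in)] <- "inside"
        truth$host[seq_len(n_in)] <- owner
      }
      n_out <- n_guest - n_in
      if (n_out > 0) {
        out_rows <- n_in + seq_len(n_out)
        if (!is.null(r_annulus)) {
          stopifnot(length(r_annulus) == 2L, r_annulus[1] < r_annulus[2])
          owner <- sample.int(n_host, n_out, replace = TRUE)
          r <- (r_annulus[1]^3 +
                  stats::runif(n_out) *
                    (r_annulus[2]^3 - r_annulus[1]^3))^(1 / 3)
          guests[out_rows, ] <- hosts[owner, , drop = FALSE] +
            .unit_sphere(n_out) * r
          truth$placement[out_rows] <- "annulus"
          truth$host[out_rows] <- owner
        } else {
          for (i in out_rows) {
            ok <- FALSE
            for (try in 1:1000) {
              p <- stats::runif(3, 0, box_length)
              d <- .pair_dist(rbind(p), hosts, box_spec(rep(box_length, 3)))
              if (min(d) >= r_exclude) { ok <- TRUE; break }
            }
            if (!ok) {
              stop("overcrowded box: could not place guest ", i,
                   " beyond ", r_exclude, " A of all hosts after 1000 tries")
            }
            guests[i, ] <- p
          }
        }
      }
      list(guests = guests, truth = truth)
    }

    placed <- place_guests()
    guests <- placed$guests
    truth <- placed$truth

    # atom layout: hosts first, then guests
    if (host_style == "point") {
      host_atoms <- lapply(seq_len(n_host), function(i) hosts[i, , drop = FALSE])
      host_el <- rep("X", n_host)
      host_masses <- rep(host_mass, n_host)
      atoms_per_host <- 1L
    } else {
      ang <- seq(0, 2 * pi, length.out = 8)[1:7]
      ring0 <- cbind(3.0 * cos(ang), 3.0 * sin(ang), 0)
      host_atoms <- lapply(seq_len(n_host), function(i) {
        R <- .random_rotation()
        sweep(ring0 %*% t(R), 2, hosts[i, ], "+")
      })
      host_el <- rep("X", 7L * n_host)
      host_masses <- rep(host_mass / 7, 7L * n_host)
      atoms_per_host <- 7L
    }
    base <- rbind(do.call(rbind, host_atoms), guests)
    elements <- c(host_el, rep("X", n_guest))
    masses <- c(host_masses, rep(guest_mass, n_guest))

    host_idx <- split(seq_len(atoms_per_host * n_host),
                      rep(seq_len(n_host), each = atoms_per_host))
    guest_idx <- as.list(as.integer(atoms_per_host * n_host) + seq_len(n_guest))
    top <- topology(seq_len(n_host + n_guest),
                    c(rep("host", n_host), rep("guest", n_guest)),
                    c(unname(host_idx), guest_idx), nrow(base))

    mol_of_atom <- rep(seq_len(n_host + n_guest),
                       c(rep(atoms_per_host, n_host), rep(1L, n_guest)))
    guest_rows <- atoms_per_host * n_host + seq_len(n_guest)
    coords <- lapply(seq_len(n_frames), function(f) {
      fr <- base
      if (independent_frames && f > 1L) {
        fr[guest_rows, ] <- place_guests()$guests
      }
      shift <- matrix(stats::rnorm(3 * (n_host + n_guest), sd = jitter_sigma),
                      ncol = 3)
      fr + shift[mol_of_atom, , drop = FALSE]
    })
    traj <- trajectory(coords, elements, masses, top,
                       box_spec(rep(box_length, 3)))
    structure(list(trajectory = traj, truth = truth,
                   config = list(n_host = n_host, n_guest = n_guest,
                                 box_length = box_length, f_inside = f_inside,
                                 r_cavity = r_cavity, r_annulus = r_annulus,
                                 r_exclude = r_exclude,
                                 jitter_sigma = jitter_sigma,
                                 n_frames = n_frames, host_style = host_style,
                                 temperature_C = temperature_C,
                                 pressure_atm = pressure_atm, seed = seed)),
              class = "inclusion_system")
  })
}

.random_rotation <- function() {
  # QR of a Gaussian matrix, determinant fixed to +1
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Random proper rotation matrix
#' @param seed optional RNG seed.
#' @return 3 x 3 rotation matrix (det +1).
#' @export
random_rotation <- function(seed = NULL) .with_seed(seed, .random_rotation())

# ---- stacked dimers -------------------------------------------------------

#' Generate a stacked aromatic dimer with prescribed geometry
#'
#' Monomer B is monomer A rotated by `twist` degrees about A's plane
#' normal (through A's COM), translated by `shift_x`, `shift_y`,
#' `separation` along A's long axis, short axis and normal, then given
#' isotropic Gaussian coordinate noise. The frame is A's own
#' [principal_axes()] frame, so [stack_descriptors()] round-trips the
#' parameters exactly in the noise-free case.
#'
#' @param template template name for [monomer_template()].
#' @param separation interplanar separation (Angstrom).
#' @param twist long-axis twist (degrees).
#' @param shift_x,shift_y in-plane COM shifts (Angstrom, non-negative).
#' @param noise_sigma isotropic coordinate noise s.d. on monomer B
#'   (Angstrom).
#' @param seed RNG seed.
#' @return list: `monA`, `monB` (n x 3), `masses`, `elements`, `truth`.
#' @export
gen_stacked_dimer <- function(template = "naphthalene", separation = 3.3,
                              twist = 0, shift_x = 0, shift_y = 0,
                              noise_sigma = 0, seed = NULL) {
  tpl <- monomer_template(template)
  ax <- principal_axes(tpl$coords, tpl$masses)
  th <- twist * pi / 180
  n <- ax$normal
  # Rodrigues rotation about the plane normal
  K <- matrix(c(0, n[3], -n[2], -n[3], 0, n[1], n[2], -n[1], 0), 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  X <- sweep(tpl$coords, 2, ax$origin)
  monB <- sweep(X %*% t(R), 2, ax$origin, "+")
  offset <- shift_x * ax$long_axis + shift_y * ax$short_axis + separation * n
  monB <- sweep(monB, 2, offset, "+")
  .with_seed(seed, {
    if (noise_sigma > 0) {
      monB <- monB + matrix(stats::rnorm(length(monB), sd = noise_sigma),
                            ncol = 3)
    }
    list(monA = tpl$coords, monB = monB, masses = tpl$masses,
         elements = tpl$elements,
         truth = list(template = template, separation = separation,
                      twist = twist, shift_x = shift_x, shift_y = shift_y,
                      noise_sigma = noise_sigma))
  })
}

# ---- thermograms ----------------------------------------------------------

#' Generate a pure / mixture DSC thermogram pair with known truth
#'
#' The pure curve carries a Gaussian melting endotherm of specific
#' enthalpy `dH_fus` (per gram of guest); the mixture curve (per gram of
#' sample, guest mass fraction `w_guest`) carries the free-guest peak of
#' area `w_guest * dH_fus * (1 - f_complexed)`, shifted by `mix_T_shift`,
#' plus an optional premelting peak. Additive Gaussian noise is scaled to
#' each curve's own ideal peak height.
#'
#' @param dH_fus pure-guest fusion enthalpy (J/g).
#' @param T_m pure-guest melting temperature (degrees C).
#' @param peak_width Gaussian s.d. of the endotherm (degrees C).
#' @param f_complexed complexed guest fraction in [0, 1].
#' @param heating_rate degrees C per minute.
#' @param noise_sigma noise s.d. as a fraction of the curve's own ideal
#'   peak height.
#' @param w_guest guest mass fraction of the mixture.
#' @param mix_T_shift melting-point shift of the mixture peak (degrees C).
#' @param premelting optional list(T_m=, dH=, width=) secondary transition
#'   added to both curves (scaled by `w_guest` in the mixture).
#' @param dT temperature grid step (degrees C).
#' @param seed RNG seed.
#' @return list: `pure`, `mix` ([thermogram()]s), `truth` (f_complexed,
#'   suggested integration windows, peak heights).
#' @export
gen_thermogram_pair <- function(dH_fus, T_m, peak_width = 2,
                                f_complexed = 0, heating_rate = 5,
                                noise_sigma = 0, w_guest = 0.5,
                                mix_T_shift = -2.5, premelting = NULL,
                                dT = 0.02, seed = NULL) {
  stopifnot(dH_fus > 0, f_complexed >= 0, f_complexed <= 1)
  lo <- min(T_m - 35, T_m + mix_T_shift - 15)
  hi <- T_m + 15
  if (!is.null(premelting)) lo <- min(lo, premelting$T_m - 15)
  Tg <- seq(lo, hi, by = dT)
  rate_s <- heating_rate / 60  # degC per second
  gauss <- function(area, mu, sd) area * rate_s * stats::dnorm(Tg, mu, sd)

  q_pure <- gauss(dH_fus, T_m, peak_width)
  q_mix <- gauss(w_guest * dH_fus * (1 - f_complexed), T_m + mix_T_shift,
                 peak_width)
  if (!is.null(premelting)) {
    q_pure <- q_pure + gauss(premelting$dH, premelting$T_m, premelting$width)
    q_mix <- q_mix + gauss(w_guest * premelting$dH, premelting$T_m,
                           premelting$width)
  }
  h_pure <- max(q_pure)
  h_mix <- max(q_mix)
  .with_seed(seed, {
    if (noise_sigma > 0) {
      q_pure <- q_pure + stats::rnorm(length(Tg), sd = noise_sigma * h_pure)
      if (h_mix > 0) {
        q_mix <- q_mix + stats::rnorm(length(Tg), sd = noise_sigma * h_mix)
      }
    }
    list(
      pure = thermogram(Tg, q_pure, heating_rate),
      mix = thermogram(Tg, q_mix, heating_rate),
      truth = list(dH_fus = dH_fus, f_complexed = f_complexed,
                   w_guest = w_guest, T_m = T_m, mix_T_shift = mix_T_shift,
                   peak_width = peak_width,
                   window_pure = c(T_m - 6 * peak_width, T_m + 6 * peak_width),
                   window_mix = c(T_m + mix_T_shift - 6 * peak_width,
                                  T_m + mix_T_shift + 6 * peak_width),
                   h_pure = h_pure, h_mix = h_mix)
    )
  })
}

#' Generate a pure / mixture IR spectrum pair with known attenuation
#'
#' The pure spectrum carries Gaussian aromatic C-H bands inside the target
#' window; the mixture spectrum is the pure spectrum with the in-band
#' signal scaled by `1 - attenuation`.
#'
#' @param attenuation true band attenuation in [0, 1].
#' @param band `c(lo, hi)` window (cm^-1).
#' @param noise_sigma additive noise s.d. (absorbance units).
#' @param seed RNG seed.
#' @return list: `pure`, `mix` ([spectrum()]s), `truth`.
#' @export
gen_ir_pair <- function(attenuation, band = c(2500, 3200),
                        noise_sigma = 0, seed = NULL) {
  stopifnot(attenuation >= 0, attenuation <= 1)
  wn <- seq(band[1] - 300, band[2] + 300, by = 2)
  centers <- band[1] + c(0.45, 0.6, 0.75) * diff(band)
  in_band <- rowSums(vapply(centers, function(mu) {
    stats::dnorm(wn, mu, 35) * 25
  }, numeric(length(wn))))
  out_band <- stats::dnorm(wn, band[1] - 180, 50) * 10
  pure <- in_band + out_band
  mix <- (1 - attenuation) * in_band + out_band
  .with_seed(seed, {
    if (noise_sigma > 0) {
      pure <- pure + stats::rnorm(length(wn), sd = noise_sigma)
      mix <- mix + stats::rnorm(length(wn), sd = noise_sigma)
    }
    list(pure = ir_spectrum(wn, pure), mix = ir_spectrum(wn, mix),
         truth = list(attenuation = attenuation, band = band))
  })
}
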