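# pi-stacking dimer descriptors

test_that("ideal_stack is a rigid normal translation with an inverse", {
  tpl <- monomer_template("naphthalene")
  expect_equal(ideal_stack(tpl$coords, 0), tpl$coords)
  up <- ideal_stack(tpl$coords, 3.4)
  d <- sqrt(rowSums((up - tpl$coords)^2))
  expect_equal(d, rep(3.4, nrow(up)), tolerance = 1e-12)
  back <- ideal_stack(up, -3.4, normal = fit_plane(tpl$coords)$normal)
  expect_lt(max(abs(back - tpl$coords)), 1e-9)
})

test_that("a perfect eclipsed stack has zero twist, shifts and RMSD", {
  tpl <- monomer_template("anthracene")
  monB <- ideal_stack(tpl$coords, 3.4)
  d <- stack_descriptors(tpl$coords, monB, tpl$masses)
  expect_equal(d$separation, 3.4, tolerance = 1e-9)
  expect_equal(d$twist, 0, tolerance = 1e-9)
  expect_equal(d$shift_x, 0, tolerance = 1e-9)
  expect_equal(d$shift_y, 0, tolerance = 1e-9)
  expect_equal(d$stack_rmsd, 0, tolerance = 1e-9)
  expect_false(d$degenerate)
})

test_that("generated dimers round-trip their construction parameters", {
  cases <- list(
    list(template = "naphthalene", sep = 3.3, twist = 9.6,
         sx = 1.4, sy = 1.5),
    list(template = "anthracene", sep = 3.0, twist = 28.6,
         sx = 2.9, sy = 1.6),
    list(template = "dibenzofuran", sep = 3.3, twist = 15, sx = 0.5, sy = 0.2),
    list(template = "anthracene", sep = 3.5, twist = 89, sx = 0, sy = 2.2))
  for (cs in cases) {
    dim <- gen_stacked_dimer(cs$template, cs$sep, cs$twist, cs$sx, cs$sy)
    d <- stack_descriptors(dim$monA, dim$monB, dim$masses)
    expect_equal(d$separation, cs$sep, tolerance = 1e-6)
    expect_equal(d$twist, cs$twist, tolerance = 1e-6)
    expect_equal(d$shift_x, cs$sx, tolerance = 1e-6)
    expect_equal(d$shift_y, cs$sy, tolerance = 1e-6)
    expect_equal(d$stack_rmsd,
                 oracle_rmsd(dim$monB,
                             ideal_stack(dim$monA, cs$sep)),
                 tolerance = 1e-9)
  }
})

test_that("descriptors are invariant under rigid motion of the dimer", {
  dim <- gen_stacked_dimer("anthracene", 3.0, 28.6, 2.9, 1.6)
  d0 <- stack_descriptors(dim$monA, dim$monB, dim$masses)
  set.seed(5)
  for (rep in 1:25) {
    R <- random_rotation()
    t <- rnorm(3, sd = 10)
    d <- stack_descriptors(rigid_motion(dim$monA, R, t),
                           rigid_motion(dim$monB, R, t), dim$masses)
    for (col in c("separation", "twist", "shift_x", "shift_y", "stack_rmsd")) {
      expect_equal(d[[col]], d0[[col]], tolerance = 1e-8)
    }
  }
})

test_that("pure in-plane offsets obey the RMSD decomposition", {
  tpl <- monomer_template("naphthalene")
  ax <- principal_axes(tpl$coords, tpl$masses)
  for (shifts in list(c(1.2, 0), c(0, 0.8), c(1.5, 2.0))) {
    monB <- sweep(ideal_stack(tpl$coords, 3.3), 2,
                  shifts[1] * ax$long_axis + shifts[2] * ax$short_axis, "+")
    d <- stack_descriptors(tpl$coords, monB, tpl$masses)
    # rigid offset, no twist: rmsd^2 = shift_x^2 + shift_y^2 exactly
    expect_equal(d$stack_rmsd^2, sum(shifts^2), tolerance = 1e-9)
    expect_equal(d$twist, 0, tolerance = 1e-9)
  }
})

test_that("noisy dimers recover the truth within Monte Carlo scatter", {
  truth <- list(sep = 3.3, twist = 20, sx = 1.0, sy = 0.5)
  got <- t(vapply(1:40, function(s) {
    dim <- gen_stacked_dimer("naphthalene", truth$sep, truth$twist,
                             truth$sx, truth$sy, noise_sigma = 0.05,
                             seed = 1000 + s)
    unlist(stack_descriptors(dim$monA, dim$monB,
                             dim$masses)[c("separation", "twist",
                                           "shift_x", "shift_y")])
  }, numeric(4)))
  mu <- colMeans(got)
  se <- apply(got, 2, stats::sd) / sqrt(nrow(got))
  tr <- unlist(truth)
  for (k in 1:4) {
    expect_lt(abs(mu[k] - tr[k]), 3 * se[k] + 0.02)
  }
})

test_that("benzene dimers flag the undefined twist", {
  dim <- gen_stacked_dimer("benzene", 3.4, 0, 0.5, 0)
  d <- stack_descriptors(dim$monA, dim$monB, dim$masses)
  expect_true(d$degenerate)
  expect_true(is.na(d$twist))
  expect_equal(d$separation, 3.4, tolerance = 1e-9)
})

test_that("atom_map must be a bijection and reorders consistently", {
  dim <- gen_stacked_dimer("naphthalene", 3.3, 9.6, 1.4, 1.5)
  n <- nrow(dim$monB)
  expect_error(stack_descriptors(dim$monA, dim$monB, dim$masses,
                                 atom_map = rep(1L, n)), "bijection")
  perm <- sample(n)
  d0 <- stack_descriptors(dim$monA, dim$monB, dim$masses)
  dp <- stack_descriptors(dim$monA, dim$monB[perm, ], dim$masses,
                          massesB = dim$masses[perm], atom_map = perm)
  expect_equal(dp$stack_rmsd, d0$stack_rmsd, tolerance = 1e-9)
  expect_equal(dp$twist, d0$twist, tolerance = 1e-9)
})
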