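# trajectory data model and XYZ / PDB / TSV round trips

make_pdb_lines <- function(frames, elements, resno, chain = "A",
                           cryst = NULL) {
  out <- character()
  if (!is.null(cryst)) {
    out <- c(out, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      cryst[1], cryst[2], cryst[3], 90, 90, 90))
  }
  multi <- length(frames) > 1
  for (f in seq_along(frames)) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", f))
    X <- frames[[f]]
    for (i in seq_len(nrow(X))) {
      out <- c(out, sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        i, elements[i], "LIG", chain, resno[i],
        X[i, 1], X[i, 2], X[i, 3], 1, 0, elements[i]))
    }
    if (multi) out <- c(out, "ENDMDL")
  }
  c(out, "END")
}

test_that("XYZ write/read round-trips coordinates and box", {
  set.seed(1)
  coords <- list(matrix(rnorm(9, sd = 3), 3), matrix(rnorm(9, sd = 3), 3))
  top <- topology(1:2, c("host", "guest"), list(1:2, 3L), 3)
  traj <- trajectory(coords, c("C", "O", "H"), topology = top,
                     box = box_spec(c(20, 25, 30)))
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_trajectory(traj, path)
  back <- read_xyz_trajectory(path, top)
  expect_equal(length(back$coords), 2L)
  for (f in 1:2) {
    expect_lt(max(abs(back$coords[[f]] - coords[[f]])), 1e-6)
  }
  expect_true(back$box$periodic)
  expect_equal(back$box$lengths, c(20, 25, 30))
  expect_equal(back$elements, c("C", "O", "H"))
})

test_that("bare three-float comment line is read as a box", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "10.0 11.0 12.0",
               "C 0 0 0", "C 1 0 0"), path)
  top <- topology(1L, "host", list(1:2), 2)
  traj <- read_xyz_trajectory(path, top)
  expect_equal(traj$box$lengths, c(10, 11, 12))
})

test_that("frame declaring more atoms than it lists is a structural error", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "", "C 0 0 0", "C 1 0 0", "C 2 0 0",
               "4", "", "C 0 0 0", "C 1 0 0", "C 2 0 0"), path)
  top <- topology(1L, "host", list(1:3), 3)
  expect_error(read_xyz_trajectory(path, top), "frame 2")
})

test_that("malformed count line names the frame", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "", "C 0 0 0", "C 1 0 0",
               "oops", "", "C 0 0 0", "C 1 0 0"), path)
  top <- topology(1L, "host", list(1:2), 2)
  expect_error(read_xyz_trajectory(path, top), "frame 2")
})

test_that("triclinic lattices are rejected explicitly", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", 'Lattice="10 0 0 2 10 0 0 0 10"', "C 0 0 0"), path)
  expect_error(read_xyz_trajectory(path, topology(1L, "host", list(1L), 1)),
               "triclinic|orthorhombic")
})

test_that("generated inclusion system survives an XYZ round trip", {
  sys <- gen_inclusion_trajectory(n_host = 100, n_guest = 900,
                                  n_frames = 1, f_inside = 0.2, seed = 5)
  traj <- sys$trajectory
  expect_equal(nrow(traj$topology), 1000L)
  expect_equal(sum(traj$topology$role == "host"), 100L)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_trajectory(traj, path)
  back <- read_xyz_trajectory(path, traj$topology)
  expect_lt(max(abs(back$coords[[1]] - traj$coords[[1]])), 1e-6)
})

test_that("topology must partition the atom list", {
  expect_error(topology(1:2, c("host", "guest"), list(1:2, 4L), 4),
               "partition")
  expect_error(topology(1:2, c("host", "guest"), list(1:3, 3:4), 4),
               "partition")
  expect_silent(topology(1:2, c("host", "guest"), list(1:2, 3:4), 4))
})

test_that("single-model PDB becomes a one-frame trajectory", {
  X <- matrix(c(0, 0, 0, 1.4, 0, 0, 2.1, 1.2, 0, 1.4, 2.4, 0, 0, 2.4, 0),
              ncol = 3, byrow = TRUE)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(make_pdb_lines(list(X), rep("C", 5), rep(1L, 5)), path)
  traj <- read_pdb_models(path)
  expect_equal(length(traj$coords), 1L)
  expect_equal(nrow(traj$coords[[1]]), 5L)
  expect_lt(max(abs(traj$coords[[1]] - X)), 1e-3)
  expect_equal(traj$masses, rep(12.011, 5))
})

test_that("multi-model PDB of one benzene gives identical topology per frame", {
  tpl <- monomer_template("benzene")
  frames <- list(tpl$coords, tpl$coords + 1, tpl$coords + 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(make_pdb_lines(frames, tpl$elements, rep(1L, 12)), path)
  traj <- read_pdb_models(path)
  expect_equal(length(traj$coords), 3L)
  expect_equal(nrow(traj$topology), 1L)
  expect_lt(max(abs(traj$coords[[3]] - traj$coords[[1]] - 2)), 1e-3)
})

test_that("CRYST1 60 60 60 becomes a periodic 60-cube box", {
  X <- matrix(rnorm(15), 5)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(make_pdb_lines(list(X), rep("O", 5), 1:5, cryst = c(60, 60, 60)),
             path)
  traj <- read_pdb_models(path)
  expect_true(traj$box$periodic)
  expect_equal(traj$box$lengths, c(60, 60, 60))
  expect_equal(nrow(traj$topology), 5L)  # one molecule per residue
})

test_that("TSV reports round-trip and keep provenance", {
  df <- data.frame(system = c("a", "b", "c"),
                   alpha_min = c(0.9012345, 2.5, 0),
                   alpha_max = c(1.25, 3, 0.125))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(df, path, seed = 42)
  expect_match(readLines(path, n = 1), "^# cyclohost .*seed=42")
  back <- read_report(path)
  expect_equal(nrow(back), 3L)
  expect_equal(back$alpha_min, signif(df$alpha_min, 6))
  # empty records give a header-only file
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_report(df[0, ], path2)
  expect_equal(nrow(read_report(path2)), 0L)
  expect_equal(names(read_report(path2)), names(df))
})
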