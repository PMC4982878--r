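# Trajectory data model and text-format I/O.
#
# All coordinates are Angstrom, all masses amu; no unit auto-detection.
# Atom order is the molecule identity carrier: topology indices refer to
# positions in the atom list and must be identical in every frame.

.ATOMIC_MASSES <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904, X = 1.0
)

#' Atomic mass lookup
#'
#' @param element character vector of chemical symbols (case-insensitive in
#'   the usual PDB sense: "C", "CL", "Cl" all resolve).
#' @return numeric vector of masses in amu.
#' @export
element_mass <- function(element) {
  key <- paste0(
    toupper(substr(element, 1, 1)),
    tolower(substr(element, 2, nchar(element)))
  )
  m <- .ATOMIC_MASSES[key]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Orthorhombic simulation box
#'
#' @param lengths numeric 3-vector of box edge lengths (Angstrom), or NULL
#'   for a non-periodic system.
#' @param periodic logical; defaults to TRUE when lengths are given.
#' @return object of class `box_spec`.
#' @export
box_spec <- function(lengths = NULL, periodic = !is.null(lengths)) {
  if (periodic) {
    if (is.null(lengths) || length(lengths) != 3L || !all(is.finite(lengths))) {
      stop("periodic box requires three finite edge lengths")
    }
    if (any(lengths <= 0)) stop("box lengths must be positive")
    lengths <- as.numeric(lengths)
  } else {
    lengths <- NULL
  }
  structure(list(lengths = lengths, periodic = periodic), class = "box_spec")
}

#' Molecule-level topology table
#'
#' Groups atoms (by position in the frame atom list) into molecules with a
#' host/guest/other role. Index ranges must partition the atom list: no
#' overlaps, no gaps.
#'
#' @param molecule_id integer vector, one entry per molecule.
#' @param role character vector in {"host","guest","other"}.
#' @param atom_indices list of integer vectors, atoms of each molecule.
#' @param n_atoms total atom count the topology must cover.
#' @return data frame of class `topology` with list-column `atom_indices`.
#' @export
topology <- function(molecule_id, role, atom_indices, n_atoms) {
  stopifnot(length(molecule_id) == length(role),
            length(role) == length(atom_indices))
  role <- match.arg(role, c("host", "guest", "other"), several.ok = TRUE)
  all_idx <- as.integer(sort(unlist(atom_indices, use.names = FALSE)))
  if (length(all_idx) != n_atoms || !identical(all_idx, seq_len(n_atoms))) {
    stop("topology atom indices must partition 1..n_atoms ",
         "(no overlap, no gap); got ", length(all_idx), " indices for ",
         n_atoms, " atoms")
  }
  if (anyDuplicated(molecule_id)) stop("duplicate molecule_id in topology")
  out <- data.frame(molecule_id = as.integer(molecule_id),
                    role = role, stringsAsFactors = FALSE)
  out$atom_indices <- atom_indices
  class(out) <- c("topology", class(out))
  out
}

#' Read a topology CSV
#'
#' Expected columns: `molecule_id,role,first_atom,last_atom` with 1-based
#' inclusive atom ranges.
#'
#' @param path CSV file path.
#' @param n_atoms total atom count to validate the partition against.
#' @return a [topology()] table.
#' @export
read_topology_csv <- function(path, n_atoms) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule_id", "role", "first_atom", "last_atom")
  if (!all(need %in% names(df))) {
    stop("topology CSV must have columns ", paste(need, collapse = ","))
  }
  topology(df$molecule_id, df$role,
           Map(seq.int, df$first_atom, df$last_atom), n_atoms)
}

#' Construct a trajectory object
#'
#' @param coords list of n_atoms x 3 numeric matrices, one per frame.
#' @param elements character vector of element symbols, one per atom.
#' @param masses numeric vector of atomic masses (amu); defaults from
#'   [element_mass()].
#' @param topology a [topology()] table covering all atoms.
#' @param box a [box_spec()].
#' @return object of class `trajectory`.
#' @export
trajectory <- function(coords, elements, masses = element_mass(elements),
                       topology, box = box_spec()) {
  if (length(coords) < 1L) stop("trajectory needs at least one frame")
  n_atoms <- nrow(coords[[1]])
  for (i in seq_along(coords)) {
    fr <- coords[[i]]
    if (!is.matrix(fr) || ncol(fr) != 3L || nrow(fr) != n_atoms) {
      stop("frame ", i, " is not an n_atoms x 3 matrix matching frame 1")
    }
    if (!all(is.finite(fr))) stop("frame ", i, " has non-finite coordinates")
  }
  if (length(elements) != n_atoms || length(masses) != n_atoms) {
    stop("elements/masses length must equal atom count")
  }
  if (any(masses <= 0)) stop("atomic masses must be positive")
  if (!inherits(topology, "topology")) stop("topology must be a topology()")
  structure(list(coords = coords, elements = elements,
                 masses = as.numeric(masses), topology = topology, box = box),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frame(s), %d atoms, %d molecule(s) [%s]\n",
              length(x$coords), nrow(x$coords[[1]]), nrow(x$topology),
              if (x$box$periodic)
                paste0("periodic ", paste(signif(x$box$lengths, 6),
                                          collapse = " x "), " A")
              else "non-periodic"))
  invisible(x)
}

n_frames <- function(traj) length(traj$coords)
n_atoms <- function(traj) nrow(traj$coords[[1]])

molecule_roles <- function(traj) {
  stats::setNames(traj$topology$role, traj$topology$molecule_id)
}

# ---- XYZ ------------------------------------------------------------------

.parse_xyz_comment_box <- function(comment) {
  m <- regmatches(comment,
                  regexpr('Lattice="[^"]*"', comment, perl = TRUE))
  if (length(m) == 1L) {
    vals <- as.numeric(strsplit(gsub('Lattice="|"', "", m), "[[:space:]]+")[[1]])
    if (length(vals) != 9L || anyNA(vals)) {
      stop("malformed Lattice= entry in XYZ comment line")
    }
    off_diag <- vals[-c(1, 5, 9)]
    if (any(abs(off_diag) > 1e-9)) {
      stop("unsupported triclinic lattice in XYZ comment; ",
           "only orthorhombic boxes are supported")
    }
    return(box_spec(vals[c(1, 5, 9)]))
  }
  toks <- strsplit(trimws(comment), "[[:space:]]+")[[1]]
  if (length(toks) == 3L && !anyNA(suppressWarnings(as.numeric(toks)))) {
    return(box_spec(as.numeric(toks)))
  }
  box_spec()
}

#' Read a multi-frame XYZ trajectory
#'
#' Standard XYZ blocks (count line, comment line, `element x y z` rows).
#' The comment line may carry an orthorhombic box either as extended-XYZ
#' `Lattice="ax 0 0 0 by 0 0 0 cz"` or as three bare floats; otherwise the
#' trajectory is non-periodic.
#'
#' @param path XYZ file path.
#' @param topology a [topology()] table covering all atoms (see
#'   [read_topology_csv()]).
#' @return a [trajectory()].
#' @export
read_xyz_trajectory <- function(path, topology) {
  lines <- readLines(path)
  coords <- list()
  elements <- NULL
  box <- NULL
  pos <- 1L
  frame <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos])) && pos == length(lines)) break
    frame <- frame + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat <= 0L) {
      stop("malformed atom-count line at frame ", frame,
           " (line ", pos, "): '", lines[pos], "'")
    }
    if (pos + 1L + nat > length(lines)) {
      stop("truncated frame ", frame, ": declared ", nat,
           " atoms but file ends early")
    }
    comment <- lines[pos + 1L]
    rows <- lines[(pos + 2L):(pos + 1L + nat)]
    toks <- strsplit(trimws(rows), "[[:space:]]+")
    bad <- which(vapply(toks, length, 1L) < 4L)
    if (length(bad)) {
      stop("frame ", frame, ": atom row ", bad[1], " has fewer than 4 fields",
           " (atom count mismatch between declared and listed atoms?)")
    }
    el <- vapply(toks, `[[`, "", 1L)
    xyz <- matrix(as.numeric(unlist(lapply(toks, function(t) t[2:4]))),
                  ncol = 3L, byrow = TRUE)
    if (anyNA(xyz)) stop("frame ", frame, ": non-numeric coordinate field")
    if (is.null(elements)) {
      elements <- el
      box <- .parse_xyz_comment_box(comment)
    } else if (length(el) != length(elements)) {
      stop("frame ", frame, ": atom count ", length(el),
           " differs from frame 1 (", length(elements), ")")
    }
    coords[[frame]] <- xyz
    pos <- pos + 2L + nat
    while (pos <= length(lines) && !nzchar(trimws(lines[pos]))) pos <- pos + 1L
  }
  if (frame == 0L) stop("no frames found in ", path)
  trajectory(coords, elements, topology = topology, box = box)
}

#' Write a multi-frame XYZ trajectory
#'
#' Writes extended-XYZ with a `Lattice=` comment when the box is periodic.
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @export
write_xyz_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nat <- n_atoms(traj)
  comment <- if (traj$box$periodic) {
    L <- traj$box$lengths
    sprintf('Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g"', L[1], L[2], L[3])
  } else ""
  for (i in seq_along(traj$coords)) {
    writeLines(as.character(nat), con)
    writeLines(sprintf("%s frame=%d", comment, i), con)
    fr <- traj$coords[[i]]
    writeLines(sprintf("%-3s %18.10f %18.10f %18.10f",
                       traj$elements, fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

# ---- PDB ------------------------------------------------------------------

#' Read a (possibly multi-model) PDB file as a trajectory
#'
#' Each MODEL becomes a frame; an optional CRYST1 record becomes an
#' orthorhombic box (triclinic cells are rejected). Molecules are defined by
#' chain + residue number; masses are filled from the element symbol, which
#' is taken from the element column when present and inferred from the atom
#' name otherwise. All molecules get role "other"; reassign roles with
#' [set_roles()] before host/guest analyses.
#'
#' @param path PDB file path.
#' @return a [trajectory()].
#' @export
read_pdb_models <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  el <- atom$elesy
  if (is.null(el)) el <- rep(NA_character_, nrow(atom))
  el <- trimws(el)
  missing_el <- is.na(el) | !nzchar(el)
  if (any(missing_el)) {
    # infer from atom name: leading letters, strip digits/primes
    guess <- sub("^[0-9']*", "", trimws(atom$elety[missing_el]))
    guess <- sub("[0-9'].*$", "", guess)
    one <- substr(guess, 1, 1)
    two <- substr(guess, 1, 2)
    known2 <- two %in% c("Cl", "CL", "Br", "BR")
    inferred <- ifelse(known2, two, one)
    if (any(!nzchar(inferred))) {
      stop("cannot infer element for atom(s) ",
           paste(which(missing_el)[!nzchar(inferred)], collapse = ", "),
           ": empty element field and unrecognizable atom name")
    }
    el[missing_el] <- inferred
  }
  masses <- element_mass(el)

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  coords <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
  })

  mol_key <- paste(atom$chain, atom$resno, sep = "//")
  mol_ids <- match(mol_key, unique(mol_key))
  top <- topology(seq_along(unique(mol_key)),
                  rep("other", length(unique(mol_key))),
                  split(seq_along(mol_ids), mol_ids)[as.character(
                    seq_along(unique(mol_key)))],
                  n_atoms = nrow(atom))

  box <- box_spec()
  cr <- grep("^CRYST1", readLines(path), value = TRUE)
  if (length(cr) >= 1L) {
    f <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                      substr(cr[1], 25, 33), substr(cr[1], 34, 40),
                      substr(cr[1], 41, 47), substr(cr[1], 48, 54)))
    if (!anyNA(f[1:3]) && all(f[1:3] > 0)) {
      angles <- f[4:6]
      if (anyNA(angles)) angles <- c(90, 90, 90)
      if (any(abs(angles - 90) > 1e-6)) {
        stop("unsupported triclinic CRYST1 cell; orthorhombic only")
      }
      box <- box_spec(f[1:3])
    }
  }
  trajectory(coords, el, masses, top, box)
}

#' Assign host/guest roles on a trajectory
#'
#' @param traj a [trajectory()].
#' @param roles character vector, one role per molecule (recycled if length
#'   1), or a named vector keyed by molecule_id.
#' @return the trajectory with updated topology roles.
#' @export
set_roles <- function(traj, roles) {
  if (!is.null(names(roles))) {
    idx <- match(as.character(traj$topology$molecule_id), names(roles))
    if (anyNA(idx)) stop("roles missing for some molecule_ids")
    roles <- roles[idx]
  }
  roles <- rep_len(roles, nrow(traj$topology))
  if (!all(roles %in% c("host", "guest", "other"))) {
    stop("roles must be host/guest/other")
  }
  traj$topology$role <- as.character(roles)
  traj
}

# ---- reports --------------------------------------------------------------

#' Write a tabular report as TSV
#'
#' Tab-separated with a header row; floating-point columns are written at 6
#' significant digits. A provenance comment header (package version, seed if
#' given) is prepended so every report records how it was made.
#'
#' @param records data frame with named columns.
#' @param path output path.
#' @param seed optional integer recorded in the provenance header.
#' @export
write_report <- function(records, path, seed = NULL) {
  stopifnot(is.data.frame(records))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open '", path, "' for writing")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("cyclohost"))
  writeLines(sprintf("# cyclohost %s%s", ver,
                     if (is.null(seed)) "" else paste0(" seed=", seed)), con)
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  }
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV report written by [write_report()]
#'
#' @param path report path.
#' @return data frame (provenance header skipped).
#' @export
read_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
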