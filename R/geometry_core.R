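# Geometric primitives: centres of mass, minimum-image displacements,
# best-fit planes and in-plane principal axes for planar aromatics.

#' Centre of mass
#'
#' @param coords n x 3 matrix of positions (Angstrom).
#' @param masses length-n vector of masses (amu).
#' @return 3-vector, sum(m_i r_i) / sum(m_i).
#' @export
center_of_mass <- function(coords, masses) {
  coords <- rbind(coords)
  if (nrow(coords) == 0L) stop("center_of_mass of an empty coordinate set")
  if (length(masses) != nrow(coords)) stop("masses/coords length mismatch")
  tot <- sum(masses)
  if (!(tot > 0)) stop("total mass must be positive")
  colSums(coords * masses) / tot
}

#' Minimum-image displacement in an orthorhombic periodic box
#'
#' @param a,b 3-vectors (or n x 3 matrices) of positions.
#' @param box a periodic [box_spec()].
#' @return displacement b - a with each component wrapped into
#'   `[-L/2, L/2)`.
#' @export
minimum_image_displacement <- function(a, b, box) {
  if (!inherits(box, "box_spec") || !box$periodic) {
    stop("minimum_image_displacement requires a periodic box; ",
         "use plain b - a for non-periodic systems")
  }
  d <- rbind(b) - rbind(a)
  L <- box$lengths
  for (k in 1:3) {
    d[, k] <- d[, k] - L[k] * floor(d[, k] / L[k] + 0.5)
  }
  if (nrow(d) == 1L) drop(d) else d
}

#' Least-squares plane through a point set
#'
#' @param coords n x 3 matrix, n >= 3, not collinear.
#' @return list with unit `normal` (sign fixed so its largest-magnitude
#'   component is positive) and `centroid`.
#' @export
fit_plane <- function(coords) {
  coords <- rbind(coords)
  if (nrow(coords) < 3L) stop("fit_plane needs at least 3 points")
  ctr <- colMeans(coords)
  X <- sweep(coords, 2, ctr)
  e <- eigen(crossprod(X), symmetric = TRUE)
  # collinear: two near-zero eigenvalues
  if (e$values[2] <= 1e-10 * max(e$values[1], 1)) {
    stop("degenerate (collinear) point set: no unique plane")
  }
  n <- e$vectors[, 3]
  k <- which.max(abs(n))
  if (n[k] < 0) n <- -n
  list(normal = n, centroid = ctr)
}

.fix_sign <- function(v) {
  k <- which.max(abs(v))
  if (v[k] < 0) -v else v
}

#' Body-fixed axes of a planar molecule
#'
#' Axes come from the mass-weighted gyration tensor: the plane normal ("z")
#' is the smallest-eigenvalue direction, the long axis ("x") the largest,
#' and the short axis ("y") completes a right-handed frame. For molecules
#' whose two in-plane eigenvalues coincide (e.g. benzene) the in-plane axes
#' are arbitrary and `degenerate_long_axis` is set; callers must then treat
#' any twist angle as undefined.
#'
#' @param coords n x 3 matrix.
#' @param masses length-n masses (amu); unit masses give centroid-based axes.
#' @return list: `origin` (COM), `normal`, `long_axis`, `short_axis` (unit
#'   3-vectors, mutually orthogonal, right-handed), `degenerate_long_axis`.
#' @export
principal_axes <- function(coords, masses = rep(1, nrow(rbind(coords)))) {
  coords <- rbind(coords)
  com <- center_of_mass(coords, masses)
  X <- sweep(coords, 2, com)
  S <- crossprod(X * sqrt(masses / sum(masses)))  # gyration tensor
  e <- eigen(S, symmetric = TRUE)                 # values decreasing
  normal <- .fix_sign(e$vectors[, 3])
  long <- e$vectors[, 1]
  # project into the plane (numerically already there) and normalize
  long <- long - sum(long * normal) * normal
  long <- .fix_sign(long / sqrt(sum(long^2)))
  short <- c(normal[2] * long[3] - normal[3] * long[2],
             normal[3] * long[1] - normal[1] * long[3],
             normal[1] * long[2] - normal[2] * long[1])
  short <- short / sqrt(sum(short^2))
  # right-handed: long x short = normal
  cr <- c(long[2] * short[3] - long[3] * short[2],
          long[3] * short[1] - long[1] * short[3],
          long[1] * short[2] - long[2] * short[1])
  if (sum(cr * normal) < 0) short <- -short
  degen <- (e$values[1] - e$values[2]) <= 1e-6 * max(e$values[1], 1e-12)
  list(origin = com, normal = normal, long_axis = long, short_axis = short,
       degenerate_long_axis = degen)
}
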