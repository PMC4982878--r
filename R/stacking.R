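# Pi-stacking dimer geometry: interplanar separation, long-axis twist,
# in-plane shifts and RMSD from a perfectly eclipsed stack.

#' Perfectly eclipsed stack reference
#'
#' Copies a planar monomer translated by `d` along its best-fit plane
#' normal — the zero-distortion reference for stack RMSD.
#'
#' @param monomer n x 3 coordinate matrix.
#' @param d translation distance (Angstrom); may be negative to stack on
#'   the other face.
#' @param normal optional unit 3-vector overriding the fitted plane normal.
#' @return n x 3 matrix.
#' @export
ideal_stack <- function(monomer, d, normal = NULL) {
  monomer <- rbind(monomer)
  if (is.null(normal)) normal <- fit_plane(monomer)$normal
  sweep(monomer, 2, d * normal, "+")
}

#' Geometry descriptors of a stacked dimer
#'
#' Builds a body-fixed frame on monomer A (plane normal "z", long axis "x",
#' short axis "y" — see [principal_axes()]) and measures monomer B in it:
#' \describe{
#'   \item{separation}{|(COM_B - COM_A) . normal_A| (Angstrom).}
#'   \item{twist}{angle between the long axes of A and B projected into
#'     A's plane, folded to [0, 90] degrees (long axes are headless).}
#'   \item{shift_x, shift_y}{magnitudes of the in-plane COM offset along
#'     A's long and short axes. Magnitudes, not signed values: the
#'     deterministic axis-sign convention makes signs arbitrary, and
#'     magnitudes are what make the descriptors invariant under rigid
#'     motion of the whole dimer.}
#'   \item{stack_rmsd}{RMSD of monomer B against an eclipsed copy of
#'     monomer A translated by the measured separation toward B, under
#'     `atom_map`, with no rotational re-fit — a re-fit would remove
#'     exactly the distortion being measured.}
#' }
#'
#' @param monA,monB n x 3 coordinate matrices of the two monomers.
#' @param massesA,massesB atomic masses; unit masses give centroid-based
#'   descriptors.
#' @param atom_map integer vector pairing each atom of B with an atom of A
#'   (a bijection); defaults to the identity.
#' @param symmetrize_separation if TRUE, separation is the mean of the
#'   projections onto both monomer normals instead of A's alone.
#' @return object of class `stack_descriptor` (a one-row data frame):
#'   separation, twist, shift_x, shift_y, stack_rmsd, degenerate.
#' @export
stack_descriptors <- function(monA, monB, massesA = rep(1, nrow(rbind(monA))),
                              massesB = massesA,
                              atom_map = seq_len(nrow(rbind(monB))),
                              symmetrize_separation = FALSE) {
  monA <- rbind(monA); monB <- rbind(monB)
  if (nrow(monA) != nrow(monB)) stop("monomers must have equal atom counts")
  if (length(atom_map) != nrow(monB) ||
      !setequal(atom_map, seq_len(nrow(monA)))) {
    stop("atom_map must be a bijection onto monomer A's atom indices")
  }
  axA <- principal_axes(monA, massesA)
  dcom <- center_of_mass(monB, massesB) - axA$origin
  sep_signed <- sum(dcom * axA$normal)
  separation <- abs(sep_signed)
  if (symmetrize_separation) {
    nB <- fit_plane(monB)$normal
    if (sum(nB * axA$normal) < 0) nB <- -nB
    separation <- (abs(sep_signed) + abs(sum(dcom * nB))) / 2
  }
  shift_x <- abs(sum(dcom * axA$long_axis))
  shift_y <- abs(sum(dcom * axA$short_axis))

  degen <- axA$degenerate_long_axis
  twist <- NA_real_
  if (!degen) {
    axB <- principal_axes(monB, massesB)
    if (axB$degenerate_long_axis) {
      degen <- TRUE
    } else {
      # project B's long axis into A's plane
      p <- axB$long_axis - sum(axB$long_axis * axA$normal) * axA$normal
      pn <- sqrt(sum(p^2))
      if (pn < 1e-9) {
        degen <- TRUE
      } else {
        cosang <- abs(sum(p / pn * axA$long_axis))
        twist <- acos(min(1, max(-1, cosang))) * 180 / pi
      }
    }
  }

  ref <- ideal_stack(monA, sign(sep_signed) * separation, normal = axA$normal)
  dev <- monB - ref[atom_map, , drop = FALSE]
  rmsd <- sqrt(mean(rowSums(dev^2)))

  structure(data.frame(separation = separation, twist = twist,
                       shift_x = shift_x, shift_y = shift_y,
                       stack_rmsd = rmsd, degenerate = degen),
            class = c("stack_descriptor", "data.frame"))
}
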