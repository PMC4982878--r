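# Host-centred centre-of-mass radial distribution function, cumulative
# guest counts, inclusion numbers and internal/external classification.
#
# The RDF follows g(r) = N(r) / (4 pi r^2 rho dr) with N(r) the mean number
# of guest COMs per host per frame in the spherical shell [r, r+dr), using
# minimum-image distances in periodic boxes. Inclusion numbers integrate
# the raw shell counts, so they are independent of the density convention.

#' RDF binning and normalization parameters
#'
#' @param dr shell thickness (Angstrom).
#' @param r_max outermost radius (Angstrom); must not exceed half the
#'   smallest box length for a periodic system.
#' @param normalization "box_density" (rho = n_guest / V_box, the
#'   convention under which an uncorrelated system gives g = 1) or
#'   "paper_sphere" (rho = n_guest / ((4/3) pi r_max^3), a sphere-volume
#'   density convention that rescales g by a constant factor).
#' @return object of class `rdf_params`.
#' @export
rdf_params <- function(dr = 0.1, r_max = 15,
                       normalization = c("box_density", "paper_sphere")) {
  normalization <- match.arg(normalization)
  if (!(dr > 0)) stop("dr must be positive")
  if (!(r_max > dr)) stop("r_max must exceed dr")
  structure(list(dr = dr, r_max = r_max, normalization = normalization),
            class = "rdf_params")
}

# COMs of all molecules with a given role, one matrix per frame
.role_coms <- function(traj, role) {
  sel <- traj$topology$role == role
  idx_list <- traj$topology$atom_indices[sel]
  if (all(lengths(idx_list) == 1L)) {
    ix <- unlist(idx_list, use.names = FALSE)
    return(lapply(traj$coords, function(fr) fr[ix, , drop = FALSE]))
  }
  lapply(traj$coords, function(fr) {
    t(vapply(idx_list, function(ix) {
      center_of_mass(fr[ix, , drop = FALSE], traj$masses[ix])
    }, numeric(3)))
  })
}

# guest x host minimum-image distance matrix for one frame
.pair_dist <- function(G, H, box) {
  d2 <- matrix(0, nrow(G), nrow(H))
  for (k in 1:3) {
    dk <- outer(G[, k], H[, k], "-")
    if (box$periodic) {
      L <- box$lengths[k]
      dk <- dk - L * floor(dk / L + 0.5)
    }
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

#' Host-centred COM radial distribution function
#'
#' @param traj a [trajectory()] with at least one host and one guest.
#' @param params an [rdf_params()].
#' @param assignment "all_pairs" counts every host-guest pair falling in a
#'   shell (the double-loop definition); "nearest_host" bins each guest
#'   once, at its distance to the nearest host, so that integrated counts
#'   cannot exceed guests/hosts when cavities overlap.
#' @return object of class `rdf_profile`: `r` (bin centres), `shell_counts`
#'   (mean guests per host per frame in each shell), `g`, `rho`, plus
#'   bookkeeping (`dr`, `n_hosts`, `n_guests`, `n_frames`, `normalization`,
#'   `assignment`).
#' @export
compute_rdf <- function(traj, params = rdf_params(),
                        assignment = c("all_pairs", "nearest_host")) {
  assignment <- match.arg(assignment)
  if (traj$box$periodic && params$r_max > min(traj$box$lengths) / 2 + 1e-9) {
    stop("r_max (", params$r_max, " A) exceeds half the smallest box length")
  }
  hosts <- .role_coms(traj, "host")
  guests <- .role_coms(traj, "guest")
  nh <- nrow(hosts[[1]])
  ng <- nrow(guests[[1]])
  if (nh < 1L) stop("trajectory has no host molecules")
  if (ng < 1L) stop("trajectory has no guest molecules")

  edges <- seq(0, params$r_max, by = params$dr)
  if (abs(edges[length(edges)] - params$r_max) > 1e-9) {
    edges <- c(edges, params$r_max)
  }
  nbin <- length(edges) - 1L
  counts <- numeric(nbin)
  for (f in seq_along(traj$coords)) {
    D <- .pair_dist(guests[[f]], hosts[[f]], traj$box)
    d <- if (assignment == "nearest_host") {
      apply(D, 1, min)
    } else {
      as.vector(D)
    }
    d <- d[d < params$r_max]
    bin <- findInterval(d, edges, rightmost.closed = FALSE)
    tab <- tabulate(bin, nbins = nbin)
    counts <- counts + tab
  }
  shell_counts <- counts / (nh * length(traj$coords))
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  vol_box <- if (traj$box$periodic) prod(traj$box$lengths) else NA_real_
  rho <- switch(params$normalization,
    box_density = {
      if (!traj$box$periodic) {
        stop("box_density normalization needs a periodic box volume; ",
             "use normalization = 'paper_sphere'")
      }
      ng / vol_box
    },
    paper_sphere = ng / ((4 / 3) * pi * params$r_max^3)
  )
  widths <- diff(edges)
  g <- shell_counts / (4 * pi * mid^2 * rho * widths)
  structure(list(r = mid, shell_counts = shell_counts, g = g, rho = rho,
                 edges = edges, dr = params$dr, n_hosts = nh, n_guests = ng,
                 n_frames = length(traj$coords),
                 normalization = params$normalization,
                 assignment = assignment),
            class = "rdf_profile")
}

#' @export
print.rdf_profile <- function(x, ...) {
  cat(sprintf(
    "<rdf_profile> %d shells to %.4g A (dr = %.3g), %d hosts x %d guests x %d frames, %s/%s\n",
    length(x$r), max(x$edges), x$dr, x$n_hosts, x$n_guests, x$n_frames,
    x$normalization, x$assignment))
  invisible(x)
}

#' Cumulative guest count from an RDF profile
#'
#' Integrates raw shell counts out to radius `r`: full shells below `r`
#' plus a linear fraction of the straddling shell. With box-density rho
#' this equals the integral of g(r) 4 pi r^2 rho dr.
#'
#' @param profile an `rdf_profile`.
#' @param r radius (Angstrom), 0 <= r <= r_max.
#' @return mean number of guests per host within `r`.
#' @export
cumulative_count <- function(profile, r) {
  if (r < 0) stop("radius must be non-negative")
  if (r > max(profile$edges) + 1e-9) {
    stop("radius ", r, " exceeds the profile r_max ", max(profile$edges))
  }
  edges <- profile$edges
  full <- which(edges[-1] <= r + 1e-12)
  out <- sum(profile$shell_counts[full])
  strad <- length(full) + 1L
  if (strad <= length(profile$shell_counts) && r > edges[strad]) {
    frac <- (r - edges[strad]) / (edges[strad + 1L] - edges[strad])
    out <- out + frac * profile$shell_counts[strad]
  }
  out
}

#' Inclusion numbers alpha_min / alpha_max
#'
#' alpha_min is the mean number of guest COMs per host within the cavity
#' radius; alpha_max extends the cavity radius by `extension` (defaults 4 A
#' and +3 A, i.e. the 4 A / 7 A pair). Each guest is counted at its nearest
#' host only, so alpha_max can never exceed guests/hosts.
#'
#' @param traj a [trajectory()].
#' @param r_cavity cavity radius (Angstrom).
#' @param extension added radius for alpha_max (Angstrom).
#' @param params an [rdf_params()]; r_max must cover r_cavity + extension.
#' @return object of class `inclusion_report`: `alpha_min`, `alpha_max`,
#'   `r_cavity`, `r_extended`, the underlying `profile`, and `per_host` —
#'   one row per (frame, host) with internal/external/free label and guest
#'   counts from [classify_complexes()].
#' @export
inclusion_numbers <- function(traj, r_cavity = 4, extension = 3,
                              params = rdf_params()) {
  if (params$r_max < r_cavity + extension) {
    stop("params$r_max must reach r_cavity + extension")
  }
  prof <- compute_rdf(traj, params, assignment = "nearest_host")
  a_min <- cumulative_count(prof, r_cavity)
  a_max <- cumulative_count(prof, r_cavity + extension)
  per_host <- do.call(rbind, lapply(seq_len(n_frames(traj)), function(f) {
    cl <- classify_complexes(frame_of(traj, f), r_internal = r_cavity,
                             r_external = r_cavity + extension)
    cl$frame <- f
    cl
  }))
  structure(list(alpha_min = a_min, alpha_max = a_max,
                 r_cavity = r_cavity, r_extended = r_cavity + extension,
                 profile = prof, per_host = per_host),
            class = "inclusion_report")
}

#' @export
print.inclusion_report <- function(x, ...) {
  cat(sprintf(
    "<inclusion_report> alpha_min (r = %.3g A) = %.4f, alpha_max (r = %.3g A) = %.4f\n",
    x$r_cavity, x$alpha_min, x$r_extended, x$alpha_max))
  invisible(x)
}

#' Extract a single frame as a one-frame trajectory
#'
#' @param traj a [trajectory()].
#' @param i frame index.
#' @return one-frame [trajectory()].
#' @export
frame_of <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  trajectory(traj$coords[i], traj$elements, traj$masses,
             traj$topology, traj$box)
}

#' Classify hosts as internal / external / free complexes
#'
#' Each guest is assigned to its nearest host (no double counting). A host
#' is `internal` if at least one assigned guest COM lies within
#' `r_internal`, `external` if none does but at least one lies within
#' `r_external`, and `free` otherwise.
#'
#' @param frame a one-frame [trajectory()] (see [frame_of()]).
#' @param r_internal cavity radius (Angstrom).
#' @param r_external outer radius (Angstrom), > r_internal.
#' @return data frame: host molecule_id, label, n_internal, n_external.
#' @export
classify_complexes <- function(frame, r_internal = 4, r_external = 7) {
  if (r_internal >= r_external) {
    stop("r_internal must be smaller than r_external")
  }
  H <- .role_coms(frame, "host")[[1]]
  G <- .role_coms(frame, "guest")[[1]]
  host_ids <- frame$topology$molecule_id[frame$topology$role == "host"]
  D <- .pair_dist(G, H, frame$box)
  nearest <- max.col(-D, ties.method = "first")
  dmin <- D[cbind(seq_len(nrow(D)), nearest)]
  n_int <- tabulate(nearest[dmin < r_internal], nbins = nrow(H))
  n_ext <- tabulate(nearest[dmin >= r_internal & dmin < r_external],
                    nbins = nrow(H))
  label <- ifelse(n_int > 0, "internal", ifelse(n_ext > 0, "external", "free"))
  data.frame(molecule_id = host_ids, label = label,
             n_internal = n_int, n_external = n_ext,
             stringsAsFactors = FALSE)
}
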