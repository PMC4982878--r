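# Independent brute-force oracles. These deliberately avoid the package's
# vectorized internals: plain loops and explicit sums only.

# minimum-image displacement by explicit search over all 27 periodic images
oracle_min_image <- function(a, b, lengths) {
  best <- NULL
  best_n <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- (b + c(i, j, k) * lengths) - a
    n <- sqrt(sum(d^2))
    if (n < best_n) { best_n <- n; best <- d }
  }
  best
}

oracle_min_dist <- function(a, b, lengths) {
  sqrt(sum(oracle_min_image(a, b, lengths)^2))
}

# COM of each molecule of a role, via explicit mass-weighted sums
oracle_coms <- function(traj, frame, role) {
  sel <- which(traj$topology$role == role)
  out <- matrix(NA_real_, length(sel), 3)
  for (i in seq_along(sel)) {
    ix <- traj$topology$atom_indices[[sel[i]]]
    m <- traj$masses[ix]
    acc <- c(0, 0, 0)
    for (j in seq_along(ix)) acc <- acc + m[j] * traj$coords[[frame]][ix[j], ]
    out[i, ] <- acc / sum(m)
  }
  out
}

# RDF shell counts by a triple loop over frames, hosts and guests
oracle_shell_counts <- function(traj, dr, r_max) {
  edges <- seq(0, r_max, by = dr)
  counts <- numeric(length(edges) - 1)
  L <- traj$box$lengths
  for (f in seq_along(traj$coords)) {
    H <- oracle_coms(traj, f, "host")
    G <- oracle_coms(traj, f, "guest")
    for (h in seq_len(nrow(H))) {
      for (g in seq_len(nrow(G))) {
        d <- if (traj$box$periodic) oracle_min_dist(H[h, ], G[g, ], L)
             else sqrt(sum((H[h, ] - G[g, ])^2))
        if (d < r_max) {
          b <- findInterval(d, edges)
          counts[b] <- counts[b] + 1
        }
      }
    }
  }
  counts / (nrow(oracle_coms(traj, 1, "host")) * length(traj$coords))
}

# mean number of host-guest pairs closer than r, per host per frame
oracle_pairs_within <- function(traj, r) {
  L <- traj$box$lengths
  total <- 0
  for (f in seq_along(traj$coords)) {
    H <- oracle_coms(traj, f, "host")
    G <- oracle_coms(traj, f, "guest")
    for (h in seq_len(nrow(H))) for (g in seq_len(nrow(G))) {
      d <- if (traj$box$periodic) oracle_min_dist(H[h, ], G[g, ], L)
           else sqrt(sum((H[h, ] - G[g, ])^2))
      if (d < r) total <- total + 1
    }
  }
  total / (nrow(oracle_coms(traj, 1, "host")) * length(traj$coords))
}

# explicit-sum RMSD between paired coordinate sets
oracle_rmsd <- function(A, B) {
  s <- 0
  for (i in seq_len(nrow(A))) s <- s + sum((A[i, ] - B[i, ])^2)
  sqrt(s / nrow(A))
}

# build a point-molecule trajectory from explicit host/guest coordinates
make_point_traj <- function(hosts, guests, box_lengths = NULL,
                            n_frames_dup = 1) {
  hosts <- rbind(hosts); guests <- rbind(guests)
  nh <- nrow(hosts); ng <- nrow(guests)
  base <- rbind(hosts, guests)
  top <- topology(seq_len(nh + ng),
                  c(rep("host", nh), rep("guest", ng)),
                  as.list(seq_len(nh + ng)), nh + ng)
  box <- if (is.null(box_lengths)) box_spec() else box_spec(box_lengths)
  trajectory(rep(list(base), n_frames_dup), rep("X", nh + ng),
             rep(1, nh + ng), top, box)
}

rigid_motion <- function(coords, R, t) {
  sweep(rbind(coords) %*% t(R), 2, t, "+")
}
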