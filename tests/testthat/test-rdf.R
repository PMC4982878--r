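# host-centred RDF, cumulative counts, inclusion numbers, classification

test_that("a single pair lands in exactly one shell", {
  traj <- make_point_traj(c(0, 0, 0), c(3.05, 0, 0), c(30, 30, 30))
  prof <- compute_rdf(traj, rdf_params(dr = 0.1, r_max = 15))
  in_shell <- prof$edges[-length(prof$edges)] <= 3.05 &
    prof$edges[-1] > 3.05
  expect_equal(prof$shell_counts[in_shell], 1)
  expect_equal(sum(prof$shell_counts), 1)
  expect_equal(cumulative_count(prof, 0), 0)
  expect_equal(cumulative_count(prof, 4), 1)
  expect_error(cumulative_count(prof, -1), "non-negative")
})

test_that("shell counts equal the brute-force double loop", {
  sys <- gen_inclusion_trajectory(n_host = 4, n_guest = 20, box_length = 30,
                                  f_inside = 0.5, r_exclude = 6,
                                  jitter_sigma = 0.3, n_frames = 10,
                                  seed = 21)
  prof <- compute_rdf(sys$trajectory, rdf_params(dr = 0.1, r_max = 12))
  expect_equal(prof$shell_counts,
               oracle_shell_counts(sys$trajectory, 0.1, 12),
               tolerance = 1e-12)
})

test_that("multi-atom hosts use proper molecular centres of mass", {
  sys <- gen_inclusion_trajectory(n_host = 4, n_guest = 12, box_length = 30,
                                  f_inside = 0.5, n_frames = 2,
                                  host_style = "ring7", jitter_sigma = 0.1,
                                  seed = 33)
  prof <- compute_rdf(sys$trajectory, rdf_params(dr = 0.2, r_max = 12))
  expect_equal(prof$shell_counts,
               oracle_shell_counts(sys$trajectory, 0.2, 12),
               tolerance = 1e-12)
})

test_that("cumulative count matches direct pair counting and is monotone", {
  sys <- gen_inclusion_trajectory(n_host = 4, n_guest = 30, box_length = 30,
                                  f_inside = 0.3, r_exclude = 6,
                                  jitter_sigma = 0.2, n_frames = 5, seed = 8)
  prof <- compute_rdf(sys$trajectory, rdf_params(dr = 0.1, r_max = 12))
  rs <- c(2, 3.7, 4, 5.55, 7, 11)
  prev <- 0
  for (r in rs) {
    cc <- cumulative_count(prof, r)
    direct <- oracle_pairs_within(sys$trajectory, r)
    strad <- findInterval(r, prof$edges)
    slack <- if (strad <= length(prof$shell_counts))
      prof$shell_counts[strad] else 0
    expect_lte(abs(cc - direct), slack + 1e-12)
    expect_gte(cc, prev - 1e-12)  # monotone in r
    prev <- cc
  }
})

test_that("both density normalizations scale g but not the counts", {
  sys <- gen_inclusion_trajectory(n_host = 4, n_guest = 30, box_length = 30,
                                  f_inside = 0, r_exclude = 0,
                                  jitter_sigma = 0, n_frames = 3, seed = 2)
  p1 <- compute_rdf(sys$trajectory, rdf_params(0.1, 12, "box_density"))
  p2 <- compute_rdf(sys$trajectory, rdf_params(0.1, 12, "paper_sphere"))
  expect_equal(p1$shell_counts, p2$shell_counts)
  expect_equal(p1$g * p1$rho, p2$g * p2$rho, tolerance = 1e-12)
  expect_equal(p2$rho, 30 / ((4 / 3) * pi * 12^3))
})

test_that("precondition violations are caught", {
  traj <- make_point_traj(c(0, 0, 0), c(3, 0, 0), c(20, 20, 20))
  expect_error(compute_rdf(traj, rdf_params(r_max = 15)), "half")
  no_guest <- make_point_traj(rbind(c(0, 0, 0), c(5, 5, 5)),
                              matrix(0, 0, 3), c(30, 30, 30))
  no_guest$topology$role <- c("host", "host")
  expect_error(compute_rdf(no_guest, rdf_params(r_max = 12)), "guest")
  expect_error(rdf_params(dr = 0), "positive")
})

test_that("inclusion numbers hit constructed shell placements", {
  # all guests beyond 7 A of every host
  far <- gen_inclusion_trajectory(n_host = 8, n_guest = 40, box_length = 60,
                                  f_inside = 0, r_exclude = 8,
                                  jitter_sigma = 0, n_frames = 2, seed = 4)
  rep_far <- inclusion_numbers(far$trajectory)
  expect_equal(rep_far$alpha_min, 0)
  expect_equal(rep_far$alpha_max, 0)

  # all guests in the 4-7 A annulus
  ann <- gen_inclusion_trajectory(n_host = 8, n_guest = 40, box_length = 60,
                                  f_inside = 0, r_annulus = c(4.5, 6.5),
                                  jitter_sigma = 0, n_frames = 2, seed = 4)
  rep_ann <- inclusion_numbers(ann$trajectory)
  expect_equal(rep_ann$alpha_min, 0)
  expect_equal(rep_ann$alpha_max, 5)  # n_guest / n_host exactly
  expect_lte(rep_ann$alpha_min, rep_ann$alpha_max)
})

test_that("alpha_min <= alpha_max <= guests per host always", {
  for (f in c(0, 0.4, 1)) {
    sys <- gen_inclusion_trajectory(n_host = 8, n_guest = 48, box_length = 60,
                                    f_inside = f, jitter_sigma = 0.1,
                                    n_frames = 3, seed = 100 + round(10 * f))
    rep <- inclusion_numbers(sys$trajectory)
    expect_lte(rep$alpha_min, rep$alpha_max + 1e-12)
    expect_lte(rep$alpha_max, 48 / 8 + 1e-12)
  }
})

test_that("classification separates internal, external and free hosts", {
  t1 <- make_point_traj(c(0, 0, 0), c(3, 0, 0), c(40, 40, 40))
  expect_equal(classify_complexes(frame_of(t1, 1))$label, "internal")
  t2 <- make_point_traj(c(0, 0, 0), c(6, 0, 0), c(40, 40, 40))
  expect_equal(classify_complexes(frame_of(t2, 1))$label, "external")
  t3 <- make_point_traj(c(0, 0, 0), c(15, 0, 0), c(40, 40, 40))
  expect_equal(classify_complexes(frame_of(t3, 1))$label, "free")
  expect_error(classify_complexes(frame_of(t1, 1), 7, 4), "smaller")
})

test_that("each guest counts toward its nearest host only", {
  hosts <- rbind(c(10, 10, 10), c(30, 10, 10))  # 20 A apart
  guest <- c(15, 10, 10)                        # 5 A from A, 15 A from B
  traj <- make_point_traj(hosts, guest, c(60, 60, 60))
  cl <- classify_complexes(frame_of(traj, 1))
  expect_equal(cl$label, c("external", "free"))
  expect_equal(cl$n_external, c(1L, 0L))
  # and inclusion numbers integrate that single assignment
  rep <- inclusion_numbers(traj)
  expect_equal(rep$alpha_max, 0.5)  # 1 guest / 2 hosts
})
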