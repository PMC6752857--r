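# Geometric descriptors: distances, radius of gyration, RMSF, H-bonds.

test_that("region distance matches identity, 3-4-5 and weighted-centroid oracles", {
  topo <- toy_topology(4, residue_seq = c(1, 1, 2, 2), mass = c(1, 1, 1, 1))
  fr <- rbind(c(0, 0, 0), c(0, 0, 0), c(3, 4, 0), c(3, 4, 0))
  ens <- make_ensemble(topo, list(fr, fr))
  rA <- region_def("a", "A", 1, 1); rB <- region_def("b", "A", 2, 2)

  same <- region_distance(ens, rA, rA)
  expect_identical(unique(unlist(same$values)), 0)

  d <- region_distance(ens, rA, rB)
  expect_equal(unlist(d$values), c(5, 5))

  # asymmetric masses, hand-placed coordinates
  topo2 <- toy_topology(4, residue_seq = c(1, 1, 2, 2), mass = c(1, 3, 2, 5))
  fr2 <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 5, 1), c(4, 7, -1))
  ens2 <- make_ensemble(topo2, list(fr2))
  expect_equal(unlist(region_distance(ens2, rA, rB)$values),
               oracle_distance(fr2[1:2, ], c(1, 3), fr2[3:4, ], c(2, 5)),
               tolerance = 1e-12)
  expect_error(region_distance(ens, region_def("x", "Q", 1, 2), rB),
               class = "ensdiff_empty_region_error")
})

test_that("radius of gyration matches closed forms and the direct-formula oracle", {
  topo1 <- toy_topology(1)
  e1 <- make_ensemble(topo1, list(matrix(c(1, 2, 3), 1)))
  expect_identical(unlist(radius_of_gyration(e1, 1L)$values), 0)

  topo2 <- toy_topology(2, mass = 1)
  e2 <- make_ensemble(topo2, list(rbind(c(0, 0, 0), c(2, 0, 0))))
  expect_equal(unlist(radius_of_gyration(e2, 1:2)$values), 1)

  topo4 <- toy_topology(4, mass = c(12, 1, 16, 14))
  fr <- rbind(c(0, 0, 0), c(1.1, -0.3, 2), c(-2, 1, 0.5), c(3, 3, -1))
  e4 <- make_ensemble(topo4, list(fr))
  expect_equal(unlist(radius_of_gyration(e4, 1:4)$values),
               oracle_rg(fr, c(12, 1, 16, 14)), tolerance = 1e-12)
})

test_that("RMSF is zero for static and rigid-rotated trajectories, and recovers planted fluctuation", {
  set.seed(31)
  n <- 8
  topo <- toy_topology(n, residue_seq = 1:n)
  base <- cbind(rnorm(n, sd = 3), rnorm(n, sd = 3), rnorm(n, sd = 3))

  static <- make_ensemble(topo, list(base, base, base))
  r0 <- rmsf(static, 1:4, 5:8)
  expect_equal(r0$per_residue$rmsf, rep(0, 4), tolerance = 1e-9)

  # one atom alternates x = +/-1; fit atoms stay fixed
  fr_a <- base; fr_a[5, ] <- c(1, 0, 0)
  fr_b <- base; fr_b[5, ] <- c(-1, 0, 0)
  alt <- make_ensemble(topo, list(fr_a, fr_b, fr_a, fr_b))
  ra <- rmsf(alt, 1:4, 5:5)
  expect_equal(ra$per_residue$rmsf, 1.0, tolerance = 1e-9)

  # rigid-body rotated+translated copies of one frame: fit removes the motion
  frames <- lapply(1:5, function(i) {
    rot <- rand_rotation()
    sweep(base %*% t(rot), 2, rnorm(3, sd = 10), `+`)
  })
  rigid <- make_ensemble(topo, frames)
  rr <- rmsf(rigid, 1:n, 1:n)
  expect_lt(max(rr$per_residue$rmsf), 1e-6)

  expect_error(rmsf(make_ensemble(topo, list(base)), 1:4, 5:8),
               class = "ensdiff_insufficient_data_error")
  line <- toy_topology(4)
  line_fr <- cbind(1:4, 0, 0)
  expect_error(rmsf(make_ensemble(line, list(line_fr, line_fr)), 1:4, 1:4),
               class = "ensdiff_fit_error")
})

test_that("RMSF matches an independent Kabsch + fluctuation oracle", {
  set.seed(77)
  n <- 10
  topo <- toy_topology(n, residue_seq = 1:n)
  frames <- lapply(1:6, function(i) {
    base <- cbind(seq_len(n), (seq_len(n))^0.5, rep(c(0, 1), length.out = n))
    jit <- base + matrix(rnorm(3 * n, sd = 0.4), ncol = 3)
    rot <- rand_rotation()
    sweep(jit %*% t(rot), 2, rnorm(3, sd = 5), `+`)
  })
  ens <- make_ensemble(topo, frames)
  got <- rmsf(ens, 1:n, 1:n)
  want <- oracle_rmsf(frames, 1:n, 1:n)
  expect_equal(got$per_residue$rmsf, want, tolerance = 1e-9)
})

test_that("descriptors are invariant under a global rigid-body motion", {
  toy <- generate_toy_ensemble(toy_ensemble_spec(n_replicas = 2, n_frames = 4, seed = 3))
  set.seed(12)
  moved <- transform_ensemble(toy$bound, rand_rotation(), c(25, -10, 5))
  expect_equal(unlist(region_distance(moved, toy$regions$CDR_A, toy$regions$CDR_B)$values),
               unlist(region_distance(toy$bound, toy$regions$CDR_A, toy$regions$CDR_B)$values),
               tolerance = 1e-9)
  expect_equal(unlist(radius_of_gyration(moved, toy$regions$CDR_A)$values),
               unlist(radius_of_gyration(toy$bound, toy$regions$CDR_A)$values),
               tolerance = 1e-9)
  selA <- select_chain(toy$bound, "A"); selB <- select_chain(toy$bound, "B")
  expect_identical(unlist(hbond_count(moved, selA, selB)$values),
                   unlist(hbond_count(toy$bound, selA, selB)$values))
  # SASA: lattice orientation is fixed, so invariance holds to sampling accuracy
  s0 <- unlist(sasa(toy$bound, toy$regions$CDR_A, n_points = 960)$values)
  s1 <- unlist(sasa(moved, toy$regions$CDR_A, n_points = 960)$values)
  expect_equal(s1, s0, tolerance = 0.02)
  fit <- sort(c(select_region(toy$bound, toy$regions$distal_A),
                select_region(toy$bound, toy$regions$distal_B)))
  expect_equal(rmsf(moved, fit, toy$regions$CDR_A)$region_mean,
               rmsf(toy$bound, fit, toy$regions$CDR_A)$region_mean,
               tolerance = 1e-6)
})

test_that("hydrogen-bond detector accepts and rejects hand-built geometries", {
  # donor N with H, acceptor O; second residue on chain B
  topo <- data.frame(
    atom_id = 1:3, atom_name = c("N", "H", "O"), element = c("N", "H", "O"),
    residue_seq = c(1, 1, 1), insert = "", residue_name = "GLY",
    chain_id = c("A", "A", "B"),
    component = c("receptor_alpha", "receptor_alpha", "receptor_beta"),
    mass = ensdiff:::atomic_mass(c("N", "H", "O")),
    vdw_radius = ensdiff:::vdw_radius(c("N", "H", "O")),
    donor = c(TRUE, FALSE, FALSE), acceptor = c(TRUE, FALSE, TRUE),
    polar_h = c(FALSE, TRUE, FALSE), stringsAsFactors = FALSE)
  place <- function(dist, angle_deg) {
    th <- angle_deg * pi / 180
    rbind(c(0, 0, 0), c(1, 0, 0), dist * c(cos(th), sin(th), 0))
  }
  sel <- list(A = 1:2, B = 3L)
  count1 <- function(fr) unlist(hbond_count(make_ensemble(topo, list(fr)),
                                            sel$A, sel$B)$values)
  expect_identical(count1(place(2.9, 0)), 1)     # ideal geometry
  expect_identical(count1(place(2.9, 45)), 0)    # angle criterion violated
  expect_identical(count1(place(2.9, 29)), 1)    # just inside the 30 degree cone
  expect_identical(count1(place(3.6, 0)), 0)     # distance criterion violated
  expect_identical(count1(place(3.45, 0)), 1)    # just inside 3.5 A

  # empty selection gives zero for every frame
  ens <- make_ensemble(topo, list(place(2.9, 0), place(2.9, 0)))
  expect_identical(unlist(hbond_count(ens, integer(0), sel$B)$values), c(0, 0))
  expect_error(hbond_count(ens, 1:2, 2:3), class = "ensdiff_argument_error")
})

test_that("occupancy table is sparse, consistent with counts, and concentrates on the Bernoulli rate", {
  toy <- generate_toy_ensemble(toy_ensemble_spec(
    n_replicas = 2, n_frames = 1000, base_jitter = 0.05, loop_jitter_bound = 0.05,
    loop_jitter_unbound = 0.05, loop_shift = 0, ligand_attached = FALSE,
    hbond_p_bound = 0.3, hbond_p_unbound = 0.3, seed = 21))
  selA <- select_chain(toy$bound, "A"); selB <- select_chain(toy$bound, "B")
  tab <- hbond_frequency_table(toy$bound, selA, selB)
  counts <- hbond_count(toy$bound, selA, selB)

  expect_true(all(tab$frequency > 0))            # never-formed pairs are absent
  expect_true(all(tab$frequency <= 1))
  # total bond-frames agree between the two H-bond operations
  expect_equal(sum(tab$frequency) * attr(tab, "n_frames"),
               sum(unlist(counts$values)))
  # designated interface bond present in ~30% of 2000 frames
  main <- tab[which.max(tab$frequency), ]
  expect_equal(main$frequency, 0.30, tolerance = 0.11)
  expect_identical(main$chain_pair, "A-B")
})
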