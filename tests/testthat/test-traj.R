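# Trajectory analyses: H-bond detection vs exhaustive oracle, occupancy and
# persistence, RMSF closed forms, proximity profiles, replica aggregation.

test_that("H-bond detector honors the geometric cutoffs on a minimal triplet", {
  atoms <- data.frame(atom_id = 1:3, atom_name = c("N", "H", "O"),
                      element = c("N", "H", "O"), residue_id = c(1L, 1L, 2L),
                      residue_name = "GLY", chain = "A")
  topo <- topology(atoms)
  mk_frame <- function(d_ha) rbind(c(0, 0, 0), c(1, 0, 0), c(1 + d_ha, 0, 0))
  expect_equal(nrow(detect_hbonds_frame(mk_frame(2.0), topo)), 1L)  # inside
  expect_equal(nrow(detect_hbonds_frame(mk_frame(2.6), topo)), 0L)  # too far
  # bent below 120 deg: acceptor at 100 deg from the donor direction
  ang <- 100 * pi / 180
  bent <- rbind(c(0, 0, 0), c(1, 0, 0),
                c(1, 0, 0) + 2 * c(cos(ang), sin(ang), 0))
  expect_equal(nrow(detect_hbonds_frame(bent, topo)), 0L)
  # explicit-H requirement
  topo_noh <- topology(atoms[atoms$element != "H", ])
  expect_error(detect_hbonds_frame(mk_frame(2), topo_noh),
               class = "ss_config_error")
})

test_that("detector output equals the exhaustive triplet oracle on random frames", {
  for (s in 1:100) {
    fr <- random_frame(n_atoms = 50, seed = s)
    topo <- topology(fr$atoms)
    got <- detect_hbonds_frame(fr$xyz, topo)
    want <- oracle_hbonds(fr$xyz, fr$atoms)
    expect_identical(hbond_key_set(got), hbond_key_set(want))
  }
})

test_that("occupancy matrix matches scheduled fractions and excludes intra-region pairs", {
  topo <- toy_system(residues = c(205L, 230L, 226L, 259L))
  regions <- region_map(list(switch1 = 197:207, switch2 = 225:235,
                             switch3 = 252:268))
  spec <- toy_trajectory_spec(
    topo, hbond_schedule = c("205-230" = 0.9, "226-259" = 0.45),
    n_frames = 100, n_replicas = 1)
  traj <- generate_toy_trajectories(spec)[[1]]
  occ <- hbond_occupancy(traj, regions)
  expect_equal(occ$occupancy[occ$donor_res == 205 & occ$acceptor_res == 230],
               0.90)
  expect_equal(occ$occupancy[occ$donor_res == 226 & occ$acceptor_res == 259],
               0.45)
  expect_equal(occ$region_pair,
               c("switch1:switch2", "switch2:switch3"))

  # an always-on bond scores 1.0
  spec1 <- toy_trajectory_spec(topo, hbond_schedule = c("205-230" = 1),
                               n_frames = 50, n_replicas = 1)
  occ1 <- hbond_occupancy(generate_toy_trajectories(spec1)[[1]], regions)
  expect_equal(occ1$occupancy, 1.0)

  # intra-region pair (both in switch2) never appears in the matrix
  spec2 <- toy_trajectory_spec(topo, hbond_schedule = c("226-230" = 1),
                               n_frames = 20, n_replicas = 1)
  occ2 <- hbond_occupancy(generate_toy_trajectories(spec2)[[1]], regions)
  expect_equal(nrow(occ2), 0L)
  # empty region rejected at map construction
  expect_error(region_map(list(switch1 = integer())), class = "ss_config_error")
})

test_that("persistence mask thresholds behave and stay monotone", {
  df <- structure(data.frame(donor_res = 1:3, acceptor_res = 4:6,
                             region_pair = "a:b",
                             occupancy = c(0.6, 0, 1)),
                  class = c("occupancy_matrix", "data.frame"))
  m <- persistence_mask(df, c(0.25, 0.5, 0.75))
  expect_equal(unlist(m[1, c("ge_0.25", "ge_0.5", "ge_0.75")],
                      use.names = FALSE), c(TRUE, TRUE, FALSE))
  expect_equal(m$levels_passed, c(2, 0, 3))
  expect_error(persistence_mask(df, c(0.5, 0.25)),
               class = "ss_validation_error")
  # randomized property: mask equals direct comparison, monotone in threshold
  set.seed(42)
  for (i in 1:20) {
    occ <- runif(10)
    d <- structure(data.frame(donor_res = 1:10, acceptor_res = 11:20,
                              region_pair = "a:b", occupancy = occ),
                   class = c("occupancy_matrix", "data.frame"))
    th <- sort(runif(4))
    mm <- persistence_mask(d, th)
    for (j in seq_along(th))
      expect_identical(mm[[sprintf("ge_%g", th[j])]], occ >= th[j])
    mask_mat <- sapply(sprintf("ge_%g", th), function(cn) mm[[cn]])
    expect_true(all(t(apply(mask_mat, 1, function(r) diff(as.integer(r)) <= 0))))
  }
})

test_that("RMSF closed forms: static zero, alternation d, translation invariance", {
  topo <- toy_system(residues = c(52L, 173L))
  n_at <- nrow(topo$atoms)
  rest <- attr(topo, "rest")
  static <- trajectory(topo, array(rep(rest, each = 10),
                                   dim = c(10, n_at, 3)))
  expect_true(all(compute_rmsf(static, selection = c("N", "O"))$rmsf == 0))

  # one atom alternating +/- d about its mean along x -> rmsf exactly d
  d <- 0.7
  frames <- array(rep(rest, each = 10), dim = c(10, n_at, 3))
  i_n <- which(topo$atoms$atom_name == "N")[1]
  frames[, i_n, 1] <- rest[i_n, 1] + d * rep(c(1, -1), 5)
  traj <- trajectory(topo, frames)
  prof <- compute_rmsf(traj, selection = "N")
  expect_equal(prof$rmsf[prof$residue_id == 52], d)

  # global rigid translation (same shift in every frame) leaves RMSF unchanged
  shifted <- frames
  for (f in 1:10) shifted[f, , ] <- sweep(frames[f, , ], 2, -c(5.5, -2, 17))
  expect_equal(compute_rmsf(trajectory(topo, shifted), selection = "N")$rmsf,
               prof$rmsf)
  expect_warning(compute_rmsf(
    trajectory(topo, array(rest, dim = c(1, n_at, 3))), selection = "N"),
    "single frame")
})

test_that("with superposition, RMSF is invariant under per-frame rigid rotations", {
  topo <- toy_system(residues = c(52L, 173L, 201L))
  spec <- toy_trajectory_spec(topo, jitter_sd = 0.2, n_frames = 40,
                              n_replicas = 1, seed = 13)
  traj <- generate_toy_trajectories(spec)[[1]]
  base <- compute_rmsf(traj, selection = c("N", "O"), superpose = TRUE)
  rot <- traj
  set.seed(99)
  for (f in seq_len(40)) {
    th <- runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
                c(0, sin(th[1]), cos(th[1])))
    Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
                c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
    rot$frames[f, , ] <- rot$frames[f, , ] %*% (Rx %*% Rz)
  }
  rotated <- compute_rmsf(rot, selection = c("N", "O"), superpose = TRUE)
  expect_equal(rotated$rmsf, base$rmsf, tolerance = 1e-6)
})

test_that("isotropic Gaussian jitter converges to sigma*sqrt(3) RMSF", {
  topo <- toy_topology(c(52L, 173L), proton_labels = "a")
  spec <- toy_trajectory_spec(topo, jitter_sd = 0.3, n_frames = 1e4,
                              n_replicas = 1, seed = 21)
  traj <- generate_toy_trajectories(spec)[[1]]
  prof <- compute_rmsf(traj, selection = c("N", "O"))
  expect_lt(max(abs(prof$rmsf - 0.3 * sqrt(3)) / (0.3 * sqrt(3))), 0.05)
})

test_that("proximity profile matches scheduled fractions and sums to one", {
  topo <- toy_system(residues = c(52L, 173L, 201L), labels = c("a", "b"))
  spec <- toy_trajectory_spec(
    topo,
    proximity_schedule = c("a:52" = 0.9, "b:173" = 0.7, "b:201" = 0.2),
    n_frames = 200, n_replicas = 1)
  traj <- generate_toy_trajectories(spec)[[1]]
  prof <- proton_proximity_profile(traj)
  expect_equal(prof$a[["52"]], 0.90)
  expect_equal(prof$a[["none_in_radius"]], 0.10)
  expect_equal(prof$b[["173"]], 0.70)
  expect_equal(prof$b[["201"]], 0.20)
  for (lab in names(prof)) expect_equal(sum(prof[[lab]]), 1, tolerance = 1e-9)

  # all frames beyond the radius
  spec_far <- toy_trajectory_spec(topo, n_frames = 30, n_replicas = 1)
  prof_far <- proton_proximity_profile(generate_toy_trajectories(spec_far)[[1]])
  expect_equal(prof_far$a[["none_in_radius"]], 1.0)
  # unlabeled topology is a configuration error
  at <- topo$atoms
  expect_error(proton_proximity_profile(
    trajectory(topology(at), array(attr(topo, "rest"),
                                   dim = c(1, nrow(at), 3)))),
    class = "ss_config_error")
})

test_that("equivalent 'd' protons are averaged arithmetically on asymmetric schedules", {
  topo <- toy_system(residues = c(50L, 52L), labels = c("a", "d"))
  spec <- toy_trajectory_spec(
    topo, proximity_schedule = c("d#1:50" = 0.8, "d#2:50" = 0.6),
    n_frames = 100, n_replicas = 1)
  prof <- proton_proximity_profile(generate_toy_trajectories(spec)[[1]])
  expect_equal(prof$d[["50"]], 0.7)          # (0.8 + 0.6) / 2
  expect_equal(prof$d[["none_in_radius"]], 0.3)
})

test_that("occupancy and proximity are invariant under frame reordering", {
  topo <- toy_system(residues = c(205L, 230L, 52L), labels = "a")
  spec <- toy_trajectory_spec(topo, hbond_schedule = c("205-230" = 0.6),
                              proximity_schedule = c("a:52" = 0.35),
                              n_frames = 40, n_replicas = 1, seed = 3)
  traj <- generate_toy_trajectories(spec)[[1]]
  perm <- sample(40)
  shuf <- trajectory(topo, traj$frames[perm, , , drop = FALSE])
  regions <- region_map(list(switch1 = 197:207, switch2 = 225:235))
  expect_equal(hbond_occupancy(shuf, regions)$occupancy,
               hbond_occupancy(traj, regions)$occupancy)
  expect_equal(proton_proximity_profile(shuf)$a,
               proton_proximity_profile(traj)$a)
})

test_that("unsatisfiable schedules raise construction errors naming the conflict", {
  topo <- toy_system(residues = c(50L, 52L), labels = "a")
  spec <- toy_trajectory_spec(
    topo, proximity_schedule = c("a:50" = 0.7, "a:52" = 0.6),
    n_frames = 100, n_replicas = 1)
  expect_error(generate_toy_trajectories(spec), "unsatisfiable",
               class = "ss_construction_error")
  topo2 <- toy_system(residues = c(205L, 226L, 230L))
  spec2 <- toy_trajectory_spec(
    topo2, hbond_schedule = c("205-230" = 0.5, "226-230" = 0.5),
    n_frames = 10, n_replicas = 1)
  expect_error(generate_toy_trajectories(spec2), "conflicting",
               class = "ss_construction_error")
})

test_that("replica aggregation: hand arithmetic, format, key mismatch", {
  agg <- aggregate_replicas(list(10, 10, 10))
  expect_equal(agg$mean, 10)
  expect_equal(agg$sem, 0)
  agg2 <- aggregate_replicas(list(96, 98))
  expect_equal(agg2$mean, 97)
  expect_equal(agg2$sem, 1)
  expect_equal(agg2$label, "97.0±1.0")
  # fraction-valued inputs render as percentages
  agg3 <- aggregate_replicas(list(c(g52 = 0.96), c(g52 = 0.99)))
  expect_equal(agg3$label, "97.5±1.5%")
  expect_error(aggregate_replicas(list(c(a = 1), c(b = 1))),
               class = "ss_aggregation_error")
  expect_error(aggregate_replicas(list(1)), class = "ss_aggregation_error")
})

test_that("bernoulli replicas recover a true frequency within 2 s.e.m.", {
  topo <- toy_system(residues = 52L, labels = "a")
  spec <- toy_trajectory_spec(
    topo, proximity_schedule = c("a:52" = 0.974), n_frames = 100,
    n_replicas = 100, assignment = "bernoulli", seed = 17)
  trajs <- generate_toy_trajectories(spec)
  freqs <- vapply(trajs, function(tr)
    proton_proximity_profile(tr)$a[["52"]], numeric(1))
  agg <- aggregate_replicas(lapply(freqs, function(f) c(g52 = f)))
  expect_gt(agg$sem, 0)
  expect_lt(abs(agg$mean - 0.974), 2 * agg$sem)
  expect_match(agg$label, "^\\d+\\.\\d±\\d+\\.\\d%$")
})
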