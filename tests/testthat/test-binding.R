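# Contact kinetics, pose clustering, occupancy affinities and state
# detection.

test_that("the hysteretic contact rule follows the on/off thresholds", {
  probe <- point_probe(0)
  rec <- atom_set(0, 0, 0, "C")
  d_seq <- c(8, 6, 10, 17, 6)
  traj <- fake_trajectory(cbind(d_seq, 0, 0))
  cs <- contact_series(traj, probe, rec, on_A = 7, off_A = 16)
  expect_equal(cs$frames$bound, c(FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(nrow(cs$intervals), 2)
  # equal thresholds reduce to plain thresholding
  cs2 <- contact_series(traj, probe, rec, on_A = 10, off_A = 10)
  expect_equal(cs2$frames$bound, d_seq < 10)
})

test_that("contact distances match the brute-force pair minimum", {
  body <- toy_probe_body()
  rec <- toy_bead_protein(n_atoms = 25, radius_A = 10, seed = 3)
  set.seed(12)
  xyz <- matrix(rnorm(30, sd = 15), ncol = 3)
  traj <- fake_trajectory(xyz)
  cs <- contact_series(traj, body, rec)
  for (i in 1:10) {
    bxyz <- as.matrix(body$atoms[body$atoms$element != "H",
                                 c("x", "y", "z")])
    bxyz <- sweep(bxyz, 2, xyz[i, ], "+")
    rxyz <- as.matrix(rec[rec$element != "H", c("x", "y", "z")])
    dmin <- min(vapply(seq_len(nrow(bxyz)), function(a) {
      min(sqrt(colSums((t(rxyz) - bxyz[a, ])^2)))
    }, numeric(1)))
    expect_equal(cs$frames$min_dist_A[i], dmin, tolerance = 1e-9)
  }
  expect_error(contact_series(fake_trajectory(matrix(0, 0, 3)),
                              body, rec), "empty")
})

test_that("contact flags agree with an independent state machine", {
  probe <- point_probe(0)
  rec <- atom_set(0, 0, 0, "C")
  set.seed(99)
  for (rep in 1:20) {
    d_seq <- runif(50, 0, 25)
    traj <- fake_trajectory(cbind(d_seq, 0, 0))
    cs <- contact_series(traj, probe, rec, on_A = 7, off_A = 16)
    expect_equal(cs$frames$bound, oracle_hysteresis(d_seq, 7, 16))
  }
  # high-volume check on the flag sequence itself (1000 random series)
  set.seed(100)
  for (rep in 1:1000) {
    d_seq <- runif(30, 0, 25)
    got <- smfsbd:::.hysteresis_flags(d_seq, 7, 16)
    expect_identical(got, oracle_hysteresis(d_seq, 7, 16))
  }
})

test_that("pose clustering recovers engineered sites and occupancies", {
  probe <- point_probe(0)
  rec <- atom_set(c(-15, 15), c(0, 0), c(0, 0), c("O", "O"))
  sites <- list(proximal = c(-15, 0, 4), distal = c(15, 0, 4))
  # frames alternating between two tight pockets, plus unbound excursions
  set.seed(5)
  n_a <- 60; n_b <- 30; n_u <- 30
  xyz <- rbind(
    cbind(rnorm(n_a, -15, 0.5), rnorm(n_a, 0, 0.5), rnorm(n_a, 4, 0.3)),
    cbind(rnorm(n_b, 15, 0.5), rnorm(n_b, 0, 0.5), rnorm(n_b, 4, 0.3)),
    cbind(rnorm(n_u, 0, 2), rnorm(n_u, 40, 2), rnorm(n_u, 30, 2)))
  cs <- contact_series(fake_trajectory(xyz), probe, rec)
  cl <- cluster_poses(cs, sites)
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$site, c("proximal", "distal"))
  prox <- cl[cl$site == "proximal", ]
  expect_lt(sqrt(sum((c(prox$cx, prox$cy, prox$cz) - sites$proximal)^2)), 3)
  # occupancies sum to the bound fraction
  expect_equal(sum(cl$occupancy), mean(cs$frames$bound))
  # all frames at one point give one cluster with the bound fraction
  one <- fake_trajectory(matrix(rep(c(-15, 0, 4), each = 20), ncol = 3))
  cs1 <- contact_series(one, probe, rec)
  cl1 <- cluster_poses(cs1, sites)
  expect_equal(nrow(cl1), 1)
  expect_equal(cl1$occupancy, mean(cs1$frames$bound))
  # distant poses are filtered by the 10 A interface criterion
  farxyz <- rbind(xyz[1:10, ], cbind(rnorm(50, 0, 0.5), 40, 40))
  csf <- contact_series(fake_trajectory(farxyz), probe, rec,
                        on_A = 100, off_A = 100)
  clf <- cluster_poses(csf, sites)
  expect_true(all(clf$mean_interface_A <= 10))
})

test_that("site labels are stable under 1 A pose jitter", {
  probe <- point_probe(0)
  rec <- atom_set(c(-15, 15), c(0, 0), c(0, 0), c("O", "O"))
  sites <- list(proximal = c(-15, 0, 4), distal = c(15, 0, 4))
  set.seed(8)
  base <- rbind(
    cbind(rnorm(100, -15, 1), rnorm(100, 0, 1), rnorm(100, 4, 1)),
    cbind(rnorm(100, 15, 1), rnorm(100, 0, 1), rnorm(100, 4, 1)))
  lab <- function(xyz) {
    cs <- assign_frame_sites(
      contact_series(fake_trajectory(xyz), probe, rec), sites)
    cs$frames$site
  }
  l0 <- lab(base)
  l1 <- lab(base + matrix(runif(length(base), -1, 1), ncol = 3))
  same <- l0 == l1
  expect_gte(mean(same, na.rm = TRUE), 0.99)
})

test_that("occupancy KD follows the single-molecule closed form", {
  probe <- point_probe(0)
  rec <- atom_set(0, 0, 0, "C")
  # p_bound = 0.5 in a 1.66e6 A^3 box -> KD = 1/(NA V) ~ 1 mM
  d_seq <- rep(c(5, 20), 50)
  cs <- contact_series(fake_trajectory(cbind(d_seq, 0, 0)), probe, rec,
                       on_A = 7, off_A = 7)
  kd <- occupancy_kd(list(cs), 1.66e6)
  expect_equal(kd$p_bound, 0.5)
  expect_equal(kd$KD_M, 1 / (6.02214076e23 * 1.66e6 * 1e-27),
               tolerance = 1e-9)
  expect_equal(kd$KD_M, 1e-3, tolerance = 0.01)
  # p -> 1 sends KD to 0
  cs_all <- contact_series(fake_trajectory(cbind(rep(5, 100), 0, 0)),
                           probe, rec, on_A = 7, off_A = 7)
  expect_equal(occupancy_kd(list(cs_all), 1.66e6)$KD_M, 0)
  # no binding reports the sentinel
  cs_none <- contact_series(fake_trajectory(cbind(rep(50, 100), 0, 0)),
                            probe, rec)
  expect_true(is.na(occupancy_kd(list(cs_none), 1.66e6)$KD_M))
})

test_that("deeper wells bind more tightly, monotonically", {
  body <- point_probe(1)
  p <- bd_params(timestep_fs = 500, duration_ns = 150,
                 record_every_ns = 0.25)
  kds <- vapply(c(-2, -5, -9), function(q) {
    rec <- atom_set(0, 0, 0, "O", charge_e = q)
    cats <- assign_lj_categories(body$atoms)$category_params
    gs <- build_grid_set(rec, cats, spacing = 1.5, margin_A = 18)
    reps <- lapply(1:6, function(i) {
      tr <- run_trajectory(body, gs, p, rigid_state(c(0, 0, 10)),
                           seed = 300 + i)
      contact_series(tr, body, rec)
    })
    occupancy_kd(reps, (2 * 18)^3)$KD_M
  }, numeric(1))
  expect_true(all(diff(kds) < 0))
})

test_that("occupancy estimates converge to the Boltzmann integral", {
  body <- point_probe(1)
  rec <- atom_set(0, 0, 0, "O", charge_e = -5)
  cats <- assign_lj_categories(body$atoms)$category_params
  gs <- build_grid_set(rec, cats, spacing = 1, margin_A = 16)
  # analytic single-molecule occupancy: Boltzmann weight of the bound
  # region (within 8 A of the receptor atom) over the confinement box,
  # computed by direct summation over the energy grid
  box_lo <- gs[[1]]$origin + gs[[1]]$spacing
  box_hi <- gs[[1]]$origin + gs[[1]]$spacing * (gs[[1]]$dims - 2)
  ax <- lapply(1:3, function(a) seq(box_lo[a], box_hi[a], by = 1))
  nodes <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  e <- interpolate_grid(gs$electrostatic, nodes)$energy +
    interpolate_grid(gs$LJ_CS, nodes)$energy
  wts <- exp(-e / kBT(300, "kJ_mol"))
  r <- sqrt(rowSums(nodes^2))
  p_analytic <- sum(wts[r < 8]) / sum(wts)
  p <- bd_params(timestep_fs = 500, duration_ns = 400,
                 record_every_ns = 0.25)
  reps <- lapply(1:10, function(i) {
    tr <- run_trajectory(body, gs, p, rigid_state(c(0, 0, 12)),
                         seed = 500 + i)
    contact_series(tr, body, rec, on_A = 8, off_A = 8)
  })
  p_hat <- mean(unlist(lapply(reps, function(cs) cs$frames$bound)))
  expect_equal(p_hat, p_analytic, tolerance = 0.1)
})

test_that("state detection behaves on monotone and sign-flipped input", {
  prof <- data.frame(reaction_coord_A = seq(0, 50, length.out = 100),
                     energy_kJ_mol = seq(0, -30, length.out = 100))
  expect_equal(nrow(detect_states(prof)), 0)
  # synthetic two-trough profile
  x <- seq(0, 80, length.out = 300)
  e <- -12 * exp(-(x - 20)^2 / 18) - 8 * exp(-(x - 55)^2 / 18)
  prof2 <- data.frame(reaction_coord_A = x, energy_kJ_mol = e)
  st <- detect_states(prof2, smoothing_window = 5,
                      prominence_kJ_mol = 2)
  expect_equal(st$position_A, c(20, 55), tolerance = 2 / 20)
  # the magnitude sign convention (positive peaks at the states)
  # yields the same states
  st_flip <- detect_states(
    data.frame(reaction_coord_A = x, energy_kJ_mol = -e),
    smoothing_window = 5, prominence_kJ_mol = 2)
  expect_equal(st_flip$position_A, st$position_A)
})
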