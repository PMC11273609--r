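# Overdamped rigid-body propagator: deterministic limits, free
# diffusion, equipartition, Boltzmann sampling, energies and pulling.

no_box <- rbind(rep(-1e9, 3), rep(1e9, 3))

test_that("the force-free deterministic limit leaves the state fixed", {
  body <- toy_probe_body()
  st <- rigid_state(c(3, -2, 7), c(0.5, 0.5, 0.5, 0.5))
  out <- bd_step(st, body, NULL, bd_params(), n_steps = 50,
                 box = no_box, thermal = FALSE)
  expect_equal(out$position, st$position)
  expect_equal(out$orientation, st$orientation)
})

test_that("trajectory bookkeeping records start and end frames", {
  body <- toy_probe_body()
  p <- bd_params(duration_ns = 1, record_every_ns = 1, seed = 2)
  tr <- run_trajectory(body, NULL, p, box = no_box)
  expect_equal(nrow(tr$frames), 2)
  expect_equal(tr$frames$time_ns, c(0, 1))
  # same seed, same trajectory
  tr2 <- run_trajectory(body, NULL, p, box = no_box)
  expect_identical(tr$frames, tr2$frames)
  tr3 <- run_trajectory(body, NULL, p, box = no_box, seed = 99)
  expect_false(identical(tr$frames$x, tr3$frames$x))
  # quaternions stay unit norm
  q <- as.matrix(tr$frames[, c("qw", "qx", "qy", "qz")])
  expect_equal(rowSums(q^2), rep(1, nrow(q)), tolerance = 1e-9)
})

test_that("free translational diffusion satisfies MSD = 6 D t", {
  body <- toy_probe_body()
  t_end <- 10
  p <- bd_params(timestep_fs = 1e5, duration_ns = t_end,
                 record_every_ns = t_end)
  msd <- vapply(1:1000, function(i) {
    tr <- run_trajectory(body, NULL, p, box = no_box, seed = i)
    f <- tr$frames[nrow(tr$frames), ]
    f$x^2 + f$y^2 + f$z^2
  }, numeric(1))
  expect_equal(mean(msd), 6 * mean(body$D_trans_A2_ns) * t_end,
               tolerance = 0.05)
})

test_that("free rotational diffusion decays as exp(-2 D_rot t)", {
  body <- toy_probe_body()
  Dr <- body$D_rot_rad2_ns[1]
  t_end <- 0.5 / (2 * Dr)
  p <- bd_params(timestep_fs = 1e5 * t_end / 100,
                 duration_ns = t_end, record_every_ns = t_end)
  cosr <- vapply(1:1000, function(i) {
    tr <- run_trajectory(body, NULL, p, box = no_box, seed = 2000 + i)
    f <- tr$frames[nrow(tr$frames), ]
    R <- quat_mat(c(f$qw, f$qx, f$qy, f$qz))
    R[3, 3]                       # body z-axis against its start
  }, numeric(1))
  expect_equal(mean(cosr), exp(-2 * Dr * t_end), tolerance = 0.1)
})

test_that("a harmonic well equilibrates to variance kBT/k", {
  body <- toy_probe_body()
  k <- 0.5
  p <- bd_params(timestep_fs = 1e3, duration_ns = 250,
                 record_every_ns = 0.05, seed = 31)
  tr <- run_trajectory(body, NULL, p, box = no_box,
                       external = list(type = "harmonic", k = k,
                                       center = c(0, 0, 0)))
  x <- tr$frames$x[-(1:200)]      # drop equilibration
  expect_equal(var(x), kBT(300, "kJ_mol") / k, tolerance = 0.05)
})

test_that("a double well is sampled with Boltzmann statistics", {
  probe <- point_probe(0)
  h <- 5; w <- 5
  p <- bd_params(timestep_fs = 500, duration_ns = 1000,
                 record_every_ns = 0.25, seed = 47)
  tr <- run_trajectory(probe, NULL, p,
                       start = rigid_state(c(w, 0, 0)),
                       external = list(type = "double_well", height = h,
                                       center = 0, half_sep = w),
                       box = rbind(c(-12, -10, -10), c(12, 10, 10)),
                       k_wall = 20)
  expect_gt(p$n_steps, 1e6)
  x <- tr$frames$x[-(1:200)]
  edges <- seq(-10, 10, by = 1)
  keep <- x > -10 & x < 10
  obs <- table(cut(x[keep], edges))
  U <- function(z) h * ((z^2 - w^2) / w^2)^2
  beta <- 1 / kBT(300, "kJ_mol")
  p_bin <- vapply(seq_len(length(edges) - 1), function(i) {
    integrate(function(z) exp(-beta * U(z)), edges[i],
              edges[i + 1])$value
  }, numeric(1))
  p_bin <- p_bin / sum(p_bin)
  ct <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = p_bin))
  expect_gt(ct$p.value, 0.001)
  # both wells visited
  expect_gt(mean(x < 0), 0.2)
  expect_gt(mean(x > 0), 0.2)
})

test_that("interaction energy matches the pairwise sum and symmetries", {
  rec <- toy_two_well_receptor(half_size_A = 15)
  body <- toy_probe_body()
  cats <- assign_lj_categories(body$atoms)$category_params
  gs <- build_grid_set(rec$atoms, cats, spacing = 1, margin_A = 15,
                       smooth_width_A = 0)
  st <- rigid_state(c(-12, 2, 9), c(0.9, 0.1, 0.3, 0.2))
  e_grid <- interaction_energy(st, body, gs)
  e_direct <- oracle_pair_energy(body$atoms, st$position,
                                 st$orientation / sqrt(sum(st$orientation^2)),
                                 rec$atoms, cats)
  expect_equal(e_grid, e_direct, tolerance = 0.05)
  # far from all atoms (but inside the grid) the energy vanishes
  far <- rigid_state(c(28, 28, 12))
  expect_lt(abs(interaction_energy(far, body, gs)), 0.1)
  # rotating receptor and pose together by 90 deg about z preserves energy
  rot <- rec$atoms
  tmp <- rot$x; rot$x <- -rot$y; rot$y <- tmp
  gs_rot <- build_grid_set(rot, cats, spacing = 1, margin_A = 15,
                           smooth_width_A = 0)
  qz <- c(cos(pi / 4), 0, 0, sin(pi / 4))
  st_rot <- rigid_state(c(-st$position[2], st$position[1],
                          st$position[3]),
                        quat_mul_oracle(qz, st$orientation))
  expect_equal(interaction_energy(st_rot, body, gs_rot), e_grid,
               tolerance = 0.05)
})

test_that("steered pulling reads out engineered minima", {
  # flat profile over a potential-free system
  body <- toy_probe_body()
  empty <- structure(list(), class = "grid_set")
  p <- bd_params(timestep_fs = 500, record_every_ns = 0.1, seed = 5)
  prof0 <- steered_pull(body, empty, c(-20, 0, 8), c(20, 0, 8),
                        velocity_A_per_ns = 2, spring_k = 20, params = p)
  expect_true(all(prof0$energy_kJ_mol == 0))
  # two charged pockets produce two troughs at their positions
  rec <- toy_two_well_receptor(well_charge_proximal = -8,
                               well_charge_distal = -4,
                               separation_A = 40)
  cats <- assign_lj_categories(body$atoms)$category_params
  gs <- build_grid_set(rec$atoms, cats, spacing = 2, margin_A = 20)
  run_pull <- function(v) {
    steered_pull(body, gs, c(-45, 0, 8), c(45, 0, 8),
                 velocity_A_per_ns = v, spring_k = 20, params = p,
                 site = c(45, 0, 8))
  }
  prof <- run_pull(1)
  st <- detect_states(prof, smoothing_window = 15, prominence_kJ_mol = 3)
  expect_equal(nrow(st), 2)
  # wells at x = -20, +20 lie at reaction coordinates 65 and 25
  expect_equal(sort(st$position_A), c(25, 65), tolerance = 2 / 25)
  # halving the velocity leaves the trough positions in place
  st2 <- detect_states(run_pull(0.5), smoothing_window = 15,
                       prominence_kJ_mol = 3)
  expect_equal(sort(st2$position_A), sort(st$position_A),
               tolerance = 2 / 25)
})
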