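# Potential grids: LJ clustering, electrostatics, smoothing and
# interpolation.

test_that("LJ categories follow the H / O,N / C,S clustering", {
  a <- atom_set(c(0, 3), c(0, 0), c(0, 0), c("C", "S"))
  res <- assign_lj_categories(a)
  expect_equal(res$atoms$category, c("CS", "CS"))
  ap <- atom_params()
  expect_equal(res$category_params$Rmin_A[res$category_params$category == "CS"],
               mean(ap$Rmin_A[ap$element %in% c("C", "S")]))
  # all-hydrogen input populates only the H category
  h <- atom_set(0:2, rep(0, 3), rep(0, 3), rep("H", 3))
  ch <- assign_lj_categories(h)
  expect_equal(ch$category_params$category, "H")
  # category averages equal the brute-force mean over member atoms
  mix <- atom_set(1:6, rep(0, 6), rep(0, 6),
                  c("H", "O", "N", "C", "S", "O"))
  cm <- assign_lj_categories(mix)
  on <- cm$category_params[cm$category_params$category == "ON", ]
  idx <- match(c("O", "N", "O"), ap$element)
  expect_equal(on$epsilon_kJ_mol, mean(ap$epsilon_kJ_mol[idx]))
  # unknown element falls back with a warning
  fe <- suppressWarnings(atom_set(c(0, 1), c(0, 0), c(0, 0),
                                  c("C", "FE")))
  expect_warning(res_fe <- assign_lj_categories(fe), "outside")
  expect_false(anyNA(res_fe$atoms$category))
})

test_that("electrostatic grid matches the screened-Coulomb closed form", {
  one <- atom_set(0, 0, 0, "O", charge_e = 1)
  g <- electrostatic_grid(one, ionic_strength_mM = 0, spacing = 1,
                          margin_A = 15)
  # node exactly 10 A along +x from the charge
  pt <- c(10, 0, 0)
  v <- interpolate_grid(g, pt)$energy
  expect_equal(v, 1389.35458 / (78.5 * 10), tolerance = 1e-9)
  # sign flips with the charge
  gneg <- electrostatic_grid(atom_set(0, 0, 0, "O", charge_e = -1),
                             ionic_strength_mM = 0, spacing = 1,
                             margin_A = 15)
  expect_equal(interpolate_grid(gneg, pt)$energy, -v)
  # screening reduces the magnitude pointwise
  gsalt <- electrostatic_grid(one, ionic_strength_mM = 250, spacing = 1,
                              margin_A = 15)
  expect_lt(interpolate_grid(gsalt, pt)$energy, v)
  expect_gt(interpolate_grid(gsalt, pt)$energy, 0)
})

test_that("LJ grid reproduces the direct pairwise sum", {
  rec <- toy_bead_protein(n_atoms = 10, radius_A = 5, seed = 23)
  cats <- assign_lj_categories(rec)$category_params
  g <- lj_grid(rec, cats, "CS", spacing = 1, margin_A = 20)
  ap <- atom_params()
  cp <- cats[cats$category == "CS", ]
  set.seed(4)
  for (i in 1:20) {
    # random node of the grid, away from clash regions
    pt <- round(runif(3, 8, 15)) * sample(c(-1, 1), 3, TRUE)
    r <- sqrt((rec$x - pt[1])^2 + (rec$y - pt[2])^2 + (rec$z - pt[3])^2)
    idx <- match(rec$element, ap$element)
    Rm <- (cp$Rmin_A + ap$Rmin_A[idx]) / 2
    ep <- sqrt(cp$epsilon_kJ_mol * ap$epsilon_kJ_mol[idx])
    sr6 <- (Rm / r)^6
    direct <- min(sum(ep * (sr6^2 - 2 * sr6)), 100)
    expect_equal(interpolate_grid(g, pt)$energy, direct,
                 tolerance = 1e-9)
  }
  # decay far from all atoms
  expect_lt(abs(interpolate_grid(g, c(24, 24, 24))$energy), 0.05)
  # minimum of the probe-atom pair potential is -epsilon at Rmin
  one <- atom_set(0, 0, 0, "C")
  cats1 <- assign_lj_categories(one)$category_params
  Rmin_ij <- (cats1$Rmin_A + ap$Rmin_A[ap$element == "C"]) / 2
  eps_ij <- sqrt(cats1$epsilon_kJ_mol * ap$epsilon_kJ_mol[ap$element == "C"])
  g1 <- lj_grid(one, cats1, "CS", spacing = 0.25, margin_A = 10)
  expect_equal(interpolate_grid(g1, c(Rmin_ij, 0, 0))$energy, -eps_ij,
               tolerance = 0.01)
})

test_that("Gaussian smoothing preserves constants, mass and width", {
  const <- potential_grid(c(0, 0, 0), 1, array(3.5, c(12, 12, 12)),
                          "electrostatic")
  sm <- smooth_grid(const, 1)
  expect_equal(sm$values, const$values, tolerance = 1e-12)
  # delta spike spreads into a Gaussian of the filter width
  v <- array(0, c(21, 21, 21))
  v[11, 11, 11] <- 1
  spike <- potential_grid(c(-10, -10, -10), 1, v, "electrostatic")
  sm2 <- smooth_grid(spike, 1)
  expect_equal(sum(sm2$values), 1, tolerance = 1e-3)  # mass conserved
  prof <- sm2$values[, 11, 11]
  x <- -10:10
  sigma_hat <- sqrt(sum(prof * x^2) / sum(prof))
  expect_equal(sigma_hat, 1, tolerance = 0.02)
  # two passes of sigma equal one pass of sqrt(2) sigma
  twice <- smooth_grid(smooth_grid(spike, 1), 1)
  once <- smooth_grid(spike, sqrt(2))
  expect_equal(twice$values, once$values, tolerance = 1e-3)
})

test_that("trilinear interpolation is exact on nodes and linear fields", {
  set.seed(8)
  v <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  g <- potential_grid(c(1, 2, 3), 2, v, "electrostatic")
  # node value exactly
  expect_equal(interpolate_grid(g, c(1 + 2 * 2, 2 + 2 * 1, 3 + 2 * 3))$energy,
               v[3, 2, 4])
  # linear field: exact value and gradient anywhere inside
  ax <- c(0.7, -1.3, 0.4)
  lin <- array(0, c(6, 5, 4))
  for (i in 1:6) for (j in 1:5) for (k in 1:4) {
    p <- c(1, 2, 3) + 2 * c(i - 1, j - 1, k - 1)
    lin[i, j, k] <- sum(ax * p) + 5
  }
  gl <- potential_grid(c(1, 2, 3), 2, lin, "electrostatic")
  pt <- c(4.3, 6.1, 5.7)
  r <- interpolate_grid(gl, pt)
  expect_equal(r$energy, sum(ax * pt) + 5, tolerance = 1e-10)
  expect_equal(as.numeric(r$gradient), ax, tolerance = 1e-10)
  # gradient matches central finite differences on a smooth field
  sm <- smooth_grid(g, 2)
  p0 <- c(6, 7, 6)
  grad <- as.numeric(interpolate_grid(sm, p0)$gradient)
  h <- 1e-5
  fd <- vapply(1:3, function(a) {
    dp <- numeric(3); dp[a] <- h
    (interpolate_grid(sm, p0 + dp)$energy -
     interpolate_grid(sm, p0 - dp)$energy) / (2 * h)
  }, numeric(1))
  expect_equal(grad, fd, tolerance = 1e-6)
})

test_that("grid energies converge to the direct sum as spacing shrinks", {
  rec <- toy_two_well_receptor(half_size_A = 15)
  body <- toy_probe_body()
  cats <- assign_lj_categories(body$atoms)$category_params
  st <- rigid_state(c(-10, 3, 9))
  direct <- oracle_pair_energy(body$atoms, st$position, st$orientation,
                               rec$atoms, cats)
  errs <- vapply(c(2, 1, 0.5), function(h) {
    gs <- build_grid_set(rec$atoms, cats, spacing = h, margin_A = 15,
                         smooth_width_A = 0)
    abs(interaction_energy(st, body, gs) - direct)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))      # monotone decrease
  expect_lt(errs[3], 0.15)
})
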