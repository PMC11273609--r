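# Independent oracles and shared fixtures for the test suite.  These
# re-derive expected values from first principles, separately from the
# package implementation.

# Closed-form worm-like-chain interpolation force (pN), written out
# independently of the package's internal helper.
oracle_wlc <- function(extension_nm, contour_nm, persistence_nm,
                       temperature_K) {
  kBT <- 0.01380649 * temperature_K
  x <- extension_nm / contour_nm
  (kBT / persistence_nm) * (1 / (4 * (1 - x)^2) - 1 / 4 + x)
}

# CDF of the truncated-at-10-pN two-component Gaussian rupture mixture.
oracle_mixture_cdf <- function(preset) {
  lo <- function(q) pnorm(q, preset$mu_low_pN, preset$sigma_low_pN)
  hi <- function(q) pnorm(q, preset$mu_high_pN, preset$sigma_high_pN)
  z_lo <- lo(10); z_hi <- hi(10)
  w <- preset$w_low
  function(q) {
    w * (pmax(lo(q) - z_lo, 0) / (1 - z_lo)) +
      (1 - w) * (pmax(hi(q) - z_hi, 0) / (1 - z_hi))
  }
}

# Direct state-machine re-implementation of the hysteretic contact rule.
oracle_hysteresis <- function(d, on_A, off_A) {
  out <- logical(length(d))
  bound <- FALSE
  for (i in seq_along(d)) {
    if (!bound) {
      if (d[i] < on_A) bound <- TRUE
    } else {
      if (d[i] >= off_A) bound <- FALSE
    }
    out[i] <- bound
  }
  out
}

# Brute-force screened-Coulomb + 12-6 LJ energy of a posed body against
# a receptor (kJ/mol), summing atom pairs directly.
oracle_pair_energy <- function(body_atoms, pos, quat, receptor,
                               category_params,
                               ionic_strength_mM = 250,
                               temperature_K = 300, dielectric = 78.5) {
  ap <- atom_params()
  kap <- debye_kappa(ionic_strength_mM, temperature_K, dielectric)
  R <- quat_mat(quat)
  xyz <- as.matrix(body_atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, pos, "+")
  e <- 0
  ridx <- match(receptor$element, ap$element)
  for (i in seq_len(nrow(body_atoms))) {
    r <- sqrt((receptor$x - xyz[i, 1])^2 + (receptor$y - xyz[i, 2])^2 +
              (receptor$z - xyz[i, 3])^2)
    e <- e + sum(1389.35458 * body_atoms$charge_e[i] *
                 receptor$charge_e * exp(-kap * r) / (dielectric * r))
    cp <- category_params[category_params$category ==
                          body_atoms$category[i], ]
    Rm <- (cp$Rmin_A + ap$Rmin_A[ridx]) / 2
    ep <- sqrt(cp$epsilon_kJ_mol * ap$epsilon_kJ_mol[ridx])
    sr6 <- (Rm / r)^6
    e <- e + sum(ep * (sr6^2 - 2 * sr6))
  }
  e
}

# quaternion (w,x,y,z) -> rotation matrix, independent of the package
quat_mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Hamilton product of two quaternions (w,x,y,z)
quat_mul_oracle <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

# Construct a bd_trajectory object directly from a COM path (identity
# orientation), for exercising the contact machinery on controlled
# distance sequences.
fake_trajectory <- function(xyz, time_ns = seq_len(nrow(xyz)) - 1) {
  n <- nrow(xyz)
  frames <- data.frame(time_ns = time_ns, x = xyz[, 1], y = xyz[, 2],
                       z = xyz[, 3], qw = rep(1, n), qx = rep(0, n),
                       qy = rep(0, n), qz = rep(0, n),
                       energy_kJ_mol = rep(0, n))
  structure(list(frames = frames, params = NULL, seed = NA),
            class = "bd_trajectory")
}

# Single-atom mobile body (point probe) with a given charge.
point_probe <- function(charge_e = 1) {
  mobile_body(atom_set(0, 0, 0, "C", charge_e = charge_e),
              surface_only = FALSE)
}
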