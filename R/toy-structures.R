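# Programmatically generated bead-model "proteins" for desk-scale
# simulation and testing: small atom sets standing in for the mobile
# cytochrome and the membrane receptor.

#' Random bead-model protein
#'
#' Atoms drawn uniformly inside a sphere, with a realistic element
#' mixture and an optional net charge spread uniformly over the atoms.
#'
#' @param n_atoms number of atoms.
#' @param radius_A sphere radius (Angstrom).
#' @param net_charge_e total charge (e).
#' @param seed integer seed.
#' @param elements element pool to sample from.
#' @return an `atom_set`.
#' @export
toy_bead_protein <- function(n_atoms = 20, radius_A = 8,
                             net_charge_e = 0, seed = 1,
                             elements = c("C", "C", "C", "N", "O", "S")) {
  .with_seed(seed, {
    u <- matrix(rnorm(3 * n_atoms), ncol = 3)
    u <- u / sqrt(rowSums(u^2)) * radius_A * runif(n_atoms)^(1 / 3)
    atom_set(u[, 1], u[, 2], u[, 3],
             sample(elements, n_atoms, replace = TRUE),
             charge_e = rep(net_charge_e / n_atoms, n_atoms))
  })
}

#' Toy receptor with two engineered binding wells
#'
#' A flat plate of neutral carbon atoms in the z = 0 plane with two
#' charged pockets on top: a deeper "proximal" well (standing in for
#' the electron-transfer site) and a shallower "distal" well (the
#' peripheral ring site).  A positively charged mobile body is
#' attracted to both, more strongly to the proximal one.
#'
#' @param well_charge_proximal,well_charge_distal charges (e, negative
#'   attracts a positive probe) placed at the two sites.
#' @param separation_A distance between the two wells along x.
#' @param half_size_A plate half-extent (Angstrom).
#' @param spacing_A plate atom spacing.
#' @return list with `atoms` (an `atom_set`) and `sites`, a named list
#'   of the annotated `proximal` and `distal` site points (on top of
#'   the wells).
#' @export
toy_two_well_receptor <- function(well_charge_proximal = -6,
                                  well_charge_distal = -2,
                                  separation_A = 30, half_size_A = 25,
                                  spacing_A = 5) {
  gx <- seq(-half_size_A, half_size_A, by = spacing_A)
  plate <- expand.grid(x = gx, y = gx)
  x_p <- -separation_A / 2
  x_d <- separation_A / 2
  xs <- c(plate$x, x_p, x_d)
  ys <- c(plate$y, 0, 0)
  zs <- c(rep(0, nrow(plate)), 2, 2)
  ele <- c(rep("C", nrow(plate)), "O", "O")
  q <- c(rep(0, nrow(plate)), well_charge_proximal, well_charge_distal)
  list(
    atoms = atom_set(xs, ys, zs, ele, charge_e = q),
    sites = list(proximal = c(x_p, 0, 6), distal = c(x_d, 0, 6))
  )
}

#' Toy mobile probe body
#'
#' A compact few-atom body carrying a net positive charge, standing in
#' for the small soluble cytochrome in toy simulations.
#'
#' @param net_charge_e total charge (e).
#' @param temperature_K temperature for the hydrodynamic properties.
#' @return a [mobile_body()].
#' @export
toy_probe_body <- function(net_charge_e = 2, temperature_K = 300) {
  a <- atom_set(
    x = c(0, 1.5, -1.5, 0),
    y = c(0, 0, 0, 1.5),
    z = c(0, 0, 0, 0),
    element = c("C", "N", "O", "C"),
    charge_e = rep(net_charge_e / 4, 4)
  )
  mobile_body(a, temperature_K = temperature_K, surface_only = FALSE)
}
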