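# Precomputed receptor potential grids for BD force evaluation.

#' Assign Lennard-Jones categories to atoms
#'
#' Clusters atoms into the three LJ categories used for grid potentials:
#' `H` (all hydrogens), `ON` (oxygen and nitrogen) and `CS` (carbon and
#' sulfur).  Each category's `Rmin` and `epsilon` are the arithmetic
#' means of the member atoms' per-element parameters from the packaged
#' table.  Elements outside H/C/N/O/S fall back, with a warning, to the
#' nearest category by vdW radius.
#'
#' @param atoms an `atom_set` (or plain data frame with an `element`
#'   column).
#' @param params parameter table (see [atom_params()]).
#' @return list with `atoms` (categories filled in) and
#'   `category_params`, a data frame `category`, `Rmin_A`,
#'   `epsilon_kJ_mol` averaged over the member atoms present.
#' @export
assign_lj_categories <- function(atoms, params = atom_params()) {
  ele <- toupper(atoms$element)
  cat_of <- function(e) {
    if (e == "H") return("H")
    if (e %in% c("O", "N")) return("ON")
    if (e %in% c("C", "S")) return("CS")
    NA_character_
  }
  categ <- vapply(ele, cat_of, character(1))
  if (anyNA(categ)) {
    unknown <- unique(ele[is.na(categ)])
    warning("element(s) ", paste(unknown, collapse = ", "),
            " outside the H/ON/CS clustering; assigning nearest ",
            "category by vdW radius")
    idx <- match(ele, params$element)
    refs <- c(H = params$vdw_radius_A[params$element == "H"],
              ON = mean(params$vdw_radius_A[params$element %in% c("O", "N")]),
              CS = mean(params$vdw_radius_A[params$element %in% c("C", "S")]))
    for (i in which(is.na(categ))) {
      categ[i] <- names(refs)[which.min(abs(refs - params$vdw_radius_A[idx[i]]))]
    }
  }
  atoms$category <- unname(categ)
  idx <- match(ele, params$element)
  cp <- do.call(rbind, lapply(c("H", "ON", "CS"), function(cc) {
    member <- categ == cc
    if (!any(member)) return(NULL)
    data.frame(category = cc,
               Rmin_A = mean(params$Rmin_A[idx[member]]),
               epsilon_kJ_mol = mean(params$epsilon_kJ_mol[idx[member]]),
               stringsAsFactors = FALSE)
  }))
  list(atoms = atoms, category_params = cp)
}

#' Construct a potential grid
#'
#' @param origin length-3 origin of the first node (Angstrom).
#' @param spacing node spacing (Angstrom).
#' @param values 3-D array of node values (kJ/mol, per unit probe
#'   charge for electrostatic grids).
#' @param kind one of `"electrostatic"`, `"LJ_H"`, `"LJ_ON"`, `"LJ_CS"`.
#' @return list of class `potential_grid`.
#' @export
potential_grid <- function(origin, spacing, values, kind) {
  stopifnot(length(origin) == 3, spacing > 0, length(dim(values)) == 3,
            all(dim(values) >= 2), all(is.finite(values)))
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = dim(values), values = values, kind = kind),
            class = "potential_grid")
}

# node coordinate vectors along each axis
.grid_axes <- function(grid) {
  lapply(1:3, function(a) {
    grid$origin[a] + grid$spacing * (seq_len(grid$dims[a]) - 1)
  })
}

# default grid frame: receptor bounding box plus margin
.grid_frame <- function(receptor, spacing, margin_A = 30) {
  xyz <- as.matrix(receptor[, c("x", "y", "z")])
  lo <- floor(apply(xyz, 2, min) - margin_A)
  dims <- ceiling((apply(xyz, 2, max) + margin_A - lo) / spacing) + 1
  list(origin = lo, dims = as.integer(dims))
}

#' Debye-Hueckel electrostatic grid of a receptor
#'
#' Screened-Coulomb potential energy of a unit positive probe charge,
#' summed over the receptor partial charges at every node:
#' `V(r) = ke * sum_i q_i exp(-r_i/lambda) / (eps_r r_i)` with relative
#' dielectric 78.5 and the Debye length computed from the ionic
#' strength at the given temperature.  Distances are floored at a small
#' softening radius so node values stay finite inside atoms (clashes
#' are governed by the LJ grids).
#'
#' @param receptor an `atom_set` with charges.
#' @param ionic_strength_mM ionic strength (mM); 0 gives unscreened
#'   Coulomb.
#' @param temperature_K temperature (K).
#' @param spacing grid spacing (Angstrom), default 1.
#' @param margin_A margin beyond the receptor bounding box.
#' @param dielectric relative dielectric constant.
#' @return a `potential_grid` of kind `"electrostatic"` (kJ/mol per e).
#' @export
electrostatic_grid <- function(receptor, ionic_strength_mM = 250,
                               temperature_K = 300, spacing = 1,
                               margin_A = 30, dielectric = 78.5) {
  stopifnot(inherits(receptor, "atom_set"), spacing > 0,
            ionic_strength_mM >= 0)
  fr <- .grid_frame(receptor, spacing, margin_A)
  ax <- lapply(1:3, function(a) fr$origin[a] + spacing * (seq_len(fr$dims[a]) - 1))
  kappa <- debye_kappa(ionic_strength_mM, temperature_K, dielectric)
  vals <- array(0, fr$dims)
  nx <- fr$dims[1]; ny <- fr$dims[2]; nz <- fr$dims[3]
  X <- rep(ax[[1]], times = ny * nz)
  Y <- rep(rep(ax[[2]], each = nx), times = nz)
  Z <- rep(ax[[3]], each = nx * ny)
  v <- numeric(length(X))
  for (i in seq_len(nrow(receptor))) {
    q <- receptor$charge_e[i]
    if (q == 0) next
    r <- sqrt((X - receptor$x[i])^2 + (Y - receptor$y[i])^2 +
              (Z - receptor$z[i])^2)
    r <- pmax(r, 0.5 * spacing)
    v <- v + .ke_kJ_A * q * exp(-kappa * r) / (dielectric * r)
  }
  potential_grid(fr$origin, spacing, array(v, fr$dims), "electrostatic")
}

#' Inverse Debye length
#'
#' @param ionic_strength_mM ionic strength (mM).
#' @param temperature_K temperature (K).
#' @param dielectric relative dielectric constant.
#' @return kappa in 1/Angstrom (0 at zero ionic strength).
#' @export
debye_kappa <- function(ionic_strength_mM, temperature_K = 300,
                        dielectric = 78.5) {
  if (ionic_strength_mM <= 0) return(0)
  I <- ionic_strength_mM * 1e-3 * 1e3        # mol/m^3
  eps0 <- 8.8541878128e-12
  e <- 1.602176634e-19
  kB <- 1.380649e-23
  lambda_m <- sqrt(dielectric * eps0 * kB * temperature_K /
                   (2 * .NA_mol * e^2 * I))
  1e-10 / lambda_m                            # 1/Angstrom
}

#' Lennard-Jones category grid of a receptor
#'
#' At each node, the 12-6 interaction energy of one probe atom of the
#' given category with every receptor atom, using Lorentz-Berthelot
#' combining of the probe category parameters with the receptor atoms'
#' per-element parameters, capped at `cap_kJ_mol` so clash regions stay
#' finite.
#'
#' @param receptor an `atom_set`.
#' @param category_params category parameter frame from
#'   [assign_lj_categories()] of the *mobile* body.
#' @param category probe category, `"H"`, `"ON"` or `"CS"`.
#' @param spacing grid spacing (Angstrom).
#' @param cap_kJ_mol ceiling for repulsive values (default +100).
#' @param margin_A margin beyond the receptor bounding box.
#' @param params per-element parameter table for the receptor atoms.
#' @return a `potential_grid` of kind `paste0("LJ_", category)`.
#' @export
lj_grid <- function(receptor, category_params, category, spacing = 1,
                    cap_kJ_mol = 100, margin_A = 30,
                    params = atom_params()) {
  stopifnot(inherits(receptor, "atom_set"),
            category %in% c("H", "ON", "CS"))
  cp <- category_params[category_params$category == category, ]
  if (nrow(cp) != 1L) stop("no parameters for category ", category)
  fr <- .grid_frame(receptor, spacing, margin_A)
  ax <- lapply(1:3, function(a) fr$origin[a] + spacing * (seq_len(fr$dims[a]) - 1))
  nx <- fr$dims[1]; ny <- fr$dims[2]; nz <- fr$dims[3]
  X <- rep(ax[[1]], times = ny * nz)
  Y <- rep(rep(ax[[2]], each = nx), times = nz)
  Z <- rep(ax[[3]], each = nx * ny)
  idx <- match(receptor$element, params$element)
  v <- numeric(length(X))
  for (i in seq_len(nrow(receptor))) {
    Rmin_ij <- (cp$Rmin_A + params$Rmin_A[idx[i]]) / 2
    eps_ij <- sqrt(cp$epsilon_kJ_mol * params$epsilon_kJ_mol[idx[i]])
    r <- sqrt((X - receptor$x[i])^2 + (Y - receptor$y[i])^2 +
              (Z - receptor$z[i])^2)
    r <- pmax(r, 1e-3)
    sr6 <- (Rmin_ij / r)^6
    v <- v + eps_ij * (sr6^2 - 2 * sr6)
  }
  v <- pmin(v, cap_kJ_mol)
  potential_grid(fr$origin, spacing, array(v, fr$dims),
                 paste0("LJ_", category))
}

#' Gaussian smoothing of a potential grid
#'
#' Separable 3-D Gaussian convolution with standard deviation `width_A`
#' (in Angstrom, converted to voxels), nearest-value padding at the
#' edges.
#'
#' @param grid a `potential_grid`.
#' @param width_A filter width (Angstrom), default 1.
#' @return the smoothed `potential_grid`.
#' @export
smooth_grid <- function(grid, width_A = 1.0) {
  stopifnot(inherits(grid, "potential_grid"), width_A >= 0)
  if (width_A == 0) return(grid)
  sigma <- width_A / grid$spacing
  rad <- max(1L, ceiling(3 * sigma))
  kern <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  v <- grid$values
  for (axis in 1:3) {
    v <- .conv_axis(v, kern, axis)
  }
  grid$values <- v
  grid
}

# 1-D convolution along one axis of a 3-D array with nearest padding
.conv_axis <- function(v, kern, axis) {
  d <- dim(v)
  rad <- (length(kern) - 1L) / 2L
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  vp <- aperm(v, perm)
  dp <- dim(vp)
  m <- matrix(vp, nrow = dp[1])
  n <- nrow(m)
  padded <- rbind(m[rep(1L, rad), , drop = FALSE], m,
                  m[rep(n, rad), , drop = FALSE])
  out <- matrix(0, n, ncol(m))
  for (k in seq_along(kern)) {
    out <- out + kern[k] * padded[(k - 1L) + seq_len(n), , drop = FALSE]
  }
  inv <- order(perm)
  aperm(array(out, dp), inv)
}

#' Trilinear interpolation of a grid with analytic gradient
#'
#' Returns the trilinearly interpolated energy and its analytic gradient
#' at arbitrary points.  Points outside the grid are clamped to the
#' boundary for the grid contribution and receive an additional harmonic
#' restoring-wall energy `0.5 * k_wall * d^2` (gradient included), where
#' `d` is the distance outside the box; this is the out-of-bounds policy
#' of the BD propagator.
#'
#' @param grid a `potential_grid`.
#' @param points numeric matrix (n x 3) or length-3 vector (Angstrom).
#' @param k_wall harmonic wall constant (kJ/mol/Angstrom^2).
#' @return list with `energy` (length n) and `gradient` (n x 3).
#' @export
interpolate_grid <- function(grid, points, k_wall = 10) {
  stopifnot(inherits(grid, "potential_grid"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  res <- cpp_interp_trilinear(grid$values, grid$origin, grid$spacing,
                              points, k_wall)
  list(energy = res$energy, gradient = res$gradient)
}
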