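# Rigid-body mechanical and hydrodynamic properties of the mobile protein.

#' Packaged per-element parameter table
#'
#' Masses, van der Waals radii, Lennard-Jones `Rmin`/`epsilon` and
#' default partial charges per element.  LJ values are generic
#' protein-force-field-scale parameters (full `Rmin` in Angstrom,
#' `epsilon` in kJ/mol).
#'
#' @return data frame with one row per element.
#' @export
atom_params <- function() {
  read.delim(system.file("extdata", "atom_params.tsv",
                         package = "smfsbd"),
             stringsAsFactors = FALSE)
}

#' Construct an atom set
#'
#' @param x,y,z coordinates (Angstrom).
#' @param element element symbols (e.g. `"C"`, `"FE"`).
#' @param charge_e partial charges (e); defaults from the packaged
#'   parameter table.
#' @param params parameter table (see [atom_params()]).
#' @return data frame of class `atom_set` with columns `x`, `y`, `z`,
#'   `element`, `mass_amu`, `charge_e`, `category`.
#' @export
atom_set <- function(x, y, z, element, charge_e = NULL,
                     params = atom_params()) {
  stopifnot(length(x) >= 1, length(x) == length(y),
            length(x) == length(z), length(x) == length(element))
  stopifnot(all(is.finite(c(x, y, z))))
  element <- toupper(element)
  idx <- match(element, params$element)
  if (anyNA(idx)) {
    bad <- unique(element[is.na(idx)])
    stop("unknown element(s): ", paste(bad, collapse = ", "))
  }
  a <- data.frame(
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    element = element,
    mass_amu = params$mass_amu[idx],
    charge_e = if (is.null(charge_e)) params$default_charge_e[idx]
               else as.numeric(charge_e),
    category = NA_character_,
    stringsAsFactors = FALSE
  )
  class(a) <- c("atom_set", "data.frame")
  assign_lj_categories(a, params)$atoms
}

#' Load a structure from a PDB file
#'
#' Reads ATOM and HETATM records through bio3d, infers elements from the
#' element column (falling back to the first letter of the atom name)
#' and attaches masses, default charges and LJ categories from the
#' packaged parameter table.
#'
#' @param path path to a PDB-format file.
#' @param charge_e optional per-atom charge vector (e), in file order.
#' @return an `atom_set`.
#' @export
load_structure <- function(path, charge_e = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e) stop("failed to parse PDB file '",
                                           path, "': ", conditionMessage(e)))
  at <- pdb$atom
  ele <- toupper(trimws(at$elesy))
  missing <- is.na(ele) | ele == ""
  ele[missing] <- substr(gsub("[^A-Za-z].*", "", trimws(at$elety[missing])),
                         1, 1)
  atom_set(at$x, at$y, at$z, ele, charge_e = charge_e)
}

#' Write an atom set to a PDB file
#'
#' @param atoms an `atom_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path) {
  stopifnot(inherits(atoms, "atom_set"))
  n <- nrow(atoms)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                   type = rep("ATOM", n),
                   elety = atoms$element,
                   resno = seq_len(n),
                   resid = rep("TOY", n),
                   chain = rep("A", n),
                   elesy = atoms$element)
  invisible(path)
}

#' Mass, centre of mass and inertia tensor
#'
#' Standard rigid-body sums over point masses, with the inertia tensor
#' taken about the centre of mass.
#'
#' @param atoms an `atom_set`.
#' @return list with `mass_amu`, `com` (length-3, Angstrom) and
#'   `inertia` (3x3, amu Angstrom^2).
#' @export
mass_and_inertia <- function(atoms) {
  stopifnot(inherits(atoms, "atom_set"), nrow(atoms) >= 1)
  m <- atoms$mass_amu
  if (sum(m) <= 0) stop("zero total mass")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  com <- colSums(xyz * m) / sum(m)
  r <- sweep(xyz, 2, com)
  r2 <- rowSums(r^2)
  I <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3) {
    I[a, b] <- sum(m * ((a == b) * r2 - r[, a] * r[, b]))
  }
  list(mass_amu = sum(m), com = unname(com), inertia = I)
}

# Discretised rolling-probe surface test: a probe position is solvent if
# it clears every atom's vdW radius by the probe radius; an atom is
# surface if some solvent node on a 1 A grid lies within reach of a
# probe touching it.
.surface_atoms <- function(atoms, probe_A = 1.4, grid_A = 1.0,
                           params = atom_params()) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rv <- params$vdw_radius_A[match(atoms$element, params$element)]
  pad <- max(rv) + probe_A + 2 * grid_A
  gx <- seq(min(xyz[, 1]) - pad, max(xyz[, 1]) + pad, by = grid_A)
  gy <- seq(min(xyz[, 2]) - pad, max(xyz[, 2]) + pad, by = grid_A)
  gz <- seq(min(xyz[, 3]) - pad, max(xyz[, 3]) + pad, by = grid_A)
  nodes <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  # clearance of each node above the nearest vdW surface
  clear <- rep(Inf, nrow(nodes))
  nearest <- matrix(Inf, nrow(nodes), nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    d <- sqrt((nodes[, 1] - xyz[i, 1])^2 + (nodes[, 2] - xyz[i, 2])^2 +
              (nodes[, 3] - xyz[i, 3])^2)
    nearest[, i] <- d
    clear <- pmin(clear, d - rv[i])
  }
  solvent <- clear >= probe_A
  reach <- rv + probe_A + grid_A  # one-node slack for discretisation
  vapply(seq_len(nrow(atoms)), function(i) {
    any(solvent & nearest[, i] <= reach[i])
  }, logical(1))
}

#' Bead-model translational and rotational diffusion coefficients
#'
#' Surface atoms (identified with a discretised rolling-probe test) are
#' replaced by Stokes beads of a common hydrodynamic radius, and the
#' translational diffusion tensor is estimated with the Kirkwood
#' double-sum approximation built from the diagonal Oseen tensor:
#' \deqn{D_{\alpha\beta} = \frac{k_BT}{N^2}\Big[\delta_{\alpha\beta}
#'   \sum_i \frac{1}{6\pi\eta a} + \sum_{i\neq j}
#'   \frac{\delta_{\alpha\beta} + \hat R_\alpha \hat R_\beta}
#'        {8\pi\eta R_{ij}}\Big]}
#' Off-diagonal translation-rotation coupling is dropped; the three
#' eigenvalues (the diagonal in the principal frame) are returned.
#' Rotational diffusion uses the equivalent-sphere radius implied by the
#' mean translational coefficient.
#'
#' @param atoms an `atom_set` (every atom is a bead when `surface_only`
#'   is `FALSE` or the structure has 3 atoms or fewer).
#' @param temperature_K temperature (K).
#' @param viscosity_Pa_s solvent viscosity (Pa s); default water at
#'   ~300 K.
#' @param bead_radius_A hydrodynamic bead radius (Angstrom); default
#'   2.3 = 1.2 atomic + 1.1 hydration.
#' @param surface_only replace only rolling-probe surface atoms by
#'   beads (the bead-shell model); interior atoms carry no drag.
#' @return list with `D_trans_A2_ns` (3 eigenvalues, Angstrom^2/ns),
#'   `D_rot_rad2_ns` (3 values, rad^2/ns), `n_beads`, and the implied
#'   `stokes_radius_A`.
#' @examples
#' one <- atom_set(0, 0, 0, "C")
#' diffusion_coefficients(one, bead_radius_A = 20)$D_trans_A2_ns
#' @export
diffusion_coefficients <- function(atoms, temperature_K = 300,
                                   viscosity_Pa_s = 0.89e-3,
                                   bead_radius_A = 2.3,
                                   surface_only = TRUE) {
  stopifnot(inherits(atoms, "atom_set"), nrow(atoms) >= 1)
  use <- if (surface_only && nrow(atoms) > 3L) {
    s <- .surface_atoms(atoms)
    if (!any(s)) rep(TRUE, nrow(atoms)) else s
  } else rep(TRUE, nrow(atoms))
  xyz <- as.matrix(atoms[use, c("x", "y", "z"), drop = FALSE])
  N <- nrow(xyz)
  kT <- 1.380649e-23 * temperature_K            # J
  a_m <- bead_radius_A * 1e-10
  eta <- viscosity_Pa_s

  D <- diag(3) * N * kT / (6 * pi * eta * a_m)  # self terms
  if (N > 1) {
    for (i in seq_len(N - 1)) {
      for (j in (i + 1):N) {
        Rv <- (xyz[j, ] - xyz[i, ]) * 1e-10
        R <- sqrt(sum(Rv^2))
        if (R <= 0) next
        Rh <- Rv / R
        D <- D + 2 * kT * (diag(3) + outer(Rh, Rh)) / (8 * pi * eta * R)
      }
    }
  }
  D <- D / N^2                                   # m^2/s tensor
  ev <- eigen(D, symmetric = TRUE)$values        # principal frame
  D_trans <- ev * 1e11                           # -> Angstrom^2/ns
  a_eq <- kT / (6 * pi * eta * mean(ev))         # equivalent sphere (m)
  D_rot <- kT / (8 * pi * eta * a_eq^3) * 1e-9   # rad^2/ns
  list(
    D_trans_A2_ns = D_trans,
    D_rot_rad2_ns = rep(D_rot, 3),
    n_beads = N,
    stokes_radius_A = a_eq * 1e10
  )
}

#' Friction coefficients from diffusion coefficients
#'
#' Stokes-Einstein inversion: `friction = kBT / D`, componentwise, on
#' the simulation energy scale (kJ/mol).
#'
#' @param D diffusion coefficients (Angstrom^2/ns for translation,
#'   rad^2/ns for rotation); all entries must be positive.
#' @param temperature_K temperature (K).
#' @return friction coefficients (kJ/mol ns / Angstrom^2 or
#'   kJ/mol ns / rad^2), same shape as `D`.
#' @export
friction_from_diffusion <- function(D, temperature_K = 300) {
  if (any(D <= 0)) stop("diffusion coefficients must be positive")
  kBT(temperature_K, "kJ_mol") / D
}

#' Assemble a rigid mobile body
#'
#' Bundles the atoms (re-centred on the centre of mass), mass, inertia
#' tensor and diffusion/friction coefficients needed by the BD
#' propagator.
#'
#' @param atoms an `atom_set`.
#' @param temperature_K temperature (K).
#' @param ... passed to [diffusion_coefficients()].
#' @return A list of class `mobile_body`: `atoms` (body frame, COM at
#'   the origin), `mass_amu`, `inertia`, `D_trans_A2_ns`,
#'   `D_rot_rad2_ns`, `friction_trans`, `friction_rot`,
#'   `temperature_K`.
#' @export
mobile_body <- function(atoms, temperature_K = 300, ...) {
  mi <- mass_and_inertia(atoms)
  dc <- diffusion_coefficients(atoms, temperature_K = temperature_K, ...)
  body_atoms <- atoms
  body_atoms$x <- atoms$x - mi$com[1]
  body_atoms$y <- atoms$y - mi$com[2]
  body_atoms$z <- atoms$z - mi$com[3]
  structure(
    list(
      atoms = body_atoms,
      mass_amu = mi$mass_amu,
      inertia = mi$inertia,
      D_trans_A2_ns = dc$D_trans_A2_ns,
      D_rot_rad2_ns = dc$D_rot_rad2_ns,
      friction_trans = friction_from_diffusion(dc$D_trans_A2_ns,
                                               temperature_K),
      friction_rot = friction_from_diffusion(dc$D_rot_rad2_ns,
                                             temperature_K),
      temperature_K = temperature_K
    ),
    class = "mobile_body"
  )
}
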