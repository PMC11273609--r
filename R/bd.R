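# R interface to the overdamped rigid-body BD propagator.

#' BD run parameters
#'
#' @param timestep_fs integration time step (fs), default 100.
#' @param temperature_K bath temperature (K), default 300.
#' @param record_every_ns frame recording interval (ns), default 1.
#' @param duration_ns trajectory length (ns).
#' @param n_replicas number of independent replicas.
#' @param seed integer seed.
#' @return list of class `bd_params`.
#' @export
bd_params <- function(timestep_fs = 100, temperature_K = 300,
                      record_every_ns = 1, duration_ns = 1000,
                      n_replicas = 1L, seed = 1L) {
  stopifnot(timestep_fs > 0, duration_ns > 0, record_every_ns > 0,
            temperature_K >= 0, n_replicas >= 1)
  dt_ns <- timestep_fs * 1e-6
  rec <- max(1L, round(record_every_ns / dt_ns))
  structure(
    list(timestep_fs = timestep_fs, dt_ns = dt_ns,
         temperature_K = temperature_K,
         record_every_ns = record_every_ns, record_every_steps = rec,
         duration_ns = duration_ns,
         n_steps = round(duration_ns / dt_ns),
         n_replicas = as.integer(n_replicas), seed = as.integer(seed)),
    class = "bd_params"
  )
}

#' Rigid-body state
#'
#' @param position COM position (Angstrom, length 3).
#' @param orientation unit quaternion `(w, x, y, z)`; renormalised.
#' @param time_ns time stamp (ns).
#' @return list of class `rigid_state`.
#' @export
rigid_state <- function(position = c(0, 0, 0),
                        orientation = c(1, 0, 0, 0), time_ns = 0) {
  stopifnot(length(position) == 3, length(orientation) == 4)
  n <- sqrt(sum(orientation^2))
  stopifnot(n > 0)
  structure(list(position = as.numeric(position),
                 orientation = as.numeric(orientation) / n,
                 time_ns = time_ns),
            class = "rigid_state")
}

# marshal body + grids for the C++ core
.bd_args <- function(body, grids) {
  stopifnot(inherits(body, "mobile_body"))
  atoms <- as.matrix(body$atoms[, c("x", "y", "z")])
  cat_idx <- match(body$atoms$category, c("H", "ON", "CS")) - 1L
  cat_idx[is.na(cat_idx)] <- -1L
  glist <- list()
  if (!is.null(grids)) {
    stopifnot(inherits(grids, "grid_set") || is.list(grids))
    for (nm in names(grids)) {
      g <- grids[[nm]]
      glist[[nm]] <- list(values = g$values, origin = g$origin,
                          spacing = g$spacing)
    }
  }
  list(atoms = atoms, charge = body$atoms$charge_e, cat = cat_idx,
       grids = glist)
}

# confinement box from the grid frame (inset by one spacing), or an
# explicit box
.bd_box <- function(grids, box = NULL) {
  if (!is.null(box)) {
    return(list(lo = box[1, ], hi = box[2, ]))
  }
  if (is.null(grids) || length(grids) == 0) {
    return(list(lo = numeric(0), hi = numeric(0)))
  }
  g <- grids[[1]]
  list(lo = g$origin + g$spacing,
       hi = g$origin + g$spacing * (g$dims - 2))
}

.ext_code <- function(external) {
  if (is.null(external)) return(list(type = 0L, par = numeric(0)))
  type <- match.arg(external$type, c("harmonic", "double_well"))
  if (type == "harmonic") {
    list(type = 1L, par = c(external$k, external$center))
  } else {
    list(type = 2L,
         par = c(external$height, external$center, external$half_sep))
  }
}

#' Advance a rigid body by one (or a few) BD steps
#'
#' Overdamped (Ermak-McCammon) update per principal body axis:
#' `dx = (D/kBT) F dt + sqrt(2 D dt) xi`, with the rotational analogue
#' applied in the body frame and the quaternion renormalised each step.
#' Fluctuation-dissipation holds by construction.  With
#' `thermal = FALSE` the noise term is switched off (the T -> 0
#' deterministic limit used by tests).
#'
#' @param state a [rigid_state()].
#' @param body a [mobile_body()].
#' @param grids a `grid_set` (or `NULL` for free diffusion).
#' @param params a [bd_params()].
#' @param n_steps number of elementary steps to take (default 1).
#' @param external optional external test potential acting on the COM:
#'   `list(type = "harmonic", k =, center =)` or
#'   `list(type = "double_well", height =, center =, half_sep =)`
#'   (1-D in x).
#' @param box optional 2x3 matrix (rows lo, hi) for the confining
#'   harmonic wall; defaults to the grid frame.
#' @param k_wall wall stiffness (kJ/mol/Angstrom^2).
#' @param thermal include the stochastic term.
#' @return the updated `rigid_state`.
#' @export
bd_step <- function(state, body, grids = NULL, params = bd_params(),
                    n_steps = 1L, external = NULL, box = NULL,
                    k_wall = 10, thermal = TRUE) {
  a <- .bd_args(body, grids)
  bx <- .bd_box(grids, box)
  ex <- .ext_code(external)
  res <- cpp_bd_run(a$atoms, a$charge, a$cat, a$grids,
                    body$D_trans_A2_ns, body$D_rot_rad2_ns,
                    params$temperature_K, params$dt_ns, n_steps,
                    as.integer(n_steps), state$position,
                    state$orientation, ex$type, ex$par, bx$lo, bx$hi,
                    k_wall, thermal, FALSE, 0, numeric(3), numeric(3))
  m <- nrow(res$positions)
  rigid_state(res$positions[m, ], res$quaternions[m, ],
              state$time_ns + n_steps * params$dt_ns)
}

#' Run a BD trajectory
#'
#' Repeated overdamped steps from a start pose, recording the state and
#' the body-receptor interaction energy every `record_every_ns`.
#' Deterministic for a fixed seed.
#'
#' @inheritParams bd_step
#' @param start starting [rigid_state()].
#' @param seed integer seed; defaults to `params$seed`.
#' @return A list of class `bd_trajectory`: `frames` (data frame with
#'   `time_ns`, `x`, `y`, `z`, `qw`, `qx`, `qy`, `qz`,
#'   `energy_kJ_mol`), plus `params`, `seed`.
#' @export
run_trajectory <- function(body, grids = NULL, params = bd_params(),
                           start = rigid_state(), external = NULL,
                           box = NULL, k_wall = 10, thermal = TRUE,
                           seed = params$seed) {
  a <- .bd_args(body, grids)
  bx <- .bd_box(grids, box)
  ex <- .ext_code(external)
  res <- .with_seed(seed,
    cpp_bd_run(a$atoms, a$charge, a$cat, a$grids, body$D_trans_A2_ns,
               body$D_rot_rad2_ns, params$temperature_K, params$dt_ns,
               params$n_steps, params$record_every_steps,
               start$position, start$orientation, ex$type, ex$par,
               bx$lo, bx$hi, k_wall, thermal, FALSE, 0, numeric(3),
               numeric(3)))
  frames <- data.frame(
    time_ns = res$time_ns,
    x = res$positions[, 1], y = res$positions[, 2],
    z = res$positions[, 3],
    qw = res$quaternions[, 1], qx = res$quaternions[, 2],
    qy = res$quaternions[, 3], qz = res$quaternions[, 4],
    energy_kJ_mol = res$energy_kJ_mol
  )
  structure(list(frames = frames, params = params, seed = seed),
            class = "bd_trajectory")
}

#' Interaction energy of a pose
#'
#' Sum of electrostatic (charge times potential) and per-category LJ
#' grid energies over the body atoms after the rigid transform.
#'
#' @param state a [rigid_state()].
#' @param body a [mobile_body()].
#' @param grids a `grid_set`.
#' @return energy in kJ/mol.
#' @export
interaction_energy <- function(state, body, grids) {
  a <- .bd_args(body, grids)
  cpp_pose_energy(a$atoms, a$charge, a$cat, a$grids, state$position,
                  state$orientation)
}

#' Steered pulling of the mobile body along a path
#'
#' The COM is harmonically restrained to a point moving at constant
#' velocity from `path_start` to `path_end`; orientation stays free.
#' Records the interaction energy against the COM-site distance
#' (reaction coordinate), where the site defaults to `path_end`.
#'
#' @param body a [mobile_body()].
#' @param grids a `grid_set`.
#' @param path_start,path_end endpoints of the pulling path (Angstrom).
#' @param velocity_A_per_ns restraint-point speed (Angstrom/ns); the
#'   reference study's value is 0.05.
#' @param spring_k restraint stiffness (kJ/mol/Angstrom^2).
#' @param params a [bd_params()]; its `duration_ns` is overridden by
#'   the path length / velocity.
#' @param site reference point for the reaction coordinate.
#' @param seed integer seed.
#' @return A data frame of class `pull_profile`: `time_ns`,
#'   `reaction_coord_A` (COM-site distance), `energy_kJ_mol`, `x`, `y`,
#'   `z`.
#' @export
steered_pull <- function(body, grids, path_start, path_end,
                         velocity_A_per_ns = 0.05, spring_k = 5,
                         params = bd_params(), site = path_end,
                         seed = params$seed) {
  stopifnot(length(path_start) == 3, length(path_end) == 3)
  path <- as.numeric(path_end) - as.numeric(path_start)
  L <- sqrt(sum(path^2))
  stopifnot(L > 0, velocity_A_per_ns > 0)
  duration <- L / velocity_A_per_ns
  params$n_steps <- round(duration / params$dt_ns)
  vel <- path / L * velocity_A_per_ns
  a <- .bd_args(body, grids)
  bx <- .bd_box(grids, NULL)
  res <- .with_seed(seed,
    cpp_bd_run(a$atoms, a$charge, a$cat, a$grids, body$D_trans_A2_ns,
               body$D_rot_rad2_ns, params$temperature_K, params$dt_ns,
               params$n_steps, params$record_every_steps,
               as.numeric(path_start), c(1, 0, 0, 0), 0L, numeric(0),
               bx$lo, bx$hi, 10, TRUE, TRUE, spring_k,
               as.numeric(path_start), vel))
  rc <- sqrt((res$positions[, 1] - site[1])^2 +
             (res$positions[, 2] - site[2])^2 +
             (res$positions[, 3] - site[3])^2)
  out <- data.frame(time_ns = res$time_ns, reaction_coord_A = rc,
                    energy_kJ_mol = res$energy_kJ_mol,
                    x = res$positions[, 1], y = res$positions[, 2],
                    z = res$positions[, 3])
  class(out) <- c("pull_profile", "data.frame")
  out
}
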