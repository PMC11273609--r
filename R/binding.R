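# Contact kinetics, pose clustering, occupancy affinities and
# intermediate-state detection.

# quaternion (w,x,y,z) -> rotation matrix (body -> world)
.quat_to_mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# hysteretic bound flags from a min-distance series
.hysteresis_flags <- function(d, on_A, off_A) {
  bound <- logical(length(d))
  state <- FALSE
  for (i in seq_along(d)) {
    if (!state && d[i] < on_A) state <- TRUE
    else if (state && d[i] >= off_A) state <- FALSE
    bound[i] <- state
  }
  bound
}

#' Contact series of a trajectory against a receptor
#'
#' Computes, per recorded frame, the minimum heavy-atom distance between
#' the transformed mobile body and the receptor, and derives a
#' hysteretic bound flag: contact is established when any heavy-atom
#' pair comes within `on_A` (default 7 Angstrom) and lost only once no
#' pair remains within `off_A` (default 16 Angstrom), which suppresses
#' boundary flicker.
#'
#' @param traj a `bd_trajectory` (see [run_trajectory()]).
#' @param body a [mobile_body()].
#' @param receptor an `atom_set`.
#' @param on_A,off_A hysteresis thresholds (Angstrom); `on_A <= off_A`.
#' @return A list of class `contact_series`: `frames` (data frame with
#'   `time_ns`, `min_dist_A`, `bound`, `x`, `y`, `z`), and `intervals`
#'   (data frame of bound intervals with `start_ns`, `end_ns`,
#'   `duration_ns`).
#' @export
contact_series <- function(traj, body, receptor, on_A = 7, off_A = 16) {
  stopifnot(inherits(traj, "bd_trajectory"), on_A <= off_A)
  fr <- traj$frames
  if (nrow(fr) == 0L) stop("empty trajectory")
  heavy_b <- body$atoms[body$atoms$element != "H", c("x", "y", "z")]
  heavy_r <- as.matrix(receptor[receptor$element != "H",
                                c("x", "y", "z")])
  bm <- as.matrix(heavy_b)
  mind <- vapply(seq_len(nrow(fr)), function(i) {
    R <- .quat_to_mat(c(fr$qw[i], fr$qx[i], fr$qy[i], fr$qz[i]))
    pw <- bm %*% t(R)
    pw <- sweep(pw, 2, c(fr$x[i], fr$y[i], fr$z[i]), "+")
    sqrt(min(outer(rowSums(pw^2), rowSums(heavy_r^2), "+") -
             2 * pw %*% t(heavy_r)))
  }, numeric(1))
  bound <- .hysteresis_flags(mind, on_A, off_A)
  frames <- data.frame(time_ns = fr$time_ns, min_dist_A = mind,
                       bound = bound, x = fr$x, y = fr$y, z = fr$z)
  r <- rle(bound)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  iv <- data.frame(start_ns = fr$time_ns[starts[r$values]],
                   end_ns = fr$time_ns[ends[r$values]])
  iv$duration_ns <- iv$end_ns - iv$start_ns
  structure(list(frames = frames, intervals = iv,
                 on_A = on_A, off_A = off_A),
            class = "contact_series")
}

#' Cluster bound poses into binding sites
#'
#' Single-linkage clustering of the COM positions of bound frames,
#' cut at the linkage distance.  Each cluster is labelled by the
#' nearest annotated receptor site (an electron-transfer site point vs
#' a peripheral-ring point supplied with the receptor fixture):
#' `"proximal"`, `"distal"`, or `"other"` when no site is within
#' `label_within_A`.  Clusters whose mean interface (minimum heavy-atom)
#' distance exceeds `max_interface_A` are discarded.
#'
#' @param series a [contact_series()] (its bound frames carry COM
#'   positions and interface distances).
#' @param sites named list of length-3 points: `proximal` (the ET
#'   site) and `distal` (the peripheral site).
#' @param linkage_A single-linkage cut distance (Angstrom), default 8.
#' @param max_interface_A pose filter: clusters farther than this from
#'   the receptor surface are dropped (default 10).
#' @param label_within_A labelling radius around an annotated site.
#' @return A data frame of class `pose_clusters`, one row per cluster:
#'   `cluster`, `site`, `n_frames`, `occupancy` (fraction of all
#'   frames), `cx`, `cy`, `cz` (representative = medoid),
#'   `mean_interface_A`.  The bound fraction not covered by clusters
#'   plus the cluster occupancies plus the unbound fraction sums to 1.
#' @export
cluster_poses <- function(series, sites, linkage_A = 8,
                          max_interface_A = 10, label_within_A = 20) {
  stopifnot(inherits(series, "contact_series"))
  fr <- series$frames
  b <- fr[fr$bound, , drop = FALSE]
  if (nrow(b) == 0L) stop("no bound frames to cluster")
  xyz <- as.matrix(b[, c("x", "y", "z")])
  cl <- if (nrow(b) == 1L) 1L else {
    cutree(hclust(dist(xyz), method = "single"), h = linkage_A)
  }
  n_total <- nrow(fr)
  out <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    member <- cl == k
    pts <- xyz[member, , drop = FALSE]
    # medoid representative
    if (nrow(pts) == 1L) rep_i <- 1L else {
      dm <- as.matrix(dist(pts))
      rep_i <- which.min(rowSums(dm))
    }
    ctr <- pts[rep_i, ]
    site <- "other"
    if (length(sites)) {
      ds <- vapply(sites, function(s) sqrt(sum((ctr - s)^2)), numeric(1))
      if (min(ds) <= label_within_A) {
        nm <- names(sites)[which.min(ds)]
        site <- if (nm == "proximal") "proximal"
                else if (nm == "distal") "distal" else nm
      }
    }
    data.frame(cluster = k, site = site, n_frames = sum(member),
               occupancy = sum(member) / n_total,
               cx = ctr[1], cy = ctr[2], cz = ctr[3],
               mean_interface_A = mean(b$min_dist_A[member]))
  }))
  out <- out[out$mean_interface_A <= max_interface_A, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pose_clusters", "data.frame")
  out
}

#' Occupancy-based dissociation constant per binding site
#'
#' For a single mobile molecule in a simulation volume `V`, the bound
#' fraction `p` at a site implies
#' `KD = (1 - p) / p * 1 / (N_A V)` in molar units: the free-molecule
#' concentration seen by the site is one molecule per simulation box.
#' Confidence intervals are bootstrapped over replicas.
#'
#' @param replicas list of [contact_series()] objects (>= 1; >= 10 for
#'   a meaningful CI), optionally each with a `site` column added to
#'   `frames` (e.g. from [assign_frame_sites()]); without site labels a
#'   single pooled site `"all"` is reported.
#' @param simulation_volume_A3 simulation box volume (Angstrom^3).
#' @param n_boot bootstrap draws.
#' @param conf confidence level.
#' @param seed seed for the bootstrap.
#' @return A data frame, one row per site: `site`, `p_bound`, `KD_M`,
#'   `KD_lo_M`, `KD_hi_M`, `n_replicas`.  Sites with no bound frames
#'   report `KD_M = NA` (no binding detected).
#' @export
occupancy_kd <- function(replicas, simulation_volume_A3, n_boot = 500L,
                         conf = 0.95, seed = 1L) {
  stopifnot(length(replicas) >= 1, simulation_volume_A3 > 0)
  V_L <- simulation_volume_A3 * 1e-27
  c_box <- 1 / (.NA_mol * V_L)          # molar concentration of 1 molecule
  tabs <- lapply(replicas, function(cs) {
    fr <- cs$frames
    site <- if ("site" %in% names(fr)) fr$site else
      ifelse(fr$bound, "all", NA)
    list(n = nrow(fr), site = site, bound = fr$bound)
  })
  sites <- unique(unlist(lapply(tabs, function(t)
    t$site[t$bound & !is.na(t$site)])))
  if (length(sites) == 0L) {
    return(data.frame(site = "all", p_bound = 0, KD_M = NA_real_,
                      KD_lo_M = NA_real_, KD_hi_M = NA_real_,
                      n_replicas = length(replicas)))
  }
  p_site <- function(idx, s) {
    n <- sum(vapply(tabs[idx], `[[`, numeric(1), "n"))
    nb <- sum(vapply(tabs[idx], function(t)
      sum(t$bound & !is.na(t$site) & t$site == s), numeric(1)))
    nb / n
  }
  kd <- function(p) if (p <= 0) NA_real_ else (1 - p) / p * c_box
  alpha <- (1 - conf) / 2
  out <- do.call(rbind, lapply(sites, function(s) {
    p <- p_site(seq_along(tabs), s)
    boots <- .with_seed(seed, vapply(seq_len(n_boot), function(b) {
      idx <- sample(length(tabs), replace = TRUE)
      kd(p_site(idx, s))
    }, numeric(1)))
    ci <- quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE,
                   names = FALSE)
    data.frame(site = s, p_bound = p, KD_M = kd(p),
               KD_lo_M = ci[1], KD_hi_M = ci[2],
               n_replicas = length(replicas))
  }))
  rownames(out) <- NULL
  out
}

#' Label each bound frame with its nearest annotated site
#'
#' @param series a [contact_series()].
#' @param sites named list of site points (see [cluster_poses()]).
#' @param label_within_A labelling radius.
#' @return the `contact_series` with a `site` column on `frames`
#'   (`NA` for unbound frames).
#' @export
assign_frame_sites <- function(series, sites, label_within_A = 20) {
  fr <- series$frames
  site <- rep(NA_character_, nrow(fr))
  if (any(fr$bound)) {
    xyz <- as.matrix(fr[fr$bound, c("x", "y", "z")])
    dmat <- vapply(sites, function(s) {
      sqrt(colSums((t(xyz) - s)^2))
    }, numeric(nrow(xyz)))
    dmat <- matrix(dmat, nrow = nrow(xyz))
    nearest <- names(sites)[apply(dmat, 1, which.min)]
    nearest[apply(dmat, 1, min) > label_within_A] <- "other"
    site[fr$bound] <- nearest
  }
  series$frames$site <- site
  series
}

#' Detect intermediate states on a pulling energy profile
#'
#' Moving-average smoothing of the interaction energy against the
#' reaction coordinate, then local-minimum detection with a prominence
#' threshold measured on the magnitude of the interaction energy, so
#' the result is independent of the sign convention.  States are
#' returned ordered along the reaction coordinate.
#'
#' @param profile a `pull_profile` from [steered_pull()], or a data
#'   frame with `reaction_coord_A` and `energy_kJ_mol`.
#' @param smoothing_window moving-average window (frames).
#' @param prominence_kJ_mol minimum prominence of a state (kJ/mol).
#' @return data frame with `position_A` (reaction coordinate) and
#'   `depth_kJ_mol` (smoothed energy at the state), possibly empty.
#' @export
detect_states <- function(profile, smoothing_window = 5L,
                          prominence_kJ_mol = 1) {
  stopifnot(nrow(profile) >= 20)
  ord <- order(profile$reaction_coord_A)
  x <- profile$reaction_coord_A[ord]
  e <- profile$energy_kJ_mol[ord]
  # accept either sign convention: a predominantly positive profile is
  # an interaction-energy magnitude, so flip it to attractive wells
  if (sum(e) > 0) e <- -e
  w <- max(1L, as.integer(smoothing_window))
  sm <- stats::filter(e, rep(1 / w, w), sides = 2)
  sm <- as.numeric(sm)
  # fill the filter's edge NAs with the raw values
  sm[is.na(sm)] <- e[is.na(sm)]
  n <- length(sm)
  states <- list()
  for (i in 2:(n - 1)) {
    if (!(sm[i] < sm[i - 1] && sm[i] <= sm[i + 1])) next
    # prominence: lowest barrier separating this minimum from a deeper one
    left_max <- -Inf
    j <- i - 1
    while (j >= 1 && sm[j] >= sm[i]) {
      left_max <- max(left_max, sm[j]); j <- j - 1
    }
    if (j < 1) left_max <- max(sm[1:i])
    right_max <- -Inf
    j <- i + 1
    while (j <= n && sm[j] >= sm[i]) {
      right_max <- max(right_max, sm[j]); j <- j + 1
    }
    if (j > n) right_max <- max(sm[i:n])
    prom <- min(left_max, right_max) - sm[i]
    if (is.finite(prom) && prom >= prominence_kJ_mol) {
      states[[length(states) + 1L]] <-
        data.frame(position_A = x[i], depth_kJ_mol = sm[i])
    }
  }
  if (length(states) == 0L) {
    return(data.frame(position_A = numeric(), depth_kJ_mol = numeric()))
  }
  out <- do.call(rbind, states)
  out[order(out$position_A), , drop = FALSE]
}
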