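# Synthetic force-distance curve generation.
#
# The generator emulates the retract half of a PeakForce QNM cycle:
# white Gaussian baseline noise everywhere; with probability p_event a
# worm-like-chain tether ramp that terminates in a one-sample force drop
# at the target rupture force (drawn from the condition's two-component
# Gaussian mixture) at a separation offset in [offset_min, offset_max];
# and with probability p_nonspecific a surface-adhesion spike below 5 nm.

# Run code with a fixed seed, restoring the caller's RNG state after.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Worm-like-chain tether force
#'
#' Interpolation-formula force of a worm-like chain at a given end-to-end
#' extension: `F = (kBT/Lp) * (1/(4(1-x)^2) - 1/4 + x)` with
#' `x = extension / contour`.  Used as the stretch model of the PEG
#' tether linking the cytochrome to the AFM tip.
#'
#' @param extension_nm end-to-end extension (nm); must satisfy
#'   `0 <= extension < contour`.
#' @param params an [acquisition_params()] object supplying temperature,
#'   persistence length and contour length.
#' @return force in pN (vectorised over `extension_nm`).
#' @examples
#' p <- acquisition_params()
#' tether_force(0, p)                        # 0
#' tether_force(p$tether_contour_nm / 2, p)  # ~13.5 pN
#' @export
tether_force <- function(extension_nm, params = acquisition_params()) {
  L <- params$tether_contour_nm
  if (any(extension_nm < 0) || any(extension_nm >= L)) {
    stop("extension must lie in [0, contour length)")
  }
  .wlc_force(extension_nm / L, params$tether_persistence_nm,
             params$temperature_K)
}

# WLC interpolation formula on the fractional extension x in [0, 1).
.wlc_force <- function(x, persistence_nm, temperature_K) {
  (kBT(temperature_K) / persistence_nm) *
    (1 / (4 * (1 - x)^2) - 0.25 + x)
}

# Invert the WLC formula: fractional extension at which the tether
# carries force f (pN).  Monotone interpolation on a dense grid.
.wlc_inverse <- function(f, persistence_nm, temperature_K) {
  x <- seq(0, 0.999, length.out = 4000L)
  ff <- .wlc_force(x, persistence_nm, temperature_K)
  stats::approx(ff, x, xout = pmin(f, max(ff)), rule = 2)$y
}

#' Generate one synthetic retract force-distance curve
#'
#' @param preset a one-row condition preset (see [builtin_presets()],
#'   [get_preset()]).
#' @param params an [acquisition_params()] object.
#' @param seed integer seed; identical `(preset, params, seed)` give
#'   bit-identical curves.
#' @return A list of class `force_curve` with elements `separation_nm`,
#'   `force_pN`, `segment` (`"retract"`) and `truth`, a one-row data
#'   frame recording what was generated (event present, mixture
#'   component, rupture force, separation offset, nonspecific spike).
#' @export
generate_curve <- function(preset, params = acquisition_params(), seed) {
  .check_preset(preset)
  stopifnot(inherits(params, "acquisition_params"))
  .with_seed(seed, .generate_curve_impl(preset, params))
}

.generate_curve_impl <- function(preset, params) {
  n <- params$samples_per_curve
  s <- seq(0, params$modulation_amplitude_nm, length.out = n)
  f <- rnorm(n, 0, params$baseline_noise_pN)

  has_event <- runif(1) < preset$p_event
  component <- NA_integer_
  f_rup <- NA_real_
  offset <- NA_real_
  if (has_event) {
    component <- if (runif(1) < preset$w_low) 1L else 2L
    mu <- if (component == 1L) preset$mu_low_pN else preset$mu_high_pN
    sg <- if (component == 1L) preset$sigma_low_pN else preset$sigma_high_pN
    repeat {
      f_rup <- rnorm(1, mu, sg)
      if (f_rup > 10) break  # truncate to physically meaningful forces
    }
    offset <- runif(1, preset$offset_min_nm, preset$offset_max_nm)
    # Effective contour = offset plus extension headroom so the WLC
    # reaches exactly f_rup at the rupture separation (the PEG contour
    # plus protein-height allowance of the real geometry).
    x_rup <- .wlc_inverse(f_rup, params$tether_persistence_nm,
                          params$temperature_K)
    L_eff <- offset / x_rup
    ramp <- s <= offset
    f[ramp] <- f[ramp] + .wlc_force(s[ramp] / L_eff,
                                    params$tether_persistence_nm,
                                    params$temperature_K)
    # pin the final loaded sample to the true rupture force so the
    # recorded peak is the rupture point, not the previous sample
    i_last <- max(which(ramp))
    f[i_last] <- f[i_last] - .wlc_force(s[i_last] / L_eff,
                                        params$tether_persistence_nm,
                                        params$temperature_K) + f_rup
  }

  has_ns <- runif(1) < preset$p_nonspecific
  ns_amp <- NA_real_
  ns_pos <- NA_real_
  if (has_ns) {
    ns_amp <- runif(1, 100, 400)
    ns_pos <- runif(1, 0.5, 4)
    rise <- s <= ns_pos
    f[rise] <- f[rise] + ns_amp * exp(-(ns_pos - s[rise]) / 1.0)
  }

  structure(
    list(
      separation_nm = s,
      force_pN = f,
      segment = "retract",
      truth = data.frame(
        has_event = has_event, component = component,
        rupture_force_pN = f_rup, offset_nm = offset,
        has_nonspecific = has_ns, ns_amplitude_pN = ns_amp,
        ns_position_nm = ns_pos
      )
    ),
    class = "force_curve"
  )
}

#' Generate a bundle of synthetic curves with a truth table
#'
#' @inheritParams generate_curve
#' @param n_curves number of retract curves to generate.
#' @param n_complexes number of receptor complexes notionally imaged;
#'   the denominator of [cumulative_probability()].  Defaults to
#'   `n_curves` (one force-distance cycle per imaged complex).
#' @param seed integer master seed; per-curve seeds are derived from it.
#' @return A list of class `curve_bundle`: `curves` (list of
#'   `force_curve`), `truth` (data frame, one row per curve),
#'   `preset`, `params`, `n_complexes`, `seed`.
#' @examples
#' b <- generate_dataset(get_preset("WT_10mM_oxred"), n_curves = 20, seed = 1)
#' mean(b$truth$has_event)
#' @export
generate_dataset <- function(preset, params = acquisition_params(),
                             n_curves, n_complexes = n_curves, seed) {
  .check_preset(preset)
  stopifnot(n_curves >= 0, n_curves >= 0 || n_complexes >= 1)
  if (n_curves > 0) stopifnot(n_complexes >= 1)
  curve_seeds <- .with_seed(seed,
    sample.int(.Machine$integer.max, max(n_curves, 1L)))
  curves <- if (n_curves == 0L) list() else
    lapply(seq_len(n_curves), function(i) {
      generate_curve(preset, params, seed = curve_seeds[i])
    })
  truth <- if (n_curves == 0L) {
    data.frame(curve_id = integer(), has_event = logical(),
               component = integer(), rupture_force_pN = numeric(),
               offset_nm = numeric(), has_nonspecific = logical(),
               ns_amplitude_pN = numeric(), ns_position_nm = numeric())
  } else {
    cbind(curve_id = seq_len(n_curves),
          do.call(rbind, lapply(curves, `[[`, "truth")))
  }
  structure(
    list(curves = curves, truth = truth, preset = preset,
         params = params, n_complexes = n_complexes, seed = seed),
    class = "curve_bundle"
  )
}

#' @export
print.curve_bundle <- function(x, ...) {
  cat("curve_bundle:", length(x$curves), "curves, condition",
      x$preset$label, "\n")
  cat("  events:", sum(x$truth$has_event), " nonspecific:",
      sum(x$truth$has_nonspecific), " complexes imaged:",
      x$n_complexes, "\n")
  invisible(x)
}
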