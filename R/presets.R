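#' Experimental condition presets for the synthetic curve generator
#'
#' Returns one preset per measured condition of the RC-LH1 (or RC-only)
#' vs cytochrome c2 force-spectroscopy study: the wild-type receptor and
#' the three binding-interface mutants, each at four NaCl concentrations
#' with an oxidised receptor and reduced cytochrome; the same four
#' constructs at 10 mM NaCl with both partners oxidised; and the RC-only
#' (no LH1 ring) construct.
#'
#' Peak positions (`mu_low_pN`, `mu_high_pN`) and cumulative interaction
#' probabilities (`p_event`) are the measured condition values where the
#' study reports them numerically; remaining entries are documented
#' defaults that follow the reported trends (see the package vignette).
#' Component widths default to 25 / 30 pN and the low-force mixture
#' weight `w_low` to 0.40 (0.30 for the fully oxidised pairs, whose
#' low-force component is attenuated).
#'
#' @return A data frame of class `condition_presets`, one row per
#'   condition, with columns `label`, `construct`, `salt_mM`,
#'   `redox_pair`, `p_event`, `w_low`, `mu_low_pN`, `sigma_low_pN`,
#'   `mu_high_pN`, `sigma_high_pN`, `p_nonspecific`, `offset_min_nm`,
#'   `offset_max_nm`.
#' @examples
#' p <- builtin_presets()
#' subset(p, construct == "WT" & redox_pair == "ox/red")$p_event
#' @export
builtin_presets <- function() {
  row <- function(construct, salt, redox, p_event, w_low,
                  mu_lo, mu_hi, sd_lo = 25, sd_hi = 30) {
    data.frame(
      label = sprintf("%s_%dmM_%s", construct, salt,
                      if (redox == "ox/red") "oxred" else "oxox"),
      construct = construct, salt_mM = salt, redox_pair = redox,
      p_event = p_event, w_low = w_low,
      mu_low_pN = mu_lo, sigma_low_pN = sd_lo,
      mu_high_pN = mu_hi, sigma_high_pN = sd_hi,
      p_nonspecific = 0.10, offset_min_nm = 10, offset_max_nm = 20,
      stringsAsFactors = FALSE
    )
  }
  pr <- rbind(
    # oxidised receptor / reduced cytochrome, salt series
    row("WT",     10, "ox/red", 0.34, 0.40, 154, 332),
    row("WT",     50, "ox/red", 0.32, 0.40, 154, 332),
    row("WT",    100, "ox/red", 0.28, 0.40, 154, 332),
    row("WT",    200, "ox/red", 0.26, 0.40, 154, 332),
    row("NM188D", 10, "ox/red", 0.40, 0.45, 154, 332),
    row("NM188D", 50, "ox/red", 0.36, 0.45, 154, 332),
    row("NM188D", 100, "ox/red", 0.27, 0.40, 154, 332),
    row("NM188D", 200, "ox/red", 0.24, 0.35, 154, 332),
    row("QL264E", 10, "ox/red", 0.39, 0.45, 154, 332),
    row("QL264E", 50, "ox/red", 0.35, 0.45, 154, 332),
    row("QL264E", 100, "ox/red", 0.27, 0.40, 154, 332),
    row("QL264E", 200, "ox/red", 0.24, 0.35, 154, 332),
    row("DM184K", 10, "ox/red", 0.24, 0.35, 154, 332),
    row("DM184K", 50, "ox/red", 0.22, 0.33, 154, 332),
    row("DM184K", 100, "ox/red", 0.20, 0.31, 154, 332),
    row("DM184K", 200, "ox/red", 0.18, 0.30, 154, 332),
    # both partners oxidised, lowest salt
    row("WT",     10, "ox/ox", 0.32, 0.30, 173, 370),
    row("NM188D", 10, "ox/ox", 0.37, 0.30, 154, 332),
    row("QL264E", 10, "ox/ox", 0.36, 0.30, 154, 332),
    row("DM184K", 10, "ox/ox", 0.20, 0.30, 154, 332),
    # receptor without the LH1 antenna ring
    row("RConly", 10, "ox/red", 0.30, 0.40, 124, 247)
  )
  class(pr) <- c("condition_presets", "data.frame")
  pr
}

#' Look up a single condition preset by label
#'
#' @param label preset label such as `"WT_10mM_oxred"`; see
#'   [builtin_presets()] for the full list.
#' @return A one-row preset data frame.
#' @export
get_preset <- function(label) {
  pr <- builtin_presets()
  hit <- pr[pr$label == label, , drop = FALSE]
  if (nrow(hit) == 0L) {
    stop("unknown preset label '", label, "'; see builtin_presets()$label")
  }
  hit
}

.check_preset <- function(preset) {
  stopifnot(
    is.data.frame(preset), nrow(preset) == 1L,
    preset$p_event >= 0, preset$p_event <= 1,
    preset$w_low >= 0, preset$w_low <= 1,
    preset$mu_low_pN < preset$mu_high_pN,
    preset$sigma_low_pN >= 0, preset$sigma_high_pN >= 0,
    preset$p_nonspecific >= 0, preset$p_nonspecific <= 1,
    preset$offset_min_nm >= 0,
    preset$offset_max_nm >= preset$offset_min_nm
  )
  invisible(preset)
}

#' Acquisition parameters for synthetic force-distance curves
#'
#' Instrumental settings of the emulated PeakForce QNM acquisition.
#' Defaults follow the reported instrument regime: cantilever spring
#' constants of order 0.1 N/m, a Z-modulation amplitude of 20-25 nm
#' (large enough to fully stretch the ~9.5 nm PEG tether), and a retract
#' velocity chosen so that instantaneous loading rates just before
#' rupture cluster around 2.5e6 pN/s.
#'
#' @param spring_constant_N_per_m cantilever spring constant (N/m).
#' @param modulation_amplitude_nm Z-modulation amplitude (nm); the
#'   retract segment spans 0 to this separation.
#' @param retract_velocity_nm_per_s tip retract velocity (nm/s).
#' @param samples_per_curve number of samples per retract segment.
#' @param baseline_noise_pN standard deviation of the white baseline
#'   force noise (pN).
#' @param temperature_K bath temperature (K).
#' @param tether_contour_nm contour length of the PEG tether (nm).
#' @param tether_persistence_nm persistence length of the tether (nm).
#' @return A list of class `acquisition_params`.
#' @export
acquisition_params <- function(spring_constant_N_per_m = 0.15,
                               modulation_amplitude_nm = 25,
                               retract_velocity_nm_per_s = 7800,
                               samples_per_curve = 512L,
                               baseline_noise_pN = 8,
                               temperature_K = 298,
                               tether_contour_nm = 9.5,
                               tether_persistence_nm = 0.38) {
  stopifnot(
    spring_constant_N_per_m > 0, spring_constant_N_per_m < 10,
    modulation_amplitude_nm >= tether_contour_nm,
    retract_velocity_nm_per_s > 0,
    samples_per_curve >= 16,
    baseline_noise_pN >= 0,
    temperature_K > 0,
    tether_contour_nm > 0, tether_persistence_nm > 0
  )
  structure(
    list(
      spring_constant_N_per_m = spring_constant_N_per_m,
      modulation_amplitude_nm = modulation_amplitude_nm,
      retract_velocity_nm_per_s = retract_velocity_nm_per_s,
      samples_per_curve = as.integer(samples_per_curve),
      baseline_noise_pN = baseline_noise_pN,
      temperature_K = temperature_K,
      tether_contour_nm = tether_contour_nm,
      tether_persistence_nm = tether_persistence_nm
    ),
    class = "acquisition_params"
  )
}

#' Rupture-detection parameters
#'
#' @param force_threshold_multiple detection threshold as a multiple of
#'   the estimated baseline noise SD; must be at least 3.
#' @param specific_window_nm closed separation interval (nm) within
#'   which a rupture is classified as a specific tether-mediated event.
#'   The default `[8, 25]` brackets the expected 10-20 nm offset with
#'   allowance for linker polydispersity.
#' @param slope_fit_window number of samples before the force peak used
#'   for the loading-rate slope fit.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(force_threshold_multiple = 5,
                             specific_window_nm = c(8, 25),
                             slope_fit_window = 8L) {
  stopifnot(
    force_threshold_multiple >= 3,
    length(specific_window_nm) == 2L,
    specific_window_nm[1] > 0,
    specific_window_nm[2] > specific_window_nm[1],
    slope_fit_window >= 2
  )
  structure(
    list(
      force_threshold_multiple = force_threshold_multiple,
      specific_window_nm = as.numeric(specific_window_nm),
      slope_fit_window = as.integer(slope_fit_window)
    ),
    class = "detection_params"
  )
}
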