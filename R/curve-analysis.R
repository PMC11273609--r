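# Rupture-event detection and curve-level statistics.

#' Detect rupture events in a retract force-distance curve
#'
#' The baseline force and its noise SD are estimated from the
#' far-from-surface tail of the retract segment (outer 20% of the
#' separation range, median / MAD).  Contiguous runs of samples above
#' `baseline + multiple * SD` are candidate events; each contributes one
#' event at its force maximum, provided the force falls back to within
#' the threshold of baseline within a few samples after the peak (the
#' signature of an unbinding force drop).  The event force is the peak
#' force minus baseline, the separation is taken at the peak, and the
#' loading rate is the slope of force against separation over
#' `slope_fit_window` samples before the peak multiplied by the retract
#' velocity.
#'
#' @param curve a `force_curve` (see [generate_curve()]).
#' @param det a [detection_params()] object.
#' @param params the [acquisition_params()] of the acquisition (supplies
#'   the retract velocity for loading rates).
#' @return A data frame with one row per detected event: `force_pN`,
#'   `separation_nm`, `loading_rate_pN_per_s`, `specific`.
#' @export
detect_ruptures <- function(curve, det = detection_params(),
                            params = acquisition_params()) {
  stopifnot(inherits(curve, "force_curve"))
  s <- curve$separation_nm
  f <- curve$force_pN
  n <- length(f)
  if (n < det$slope_fit_window + 2L) {
    stop("curve shorter than the slope fit window")
  }
  if (!identical(curve$segment, "retract")) {
    stop("rupture detection requires a retract segment")
  }

  tail_idx <- which(s >= max(s) - 0.2 * diff(range(s)))
  baseline <- median(f[tail_idx])
  noise_sd <- mad(f[tail_idx])
  if (noise_sd <= 0) noise_sd <- max(sd(f[tail_idx]), 1e-9)
  threshold <- baseline + det$force_threshold_multiple * noise_sd

  above <- f > threshold
  if (!any(above)) return(.empty_events())

  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  starts <- starts[keep]; ends <- ends[keep]

  events <- lapply(seq_along(starts), function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    peak <- i0 - 1L + which.max(f[i0:i1])
    # require a drop back below threshold within a few samples
    drop_idx <- seq(peak + 1L, min(peak + 5L, n))
    if (peak >= n || !any(f[drop_idx] < threshold)) return(NULL)
    w <- max(1L, peak - det$slope_fit_window + 1L):peak
    slope <- if (length(w) >= 2L && diff(range(s[w])) > 0) {
      coef(stats::lm.fit(cbind(1, s[w]), f[w]))[2]
    } else NA_real_
    rate <- abs(slope) * params$retract_velocity_nm_per_s
    data.frame(
      force_pN = f[peak] - baseline,
      separation_nm = s[peak],
      loading_rate_pN_per_s = unname(rate)
    )
  })
  events <- do.call(rbind, events)
  if (is.null(events) || nrow(events) == 0L) return(.empty_events())
  events$specific <- vapply(events$separation_nm, classify_specific,
                            logical(1), det = det)
  events
}

.empty_events <- function() {
  data.frame(force_pN = numeric(), separation_nm = numeric(),
             loading_rate_pN_per_s = numeric(), specific = logical())
}

#' Classify a rupture event as specific or nonspecific
#'
#' Specific tether-mediated unbinding events are offset from the surface
#' by roughly the tether length plus receptor height; anything rupturing
#' closer to the surface is surface adhesion.  An event is specific iff
#' its separation lies in the closed specific window.
#'
#' @param separation_nm separation of the event (nm), or a data frame
#'   with a `separation_nm` column.
#' @param det a [detection_params()] object.
#' @return logical.
#' @export
classify_specific <- function(separation_nm, det = detection_params()) {
  if (is.data.frame(separation_nm)) {
    separation_nm <- separation_nm$separation_nm
  }
  separation_nm >= det$specific_window_nm[1] &
    separation_nm <= det$specific_window_nm[2]
}

#' Analyse every curve of a bundle
#'
#' Runs [detect_ruptures()] over a curve bundle and returns the pooled
#' event table.  Where a curve holds several specific events only the
#' one at the largest separation (the final tether rupture) is flagged
#' with `final_specific = TRUE`; that event represents the curve in the
#' force histogram, and the curve counts once towards the cumulative
#' interaction probability.
#'
#' @param bundle a `curve_bundle` from [generate_dataset()] or
#'   [read_curve_bundle()].
#' @param det a [detection_params()] object.
#' @return A data frame of events with columns `curve_id`, `force_pN`,
#'   `separation_nm`, `loading_rate_pN_per_s`, `specific`,
#'   `final_specific`.
#' @export
analyze_bundle <- function(bundle, det = detection_params()) {
  stopifnot(inherits(bundle, "curve_bundle"))
  ev <- lapply(seq_along(bundle$curves), function(i) {
    e <- detect_ruptures(bundle$curves[[i]], det, bundle$params)
    if (nrow(e) == 0L) return(NULL)
    e$curve_id <- i
    e
  })
  ev <- do.call(rbind, ev)
  if (is.null(ev)) {
    ev <- cbind(.empty_events(), curve_id = integer())
  }
  ev$final_specific <- FALSE
  if (nrow(ev) > 0L) {
    sp <- ev[ev$specific, , drop = FALSE]
    if (nrow(sp) > 0L) {
      last <- tapply(seq_len(nrow(ev)),
                     ev$curve_id,
                     function(ix) {
                       ix <- ix[ev$specific[ix]]
                       if (length(ix) == 0L) return(NA_integer_)
                       ix[which.max(ev$separation_nm[ix])]
                     })
      last <- last[!is.na(last)]
      ev$final_specific[unlist(last)] <- TRUE
    }
  }
  rownames(ev) <- NULL
  ev[, c("curve_id", "force_pN", "separation_nm",
         "loading_rate_pN_per_s", "specific", "final_specific")]
}

#' Cumulative interaction probability
#'
#' The ratio between the number of force-distance curves displaying a
#' (specific) unbinding event and the total number of receptor complexes
#' imaged, expressed in percent.
#'
#' @param n_event_curves number of curves with at least one specific
#'   rupture event.
#' @param n_complexes total number of complexes imaged.
#' @return percent (0-100).
#' @examples
#' cumulative_probability(340, 1000)  # 34
#' @export
cumulative_probability <- function(n_event_curves, n_complexes) {
  stopifnot(n_event_curves >= 0)
  if (length(n_complexes) != 1L || n_complexes < 1) {
    stop("n_complexes must be a positive count")
  }
  100 * n_event_curves / n_complexes
}

#' Most probable loading rate
#'
#' Instantaneous loading rates just before rupture are broadly,
#' approximately log-normally distributed; the most probable value is
#' located as the peak of a Gaussian kernel density estimate on
#' log10(rate).
#'
#' @param events an event data frame (see [detect_ruptures()]) or a
#'   numeric vector of loading rates (pN/s).
#' @param min_events minimum number of events required.
#' @return the modal loading rate in pN/s.
#' @export
loading_rate_mode <- function(events, min_events = 30L) {
  r <- if (is.data.frame(events)) events$loading_rate_pN_per_s else events
  r <- r[is.finite(r) & r > 0]
  if (length(r) < min_events) {
    stop("need at least ", min_events, " events with finite loading rates")
  }
  if (diff(range(r)) == 0) return(r[1])
  d <- density(log10(r))
  10^d$x[which.max(d$y)]
}
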