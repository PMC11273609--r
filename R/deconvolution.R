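# Probability-normalised force histograms and Gaussian deconvolution.

#' Build a probability-normalised force histogram
#'
#' Bin heights are scaled so that their sum equals the cumulative
#' interaction probability: the total area of the histogram *is* the
#' probability that an imaged complex shows an unbinding event, and each
#' bin height is the interaction probability contributed by that force
#' range (percent per bin).
#'
#' @param forces_pN vector of rupture forces (pN); must be nonempty.
#' @param cumulative_percent cumulative interaction probability (%).
#' @param bin_width_pN histogram bin width (pN), default 20.
#' @return A list of class `force_histogram` with `bin_edges_pN`,
#'   `mids_pN`, `heights` (percent per bin) and `cumulative_percent`.
#' @export
build_histogram <- function(forces_pN, cumulative_percent,
                            bin_width_pN = 20) {
  if (length(forces_pN) == 0L) stop("no forces supplied")
  stopifnot(bin_width_pN > 0, cumulative_percent >= 0)
  edges <- seq(0, max(forces_pN) + bin_width_pN, by = bin_width_pN)
  counts <- tabulate(findInterval(forces_pN, edges,
                                  rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  structure(
    list(
      bin_edges_pN = edges,
      mids_pN = (edges[-1] + edges[-length(edges)]) / 2,
      heights = counts / sum(counts) * cumulative_percent,
      cumulative_percent = cumulative_percent
    ),
    class = "force_histogram"
  )
}

# sum of k Gaussian peaks evaluated at x; theta = (A1, m1, s1, ...)
.gauss_sum <- function(x, theta) {
  k <- length(theta) / 3L
  y <- 0
  for (j in seq_len(k)) {
    A <- theta[3 * j - 2]; m <- theta[3 * j - 1]; s <- theta[3 * j]
    y <- y + A * exp(-(x - m)^2 / (2 * s^2))
  }
  y
}

#' Deconvolve a force histogram into Gaussian components
#'
#' Fits a sum of `k` Gaussian peaks to the probability-normalised bin
#' heights at the bin centres by nonlinear least squares
#' (Levenberg-Marquardt), with multistart initialisation: means are
#' seeded from a k-means split of the bin centres weighted by heights,
#' plus jittered restarts under a fixed internal seed.  Components are
#' returned ordered by increasing mean, so the low-force (encounter
#' complex) component always comes first.
#'
#' @param hist a [build_histogram()] object.
#' @param k number of components, 1 or 2.
#' @param n_starts number of jittered restarts.
#' @return A list of class `mixture_fit`: `k`, `amplitude_percent`,
#'   `mean_pN`, `sd_pN` (each length `k`), `residual_norm`, `rss`,
#'   `n_bins`, `vcov` (parameter covariance when available),
#'   `cumulative_percent`, `converged`.
#' @export
fit_mixture <- function(hist, k = 2, n_starts = 5L) {
  stopifnot(inherits(hist, "force_histogram"), k %in% c(1L, 2L))
  x <- hist$mids_pN
  y <- hist$heights
  occupied <- sum(y > 0)
  if (occupied < 5L) stop("need at least 5 occupied bins, have ", occupied)

  starts <- .mixture_starts(x, y, k, n_starts)
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch({
      df <- data.frame(x = x, y = y)
      if (k == 1L) {
        minpack.lm::nlsLM(
          y ~ A1 * exp(-(x - m1)^2 / (2 * s1^2)), data = df,
          start = list(A1 = th0[1], m1 = th0[2], s1 = th0[3]),
          lower = c(0, min(x), 1e-3),
          upper = c(Inf, max(x), diff(range(x)) + 1),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        )
      } else {
        minpack.lm::nlsLM(
          y ~ A1 * exp(-(x - m1)^2 / (2 * s1^2)) +
              A2 * exp(-(x - m2)^2 / (2 * s2^2)), data = df,
          start = list(A1 = th0[1], m1 = th0[2], s1 = th0[3],
                       A2 = th0[4], m2 = th0[5], s2 = th0[6]),
          lower = c(0, min(x), 1e-3, 0, min(x), 1e-3),
          upper = rep(c(Inf, max(x), diff(range(x)) + 1), 2),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        )
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop("mixture fit failed to converge from any start (k = ", k,
         ", ", occupied, " occupied bins)")
  }

  th <- coef(best$fit)
  V <- tryCatch(vcov(best$fit), error = function(e) NULL)
  ord <- order(th[seq(2, 3 * k, by = 3)])
  amp <- th[seq(1, 3 * k, by = 3)][ord]
  mu <- th[seq(2, 3 * k, by = 3)][ord]
  sg <- abs(th[seq(3, 3 * k, by = 3)][ord])
  structure(
    list(
      k = k,
      amplitude_percent = unname(amp),
      mean_pN = unname(mu),
      sd_pN = unname(sg),
      residual_norm = sqrt(best$rss),
      rss = best$rss,
      n_bins = length(x),
      vcov = V,
      bin_width_pN = diff(hist$bin_edges_pN[1:2]),
      cumulative_percent = hist$cumulative_percent,
      converged = TRUE
    ),
    class = "mixture_fit"
  )
}

# Initial parameter sets: weighted k-means split of bin centres, then
# jittered copies under a fixed internal seed.
.mixture_starts <- function(x, y, k, n_starts) {
  wx <- rep(x, times = pmax(round(y * 100), ifelse(y > 0, 1, 0)))
  base_means <- if (k == 1L) {
    sum(x * y) / sum(y)
  } else if (length(unique(wx)) >= 2L) {
    sort(.with_seed(707L, kmeans(wx, centers = 2L, nstart = 3L))$centers[, 1])
  } else {
    quantile(x[y > 0], c(0.25, 0.75), names = FALSE)
  }
  sd0 <- max(diff(range(x[y > 0])) / (4 * k), 10)
  amp0 <- max(y)
  base <- as.numeric(rbind(amp0, base_means, sd0))
  jitters <- .with_seed(708L, lapply(seq_len(max(n_starts - 1L, 0L)),
    function(i) {
      base * exp(rnorm(length(base), 0, 0.15))
    }))
  c(list(base), jitters)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("mixture_fit: k =", x$k, "\n")
  for (j in seq_len(x$k)) {
    cat(sprintf("  component %d: mean %.1f pN, sd %.1f pN, amplitude %.2f%%\n",
                j, x$mean_pN[j], x$sd_pN[j], x$amplitude_percent[j]))
  }
  pr <- component_probabilities(x)
  cat(sprintf("  component probabilities: %s (cumulative %.1f%%)\n",
              paste(sprintf("%.1f%%", pr), collapse = " + "),
              x$cumulative_percent))
  invisible(x)
}

#' Component interaction probabilities
#'
#' Each fitted Gaussian's area, expressed on the histogram's percent
#' scale (area under the peak divided by the bin width), is the
#' interaction probability of that component: the low-force value is the
#' probability of rupturing an encounter complex, the high-force value
#' that of a productive ET complex.
#'
#' @param fit a [fit_mixture()] object.
#' @param hist optional; unused beyond interface compatibility (the fit
#'   carries its histogram's bin width and cumulative probability).
#' @return named numeric vector, `low` (and `high` when `k = 2`) in
#'   percent.
#' @export
component_probabilities <- function(fit, hist = NULL) {
  stopifnot(inherits(fit, "mixture_fit"))
  area <- fit$amplitude_percent * fit$sd_pN * sqrt(2 * pi) /
    fit$bin_width_pN
  setNames(area, if (fit$k == 2L) c("low", "high") else "low")
}

#' Choose between one- and two-component fits
#'
#' Fits both `k = 1` and `k = 2` by least squares and compares with the
#' Bayesian information criterion computed from the residual sum of
#' squares (`n log(RSS/n) + p log n`).  Ties, and any fit failure at
#' `k = 2`, resolve to the simpler model.
#'
#' @param hist a [build_histogram()] object.
#' @return integer, 1 or 2.
#' @export
select_k <- function(hist) {
  f1 <- fit_mixture(hist, k = 1)
  f2 <- tryCatch(fit_mixture(hist, k = 2), error = function(e) NULL)
  if (is.null(f2)) return(1L)
  # a two-component fit that collapses onto one population (vanishing
  # amplitude, or means closer than the component width) is degenerate
  degenerate <- min(f2$amplitude_percent) <
                  0.05 * max(f2$amplitude_percent) ||
                diff(f2$mean_pN) < max(f1$sd_pN, mean(f2$sd_pN))
  if (degenerate) return(1L)
  n <- f1$n_bins
  bic <- function(f) n * log(f$rss / n) + (3 * f$k) * log(n)
  if (bic(f2) < bic(f1)) 2L else 1L
}

#' Full deconvolution pipeline on a curve bundle
#'
#' Detects ruptures on every curve, keeps each curve's final specific
#' event, computes the cumulative interaction probability against the
#' bundle's number of imaged complexes, builds the probability-normalised
#' histogram and fits the two-component mixture.
#'
#' @param bundle a `curve_bundle`.
#' @param det a [detection_params()] object.
#' @param bin_width_pN histogram bin width (pN).
#' @param k number of mixture components (default 2).
#' @return A list with `events`, `cumulative_percent`, `histogram`,
#'   `fit` and `component_percent`.
#' @export
deconvolve_bundle <- function(bundle, det = detection_params(),
                              bin_width_pN = 20, k = 2) {
  events <- analyze_bundle(bundle, det)
  n_event_curves <- length(unique(events$curve_id[events$specific]))
  cum <- cumulative_probability(n_event_curves, bundle$n_complexes)
  forces <- events$force_pN[events$final_specific]
  hist <- build_histogram(forces, cum, bin_width_pN)
  fit <- fit_mixture(hist, k = k)
  list(
    events = events,
    cumulative_percent = cum,
    histogram = hist,
    fit = fit,
    component_percent = component_probabilities(fit)
  )
}
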