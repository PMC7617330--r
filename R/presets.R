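#' FUCCI4 cohort presets
#'
#' A preset bundles everything the trace generator needs: the sampling
#' interval, per-phase duration distributions, the prolonged-G2 mixture
#' structure, reporter kinetics and the intensity noise level. The two named
#' presets encode the study conditions for MDCK monolayers:
#'
#' * `"low_density"` -- G2 duration with cohort mean 3.0 h, SD 0.8 h and
#'   99th percentile 4.5 h (skew-normal calibrated to all three; see
#'   [dist_skewnormal()]).
#' * `"high_density"` -- two-component G2 mixture: with probability
#'   `1 - prolonged_fraction` a draw from the low-density distribution, and
#'   with probability `prolonged_fraction` a draw from a prolonged component
#'   supported on (4.5, 10] h. The mixture weight is calibrated so that
#'   P(G2 > 4.5 h) = 45.8\% and the prolonged-component mean so that the
#'   overall mean is 4.6 h.
#'
#' G0/G1 and S durations have no published cohort values at these densities;
#' the defaults (lognormal, G0/G1 8 +/- 2 h, S 7 +/- 1.5 h, consistent with an
#' 18-19 h MDCK cycle) are configurable placeholders and are never asserted
#' against external numbers.
#'
#' @param name `"low_density"` or `"high_density"`.
#' @param dt sampling interval in hours (default 1/6, i.e. 10 min).
#' @param dist_g0g1,dist_s duration distributions for G0/G1 and S.
#' @param g2_mean,g2_sd,g2_q99 low-density G2 calibration targets (h).
#' @param hd_g2_mean high-density overall mean G2 (h).
#' @param hd_prolonged_pct fraction of high-density cells with G2 > `g2_q99`.
#' @param hd_prolonged_max upper support of the prolonged component (h).
#' @param noise_sd multiplicative intensity noise SD (0 disables noise).
#' @param censor_frac fraction of traces emitted censored (start or end).
#' @param mitosis_h duration of the mitotic (H1-high) flanks bracketing each
#'   trace (h).
#' @param channels per-channel kinetic constants; see Details.
#'
#' @details Reporter kinetics follow the FUCCI4 logic: the Cdt1 reporter rises
#' from completion of division and is degraded from S onset; the geminin
#' reporter rises from S onset and collapses at mitosis; the SLBP reporter is
#' present through G0/G1 and S and degraded from G2 onset; the H1 channel is
#' high during mitosis (chromosome condensation), so nuclear envelope
#' breakdown is the first H1-high frame of the terminal mitosis. Rises and
#' decays are exponential with per-channel rate constants (1/h); degradation
#' *onsets* are the ground-truth phase boundaries.
#'
#' @return A `fucci_preset` object.
#' @export
fucci_preset <- function(name = c("low_density", "high_density"),
                         dt = 1 / 6,
                         dist_g0g1 = dist_lognormal(8, 2),
                         dist_s = dist_lognormal(7, 1.5),
                         g2_mean = 3.0, g2_sd = 0.8, g2_q99 = 4.5,
                         hd_g2_mean = 4.6,
                         hd_prolonged_pct = 0.458,
                         hd_prolonged_max = 10,
                         noise_sd = 0.1,
                         censor_frac = 0,
                         mitosis_h = 0.5,
                         channels = fucci_channel_defaults()) {
  name <- match.arg(name)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (censor_frac < 0 || censor_frac > 1)
    stop("censor_frac must be in [0, 1]", call. = FALSE)

  g2_low <- dist_skewnormal(g2_mean, g2_sd, g2_q99)
  if (name == "low_density") {
    dist_g2 <- g2_low
    prolonged_fraction <- 0
    dist_g2_prolonged <- NULL
  } else {
    # Mixture weight p: (1 - p) * P_low(G2 > q99) + p * 1 = prolonged_pct,
    # with P_low(G2 > q99) = 0.01 by the q99 calibration.
    p <- (hd_prolonged_pct - 0.01) / 0.99
    if (p <= 0 || p >= 1) stop("inconsistent prolonged fraction", call. = FALSE)
    m_prol <- (hd_g2_mean - (1 - p) * g2_mean) / p
    if (m_prol <= g2_q99 || m_prol >= hd_prolonged_max)
      stop("prolonged-component mean outside its support", call. = FALSE)
    dist_g2_prolonged <- dist_scaled_beta(g2_q99, hd_prolonged_max, m_prol)
    dist_g2 <- dist_mixture(list(g2_low, dist_g2_prolonged), c(1 - p, p))
    prolonged_fraction <- p
  }

  structure(list(
    name = name, dt = dt,
    dist_g0g1 = dist_g0g1, dist_s = dist_s, dist_g2 = dist_g2,
    prolonged_fraction = prolonged_fraction,
    dist_g2_prolonged = dist_g2_prolonged,
    noise_sd = noise_sd, censor_frac = censor_frac,
    mitosis_h = mitosis_h, channels = channels
  ), class = "fucci_preset")
}

#' Default FUCCI4 reporter kinetics
#'
#' Amplitudes are arbitrary fluorescence units; rates are 1/h. Rise rates for
#' the degradation-defined reporters (Cdt1, SLBP) are fast so the plateau is
#' reached well before the degradation onset that defines the boundary; the
#' geminin rise is slower because its *onset* is the detected event.
#'
#' @return nested list of per-channel kinetic parameters.
#' @export
fucci_channel_defaults <- function() {
  list(
    cdt1    = list(amp = 1000, base = 0,  rise = 12, decay = 3),
    slbp    = list(amp = 1000, base = 0,  rise = 12, decay = 3),
    geminin = list(amp = 1000, base = 30, rise = 2,  decay = 6),
    h1      = list(high = 1200, base = 60)
  )
}

#' @export
print.fucci_preset <- function(x, ...) {
  cat("<fucci_preset>", x$name, "\n")
  cat("  dt:", format(x$dt, digits = 4), "h  noise_sd:", x$noise_sd,
      " censor_frac:", x$censor_frac, "\n")
  cat("  G2 mean:", format(dist_mean(x$dist_g2), digits = 4), "h",
      " prolonged fraction:", format(x$prolonged_fraction, digits = 4), "\n")
  invisible(x)
}
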