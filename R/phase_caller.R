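#' Phase-caller configuration
#'
#' @param min_run minimum number of consecutive frames a threshold-based onset
#'   must persist (geminin rise, H1 condensation).
#' @param rise_frac fraction of the geminin dynamic range used as the rise
#'   threshold.
#' @param ambiguity_gap_h if the Cdt1-degradation and geminin-rise estimates of
#'   the S onset differ by more than this (hours) the call is flagged
#'   ambiguous.
#' @param log_floor_drop decay fits stop once the (smoothed) log signal has
#'   fallen this many nats below its running peak; beyond that the exponential
#'   model is indistinguishable from background.
#' @return a `caller_config` list.
#' @export
caller_config <- function(min_run = 3, rise_frac = 0.25, ambiguity_gap_h = 1,
                          log_floor_drop = 3.5) {
  structure(list(min_run = min_run, rise_frac = rise_frac,
                 ambiguity_gap_h = ambiguity_gap_h,
                 log_floor_drop = log_floor_drop), class = "caller_config")
}

#' Call cell-cycle phase boundaries on a FUCCI4 trace
#'
#' Locates the four boundary events that define the phase lengths:
#'
#' * completion of division: first frame after the initial H1-high
#'   (chromosome-condensed) run; absent -> `censored` at the start;
#' * S onset: onset of sustained Cdt1 decline, cross-checked against the
#'   geminin rise onset (the earlier of the two is used; a large disagreement
#'   flags the call `ambiguous`);
#' * G2 onset: onset of sustained SLBP decline;
#' * NEB: first frame of the terminal H1-high run; absent -> `censored` at
#'   the end.
#'
#' Degradation onsets are located by an exhaustive two-segment change-point
#' fit in log-intensity space: a flat plateau followed by a linear decline
#' (exponential decay), the change point minimizing the total squared error.
#' This is exact on noiseless traces and unbiased under multiplicative noise,
#' which is additive on the log scale. All boundaries land on the acquisition
#' grid, so durations are multiples of `dt`.
#'
#' @param trace a `fucci_trace`.
#' @param config a [caller_config()].
#' @return one-row data.frame (`phase_call`): boundary times `t_div_end`,
#'   `t_cdt1_deg`, `t_slbp_deg`, `t_neb`, durations `dur_g0g1`, `dur_s`,
#'   `dur_g2` (NA for phases lost to censoring) and `quality` in
#'   `complete`/`censored`/`ambiguous`.
#' @export
detect_events <- function(trace, config = caller_config()) {
  stopifnot(inherits(trace, "fucci_trace"))
  t <- trace$t
  n <- length(t)
  dt <- trace$dt
  steps <- diff(t)
  if (n < 6 || any(abs(steps - stats::median(steps)) > 1e-6))
    stop("trace time grid must be uniform", call. = FALSE)

  # --- mitosis flanks from the H1 channel ------------------------------
  h1s <- runmed3(trace$h1)
  thr <- (min(h1s) + max(h1s)) / 2
  high <- h1s > thr
  t_div <- NA_real_
  t_neb <- NA_real_
  if (high[1]) {
    i <- which(!high)[1]
    if (!is.na(i)) t_div <- t[i]
  }
  if (high[n]) {
    j <- n - which(!rev(high))[1] + 2L # first frame of the terminal run
    if (j >= 1 && j <= n) t_neb <- t[j]
  }
  censored_start <- is.na(t_div) || isTRUE(trace$censored_start)
  censored_end <- is.na(t_neb) || isTRUE(trace$censored_end)
  if (is.na(t_div)) t_div <- t[1]
  if (is.na(t_neb)) t_neb <- t[n] + dt

  win <- which(t > t_div & t < t_neb)
  out <- data.frame(cell_id = trace$cell_id,
                    t_div_end = if (censored_start) NA_real_ else t_div,
                    t_cdt1_deg = NA_real_, t_slbp_deg = NA_real_,
                    t_neb = if (censored_end) NA_real_ else t_neb,
                    dur_g0g1 = NA_real_, dur_s = NA_real_, dur_g2 = NA_real_,
                    quality = "censored",
                    experiment_id = trace$experiment_id,
                    condition = trace$condition, stringsAsFactors = FALSE)
  if (length(win) < 8) return(out)

  # --- S onset: Cdt1 decline, geminin rise cross-check ------------------
  t_cdt1 <- decay_onset(trace$cdt1, t, win, config)
  t_gem <- rise_onset(trace$geminin, t, win, config)
  ambiguous <- FALSE
  if (!is.na(t_cdt1) && !is.na(t_gem)) {
    if (abs(t_cdt1 - t_gem) > config$ambiguity_gap_h) ambiguous <- TRUE
    t_s <- min(t_cdt1, t_gem)
  } else t_s <- if (!is.na(t_cdt1)) t_cdt1 else t_gem

  # --- G2 onset: SLBP decline (searched after the S onset) --------------
  t_slbp <- NA_real_
  if (!is.na(t_s)) {
    win2 <- win[t[win] >= t_s]
    if (length(win2) >= 6) t_slbp <- decay_onset(trace$slbp, t, win2, config)
  }

  out$t_cdt1_deg <- t_s
  out$t_slbp_deg <- t_slbp
  ok_order <- !is.na(t_s) && !is.na(t_slbp) && t_div < t_s &&
    t_s < t_slbp && t_slbp < t_neb
  if (!censored_start && !is.na(t_s)) out$dur_g0g1 <- t_s - t_div
  if (!is.na(t_s) && !is.na(t_slbp) && t_slbp > t_s) out$dur_s <- t_slbp - t_s
  if (!censored_end && !is.na(t_slbp)) out$dur_g2 <- t_neb - t_slbp

  out$quality <- if (censored_start || censored_end) "censored"
  else if (ambiguous || !ok_order) "ambiguous"
  else "complete"
  if (out$quality != "complete" && !ok_order) {
    # keep only the durations that are well defined
    if (is.na(t_s) || !(t_div < t_s)) out$dur_g0g1 <- NA_real_
    if (is.na(t_s) || is.na(t_slbp) || !(t_s < t_slbp)) out$dur_s <- NA_real_
    if (is.na(t_slbp) || !(t_slbp < t_neb)) out$dur_g2 <- NA_real_
  }
  out
}

#' Call phases on a whole cohort
#'
#' @param traces list of `fucci_trace`.
#' @param config a [caller_config()].
#' @return data.frame of phase calls, one row per cell.
#' @export
detect_events_cohort <- function(traces, config = caller_config()) {
  do.call(rbind, lapply(traces, detect_events, config = config))
}

runmed3 <- function(x) {
  if (length(x) < 3) return(x)
  stats::runmed(x, 3)
}

# Exhaustive two-segment change-point fit on log intensities: flat plateau up
# to the onset frame, linear (exponential) decline after it. Returns the onset
# time, or NA when no decline is present in the window.
decay_onset <- function(y, t, win, config) {
  yl <- log(pmax(y[win], 1e-8))
  tw <- t[win]
  n <- length(yl)
  # truncate once the signal has clearly left the exponential regime
  peak <- cummax(runmed3(yl))
  below <- which(runmed3(yl) < peak - config$log_floor_drop)
  if (length(below)) {
    n <- max(below[1], 8L)
    if (n > length(yl)) n <- length(yl)
    yl <- yl[seq_len(n)]; tw <- tw[seq_len(n)]
  }
  if (n < 6) return(NA_real_)

  cy <- cumsum(yl); cy2 <- cumsum(yl^2)
  cty <- cumsum(tw * yl); ct <- cumsum(tw); ct2 <- cumsum(tw^2)
  cand <- 2:(n - 3) # onset frame: >=2 plateau frames, >=3 decline frames
  m <- length(cand)
  A <- cy[cand] / cand
  sse1 <- cy2[cand] - cand * A^2
  n2 <- n - cand
  sy <- cy[n] - cy[cand]
  sy2 <- cy2[n] - cy2[cand]
  sty <- cty[n] - cty[cand]
  st <- ct[n] - ct[cand]
  st2 <- ct2[n] - ct2[cand]
  tc <- tw[cand]
  sdr <- (sty - tc * sy) - A * (st - tc * n2)      # sum d * r
  sd2 <- st2 - 2 * tc * st + tc^2 * n2             # sum d^2
  sr2 <- sy2 - 2 * A * sy + n2 * A^2               # sum r^2
  slope <- pmin(sdr / sd2, 0)                      # decline only
  sse2 <- sr2 - 2 * slope * sdr + slope^2 * sd2
  tot <- sse1 + sse2
  best <- which.min(tot)
  if (slope[best] == 0) return(NA_real_) # no decline found
  tw[cand[best]]
}

# Threshold rule for an expression rise: last baseline frame before the signal
# stays above baseline + rise_frac * range for min_run consecutive frames.
rise_onset <- function(y, t, win, config) {
  ys <- runmed3(y[win])
  tw <- t[win]
  n <- length(ys)
  base <- stats::median(ys[seq_len(max(3, min(6, n %/% 4)))])
  rng <- max(ys) - base
  if (rng <= 0) return(NA_real_)
  thr <- base + config$rise_frac * rng
  above <- ys > thr
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= config$min_run) {
      onset <- i - run # last frame at baseline
      if (onset < 1) onset <- 1L
      return(tw[onset])
    }
  }
  NA_real_
}
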