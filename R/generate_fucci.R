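#' Synthesize a FUCCI4 cell-cycle trace cohort with known ground truth
#'
#' Generates per-cell four-channel fluorescence time series sampled every
#' `preset$dt` hours, together with the exact phase-boundary times used to
#' build each trace. Phase durations are drawn from the preset's duration
#' distributions, boundaries are snapped to the acquisition grid (so true
#' durations are multiples of `dt`), and channels follow the FUCCI4 reporter
#' logic (see [fucci_preset()]). Each trace is bracketed by short H1-high
#' mitotic flanks: the end of the initial flank marks completion of division
#' and the first frame of the terminal flank marks nuclear envelope breakdown
#' (NEB).
#'
#' Intensity noise is multiplicative Gaussian, `I * (1 + eps)` with
#' `eps ~ N(0, noise_sd)`, floored at zero. With `censor_frac > 0` a random
#' subset of traces is truncated at the start (begins mid-cycle) or before NEB
#' and flagged accordingly.
#'
#' @param preset a [fucci_preset()].
#' @param n_cells number of cells (>= 1).
#' @param seed integer seed; the cohort is bit-reproducible given the seed.
#' @param n_experiments cells are assigned round-robin to this many
#'   pseudo-experiments (experiment-level statistics act on their means).
#' @return list with `traces` (list of `fucci_trace`) and `truth`
#'   (data.frame, one row per cell: boundary times, durations, prolonged-
#'   component flag, censoring flags).
#' @export
generate_fucci_cohort <- function(preset, n_cells, seed = NULL,
                                  n_experiments = 3) {
  stopifnot(inherits(preset, "fucci_preset"))
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  dt <- preset$dt

  g1 <- sample_duration(preset$dist_g0g1, n_cells)
  s <- sample_duration(preset$dist_s, n_cells)
  g2 <- sample_duration(preset$dist_g2, n_cells)
  comp <- attr(g2, "component")
  prolonged <- if (is.null(comp)) rep(FALSE, n_cells) else comp == 2L

  snap <- function(x) round(x / dt) * dt
  min_frames <- 2L # every phase spans at least 2 frames after snapping
  censor <- if (preset$censor_frac > 0)
    sample(c("none", "start", "end"), n_cells, replace = TRUE,
           prob = c(1 - preset$censor_frac, preset$censor_frac / 2,
                    preset$censor_frac / 2))
  else rep("none", n_cells)

  traces <- vector("list", n_cells)
  truth <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    t_s <- snap(g1[i])
    t_g2 <- snap(g1[i] + s[i])
    t_neb <- snap(g1[i] + s[i] + g2[i])
    t_s <- max(t_s, min_frames * dt)
    t_g2 <- max(t_g2, t_s + min_frames * dt)
    t_neb <- max(t_neb, t_g2 + min_frames * dt)
    id <- sprintf("cell_%04d", i)
    tr <- synth_fucci_trace(id, t_s, t_g2, t_neb, preset, censor[i])
    tr$experiment_id <- sprintf("exp_%d", ((i - 1L) %% n_experiments) + 1L)
    tr$condition <- preset$name
    traces[[i]] <- tr
    truth[[i]] <- data.frame(
      cell_id = id, t_div_end = 0, t_cdt1_deg = t_s, t_slbp_deg = t_g2,
      t_neb = t_neb, dur_g0g1 = t_s, dur_s = t_g2 - t_s,
      dur_g2 = t_neb - t_g2, prolonged = prolonged[i],
      censored_start = tr$censored_start, censored_end = tr$censored_end,
      experiment_id = tr$experiment_id, condition = tr$condition,
      stringsAsFactors = FALSE
    )
  }
  list(traces = traces, truth = do.call(rbind, truth))
}

# Build one trace from exact grid-aligned boundaries (division end at t = 0).
synth_fucci_trace <- function(cell_id, t_s, t_g2, t_neb, preset, censor = "none") {
  dt <- preset$dt
  ch <- preset$channels
  m <- round(preset$mitosis_h / dt) * dt
  t <- seq(-m, t_neb + m, by = dt)
  t <- round(t / dt) * dt # keep the grid exactly uniform

  rise <- function(amp, k, tau) amp * (1 - exp(-k * pmax(tau, 0)))

  # Cdt1: rises from division end, degraded from S onset.
  cdt1 <- ifelse(t <= t_s,
                 ch$cdt1$base + rise(ch$cdt1$amp, ch$cdt1$rise, t),
                 NA_real_)
  v_s <- ch$cdt1$base + rise(ch$cdt1$amp, ch$cdt1$rise, t_s)
  cdt1[t > t_s] <- v_s * exp(-ch$cdt1$decay * (t[t > t_s] - t_s))

  # SLBP: present through G0/G1 + S, degraded from G2 onset.
  slbp <- ifelse(t <= t_g2,
                 ch$slbp$base + rise(ch$slbp$amp, ch$slbp$rise, t),
                 NA_real_)
  v_g2 <- ch$slbp$base + rise(ch$slbp$amp, ch$slbp$rise, t_g2)
  slbp[t > t_g2] <- v_g2 * exp(-ch$slbp$decay * (t[t > t_g2] - t_g2))

  # Geminin: baseline until S onset, rises through S + G2, collapses at NEB.
  geminin <- rep(ch$geminin$base, length(t))
  in_rise <- t > t_s & t < t_neb
  geminin[in_rise] <- ch$geminin$base +
    rise(ch$geminin$amp, ch$geminin$rise, t[in_rise] - t_s)
  v_neb <- ch$geminin$base + rise(ch$geminin$amp, ch$geminin$rise, t_neb - t_s)
  post <- t >= t_neb
  geminin[post] <- ch$geminin$base +
    (v_neb - ch$geminin$base) * exp(-ch$geminin$decay * (t[post] - t_neb))

  # H1 condensation channel: high during the mitotic flanks.
  h1 <- ifelse(t < 0 | t >= t_neb, ch$h1$high, ch$h1$base)

  censored_start <- FALSE
  censored_end <- FALSE
  keep <- rep(TRUE, length(t))
  if (censor == "start") {
    cut <- stats::runif(1, dt, max(t_s - dt, dt))
    keep <- t >= cut
    censored_start <- TRUE
  } else if (censor == "end") {
    cut <- stats::runif(1, t_s + dt, t_neb - dt)
    keep <- t <= cut
    censored_end <- TRUE
  }

  noisy <- function(x) {
    if (preset$noise_sd == 0) return(x)
    pmax(x * (1 + stats::rnorm(length(x), 0, preset$noise_sd)), 0)
  }
  structure(list(
    cell_id = cell_id, t = t[keep], dt = dt,
    cdt1 = noisy(cdt1[keep]), slbp = noisy(slbp[keep]),
    geminin = noisy(geminin[keep]), h1 = noisy(h1[keep]),
    censored_start = censored_start, censored_end = censored_end,
    experiment_id = NA_character_, condition = NA_character_
  ), class = "fucci_trace")
}

#' Convert a trace cohort to a long-format table
#'
#' One row per cell-timepoint with the four channel intensities; the inverse
#' of [traces_from_table()]. This is the on-disk exchange format (write with
#' [utils::write.csv()]).
#'
#' @param traces list of `fucci_trace`.
#' @return data.frame in long format.
#' @export
traces_to_table <- function(traces) {
  do.call(rbind, lapply(traces, function(tr) {
    data.frame(cell_id = tr$cell_id, t = tr$t, cdt1 = tr$cdt1, slbp = tr$slbp,
               geminin = tr$geminin, h1 = tr$h1,
               censored_start = tr$censored_start,
               censored_end = tr$censored_end,
               experiment_id = tr$experiment_id, condition = tr$condition,
               stringsAsFactors = FALSE)
  }))
}

#' @rdname traces_to_table
#' @param tab a long-format trace table.
#' @export
traces_from_table <- function(tab) {
  lapply(split(tab, tab$cell_id), function(d) {
    d <- d[order(d$t), ]
    structure(list(
      cell_id = d$cell_id[1], t = d$t, dt = stats::median(diff(d$t)),
      cdt1 = d$cdt1, slbp = d$slbp, geminin = d$geminin, h1 = d$h1,
      censored_start = d$censored_start[1], censored_end = d$censored_end[1],
      experiment_id = d$experiment_id[1], condition = d$condition[1]
    ), class = "fucci_trace")
  })
}
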