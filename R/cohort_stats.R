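#' Cohort-level phase statistics
#'
#' Summarizes a table of phase calls the way monolayer cohorts are reported:
#' per-phase mean and SD computed on the *means of independent experiments*
#' (never on pooled cells), the 99th-percentile G2 reference threshold, the
#' prolonged-G2 fraction relative to that threshold, and (optionally) the
#' fraction of cells in G2 at a snapshot time.
#'
#' @param calls data.frame of phase calls ([detect_events_cohort()] output or
#'   the generator's truth table). Only `quality == "complete"` rows (or rows
#'   with non-NA durations, for truth tables without a quality column) enter
#'   the statistics.
#' @param reference_calls optional reference cohort used for the
#'   prolonged-G2 threshold; when `NULL` the threshold is self-referential
#'   (the cohort's own G2 q99).
#' @param snapshot_time optional time (h) at which G2 occupancy is evaluated;
#'   requires boundary-time columns spanning the snapshot.
#' @param q probability for the reference quantile (default 0.99).
#' @return list of class `cohort_phase_stats`: `phase_means`, `phase_sds`
#'   (h, across experiment means; SD is NA with a single experiment),
#'   `q99_reference` (h), `prolonged_fraction` (%), `g2_occupancy` (% or NA),
#'   `n_complete`.
#' @export
cohort_stats <- function(calls, reference_calls = NULL, snapshot_time = NULL,
                         q = 0.99) {
  calls <- complete_calls(calls)
  if (nrow(calls) == 0) stop("empty cohort: no complete phase calls", call. = FALSE)

  exp_means <- function(col) {
    ok <- !is.na(calls[[col]])
    if (!any(ok)) return(numeric(0))
    tapply(calls[[col]][ok], calls$experiment_id[ok], mean)
  }
  phases <- c(g0g1 = "dur_g0g1", s = "dur_s", g2 = "dur_g2")
  means <- vapply(phases, function(col) {
    m <- exp_means(col); if (length(m)) mean(m) else NA_real_
  }, 0)
  sds <- vapply(phases, function(col) {
    m <- exp_means(col); if (length(m) > 1) stats::sd(m) else NA_real_
  }, 0)

  ref <- if (is.null(reference_calls)) calls else complete_calls(reference_calls)
  ref_g2 <- ref$dur_g2[!is.na(ref$dur_g2)]
  if (!length(ref_g2)) stop("reference cohort has no complete G2 durations", call. = FALSE)
  q99 <- unname(stats::quantile(ref_g2, q, type = 7))

  g2 <- calls$dur_g2[!is.na(calls$dur_g2)]
  prolonged <- 100 * mean(g2 > q99)

  occ <- NA_real_
  if (!is.null(snapshot_time)) {
    need <- c("t_div_end", "t_slbp_deg", "t_neb")
    if (!all(need %in% names(calls)))
      stop("snapshot occupancy needs boundary-time columns", call. = FALSE)
    span <- !is.na(calls$t_div_end) & !is.na(calls$t_neb) &
      calls$t_div_end <= snapshot_time & snapshot_time < calls$t_neb
    if (!any(span)) stop("no traces span the snapshot time", call. = FALSE)
    in_g2 <- span & !is.na(calls$t_slbp_deg) &
      calls$t_slbp_deg <= snapshot_time
    occ <- 100 * sum(in_g2) / sum(span)
  }

  structure(list(phase_means = means, phase_sds = sds, q99_reference = q99,
                 prolonged_fraction = prolonged, g2_occupancy = occ,
                 n_complete = nrow(calls)), class = "cohort_phase_stats")
}

complete_calls <- function(calls) {
  if ("quality" %in% names(calls)) calls[calls$quality == "complete", , drop = FALSE]
  else calls[!is.na(calls$dur_g2), , drop = FALSE]
}

#' @export
print.cohort_phase_stats <- function(x, ...) {
  cat("<cohort_phase_stats>  n =", x$n_complete, "complete cells\n")
  for (ph in names(x$phase_means))
    cat(sprintf("  %-5s mean %5.2f h  sd(exp) %s h\n", ph, x$phase_means[ph],
                ifelse(is.na(x$phase_sds[ph]), "  NA",
                       sprintf("%4.2f", x$phase_sds[ph]))))
  cat(sprintf("  G2 q99 reference: %.2f h   prolonged fraction: %.1f%%\n",
              x$q99_reference, x$prolonged_fraction))
  if (!is.na(x$g2_occupancy))
    cat(sprintf("  G2 occupancy at snapshot: %.1f%%\n", x$g2_occupancy))
  invisible(x)
}
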