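#' Normalize per-cell stain intensities to a co-stain and a control condition
#'
#' Standard two-step immunofluorescence normalization: the per-cell ratio
#' target/normalizer corrects for staining efficiency, and within each
#' experiment all ratios are rescaled by the median ratio of the control
#' condition so that experiments are comparable. The unscaled ratios are kept
#' (`ratio` column) because experiment-level statistics act on the original,
#' not rescaled, values.
#'
#' @param table data.frame with columns `cell_id`, `target_intensity`,
#'   `normalizer_intensity`, `experiment_id`, `condition`.
#' @param control_condition label of the control condition; must be present
#'   in every experiment.
#' @return the input with added columns `ratio` and `rescaled`.
#' @export
normalize_intensity <- function(table, control_condition) {
  need <- c("target_intensity", "normalizer_intensity", "experiment_id",
            "condition")
  if (!all(need %in% names(table)))
    stop("missing columns: ", paste(setdiff(need, names(table)), collapse = ", "),
         call. = FALSE)
  if (any(table$target_intensity <= 0 | table$normalizer_intensity <= 0))
    stop("intensities must be > 0 for normalized ratios", call. = FALSE)
  table$ratio <- table$target_intensity / table$normalizer_intensity
  table$rescaled <- NA_real_
  for (ex in unique(table$experiment_id)) {
    in_ex <- table$experiment_id == ex
    ctrl <- in_ex & table$condition == control_condition
    if (!any(ctrl))
      stop("control condition '", control_condition,
           "' missing in experiment ", ex, call. = FALSE)
    med <- stats::median(table$ratio[ctrl])
    table$rescaled[in_ex] <- table$ratio[in_ex] / med
  }
  table
}

#' Experiment-level two-group tests
#'
#' The tests operate on *experiment means* (one value per experiment per
#' group), never on pooled cells:
#'
#' * `paired_t` -- two-sided paired t test,
#' * `ratio_paired_t` -- two-sided paired t test on natural-log-transformed
#'   values (tests mean ratio = 1),
#' * `mann_whitney` -- two-sided Wilcoxon rank-sum test,
#' * `pearson` -- Pearson correlation with two-sided p.
#'
#' A paired test with zero variance of the (log-)differences is reported as a
#' degenerate case (`degenerate = TRUE`, statistic and p `NA`) rather than
#' `NaN`.
#'
#' @param x,y paired lists of per-experiment means (for `pearson`, the two
#'   correlated variables).
#' @param kind test kind.
#' @return list with `statistic`, `p`, `kind`, and `degenerate`.
#' @export
group_test <- function(x, y, kind = c("paired_t", "ratio_paired_t",
                                      "mann_whitney", "pearson")) {
  kind <- match.arg(kind)
  if (kind %in% c("paired_t", "ratio_paired_t", "pearson")) {
    if (length(x) != length(y)) stop("paired inputs must have equal length", call. = FALSE)
    if (length(x) < 3) stop("need >= 3 pairs", call. = FALSE)
  } else if (length(x) < 2 || length(y) < 2) {
    stop("need >= 2 observations per group", call. = FALSE)
  }
  if (kind == "ratio_paired_t") {
    if (any(x <= 0 | y <= 0)) stop("ratio paired t needs positive values", call. = FALSE)
    x <- log(x); y <- log(y)
    kind_run <- "paired_t"
  } else kind_run <- kind

  if (kind_run == "paired_t") {
    d <- x - y
    if (stats::sd(d) < 1e-12 * max(abs(d), 1)) {
      # identical pairs: no effect, no evidence (t = 0, p = 1); constant
      # nonzero (log-)difference: zero-variance degenerate case
      if (max(abs(d)) < 1e-12 * max(abs(c(x, y)), 1))
        return(list(statistic = 0, p = 1, kind = kind, degenerate = FALSE))
      return(list(statistic = NA_real_, p = NA_real_, kind = kind,
                  degenerate = TRUE))
    }
    ht <- stats::t.test(x, y, paired = TRUE)
  } else if (kind_run == "mann_whitney") {
    ht <- stats::wilcox.test(x, y, exact = FALSE)
  } else {
    ht <- stats::cor.test(x, y, method = "pearson")
  }
  list(statistic = unname(ht$statistic), p = ht$p.value, kind = kind,
       degenerate = FALSE)
}

#' Mitotic fraction per time window and fold change over baseline
#'
#' @param events an event table ([generate_wound_timecourse()] format): NEB
#'   times plus `population_size`.
#' @param windows list (or 2-column matrix) of `(start, end]` windows in h.
#' @param baseline index of the baseline window (default 1).
#' @return data.frame with `start`, `end`, `n_events`, `fraction` (%) and
#'   `fold_change` vs the baseline window (NA, with a warning, if the
#'   baseline fraction is zero).
#' @export
mitotic_fraction_timecourse <- function(events, windows, baseline = 1) {
  if (is.list(windows)) windows <- do.call(rbind, windows)
  pop <- unique(events$population_size)
  if (length(pop) != 1) stop("mixed population sizes", call. = FALSE)
  neb <- events$neb_time[!is.na(events$neb_time)]
  n_ev <- apply(windows, 1, function(w) sum(neb > w[1] & neb <= w[2]))
  frac <- 100 * n_ev / pop
  base <- frac[baseline]
  if (base == 0) {
    warning("baseline mitotic fraction is zero; fold change undefined")
    fold <- rep(NA_real_, length(frac))
  } else fold <- frac / base
  data.frame(start = windows[, 1], end = windows[, 2], n_events = n_ev,
             fraction = frac, fold_change = fold)
}

#' Classify monolayer density
#'
#' MDCK monolayer density classes: low 1000--2200 cells/mm^2, high
#' 2600--4500, contact-inhibited (CIP) above 4500; densities in the gaps
#' (below 1000 or 2200--2600) carry no class.
#'
#' @param density cells/mm^2 (vectorized, >= 0).
#' @return factor with levels `low`, `high`, `CIP`, `unclassified`.
#' @export
classify_density <- function(density) {
  if (any(density < 0)) stop("density must be >= 0", call. = FALSE)
  out <- rep("unclassified", length(density))
  out[density >= 1000 & density <= 2200] <- "low"
  out[density >= 2600 & density <= 4500] <- "high"
  out[density > 4500] <- "CIP"
  factor(out, levels = c("low", "high", "CIP", "unclassified"))
}
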