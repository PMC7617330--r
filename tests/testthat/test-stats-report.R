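test_that("intensity normalization rescales to the control median per experiment", {
  tab <- data.frame(cell_id = 1:4,
                    target_intensity = c(1, 2, 3, 4),
                    normalizer_intensity = 1,
                    experiment_id = "e1",
                    condition = c("ctrl", "ctrl", "ctrl", "test"))
  out <- normalize_intensity(tab, "ctrl")
  expect_equal(out$rescaled[4], 2.0) # control median = 2
  expect_equal(out$ratio, c(1, 2, 3, 4)) # originals kept
  # all-identical cells rescale to exactly 1
  tab2 <- tab; tab2$target_intensity <- 5
  expect_equal(unique(normalize_intensity(tab2, "ctrl")$rescaled), 1.0)
  tab3 <- tab; tab3$condition <- "test"
  expect_error(normalize_intensity(tab3, "ctrl"), "missing in experiment e1")
  tab4 <- tab; tab4$target_intensity[1] <- 0
  expect_error(normalize_intensity(tab4, "ctrl"), "> 0")
})

test_that("a known condition effect survives experiment-specific gains", {
  set.seed(17)
  make_exp <- function(id, gain) {
    n <- 60
    cond <- rep(c("ctrl", "dense"), each = n)
    eff <- ifelse(cond == "dense", 2, 1)
    data.frame(cell_id = paste0(id, "_", 1:(2 * n)),
               target_intensity = gain * eff * rlnorm(2 * n, 0, 0.2),
               normalizer_intensity = rlnorm(2 * n, 0, 0.1),
               experiment_id = id, condition = cond)
  }
  tab <- rbind(make_exp("e1", 1), make_exp("e2", 7))
  out <- normalize_intensity(tab, "ctrl")
  m <- tapply(out$rescaled, list(out$experiment_id, out$condition), mean)
  expect_equal(mean(m[, "dense"] / m[, "ctrl"]), 2, tolerance = 0.15)
  # rescaling preserves the within-experiment ordering of condition effects
  r <- tapply(out$ratio, list(out$experiment_id, out$condition), mean)
  expect_equal(sign(r[, "dense"] - r[, "ctrl"]),
               sign(m[, "dense"] - m[, "ctrl"]))
})

test_that("group tests handle their canonical and degenerate cases", {
  same <- group_test(c(1, 2, 3), c(1, 2, 3), kind = "paired_t")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_false(same$degenerate)
  # constant ratio: zero variance on the log scale -> degenerate flag
  const <- group_test(c(1, 2, 3), c(2, 4, 6), kind = "ratio_paired_t")
  expect_true(const$degenerate)
  expect_true(is.na(const$p))
  expect_error(group_test(c(1, 2), c(3, 4), kind = "paired_t"), ">= 3 pairs")
  expect_error(group_test(c(1, -2, 3), c(1, 2, 3), kind = "ratio_paired_t"),
               "positive")
  # pearson matches cor.test
  set.seed(2); x <- rnorm(10); y <- x + rnorm(10)
  g <- group_test(x, y, kind = "pearson")
  ct <- cor.test(x, y)
  expect_equal(g$statistic, unname(ct$statistic))
  expect_equal(g$p, ct$p.value)
  # mann-whitney two-sided rank-sum
  mw <- group_test(c(1, 2, 3, 4), c(10, 11, 12, 13), kind = "mann_whitney")
  expect_lt(mw$p, 0.05)
})

test_that("paired tests hold their nominal type-I error on experiment means", {
  set.seed(19)
  n_rep <- 2000 # quick calibration; the acceptance suite runs 10,000
  hits <- hits_ratio <- 0
  for (i in seq_len(n_rep)) {
    x <- rnorm(4); y <- rnorm(4)
    hits <- hits + (group_test(x, y, kind = "paired_t")$p < 0.05)
    a <- rlnorm(4); b <- rlnorm(4)
    hits_ratio <- hits_ratio + (group_test(a, b, kind = "ratio_paired_t")$p < 0.05)
  }
  expect_gt(hits / n_rep, 0.03)
  expect_lt(hits / n_rep, 0.07)
  expect_gt(hits_ratio / n_rep, 0.03)
  expect_lt(hits_ratio / n_rep, 0.07)
})

test_that("mitotic fractions and fold changes follow the counting rules", {
  ev <- data.frame(cell_id = paste0("c", 1:100),
                   neb_time = c(runif(5, 0.1, 1), rep(NA, 95)),
                   condition = "x", experiment_id = "e1",
                   population_size = 100)
  tc <- mitotic_fraction_timecourse(ev, cbind(0, 1))
  expect_equal(tc$fraction, 5.0)
  ev2 <- ev
  ev2$neb_time <- c(runif(1, 0.1, 1), runif(3, 1.1, 2), rep(NA, 96))
  tc2 <- mitotic_fraction_timecourse(ev2, cbind(c(0, 1), c(1, 2)))
  expect_equal(tc2$fold_change, c(1, 3))
  ev3 <- ev; ev3$neb_time <- NA_real_
  expect_warning(tc3 <- mitotic_fraction_timecourse(ev3, cbind(c(0, 1), c(1, 2))),
                 "baseline")
  expect_true(all(is.na(tc3$fold_change)))
})

test_that("density classes follow the published ranges", {
  expect_equal(as.character(classify_density(c(1500, 5000, 2400, 800, 2600,
                                               4500, 1000, 2200))),
               c("low", "CIP", "unclassified", "unclassified", "high",
                 "high", "low", "low"))
  expect_error(classify_density(-5), ">= 0")
})
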