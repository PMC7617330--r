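test_that("integer translations are recovered exactly on interior windows", {
  sp <- generate_speckle_pair(c(3, -2), c(128, 128), seed = 5)
  # image_b is image_a translated (interior)
  expect_equal(sp$image_b[10:119, 10:119], sp$image_a[(10:119) + 2, (10:119) - 3])
  f <- compute_piv(sp$image_a, sp$image_b)
  cx <- attr(f, "centers_x"); cy <- attr(f, "centers_y")
  interior <- outer(cy > 24 & cy < 104, cx > 24 & cx < 104, "&")
  expect_equal(f$u[interior], rep(3, sum(interior)))
  expect_equal(f$v[interior], rep(-2, sum(interior)))
  expect_true(all(f$mask[interior])) # |v| = 3.61 <= 5 px/frame
})

test_that("vectors above 5 px/frame are excluded", {
  sp <- generate_speckle_pair(c(5, 4), c(128, 128), seed = 6)
  f <- compute_piv(sp$image_a, sp$image_b)
  expect_true(all(!f$mask)) # |v| ~ 6.4
  # the displacements themselves are still recovered
  expect_equal(mean(f$u), 5, tolerance = 0.05)
  expect_equal(mean(f$v), 4, tolerance = 0.05)
})

test_that("identical images give an exactly zero field", {
  sp <- generate_speckle_pair(c(0, 0), c(96, 96), seed = 8)
  expect_identical(sp$image_a, sp$image_b)
  f <- compute_piv(sp$image_a, sp$image_b)
  expect_equal(max(abs(f$u)), 0)
  expect_equal(max(abs(f$v)), 0)
})

test_that("smooth shear flow is recovered with low RMS error and bias", {
  fl <- function(x, y) list(u = 3 * (y - 96) / 96, v = rep(0, length(x)))
  sp <- generate_speckle_pair(fl, c(192, 192), seed = 7)
  f <- compute_piv(sp$image_a, sp$image_b)
  cy <- attr(f, "centers_y")
  true_u <- outer(3 * (cy - 96) / 96, rep(1, ncol(f$u)))
  err <- sqrt(mean((f$u - true_u)^2 + f$v^2))
  expect_lt(err, 0.2)
  expect_lt(abs(mean(f$u - true_u)), 0.1) # sub-pixel bias bound
})

test_that("window geometry follows size and overlap and rejects small images", {
  sp <- generate_speckle_pair(c(1, 0), c(96, 96), seed = 9)
  f <- compute_piv(sp$image_a, sp$image_b, piv_config(window = 24, overlap = 0.5))
  expect_equal(diff(attr(f, "centers_x"))[1], 12) # 50% overlap -> step 12
  expect_equal(attr(f, "centers_x")[1], 12.5) # first full window center
  expect_error(compute_piv(matrix(0, 10, 10), matrix(0, 10, 10)),
               "smaller than one window")
  expect_error(compute_piv(sp$image_a, sp$image_a[1:90, ]), "same shape")
})

test_that("excluded vectors never contribute to speed summaries", {
  u <- matrix(2, 4, 4); v <- matrix(0, 4, 4)
  u[1, 1] <- 50 # huge spurious vector
  mask <- u <= 5
  f <- vector_field(u, v, 12, role = "displacement", units = "px", mask = mask)
  cfg <- piv_config(px_size = 0.65, dt = 1 / 6)
  out <- speed_summary(list(f), cfg)
  expect_equal(out$mean_speed, 2 * 0.65 * 6) # 7.8 um/h
})

test_that("speed-density correlation recovers exact and noisy relations", {
  cfg <- piv_config(px_size = 0.65, dt = 1 / 6)
  # exactly linear-decreasing speeds -> r = -1
  dens <- c(1000, 2000, 3000, 4000)
  fields <- lapply(c(4, 3, 2, 1), function(sp)
    vector_field(matrix(sp, 3, 3), matrix(0, 3, 3), 12,
                 role = "displacement", units = "px"))
  out <- speed_summary(fields, cfg, dens)
  expect_equal(out$pearson_r, -1)
  # generator-imposed monotone relation with noise
  mv <- make_speed_density_movies(12, seed = 10)
  out2 <- speed_summary(mv$fields, cfg, mv$densities)
  r_true <- cor(mv$densities, mv$true_speeds_px)
  expect_lt(out2$pearson_r, -0.8)
  expect_equal(out2$pearson_r, r_true, tolerance = 0.05)
  expect_lt(out2$p, 0.001)
})

test_that("speckle generator rejects flows beyond the capture range", {
  expect_error(generate_speckle_pair(c(13, 0), c(64, 64), seed = 1),
               "capture range")
})
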