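strip_scene <- function(n = 128, spacing = 2, magnitude = 100, aspect = 0.05) {
  generate_traction_scene("contractile_strip", magnitude, gel_spec(),
                          grid = list(n = n, spacing = spacing),
                          strip_frac = 200 / (n * spacing),
                          strip_aspect = aspect)
}

test_that("zero traction recovers zero stress", {
  z <- vector_field(matrix(0, 16, 16), matrix(0, 16, 16), 5,
                    role = "traction", units = "Pa")
  mask <- matrix(TRUE, 16, 16)
  st <- recover_stress(z, mask)
  expect_equal(max(abs(st$sxx)) + max(abs(st$syy)) + max(abs(st$sxy)), 0)
})

test_that("contractile strip reproduces the 1-D force-balance oracle", {
  sc <- strip_scene()
  st <- recover_stress(sc$scene$traction, sc$scene$mask, nu_m = 0.5)
  ts <- tension_summary(st)
  # peak tension at the midline: 100 Pa x 100 um = 10 mN/m, within 1%
  expect_equal(max(ts$tension_map, na.rm = TRUE), 10, tolerance = 0.01)
  # triangular profile along x matches the direct quadrature of T
  rows <- which(apply(sc$scene$mask, 1, any))
  cols <- which(apply(sc$scene$mask, 2, any))
  prof <- colMeans(ts$tension_map[rows, cols])
  oracle <- strip_tension_mNm(sc$scene$traction, sc$scene$mask)
  expect_equal(prof, oracle, tolerance = 0.02)
  # free edges carry (near) zero tension: below the half-element quadrature
  edge <- c(prof[1], prof[length(prof)])
  expect_lt(max(abs(edge)), 0.025 * max(prof))
  # mask average equals the triangle mean = half the peak
  expect_equal(ts$average_normal_tension, max(prof) / 2, tolerance = 0.01)
  # discrete equilibrium residual of the solve
  expect_lt(st$residual, 1e-3)
})

test_that("the 1-D strip solution is independent of the monolayer Poisson ratio", {
  sc <- strip_scene()
  p1 <- max(tension_summary(recover_stress(sc$scene$traction, sc$scene$mask,
                                           nu_m = 0.5))$tension_map, na.rm = TRUE)
  p2 <- max(tension_summary(recover_stress(sc$scene$traction, sc$scene$mask,
                                           nu_m = 0.3))$tension_map, na.rm = TRUE)
  expect_equal(p1, p2, tolerance = 0.01)
})

test_that("rotating the scene by 90 degrees rotates the recovered tensor", {
  sc <- generate_traction_scene("contractile_strip", 100,
                                grid = list(n = 64, spacing = 5),
                                strip_aspect = 0.3)
  tr <- sc$scene$traction; mask <- sc$scene$mask
  st <- recover_stress(tr, mask)
  # this array op rotates the grid 90 deg clockwise: (x, y) -> (y, -x),
  # under which vectors transform as (u, v) -> (v, -u)
  rot <- function(m) t(m)[nrow(t(m)):1, ]
  tr90 <- vector_field(rot(tr$v), rot(-tr$u), tr$spacing, role = "traction",
                       units = "Pa")
  st90 <- recover_stress(tr90, rot(mask))
  expect_equal(st90$sxx, rot(st$syy), tolerance = 1e-6)
  expect_equal(st90$syy, rot(st$sxx), tolerance = 1e-6)
  ts <- tension_summary(st); ts90 <- tension_summary(st90)
  expect_equal(ts90$average_normal_tension, ts$average_normal_tension,
               tolerance = 1e-6)
})

test_that("uniform isotropic tension averages to 2s under the sum convention", {
  mask <- matrix(TRUE, 8, 8)
  st <- structure(list(sxx = matrix(0.003, 8, 8), sxy = matrix(0, 8, 8),
                       syy = matrix(0.003, 8, 8), mask = mask, nu_m = 0.5,
                       spacing = 5, residual = 0), class = "stress_field")
  ts <- tension_summary(st)
  expect_equal(ts$average_normal_tension, 6) # 2 x 3 mN/m
  expect_equal(tension_summary(st, convention = "half")$average_normal_tension, 3)
  expect_error(tension_summary(structure(list(mask = matrix(FALSE, 2, 2),
                                              sxx = matrix(0, 2, 2),
                                              syy = matrix(0, 2, 2),
                                              sxy = matrix(0, 2, 2)),
                                         class = "stress_field")), "empty mask")
})

test_that("divergence of the recovered stress reproduces smooth tractions", {
  # smooth contractile disc on a full square mask (no load discontinuity)
  n <- 96; spacing <- 5
  x <- ((1:n) - (n + 1) / 2) * spacing
  X <- matrix(x, n, n, byrow = TRUE); Y <- matrix(x, n, n)
  s2 <- 80^2
  tx <- -100 * (X / 80) * exp(-(X^2 + Y^2) / (2 * s2))
  ty <- -100 * (Y / 80) * exp(-(X^2 + Y^2) / (2 * s2))
  tr <- vector_field(tx - mean(tx), ty - mean(ty), spacing, role = "traction",
                     units = "Pa")
  mask <- matrix(TRUE, n, n)
  st <- recover_stress(tr, mask)
  dv <- stress_divergence_fd(st)
  core <- matrix(FALSE, n, n)
  core[10:(n - 9), 10:(n - 9)] <- TRUE
  rel <- sqrt(sum((dv$dx[core] - tr$u[core])^2 + (dv$dy[core] - tr$v[core])^2) /
                sum(tr$u[core]^2 + tr$v[core]^2))
  expect_lt(rel, 0.01)
})

test_that("disconnected islands are solved independently", {
  n <- 64; spacing <- 5
  tx <- matrix(0, n, n); ty <- matrix(0, n, n)
  mask <- matrix(FALSE, n, n)
  mask[10:25, 10:25] <- TRUE
  mask[40:55, 40:55] <- TRUE
  tx[10:25, 10:17] <- 50; tx[10:25, 18:25] <- -50
  tx[40:55, 40:47] <- 80; tx[40:55, 48:55] <- -80
  tr <- vector_field(tx, ty, spacing, role = "traction", units = "Pa")
  st <- recover_stress(tr, mask)
  ts <- tension_summary(st)
  # each island carries its own triangular profile; peaks scale with load
  p1 <- max(ts$tension_map[10:25, 10:25], na.rm = TRUE)
  p2 <- max(ts$tension_map[40:55, 40:55], na.rm = TRUE)
  expect_equal(p2 / p1, 80 / 50, tolerance = 0.05)
  expect_true(all(is.na(ts$tension_map[!st$mask])))
})

test_that("an unbalanced net force triggers mean removal with a warning", {
  n <- 32
  tx <- matrix(10, n, n) # grossly unbalanced
  tr <- vector_field(tx, matrix(0, n, n), 5, role = "traction", units = "Pa")
  expect_warning(recover_stress(tr, matrix(TRUE, n, n)), "imbalance")
})
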