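test_that("forward operator is linear and maps zero to zero", {
  g <- gel_spec(12600, 0.49, thickness = 60)
  z <- vector_field(matrix(0, 32, 32), matrix(0, 32, 32), 5, role = "traction",
                    units = "Pa")
  dz <- forward_displacement(z, g)
  expect_equal(max(abs(dz$u)), 0)
  expect_equal(max(abs(dz$v)), 0)
  tr <- band_limited_traction(n = 32)
  d1 <- forward_displacement(tr, g)
  tr3 <- vector_field(3 * tr$u, 3 * tr$v, tr$spacing, role = "traction",
                      units = "Pa")
  d3 <- forward_displacement(tr3, g)
  expect_equal(d3$u, 3 * d1$u, tolerance = 1e-12)
})

test_that("finite-thickness kernel matches the independent Boussinesq oracle", {
  tr <- band_limited_traction(n = 64, spacing = 5)
  # semi-infinite gel against the closed-form half-space tensor
  g_inf <- gel_spec(12600, 0.49, thickness = Inf)
  d_pkg <- forward_displacement(tr, g_inf)
  d_ora <- boussinesq_forward(tr$u, tr$v, tr$spacing, 12600, 0.49)
  rel <- sqrt(sum((d_pkg$u - d_ora$u)^2 + (d_pkg$v - d_ora$v)^2) /
                sum(d_ora$u^2 + d_ora$v^2))
  expect_lt(rel, 1e-10)
  # a gel 1e4 x the field size behaves as a half-space to < 1%
  g_thick <- gel_spec(12600, 0.49, thickness = 1e4 * 64 * 5)
  d_thick <- forward_displacement(tr, g_thick)
  rel2 <- sqrt(sum((d_thick$u - d_ora$u)^2 + (d_thick$v - d_ora$v)^2) /
                 sum(d_ora$u^2 + d_ora$v^2))
  expect_lt(rel2, 0.01)
})

test_that("layer compliance converges monotonically to Boussinesq in kh", {
  g <- gel_spec(12600, 0.45, thickness = 1)
  kh <- seq(0.5, 8, by = 0.25)
  q <- layer_compliance(kh / g$thickness, g)
  q_b <- (1 - g$nu) / (g$mu * kh / g$thickness)
  ratioL <- q$QL / q_b
  expect_true(all(diff(ratioL) > -1e-9))
  expect_lt(abs(ratioL[length(ratioL)] - 1), 1e-4)
  # transverse branch is tanh(kh)/(mu k) exactly
  expect_equal(q$QT, tanh(kh) / (g$mu * kh / g$thickness), tolerance = 1e-12)
})

test_that("thin bonded layers reduce to the shear-lag limit u = T h / mu", {
  g <- gel_spec(10000, 0.4, thickness = 2)
  k <- 0.005 # kh = 0.01
  q <- layer_compliance(k, g)
  expect_equal(q$QL * g$mu / g$thickness, 1, tolerance = 0.01)
  expect_equal(q$QT * g$mu / g$thickness, 1, tolerance = 0.01)
})

test_that("forward -> inverse round trip is exact with zero regularization", {
  g <- gel_spec(12600, 0.49, thickness = 60)
  tr <- band_limited_traction(n = 64, spacing = 5)
  d <- forward_displacement(tr, g)
  rec <- invert_traction(d, g, reg_lambda = 0)
  rel <- sqrt(sum((rec$u - tr$u)^2 + (rec$v - tr$v)^2) /
                sum(tr$u^2 + tr$v^2))
  expect_lt(rel, 1e-6)
  # zero displacement -> zero traction
  z <- vector_field(matrix(0, 32, 32), matrix(0, 32, 32), 5,
                    role = "displacement", units = "um")
  tz <- invert_traction(z, gel_spec())
  expect_equal(max(abs(tz$u)), 0)
})

test_that("regularized inversion bounds the error on noisy scenes", {
  # displacement noise of 1% of the maximum is ~3% of the RMS; the k-linear
  # noise amplification of the inverse operator then sets an L2 floor of a
  # few times the data noise -- tighter for smooth scenes, looser for the
  # discontinuous strip whose edges cost extra under any spectral filter.
  run <- function(pattern, bound, seed, nseed) {
    sc <- generate_traction_scene(pattern, 100, gel_spec(12600, 0.49, 60),
                                  grid = list(n = 64, spacing = 5),
                                  seed = seed, dipole_sigma = 40)
    tr <- sc$scene$traction
    d <- forward_displacement(tr, sc$scene$gel)
    dmax <- max(abs(c(d$u, d$v)))
    set.seed(nseed)
    d$u <- d$u + rnorm(length(d$u), 0, 0.01 * dmax)
    d$v <- d$v + rnorm(length(d$v), 0, 0.01 * dmax)
    lam <- gcv_lambda(d, sc$scene$gel)$lambda
    rec <- invert_traction(d, sc$scene$gel, reg_lambda = lam)
    rel <- sqrt(sum((rec$u - tr$u)^2 + (rec$v - tr$v)^2) /
                  sum(tr$u^2 + tr$v^2))
    expect_lt(rel, bound)
    # regularization actually helps relative to the raw inverse
    raw <- invert_traction(d, sc$scene$gel, reg_lambda = 1e-8)
    rel_raw <- sqrt(sum((raw$u - tr$u)^2 + (raw$v - tr$v)^2) /
                      sum(tr$u^2 + tr$v^2))
    expect_lt(rel, rel_raw)
  }
  run("random_dipoles", 0.30, 21, 22)
  run("contractile_strip", 0.35, 13, 14)
})

test_that("Parseval bound: recovered traction energy is controlled by the data", {
  g <- gel_spec(12600, 0.49, 60)
  tr <- band_limited_traction(n = 32)
  d <- forward_displacement(tr, g)
  rec <- invert_traction(d, g, reg_lambda = 0)
  # ||T||_2 <= max|Q^-1| * ||u||_2 over the retained band
  k <- 2 * pi * abs(epimech:::fft_freq(32)) / (32 * tr$spacing)
  kmax <- sqrt(2) * max(k)
  qmin <- min(unlist(layer_compliance(kmax, g)))
  expect_lte(sqrt(sum(rec$u^2 + rec$v^2)),
             (1 / qmin) * sqrt(sum(d$u^2 + d$v^2)) * (1 + 1e-9))
})

test_that("traction scenes are force-balanced and respect their contracts", {
  sc <- generate_traction_scene("random_dipoles", 200, seed = 15)
  tr <- sc$scene$traction
  expect_lt(abs(sum(tr$u)) + abs(sum(tr$v)),
            1e-6 * sum(abs(tr$u) + abs(tr$v)))
  expect_true(all(tr$u[!sc$scene$mask] == 0))
  # zero magnitude -> pure noise displacement, zero truth
  sc0 <- generate_traction_scene("contractile_strip", 0, noise_sd = 0.01, seed = 16)
  expect_equal(max(abs(sc0$scene$traction$u)), 0)
  expect_gt(sd(sc0$displacement$u), 0)
  # strip displacement is antisymmetric about the midline (noiseless)
  sc1 <- generate_traction_scene("contractile_strip", 100,
                                 grid = list(n = 64, spacing = 5))
  u <- sc1$displacement$u
  expect_equal(u, -u[, ncol(u):1], tolerance = 1e-10)
  expect_error(generate_traction_scene("vortex", 1), "unknown")
})

test_that("inversion is stable under grid refinement on smooth scenes", {
  g <- gel_spec(12600, 0.49, 60)
  # same physical smooth traction sampled at two resolutions
  f <- function(n, spacing) {
    x <- ((1:n) - (n + 1) / 2) * spacing
    X <- matrix(x, n, n, byrow = TRUE); Y <- matrix(x, n, n)
    s2 <- 60^2
    tx <- 100 * (X / 60) * exp(-(X^2 + Y^2) / (2 * s2))
    ty <- 100 * (Y / 60) * exp(-(X^2 + Y^2) / (2 * s2))
    vector_field(tx - mean(tx), ty - mean(ty), spacing, role = "traction",
                 units = "Pa")
  }
  t1 <- f(48, 10); t2 <- f(96, 5)
  r1 <- invert_traction(forward_displacement(t1, g), g, 0)
  r2 <- invert_traction(forward_displacement(t2, g), g, 0)
  # compare on the coarse grid (every second fine pixel offset-matched)
  idx <- seq(1, 95, by = 2)
  rel <- sqrt(sum((r2$u[idx, idx] + r2$u[idx + 1, idx + 1] - 2 * r1$u)^2) /
                sum((2 * r1$u)^2))
  expect_lt(rel, 0.02)
})
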