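test_that("equal channels give index 0.5 on every valid pixel", {
  p <- fret_image_pair(matrix(1000, 32, 32), matrix(1000, 32, 32),
                       background_donor = 0, background_acceptor = 0)
  im <- compute_fret_index(p)
  expect_true(all(im$valid))
  expect_equal(unique(as.vector(im$index)), 0.5)
})

test_that("sub-threshold channels invalidate the map", {
  # donor everywhere below 4% of the 12-bit range
  p <- fret_image_pair(matrix(100, 32, 32), matrix(2000, 32, 32),
                       background_donor = 0, background_acceptor = 0)
  expect_warning(im <- compute_fret_index(p), "below threshold")
  expect_false(any(im$valid))
  expect_true(all(is.na(im$index)))
})

test_that("noiseless scenes are recovered exactly at pixel and contact level", {
  sc <- generate_fret_scene(2, c(0.3, 0.7), seed = 9)
  im <- compute_fret_index(sc$pair)
  for (i in 1:2) {
    on <- sc$contact_labels == i & im$valid
    expect_gt(sum(on), 50)
    expect_lt(max(abs(im$index[on] - c(0.3, 0.7)[i])), 1e-3)
  }
  tab <- contact_table(im, sc$pair)
  expect_equal(nrow(tab), 2)
  expect_equal(sort(tab$mean_index), c(30, 70), tolerance = 1e-3)
  expect_true(all(tab$mean_index >= 0 & tab$mean_index <= 100))
})

test_that("index is invariant to joint channel rescaling and monotone in acceptor", {
  sc <- generate_fret_scene(1, 0.4, background = 0, seed = 10, signal = 3000)
  im1 <- compute_fret_index(sc$pair)
  p2 <- fret_image_pair(sc$pair$donor / 2, sc$pair$acceptor / 2,
                        background_donor = 0, background_acceptor = 0)
  im2 <- compute_fret_index(p2)
  both <- im1$valid & im2$valid
  expect_equal(im2$index[both], im1$index[both], tolerance = 1e-12)
  # raising the acceptor strictly raises the index
  p3 <- fret_image_pair(sc$pair$donor, pmin(sc$pair$acceptor * 1.3, 4095),
                        background_donor = 0, background_acceptor = 0)
  im3 <- compute_fret_index(p3)
  on <- sc$contact_labels == 1 & im1$valid & im3$valid
  expect_true(all(im3$index[on] > im1$index[on]))
})

test_that("contact filtering and empty-scene contracts hold", {
  sc <- generate_fret_scene(2, c(0.3, 0.7), seed = 9)
  im <- compute_fret_index(sc$pair)
  expect_warning(tab <- contact_table(im, sc$pair, min_pixels = 10000),
                 "size filter")
  expect_equal(nrow(tab), 0)
  flat <- fret_image_pair(matrix(100, 32, 32), matrix(100, 32, 32),
                          background_donor = 100, background_acceptor = 100)
  imf <- suppressWarnings(compute_fret_index(flat))
  expect_warning(tabf <- contact_table(imf, flat), "no contacts|flat")
  expect_equal(nrow(tabf), 0)
})

test_that("threshold sweep across the 3-5% band shifts contact means boundedly", {
  sc <- generate_fret_scene(2, c(0.35, 0.65), noise_sd = 20, seed = 11)
  means_at <- function(th) {
    im <- compute_fret_index(sc$pair, threshold_frac = th)
    sort(contact_table(im, sc$pair)$mean_index)
  }
  m3 <- means_at(0.03); m5 <- means_at(0.05)
  expect_equal(length(m3), 2)
  expect_equal(length(m5), 2)
  expect_lt(max(abs(m3 - m5)), 1.0) # bounded sensitivity (< 1 index point)
})

test_that("scene generation validates its inputs", {
  expect_error(generate_fret_scene(2, c(0.3)), "one index value")
  expect_error(generate_fret_scene(1, 1.2), "in \\(0, 1\\)")
  expect_error(generate_fret_scene(1, 0.5, background = 3000, signal = 2000),
               "overflow")
})
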