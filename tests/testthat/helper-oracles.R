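# Independent oracles used by the tests. These implementations deliberately
# share no code with the package: the Boussinesq tensor is the textbook
# closed-form half-space solution assembled as a full 2x2 Fourier tensor, and
# the strip tension profile is a direct quadrature of the force balance.

# Half-space (Boussinesq) surface displacement from an in-plane traction
# field: u_hat = G(k) t_hat with
#   G(k) = 2 (1 + nu) / (E k^3) * [ (1-nu) k^2 + nu ky^2,  -nu kx ky
#                                   -nu kx ky,  (1-nu) k^2 + nu kx^2 ]
boussinesq_forward <- function(tx, ty, spacing, E, nu) {
  n1 <- nrow(tx); n2 <- ncol(tx)
  freq <- function(n) {
    half <- floor((n - 1) / 2)
    c(0:half, -(n - half - 1):-1)
  }
  kx <- 2 * pi * freq(n2) / (n2 * spacing)
  ky <- 2 * pi * freq(n1) / (n1 * spacing)
  KX <- matrix(kx, n1, n2, byrow = TRUE)
  KY <- matrix(ky, n1, n2)
  K <- sqrt(KX^2 + KY^2)
  K[1, 1] <- 1 # zero mode handled below
  pref <- 2 * (1 + nu) / (E * K^3)
  Gxx <- pref * ((1 - nu) * K^2 + nu * KY^2)
  Gyy <- pref * ((1 - nu) * K^2 + nu * KX^2)
  Gxy <- -pref * nu * KX * KY
  FX <- stats::fft(tx); FY <- stats::fft(ty)
  UX <- Gxx * FX + Gxy * FY
  UY <- Gxy * FX + Gyy * FY
  UX[1, 1] <- 0; UY[1, 1] <- 0
  list(u = Re(stats::fft(UX, inverse = TRUE)) / (n1 * n2),
       v = Re(stats::fft(UY, inverse = TRUE)) / (n1 * n2))
}

# 1-D force-balance quadrature for the contractile strip: sxx(x) = int T dx'
# from the left free edge, per unit width; units Pa * um = 1e-3 mN/m.
# Returns the tension profile in mN/m at the element centers of the masked
# columns.
strip_tension_mNm <- function(traction, mask) {
  cols <- which(apply(mask, 2, any))
  s <- traction$spacing
  txc <- vapply(cols, function(c) mean(traction$u[mask[, c], c]), 0)
  # integrate from the left free edge to the element center: half-cell first
  (cumsum(txc) - txc / 2) * s * 1e-3
}

# random zero-mean traction field with its spectrum truncated well below the
# Nyquist frequency (band-limited fixture for exact round trips)
band_limited_traction <- function(n = 64, spacing = 5, seed = 3, scale = 100) {
  set.seed(seed)
  bl <- function(m) {
    F <- stats::fft(m)
    k <- abs(epimech:::fft_freq(n))
    keep <- outer(k, k, function(a, b) pmax(a, b) <= n / 6)
    Re(stats::fft(F * keep, inverse = TRUE)) / n^2
  }
  tx <- bl(matrix(rnorm(n^2), n, n)); ty <- bl(matrix(rnorm(n^2), n, n))
  vector_field(scale * (tx - mean(tx)), scale * (ty - mean(ty)), spacing,
               role = "traction", units = "Pa")
}

# correlation-by-construction movies: per-movie uniform speed linearly
# decreasing in density plus jitter
make_speed_density_movies <- function(n_movies, seed, noise = 0.15) {
  set.seed(seed)
  dens <- seq(1000, 4500, length.out = n_movies)
  speeds_px <- seq(3, 0.8, length.out = n_movies) *
    (1 + stats::rnorm(n_movies, 0, noise))
  fields <- lapply(speeds_px, function(sp) {
    th <- stats::runif(1, 0, 2 * pi)
    vector_field(matrix(sp * cos(th), 5, 5), matrix(sp * sin(th), 5, 5),
                 spacing = 12, role = "displacement", units = "px")
  })
  list(fields = fields, densities = dens, true_speeds_px = speeds_px)
}
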