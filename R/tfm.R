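#' Elastic substrate specification
#'
#' @param E Young's modulus in Pa (default 12600, a 12.6 kPa silicone gel).
#' @param nu Poisson ratio; soft silicones are nearly incompressible, default
#'   0.49.
#' @param thickness gel thickness in um; `Inf` selects the semi-infinite
#'   (Boussinesq) half-space.
#' @return a `gel_spec` object.
#' @export
gel_spec <- function(E = 12600, nu = 0.49, thickness = Inf) {
  if (E <= 0) stop("E must be > 0", call. = FALSE)
  if (nu < 0 || nu >= 0.5) stop("nu must be in [0, 0.5)", call. = FALSE)
  if (thickness <= 0) stop("thickness must be > 0 (or Inf)", call. = FALSE)
  structure(list(E = E, nu = nu, thickness = thickness,
                 mu = E / (2 * (1 + nu)),
                 lambda = E * nu / ((1 + nu) * (1 - 2 * nu))),
            class = "gel_spec")
}

#' Surface response of an elastic layer in Fourier space
#'
#' For each wavevector magnitude `k` (1/um) returns the longitudinal and
#' transverse surface compliances `QL`, `QT` (um/Pa): the in-plane surface
#' displacement produced by a unit in-plane surface traction of that spatial
#' frequency, for a layer of thickness `h` bonded to a rigid base with a
#' traction-free normal stress at the surface.
#'
#' The transverse (anti-plane shear) problem has the closed form
#' `QT = tanh(kh) / (mu k)`. The longitudinal (plane-strain) response is
#' computed exactly per wavevector by solving the constant-coefficient Navier
#' boundary-value problem through the thickness (4x4 matrix exponential of the
#' first-order system; bonded base `u = 0`, surface `sigma_zz = 0`,
#' `sigma_xz = 1`). For `kh > 8` the layer correction is below 1e-7 and the
#' Boussinesq half-space forms `QL = (1 - nu)/(mu k)`, `QT = 1/(mu k)` are
#' used directly.
#'
#' @param k wavevector magnitudes (1/um), k > 0.
#' @param gel a [gel_spec()].
#' @return list with vectors `QL`, `QT`.
#' @export
layer_compliance <- function(k, gel) {
  stopifnot(inherits(gel, "gel_spec"), all(k > 0))
  mu <- gel$mu; la <- gel$lambda; h <- gel$thickness
  if (is.infinite(h)) {
    return(list(QL = (1 - gel$nu) / (mu * k), QT = 1 / (mu * k)))
  }
  kh <- k * h
  QT <- tanh(kh) / (mu * k)
  QL <- numeric(length(k))
  far <- kh > 8
  QL[far] <- (1 - gel$nu) / (mu * k[far])
  near <- which(!far)
  if (length(near)) {
    # solve once per distinct kh; QL scales as f(kh)/(mu k)
    khn <- kh[near]
    ui <- !duplicated(khn)
    f_of <- vapply(khn[ui], function(x) layer_long_factor(x, mu, la), 0)
    lut <- stats::setNames(f_of, format(khn[ui], digits = 15))
    QL[near] <- lut[format(khn, digits = 15)] / (mu * k[near])
  }
  list(QL = QL, QT = QT)
}

# Dimensionless longitudinal surface compliance factor f(kh):
# u_long(surface) = f(kh) / (mu k) per unit longitudinal traction.
# State y = (U, U', V, V') in the scaled depth zeta = k z, solving the
# plane-strain Navier system for e^{i k x} dependence (V = i u_z).
layer_long_factor <- function(kh, mu, la) {
  l2m <- la + 2 * mu
  lpm <- la + mu
  M <- matrix(c(
    0, 1, 0, 0,
    l2m / mu, 0, 0, -lpm / mu,
    0, 0, 0, 1,
    0, lpm / l2m, mu / l2m, 0
  ), 4, 4, byrow = TRUE)
  Phi <- as.matrix(Matrix::expm(Matrix::Matrix(M * kh)))
  # y(0) = alpha * e2 + beta * e4 (bonded base: U = V = 0)
  y_a <- Phi[, 2]; y_b <- Phi[, 4]
  # surface BCs (unit tangential traction, zero normal stress), in scaled
  # variables d/dz = k d/dzeta:
  #   mu k (U' + V) = 1      [sigma_xz]
  #   la U - l2m V' = 0      [sigma_zz / k]
  A <- rbind(c(y_a[2] + y_a[3], y_b[2] + y_b[3]),
             c(la * y_a[1] - l2m * y_a[4], la * y_b[1] - l2m * y_b[4]))
  rhs <- c(1, 0) # working in units with mu k = 1; rescaled below
  ab <- solve(A, rhs)
  # rhs normalizes the shear BC to U' + V = 1, i.e. traction mu*k; the surface
  # displacement for unit traction is U/(mu k), so U itself is f(kh)
  ab[1] * y_a[1] + ab[2] * y_b[1]
}

#' Forward traction-to-displacement operator (finite-thickness Fourier TFM)
#'
#' Computes the gel-surface displacement field produced by an in-plane
#' traction field on a regular grid, by applying the layer surface compliance
#' tensor per wavevector: the traction spectrum is split into longitudinal
#' (parallel to k) and transverse components, multiplied by `QL` / `QT`, and
#' transformed back. The zero-frequency (rigid translation) mode is set to
#' zero, so a net-force-free traction maps to a zero-mean displacement.
#'
#' @param traction a `vector_field` with role `"traction"` (Pa).
#' @param gel a [gel_spec()].
#' @param pad zero-pad the field to twice its extent before transforming
#'   (reduces periodic wrap-around for compactly supported islands). The
#'   default `FALSE` keeps the operator strictly periodic so that
#'   [invert_traction()] is its exact inverse.
#' @return a `vector_field` with role `"displacement"` (um).
#' @export
forward_displacement <- function(traction, gel, pad = FALSE) {
  stopifnot(inherits(traction, "vector_field"))
  if (anyNA(traction$u) || anyNA(traction$v))
    stop("traction field contains NA", call. = FALSE)
  uv <- tfm_apply(traction$u, traction$v, traction$spacing, gel,
                  inverse = FALSE, reg_lambda = 0, pad = pad)
  vector_field(uv$u, uv$v, traction$spacing, role = "displacement",
               units = "um", origin = traction$origin)
}

#' Inverse displacement-to-traction operator
#'
#' Recovers the traction field from a measured surface displacement field by
#' per-wavevector (Tikhonov-regularized) inversion of the layer compliance.
#' With `reg_lambda = 0` the inversion is exact and the forward -> inverse
#' round trip reproduces the input traction to floating-point accuracy; with
#' noise, choose `reg_lambda` by hand or via [lcurve_lambda()]. The mean
#' displacement (rigid motion) is removed before inversion and the
#' zero-frequency traction mode is set to zero.
#'
#' @param displacement a `vector_field` with role `"displacement"` (um).
#' @param gel a [gel_spec()].
#' @param reg_lambda dimensionless Tikhonov parameter, scaled relative to the
#'   largest compliance eigenvalue on the grid.
#' @param pad as in [forward_displacement()].
#' @return a `vector_field` with role `"traction"` (Pa).
#' @export
invert_traction <- function(displacement, gel, reg_lambda = 0, pad = FALSE) {
  stopifnot(inherits(displacement, "vector_field"))
  if (anyNA(displacement$u) || anyNA(displacement$v))
    stop("displacement field contains NA", call. = FALSE)
  uu <- displacement$u - mean(displacement$u)
  vv <- displacement$v - mean(displacement$v)
  uv <- tfm_apply(uu, vv, displacement$spacing, gel,
                  inverse = TRUE, reg_lambda = reg_lambda, pad = pad)
  vector_field(uv$u, uv$v, displacement$spacing, role = "traction",
               units = "Pa", origin = displacement$origin)
}

# Shared spectral machinery for the forward and inverse operators.
tfm_apply <- function(ux, uy, spacing, gel, inverse, reg_lambda, pad) {
  ny0 <- nrow(ux); nx0 <- ncol(ux)
  if (pad) {
    ny <- 2L * ny0; nx <- 2L * nx0
    X <- matrix(0, ny, nx); Y <- matrix(0, ny, nx)
    X[1:ny0, 1:nx0] <- ux; Y[1:ny0, 1:nx0] <- uy
  } else {
    ny <- ny0; nx <- nx0; X <- ux; Y <- uy
  }
  kx <- 2 * pi * fft_freq(nx) / (nx * spacing)
  ky <- 2 * pi * fft_freq(ny) / (ny * spacing)
  KX <- matrix(kx, ny, nx, byrow = TRUE)
  KY <- matrix(ky, ny, nx)
  K <- sqrt(KX^2 + KY^2)
  nz <- K > 0

  q <- layer_compliance(K[nz], gel)
  QL <- numeric(length(K)); QT <- numeric(length(K))
  QL[nz] <- q$QL; QT[nz] <- q$QT
  if (inverse) {
    if (reg_lambda == 0) {
      bad <- nz & (QL <= 0 | QT <= 0)
      if (any(bad)) {
        i <- which(bad)[1]
        stop(sprintf("singular transfer at wavevector (%.4g, %.4g) with reg_lambda = 0",
                     KX[i], KY[i]), call. = FALSE)
      }
      QL[nz] <- 1 / QL[nz]; QT[nz] <- 1 / QT[nz]
    } else {
      l2 <- (reg_lambda * max(QL, QT))^2
      QL[nz] <- QL[nz] / (QL[nz]^2 + l2)
      QT[nz] <- QT[nz] / (QT[nz]^2 + l2)
    }
  }

  FX <- stats::fft(X); FY <- stats::fft(Y)
  ex <- ifelse(nz, KX / ifelse(nz, K, 1), 0)
  ey <- ifelse(nz, KY / ifelse(nz, K, 1), 0)
  L <- FX * ex + FY * ey # longitudinal amplitude
  GX <- QL * L * ex + QT * (FX - L * ex)
  GY <- QL * L * ey + QT * (FY - L * ey)
  GX[!nz] <- 0; GY[!nz] <- 0
  outx <- Re(stats::fft(GX, inverse = TRUE)) / (ny * nx)
  outy <- Re(stats::fft(GY, inverse = TRUE)) / (ny * nx)
  list(u = outx[1:ny0, 1:nx0], v = outy[1:ny0, 1:nx0])
}

fft_freq <- function(n) {
  half <- floor((n - 1) / 2)
  c(0:half, -(n - half - 1):-1)
}

#' Automatic Tikhonov parameter by generalized cross-validation
#'
#' Spectral GCV for the per-wavevector Tikhonov filter: minimizes
#' `||(1 - f) u||^2 / (1 - mean(f))^2` over `lambda`, with `f` the filter
#' factors `Q^2 / (Q^2 + lambda^2 Qmax^2)`. For this mildly ill-conditioned
#' periodic operator GCV gives a reliable corner where the classical L-curve
#' is degenerate (the solution norm stays bounded as `lambda -> 0`), so GCV
#' is the default automatic choice; [lcurve_lambda()] remains available.
#'
#' @param displacement a displacement `vector_field` (um).
#' @param gel a [gel_spec()].
#' @param lambdas candidate dimensionless regularization parameters.
#' @return list with `lambda` (GCV minimizer), `lambdas`, `gcv`.
#' @export
gcv_lambda <- function(displacement, gel,
                       lambdas = 10^seq(-4, 0, length.out = 41)) {
  stopifnot(inherits(displacement, "vector_field"))
  uu <- displacement$u - mean(displacement$u)
  vv <- displacement$v - mean(displacement$v)
  ny <- nrow(uu); nx <- ncol(uu)
  kx <- 2 * pi * fft_freq(nx) / (nx * displacement$spacing)
  ky <- 2 * pi * fft_freq(ny) / (ny * displacement$spacing)
  KX <- matrix(kx, ny, nx, byrow = TRUE)
  KY <- matrix(ky, ny, nx)
  K <- sqrt(KX^2 + KY^2)
  nz <- K > 0
  q <- layer_compliance(K[nz], gel)
  FX <- stats::fft(uu); FY <- stats::fft(vv)
  ex <- KX[nz] / K[nz]; ey <- KY[nz] / K[nz]
  L <- FX[nz] * ex + FY[nz] * ey
  TX <- FX[nz] - L * ex; TY <- FY[nz] - L * ey
  pw_long <- Mod(L)^2
  pw_tran <- Mod(TX)^2 + Mod(TY)^2
  qmax <- max(q$QL, q$QT)
  gcv <- vapply(lambdas, function(lam) {
    l2 <- (lam * qmax)^2
    fL <- q$QL^2 / (q$QL^2 + l2)
    fT <- q$QT^2 / (q$QT^2 + l2)
    res <- sum((1 - fL)^2 * pw_long) + sum((1 - fT)^2 * pw_tran)
    tr <- 1 - (sum(fL) + 2 * sum(fT)) / (3 * length(fL))
    res / tr^2
  }, 0)
  list(lambda = lambdas[which.min(gcv)], lambdas = lambdas, gcv = gcv)
}

#' L-curve choice of the Tikhonov parameter
#'
#' Sweeps `lambdas`, records the residual norm ||forward(T(lambda)) - u|| and
#' the solution norm ||T(lambda)||, and returns the lambda at the corner
#' (maximum curvature of the log-log L-curve).
#'
#' @param displacement a displacement `vector_field` (um).
#' @param gel a [gel_spec()].
#' @param lambdas candidate dimensionless regularization parameters.
#' @param pad as in [invert_traction()].
#' @return list with `lambda` (corner value), `lambdas`, `residual_norm`,
#'   `solution_norm`.
#' @export
lcurve_lambda <- function(displacement, gel,
                          lambdas = 10^seq(-6, -1, length.out = 21),
                          pad = FALSE) {
  rn <- sn <- numeric(length(lambdas))
  for (i in seq_along(lambdas)) {
    tr <- invert_traction(displacement, gel, reg_lambda = lambdas[i], pad = pad)
    fw <- forward_displacement(tr, gel, pad = pad)
    du <- fw$u - (displacement$u - mean(displacement$u))
    dv <- fw$v - (displacement$v - mean(displacement$v))
    rn[i] <- sqrt(sum(du^2 + dv^2))
    sn[i] <- sqrt(sum(tr$u^2 + tr$v^2))
  }
  x <- log(rn); y <- log(sn)
  n <- length(x)
  curv <- rep(-Inf, n)
  for (i in 2:(n - 1)) {
    dx1 <- x[i] - x[i - 1]; dx2 <- x[i + 1] - x[i]
    dy1 <- y[i] - y[i - 1]; dy2 <- y[i + 1] - y[i]
    d1 <- dy1 / dx1; d2 <- dy2 / dx2
    curv[i] <- (d2 - d1) / ((dx1 + dx2) / 2) /
      (1 + ((d1 + d2) / 2)^2)^1.5
  }
  list(lambda = lambdas[which.max(curv)], lambdas = lambdas,
       residual_norm = rn, solution_norm = sn)
}
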