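#' Monolayer stress microscopy: recover the line-tension tensor
#'
#' Recovers the in-monolayer line-tension tensor sigma.h (N/m) from the
#' traction field T (Pa, the traction the cells exert on the substrate) by
#' solving the 2-D force balance
#'
#'   d(sxx)/dx + d(sxy)/dy = Tx,   d(sxy)/dx + d(syy)/dy = Ty
#'
#' closed with plane-stress compatibility at monolayer Poisson ratio `nu_m`
#' and stress-free (zero normal and shear line tension) conditions on the
#' free edges of the monolayer footprint. The discretization is a bilinear
#' (Q4) finite-element elastostatic solve on the traction grid: each masked
#' pixel is one element carrying its traction value as a distributed load,
#' free edges are natural boundary conditions, and the in-sheet elastic
#' modulus drops out of the recovered stress (only `nu_m` matters; the
#' problem is statically determinate in 1-D geometries and `nu_m`-independent
#' there). Disconnected footprint components are solved independently. A net
#' force imbalance beyond `balance_tol` (relative) is removed by subtracting
#' the mean traction, with a warning.
#'
#' @param traction a `vector_field` with role `"traction"` (Pa).
#' @param mask logical matrix of the monolayer footprint (same shape as the
#'   traction grid); defaults to pixels with nonzero traction, dilated once.
#' @param nu_m monolayer Poisson ratio (default 0.5, the standard monolayer
#'   stress microscopy assumption).
#' @param balance_tol relative net-force tolerance before mean removal.
#' @return a `stress_field` object: `sxx`, `sxy`, `syy` (N/m) on the traction
#'   grid (zero outside the mask), `mask`, `nu_m`, `spacing` (um), and
#'   `residual`, the relative discrete equilibrium residual ||K v - F|| /
#'   ||F|| of the solve.
#' @export
recover_stress <- function(traction, mask = NULL, nu_m = 0.5,
                           balance_tol = 1e-6) {
  stopifnot(inherits(traction, "vector_field"))
  tx <- traction$u; ty <- traction$v
  ny <- nrow(tx); nx <- ncol(tx)
  if (is.null(mask)) {
    mask <- tx != 0 | ty != 0
    mask <- EBImage::dilate(mask * 1, EBImage::makeBrush(3, "box")) > 0
  }
  if (!all(dim(mask) == dim(tx))) stop("mask shape mismatch", call. = FALSE)
  s <- traction$spacing

  tmag <- sqrt(mean(tx[mask]^2 + ty[mask]^2))
  if (tmag > 0) {
    imb <- max(abs(mean(tx[mask])), abs(mean(ty[mask]))) / tmag
    if (imb > balance_tol) {
      warning(sprintf("net traction imbalance (%.2g relative); removing mean", imb))
      tx[mask] <- tx[mask] - mean(tx[mask])
      ty[mask] <- ty[mask] - mean(ty[mask])
    }
  }

  sxx <- sxy <- syy <- matrix(0, ny, nx)
  labels <- EBImage::bwlabel(mask * 1)
  resid <- 0
  for (lab in setdiff(unique(as.vector(labels)), 0)) {
    comp <- labels == lab
    sol <- msm_solve_component(tx, ty, comp, nu_m, s)
    sxx[comp] <- sol$sxx
    sxy[comp] <- sol$sxy
    syy[comp] <- sol$syy
    resid <- max(resid, sol$residual)
  }
  structure(list(sxx = sxx * 1e-6, sxy = sxy * 1e-6, syy = syy * 1e-6,
                 mask = mask, nu_m = nu_m, spacing = s, residual = resid),
            class = "stress_field")
}

# Q4 plane-stress FEM solve of div(sigma) = T on one connected component.
# Element stress is evaluated at the element center; units: T in Pa, spacing
# in um -> stress in Pa*um (caller converts to N/m).
msm_solve_component <- function(tx, ty, comp, nu_m, s) {
  ny <- nrow(comp); nx <- ncol(comp)
  el <- which(comp, arr.ind = TRUE) # elements = masked pixels
  ne <- nrow(el)
  # node ids on the (ny+1) x (nx+1) corner grid
  nid <- function(r, c) (c - 1L) * (ny + 1L) + r
  n1 <- nid(el[, 1], el[, 2])       # top-left (r, c)
  n2 <- nid(el[, 1] + 1L, el[, 2])  # bottom-left
  n3 <- nid(el[, 1] + 1L, el[, 2] + 1L)
  n4 <- nid(el[, 1], el[, 2] + 1L)
  conn <- cbind(n1, n2, n3, n4)
  nodes <- sort(unique(as.vector(conn)))
  remap <- integer(max(nodes)); remap[nodes] <- seq_along(nodes)
  conn <- matrix(remap[conn], ne, 4)
  nn <- length(nodes)

  ke <- q4_stiffness(nu_m, s)
  # assemble sparse stiffness
  dofs <- cbind(2 * conn[, 1] - 1, 2 * conn[, 1],
                2 * conn[, 2] - 1, 2 * conn[, 2],
                2 * conn[, 3] - 1, 2 * conn[, 3],
                2 * conn[, 4] - 1, 2 * conn[, 4])
  ii <- rep(t(dofs), each = 8)
  jj <- as.vector(apply(dofs, 1, function(d) rep(d, times = 8)))
  vv <- rep(as.vector(ke), times = ne)
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(2 * nn, 2 * nn))

  # loads: body force b = -T distributed over each element
  F <- numeric(2 * nn)
  fx <- -tx[comp] * s^2 / 4
  fy <- -ty[comp] * s^2 / 4
  for (a in 1:4) {
    # each element's a-th corner is a distinct node, so plain indexing is safe
    F[2 * conn[, a] - 1] <- F[2 * conn[, a] - 1] + fx
    F[2 * conn[, a]] <- F[2 * conn[, a]] + fy
  }

  # pin rigid-body modes: one node fully, plus vy at a node with a different
  # x-coordinate (kills rotation); balanced loads make reactions negligible
  node_rc <- cbind((nodes - 1L) %% (ny + 1L) + 1L, (nodes - 1L) %/% (ny + 1L) + 1L)
  a1 <- 1L
  a2 <- which(node_rc[, 2] != node_rc[a1, 2])[1]
  fixed <- c(2 * a1 - 1, 2 * a1, 2 * a2)
  free <- setdiff(seq_len(2 * nn), fixed)
  v <- numeric(2 * nn)
  v[free] <- as.vector(Matrix::solve(K[free, free], F[free]))
  residual <- sqrt(sum((as.vector(K %*% v) - F)[free]^2)) /
    max(sqrt(sum(F^2)), 1e-300)

  # element-center stress: sigma = D B(0,0) v_e
  D <- d_plane_stress(nu_m)
  B <- q4_b_center(s)
  ve <- matrix(v[t(dofs)], ne, 8, byrow = TRUE)
  sig <- ve %*% t(D %*% B)
  list(sxx = sig[, 1], syy = sig[, 2], sxy = sig[, 3], residual = residual)
}

d_plane_stress <- function(nu) {
  matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3) / (1 - nu^2)
}

# 8x8 Q4 plane-stress element stiffness on a square element of side s
# (unit sheet modulus), 2x2 Gauss integration. Node order: TL, BL, BR, TR in
# (row, col) grid terms, i.e. counterclockwise in (x = col, y = -row)... the
# element is square and axis-aligned, so only consistency matters: local
# coordinates (xi, eta) map to (x, y) = (col, row) directions.
q4_stiffness <- function(nu, s) {
  D <- d_plane_stress(nu)
  gp <- c(-1, 1) / sqrt(3)
  ke <- matrix(0, 8, 8)
  for (xi in gp) for (eta in gp) {
    B <- q4_b(xi, eta, s)
    ke <- ke + t(B) %*% D %*% B * (s / 2)^2
  }
  ke
}

# B matrix at local (xi, eta); node order must match `conn`:
# node 1 (r, c), node 2 (r+1, c), node 3 (r+1, c+1), node 4 (r, c+1).
# x runs with c, y with r; shape functions on [-1, 1]^2 with node local
# coords (x, y): n1 (-1,-1), n2 (-1,+1), n3 (+1,+1), n4 (+1,-1).
q4_b <- function(xi, eta, s) {
  lx <- c(-1, -1, 1, 1)
  ly <- c(-1, 1, 1, -1)
  dNdxi <- lx * (1 + ly * eta) / 4
  dNdeta <- ly * (1 + lx * xi) / 4
  # jacobian: dx/dxi = s/2, dy/deta = s/2
  dNdx <- dNdxi * 2 / s
  dNdy <- dNdeta * 2 / s
  B <- matrix(0, 3, 8)
  B[1, seq(1, 8, 2)] <- dNdx
  B[2, seq(2, 8, 2)] <- dNdy
  B[3, seq(1, 8, 2)] <- dNdy
  B[3, seq(2, 8, 2)] <- dNdx
  B
}

q4_b_center <- function(s) q4_b(0, 0, s)

#' Scalar tension map and average normal tension
#'
#' @param stress a `stress_field` from [recover_stress()].
#' @param convention `"sum"` reports tr(sigma).h = sxx + syy (matching the
#'   usual "tr(sigma) . h" axis label); `"half"` reports the mean normal
#'   tension (sxx + syy)/2.
#' @return list with `tension_map` (mN/m, NA outside the mask) and
#'   `average_normal_tension` (mN/m, mask mean).
#' @export
tension_summary <- function(stress, convention = c("sum", "half")) {
  convention <- match.arg(convention)
  stopifnot(inherits(stress, "stress_field"))
  if (!any(stress$mask)) stop("empty mask", call. = FALSE)
  tr <- (stress$sxx + stress$syy) * 1e3 # N/m -> mN/m
  if (convention == "half") tr <- tr / 2
  map <- tr
  map[!stress$mask] <- NA_real_
  list(tension_map = map,
       average_normal_tension = mean(tr[stress$mask]))
}

#' Principal line tensions
#'
#' Eigen-decomposition of the symmetric tensor per masked pixel.
#'
#' @param stress a `stress_field`.
#' @return list of matrices `s1`, `s2` (major/minor principal tension, N/m).
#' @export
principal_tensions <- function(stress) {
  m <- (stress$sxx + stress$syy) / 2
  r <- sqrt(((stress$sxx - stress$syy) / 2)^2 + stress$sxy^2)
  s1 <- m + r; s2 <- m - r
  s1[!stress$mask] <- NA_real_; s2[!stress$mask] <- NA_real_
  list(s1 = s1, s2 = s2)
}

#' Central-difference divergence of a stress field
#'
#' Interior finite-difference divergence of sigma.h (returned in Pa, i.e.
#' (N/m)/um * 1e6), used to check that the recovered stress reproduces the
#' traction on smooth interiors.
#'
#' @param stress a `stress_field`.
#' @return list of matrices `dx`, `dy` (Pa; NA at pixels without full
#'   interior neighborhoods).
#' @export
stress_divergence_fd <- function(stress) {
  s <- stress$spacing
  cd <- function(m, along) {
    out <- matrix(NA_real_, nrow(m), ncol(m))
    if (along == "x") out[, 2:(ncol(m) - 1)] <- (m[, 3:ncol(m)] - m[, 1:(ncol(m) - 2)]) / (2 * s)
    else out[2:(nrow(m) - 1), ] <- (m[3:nrow(m), ] - m[1:(nrow(m) - 2), ]) / (2 * s)
    out
  }
  list(dx = (cd(stress$sxx, "x") + cd(stress$sxy, "y")) * 1e6,
       dy = (cd(stress$sxy, "x") + cd(stress$syy, "y")) * 1e6)
}
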