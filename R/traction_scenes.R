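#' Synthetic traction scenes with known ground truth
#'
#' Builds a traction field + monolayer mask on a regular grid, balances the
#' net force exactly, and produces the matching gel-surface displacement with
#' the forward layer operator (plus optional Gaussian measurement noise) --
#' the standard fixture for traction-recovery and stress-recovery round
#' trips.
#'
#' Patterns:
#' * `contractile_strip` -- a rectangular island contracting along x: uniform
#'   inward traction (+magnitude on the left half, -magnitude on the right),
#'   the classic statically determinate 1-D oracle;
#' * `contractile_disc` -- a disc island with uniform radially inward
#'   traction in an outer annulus;
#' * `random_dipoles` -- a sum of randomly placed, randomly oriented Gaussian
#'   force dipoles (each individually force-free).
#'
#' @param pattern one of `"contractile_strip"`, `"contractile_disc"`,
#'   `"random_dipoles"`.
#' @param magnitude traction scale in Pa (>= 0).
#' @param gel a [gel_spec()].
#' @param grid list with `n` (grid points per side) and `spacing` (um).
#' @param noise_sd additive Gaussian noise SD on the displacement (um).
#' @param seed integer seed.
#' @param n_dipoles,dipole_sigma random-dipole parameters (count; Gaussian
#'   blob radius in um).
#' @param strip_frac,strip_aspect strip length as a fraction of the domain
#'   and width/length aspect ratio.
#' @return list with `scene` (list: `traction` vector_field, `mask`, `gel`,
#'   `pattern`) and `displacement` (vector_field, um).
#' @export
generate_traction_scene <- function(pattern, magnitude, gel = gel_spec(),
                                    grid = list(n = 64, spacing = 5),
                                    noise_sd = 0, seed = NULL,
                                    n_dipoles = 12, dipole_sigma = 20,
                                    strip_frac = 0.5, strip_aspect = 0.5) {
  if (!pattern %in% c("contractile_strip", "contractile_disc", "random_dipoles"))
    stop("unknown traction pattern: ", pattern, call. = FALSE)
  if (magnitude < 0) stop("magnitude must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- grid$n; s <- grid$spacing
  x <- ((1:n) - (n + 1) / 2) * s # centered coordinates (um)
  X <- matrix(x, n, n, byrow = TRUE)
  Y <- matrix(x, n, n)
  tx <- matrix(0, n, n); ty <- matrix(0, n, n)

  if (pattern == "contractile_strip") {
    hl <- strip_frac * n * s / 2 # half-length along x
    hw <- strip_aspect * hl # half-width along y
    mask <- abs(X) <= hl & abs(Y) <= hw
    tx[mask] <- ifelse(X[mask] < 0, magnitude, -magnitude)
  } else if (pattern == "contractile_disc") {
    R <- 0.4 * n * s
    r <- sqrt(X^2 + Y^2)
    mask <- r <= R
    ring <- mask & r > 0.5 * R
    tx[ring] <- -magnitude * X[ring] / r[ring]
    ty[ring] <- -magnitude * Y[ring] / r[ring]
  } else {
    mask <- abs(X) <= 0.45 * n * s & abs(Y) <= 0.45 * n * s
    for (i in seq_len(n_dipoles)) {
      cx <- stats::runif(1, -0.3, 0.3) * n * s
      cy <- stats::runif(1, -0.3, 0.3) * n * s
      th <- stats::runif(1, 0, 2 * pi)
      sep <- stats::runif(1, 1, 2) * dipole_sigma
      g1 <- exp(-((X - cx - sep * cos(th) / 2)^2 +
                    (Y - cy - sep * sin(th) / 2)^2) / (2 * dipole_sigma^2))
      g2 <- exp(-((X - cx + sep * cos(th) / 2)^2 +
                    (Y - cy + sep * sin(th) / 2)^2) / (2 * dipole_sigma^2))
      amp <- magnitude * stats::runif(1, 0.3, 1)
      tx <- tx - amp * cos(th) * (g1 - g2)
      ty <- ty - amp * sin(th) * (g1 - g2)
    }
    tx[!mask] <- 0; ty[!mask] <- 0
  }

  # enforce exact force balance over the mask
  if (any(mask) && magnitude > 0) {
    tx[mask] <- tx[mask] - mean(tx[mask])
    ty[mask] <- ty[mask] - mean(ty[mask])
  }
  traction <- vector_field(tx, ty, s, role = "traction", units = "Pa",
                           origin = c(x[1], x[1]))
  disp <- forward_displacement(traction, gel)
  if (noise_sd > 0) {
    disp$u <- disp$u + stats::rnorm(n * n, 0, noise_sd)
    disp$v <- disp$v + stats::rnorm(n * n, 0, noise_sd)
  }
  list(scene = list(traction = traction, mask = mask, gel = gel,
                    pattern = pattern),
       displacement = disp)
}
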