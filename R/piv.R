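#' PIV configuration
#'
#' Defaults follow standard practice for monolayer motility analysis:
#' 24 x 24 px interrogation windows with 50\% overlap, single-pass direct
#' cross-correlation, and exclusion of abnormally large vectors
#' (> 5 px/frame).
#'
#' @param window interrogation window size in px (>= 8).
#' @param overlap window overlap fraction in [0, 1).
#' @param max_magnitude exclusion threshold, px/frame.
#' @param px_size pixel size (um/px), used by [speed_summary()].
#' @param dt frame interval (h/frame), used by [speed_summary()].
#' @return a `piv_config` list.
#' @export
piv_config <- function(window = 24, overlap = 0.5, max_magnitude = 5,
                       px_size = 0.65, dt = 1 / 6) {
  if (window < 8) stop("window must be >= 8 px", call. = FALSE)
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)", call. = FALSE)
  if (max_magnitude <= 0) stop("max_magnitude must be > 0", call. = FALSE)
  structure(list(window = window, overlap = overlap,
                 max_magnitude = max_magnitude, px_size = px_size, dt = dt),
            class = "piv_config")
}

#' Single-pass cross-correlation PIV
#'
#' Computes one displacement vector per interrogation window from the peak of
#' the zero-mean direct cross-correlation between corresponding windows of an
#' image pair, with three-point Gaussian sub-pixel refinement per axis. The
#' displacement search range is limited to half the window size. Windows that
#' would overlap the image border are dropped, and vectors with magnitude
#' above `config$max_magnitude` are flagged excluded (they remain in the grid
#' but carry no value in downstream means).
#'
#' @param image_a,image_b numeric matrices `[y, x]` of equal shape.
#' @param config a [piv_config()].
#' @return a `vector_field` (units px/frame) on the window-center grid; grid
#'   centers are attached as attributes `centers_x` / `centers_y` (px).
#' @export
compute_piv <- function(image_a, image_b, config = piv_config()) {
  if (!all(dim(image_a) == dim(image_b)))
    stop("images must have the same shape", call. = FALSE)
  w <- config$window
  ny <- nrow(image_a); nx <- ncol(image_a)
  if (ny < w || nx < w) stop("image smaller than one window", call. = FALSE)
  step <- max(1L, round(w * (1 - config$overlap)))
  x0s <- seq(1L, nx - w + 1L, by = step)
  y0s <- seq(1L, ny - w + 1L, by = step)
  half <- w %/% 2L
  S <- w + 2L * half # search-area size
  L <- 2L^ceiling(log2(S + w)) # FFT size for linear correlation

  u <- matrix(NA_real_, length(y0s), length(x0s))
  v <- matrix(NA_real_, length(y0s), length(x0s))
  pa <- matrix(0, L, L); pb <- matrix(0, L, L); pe <- matrix(0, L, L)
  ones <- matrix(0, L, L); ones[1:w, 1:w] <- 1
  f_ones <- stats::fft(ones)
  xcorr <- function(fa, B) {
    pbL <- matrix(0, L, L); pbL[1:S, 1:S] <- B
    Re(stats::fft(Conj(fa) * stats::fft(pbL), inverse = TRUE)) / L^2
  }
  for (iy in seq_along(y0s)) for (ix in seq_along(x0s)) {
    ya <- y0s[iy]:(y0s[iy] + w - 1L)
    xa <- x0s[ix]:(x0s[ix] + w - 1L)
    a <- image_a[ya, xa]
    a <- a - mean(a)
    sa <- sqrt(sum(a^2))
    if (sa == 0) next
    # search area in image_b, zero-padded where it leaves the image
    B <- matrix(0, S, S)
    ys <- (y0s[iy] - half):(y0s[iy] + w - 1L + half)
    xs <- (x0s[ix] - half):(x0s[ix] + w - 1L + half)
    oky <- ys >= 1 & ys <= ny; okx <- xs >= 1 & xs <= nx
    B[oky, okx] <- image_b[ys[oky], xs[okx]]
    pa[] <- 0; pa[1:w, 1:w] <- a
    fa <- stats::fft(pa)
    num <- xcorr(fa, B)
    sb <- xcorr(f_ones, B)
    sb2 <- xcorr(f_ones, B^2)
    den <- sa * sqrt(pmax(sb2 - sb^2 / w^2, 1e-12))
    # normalized cross-correlation; displacement d maps to index d + half + 1
    ncc <- (num / den)[1:(2L * half + 1L), 1:(2L * half + 1L)]
    d <- piv_peak(ncc, half)
    u[iy, ix] <- d[1]
    v[iy, ix] <- d[2]
  }
  mag <- sqrt(u^2 + v^2)
  mask <- is.finite(mag) & mag <= config$max_magnitude
  fld <- vector_field(u, v, spacing = step, role = "displacement",
                      units = "px", mask = mask,
                      origin = c(x0s[1] + (w - 1) / 2, y0s[1] + (w - 1) / 2))
  attr(fld, "centers_x") <- x0s + (w - 1) / 2
  attr(fld, "centers_y") <- y0s + (w - 1) / 2
  fld
}

# Integer peak (ties broken toward the smaller displacement) + 3-point
# Gaussian sub-pixel fit per axis. `cc[dy + half + 1, dx + half + 1]` holds the
# correlation at displacement (dx, dy), dx/dy in -half..half.
piv_peak <- function(cc, half) {
  shifts <- -half:half
  best <- which(cc >= max(cc) - 1e-12, arr.ind = TRUE)
  if (nrow(best) > 1) {
    m2 <- shifts[best[, 1]]^2 + shifts[best[, 2]]^2
    best <- best[order(m2)[1], , drop = FALSE]
  }
  py <- best[1, 1]; px <- best[1, 2]
  dy <- shifts[py]; dx <- shifts[px]
  # a perfect normalized match is an exact integer displacement
  if (cc[py, px] >= 1 - 1e-9) return(c(dx, dy))

  subpix <- function(cm, c0, cp) {
    if (is.na(cm) || is.na(cp)) return(0)
    if (cm > 0 && c0 > 0 && cp > 0) {
      den <- 2 * (log(cm) + log(cp) - 2 * log(c0))
      if (den < 0) return((log(cm) - log(cp)) / den)
    }
    den <- 2 * (cm + cp - 2 * c0)
    if (den < 0) return((cm - cp) / den)
    0
  }
  at <- function(iy, ix) {
    if (iy < 1 || ix < 1 || iy > nrow(cc) || ix > ncol(cc)) return(NA_real_)
    cc[iy, ix]
  }
  ddx <- subpix(at(py, px - 1L), cc[py, px], at(py, px + 1L))
  ddy <- subpix(at(py - 1L, px), cc[py, px], at(py + 1L, px))
  c(dx + ddx, dy + ddy)
}

#' Per-movie mean speed and its correlation with cell density
#'
#' @param fields list of `vector_field`s (px/frame), one per movie (or a list
#'   of per-frame fields per movie; vectors are pooled within a movie).
#' @param config the [piv_config()] carrying `px_size` and `dt`.
#' @param densities optional cell densities (cells/mm^2), one per movie; when
#'   given (>= 3 movies) the Pearson correlation of mean speed vs density is
#'   returned.
#' @return list with `mean_speed` (um/h per movie), and `pearson_r`, `p` when
#'   densities are supplied.
#' @export
speed_summary <- function(fields, config, densities = NULL) {
  one <- function(f) {
    if (inherits(f, "vector_field")) f <- list(f)
    mags <- unlist(lapply(f, field_magnitude, valid_only = TRUE))
    if (!length(mags)) {
      warning("all vectors excluded; mean speed undefined")
      return(NA_real_)
    }
    mean(mags) * config$px_size / config$dt
  }
  speeds <- vapply(fields, one, 0)
  out <- list(mean_speed = speeds)
  if (!is.null(densities)) {
    if (length(densities) != length(speeds))
      stop("one density per movie required", call. = FALSE)
    if (sum(is.finite(speeds)) < 3)
      stop("need >= 3 movies for a correlation", call. = FALSE)
    ct <- stats::cor.test(densities, speeds, method = "pearson")
    out$pearson_r <- unname(ct$estimate)
    out$p <- ct$p.value
  }
  out
}

#' Synthetic speckle image pair advected by a known flow
#'
#' Renders Gaussian speckles at random positions and advects them by a known
#' flow to produce a PIV test pair with exact ground truth. A uniform integer
#' shift is applied by exact array translation, so `image_b` equals `image_a`
#' translated (interior pixels); any other flow re-renders the speckles at
#' their advected positions.
#'
#' @param flow either a length-2 numeric (uniform shift, px) or a
#'   `function(x, y)` returning `list(u, v)` in px evaluated at particle
#'   positions.
#' @param image_size `c(ny, nx)` in px.
#' @param seed integer seed.
#' @param density speckle density (particles/px^2).
#' @param sigma speckle radius (px).
#' @param window PIV window size used to validate the capture range.
#' @return list with `image_a`, `image_b` matrices.
#' @export
generate_speckle_pair <- function(flow, image_size = c(128, 128), seed = NULL,
                                  density = 0.08, sigma = 1.2, window = 24) {
  if (!is.null(seed)) set.seed(seed)
  ny <- image_size[1]; nx <- image_size[2]
  uniform <- is.numeric(flow) && length(flow) == 2
  max_mag <- if (uniform) sqrt(sum(flow^2)) else NULL

  margin <- ceiling(4 * sigma) + (if (uniform) ceiling(max(abs(flow))) else
    ceiling(window / 2))
  n_part <- round(density * (ny + 2 * margin) * (nx + 2 * margin))
  px <- stats::runif(n_part, 1 - margin, nx + margin)
  py <- stats::runif(n_part, 1 - margin, ny + margin)
  amp <- stats::runif(n_part, 0.5, 1)

  img_a <- render_speckles(px, py, amp, ny, nx, sigma)
  if (uniform && all(flow == round(flow))) {
    if (max_mag >= window / 2)
      stop("flow exceeds the PIV capture range (window/2)", call. = FALSE)
    img_b <- shift_image(img_a, round(flow[1]), round(flow[2]))
  } else {
    if (uniform) {
      ux <- rep(flow[1], n_part); uy <- rep(flow[2], n_part)
    } else {
      fl <- flow(px, py)
      ux <- fl$u; uy <- fl$v
    }
    if (max(sqrt(ux^2 + uy^2)) >= window / 2)
      stop("flow exceeds the PIV capture range (window/2)", call. = FALSE)
    img_b <- render_speckles(px + ux, py + uy, amp, ny, nx, sigma)
  }
  list(image_a = img_a, image_b = img_b)
}

render_speckles <- function(px, py, amp, ny, nx, sigma) {
  img <- matrix(0, ny, nx)
  r <- ceiling(4 * sigma)
  for (i in seq_along(px)) {
    if (px[i] + r < 1 || px[i] - r > nx || py[i] + r < 1 || py[i] - r > ny) next
    xs <- max(1L, floor(px[i] - r)):min(nx, ceiling(px[i] + r))
    ys <- max(1L, floor(py[i] - r)):min(ny, ceiling(py[i] + r))
    gx <- exp(-(xs - px[i])^2 / (2 * sigma^2))
    gy <- exp(-(ys - py[i])^2 / (2 * sigma^2))
    img[ys, xs] <- img[ys, xs] + amp[i] * outer(gy, gx)
  }
  img
}

shift_image <- function(img, dx, dy) {
  ny <- nrow(img); nx <- ncol(img)
  out <- matrix(0, ny, nx)
  src_x <- (1:nx) - dx; src_y <- (1:ny) - dy
  okx <- src_x >= 1 & src_x <= nx
  oky <- src_y >= 1 & src_y <= ny
  out[oky, okx] <- img[src_y[oky], src_x[okx]]
  out
}
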