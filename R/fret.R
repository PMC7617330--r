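#' Pixel-wise FRET index from a donor/acceptor image pair
#'
#' Reproduces the standard ratiometric tension-sensor pipeline: each channel
#' is background-subtracted, Gaussian-smoothed (radius `smooth_radius`), and
#' thresholded at `threshold_frac` of the 12-bit range (pixels where either
#' smoothed channel falls at or below the threshold are masked invalid); the
#' index on valid pixels is
#'
#'   index = I_EYFP / (I_mTFP + I_EYFP)
#'
#' which decreases as tension across the sensor separates the FRET pair.
#'
#' @param pair a `fret_image_pair` (see [fret_image_pair()]).
#' @param smooth_radius Gaussian radius in px (default 1).
#' @param threshold_frac threshold as a fraction of the 12-bit range; default
#'   0.04, the midpoint of the conventional 3--5\% band.
#' @return list with `index` (matrix in [0,1], NA where invalid) and `valid`
#'   (logical matrix).
#' @export
compute_fret_index <- function(pair, smooth_radius = 1, threshold_frac = 0.04) {
  stopifnot(inherits(pair, "fret_image_pair"))
  don <- pair$donor - pair$background_donor
  acc <- pair$acceptor - pair$background_acceptor
  don <- gauss_smooth(pmax(don, 0), smooth_radius)
  acc <- gauss_smooth(pmax(acc, 0), smooth_radius)
  thr <- threshold_frac * (2^pair$bit_depth - 1)
  valid <- don > thr & acc > thr
  if (!any(valid)) warning("all pixels below threshold; empty index map")
  index <- matrix(NA_real_, nrow(don), ncol(don))
  index[valid] <- acc[valid] / (don[valid] + acc[valid])
  list(index = index, valid = valid)
}

gauss_smooth <- function(m, radius) {
  if (radius <= 0) return(m)
  EBImage::gblur(m, sigma = radius)
}

#' Donor/acceptor image pair container
#'
#' @param donor,acceptor intensity matrices (counts); values must lie within
#'   the stated bit depth.
#' @param bit_depth bit depth of the data (default 12).
#' @param background_donor,background_acceptor per-channel scalar (or image)
#'   background; when `NULL` it is estimated as the modal rounded intensity of
#'   the channel (the off-contact background dominates the histogram).
#' @return a `fret_image_pair`.
#' @export
fret_image_pair <- function(donor, acceptor, bit_depth = 12,
                            background_donor = NULL, background_acceptor = NULL) {
  if (!all(dim(donor) == dim(acceptor)))
    stop("donor and acceptor must have the same shape", call. = FALSE)
  maxv <- 2^bit_depth - 1
  if (min(donor) < 0 || min(acceptor) < 0 || max(donor) > maxv ||
      max(acceptor) > maxv)
    stop(sprintf("intensities must lie in [0, %d]", maxv), call. = FALSE)
  mode_of <- function(m) {
    tb <- table(round(as.vector(m)))
    as.numeric(names(tb)[which.max(tb)])
  }
  if (is.null(background_donor)) background_donor <- mode_of(donor)
  if (is.null(background_acceptor)) background_acceptor <- mode_of(acceptor)
  structure(list(donor = donor, acceptor = acceptor, bit_depth = bit_depth,
                 background_donor = background_donor,
                 background_acceptor = background_acceptor),
            class = "fret_image_pair")
}

#' Per-contact mean FRET index
#'
#' Segments cell-cell contact regions on the (smoothed, background-subtracted)
#' acceptor channel -- Otsu threshold followed by connected-component
#' labeling -- and reports the mean index (as a percentage) over the valid
#' pixels of each contact. Contacts smaller than `min_pixels` are dropped.
#'
#' @param index_map result of [compute_fret_index()].
#' @param pair the co-registered `fret_image_pair` (acceptor channel drives
#'   the segmentation).
#' @param min_pixels minimum contact size in px (default 20).
#' @param smooth_radius Gaussian radius used on the acceptor before Otsu.
#' @return data.frame (`contact_table`): `contact_id`, `pixel_count`,
#'   `mean_index` (%, in [0, 100]).
#' @export
contact_table <- function(index_map, pair, min_pixels = 20, smooth_radius = 1) {
  acc <- gauss_smooth(pmax(pair$acceptor - pair$background_acceptor, 0),
                      smooth_radius)
  rng <- range(acc)
  empty <- data.frame(contact_id = integer(0), pixel_count = integer(0),
                      mean_index = numeric(0))
  if (diff(rng) <= 0) {
    warning("acceptor channel is flat; no contacts found")
    return(empty)
  }
  norm <- (acc - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  fg <- norm > thr
  labels <- EBImage::bwlabel(fg * 1)
  ids <- setdiff(unique(as.vector(labels)), 0)
  rows <- lapply(ids, function(id) {
    px <- labels == id
    npx <- sum(px)
    if (npx < min_pixels) return(NULL)
    vals <- index_map$index[px & index_map$valid]
    if (!length(vals)) return(NULL)
    data.frame(contact_id = id, pixel_count = npx,
               mean_index = 100 * mean(vals))
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    warning("no contacts passed the size filter")
    return(empty)
  }
  out <- do.call(rbind, rows)
  out$contact_id <- seq_len(nrow(out))
  out
}

#' Synthetic FRET tension-sensor scene
#'
#' Renders a 12-bit donor/acceptor image pair containing `n_contacts` thin
#' junction-like ridges, each carrying a prescribed FRET index: on contact
#' pixels the background-free channel intensities split a fixed total signal
#' so that acceptor/(donor + acceptor) equals the assigned index exactly;
#' off-contact pixels sit at the background level. Additive Gaussian noise of
#' SD `noise_sd` (counts) is applied to both channels.
#'
#' @param n_contacts number of junction segments.
#' @param index_values FRET index per contact, each in (0, 1).
#' @param background background level in counts (both channels).
#' @param noise_sd Gaussian noise SD in counts.
#' @param seed integer seed.
#' @param image_size `c(ny, nx)`.
#' @param signal total (donor + acceptor) contact signal in counts.
#' @param thickness ridge thickness in px.
#' @return list: `pair` (a `fret_image_pair` with known background),
#'   `true_index` (matrix, NA off contact), `contact_labels` (integer matrix).
#' @export
generate_fret_scene <- function(n_contacts, index_values, background = 100,
                                noise_sd = 0, seed = NULL,
                                image_size = c(128, 128), signal = 2000,
                                thickness = 3) {
  if (length(index_values) != n_contacts)
    stop("one index value per contact required", call. = FALSE)
  if (any(index_values <= 0 | index_values >= 1))
    stop("index values must lie in (0, 1)", call. = FALSE)
  if (background + signal > 4095)
    stop("background + signal overflows the 12-bit range", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ny <- image_size[1]; nx <- image_size[2]
  donor <- matrix(background, ny, nx)
  acceptor <- matrix(background, ny, nx)
  true_index <- matrix(NA_real_, ny, nx)
  labels <- matrix(0L, ny, nx)

  # evenly separated horizontal ridges with jittered length
  rows0 <- round(seq(0.2, 0.8, length.out = max(n_contacts, 2)) * ny)
  for (i in seq_len(n_contacts)) {
    r0 <- rows0[i] + seq_len(thickness) - (thickness + 1) %/% 2
    c0 <- round(stats::runif(1, 0.1, 0.25) * nx):round(stats::runif(1, 0.75, 0.9) * nx)
    idx <- index_values[i]
    donor[r0, c0] <- background + (1 - idx) * signal
    acceptor[r0, c0] <- background + idx * signal
    true_index[r0, c0] <- idx
    labels[r0, c0] <- i
  }
  if (noise_sd > 0) {
    donor <- donor + stats::rnorm(ny * nx, 0, noise_sd)
    acceptor <- acceptor + stats::rnorm(ny * nx, 0, noise_sd)
  }
  donor <- pmin(pmax(donor, 0), 4095)
  acceptor <- pmin(pmax(acceptor, 0), 4095)
  pair <- fret_image_pair(donor, acceptor,
                          background_donor = background,
                          background_acceptor = background)
  list(pair = pair, true_index = true_index, contact_labels = labels)
}
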