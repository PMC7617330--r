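#' Duration distributions for cell-cycle phase lengths
#'
#' Small algebra of positive duration distributions used by the synthetic
#' trace generator. Each distribution is a list with a `family` tag plus
#' parameters, created by one of the `dist_*()` constructors. Supported
#' families:
#'
#' * `fixed` -- a point mass (noiseless fixtures),
#' * `lognormal` -- parameterized by target mean and SD on the hour scale
#'   (guarantees positivity),
#' * `skewnormal` -- a skew-normal calibrated to a target mean, SD *and*
#'   99th percentile; used for the low-density G2 duration where all three
#'   cohort summaries are known and a two-parameter family cannot match them,
#' * `scaled_beta` -- `lo + (hi - lo) * Beta(a, b)`, for bounded-support
#'   components such as the prolonged-G2 population,
#' * `mixture` -- finite mixture of the above.
#'
#' @param value,mean,sd,q99,lo,hi,concentration,components,weights
#'   family parameters; durations are in hours throughout.
#' @return A `duration_dist` object.
#' @name duration_dist
NULL

new_duration_dist <- function(family, ...) {
  d <- c(list(family = family), list(...))
  class(d) <- "duration_dist"
  d
}

#' @rdname duration_dist
#' @export
dist_fixed <- function(value) {
  if (!is.finite(value) || value <= 0) stop("fixed duration must be > 0", call. = FALSE)
  new_duration_dist("fixed", value = value)
}

#' @rdname duration_dist
#' @export
dist_lognormal <- function(mean, sd) {
  if (mean <= 0 || sd <= 0) stop("lognormal mean and sd must be > 0", call. = FALSE)
  sdlog2 <- log(1 + (sd / mean)^2)
  new_duration_dist("lognormal", mean = mean, sd = sd,
                    meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' @rdname duration_dist
#' @export
dist_scaled_beta <- function(lo, hi, mean, concentration = 4) {
  if (hi <= lo) stop("scaled beta needs hi > lo", call. = FALSE)
  m <- (mean - lo) / (hi - lo)
  if (m <= 0 || m >= 1) stop("scaled beta mean must lie inside (lo, hi)", call. = FALSE)
  new_duration_dist("scaled_beta", lo = lo, hi = hi, mean = mean,
                    a = m * concentration, b = (1 - m) * concentration)
}

#' @rdname duration_dist
#' @export
dist_mixture <- function(components, weights) {
  if (length(components) != length(weights)) stop("mixture lengths differ", call. = FALSE)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("mixture weights must be nonnegative and sum to 1", call. = FALSE)
  new_duration_dist("mixture", components = components, weights = weights)
}

# Owen's T function by direct quadrature of its defining integral; accurate
# to ~1e-10 over the ranges used here (|h| < 8, |a| < 50).
owen_t <- function(h, a) {
  if (a == 0) return(0)
  s <- sign(a); a <- abs(a)
  f <- function(x) exp(-0.5 * h^2 * (1 + x^2)) / (1 + x^2)
  s * stats::integrate(f, 0, a, rel.tol = 1e-11, abs.tol = 1e-13)$value / (2 * pi)
}

# Skew-normal CDF (Azzalini parameterization: location xi, scale omega,
# shape alpha).
psn <- function(x, xi, omega, alpha) {
  z <- (x - xi) / omega
  stats::pnorm(z) - 2 * owen_t(z, alpha)
}

#' @rdname duration_dist
#' @export
dist_skewnormal <- function(mean, sd, q99) {
  if (sd <= 0) stop("skewnormal sd must be > 0", call. = FALSE)
  zq <- (q99 - mean) / sd
  b <- sqrt(2 / pi)
  # Standardized 99th percentile ranges from qnorm(.99) at alpha = 0 down to
  # ~1.30 as alpha -> -Inf; solve for the shape that places q99 as requested.
  par_for <- function(alpha) {
    delta <- alpha / sqrt(1 + alpha^2)
    vz <- 1 - b^2 * delta^2
    omega <- sd / sqrt(vz)
    xi <- mean - omega * b * delta
    c(xi = xi, omega = omega, alpha = alpha)
  }
  f <- function(alpha) {
    p <- par_for(alpha)
    q <- stats::uniroot(function(x) psn(x, p[1], p[2], p[3]) - 0.99,
                        lower = mean - 10 * sd, upper = mean + 10 * sd,
                        tol = 1e-10)$root
    q - q99
  }
  if (zq >= stats::qnorm(0.99) - 1e-6) {
    if (zq > stats::qnorm(0.99) + 1e-6)
      stop("skewnormal cannot place q99 further out than the normal; use lognormal",
           call. = FALSE)
    p <- par_for(0)
  } else {
    if (f(-60) > 0) stop("requested q99 too close to the mean for a skew-normal",
                         call. = FALSE)
    alpha <- stats::uniroot(f, lower = -60, upper = 0, tol = 1e-9)$root
    p <- par_for(alpha)
  }
  new_duration_dist("skewnormal", mean = mean, sd = sd, q99 = q99,
                    xi = unname(p[1]), omega = unname(p[2]), alpha = unname(p[3]))
}

#' Sample phase durations
#'
#' Draws `n` durations (hours) from a `duration_dist`. Draws are rejected and
#' redrawn while not strictly positive (relevant only for the unbounded
#' skew-normal tail, where the rejected mass is negligible).
#'
#' @param dist a `duration_dist`.
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
sample_duration <- function(dist, n) {
  stopifnot(inherits(dist, "duration_dist"))
  if (n == 0) return(numeric(0))
  x <- switch(dist$family,
    fixed = rep(dist$value, n),
    lognormal = stats::rlnorm(n, dist$meanlog, dist$sdlog),
    scaled_beta = dist$lo + (dist$hi - dist$lo) * stats::rbeta(n, dist$a, dist$b),
    skewnormal = {
      delta <- dist$alpha / sqrt(1 + dist$alpha^2)
      z0 <- abs(stats::rnorm(n)); z1 <- stats::rnorm(n)
      dist$xi + dist$omega * (delta * z0 + sqrt(1 - delta^2) * z1)
    },
    mixture = {
      k <- sample.int(length(dist$weights), n, replace = TRUE, prob = dist$weights)
      out <- numeric(n)
      for (j in seq_along(dist$weights)) {
        idx <- which(k == j)
        if (length(idx)) out[idx] <- sample_duration(dist$components[[j]], length(idx))
      }
      attr(out, "component") <- k
      out
    },
    stop("unknown duration family: ", dist$family, call. = FALSE)
  )
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- sample_duration(dist, length(bad))
    bad <- which(x <= 0)
  }
  x
}

#' Theoretical mean of a duration distribution
#' @param dist a `duration_dist`.
#' @return mean in hours.
#' @export
dist_mean <- function(dist) {
  switch(dist$family,
    fixed = dist$value,
    lognormal = dist$mean,
    scaled_beta = dist$mean,
    skewnormal = dist$mean,
    mixture = sum(dist$weights * vapply(dist$components, dist_mean, 0)),
    stop("unknown duration family")
  )
}

#' Theoretical quantile of a duration distribution
#'
#' Closed form where available, otherwise by root finding on the CDF
#' (mixtures).
#'
#' @param dist a `duration_dist`.
#' @param p probability.
#' @return quantile in hours.
#' @export
dist_quantile <- function(dist, p) {
  cdf <- function(x) dist_cdf(dist, x)
  switch(dist$family,
    fixed = dist$value,
    lognormal = stats::qlnorm(p, dist$meanlog, dist$sdlog),
    stats::uniroot(function(x) cdf(x) - p, lower = 1e-6, upper = 200,
                   tol = 1e-9)$root
  )
}

dist_cdf <- function(dist, x) {
  switch(dist$family,
    fixed = as.numeric(x >= dist$value),
    lognormal = stats::plnorm(x, dist$meanlog, dist$sdlog),
    scaled_beta = stats::pbeta((x - dist$lo) / (dist$hi - dist$lo), dist$a, dist$b),
    skewnormal = psn(x, dist$xi, dist$omega, dist$alpha),
    mixture = sum(dist$weights *
                    vapply(dist$components, function(d) dist_cdf(d, x), 0)),
    stop("unknown duration family")
  )
}
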