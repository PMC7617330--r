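#' Gridded 2-component vector fields
#'
#' Container for displacement / velocity / traction fields on a regular grid.
#' Components are matrices indexed `[row = y, col = x]`; `spacing` is the grid
#' pitch and `units` the unit of the components (the role tag keeps
#' displacement in length units, velocity in length/time and traction in Pa).
#' Vectors flagged invalid in `mask` carry no value in downstream summaries.
#'
#' @param u,v component matrices (same shape).
#' @param spacing grid spacing (same unit for x and y).
#' @param role one of `"displacement"`, `"velocity"`, `"traction"`.
#' @param units unit string for the components (e.g. `"um"`, `"px"`, `"Pa"`).
#' @param mask logical validity matrix (default all valid).
#' @param origin coordinates of the `[1, 1]` grid point.
#' @return a `vector_field` object.
#' @export
vector_field <- function(u, v, spacing, role = c("displacement", "velocity",
                                                 "traction"),
                         units = "um", mask = NULL, origin = c(0, 0)) {
  role <- match.arg(role)
  u <- as.matrix(u); v <- as.matrix(v)
  if (!all(dim(u) == dim(v))) stop("u and v must have the same shape", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(u), ncol(u))
  if (!all(dim(mask) == dim(u))) stop("mask shape mismatch", call. = FALSE)
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  structure(list(u = u, v = v, mask = mask, spacing = spacing, role = role,
                 units = units, origin = origin), class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  cat(sprintf("<vector_field> %s [%s], %d x %d, spacing %g, %d/%d valid\n",
              x$role, x$units, nrow(x$u), ncol(x$u), x$spacing,
              sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Vector magnitudes of a field
#' @param field a `vector_field`.
#' @param valid_only drop invalid vectors.
#' @return numeric vector (valid_only) or matrix.
#' @export
field_magnitude <- function(field, valid_only = FALSE) {
  m <- sqrt(field$u^2 + field$v^2)
  if (valid_only) m[field$mask] else m
}

#' Write / read a vector field as a delimited grid with a JSON sidecar
#'
#' The field is stored as a long-format CSV (`x`, `y`, `u`, `v`, `valid`) next
#' to a `.json` sidecar carrying spacing, units, role and origin.
#'
#' @param field a `vector_field`.
#' @param path CSV path; the sidecar is `paste0(path, ".json")`.
#' @export
write_field <- function(field, path) {
  nr <- nrow(field$u); nc <- ncol(field$u)
  xy <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  d <- data.frame(
    x = field$origin[1] + (xy$col - 1) * field$spacing,
    y = field$origin[2] + (xy$row - 1) * field$spacing,
    u = as.vector(field$u), v = as.vector(field$v),
    valid = as.vector(field$mask))
  utils::write.csv(d, path, row.names = FALSE)
  meta <- list(nrow = nr, ncol = nc, spacing = field$spacing,
               role = field$role, units = field$units, origin = field$origin)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- utils::read.csv(path)
  shape <- c(meta$nrow, meta$ncol)
  vector_field(matrix(d$u, shape[1], shape[2]),
               matrix(d$v, shape[1], shape[2]),
               spacing = meta$spacing, role = meta$role, units = meta$units,
               mask = matrix(d$valid, shape[1], shape[2]),
               origin = meta$origin)
}
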