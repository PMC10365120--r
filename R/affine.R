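#' Apply a 4x4 affine transform to 3-D points
#'
#' Points are given one per row. The convention throughout the package is
#' 0-based voxel indices with voxel centers at integer indices, and RAS+
#' world coordinates in millimeters, matching common NIfTI practice.
#'
#' @param affine 4x4 numeric matrix (must be invertible for inversion).
#' @param points numeric matrix with 3 columns, or a length-3 vector.
#' @return transformed points, same shape as the input.
#' @examples
#' aff <- diag(c(1.5, 1.5, 1.5, 1))
#' apply_affine(aff, c(2, 2, 2))  # -> (3, 3, 3) mm
#' @export
apply_affine <- function(affine, points) {
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  vec_in <- is.null(dim(points))
  if (vec_in) points <- matrix(points, nrow = 1L)
  stopifnot(ncol(points) == 3L)
  out <- points %*% t(affine[1:3, 1:3, drop = FALSE])
  out <- sweep(out, 2L, affine[1:3, 4L], "+")
  if (vec_in) out <- drop(out)
  out
}

#' Invert an affine transform
#'
#' @param affine 4x4 numeric matrix.
#' @return the inverse 4x4 matrix.
#' @export
invert_affine <- function(affine) {
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  d <- det(affine)
  if (!is.finite(d) || abs(d) < 1e-12)
    stop("singular_affine: affine matrix is not invertible", call. = FALSE)
  solve(affine)
}

#' Map world-mm points to (0-based, fractional) voxel indices
#' @param affine 4x4 voxel-to-world matrix.
#' @param points n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of fractional voxel indices.
#' @export
world_to_voxel <- function(affine, points) {
  apply_affine(invert_affine(affine), points)
}

#' Map (0-based) voxel indices to world mm
#' @inheritParams world_to_voxel
#' @export
voxel_to_world <- function(affine, points) {
  apply_affine(affine, points)
}

# Nearest-voxel 1-based linear index into a 3-D array; NA when outside grid.
.voxel_linear_index <- function(vox, dim3) {
  iv <- round(vox)
  ok <- iv[, 1L] >= 0 & iv[, 1L] < dim3[1L] &
        iv[, 2L] >= 0 & iv[, 2L] < dim3[2L] &
        iv[, 3L] >= 0 & iv[, 3L] < dim3[3L]
  idx <- rep(NA_integer_, nrow(iv))
  idx[ok] <- 1L + iv[ok, 1L] + dim3[1L] * (iv[ok, 2L] + dim3[2L] * iv[ok, 3L])
  idx
}

# Precompute trilinear interpolation corner indices and weights for a set
# of fractional 0-based voxel coordinates, so several volumes on the same
# grid can be sampled at the same points cheaply. Points outside the grid
# (beyond the outermost voxel centers) are flagged.
.trilinear_weights <- function(dim3, vox) {
  d <- dim3
  x <- vox[, 1L]; y <- vox[, 2L]; z <- vox[, 3L]
  ok <- x >= 0 & x <= d[1L] - 1 & y >= 0 & y <= d[2L] - 1 &
    z >= 0 & z <= d[3L] - 1
  ok[is.na(ok)] <- FALSE
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmax(pmin(floor(x), d[1L] - 2), 0)
  y0 <- pmax(pmin(floor(y), d[2L] - 2), 0)
  z0 <- pmax(pmin(floor(z), d[3L] - 2), 0)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  base <- 1 + x0 + d[1L] * (y0 + d[2L] * z0)
  dx <- 1; dy <- d[1L]; dz <- d[1L] * d[2L]
  idx <- cbind(base, base + dx, base + dy, base + dx + dy,
               base + dz, base + dx + dz, base + dy + dz,
               base + dx + dy + dz)
  w <- cbind((1 - fx) * (1 - fy) * (1 - fz), fx * (1 - fy) * (1 - fz),
             (1 - fx) * fy * (1 - fz),       fx * fy * (1 - fz),
             (1 - fx) * (1 - fy) * fz,       fx * (1 - fy) * fz,
             (1 - fx) * fy * fz,             fx * fy * fz)
  list(ok = ok, idx = idx, w = w, n = length(ok))
}

.trilinear_apply <- function(vol, tw) {
  out <- rep(NA_real_, tw$n)
  if (nrow(tw$idx) == 0L) return(out)
  acc <- tw$w[, 1L] * vol[tw$idx[, 1L]]
  for (k in 2:8) acc <- acc + tw$w[, k] * vol[tw$idx[, k]]
  out[tw$ok] <- acc
  out
}

# Trilinear interpolation of a 3-D array at fractional 0-based voxel
# coordinates; NA outside the grid. Vectorized over points.
.trilinear <- function(vol, vox) {
  .trilinear_apply(vol, .trilinear_weights(dim(vol), vox))
}
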