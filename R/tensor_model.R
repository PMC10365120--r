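#' Stejskal-Tanner design matrix for log-linear tensor fitting
#'
#' Row i of the design is
#' `-b_i * (gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz)` followed by a
#' constant 1 for the log baseline signal, so that
#' `ln S = X %*% c(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz, ln S0)`.
#'
#' @param gtab a [gradient_table()].
#' @return (frames x 7) numeric matrix.
#' @export
build_design_matrix <- function(gtab) {
  stopifnot(inherits(gtab, "gradient_table"))
  g <- gtab$bvecs
  b <- gtab$bvals
  X <- cbind(g[, 1L]^2, g[, 2L]^2, g[, 3L]^2,
             2 * g[, 1L] * g[, 2L], 2 * g[, 1L] * g[, 3L],
             2 * g[, 2L] * g[, 3L])
  cbind(-b * X, 1)
}

# Closed-form eigenvalues of symmetric 3x3 tensors, vectorized over voxels.
# `C` is an n x 6 matrix of (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz). Returns an
# n x 3 matrix sorted in descending order. Uses the standard trigonometric
# solution for the characteristic cubic, which is numerically stable for
# the symmetric case.
.sym3_eigvals <- function(C) {
  a <- C[, 1L]; b <- C[, 2L]; cc <- C[, 3L]
  d <- C[, 4L]; e <- C[, 5L]; f <- C[, 6L]
  q <- (a + b + cc) / 3
  p1 <- d^2 + e^2 + f^2
  p2 <- (a - q)^2 + (b - q)^2 + (cc - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  iso <- p <= .Machine$double.eps * pmax(abs(q), 1e-300)
  ps <- ifelse(iso, 1, p)
  a2 <- (a - q) / ps; b2 <- (b - q) / ps; c2 <- (cc - q) / ps
  d2 <- d / ps; e2 <- e / ps; f2 <- f / ps
  detB <- a2 * (b2 * c2 - f2^2) - d2 * (d2 * c2 - f2 * e2) +
    e2 * (d2 * f2 - e2 * b2)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  out <- cbind(l1, l2, l3)
  out[iso, ] <- q[iso]
  out
}

# Orthonormal eigenvector triads for symmetric 3x3 tensors, vectorized.
# `C` n x 6 coefficients, `ev` n x 3 eigenvalues sorted descending.
# Returns an n x 9 matrix with columns (e1x,e1y,e1z, e2x,..., e3z).
# Uses spectral projectors where eigenvalues are separated; in nearly
# degenerate subspaces any orthonormal completion is valid and one is
# chosen deterministically.
.sym3_eigvecs <- function(C, ev) {
  n <- nrow(C)
  a <- C[, 1L]; b <- C[, 2L]; cc <- C[, 3L]
  d <- C[, 4L]; e <- C[, 5L]; f <- C[, 6L]
  scale <- pmax(abs(ev[, 1L]), abs(ev[, 3L]), 1e-300)
  tol <- 1e-7
  finite <- is.finite(ev[, 1L]) & is.finite(ev[, 3L])
  sep12 <- (ev[, 1L] - ev[, 2L]) > tol * scale & finite
  sep23 <- (ev[, 2L] - ev[, 3L]) > tol * scale & finite
  sep12[is.na(sep12)] <- FALSE
  sep23[is.na(sep23)] <- FALSE

  # product (A - l2 I)(A - l3 I), columns span the l1 eigenvector; by
  # symmetry the same expression with the other eigenvalue pairs isolates
  # the others.
  projector_col <- function(lA, lB) {
    aA <- a - lA; bA <- b - lA; cA <- cc - lA
    aB <- a - lB; bB <- b - lB; cB <- cc - lB
    P <- cbind(aA * aB + d * d + e * e,
               d * aB + bA * d + f * e,
               e * aB + f * d + cA * e,
               aA * d + d * bB + e * f,
               d * d + bA * bB + f * f,
               e * d + f * bB + cA * f,
               aA * e + d * f + e * cB,
               d * e + bA * f + f * cB,
               e * e + f * f + cA * cB)
    # pick, per voxel, the column of largest norm
    nrm <- cbind(P[, 1L]^2 + P[, 2L]^2 + P[, 3L]^2,
                 P[, 4L]^2 + P[, 5L]^2 + P[, 6L]^2,
                 P[, 7L]^2 + P[, 8L]^2 + P[, 9L]^2)
    pick <- max.col(nrm, ties.method = "first")
    off <- (pick - 1L) * 3L
    rows <- seq_len(nrow(P))
    v <- cbind(P[cbind(rows, off + 1L)], P[cbind(rows, off + 2L)],
               P[cbind(rows, off + 3L)])
    v / pmax(sqrt(rowSums(v^2)), 1e-300)
  }
  cross3 <- function(u, v) {
    cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
          u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
          u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  }
  # deterministic unit vector orthogonal to u
  perp <- function(u) {
    ax <- abs(u)
    pick <- max.col(-ax, ties.method = "first")  # least-aligned axis
    w <- matrix(0, nrow(u), 3L)
    w[cbind(seq_len(nrow(u)), pick)] <- 1
    w <- w - u * rowSums(w * u)
    w / pmax(sqrt(rowSums(w^2)), 1e-300)
  }

  e1 <- matrix(0, n, 3L); e2 <- matrix(0, n, 3L); e3 <- matrix(0, n, 3L)
  # fully (near-)isotropic: identity basis
  iso <- !sep12 & !sep23 & finite
  e1[iso, 1L] <- 1; e2[iso, 2L] <- 1; e3[iso, 3L] <- 1

  both <- sep12 & sep23
  if (any(both)) {
    sub <- which(both)
    p1 <- projector_col(ev[, 2L], ev[, 3L])[sub, , drop = FALSE]
    p3 <- projector_col(ev[, 1L], ev[, 2L])[sub, , drop = FALSE]
    e1[sub, ] <- p1
    e3[sub, ] <- p3
    e2[sub, ] <- cross3(p3, p1)
  }
  top <- sep12 & !sep23   # prolate: l2 ~ l3
  if (any(top)) {
    sub <- which(top)
    p1 <- projector_col(ev[, 2L], ev[, 3L])[sub, , drop = FALSE]
    w <- perp(p1)
    e1[sub, ] <- p1
    e2[sub, ] <- w
    e3[sub, ] <- cross3(p1, w)
  }
  bot <- !sep12 & sep23   # oblate: l1 ~ l2
  if (any(bot)) {
    sub <- which(bot)
    p3 <- projector_col(ev[, 1L], ev[, 2L])[sub, , drop = FALSE]
    w <- perp(p3)
    e3[sub, ] <- p3
    e1[sub, ] <- w
    e2[sub, ] <- cross3(p3, w)
  }
  if (any(!finite)) {
    e1[!finite, ] <- NaN; e2[!finite, ] <- NaN; e3[!finite, ] <- NaN
  }
  cbind(e1, e2, e3)
}

#' Fit the diffusion tensor per voxel by log-linear least squares
#'
#' Signals are floored at `1e-6 * max(signal)` before taking logarithms, then
#' `ln S = X (D, ln S0)` is solved by ordinary least squares per voxel.
#' Negative eigenvalues are clamped to zero and counted in the QC field
#' `n_clamped`; eigenvectors are computed from the unclamped tensor.
#'
#' @param dwi a [dwi_dataset()].
#' @param mask optional 3-D logical array; defaults to `dwi$mask`, or all
#'   voxels when that is absent. Voxels outside the mask get NaN outputs.
#' @param compute_eigvecs logical; set FALSE to skip the eigenvector triads
#'   (eigenvalue-derived scalar maps do not need them).
#' @return an object of class `tensor_field` with per-voxel arrays `coeffs`
#'   (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz in mm^2/s), `eigvals` (descending),
#'   `eigvecs` (3 x 3 per voxel, columns matched to eigenvalues), `s0`,
#'   plus `affine`, `mask` and the QC counter `n_clamped`.
#' @export
fit_tensor <- function(dwi, mask = NULL, compute_eigvecs = TRUE) {
  stopifnot(inherits(dwi, "dwi_dataset"))
  X <- build_design_matrix(dwi$gtab)
  if (qr(X)$rank < 7L)
    stop("design_rank_error: gradient scheme does not span a rank-7 design",
         call. = FALSE)
  d4 <- dim(dwi$signal)
  d3 <- d4[1:3]
  nvox <- prod(d3)
  if (is.null(mask)) mask <- dwi$mask
  if (is.null(mask)) mask <- array(TRUE, dim = d3)
  midx <- which(mask)

  S <- matrix(dwi$signal, nrow = nvox)[midx, , drop = FALSE]
  dead <- rowSums(S != 0) == 0L          # all-zero voxels -> NaN outputs
  eps <- 1e-6 * max(S, 0)
  if (eps <= 0) eps <- .Machine$double.xmin
  lnS <- log(pmax(S, eps))
  # OLS for all voxels at once: beta = lnS %*% t(pinv(X))
  pinv <- solve(crossprod(X), t(X))
  beta <- lnS %*% t(pinv)
  coeffs <- beta[, 1:6, drop = FALSE]
  s0 <- exp(beta[, 7L])
  coeffs[dead, ] <- NaN
  s0[dead] <- NaN

  ev <- .sym3_eigvals(coeffs)
  n_clamped <- sum(ev < 0, na.rm = TRUE)
  vecs <- if (compute_eigvecs) .sym3_eigvecs(coeffs, ev) else NULL
  ev_clamped <- pmax(ev, 0)
  ev_clamped[dead, ] <- NaN

  full <- function(m, k) {
    out <- matrix(NaN, nvox, k)
    out[midx, ] <- m
    out
  }
  tf <- list(
    coeffs = array(full(coeffs, 6L), dim = c(d3, 6L)),
    eigvals = array(full(ev_clamped, 3L), dim = c(d3, 3L)),
    eigvecs = if (compute_eigvecs)
      array(full(vecs, 9L), dim = c(d3, 3L, 3L)) else NULL,
    s0 = array(replace(rep(NaN, nvox), midx, s0), dim = d3),
    affine = dwi$affine,
    mask = mask,
    n_clamped = n_clamped
  )
  class(tf) <- "tensor_field"
  tf
}


#' @export
print.tensor_field <- function(x, ...) {
  d <- dim(x$s0)
  cat(sprintf("tensor_field: %d x %d x %d grid, %d in-mask voxels, %d clamped eigenvalues\n",
              d[1L], d[2L], d[3L], sum(x$mask), x$n_clamped))
  invisible(x)
}

#' Scalar diffusion maps from a fitted tensor field
#'
#' Computes, from the sorted eigenvalues (l1 >= l2 >= l3):
#' \itemize{
#'   \item FA = sqrt(1/2) sqrt((l1-l2)^2 + (l2-l3)^2 + (l3-l1)^2) /
#'     sqrt(l1^2 + l2^2 + l3^2), with FA of the zero tensor defined as 0;
#'   \item MD = (l1 + l2 + l3) / 3;
#'   \item AD = l1;
#'   \item RD = (l2 + l3) / 2.
#' }
#' Out-of-mask voxels are NaN.
#'
#' @param tf a `tensor_field` from [fit_tensor()].
#' @return an object of class `scalar_maps` with 3-D arrays `fa`, `md`,
#'   `ad`, `rd` and the shared `affine`.
#' @export
compute_scalar_maps <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  d3 <- dim(tf$s0)
  ev <- matrix(tf$eigvals, ncol = 3L)
  l1 <- ev[, 1L]; l2 <- ev[, 2L]; l3 <- ev[, 3L]
  ss <- l1^2 + l2^2 + l3^2
  fa <- sqrt(0.5) * sqrt((l1 - l2)^2 + (l2 - l3)^2 + (l3 - l1)^2) /
    sqrt(ifelse(ss > 0, ss, 1))
  fa[ss == 0] <- 0
  md <- (l1 + l2 + l3) / 3
  structure(list(fa = array(fa, d3), md = array(md, d3),
                 ad = array(l1, d3), rd = array((l2 + l3) / 2, d3),
                 affine = tf$affine),
            class = "scalar_maps")
}

#' Write the four scalar maps as NIfTI volumes
#'
#' @param maps a `scalar_maps` object.
#' @param dir output directory; files are named fa.nii.gz, md.nii.gz,
#'   ad.nii.gz, rd.nii.gz.
#' @export
save_scalar_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "scalar_maps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (m in c("fa", "md", "ad", "rd"))
    write_nifti_volume(maps[[m]], maps$affine,
                       file.path(dir, paste0(m, ".nii.gz")))
  invisible(dir)
}
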