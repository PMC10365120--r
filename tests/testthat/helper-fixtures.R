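# Shared fixtures, built once per test run and cached across files.
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

default_gtab <- function() fixture("gtab", function() make_gradient_table())

# Build a tensor_field by hand from per-voxel eigenvalue and principal-axis
# rules (functions of world-mm voxel-center coordinates).
manual_field <- function(d3, voxel = 1.5,
                         lam_fun = function(w) matrix(c(1.7, 0.3, 0.3) * 1e-3,
                                                      nrow(w), 3L,
                                                      byrow = TRUE),
                         e1_fun = function(w) matrix(c(1, 0, 0), nrow(w), 3L,
                                                     byrow = TRUE)) {
  d3 <- as.integer(d3)
  aff <- diag(c(voxel, voxel, voxel, 1))
  nvox <- prod(d3)
  i0 <- seq_len(nvox) - 1L
  vox <- cbind(i0 %% d3[1L], (i0 %/% d3[1L]) %% d3[2L],
               i0 %/% (d3[1L] * d3[2L]))
  w <- voxel_to_world(aff, vox)
  lam <- lam_fun(w)
  e1 <- e1_fun(w)
  e1 <- e1 / sqrt(rowSums(e1^2))
  # deterministic orthonormal completion
  pick <- max.col(-abs(e1), ties.method = "first")
  e2 <- matrix(0, nvox, 3L)
  e2[cbind(seq_len(nvox), pick)] <- 1
  e2 <- e2 - e1 * rowSums(e2 * e1)
  e2 <- e2 / sqrt(rowSums(e2^2))
  e3 <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  outer6 <- function(e) cbind(e[, 1L]^2, e[, 2L]^2, e[, 3L]^2,
                              e[, 1L] * e[, 2L], e[, 1L] * e[, 3L],
                              e[, 2L] * e[, 3L])
  coeffs <- lam[, 1L] * outer6(e1) + lam[, 2L] * outer6(e2) +
    lam[, 3L] * outer6(e3)
  structure(list(coeffs = array(coeffs, c(d3, 6L)),
                 eigvals = array(lam, c(d3, 3L)),
                 eigvecs = array(cbind(e1, e2, e3), c(d3, 3L, 3L)),
                 s0 = array(1, d3), affine = aff,
                 mask = array(TRUE, d3), n_clamped = 0L),
            class = "tensor_field")
}

# Prolate slab along x: anisotropic inside x-voxel range, isotropic outside.
slab_field <- function(d3 = c(40L, 16L, 16L), x_vox = 10:29,
                       lam_in = c(1.7, 0.3, 0.3) * 1e-3,
                       lam_bg = rep(0.7e-3, 3L), voxel = 1.5) {
  manual_field(d3, voxel, lam_fun = function(w) {
    xv <- round(w[, 1L] / voxel)
    inside <- xv >= min(x_vox) & xv <= max(x_vox)
    out <- matrix(lam_bg, nrow(w), 3L, byrow = TRUE)
    out[inside, ] <- matrix(lam_in, sum(inside), 3L, byrow = TRUE)
    out
  })
}

# Reduced single-hemisphere SLF-like scene used by segmentation, profile
# and pipeline tests (the full bilateral scene is exercised separately).
left_scene <- function() fixture("left_scene", function()
  make_slf_like_scene(grid_shape = c(24L, 48L, 24L),
                      center_mm = c(-18, -9, 17), hemispheres = "L"))

# Noiseless end-to-end products on the left scene: fitted tensors, maps,
# whole-brain tractogram.
left_tracked <- function() fixture("left_tracked", function() {
  scene <- left_scene()
  dwi <- simulate_dwi(scene$field, default_gtab(), snr = Inf)
  tf <- fit_tensor(dwi)
  maps <- compute_scalar_maps(tf)
  tg <- track_whole_brain(tf, maps)
  list(scene = scene, dwi = dwi, tf = tf, maps = maps, tg = tg)
})

# Random SPD tensor at brain-diffusivity scale
random_spd_tensor <- function() {
  M <- matrix(stats::rnorm(9L), 3L)
  A <- crossprod(M)
  A <- A / max(abs(A)) * 1.5e-3 + diag(3L) * 1e-4
  A
}

# Independently coded forward Stejskal-Tanner signal for a 3x3 tensor
forward_signal <- function(A, gtab, s0 = 1) {
  vapply(seq_along(gtab$bvals), function(i) {
    g <- gtab$bvecs[i, ]
    s0 * exp(-gtab$bvals[i] * drop(t(g) %*% A %*% g))
  }, numeric(1L))
}

# Independently coded scalar-metric oracle from a 3x3 tensor via eigen()
metric_oracle <- function(A) {
  l <- sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values,
            decreasing = TRUE)
  l <- pmax(l, 0)
  fa <- if (sum(l^2) == 0) 0 else
    sqrt(0.5) * sqrt((l[1] - l[2])^2 + (l[2] - l[3])^2 + (l[3] - l[1])^2) /
      sqrt(sum(l^2))
  c(fa = fa, md = mean(l), ad = l[1], rd = (l[2] + l[3]) / 2)
}

# 6-vector (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) from a symmetric 3x3 matrix
tensor_to_coeffs <- function(A) {
  c(A[1, 1], A[2, 2], A[3, 3], A[1, 2], A[1, 3], A[2, 3])
}
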