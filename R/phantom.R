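# Synthetic DWI phantom: ground-truth tensor fields built from tubular
# bundles, forward-simulated diffusion signals with Rician noise, and
# two-group cohorts with node-localized eigenvalue effects.

# run a block of code with an isolated RNG stream, restoring caller state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

#' Synthetic acquisition scheme by electrostatic repulsion
#'
#' Generates `n_dirs` diffusion directions spread over the sphere by
#' minimizing an antipodally symmetric electrostatic energy, starting from
#' a deterministic golden-spiral configuration, preceded by `n_b0`
#' unweighted frames. The default reproduces the emulated protocol: 3
#' b = 0 frames plus 64 directions at b = 1000 s/mm^2.
#'
#' @param n_dirs number of diffusion-weighted directions (>= 6).
#' @param n_b0 number of leading b = 0 frames.
#' @param b b-value of the weighted frames (s/mm^2).
#' @param n_iter repulsion iterations.
#' @return a [gradient_table()] with `n_b0 + n_dirs` frames.
#' @export
make_gradient_table <- function(n_dirs = 64L, n_b0 = 3L, b = 1000,
                                n_iter = 100L) {
  stopifnot(n_dirs >= 6L, n_b0 >= 1L)
  # deterministic golden-spiral start on the upper hemisphere (directions
  # are antipodally symmetric, so a full-sphere start would begin with
  # near-duplicate +/-g pairs)
  i <- seq_len(n_dirs)
  ga <- pi * (3 - sqrt(5))
  z <- 1 - (i - 0.5) / n_dirs
  r <- sqrt(pmax(1 - z^2, 0))
  th <- ga * (i - 1)
  X <- cbind(r * cos(th), r * sin(th), z)
  step <- 0.05
  for (it in seq_len(n_iter)) {
    F <- matrix(0, n_dirs, 3L)
    for (k in seq_len(n_dirs)) {
      dplus <- sweep(X, 2L, X[k, ], "-")       # xj - xk
      dminus <- sweep(X, 2L, -X[k, ], "-")     # xj + xk
      np <- sqrt(rowSums(dplus^2)); nm <- sqrt(rowSums(dminus^2))
      np[k] <- Inf; nm[nm < 1e-9] <- Inf
      # Coulomb force on xk from every xj and its antipode -xj
      F[k, ] <- -colSums(dplus / np^3) + colSums(dminus / nm^3)
    }
    # project force onto the tangent plane and take a small step
    F <- F - X * rowSums(F * X)
    X <- X + step * F / max(sqrt(rowSums(F^2)))
    X <- X / sqrt(rowSums(X^2))
  }
  gradient_table(c(rep(0, n_b0), rep(b, n_dirs)),
                 rbind(matrix(0, n_b0, 3L), X))
}

#' Minimum pairwise angle of a direction set, antipodally aware
#' @param bvecs n x 3 unit vectors.
#' @return smallest angle (degrees) between any two directions, treating
#'   g and -g as the same direction.
#' @export
min_pairwise_angle <- function(bvecs) {
  G <- abs(tcrossprod(bvecs))
  diag(G) <- 0
  acos(pmin(max(G), 1)) * 180 / pi
}

#' Tubular bundle specification
#'
#' A bundle is a tube of given radius around a parametric centerline with
#' prescribed eigenvalues inside. Centerline types:
#' \itemize{
#'   \item "straight": `p0` to `p1`;
#'   \item "arc": circle of `radius` about `center` in the plane spanned by
#'     orthonormal `u`, `v`, over angles `theta` (length 2, radians);
#'   \item "arch": x fixed at `x0`, y linear from `y_range[1]` to
#'     `y_range[2]`, z arched as `z_base + arch_height * sin(pi t)` - the
#'     shape used for the SLF-like phantom bundles.
#' }
#'
#' @param name bundle name.
#' @param type centerline type ("straight", "arc", "arch").
#' @param params named list of centerline parameters (see above).
#' @param radius_mm tube radius (mm), larger than half a voxel.
#' @param eigvals length-3 eigenvalues inside the bundle (mm^2/s),
#'   descending, all positive.
#' @return an object of class `bundle_spec`.
#' @export
bundle_spec <- function(name, type, params, radius_mm,
                        eigvals = c(1.7, 0.3, 0.3) * 1e-3) {
  stopifnot(type %in% c("straight", "arc", "arch"),
            length(eigvals) == 3L, all(diff(eigvals) <= 0), all(eigvals > 0))
  structure(list(name = name, type = type, params = params,
                 radius_mm = radius_mm, eigvals = eigvals),
            class = "bundle_spec")
}

#' Evaluate a bundle centerline and its unit tangent
#'
#' @param spec a [bundle_spec()].
#' @param t parameter values in [0, 1].
#' @param offset optional length-3 world translation (subject jitter).
#' @return list(points, tangents), both length(t) x 3.
#' @export
bundle_centerline <- function(spec, t, offset = c(0, 0, 0)) {
  p <- spec$params
  if (spec$type == "straight") {
    d <- p$p1 - p$p0
    pts <- outer(t, d) + matrix(p$p0, length(t), 3L, byrow = TRUE)
    tan <- matrix(d / sqrt(sum(d^2)), length(t), 3L, byrow = TRUE)
  } else if (spec$type == "arc") {
    th <- p$theta[1L] + t * (p$theta[2L] - p$theta[1L])
    pts <- matrix(p$center, length(t), 3L, byrow = TRUE) +
      p$radius * (outer(cos(th), p$u) + outer(sin(th), p$v))
    dth <- sign(p$theta[2L] - p$theta[1L])
    tan <- dth * (outer(-sin(th), p$u) + outer(cos(th), p$v))
  } else {  # arch
    y <- p$y_range[1L] + t * (p$y_range[2L] - p$y_range[1L])
    z <- p$z_base + p$arch_height * sin(pi * t)
    pts <- cbind(p$x0, y, z)
    dy <- p$y_range[2L] - p$y_range[1L]
    dz <- p$arch_height * pi * cos(pi * t)
    tan <- cbind(0, dy, dz)
    tan <- tan / sqrt(rowSums(tan^2))
  }
  pts <- sweep(pts, 2L, offset, "+")
  list(points = pts, tangents = tan)
}

# deterministic unit vector orthogonal to each row of t (n x 3)
.perp_rows <- function(tn) {
  pick <- max.col(-abs(tn), ties.method = "first")
  w <- matrix(0, nrow(tn), 3L)
  w[cbind(seq_len(nrow(tn)), pick)] <- 1
  w <- w - tn * rowSums(w * tn)
  w / sqrt(rowSums(w^2))
}

#' Rasterize ground-truth bundles into a tensor field
#'
#' Inside each bundle the principal eigenvector follows the local
#' centerline tangent; the background is isotropic. Voxels claimed by more
#' than one bundle go to the nearest centerline. The result carries the
#' ground truth needed downstream: per-voxel bundle id, 100-level node
#' index along the centerline, eigenvalues and eigenvector basis.
#'
#' @param specs list of [bundle_spec()].
#' @param grid_shape integer 3-vector.
#' @param affine 4x4 voxel-to-world matrix.
#' @param background_eigvals isotropic background eigenvalues (mm^2/s).
#' @param offsets optional list of per-bundle world translations.
#' @param n_samples centerline samples used for nearest-point queries.
#' @param n_nodes node resolution of the ground-truth node index.
#' @return an object of class `phantom_field`: arrays `coeffs`
#'   (grid x 6), `eigvals` (grid x 3), `eigvecs` (grid x 3 x 3),
#'   `bundle_id` (0 = background), `node`, plus `affine`, `specs`.
#' @export
rasterize_tensor_field <- function(specs, grid_shape, affine,
                                   background_eigvals = rep(0.7e-3, 3L),
                                   offsets = NULL, n_samples = 256L,
                                   n_nodes = 100L) {
  grid_shape <- as.integer(grid_shape)
  nvox <- prod(grid_shape)
  i0 <- seq_len(nvox) - 1L
  vox <- cbind(i0 %% grid_shape[1L],
               (i0 %/% grid_shape[1L]) %% grid_shape[2L],
               i0 %/% (grid_shape[1L] * grid_shape[2L]))
  world <- voxel_to_world(affine, vox)
  wmin <- apply(world, 2L, min); wmax <- apply(world, 2L, max)

  best_dist <- rep(Inf, nvox)
  bundle_id <- integer(nvox)
  node_idx <- integer(nvox)
  tangent <- matrix(0, nvox, 3L)
  tt <- seq(0, 1, length.out = n_samples)
  for (bi in seq_along(specs)) {
    sp <- specs[[bi]]
    off <- if (is.null(offsets)) c(0, 0, 0) else offsets[[bi]]
    cl <- bundle_centerline(sp, tt, off)
    if (any(apply(cl$points, 2L, min) < wmin - sp$radius_mm) ||
        any(apply(cl$points, 2L, max) > wmax + sp$radius_mm))
      stop("phantom_error: bundle '", sp$name, "' extends outside the grid",
           call. = FALSE)
    seg <- sqrt(rowSums(diff(cl$points)^2))
    arc <- c(0, cumsum(seg))
    node_of_sample <- pmin(pmax(round(arc / arc[n_samples] *
                                        (n_nodes - 1L)) + 1L, 1L), n_nodes)
    # candidate voxels: centerline bounding box padded by the radius
    lo <- apply(cl$points, 2L, min) - sp$radius_mm - 1e-9
    hi <- apply(cl$points, 2L, max) + sp$radius_mm + 1e-9
    cand <- which(world[, 1L] >= lo[1L] & world[, 1L] <= hi[1L] &
                  world[, 2L] >= lo[2L] & world[, 2L] <= hi[2L] &
                  world[, 3L] >= lo[3L] & world[, 3L] <= hi[3L])
    if (length(cand) == 0L) next
    W <- world[cand, , drop = FALSE]
    # nearest centerline sample per candidate voxel (chunked)
    cn2 <- rowSums(cl$points^2)
    nearest <- integer(length(cand))
    ndist <- numeric(length(cand))
    chunk <- 4096L
    for (c0 in seq(1L, length(cand), by = chunk)) {
      c1 <- min(c0 + chunk - 1L, length(cand))
      Wc <- W[c0:c1, , drop = FALSE]
      D2 <- outer(rowSums(Wc^2), cn2, "+") - 2 * tcrossprod(Wc, cl$points)
      j <- max.col(-D2, ties.method = "first")
      nearest[c0:c1] <- j
      ndist[c0:c1] <- sqrt(pmax(D2[cbind(seq_len(nrow(D2)), j)], 0))
    }
    inside <- ndist <= sp$radius_mm & ndist < best_dist[cand]
    vi <- cand[inside]
    best_dist[vi] <- ndist[inside]
    bundle_id[vi] <- bi
    node_idx[vi] <- node_of_sample[nearest[inside]]
    tangent[vi, ] <- cl$tangents[nearest[inside], , drop = FALSE]
  }

  eigvals <- matrix(background_eigvals, nvox, 3L, byrow = TRUE)
  e1 <- matrix(0, nvox, 3L); e1[, 1L] <- 1
  e2 <- matrix(0, nvox, 3L); e2[, 2L] <- 1
  e3 <- matrix(0, nvox, 3L); e3[, 3L] <- 1
  inb <- bundle_id > 0L
  if (any(inb)) {
    lam <- t(vapply(specs, function(s) s$eigvals, numeric(3L)))
    eigvals[inb, ] <- lam[bundle_id[inb], , drop = FALSE]
    tn <- tangent[inb, , drop = FALSE]
    u <- .perp_rows(tn)
    v <- cbind(tn[, 2L] * u[, 3L] - tn[, 3L] * u[, 2L],
               tn[, 3L] * u[, 1L] - tn[, 1L] * u[, 3L],
               tn[, 1L] * u[, 2L] - tn[, 2L] * u[, 1L])
    e1[inb, ] <- tn; e2[inb, ] <- u; e3[inb, ] <- v
  }
  pf <- list(grid_shape = grid_shape, affine = affine, specs = specs,
             eigvals = eigvals, e1 = e1, e2 = e2, e3 = e3,
             bundle_id = array(bundle_id, grid_shape),
             node = array(node_idx, grid_shape))
  class(pf) <- "phantom_field"
  pf
}

# tensor coefficients (nvox x 6) from a phantom field's eigensystem
.phantom_coeffs <- function(pf) {
  outer6 <- function(e) cbind(e[, 1L]^2, e[, 2L]^2, e[, 3L]^2,
                              e[, 1L] * e[, 2L], e[, 1L] * e[, 3L],
                              e[, 2L] * e[, 3L])
  pf$eigvals[, 1L] * outer6(pf$e1) + pf$eigvals[, 2L] * outer6(pf$e2) +
    pf$eigvals[, 3L] * outer6(pf$e3)
}

#' Ground-truth tensor field as a `tensor_field` object
#'
#' Converts a rasterized phantom into the same container [fit_tensor()]
#' produces, so noiseless signals can be checked against it directly.
#'
#' @param pf a `phantom_field`.
#' @return a `tensor_field`.
#' @export
phantom_tensor_field <- function(pf) {
  stopifnot(inherits(pf, "phantom_field"))
  d3 <- pf$grid_shape
  structure(list(
    coeffs = array(.phantom_coeffs(pf), dim = c(d3, 6L)),
    eigvals = array(pf$eigvals, dim = c(d3, 3L)),
    eigvecs = array(cbind(pf$e1, pf$e2, pf$e3), dim = c(d3, 3L, 3L)),
    s0 = array(1, dim = d3),
    affine = pf$affine,
    mask = array(TRUE, dim = d3),
    n_clamped = 0L), class = "tensor_field")
}

#' Forward-simulate a diffusion-weighted dataset
#'
#' Noiseless signals follow the Stejskal-Tanner equation
#' `S = s0 exp(-b g' D g)`; Rician noise is added as the magnitude of a
#' complex Gaussian perturbation with standard deviation `s0 / snr` per
#' channel, the noise model of magnitude MRI.
#'
#' @param field a `phantom_field` or `tensor_field` (its tensors are used).
#' @param gtab a [gradient_table()].
#' @param s0 baseline signal (arbitrary units).
#' @param snr signal-to-noise ratio at b = 0; `Inf` for noiseless data.
#' @param rng_seed integer seed; the caller's RNG state is untouched.
#' @return a [dwi_dataset()].
#' @export
simulate_dwi <- function(field, gtab, s0 = 1000, snr = 30, rng_seed = 1L) {
  stopifnot(snr > 0)
  if (inherits(field, "phantom_field")) {
    C <- .phantom_coeffs(field)
    d3 <- field$grid_shape
    affine <- field$affine
  } else if (inherits(field, "tensor_field")) {
    d3 <- dim(field$s0)
    C <- matrix(field$coeffs, ncol = 6L)
    affine <- field$affine
  } else stop("unsupported field object")
  X6 <- build_design_matrix(gtab)[, 1:6, drop = FALSE]
  S <- s0 * exp(C %*% t(X6))          # nvox x frames
  if (is.finite(snr)) {
    sigma <- s0 / snr
    S <- .with_seed(rng_seed, {
      e1 <- matrix(stats::rnorm(length(S), 0, sigma), nrow(S))
      e2 <- matrix(stats::rnorm(length(S), 0, sigma), nrow(S))
      sqrt((S + e1)^2 + e2^2)
    })
  }
  dwi_dataset(array(S, dim = c(d3, length(gtab))), affine, gtab)
}

# Gaussian smoothing of a 3-D volume by separable shift-and-add convolution
.smooth3 <- function(vol, sigma_vox) {
  if (sigma_vox <= 0) return(vol)
  half <- max(1L, ceiling(2.5 * sigma_vox))
  k <- stats::dnorm(-half:half, sd = sigma_vox)
  k <- k / sum(k)
  d <- dim(vol)
  for (ax in 1:3) {
    out <- array(0, d)
    for (s in -half:half) {
      w <- k[s + half + 1L]
      src <- max(1L, 1L - s):min(d[ax], d[ax] - s)
      dst <- src + s
      if (ax == 1L) out[dst, , ] <- out[dst, , ] + w * vol[src, , ]
      else if (ax == 2L) out[, dst, ] <- out[, dst, ] + w * vol[, src, ]
      else out[, , dst] <- out[, , dst] + w * vol[, , src]
    }
    vol <- out
  }
  vol
}

#' SLF-like two-bundle-per-hemisphere phantom scene
#'
#' Builds the geometry every segmentation and profiling test runs on: per
#' hemisphere, a dorsal arch ("SLF II"-like) and a ventral arch
#' ("SLF III"-like) running anterior to posterior, threading a shared
#' posterior waypoint plane and separate anterior boxes; phantom-space
#' waypoint ROIs; a fiber probability map (normalized smoothed bundle
#' density); and a spherical lesion mask overlapping the left dorsal
#' bundle (when present).
#'
#' @param grid_shape grid dimensions (default 60 x 72 x 60).
#' @param voxel_mm isotropic voxel size (default 1.5).
#' @param center_mm world coordinate at the grid center; the default
#'   centers the default bilateral scene, while reduced single-hemisphere
#'   grids should center on their bundles (e.g. c(-18, -9, 17) for "L").
#' @param hemispheres subset of c("L", "R").
#' @param radius_mm bundle tube radius.
#' @param eigvals in-bundle eigenvalues (mm^2/s).
#' @param background_eigvals isotropic background eigenvalues.
#' @param prob_smooth_mm Gaussian sigma of the probability-map smoothing.
#' @return list with `specs`, `affine`, `grid_shape`, `rois` (named list of
#'   phantom-space [waypoint_roi_plane()]), `prob_map` (per-bundle list of
#'   3-D arrays plus `union`), `lesion_mask`, `background_eigvals`, and the
#'   geometry constants `y_anterior`, `y_posterior`.
#' @export
make_slf_like_scene <- function(grid_shape = c(60L, 72L, 60L),
                                voxel_mm = 1.5,
                                center_mm = c(0, 0, 0),
                                hemispheres = c("L", "R"),
                                radius_mm = 4,
                                eigvals = c(1.7, 0.3, 0.3) * 1e-3,
                                background_eigvals = rep(0.7e-3, 3L),
                                prob_smooth_mm = 2) {
  grid_shape <- as.integer(grid_shape)
  affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  affine[1:3, 4L] <- center_mm - (grid_shape - 1) / 2 * voxel_mm
  y_a <- 2; y_p <- -25
  y_range <- c(22, -40)
  z2 <- 20; z3 <- 6; arch <- 8
  specs <- list()
  rois <- list()
  for (h in hemispheres) {
    x0 <- if (h == "L") -18 else 18
    xr <- sort(x0 + c(-8, 8))
    specs[[paste0(h, "_SLF_II")]] <- bundle_spec(
      paste0(h, "_SLF_II"), "arch",
      list(x0 = x0, y_range = y_range, z_base = z2, arch_height = arch),
      radius_mm, eigvals)
    specs[[paste0(h, "_SLF_III")]] <- bundle_spec(
      paste0(h, "_SLF_III"), "arch",
      list(x0 = x0, y_range = y_range, z_base = z3, arch_height = arch),
      radius_mm, eigvals)
    rois[[paste0(h, "_SLF_II_anterior")]] <- waypoint_roi_plane(
      paste0(h, "_SLF_II_anterior"), y_a, xr, c(z2 + 1, z2 + 13), 3, h,
      "phantom")
    rois[[paste0(h, "_SLF_III_anterior")]] <- waypoint_roi_plane(
      paste0(h, "_SLF_III_anterior"), y_a, xr, c(z3 - 5, z3 + 7 + 5), 3, h,
      "phantom")
    rois[[paste0(h, "_SLF_anterior")]] <- waypoint_roi_plane(
      paste0(h, "_SLF_anterior"), y_a, xr, c(z3 - 5, z2 + 13), 3, h,
      "phantom")
    rois[[paste0(h, "_posterior")]] <- waypoint_roi_plane(
      paste0(h, "_posterior"), y_p, xr, c(z3 - 6, z2 + 14), 3, h, "phantom")
  }
  base <- rasterize_tensor_field(specs, grid_shape, affine,
                                 background_eigvals)
  sig_vox <- prob_smooth_mm / voxel_mm
  prob <- list()
  for (bi in seq_along(specs)) {
    dens <- .smooth3(array(as.numeric(base$bundle_id == bi), grid_shape),
                     sig_vox)
    prob[[names(specs)[bi]]] <- dens / max(dens)
  }
  dens_u <- .smooth3(array(as.numeric(base$bundle_id > 0L), grid_shape),
                     sig_vox)
  prob$union <- dens_u / max(dens_u)

  lesion <- array(FALSE, grid_shape)
  les_h <- if ("L" %in% hemispheres) "L" else hemispheres[1L]
  cl <- bundle_centerline(specs[[paste0(les_h, "_SLF_II")]], 0.5)
  center <- drop(cl$points)
  i0 <- seq_len(prod(grid_shape)) - 1L
  vox <- cbind(i0 %% grid_shape[1L],
               (i0 %/% grid_shape[1L]) %% grid_shape[2L],
               i0 %/% (grid_shape[1L] * grid_shape[2L]))
  world <- voxel_to_world(affine, vox)
  d2c <- rowSums(sweep(world, 2L, center, "-")^2)
  lesion[d2c <= 6^2] <- TRUE

  list(specs = specs, affine = affine, grid_shape = grid_shape,
       rois = rois, prob_map = prob, lesion_mask = lesion,
       background_eigvals = background_eigvals,
       y_anterior = y_a, y_posterior = y_p, field = base)
}

#' Node-localized group effect on bundle eigenvalues
#'
#' Effects are injected on the generative eigenvalues so that FA, MD, AD
#' and RD stay mutually consistent: an AD effect scales (or shifts) l1, an
#' RD effect l2 and l3, an MD effect all three; an FA effect scales the
#' deviations from the eigenvalue mean, preserving MD.
#'
#' @param bundle name of the target bundle in the scene.
#' @param metric one of "fa", "md", "ad", "rd".
#' @param node_range length-2 integer range in 1..100.
#' @param value effect size: a multiplicative factor (`mode =
#'   "multiplicative"`, e.g. 1.1 for +10 percent) or an additive shift in
#'   mm^2/s.
#' @param group group label the effect applies to.
#' @param mode "multiplicative" (default) or "additive" ("fa" supports
#'   only multiplicative).
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(bundle, metric, node_range, value, group,
                        mode = c("multiplicative", "additive")) {
  mode <- match.arg(mode)
  stopifnot(metric %in% c("fa", "md", "ad", "rd"),
            length(node_range) == 2L, node_range[1L] >= 1L,
            node_range[1L] <= node_range[2L])
  if (metric == "fa" && mode == "additive")
    stop("fa effects are multiplicative (deviation scaling)", call. = FALSE)
  structure(list(bundle = bundle, metric = metric,
                 node_range = as.integer(node_range), value = value,
                 group = group, mode = mode),
            class = "effect_spec")
}

# apply an effect to a 3-column eigenvalue matrix (rows = voxels or nodes)
.apply_effect_lam <- function(lam, eff) {
  f <- eff$value
  if (eff$mode == "multiplicative") {
    switch(eff$metric,
      ad = { lam[, 1L] <- lam[, 1L] * f },
      rd = { lam[, 2L] <- lam[, 2L] * f; lam[, 3L] <- lam[, 3L] * f },
      md = { lam <- lam * f },
      fa = {
        m <- rowMeans(lam)
        lam <- m + f * (lam - m)
      })
  } else {
    switch(eff$metric,
      ad = { lam[, 1L] <- lam[, 1L] + f },
      rd = { lam[, 2L] <- lam[, 2L] + f; lam[, 3L] <- lam[, 3L] + f },
      md = { lam <- lam + f })
  }
  if (any(lam[, 1L] < lam[, 2L] - 1e-15 | lam[, 2L] < lam[, 3L] - 1e-15) ||
      any(lam <= 0))
    stop("effect_error: effect breaks eigenvalue ordering or positivity",
         call. = FALSE)
  lam
}

#' Scalar metrics from eigenvalue rows
#' @param lam n x 3 matrix of eigenvalues, descending.
#' @return n x 4 matrix with columns fa, md, ad, rd.
#' @export
eigvals_to_metrics <- function(lam) {
  l1 <- lam[, 1L]; l2 <- lam[, 2L]; l3 <- lam[, 3L]
  ss <- l1^2 + l2^2 + l3^2
  fa <- sqrt(0.5) * sqrt((l1 - l2)^2 + (l2 - l3)^2 + (l3 - l1)^2) /
    sqrt(ifelse(ss > 0, ss, 1))
  fa[ss == 0] <- 0
  cbind(fa = fa, md = (l1 + l2 + l3) / 3, ad = l1, rd = (l2 + l3) / 2)
}

#' Cohort specification for two-group phantom simulation
#'
#' Defaults mirror the emulated study conditions: 15 subjects per group on
#' a 3 b0 + 64 direction, b = 1000 s/mm^2, 1.5 mm isotropic protocol.
#'
#' @param n_per_group subjects per group (>= 2, default 15).
#' @param snr Rician signal-to-noise ratio at b = 0 (default 30).
#' @param jitter_sd_mm SD of the per-subject rigid translation of the
#'   bundle geometry (default 0.5 mm).
#' @param effects list of [effect_spec()].
#' @param groups length-2 group labels (first = patients).
#' @param rng_seed master seed; all subject-level randomness derives from
#'   it.
#' @param s0 baseline signal.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 15L, snr = 30, jitter_sd_mm = 0.5,
                        effects = list(), groups = c("AVM", "control"),
                        rng_seed = 1L, s0 = 1000) {
  stopifnot(n_per_group >= 2L, snr > 0, length(groups) == 2L)
  structure(list(n_per_group = as.integer(n_per_group), snr = snr,
                 jitter_sd_mm = jitter_sd_mm, effects = effects,
                 groups = groups, rng_seed = as.integer(rng_seed), s0 = s0),
            class = "cohort_spec")
}

#' Simulate a two-group cohort on a phantom scene
#'
#' Per subject: the scene's bundle geometry is rigidly jittered, group
#' effects are applied to the eigenvalues within their mapped node range,
#' and a DWI dataset is simulated with a fresh sub-seed. The returned
#' ledger records the true node-wise metric profile of every bundle for
#' both groups.
#'
#' @param scene a [make_slf_like_scene()] scene.
#' @param spec a [cohort_spec()].
#' @param gtab gradient table; default [make_gradient_table()] defaults.
#' @return list with `subjects` (each: `dwi`, `subject_id`, `group`,
#'   `offset`) and `truth` (per bundle and group, a 100 x 4 node-by-metric
#'   matrix of true values).
#' @export
make_cohort <- function(scene, spec = cohort_spec(),
                        gtab = make_gradient_table()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_per_group
  groups <- rep(spec$groups, each = n)
  ids <- sprintf("%s_%02d", groups, c(seq_len(n), seq_len(n)))
  offsets <- .with_seed(spec$rng_seed,
                        matrix(stats::rnorm(2L * n * 3L, 0,
                                            spec$jitter_sd_mm), ncol = 3L))
  subjects <- vector("list", 2L * n)
  for (si in seq_len(2L * n)) {
    off <- offsets[si, ]
    pf <- rasterize_tensor_field(
      scene$specs, scene$grid_shape, scene$affine,
      scene$background_eigvals,
      offsets = rep(list(off), length(scene$specs)))
    for (eff in spec$effects) {
      if (!identical(eff$group, groups[si])) next
      bi <- match(eff$bundle, names(scene$specs))
      if (is.na(bi))
        stop("effect_error: unknown bundle '", eff$bundle, "'",
             call. = FALSE)
      hit <- which(as.vector(pf$bundle_id) == bi &
                     as.vector(pf$node) >= eff$node_range[1L] &
                     as.vector(pf$node) <= eff$node_range[2L])
      if (length(hit))
        pf$eigvals[hit, ] <- .apply_effect_lam(
          pf$eigvals[hit, , drop = FALSE], eff)
    }
    dwi <- simulate_dwi(pf, gtab, s0 = spec$s0, snr = spec$snr,
                        rng_seed = spec$rng_seed * 10000L + si)
    subjects[[si]] <- list(dwi = dwi, subject_id = ids[si],
                           group = groups[si], offset = off)
  }

  truth <- list()
  for (bi in seq_along(scene$specs)) {
    bn <- names(scene$specs)[bi]
    lam0 <- matrix(scene$specs[[bi]]$eigvals, 100L, 3L, byrow = TRUE)
    for (g in spec$groups) {
      lam <- lam0
      for (eff in spec$effects) {
        if (!identical(eff$group, g) || !identical(eff$bundle, bn)) next
        rng <- eff$node_range[1L]:eff$node_range[2L]
        lam[rng, ] <- .apply_effect_lam(lam[rng, , drop = FALSE], eff)
      }
      truth[[paste0(bn, "|", g)]] <- eigvals_to_metrics(lam)
    }
  }
  list(subjects = subjects, truth = truth, spec = spec, gtab = gtab)
}
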