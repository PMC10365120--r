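#' Deterministic tracking parameters
#'
#' Termination follows the classical FACT rules: a streamline stops when it
#' would enter a voxel with FA below `fa_stop` (default 0.2), when the turn
#' between the last path segment and the next step exceeds `max_angle_deg`
#' (default 30 degrees), when it leaves the grid, or when it exceeds
#' `max_len_mm`. Streamlines shorter than `min_len_mm` are discarded.
#'
#' @param fa_stop FA termination threshold, in (0, 1).
#' @param max_angle_deg maximum turning angle per step, in (0, 90) degrees.
#' @param step_mm step length in mm; default 0.75 (half a 1.5 mm voxel), so
#'   that sub-voxel stepping keeps the angle rule meaningful while the
#'   eigenvector is still read per voxel.
#' @param seed_fa_min minimum FA for seeding (default 0.3).
#' @param max_len_mm,min_len_mm streamline length bounds in mm.
#' @param seeds_per_voxel seeds per eligible voxel; values above one add
#'   uniform jitter inside the voxel, reproducible via `rng_seed`.
#' @param rng_seed integer seed for any stochastic seeding.
#' @return an object of class `tracking_params`.
#' @export
tracking_params <- function(fa_stop = 0.2, max_angle_deg = 30,
                            step_mm = 0.75, seed_fa_min = 0.3,
                            max_len_mm = 250, min_len_mm = 20,
                            seeds_per_voxel = 1L, rng_seed = 1L) {
  stopifnot(fa_stop > 0, fa_stop < 1,
            max_angle_deg > 0, max_angle_deg < 90,
            step_mm > 0, min_len_mm < max_len_mm, seeds_per_voxel >= 1L)
  structure(list(fa_stop = fa_stop, max_angle_deg = max_angle_deg,
                 step_mm = step_mm, seed_fa_min = seed_fa_min,
                 max_len_mm = max_len_mm, min_len_mm = min_len_mm,
                 seeds_per_voxel = as.integer(seeds_per_voxel),
                 rng_seed = as.integer(rng_seed)),
            class = "tracking_params")
}

#' Seed points for whole-brain tracking
#'
#' One seed is placed at the center of every voxel whose FA is at least
#' `seed_fa_min`, in deterministic raster-scan order (first grid axis
#' fastest). With `seeds_per_voxel > 1`, additional seeds are jittered
#' uniformly inside each voxel using `rng_seed`.
#'
#' @param maps a `scalar_maps` object (the FA map is used).
#' @param params a [tracking_params()].
#' @return n x 3 matrix of world-mm seed coordinates.
#' @export
generate_seeds <- function(maps, params = tracking_params()) {
  stopifnot(inherits(maps, "scalar_maps"))
  fa <- maps$fa
  idx <- which(!is.na(fa) & fa >= params$seed_fa_min)
  if (length(idx) == 0L)
    stop("empty_seed_error: no voxel has FA >= seed_fa_min", call. = FALSE)
  d <- dim(fa)
  i0 <- (idx - 1L)
  vox <- cbind(i0 %% d[1L],
               (i0 %/% d[1L]) %% d[2L],
               i0 %/% (d[1L] * d[2L]))
  if (params$seeds_per_voxel > 1L) {
    k <- params$seeds_per_voxel
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(params$rng_seed)
    jit <- matrix(stats::runif(nrow(vox) * (k - 1L) * 3L, -0.5, 0.5),
                  ncol = 3L)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    vox <- rbind(vox, vox[rep(seq_len(nrow(vox)), k - 1L), ] + jit)
  }
  voxel_to_world(maps$affine, vox)
}

# Principal eigenvector per voxel as an (nvox x 3) matrix.
.principal_dirs <- function(tf) {
  if (is.null(tf$eigvecs))
    stop("tensor field was fitted without eigenvectors", call. = FALSE)
  matrix(tf$eigvecs, ncol = 9L)[, 1:3, drop = FALSE]
}

# Track one half of each seed's streamline (batch, vectorized over seeds).
# Returns a list of per-seed point matrices EXCLUDING the seed point.
.track_half <- function(E1, fa_vec, dim3, affine, inv_affine, seeds, dirs,
                        params) {
  n <- nrow(seeds)
  step <- params$step_mm
  cos_max <- cos(params$max_angle_deg * pi / 180)
  max_steps <- ceiling(params$max_len_mm / 2 / step)
  P <- seeds
  D <- dirs
  active <- rep(TRUE, n)
  hist <- vector("list", max_steps)
  for (s in seq_len(max_steps)) {
    if (!any(active)) { hist <- hist[seq_len(s - 1L)]; break }
    newP <- matrix(NA_real_, n, 3L)
    ai <- which(active)
    cand <- P[ai, , drop = FALSE] + step * D[ai, , drop = FALSE]
    # the point reached by this (valid) step is always recorded; whether
    # tracking continues from it is decided below, so a terminal point may
    # lie in the look-ahead voxel that triggered termination
    newP[ai, ] <- cand
    vox <- apply_affine(inv_affine, cand)
    lin <- .voxel_linear_index(vox, dim3)
    inside <- !is.na(lin)
    fa_ok <- inside
    fa_ok[inside] <- !is.na(fa_vec[lin[inside]]) &
      fa_vec[lin[inside]] >= params$fa_stop
    active[ai] <- FALSE
    if (any(fa_ok)) {
      ki <- ai[fa_ok]
      # next direction: principal eigenvector of the entered voxel,
      # sign-aligned with the direction just travelled
      v <- E1[lin[fa_ok], , drop = FALSE]
      dprev <- D[ki, , drop = FALSE]
      sgn <- sign(rowSums(v * dprev))
      sgn[sgn == 0] <- 1
      v <- v * sgn
      cosang <- rowSums(v * dprev)
      turn_ok <- is.finite(cosang) & cosang >= cos_max
      P[ki, ] <- cand[fa_ok, , drop = FALSE]
      D[ki, ] <- v
      active[ki[turn_ok]] <- TRUE
    }
    hist[[s]] <- newP
    if (!any(active) && s < max_steps) { hist <- hist[seq_len(s)]; break }
  }
  ns <- length(hist)
  if (ns == 0L) return(rep(list(NULL), n))
  H <- array(unlist(hist, use.names = FALSE), dim = c(n, 3L, ns))
  lapply(seq_len(n), function(i) {
    sl <- H[i, , , drop = TRUE]
    if (ns == 1L) sl <- matrix(sl, 3L, 1L)
    ok <- is.finite(sl[1L, ])
    if (!any(ok)) return(NULL)
    t(sl[, ok, drop = FALSE])
  })
}

# Batch FACT tracking from arbitrary seeds; returns list of streamline
# matrices (NULL where tracking failed or the result is too short).
.track_batch <- function(tf, maps, seeds, params) {
  dim3 <- dim(maps$fa)
  fa_vec <- as.vector(maps$fa)
  E1 <- .principal_dirs(tf)
  inv_affine <- invert_affine(tf$affine)
  vox0 <- apply_affine(inv_affine, seeds)
  lin0 <- .voxel_linear_index(vox0, dim3)
  ok0 <- !is.na(lin0) & !is.na(fa_vec[pmax(lin0, 1L)]) &
    fa_vec[pmax(lin0, 1L)] >= params$fa_stop
  d0 <- matrix(NA_real_, nrow(seeds), 3L)
  d0[ok0, ] <- E1[lin0[ok0], , drop = FALSE]
  ok0 <- ok0 & is.finite(d0[, 1L]) & rowSums(d0^2) > 0.5
  idx <- which(ok0)
  out <- vector("list", nrow(seeds))
  if (length(idx) == 0L) return(out)
  sub_seeds <- seeds[idx, , drop = FALSE]
  sub_dirs <- d0[idx, , drop = FALSE]
  fwd <- .track_half(E1, fa_vec, dim3, tf$affine, inv_affine,
                     sub_seeds, sub_dirs, params)
  bwd <- .track_half(E1, fa_vec, dim3, tf$affine, inv_affine,
                     sub_seeds, -sub_dirs, params)
  for (j in seq_along(idx)) {
    b <- bwd[[j]]
    f <- fwd[[j]]
    pts <- rbind(if (!is.null(b)) b[rev(seq_len(nrow(b))), , drop = FALSE],
                 sub_seeds[j, , drop = FALSE],
                 f)
    if (nrow(pts) < 2L) next
    len <- (nrow(pts) - 1L) * params$step_mm
    if (len < params$min_len_mm || len > params$max_len_mm) next
    out[[idx[j]]] <- pts
  }
  out
}

#' Track a single streamline from a seed point
#'
#' Follows the per-voxel principal eigenvector bidirectionally from the
#' seed (both polarities of the seed-voxel eigenvector, concatenated),
#' reading the eigenvector of the voxel containing the current point
#' (nearest-voxel lookup, as in classical FACT) and sign-aligning it with
#' the previous step direction.
#'
#' @param tf a `tensor_field` with eigenvectors.
#' @param maps matching `scalar_maps` (the FA map drives termination).
#' @param seed length-3 world-mm coordinate inside the grid.
#' @param params a [tracking_params()].
#' @return an n x 3 point matrix, or NULL if the track is shorter than
#'   `min_len_mm` or the seed is degenerate.
#' @export
track_streamline <- function(tf, maps, seed, params = tracking_params()) {
  stopifnot(inherits(tf, "tensor_field"), inherits(maps, "scalar_maps"))
  .track_batch(tf, maps, matrix(seed, nrow = 1L), params)[[1L]]
}

#' Whole-brain deterministic tractography
#'
#' Runs [track_streamline()] from every seed produced by
#' [generate_seeds()], in seed order. The result is fully deterministic
#' given the inputs and parameters.
#'
#' @inheritParams track_streamline
#' @return a [tractogram()] on the tensor field's grid.
#' @export
track_whole_brain <- function(tf, maps, params = tracking_params()) {
  seeds <- generate_seeds(maps, params)
  sls <- .track_batch(tf, maps, seeds, params)
  sls <- sls[!vapply(sls, is.null, logical(1L))]
  tractogram(sls, tf$affine, dim(maps$fa), validate = FALSE)
}
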