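#' Coronal-plane waypoint ROI
#'
#' A waypoint region of interest defined analytically as a slab around a
#' coronal plane (fixed world y), restricted to an in-plane bounding box in
#' x and z. This mirrors the classical definition of the SLF branch
#' waypoints on the anterior- and posterior-commissure coronal slices.
#'
#' @param name ROI name.
#' @param y_mm world y coordinate of the plane (mm).
#' @param x_range,z_range length-2 numeric, in-plane box bounds (mm).
#' @param thickness_mm slab thickness (mm); must cover at least one voxel.
#' @param hemisphere "L", "R" or NA.
#' @param space coordinate space tag ("MNI", "native" or "phantom").
#' @return an object of class `waypoint_roi` (geometry "plane").
#' @export
waypoint_roi_plane <- function(name, y_mm, x_range, z_range,
                               thickness_mm = 3, hemisphere = NA_character_,
                               space = "MNI") {
  stopifnot(length(x_range) == 2L, length(z_range) == 2L, thickness_mm > 0)
  structure(list(name = name, space = space, geometry = "plane",
                 y_mm = y_mm, x_range = sort(x_range),
                 z_range = sort(z_range), thickness_mm = thickness_mm,
                 hemisphere = hemisphere),
            class = "waypoint_roi")
}

#' Binary-mask waypoint ROI
#'
#' @param name ROI name.
#' @param mask 3-D logical/0-1 array.
#' @param affine 4x4 voxel-to-world matrix of the mask grid.
#' @param hemisphere,space as in [waypoint_roi_plane()].
#' @return an object of class `waypoint_roi` (geometry "mask").
#' @export
waypoint_roi_mask <- function(name, mask, affine,
                              hemisphere = NA_character_, space = "native") {
  mask <- array(mask != 0, dim = dim(mask))
  if (!any(mask))
    stop("roi_error: empty ROI mask", call. = FALSE)
  structure(list(name = name, space = space, geometry = "mask",
                 mask = mask, affine = affine, hemisphere = hemisphere),
            class = "waypoint_roi")
}

#' @export
print.waypoint_roi <- function(x, ...) {
  if (x$geometry == "plane")
    cat(sprintf("waypoint_roi '%s' [%s]: coronal plane y = %g mm (±%g), x %g..%g, z %g..%g\n",
                x$name, x$space, x$y_mm, x$thickness_mm / 2,
                x$x_range[1L], x$x_range[2L], x$z_range[1L], x$z_range[2L]))
  else
    cat(sprintf("waypoint_roi '%s' [%s]: mask with %d voxels\n",
                x$name, x$space, sum(x$mask)))
  invisible(x)
}

#' Which points fall inside a waypoint ROI
#'
#' @param roi a `waypoint_roi`.
#' @param points n x 3 matrix of world-mm coordinates.
#' @return logical vector of length n.
#' @export
roi_contains <- function(roi, points) {
  stopifnot(inherits(roi, "waypoint_roi"))
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  if (roi$geometry == "plane") {
    abs(points[, 2L] - roi$y_mm) <= roi$thickness_mm / 2 &
      points[, 1L] >= roi$x_range[1L] & points[, 1L] <= roi$x_range[2L] &
      points[, 3L] >= roi$z_range[1L] & points[, 3L] <= roi$z_range[2L]
  } else {
    vox <- world_to_voxel(roi$affine, points)
    lin <- .voxel_linear_index(vox, dim(roi$mask))
    out <- rep(FALSE, nrow(points))
    ok <- !is.na(lin)
    out[ok] <- roi$mask[lin[ok]]
    out
  }
}

#' Waypoint ROIs for the SLF II / SLF III dissection
#'
#' Returns, per hemisphere, the two anterior ROIs on the coronal plane at
#' the anterior commissure (y = 2 mm: a dorsal box for SLF II and a ventral
#' box for SLF III) and the shared posterior ROI on the plane at the
#' posterior commissure (y = -25 mm), plus a merged anterior box used to
#' define the whole SLF. The in-plane box bounds are configurable defaults,
#' not anatomically validated extents; phantom-space analyses supply their
#' own boxes.
#'
#' @param y_anterior,y_posterior coronal plane coordinates in mm.
#' @param x_inner,x_outer absolute lateral bounds of the boxes (mm).
#' @param z_slf2,z_slf3 length-2 dorsal/ventral box bounds for SLF II and
#'   SLF III (mm); must be disjoint for disjoint branch membership.
#' @param z_posterior length-2 bounds of the shared posterior box (mm).
#' @param thickness_mm slab thickness (mm).
#' @param space space tag recorded on the ROIs.
#' @return named list of `waypoint_roi` objects:
#'   `<hemi>_SLF_II_anterior`, `<hemi>_SLF_III_anterior`,
#'   `<hemi>_SLF_anterior`, `<hemi>_posterior` for hemi in L, R.
#' @export
define_slf_rois <- function(y_anterior = 2, y_posterior = -25,
                            x_inner = 12, x_outer = 40,
                            z_slf2 = c(18, 40), z_slf3 = c(2, 16),
                            z_posterior = c(2, 40), thickness_mm = 3,
                            space = "MNI") {
  out <- list()
  for (h in c("L", "R")) {
    xr <- if (h == "L") c(-x_outer, -x_inner) else c(x_inner, x_outer)
    out[[paste0(h, "_SLF_II_anterior")]] <- waypoint_roi_plane(
      paste0(h, "_SLF_II_anterior"), y_anterior, xr, z_slf2,
      thickness_mm, h, space)
    out[[paste0(h, "_SLF_III_anterior")]] <- waypoint_roi_plane(
      paste0(h, "_SLF_III_anterior"), y_anterior, xr, z_slf3,
      thickness_mm, h, space)
    out[[paste0(h, "_SLF_anterior")]] <- waypoint_roi_plane(
      paste0(h, "_SLF_anterior"), y_anterior, xr,
      range(c(z_slf2, z_slf3)), thickness_mm, h, space)
    out[[paste0(h, "_posterior")]] <- waypoint_roi_plane(
      paste0(h, "_posterior"), y_posterior, xr, z_posterior,
      thickness_mm, h, space)
  }
  out
}

#' Transform waypoint ROIs with an affine
#'
#' Plane ROIs are transformed analytically, which requires the affine to
#' keep coronal planes coronal (no shear or rotation mixing y with x or z);
#' mask ROIs have their stored affine composed with the transform, or are
#' resampled by nearest neighbor when a `target` grid is given.
#'
#' @param rois a `waypoint_roi` or list of them.
#' @param affine invertible 4x4 transform from the ROIs' space to the
#'   target space (world mm to world mm).
#' @param target optional list(shape, affine) describing a target grid for
#'   nearest-neighbor resampling of mask ROIs.
#' @return transformed ROI(s), same structure as the input.
#' @export
transform_rois <- function(rois, affine, target = NULL) {
  if (inherits(rois, "waypoint_roi"))
    return(.transform_roi(rois, affine, target))
  lapply(rois, .transform_roi, affine = affine, target = target)
}

.transform_roi <- function(roi, affine, target = NULL) {
  invert_affine(affine)
  if (roi$geometry == "plane") {
    A <- affine[1:3, 1:3]
    offdiag <- A; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-9))
      stop("roi_transform_error: plane ROIs support only axis-aligned ",
           "(diagonal) affines; rasterize to a mask first", call. = FALSE)
    t3 <- affine[1:3, 4L]
    roi$y_mm <- A[2L, 2L] * roi$y_mm + t3[2L]
    roi$thickness_mm <- abs(A[2L, 2L]) * roi$thickness_mm
    roi$x_range <- sort(A[1L, 1L] * roi$x_range + t3[1L])
    roi$z_range <- sort(A[3L, 3L] * roi$z_range + t3[3L])
    roi$space <- "native"
    roi
  } else {
    new_affine <- affine %*% roi$affine
    if (is.null(target)) {
      roi$affine <- new_affine
      roi$space <- "native"
      return(roi)
    }
    d <- as.integer(target$shape)
    i0 <- seq_len(prod(d)) - 1L
    vox <- cbind(i0 %% d[1L], (i0 %/% d[1L]) %% d[2L],
                 i0 %/% (d[1L] * d[2L]))
    world <- voxel_to_world(target$affine, vox)
    src <- world_to_voxel(new_affine, world)
    lin <- .voxel_linear_index(src, dim(roi$mask))
    new_mask <- rep(FALSE, prod(d))
    ok <- !is.na(lin)
    new_mask[ok] <- roi$mask[lin[ok]]
    waypoint_roi_mask(roi$name, array(new_mask, dim = d), target$affine,
                      roi$hemisphere, "native")
  }
}

#' Fiber bundle: streamlines of a tractogram assigned to a named tract
#'
#' @param name tract name (e.g. "SLF", "SLF_II", "SLF_III").
#' @param hemisphere "L" or "R".
#' @param tg the source [tractogram()].
#' @param indices integer indices of member streamlines in `tg`.
#' @param scores optional per-member probability scores in [0, 1].
#' @return an object of class `tract_bundle` with per-member `lengths_mm`.
#' @export
tract_bundle <- function(name, hemisphere, tg, indices, scores = NULL) {
  stopifnot(inherits(tg, "tractogram"))
  indices <- as.integer(indices)
  if (!is.null(scores)) {
    stopifnot(length(scores) == length(indices))
    if (length(scores) && (min(scores) < 0 || max(scores) > 1))
      stop("bundle_error: scores must lie in [0, 1]", call. = FALSE)
  }
  lens <- .streamline_lengths(tg$streamlines[indices])
  structure(list(name = name, hemisphere = hemisphere, tractogram = tg,
                 indices = indices, scores = scores, lengths_mm = lens),
            class = "tract_bundle")
}

#' @export
length.tract_bundle <- function(x) length(x$indices)

#' @export
print.tract_bundle <- function(x, ...) {
  cat(sprintf("tract_bundle %s (%s): %d streamlines, mean length %.1f mm\n",
              x$name, x$hemisphere, length(x$indices),
              if (length(x$indices)) mean(x$lengths_mm) else NA))
  invisible(x)
}

#' Extract the member streamlines of a bundle
#' @param bundle a `tract_bundle`.
#' @export
bundle_streamlines <- function(bundle) {
  bundle$tractogram$streamlines[bundle$indices]
}

# Flatten a list of streamlines into one big point matrix + an id vector.
.flatten_streamlines <- function(sls) {
  np <- vapply(sls, nrow, integer(1L))
  list(points = do.call(rbind, sls), id = rep(seq_along(sls), np))
}

#' Assign streamlines to a tract by a waypoint ROI pair
#'
#' A streamline belongs to the tract iff at least one of its points lies in
#' `roi_a` and at least one lies in `roi_b`. Membership is independent of
#' point order and of the order of the two ROIs.
#'
#' @param tg a [tractogram()] in the same space as the ROIs.
#' @param roi_a,roi_b `waypoint_roi` objects.
#' @param name,hemisphere labels for the resulting bundle.
#' @return a [tract_bundle()] (possibly empty, with a warning).
#' @export
assign_by_waypoints <- function(tg, roi_a, roi_b, name = "tract",
                                hemisphere = NA_character_) {
  stopifnot(inherits(tg, "tractogram"))
  if (length(tg) == 0L)
    return(tract_bundle(name, hemisphere, tg, integer(0L)))
  fl <- .flatten_streamlines(tg$streamlines)
  in_a <- roi_contains(roi_a, fl$points)
  in_b <- roi_contains(roi_b, fl$points)
  hit_a <- unique(fl$id[in_a])
  hit_b <- unique(fl$id[in_b])
  members <- sort(intersect(hit_a, hit_b))
  if (length(members) == 0L)
    warning("empty bundle: no streamline intersects both waypoint ROIs (",
            name, ")")
  tract_bundle(name, hemisphere, tg, members)
}

#' Score bundle streamlines against a fiber probability map
#'
#' The score of a streamline is the mean of the trilinearly interpolated
#' probability values over its points; points outside the map contribute 0.
#'
#' @param bundle a [tract_bundle()].
#' @param prob_map 3-D array with values in [0, 1].
#' @param affine 4x4 voxel-to-world matrix of the map.
#' @return numeric vector of per-streamline scores in [0, 1].
#' @export
score_against_probability_map <- function(bundle, prob_map, affine) {
  stopifnot(inherits(bundle, "tract_bundle"))
  if (length(bundle) == 0L) return(numeric(0L))
  rng <- range(prob_map, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 1)
    stop("probability_map_error: values outside [0, 1]", call. = FALSE)
  fl <- .flatten_streamlines(bundle_streamlines(bundle))
  vox <- world_to_voxel(affine, fl$points)
  p <- .trilinear(prob_map, vox)
  p[is.na(p)] <- 0
  as.numeric(rowsum(p, fl$id)) / tabulate(fl$id)
}

#' Clean a bundle by probability score and length outliers
#'
#' Streamlines with a score below the `score_quantile` quantile of the
#' bundle's score distribution are discarded, as are streamlines whose
#' length z-score (relative to the bundle's length distribution) exceeds
#' `length_z_max` in absolute value. The z-score pruning is iterated to a
#' fixpoint (at most `max_rounds` rounds) because removing an extreme
#' length changes the distribution.
#'
#' @param bundle a [tract_bundle()].
#' @param scores per-streamline scores (e.g. from
#'   [score_against_probability_map()]); NULL skips score-based pruning.
#' @param score_quantile quantile below which scores are discarded
#'   (default 0.05).
#' @param length_z_max maximum |z| of streamline length (default 3).
#' @param max_rounds iteration cap for the z-score pruning.
#' @return the cleaned [tract_bundle()] (a subset of the input).
#' @export
clean_bundle <- function(bundle, scores = NULL, score_quantile = 0.05,
                         length_z_max = 3, max_rounds = 5L) {
  stopifnot(inherits(bundle, "tract_bundle"))
  if (length(bundle) == 0L)
    stop("bundle_error: cannot clean an empty bundle", call. = FALSE)
  keep <- rep(TRUE, length(bundle))
  if (!is.null(scores) && score_quantile > 0) {
    thr <- stats::quantile(scores, score_quantile, names = FALSE)
    keep <- scores >= thr
  }
  if (is.finite(length_z_max)) {
    for (round in seq_len(max_rounds)) {
      lens <- bundle$lengths_mm[keep]
      if (length(lens) < 3L) break
      mu <- mean(lens)
      sdv <- stats::sd(lens)
      if (!is.finite(sdv) || sdv == 0) break
      z <- abs(bundle$lengths_mm - mu) / sdv
      new_keep <- keep & z <= length_z_max
      if (identical(new_keep, keep)) break
      keep <- new_keep
    }
  }
  if (!any(keep))
    warning("bundle emptied by cleaning (", bundle$name, ")")
  tract_bundle(bundle$name, bundle$hemisphere, bundle$tractogram,
               bundle$indices[keep],
               if (!is.null(bundle$scores)) bundle$scores[keep])
}

#' Lesion - fiber-tract overlap screen
#'
#' Decides whether a lesion affects a tract by comparing the lesion mask
#' with a fiber probability map: under the default "any" rule the tract is
#' affected iff any lesion voxel has fiber probability above `threshold`;
#' under "majority", iff more than half of the lesion voxels do.
#'
#' @param lesion_mask 3-D logical/0-1 array.
#' @param fiber_prob_map 3-D array in [0, 1], same grid.
#' @param threshold probability cut-off (default 0.5).
#' @param rule "any" (default) or "majority".
#' @return "affected" or "not_affected".
#' @export
lesion_overlap_screen <- function(lesion_mask, fiber_prob_map,
                                  threshold = 0.5,
                                  rule = c("any", "majority")) {
  rule <- match.arg(rule)
  stopifnot(all(dim(lesion_mask) == dim(fiber_prob_map)))
  idx <- which(lesion_mask != 0)
  if (length(idx) == 0L) {
    warning("empty lesion mask; returning not_affected")
    return("not_affected")
  }
  hits <- fiber_prob_map[idx] > threshold
  affected <- if (rule == "any") any(hits) else mean(hits) > 0.5
  if (affected) "affected" else "not_affected"
}
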