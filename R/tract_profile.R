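#' Resample a streamline to equally spaced nodes
#'
#' Places `n_nodes` points at arc-length positions `k * L / (n_nodes - 1)`,
#' `k = 0 .. n_nodes - 1`, by piecewise-linear interpolation along the
#' polyline. The first and last points are preserved exactly.
#'
#' @param points n x 3 streamline point matrix (world mm).
#' @param n_nodes number of output nodes (default 100).
#' @return an `n_nodes` x 3 point matrix.
#' @export
resample_streamline <- function(points, n_nodes = 100L) {
  points <- as.matrix(points)
  if (nrow(points) < 2L)
    stop("streamline_error: cannot resample a single-point streamline",
         call. = FALSE)
  seg <- sqrt(rowSums(diff(points)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L <= 0)
    stop("streamline_error: zero-length streamline", call. = FALSE)
  target <- seq(0, L, length.out = n_nodes)
  out <- .lininterp3(s, points, target)
  out[1L, ] <- points[1L, ]
  out[n_nodes, ] <- points[nrow(points), ]
  out
}

# piecewise-linear interpolation of an n x 3 polyline at arc positions xq
.lininterp3 <- function(s, points, xq) {
  j <- findInterval(xq, s, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1L), length(s) - 1L)
  f <- (xq - s[j]) / (s[j + 1L] - s[j])
  points[j, , drop = FALSE] * (1 - f) +
    points[j + 1L, , drop = FALSE] * f
}

# Resample every streamline of a list to n_nodes equally spaced points;
# returns an (m * n_nodes) x 3 matrix, streamline-major. Vectorized by
# concatenating arc lengths with per-streamline offsets.
.resample_many <- function(sls, n_nodes) {
  m <- length(sls)
  np <- vapply(sls, nrow, integer(1L))
  pts <- do.call(rbind, sls)
  id <- rep.int(seq_len(m), np)
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
  first_of <- cumsum(c(1L, np[-m]))
  seg[first_of[-1L] - 1L] <- 0            # break between streamlines
  s <- cumsum(c(0, seg))
  L <- s[cumsum(np)] - s[first_of]
  if (any(L <= 0))
    stop("streamline_error: zero-length streamline", call. = FALSE)
  # strictly separate the global arc coordinate of distinct streamlines
  gap <- cumsum(c(0, rep(1, m - 1L)))
  s <- s + gap[id]
  s0 <- s[first_of]
  xq <- rep(s0, each = n_nodes) +
    as.vector(vapply(L, function(l) seq(0, l, length.out = n_nodes),
                     numeric(n_nodes)))
  out <- .lininterp3(s, pts, xq)
  # endpoints exactly preserved
  ends <- cumsum(np)
  out[seq(1L, m * n_nodes, by = n_nodes), ] <-
    pts[first_of, , drop = FALSE]
  out[seq(n_nodes, m * n_nodes, by = n_nodes), ] <-
    pts[ends, , drop = FALSE]
  out
}

#' Give all streamlines of a bundle a consistent point order
#'
#' Streamlines are ordered anterior to posterior (decreasing world y,
#' comparing the two endpoints). When the endpoint y coordinates tie,
#' the endpoint closer to `anterior_point` (e.g. the anterior waypoint ROI
#' centroid) is put first.
#'
#' @param bundle a [tract_bundle()].
#' @param anterior_point optional length-3 world-mm tie-break reference.
#' @return the bundle with member streamlines consistently oriented.
#' @export
orient_bundle <- function(bundle, anterior_point = NULL) {
  stopifnot(inherits(bundle, "tract_bundle"))
  tg <- bundle$tractogram
  for (i in bundle$indices) {
    s <- tg$streamlines[[i]]
    y_first <- s[1L, 2L]
    y_last <- s[nrow(s), 2L]
    flip <- if (y_first != y_last) {
      y_first < y_last
    } else if (!is.null(anterior_point)) {
      sum((s[1L, ] - anterior_point)^2) > sum((s[nrow(s), ] - anterior_point)^2)
    } else FALSE
    if (flip) tg$streamlines[[i]] <- s[rev(seq_len(nrow(s))), , drop = FALSE]
  }
  tract_bundle(bundle$name, bundle$hemisphere, tg, bundle$indices,
               bundle$scores)
}

#' Tract profile: per-node diffusion metrics along a bundle
#'
#' Every member streamline is resampled to `n_nodes` equally spaced points;
#' at each node, FA, MD, AD and RD are sampled from the scalar maps by
#' trilinear interpolation at each streamline's node point and averaged
#' across streamlines. With `weighting = "gaussian_distance"`, streamline
#' contributions at a node are weighted by `exp(-d^2 / (2 sigma^2))`, where
#' `d` is the distance to the node's cross-streamline mean position and
#' `sigma` the node's point-cloud standard deviation, down-weighting
#' spatial stragglers.
#'
#' @param bundle an oriented, cleaned [tract_bundle()] (see
#'   [orient_bundle()]).
#' @param maps a `scalar_maps` object in the same space.
#' @param n_nodes number of nodes (default 100).
#' @param weighting "uniform" (default) or "gaussian_distance".
#' @param subject_id,group labels stored on the profile.
#' @return an object of class `tract_profile` with `n_nodes` x 4 matrices
#'   `mean` and `se` (columns fa, md, ad, rd), a per-node `support` count,
#'   and the identifying labels.
#' @export
compute_tract_profile <- function(bundle, maps, n_nodes = 100L,
                                  weighting = c("uniform",
                                                "gaussian_distance"),
                                  subject_id = NA_character_,
                                  group = NA_character_) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(bundle, "tract_bundle"), inherits(maps, "scalar_maps"))
  m <- length(bundle)
  if (m == 0L)
    stop("bundle_error: cannot profile an empty bundle", call. = FALSE)
  pts <- .resample_many(bundle_streamlines(bundle), n_nodes)
  node <- rep(seq_len(n_nodes), times = m)
  vox <- world_to_voxel(maps$affine, pts)

  w <- rep(1, nrow(pts))
  if (weighting == "gaussian_distance" && m > 1L) {
    cx <- rowsum(pts, node) / m                 # node-wise mean position
    dvec <- pts - cx[node, , drop = FALSE]
    d2 <- rowSums(dvec^2)
    sig2 <- as.numeric(rowsum(d2, node)) / m    # node point-cloud variance
    sig2_safe <- ifelse(sig2 > 0, sig2, 1)
    w <- ifelse(sig2[node] > 0, exp(-d2 / (2 * sig2_safe[node])), 1)
  }

  tw <- .trilinear_weights(dim(maps$fa), vox)
  vals <- cbind(fa = .trilinear_apply(maps$fa, tw),
                md = .trilinear_apply(maps$md, tw),
                ad = .trilinear_apply(maps$ad, tw),
                rd = .trilinear_apply(maps$rd, tw))
  mean_mat <- matrix(NA_real_, n_nodes, 4L,
                     dimnames = list(NULL, colnames(vals)))
  se_mat <- mean_mat
  support <- integer(n_nodes)
  for (j in seq_len(4L)) {
    v <- vals[, j]
    ok <- is.finite(v)
    wj <- w * ok
    sw <- as.numeric(rowsum(wj, node))
    sv <- as.numeric(rowsum(ifelse(ok, wj * v, 0), node))
    mu <- ifelse(sw > 0, sv / sw, NA_real_)
    dev2 <- ifelse(ok, wj * (v - mu[node])^2, 0)
    varw <- ifelse(sw > 0, as.numeric(rowsum(dev2, node)) / sw, NA_real_)
    cnt <- as.numeric(rowsum(as.numeric(ok), node))
    mean_mat[, j] <- mu
    se_mat[, j] <- sqrt(varw) / sqrt(pmax(cnt, 1))
    if (j == 1L) support <- as.integer(cnt)
  }
  if (any(support == 0L))
    warning("node(s) with zero finite samples in tract profile")
  structure(list(subject_id = subject_id, group = group,
                 tract = bundle$name, hemisphere = bundle$hemisphere,
                 n_nodes = as.integer(n_nodes), mean = mean_mat,
                 se = se_mat, support = support, n_streamlines = m),
            class = "tract_profile")
}

#' @export
print.tract_profile <- function(x, ...) {
  cat(sprintf("tract_profile %s (%s) subject %s [%s]: %d nodes, %d streamlines\n",
              x$tract, x$hemisphere, x$subject_id, x$group, x$n_nodes,
              x$n_streamlines))
  invisible(x)
}

#' Convert tract profiles to the long-format profile table
#'
#' @param profiles a `tract_profile` or list of them.
#' @return data frame in the [profile_schema] layout.
#' @export
profiles_to_df <- function(profiles) {
  if (inherits(profiles, "tract_profile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(subject_id = p$subject_id, group = p$group, tract = p$tract,
               hemisphere = p$hemisphere, node = seq_len(p$n_nodes),
               fa = p$mean[, "fa"], md = p$mean[, "md"],
               ad = p$mean[, "ad"], rd = p$mean[, "rd"],
               stringsAsFactors = FALSE)
  }))
}
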