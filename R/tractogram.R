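#' Validate a streamline point matrix
#'
#' A streamline is an ordered sequence of 3-D world coordinates (mm), stored
#' as an n x 3 numeric matrix with at least 2 rows, finite coordinates and
#' no repeated consecutive points.
#'
#' @param points n x 3 numeric matrix.
#' @return the matrix, invisibly, after validation.
#' @export
as_streamline <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 2L)
    stop("streamline_error: need an n x 3 matrix with n >= 2", call. = FALSE)
  if (any(!is.finite(points)))
    stop("streamline_error: non-finite coordinates", call. = FALSE)
  d <- diff(points)
  if (any(rowSums(d^2) == 0))
    stop("streamline_error: repeated consecutive points", call. = FALSE)
  points
}

#' Arc length of a streamline in mm
#' @param points n x 3 matrix of world coordinates.
#' @export
streamline_length <- function(points) {
  sum(sqrt(rowSums(diff(points)^2)))
}

# Arc lengths of a list of streamlines, vectorized over the whole set.
.streamline_lengths <- function(sls) {
  if (length(sls) == 0L) return(numeric(0L))
  np <- vapply(sls, nrow, integer(1L))
  pts <- do.call(rbind, sls)
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
  first_of <- cumsum(c(1L, np[-length(np)]))
  seg[first_of[-1L] - 1L] <- 0
  as.numeric(rowsum(c(0, seg), rep.int(seq_along(sls), np)))
}

#' Tractogram: a set of streamlines tied to a reference grid
#'
#' @param streamlines list of n x 3 world-mm point matrices.
#' @param reference_affine 4x4 voxel-to-world matrix of the reference grid.
#' @param reference_shape integer 3-vector, spatial grid dimensions.
#' @param validate check every streamline and the bounding-box invariant
#'   (all points inside the reference grid expanded by one voxel).
#' @return an object of class `tractogram`.
#' @export
tractogram <- function(streamlines, reference_affine, reference_shape,
                       validate = TRUE) {
  stopifnot(is.list(streamlines), length(reference_shape) == 3L)
  reference_shape <- as.integer(reference_shape)
  if (validate && length(streamlines) > 0L) {
    streamlines <- lapply(streamlines, as_streamline)
    pts <- do.call(rbind, streamlines)
    vox <- world_to_voxel(reference_affine, pts)
    lo <- -1; hi <- reference_shape  # centers 0..dim-1, expanded one voxel
    if (any(vox < rep(lo, each = nrow(vox))) ||
        any(sweep(vox, 2L, hi, ">")))
      stop("tractogram_error: streamline points outside the reference grid",
           call. = FALSE)
  }
  structure(list(streamlines = streamlines,
                 reference_affine = reference_affine,
                 reference_shape = reference_shape),
            class = "tractogram")
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' @export
print.tractogram <- function(x, ...) {
  n <- length(x$streamlines)
  cat(sprintf("tractogram: %d streamlines on a %s grid\n", n,
              paste(x$reference_shape, collapse = " x ")))
  invisible(x)
}

# --- TrackVis .trk format (version 2) -------------------------------------
#
# Streamline coordinates are stored in the conventional trk "voxmm" frame:
# (voxel_index + 0.5) * voxel_size, where voxel_index is the fractional
# 0-based index obtained from world mm via the inverse of the vox_to_ras
# header matrix. Points are 32-bit floats, so round trips are exact to about
# 1e-4 mm at brain-scale coordinates.

#' Save a tractogram as a TrackVis .trk file
#'
#' @param tg a [tractogram()].
#' @param path output path.
#' @export
save_tractogram <- function(tg, path) {
  stopifnot(inherits(tg, "tractogram"))
  vs <- sqrt(colSums(tg$reference_affine[1:3, 1:3]^2))
  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(s, n) {
    raw_s <- charToRaw(s)
    writeBin(c(raw_s, raw(n - length(raw_s))), con)
  }
  wchar("TRACK", 6L)
  writeBin(as.integer(tg$reference_shape), con, size = 2L, endian = "little")
  writeBin(as.numeric(vs), con, size = 4L, endian = "little")
  writeBin(numeric(3L), con, size = 4L, endian = "little")      # origin
  writeBin(0L, con, size = 2L, endian = "little")               # n_scalars
  wchar("", 200L)
  writeBin(0L, con, size = 2L, endian = "little")               # n_properties
  wchar("", 200L)
  writeBin(as.numeric(t(tg$reference_affine)), con, size = 4L,
           endian = "little")                                   # vox_to_ras
  wchar("", 444L)
  wchar("RAS", 4L)                                              # voxel_order
  wchar("", 4L)
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4L, endian = "little")
  wchar("", 2L)
  writeBin(as.raw(rep(0L, 6L)), con)
  writeBin(length(tg$streamlines), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")               # version
  writeBin(1000L, con, size = 4L, endian = "little")            # hdr_size
  inv <- invert_affine(tg$reference_affine)
  for (s in tg$streamlines) {
    vox <- apply_affine(inv, s)
    voxmm <- sweep(sweep(vox, 2L, 0.5, "+"), 2L, vs, "*")
    writeBin(nrow(s), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Load a TrackVis .trk file
#'
#' @param path .trk file written by [save_tractogram()] or a compatible tool
#'   (version 2 headers with a valid vox_to_ras matrix).
#' @return a [tractogram()].
#' @export
load_tractogram <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 6L)[1:5])
  if (!identical(magic, "TRACK"))
    stop("trk_parse_error: not a TrackVis .trk file", call. = FALSE)
  dim3 <- readBin(con, "integer", 3L, size = 2L, endian = "little")
  vs <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  readBin(con, "numeric", 3L, size = 4L, endian = "little")      # origin
  n_scalars <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  n_props <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  aff <- matrix(readBin(con, "numeric", 16L, size = 4L, endian = "little"),
                4L, 4L, byrow = TRUE)
  readBin(con, "raw", 444L + 4L + 4L)
  readBin(con, "numeric", 6L, size = 4L, endian = "little")
  readBin(con, "raw", 2L + 6L)
  n_count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(hdr_size, 1000L))
    stop("trk_parse_error: bad header size ", hdr_size, call. = FALSE)
  if (abs(det(aff)) < 1e-12)
    stop("trk_parse_error: header vox_to_ras matrix is singular",
         call. = FALSE)
  streamlines <- vector("list", max(n_count, 0L))
  i <- 0L
  repeat {
    np <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(np) == 0L) break
    vals <- readBin(con, "numeric", np * (3L + n_scalars), size = 4L,
                    endian = "little")
    if (n_props > 0L) readBin(con, "numeric", n_props, size = 4L,
                              endian = "little")
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(sweep(m, 2L, vs, "/"), 2L, 0.5, "-")
    i <- i + 1L
    streamlines[[i]] <- apply_affine(aff, vox)
  }
  if (i != n_count)
    warning("trk stream count (", i, ") differs from header n_count (",
            n_count, ")")
  tractogram(streamlines[seq_len(i)], aff, dim3, validate = FALSE)
}
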