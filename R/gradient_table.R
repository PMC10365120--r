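#' Diffusion gradient table
#'
#' Bundles the diffusion sensitization scheme of an acquisition: one b-value
#' (s/mm^2) and one unit direction vector per frame. Frames with
#' `bval <= b0_threshold` are treated as unweighted (b = 0) frames; their
#' direction vector is irrelevant and may be the zero vector. Direction
#' vectors of diffusion-weighted frames are re-normalized to unit length.
#'
#' @param bvals numeric vector of b-values (s/mm^2).
#' @param bvecs numeric matrix, one 3-vector per row (or 3 x n, autodetected).
#' @param b0_threshold b-values at or below this count as b = 0 (default 50).
#' @return an object of class `gradient_table` with elements `bvals`,
#'   `bvecs` (n x 3, unit rows for weighted frames), `b0_threshold`.
#' @export
gradient_table <- function(bvals, bvecs, b0_threshold = 50) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L && nrow(bvecs) == 3L) bvecs <- t(bvecs)
  if (ncol(bvecs) != 3L)
    stop("gradient_error: bvecs must be n x 3 or 3 x n", call. = FALSE)
  if (length(bvals) != nrow(bvecs))
    stop("gradient_error: bvals and bvecs disagree on frame count",
         call. = FALSE)
  if (any(!is.finite(bvals)) || any(bvals < 0))
    stop("gradient_error: b-values must be finite and non-negative",
         call. = FALSE)
  dwi <- bvals > b0_threshold
  if (!any(!dwi))
    stop("gradient_error: at least one b = 0 frame is required", call. = FALSE)
  if (!any(dwi))
    stop("gradient_error: at least one diffusion-weighted frame is required",
         call. = FALSE)
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(dwi & nrm < 1e-8))
    stop("gradient_error: zero direction vector on a weighted frame",
         call. = FALSE)
  bvecs[dwi, ] <- bvecs[dwi, , drop = FALSE] / nrm[dwi]
  structure(list(bvals = bvals, bvecs = bvecs, b0_threshold = b0_threshold),
            class = "gradient_table")
}

#' Logical mask of the unweighted (b = 0) frames of a gradient table
#' @param gtab a `gradient_table`.
#' @export
is_b0 <- function(gtab) {
  stopifnot(inherits(gtab, "gradient_table"))
  gtab$bvals <= gtab$b0_threshold
}

#' @export
length.gradient_table <- function(x) length(x$bvals)

#' @export
print.gradient_table <- function(x, ...) {
  cat(sprintf("gradient_table: %d frames (%d b0, %d weighted), b up to %g s/mm^2\n",
              length(x$bvals), sum(is_b0(x)), sum(!is_b0(x)), max(x$bvals)))
  invisible(x)
}

#' Write a gradient table as FSL-style .bval/.bvec text files
#'
#' The FSL layout is one space-separated row of b-values and three rows of
#' direction components (x, y, z), one column per frame.
#'
#' @param gtab a `gradient_table`.
#' @param bval_path,bvec_path output paths.
#' @export
save_gradients <- function(gtab, bval_path, bvec_path) {
  stopifnot(inherits(gtab, "gradient_table"))
  writeLines(paste(format(gtab$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  vec_lines <- apply(t(gtab$bvecs), 1L, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " "))
  writeLines(vec_lines, bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Read FSL-style .bval/.bvec text files
#'
#' Both the FSL row layout (3 rows x n frames) and its transpose are
#' accepted; the orientation is autodetected from the shape.
#'
#' @param bval_path,bvec_path input paths.
#' @param b0_threshold passed to [gradient_table()].
#' @return a `gradient_table`.
#' @export
load_gradients <- function(bval_path, bvec_path, b0_threshold = 50) {
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- lapply(readLines(bvec_path), function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1L]]))
    v[!is.na(v)]
  })
  rows <- rows[lengths(rows) > 0L]
  n <- unique(lengths(rows))
  if (length(n) != 1L)
    stop("gradient_error: ragged bvec file", call. = FALSE)
  m <- do.call(rbind, rows)
  # FSL layout: 3 rows x n frames. Accept the transpose too.
  if (nrow(m) == 3L && ncol(m) != 3L) m <- t(m)
  if (nrow(m) == 3L && ncol(m) == 3L) m <- t(m)  # fix ambiguity: FSL wins
  gradient_table(bvals, m, b0_threshold = b0_threshold)
}
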