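# Spot calling -----------------------------------------------------------------
#
# The fitted density images are demixed and deconvolved, so rolony detection
# reduces to finding local maxima in each per-barcode image. The detection
# threshold is calibrated from the density images of the unused barcodes: any
# blob there must be noise, so the threshold is the smallest value that would
# exclude every one of them.

#' Local maxima of a density image
#'
#' A voxel is a local maximum if its value is positive and no voxel in the
#' surrounding `(2 * footprint_radius + 1)`-per-side box exceeds it. On a
#' plateau of tied values within one footprint, only the lexicographically
#' smallest coordinate is returned.
#'
#' @param img Non-negative spatial array (2-D or 3-D), or a density column
#'   with `shape` supplied.
#' @param footprint_radius Neighborhood half-width in voxels (default 1).
#' @param shape Spatial extents when `img` is a bare vector.
#' @return A tibble with 0-based coordinate columns, `voxel` (0-based
#'   row-major index) and `value`, ordered by voxel.
#' @export
find_local_maxima <- function(img, footprint_radius = 1L, shape = NULL) {
  if (is.null(dim(img))) {
    stopifnot(!is.null(shape))
    img <- unflatten_spatial(img, shape)
  }
  shape <- dim(img)
  d <- length(shape)
  stopifnot(all(img >= 0), footprint_radius >= 1L)
  # neighborhood max by iterated dilation along each dimension
  dil <- img
  for (k in seq_len(d)) dil <- dilate_dim(dil, k, footprint_radius)
  cand <- which(img > 0 & img >= dil)
  if (length(cand) == 0L) {
    return(tibble::tibble(!!!empty_coord_cols(d), voxel = integer(), value = numeric()))
  }
  coords1 <- arrayInd(cand, shape)               # 1-based array coords
  vals <- img[cand]
  keep <- rep(TRUE, length(cand))
  # plateau ties: drop a candidate if an equal-valued candidate within the
  # footprint has a lexicographically smaller coordinate
  if (length(cand) > 1L) {
    ord <- do.call(order, as.data.frame(coords1))
    for (ii in seq_along(cand)) {
      i <- ord[ii]
      if (!keep[i]) next
      for (jj in seq_along(cand)) {
        j <- ord[jj]
        if (jj <= ii || !keep[j]) next
        if (vals[i] == vals[j] &&
            all(abs(coords1[i, ] - coords1[j, ]) <= footprint_radius)) {
          keep[j] <- FALSE
        }
      }
    }
  }
  coords0 <- coords1[keep, , drop = FALSE] - 1L
  colnames(coords0) <- spatial_axis_names(d)
  out <- tibble::as_tibble(coords0)
  out$voxel <- coords_to_voxel(coords0, shape)
  out$value <- vals[keep]
  dplyr::arrange(out, .data$voxel)
}

empty_coord_cols <- function(d) {
  stats::setNames(rep(list(integer()), d), spatial_axis_names(d))
}

# running max along dimension k with window radius w (replicate-pad edges)
dilate_dim <- function(arr, k, w) {
  out <- arr
  n <- dim(arr)[k]
  for (off in c(-(w:1), 1:w)) {
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- pmax(out, slice_index(arr, k, idx))
  }
  out
}

slice_index <- function(arr, k, idx) {
  d <- length(dim(arr))
  args <- rep(list(quote(expr = )), d)
  args[[k]] <- idx
  do.call(`[`, c(list(arr), args, list(drop = FALSE)))
}

#' Spot-calling threshold from unused barcodes
#'
#' Returns the smallest threshold that excludes (under a strict `>` test)
#' every local maximum found in the density images of the unused barcodes:
#' the largest such maximum plus one unit in the last place, or 0 when the
#' unused densities contain no blob at all.
#'
#' @param F `M x J` density matrix (e.g. `fit$params$F`).
#' @param cb A `codebook` with at least one unused barcode.
#' @param spatial_shape Spatial extents of the grid.
#' @param footprint_radius Local-maximum footprint (default 1).
#' @return A non-negative scalar threshold.
#' @export
threshold_from_unused <- function(F, cb, spatial_shape, footprint_radius = 1L) {
  stopifnot(inherits(cb, "codebook"))
  if (!any(cb$unused)) {
    stop("codebook has no unused barcodes; run augment_codebook() or supply a manual threshold",
         call. = FALSE)
  }
  peak <- 0
  for (j in which(cb$unused)) {
    lm <- find_local_maxima(F[, j], footprint_radius, shape = spatial_shape)
    if (nrow(lm) > 0L) peak <- max(peak, max(lm$value))
  }
  if (peak == 0) 0 else peak * (1 + .Machine$double.eps)
}

#' Call spots from fitted density images
#'
#' Finds local maxima in each non-unused barcode's density image and flags
#' those whose density strictly exceeds the threshold.
#'
#' @param F `M x J` density matrix, or a `density_fit` (then the remaining
#'   arguments default from the fit).
#' @param cb A `codebook`.
#' @param spatial_shape Spatial extents.
#' @param threshold Detection threshold; `NULL` (default) derives it from the
#'   unused barcodes via [threshold_from_unused()].
#' @param footprint_radius Local-maximum footprint (default 1).
#' @param blur Optional: call spots on the blurred densities `K * F` instead
#'   of `F` (visualization-style smoothing; default `FALSE`).
#' @param psf `psf` used when `blur = TRUE`.
#' @return A `spot_table` tibble with columns `gene`, `barcode_index`
#'   (0-based), one 0-based coordinate column per spatial dimension, `voxel`,
#'   `density` and `passes_threshold`, ordered by (barcode, voxel).
#' @export
call_spots <- function(F, cb = NULL, spatial_shape = NULL, threshold = NULL,
                       footprint_radius = 1L, blur = FALSE, psf = NULL) {
  if (inherits(F, "density_fit")) {
    fit <- F
    cb <- cb %||% fit$codebook
    spatial_shape <- spatial_shape %||% fit$spatial_shape
    psf <- psf %||% fit$psf
    F <- fit$params$F
  }
  stopifnot(inherits(cb, "codebook"), !is.null(spatial_shape))
  if (blur) {
    stopifnot(!is.null(psf))
    F <- convolve_density(F, spatial_shape, psf_operators(psf, spatial_shape))
  }
  if (is.null(threshold)) {
    threshold <- threshold_from_unused(F, cb, spatial_shape, footprint_radius)
  }
  d <- length(spatial_shape)
  rows <- lapply(which(!cb$unused), function(j) {
    lm <- find_local_maxima(F[, j], footprint_radius, shape = spatial_shape)
    if (nrow(lm) == 0L) return(NULL)
    dplyr::mutate(lm, gene = cb$gene_names[j], barcode_index = j - 1L,
                  .before = 1L)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(gene = character(), barcode_index = integer(),
                          !!!empty_coord_cols(d), voxel = integer(),
                          value = numeric())
  }
  out <- dplyr::rename(out, density = "value")
  out$passes_threshold <- out$density > threshold
  out <- dplyr::arrange(out, .data$barcode_index, .data$voxel)
  attr(out, "threshold") <- threshold
  class(out) <- c("spot_table", class(out))
  out
}
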