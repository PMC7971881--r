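# Image stacks ----------------------------------------------------------------
#
# An image stack holds the observed (or reconstructed) intensities of a
# multi-round, multi-channel experiment. Internally the data live in an
# M x (R*C) matrix: one row per voxel (row-major order over the spatial grid,
# 0-based when exposed), one column per (round, channel) frame with column
# index (r-1)*C + c. This layout makes the forward model and its gradients
# plain matrix algebra.

#' Construct an image stack
#'
#' @param data Either an array indexed `[round, channel, spatial...]`
#'   (3- or 4-D spatial part collapsed, i.e. total rank `2 + d`), or an
#'   `M x (R*C)` matrix (then `R`, `C` and `spatial_shape` are required).
#' @param R,C Number of imaging rounds / channels (required for matrix input).
#' @param spatial_shape Integer vector of 2 or 3 spatial extents whose product
#'   is the number of voxels `M` (required for matrix input).
#'
#' @details All intensities must be finite and non-negative. Voxels are
#' indexed row-major (last spatial dimension fastest), 0-based in every
#' user-facing table.
#'
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, R = NULL, C = NULL, spatial_shape = NULL) {
  if (is.array(data) && length(dim(data)) >= 4L) {
    d <- dim(data)
    R <- d[1L]; C <- d[2L]
    spatial_shape <- d[-(1:2)]
    M <- prod(spatial_shape)
    mat <- matrix(0, M, R * C)
    for (r in seq_len(R)) {
      for (cc in seq_len(C)) {
        frame <- array(data[r, cc, ], dim = spatial_shape)
        mat[, rc_index(r, cc, C)] <- flatten_spatial(frame)
      }
    }
  } else if (is.matrix(data)) {
    if (is.null(R) || is.null(C) || is.null(spatial_shape)) {
      stop("matrix input requires R, C and spatial_shape", call. = FALSE)
    }
    if (nrow(data) != prod(spatial_shape) || ncol(data) != R * C) {
      stop("matrix dimensions do not match R, C and spatial_shape", call. = FALSE)
    }
    mat <- data
  } else {
    stop("data must be an array [round, channel, spatial...] or an M x (R*C) matrix",
         call. = FALSE)
  }
  if (length(spatial_shape) < 2L || length(spatial_shape) > 3L) {
    stop("spatial_shape must have 2 or 3 dimensions", call. = FALSE)
  }
  if (any(!is.finite(mat))) stop("image stack contains non-finite values", call. = FALSE)
  if (any(mat < 0)) stop("image stack contains negative values", call. = FALSE)
  structure(
    list(data = mat, R = as.integer(R), C = as.integer(C),
         spatial_shape = as.integer(spatial_shape)),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %d rounds x %d channels, spatial %s (%d voxels)\n",
              x$R, x$C, paste(x$spatial_shape, collapse = " x "),
              prod(x$spatial_shape)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) c(x$R, x$C, x$spatial_shape)

n_voxels <- function(x) as.integer(prod(x$spatial_shape))

rc_index <- function(r, cc, C) (r - 1L) * C + cc

# row-major flatten of a per-(r,c) vector: b[r,c] -> index (r-1)*C + c
rc_vec <- function(m) as.vector(t(m))
rc_unvec <- function(v, R, C) matrix(v, R, C, byrow = TRUE)

# spatial array <-> row-major voxel vector
flatten_spatial <- function(arr) {
  d <- length(dim(arr))
  as.vector(aperm(arr, d:1))
}
unflatten_spatial <- function(vec, shape) {
  d <- length(shape)
  aperm(array(vec, dim = rev(shape)), d:1)
}

#' Convert between voxel indices and grid coordinates
#'
#' Voxel indices are 0-based and row-major (the last spatial dimension moves
#' fastest), matching every table the package emits.
#'
#' @param m Integer vector of 0-based voxel indices.
#' @param coords Integer matrix of 0-based coordinates, one row per voxel.
#' @param shape Spatial extents of the grid.
#' @return `voxel_to_coords()`: a matrix of 0-based coordinates;
#'   `coords_to_voxel()`: a vector of 0-based indices.
#' @export
voxel_to_coords <- function(m, shape) {
  d <- length(shape)
  out <- matrix(0L, length(m), d)
  rem <- as.integer(m)
  for (k in d:1) {
    out[, k] <- rem %% shape[k]
    rem <- rem %/% shape[k]
  }
  out
}
#' @rdname voxel_to_coords
#' @export
coords_to_voxel <- function(coords, shape) {
  coords <- matrix(as.integer(coords), ncol = length(shape))
  m <- integer(nrow(coords))
  for (k in seq_along(shape)) m <- m * shape[k] + coords[, k]
  m
}

#' Extract one (round, channel) frame as a spatial array
#'
#' @param x An `image_stack`.
#' @param r,c 1-based round and channel indices.
#' @return A numeric array with dimensions `spatial_shape(x)`.
#' @export
stack_frame <- function(x, r, c) {
  stopifnot(inherits(x, "image_stack"))
  unflatten_spatial(x$data[, rc_index(r, c, x$C)], x$spatial_shape)
}

#' Convert an image stack to a tidy tibble
#'
#' One row per (round, channel, voxel) with 0-based coordinates.
#'
#' @param x An `image_stack`.
#' @param ... Unused.
#' @return A tibble with columns `round`, `channel` (0-based), one coordinate
#'   column per spatial dimension, and `value`.
#' @method tidy image_stack
#' @export
tidy.image_stack <- function(x, ...) {
  shape <- x$spatial_shape
  M <- prod(shape)
  coords <- voxel_to_coords(0:(M - 1L), shape)
  colnames(coords) <- spatial_axis_names(length(shape))
  frames <- expand.grid(channel = seq_len(x$C) - 1L, round = seq_len(x$R) - 1L)
  out <- tibble::tibble(
    round = rep(frames$round, each = M),
    channel = rep(frames$channel, each = M)
  )
  # columns of x$data are ordered (r-1)*C + c which matches expand.grid order
  out <- dplyr::bind_cols(
    out,
    tibble::as_tibble(coords[rep(seq_len(M), nrow(frames)), , drop = FALSE])
  )
  out$value <- as.vector(x$data)
  out
}

spatial_axis_names <- function(d) {
  if (d == 2L) c("y", "x") else c("z", "y", "x")
}

#' Maximum projection of a stack over rounds and channels
#'
#' @param x An `image_stack`.
#' @return A spatial array of per-voxel maxima.
#' @export
max_projection <- function(x) {
  stopifnot(inherits(x, "image_stack"))
  unflatten_spatial(apply(x$data, 1L, max), x$spatial_shape)
}
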