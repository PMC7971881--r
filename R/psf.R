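# Point-spread function --------------------------------------------------------
#
# The optics smear a point source into a blob; we model that blur as a
# separable, truncated, sum-normalized Gaussian kernel applied with reflective
# boundary handling. Sum-normalization pins down the otherwise arbitrary
# F-versus-K scale. The kernel is applied through small per-dimension dense
# convolution matrices, which also makes the exact adjoint (the transpose)
# available to the optimizer.

#' Gaussian point-spread function
#'
#' @param sigma Gaussian width in voxels; a scalar (recycled over spatial
#'   dimensions) or one value per spatial dimension. `sigma = 0` gives the
#'   identity kernel (no blur).
#' @param truncation_radius Kernel support half-width in units of sigma
#'   (default 4).
#' @return An object of class `psf`.
#' @export
psf_gaussian <- function(sigma = 1.5, truncation_radius = 4) {
  stopifnot(all(sigma >= 0), truncation_radius > 0)
  structure(list(sigma = as.numeric(sigma),
                 truncation_radius = as.numeric(truncation_radius)),
            class = "psf")
}

#' @export
print.psf <- function(x, ...) {
  cat(sprintf("<psf> Gaussian, sigma = %s voxels, truncated at %g sigma\n",
              paste(signif(x$sigma, 4), collapse = " x "), x$truncation_radius))
  invisible(x)
}

psf_sigmas <- function(psf, d) {
  s <- psf$sigma
  if (length(s) == 1L) rep(s, d) else {
    stopifnot(length(s) == d)
    s
  }
}

# 1-D truncated, sum-normalized Gaussian taps
gaussian_taps <- function(sigma, truncation_radius) {
  if (sigma == 0) return(1)
  rad <- ceiling(truncation_radius * sigma)
  w <- exp(-((-rad):rad)^2 / (2 * sigma^2))
  w / sum(w)
}

# dense n x n convolution matrix with reflective ("symmetric") boundaries
conv_matrix_1d <- function(n, taps) {
  rad <- (length(taps) - 1L) %/% 2L
  Cm <- matrix(0, n, n)
  for (k in seq_along(taps)) {
    off <- k - rad - 1L
    for (i in seq_len(n)) {
      j <- reflect_index(i + off, n)
      Cm[i, j] <- Cm[i, j] + taps[k]
    }
  }
  Cm
}

# whole-sample reflection: ... 3 2 1 | 1 2 3 ... n | n n-1 ...
reflect_index <- function(i, n) {
  period <- 2L * n
  i <- ((i - 1L) %% period) + 1L
  ifelse(i > n, period - i + 1L, i)
}

# per-dimension convolution matrices for a grid
psf_operators <- function(psf, shape) {
  d <- length(shape)
  sig <- psf_sigmas(psf, d)
  lapply(seq_len(d), function(k) {
    conv_matrix_1d(shape[k], gaussian_taps(sig[k], psf$truncation_radius))
  })
}

# apply a matrix along dimension k of an array
apply_along_dim <- function(arr, k, Mk) {
  d <- length(dim(arr))
  if (d == 2L) {
    if (k == 1L) return(Mk %*% arr)
    return(arr %*% t(Mk))
  }
  perm <- c(k, setdiff(seq_len(d), k))
  tmp <- aperm(arr, perm)
  dims <- dim(tmp)
  tmp <- Mk %*% matrix(tmp, dims[1L], prod(dims[-1L]))
  dim(tmp) <- dims
  aperm(tmp, order(perm))
}

# blur one spatial array
convolve_spatial <- function(arr, ops, transpose = FALSE) {
  for (k in seq_along(ops)) {
    Mk <- if (transpose) t(ops[[k]]) else ops[[k]]
    arr <- apply_along_dim(arr, k, Mk)
  }
  arr
}

# blur every column of a density matrix (M x J, rows row-major voxels).
# Row-major voxel order means array(Fmat, c(rev(shape), J)) indexes
# [i_d, ..., i_1, j], so spatial dim k of the grid is array dim (d - k + 1).
# The 2-D fast path stays in plain matrix products (no aperm copies).
convolve_density <- function(Fmat, shape, ops, transpose = FALSE) {
  Fmat <- as.matrix(Fmat)
  d <- length(shape)
  J <- ncol(Fmat)
  if (d == 2L) {
    n1 <- shape[1L]; n2 <- shape[2L]
    M2 <- if (transpose) t(ops[[2L]]) else ops[[2L]]
    tM1 <- if (transpose) ops[[1L]] else t(ops[[1L]])
    tmp <- M2 %*% matrix(Fmat, n2, n1 * J)      # conv along spatial dim 2
    out <- matrix(0, n1 * n2, J)
    dim(tmp) <- c(n2, n1, J)
    for (j in seq_len(J)) {
      out[, j] <- tmp[, , j] %*% tM1            # conv along spatial dim 1
    }
    return(out)
  }
  A <- array(Fmat, dim = c(rev(shape), J))
  for (k in seq_len(d)) {
    Mk <- if (transpose) t(ops[[k]]) else ops[[k]]
    A <- apply_along_dim(A, d - k + 1L, Mk)
  }
  matrix(A, prod(shape), J)
}
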