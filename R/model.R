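# Observation model ------------------------------------------------------------
#
# The generative model for an in situ sequencing stack:
#
#   X[m, r, c] ~ a[m] + b[r, c] + alpha[r, c] *
#                sum_{j, m', c'} K[m, m'] F[m', j] phi[c, c'] Z[r, c', j]
#
# where F holds the per-barcode rolony densities, a is a per-voxel background,
# b a per-frame offset, alpha a per-frame gain, phi the channel cross-talk
# matrix, and Z the codebook after round-to-round phasing:
#
#   Z[1, c, j] = B[1, c, j];  Z[r, c, j] = rho[c] * Z[r-1, c, j] + B[r, c, j].
#
# Collecting the per-frame response of each barcode gives the gain tensor
#   G[r, c, j] = alpha[r, c] * sum_{c'} phi[c, c'] Z[r, c', j],
# so the reconstruction is a[m] + b[r, c] + sum_j (K * F[, j])[m] G[r, c, j].

#' Construct model parameters
#'
#' @param F Non-negative `M x J` density matrix (rows = voxels, row-major).
#' @param a Non-negative background vector of length `M`.
#' @param b Non-negative `R x C` per-frame offset matrix.
#' @param alpha Non-negative `R x C` per-frame gain matrix.
#' @param phi `C x C` channel cross-talk matrix with entries in `[0, 1]`.
#' @param rho Per-channel phasing factors in `[0, 1]`, length `C`.
#' @return An object of class `model_params`.
#' @export
model_params <- function(F, a, b, alpha, phi, rho) {
  F <- as.matrix(F); b <- as.matrix(b); alpha <- as.matrix(alpha)
  phi <- as.matrix(phi)
  check_range <- function(x, name, lo = 0, hi = Inf) {
    if (any(!is.finite(x))) stop(sprintf("%s contains non-finite values", name), call. = FALSE)
    if (any(x < lo) || any(x > hi)) {
      stop(sprintf("%s must lie in [%s, %s]", name, lo, hi), call. = FALSE)
    }
  }
  check_range(F, "F"); check_range(a, "a"); check_range(b, "b")
  check_range(alpha, "alpha")
  check_range(phi, "phi", 0, 1); check_range(rho, "rho", 0, 1)
  stopifnot(length(a) == nrow(F), all(dim(b) == dim(alpha)),
            nrow(phi) == ncol(phi), ncol(alpha) == nrow(phi),
            length(rho) == nrow(phi))
  structure(list(F = F, a = as.numeric(a), b = b, alpha = alpha,
                 phi = phi, rho = as.numeric(rho)),
            class = "model_params")
}

#' Default parameters (identity optics, unit gain, zero background)
#'
#' @param M,J Number of voxels and barcodes.
#' @param R,C Rounds and channels.
#' @return A `model_params` object with `F = 0`, `a = 0`, `b = 0`,
#'   `alpha = 1`, `phi = I`, `rho = 0`.
#' @export
default_params <- function(M, J, R, C) {
  model_params(
    F = matrix(0, M, J), a = rep(0, M), b = matrix(0, R, C),
    alpha = matrix(1, R, C), phi = diag(C), rho = rep(0, C)
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> M = %d voxels, J = %d barcodes, %d x %d frames; %d nonzero densities\n",
              nrow(x$F), ncol(x$F), nrow(x$b), ncol(x$b), sum(x$F > 0)))
  invisible(x)
}

#' Apply round-to-round phasing to a codebook
#'
#' Incomplete stripping lets a fraction `rho[c]` of each round's signal carry
#' over into the next round: `Z[r] = rho * Z[r-1] + B[r]`, with `Z[1] = B[1]`.
#'
#' @param cb A `codebook` (or bare binary `R x C x J` array).
#' @param rho Per-channel phasing factors in `[0, 1]`.
#' @return Numeric `R x C x J` array `Z` (satisfies `Z >= B`).
#' @export
phase_codebook <- function(cb, rho) {
  B <- if (inherits(cb, "codebook")) cb$B else cb
  d <- dim(B); R <- d[1L]; C <- d[2L]
  stopifnot(length(rho) == C)
  bad <- which(rho < 0 | rho > 1)
  if (length(bad)) {
    stop(sprintf("phasing factor for channel %s outside [0, 1]",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  Z <- array(0, dim = d)
  Z[1L, , ] <- B[1L, , ]
  if (R > 1L) {
    for (r in 2:R) {
      Z[r, , ] <- sweep(array(Z[r - 1L, , ], d[2:3]), 1L, rho, `*`) +
        array(B[r, , ], d[2:3])
    }
  }
  Z
}

#' Per-frame gain tensor G
#'
#' `G[r, c, j] = alpha[r, c] * sum_{c'} phi[c, c'] Z[r, c', j]`: the expected
#' fluorescence contribution of one unit of barcode-`j` density in frame
#' `(r, c)`.
#'
#' @param Z Phased codebook array (`R x C x J`), from [phase_codebook()].
#' @param alpha `R x C` gain matrix.
#' @param phi `C x C` cross-talk matrix.
#' @return Numeric `R x C x J` array.
#' @export
gain_tensor <- function(Z, alpha, phi) {
  d <- dim(Z)
  stopifnot(length(d) == 3L)
  if (!all(dim(alpha) == d[1:2]) || !all(dim(phi) == d[2L])) {
    stop("alpha/phi dimensions do not match the phased codebook", call. = FALSE)
  }
  # H[r, c, j] = sum_c' phi[c, c'] Z[r, c', j]
  H <- apply_along_dim(Z, 2L, phi)
  sweep(H, 1:2, alpha, `*`)
}

# (R*C) x J matrix form of an (R, C, J) tensor, row index (r-1)*C + c
gain_matrix <- function(G) {
  d <- dim(G)
  matrix(aperm(G, c(2L, 1L, 3L)), d[1L] * d[2L], d[3L])
}

#' Render the forward model into an image stack
#'
#' @param params A `model_params` object.
#' @param psf A `psf` object.
#' @param cb A `codebook` with `J` matching `ncol(params$F)`.
#' @param spatial_shape Spatial grid extents (product = `nrow(params$F)`).
#' @return An `image_stack` holding the reconstruction.
#' @export
forward_model <- function(params, psf, cb, spatial_shape) {
  stopifnot(inherits(params, "model_params"), inherits(cb, "codebook"))
  if (ncol(params$F) != n_barcodes(cb)) {
    stop("codebook J does not match the density matrix", call. = FALSE)
  }
  if (prod(spatial_shape) != nrow(params$F)) {
    stop("spatial_shape does not match the density matrix", call. = FALSE)
  }
  R <- cb_rounds(cb); C <- cb_channels(cb)
  ops <- psf_operators(psf, spatial_shape)
  mat <- reconstruction_matrix(params, ops, cb, spatial_shape)
  image_stack(mat, R = R, C = C, spatial_shape = spatial_shape)
}

# M x (R*C) reconstruction, given precomputed conv operators
reconstruction_matrix <- function(params, ops, cb, shape) {
  Z <- phase_codebook(cb, params$rho)
  G <- gain_tensor(Z, params$alpha, params$phi)
  W <- convolve_density(params$F, shape, ops)
  sweep(W %*% t(gain_matrix(G)), 2L, rc_vec(params$b), `+`) + params$a
}

#' Squared reconstruction loss
#'
#' Sum over voxels, rounds and channels of squared differences between the
#' observed stack and the model reconstruction.
#'
#' @param X,reconstruction `image_stack`s of identical dimensions.
#' @return A non-negative scalar.
#' @export
reconstruction_loss <- function(X, reconstruction) {
  stopifnot(inherits(X, "image_stack"), inherits(reconstruction, "image_stack"))
  if (!identical(dim(X), dim(reconstruction))) {
    stop("stack dimensions differ", call. = FALSE)
  }
  sum((X$data - reconstruction$data)^2)
}

#' Linear sparsity penalty on the total rendered density
#'
#' `sum_{m,r,c,c',j} alpha[r,c] F[m,j] phi[c,c'] Z[r,c',j]`, equivalently
#' `sum_{m,j} F[m,j] * colSums(G)[j]`. Linear in `F`, so under non-negativity
#' it plays the role of an L1 penalty.
#'
#' @param params A `model_params` object.
#' @param Z Phased codebook array (defaults must be supplied by the caller via
#'   [phase_codebook()]).
#' @return A non-negative scalar.
#' @export
sparsity_loss <- function(params, Z) {
  G <- gain_tensor(Z, params$alpha, params$phi)
  s <- colSums(gain_matrix(G))
  sum(colSums(params$F) * s)
}

#' Resolve the overall-scale ambiguity of fitted parameters
#'
#' The model output is unchanged under `(F, alpha, phi) -> (kF, alpha/u,
#' phi/v)` rescalings, so fitted parameters are only identified up to scale.
#' This canonicalizes them: each row of `phi` is divided by its diagonal value
#' (the corresponding column of `alpha` absorbs it), then `alpha` is divided
#' by its sum and `F` multiplied by the same factor. The reconstruction is
#' unchanged to floating-point roundoff.
#'
#' @param params A `model_params` object.
#' @return A `model_params` object with `sum(alpha) == 1` and
#'   `diag(phi) == 1`.
#' @export
normalize_scale <- function(params) {
  stopifnot(inherits(params, "model_params"))
  dphi <- diag(params$phi)
  if (any(dphi <= 0)) stop("phi has a non-positive diagonal entry", call. = FALSE)
  phi <- params$phi / dphi                 # divide each row by its diagonal
  alpha <- sweep(params$alpha, 2L, dphi, `*`)
  s <- sum(alpha)
  if (s <= 0) stop("alpha has non-positive sum", call. = FALSE)
  model_params(F = params$F * s, a = params$a, b = params$b,
               alpha = alpha / s, phi = phi, rho = params$rho)
}
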