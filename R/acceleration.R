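# Acceleration -----------------------------------------------------------------
#
# Three composable strategies for large stacks: (i) coarse-to-fine — fit on a
# block-mean downsampled stack, then use the upsampled densities to initialize
# the full-resolution fit; (ii) barcode sparsification — drop barcodes whose
# coarse density is negligible within a patch; (iii) patch parallelism — split
# the grid into core tiles, fit each tile with a halo wide enough to absorb
# PSF spill-over, and stitch the core regions back together. Patches are
# independent, so execution order cannot change the result.

#' Block-mean downsample a stack
#'
#' Averages `factor`-per-side spatial blocks; partial edge blocks average
#' over their actual voxels. Rounds and channels are untouched.
#'
#' @param X An `image_stack`.
#' @param factor Positive integer downsampling factor.
#' @return An `image_stack` on the coarser grid.
#' @export
downsample_stack <- function(X, factor) {
  stopifnot(inherits(X, "image_stack"), factor >= 1)
  factor <- as.integer(factor)
  if (factor == 1L) return(X)
  if (all(factor > X$spatial_shape)) {
    stop("downsampling factor exceeds every spatial dimension", call. = FALSE)
  }
  shape <- X$spatial_shape
  coarse_shape <- pmax((shape + factor - 1L) %/% factor, 1L)
  Mc <- prod(coarse_shape)
  coords <- voxel_to_coords(0:(prod(shape) - 1L), shape)
  block <- coords %/% factor
  cidx <- coords_to_voxel(block, coarse_shape) + 1L
  counts <- tabulate(cidx, Mc)
  out <- matrix(0, Mc, ncol(X$data))
  for (k in seq_len(ncol(X$data))) {
    out[, k] <- as.vector(rowsum(X$data[, k], cidx, reorder = TRUE)) / counts
  }
  image_stack(out, R = X$R, C = X$C, spatial_shape = coarse_shape)
}

#' Upsample a coarse density matrix to a fine grid
#'
#' Replicates each coarse value into its `factor`-block and divides by the
#' number of fine voxels per block, so the total summed density is preserved.
#'
#' @param F_coarse `Mc x J` coarse density matrix.
#' @param factor Integer upsampling factor.
#' @param fine_shape Spatial extents of the fine grid.
#' @return An `M x J` density matrix on the fine grid.
#' @export
upsample_density <- function(F_coarse, factor, fine_shape) {
  factor <- as.integer(factor)
  F_coarse <- as.matrix(F_coarse)
  coarse_shape <- pmax((fine_shape + factor - 1L) %/% factor, 1L)
  if (nrow(F_coarse) != prod(coarse_shape)) {
    stop("coarse density does not match fine_shape / factor", call. = FALSE)
  }
  if (factor == 1L) return(F_coarse)
  coords <- voxel_to_coords(0:(prod(fine_shape) - 1L), fine_shape)
  block <- coords %/% factor
  cidx <- coords_to_voxel(block, coarse_shape) + 1L
  counts <- tabulate(cidx, prod(coarse_shape))
  F_coarse[cidx, , drop = FALSE] / counts[cidx]
}

#' Barcodes worth keeping in a region
#'
#' Returns the indices of barcodes whose maximum coarse density exceeds
#' `tol`. Unused barcodes are always retained — they are needed downstream to
#' set the spot-calling threshold.
#'
#' @param F_coarse Density matrix from a coarse fit.
#' @param cb A `codebook`.
#' @param tol Non-negative retention tolerance (default machine epsilon).
#' @return Sorted integer vector of retained barcode indices (1-based).
#' @export
sparsify_barcodes <- function(F_coarse, cb, tol = .Machine$double.eps) {
  stopifnot(inherits(cb, "codebook"), tol >= 0)
  peak <- apply(as.matrix(F_coarse), 2L, max)
  sort(union(which(peak > tol), which(cb$unused)))
}

#' Partition a grid into core patches with halos
#'
#' Core boxes tile the grid exactly; each padded box is its core expanded by
#' `halo` voxels and clipped to the grid.
#'
#' @param spatial_shape Grid extents.
#' @param patch_size Core patch extents (scalar recycled; edge patches may be
#'   smaller).
#' @param halo Non-negative halo width in voxels.
#' @return An object of class `patch_grid`: tibble with one row per patch and
#'   list-columns `core_lo`, `core_hi`, `pad_lo`, `pad_hi` (0-based inclusive
#'   bounds).
#' @export
patch_grid <- function(spatial_shape, patch_size, halo = 0L) {
  d <- length(spatial_shape)
  patch_size <- rep(as.integer(patch_size), length.out = d)
  stopifnot(all(patch_size >= 1L), halo >= 0L)
  starts <- lapply(seq_len(d), function(k) {
    seq.int(0L, spatial_shape[k] - 1L, by = patch_size[k])
  })
  grid <- expand.grid(rev(starts))[, d:1, drop = FALSE]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    lo <- as.integer(grid[i, ])
    hi <- pmin(lo + patch_size - 1L, spatial_shape - 1L)
    list(core_lo = lo, core_hi = hi,
         pad_lo = pmax(lo - as.integer(halo), 0L),
         pad_hi = pmin(hi + as.integer(halo), spatial_shape - 1L))
  })
  out <- tibble::tibble(
    patch = seq_along(rows),
    core_lo = purrr::map(rows, "core_lo"),
    core_hi = purrr::map(rows, "core_hi"),
    pad_lo = purrr::map(rows, "pad_lo"),
    pad_hi = purrr::map(rows, "pad_hi")
  )
  attr(out, "spatial_shape") <- as.integer(spatial_shape)
  attr(out, "halo") <- as.integer(halo)
  class(out) <- c("patch_grid", class(out))
  out
}

# extract the sub-stack covering box [lo, hi]
crop_stack <- function(X, lo, hi) {
  sel <- window_voxels(lo, hi, X$spatial_shape)
  image_stack(X$data[sel + 1L, , drop = FALSE], R = X$R, C = X$C,
              spatial_shape = hi - lo + 1L)
}

subset_codebook <- function(cb, idx) {
  codebook(cb$B[, , idx, drop = FALSE], gene_names = cb$gene_names[idx],
           unused = cb$unused[idx])
}

#' Accelerated fit: patches + coarse-to-fine + barcode sparsification
#'
#' Per padded patch: fit a block-mean downsampled copy (`coarse_iters`
#' iterations, PSF width divided by `factor`), drop barcodes with negligible
#' coarse density, then fit the patch at full resolution restricted to the
#' retained barcodes, initialized from the upsampled coarse densities.
#' Patch results are stitched by keeping each patch's core region. With a
#' single full-grid patch and `factor = 1` the procedure reduces exactly to
#' [fit_densities()].
#'
#' @param X An `image_stack`.
#' @param cb A `codebook`.
#' @param psf A `psf`.
#' @param config `fit_config` for the fine fits.
#' @param patches A `patch_grid` (default: one patch covering the grid, halo
#'   `ceil(4 * max(sigma))`).
#' @param factor Coarse-to-fine downsampling factor (default 2; 1 skips the
#'   coarse stage).
#' @param tol Sparsification tolerance (default machine epsilon).
#' @param coarse_iters Outer iterations for the coarse stage (default 20).
#' @return A `density_fit` whose `F`, `a` are stitched from patch cores;
#'   frame-level parameters (`b`, `alpha`, `phi`, `rho`) are core-size
#'   weighted averages, re-normalized. The per-patch fits are kept in
#'   `patch_fits`.
#' @export
fit_accelerated <- function(X, cb, psf = psf_gaussian(1.5),
                            config = fit_config(), patches = NULL,
                            factor = 2L, tol = .Machine$double.eps,
                            coarse_iters = 20L) {
  stopifnot(inherits(X, "image_stack"), inherits(cb, "codebook"))
  d <- length(X$spatial_shape)
  if (is.null(patches)) {
    halo <- ceiling(4 * max(psf_sigmas(psf, d)))
    patches <- patch_grid(X$spatial_shape, X$spatial_shape, halo)
  }
  J <- n_barcodes(cb)
  M <- n_voxels(X)
  # noise is spatially homogeneous, so the global unexplained budget is
  # allocated per voxel; a fraction of each patch's own variance would
  # starve patches that hold few rolonies
  omega_global <- select_noise_threshold(X, config)
  Ffull <- matrix(0, M, J)
  afull <- numeric(M)
  acc <- list(b = 0, alpha = 0, phi = 0, rho = 0, w = 0)
  patch_fits <- vector("list", nrow(patches))
  for (i in seq_len(nrow(patches))) {
    res <- tryCatch(
      fit_one_patch(X, cb, psf, config,
                    patches$pad_lo[[i]], patches$pad_hi[[i]],
                    factor, tol, coarse_iters,
                    omega_per_voxel = omega_global / M),
      error = function(e) {
        stop(sprintf("patch %d failed: %s", i, conditionMessage(e)),
             call. = FALSE)
      }
    )
    patch_fits[[i]] <- res
    # keep only the core region of this patch
    core_lo <- patches$core_lo[[i]]; core_hi <- patches$core_hi[[i]]
    sel_global <- window_voxels(core_lo, core_hi, X$spatial_shape)
    sel_local <- window_voxels(core_lo - patches$pad_lo[[i]],
                               core_hi - patches$pad_lo[[i]],
                               patches$pad_hi[[i]] - patches$pad_lo[[i]] + 1L)
    Ffull[sel_global + 1L, res$active] <- res$fit$params$F[sel_local + 1L, ]
    afull[sel_global + 1L] <- res$fit$params$a[sel_local + 1L]
    w <- length(sel_global)
    acc$b <- acc$b + w * res$fit$params$b
    acc$alpha <- acc$alpha + w * res$fit$params$alpha
    acc$phi <- acc$phi + w * res$fit$params$phi
    acc$rho <- acc$rho + w * res$fit$params$rho
    acc$w <- acc$w + w
  }
  params <- normalize_scale(model_params(
    F = Ffull, a = afull, b = acc$b / acc$w, alpha = acc$alpha / acc$w,
    phi = pmin(acc$phi / acc$w, 1), rho = pmin(acc$rho / acc$w, 1)
  ))
  last <- patch_fits[[length(patch_fits)]]$fit
  out <- new_density_fit(params, omega = last$omega, lambda = last$lambda,
                         trajectory = last$trajectory,
                         converged = all(vapply(patch_fits,
                                                function(p) p$fit$converged,
                                                logical(1))),
                         recon = NA_real_, spars = NA_real_,
                         X = X, cb = cb, psf = psf, config = config,
                         lambda_trace = last$lambda_trace)
  rec <- reconstruct(out)
  out$reconstruction_loss <- reconstruction_loss(X, rec)
  out$sparsity_loss <- sparsity_loss(out$params,
                                     phase_codebook(cb, out$params$rho))
  out$patch_fits <- patch_fits
  out
}

fit_one_patch <- function(X, cb, psf, config, lo, hi, factor, tol,
                          coarse_iters, omega_per_voxel) {
  Xp <- crop_stack(X, lo, hi)
  omega_p <- omega_per_voxel * n_voxels(Xp)
  active <- seq_len(n_barcodes(cb))
  init <- NULL
  if (factor > 1L) {
    Xc <- downsample_stack(Xp, factor)
    psf_c <- psf_gaussian(psf$sigma / factor, psf$truncation_radius)
    cfg_c <- config
    cfg_c$max_iters <- as.integer(coarse_iters)
    coarse <- fit_densities(Xc, cb, psf_c, cfg_c)
    active <- sparsify_barcodes(coarse$params$F, cb, tol)
    F0 <- upsample_density(coarse$params$F[, active, drop = FALSE], factor,
                           Xp$spatial_shape)
    init <- model_params(F = F0, a = upsample_a(coarse$params$a, factor,
                                                Xp$spatial_shape),
                         b = coarse$params$b, alpha = coarse$params$alpha,
                         phi = coarse$params$phi, rho = coarse$params$rho)
  }
  cbp <- subset_codebook(cb, active)
  fit <- fit_densities(Xp, cbp, psf, config, init = init, omega = omega_p)
  list(fit = fit, active = active, lo = lo, hi = hi)
}

# background is an intensity (not a density): replicate without mass division
upsample_a <- function(a_coarse, factor, fine_shape) {
  coarse_shape <- pmax((fine_shape + factor - 1L) %/% factor, 1L)
  coords <- voxel_to_coords(0:(prod(fine_shape) - 1L), fine_shape)
  cidx <- coords_to_voxel(coords %/% factor, coarse_shape) + 1L
  a_coarse[cidx]
}
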