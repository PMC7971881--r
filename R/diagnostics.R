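# Model diagnostics ------------------------------------------------------------
#
# A fitted model can be checked without ground truth. The "cleaned image" for
# barcode j* subtracts from the data the background, the per-frame offsets and
# every barcode's rendered contribution except j*'s; if the model is right,
# what remains is (approximately) a rank-one tensor: the blurred density of j*
# times its per-frame gain signature G[, , j*]. The top singular pair of the
# windowed cleaned image therefore gives both a quality score (R^2 of the
# rank-one approximation) and an independent estimate of G to compare against
# the fitted one.

#' Cleaned image for one barcode
#'
#' `cleaned[m, r, c] = X[m, r, c] - a[m] - b[r, c] -
#'   sum_{j != j*} (K * F[, j])[m] G[r, c, j]` — the data with everything
#' except barcode `j_star`'s contribution subtracted. Entries may be negative.
#'
#' @param X Observed `image_stack`.
#' @param params Fitted `model_params`.
#' @param psf A `psf`.
#' @param cb A `codebook`.
#' @param j_star Barcode index (1-based) whose contribution is retained.
#' @return An object of class `cleaned_image`: list with `data`
#'   (`M x (R*C)` matrix), `barcode_index`, `spatial_shape`, `R`, `C`, and
#'   `gain` (the fitted `G[, , j_star]` as an `R x C` matrix).
#' @export
cleaned_image <- function(X, params, psf, cb, j_star) {
  stopifnot(inherits(X, "image_stack"), inherits(params, "model_params"))
  J <- ncol(params$F)
  if (!(j_star %in% seq_len(J))) {
    stop(sprintf("j_star must be in 1..%d", J), call. = FALSE)
  }
  shape <- X$spatial_shape
  ops <- psf_operators(psf, shape)
  Z <- phase_codebook(cb, params$rho)
  G <- gain_tensor(Z, params$alpha, params$phi)
  Gmat <- gain_matrix(G)
  W <- convolve_density(params$F, shape, ops)
  # total barcode contribution minus j_star's own
  others <- W %*% t(Gmat) - W[, j_star, drop = FALSE] %*% t(Gmat[, j_star, drop = FALSE])
  cleaned <- X$data - params$a -
    matrix(rc_vec(params$b), nrow(X$data), X$R * X$C, byrow = TRUE) - others
  structure(
    list(data = cleaned, barcode_index = j_star, spatial_shape = shape,
         R = X$R, C = X$C, gain = t(matrix(Gmat[, j_star], X$C, X$R))),
    class = "cleaned_image"
  )
}

#' @export
print.cleaned_image <- function(x, ...) {
  cat(sprintf("<cleaned_image> barcode %d, %d x %d frames on %s grid\n",
              x$barcode_index, x$R, x$C,
              paste(x$spatial_shape, collapse = " x ")))
  invisible(x)
}

#' Rank-one SVD diagnostic for a spot
#'
#' Extracts a voxel window from a cleaned image, reshapes it to
#' (voxels x frames), and computes the top singular pair. If the model is
#' right the window is approximately the outer product of a spatial profile
#' and the barcode's gain signature, so the squared correlation between the
#' window and its rank-one approximation (`r_squared`) should be near 1.
#' Singular-vector signs are fixed so the temporal vector's
#' largest-magnitude entry is positive.
#'
#' @param cleaned A `cleaned_image`.
#' @param center Spot coordinates, 0-based, one per spatial dimension.
#' @param window_size Window edge length in voxels (default 10), clipped to
#'   the grid.
#' @return An object of class `spot_quality`: list with `r_squared`,
#'   `spatial_vector`, `temporal_vector` (length `R*C`), `center`,
#'   `barcode_index` and `window` (the 0-based corner/extent actually used).
#' @export
rank_one_diagnostic <- function(cleaned, center, window_size = 10L) {
  stopifnot(inherits(cleaned, "cleaned_image"))
  shape <- cleaned$spatial_shape
  d <- length(shape)
  center <- as.integer(center)
  stopifnot(length(center) == d, all(center >= 0), all(center < shape))
  half <- window_size %/% 2L
  lo <- pmax(center - half, 0L)
  hi <- pmin(lo + window_size - 1L, shape - 1L)
  lo <- pmax(hi - window_size + 1L, 0L)
  sel <- window_voxels(lo, hi, shape)
  Wm <- cleaned$data[sel + 1L, , drop = FALSE]
  if (all(Wm == 0)) {
    return(new_spot_quality(0, rep(0, nrow(Wm)), rep(0, ncol(Wm)),
                            center, cleaned$barcode_index, lo, hi))
  }
  sv <- svd(Wm, nu = 1L, nv = 1L)
  u <- sv$u[, 1L]; v <- sv$v[, 1L]; s1 <- sv$d[1L]
  if (v[which.max(abs(v))] < 0) { v <- -v; u <- -u }
  approx1 <- s1 * outer(u, v)
  r2 <- suppressWarnings(stats::cor(as.vector(Wm), as.vector(approx1)))^2
  if (!is.finite(r2)) r2 <- 0
  new_spot_quality(r2, s1 * u, v, center, cleaned$barcode_index, lo, hi)
}

new_spot_quality <- function(r2, spatial, temporal, center, j, lo, hi) {
  structure(
    list(r_squared = r2, spatial_vector = spatial, temporal_vector = temporal,
         center = center, barcode_index = j,
         window = list(corner = lo, extent = hi - lo + 1L)),
    class = "spot_quality"
  )
}

#' @export
print.spot_quality <- function(x, ...) {
  cat(sprintf("<spot_quality> barcode %d at (%s): R^2 = %.4f\n",
              x$barcode_index, paste(x$center, collapse = ", "), x$r_squared))
  invisible(x)
}

# 0-based row-major voxel indices of the box [lo, hi] (inclusive, 0-based)
window_voxels <- function(lo, hi, shape) {
  ranges <- Map(function(l, h) l:h, as.list(lo), as.list(hi))
  grid <- as.matrix(expand.grid(rev(ranges)))[, length(shape):1, drop = FALSE]
  sort(coords_to_voxel(grid, shape))
}

#' Percentage of variance left unexplained by a reconstruction
#'
#' `100 * sum((X - reconstruction)^2) / sum((X - mean(X))^2)`.
#'
#' @param X,reconstruction `image_stack`s of identical dimensions.
#' @return Percentage unexplained (scalar); `NA` with a warning when `X` is
#'   constant (the denominator vanishes).
#' @export
residual_summary <- function(X, reconstruction) {
  stopifnot(inherits(X, "image_stack"), inherits(reconstruction, "image_stack"))
  if (!identical(dim(X), dim(reconstruction))) {
    stop("stack dimensions differ", call. = FALSE)
  }
  tss <- sum((X$data - mean(X$data))^2)
  if (tss == 0) {
    warning("X is constant: percentage unexplained is undefined")
    return(NA_real_)
  }
  100 * sum((X$data - reconstruction$data)^2) / tss
}

#' Quality scores for every passing spot of a fit
#'
#' Runs [cleaned_image()] and [rank_one_diagnostic()] for each spot.
#'
#' @param X Observed `image_stack`.
#' @param fit A `density_fit`.
#' @param spots A `spot_table` (defaults to `call_spots(fit)`).
#' @param window_size Diagnostic window edge length (default 10).
#' @param passing_only Score only spots that pass the threshold (default
#'   `TRUE`).
#' @return A tibble with the spot columns plus `r_squared`, and the
#'   `spot_quality` objects in the `quality` list-column.
#' @export
spot_qualities <- function(X, fit, spots = NULL, window_size = 10L,
                           passing_only = TRUE) {
  stopifnot(inherits(fit, "density_fit"))
  spots <- spots %||% call_spots(fit)
  if (passing_only) spots <- dplyr::filter(spots, .data$passes_threshold)
  d <- length(fit$spatial_shape)
  axes <- spatial_axis_names(d)
  cleaned_cache <- new.env(parent = emptyenv())
  qualities <- purrr::map(seq_len(nrow(spots)), function(i) {
    j0 <- spots$barcode_index[i]
    key <- as.character(j0)
    if (is.null(cleaned_cache[[key]])) {
      cleaned_cache[[key]] <- cleaned_image(X, fit$params, fit$psf,
                                            fit$codebook, j0 + 1L)
    }
    center <- as.integer(unlist(spots[i, axes]))
    rank_one_diagnostic(cleaned_cache[[key]], center, window_size)
  })
  spots$r_squared <- vapply(qualities, function(q) q$r_squared, numeric(1))
  spots$quality <- qualities
  spots
}

#' Histogram of spot quality scores
#'
#' Bins R^2 values into 20 equal bins over `[0, 1]`.
#'
#' @param qualities A numeric vector of R^2 values, a list of `spot_quality`
#'   objects, or a tibble with an `r_squared` column.
#' @param bins Number of bins (default 20).
#' @return A tibble of class `quality_histogram` with `bin_lower`,
#'   `bin_upper`, `count`; the input scores are kept in the `r_squared`
#'   attribute.
#' @export
quality_histogram <- function(qualities, bins = 20L) {
  r2 <- if (is.numeric(qualities)) {
    qualities
  } else if (is.data.frame(qualities)) {
    qualities$r_squared
  } else {
    vapply(qualities, function(q) q$r_squared, numeric(1))
  }
  stopifnot(all(r2 >= 0 & r2 <= 1))
  breaks <- seq(0, 1, length.out = bins + 1L)
  counts <- if (length(r2) == 0L) rep(0L, bins) else {
    as.integer(table(cut(r2, breaks, include.lowest = TRUE)))
  }
  out <- tibble::tibble(bin_lower = breaks[-(bins + 1L)],
                        bin_upper = breaks[-1L],
                        count = counts)
  attr(out, "r_squared") <- r2
  class(out) <- c("quality_histogram", class(out))
  out
}
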