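# Synthetic data ---------------------------------------------------------------
#
# The generator emulates a registered, background-subtracted stack: rolonies
# placed uniformly at distinct voxels, barcodes drawn from a per-gene
# frequency vector, amplitudes uniform on a configurable range, the forward
# model applied, optional per-rolony round dropout (a rolony simply vanishes
# from one or more rounds — a failure mode the observation model itself does
# not describe), and i.i.d. Gaussian noise truncated at zero. The matching
# and ROC utilities quantify recovery against the known truth.

#' Simulation settings
#'
#' @param R,C,J Rounds, channels, barcodes.
#' @param spatial_shape Grid extents (default `c(150, 150)`).
#' @param n_spots Number of rolonies (default 100).
#' @param amplitude_low,amplitude_high Uniform amplitude range (default 0.5–1).
#' @param psf_sigma Gaussian PSF width in voxels (default 1.5).
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param dropout_fraction Fraction of rolonies subject to round dropout
#'   (default 0).
#' @param dropout_rounds Number of distinct rounds dropped per affected
#'   rolony (default 1).
#' @param gene_freq Optional per-gene sampling weights (default uniform).
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(R = 7L, C = 4L, J = 20L, spatial_shape = c(150L, 150L),
                       n_spots = 100L, amplitude_low = 0.5,
                       amplitude_high = 1, psf_sigma = 1.5, noise_sd = 0,
                       dropout_fraction = 0, dropout_rounds = 1L,
                       gene_freq = NULL, seed = 1L) {
  stopifnot(amplitude_low > 0, amplitude_high >= amplitude_low,
            noise_sd >= 0, dropout_fraction >= 0, dropout_fraction <= 1,
            dropout_rounds >= 1L, dropout_rounds < R)
  structure(list(R = as.integer(R), C = as.integer(C), J = as.integer(J),
                 spatial_shape = as.integer(spatial_shape),
                 n_spots = as.integer(n_spots),
                 amplitude_low = amplitude_low, amplitude_high = amplitude_high,
                 psf_sigma = psf_sigma, noise_sd = noise_sd,
                 dropout_fraction = dropout_fraction,
                 dropout_rounds = as.integer(dropout_rounds),
                 gene_freq = gene_freq, seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw ground-truth rolonies
#'
#' Voxels uniform without replacement; barcodes from `gene_freq` (uniform by
#' default); amplitudes uniform on the configured range. An exactly sized
#' subset of `round(dropout_fraction * n_spots)` rolonies receives
#' `dropout_rounds` distinct dropped rounds each.
#'
#' @param config A `sim_config`.
#' @param cb A `codebook` (unused barcodes are never assigned to truth spots).
#' @return A `sim_truth` tibble: `voxel` (0-based), coordinate columns,
#'   `barcode_index` (0-based), `amplitude`, `dropped_rounds` (list-column of
#'   0-based round indices, possibly empty).
#' @export
simulate_truth <- function(config, cb) {
  stopifnot(inherits(config, "sim_config"), inherits(cb, "codebook"))
  M <- prod(config$spatial_shape)
  if (config$n_spots > M) {
    stop("more spots requested than voxels available", call. = FALSE)
  }
  usable <- which(!cb$unused)
  freq <- config$gene_freq %||% rep(1, length(usable))
  stopifnot(length(freq) == length(usable))
  withr::with_seed(config$seed, {
    voxels <- sample.int(M, config$n_spots) - 1L
    barcodes <- usable[sample.int(length(usable), config$n_spots,
                                  replace = TRUE, prob = freq)] - 1L
    amplitudes <- stats::runif(config$n_spots, config$amplitude_low,
                               config$amplitude_high)
    n_drop <- round(config$dropout_fraction * config$n_spots)
    dropped <- replicate(config$n_spots, integer(0), simplify = FALSE)
    if (n_drop > 0L) {
      which_drop <- sample.int(config$n_spots, n_drop)
      for (i in which_drop) {
        dropped[[i]] <- sort(sample.int(config$R, config$dropout_rounds) - 1L)
      }
    }
    coords <- voxel_to_coords(voxels, config$spatial_shape)
    colnames(coords) <- spatial_axis_names(length(config$spatial_shape))
    out <- tibble::tibble(voxel = voxels)
    out <- dplyr::bind_cols(out, tibble::as_tibble(coords))
    out$barcode_index <- barcodes
    out$amplitude <- amplitudes
    out$dropped_rounds <- dropped
    class(out) <- c("sim_truth", class(out))
    out
  })
}

#' Render a truth table into an image stack
#'
#' Builds `F` from the truth, applies the forward model, removes each dropped
#' (rolony, round) contribution from that round's frames only, then adds
#' i.i.d. Gaussian noise truncated at zero.
#'
#' @param truth A `sim_truth` tibble.
#' @param cb A `codebook`.
#' @param spatial_shape Grid extents.
#' @param psf A `psf`.
#' @param params_true Optional `model_params` supplying `a`, `b`, `alpha`,
#'   `phi`, `rho` (its `F` slot is ignored); defaults to zero background,
#'   unit gain, identity cross-talk, no phasing.
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed Integer seed for the noise draw.
#' @return An `image_stack`.
#' @export
render_stack <- function(truth, cb, spatial_shape, psf = psf_gaussian(1.5),
                         params_true = NULL, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(cb, "codebook"))
  M <- prod(spatial_shape)
  R <- cb_rounds(cb); C <- cb_channels(cb); J <- n_barcodes(cb)
  params <- params_true %||% default_params(M, J, R, C)
  Fmat <- matrix(0, M, J)
  if (nrow(truth) > 0L) {
    for (i in seq_len(nrow(truth))) {
      Fmat[truth$voxel[i] + 1L, truth$barcode_index[i] + 1L] <-
        Fmat[truth$voxel[i] + 1L, truth$barcode_index[i] + 1L] +
        truth$amplitude[i]
    }
  }
  params <- model_params(F = Fmat, a = params$a, b = params$b,
                         alpha = params$alpha, phi = params$phi,
                         rho = params$rho)
  stack <- forward_model(params, psf, cb, spatial_shape)
  mat <- stack$data
  # dropout: remove each dropped rolony's own contribution from its rounds
  ops <- psf_operators(psf, spatial_shape)
  Z <- phase_codebook(cb, params$rho)
  G <- gain_tensor(Z, params$alpha, params$phi)
  for (i in seq_len(nrow(truth))) {
    rounds <- truth$dropped_rounds[[i]]
    if (length(rounds) == 0L) next
    delta <- matrix(0, M, 1L)
    delta[truth$voxel[i] + 1L, 1L] <- truth$amplitude[i]
    spot_img <- convolve_density(delta, spatial_shape, ops)[, 1L]
    j <- truth$barcode_index[i] + 1L
    for (r0 in rounds) {
      for (cc in seq_len(C)) {
        k <- rc_index(r0 + 1L, cc, C)
        mat[, k] <- pmax(mat[, k] - spot_img * G[r0 + 1L, cc, j], 0)
      }
    }
  }
  if (noise_sd > 0) {
    noise <- withr::with_seed(seed, matrix(stats::rnorm(length(mat), 0, noise_sd),
                                           nrow(mat), ncol(mat)))
    mat <- pmax(mat + noise, 0)
  }
  image_stack(mat, R = R, C = C, spatial_shape = spatial_shape)
}

#' Simulate a stack end to end
#'
#' Convenience wrapper: [simulate_truth()] then [render_stack()].
#'
#' @param config A `sim_config`.
#' @param cb Optional `codebook` (default: random one-hot book from the
#'   config dimensions, augmented with 2 unused barcodes).
#' @param params_true Optional true `model_params` (see [render_stack()]).
#' @return A list with `stack`, `truth`, `codebook`, `psf`.
#' @export
simulate_stack <- function(config, cb = NULL, params_true = NULL) {
  cb <- cb %||% augment_codebook(
    random_codebook(config$R, config$C, config$J, seed = config$seed),
    n_unused = 2L, min_round_diff = 3L, seed = config$seed + 1L
  )
  psf <- psf_gaussian(config$psf_sigma)
  truth <- simulate_truth(config, cb)
  stack <- render_stack(truth, cb, config$spatial_shape, psf,
                        params_true = params_true,
                        noise_sd = config$noise_sd, seed = config$seed + 2L)
  list(stack = stack, truth = truth, codebook = cb, psf = psf)
}

#' Inject synthetic rolonies into a background stack
#'
#' Places `n_inject` rolonies at uniformly random voxels, each rendered
#' through the forward model with its amplitude set so the rendered peak
#' intensity equals `scale_intensity * max(background)`.
#'
#' @param background An `image_stack` with a positive maximum.
#' @param cb A `codebook`.
#' @param psf A `psf`.
#' @param n_inject Number of rolonies to inject.
#' @param scale_intensity Peak intensity as a fraction of the background
#'   maximum, in `(0, 1]`.
#' @param seed Integer seed.
#' @return A list with `stack` (background plus injections) and `truth`
#'   (a `sim_truth` tibble for the injected rolonies).
#' @export
inject_spots <- function(background, cb, psf, n_inject,
                         scale_intensity = 1, seed = 1L) {
  stopifnot(inherits(background, "image_stack"), inherits(cb, "codebook"),
            scale_intensity > 0, scale_intensity <= 1)
  ref <- max(background$data)
  if (n_inject == 0L) {
    return(list(stack = background, truth = empty_truth(background$spatial_shape)))
  }
  if (ref <= 0) {
    stop("background maximum is zero: injected intensities need a positive reference",
         call. = FALSE)
  }
  shape <- background$spatial_shape
  M <- prod(shape)
  usable <- which(!cb$unused)
  R <- cb_rounds(cb); C <- cb_channels(cb)
  d <- length(shape)
  Z <- phase_codebook(cb, rep(0, C))
  G <- gain_tensor(Z, matrix(1, R, C), diag(C))
  withr::with_seed(seed, {
    voxels <- sample.int(M, n_inject) - 1L
    barcodes <- usable[sample.int(length(usable), n_inject, replace = TRUE)] - 1L
  })
  gmax <- apply(G, 3L, max)
  # actual rendered peak of a unit-density spot at each voxel (boundary
  # reflection raises the peak near edges, so measure rather than assume)
  ops <- psf_operators(psf, shape)
  unit_peaks <- vapply(voxels, function(v) {
    delta <- matrix(0, M, 1L); delta[v + 1L, 1L] <- 1
    max(convolve_density(delta, shape, ops))
  }, numeric(1))
  amplitudes <- scale_intensity * ref / (unit_peaks * gmax[barcodes + 1L])
  coords <- voxel_to_coords(voxels, shape)
  colnames(coords) <- spatial_axis_names(d)
  truth <- tibble::tibble(voxel = voxels)
  truth <- dplyr::bind_cols(truth, tibble::as_tibble(coords))
  truth$barcode_index <- barcodes
  truth$amplitude <- amplitudes
  truth$dropped_rounds <- replicate(n_inject, integer(0), simplify = FALSE)
  class(truth) <- c("sim_truth", class(truth))
  injected <- render_stack(truth, cb, shape, psf, noise_sd = 0)
  stack <- image_stack(background$data + injected$data, R = R, C = C,
                       spatial_shape = shape)
  list(stack = stack, truth = truth)
}

empty_truth <- function(shape) {
  d <- length(shape)
  out <- tibble::tibble(voxel = integer())
  out <- dplyr::bind_cols(out, tibble::as_tibble(
    stats::setNames(as.data.frame(matrix(integer(), 0, d)),
                    spatial_axis_names(d))))
  out$barcode_index <- integer()
  out$amplitude <- numeric()
  out$dropped_rounds <- list()
  class(out) <- c("sim_truth", class(out))
  out
}

#' Match called spots to ground truth
#'
#' Greedy nearest-neighbor matching: all (call, truth) pairs within Euclidean
#' distance `radius` are considered in order of increasing distance, each
#' call and each truth used at most once. A matched pair is a *detection*;
#' it is *correct* when the barcodes also agree.
#'
#' @param called A `spot_table` (typically filtered to passing spots).
#' @param truth A `sim_truth` tibble.
#' @param radius Matching radius in voxels (default 2).
#' @return A list of class `spot_matching`: `pairs` (tibble with `call_row`,
#'   `truth_row`, `distance`, `barcode_match`), `unmatched_calls`,
#'   `unmatched_truth` (integer row indices), and the rates `detection_rate`
#'   (detections / truths), `correct_rate` (correct / truths), `fpr`
#'   (unmatched calls / calls).
#' @export
match_spots <- function(called, truth, radius = 2) {
  axes <- intersect(spatial_axis_names(3L), names(truth))
  cc <- as.matrix(called[, axes, drop = FALSE])
  tc <- as.matrix(truth[, axes, drop = FALSE])
  n_call <- nrow(cc); n_truth <- nrow(tc)
  pairs <- NULL
  if (n_call > 0L && n_truth > 0L) {
    cand <- list()
    for (i in seq_len(n_call)) {
      dvec <- sqrt(colSums((t(tc) - cc[i, ])^2))
      hit <- which(dvec <= radius)
      if (length(hit)) {
        cand[[length(cand) + 1L]] <-
          cbind(call_row = i, truth_row = hit, distance = dvec[hit])
      }
    }
    if (length(cand)) {
      cand <- do.call(rbind, cand)
      cand <- cand[order(cand[, "distance"], cand[, "call_row"],
                         cand[, "truth_row"]), , drop = FALSE]
      used_call <- logical(n_call); used_truth <- logical(n_truth)
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, "call_row"]; j <- cand[k, "truth_row"]
        if (!used_call[i] && !used_truth[j]) {
          keep[k] <- TRUE
          used_call[i] <- TRUE; used_truth[j] <- TRUE
        }
      }
      pairs <- cand[keep, , drop = FALSE]
    }
  }
  if (is.null(pairs)) {
    pairs <- matrix(numeric(), 0L, 3L,
                    dimnames = list(NULL, c("call_row", "truth_row", "distance")))
  }
  pairs <- tibble::as_tibble(pairs)
  pairs$call_row <- as.integer(pairs$call_row)
  pairs$truth_row <- as.integer(pairs$truth_row)
  pairs$barcode_match <- if (nrow(pairs)) {
    called$barcode_index[pairs$call_row] == truth$barcode_index[pairs$truth_row]
  } else logical(0)
  structure(
    list(pairs = pairs,
         unmatched_calls = setdiff(seq_len(n_call), pairs$call_row),
         unmatched_truth = setdiff(seq_len(n_truth), pairs$truth_row),
         detection_rate = if (n_truth) nrow(pairs) / n_truth else NA_real_,
         correct_rate = if (n_truth) sum(pairs$barcode_match) / n_truth else NA_real_,
         fpr = if (n_call) (n_call - nrow(pairs)) / n_call else 0),
    class = "spot_matching"
  )
}

#' @export
print.spot_matching <- function(x, ...) {
  cat(sprintf("<spot_matching> %d pairs; detection %.3f, correct-barcode %.3f, FPR %.3f\n",
              nrow(x$pairs), x$detection_rate, x$correct_rate, x$fpr))
  invisible(x)
}

#' ROC curve over the spot-calling threshold
#'
#' Sweeps the detection threshold over the fitted densities and, at each
#' value, matches the passing spots against truth. Two recovery rates are
#' reported: barcode-strict (`tpr_strict` = correctly identified / truths)
#' and detection-only (`tpr_detection` = detected / truths, the "total hit
#' rate"); `fpr` is the fraction of calls left unmatched. AUROC integrates
#' the strict curve over FPR by the trapezoid rule, with the curve anchored
#' at (0, 0) and extended horizontally to FPR = 1.
#'
#' @param F `M x J` density matrix (or a `density_fit`).
#' @param cb A `codebook` (defaulted from the fit).
#' @param spatial_shape Grid extents (defaulted from the fit).
#' @param truth A `sim_truth` tibble.
#' @param radius Matching radius in voxels (default 2).
#' @param thresholds Sorted threshold values; default: all distinct local-
#'   maximum densities (capped at 50 quantiles).
#' @param footprint_radius Local-maximum footprint (default 1).
#' @return A list of class `roc_result`: `curve` (tibble with `threshold`,
#'   `fpr`, `tpr_strict`, `tpr_detection`, `n_calls`) and `auroc`.
#' @export
roc_curve <- function(F, cb = NULL, spatial_shape = NULL, truth, radius = 2,
                      thresholds = NULL, footprint_radius = 1L) {
  if (inherits(F, "density_fit")) {
    fit <- F
    cb <- cb %||% fit$codebook
    spatial_shape <- spatial_shape %||% fit$spatial_shape
    F <- fit$params$F
  }
  stopifnot(inherits(cb, "codebook"))
  if (nrow(truth) == 0L) stop("truth table is empty", call. = FALSE)
  all_calls <- call_spots(F, cb, spatial_shape, threshold = 0,
                          footprint_radius = footprint_radius)
  if (is.null(thresholds)) {
    vals <- sort(unique(all_calls$density))
    if (length(vals) > 50L) {
      vals <- unique(stats::quantile(vals, seq(0, 1, length.out = 50L),
                                     names = FALSE, type = 1L))
    }
    thresholds <- c(0, vals)
  }
  rows <- lapply(thresholds, function(th) {
    keep <- all_calls[all_calls$density > th, , drop = FALSE]
    m <- match_spots(keep, truth, radius)
    tibble::tibble(threshold = th, fpr = m$fpr,
                   tpr_strict = m$correct_rate,
                   tpr_detection = m$detection_rate,
                   n_calls = nrow(keep))
  })
  curve <- dplyr::bind_rows(rows)
  structure(list(curve = curve, auroc = auroc_trapezoid(curve)),
            class = "roc_result")
}

auroc_trapezoid <- function(curve) {
  pts <- dplyr::arrange(
    dplyr::summarise(dplyr::group_by(curve, .data$fpr),
                     tpr = max(.data$tpr_strict), .groups = "drop"),
    .data$fpr
  )
  x <- c(0, pts$fpr); y <- c(0, pts$tpr)
  # anchor at the origin, carry the best achieved rate out to FPR = 1
  y[1] <- if (any(pts$fpr == 0)) max(pts$tpr[pts$fpr == 0]) else 0
  if (max(x) < 1) { x <- c(x, 1); y <- c(y, y[length(y)]) }
  keep <- !duplicated(x)
  x <- x[keep]; y <- y[keep]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d thresholds, AUROC = %.4f\n",
              nrow(x$curve), x$auroc))
  invisible(x)
}

#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auroc = x$auroc, n_thresholds = nrow(x$curve))
}
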