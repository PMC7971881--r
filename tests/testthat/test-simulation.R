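test_that("simulated truth is reproducible and respects the config", {
  cb <- balanced_codebook(5, 3, 6, seed = 2)
  cfg <- sim_config(R = 5, C = 3, J = 6, spatial_shape = c(20L, 20L),
                    n_spots = 40L, dropout_fraction = 0.5,
                    dropout_rounds = 2L, seed = 5L)
  t1 <- simulate_truth(cfg, cb)
  t2 <- simulate_truth(cfg, cb)
  expect_identical(as.data.frame(t1[, c("voxel", "barcode_index", "amplitude")]),
                   as.data.frame(t2[, c("voxel", "barcode_index", "amplitude")]))
  expect_equal(nrow(t1), 40L)
  expect_equal(anyDuplicated(t1$voxel), 0L)
  expect_true(all(t1$amplitude >= cfg$amplitude_low &
                    t1$amplitude <= cfg$amplitude_high))
  # exact dropout subset sizing: round(0.5 * 40) = 20 spots carry drops
  n_dropped <- sum(vapply(t1$dropped_rounds, length, integer(1)) > 0)
  expect_equal(n_dropped, 20L)
  expect_true(all(vapply(t1$dropped_rounds, length, integer(1)) %in% c(0L, 2L)))
  # empty truth
  cfg0 <- sim_config(R = 5, C = 3, J = 6, spatial_shape = c(20L, 20L),
                     n_spots = 0L)
  expect_equal(nrow(simulate_truth(cfg0, cb)), 0L)
  cfg_big <- sim_config(R = 5, C = 3, J = 6, spatial_shape = c(3L, 3L),
                        n_spots = 100L)
  expect_error(simulate_truth(cfg_big, cb), "voxels")
})

test_that("rendering matches the forward model and implements dropout", {
  cb <- balanced_codebook(4, 2, 4, seed = 3)
  shape <- c(14L, 14L)
  cfg <- sim_config(R = 4, C = 2, J = 4, spatial_shape = shape, n_spots = 3L,
                    seed = 9L)
  truth <- simulate_truth(cfg, cb)
  psf <- psf_gaussian(1)
  # no noise, no dropout: exactly the forward model
  X <- render_stack(truth, cb, shape, psf)
  Fmat <- matrix(0, prod(shape), 4)
  Fmat[cbind(truth$voxel + 1L, truth$barcode_index + 1L)] <- truth$amplitude
  p <- default_params(prod(shape), 4, 4, 2); p$F <- Fmat
  want <- forward_model(model_params(Fmat, p$a, p$b, p$alpha, p$phi, p$rho),
                        psf, cb, shape)
  expect_equal(X$data, want$data, tolerance = 1e-12)

  # drop round 2 for rolony 1: those frames lose exactly its contribution
  truth_d <- truth
  truth_d$dropped_rounds[[1]] <- 1L       # 0-based round index
  Xd <- render_stack(truth_d, cb, shape, psf)
  r0 <- 2L
  for (cc in 1:2) {
    k <- demixr:::rc_index(r0, cc, 2L)
    delta <- matrix(0, prod(shape), 1); delta[truth$voxel[1] + 1L] <- truth$amplitude[1]
    spot <- demixr:::convolve_density(delta, shape,
                                      demixr:::psf_operators(psf, shape))[, 1]
    G <- gain_tensor(phase_codebook(cb, rep(0, 2)), matrix(1, 4, 2), diag(2))
    expect_equal(Xd$data[, k],
                 pmax(X$data[, k] - spot * G[r0, cc, truth$barcode_index[1] + 1L], 0),
                 tolerance = 1e-12)
  }
  other_frames <- setdiff(seq_len(8), demixr:::rc_index(r0, 1:2, 2L))
  expect_equal(Xd$data[, other_frames], X$data[, other_frames])

  # empty truth renders background (zero here) plus truncated noise
  Xe <- render_stack(truth[0, ], cb, shape, psf, noise_sd = 0.1, seed = 4)
  expect_true(all(Xe$data >= 0))
  expect_gt(stats::sd(Xe$data), 0)
})

test_that("spot injection scales peaks to the background maximum", {
  cb <- balanced_codebook(4, 2, 4, seed = 3)
  shape <- c(16L, 16L)
  bg <- withr::with_seed(12, image_stack(matrix(runif(prod(shape) * 8, 0, 0.5),
                                                prod(shape), 8),
                                         R = 4, C = 2, spatial_shape = shape))
  psf <- psf_gaussian(1)
  out0 <- inject_spots(bg, cb, psf, n_inject = 0L)
  expect_equal(out0$stack$data, bg$data)
  out <- inject_spots(bg, cb, psf, n_inject = 5L, scale_intensity = 0.8,
                      seed = 2L)
  expect_equal(nrow(out$truth), 5L)
  expect_true(all(out$stack$data >= bg$data - 1e-12))
  # each injected rolony, rendered alone, peaks at the requested level
  # (overlapping injections can only add)
  rendered <- out$stack$data - bg$data
  expect_gte(max(rendered), 0.8 * max(bg$data) * (1 - 1e-9))
  for (i in seq_len(nrow(out$truth))) {
    solo <- render_stack(out$truth[i, ], cb, shape, psf)
    expect_equal(max(solo$data), 0.8 * max(bg$data), tolerance = 1e-9)
  }
  zero_bg <- image_stack(matrix(0, prod(shape), 8), R = 4, C = 2,
                         spatial_shape = shape)
  expect_error(inject_spots(zero_bg, cb, psf, 3L), "positive reference")
})

test_that("greedy matching handles the barcode-swap case exactly", {
  # three truths and three calls at the right places, one barcode swapped
  shape <- c(10L, 10L)
  truth <- tibble::tibble(voxel = c(5L, 37L, 81L))
  co <- voxel_to_coords(truth$voxel, shape)
  truth$y <- co[, 1]; truth$x <- co[, 2]
  truth$barcode_index <- c(0L, 1L, 2L)
  truth$amplitude <- 1
  truth$dropped_rounds <- replicate(3, integer(0), simplify = FALSE)
  called <- tibble::tibble(gene = c("a", "b", "c"),
                           barcode_index = c(0L, 2L, 1L),  # 2 and 3 swapped
                           y = truth$y, x = truth$x,
                           voxel = truth$voxel,
                           density = c(1, 1, 1), passes_threshold = TRUE)
  m <- match_spots(called, truth, radius = 2)
  expect_equal(m$detection_rate, 1)
  expect_equal(m$correct_rate, 1 / 3)
  expect_equal(m$fpr, 0)
  # exact self-match
  called2 <- called; called2$barcode_index <- truth$barcode_index
  m2 <- match_spots(called2, truth, radius = 2)
  expect_equal(m2$correct_rate, 1)
  expect_equal(length(m2$unmatched_truth), 0L)
  # no calls at all
  m0 <- match_spots(called[0, ], truth, radius = 2)
  expect_equal(m0$detection_rate, 0)
  expect_equal(length(m0$unmatched_truth), 3L)
})

test_that("matching is greedy nearest-neighbor with one-to-one use", {
  shape <- c(10L, 10L)
  truth <- tibble::tibble(voxel = 0L, y = 0L, x = 0L, barcode_index = 0L,
                          amplitude = 1,
                          dropped_rounds = list(integer(0)))
  # two calls near one truth: only the nearer matches
  called <- tibble::tibble(gene = "a", barcode_index = 0L,
                           y = c(1L, 0L), x = c(1L, 0L), voxel = c(11L, 0L),
                           density = 1, passes_threshold = TRUE)
  m <- match_spots(called, truth, radius = 3)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$pairs$call_row, 2L)      # distance 0 beats sqrt(2)
  expect_equal(m$fpr, 0.5)
})

test_that("ROC curves behave correctly at the extremes", {
  cb <- balanced_codebook(4, 2, 4, seed = 3)
  shape <- c(12L, 12L)
  cfg <- sim_config(R = 4, C = 2, J = 4, spatial_shape = shape, n_spots = 5L,
                    seed = 31L)
  truth <- simulate_truth(cfg, cb)
  # a perfect density matrix: deltas exactly at the truth
  F <- matrix(0, prod(shape), 4)
  F[cbind(truth$voxel + 1L, truth$barcode_index + 1L)] <- truth$amplitude
  roc <- roc_curve(F, cb, shape, truth, radius = 2)
  expect_equal(roc$auroc, 1)
  expect_true(any(roc$curve$fpr == 0 & roc$curve$tpr_strict == 1))
  # detection-only rate dominates the strict rate everywhere
  expect_true(all(roc$curve$tpr_detection >= roc$curve$tpr_strict - 1e-12))
  expect_error(roc_curve(F, cb, shape, truth[0, ]), "empty")
})

test_that("pure-noise densities score near chance", {
  cb <- balanced_codebook(4, 2, 4, seed = 3)
  shape <- c(12L, 12L)
  cfg <- sim_config(R = 4, C = 2, J = 4, spatial_shape = shape, n_spots = 5L,
                    seed = 31L)
  truth <- simulate_truth(cfg, cb)
  aurocs <- vapply(1:20, function(seed) {
    F <- withr::with_seed(seed, matrix(runif(prod(shape) * 4), prod(shape), 4))
    roc_curve(F, cb, shape, truth, radius = 1)$auroc
  }, numeric(1))
  # noise should not look like signal: clearly below a strong detector
  expect_lt(mean(aurocs), 0.5)
})

test_that("the full pipeline separates signal from noise almost perfectly", {
  sim <- ref_sim()
  fit <- ref_fit()
  roc <- roc_curve(fit, truth = sim$truth, radius = 2)
  expect_gte(roc$auroc, 0.95)
  expect_true(all(roc$curve$tpr_detection >= roc$curve$tpr_strict - 1e-12))
})
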