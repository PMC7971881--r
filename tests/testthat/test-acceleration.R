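ref_stack_4x4 <- function() {
  withr::with_seed(31, image_stack(matrix(runif(16 * 4), 16, 4), R = 2, C = 2,
                                   spatial_shape = c(4L, 4L)))
}

test_that("block-mean downsampling matches explicit block means", {
  X <- ref_stack_4x4()
  down <- downsample_stack(X, 2)
  expect_equal(down$spatial_shape, c(2L, 2L))
  for (k in seq_len(ncol(X$data))) {
    fr <- demixr:::unflatten_spatial(X$data[, k], c(4L, 4L))
    want <- matrix(c(mean(fr[1:2, 1:2]), mean(fr[1:2, 3:4]),
                     mean(fr[3:4, 1:2]), mean(fr[3:4, 3:4])),
                   2, 2, byrow = TRUE)
    expect_equal(demixr:::unflatten_spatial(down$data[, k], c(2L, 2L)), want)
  }
  # factor 1 is the identity; constants stay constant; edge blocks average
  expect_equal(downsample_stack(X, 1)$data, X$data)
  const <- image_stack(matrix(3, 25, 4), R = 2, C = 2,
                       spatial_shape = c(5L, 5L))
  d3 <- downsample_stack(const, 2)
  expect_true(all(d3$data == 3))
  expect_error(downsample_stack(const, 9), "factor")
})

test_that("upsampling preserves total density and round-trips mass", {
  Fc <- withr::with_seed(5, matrix(runif(4 * 3), 4, 3))
  Ff <- upsample_density(Fc, 2, c(4L, 4L))
  expect_equal(colSums(Ff), colSums(Fc), tolerance = 1e-12)
  expect_equal(upsample_density(Fc, 1, c(2L, 2L)), Fc)
  expect_error(upsample_density(Fc, 3, c(10L, 10L)), "coarse")
  # a bright rolony lands in the correct factor-block after the round trip
  shape <- c(8L, 8L)
  F <- matrix(0, 64, 1)
  v <- coords_to_voxel(matrix(c(5L, 2L), 1), shape) + 1L
  F[v, 1] <- 4
  cb <- random_codebook(2, 2, 1, seed = 3)
  p <- default_params(64, 1, 2, 2); p$F <- F
  X <- forward_model(model_params(F, p$a, p$b, p$alpha, p$phi, p$rho),
                     psf_gaussian(0), cb, shape)
  down <- downsample_stack(X, 2)
  # the coarse voxel holding the mass maps back onto the same block
  up <- upsample_density(matrix(down$data[, 1], ncol = 1), 2, shape)
  block <- voxel_to_coords(which.max(up[, 1]) - 1L, shape) %/% 2L
  expect_equal(as.vector(block), as.vector(c(5L, 2L) %/% 2L))
})

test_that("barcode sparsification retains active and unused barcodes", {
  cb <- codebook(local({
    B <- array(0, c(2, 2, 4)); B[1, 1, ] <- 1; B[2, 2, ] <- 1; B
  }), unused = c(FALSE, FALSE, FALSE, TRUE))
  Fc <- matrix(0, 9, 4)
  Fc[3, 1] <- 0.5; Fc[7, 3] <- 1e-9
  expect_equal(sparsify_barcodes(Fc, cb, tol = 1e-6), c(1L, 4L))
  expect_equal(sparsify_barcodes(Fc, cb, tol = 0), c(1L, 3L, 4L))
  expect_equal(sparsify_barcodes(matrix(0, 9, 4), cb), 4L)
  Fpos <- matrix(1, 9, 4)
  expect_equal(sparsify_barcodes(Fpos, cb, tol = 0), 1:4)
  # direct max-scan oracle on a random instance
  Fr <- withr::with_seed(8, matrix(runif(36) - 0.3, 9, 4))
  Fr <- pmax(Fr, 0)
  tol <- 0.2
  oracle <- sort(union(which(apply(Fr, 2, max) > tol), 4L))
  expect_equal(sparsify_barcodes(Fr, cb, tol), oracle)
})

test_that("patch grids tile the grid exactly with clipped halos", {
  pg <- patch_grid(c(10L, 7L), c(4L, 3L), halo = 2L)
  covered <- integer(0)
  for (i in seq_len(nrow(pg))) {
    sel <- demixr:::window_voxels(pg$core_lo[[i]], pg$core_hi[[i]], c(10L, 7L))
    covered <- c(covered, sel)
    pad_lo <- pg$pad_lo[[i]]; pad_hi <- pg$pad_hi[[i]]
    expect_true(all(pad_lo >= 0) && all(pad_hi <= c(9L, 6L)))
    expect_true(all(pad_lo <= pg$core_lo[[i]]))
    expect_true(all(pad_hi >= pg$core_hi[[i]]))
  }
  expect_equal(sort(covered), 0:69)       # disjoint and covering
  expect_equal(anyDuplicated(covered), 0L)
})

test_that("degenerate acceleration reproduces the plain fit exactly", {
  cb <- random_codebook(4, 2, 3, seed = 14)
  shape <- c(16L, 16L); M <- prod(shape)
  p <- default_params(M, 3, 4, 2)
  p$F[60, 1] <- 2; p$F[130, 3] <- 1.5
  psf <- psf_gaussian(1)
  X0 <- forward_model(p, psf, cb, shape)
  noise <- withr::with_seed(3, matrix(rnorm(length(X0$data), 0, 0.005),
                                      nrow(X0$data)))
  X <- image_stack(pmax(X0$data + noise, 0), R = 4, C = 2,
                   spatial_shape = shape)
  cfg <- fit_config(max_iters = 15, unexplained_fraction_target = 0.3)
  plain <- fit_densities(X, cb, psf, cfg)
  accel <- fit_accelerated(X, cb, psf, cfg,
                           patches = patch_grid(shape, shape, halo = 0L),
                           factor = 1, tol = 0)
  expect_lte(max(abs(plain$params$F - accel$params$F)), 1e-9)
})

test_that("a rolony straddling a patch border is called exactly once", {
  # well-separated codes (6 rounds, 3 channels, pairwise distance >= 3) so
  # demixing is sharp and the only question is patch stitching
  cb <- augment_codebook(codebook(array(0, c(6, 3, 0))), 4L,
                         min_round_diff = 3L, seed = 2L)
  cb$unused <- c(FALSE, FALSE, FALSE, TRUE)
  cb$gene_names <- c("g1", "g2", "g3", "unused1")
  shape <- c(20L, 20L); M <- prod(shape)
  p <- default_params(M, n_barcodes(cb), 6, 3)
  border_voxel <- coords_to_voxel(matrix(c(9L, 10L), 1), shape) + 1L
  p$F[border_voxel, 2] <- 3
  psf <- psf_gaussian(1)
  X <- forward_model(p, psf, cb, shape)
  cfg <- fit_config(max_iters = 25, unexplained_fraction_target = 0.02)
  accel <- fit_accelerated(X, cb, psf, cfg,
                           patches = patch_grid(shape, c(10L, 10L), halo = 4L),
                           factor = 1, tol = 0)
  spots <- call_spots(accel)
  passing <- spots[spots$passes_threshold, ]
  expect_equal(nrow(passing), 1L)
  expect_equal(passing$barcode_index, 1L)
  expect_lte(max(abs(c(passing$y, passing$x) - c(9L, 10L))), 1L)
})
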