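test_that("noise threshold is the targeted fraction of frame-centered variance", {
  tp <- tiny_problem()
  cfg <- fit_config(unexplained_fraction_target = 0.2)
  centered <- sweep(tp$X$data, 2, colMeans(tp$X$data))
  expect_equal(select_noise_threshold(tp$X, cfg), 0.2 * sum(centered^2))
  cfg1 <- fit_config(unexplained_fraction_target = 1 - 1e-12)
  expect_equal(select_noise_threshold(tp$X, cfg1), sum(centered^2),
               tolerance = 1e-9)
  const <- image_stack(matrix(3, tp$M, tp$R * tp$C), R = tp$R, C = tp$C,
                       spatial_shape = tp$shape)
  expect_equal(select_noise_threshold(const, cfg), 0)
})

test_that("normalize_scale canonicalizes without changing the model", {
  tp <- tiny_problem()
  psf <- psf_gaussian(1)
  p <- tp$params
  n1 <- normalize_scale(p)
  expect_equal(sum(n1$alpha), 1)
  expect_equal(diag(n1$phi), rep(1, tp$C))
  # reconstruction is unchanged
  r0 <- forward_model(p, psf, tp$cb, tp$shape)
  r1 <- forward_model(n1, psf, tp$cb, tp$shape)
  expect_equal(r1$data, r0$data, tolerance = 1e-12)
  # idempotent
  n2 <- normalize_scale(n1)
  expect_equal(n2$F, n1$F, tolerance = 1e-12)
  expect_equal(n2$alpha, n1$alpha, tolerance = 1e-12)
  # the rescaled model maps to the same canonical point
  p2 <- model_params(4 * p$F, p$a, p$b, p$alpha / 2, p$phi / 2, p$rho)
  n3 <- normalize_scale(p2)
  expect_equal(n3$F, n1$F, tolerance = 1e-9)
  expect_equal(n3$alpha, n1$alpha, tolerance = 1e-9)
  expect_equal(n3$phi, n1$phi, tolerance = 1e-9)
  bad <- p; bad$alpha[] <- 0
  expect_error(normalize_scale(model_params(p$F, p$a, p$b, bad$alpha,
                                            p$phi, p$rho)), "alpha")
})

test_that("step sizes bound the block Lipschitz constants", {
  # single barcode active in one (r, c), identity PSF, unit alpha:
  # the F-block operator is a 0/1 indicator, Lipschitz constant 2
  B <- array(0, c(2, 2, 1)); B[1, 1, 1] <- 1
  cb <- codebook(B)
  shape <- c(3L, 3L)
  X <- image_stack(matrix(0.5, 9, 4), R = 2, C = 2, spatial_shape = shape)
  p <- default_params(9, 1, 2, 2)
  steps <- estimate_step_sizes(X, cb, psf_gaussian(0), params = p)
  lipF <- steps$lipschitz[steps$block == "F"]
  expect_lt(abs(lipF - 2) / 2, 0.05)
  expect_true(all(steps$step_size > 0))

  # scaling X leaves step sizes unchanged (operator-only quantities)
  X2 <- image_stack(X$data * 7, R = 2, C = 2, spatial_shape = shape)
  steps2 <- estimate_step_sizes(X2, cb, psf_gaussian(0), params = p)
  expect_equal(steps2$lipschitz, steps$lipschitz, tolerance = 1e-12)

  # power-iteration estimate upper-bounds the dense-SVD square on random
  # tiny instances
  for (seed in 1:3) {
    tp <- tiny_problem(R = 3, C = 2, J = 2, shape = c(3, 3), seed = seed)
    psf <- psf_gaussian(0.6)
    st <- demixr:::fit_state(tp$X, tp$cb, psf, tp$params)
    est <- demixr:::block_steps(st, iters = 60)$lipschitz$F / 2
    K <- oracle_psf_matrix(psf, c(3, 3))
    Gmat <- demixr:::gain_matrix(gain_tensor(
      phase_codebook(tp$cb, tp$params$rho), tp$params$alpha, tp$params$phi))
    dense <- kronecker(Gmat, K)   # vec(K F G^T) = (G kron K) vec(F)
    s2 <- max(svd(dense, nu = 0, nv = 0)$d)^2
    expect_gte(est, s2 - 1e-6)
    expect_lt(est, s2 * 1.1)
  }
  expect_error(
    estimate_step_sizes(X, codebook(array(0, c(2, 2, 0))), psf_gaussian(0)),
    "degenerate"
  )
})

test_that("fit handles degenerate stacks per contract", {
  cb <- random_codebook(3, 2, 2, seed = 2)
  zero <- image_stack(matrix(0, 16, 6), R = 3, C = 2, spatial_shape = c(4, 4))
  expect_warning(fit0 <- fit_densities(zero, cb, psf_gaussian(1)), "all zeros")
  expect_true(all(fit0$params$F == 0))
  expect_true(all(fit0$params$a == 0))
  expect_true(all(fit0$params$b == 0))
  bad <- zero; bad$data[1, 1] <- NaN
  expect_error(fit_densities(bad, cb, psf_gaussian(1)), "NaN")
  wrong <- image_stack(matrix(1, 16, 4), R = 2, C = 2, spatial_shape = c(4, 4))
  expect_error(fit_densities(wrong, cb, psf_gaussian(1)), "rounds/channels")
})

test_that("a noiseless single rolony is recovered with little off-support mass", {
  cb <- random_codebook(5, 3, 3, seed = 2)
  shape <- c(12L, 12L); M <- prod(shape)
  p <- default_params(M, 3, 5, 3)
  m0 <- coords_to_voxel(matrix(c(5L, 6L), 1), shape) + 1L
  p$F[m0, 2] <- 3
  psf <- psf_gaussian(0)
  X <- forward_model(p, psf, cb, shape)
  fit <- fit_densities(X, cb, psf,
                       fit_config(max_iters = 60,
                                  unexplained_fraction_target = 0.05))
  Fh <- fit$params$F
  expect_equal(as.vector(arrayInd(which.max(Fh), dim(Fh))), c(m0, 2L))
  expect_lt(1 - Fh[m0, 2] / sum(Fh), 0.05)
})

test_that("two overlapping rolonies of different barcodes are demixed", {
  cb <- random_codebook(6, 3, 4, seed = 4)
  shape <- c(24L, 24L); M <- prod(shape)
  p <- default_params(M, 4, 6, 3)
  v1 <- coords_to_voxel(matrix(c(11L, 11L), 1), shape) + 1L
  v2 <- coords_to_voxel(matrix(c(12L, 12L), 1), shape) + 1L
  p$F[v1, 1] <- 3; p$F[v2, 3] <- 2.5
  psf <- psf_gaussian(1.3)
  X0 <- forward_model(p, psf, cb, shape)
  noise <- withr::with_seed(9, matrix(rnorm(length(X0$data), 0, 0.01),
                                      nrow(X0$data)))
  X <- image_stack(pmax(X0$data + noise, 0), R = 6, C = 3,
                   spatial_shape = shape)
  fit <- fit_densities(X, cb, psf,
                       fit_config(max_iters = 40,
                                  unexplained_fraction_target = 0.3))
  top <- arrayInd(order(fit$params$F, decreasing = TRUE)[1:2],
                  dim(fit$params$F))
  found <- apply(top, 1, function(row) {
    co <- voxel_to_coords(row[1] - 1L, shape)
    list(coords = co, j = row[2])
  })
  has <- function(target_v, target_j) {
    any(vapply(found, function(f) {
      f$j == target_j && all(abs(f$coords - voxel_to_coords(target_v - 1L, shape)) <= 1)
    }, logical(1)))
  }
  expect_true(has(v1, 1))
  expect_true(has(v2, 3))
})

test_that("the optimization contract holds on the reference simulation", {
  fit <- ref_fit()
  traj <- tidy(fit)
  # penalized objective monotone non-increasing across outer iterations
  expect_true(all(diff(traj$objective) <= 1e-9 * traj$objective[1]))
  # non-negativity after every projection (final parameters)
  p <- fit$params
  expect_true(all(p$F >= 0) && all(p$a >= 0) && all(p$b >= 0) &&
                all(p$alpha >= 0))
  expect_true(all(p$phi >= 0 & p$phi <= 1 + 1e-12))
  expect_true(all(p$rho >= 0 & p$rho <= 1))
  # constraint met at convergence
  expect_true(fit$converged)
  expect_lte(fit$reconstruction_loss, fit$omega * (1 + 1e-6))
  # glance is consistent
  g <- glance(fit)
  expect_equal(g$reconstruction_loss, fit$reconstruction_loss)
})

test_that("fitted gains track the simulation truth", {
  sim <- ref_sim()
  fit <- ref_fit()
  a_hat <- as.vector(fit$params$alpha)
  a_true <- as.vector(sim$alpha_true)
  expect_gte(stats::cor(a_hat, a_true), 0.95)
})

test_that("fits are scale-canonical in the input intensity", {
  cb <- random_codebook(4, 2, 2, seed = 6)
  shape <- c(10L, 10L); M <- prod(shape)
  p <- default_params(M, 2, 4, 2)
  p$F[c(23, 71), c(1, 2)] <- c(2, 3)
  psf <- psf_gaussian(1)
  X <- forward_model(p, psf, cb, shape)
  cfg <- fit_config(max_iters = 30, unexplained_fraction_target = 0.05)
  f1 <- fit_densities(X, cb, psf, cfg)
  c_scale <- 3.7
  X2 <- image_stack(X$data * c_scale, R = 4, C = 2, spatial_shape = shape)
  f2 <- fit_densities(X2, cb, psf, cfg)
  # omega scales by c^2 automatically; canonical F scales by c
  expect_equal(f2$omega, f1$omega * c_scale^2, tolerance = 1e-9)
  expect_equal(f2$params$F, f1$params$F * c_scale, tolerance = 0.05 * max(f1$params$F) * c_scale)
})
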