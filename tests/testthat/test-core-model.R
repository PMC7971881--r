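test_that("phasing recursion matches its closed form", {
  # rho = 0 collapses Z to B
  cb <- random_codebook(4, 3, 3, seed = 1)
  expect_equal(phase_codebook(cb, rep(0, 3)), cb$B + 0)

  # a single round-1 activation decays geometrically with the channel's rho
  B <- array(0, c(5, 2, 1)); B[1, 1, 1] <- 1
  B[, 2, 1] <- 1  # keep the codebook valid in channel 2 (not under test)
  Z <- phase_codebook(B, c(0.5, 0))
  expect_equal(Z[, 1, 1], 0.5^(0:4))
  Zc <- phase_codebook(B, c(1, 0))
  expect_equal(Zc[, 1, 1], rep(1, 5))

  # Z >= B for any rho in [0, 1]
  tp <- tiny_problem()
  for (rho1 in c(0, 0.3, 1)) {
    Z <- phase_codebook(tp$cb, rep(rho1, tp$C))
    expect_true(all(Z >= tp$cb$B))
  }
  expect_error(phase_codebook(tp$cb, c(1.5, 0)), "channel 1")
})

test_that("gain tensor matches the triple-loop oracle and is bilinear", {
  tp <- tiny_problem(R = 3, C = 2, J = 2)
  Z <- phase_codebook(tp$cb, tp$params$rho)
  G <- gain_tensor(Z, tp$params$alpha, tp$params$phi)
  Go <- array(0, dim(Z))
  for (r in 1:3) for (cc in 1:2) for (j in 1:2) {
    Go[r, cc, j] <- tp$params$alpha[r, cc] * sum(tp$params$phi[cc, ] * Z[r, , j])
  }
  expect_equal(G, Go, tolerance = 1e-14)

  # identity phi, unit alpha, rho = 0 gives back B
  expect_equal(gain_tensor(tp$cb$B + 0, matrix(1, 3, 2), diag(2)), tp$cb$B + 0)
  # halving alpha and phi quarters G
  G4 <- gain_tensor(Z, tp$params$alpha / 2, tp$params$phi / 2)
  expect_equal(G4, G / 4, tolerance = 1e-14)
  expect_error(gain_tensor(Z, matrix(1, 4, 2), diag(2)), "dimensions")
})

test_that("forward model agrees with the brute-force loop oracle", {
  tp <- tiny_problem(R = 3, C = 2, J = 2, shape = c(4, 4))
  psf <- psf_gaussian(0.9)
  rec <- forward_model(tp$params, psf, tp$cb, tp$shape)
  oracle <- oracle_reconstruction(tp$params, psf, tp$cb, tp$shape)
  for (r in 1:tp$R) for (cc in 1:tp$C) {
    expect_equal(rec$data[, demixr:::rc_index(r, cc, tp$C)], oracle[, r, cc],
                 tolerance = 1e-12)
  }
})

test_that("forward model handles degenerate inputs per contract", {
  tp <- tiny_problem()
  p0 <- default_params(tp$M, tp$J, tp$R, tp$C)
  p0$a <- runif(tp$M); p0$b <- matrix(runif(tp$R * tp$C), tp$R, tp$C)
  p0 <- model_params(p0$F, p0$a, p0$b, p0$alpha, p0$phi, p0$rho)
  rec <- forward_model(p0, psf_gaussian(1), tp$cb, tp$shape)
  # F = 0: reconstruction is a + b
  for (r in 1:tp$R) for (cc in 1:tp$C) {
    expect_equal(rec$data[, demixr:::rc_index(r, cc, tp$C)],
                 p0$a + p0$b[r, cc])
  }
  # single rolony, identity optics: v * B at the voxel, zero elsewhere
  p1 <- default_params(tp$M, tp$J, tp$R, tp$C)
  p1$F[5, 2] <- 2.2
  rec1 <- forward_model(p1, psf_gaussian(0), tp$cb, tp$shape)
  for (r in 1:tp$R) for (cc in 1:tp$C) {
    want <- rep(0, tp$M); want[5] <- 2.2 * tp$cb$B[r, cc, 2]
    expect_equal(rec1$data[, demixr:::rc_index(r, cc, tp$C)], want)
  }
  expect_error(forward_model(p1, psf_gaussian(1), tp$cb, c(5, 5)),
               "spatial_shape")
})

test_that("identity-PSF forward model equals the direct mixture", {
  # identity PSF, phi = I, rho = 0: X = F alpha B + a + b, checked on M <= 64
  tp <- tiny_problem(R = 4, C = 3, J = 3, shape = c(8, 8))
  p <- tp$params
  p <- model_params(p$F, p$a, p$b, p$alpha, diag(tp$C), rep(0, tp$C))
  rec <- forward_model(p, psf_gaussian(0), tp$cb, tp$shape)
  for (r in 1:tp$R) for (cc in 1:tp$C) {
    direct <- p$a + p$b[r, cc] +
      p$alpha[r, cc] * as.vector(p$F %*% tp$cb$B[r, cc, ])
    expect_equal(rec$data[, demixr:::rc_index(r, cc, tp$C)], direct,
                 tolerance = 1e-12)
  }
})

test_that("losses match elementwise oracles", {
  tp <- tiny_problem(shape = c(4, 4))
  psf <- psf_gaussian(0.7)
  rec <- forward_model(tp$params, psf, tp$cb, tp$shape)
  expect_equal(reconstruction_loss(tp$X, rec), sum((tp$X$data - rec$data)^2))
  expect_equal(reconstruction_loss(rec, rec), 0)
  ones <- image_stack(matrix(1, tp$M, tp$R * tp$C), R = tp$R, C = tp$C,
                      spatial_shape = tp$shape)
  zeros <- image_stack(matrix(0, tp$M, tp$R * tp$C), R = tp$R, C = tp$C,
                       spatial_shape = tp$shape)
  expect_equal(reconstruction_loss(ones, zeros), tp$M * tp$R * tp$C)

  Z <- phase_codebook(tp$cb, tp$params$rho)
  sl <- sparsity_loss(tp$params, Z)
  slo <- 0
  for (m in 1:tp$M) for (r in 1:tp$R) for (cc in 1:tp$C) {
    for (cp in 1:tp$C) for (j in 1:tp$J) {
      slo <- slo + tp$params$alpha[r, cc] * tp$params$F[m, j] *
        tp$params$phi[cc, cp] * Z[r, cp, j]
    }
  }
  expect_equal(sl, slo, tolerance = 1e-12)
  # linear in F; zero at F = 0
  p2 <- tp$params; p2$F <- 2 * p2$F
  expect_equal(sparsity_loss(p2, Z), 2 * sl, tolerance = 1e-12)
  p0 <- tp$params; p0$F[] <- 0
  expect_equal(sparsity_loss(p0, Z), 0)
})

test_that("the overall-scale rescaling leaves model and losses unchanged", {
  tp <- tiny_problem(shape = c(5, 4))
  psf <- psf_gaussian(1.1)
  p <- tp$params
  p2 <- model_params(F = 4 * p$F, a = p$a, b = p$b, alpha = p$alpha / 2,
                     phi = p$phi / 2, rho = p$rho)
  r1 <- forward_model(p, psf, tp$cb, tp$shape)
  r2 <- forward_model(p2, psf, tp$cb, tp$shape)
  expect_equal(r1$data, r2$data, tolerance = 1e-9)
  expect_equal(reconstruction_loss(tp$X, r1), reconstruction_loss(tp$X, r2),
               tolerance = 1e-9)
  Z <- phase_codebook(tp$cb, p$rho)
  expect_equal(sparsity_loss(p, Z), sparsity_loss(p2, Z), tolerance = 1e-9)
})
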