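# Sparse non-negative regression -----------------------------------------------
#
# The estimation problem: minimize the linear sparsity penalty over all
# non-negative parameters, subject to the squared reconstruction loss staying
# below a noise threshold omega. We solve the penalized (Lagrangian) surrogate
#
#   minimize  L_reconstruction + lambda * L_sparsity   over params >= 0
#
# by block projected gradient descent (blocks: F, a, b, alpha, phi, rho) with
# step sizes set from power-iteration bounds on each block's operator norm,
# and adjust lambda by bisection so the solution's reconstruction loss lands
# just below omega. Every block update carries a backtracking safeguard
# (revert and halve the step on any objective increase), which makes the
# objective monotone non-increasing by construction; this matters for rho,
# whose geometric recursion makes the model nonlinear in that block.

#' Optimization settings
#'
#' @param max_iters Maximum outer (full-cycle) iterations per penalized solve.
#' @param inner_iters_per_block Gradient steps taken on the density block `F`
#'   per outer iteration (the remaining blocks take one step each).
#' @param tol_rel_objective Relative objective-change tolerance for early
#'   stopping.
#' @param unexplained_fraction_target Fraction of the per-frame-centered total
#'   sum of squares used as the noise threshold omega (see
#'   [select_noise_threshold()]).
#' @param lagrange_bisection_iters Maximum penalized solves spent locating the
#'   Lagrange multiplier.
#' @param seed Integer seed (used only for power-iteration start vectors).
#' @param learn_phi,learn_rho Update the cross-talk matrix / phasing factors?
#'   The model works without them on well-behaved data; they capture
#'   channel bleed-through and chemical carry-over when present.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(max_iters = 100L,
                       inner_iters_per_block = 5L,
                       tol_rel_objective = 1e-6,
                       unexplained_fraction_target = 0.1,
                       lagrange_bisection_iters = 8L,
                       seed = 1L,
                       learn_phi = TRUE,
                       learn_rho = TRUE) {
  stopifnot(max_iters >= 1L, inner_iters_per_block >= 1L,
            tol_rel_objective > 0,
            unexplained_fraction_target > 0, unexplained_fraction_target < 1,
            lagrange_bisection_iters >= 1L)
  structure(list(max_iters = as.integer(max_iters),
                 inner_iters_per_block = as.integer(inner_iters_per_block),
                 tol_rel_objective = tol_rel_objective,
                 unexplained_fraction_target = unexplained_fraction_target,
                 lagrange_bisection_iters = as.integer(lagrange_bisection_iters),
                 seed = as.integer(seed),
                 learn_phi = isTRUE(learn_phi),
                 learn_rho = isTRUE(learn_rho)),
            class = "fit_config")
}

#' Automatic noise threshold
#'
#' omega = `unexplained_fraction_target` times the total sum of squares of the
#' stack after centering each (round, channel) frame at its mean — the
#' variance a background-plus-offset model cannot explain.
#'
#' @param X An `image_stack`.
#' @param config A `fit_config` (only the target fraction is used).
#' @return A non-negative scalar omega.
#' @export
select_noise_threshold <- function(X, config = fit_config()) {
  stopifnot(inherits(X, "image_stack"))
  centered <- sweep(X$data, 2L, colMeans(X$data), `-`)
  config$unexplained_fraction_target * sum(centered^2)
}

# generic power iteration on op/adjoint closures; returns sigma_max^2 bound
power_iter_sq <- function(op, adj, n, iters = 30L, seed = 1L, tol = 1e-12) {
  v <- withr::with_seed(seed, stats::rnorm(n))
  v <- v / sqrt(sum(v^2))
  est <- 0
  for (k in seq_len(max(iters, 10L))) {
    w <- adj(op(v))
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    new_est <- sum(v * w)              # Rayleigh quotient for (A^T A)
    v <- w / nw
    if (k >= 10L && abs(new_est - est) <= tol * max(new_est, 1)) {
      est <- new_est
      break
    }
    est <- new_est
  }
  est * (1 + 1e-3)                     # small safety margin toward an upper bound
}

#' Automatic per-block step sizes
#'
#' For each parameter block the gradient of the reconstruction loss is
#' Lipschitz with constant twice the squared operator norm of the block's
#' linear map into image space; the step size is the reciprocal of a
#' power-iteration upper bound on that constant. Evaluated at `params`
#' (defaults to the optimizer's initialization).
#'
#' @param X An `image_stack`.
#' @param cb A `codebook`.
#' @param psf A `psf`.
#' @param params Optional `model_params` at which to evaluate the operators.
#' @param iters Power iterations per block (at least 10).
#' @param seed Seed for power-iteration start vectors.
#' @return A tibble with columns `block`, `lipschitz`, `step_size`.
#' @export
estimate_step_sizes <- function(X, cb, psf, params = NULL, iters = 30L, seed = 1L) {
  stopifnot(inherits(X, "image_stack"), inherits(cb, "codebook"))
  if (all(cb$B == 0) || n_barcodes(cb) == 0L) {
    stop("degenerate (all-zero) codebook: no operator to scale against", call. = FALSE)
  }
  st <- fit_state(X, cb, psf,
                  params %||% init_params(X, cb))
  steps <- block_steps(st, iters = iters, seed = seed,
                       learn_phi = TRUE, learn_rho = TRUE)
  tibble::tibble(
    block = names(steps$lipschitz),
    lipschitz = unlist(steps$lipschitz),
    step_size = unlist(steps$step)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- internal optimizer state -------------------------------------------------

init_params <- function(X, cb) {
  M <- n_voxels(X); J <- n_barcodes(cb); R <- X$R; C <- X$C
  a0 <- apply(X$data, 1L, min)
  resid <- sweep(X$data, 1L, a0, `-`)
  b0 <- rc_unvec(apply(resid, 2L, min), R, C)
  model_params(F = matrix(0, M, J), a = a0, b = b0,
               alpha = matrix(1 / (R * C), R, C), phi = diag(C),
               rho = rep(0, C))
}

fit_state <- function(X, cb, psf, params) {
  st <- new.env(parent = emptyenv())
  st$X <- X$data
  st$shape <- X$spatial_shape
  st$R <- X$R; st$C <- X$C; st$J <- n_barcodes(cb)
  st$M <- n_voxels(X)
  st$B <- cb$B
  st$ops <- psf_operators(psf, X$spatial_shape)
  st$F <- params$F; st$a <- params$a; st$b <- params$b
  st$alpha <- params$alpha; st$phi <- params$phi; st$rho <- params$rho
  refresh_code(st)
  st$W <- convolve_density(st$F, st$shape, st$ops)
  refresh_A(st)
  st
}

# Z, H depend on (rho, phi); G additionally on alpha. Split so alpha-only
# updates skip the phasing recursion.
refresh_code <- function(st) {
  st$Z <- phase_codebook(st$B, st$rho)
  st$H <- apply_along_dim(st$Z, 2L, st$phi)
  st$Hmat <- gain_matrix(st$H)
  refresh_gain(st)
}

refresh_gain <- function(st) {
  st$G <- sweep(st$H, 1:2, st$alpha, `*`)
  st$Gmat <- gain_matrix(st$G)
  st$tGmat <- t(st$Gmat)
  st$s <- colSums(st$Gmat)
  invisible(st)
}

refresh_A <- function(st) {
  if (is.null(st$bg)) refresh_bg(st)
  st$A <- st$W %*% st$tGmat + st$bg
  invisible(st)
}

# cached background image a[m] + b[r,c]; recompute when a or b changes
refresh_bg <- function(st) {
  st$bg <- matrix(rc_vec(st$b), st$M, st$R * st$C, byrow = TRUE) + st$a
  invisible(st)
}

state_params <- function(st) {
  model_params(F = st$F, a = st$a, b = st$b, alpha = st$alpha,
               phi = st$phi, rho = st$rho)
}

objective <- function(st, lambda) {
  recon <- sum((st$A - st$X)^2)
  spars <- sum(colSums(st$F) * st$s)
  list(recon = recon, spars = spars, obj = recon + lambda * spars)
}

# phi-type contraction: given T (RC x J), return C x C matrix
#   out[c, c'] = sum_{r, j} T[(r,c), j] * alpha[r, c] * Z[r, c', j]
contract_phi <- function(st, Tmat) {
  C <- st$C; R <- st$R; J <- st$J
  arrT <- array(Tmat, dim = c(C, R, J))
  U <- arrT * as.vector(t(st$alpha))            # recycles (C, R) over j
  Umat <- matrix(U, C, R * J)
  Zmat <- matrix(aperm(st$Z, c(1L, 3L, 2L)), R * J, C)
  Umat %*% Zmat
}

# rho-type contraction: given T (RC x J) and derivative tensor D (R, C, J),
#   out[c] = sum_{r, ch, j} T[(r,ch), j] * alpha[r, ch] * phi[ch, c] * D[r, c, j]
contract_rho <- function(st, Tmat, D) {
  C <- st$C; R <- st$R; J <- st$J
  arrT <- array(Tmat, dim = c(C, R, J))
  U <- arrT * as.vector(t(st$alpha))
  V <- apply_along_dim(U, 1L, t(st$phi))        # contract channel index with phi
  Dperm <- aperm(D, c(2L, 1L, 3L))
  rowSums(matrix(V * Dperm, C))
}

# dZ/drho (one column per channel's own factor): D[r,c,j]
rho_derivative <- function(st) {
  d <- dim(st$Z)
  D <- array(0, dim = d)
  if (d[1L] > 1L) {
    for (r in 2:d[1L]) {
      D[r, , ] <- sweep(array(D[r - 1L, , ], d[2:3]), 1L, st$rho, `*`) +
        array(st$Z[r - 1L, , ], d[2:3])
    }
  }
  D
}

block_steps <- function(st, iters = 30L, seed = 1L, learn_phi = TRUE,
                        learn_rho = TRUE) {
  margin <- function(x) 2 * x            # Lipschitz = 2 * sigma_max^2
  # F block factors as (G kron K): sigma = sigma(K) * sigma(G)
  sig_K2 <- prod(vapply(seq_along(st$ops), function(k) {
    Mk <- st$ops[[k]]
    power_iter_sq(function(v) Mk %*% v, function(v) t(Mk) %*% v,
                  nrow(Mk), iters, seed + k)
  }, numeric(1)))
  sig_G2 <- power_iter_sq(function(v) st$Gmat %*% v,
                          function(v) t(st$Gmat) %*% v,
                          st$J, iters, seed + 11L)
  RC <- st$R * st$C
  lip <- list(
    F = margin(sig_K2 * sig_G2),
    # a maps to a constant image per frame, b to a constant image per voxel;
    # their operators are rank-structured and power iteration is immediate
    a = margin(power_iter_sq(function(v) rep(v, RC),
                             function(v) rowSums(matrix(v, st$M, RC)),
                             st$M, 10L, seed + 14L)),
    b = margin(power_iter_sq(function(v) rep(v, each = st$M),
                             function(v) colSums(matrix(v, st$M, RC)),
                             RC, 10L, seed + 15L))
  )
  # alpha: diagonal operator, one image column per (r,c)
  Q <- st$W %*% t(st$Hmat)
  lip$alpha <- margin(max(colSums(Q^2)))
  if (learn_phi) {
    op <- function(v) {
      Delta <- matrix(v, st$C, st$C)
      Hd <- apply_along_dim(st$Z, 2L, Delta)
      Gd <- sweep(Hd, 1:2, st$alpha, `*`)
      as.vector(st$W %*% t(gain_matrix(Gd)))
    }
    adj <- function(v) {
      Y <- matrix(v, st$M, st$R * st$C)
      as.vector(contract_phi(st, t(Y) %*% st$W))
    }
    lip$phi <- margin(power_iter_sq(op, adj, st$C^2, iters, seed + 12L))
  }
  if (learn_rho) {
    D <- rho_derivative(st)
    op <- function(v) {
      Zd <- sweep(D, 2L, v, `*`)
      Hd <- apply_along_dim(Zd, 2L, st$phi)
      Gd <- sweep(Hd, 1:2, st$alpha, `*`)
      as.vector(st$W %*% t(gain_matrix(Gd)))
    }
    adj <- function(v) {
      Y <- matrix(v, st$M, st$R * st$C)
      contract_rho(st, t(Y) %*% st$W, D)
    }
    lip$rho <- margin(power_iter_sq(op, adj, st$C, iters, seed + 13L))
  }
  list(lipschitz = lip,
       step = lapply(lip, function(L) if (L > 0) 1 / L else 1))
}

# one safeguarded block update; `apply_step(step)` mutates st and refreshes
# caches; `restore()` reverts to the pre-update values. Halve on increase.
safeguard <- function(st, lambda, step, apply_step, restore, max_halvings = 4L) {
  before <- objective(st, lambda)$obj
  for (k in 0:max_halvings) {
    apply_step(step / 2^k)
    after <- objective(st, lambda)$obj
    if (after <= before * (1 + 1e-12)) return(invisible(TRUE))
    restore()
  }
  invisible(FALSE)
}

# squared spectral norm of the blur operator (product over separable factors)
psf_norm_sq <- function(ops) {
  prod(vapply(ops, function(Mk) max(svd(Mk, nu = 0, nv = 0)$d)^2, numeric(1)))
}

# largest step multiplier keeping x + t*d inside [lo, hi]; d is the projected
# direction so t = 1 is always feasible
max_feasible_t <- function(x, d, lo = 0, hi = Inf) {
  t_max <- Inf
  neg <- d < 0
  if (any(neg)) t_max <- min(t_max, min((x[neg] - lo) / -d[neg]))
  if (is.finite(hi)) {
    pos <- d > 0
    if (any(pos)) t_max <- min(t_max, min((hi - x[pos]) / d[pos]))
  }
  max(t_max, 1)
}

# exact minimizing step along direction with image-space increment dA and
# sparsity increment sp_d:  obj(t) = ||E + t dA||^2 + lambda (sp0 + t sp_d)
exact_t <- function(E, dA, sp_d, lambda, t_max) {
  den <- sum(dA * dA)
  if (den == 0) return(0)
  t_opt <- -(2 * sum(E * dA) + lambda * sp_d) / (2 * den)
  min(max(t_opt, 0), t_max)
}

solve_penalized <- function(st, lambda, config) {
  traj <- vector("list", config$max_iters)
  prev_obj <- objective(st, lambda)$obj
  converged <- FALSE
  if (is.null(st$sig_K2)) st$sig_K2 <- psf_norm_sq(st$ops)
  for (it in seq_len(config$max_iters)) {
    # --- F block: projected gradient + exact line search, several passes ---
    sig_G2 <- max(eigen(crossprod(st$Gmat), symmetric = TRUE,
                        only.values = TRUE)$values, 0)
    stepF <- if (sig_G2 > 0) 1 / (2 * st$sig_K2 * sig_G2 * (1 + 1e-3)) else 1
    for (k in seq_len(config$inner_iters_per_block)) {
      E <- st$A - st$X
      grad <- 2 * convolve_density(E %*% st$Gmat, st$shape, st$ops,
                                   transpose = TRUE) +
        lambda * matrix(st$s, st$M, st$J, byrow = TRUE)
      d <- pmax(st$F - stepF * grad, 0) - st$F
      if (all(d == 0)) break
      Wd <- convolve_density(d, st$shape, st$ops)
      dA <- Wd %*% st$tGmat
      t_star <- exact_t(E, dA, sum(colSums(d) * st$s), lambda,
                        max_feasible_t(st$F, d))
      if (t_star == 0) break
      st$F <- pmax(st$F + t_star * d, 0)
      st$W <- st$W + t_star * Wd
      st$A <- st$A + t_star * dA
    }
    # periodic exact refresh to stop incremental drift
    st$W <- convolve_density(st$F, st$shape, st$ops)
    refresh_A(st)
    # --- a block: exact minimizer (separable quadratic), clamped ---
    resid_wo_a <- st$X - (st$A - st$a)
    st$a <- pmax(rowMeans(resid_wo_a), 0)
    refresh_bg(st); refresh_A(st)
    # --- b block: exact minimizer, clamped ---
    resid_wo_b <- st$X - sweep(st$A, 2L, rc_vec(st$b), `-`)
    st$b <- rc_unvec(pmax(colMeans(resid_wo_b), 0), st$R, st$C)
    refresh_bg(st); refresh_A(st)
    # --- alpha block: per-frame exact minimizer (decoupled coordinates) ---
    {
      Q <- st$W %*% t(st$Hmat)
      fsum <- colSums(st$F)
      num <- colSums((st$X - st$bg) * Q) - (lambda / 2) * as.vector(st$Hmat %*% fsum)
      den <- colSums(Q * Q)
      alpha_new <- rc_vec(st$alpha)
      upd <- den > 0
      alpha_new[upd] <- pmax(num[upd] / den[upd], 0)
      st$alpha <- rc_unvec(alpha_new, st$R, st$C)
      refresh_gain(st); refresh_A(st)
    }
    # --- phi block: projected gradient + exact line search ---
    if (config$learn_phi) {
      E <- st$A - st$X
      fsum <- colSums(st$F)
      Tsp <- matrix(fsum, st$R * st$C, st$J, byrow = TRUE)
      Csp <- contract_phi(st, Tsp)
      grad <- 2 * contract_phi(st, crossprod(E, st$W)) + lambda * Csp
      if (is.null(st$step_phi) || it %% 5L == 1L) st$step_phi <- phi_step_size(st)
      step_phi <- st$step_phi
      # the diagonal response is redundant with alpha (canonical form has
      # unit diagonal), so only the off-diagonal cross-talk is learned
      diag(grad) <- 0
      d <- pmin(pmax(st$phi - step_phi * grad, 0), 1) - st$phi
      if (any(d != 0)) {
        Hd <- apply_along_dim(st$Z, 2L, d)
        Gd <- sweep(Hd, 1:2, st$alpha, `*`)
        dA <- st$W %*% t(gain_matrix(Gd))
        t_star <- exact_t(E, dA, sum(d * Csp), lambda,
                          max_feasible_t(st$phi, d, 0, 1))
        if (t_star > 0) {
          st$phi <- pmin(pmax(st$phi + t_star * d, 0), 1)
          refresh_code(st); refresh_A(st)
        }
      }
    }
    # --- rho block: safeguarded projected gradient (model nonlinear in rho) ---
    if (config$learn_rho) {
      D <- rho_derivative(st)
      E <- st$A - st$X
      fsum <- colSums(st$F)
      Tsp <- matrix(fsum, st$R * st$C, st$J, byrow = TRUE)
      grad <- 2 * contract_rho(st, crossprod(E, st$W), D) +
        lambda * contract_rho(st, Tsp, D)
      if (is.null(st$step_rho) || it %% 5L == 1L) st$step_rho <- rho_step_size(st, D)
      step_rho <- st$step_rho
      safeguard(st, lambda, step_rho,
                apply_step = function(s) {
                  st$rho <- pmin(pmax(st$rho - s * grad, 0), 1)
                  refresh_code(st); refresh_A(st)
                },
                restore = local({
                  sr <- st$rho
                  function() { st$rho <- sr; refresh_code(st); refresh_A(st) }
                }))
    }
    ob <- objective(st, lambda)
    traj[[it]] <- c(iteration = it, reconstruction_loss = ob$recon,
                    sparsity_loss = ob$spars, objective = ob$obj)
    if (abs(prev_obj - ob$obj) <= config$tol_rel_objective * max(abs(prev_obj), 1e-300)) {
      converged <- TRUE
      traj <- traj[seq_len(it)]
      break
    }
    prev_obj <- ob$obj
  }
  traj <- traj[!vapply(traj, is.null, logical(1))]
  ob <- objective(st, lambda)
  list(
    trajectory = tibble::as_tibble(do.call(rbind, traj)),
    converged = converged,
    recon = ob$recon,
    spars = ob$spars,
    params = state_params(st)
  )
}

# power-iteration step for the phi operator, warm-started across iterations
phi_step_size <- function(st, iters = 6L) {
  op <- function(v) {
    Delta <- matrix(v, st$C, st$C)
    Hd <- apply_along_dim(st$Z, 2L, Delta)
    Gd <- sweep(Hd, 1:2, st$alpha, `*`)
    as.vector(st$W %*% t(gain_matrix(Gd)))
  }
  adj <- function(v) {
    Y <- matrix(v, st$M, st$R * st$C)
    as.vector(contract_phi(st, t(Y) %*% st$W))
  }
  v <- st$pv_phi %||% rep(1, st$C^2)
  est <- 0
  for (k in seq_len(iters)) {
    w <- adj(op(v))
    nw <- sqrt(sum(w * w))
    if (nw == 0) return(1)
    est <- sum(v * w) / sum(v * v)
    v <- w / nw
  }
  st$pv_phi <- v
  1 / (2 * est * (1 + 0.05))
}

rho_step_size <- function(st, D, iters = 6L) {
  op <- function(v) {
    Zd <- sweep(D, 2L, v, `*`)
    Hd <- apply_along_dim(Zd, 2L, st$phi)
    Gd <- sweep(Hd, 1:2, st$alpha, `*`)
    as.vector(st$W %*% t(gain_matrix(Gd)))
  }
  adj <- function(v) {
    Y <- matrix(v, st$M, st$R * st$C)
    contract_rho(st, t(Y) %*% st$W, D)
  }
  v <- st$pv_rho %||% rep(1, st$C)
  est <- 0
  for (k in seq_len(iters)) {
    w <- adj(op(v))
    nw <- sqrt(sum(w * w))
    if (nw == 0) return(1)
    est <- sum(v * w) / sum(v * v)
    v <- w / nw
  }
  st$pv_rho <- v
  1 / (2 * est * (1 + 0.05))
}

# lambda at which F = 0 is stationary for the penalized problem
lambda_max_bound <- function(st) {
  E0 <- st$A - st$X
  grad0 <- convolve_density(E0 %*% st$Gmat, st$shape, st$ops, transpose = TRUE)
  s_safe <- pmax(st$s, .Machine$double.eps)
  lam <- max(0, max(sweep(-2 * grad0, 2L, s_safe, `/`)))
  lam
}

#' Fit the observation model to an image stack
#'
#' Estimates the rolony densities `F` and the remaining observation-model
#' parameters by sparse non-negative regression: minimize the linear sparsity
#' penalty subject to the squared reconstruction loss not exceeding an
#' automatically chosen noise threshold omega. Solved in penalized form with
#' the multiplier located by bisection so the reconstruction loss lands within
#' 5% below omega. The returned parameters are scale-canonicalized via
#' [normalize_scale()].
#'
#' @param X An `image_stack` (registered, background-subtracted).
#' @param cb A `codebook` matching `X`'s rounds and channels.
#' @param psf A `psf` object (default Gaussian, sigma 1.5 voxels).
#' @param config A `fit_config`.
#' @param init Optional `model_params` used as a warm start (e.g. an upsampled
#'   coarse fit).
#' @param omega Optional explicit noise threshold, overriding the automatic
#'   choice.
#' @return An object of class `density_fit`: a list with elements `params`
#'   (normalized `model_params`), `omega`, `lambda`, `trajectory` (tibble of
#'   per-iteration losses), `converged`, `reconstruction_loss`,
#'   `sparsity_loss`, `spatial_shape`, plus the codebook and psf used.
#' @export
fit_densities <- function(X, cb, psf = psf_gaussian(1.5),
                          config = fit_config(), init = NULL, omega = NULL) {
  stopifnot(inherits(X, "image_stack"), inherits(cb, "codebook"),
            inherits(psf, "psf"), inherits(config, "fit_config"))
  if (any(is.nan(X$data))) stop("image stack contains NaN values", call. = FALSE)
  if (X$R != cb_rounds(cb) || X$C != cb_channels(cb)) {
    stop("codebook rounds/channels do not match the stack", call. = FALSE)
  }
  omega <- omega %||% select_noise_threshold(X, config)
  if (all(X$data == 0)) {
    warning("image stack is all zeros; returning an empty fit")
    params <- init_params(X, cb)
    return(new_density_fit(params, omega, lambda = 0,
                           trajectory = tibble::tibble(
                             iteration = integer(), reconstruction_loss = numeric(),
                             sparsity_loss = numeric(), objective = numeric()),
                           converged = TRUE, recon = 0, spars = 0,
                           X = X, cb = cb, psf = psf, config = config,
                           lambda_trace = tibble::tibble()))
  }
  params0 <- init %||% init_params(X, cb)
  st <- fit_state(X, cb, psf, params0)
  lam_max <- lambda_max_bound(st)
  if (lam_max == 0) lam_max <- 1
  band_lo <- 0.95 * omega

  solves <- list()
  run_at <- function(lambda, warm) {
    st <- fit_state(X, cb, psf, warm)
    res <- solve_penalized(st, lambda, config)
    res$lambda <- lambda
    res
  }
  nearest_warm <- function(lambda) {
    if (length(solves) == 0L) return(params0)
    lams <- vapply(solves, function(r) r$lambda, numeric(1))
    solves[[which.min(abs(log(pmax(lams, 1e-300)) - log(max(lambda, 1e-300))))]]$params
  }

  lo <- lam_max * 1e-4; hi <- lam_max
  best <- NULL
  for (k in seq_len(config$lagrange_bisection_iters)) {
    lambda <- if (k == 1L) sqrt(lo * hi) else sqrt(lo * hi)
    res <- run_at(lambda, nearest_warm(lambda))
    solves[[length(solves) + 1L]] <- res
    feasible <- res$recon <= omega
    if (feasible && (is.null(best) || res$lambda > best$lambda)) best <- res
    if (feasible && res$recon >= band_lo) break
    if (feasible) lo <- lambda else hi <- lambda
    if (hi / lo < 1.01) break
  }
  if (is.null(best)) {
    # even the loosest lambda tried could not satisfy the constraint; try a
    # plain least-squares pass (lambda ~ 0)
    res <- run_at(lam_max * 1e-8, nearest_warm(0))
    solves[[length(solves) + 1L]] <- res
    if (res$recon <= omega) best <- res
  }
  infeasible <- is.null(best)
  if (infeasible) {
    warning("reconstruction constraint unattainable at this omega; returning the best (infeasible) solution")
    recons <- vapply(solves, function(r) r$recon, numeric(1))
    best <- solves[[which.min(recons)]]
  }
  params <- normalize_scale(best$params)
  lambda_trace <- tibble::tibble(
    lambda = vapply(solves, function(r) r$lambda, numeric(1)),
    reconstruction_loss = vapply(solves, function(r) r$recon, numeric(1)),
    sparsity_loss = vapply(solves, function(r) r$spars, numeric(1)),
    feasible = vapply(solves, function(r) r$recon <= omega, logical(1))
  )
  new_density_fit(params, omega, best$lambda, best$trajectory,
                  converged = best$converged && !infeasible,
                  recon = best$recon, spars = best$spars,
                  X = X, cb = cb, psf = psf, config = config,
                  lambda_trace = lambda_trace)
}

new_density_fit <- function(params, omega, lambda, trajectory, converged,
                            recon, spars, X, cb, psf, config, lambda_trace) {
  structure(
    list(params = params, omega = omega, lambda = lambda,
         trajectory = trajectory, converged = converged,
         reconstruction_loss = recon, sparsity_loss = spars,
         spatial_shape = X$spatial_shape, R = X$R, C = X$C,
         codebook = cb, psf = psf, config = config,
         lambda_trace = lambda_trace),
    class = "density_fit"
  )
}

#' @export
print.density_fit <- function(x, ...) {
  cat(sprintf(paste0("<density_fit> %d barcodes on %s grid\n",
                     "  reconstruction loss %.4g (omega %.4g), sparsity %.4g, lambda %.4g\n",
                     "  %d iterations, converged: %s\n"),
              ncol(x$params$F), paste(x$spatial_shape, collapse = " x "),
              x$reconstruction_loss, x$omega, x$sparsity_loss, x$lambda,
              nrow(x$trajectory), x$converged))
  invisible(x)
}

#' Reconstruction implied by a fit
#'
#' @param x A `density_fit`.
#' @return An `image_stack` of predicted intensities.
#' @export
reconstruct <- function(x) {
  stopifnot(inherits(x, "density_fit"))
  forward_model(x$params, x$psf, x$codebook, x$spatial_shape)
}

#' @method tidy density_fit
#' @export
tidy.density_fit <- function(x, ...) x$trajectory

#' @method glance density_fit
#' @export
glance.density_fit <- function(x, ...) {
  tibble::tibble(
    iterations = nrow(x$trajectory),
    converged = x$converged,
    reconstruction_loss = x$reconstruction_loss,
    sparsity_loss = x$sparsity_loss,
    omega = x$omega,
    lambda = x$lambda,
    n_barcodes = ncol(x$params$F),
    n_voxels = nrow(x$params$F)
  )
}
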