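# demixr

Demixing and deconvolution of barcoded in situ sequencing image stacks.

In barcoded in situ sequencing (and related multiplexed FISH protocols),
every transcript species carries a barcode: a prescribed pattern of
fluorescence across `R` imaging rounds and `C` color channels. The raw data
— a registered, background-subtracted stack `X[m, r, c]` over voxels `m` —
are *mixed* (each voxel sums contributions from every nearby rolony active
in that frame) and *convolved* (the optics smear each point source by the
point-spread function `K`). `demixr` inverts both at once.

The core is a generative observation model

    X[m,r,c] ≈ a[m] + b[r,c] + α[r,c] · Σ_{j,m',c'} K[m,m'] F[m',j] φ[c,c'] Z[r,c',j],
    Z[1] = B[1],   Z[r] = ρ ∘ Z[r-1] + B[r],

where `B` is the binary codebook, `F ≥ 0` the per-voxel, per-barcode rolony
density (the estimand), `a`/`b` background and offsets, `α` per-frame
gains, `φ` channel cross-talk and `ρ` round-to-round phasing. Estimation is
a sparse non-negative regression,

    min L_sparsity   subject to   L_reconstruction ≤ ω,   all parameters ≥ 0,

solved in penalized form by block projected gradient descent with automatic
(power-iteration) step sizes and a bisection on the Lagrange multiplier.
The fitted `F` is a demixed, deconvolved image per barcode; rolonies are
its local maxima, with the detection threshold calibrated from *unused
barcodes* — valid codes absent from the experiment, whose fitted blobs must
be noise. Rank-one SVD diagnostics score each called spot, and
coarse-to-fine, barcode-sparsification and patch-parallel strategies
accelerate large stacks.

## Worked example

```r
library(demixr)

# simulate a small experiment: 7 rounds x 4 channels, 10 genes + 2 unused
# barcodes, 30 rolonies on a 100 x 100 grid, peak SNR about 7
cb  <- augment_codebook(balanced_codebook(7, 4, 10, seed = 7), n_unused = 2)
cfg <- sim_config(R = 7, C = 4, J = 10, spatial_shape = c(100, 100),
                  n_spots = 30, amplitude_low = 2, amplitude_high = 4,
                  noise_sd = 0.02, seed = 7)
sim <- simulate_stack(cfg, cb = cb)

fit <- fit_densities(sim$stack, sim$codebook, sim$psf,
                     fit_config(max_iters = 40,
                                unexplained_fraction_target = 0.45))
fit
#> <density_fit> 12 barcodes on 100 x 100 grid
#>   reconstruction loss 42.19 (omega 43.53), sparsity 402.8, lambda 0.04195
#>   20 iterations, converged: TRUE

spots <- call_spots(fit)
sum(spots$passes_threshold)
#> [1] 30

roc <- roc_curve(fit, truth = sim$truth)
roc
#> <roc_result> 31 thresholds, AUROC = 1.0000
```

The fit reports the squared reconstruction loss against its noise threshold
omega (the constraint is satisfied: 42.2 ≤ 43.5), the linear sparsity
penalty, and the Lagrange multiplier the bisection settled on. All 30
passing spots sit at true rolony locations with the right barcode — the
unused-barcode threshold admitted no false calls here, and the
threshold-swept recovery curve has AUROC 1. `tidy(fit)` returns the
per-iteration losses, `glance(fit)` a one-row summary, `autoplot(roc)` the
recovery curve, and `spot_qualities()` + `quality_histogram()` the per-spot
rank-one R² diagnostics.

A command-line tool wrapping the same functions (subcommands `fit`,
`spots`, `simulate`, `diagnose`, `benchmark`) is installed at
`system.file("cli", "demixr", package = "demixr")`.

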