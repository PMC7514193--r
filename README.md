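# petfoe

Iterative reconstruction of 2D PET sinograms at low count rates, with a
cross-entropy (Kullback–Leibler) data-fidelity term and a
**Field-of-Experts (FoE)** image prior built from learned 5×5 filters
with Student-t expert potentials.

PET measurements are Poisson counts `y_i` with expectation
`ȳ_i = Σ_j a_ij x_j`, where `x ≥ 0` is the activity image and `A` the
system matrix. The package minimizes

    J(x) = D(y, Ax) + β E(x)

where `D` is the Kullback–Leibler divergence (its minimizer is the
Poisson maximum-likelihood estimate) and

    E(x) = Σ_k Σ_p α_k log(1 + ((J_k ∗ x)_p)² / 2)

is the FoE energy: a Markov-random-field prior whose clique potentials
are Student-t experts `φ(z, α) = (1 + z²/2)^(−α)` of learned linear
filter responses. Minimization uses a gradient step with the variable
per-pixel step size `x_j / s_j` (`s_j = Σ_i a_ij`), which for `β = 0`
is algebraically the classical ML-EM update; a clamp-and-backtrack
safeguard keeps iterates non-negative and the objective non-increasing.
Defaults follow the method's published operating point (`β = 0.5`,
27 iterations; EM baseline at 12 iterations; a one-step-late
relative-difference baseline "CP" with β = 0.01, γ = 0.1, λ = 0.97).

The package also provides everything needed to evaluate the method at
desk scale: an exact-adjoint parallel-beam sparse projector, cylindrical
rod and lesion software phantoms, a seeded Poisson sinogram simulator,
contrast-resolution and profile metrics, a channelized Hotelling
observer with Mann–Whitney AUC, and a contrastive-divergence trainer for
the prior's filters (a trained synthetic bank ships with the package).
See `vignette("foe-pet-reconstruction")` for the model, parameter
meanings and numerical choices.

## Worked example

Simulate a low-count scan of the rod phantom (hot rods of 2–5 mm at
8:1 over background) and compare EM with the FoE-regularized scheme at
a matched iteration count:

```r
library(petfoe)

geom    <- pet_geometry(48, 48, pixel_size = 1.6, n_radial = 64, n_angles = 60)
A       <- build_system_matrix(geom)
spec    <- rod_phantom_spec()            # 60 mm body, rods of 2-5 mm at 8:1
phantom <- make_rod_phantom(spec, geom)
y       <- simulate_sinogram(A, phantom, target_counts = 1.25e5, seed = 1)

em  <- reconstruct(y, A, recon_config("EM", n_iterations = 27))
foe <- reconstruct(y, A, recon_config("MXE_FOE"))   # beta = 0.5, 27 iters

roi <- rod_study_rois(spec, geom)
for (fit in list(em, foe)) {
  bg <- fit$image$values[roi$background$rows, roi$background$cols]
  cat(sprintf("%-8s CR = %.3f   background sd = %.3f\n",
              fit$config$algorithm, contrast_resolution(fit$image, roi), sd(bg)))
}
#> EM       CR = 0.657   background sd = 0.255
#> MXE_FOE  CR = 0.642   background sd = 0.134
```

The regularized reconstruction roughly halves the background noise
(standard deviation 0.134 vs 0.255 on a background of mean 1) while the
rod contrast resolution `CR = (μ_t − μ_b)/(μ_t + μ_b)` stays within a
few percent of EM's — noise suppression without contrast loss, which is
the method's point. `reconstruct()` also returns the per-iteration
objective trace (non-increasing for the regularized scheme by
construction) and the count of negativity clips per iteration.

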