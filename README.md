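# iasmeg

Hierarchical Bayesian reconstruction of neural current dipole activity from
MEG/EEG sensor data by an iterative alternating sequential (IAS) algorithm,
for researchers who have a lead field, a source space with preferred dipole
orientations, and preprocessed sensor recordings, and who want focal or
distributed source estimates with a single physically interpretable tuning
input: the signal-to-noise ratio.

## The model

Measurements `b ∈ R^m` relate linearly to the dipole moments
`Q = (q_1, …, q_n)`, `q_j ∈ R^3`, through the lead field `M` with Gaussian
noise, `b = M Q + ε`, `ε ~ N(0, Σ)`. Each dipole has a conditionally
Gaussian prior `q_j | θ_j ~ N(0, θ_j C_j)` whose local anatomical covariance

    C_j = ν_j ν_j' + δ (ξ_j ξ_j' + ζ_j ζ_j')      (eigenvalues 1, δ, δ)

prefers the orientation `ν_j` extracted from anatomy, and each variance
`θ_j` follows a gamma hyperprior with shape `β = η + 5/2` and a
sensitivity-weighted scale

    θ*_j = P (1 − 1/SNR) / (β ‖M_j C_j^{1/2}‖_F²),

which makes deep and superficial dipoles a priori exchangeable (automatic
depth weighting). The joint MAP estimate of `(Q, Θ)` minimizes the Gibbs
energy

    E(Q, Θ) = ½‖b − MQ‖²_Σ + ½ Σ_j ‖q_j‖²_{C_j}/θ_j
              − η Σ_j log θ_j + Σ_j θ_j/θ*_j,

and the IAS algorithm alternates two steps until the variance vector
stabilizes:

1. **Dipole update** — a quadratic problem solved by priorconditioned CGLS:
   left preconditioning by the noise whitener, right preconditioning by a
   Cholesky factor of the prior covariance, with Morozov-discrepancy early
   stopping.
2. **Variance update** — the closed form
   `θ_j = θ*_j (η/2 + √(η²/4 + ‖q_j‖²_{C_j}/(2θ*_j)))`.

Small `η` (10⁻⁴–10⁻³) yields focal reconstructions, larger `η` (10⁻²–10⁻¹)
distributed ones. Time series are processed slice by slice with warm
starting: each slice's variances initialize the next.

The package also ships a synthetic data generator (quasi-uniform spherical
source space, spherical-conductor magnetometer lead field, patch
activations, SNR-calibrated noise) and sliced axial/coronal/sagittal
activity-map visualization.

## Worked example

Simulate a 5-dipole tangential patch on a 400-dipole spherical source
space observed by 60 magnetometers at SNR 15, then reconstruct it:

```r
library(iasmeg)

sc    <- make_scenario(n = 400, m = 60, patch_size = 5, snr = 15, seed = 3)
prior <- anatomical_prior(sc$space, delta = 0.05)
model <- set_parameters(sc$leadfield, sc$noisy, prior, snr = 15, eta = 0.001)
print(model)
#> IAS hyper model
#>   snr = 15, eta = 0.001 (beta = 2.501), sigma_scaled = 0.2582
#>   theta*: n = 400, range [39.62, 54.96], cutoff 54.96 (q = 1)

fit <- ias_solve(model$data[, 1], prior, model)
print(fit)
#> IAS fit: 30 outer iterations (not converged), final energy 33.9414
#>   peak intensity 4.772 at dipole 261

sc$support   # ground truth: 227 240 261 282 295
com <- intensity_center_of_mass(sc$space, fit$field$intensities)
sqrt(sum((com - sc$center)^2))   # 0.0085 m, vs 0.0135 m grid spacing
```

The peak lands on dipole 261, a member of the planted patch, and the
intensity center of mass sits 8.5 mm from the true patch center — well
under one grid spacing. (At this very focal `η` the variance vector keeps
shrinking on the inactive dipoles, so the outer loop runs to its iteration
cap rather than the `τ = 0.01` tolerance; the reconstruction is stable well
before that.) `render_activity_map(sc$space, fit$field$intensities, "act")`
writes the ten-layer sliced views; `render_single_slice()` plots the three
slices through any chosen point.

A shell interface wraps the same pipeline:

```sh
cli=$(Rscript -e 'cat(system.file("cli", "ias.R", package = "iasmeg"))')
Rscript $cli simulate --out scen --n 400 --m 60 --snr 15 --seed 3
Rscript $cli run --leadfield scen/leadfield.tsv --positions scen/positions.tsv \
    --orientations scen/orientations.tsv --data scen/data.tsv \
    --snr 15 --eta 0.001 --out result
Rscript $cli viz --result result --positions scen/positions.tsv \
    --orientations scen/orientations.tsv --out figures
```

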