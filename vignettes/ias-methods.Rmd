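---
title: "The IAS hierarchical model and its numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The IAS hierarchical model and its numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the model it implements, the
parameters that matter, and the numerical decisions taken where the
mathematics leaves freedom. It states no empirical results beyond what the
test suite and `scripts/acceptance.R` themselves compute.

## The inverse problem and the hierarchical prior

M/EEG source reconstruction asks for the current dipole moments
$q_1,\dots,q_n \in \mathbb{R}^3$ at $n$ fixed source-space locations given
$m \ll 3n$ sensor readings $b = MQ + \varepsilon$, with lead field
$M \in \mathbb{R}^{m\times 3n}$ and Gaussian noise
$\varepsilon \sim N(0,\Sigma)$. The problem is severely underdetermined and
ill-conditioned, and plain minimum-norm-type estimators are biased towards
superficial sources.

The model addresses both issues hierarchically:

* **Anatomical prior.** $q_j \mid \theta_j \sim N(0, \theta_j C_j)$ with
  $C_j = \nu_j\nu_j^\top + \delta(\xi_j\xi_j^\top + \zeta_j\zeta_j^\top)
  = (1-\delta)\nu_j\nu_j^\top + \delta I$. The preferred orientation
  $\nu_j$ (cortical surface normal) carries unit prior variance; the
  tangent plane carries the fraction $\delta$. Because
  $\xi\xi^\top + \zeta\zeta^\top = I - \nu\nu^\top$, **any** orthonormal
  completion of $\nu$ yields the same $C_j$; the package fixes one
  deterministically (the coordinate axis least parallel to $\nu$,
  orthogonalized against it, with $\zeta = \nu \times \xi$) so that the
  Cholesky factor — and hence every downstream number — is bit-reproducible
  across runs. Right-handedness is enforced for the same reason, although
  only orthonormality is mathematically required. Zero-norm orientations in
  input files are rejected outright: substituting a default direction would
  silently mask segmentation errors upstream.

* **Gamma hyperprior with sensitivity weighting.**
  $\theta_j \sim \Gamma(\beta, \theta^*_j)$ with shape
  $\beta = \eta + 5/2$. The scale is set from an exchangeability argument —
  for a given SNR, all dipole configurations of equal support size should
  be a priori equally able to explain the measured power — which gives
  $\theta^*_j \propto 1/\|M_j C_j^{1/2}\|_F^2$, i.e. automatic depth
  weighting. Two algebraically related forms of the constant exist,
  $P - \mathrm{trace}(\Sigma)$ and $P(1 - 1/\mathrm{SNR})$; they coincide
  exactly when $\mathrm{trace}(\Sigma) = P/\mathrm{SNR}$, which is how the
  package constructs $\Sigma$ from the user's SNR. The SNR form is taken as
  canonical because SNR is the user input; a user-supplied full $\Sigma$
  overrides the homoscedastic default but the scale formula still uses the
  SNR form.

The joint MAP estimate minimizes the Gibbs energy (negative log posterior)

$$E(Q,\Theta) = \tfrac12\|b - MQ\|^2_\Sigma
  + \tfrac12\sum_j \frac{\|q_j\|^2_{C_j}}{\theta_j}
  - \eta\sum_j\log\theta_j + \sum_j\frac{\theta_j}{\theta^*_j},$$

with $\|v\|^2_A = v^\top A^{-1} v$. Each term is jointly convex in
$(Q,\Theta)$ (the quadratic-over-linear term by the perspective
construction), so the minimizer is unique and the alternating scheme below
converges to it — a property the test suite verifies against an
independent brute-force minimizer on small problems.

## The IAS iteration

Initialized at $\Theta = \Theta^*$ (or a warm start), the algorithm
alternates:

1. **Q-step.** Minimize $E$ in $Q$ at fixed $\Theta$. After left
   preconditioning with the noise whitener $W$ ($W\Sigma W^\top = I$) and
   the change of variables $Q = D_\theta^\top w$ with
   $D_\theta^\top D_\theta = C_\theta = \mathrm{diag}(\theta_j C_j)$, the
   objective becomes $\|y - Aw\|^2 + \|w\|^2$ with $A = WMD_\theta^\top$
   and $y = Wb$ — the prior penalty is exactly the unit-weight ridge in the
   priorconditioned variables. The package runs **damped CGLS**
   (conjugate gradients on $A^\top A + \lambda I$, $\lambda$ = `damp`)
   from $w = 0$ with Morozov-discrepancy early stopping:
   terminate as soon as $\|y - Aw_k\|^2 \le m \cdot \texttt{noise\_level}^2$
   (after exact whitening the whitened noise has unit component variance,
   so `noise_level = 1`). With the default `damp = 1` the converged inner
   solution is the exact minimizer of the quadratic step, which is what the
   outer alternation needs in order to descend the Gibbs energy
   monotonically; with `damp = 0` the penalty is dropped and the
   early-stopped low-rank Krylov iterate alone carries the regularization —
   the variant that treats truncation itself as the regularizer. Both
   routes are exposed and both are validated against dense oracles; the
   damped default was chosen because it makes the fixed point agree with
   the global minimizer of the energy, at negligible extra cost (the
   discrepancy stop fires after a handful of iterations in realistic
   regimes either way).

2. **$\Theta$-step.** At fixed $Q$ the energy separates per dipole and has
   the closed-form minimizer
   $\theta_j = \theta^*_j\big(\eta/2 + \sqrt{\eta^2/4 +
   \|q_j\|^2_{C_j}/(2\theta^*_j)}\big)$, so
   $\theta_j \ge \eta\,\theta^*_j$ with equality exactly for silent
   dipoles.

The outer loop stops when the relative Euclidean change
$\|\Theta^{k+1}-\Theta^k\|/\|\Theta^k\|$ falls below $\tau$ or after
`n_outer` iterations. The Euclidean norm was chosen for the stopping metric
(the convergence criterion's norm is otherwise unconstrained) because it is
stable under the large dynamic range that sensitivity weighting induces in
$\Theta$; the same metric is reported in the diagnostics. For zero data the
iteration reaches its fixed point $Q = 0$, $\Theta = \eta\Theta^*$ after
exactly two outer iterations — the second confirms the first — which the
suite asserts.

**Time series.** Slices are processed independently except that with
`warm_start = TRUE` slice $s$ initializes $\Theta$ at the slice $s-1$
estimate. Evoked activity varies slowly on the millisecond grid, so the
previous variances are usually close to the new fixed point and the outer
loop shortens; a failed (non-finite) slice resets the warm start.

## Parameters

| name | meaning | default | notes |
|---|---|---|---|
| `snr` | signal-to-noise power ratio | required | the single required input; must exceed 1 |
| `eta` | focality, $\beta - 5/2$ | 0.01 | 0.001 for focal sources; sensible range $[10^{-4}, 10^{-1}]$ |
| `delta` | transverse prior variance | 0.05 | 1 = isotropic prior (no orientation preference) |
| `cutoff_quantile` | $\theta^*$ truncation level | 1 (none) | clips the upper tail of $\theta^*$ |
| `tau` | outer tolerance on $\Delta\Theta$ | 0.01 | |
| `n_outer` | outer iteration cap | 30 | |
| `max_it` | inner CGLS cap | 120 | |
| `damp` | inner prior-penalty weight | 1 | 0 = pure early-stopped Krylov route |

**Scaling.** Raw lead fields (T/(A·m)) and data (T) sit ~10 orders of
magnitude apart. `set_parameters()` rescales $M$ by
$1/\max_j\|M_j\|_F$ and the data so its median column norm is $\sqrt m$,
estimates the signal power $P$ as the mean squared column norm of a
user-designated window (unbiased for stationary segments), and sets
$\sigma^2 = P/(\mathrm{SNR}\cdot m)$. `run_pipeline()` undoes the scaling
so reconstructed moments return in input units.

**Truncation.** Deep, poorly seen dipoles receive very large $\theta^*_j$.
The optional truncation *clips* values above the chosen empirical quantile
rather than deleting dipoles, preserving the source-space size and all
index bookkeeping; whether removal should mean exclusion is ambiguous, and
clipping is the conservative reading (an `exclude` mode would be a natural
extension). Quantiles use linear interpolation between order statistics
(`stats::quantile` type 7), fixed so the cutoff is bit-reproducible.

## Numerical safeguards

* CGLS carries a stagnation guard for undamped rank-deficient systems
  (relative residual decrease below $10^{-12}$) and a gradient-based
  convergence stop for the damped route; the whitened data-residual norms
  are non-increasing up to the documented $O(\varepsilon\,\kappa^2)$ drift
  of the recursive CG residual.
* Slice parcellation pins the first and last layer boundaries to the exact
  coordinate extremes so rounding in
  $z_\ell = z_{\min} + \ell(z_{\max}-z_{\min})/10$ cannot orphan the
  extremal dipoles, and the maximal coordinate is closed into the top layer
  (the half-open convention would otherwise leave it unassigned).
* A degenerate slicing direction ($z_{\max} = z_{\min}$) puts all dipoles
  in layer 1 rather than failing.
* Orientations are renormalized on load (tolerance $10^{-8}$); zero or
  non-finite orientations are errors.

## The synthetic generator

`make_scenario()` defines the package's standard validation conditions:
a Fibonacci-lattice source space of $n = 400$ dipoles on an 8 cm sphere, 60
radial magnetometers at 12 cm, a compact patch of 5 dipoles activated along
their preferred orientations at 10 nAm, and white sensor noise calibrated
to SNR 15. Patch size, SNR and the 60-channel array emulate a typical
evoked-response magnetometer study at moderate resolution; the counts keep
a full validation run in seconds. The forward model is the closed-form
spherical-conductor (Sarvas) solution, which includes volume currents and
is validated in the suite by two physical facts: radial dipoles are
magnetically silent, and the radial field component equals that of the
primary current alone. Because of radial silence, scenarios meant to be
*seen* by MEG use tangential preferred orientations — the generator's
radial default emulates the geometry of cortical normals, and a
radially-oriented patch on a sphere would be invisible by construction.

What the generator does **not** emulate: realistic (BEM) head geometry,
gradiometer pickup, temporally or spatially correlated sensor noise, and
structured physiological background (a crude stand-in,
`add_brain_noise()`, scales random dipole activity to a target brain-SNR).
Passing the recovery tests therefore demonstrates correctness of the
inference machinery under its own model assumptions, not performance on
real recordings, where lead-field error and correlated noise dominate.

## Validation problem sizes

The suite's heavier checks use: 1000 random triples for the closed-form
variance update against numerical 1-D minimization; 20 random
$(n{=}3, m{=}5)$ problems against a multi-start brute-force energy
minimizer ($10^{-6}$ relative agreement); 50 random systems up to
$30 \times 60$ for CGLS against dense solutions ($10^{-6}$); and ten seeded
400-dipole recovery scenarios for localization (intensity center of mass
within two grid spacings), focality monotonicity in $\eta$, and warm-start
iteration counts. These sizes were chosen so the whole suite runs in well
under a minute while still exercising every code path at realistic
conditioning.

## Known limitations

* Point estimates only: no posterior uncertainty quantification.
* The homoscedastic noise default ignores inter-channel correlation unless
  a full $\Sigma$ is supplied.
* EEG users must supply an external lead field (the synthetic forward model
  is MEG-only; multilayer-sphere EEG forward modeling is out of scope).
* On-disk interchange is delimited text; binary container formats are not
  read or written.
* The discrepancy stop assumes the SNR estimate is roughly right; a badly
  overestimated SNR shrinks the implied noise level and defers the inner
  stop to the iteration cap.
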