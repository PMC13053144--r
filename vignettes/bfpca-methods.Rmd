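---
title: "Joint Bayesian estimation of functional principal components: model, sampler, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint Bayesian estimation of functional principal components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfpca)
```

## The model

Dense functional data `Y_i(t_m)`, `i = 1..N`, `m = 1..M`, on a common grid
in `[0, 1]` are modeled as

$$Y_i(t) = \mu(t) + \sum_{k=1}^{K} \xi_{ik}\,\phi_k(t) + \varepsilon_i(t),
\qquad \xi_{ik} \sim N(0, \lambda_k), \quad
\varepsilon_i(t) \sim N(0, \sigma^2),$$

with the eigenfunctions $\phi_k$ orthonormal in $L^2([0,1])$ and the scores
and errors mutually independent. All functional components are expanded in
a $Q$-dimensional spline basis $B(t)$ that is itself orthonormal in
$L^2([0,1])$: $\mu = B w_\mu$ and $\phi_k = B \psi_k$. Because the basis is
orthonormal, $\langle \phi_k, \phi_{k'} \rangle = \psi_k^\top \psi_{k'}$,
so the functions are orthonormal **exactly when** the $Q \times K$
coefficient matrix $\Psi$ has orthonormal columns. This reduces an
infinite-dimensional constraint to a constraint on a small matrix — the
point of the whole construction — and it is why `K` and `Q`, not `M`,
determine the hard part of the sampling problem.

The rank `K` is fixed by the analyst; the package reports percent variance
explained (with intervals) to support that choice, but does not select `K`
itself.

## The basis

The basis is assembled from `[1, t, cubic B-splines of dimension Q]` on
equally spaced interior knots, swept by a modified Gram–Schmidt
orthonormalization (two projection passes per column) against the $L^2$
inner product evaluated on an internal Gauss–Legendre rule with
`max(1000, 20 Q)` nodes. The full cubic B-spline system already spans
constants and linear trends, so the combined design has rank exactly `Q`
and the sweep drops the two redundant spline directions; the first two
output functions span intercept and slope exactly, and the remaining ones
keep the local support of B-splines away from those two polynomial
directions. A sequential (rather than symmetric) orthonormalization was
chosen because a symmetric orthonormalization of a rank-deficient design is
singular, and sequencing `1, t` first pins the interpretable leading
functions. The default `Q = 20` follows standard penalized-spline practice
for this type of data (recommended range roughly 20–40); `Q` must satisfy
`K <= Q <= M`.

A `"vector"` mode is available in which orthonormality is imposed on the
data grid (`t(B) B = I`) instead of in $L^2$; functional orthonormality is
the default because it is invariant to the sampling density of the grid.

Time stamps outside `[0, 1]` are affinely rescaled on input (the map is
stored for reporting); stamps already inside `[0, 1]` — e.g. quadrature
nodes — are kept as-is.

Gauss–Legendre nodes and weights are computed by a vectorized Newton
iteration on the Legendre recurrence and cached per session; the rule is
validated against an independent implementation in the test suite.

## Priors and the smoothing penalty

Smoothness of $\mu$ and each $\phi_k$ is encoded by the quadratic form of
$P_\alpha = \alpha\,G_0 + (1-\alpha)\,S$, where $G_0$ is the $L^2$ Gram
matrix of the basis (the identity in functional mode) and
$S_{ij} = \int B_i'' B_j''$: the penalty
$\alpha \int f^2 + (1-\alpha) \int (f'')^2$ with default
$\alpha = 0.1$. $\alpha = 0$ is the classic curvature-only penalized-spline
prior; any $\alpha \in [0,1]$ is accepted, and for $\alpha > 0$ the penalty
matrix is full rank, making the implied Gaussian priors proper.

Hyperpriors (shape–rate throughout): Gamma(0.001, 0.001) on the mean
smoothing parameter $h_\mu$; inverse-Gamma(0.001, 0.001) on $\sigma^2$ and
on each eigenvalue; Gamma(0.01, trace$(P_\alpha)/2 + 0.01$) on each
component smoothing parameter $h_k$. The rate bound matters: the joint
prior on $(\Psi, H)$ — a uniform-on-Stiefel component times the smoothing
kernel $\exp(-h_k \psi_k^\top P_\alpha \psi_k / 2)$ — is proper only when
the Gamma rate on $h_k$ exceeds trace$(P_\alpha)/2$, and the package
refuses configurations that violate the bound. The smoothing-prior
normalizing exponent is implemented as $Q/2$ (with full-rank $P_\alpha$
asserted when $\alpha > 0$), matching the rank of the penalty in every
supported configuration.

The latent-matrix prior is i.i.d. `N(0,1)` on the entries of a `Q x K`
matrix `X`; its orthonormal polar factor
$\Psi = X(X^\top X)^{-1/2}$ is then uniform on the Stiefel manifold. The
polar factor is computed through the eigendecomposition of $X^\top X$, with
a relative `1e-12` spectral ridge (logged) if a draw ever becomes
numerically rank deficient.

## The sampler

All conditionals except the one of $\Psi$ are analytic, so the package uses
a blocked Gibbs scheme with exact draws for: the mean coefficients
(Gaussian), the scores (row-wise Gaussian), $\sigma^2$, $h_\mu$, each $h_k$
(Gamma/inverse-Gamma), and the eigenvalues — inverse-Gamma truncated to the
order constraint $\lambda_1 < \dots < \lambda_K$, which is imposed during
sampling (increasing, matching the ordered-positive convention; reporting
order is by decreasing variance after post-processing).

The latent matrix is updated by Hamiltonian Monte Carlo with analytic
gradients through the polar map (the Fréchet derivative of
$A \mapsto A^{-1/2}$ via divided differences on the spectrum of
$X^\top X$), verified against finite differences in the tests. Four
design choices matter for mixing, and each targets a specific flat or
stiff direction of this posterior:

* **Radial refresh.** Under the `N(0,1)` measure the orthonormal and PSD
  polar factors of `X` are independent, so the PSD factor of a *fresh*
  standard-normal matrix is an exact Gibbs draw of the data-uninformed
  "radial" part of `X`. Refreshing it each scan removes the worst scale
  mismatch between prior-only and data-tight directions.
* **Preconditioning.** The Hamiltonian update is preconditioned per
  component column by the conditional precision
  $(\Xi^\top\Xi)_{kk}\,B^\top B/\sigma^2 + h_k P_\alpha + I$, and the mean
  block by $N B^\top B/\sigma^2 + h_\mu P_\alpha$ — all quantities held
  fixed during the update, so invariance is untouched. This equalizes
  scales across components whose eigenvalues differ by orders of
  magnitude. Step size is tuned by dual averaging during warm-up
  (target acceptance 0.8); the leapfrog count is jittered up to
  `n_leapfrog` (default 16).
* **Joint mean update.** The mean coefficients ride in the same Hamiltonian
  as `X`, because mean shape and eigenfunction shape are strongly coupled
  whenever the true mean loads on an eigenfunction — the hard case of the
  dense-CGM scenario, whose mean is exactly a combination of
  $\phi_1$ and $\phi_3$.
* **Exact valley moves.** Two likelihood-invariant directions are sampled
  exactly rather than traversed by diffusion: (i) shifting a score column
  by a constant while the mean absorbs that multiple of the eigenfunction
  (the conditional of the shift is Gaussian); and (ii) jointly rotating a
  pair of coefficient columns and their score columns — the likelihood is
  exactly invariant, and the remaining score-prior and smoothing terms are
  linear in $\cos 2\theta$ and $\sin 2\theta$, so the rotation angle's
  conditional is von Mises in $2\theta$ and is drawn exactly
  (Best–Fisher sampler, validated against Bessel-function moments). The
  rotation moves also equilibrate the genuine rotation ambiguity between
  components with close eigenvalues, and, by visiting angles near
  $\pm\pi/2$, the label-switching modes.

Chains are initialized at an eigendecomposition of the projected data
covariance, overdispersed by random column sign flips, multiplicative
eigenvalue jitter, and latent-matrix noise; per-chain seeds derive
deterministically from the single user seed.

## Post-processing and diagnostics

The FPCA likelihood is invariant to permuting components and to jointly
negating an eigenfunction and its scores, so raw draws are not comparable
across (or even within) chains. Post-processing applies, in order:

1. **Per-draw reordering** by the draw's cross-sectional score sample
   variance, decreasing, ties broken by original index. A per-draw
   permutation (rather than one pooled reordering) is used deliberately:
   with adjacent eigenvalues the sampler can relabel components mid-chain,
   and a single permutation provably cannot repair that; the per-draw rule
   handles both the global ordering and within-chain label switching. The
   applied permutations are recorded, and re-applying the pipeline is
   idempotent.
2. **Sign alignment** maximizing the Pearson correlation (over grid points)
   of each drawn eigenfunction with the reference — the first retained draw
   of the first chain, shared across *all* chains so that between-chain
   diagnostics compare like with like. A zero-variance draw falls back to
   the quadrature inner product's sign.
3. **Orthonormalized point estimate**: the element-wise mean of the aligned
   coefficient draws is not orthonormal, so its polar factor is taken;
   $\hat\Phi = B\hat\Psi$ is then exactly orthonormal.
4. **Equal-tail bands** from empirical quantiles (linear interpolation
   between order statistics, type 7, fixed for bit-reproducibility) for
   $\mu(t_m)$, each $\phi_k(t_m)$, eigenvalues, and scores.
5. **Percent variance explained** per draw as
   $100\,\lambda_k / (\sum_j \lambda_j + [\sigma^2])$; the noise term is
   included only on request (`pve_include_noise`), as both conventions are
   in use; the default excludes it.
6. **Split-chain Gelman–Rubin statistics** (classic variant, not
   rank-normalized; each chain split in half) for every monitored scalar:
   eigenfunction values at every grid point, every score, every eigenvalue,
   and $\sigma^2$ — computed on aligned draws, since otherwise sign and
   label ambiguity masquerade as non-convergence. Identically constant
   chains return 1 by convention; a single chain falls back to comparing
   its halves, with a warning.

Score-variance ordering uses each draw's own cross-sectional variance;
pooling across chains first was rejected because it cannot see within-chain
relabeling (the documented alternative reading).

## The multilevel extension

For nested curves `Y_ij(t)` (subject `i`, visit `j`) the model adds a
second eigen-system:

$$Y_{ij}(t) = \mu(t) + \eta_j(t) + \sum_k \xi_{ik} \phi^{(1)}_k(t)
 + \sum_l \zeta_{ijl} \phi^{(2)}_l(t) + \varepsilon_{ij}(t).$$

Both coefficient matrices get independent latent matrices, polar maps,
ordered eigenvalues, and smoothing parameters (the same hyperpriors at both
levels); no orthogonality is imposed *between* levels, mirroring the model
statement. The visit-specific deviations $\eta_j$ are penalized splines
sharing the basis and penalty with one common smoothing parameter; they
default to off, since visit order is typically not meaningful in the
motivating designs. `K2 = 0` drops the visit-level block, and with one
visit per subject the model (and the generator) degenerate exactly to the
single-level case — both degeneracies are tested.

Both latent matrices and the mean are moved in one joint Hamiltonian, and
an additional exact Gibbs move translates per-subject score mass between a
level-1 and a level-2 component (the conditional of the per-subject shifts
is Gaussian, with the likelihood entering only through the difference of
the two shapes). This targets the characteristic weak identification of
two-level functional models: a shape attributable to either level.

## Simulation scenarios and the evaluation harness

Two built-in generative truths drive testing and calibration:

* **Dense-CGM-style** (`scenario_s1`): $\mu(t) = 140 - 20 f_2(t)$,
  $\sigma^2 = 4$, $\lambda = (2250, 450, 150)$, eigenfunctions built from
  shifted Legendre polynomials — $\phi_1 = f_0$,
  $\phi_2 = \sqrt{84/31}\,(f_1 - 0.5 f_3)$, $\phi_3 = -\sqrt{5} f_2$. The
  normalizing constants are forced by the unit-norm requirement, and
  construction asserts orthonormality at `1e-8` on a dense quadrature, so a
  misread constant cannot pass silently. The mean is exactly
  $140\,\phi_1 + 4\sqrt5\,\phi_3$, which deliberately lets information leak
  between mean and covariance — the hard case.
* **Trigonometric** (`scenario_s2`): $\mu = 0$, $\sigma^2 = 0.35$,
  $\lambda = (1, 0.5, 0.25)$, eigenfunctions
  $\sqrt2 \sin 2\pi t, \sqrt2 \cos 4\pi t, \sqrt2 \sin 4\pi t$. The
  adjacent eigenvalues make rotation ambiguity between components a real
  feature of the posterior at `N = 50`.

Datasets are drawn at `N = 50` curves on `M = 50` Gauss–Legendre nodes by
default ("observed according to quadrature"), deterministically from a
seed; a trapezoid grid is available by flag. The two-level generator
reuses the dense-CGM system at level 1 with
$\lambda^{(1)} = (2250, 450)$ and the trigonometric system at level 2 with
$\lambda^{(2)} = (900, 300, 100)$, $\sigma^2 = 4$ — documented stand-ins
chosen once, modeled on the dense-CGM scenario. A known property of this
stand-in: the level-1 S-shaped component and the level-2 $\sin 2\pi t$
component are both odd about $t = 1/2$, so the two-level posterior is
genuinely weakly identified along the corresponding cross-level direction;
eigenvalue recovery is unaffected, but convergence diagnostics for the
affected score blocks remain elevated at realistic run lengths. Simulated
findings against the two-level stand-in are not comparisons to any external
reference.

The evaluation module scores a fit against its generative truth:
quadrature-weighted integrated squared error for eigenfunctions and mean,
pointwise coverage of equal-tail bands (closed intervals, so touching
counts as covering), and score MSE/coverage per component — after aligning
estimated signs to the truth (the per-component ISE-minimizing sign, which
coincides with exhaustive search over sign vectors). `run_replicate_study`
chains simulate → fit → post-process → align → score over `B` replicates
with fully derived seeds; failed replicates are excluded and reported, not
retried, keeping the seed-to-output map deterministic.

## Problem sizes and numerical choices

The package's own experiments use: one full-size fit of the dense-CGM
scenario (`N = M = 50`, `K = 3`, `Q = 20`, 4 chains × 1500 iterations,
1000 warm-up) for the convergence headline; five such replicates for
eigenvalue/noise recovery; `B = 5` trigonometric replicates at 2 × 800/500
for band calibration; and reduced-scale two-level runs (`N = 40`, `J = 3`,
`M = 40`, `Q = 15`, 2 × 800/500). Replicate counts and the two-level sizes
were chosen so the whole experimental suite runs in minutes on one CPU
while leaving the per-fit configuration of the headline run at full size;
the calibration band (mean pointwise coverage of 95% bands within
`[0.85, 1]`) is a property-style check, not an estimate of a published
number.

Numerical conventions worth knowing: quantiles are type 7; penalty and
Gram matrices are symmetrized after assembly; the second-derivative Gram
uses analytic spline derivatives on a dense rule (piecewise-linear
integrands, so essentially exact); truncated inverse-Gamma draws fall back
to the current value when the constraint interval carries no resolvable
mass; divergent Hamiltonian trajectories (non-finite state or energy error
above 1000) are rejected and counted in the diagnostics; and reconstruction
`Xi (B Psi)'` is invariant under all post-processing up to the last ulp
(column permutation reorders floating-point additions).

## Limitations

* Dense, complete, common-grid data only; no sparse/irregular designs and
  no non-Gaussian likelihoods.
* `K` is fixed by the user; percent variance explained is reported to guide
  the choice, but no automatic selection is done.
* The two-level extension handles nested (not crossed) designs with at most
  two levels.
* Synthetic scenarios emulate dense CGM-like data with Gaussian scores and
  errors on a common grid; passing tests on them says nothing about
  behavior under, e.g., heavy-tailed errors, missingness, or grid
  misalignment, which real CGM data exhibit.
* With closely spaced eigenvalues the posterior genuinely mixes over
  rotations of the corresponding eigen-subspace; point estimates of
  individual eigenfunctions are then summaries of a rotation-diffuse
  posterior and their bands widen accordingly. The cross-level analogue in
  the two-level model is described above.
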