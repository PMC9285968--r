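---
title: "Space-time shape uncertainty in boundary-integral electrocardiography"
author: "ecguq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space-time shape uncertainty in boundary-integral electrocardiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecguq)
```

## The problem

In electrocardiographic imaging, the potential $u$ on a surface enclosing
the heart (the pericardium $\Sigma$) drives, through the passive torso
volume conductor, the potential $y$ recorded on the chest $\Gamma$.  The
forward problem maps $u \mapsto y$; the inverse problem — reconstructing
$u$ from noisy chest recordings $y_d$ — is severely ill-posed.  Both
problems take the anatomy as known, yet the pericardial contour comes from
segmenting noisy, low-resolution, ECG-gated images of a moving organ: it
carries a time-dependent *shape uncertainty*.  This package quantifies how
that uncertainty propagates into the chest potential (forward) and into
the regularised reconstruction (inverse), on two-dimensional torso
cross-sections.

## Forward model and discretisation

On a homogeneous, unit-conductivity torso slice $D$ with fixed outer
boundary $\Gamma$ and moving inner boundary $\Sigma(t)$, the potential is
harmonic with zero Neumann data on the chest and Dirichlet data $u$ on the
pericardium.  The problem is recast as boundary integral equations with
the logarithmic fundamental solution
$G(x, x') = -\tfrac{1}{2\pi}\log\lVert x - x'\rVert$: the single- and
double-layer operators $V$ and $K$, restricted to the two boundary
components, form a $2\times 2$ block system whose unknowns are the chest
trace and the (speed-weighted) pericardial normal derivative.  Eliminating
either unknown defines the discrete solution operator $A$ (pericardial
values to chest trace) and the Poincaré–Steklov operator $B$
(Dirichlet-to-Neumann map on $\Sigma$), both of which the package builds
explicitly (`build_transfer()`), with a Schur-complement construction
available as an independent cross-check.

Boundaries are stored as truncated trigonometric polynomials
(`closed_curve`), fitted to contour points by a truncated discrete Fourier
transform at the lowest order reaching a relative RMS error threshold
($10^{-3}$ by default).  The Nyström collocation discretisation uses
equispaced parameter nodes $s_i = i/n$.  Smooth (off-boundary and
double-layer) kernels are integrated by the plain trapezoidal rule, which
is spectrally accurate for periodic analytic integrands; the same-boundary
single layer splits off the periodic logarithm
$-\tfrac{1}{4\pi}\log(4\sin^2(\pi(s - s')))$, integrated by its exact
trigonometric quadrature weights (`kress_weights()`), plus a smooth
remainder; the same-boundary double-layer diagonal is the curvature limit
of the kernel.  On concentric circles, where separation of variables gives
closed forms (mode $m$ maps to chest amplitude $2a^mb^m/(a^{2m}+b^{2m})$),
the discrete operators are exact to $10^{-10}$ by $n = 128$; the test
suite pins these oracles, the Gauss jump identity
$(\tfrac12 I + K_{\partial D})\,\mathbf 1 = 0$ on both components, and the
agreement of the Schur and column-solve paths.

Exterior normals follow one convention everywhere: outward on the chest,
pointing *into* the cardiac cavity on the pericardium, realised by a
per-role sign rather than by reversing parameterisations.  The row-sum
identity above validates the convention at assembly level.

## The prescribed pericardial potential

The analytic pericardial potential emulates a left-bundle-branch-block
activation: two wavefronts leave the right-ventricular free wall ($s = 0$)
and meet at the left-ventricular free wall ($s = 0.5$) after 150 ms, so
the activation time is $\tau(s) = 300\,\min(s, 1-s)$ ms.  The waveform at
each site is a difference of logistic fronts,
$u = \mathrm{logis}((\tilde t-\tau)/w_d) -
\mathrm{logis}((\tilde t-\tau-\mathrm{APD})/w_r)$ with
$\tilde t = t \bmod T$, defaults $w_d = 5$ ms (sharp depolarisation),
$\mathrm{APD} = 250$ ms, $w_r = 30$ ms (gradual repolarisation),
amplitude 1, $T = 690$ ms.  All constants are exposed in
`potential_params()`.  The potential is attached to the curvilinear
coordinate $s$, so its collocation values do not change when the boundary
deforms (a material description).

Two consequences of this template matter for the studies below.  First,
during the plateau (roughly 160–400 ms into the beat) the potential is
nearly constant in $s$; since the forward map preserves constants exactly,
the chest potential is then almost insensitive to the shape.  The
uncertainty studies therefore default to a mid-depolarisation snapshot
($t = 100$ ms), when the potential carries steep spatial gradients — the
regime in which shape uncertainty acts.  Second, the amplitude scale is
arbitrary (units of 1); noise variances quote their achieved
signal-to-noise ratio rather than asserting one.

## Synthetic space-time geometry

No clinical geometry ships with the package; `synthesize_torso()` builds a
deterministic, seeded emulation of a mid-ventricular short-axis
cross-section: a fixed chest oval of semi-axes $180 \times 120$ mm with a
mild third-harmonic perturbation, and a pericardium of mean radius 45 mm
with two low-order radial harmonics.  The pericardium centre
$(-30, 55)$ mm places the epicardium about 15 mm from the anterior chest
wall.  This proximity is anatomically realistic and scientifically
load-bearing: the chest potential's sensitivity to the $k$-th boundary
harmonic decays geometrically with the wall distance, so a heart centred
deep in the torso would make every study trivially flat, whereas the
near-wall configuration concentrates forward-problem uncertainty at the
chest points closest to the heart.

The enclosed area oscillates $T$-periodically through a smooth two-harmonic
waveform constrained to a stationary maximum at $t = 0$ (diastole) and a
stationary minimum at the stored instant nearest $t = 270$ ms (systole),
sampled at 50 instants.  Curves in time are interpolated trigonometrically
(`pericardium_at_time()`), which preserves smooth periodicity; linear
interpolation would break $C^1$ continuity at the stored instants and is
not offered.

## The random deformation field

Shape uncertainty is a random displacement of the reference pericardium's
space-time collocation points.  Its covariance is a tensor product of

* a spatial Matérn kernel in the Euclidean distance between reference
  positions, correlation length $\rho = 50$ mm and variance
  $\sigma^2 = 4/3$ mm², with smoothness $\nu = 5/2$ for the first
  displacement component and the Gaussian limit $\nu = \infty$ for the
  second, and no cross-component correlation;
* a sine-power kernel $\tfrac12(\cos\theta + 1)$ in the geodesic distance
  $\theta$ on the heartbeat circle $t \mapsto 2\pi t/T$, making the field
  exactly periodic over the beat.

The covariance over all space-time degrees of freedom (ordered
component-major, then time, then $s$) is compressed by a pivoted Cholesky
factorisation with lazily evaluated columns (`pivoted_cholesky()`),
stopping at a trace residual tolerance.  The columns of the factor are the
weighted modes $m_k = \sqrt{\lambda_k}\chi_k$ of a finite-rank
Karhunen–Loève expansion
$\chi(\hat z,\xi) = \hat z + \sum_k m_k(\hat z)\,\xi_k$ with independent
$\xi_k \sim U(-1,1)$.  The expansion is implemented literally with uniform
parameters, so the per-coordinate displacement variance is
$\tfrac13\sum_k m_k^2$ (no rescaling to unit variance is applied); the
95 % shape band is $1.96$ times the resulting standard deviation.

Two tolerance semantics exist for the stopping rule.  `build_kl()`
defaults to a *relative* trace residual (the conventional reading for the
algorithm); the study driver `uq_snapshot()` uses an *absolute* residual
of $10^{-4}$, which on this geometry yields on the order of one hundred
modes for a single instant — the genuinely high-dimensional regime the
uncertainty studies are designed to exercise — where the relative reading
would retain only ~34.  Both are exposed; the choice is a modelling
decision about how much trailing variance to keep, not a numerical
necessity.

Sampled deformations must remain admissible (a surrogate for the uniform
bi-Lipschitz condition that keeps the boundary value problem well-posed):
minimum parameterisation speed above $10^{-3}$ of the mean, no
self-intersection, strictly inside the chest.  `sample_deformation()`
enforces all three; the moment-estimation loops use a fast variant (speed
and a polar clearance test) because the full self-intersection test is
quadratic in the grid size.  An inadmissible node raises an error naming
the node — skipping it silently would bias the moments.

## Moment estimation

Moments of a field over $\xi \in [-1,1]^K$ are approximated by
$\mathcal M_m \approx \sum_i w_i\, y(\xi_i)^m$ with weights that absorb
the uniform density $2^{-K}$.  Two rules are provided:

* **Anisotropic sparse Gauss–Legendre** (`sparse_rule()`): a
  combination-technique rule over the anisotropic total-degree index set
  $\{k : \sum_j \alpha_j k_j \le L\}$, one-dimensional order
  $m(l) = l + 1$, duplicate nodes merged.  The dimension weights default
  to $\alpha_j = \max(1, \log_2(r_{\max}/r_j))$ with $r_j$ the sup norm of
  mode $j$, so dimensions whose modes have decayed most are refined last.
  Level 0 is the single midpoint node; constants integrate exactly at
  every level.  The construction is verified node-for-node against a
  brute-force Smolyak enumeration in the tests.
* **Halton quasi-Monte Carlo** (`halton_rule()`): the unscrambled
  radical-inverse sequence in the first $K$ prime bases, mapped to the
  cube, equal weights — bit-reproducible by construction.

## The convergence studies and their protocol

`forward_uq_study()` estimates the first and second moments of the chest
potential at the snapshot instant with sparse rules of increasing level
and measures relative sup-norm errors against a Halton reference
($N = 10^5$ in the acceptance study).  Two effects shape the error curves.
The sparse errors first decay as the rule refines the leading dimensions;
once they fall below the reference's own quadrature accuracy, the measured
"error" is a flat floor that reflects the reference, not the rule.  The
reported convergence rate is therefore fitted over the levels up to the
first one attaining the *validation accuracy* of $5\cdot10^{-5}$ — the
accuracy at which the sparse rule counts as validated against quasi-Monte
Carlo — and the unrestricted fit is reported alongside (`rate_full`).  On
the default geometry the windowed rate is about $0.6$–$0.7$ and the
top-budget (≈$1.4\cdot10^4$ raw nodes) discrepancy is below $10^{-5}$,
comfortably within the validation accuracy.

`inverse_uq_study()` repeats the exercise for the inverse problem on a
reduced problem ($n = 64$): fixed noisy chest data are generated once on
the reference geometry (variance $10^{-8}$, ~46 dB at unit amplitude), and
at every quadrature node the transfer operators of the deformed geometry
are rebuilt and the reconstruction recomputed under all four
regularisations, sharing one assembly per node.  The regularisation
parameter for each kind is selected by the L-curve criterion on the
reference problem — the maximal-curvature corner of the log residual
versus log penalty curve, maximised over time steps when a series is given
— because regularisation parameters are meaningful only relative to a
problem's spectrum and noise; values transplanted from a different
geometry can under-regularise by orders of magnitude.

The four regularisations penalise, respectively, the $L^2$ norm of the
Dirichlet data (`tik0`, $M = S_\Sigma$), the $L^2$ norm of the Neumann
data (`tik1`, $M = B^\top S_\Sigma B$), the $H^{1/2}$ trace norm
naturally induced by the boundary-integral formulation (`h12`,
$M = \tfrac12(B^\top S_\Sigma + S_\Sigma B)$, the exact symmetrised
gradient of the discrete quadratic form; the unsymmetrised variant is
available as an option), and a smoothed total variation of the Neumann
data (`tv`), linearised once — lagged diffusivity — around the zero-order
Tikhonov solution with weights
$W_{ii} = [2\sqrt{(Bu_0)_i^2 + \beta}]^{-1}$, $\beta = 10^{-5}$.  The
normal equations are fixed as
$(A^\top S_\Gamma A + \lambda^2 M)u = A^\top S_\Gamma y_d$.

The study reproduces the qualitative finding that motivates the $H^{1/2}$
choice: the quadratic regularisations' moment errors keep decreasing with
budget (within their validation window), while the total-variation curve
flattens well above the validation accuracy (around $2\cdot10^{-4}$) — the
lagged-diffusivity weights make the node-to-node dependence on $\xi$
non-smooth, which defeats polynomial-exactness-based quadrature.  The
same study shows the headline asymmetry: the maximal pointwise standard
deviation of the reconstruction exceeds that of the forward solution by
a factor of two to three under identical sampling, i.e. shape
uncertainty matters far more for the inverse problem.

## Problem sizes and numerical choices

The studies are sized for a single CPU: the acceptance study uses
$n = 128$ collocation points per boundary (the collocation error is below
$10^{-8}$ there, far beneath every quadrature error measured), a
single-instant expansion of $K \approx 95$ modes, sparse levels up to
about $1.4\cdot10^4$ raw nodes and a Halton reference of $10^5$ points;
the inverse study uses $n = 64$ and $K \approx 77$.  Dense LU solves are
used throughout (systems never exceed $1024^2$).  Duplicate sparse nodes
are merged on 13 significant digits.  The L-curve drops grid points whose
normal equations are numerically singular (λ far below the noise level)
and requires at least five solvable points.  Curvature at the corner is
computed by central differences on the log-log curve, endpoints excluded,
ties broken towards the larger λ for stability.

## What the synthetic generator does and does not emulate

The generator reproduces the *scales and regimes* of a CMR-derived
anatomy — torso and pericardium dimensions, anterior-wall proximity,
heartbeat periodicity with diastole/systole phases, smooth
trigonometric-polynomial boundaries — and the full covariance model of the
deformation field.  It does not reproduce a patient's contour shapes, so
quantities tied to the specific anatomy (the exact Karhunen–Loève rank,
the exact L-curve corners, the numerical value of a convergence rate)
match real-data studies only in order of magnitude and in qualitative
behaviour.  Passing tests demonstrate the correctness of the operators,
the compression and the quadrature machinery, and the robustness of the
qualitative findings; they do not certify accuracy for any particular
clinical geometry.

## Known limitations

* Two-dimensional cross-sections only; no 3D kernels or surfaces.
* Homogeneous unit conductivity; no torso heterogeneity.
* The pericardial potential is prescribed, never simulated from ionic
  models; its template is an emulation with the stated propagation
  properties, not a validated electrogram model.
* The chest is fixed and certain; only the pericardium is uncertain.
* Total variation is linearised exactly once; no iteration to the true
  TV minimiser is attempted.
* Dense assembly and solves bound practical sizes to a few thousand
  collocation points.
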