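---
title: "Localizing cortical silences from scalp EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing cortical silences from scalp EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silencemapr)
```

## The problem

A *region of silence* is a contiguous cortical patch with no
electrophysiological activity — resected tissue, a lesion, or ischemia.
Localizing it from scalp EEG inverts the usual source-localization
question: background brain activity, normally treated as noise, is
exactly the signal whose *absence* must be detected. Classical inverse
methods (minimum-norm estimation, MUSIC, sLORETA) average background
activity away and, even when adapted to select low-power sources, do
poorly at this task; this package implements a method designed for it,
together with those adapted comparators and a complete synthetic test
harness.

The forward model is the standard linear one. With `n` electrodes, `p`
discrete cortical sources (radial dipoles), source signals `S` (p x T),
lead field `A` (n x p) and sensor noise `E`, the infinite-reference
potentials are `X = A S + E`. Only differential recordings exist in
practice: a referencing matrix `M` ((n-1) x n, one +1 and one −1 per
row) gives `Y = M X = A~ S + E~` with `A~ = M A`. The silent set `S` is
the set of rows of `S` that are identically zero; the working
assumptions are a single contiguous region, confined to one hemisphere,
small relative to the brain (`p − k ≫ k`), diagonal sensor-noise
covariance known (or estimated separately), and wide-sense-stationary
zero-mean sources with spatial covariance

  c_ij = sigma_s^2 exp(−gamma ||f_i − f_j||^2),

an isotropic exponential-decay profile with a single variance for all
non-silent sources (`f_i` are source positions in mm; `gamma` in
mm^-2).

## The two-stage algorithm

**Stage 1 (coarse grid, uncorrelated sources).** On a decimated grid
the sources are far enough apart to be treated as uncorrelated. For
each source `q` the cross-correlation coefficient `mu_qt = a~_q' y_t`
measures its instantaneous contribution; its variance, corrected for
noise and normalized by its no-silence value, is the contribution
measure

  beta_q = (Var(mu_qt) − a~_q' C~_z a~_q) / sum_j (a~_q' a~_j)^2,

which runs from 0 (all silent) to `sigma_s^2` (no silence) and needs no
estimate of `sigma_s`. Because lead fields are heavily spatially
low-passed, `beta` alone is a blurred and biased detector; the
*hemispheric baseline* sharpens it by judging each source against its
mirror twin across the longitudinal fissure,
`beta~_q = min(beta_q / beta_{q_m}, 1)` (midline-strip sources, which
have no twin, get 1). With an actual baseline recording the mirror
source is replaced by the same source in the baseline.

Silent sources are then selected by *convex spectral clustering*
(CSpeC): minimize `beta'(1−g) + lambda (1−g)' L (1−g)` over the relaxed
indicator `g in [0,1]^p` with `||g||_1 ≤ p − k`, where `L` is the
Laplacian of the z-nearest-neighbor graph (Gaussian weights,
`theta` = the standard deviation of all pairwise distances; `z = k` by
convention). The Laplacian term penalizes scattered selections, which
makes the region contiguous. `lambda` is tuned per `k` by minimizing
the sum of the two squared objective terms, each max-normalized over
the grid; `k` is chosen by matching modeled to measured scalp power
(max-normalized on the coarse grid, so `sigma_s` again cancels).

**Stage 2 (fine grid, correlated sources).** The coarse region's
center of mass initializes an iterative refinement: (i) select the
`phi` electrodes *least* affected by the current silence estimate (the
largest ratio of silenced to full modeled power) and re-fit
`(gamma, sigma_s)` by nonlinear least squares on their measured powers;
(ii) recompute the high-resolution contribution
`beta_q^high = (Var(mu_qt) − noise) / (a~_q'(A~ C_full A~')a~_q)` (in
[0,1]), baseline-ratioed if configured; (iii) re-solve CSpeC with
additional per-electrode power constraints
`(c_i' g + sigma_z_i^2 − Var(y_i))^2 ≤ zeta_i` on the selected
electrodes, where `c_i' g` is the modeled power at electrode `i` under
relaxed indicator `g`. Iterate until the center of mass moves less than
`delta` for two consecutive iterations. The whole procedure runs once
per candidate reference electrode (the ten midline positions); the
reference with the smallest normalized scalp-power mismatch wins.

## Numerical choices

* **Solver.** The CSpeC program is a convex QP: the box and cardinality
  constraints are linear (for `g ≥ 0` the l1 norm is a sum), and each
  squared power constraint is an interval constraint on an affine
  function, i.e. two linear inequalities. It is solved by an internal
  operator-splitting (ADMM) routine with over-relaxation, residual-based
  `rho` rebalancing, and a cached KKT factorization that is reused
  across the `k` grid and warm-started across the `lambda`/`k` sweeps
  and refinement iterations. Default relative tolerance 1e-7
  (config-exposed); feasibility of the returned iterate is checked and
  reported. The unit tests cross-check the solver against an
  independent active-set QP solver and against exhaustive combinatorial
  search on small graphs.
* **Power-constraint allowance.** The allowance `zeta_i` is the squared
  fit residual at the selected electrode, widened additively by the
  sampling error of a variance estimate (relative standard error
  `sqrt(2/T)`). The pure squared residual would place the constraint
  boundary exactly on the solution — with exact statistics an equality
  constraint — which is both statistically overconfident and
  numerically degenerate.
* **`(gamma, sigma_s)` fit.** The least-squares surface is multimodal:
  once the decay length `1/sqrt(gamma)` falls below the grid spacing the
  objective flattens in `gamma`. The fit refines from the previous
  iterate plus decade-spaced restarts and keeps the best residual.
  `gamma` is genuinely identifiable only on grids whose spacing
  resolves the decay length (about 3 mm at the simulation default
  `gamma = 0.12` mm^-2); on coarser grids `sigma_s` carries the fit and
  `gamma` is reported as-is.
* **Ties.** k-nearest-neighbor ties, "k smallest entries of g", and
  equal knee-point distances all resolve to the lowest index, so runs
  are bit-reproducible.
* **Degenerate inputs.** `k = 0` with nonnegative contributions returns
  `g = 1` analytically (ties resolve toward "no silence"). A source
  invisible to the array (zero denominator) gets contribution 0 with a
  warning. Doubly-silent mirrored pairs (0/0 in the ratio) count as
  silent, and the baseline division is floored at `1e-6 * max(beta)`.

## The synthetic test harness

No anatomical pipeline is bundled: the harness replaces the
MRI-derived cortex with a mirror-symmetric Fibonacci lattice on a
spherical cap (default radius 75 mm, cap half-angle 100 degrees, scalp
at 92 mm) and the boundary-element forward model with the analytic
Legendre-series potential of a radial dipole in a homogeneous
conducting sphere. This preserves everything the algorithm actually
uses — mirror symmetry, depth- and distance-dependent gains,
differential referencing — while removing all anatomy dependencies.
The electrode layout mirrors the same construction, with a ten-label
midline arc (Fpz ... Iz) serving as the reference-candidate set.

Simulated recordings follow the generative model exactly: a contiguous
silent patch (a seed source and its nearest same-hemisphere neighbors,
seeded no deeper than 30 mm below the scalp), Gaussian sources with the
exponential covariance (`gamma = 0.12` mm^-2, `sigma_s = 1` a.u.),
diagonal sensor noise with per-electrode variances drawn uniformly on
`[0, sigma_z_max]`, and `sigma_z_max` calibrated so the baseline
recording has a requested average SNR (default 9 dB). Note the SNR
definition divides electrode signal power by `sigma_z_max`;
consistency requires reading `sigma_z_max` as the *maximum noise
variance*, which is how it is implemented. A "real-PSD" mode convolves
each source with a linear-phase FIR filter of `1/f` magnitude (order
128, frequency-sampling design, unit energy) and discards the filter
warm-up; this changes temporal but not spatial structure — the zero-lag
covariance is scaled by the filter energy `rho_h(0)`, which the tests
verify — so localization is essentially PSD-insensitive.

What the harness does *not* emulate: realistic skull/CSF conduction
(three-shell or BEM head models), tangential dipole components, spatial
noise correlations, artifacts (ocular, muscular, cardiac), and
non-identical source statistics beyond the one asymmetric-variance
robustness test. Passing tests therefore demonstrate correctness of the
method under its own model assumptions at desk scale, not clinical
performance; the pipeline accepts externally supplied grids and lead
fields, so a realistic head model can be substituted without code
changes.

## Problem sizes and defaults

The bundled simulation study uses a 500-source fine grid, a 75-source
farthest-point-decimated coarse grid (15%), 64 electrodes, silent
regions of k = 20 sources, 9 dB average SNR, and T = 20,000 samples
(about 40 s at 512 Hz — within the data span the method is designed
for). Its pipeline settings are 5-point logarithmic `lambda` and `k`
grids (`k` up to 20% of the grid), `phi = ceiling((n−1)/4)` selected
electrodes, at most 5 refinement iterations, `delta` = one grid
spacing, and solver tolerance 3e-6; the package defaults are finer
(16-point `lambda` grid, 8-point `k` grid spanning 25%, 10 iterations,
1e-7) for single analyses where runtime is not a concern. Variance
estimation defaults to the sample covariance (exact for the flat-PSD
model); a Welch cross-spectral estimator (2 s Hann segments, 50%
overlap, band-integrated over 1-100 Hz) is available for band-limited
or shaped data.

## A worked example

```{r example, eval = FALSE}
bench <- make_test_bench(p_high = 300, n_elec = 64)
labels <- bench$layout$labels
scheme <- make_reference_scheme(length(labels), match("Cz", labels),
                                labels)
sim <- simulate_recording(bench$grids$high, bench$leadfields$high,
                          scheme, k = 12, snr_db = 9, T_len = 10000,
                          seed = 3)
fit <- run_silencemap(list(Cz = sim$recording), bench$leadfields,
                      bench$grids, sim$noise_model,
                      silencemap_config(lambda_grid_length = 8,
                                        k_grid_length = 5))
evaluate_silence(fit$silent_set, sim$truth, bench$grids$high,
                 fit$converged)
plot_silence(bench$grids$high, fit$silent_set, sim$truth)
```

## Known limitations

Single stationary unilateral region only (multiple, bilateral, or
propagating silences are out of scope); size estimation inherits the
method's ~30% error scale; performance degrades for deep sources and
sparse electrode coverage, where the contribution measures blur; the
hemispheric baseline presumes approximate structural and functional
symmetry and will mislead when both mirror twins are abnormal.
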