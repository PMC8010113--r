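# silencemapr

Localization of cortical **regions of silence** — contiguous patches of
brain tissue with no electrophysiological activity (surgical resections,
lesions, ischemic tissue) — from noninvasive scalp EEG.

Source localization asks *where activity is*; silence localization asks
*where it is missing*, and the background activity that source localizers
discard as noise is precisely the signal of interest. This package
implements the SilenceMap algorithm for that problem, plus the adapted
classical comparators and a fully synthetic evaluation harness, so the
whole method can be exercised end to end without any anatomical data.

Given differential recordings `Y = M A S + M E` (lead field `A`,
referencing matrix `M`), the method:

1. estimates per-source **contribution measures** from the variance of the
   cross-correlations `mu_qt = a~_q' y_t`, noise-corrected and normalized —
   `beta_q` on a coarse grid (uncorrelated-source model) and
   `beta_q^high in [0,1]` on the fine grid (correlated sources,
   `c_ij = sigma_s^2 e^{-gamma ||f_i - f_j||^2}`);
2. sharpens them with a **hemispheric baseline**,
   `beta~_q = min(beta_q / beta_{q_m}, 1)`, comparing each source with its
   mirror twin across the longitudinal fissure;
3. selects a contiguous silent set by **convex spectral clustering**
   (CSpeC): minimize `beta'(1-g) + lambda (1-g)' L (1-g)` over
   `g in [0,1]^p`, `||g||_1 <= p-k`, with per-electrode scalp-power
   constraints on the fine grid (`L` = z-nearest-neighbor graph Laplacian);
   `lambda`, the region size `k`, and the reference electrode are all
   chosen by normalized power-matching criteria;
4. iterates fine-grid covariance fitting and clustering until the region's
   center of mass stabilizes.

Modified MNE, MUSIC, and sLORETA comparators (per-time-point power
ranking, membership histogram, knee-point size estimate, center-of-mass
neighborhood) and the evaluation metrics (ΔCOM, Jaccard index, relative
size error Δk, convergence rate, hemispheric MAD) are included.

## Worked example

```r
library(silencemapr)

bench  <- make_test_bench(p_high = 300, n_elec = 64)  # synthetic head
labels <- bench$layout$labels
scheme <- make_reference_scheme(length(labels), match("Cz", labels), labels)

sim <- simulate_recording(bench$grids$high, bench$leadfields$high, scheme,
                          k = 12, snr_db = 9, T_len = 10000, seed = 3)

fit <- run_silencemap(list(Cz = sim$recording), bench$leadfields,
                      bench$grids, sim$noise_model,
                      silencemap_config(lambda_grid_length = 8,
                                        k_grid_length = 5))
fit
#> <silencemap_result> k_hat = 15, ref = Cz, converged = TRUE (3 iter)
#>   delta_pow = 0.01619; COM = (-60.2, 40.2, 4.7) mm

evaluate_silence(fit$silent_set, sim$truth, bench$grids$high, fit$converged)
#>   delta_com jaccard delta_k  k k_hat converged
#> 1  7.293971  0.6875    0.25 12    15      TRUE
```

The planted 12-source patch is recovered with 69% overlap and a
center-of-mass error of 7.3 mm (below the ~12 mm grid spacing); the size
is overestimated by 3 sources (Δk = 0.25). `plot_silence(bench$grids$high,
fit$silent_set, sim$truth)` draws the estimate against the truth, and
`run_benchmark()` scores the pipeline against the three modified source
localizers over many seeded regions.

A thin command-line wrapper is available too: `inst/cli/silencemap`
exposes `simulate`, `localize`, and `benchmark` subcommands over the same
functions.

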