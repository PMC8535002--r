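# jpllk — jump-preserving denoising of image sequences

Satellite archives, live-cell microscopy and fMRI all deliver *image
sequences*: the same scene observed at many time points, contaminated by
noise that is correlated across space **and** time. Denoising such a
sequence frame by frame wastes the information in neighboring frames;
denoising it with an ordinary 3-D smoother blurs the edges that carry most
of the scientific content. `jpllk` implements a jump-preserving local
smoother for this setting, for anyone who needs clean, edge-sharp image
stacks before segmentation, change detection or activation analysis.

## The estimator

For the observed sequence
`Z_ijk = f(x_i, y_j; t_k) + eps_ijk` on the unit design cube
(`x_i = i/nx`, `y_j = j/ny`, `t_k = k/nt`), each voxel is estimated from
the elliptical spatio-temporal neighborhood
`(x'-x)²/hx² + (y'-y)²/hy² ≤ 1`, `|t'-t| ≤ ht`:

1. a local plane `a + b(x_i-x) + c(y_j-y) + d(t_k-t)` is fitted by
   kernel-weighted least squares (truncated-Gaussian kernel); `â` is the
   local linear kernel (LLK) estimate and `(b̂, ĉ, d̂)` the gradient;
2. the neighborhood is split by the plane through the center orthogonal to
   the gradient — near an edge, approximately parallel to the edge surface —
   and the fit is repeated on each (closed) half;
3. with `e, e⁽¹⁾, e⁽²⁾` the weighted residual mean squares of the three
   fits and `D = max(e - e⁽¹⁾, e - e⁽²⁾)`: if `D ≤ u` the full fit is kept
   (no edge evidence), otherwise the one-sided fit with the smaller WRMS
   supplies the estimate, so jumps are not averaged across.

The parameters `(hx, ht, u)` (with `hy = hx`) are chosen by leave-one-out
cross-validation in which every kernel factor is replaced by the
ε-optimal **bimodal** kernel, `K_ε(0) = 0`: the self-observation deletes
itself and nearby, strongly correlated observations are down-weighted,
which keeps the score honest under spatio-temporal correlation where
ordinary CV collapses into undersmoothing.

The per-voxel fitting loop is compiled (Rcpp/RcppArmadillo); a 64×64×100
sequence denoises in a few seconds.

## Worked example

Simulate the package's reference phantom — a smooth paraboloid-plus-
sinusoid background with a circular edge of jump size 1 whose radius
oscillates in time — under correlated Gaussian noise, denoise it, and
score the result:

```r
library(jpllk)
rep <- simulate_sequence(nx = 64, ny = 64, nt = 50,
                         sigma = 0.1, rho = 0.1, seed = 1)
fit <- denoise_sequence(rep$observed, hx = 0.04, ht = 0.07, u = 0.025)
fit
#> Jump-preserving LLK denoising (jump, gaussian kernel)
#>   sequence: 64 x 64 pixels, 50 frames
#>   bandwidths: hx = 0.04, hy = 0.04, ht = 0.07; threshold u = 0.025
#>   decisions: full 90.3%, side1 4.6%, side2 5.1%, tie_avg 0.0%

evaluate_estimate(fit$fhat, rep$truth)
#> # A tibble: 1 × 4
#>        mse js_estimate js_truth     ep
#> 1 0.000397       0.112    0.107 0.0519

evaluate_estimate(rep$observed, rep$truth)   # the raw data, for contrast
#> # A tibble: 1 × 4
#>      mse js_estimate js_truth    ep
#> 1 0.0100       0.279    0.107  1.62
```

Reading the numbers: the raw sequence has MSE `sigma² = 0.01` and carries
2.6× the true cumulative jump magnitude (JS) because noise masquerades as
gradient, giving an edge-preservation error (EP) of 162%. Denoising cuts
the MSE by a factor of 25 while keeping JS within 5.2% of the truth — noise
removed, edges kept. About 10% of voxels (the band along the moving edge)
used a one-sided fit; the decision map is in `fit$decision` and
`autoplot(fit, what = "decision")` shows where.

Bandwidth selection, when you don't know the right triple:

```r
sel <- select_parameters(rep$observed,
                         hx_grid = c(0.03, 0.04),
                         ht_grid = c(0.07, 0.10),
                         u_grid  = c(0.025, 0.05))
sel$best_params          # selected (hx, hy, ht, u)
autoplot(sel)            # CV score surface
```

`tidy()` / `glance()` methods return the score table and the selected row
as tibbles; `run_experiment()` and `summarize_experiment()` reproduce
replicated simulation tables (MSE ×10³, standard error ×10⁵, EP %).

## Command line

A thin wrapper over the same functions lives at `inst/cli/jpllk.R`:

```sh
Rscript inst/cli/jpllk.R simulate --nx 64 --ny 64 --nt 50 \
    --sigma 0.1 --rho 0.1 --seed 1 --out obs.tif
Rscript inst/cli/jpllk.R denoise --input obs.tif --output denoised.tif \
    --hx 0.04 --ht 0.07 --u 0.025 --decision-map decisions.tif
Rscript inst/cli/jpllk.R evaluate --estimate denoised.tif --truth truth_obs.tif
```

Stacks may be multi-page float TIFF, directories of PNG frames, or raw
binary arrays with a JSON sidecar; integer intensities are rescaled to
[0, 1] on read (the threshold `u` lives on the squared-intensity scale, so
a common scale matters).

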