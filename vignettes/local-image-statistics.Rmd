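---
title: "Local multipoint image statistics for brain MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local multipoint image statistics for brain MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mritexture)
```

## The problem

Structural brain MRI slices are not natural scenes, and their spatial
statistics differ from the image class that shaped human vision. Two
complementary characterizations capture this. First, the *global*
second-order structure: the spatial power spectrum, which for brain slices
is approximately a power law, $P(\vec k) \approx A\,|\vec k|^{-\lambda}$,
with $\lambda$ typically between about 2 and 3. Second, the *local*
non-Gaussian structure that remains after the spectrum is equalized:
correlations among small groups of nearby pixels, measured on whitened,
binarized patches. This package implements both stages, together with the
synthetic inputs needed to verify every stage quantitatively when the
underlying clinical databases cannot be redistributed.

## The pipeline

For each database of volumes (slices plus binary parenchyma masks):

1. **ROI extraction** (`convex_hull_mask()`, `largest_inscribed_rectangle()`,
   `sample_roi()`). For every slice, the convex hull of the mask is
   rasterized, the largest axis-aligned rectangle inside it is found by the
   row-histogram dynamic program, and one $R N \times R N$ patch is placed
   uniformly at random inside that rectangle. Slices whose rectangle cannot
   hold the patch are discarded (and counted). For $N > 1$ the patch is
   reduced to $R \times R$ by $N \times N$ block averaging
   (`downsample_blocks()`), which conserves the grand mean exactly. The
   protocol's scales are $(R, N) = (64, 1)$ and $(32, 2)$.
2. **Spectrum estimation** (`roi_periodogram()`, `mean_spectrum()`).
   Unwindowed, unnormalized-FFT periodograms of all ROIs are averaged bin
   by bin. Frequencies are carried in cycles/mm from the voxel metadata;
   anisotropic in-plane voxels scale the two frequency axes independently.
3. **Slope fit** (`fit_spectral_slope()`, `default_band()`). Ordinary least
   squares of $\log_{10} P$ on $\log_{10}|\vec k|$ over *all* 2-D bins in
   the band from 2 cycles per ROI to 10% below Nyquist — $(0.03125, 0.45)$
   cycles/mm at $(64, 1)$ and an upper endpoint of $0.225$ cycles/mm after
   downsampling. The slope is reported positive; the 95% CI comes from the
   OLS coefficient distribution with bins treated as independent. A
   radially-averaged variant is available as a sensitivity flag but is not
   the default protocol.
4. **Whitening** (`build_whitening_filter()`, `whiten_roi()`). Each Fourier
   component is attenuated by the inverse square root of the database-mean
   spectrum; the DC gain is 0, so whitening also removes the mean. The gain
   grid is real and symmetric under $\vec k \to -\vec k$, so the output is
   real to machine precision (asserted at $10^{-10}$ relative).
5. **Binarization** (`binarize_per_brain()`). A one-pixel border is trimmed
   (wrap-around artifacts of the periodic filtering), the surviving pixel
   values are pooled over all ROIs of one brain, and each trimmed ROI is
   thresholded at that pooled median: strictly above → white (+1),
   otherwise black (−1).
6. **Local statistics** (`block_counts()`, `probs_to_stats()`,
   `stats_for_roi()`). All overlapping $2\times2$ neighborhoods are
   tabulated into the 16 coloring probabilities, which a linear transform
   maps to ten independent coordinates in $[-1, 1]$: the luminance
   imbalance $\gamma$; four pairwise correlations $\beta$ (horizontal,
   vertical, and the two diagonals); four three-point correlations
   $\theta$ (the four orientations of an L-shaped glider); and the
   four-point parity $\alpha$. Each coordinate is the expectation of the
   product of $\pm1$ pixel values over its template.
7. **Aggregation** (`summarize_stats()`, `bootstrap_summary()`). Means,
   SDs, skewness, excess kurtosis and the $9\times9$ covariance
   ($\gamma$ excluded) across ROIs, with percentile bootstrap CIs: slices
   are resampled with replacement (pooled across volumes), a *fresh* ROI is
   drawn per drawn slice, and the whitening filter and per-brain medians
   are recomputed within each resample (a `freeze_filter` switch trades
   this fidelity for speed).

`run_pipeline()` composes the stages in this order and writes CSV/JSON
artifacts plus a manifest (configuration echo, seed, versions) from which a
run can be reproduced exactly.

## Synthetic inputs and what they do (and do not) show

The generators provide inputs whose true parameters are known, so each
stage has a quantitative oracle:

- `gen_power_law_field()` shapes white Gaussian noise in the frequency
  domain with amplitude $|\vec k|^{-\lambda/2}$ (DC zero; optionally
  $\sqrt{g}$ extra amplitude on the two frequency axes to emulate the
  axis-aligned power excess seen in clinical spectra). The construction is
  periodic (circulant), so the expected periodogram equals the target
  spectrum *exactly*, bin by bin — slope-recovery tests are unbiased by
  design. Fields cut out of a larger field lose this exactness: their
  periodograms leak, and a small residual pair correlation (~0.03 in the
  diagonal $\beta$s at 72→64 cutting) survives whitening. That residual is
  a property of any windowed protocol, including the clinical one.
- `gen_texture()` realizes the maximum-entropy binary ensemble with one
  prescribed coordinate by one-sided Markov recursions: independent chains
  along rows/columns/diagonals for the $\beta$s, and parity recursions for
  $\theta$ (canonical orientation with the L vertex at bottom-right; the
  other three orientations are produced by mirroring, whose exact
  coordinate permutation is itself a tested property) and $\alpha$. One
  structural caveat is worth stating plainly: for the edge $\beta$s the
  maximum-entropy ensemble is a stack of independent chains, which forces
  $\alpha = \beta^2$; no stationary ensemble with $|\beta| > 1/2$ and
  $\alpha = 0$ exists at all, because the implied block probabilities turn
  negative. All other off-target coordinates converge to zero. Note also
  that sliding-window estimates from a single image have sampling SDs
  *larger* than the naive binomial $\sqrt{(1-v^2)/n}$, because overlapping
  windows share pixels; tests therefore calibrate tolerances on replicate
  ensembles rather than on single images.
- `gen_phantom_volume()` builds nested-ellipse slices (background, rim,
  tissue interior with elliptical blobs) whose intensity *ordering* mimics
  T1 (white matter brightest among brain tissues, CSF darkest) or FLAIR
  (CSF darkest, bright lesion blobs), plus Gaussian white noise with SD a
  prescribed fraction (the study conditions use 0/3/5/7%) of the most
  intense tissue value. It reproduces the contrast structure and noise
  model only — no MRI physics (sequence timing, relaxation, k-space
  sampling), and no claim of anatomical realism. Passing tests on phantoms
  validate the pipeline's mechanics, not any clinical claim.

All generators consume a single integer seed and are bit-identical across
reruns given the same seed.

## Numerical and design choices

- **Conventions.** Images are R matrices (row = image row), 1-based closed
  indices; rectangles are `(top, left, height, width)`. Pixel values after
  binarization are $+1$ (white) / $-1$ (black); block colorings are indexed
  by the 4-bit word (TL, TR, BL, BR).
- **Tie-breaking.** Equal-area rectangles are resolved by area, then
  height, then topmost, then leftmost — the protocol is silent, and
  determinism is required for reproducible runs. Threshold ties at the
  median go to black (strict `>`); any fixed rule preserves the $\gamma$
  balance for continuous-valued whitened data.
- **Trim-then-binarize.** The border is trimmed *before* the median is
  computed, so the threshold is defined on exactly the pixels that are
  analyzed; the pooled white/black imbalance per brain is then at most one
  pixel, i.e. $|\gamma| \le 2/\text{count}$ exactly. Binarizing first and
  trimming after would break this bound by a border-sampling term of order
  $1/\sqrt{\text{count}}$.
- **DC handling.** The DC bin is retained in periodograms but never enters
  a slope fit, and its whitening gain is 0: the zero-frequency power
  depends on arbitrary intensity offsets and is irrelevant after median
  binarization.
- **Sliding tabulation.** Block probabilities use all $(H-1)(W-1)$
  overlapping neighborhoods, which is what makes the stationarity
  constraint (left column of one block = right column of the next)
  meaningful; counts stay integer until normalization.
- **Exact fixed points need odd sizes.** On an even-sided checkerboard or
  stripe image the two window phases cannot balance exactly (the window
  count is odd), so canonical-pattern tests use odd sizes, where the gamut
  endpoint values are exact.
- **Moment estimators.** Skewness and excess kurtosis are the
  bias-uncorrected moment ratios $m_3/m_2^{3/2}$ and $m_4/m_2^2 - 3$
  (`e1071`, type 1). Bootstrap CIs are percentile intervals; B defaults to
  500.
- **Problem sizes in the test suite.** The suite verifies slope recovery at
  300 ROIs per slope ($\lambda \in \{2, 2.5, 3\}$, tolerance 0.05), the
  Gaussian null at 200 whitened 64×64 ROIs (3 SE), ensemble-periodogram
  unbiasedness at 500 fields (5% RMS per bin), texture recovery on 16
  replicates per coordinate/target, and bootstrap coverage with 200 outer
  replications at B = 200 against a $\beta_h = 0.4$ texture ensemble
  (nominal 95% CI, observed coverage required in [90%, 99%]). These sizes
  were chosen so each check's Monte-Carlo error is well below the property
  it verifies.

## Known limitations

- Whitening uses the empirical mean spectrum of the same ROI draw it is
  applied to; at small ensemble sizes (tens of ROIs) the shared estimation
  error induces a visible bias in the pair statistics (≈0.02 at 20 ROIs,
  vanishing like 1/n).
- The $\theta$/$\alpha$ recursions realize maximum-entropy ensembles with
  the prescribed coordinate only; joint prescription of several
  coordinates is out of scope.
- Three-dimensional (through-slice) statistics, skull stripping, DICOM
  ingestion and registration are out of scope; the mask is an input
  contract.
- Modality (unimodality/bimodality) analysis of statistic distributions is
  not implemented; skewness and excess kurtosis are.

## A minimal worked run

```{r, eval = FALSE}
vol <- gen_phantom_volume(5, 128, 128, style = "T1", noise_frac = 0.03,
                          seed = 1)
res <- run_pipeline(vol, scales = list(c(64, 1), c(32, 2)), seed = 2,
                    out_dir = "phantom-run")
res$R64N1$slope
res$R64N1$summary
```
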