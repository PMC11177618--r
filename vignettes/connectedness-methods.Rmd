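---
title: "Network connectedness mapping: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network connectedness mapping: models, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conmap)
```

## The statistic and the two-step procedure

`conmap` measures, for every voxel $v$ of a resting-state fMRI network
mask, how strongly that voxel is coupled to the rest of the network.
The per-voxel statistic is the network *connectedness*

$$ c_v = \operatorname{arctanh}\!\Big( \tfrac{1}{|N|-1}
   \sum_{u \in N,\, u \neq v} r_{uv} \Big), $$

the Fisher-z transform of the mean Pearson correlation of $v$'s time
series with every *other* voxel of the network $N$, computed over
non-censored frames. Averaging first and transforming second follows
the convention of the tools this statistic originates from; a
sensitivity variant that transforms each $r_{uv}$ before averaging is
available (`z_first = TRUE`), at quadratic memory cost because it needs
the dense correlation matrix. The self-correlation is excluded by
default ("every other voxel" read literally); `include_self = TRUE`
reproduces implementations whose row mean keeps the diagonal.

Group inference on a paired contrast of conditions (A vs B, same
subjects) proceeds in two steps:

1. **Hotspots.** Per subject and condition, a connectedness map; per
   voxel, a paired two-tailed t across subjects, standardized to the
   normal scale, $z(t) = \Phi^{-1}(F_t(t; n-1))$; clusters formed at
   $|z| > 1.96$ (two-tailed $p < .05$, deliberately lenient because
   network-wide averaging dilutes correlation differences); cluster
   sizes calibrated by a sign-flip Monte-Carlo permutation null (below).
2. **Drivers.** Each hotspot's spatially averaged series seeds a
   voxelwise connectivity map (Fisher-z Pearson r with every network
   voxel), per subject and condition; the paired contrast is thresholded
   at $|z| > 3.291$ (two-tailed $p < .001$) with a per-hotspot
   permutation cluster-size null **and** a hard 20-voxel floor, the
   conservative minimum motivated by permutation thresholds that
   typically land in the single-digit-to-teens range at this strict
   forming threshold.

Positive cluster sign always means A > B for the contrast `c(A, B)`.

## The permutation null

For $n$ subjects, each of `n_perm` permutations swaps the condition
labels of a uniformly random subset of exactly $\lfloor n/2 \rfloor$
subjects — equivalently, sign-flips those subjects' paired differences,
which is how it is implemented (a sign flip leaves $d_i^2$ unchanged, so
only permuted means need recomputing and the whole permutation bank is a
single matrix product). For each permutation the maximum cluster size
across *both* signs is recorded; one null, and hence one threshold, per
contrast (the sign-joint maximum matches reporting a single cluster-size
threshold per network). The reported threshold is the smallest integer
$s$ whose exceedance proportion among the permuted maxima is strictly
below `alpha`; with `n_perm = 100` and `alpha = 0.05` that is the 5th
largest maximum plus one. Ties are handled conservatively by
construction (the "+1" rule). Two readings of "flip half the subjects"
exist — a fresh random half each iteration versus sampling without
repetition across iterations; we draw independently per permutation,
since 100 draws are a vanishing fraction of $\binom{24}{12}$
possibilities and duplicates are harmless.

Degenerate cases are pinned down explicitly: identical conditions give
all-zero permuted maps, all max sizes 0, and threshold 1; a voxel with
zero variance of differences contributes $t = 0$ when the mean
difference is 0 and a signed sentinel otherwise; $z(t)$ is evaluated
through log-space tail probabilities with the smaller tail and the sign
restored, so $|t|$ in the hundreds maps to a large finite z (capped at
38) instead of overflowing.

## Network definition and targeting

Group masks are built from seed connectivity: per subject, the seed's
mean series is correlated with every voxel and Fisher-z transformed; a
one-sample t across subjects is standardized to z; voxels beyond the
$p = 10^{-8}$ standard-normal quantile (positive tail only — networks
are positive-connectivity structures; a two-sided flag exists) are
clustered, clusters below a simulated Gaussian-noise cluster-size
threshold are discarded, and the survivors are dilated (default one
iteration, 6-connectivity) to form the mask. The noise threshold
re-implements the mechanism of the classic cluster-simulation approach:
smoothed unit-variance Gaussian fields on the same grid, two-sided
voxel threshold, max-cluster-size distribution, same exceedance rule.
The overlap voxel count between two defined masks is reported as a
first-class quantity.

Individualized targeting selects the top fraction (default 5%) of an
anatomical mask's voxels by within-mask connectedness, and then the
search-mask voxel whose series best matches the target's mean series
(ties broken toward the lowest linear index, deterministically). Both
selections are invariant to per-voxel affine rescaling of the data.

## Preprocessing model

Residualization is one ordinary-least-squares fit per voxel whose
design contains an intercept, an optional linear trend, the nuisance
regressors, and sine/cosine terms at every DFT frequency outside the
passband (default 0.01–0.1 Hz) — bandpass and nuisance removal in a
single simultaneous linear model, which avoids filter/regression
interaction artifacts. The fit uses non-censored frames only; censored
frames are zero-filled in the output and carried as flags. Downstream
correlation code always drops flagged frames: including literal zeros
would bias r toward 0, while the zero-fill itself preserves the on-disk
convention of excised frames. Rank-deficient designs are handled by QR
projection with a warning. Spatial smoothing is separable Gaussian
convolution ($\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis,
zero-padded edges) and precedes residualization in the pipeline;
intensity normalization scales each voxel's non-censored mean to 100
and is a no-op for correlations.

## The synthetic study generator

`generate_study()` emulates a multi-subject, multi-condition
within-subject design of residualized BOLD runs. Voxel $v$'s series in
condition $c$ is

$$ y_v = \sum_{\text{networks } k \ni v} (\lambda_k + \Delta_{v,k}(c))\,
   g_k + \varepsilon_v, $$

with $g_k$ the network's latent signal — AR(1), drawn independently per
run, and standardized to unit *sample* variance so that condition
differences in coupling, not realized latent power, drive connectedness
differences (without this, a single shared latent makes all network
voxels' z values move together and the max-cluster-size null develops a
fat tail of network-spanning clusters that no real multi-source
recording shows). The noise $\varepsilon$ is AR(1) in time
($\phi = 0.3$ by default; bandpassed residuals are autocorrelated, not
white), spatially smoothed to 4-mm FWHM to mimic smoothing-induced
neighborhood correlation, and rescaled to `noise_sd` per voxel — the
smoothing sets spatial *correlation*, not amplitude, which keeps the
in-network variance at $\lambda^2 + \sigma^2$ as the model states. A
5% fraction of frames per run is zero-filled and flagged, mirroring
motion censoring.

Defaults: two overlapping 600-voxel block networks ("HCN"- and
"PN"-like, sharing a 64-voxel block) on a 20×20×12 grid of 2-mm voxels,
12 subjects, 300 frames at TR 0.555 s, `base_loading = 0.55`,
`noise_sd = 1`. The loading was chosen so the mean within-network
connectedness is about $z \approx 0.25$ — the level typical of
resting-state networks — which also places permutation cluster-size
thresholds in the tens of voxels, the regime the method operates in on
real data. Full-study scale (24 subjects, 550 frames) is available by
configuration. Ground-truth effects are coupling deltas confined to
known blocks; `truth_overlap()` scores recovery by Dice.

What the generator does **not** emulate: hemodynamic convolution,
head-motion structure, scanner drift or artifacts, anatomical geometry,
between-subject coupling differences (every subject shares the same
loadings), and multi-source network substructure beyond what the
configured latents provide. Passing recovery and calibration tests on
these data therefore demonstrates that the estimator and its
permutation calibration are correct under the stated model — not that
the pipeline is robust to every pathology of real recordings.

## Numerical and interface choices

* Voxel indices are 1-based, R's native convention (and RNifti's);
  world coordinates apply the affine to the 0-based index, so index
  `(1,1,1)` sits at the affine origin. Reported x is sign-flipped by
  default (`right_negative_x`) so right-hemisphere voxels carry
  negative x, matching the radiological table convention; this is
  configurable.
* Cluster adjacency defaults to faces-only 6-connectivity (the
  conservative choice); 18 and 26 are available everywhere.
* Correlations within floating-point reach of ±1 are clipped to
  ±(1 − 10⁻⁷) with a warning before `arctanh`.
* Constant voxel series yield `NaN` and a warning, and their pairs are
  dropped from other voxels' means rather than poisoning them.
* A hotspot set records its contrast; `find_drivers()` refuses runs
  from any other contrast, so a hotspot can never be probed with data
  that did not define it.
* All randomness (generation, permutations, noise simulations) is
  governed by explicit seeds; per-stage child seeds are derived
  arithmetically so one pipeline seed reproduces every output
  byte-for-byte.
* The iTBS schedule quotes 190 s as the *final-train onset* under 10-s
  train spacing (19 × 10 s); the literal first-to-last span is 192 s.
  Both are reported by `schedule_summary()`; the onset convention is
  the one that matches the protocol's usual quoted duration.

## Validation scale

The test suite validates calibration and recovery at a deliberate
desk scale chosen as this package's own validation design: 100
replicate null studies (12 subjects, 300 frames, 20×20×12 grid, 100
permutations) for the family-wise rate; 20 seeds for hotspot recovery
of a 40-voxel coupling decrease (Dice ≥ 0.3 against truth); 5 seeds for
driver recovery of a remote 30-voxel coupling change under the 20-voxel
floor. `scripts/acceptance.R` re-runs the same designs end to end and
writes the measured rates as JSON.

## Known limitations

Connectedness dilutes as networks grow (a fixed-size effect shifts the
network mean less in a larger mask), so detection power depends on the
mask/effect size ratio. The permutation null conditions on the observed
maps; with very few subjects the set of distinct sign-flips is small
and thresholds become coarse. Driver detection excludes the hotspot's
own voxels by default (the seed trivially correlates with itself;
`allow_self_drivers` restores inclusion). The mask-formation noise
simulation is mechanism-faithful to its classic counterpart but does not
estimate smoothness from data — the smoothing level is an input.
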