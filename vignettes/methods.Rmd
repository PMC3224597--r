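---
title: "Methods: simulating realistic 1D 1H-NMR mixture spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating realistic 1D 1H-NMR mixture spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the fixed preprocessing
contract, the numerical choices and the limitations of `nmrmixsim`. All
code chunks are illustrative (`eval = FALSE`); the same computations are
exercised, with assertions, in the package's test suite.

## 1. Model

A simulated replicate spectrum on the shared ppm grid is

$$ y(\delta) \;=\; \sum_{k=1}^{K} y_k(\delta)\, c_k\, p_k \;+\;
   \varepsilon(\delta), \qquad
   \varepsilon(\delta) \sim \mathcal N(0, \sigma_n^2), $$

where $y_k$ is the preprocessed, unit-integral-normalised standard
spectrum of metabolite $k$, $c_k$ its simulated concentration, $p_k$ its
proton count, and

$$ \sigma_n = \frac{\max_\delta y(\delta)}{\mathrm{SNR}}. $$

With `SNR = Inf` (or `noise_enabled = FALSE`) the mixture is the exact
linear combination. After noise addition the spectrum is kernel-smoothed
once more (`final_smoothing`), which autocorrelates the white noise in
the way apodization does during real spectral processing; the realised
noise SD is therefore attenuated below $\sigma_n$ by the kernel's
$\ell_2$ norm.

### Concentrations

Concentrations are strictly positive. Univariate draws use the
zero-truncated normal via the inverse CDF:

$$ c = \mu + \sigma\,\Phi^{-1}\!\big(\Phi(-\mu/\sigma) +
     u\,(1 - \Phi(-\mu/\sigma))\big), \qquad u \sim U(0,1). $$

Its mean is $\mu + \sigma\,\phi(\alpha)/(1-\Phi(\alpha))$ with
$\alpha = -\mu/\sigma$; the test suite checks the closed-form value
$1.2876$ at $\mu = \sigma = 1$ against the empirical mean.

When a template row has a mean but no SD, the fallback is
$\mathrm{sd} = \mathrm{mean} / 1.95$; when only a range is given, half
the range replaces the mean in that formula.

### Correlated concentrations

A requested correlation matrix $R$ (assembled from pairwise entries,
unspecified pairs default to 0) is first repaired to the nearest
positive semidefinite correlation matrix by alternating projections
between the PSD cone and the unit-diagonal affine set with Dykstra's
correction (tolerance $10^{-8}$, at most 200 iterations, final
eigenvalue clip plus diagonal renormalisation). An already-PSD matrix is
returned bitwise unchanged. The covariance is
$\Sigma = \mathrm{diag}(\sigma)\, R\, \mathrm{diag}(\sigma)$; if
$\Sigma$ is not positive definite its diagonal is inflated by
$|\lambda_{\min}| + 10^{-8}\,\mathrm{tr}(\Sigma)/K$. Multivariate draws
are Gaussian with rejection of any vector containing a non-positive
component; the attempt budget is `max_attempts_factor` (default 1000)
times the requested sample size, and exhausting it is an error rather
than a silent fallback.

## 2. Preprocessing contract

Each standard spectrum passes through this fixed order:

1. **Regrid** — linear interpolation onto the target grid; grid points
   outside the source range get intensity 0.
2. **Exclusion regions** — intensities in each closed ppm interval are
   set to exactly 0. Defaults: $(-\infty, 0.2]$ (internal reference) and
   $[4.5, 6.0]$ (residual water/urea).
3. **Moving-median baseline** — consecutive windows of
   `baseline_window` ppm; the within-window median, assigned at the
   window centre and linearly interpolated between centres (constant
   beyond the outermost centres), is subtracted only from points
   strictly below `max(intensity) / baseline_divisor`.
4. **Negative-artifact clip** — the spectrum is split into
   `n_noise_bins` contiguous equal-count bins; $\sigma_{med}$ is the
   median of the per-bin SDs, $M$ the median intensity, and every point
   strictly below $l = M - 3\sigma_{med}$ is set to $l$.
5. **Kernel smoothing** — see Section 4.

Unit-integral normalisation (intensities divided by their sum) is
applied once, immediately before mixing. All threshold comparisons in
the pipeline are strict `<`: a value exactly at a threshold is never
modified.

## 3. pH-driven peak shifts

Peaks are detected as strict local maxima (plateau apexes take the
centre point, ties toward lower ppm) above
$\max(0.01 \cdot \max y,\; 5\,\sigma_{med})$, then matched to tabulated
multiplet positions within `multiplet_tolerance` (0.03 ppm); unmatched
peaks are never shifted. Each multiplet gets one shift evaluated at its
mean position $\delta$ between acid-limit $a$ and base-limit $b$:

$$ \eta = s\,(a - \delta) + (1 - s)\,(b - \delta), \qquad
   s = \mathrm{logistic}(\mathrm{pH} - \mathrm{p}K_a), $$

so the shifted position is $s\,a + (1-s)\,b$: the midpoint at
$\mathrm{pH} = \mathrm{p}K_a$, monotone in pH, bounded by the limits.

**Convention note.** As written, $\mathrm{pH} \gg \mathrm{p}K_a$ drives
the peak to the *acid*-limit column $a$ and $\mathrm{pH} \ll
\mathrm{p}K_a$ to $b$. This is the relation implemented verbatim from
the source titration formula even though chemical intuition would swap
the roles; callers supply the two limit columns in whichever order
matches their titration data. Tests pin the midpoint, both limits and
monotonicity under exactly this convention.

Missing $\mathrm{p}K_a$ values are sampled once per
metabolite-replicate from $\mathcal N(6.5, 0.5)$; missing limits are
symmetric offsets $\delta \pm |\mathcal N(0.05, 0.01)|$. The spectral
segment spanning a multiplet's detected peaks out to the flanking local
minima is translated by the nearest-grid-point rounding of $\eta$;
vacated points are filled with the smaller of the two original edge
intensities, edge overruns are clipped with a warning, and the spectrum
is re-smoothed once.

## 4. Numerical choices

**Sub-threshold smoothing sources.** Kernel smoothing replaces each
point strictly below `smoothing_threshold_fraction * max` (default 0.8)
by a kernel-weighted mean of its neighbours within $\pm 3$ bandwidths
(normal kernel) or $\pm 1$ bandwidth (box, triangle, epanechnikov),
weights $K(\text{index distance}/\text{bandwidth})$ renormalised over
the neighbours actually used. Crucially, **super-threshold points are
excluded as sources as well as targets**: including them leaks peak
mass into the flanks (measured $+12\%$ area inflation for a tall
singlet) and breaks the area-faithfulness the pipeline must preserve.
An independent brute-force oracle in the tests implements the same
semantics.

**Area faithfulness.** For clean fixtures with equal line widths the
full pipeline changes relative peak areas by under 0.1% (measured
0.058% for two Lorentzians of areas 1:3, half-width 0.015 ppm, 8192
points). With unequal widths the max/10 baseline-protection threshold
acts asymmetrically on the two peaks and distortion grows to a few
percent; noisy-fixture recovery is tested at a 2% tolerance.

**Deterministic seeding.** All randomness derives from one root seed
via an LCG-style mixer, `derive_seed(root, ...)`, producing substreams
below $2^{31}$. Each experimental group's substream is keyed on the
*content digest of its concentration template*, not on the group label:
two groups with identical templates therefore produce bit-identical
replicates, and any change to a template changes only that group's
stream.

**Truncated-normal sampling.** Inverse-CDF (never rejection) for the
univariate case, so a fixed seed yields identical draws regardless of
$\mu/\sigma$; validated against a rejection-sampling oracle by a
Kolmogorov–Smirnov test.

**File formats.** Standards load from a plain-text two-column dialect
or a Bruker-style processed-data subset (binary `1r` of 32-bit signed
integers plus a `procs` file with `SI`, `OFFSET`, `SW`, `BYTORDP`,
`NC_proc`; $\mathrm{ppm}_i = \mathrm{OFFSET} - i\,\mathrm{SW}/SI$,
intensities scaled by $2^{NC_{proc}}$). The writer picks the smallest
`NC_proc` that avoids integer overflow and keeps integer data exactly
round-trippable.

## 5. Parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `n_replicates` | 50 | replicates per group |
| `ppm_min`, `ppm_max`, `n_points` | 0, 10, 16384 | shared grid |
| `snr` | 200 | noise: $\sigma_n = \max y / \mathrm{SNR}$ |
| `exclusion_regions` | $(-\infty,0.2]$, $[4.5,6]$ | ppm intervals zeroed |
| `baseline_window` | 0.3125 | ppm, moving-median window |
| `baseline_divisor` | 10 | peak-protection threshold $\max/10$ |
| `n_noise_bins` | 32 | bins for $\sigma_{med}$ |
| `kernel`, `kernel_bandwidth` | normal, 5 | bandwidth in grid points |
| `smoothing_threshold_fraction` | 0.8 | fraction of max |
| `peak_min_height_fraction` | 0.01 | detection floor, fraction of max |
| `peak_noise_multiple` | 5 | detection floor, multiples of $\sigma_{med}$ |
| `multiplet_tolerance` | 0.03 | ppm, peak-to-table matching |
| `shift_enabled` | TRUE | pH shifting on/off |
| `ph_mode`, `ph_value` | fixed, 6.3 | or sampled: `ph_mean` 6.3, `ph_sd` 0.3 |
| `pka_mean`, `pka_sd` | 6.5, 0.5 | fallback $\mathrm{p}K_a$ |
| `limit_offset_mean`, `limit_offset_sd` | 0.05, 0.01 | ppm, fallback limits |
| `max_attempts_factor` | 1000 | rejection budget multiplier |
| `rng_seed` | 1 | root seed ($< 2^{31}$) |

`load_parameters()` reads these from a `key = value` text file
(`#` comments, `Inf` accepted, exclusion regions as `lo:hi; lo:hi`);
unknown keys warn and are ignored.

## 6. Synthetic standards generator

`make_synthetic_nssd()` emulates a standards database so the pipeline is
testable without external data: Lorentzian multiplets
($\frac{1}{\pi}\frac{\gamma}{(x - x_0)^2 + \gamma^2}$, patterns 1 /
1:1 / 1:2:1 / 1:3:3:1), polynomial baselines, Gaussian noise, occasional
negative dips, and optionally asymmetric lineshapes (two half-widths
joined at the apex with matched height, renormalised to unit area). Peak
positions avoid the default exclusion regions; each metabolite carries
one $\mathrm{p}K_a$, with acid/base limit positions written for
even-indexed metabolites and omitted (exercising the fallbacks) for the
rest. The generator writes both dialects plus `protons.csv`,
`multiplets.txt`, `experiments.csv`, `synonyms.csv` and a control
concentration template, and records exact ground truth (per-peak
position, area, half-width) for assertions. It emulates *spectral
shape*, not scalar coupling physics: no second-order effects, no
field-strength dependence.

## 7. Problem sizes used in validation

- Correlation recovery: $K = 3$, $2 \times 10^4$ replicates,
  requested $(-0.7, 0.8, -0.4)$, all recovered within $\pm 0.03$.
- Two-group separation: 5 metabolites, 20 replicates per group,
  fold changes $(0.5, 0.5, 2, 2, 1)$; mean-difference signs at the
  principal peaks match the folds and the leading principal-component
  gap exceeds the pooled within-group SD.
- Grids from 512 to $2^{16}$ points in unit and property tests.

## 8. Limitations

- Lineshapes and couplings are only as realistic as the standards
  database; the built-in generator is deliberately simple.
- Peak shifting translates whole multiplet segments rigidly; it does not
  model differential shifts within a multiplet or peak-shape changes
  with pH, and overlapping multiplets that share a local minimum move as
  detected, not as tabulated.
- One $\mathrm{p}K_a$ per metabolite; polyprotic behaviour is not
  modelled.
- The titration convention maps high pH to the `acid` column (see
  Section 3); users with conventional tables should swap the columns.
- Noise is Gaussian and stationary before the final smoothing; no
  $t_1$-noise, phasing errors or solvent-suppression artifacts.
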