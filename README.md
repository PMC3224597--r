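# nmrmixsim

Simulation of realistic one-dimensional <sup>1</sup>H-NMR spectra of
complex metabolite mixtures such as human urine.

## The problem

Statistical methods for metabolomics (peak alignment, deconvolution,
biomarker discovery) need test data whose ground truth is known. Real
spectra never come with one; naive simulations (sums of idealised peaks)
miss the features that make real spectra hard: baseline distortion,
peak-position variation with pH, correlated metabolite concentrations and
apodization-coloured noise. `nmrmixsim` assembles mixture spectra from a
local database of pure-compound standard spectra so that every replicate
has a fully known composition.

## The model

Each replicate spectrum is a concentration-weighted sum of preprocessed,
unit-normalised standard spectra plus Gaussian noise:

```
y(δ) = Σ_k  y_k(δ) · c_k · p_k  +  ε(δ),      ε(δ) ~ N(0, σ_n²)
```

where `y_k` is the preprocessed standard spectrum of metabolite *k*
(normalised to unit integrated intensity), `c_k` its simulated
concentration, `p_k` its proton count, and the noise level is set by a
signal-to-noise ratio: `σ_n = max(y) / SNR`. After noise addition the
spectrum is kernel-smoothed once, which autocorrelates the noise the way
apodization does in real processing.

Concentrations are drawn from zero-truncated normal distributions
(inverse-CDF sampling). When the template gives a mean but no standard
deviation, the fallback is `sd = mean / 1.95` (or half the range divided
by 1.95 when a range is given). A user-supplied inter-metabolite
correlation matrix is repaired to the nearest positive semidefinite
correlation matrix (alternating projections with Dykstra correction)
before building the covariance `Σ = diag(σ) R diag(σ)`; positivity is
enforced by rejection.

Standard spectra are preprocessed in a fixed order: regridding onto the
target ppm grid, zeroing of exclusion regions (defaults: below 0.2 ppm
and 4.5–6.0 ppm), moving-median baseline correction (window 0.3125 ppm,
peaks above max/10 protected), negative-artifact clipping at
`median − 3·σ_med`, and kernel smoothing of sub-threshold points.

Peak positions respond to pH through a Henderson–Hasselbalch relation:
each multiplet is translated to the logistic interpolation
`s·a + (1−s)·b` between its two tabulated limit positions `a` and `b`,
with `s = logistic(pH − pKa)`. At `pH = pKa` the peak sits at the
midpoint `(a + b) / 2`.

## Worked example

The package ships a synthetic standards generator, so the full pipeline
runs without any external data:

```r
library(nmrmixsim)

db <- file.path(tempdir(), "demo-nssd")
info <- make_synthetic_nssd(3, db, seed = 42L, n_points = 4096L)

nssd <- load_nssd(db, "text")
ctrl <- read_concentration_template(file.path(db, "templates_control.csv"))
case <- apply_fold_changes(ctrl, c(met01 = 2, met03 = 0.5))

p <- default_parameters()
p$n_points <- 4096L
p$n_replicates <- 10L
p$rng_seed <- 7L

res <- simulate_experiment(nssd, ctrl, case, p)
print(res$control[[1]])
#> <mixture_spectrum> group=control replicate=1, 4096 points, 3 metabolites, sigma_n=0.421

m <- spectra_matrix(res, "control")
dim(m)
#> [1] 4096   10

round(head(res$draws$control$draws, 3), 1)
#>      met01 met02 met03
#> [1,] 129.7 184.3 265.7
#> [2,] 292.0 768.3 351.8
#> [3,] 357.9 434.9 299.2
```

`write_experiment_result(res, dir)` exports the spectra (TSV),
concentrations, shift assignments, preprocessing reports and the
parameter file. A command-line entry point is installed at
`system.file("scripts", "nmrmixsim", package = "nmrmixsim")` with
`simulate` and `make-fixtures` subcommands.

## Documentation

See the methods vignette (`vignettes/methods.Rmd`, source form) for the
full description of the preprocessing contract, the titration
convention, the seeding scheme and numerical choices.
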