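# Shared fixtures and independent oracles used across test files.

with_seed <- function(seed, expr) {
  set.seed(seed)
  expr
}

# small default grid for pipeline tests
test_grid <- function(n = 2048L, lo = 0, hi = 10) ppm_grid(lo, hi, n)

# a clean singlet standard on a grid
make_singlet <- function(centre = 3, half_width = 0.01, area = 1,
                         grid = test_grid(), baseline = 0, noise_sd = 0,
                         metabolite_id = "synthetic") {
  make_lorentzian_standard(
    lorentzian_spec(list(list(centre = centre, j_spacing = 0.02,
                              weights = 1, half_width = half_width,
                              area = area)),
                    baseline = baseline, noise_sd = noise_sd),
    grid, metabolite_id)
}

# brute-force kernel-weighted-mean oracle (independent of kernel_smooth)
oracle_kernel_smooth <- function(y, kernel, bandwidth, threshold_fraction) {
  kf <- switch(kernel,
               normal = function(u) exp(-u^2 / 2) / sqrt(2 * pi),
               box = function(u) ifelse(abs(u) <= 1, 1, 0),
               triangle = function(u) ifelse(abs(u) <= 1, 1 - abs(u), 0),
               epanechnikov = function(u)
                 ifelse(abs(u) <= 1, 0.75 * (1 - u^2), 0))
  hw <- if (kernel == "normal") ceiling(3 * bandwidth) else ceiling(bandwidth)
  n <- length(y)
  thr <- threshold_fraction * max(y)
  out <- y
  for (i in seq_len(n)) {
    if (!(y[i] < thr)) next
    js <- max(1, i - hw):min(n, i + hw)
    js <- js[y[js] < thr]           # sub-threshold neighbours only
    w <- kf((js - i) / bandwidth)
    out[i] <- sum(w * y[js]) / sum(w)
  }
  out
}

# rejection-sampling oracle for the zero-truncated normal
oracle_truncnorm_rejection <- function(mu, sigma, n) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * n, mu, sigma)
    out <- c(out, x[x > 0])
  }
  out[seq_len(n)]
}

# independent recomputation of the negative-artifact clip limit
oracle_clip_limit <- function(y, n_bins) {
  n <- length(y)
  bin <- as.integer(cut(seq_len(n), breaks = n_bins, labels = FALSE))
  sds <- vapply(split(y, bin), sd, 0)
  sds[is.na(sds)] <- 0
  median(y) - 3 * median(sds)
}

# the inter-metabolite correlation matrix demonstrated in the package's
# worked three-metabolite example (citrate, creatinine, 2-oxoglutarate)
demo_correlation_matrix <- function() {
  R <- matrix(c(1, -0.7, 0.8,
                -0.7, 1, -0.4,
                0.8, -0.4, 1), 3, 3,
              dimnames = list(c("citrate", "creatinine", "oxoglutarate"),
                              c("citrate", "creatinine", "oxoglutarate")))
  R
}

demo_correlation_spec <- function() {
  data.frame(metabolite_a = c("citrate", "citrate", "creatinine"),
             metabolite_b = c("creatinine", "oxoglutarate", "oxoglutarate"),
             r = c(-0.7, 0.8, -0.4))
}

# one shared synthetic database per test session (generated, not stored)
shared_nssd_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir) || !dir.exists(dir)) {
      dir <<- file.path(tempdir(), "nmrmixsim-test-nssd")
      make_synthetic_nssd(5, dir, seed = 20260101L, n_points = 2048L,
                          noise_sd = 0.001)
    }
    dir
  }
})
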