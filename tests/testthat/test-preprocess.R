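# Preprocessing: regridding, exclusions, baseline, artifact removal,
# smoothing, normalisation

test_that("regridding interpolates linearly and zeros outside the range", {
  s <- standard_spectrum(c(0, 1, 2), c(1, 2, 3))
  same <- regrid(s, c(0, 1, 2))
  expect_equal(same$intensity, c(1, 2, 3))
  # a line is reproduced exactly at interior points
  fine <- regrid(s, seq(0, 2, by = 0.25))
  expect_equal(fine$intensity, 1 + seq(0, 2, by = 0.25))
  # extrapolation rule
  wide <- regrid(s, seq(-1, 3, by = 0.5))
  expect_equal(wide$intensity[wide$ppm < 0], c(0, 0))
  expect_equal(wide$intensity[wide$ppm > 2], c(0, 0))
})

test_that("default exclusion regions zero exactly [0, 0.2] and [4.5, 6.0] ppm", {
  grid <- seq(0, 10, by = 0.1)
  s <- standard_spectrum(grid, rep(1, length(grid)))
  out <- apply_exclusion_regions(s, default_parameters()$exclusion_regions)
  excl <- (grid >= 0 & grid <= 0.2) | (grid >= 4.5 & grid <= 6.0)
  expect_identical(out$intensity[excl], rep(0, sum(excl)))
  expect_identical(out$intensity[!excl], rep(1, sum(!excl)))
  # idempotent and exact
  out2 <- apply_exclusion_regions(out, default_parameters()$exclusion_regions)
  expect_identical(out2$intensity, out$intensity)
  # degenerate lists
  expect_identical(apply_exclusion_regions(s, list())$intensity, s$intensity)
  expect_identical(apply_exclusion_regions(s, list(c(-1, 11)))$intensity,
                   rep(0, length(grid)))
})

test_that("baseline correction leaves constants and peaks alone, flattens offsets", {
  grid <- test_grid(1024)
  # constant spectrum: every point equals the max, nothing is below max/10
  s <- standard_spectrum(grid, rep(5, 1024))
  expect_equal(baseline_correct(s)$intensity, rep(5, 1024),
               ignore_attr = TRUE)
  # all-zero spectrum unchanged
  s0 <- standard_spectrum(grid, rep(0, 1024))
  expect_equal(baseline_correct(s0)$intensity, rep(0, 1024),
               ignore_attr = TRUE)
  # tall peak on a constant offset: off-peak points return to ~0,
  # the apex (above threshold) is untouched
  peak <- make_singlet(centre = 5, half_width = 0.02, area = 2 * pi,
                       grid = grid)$spectrum
  y <- peak$intensity / max(peak$intensity) * 100 + 5
  tall <- standard_spectrum(grid, y)
  out <- baseline_correct(tall, window = 0.3125, divisor = 10)
  apex <- which.max(y)
  expect_identical(out$intensity[apex], y[apex])
  off_peak <- abs(grid - 5) > 1
  expect_lt(max(abs(out$intensity[off_peak])), 0.5)
  # window below the grid spacing is rejected
  expect_error(baseline_correct(tall, window = 1e-4), "spacing")
})

test_that("negative-artifact removal clips at l = M - 3*sigma_med", {
  grid <- test_grid(640)
  y <- rep(0, 640); y[100] <- -10
  s <- standard_spectrum(grid, y)
  out <- remove_negative_artifacts(s, 32)
  l <- oracle_clip_limit(y, 32)
  expect_equal(attr(out, "limit"), l)
  expect_gte(min(out$intensity), l)
  expect_equal(out$intensity[100], l)

  # constant spectrum: sigma_med = 0, l = M, unchanged
  sc <- standard_spectrum(grid, rep(3, 640))
  expect_equal(remove_negative_artifacts(sc, 32)$intensity, rep(3, 640),
               ignore_attr = TRUE)

  # n_bins = 1: sigma_med is the global SD; hand oracle on 6 points
  y6 <- c(0, 1, 2, 3, 4, -20)
  s6 <- standard_spectrum(seq(0, 5, by = 1), y6)
  out6 <- remove_negative_artifacts(s6, 1)
  l6 <- median(y6) - 3 * sd(y6)
  expect_equal(attr(out6, "limit"), l6)
  expect_equal(out6$intensity, pmax(y6, l6))

  expect_error(remove_negative_artifacts(s6, 10), "exceeds")
})

test_that("clipping twice is equivalent to once with a monotone limit", {
  set.seed(8)
  grid <- test_grid(512)
  y <- rnorm(512)
  s <- standard_spectrum(grid, y)
  once <- remove_negative_artifacts(s, 16)
  twice <- remove_negative_artifacts(once, 16)
  expect_gte(attr(twice, "limit"), attr(once, "limit"))
  expect_gte(min(twice$intensity), attr(twice, "limit"))
})

test_that("kernel smoothing matches a brute-force weighted-mean oracle", {
  set.seed(21)
  grid <- test_grid(256)
  kernels <- c("normal", "box", "triangle", "epanechnikov")
  for (i in 1:25) {
    y <- rnorm(256)
    kern <- kernels[1 + (i %% 4)]
    bw <- sample(1:8, 1)
    frac <- runif(1, 0.3, 1)
    s <- standard_spectrum(grid, y)
    ours <- kernel_smooth(s, kern, bw, frac)$intensity
    oracle <- oracle_kernel_smooth(y, kern, bw, frac)
    expect_equal(ours, oracle, tolerance = 1e-12)
  }
})

test_that("kernel smoothing reduces white-noise variance and respects the threshold", {
  set.seed(33)
  grid <- test_grid(2048)
  y <- rnorm(2048)
  s <- standard_spectrum(grid, y)
  out <- kernel_smooth(s, "normal", 5, 1)
  expect_lt(var(out$intensity), var(y))
  # constant spectrum: weighted mean of constants is the constant;
  # nothing is strictly below the threshold so nothing changes
  sc <- standard_spectrum(grid, rep(2, 2048))
  expect_identical(kernel_smooth(sc, "normal", 5, 1)$intensity,
                   rep(2, 2048))
  # threshold at or below the minimum: unchanged
  ylow <- abs(y) + 10
  slow <- standard_spectrum(grid, ylow)
  frac <- min(ylow) / max(ylow) * 0.99
  expect_identical(kernel_smooth(slow, "box", 3, frac)$intensity, ylow)
  expect_error(kernel_smooth(s, "gaussianish", 5, 0.8), "kernel")
})

test_that("unit-integral normalisation is exact, idempotent and scale-invariant", {
  grid <- seq(0, 3, by = 1)
  s <- standard_spectrum(grid, c(2, 2, 2, 2))
  expect_equal(normalize_unit_integral(s)$intensity, rep(0.25, 4))
  s2 <- standard_spectrum(grid, c(1, 0, 3, 0))
  n2 <- normalize_unit_integral(s2)
  expect_equal(n2$intensity, c(0.25, 0, 0.75, 0))
  expect_equal(normalize_unit_integral(n2)$intensity, n2$intensity)
  # scale invariance
  s3 <- standard_spectrum(grid, 7.3 * c(1, 0, 3, 0))
  expect_equal(normalize_unit_integral(s3)$intensity, n2$intensity)
  expect_equal(n2$stage, "normalized")
  s0 <- standard_spectrum(grid, rep(0, 4))
  expect_error(normalize_unit_integral(s0), "no signal")
})

test_that("the full pipeline preserves relative peak areas on clean fixtures", {
  # equal half-widths so the peak-protection threshold and the
  # moving-median baseline act symmetrically on both peaks
  grid <- test_grid(8192)
  spec <- lorentzian_spec(list(
    list(centre = 2.5, j_spacing = 0.02, weights = 1, half_width = 0.015,
         area = 1),
    list(centre = 7.5, j_spacing = 0.02, weights = 1, half_width = 0.015,
         area = 3)))
  std <- make_lorentzian_standard(spec, grid)
  params <- default_parameters()
  params$n_points <- 8192L
  out <- preprocess_standard(std$spectrum, params)
  norm <- normalize_unit_integral(out$spectrum)
  region1 <- norm$ppm > 1.5 & norm$ppm < 3.5
  region2 <- norm$ppm > 6.5 & norm$ppm < 8.5
  ratio_raw <- sum(std$spectrum$intensity[region2]) /
    sum(std$spectrum$intensity[region1])
  ratio_pre <- sum(norm$intensity[region2]) / sum(norm$intensity[region1])
  # noiseless, baseline-free: relative areas move < 0.1%
  expect_equal(ratio_pre, ratio_raw, tolerance = 1e-3)
  expect_equal(sum(norm$intensity), 1, tolerance = 1e-9)

  # noisy fixture with a baseline: areas recovered within 2%
  spec_n <- lorentzian_spec(spec$multiplets, baseline = c(0.02, 0.001),
                            noise_sd = 0.003)
  std_n <- with_seed(17, make_lorentzian_standard(spec_n, grid))
  out_n <- normalize_unit_integral(
    preprocess_standard(std_n$spectrum, params)$spectrum)
  f1 <- sum(out_n$intensity[region1])
  f2 <- sum(out_n$intensity[region2])
  expect_equal(f2 / f1, 3, tolerance = 0.02)

  # an all-zero raw spectrum fails at normalisation
  zero <- standard_spectrum(grid, rep(0, length(grid)))
  pz <- preprocess_standard(zero, params)
  expect_error(normalize_unit_integral(pz$spectrum), "no signal")
})

test_that("the preprocessing report records a consistent clip limit", {
  grid <- test_grid(2048)
  std <- with_seed(3, make_lorentzian_standard(
    lorentzian_spec(list(list(centre = 3, j_spacing = 0.02, weights = 1,
                              half_width = 0.01, area = 1)),
                    noise_sd = 0.002), grid))
  params <- default_parameters(); params$n_points <- 2048L
  rep <- preprocess_standard(std$spectrum, params)$report
  expect_equal(rep$clip_limit, rep$M - 3 * rep$sigma_med)
  f <- withr::local_tempfile(fileext = ".json")
  write_preprocess_report(rep, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$clip_limit, rep$clip_limit, tolerance = 1e-12)
})
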