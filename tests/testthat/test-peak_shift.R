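# Peak detection, multiplet grouping and the pH titration shift model

test_that("peak detection finds isolated apexes and ignores noise floors", {
  grid <- test_grid(2048)
  std <- make_singlet(centre = 3, half_width = 0.02, grid = grid)
  peaks <- detect_peaks(std$spectrum)
  expect_equal(nrow(peaks), 1L)
  expect_equal(peaks$ppm, grid[which.min(abs(grid - 3))], tolerance = 1e-6)

  zero <- standard_spectrum(grid, rep(0, 2048))
  expect_equal(nrow(detect_peaks(zero)), 0L)
})

test_that("a 1:2:1 triplet yields three apexes at the constructed positions", {
  grid <- test_grid(4096)
  spec <- lorentzian_spec(list(list(centre = 4, j_spacing = 0.05,
                                    weights = c(1, 2, 1),
                                    half_width = 0.005, area = 1)))
  std <- make_lorentzian_standard(spec, grid)
  peaks <- detect_peaks(std$spectrum, min_height_fraction = 0.05)
  expect_equal(nrow(peaks), 3L)
  expect_equal(sort(peaks$ppm), std$truth$ppm, tolerance = 0.01)
})

test_that("plateau apexes take the centre point", {
  grid <- seq(0, 10, length.out = 101)
  y <- rep(0, 101); y[40:44] <- 5; y[39] <- 2; y[45] <- 2
  s <- standard_spectrum(grid, y)
  peaks <- detect_peaks(s, min_height_fraction = 0.1, noise_multiple = 0)
  expect_equal(peaks$index, 42L)
})

test_that("peaks join the multiplet with the nearest tabulated position within tolerance", {
  peaks <- data.frame(index = c(10L, 20L, 30L),
                      ppm = c(7.051, 8.5, 7.062),
                      intensity = c(1, 1, 1), multiplet = NA_integer_)
  mult <- list(list(peaks = c(7.05, 7.06), pKa = 6, acid = NULL,
                    base = NULL))
  out <- group_multiplets(peaks, mult, tolerance = 0.02)
  expect_equal(out$multiplet, c(1L, NA_integer_, 1L))

  # equidistant tabulated peaks: lower-ppm entry wins, with a warning
  two <- list(list(peaks = 6.99, pKa = NA_real_, acid = NULL, base = NULL),
              list(peaks = 7.01, pKa = NA_real_, acid = NULL, base = NULL))
  p1 <- data.frame(index = 1L, ppm = 7.00, intensity = 1,
                   multiplet = NA_integer_)
  expect_warning(res <- group_multiplets(p1, two, tolerance = 0.02),
                 "equidistant")
  expect_equal(res$multiplet, 1L)
})

test_that("pH sampling honours fixed and sampled modes", {
  p <- default_parameters()
  p$ph_mode <- "fixed"; p$ph_value <- 7
  expect_equal(sample_ph(p, 5), rep(7, 5))
  p$ph_mode <- "sampled"; p$ph_mean <- 7; p$ph_sd <- 0
  expect_equal(sample_ph(p, 4), rep(7, 4))
  p$ph_sd <- 0.5
  set.seed(12)
  x <- sample_ph(p, 1e4)
  expect_equal(mean(x), 7, tolerance = 0.02)
  expect_equal(sd(x), 0.5, tolerance = 0.02)
  p$ph_sd <- -1
  expect_error(sample_ph(p, 2), "ph_sd")
})

test_that("the titration shift hits the midpoint, limits and printed example", {
  # at pH = pKa the shifted position is the acid/base midpoint
  eta <- henderson_hasselbalch_shift(7.1, 7.0, 7.3, 6.5, 6.5)
  expect_equal(7.1 + eta, (7.0 + 7.3) / 2)
  # extreme pH drives the position to the acid limit (as the relation is
  # written) and extreme acidity to the base limit
  eta_hi <- henderson_hasselbalch_shift(7.1, 7.0, 7.3, 6.5, 6.5 + 50)
  eta_lo <- henderson_hasselbalch_shift(7.1, 7.0, 7.3, 6.5, 6.5 - 50)
  expect_equal(7.1 + eta_hi, 7.0, tolerance = 1e-12)
  expect_equal(7.1 + eta_lo, 7.3, tolerance = 1e-12)
  # direct evaluation at pH - pKa = ln 3: position (3a + b) / 4
  eta3 <- henderson_hasselbalch_shift(7.1, 7.0, 7.3, 6.5, 6.5 + log(3))
  expect_equal(7.1 + eta3, 7.075)
  expect_error(henderson_hasselbalch_shift(7.1, Inf, 7.3, 6.5, 7),
               "finite")
})

test_that("the shifted position is monotone in pH and bounded by the limits", {
  set.seed(44)
  for (i in 1:50) {
    delta <- runif(1, 1, 9)
    a <- delta + runif(1, -0.2, 0.2)
    b <- delta + runif(1, -0.2, 0.2)
    pka <- runif(1, 4, 9)
    ph <- sort(runif(20, 0, 14))
    pos <- delta + henderson_hasselbalch_shift(delta, a, b, pka, ph)
    expect_true(all(pos >= min(a, b) - 1e-9 & pos <= max(a, b) + 1e-9))
    d <- diff(pos)
    if (a < b) expect_true(all(d <= 1e-12)) else
      if (a > b) expect_true(all(d >= -1e-12))
  }
})

test_that("a singlet at pH = pKa relocates to the grid point nearest the midpoint", {
  grid <- test_grid(4096)
  std <- make_singlet(centre = 3, half_width = 0.01, grid = grid)
  params <- default_parameters()
  params$n_points <- 4096L
  pre <- preprocess_standard(std$spectrum, params)$spectrum
  mult <- list(list(peaks = 3.0, pKa = 6.0, acid = 3.2, base = 2.9))
  asg <- build_shift_assignment(pre, mult, params, pH = 6.0)
  expect_equal(nrow(asg), 1L)
  expect_equal(asg$eta, (3.2 + 2.9) / 2 - 3.0, tolerance = 1e-9)
  shifted <- shift_spectrum(pre, asg, params, resmooth = FALSE)
  apex <- shifted$ppm[which.max(shifted$intensity)]
  # the detected apex sits within one grid point of the tabulated
  # position, and eta is rounded to the grid, so the relocated apex is
  # within one grid spacing of the midpoint
  spacing <- diff(grid)[1]
  expect_lte(abs(apex - (3.2 + 2.9) / 2), spacing + 1e-12)
})

test_that("segment translation conserves the moved intensity before re-smoothing", {
  grid <- test_grid(4096)
  std <- make_singlet(centre = 3, half_width = 0.01, grid = grid)
  params <- default_parameters(); params$n_points <- 4096L
  pre <- preprocess_standard(std$spectrum, params)$spectrum
  mult <- list(list(peaks = 3.0, pKa = 6.0, acid = 3.3, base = 3.1))
  asg <- build_shift_assignment(pre, mult, params, pH = 9)  # near acid limit
  shifted <- shift_spectrum(pre, asg, params, resmooth = FALSE)
  tot_region <- function(s, lo, hi) sum(s$intensity[s$ppm > lo & s$ppm < hi])
  before <- tot_region(pre, 2.5, 3.8)
  after <- tot_region(shifted, 2.5, 3.8)
  expect_equal(after, before, tolerance = 0.01)
})

test_that("a shift rounding to zero grid points leaves the spectrum unchanged", {
  grid <- test_grid(2048)
  std <- make_singlet(centre = 3, half_width = 0.02, grid = grid)
  params <- default_parameters(); params$n_points <- 2048L
  pre <- preprocess_standard(std$spectrum, params)$spectrum
  spacing <- diff(grid)[1]
  mult <- list(list(peaks = 3.0, pKa = 6.0, acid = 3.0 + spacing / 10,
                    base = 3.0 - spacing / 10))
  asg <- build_shift_assignment(pre, mult, params, pH = 6.0)
  shifted <- shift_spectrum(pre, asg, params, resmooth = FALSE)
  expect_identical(shifted$intensity, pre$intensity)
})

test_that("a shift beyond the grid edge is clipped with a warning", {
  grid <- test_grid(1024, 0, 1)
  std <- make_singlet(centre = 0.95, half_width = 0.005, grid = grid)
  s <- std$spectrum
  peaks <- detect_peaks(s, 0.5, 0)
  asg <- data.frame(multiplet = 1L, delta = 0.95, a = 2.5, b = 2.4,
                    pKa = 6, pH = 12,
                    eta = henderson_hasselbalch_shift(0.95, 2.5, 2.4, 6, 12))
  peaks$multiplet <- 1L
  attr(asg, "peaks") <- peaks
  class(asg) <- c("shift_assignment", "data.frame")
  params <- default_parameters()
  expect_warning(out <- shift_spectrum(s, asg, params, resmooth = FALSE),
                 "grid edge")
  expect_equal(length(out$intensity), length(s$intensity))
})

test_that("fallback pKa and limits are sampled when the table omits them", {
  grid <- test_grid(2048)
  std <- make_singlet(centre = 3, half_width = 0.02, grid = grid)
  params <- default_parameters(); params$n_points <- 2048L
  pre <- preprocess_standard(std$spectrum, params)$spectrum
  mult <- list(list(peaks = 3.0, pKa = NA_real_, acid = NULL, base = NULL))
  set.seed(9)
  asg <- build_shift_assignment(pre, mult, params, pH = 6.5)
  expect_equal(nrow(asg), 1L)
  expect_true(is.finite(asg$pKa))
  expect_gt(asg$a, asg$delta)       # acid limit above, base below
  expect_lt(asg$b, asg$delta)
  # shifted position bounded by the sampled limits
  pos <- asg$delta + asg$eta
  expect_true(pos >= min(asg$a, asg$b) - 1e-9 &&
              pos <= max(asg$a, asg$b) + 1e-9)
})
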