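test_that("mask union obeys inclusion-exclusion and idempotence", {
  d <- c(4, 4, 4)
  a <- array(FALSE, d); a[1:5] <- TRUE
  b <- array(FALSE, d); b[10:16] <- TRUE
  m <- combine_masks(voi_mask(a, "ESO"), voi_mask(b, "GTV"))
  expect_equal(sum(m$indicator), 12)           # disjoint additivity
  expect_identical(m$name, "EG")
  same <- combine_masks(voi_mask(a, "ESO"), voi_mask(a, "GTV"))
  expect_identical(same$indicator, a)           # idempotence
  ov_a <- array(FALSE, d); ov_a[1:10] <- TRUE
  ov_b <- array(FALSE, d); ov_b[8:15] <- TRUE   # share voxels 8..10
  expect_equal(sum(combine_masks(voi_mask(ov_a, "ESO"),
                                 voi_mask(ov_b, "GTV"))$indicator), 15)
  set.seed(5)
  for (i in 1:20) {                             # |A u B| = |A| + |B| - |A n B|
    ra <- array(runif(64) < 0.3, d); rb <- array(runif(64) < 0.3, d)
    expect_equal(sum(combine_masks(voi_mask(ra, "ESO"),
                                   voi_mask(rb, "GTV"))$indicator),
                 sum(ra) + sum(rb) - sum(ra & rb))
  }
  expect_error(combine_masks(voi_mask(a, "ESO"),
                             voi_mask(array(FALSE, c(3, 3, 3)), "GTV")),
               "shapes")
})

test_that("fixed-bin-number discretization follows the clamped floor formula", {
  expect_equal(discretize_fixed_bin_number(c(0, 0.5, 9.99, 10), 10),
               c(1L, 1L, 10L, 10L))
  expect_equal(discretize_fixed_bin_number(rep(7, 5), 16), rep(1L, 5))
  expect_error(discretize_fixed_bin_number(1:3, 0), "positive")
  expect_error(discretize_fixed_bin_number(numeric(0), 4), "non-empty")
  set.seed(2)
  v <- rnorm(200)
  b <- discretize_fixed_bin_number(v, 12)
  expect_true(all(b[order(v)] == cummax(b[order(v)])))   # monotone in v
  expect_identical(discretize_fixed_bin_number(3.7 * v - 11, 12), b)  # affine
  expect_true(all(b >= 1 & b <= 12))
})

test_that("filter bank has 1 + |sigmas| + 8 images under any configuration", {
  ct <- random_grid(c(12, 12, 12))
  expect_length(build_filter_bank(ct), 12)     # default: 12 derived images
  cfg <- filter_config(log_sigmas = c(2, 4), bin_numbers = 10)
  expect_length(build_filter_bank(ct, cfg), 11)
  cfg0 <- filter_config(log_sigmas = numeric(0),
                        wavelet_subbands = character(0), bin_numbers = 10)
  expect_length(build_filter_bank(ct, cfg0), 1)
  expect_error(filter_config(log_sigmas = -1), "positive")
})

test_that("LoG of a constant image vanishes and the impulse response matches the analytic kernel", {
  const <- volume_grid(array(120, c(14, 14, 14)))
  lg <- fistulomics:::log_filter(const, 3)
  expect_lt(max(abs(lg$values)), 1e-6 * 120)
  # impulse at the center, spacing 1 mm, sigma 3 mm
  n <- 33; ctr <- 17; sig <- 3
  imp <- array(0, c(n, n, n)); imp[ctr, ctr, ctr] <- 1
  resp <- fistulomics:::log_filter(volume_grid(imp), sig)$values
  x <- (1:n) - ctr
  g1 <- function(x) exp(-x^2 / (2 * sig^2)) / sqrt(2 * pi * sig^2)
  G <- outer(outer(g1(x), g1(x)), g1(x))
  R2 <- outer(outer(x^2, x^2, `+`), x^2, `+`)
  analytic <- G * (R2 / sig^4 - 3 / sig^2)
  expect_lt(max(abs(resp - analytic)) / max(abs(analytic)), 1e-3)
})

test_that("stationary wavelet transform reconstructs the input exactly", {
  set.seed(9)
  x <- array(rnorm(10 * 12 * 8), c(10, 12, 8))
  bands <- swt3_coif1(x)
  expect_named(bands, c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"))
  rec <- iswt3_coif1(bands)
  expect_lt(max(abs(rec - x)) / max(abs(x)), 1e-6)
})

test_that("NIfTI round trip preserves geometry and values", {
  v <- volume_grid(array(as.double(1:60), c(3, 4, 5)),
                   spacing = c(1.152, 1.152, 3), origin = c(-10, 4, 2.5))
  f <- tempfile(fileext = ".nii.gz")
  write_nifti(v, f, datatype = "float64")
  v2 <- read_nifti(f)
  expect_identical(v2$values, v$values)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(v2$origin, v$origin, tolerance = 1e-5)
  m <- voi_mask(array(c(TRUE, FALSE), c(3, 4, 5) * c(1, 1, 2))[, , 1:5], "ESO")
  fm <- tempfile(fileext = ".nii.gz")
  write_nifti(m, fm)
  expect_identical(as_voi_mask(read_nifti(fm), "ESO")$indicator, m$indicator)
})

test_that("volume and mask constructors reject invalid input", {
  expect_error(volume_grid(array(1, c(2, 2, 2)), spacing = c(0, 1, 1)), "positive")
  expect_error(volume_grid(array(c(1, NA), c(1, 1, 2))), "finite")
  expect_error(voi_mask(array(2, c(2, 2, 2)), "ESO"), "0/1")
  grid <- random_grid(c(3, 3, 3))
  empty <- voi_mask(array(FALSE, c(3, 3, 3)), "ESO")
  expect_error(extract_first_order(grid, empty), "empty")
})
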