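# Independent literal-formula oracle for the 18 first-order features,
# written directly from the definitions (kept free of the package's own
# helper functions on purpose).
first_order_oracle <- function(v, voxvol, n_bins) {
  n <- length(v)
  rng <- range(v)
  bins <- if (rng[1] == rng[2]) rep(1L, n) else
    pmin(floor(n_bins * (v - rng[1]) / diff(rng)) + 1L, n_bins)
  p <- as.numeric(table(factor(bins, levels = 1:n_bins))) / n
  p <- p[p > 0]
  m <- sum(v) / n
  q <- stats::quantile(v, c(.1, .25, .75, .9), names = FALSE, type = 7)
  sub <- v[v >= q[1] & v <= q[4]]
  c(sum(v^2), voxvol * sum(v^2), -sum(p * log2(p)), min(v), q[1], q[4], max(v),
    m, stats::median(v), q[3] - q[2], max(v) - min(v), sum(abs(v - m)) / n,
    sum(abs(sub - mean(sub))) / length(sub), sqrt(sum(v^2) / n),
    sum((v - m)^3) / n / (sum((v - m)^2) / n)^1.5,
    sum((v - m)^4) / n / (sum((v - m)^2) / n)^2,
    sum((v - m)^2) / n, sum(p^2))
}

test_that("first-order features match the literal-formula oracle", {
  img <- random_grid(c(5, 5, 5), spacing = c(1.2, 1.2, 2), seed = 7)
  mk <- full_mask(c(5, 5, 5))
  got <- extract_first_order(img, mk, n_bins = 12)
  expect_length(got, 18)
  want <- first_order_oracle(img$values[mk$indicator], 1.2 * 1.2 * 2, 12)
  expect_equal(unname(got), want, tolerance = 1e-9)
})

test_that("first-order degenerate and hand cases", {
  cst <- volume_grid(array(3, c(2, 2, 2)))
  fo <- extract_first_order(cst, full_mask(c(2, 2, 2)), 10)
  expect_equal(fo[["Energy"]], 8 * 9)
  expect_equal(fo[["Entropy"]], 0)
  expect_equal(fo[["Variance"]], 0)
  expect_equal(fo[["Uniformity"]], 1)
  v4 <- volume_grid(array(c(1, 2, 3, 4), c(4, 1, 1)))
  fo4 <- extract_first_order(v4, full_mask(c(4, 1, 1)), 4)
  expect_equal(fo4[["Mean"]], 2.5)
  expect_equal(fo4[["Range"]], 3)
  # mean/variance invariant to voxel ordering within the mask
  set.seed(3)
  img <- random_grid(c(4, 4, 4), seed = 11)
  perm <- img
  perm$values[] <- sample(img$values)
  a <- extract_first_order(img, full_mask(c(4, 4, 4)), 8)
  b <- extract_first_order(perm, full_mask(c(4, 4, 4)), 8)
  expect_equal(a[["Mean"]], b[["Mean"]])
  expect_equal(a[["Variance"]], b[["Variance"]])
})

test_that("shape features: unit voxel, digitized sphere, dimensional scaling", {
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  sh1 <- extract_shape(voi_mask(one, "GTV"), c(1, 1, 1))
  expect_length(sh1, 14)
  expect_equal(sh1[["VoxelVolume"]], 1)
  expect_equal(sh1[["SurfaceArea"]], 6)        # voxel-face convention
  expect_equal(sh1[["Maximum3DDiameter"]], 0)

  sph <- extract_shape(sphere_mask(20), c(1, 1, 1))
  expect_gt(sph[["Sphericity"]], 0.97)
  expect_lte(sph[["Sphericity"]], 1)
  expect_equal(sph[["VoxelVolume"]], 4 / 3 * pi * 20^3, tolerance = 0.01)
  expect_equal(sph[["Maximum3DDiameter"]], 40, tolerance = 0.03)
  expect_equal(sph[["Elongation"]], 1, tolerance = 0.01)

  blob <- sphere_mask(6)
  a <- extract_shape(blob, c(1, 1, 1))
  b <- extract_shape(blob, c(2, 2, 2))
  expect_equal(b[["VoxelVolume"]], 8 * a[["VoxelVolume"]])
  expect_equal(b[["MeshVolume"]], 8 * a[["MeshVolume"]])
  expect_equal(b[["SurfaceArea"]], 4 * a[["SurfaceArea"]])
  expect_equal(b[["Sphericity"]], a[["Sphericity"]], tolerance = 1e-3)
  expect_equal(b[["MajorAxisLength"]], 2 * a[["MajorAxisLength"]])
})

# brute-force symmetric GLCM accumulated over the 13 unique directions
glcm_oracle <- function(lat, n_bins, dir) {
  d <- dim(lat)
  M <- matrix(0, n_bins, n_bins)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    a <- lat[x, y, z]
    if (a == 0) next
    X <- x + dir[1]; Y <- y + dir[2]; Z <- z + dir[3]
    if (X < 1 || Y < 1 || Z < 1 || X > d[1] || Y > d[2] || Z > d[3]) next
    b <- lat[X, Y, Z]
    if (b == 0) next
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  M
}

test_that("GLCM counts match a brute-force enumeration on random fixtures", {
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0), c(1, -1, 0),
                c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
                c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  set.seed(17)
  for (rep in 1:3) {
    lat <- array(sample(0:4, 4 * 4 * 4, replace = TRUE), c(4, 4, 4))
    cube <- fistulomics:::cpp_glcm(as.integer(lat), dim(lat), 4L)
    for (k in 1:13)
      expect_equal(matrix(cube[, , k], 4, 4), glcm_oracle(lat, 4, dirs[k, ]))
  }
})

test_that("texture profile: length, degenerate ROIs and hand-enumerated GLCM", {
  img <- random_grid(c(6, 6, 6), seed = 23)
  tx <- extract_texture(img, full_mask(c(6, 6, 6)), 8)
  expect_length(tx, 73)
  expect_equal(sum(grepl("^glcm_", names(tx))), 22)
  expect_equal(sum(grepl("^glrlm_", names(tx))), 16)
  expect_equal(sum(grepl("^glszm_", names(tx))), 16)
  expect_equal(sum(grepl("^gldm_", names(tx))), 14)
  expect_equal(sum(grepl("^ngtdm_", names(tx))), 5)

  cst <- extract_texture(volume_grid(array(7, c(3, 3, 3))),
                         full_mask(c(3, 3, 3)), 8)
  expect_equal(cst[["glcm_JointEntropy"]], 0, tolerance = 1e-12)
  expect_equal(cst[["ngtdm_Contrast"]], 0)

  # 3x1x1 strip with gray levels (1,2,1): symmetric counts {(1,2):2,(2,1):2}
  strip <- array(0, c(3, 3, 3))
  strip[1:3, 1, 1] <- c(1, 5, 1)    # discretizes to 1,2,1 with 2 bins
  m <- voi_mask(array(strip > 0, c(3, 3, 3)), "GTV")
  cube <- fistulomics:::cpp_glcm(
    as.integer(fistulomics:::discretized_lattice(volume_grid(strip), m, 2)),
    c(3L, 3L, 3L), 2L)
  expect_equal(matrix(cube[, , 1], 2, 2), rbind(c(0, 2), c(2, 0)))
  tx2 <- extract_texture(volume_grid(strip), m, 2)
  expect_equal(tx2[["glcm_Contrast"]], 1)

  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  tx1 <- extract_texture(random_grid(c(3, 3, 3)), voi_mask(single, "GTV"), 4)
  expect_length(tx1, 73)
  expect_true(all(is.finite(tx1)))    # defined degenerate outputs, no crash
})

test_that("texture features are invariant to positive affine intensity maps", {
  img <- random_grid(c(6, 6, 6), seed = 29)
  mk <- full_mask(c(6, 6, 6))
  shifted <- volume_grid(2.5 * img$values + 40, img$spacing)
  expect_equal(extract_texture(img, mk, 10), extract_texture(shifted, mk, 10),
               tolerance = 1e-12)
})

test_that("radiomics profile counting identity holds for arbitrary configs", {
  ct <- random_grid(c(10, 10, 10), seed = 31)
  mk <- voi_mask(array(ct$values > 0.3, c(10, 10, 10)), "GTV")
  cfg1 <- filter_config(log_sigmas = 2, wavelet_subbands = character(0),
                        bin_numbers = c(8, 16))
  p1 <- extract_radiomics_profile(ct, mk, cfg1)
  expect_length(p1, 14 + 2 * 2 * 91)
  expect_false(anyDuplicated(names(p1)) > 0)
  cfg2 <- filter_config(log_sigmas = numeric(0),
                        wavelet_subbands = character(0), bin_numbers = 8)
  expect_length(extract_radiomics_profile(ct, mk, cfg2), 14 + 91)
  expect_identical(extract_radiomics_profile(ct, mk, cfg2),
                   extract_radiomics_profile(ct, mk, cfg2))  # determinism
})
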