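test_that("DVH hand cases: uniform dose and four-voxel ladder", {
  uni <- volume_grid(array(10, c(3, 3, 3)))
  dv <- compute_dvh(uni, full_mask(c(3, 3, 3), "ESO"), c(2, 50, 98), c(5, 15))
  expect_true(all(dv$Dx == 10))
  expect_equal(unname(dv$Vx), c(1, 0))
  expect_equal(dv$Dmean, 10)

  lad <- volume_grid(array(c(1, 2, 3, 4), c(4, 1, 1)))
  dv2 <- compute_dvh(lad, full_mask(c(4, 1, 1), "ESO"), 50, 2.5)
  expect_equal(unname(dv2$Dx), 3)       # hottest half is {3, 4}
  expect_equal(unname(dv2$Vx), 0.5)
  expect_error(compute_dvh(lad, full_mask(c(4, 1, 1), "ESO"), 120, 5), "100")
  expect_error(compute_dvh(lad, full_mask(c(4, 1, 1), "ESO"), 50, -1),
               "non-negative")
})

test_that("Dx and Vx are monotone non-increasing; D50 ~ median; Dmean exact", {
  set.seed(13)
  for (rep in 1:5) {
    d <- volume_grid(array(runif(6^3, 0, 70), c(6, 6, 6)))
    dv <- compute_dvh(d, full_mask(c(6, 6, 6), "ESO"))
    expect_true(all(diff(dv$Dx) <= 1e-12))
    expect_true(all(diff(dv$Vx) <= 1e-12))
    expect_true(all(dv$Vx >= 0 & dv$Vx <= 1))
    expect_equal(dv$Dmean, mean(d$values))
  }
  big <- volume_grid(array(rnorm(20^3, 40, 10)^1, c(20, 20, 20)))
  big$values <- abs(big$values)
  dvb <- compute_dvh(big, full_mask(c(20, 20, 20), "ESO"), 50, numeric(0))
  expect_equal(unname(dvb$Dx), stats::median(big$values), tolerance = 1e-2)
})

test_that("dose moments: size, point mass, hand case, invariances", {
  two <- volume_grid(array(c(1, 3), c(1, 1, 2)))
  mm <- compute_dose_moments(two, full_mask(c(1, 1, 2), "ESO"))
  expect_length(mm, 63)
  expect_equal(mm[["moment_eta_002"]], 0.75 / 4^(5 / 3), tolerance = 1e-12)
  expect_equal(mm[["moment_eta_001"]], 0)      # central first order vanishes

  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  ms <- compute_dose_moments(volume_grid(array(5, c(3, 3, 3))),
                             voi_mask(single, "ESO"))
  expect_true(all(abs(ms) < 1e-14))            # point mass: all orders >= 1 are 0

  set.seed(19)
  dose <- array(runif(5^3, 1, 60), c(5, 5, 5))
  mk <- voi_mask(array(runif(5^3) < 0.6, c(5, 5, 5)), "ESO")
  base <- compute_dose_moments(volume_grid(dose, c(1, 1.3, 2)), mk)
  for (s in c(0.5, 2, 3.7)) {                  # isotropic scale invariance
    sc <- compute_dose_moments(volume_grid(dose, s * c(1, 1.3, 2)), mk)
    expect_equal(sc, base, tolerance = 1e-9)
  }
  tr <- compute_dose_moments(volume_grid(dose, c(1, 1.3, 2),
                                         origin = c(50, -20, 7)), mk)
  expect_equal(tr, base, tolerance = 1e-9)     # translation invariance
})

test_that("dose scaling covariance matches a brute-force moment oracle", {
  set.seed(23)
  dose <- array(runif(4^3, 1, 50), c(4, 4, 4))
  mk <- voi_mask(array(runif(4^3) < 0.7, c(4, 4, 4)), "GTV")
  sp <- c(1.5, 1.5, 3)
  # brute-force: literal central-moment sums with dose * voxel-volume weights
  idx <- which(mk$indicator, arr.ind = TRUE)
  w <- dose[mk$indicator] * prod(sp)
  xyz <- sweep(idx - 1, 2, sp, `*`)
  ctr <- colSums(xyz * w) / sum(w)
  brute <- function(p, q, r, k = 1) {
    mu <- sum(k * w * (xyz[, 1] - ctr[1])^p * (xyz[, 2] - ctr[2])^q *
              (xyz[, 3] - ctr[3])^r)
    mu / sum(k * w)^(1 + (p + q + r) / 3)
  }
  got <- compute_dose_moments(volume_grid(dose, sp), mk)
  for (ord in list(c(2, 0, 0), c(0, 3, 1), c(1, 1, 1), c(3, 3, 3))) {
    nm <- sprintf("moment_eta_%d%d%d", ord[1], ord[2], ord[3])
    expect_equal(got[[nm]], brute(ord[1], ord[2], ord[3]), tolerance = 1e-12)
  }
  # dose scaling k: mu000 scales by k, eta scales by k^(-(p+q+r)/3)
  gotk <- compute_dose_moments(volume_grid(3 * dose, sp), mk)
  for (ord in list(c(2, 0, 0), c(0, 0, 3))) {
    nm <- sprintf("moment_eta_%d%d%d", ord[1], ord[2], ord[3])
    expect_equal(gotk[[nm]], brute(ord[1], ord[2], ord[3], k = 3),
                 tolerance = 1e-12)
  }
  expect_error(compute_dose_moments(volume_grid(array(0, c(2, 2, 2))),
                                    full_mask(c(2, 2, 2), "ESO")), "zero")
})

test_that("dose radiomics block is the shared extraction applied to the dose grid", {
  set.seed(29)
  dose <- volume_grid(array(runif(5^3, 0, 60), c(5, 5, 5)))
  mk <- full_mask(c(5, 5, 5), "ESO")
  dr <- extract_dose_radiomics(dose, mk, 16)
  expect_length(dr, 91)
  fo <- extract_first_order(dose, mk, 16)
  tx <- extract_texture(dose, mk, 16)
  expect_equal(unname(dr[paste0("original_firstorder_", names(fo), "_bin16")]),
               unname(fo))
  expect_equal(unname(dr[paste0("original_", names(tx), "_bin16")]),
               unname(tx))
  uni <- extract_dose_radiomics(volume_grid(array(20, c(3, 3, 3))),
                                full_mask(c(3, 3, 3), "ESO"), 16)
  expect_equal(uni[["original_firstorder_Entropy_bin16"]], 0)
})

test_that("dose profile counting identities and determinism", {
  set.seed(31)
  dose <- volume_grid(array(runif(5^3, 0, 60), c(5, 5, 5)))
  mk <- full_mask(c(5, 5, 5), "GTV")
  full <- extract_dose_profile(dose, mk)
  expect_length(full, 39 + 20 + 63 + 91)       # 213 under default grids
  expect_length(default_dx_grid(), 39)
  expect_length(default_vx_grid(), 20)
  bare <- extract_dose_profile(dose, mk, x_percent = numeric(0),
                               x_gy = numeric(0))
  expect_length(bare, 154)
  expect_identical(full, extract_dose_profile(dose, mk))
})
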