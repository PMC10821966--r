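#' Filter-bank configuration
#'
#' Describes the derived-image set used for radiomics extraction: the original
#' CT plus Laplacian-of-Gaussian images at the given widths plus the 8
#' sub-bands of a single-level 3D stationary (undecimated) coiflet-1 wavelet
#' transform, and the gray-level counts used for fixed-bin-number
#' discretization. The default configuration yields 12 images
#' (1 + 3 LoG + 8 wavelet) and 5 bin numbers.
#'
#' @param log_sigmas Gaussian widths in mm for the LoG images.
#' @param wavelet_subbands Sub-band labels; each a 3-letter L/H word giving
#'   the low/high-pass choice along the x, y, z axes.
#' @param bin_numbers Gray-level counts for discretization.
#' @return A `filter_config` list.
#' @export
filter_config <- function(log_sigmas = c(1, 3, 6),
                          wavelet_subbands = c("LLL", "LLH", "LHL", "LHH",
                                               "HLL", "HLH", "HHL", "HHH"),
                          bin_numbers = c(10, 20, 30, 40, 50)) {
  log_sigmas <- as.numeric(log_sigmas)
  if (any(log_sigmas <= 0)) stop("LoG sigma must be strictly positive (mm)")
  if (length(wavelet_subbands) &&
      !all(grepl("^[LH]{3}$", wavelet_subbands)))
    stop("wavelet sub-band labels must be 3-letter L/H words")
  bin_numbers <- as.integer(bin_numbers)
  if (length(bin_numbers) == 0L || any(is.na(bin_numbers)) || any(bin_numbers < 1L))
    stop("bin_numbers must be positive integers")
  structure(list(log_sigmas = log_sigmas,
                 wavelet_subbands = wavelet_subbands,
                 bin_numbers = bin_numbers),
            class = "filter_config")
}

# --- axis-wise separable filtering -----------------------------------------

# Apply a 1D kernel along `axis` of a 3D array by shifted accumulation.
# `offsets[j]` is the source displacement of tap j. boundary: "mirror"
# (edge-duplicating reflection) or "circular".
conv_axis <- function(arr, kernel, offsets, axis, boundary = "mirror") {
  n <- dim(arr)[axis]
  out <- array(0, dim(arr))
  for (j in seq_along(kernel)) {
    idx0 <- seq_len(n) - 1L + offsets[j]
    if (boundary == "circular") {
      idx <- (idx0 %% n) + 1L
    } else {
      idx <- idx0
      repeat {
        neg <- idx < 0L
        big <- idx >= n
        if (!any(neg) && !any(big)) break
        idx[neg] <- -idx[neg] - 1L
        idx[big] <- 2L * n - idx[big] - 1L
      }
      idx <- idx + 1L
    }
    shifted <- switch(axis,
                      arr[idx, , , drop = FALSE],
                      arr[, idx, , drop = FALSE],
                      arr[, , idx, drop = FALSE])
    out <- out + kernel[j] * shifted
  }
  out
}

gaussian_kernel_1d <- function(sigma_mm, spacing_mm, order = 0L) {
  r <- max(3L, ceiling(4 * sigma_mm / spacing_mm))
  x <- (-r:r) * spacing_mm
  g <- exp(-x^2 / (2 * sigma_mm^2))
  g <- g / sum(g)                       # approximates g(x) * spacing
  if (order == 0L) return(g)
  g2 <- (x^2 - sigma_mm^2) / sigma_mm^4 * g
  g2 - mean(g2)                         # exact zero response to constants
}

# Laplacian of Gaussian in physical units: sum over axes of the 1D second
# derivative of Gaussian along that axis combined with plain Gaussians along
# the others. Mirror boundary handling.
log_filter <- function(grid, sigma_mm) {
  stopifnot(inherits(grid, "volume_grid"))
  if (sigma_mm <= 0) stop("sigma must be strictly positive")
  sm <- vector("list", 3L)
  out <- array(0, dim(grid$values))
  for (a in 1:3) {
    tmp <- grid$values
    for (b in setdiff(1:3, a)) {
      k <- gaussian_kernel_1d(sigma_mm, grid$spacing[b], 0L)
      tmp <- conv_axis(tmp, k, seq_along(k) - 1L - (length(k) - 1L) %/% 2L, b)
    }
    k2 <- gaussian_kernel_1d(sigma_mm, grid$spacing[a], 2L)
    out <- out + conv_axis(tmp, k2, seq_along(k2) - 1L - (length(k2) - 1L) %/% 2L, a)
  }
  volume_grid(out, grid$spacing, grid$origin)
}

gaussian_smooth <- function(grid, sigma_mm) {
  v <- grid$values
  for (a in 1:3) {
    k <- gaussian_kernel_1d(sigma_mm, grid$spacing[a], 0L)
    v <- conv_axis(v, k, seq_along(k) - 1L - (length(k) - 1L) %/% 2L, a)
  }
  volume_grid(v, grid$spacing, grid$origin)
}

# --- stationary wavelet transform ------------------------------------------

# Coiflet-1 analysis filters (orthonormal 6-tap pair).
.coif1_lo <- c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
               0.852572020212255, 0.337897662457809, -0.072732619512854)
.coif1_hi <- c(0.072732619512854, 0.337897662457809, -0.852572020212255,
               0.384864846864203, 0.072732619512854, -0.015655728135465)
.coif1_offsets <- -2:3

#' Single-level 3D stationary wavelet transform (coiflet-1)
#'
#' Undecimated separable analysis with circular boundary handling; the 8
#' sub-bands are labelled by the low (L) / high (H) pass choice along the x,
#' y, z array axes. Because the filter pair is orthonormal, the transform has
#' exact perfect reconstruction: [iswt3_coif1()] recovers the input (up to
#' floating-point rounding) as the adjoint synthesis averaged over sub-bands.
#'
#' @param arr 3D numeric array.
#' @return `swt3_coif1()`: named list of 8 arrays (`LLL` ... `HHH`);
#'   `iswt3_coif1()`: the reconstructed array.
#' @export
swt3_coif1 <- function(arr) {
  stopifnot(length(dim(arr)) == 3L)
  bands <- list()
  for (lab in c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")) {
    v <- arr
    for (a in 1:3) {
      f <- if (substr(lab, a, a) == "L") .coif1_lo else .coif1_hi
      v <- conv_axis(v, f, .coif1_offsets, a, boundary = "circular")
    }
    bands[[lab]] <- v
  }
  bands
}

#' @rdname swt3_coif1
#' @param bands named list of 8 sub-band arrays as returned by `swt3_coif1()`.
#' @export
iswt3_coif1 <- function(bands) {
  out <- NULL
  for (lab in names(bands)) {
    v <- bands[[lab]]
    for (a in 1:3) {
      f <- if (substr(lab, a, a) == "L") .coif1_lo else .coif1_hi
      v <- conv_axis(v, f, -.coif1_offsets, a, boundary = "circular")  # adjoint
    }
    out <- if (is.null(out)) v else out + v
  }
  out / 8
}

#' Build the derived-image filter bank
#'
#' Produces the image set over which radiomics features are computed: the
#' original image, one Laplacian-of-Gaussian image per configured sigma
#' (physical units, mirror boundaries) and the 8 stationary-wavelet sub-bands.
#' Under the default configuration this is 12 images, all on the original
#' lattice.
#'
#' @param ct A [volume_grid()].
#' @param cfg A [filter_config()].
#' @return Named list of `volume_grid` objects; names are the image labels
#'   used in feature names (`original`, `log_sigma_1mm`, ..., `wavelet_LLH`).
#' @export
build_filter_bank <- function(ct, cfg = filter_config()) {
  stopifnot(inherits(ct, "volume_grid"), inherits(cfg, "filter_config"))
  bank <- list(original = ct)
  for (s in cfg$log_sigmas) {
    lab <- sprintf("log_sigma_%gmm", s)
    bank[[lab]] <- log_filter(ct, s)
  }
  if (length(cfg$wavelet_subbands)) {
    sw <- swt3_coif1(ct$values)
    for (lab in cfg$wavelet_subbands)
      bank[[paste0("wavelet_", lab)]] <-
        volume_grid(sw[[lab]], ct$spacing, ct$origin)
  }
  bank
}
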