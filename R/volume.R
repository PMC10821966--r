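#' 3D scalar volume on a regular lattice
#'
#' A `volume_grid` holds a 3D numeric array (CT in Hounsfield units or dose in
#' Gy) together with its voxel spacing and physical origin. Voxel indices are
#' 0-based in physical mapping: position = origin + index * spacing, with no
#' direction matrix (axis-aligned lattice).
#'
#' @param values 3D numeric array; all values must be finite.
#' @param spacing numeric length-3, per-axis voxel size in mm (strictly
#'   positive).
#' @param origin numeric length-3, physical position of voxel (0,0,0) in mm.
#' @return An object of class `volume_grid` with elements `values`, `spacing`,
#'   `origin`.
#' @examples
#' vg <- volume_grid(array(rnorm(8), c(2, 2, 2)), spacing = c(1, 1, 3))
#' dim(vg$values)
#' @export
volume_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (length(values) == 0L) stop("lattice must be non-empty")
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("`values` must be finite")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Binary volume of interest mask
#'
#' A `voi_mask` is a logical lattice aligned voxel-for-voxel with a
#' [volume_grid()]. Masks are named by the anatomical VOI they delineate:
#' `"ESO"` (esophagus organ at risk), `"GTV"` (gross tumor volume) or `"EG"`
#' (their union).
#'
#' @param indicator logical (or 0/1) 3D array.
#' @param name VOI label, one of `"ESO"`, `"GTV"`, `"EG"`.
#' @return An object of class `voi_mask` with elements `indicator`, `name`.
#' @export
voi_mask <- function(indicator, name = c("ESO", "GTV", "EG")) {
  name <- match.arg(name)
  if (!is.array(indicator) || length(dim(indicator)) != 3L)
    stop("`indicator` must be a 3D array")
  if (is.numeric(indicator)) {
    if (!all(indicator %in% c(0, 1))) stop("numeric mask must contain only 0/1")
    indicator <- array(indicator != 0, dim(indicator))
  }
  if (!is.logical(indicator)) stop("`indicator` must be logical or 0/1")
  if (anyNA(indicator)) stop("mask must not contain NA")
  structure(list(indicator = indicator, name = name), class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> %s: %d voxels set of %s\n", x$name,
              sum(x$indicator), paste(dim(x$indicator), collapse = " x ")))
  invisible(x)
}

mask_count <- function(mask) sum(mask$indicator)

check_mask_grid <- function(mask, grid) {
  if (!identical(dim(mask$indicator), dim(grid$values)))
    stop("mask shape ", paste(dim(mask$indicator), collapse = "x"),
         " does not match grid shape ", paste(dim(grid$values), collapse = "x"))
  if (mask_count(mask) == 0L) stop("mask is empty: no voxels to extract from")
  invisible(TRUE)
}

#' Combine two VOI masks into their union (EG)
#'
#' The combined esophagus-plus-tumor volume `EG` is the voxelwise union of the
#' ESO and GTV masks on a shared lattice.
#'
#' @param a,b `voi_mask` objects with identical lattice shapes.
#' @return A `voi_mask` named `"EG"` whose indicator is `a | b`.
#' @examples
#' m1 <- voi_mask(array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2)), "ESO")
#' m2 <- voi_mask(array(c(FALSE, TRUE, rep(FALSE, 6)), c(2, 2, 2)), "GTV")
#' sum(combine_masks(m1, m2)$indicator)  # 2
#' @export
combine_masks <- function(a, b) {
  stopifnot(inherits(a, "voi_mask"), inherits(b, "voi_mask"))
  if (!identical(dim(a$indicator), dim(b$indicator)))
    stop("cannot combine masks: shapes ",
         paste(dim(a$indicator), collapse = "x"), " and ",
         paste(dim(b$indicator), collapse = "x"), " differ")
  voi_mask(a$indicator | b$indicator, "EG")
}

#' Fixed-bin-number gray-level discretization
#'
#' Maps intensities inside a region of interest onto `n_bins` gray levels
#' spanning the ROI range: `bin = min(n_bins, floor(n_bins * (v - min) /
#' (max - min)) + 1)`. A constant ROI maps wholly to bin 1. This is the
#' discretization applied before texture computation and for the histogram
#' based first-order statistics (entropy, uniformity); because bins span the
#' observed range, the mapping is invariant under affine rescaling
#' `v -> a*v + b` with `a > 0`.
#'
#' @param values numeric vector of ROI intensities (non-empty, finite).
#' @param n_bins positive integer count of gray levels.
#' @return Integer vector of bin indices in `1..n_bins`.
#' @examples
#' discretize_fixed_bin_number(c(0, 0.5, 9.99, 10), 10)
#' @export
discretize_fixed_bin_number <- function(values, n_bins) {
  if (length(values) == 0L) stop("`values` must be non-empty")
  if (!all(is.finite(values))) stop("`values` must be finite")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L) stop("`n_bins` must be a positive integer")
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(1L, length(values)))
  b <- floor(n_bins * (values - rng[1]) / (rng[2] - rng[1])) + 1L
  as.integer(pmin(b, n_bins))
}

# Integer-coded ROI lattice for texture matrices: in-mask voxels carry their
# gray level 1..n_bins, out-of-mask voxels 0.
discretized_lattice <- function(grid, mask, n_bins) {
  check_mask_grid(mask, grid)
  lat <- array(0L, dim(grid$values))
  lat[mask$indicator] <- discretize_fixed_bin_number(grid$values[mask$indicator], n_bins)
  lat
}
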