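#' Dose-volume histogram summaries
#'
#' Computes DVH parameters over a VOI. `Dx` is the minimum dose received by
#' the hottest x% of the VOI volume, linearly interpolated on the descending
#' sorted voxel-dose vector (so for 4 voxels with doses 1..4 Gy, D50 = 3 Gy:
#' the hottest half is \{3, 4\}). `Vx` is the fraction of VOI voxels with
#' dose strictly larger than x Gy. Both families are non-increasing in x.
#'
#' @param dose A [volume_grid()] with non-negative values (Gy).
#' @param mask A non-empty [voi_mask()] on the same lattice.
#' @param x_percent Percent-volume grid for Dx, values in (0, 100].
#' @param x_gy Dose-threshold grid for Vx, non-negative (Gy).
#' @return An object of class `dvh_summary`: list with named vectors `Dx`
#'   (`D<x>` in Gy), `Vx` (`V<x>`, fraction in \[0, 1\]) and scalars `Dmin`,
#'   `Dmax`, `Dmean`.
#' @export
compute_dvh <- function(dose, mask,
                        x_percent = default_dx_grid(),
                        x_gy = default_vx_grid()) {
  check_mask_grid(mask, dose)
  d <- dose$values[mask$indicator]
  if (any(d < 0)) stop("dose must be non-negative")
  x_percent <- as.numeric(x_percent)
  x_gy <- as.numeric(x_gy)
  if (length(x_percent) && (any(x_percent <= 0) || any(x_percent > 100)))
    stop("Dx percent volumes must lie in (0, 100]")
  if (length(x_gy) && any(x_gy < 0)) stop("Vx thresholds must be non-negative")
  ds <- sort(d, decreasing = TRUE)
  n <- length(ds)
  # rank position of the hottest x% boundary; <1 clamps to the maximum dose
  dx <- vapply(x_percent, function(x) {
    k <- x / 100 * n
    if (k <= 1) return(ds[1L])
    lo <- floor(k)
    if (lo >= n) return(ds[n])
    ds[lo] + (k - lo) * (ds[lo + 1L] - ds[lo])
  }, 0)
  vx <- vapply(x_gy, function(x) mean(d > x), 0)
  structure(list(Dx = stats::setNames(dx, sprintf("D%g", x_percent)),
                 Vx = stats::setNames(vx, sprintf("V%g", x_gy)),
                 Dmin = min(d), Dmax = max(d), Dmean = mean(d)),
            class = "dvh_summary")
}

#' Default DVH evaluation grids
#'
#' The default Dx grid has 39 percent-volume points (0.5, 0.8, 1, 2 and
#' 5..90 by 2.5 — D0.8 is included because near-maximum doses to small hot
#' sub-volumes of the esophagus are clinically prognostic) and the default Vx
#' grid has 20 thresholds (4..80 Gy by 4), so the per-VOI dose-feature count
#' is 39 + 20 + 63 + 91 = 213. Both grids are configurable.
#' @return Numeric vector of grid points.
#' @export
default_dx_grid <- function() c(0.5, 0.8, 1, 2, seq(5, 90, by = 2.5))

#' @rdname default_dx_grid
#' @export
default_vx_grid <- function() seq(4, 80, by = 4)

#' Scale-invariant 3D dose moments
#'
#' Dose-weighted central spatial moments of the dose distribution inside a
#' VOI, normalized to be invariant under isotropic spatial scaling. Moments
#' are volume integrals (each voxel weighted by dose times voxel volume
#' \eqn{\Delta V}, so that the normalization exponent cancels spatial
#' scaling): with physical voxel coordinates and the dose-weighted centroid
#' \eqn{(\bar x, \bar y, \bar z)},
#' \deqn{\mu_{pqr} = \sum_v D(v)\,\Delta V\, (x-\bar x)^p (y-\bar y)^q (z-\bar z)^r,}
#' \deqn{\eta_{pqr} = \mu_{pqr} / \mu_{000}^{1 + (p+q+r)/3}.}
#' All 63 order triples \eqn{(p,q,r) \in \{0..3\}^3} except (0,0,0) are
#' returned; the three first-order moments are exactly 0 by centering. The
#' axes encode the dose shape along the medial-lateral, anterior-posterior
#' and craniocaudal directions.
#'
#' @param dose A [volume_grid()], non-negative, with positive total dose in
#'   the mask.
#' @param mask A non-empty [voi_mask()].
#' @return Named numeric vector of length 63 (`moment_eta_pqr`).
#' @export
compute_dose_moments <- function(dose, mask) {
  check_mask_grid(mask, dose)
  d <- dose$values[mask$indicator] * prod(dose$spacing)  # dose * voxel volume
  if (any(d < 0)) stop("dose must be non-negative")
  m000 <- sum(d)
  if (m000 <= 0) stop("total dose in VOI is zero; moments undefined")
  idx <- which(mask$indicator, arr.ind = TRUE)
  xyz <- sweep(idx - 1, 2, dose$spacing, `*`)
  xyz <- sweep(xyz, 2, dose$origin, `+`)
  ctr <- colSums(xyz * d) / m000
  cx <- xyz[, 1] - ctr[1]; cy <- xyz[, 2] - ctr[2]; cz <- xyz[, 3] - ctr[3]
  pows <- expand.grid(p = 0:3, q = 0:3, r = 0:3)
  pows <- pows[rowSums(pows) > 0, ]
  xp <- outer(cx, 0:3, `^`); yq <- outer(cy, 0:3, `^`); zr <- outer(cz, 0:3, `^`)
  eta <- mapply(function(p, q, r) {
    mu <- sum(d * xp[, p + 1] * yq[, q + 1] * zr[, r + 1])
    mu / m000^(1 + (p + q + r) / 3)
  }, pows$p, pows$q, pows$r)
  stats::setNames(eta, sprintf("moment_eta_%d%d%d", pows$p, pows$q, pows$r))
}

#' Dose-based radiomics features
#'
#' First-order (18) and texture (73) features of the raw dose map within the
#' VOI — the same extraction as CT radiomics but with only the original
#' image (no filter bank) and no shape block, giving 91 values.
#'
#' @inheritParams compute_dose_moments
#' @param n_bins Gray-level count for discretization.
#' @return Named numeric vector of length 91 (`original_firstorder_*_bin<k>`,
#'   `original_<texture>_bin<k>`).
#' @export
extract_dose_radiomics <- function(dose, mask, n_bins = 25) {
  check_mask_grid(mask, dose)
  d <- dose$values[mask$indicator]
  fo <- first_order_values(d, prod(dose$spacing), n_bins)
  lat <- array(0L, dim(dose$values))
  lat[mask$indicator] <- discretize_fixed_bin_number(d, n_bins)
  tx <- texture_values(lat, as.integer(n_bins))
  v <- c(stats::setNames(fo, paste0("firstorder_", names(fo))), tx)
  stats::setNames(v, sprintf("original_%s_bin%d", names(v), n_bins))
}

#' Full dosiomics profile of a VOI
#'
#' Concatenates the three dose-feature families for one VOI: DVH parameters
#' (Dx/Vx grids), the 63 scale-invariant dose moments and the 91 dose-based
#' radiomics features. Under the default grids this is 39 + 20 + 63 + 91 =
#' 213 features per VOI, with deterministic naming (`dvh_*`, `moment_*`,
#' `dose_original_*`).
#'
#' @inheritParams compute_dose_moments
#' @param x_percent,x_gy DVH grids, see [compute_dvh()].
#' @param n_bins Gray-level count for the dose-radiomics block.
#' @return Named numeric vector (length 213 under defaults).
#' @export
extract_dose_profile <- function(dose, mask,
                                 x_percent = default_dx_grid(),
                                 x_gy = default_vx_grid(),
                                 n_bins = 25) {
  dvh <- compute_dvh(dose, mask, x_percent, x_gy)
  dr <- extract_dose_radiomics(dose, mask, n_bins)
  c(stats::setNames(c(dvh$Dx, dvh$Vx),
                    c(sprintf("dvh_D%g", x_percent), sprintf("dvh_V%g", x_gy))),
    compute_dose_moments(dose, mask),
    stats::setNames(dr, sprintf("dose_%s", names(dr))))
}
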