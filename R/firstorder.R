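#' First-order intensity statistics
#'
#' The 18 standard first-order features of the intensity distribution inside
#' a VOI. Entropy and uniformity are computed on the fixed-bin-number
#' histogram (see [discretize_fixed_bin_number()]); all other statistics use
#' the raw intensities. Moments are population moments (denominator n);
#' kurtosis is not excess-corrected. A constant ROI yields entropy 0,
#' uniformity 1, variance 0 and skewness/kurtosis reported as 0.
#'
#' @param img A [volume_grid()].
#' @param mask A [voi_mask()] on the same lattice (non-empty).
#' @param n_bins Gray-level count for the histogram-based features.
#' @return Named numeric vector of length 18.
#' @export
extract_first_order <- function(img, mask, n_bins = 25) {
  check_mask_grid(mask, img)
  v <- img$values[mask$indicator]
  first_order_values(v, prod(img$spacing), n_bins)
}

first_order_values <- function(v, voxel_volume, n_bins) {
  n <- length(v)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  q <- stats::quantile(v, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  inr <- v[v >= q[1] & v <= q[4]]
  p <- tabulate(discretize_fixed_bin_number(v, n_bins), n_bins) / n
  p <- p[p > 0]
  c(Energy = sum(v^2),
    TotalEnergy = voxel_volume * sum(v^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(v),
    Percentile10 = q[1],
    Percentile90 = q[4],
    Maximum = max(v),
    Mean = m,
    Median = stats::median(v),
    InterquartileRange = q[3] - q[2],
    Range = max(v) - min(v),
    MeanAbsoluteDeviation = mean(abs(v - m)),
    RobustMeanAbsoluteDeviation = mean(abs(inr - mean(inr))),
    RootMeanSquared = sqrt(mean(v^2)),
    Skewness = if (m2 > 0) mean((v - m)^3) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) mean((v - m)^4) / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}
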