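#' Texture features on the discretized ROI
#'
#' Computes the 73-feature texture profile: 22 gray-level co-occurrence
#' (GLCM), 16 run-length (GLRLM), 16 size-zone (GLSZM), 14 dependence (GLDM)
#' and 5 neighborhood gray-tone difference (NGTDM) features, on the ROI
#' discretized to `n_bins` gray levels. GLCM and GLRLM use the 13 unique 3D
#' directions at distance 1 with symmetric co-occurrence counting; features
#' are computed per direction and averaged (unweighted) over the directions
#' that contain at least one voxel pair/run. GLSZM/GLDM/NGTDM use the full
#' 26-neighborhood. The GLCM family is the 24-member set minus SumAverage
#' (a duplicate of twice JointAverage) and MCC, leaving 22; GLDM uses
#' dependence size = agreeing neighbors + 1 and coarseness saturates at 1e6
#' for a fully uniform ROI. Degenerate ROIs (e.g. a single voxel, where no
#' voxel pairs exist) yield all-zero GLCM/GLRLM blocks rather than an error.
#'
#' Because discretization spans the observed ROI range, every texture feature
#' is invariant under positive affine maps of the input intensities.
#'
#' @param img A [volume_grid()].
#' @param mask A non-empty [voi_mask()] on the same lattice.
#' @param n_bins Gray-level count (>= 2).
#' @return Named numeric vector of length 73 (names prefixed `glcm_`,
#'   `glrlm_`, `glszm_`, `gldm_`, `ngtdm_`).
#' @export
extract_texture <- function(img, mask, n_bins = 25) {
  check_mask_grid(mask, img)
  if (n_bins < 2) stop("texture features need n_bins >= 2")
  lat <- discretized_lattice(img, mask, n_bins)
  texture_values(lat, as.integer(n_bins))
}

texture_values <- function(lat, n_bins) {
  d <- dim(lat)
  np <- sum(lat > 0L)
  c(glcm_features(cpp_glcm(as.integer(lat), d, n_bins), n_bins),
    glrlm_features(cpp_glrlm(as.integer(lat), d, n_bins), n_bins, np),
    glszm_features(cpp_glszm(as.integer(lat), d, n_bins), n_bins, np),
    gldm_features(cpp_gldm(as.integer(lat), d, n_bins), n_bins),
    ngtdm_features(cpp_ngtdm(as.integer(lat), d, n_bins), n_bins))
}

.eps <- 2.220446e-16

glcm_single <- function(P, n_bins) {
  s <- sum(P)
  p <- P / s
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(i * p); muy <- sum(j * p)
  sigx <- sqrt(sum((i - mux)^2 * p)); sigy <- sqrt(sum((j - muy)^2 * p))
  k_diff <- 0:(n_bins - 1)
  pxmy <- as.vector(rowsum(as.vector(p), as.vector(abs(i - j)), reorder = TRUE))
  if (length(pxmy) < n_bins) pxmy <- c(pxmy, numeric(n_bins - length(pxmy)))
  k_sum <- 2:(2 * n_bins)
  pxpy <- as.vector(rowsum(as.vector(p), as.vector(i + j), reorder = TRUE))
  if (length(pxpy) < length(k_sum)) pxpy <- c(pxpy, numeric(length(k_sum) - length(pxpy)))
  HX <- -sum(px[px > 0] * log2(px[px > 0]))
  HY <- -sum(py[py > 0] * log2(py[py > 0]))
  HXY <- -sum(p * log2(p + .eps))
  pp <- outer(px, py)
  HXY1 <- -sum(p * log2(pp + .eps))
  HXY2 <- -sum(pp * log2(pp + .eps))
  da <- sum(k_diff * pxmy)
  imc2 <- 1 - exp(-2 * (HXY2 - HXY))
  c(Autocorrelation = sum(i * j * p),
    JointAverage = mux,
    ClusterProminence = sum((i + j - mux - muy)^4 * p),
    ClusterShade = sum((i + j - mux - muy)^3 * p),
    ClusterTendency = sum((i + j - mux - muy)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = if (sigx * sigy > 0) (sum(i * j * p) - mux * muy) / (sigx * sigy) else 1,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pxmy * log2(pxmy + .eps)),
    DifferenceVariance = sum((k_diff - da)^2 * pxmy),
    JointEnergy = sum(p^2),
    JointEntropy = HXY,
    Imc1 = if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0,
    Imc2 = sqrt(max(imc2, 0)),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + (i - j)^2 / n_bins^2)),
    Id = sum(p / (1 + abs(i - j))),
    Idn = sum(p / (1 + abs(i - j) / n_bins)),
    InverseVariance = sum((p / ((i - j)^2 + diag(n_bins)))[i != j]),
    MaximumProbability = max(p),
    SumEntropy = -sum(pxpy * log2(pxpy + .eps)),
    SumSquares = sum((i - mux)^2 * p))
}

glcm_features <- function(cube, n_bins) {
  nm <- c("Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
          "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
          "DifferenceEntropy", "DifferenceVariance", "JointEnergy",
          "JointEntropy", "Imc1", "Imc2", "Idm", "Idmn", "Id", "Idn",
          "InverseVariance", "MaximumProbability", "SumEntropy", "SumSquares")
  acc <- matrix(0, length(nm), 0)
  for (dd in seq_len(dim(cube)[3])) {
    P <- cube[, , dd, drop = TRUE]
    if (!is.matrix(P)) P <- matrix(P, n_bins, n_bins)
    if (sum(P) > 0) acc <- cbind(acc, glcm_single(P, n_bins))
  }
  out <- if (ncol(acc)) rowMeans(acc) else stats::setNames(numeric(length(nm)), nm)
  stats::setNames(out, paste0("glcm_", nm))
}

rlm_like_single <- function(P) {
  # shared machinery for run-length / size-zone style matrices:
  # P is nbins x maxlen counts
  Nr <- sum(P)
  p <- P / Nr
  i <- row(P); j <- col(P)
  ri <- rowSums(P); rj <- colSums(P)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  list(Nr = Nr, p = p, i = i, j = j, ri = ri, rj = rj, mu_i = mu_i, mu_j = mu_j)
}

glrlm_single <- function(P, np) {
  m <- rlm_like_single(P)
  with(m, c(
    ShortRunEmphasis = sum(P / j^2) / Nr,
    LongRunEmphasis = sum(P * j^2) / Nr,
    GrayLevelNonUniformity = sum(ri^2) / Nr,
    GrayLevelNonUniformityNormalized = sum(ri^2) / Nr^2,
    RunLengthNonUniformity = sum(rj^2) / Nr,
    RunLengthNonUniformityNormalized = sum(rj^2) / Nr^2,
    RunPercentage = Nr / np,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    RunVariance = sum((j - mu_j)^2 * p),
    RunEntropy = -sum(p * log2(p + .eps)),
    LowGrayLevelRunEmphasis = sum(P / i^2) / Nr,
    HighGrayLevelRunEmphasis = sum(P * i^2) / Nr,
    ShortRunLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / Nr,
    ShortRunHighGrayLevelEmphasis = sum(P * i^2 / j^2) / Nr,
    LongRunLowGrayLevelEmphasis = sum(P * j^2 / i^2) / Nr,
    LongRunHighGrayLevelEmphasis = sum(P * i^2 * j^2) / Nr))
}

glrlm_features <- function(cube, n_bins, np) {
  nm <- c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
          "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
          "RunLengthNonUniformityNormalized", "RunPercentage",
          "GrayLevelVariance", "RunVariance", "RunEntropy",
          "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
          "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
          "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  acc <- matrix(0, length(nm), 0)
  for (dd in seq_len(dim(cube)[3])) {
    P <- matrix(cube[, , dd], dim(cube)[1], dim(cube)[2])
    if (sum(P) > 0 && np > 0) acc <- cbind(acc, glrlm_single(P, np))
  }
  out <- if (ncol(acc)) rowMeans(acc) else stats::setNames(numeric(length(nm)), nm)
  stats::setNames(out, paste0("glrlm_", nm))
}

glszm_features <- function(P, n_bins, np) {
  nm <- c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
          "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
          "SizeZoneNonUniformityNormalized", "ZonePercentage",
          "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
          "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
          "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
          "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  if (sum(P) == 0 || np == 0)
    return(stats::setNames(numeric(length(nm)), paste0("glszm_", nm)))
  m <- rlm_like_single(P)
  out <- with(m, c(
    sum(P / j^2) / Nr, sum(P * j^2) / Nr, sum(ri^2) / Nr, sum(ri^2) / Nr^2,
    sum(rj^2) / Nr, sum(rj^2) / Nr^2, Nr / np,
    sum((i - mu_i)^2 * p), sum((j - mu_j)^2 * p), -sum(p * log2(p + .eps)),
    sum(P / i^2) / Nr, sum(P * i^2) / Nr,
    sum(P / (i^2 * j^2)) / Nr, sum(P * i^2 / j^2) / Nr,
    sum(P * j^2 / i^2) / Nr, sum(P * i^2 * j^2) / Nr))
  stats::setNames(out, paste0("glszm_", nm))
}

gldm_features <- function(P, n_bins) {
  nm <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
          "GrayLevelNonUniformity", "DependenceNonUniformity",
          "DependenceNonUniformityNormalized", "GrayLevelVariance",
          "DependenceVariance", "DependenceEntropy",
          "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
          "SmallDependenceLowGrayLevelEmphasis",
          "SmallDependenceHighGrayLevelEmphasis",
          "LargeDependenceLowGrayLevelEmphasis",
          "LargeDependenceHighGrayLevelEmphasis")
  Nd <- sum(P)
  if (Nd == 0)
    return(stats::setNames(numeric(length(nm)), paste0("gldm_", nm)))
  p <- P / Nd
  i <- row(P)
  j <- col(P)            # dependence size = agreeing neighbors + 1
  ri <- rowSums(P); rj <- colSums(P)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  out <- c(sum(P / j^2) / Nd, sum(P * j^2) / Nd,
           sum(ri^2) / Nd, sum(rj^2) / Nd, sum(rj^2) / Nd^2,
           sum((i - mu_i)^2 * p), sum((j - mu_j)^2 * p),
           -sum(p * log2(p + .eps)),
           sum(P / i^2) / Nd, sum(P * i^2) / Nd,
           sum(P / (i^2 * j^2)) / Nd, sum(P * i^2 / j^2) / Nd,
           sum(P * j^2 / i^2) / Nd, sum(P * i^2 * j^2) / Nd)
  stats::setNames(out, paste0("gldm_", nm))
}

ngtdm_features <- function(M, n_bins) {
  nm <- c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")
  ni <- M[, 1]; si <- M[, 2]
  Nv <- sum(ni)
  if (Nv == 0)
    return(stats::setNames(c(1e6, 0, 0, 0, 0), paste0("ngtdm_", nm)))
  pi_ <- ni / Nv
  lev <- seq_len(n_bins)
  act <- pi_ > 0
  Ngp <- sum(act)
  coarse <- if (sum(pi_ * si) > 0) 1 / sum(pi_ * si) else 1e6
  coarse <- min(coarse, 1e6)
  if (Ngp > 1) {
    ii <- lev[act]; pa <- pi_[act]; sa <- si[act]
    dif2 <- outer(ii, ii, function(a, b) (a - b)^2)
    contrast <- sum(outer(pa, pa) * dif2) / (Ngp * (Ngp - 1)) * sum(si) / Nv
    busy_den <- sum(abs(outer(ii * pa, ii * pa, `-`)))
    busy <- if (busy_den > 0) sum(pa * sa) / busy_den else 0
    cmplx <- sum(abs(outer(ii, ii, `-`)) *
                 outer(pa * sa, pa * sa, `+`) / outer(pa, pa, `+`)) / Nv
    strength <- if (sum(si) > 0) sum(outer(pa, pa, `+`) * dif2) / sum(si) else 0
  } else {
    contrast <- 0; busy <- 0; cmplx <- 0; strength <- 0
  }
  stats::setNames(c(coarse, contrast, busy, cmplx, strength),
                  paste0("ngtdm_", nm))
}
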