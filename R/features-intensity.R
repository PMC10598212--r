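#' First-order intensity features
#'
#' Sixteen histogram statistics of a lesion's (HU-floored) intensity set.
#' Variance, skewness and kurtosis use population moments; skewness and
#' kurtosis (excess) of a constant set are defined as 0. Entropy uses a
#' 256-bin histogram over the observed range, base-2 logarithm; a constant
#' set has entropy 0. `rmad` is the mean absolute deviation of the values
#' inside the 10th-90th percentile band; `cov` is the coefficient of
#' variation (std/mean, NA when the mean is 0).
#'
#' @param intensities numeric vector (non-empty), HU.
#' @return named numeric vector of 16 features, prefixed `fo.`.
#' @export
first_order_features <- function(intensities) {
  x <- intensities
  if (!length(x)) stop("empty intensity set")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  sdv <- sqrt(m2)
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 - 3 else 0
  ent <- if (max(x) > min(x)) {
    h <- tabulate(pmin(256L, 1L + floor((x - min(x)) / (max(x) - min(x)) * 256)),
                  nbins = 256L)
    pr <- h[h > 0] / n
    -sum(pr * log2(pr))
  } else 0
  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  band <- x[x >= q[1] & x <= q[4]]
  rmad <- mean(abs(band - mean(band)))
  c(fo.mean = mu, fo.median = stats::median(x), fo.min = min(x), fo.max = max(x),
    fo.range = max(x) - min(x), fo.variance = m2, fo.std = sdv,
    fo.skewness = skew, fo.kurtosis = kurt, fo.energy = sum(x^2),
    fo.entropy = ent, fo.p10 = q[1], fo.p90 = q[4], fo.iqr = q[3] - q[2],
    fo.rmad = rmad, fo.cov = if (mu != 0) sdv / mu else NA_real_)
}

#' Intensity-volume histogram features
#'
#' For each HU threshold x, the absolute volume (cm^3) spanned by lesion
#' voxels with intensity strictly above x ("HU > x" volumes). Non-increasing
#' in the threshold by construction.
#'
#' @param intensities numeric vector (HU-floored lesion intensities).
#' @param voxel_volume_cm3 volume of one voxel in cm^3.
#' @param thresholds HU thresholds; default 50, 100, 150, 200.
#' @return named numeric vector, prefixed `ivh.`.
#' @export
ivh_features <- function(intensities, voxel_volume_cm3,
                         thresholds = c(50, 100, 150, 200)) {
  if (!length(intensities)) stop("empty intensity set")
  v <- vapply(thresholds, function(t) sum(intensities > t) * voxel_volume_cm3,
              numeric(1))
  names(v) <- paste0("ivh.vol_hu_gt_", thresholds)
  v
}
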