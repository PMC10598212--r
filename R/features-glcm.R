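#' Names of the 18 grey-level co-occurrence (Haralick) texture features
#' @return character vector, prefixed `glcm.`.
#' @export
haralick_names <- function() {
  paste0("glcm.", c("energy", "contrast", "correlation", "sum_squares_variance",
                    "idm", "sum_average", "sum_variance", "sum_entropy",
                    "entropy", "difference_variance", "difference_entropy",
                    "imc1", "imc2", "autocorrelation", "cluster_shade",
                    "cluster_prominence", "dissimilarity", "max_probability"))
}

#' Discretize HU values onto a fixed grey-level ladder
#'
#' Values are clipped to the fixed range `[floor_hu, max_hu]` and binned
#' into `n_levels` equal-width levels on that range, so levels are
#' comparable across lesions and scanners.
#'
#' @param x numeric HU values.
#' @param n_levels number of grey levels (default 100).
#' @param floor_hu,max_hu fixed discretization range (default -100, 1000 HU).
#' @return integer levels in 1..n_levels.
#' @export
discretize_hu <- function(x, n_levels = 100L, floor_hu = -100, max_hu = 1000) {
  x <- pmin(pmax(x, floor_hu), max_hu)
  pmin(n_levels, 1L + floor((x - floor_hu) / (max_hu - floor_hu) * n_levels))
}

#' Grey-level co-occurrence matrices of a lesion
#'
#' Symmetric co-occurrence matrices at offset 1 for the four in-plane
#' directions (0, 45, 90, 135 degrees), with raw pair counts accumulated
#' over all axial slices per direction. Voxels excluded by the HU floor are
#' transparent (no pairs through them, they simply don't pair).
#'
#' @param lesion `lesion` or logical 3-D mask.
#' @param image [image_volume].
#' @param n_levels,max_hu,floor_hu discretization (see [discretize_hu]).
#' @return list of 4 `n_levels x n_levels` count matrices, one per direction.
#' @export
glcm_matrices <- function(lesion, image, n_levels = 100L, max_hu = 1000,
                          floor_hu = -100) {
  mask <- if (inherits(lesion, "lesion")) lesion$mask else lesion
  vox <- image$voxels
  d <- dim(mask)
  lev <- array(NA_integer_, d)
  sel <- mask & vox >= floor_hu
  lev[sel] <- discretize_hu(vox[sel], n_levels, floor_hu, max_hu)
  dirs <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  mats <- lapply(dirs, function(o) matrix(0, n_levels, n_levels))
  for (k in seq_len(d[3])) {
    sl <- lev[, , k]
    if (all(is.na(sl))) next
    for (di in seq_along(dirs)) {
      o <- dirs[[di]]
      ri <- max(1, 1 + o[1]):min(d[1], d[1] + o[1])
      cj <- max(1, 1 + o[2]):min(d[2], d[2] + o[2])
      a <- sl[ri - o[1], cj - o[2], drop = FALSE]
      b <- sl[ri, cj, drop = FALSE]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok)) next
      idx <- (b[ok] - 1L) * n_levels + a[ok]
      cnt <- tabulate(idx, nbins = n_levels * n_levels)
      m <- matrix(cnt, n_levels, n_levels)
      mats[[di]] <- mats[[di]] + m + t(m)       # symmetric: both orders
    }
  }
  mats
}

#' Haralick statistics of a normalized co-occurrence matrix
#'
#' The 18 texture statistics computed from a joint probability matrix
#' (entries sum to 1). Logarithms are base 2 with 0 log 0 = 0; correlation
#' and the information measures are defined as 0 for degenerate (zero
#' marginal variance / zero marginal entropy) matrices.
#'
#' @param P square numeric matrix summing to 1.
#' @return named numeric vector (see [haralick_names]).
#' @export
haralick_stats <- function(P) {
  N <- nrow(P)
  i <- matrix(seq_len(N), N, N)
  j <- t(i)
  px <- rowSums(P)
  py <- colSums(P)
  mux <- sum(seq_len(N) * px)
  muy <- sum(seq_len(N) * py)
  sx <- sqrt(sum((seq_len(N) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(N) - muy)^2 * py))
  plog <- function(p) ifelse(p > 0, log2(p), 0)
  # diagonal-band distributions
  psum <- vapply(2:(2 * N), function(k) sum(P[i + j == k]), numeric(1))
  ks <- 2:(2 * N)
  pdiff <- vapply(0:(N - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  kd <- 0:(N - 1)
  sum_avg <- sum(ks * psum)
  mean_d <- sum(kd * pdiff)
  HXY <- -sum(P * plog(P))
  pxy <- outer(px, py)
  HXY1 <- -sum(P * plog(pxy))
  HXY2 <- -sum(pxy * plog(pxy))
  HX <- -sum(px * plog(px))
  HY <- -sum(py * plog(py))
  corr <- if (sx > 0 && sy > 0) (sum(i * j * P) - mux * muy) / (sx * sy) else 0
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY))))
  out <- c(sum(P^2),
           sum((i - j)^2 * P),
           corr,
           sum((i - mux)^2 * P),
           sum(P / (1 + (i - j)^2)),
           sum_avg,
           sum((ks - sum_avg)^2 * psum),
           -sum(psum * plog(psum)),
           HXY,
           sum((kd - mean_d)^2 * pdiff),
           -sum(pdiff * plog(pdiff)),
           imc1,
           imc2,
           sum(i * j * P),
           sum((i + j - mux - muy)^3 * P),
           sum((i + j - mux - muy)^4 * P),
           sum(abs(i - j) * P),
           max(P))
  names(out) <- haralick_names()
  out
}

#' Haralick texture features of a lesion
#'
#' Co-occurrence matrices are computed per in-plane direction (accumulated
#' over slices), each normalized to a probability matrix, then averaged
#' across the directions that contain at least one pixel pair; the 18
#' Haralick statistics are computed from the averaged matrix. When no
#' direction has any valid pair the features are returned as NA (missing).
#'
#' @inheritParams glcm_matrices
#' @return named numeric vector of 18 features (possibly all NA).
#' @export
haralick_features <- function(lesion, image, n_levels = 100L, max_hu = 1000,
                              floor_hu = -100) {
  mats <- glcm_matrices(lesion, image, n_levels, max_hu, floor_hu)
  sums <- vapply(mats, sum, numeric(1))
  if (all(sums == 0)) {
    out <- rep(NA_real_, 18)
    names(out) <- haralick_names()
    return(out)
  }
  norm <- lapply(which(sums > 0), function(k) mats[[k]] / sums[k])
  P <- Reduce(`+`, norm) / length(norm)
  haralick_stats(P)
}
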