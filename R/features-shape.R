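#' Shape features of a lesion
#'
#' Six morphological descriptors computed from the binary mask and physical
#' spacing: volume (voxel count times voxel volume, cm^3), surface area
#' (normal-weighted boundary-face estimator, cm^2), surface-to-volume ratio
#' (1/cm), sphericity (pi^(1/3) (6V)^(2/3) / A, approaching 1 for a sphere),
#' maximum 3-D diameter (cm; largest voxel-centre distance plus one voxel
#' diagonal, so a single voxel has diameter equal to its diagonal), and
#' elongation (sqrt of the ratio of the second to the first principal
#' moment of the voxel-centre cloud; 1 = isotropic).
#'
#' @param lesion a `lesion` (or logical 3-D mask).
#' @param spacing voxel spacing in mm.
#' @return named numeric vector of the 6 shape features.
#' @export
shape_features <- function(lesion, spacing) {
  mask <- if (inherits(lesion, "lesion")) lesion$mask else lesion
  if (!any(mask)) stop("empty lesion mask")
  vox_vol <- prod(spacing)                       # mm^3
  n <- sum(mask)
  V <- n * vox_vol                               # mm^3
  A <- surface_area_mm2(mask, spacing)           # mm^2
  sph <- pi^(1 / 3) * (6 * V)^(2 / 3) / A
  co <- arrayInd(which(mask), dim(mask))
  ph <- sweep(co, 2, spacing, `*`)
  # max diameter over boundary voxels only (same maximum, fewer pairs)
  bnd <- boundary_voxels(mask)
  pb <- sweep(arrayInd(which(bnd), dim(mask)), 2, spacing, `*`)
  maxd <- max_pair_distance(pb) + sqrt(sum(spacing^2))
  if (n > 1) {
    ev <- eigen(stats::cov(ph), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  } else elong <- 1
  c(shape.volume_cm3 = V / 1000,
    shape.surface_area_cm2 = A / 100,
    shape.surface_to_volume = (A / 100) / (V / 1000),
    shape.sphericity = sph,
    shape.max_diameter_cm = maxd / 10,
    shape.elongation = elong)
}

# voxels with at least one 6-neighbour outside the mask (or on the border)
boundary_voxels <- function(mask) {
  d <- dim(mask)
  p <- array(FALSE, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  inner <- array(TRUE, d)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    idx <- list(2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1))
    idx[[ax]] <- idx[[ax]] + s
    inner <- inner & p[idx[[1]], idx[[2]], idx[[3]]]
  }
  mask & !inner
}

# exact maximum pairwise Euclidean distance, chunked to bound memory
max_pair_distance <- function(pts) {
  m <- nrow(pts)
  if (m < 2) return(0)
  best <- 0
  chunk <- 512L
  for (i0 in seq(1L, m, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, m)
    block <- pts[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(pts^2), `+`) -
      2 * tcrossprod(block, pts)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}
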