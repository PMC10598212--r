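#' Rasterize a physical-radius disc as pixel offsets
#'
#' A pixel offset (di, dj) belongs to the structuring element iff its centre
#' lies within the physical radius: (di * sp_row)^2 + (dj * sp_col)^2 <=
#' margin_mm^2. With non-square pixels this yields an elliptical element in
#' index space so that the physical margin is honoured along both in-plane
#' axes.
#'
#' @param margin_mm physical radius in mm.
#' @param spacing_inplane length-2 pixel size (row, col) in mm.
#' @return integer matrix with columns `di`, `dj`.
#' @export
disc_offsets <- function(margin_mm, spacing_inplane) {
  stopifnot(margin_mm > 0, all(spacing_inplane > 0))
  a <- floor(margin_mm / spacing_inplane[1])
  b <- floor(margin_mm / spacing_inplane[2])
  g <- as.matrix(expand.grid(di = -a:a, dj = -b:b))
  keep <- (g[, 1] * spacing_inplane[1])^2 + (g[, 2] * spacing_inplane[2])^2 <=
    margin_mm^2 + 1e-9
  g[keep, , drop = FALSE]
}

# shift a logical matrix by (di, dj), padding with FALSE
shift2d <- function(m, di, dj) {
  d <- dim(m)
  out <- matrix(FALSE, d[1], d[2])
  src_i <- max(1, 1 + di):min(d[1], d[1] + di)
  src_j <- max(1, 1 + dj):min(d[2], d[2] + dj)
  if (di > d[1] - 1 || di < -(d[1] - 1) || dj > d[2] - 1 || dj < -(d[2] - 1))
    return(out)
  out[src_i - di, src_j - dj] <- m[src_i, src_j]
  out
}

#' Erode or dilate a lesion mask by a physical margin, slice by slice
#'
#' Morphology is strictly 2-D per axial slice: each cross-section is eroded
#' or dilated with a rasterized disc of physical radius `margin_mm` (see
#' [disc_offsets]). There is no through-slice growth because slice thickness
#' typically exceeds the margin. Slices emptied by erosion stay empty;
#' dilation is clipped at the grid border.
#'
#' @param mask logical 3-D array (or a `lesion`).
#' @param margin_mm margin in mm (> 0). The standard rim/peripheral margin
#'   is 4 mm (0.4 cm).
#' @param mode `"erode"` or `"dilate"`.
#' @param spacing voxel spacing in mm; only the in-plane components
#'   (first two) are used.
#' @return logical 3-D array on the same grid.
#' @export
morph_margin <- function(mask, margin_mm, mode = c("erode", "dilate"), spacing) {
  mode <- match.arg(mode)
  if (inherits(mask, "lesion")) mask <- mask$mask
  stopifnot(margin_mm > 0, length(dim(mask)) == 3L)
  d <- dim(mask)
  offs <- disc_offsets(margin_mm, spacing[1:2])
  if (mode == "dilate" && (max(abs(offs[, 1])) >= d[1] || max(abs(offs[, 2])) >= d[2]))
    warning("dilation margin exceeds image extent; result clipped at the grid border")
  out <- array(FALSE, d)
  comb <- if (mode == "erode") `&` else `|`
  for (k in seq_len(d[3])) {
    sl <- mask[, , k]
    if (!any(sl)) next
    acc <- NULL
    for (r in seq_len(nrow(offs))) {
      sh <- shift2d(sl, -offs[r, 1], -offs[r, 2])
      acc <- if (is.null(acc)) sh else comb(acc, sh)
    }
    out[, , k] <- acc
  }
  out
}
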