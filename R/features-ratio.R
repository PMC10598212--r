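#' Non-shape (intensity-based) features of an arbitrary lesion mask
#'
#' The 38 intensity-derived features (16 first-order + 4 intensity-volume
#' histogram + 18 Haralick) computed on any binary mask over the image, with
#' the HU floor applied. Returns all-NA when the floored intensity set is
#' empty; texture entries are NA when no in-plane pixel pairs exist.
#'
#' @param mask logical 3-D array.
#' @param image [image_volume].
#' @param floor_hu HU exclusion floor (default -100).
#' @param n_levels,max_hu GLCM discretization.
#' @return named numeric vector of 38 features.
#' @export
nonshape_features <- function(mask, image, floor_hu = -100,
                              n_levels = 100L, max_hu = 1000) {
  nm <- c(names(first_order_features(c(0, 1))),
          paste0("ivh.vol_hu_gt_", c(50, 100, 150, 200)),
          haralick_names())
  out <- rep(NA_real_, length(nm))
  names(out) <- nm
  if (!any(mask)) return(out)
  v <- image$voxels[mask]
  v <- v[v >= floor_hu]
  if (!length(v)) return(out)
  vox_cm3 <- prod(image$spacing) / 1000
  out[1:16] <- first_order_features(v)
  out[17:20] <- ivh_features(v, vox_cm3)
  out[21:38] <- haralick_features(mask, image, n_levels, max_hu, floor_hu)
  out
}

#' Rim and peripheral ratio features
#'
#' Intra-lesion heterogeneity and lesion-context descriptors: each of the 38
#' non-shape features f is recomputed on the lesion eroded (rim) or dilated
#' (peripheral) by a physical in-plane margin, and divided by the value on
#' the standard mask: `rim_ratio.f = f(eroded)/f(standard)`,
#' `peripheral_ratio.f = f(dilated)/f(standard)`. The HU floor applies to
#' all three masks. Rim ratios are missing when erosion empties the mask;
#' any ratio with |denominator| below `tol` is missing (never infinite).
#'
#' @param lesion a `lesion`.
#' @param image [image_volume].
#' @param margin_mm physical margin (default 4 mm = 0.4 cm).
#' @param floor_hu HU floor.
#' @param tol denominator tolerance (default 1e-12).
#' @return named numeric vector of 76 ratio features
#'   (`rim_ratio.*`, `peripheral_ratio.*`).
#' @export
ratio_features <- function(lesion, image, margin_mm = 4, floor_hu = -100,
                           tol = 1e-12) {
  stopifnot(inherits(lesion, "lesion"))
  std <- nonshape_features(lesion$mask, image, floor_hu)
  er <- morph_margin(lesion$mask, margin_mm, "erode", image$spacing)
  di <- morph_margin(lesion$mask, margin_mm, "dilate", image$spacing)
  fe <- nonshape_features(er, image, floor_hu)
  fd <- nonshape_features(di, image, floor_hu)
  ratio <- function(num, den) {
    r <- num / den
    r[!is.finite(r) | is.na(den) | abs(den) < tol] <- NA_real_
    r
  }
  rim <- ratio(fe, std)
  per <- ratio(fd, std)
  names(rim) <- paste0("rim_ratio.", names(std))
  names(per) <- paste0("peripheral_ratio.", names(std))
  c(rim, per)
}
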