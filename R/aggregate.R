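#' Full per-lesion radiomics feature vector
#'
#' Computes the complete 120-feature catalogue for one lesion: shape,
#' first-order, intensity-volume histogram, Haralick texture, and the rim
#' and peripheral ratio families. Intensity features are NA when the HU
#' floor empties the lesion; rim ratios are NA when the erosion empties all
#' slices.
#'
#' @param lesion a `lesion`.
#' @param image [image_volume].
#' @param margin_mm rim/peripheral margin in mm (default 4).
#' @param floor_hu HU floor (default -100).
#' @return named numeric vector over [lesion_feature_catalogue()].
#' @export
lesion_features <- function(lesion, image, margin_mm = 4, floor_hu = -100) {
  out <- c(shape_features(lesion, image$spacing),
           nonshape_features(lesion$mask, image, floor_hu),
           ratio_features(lesion, image, margin_mm, floor_hu))
  stopifnot(identical(names(out), lesion_feature_catalogue()))
  out
}

#' Aggregate lesion feature vectors into a patient profile
#'
#' One value per feature for the whole patient: the unweighted mean over all
#' lesions in which the feature is defined (missing lesion values are
#' skipped, not zero-filled, since zero is a meaningful feature value). A
#' feature is missing at patient level iff it is missing for every lesion.
#'
#' @param lesion_features list of named numeric vectors (one per lesion),
#'   all over the same feature names.
#' @return list with `profile` (named numeric vector of per-feature means)
#'   and `n_lesions` (per-feature count of contributing lesions).
#' @export
aggregate_patient <- function(lesion_features) {
  if (!length(lesion_features))
    stop("patient must have at least one lesion with measurable disease")
  m <- do.call(rbind, lesion_features)
  cnt <- colSums(!is.na(m))
  prof <- suppressWarnings(colMeans(m, na.rm = TRUE))
  prof[cnt == 0] <- NA_real_
  list(profile = prof, n_lesions = cnt)
}

#' Extract all lesions of a scan and their feature vectors
#'
#' Convenience wrapper chaining [split_lesions], [lesion_features] and
#' [density_flags] over a labelled scan.
#'
#' @param image [image_volume].
#' @param mask [segmentation_mask] on the same grid.
#' @param margin_mm,floor_hu see [lesion_features].
#' @return data.frame: one row per lesion with id, site, voxel count,
#'   volume, density flags and the 120 catalogue features as columns.
#' @export
extract_lesion_features <- function(image, mask, margin_mm = 4, floor_hu = -100) {
  lesions <- split_lesions(mask, image$spacing)
  rows <- lapply(lesions, function(le) {
    fv <- lesion_features(le, image, margin_mm, floor_hu)
    fl <- density_flags(le, image)
    data.frame(lesion_id = le$id, site = le$site,
               voxel_count = le$voxel_count, volume_cm3 = le$volume_cm3,
               has_hyperdense = fl[["has_hyperdense"]],
               has_hypodense = fl[["has_hypodense"]],
               t(fv), check.names = FALSE)
  })
  do.call(rbind, rows)
}
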