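#' Hyper-/hypodense region flags for a lesion
#'
#' Simple configurable threshold proxy for tissue-density sub-segmentation:
#' a lesion has a hyperdense (calcified) component when at least
#' `min_fraction` of its voxels exceed `hyper_hu`, and a hypodense
#' (cystic/fatty) component when at least `min_fraction` fall below
#' `hypo_hu`. Thresholds are configuration, not learned; fractions are
#' computed over the raw lesion voxels (no HU floor, since fat and fluid
#' are exactly what the hypodense flag must see).
#'
#' @param lesion a `lesion`.
#' @param image [image_volume].
#' @param hyper_hu threshold for hyperdense voxels (default +160 HU).
#' @param hypo_hu threshold for hypodense voxels (default +20 HU).
#' @param min_fraction minimum voxel fraction to raise a flag (default 0.01).
#' @return logical vector `c(has_hyperdense, has_hypodense)`.
#' @export
density_flags <- function(lesion, image, hyper_hu = 160, hypo_hu = 20,
                          min_fraction = 0.01) {
  stopifnot(inherits(lesion, "lesion"))
  v <- image$voxels[lesion$mask]
  c(has_hyperdense = mean(v > hyper_hu) >= min_fraction,
    has_hypodense = mean(v < hypo_hu) >= min_fraction)
}
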