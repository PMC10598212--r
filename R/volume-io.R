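#' CT image volume
#'
#' Container for a 3-D scalar CT volume in Hounsfield units with physical
#' voxel spacing. The third array axis is the slice (through-plane) axis;
#' spacing is stored in millimetres throughout the package.
#'
#' @param voxels 3-D numeric array of HU values.
#' @param spacing numeric length-3, voxel size in mm along (row, column,
#'   slice). All components must be positive.
#' @param origin optional origin/orientation metadata, carried through opaque.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing, origin = NULL) {
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3-D array, got ", length(dim(voxels)), " dimensions")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  if (any(!is.finite(voxels)))
    stop("HU values must be finite")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Multi-label lesion segmentation mask
#'
#' Integer label array on the same grid as its image; 0 is background and
#' every nonzero label maps to an anatomic site name via `site_codes`.
#'
#' @param labels 3-D integer array.
#' @param site_codes named character vector mapping label value (name) to
#'   anatomic site.
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(labels, site_codes) {
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3-D array")
  storage.mode(labels) <- "integer"
  present <- setdiff(sort(unique(as.integer(labels))), 0L)
  missing_codes <- setdiff(as.character(present), names(site_codes))
  if (length(missing_codes))
    stop("labels without a site code: ", paste(missing_codes, collapse = ", "))
  structure(list(labels = labels, site_codes = site_codes),
            class = "segmentation_mask")
}

#' Anatomic sites of the segmentation dialect
#'
#' The 15 disease sites used for lesion labelling: omental and peritoneal
#' compartments, pelvic/ovarian disease, five lymph-node stations, and
#' liver/lung metastases.
#'
#' @return Character vector of 15 site identifiers.
#' @export
anatomic_sites <- function() {
  c("omentum", "right_upper_quadrant", "left_upper_quadrant", "epigastrium",
    "mesentery", "right_paracolic_gutter", "left_paracolic_gutter",
    "ovaries_pelvis", "infrarenal_ln", "suprarenal_ln", "inguinal_ln",
    "supradiaphragmatic_ln", "chest_ln", "liver_mets", "lung_mets")
}

#' Read a NIfTI volume
#'
#' Reads a 3-D scalar NIfTI file; voxel spacing is taken from the header and
#' converted to millimetres. Non-3-D inputs and missing/non-positive spacing
#' are format errors rather than silently defaulted.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An [image_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3-D volume, got ", length(d), " dimensions in ", path)
  sp <- RNifti::pixdim(img)[seq_len(3)]
  units <- tryCatch(RNifti::pixunits(img), error = function(e) "mm")
  if ("m" %in% units) sp <- sp * 1000
  if ("um" %in% units) sp <- sp / 1000
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("missing or invalid voxel spacing in header of ", path)
  image_volume(array(as.numeric(img), d), sp)
}

#' Write a volume to NIfTI
#'
#' @param volume an [image_volume], or a 3-D array with `spacing` supplied.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing spacing in mm when `volume` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, spacing = NULL) {
  if (inherits(volume, "image_volume")) {
    arr <- volume$voxels
    spacing <- volume$spacing
  } else {
    arr <- volume
    if (is.null(spacing)) stop("spacing required when writing a bare array")
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label-to-site map
#'
#' Sidecar YAML (or JSON) mapping integer mask labels to anatomic site names,
#' e.g. `1: omentum`.
#'
#' @param path YAML/JSON file.
#' @return Named character vector (names are label values).
#' @export
read_site_map <- function(path) {
  m <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  out <- vapply(m, as.character, character(1))
  if (is.null(names(out)) || any(names(out) == ""))
    stop("site map must be a mapping from label value to site name")
  unknown <- setdiff(out, anatomic_sites())
  if (length(unknown))
    warning("site names outside the standard catalogue: ",
            paste(unknown, collapse = ", "))
  out
}
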