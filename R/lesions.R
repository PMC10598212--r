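#' @keywords internal
new_lesion <- function(mask, site, spacing, label = NA_integer_, id = NA_character_) {
  vc <- sum(mask)
  structure(list(mask = mask, site = site, label = label, id = id,
                 voxel_count = vc,
                 volume_cm3 = vc * prod(spacing) / 1000),
            class = "lesion")
}

#' @export
print.lesion <- function(x, ...) {
  cat("<lesion> ", x$id, " site=", x$site, " voxels=", x$voxel_count,
      " volume=", signif(x$volume_cm3, 4), " cm^3\n", sep = "")
  invisible(x)
}

#' Label 26-connected components of a binary 3-D mask
#'
#' Voxels are connected if their faces, edges or corners touch
#' (26-neighbourhood). Components of any size are kept.
#'
#' @param mask logical 3-D array.
#' @return integer array of the same shape; 0 = background, components
#'   numbered from 1 in first-encounter order.
#' @export
label_components_26 <- function(mask) {
  d <- dim(mask)
  if (length(d) != 3L) stop("mask must be 3-D")
  lab <- array(0L, d)
  fg <- which(mask)
  if (!length(fg)) return(lab)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]      # 26 neighbours
  current <- 0L
  for (seed in fg) {
    if (lab[seed] != 0L) next
    current <- current + 1L
    lab[seed] <- current
    frontier <- seed
    while (length(frontier)) {
      co <- arrayInd(frontier, d)
      nb <- co[rep(seq_len(nrow(co)), each = nrow(offs)), , drop = FALSE] +
            offs[rep(seq_len(nrow(offs)), times = nrow(co)), , drop = FALSE]
      ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
            nb[, 2] >= 1L & nb[, 2] <= d[2] &
            nb[, 3] >= 1L & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique((nb[, 3] - 1L) * (d[1] * d[2]) + (nb[, 2] - 1L) * d[1] + nb[, 1])
      lin <- lin[mask[lin] & lab[lin] == 0L]
      lab[lin] <- current
      frontier <- lin
    }
  }
  lab
}

#' Split a multi-label mask into connected lesions
#'
#' Each label value is decomposed independently into 26-connected components;
#' every component becomes one lesion carrying the label's anatomic site.
#' Single-voxel components are kept.
#'
#' @param mask a [segmentation_mask].
#' @param spacing voxel spacing in mm (from the paired image).
#' @return list of `lesion` objects.
#' @export
split_lesions <- function(mask, spacing) {
  stopifnot(inherits(mask, "segmentation_mask"))
  labels_present <- setdiff(sort(unique(as.integer(mask$labels))), 0L)
  lesions <- list()
  for (lv in labels_present) {
    site <- mask$site_codes[[as.character(lv)]]
    if (is.null(site))
      stop("label ", lv, " has no site code")      # configuration error
    comp <- label_components_26(mask$labels == lv)
    for (k in seq_len(max(comp, 0L))) {
      id <- sprintf("%s_%d_%d", site, lv, k)
      lesions[[length(lesions) + 1L]] <-
        new_lesion(comp == k, site, spacing, label = lv, id = id)
    }
  }
  message(length(lesions), " lesion(s) from ", length(labels_present), " label(s)")
  lesions
}

#' Apply the Hounsfield-unit floor to a lesion's intensities
#'
#' Voxels with intensity strictly below `floor_hu` are excluded from all
#' intensity-based feature calculations; the value `floor_hu` itself is
#' retained.
#'
#' @param lesion a `lesion`.
#' @param image the paired [image_volume].
#' @param floor_hu exclusion threshold in HU (default -100).
#' @return list with `intensities` (numeric vector), `excluded_fraction`,
#'   and `empty` (TRUE when all voxels were excluded, in which case the
#'   lesion is skipped for intensity features).
#' @export
apply_hu_floor <- function(lesion, image, floor_hu = -100) {
  stopifnot(inherits(lesion, "lesion"), inherits(image, "image_volume"))
  if (!identical(dim(lesion$mask), dim(image$voxels)))
    stop("lesion mask grid does not match image grid")
  v <- image$voxels[lesion$mask]
  keep <- v >= floor_hu
  list(intensities = v[keep],
       excluded_fraction = if (length(v)) mean(!keep) else 0,
       empty = !any(keep))
}
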