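#' Per-lesion radiomics feature catalogue
#'
#' The fixed 120-name catalogue computed for every lesion: 6 shape, 16
#' first-order, 4 intensity-volume histogram and 18 Haralick features, plus
#' rim and peripheral ratio versions of the 38 non-shape features (shape
#' features are not included in the ratios).
#'
#' @return character vector of 120 feature names.
#' @export
lesion_feature_catalogue <- function() {
  shape <- c("shape.volume_cm3", "shape.surface_area_cm2",
             "shape.surface_to_volume", "shape.sphericity",
             "shape.max_diameter_cm", "shape.elongation")
  nonshape <- c(names(first_order_features(c(0, 1))),
                paste0("ivh.vol_hu_gt_", c(50, 100, 150, 200)),
                haralick_names())
  c(shape, nonshape,
    paste0("rim_ratio.", nonshape),
    paste0("peripheral_ratio.", nonshape))
}

#' Patient-level imaging feature catalogue
#'
#' The 164 imaging features entering the predictive models: 44 semantic and
#' volumetric descriptors (per-site volumes and lesion counts for the 15
#' anatomic sites; mean/max/total lesion volume; lesion counts above 0, 1,
#' 10 and 100 cm^3; hyper-/hypodense flags for omental and pelvic lesions;
#' ascites, pleural effusion and pleural thickening scores), 44
#' patient-averaged intensity radiomics (6 shape + 16 first-order + 4 IVH +
#' 18 Haralick), 38 rim ratios and 38 peripheral ratios.
#'
#' @return character vector of 164 column names (order fixed and versioned).
#' @export
imaging_feature_catalogue <- function() {
  sites <- anatomic_sites()
  semantic <- c(paste0("vol.", sites),
                paste0("nles.", sites),
                "vol.mean", "vol.max", "vol.total",
                paste0("nles_gt_", c(0, 1, 10, 100), "cm3"),
                "flag.omentum_hyper", "flag.omentum_hypo",
                "flag.pelvis_hyper", "flag.pelvis_hypo",
                "ascites", "pleural_effusion", "pleural_thickening")
  c(semantic, lesion_feature_catalogue())
}

#' Clinical feature catalogue
#'
#' Age, the ordinal FIGO stage, and the 9 treatment features (agent
#' indicators, schedule-combination indicators, irregular-schedule flag and
#' the number of chemotherapy sessions before the second scan).
#'
#' @return character vector of 11 column names.
#' @export
clinical_feature_catalogue <- function() {
  c("age", "figo_ordinal", treatment_feature_names())
}

#' @rdname clinical_feature_catalogue
#' @export
treatment_feature_names <- function() {
  c("carboplatin", "paclitaxel", "doxorubicin",
    "pac_weekly_carb_3weekly", "both_weekly", "both_3weekly",
    "carboplatin_mono", "irregular_schedule", "sessions_before_second_scan")
}

#' ctDNA feature catalogue
#' @return character vector of 3 column names.
#' @export
ctdna_feature_catalogue <- function() {
  c("tp53_maf", "tmad", "tp53_mutation_detected")
}
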