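#' Log-volume-ratio response endpoint
#'
#' The volumetric response to therapy is the natural logarithm of the ratio
#' of total post-treatment to total pre-treatment lesion volume:
#' `Response = ln(sum(post) / sum(pre))`. Negative values mean shrinkage. A
#' complete response (zero residual volume) is floored at `floor_cm3` so the
#' endpoint stays finite, and flagged.
#'
#' @param pre_volumes baseline lesion volumes (cm^3), non-empty, positive sum.
#' @param post_volumes post-treatment lesion volumes (cm^3); may be empty.
#' @param floor_cm3 complete-response volume floor (default 0.01 cm^3,
#'   roughly the smallest measurable lesion on 5 mm slices).
#' @return list with `response` (numeric) and `complete_response` (logical).
#' @export
compute_response <- function(pre_volumes, post_volumes, floor_cm3 = 0.01) {
  if (!length(pre_volumes) || sum(pre_volumes) <= 0)
    stop("no measurable baseline disease: pre-treatment volumes must have a positive sum")
  post <- sum(post_volumes)
  cr <- post <= 0
  if (cr) post <- floor_cm3
  list(response = log(post / sum(pre_volumes)), complete_response = cr)
}

#' Binary responder class under a volumetric criterion
#'
#' A patient is a responder when the relative volume reduction
#' `1 - exp(response)` meets the criterion threshold: 30% for the
#' RECIST-equivalent volumetric criterion, 50% for WHO, 65% for the
#' spherical-volume criterion (a sphere whose diameter shrinks 30% loses
#' 1 - 0.7^3 = 65.7% of its volume), and 30% for the ellipsoidal criterion.
#'
#' @param response log volume ratio (see [compute_response]).
#' @param criterion one of `"recist30"`, `"who50"`, `"sphere65"`,
#'   `"ellipsoid30"`.
#' @return logical vector: TRUE = responder.
#' @export
classify_volumetric_response <- function(response,
                                         criterion = c("recist30", "who50",
                                                       "sphere65", "ellipsoid30")) {
  criterion <- match.arg(criterion)
  thr <- c(recist30 = 0.30, who50 = 0.50, sphere65 = 0.65, ellipsoid30 = 0.30)[[criterion]]
  (1 - exp(response)) >= thr
}

#' Ordinal FIGO stage encoding
#'
#' Stages 1A through 4B mapped to 1..10 in order of aggressiveness. Roman
#' numerals and mixed case are normalized (`"IIIC"` -> 8).
#'
#' @param stage character vector of stage strings.
#' @return integer vector in 1..10.
#' @export
encode_figo <- function(stage) {
  lv <- c("1A", "1B", "1C", "2A", "2B", "3A", "3B", "3C", "4A", "4B")
  s <- toupper(gsub("[ .]", "", as.character(stage)))
  for (rn in list(c("IV", "4"), c("III", "3"), c("II", "2"), c("I", "1")))
    s <- sub(paste0("^", rn[1]), rn[2], s)
  out <- match(s, lv)
  if (anyNA(out))
    stop("unrecognized FIGO stage: ",
         paste(unique(stage[is.na(out)]), collapse = ", "),
         " (accepted: ", paste(lv, collapse = ", "), ")")
  out
}

#' Chemotherapy schedule class from dose dates
#'
#' The mean period is the average gap between successive doses; a regimen is
#' weekly when the mean period is 6-10 days (both included), 3-weekly when
#' 18-24 days (both included), and irregular otherwise. A single dose has no
#' defined period and is classed irregular.
#'
#' @param dates Date (or sortable numeric) vector of dose dates.
#' @return one of `"weekly"`, `"3weekly"`, `"irregular"`.
#' @export
schedule_class <- function(dates) {
  d <- sort(as.numeric(dates))
  if (length(d) < 2) return("irregular")
  mp <- mean(diff(d))
  if (mp >= 6 && mp <= 10) "weekly"
  else if (mp >= 18 && mp <= 24) "3weekly"
  else "irregular"
}

#' Encode a chemotherapy course as the 9 treatment features
#'
#' Agent indicators for carboplatin, paclitaxel and doxorubicin; indicators
#' for the typical schedule combinations (weekly paclitaxel + 3-weekly
#' carboplatin, both weekly, both 3-weekly); carboplatin monotherapy; an
#' irregular-schedule flag (any received agent on an irregular schedule);
#' and the number of chemotherapy sessions before the second scan.
#'
#' @param course list with elements `carboplatin_dates`, `paclitaxel_dates`,
#'   `doxorubicin_dates` (Date vectors, possibly empty/NULL) and
#'   `sessions_before_second_scan` (non-negative integer).
#' @return named numeric vector over [treatment_feature_names()].
#' @export
encode_regimen <- function(course) {
  dates <- list(carboplatin = course$carboplatin_dates,
                paclitaxel = course$paclitaxel_dates,
                doxorubicin = course$doxorubicin_dates)
  got <- vapply(dates, function(d) length(d) > 0, logical(1))
  cls <- vapply(dates, function(d) if (length(d)) schedule_class(d) else NA_character_,
                character(1))
  sessions <- course$sessions_before_second_scan
  if (is.null(sessions)) sessions <- NA_real_
  if (!is.na(sessions) && sessions < 0) stop("sessions_before_second_scan must be >= 0")
  out <- c(
    carboplatin = as.numeric(got[["carboplatin"]]),
    paclitaxel = as.numeric(got[["paclitaxel"]]),
    doxorubicin = as.numeric(got[["doxorubicin"]]),
    pac_weekly_carb_3weekly = as.numeric(got[["paclitaxel"]] && got[["carboplatin"]] &&
      identical(cls[["paclitaxel"]], "weekly") && identical(cls[["carboplatin"]], "3weekly")),
    both_weekly = as.numeric(got[["paclitaxel"]] && got[["carboplatin"]] &&
      identical(cls[["paclitaxel"]], "weekly") && identical(cls[["carboplatin"]], "weekly")),
    both_3weekly = as.numeric(got[["paclitaxel"]] && got[["carboplatin"]] &&
      identical(cls[["paclitaxel"]], "3weekly") && identical(cls[["carboplatin"]], "3weekly")),
    carboplatin_mono = as.numeric(got[["carboplatin"]] && !got[["paclitaxel"]] &&
      !got[["doxorubicin"]]),
    irregular_schedule = as.numeric(any(cls[got] == "irregular")),
    sessions_before_second_scan = as.numeric(sessions))
  out
}

#' Assemble the cohort feature matrix
#'
#' Builds the model input matrix from per-patient records for one of the
#' four nested feature sets: `"clinical"` (11 columns: age, FIGO ordinal and
#' 9 treatment features), `"clinical_ca125"` (12), `"clinical_ca125_radiomics"`
#' (176: + the 164 imaging features), and `"full"` (179: + 3 ctDNA
#' features). Column order is fixed by the catalogues.
#'
#' @param records data.frame with one row per patient, a `patient_id`
#'   column, and the catalogue columns present for the requested set
#'   (missing values allowed; they are imputed at model-fit time).
#' @param feature_set which nested set to assemble.
#' @return numeric matrix with patients as rownames.
#' @export
assemble_feature_table <- function(records,
                                   feature_set = c("clinical", "clinical_ca125",
                                                   "clinical_ca125_radiomics",
                                                   "full")) {
  feature_set <- match.arg(feature_set)
  if (anyDuplicated(records$patient_id))
    stop("duplicate patient ids: ",
         paste(unique(records$patient_id[duplicated(records$patient_id)]),
               collapse = ", "))
  cols <- clinical_feature_catalogue()
  if (feature_set != "clinical") cols <- c(cols, "ca125")
  if (feature_set %in% c("clinical_ca125_radiomics", "full"))
    cols <- c(cols, imaging_feature_catalogue())
  if (feature_set == "full") cols <- c(cols, ctdna_feature_catalogue())
  absent <- setdiff(cols, names(records))
  if (length(absent))
    stop("missing columns for feature set '", feature_set, "': ",
         paste(utils::head(absent, 5), collapse = ", "),
         if (length(absent) > 5) sprintf(" (+%d more)", length(absent) - 5))
  m <- as.matrix(records[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(records$patient_id)
  m
}
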