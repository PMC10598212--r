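#' Specification of a synthetic CT phantom
#'
#' Describes a labelled phantom scan: grid shape, physical spacing,
#' background HU and a list of ellipsoidal lesions. Each lesion is a list
#' with `site` (anatomic site name), `label` (positive integer), `center`
#' (voxel coordinates), `radii_mm` (length-3 physical semi-axes), `base_hu`,
#' and optionally `texture` (`list(type = "constant")`,
#' `list(type = "gaussian", sigma = )` or
#' `list(type = "checker", period = , amplitude = )`), `core_offset_hu`
#' with `core_frac` (an inner concentric ellipsoid offset in HU), and
#' `hyper_fraction`/`hyper_hu`, `hypo_fraction`/`hypo_hu` inclusions.
#'
#' @param shape integer length-3 grid dimensions.
#' @param spacing voxel size mm (default c(1, 1, 5)).
#' @param background_hu background intensity (default 0).
#' @param lesions list of lesion specifications.
#' @param seed RNG seed; the generator is a pure function of spec + seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, spacing = c(1, 1, 5), background_hu = 0,
                         lesions = list(), seed = 1L) {
  stopifnot(length(shape) == 3, all(shape >= 1), all(spacing > 0))
  for (le in lesions) {
    stopifnot(!is.null(le$site), !is.null(le$label), le$label >= 1,
              length(le$center) == 3, length(le$radii_mm) == 3,
              all(le$radii_mm > 0))
  }
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 background_hu = background_hu, lesions = lesions,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom image, segmentation mask and ground truth
#'
#' Rasterizes the spec's ellipsoidal lesions onto the grid (a voxel belongs
#' to a lesion when its centre lies inside the ellipsoid), applies the
#' texture model, optional hot/cold core and density inclusions, and
#' returns the image, the multi-label mask and an exact ground-truth table
#' (voxel counts, volumes, mean HU, inclusion fractions) so downstream
#' feature tests can assert against known values. Overlapping lesions with
#' different labels are an error (ambiguous ownership).
#'
#' @param spec a [phantom_spec].
#' @return list with `image` ([image_volume]), `mask`
#'   ([segmentation_mask]), and `truth` (data.frame).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  sp <- spec$spacing
  img <- array(spec$background_hu + 0.0, d)
  lab <- array(0L, d)
  ax <- lapply(1:3, function(a) seq_len(d[a]))
  truth <- list()
  for (le in spec$lesions) {
    e2 <- outer(outer(((ax[[1]] - le$center[1]) * sp[1] / le$radii_mm[1])^2,
                      ((ax[[2]] - le$center[2]) * sp[2] / le$radii_mm[2])^2, `+`),
                ((ax[[3]] - le$center[3]) * sp[3] / le$radii_mm[3])^2, `+`)
    inside <- e2 <= 1
    clash <- inside & lab != 0L & lab != le$label
    if (any(clash))
      stop("lesions with different labels overlap at ", sum(clash), " voxel(s)")
    lab[inside] <- as.integer(le$label)
    nvox <- sum(inside)
    vals <- rep(le$base_hu, nvox)
    tx <- if (is.null(le$texture)) list(type = "constant") else le$texture
    if (tx$type == "gaussian") {
      vals <- vals + stats::rnorm(nvox, 0, tx$sigma)
    } else if (tx$type == "checker") {
      per <- if (is.null(tx$period)) 1L else tx$period
      amp <- if (is.null(tx$amplitude)) 100 else tx$amplitude
      co <- arrayInd(which(inside), d)
      parity <- (floor(co[, 1] / per) + floor(co[, 2] / per) +
                 floor(co[, 3] / per)) %% 2
      vals <- vals + amp * parity
    } else if (tx$type != "constant") stop("unknown texture type: ", tx$type)
    core_n <- 0L
    if (!is.null(le$core_offset_hu)) {
      cf <- if (is.null(le$core_frac)) 0.5 else le$core_frac
      core <- e2[inside] <= cf^2
      vals[core] <- vals[core] + le$core_offset_hu
      core_n <- sum(core)
    }
    n_hyper <- n_hypo <- 0L
    if (!is.null(le$hyper_fraction) && le$hyper_fraction > 0) {
      n_hyper <- round(le$hyper_fraction * nvox)
      pick <- sample.int(nvox, n_hyper)
      vals[pick] <- if (is.null(le$hyper_hu)) 300 else le$hyper_hu
    }
    if (!is.null(le$hypo_fraction) && le$hypo_fraction > 0) {
      n_hypo <- round(le$hypo_fraction * nvox)
      pick <- sample.int(nvox, n_hypo)
      vals[pick] <- if (is.null(le$hypo_hu)) -50 else le$hypo_hu
    }
    img[inside] <- vals
    truth[[length(truth) + 1L]] <- data.frame(
      label = le$label, site = le$site, voxel_count = nvox,
      volume_cm3 = nvox * prod(sp) / 1000, mean_hu = mean(vals),
      core_voxels = core_n, hyper_voxels = n_hyper, hypo_voxels = n_hypo)
  }
  site_codes <- vapply(spec$lesions, function(le) le$site, character(1))
  names(site_codes) <- vapply(spec$lesions, function(le) as.character(le$label),
                              character(1))
  site_codes <- site_codes[!duplicated(names(site_codes))]
  list(image = image_volume(img, sp),
       mask = segmentation_mask(lab, site_codes),
       truth = do.call(rbind, truth))
}

#' Paired pre/post lesion volume tables with site-specific shrinkage
#'
#' Applies per-site multiplicative shrinkage factors to a baseline lesion
#' volume table, emulating site-specific differential response: post
#' volume = pre volume x factor; a factor of 0 removes the lesion from the
#' post-treatment table.
#'
#' @param baseline data.frame with columns `site` and `volume_cm3` (e.g.
#'   the `truth` of [make_phantom]).
#' @param factors named numeric vector of shrinkage factors by site
#'   (>= 0); sites not named keep factor 1.
#' @return list with `pre` and `post` volume tables (site, volume_cm3).
#' @export
make_paired_scans <- function(baseline, factors = numeric(0)) {
  stopifnot(all(factors >= 0), all(c("site", "volume_cm3") %in% names(baseline)))
  f <- ifelse(baseline$site %in% names(factors),
              factors[baseline$site], 1)
  pre <- data.frame(site = baseline$site, volume_cm3 = baseline$volume_cm3)
  post <- data.frame(site = baseline$site, volume_cm3 = baseline$volume_cm3 * f)
  post <- post[post$volume_cm3 > 0, , drop = FALSE]
  list(pre = pre, post = post)
}
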