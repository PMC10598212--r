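big_lesion <- function(n = 24, nz = 2, hu = 60, spacing = c(1, 1, 5)) {
  arr <- array(0, c(n, n, nz))
  mask <- array(FALSE, c(n, n, nz))
  cc <- (n + 1) / 2
  for (k in seq_len(nz)) {
    sl <- outer(1:n, 1:n, function(i, j) (i - cc)^2 + (j - cc)^2 <= (n / 2 - 1)^2)
    mask[, , k] <- sl
    arr[, , k][sl] <- hu
  }
  list(lesion = radresp:::new_lesion(mask, "omentum", spacing),
       image = image_volume(arr, spacing))
}

test_that("homogeneous lesion has all defined intensity rim ratios equal to 1", {
  hl <- big_lesion(hu = 60)
  img <- image_volume(array(60, dim(hl$image$voxels)), hl$image$spacing)
  r <- ratio_features(hl$lesion, img, margin_mm = 4)
  rim <- r[grep("^rim_ratio\\.", names(r))]
  # scale-dependent aggregates (energy, IVH volumes) change with region size;
  # every defined intensity *statistic* ratio is 1 (statistics that are 0 on
  # constant data, like contrast, are missing under the zero-denominator rule)
  scale_dep <- grepl("fo\\.energy|ivh\\.", names(rim))
  expect_true(all(abs(rim[!scale_dep] - 1) < 1e-9, na.rm = TRUE))
  for (key in paste0("rim_ratio.", c("fo.mean", "fo.median", "glcm.energy",
                                     "glcm.max_probability", "glcm.idm")))
    expect_equal(unname(r[key]), 1, tolerance = 1e-9)
  # homogeneous background: the peripheral mean ratio is 1 as well
  expect_equal(unname(r["peripheral_ratio.fo.mean"]), 1, tolerance = 1e-9)
})

test_that("a hot core drives the rim mean ratio above one", {
  hl <- big_lesion(hu = 40)
  arr <- hl$image$voxels
  cc <- (dim(arr)[1] + 1) / 2
  core <- outer(1:dim(arr)[1], 1:dim(arr)[2],
                function(i, j) (i - cc)^2 + (j - cc)^2 <= 4^2)
  for (k in seq_len(dim(arr)[3])) {
    sl <- arr[, , k]
    sl[core & hl$lesion$mask[, , k]] <- sl[core & hl$lesion$mask[, , k]] + 200
    arr[, , k] <- sl
  }
  img <- image_volume(arr, hl$image$spacing)
  r <- ratio_features(hl$lesion, img, margin_mm = 4)
  # direct check: eroded-core mean vs whole-lesion mean
  er <- morph_margin(hl$lesion$mask, 4, "erode", img$spacing)
  expect_equal(unname(r["rim_ratio.fo.mean"]),
               mean(arr[er]) / mean(arr[hl$lesion$mask]), tolerance = 1e-12)
  expect_gt(r["rim_ratio.fo.mean"], 1)
})

test_that("lesions thinner than twice the margin lose rim but keep peripheral ratios", {
  arr <- array(0, c(30, 5, 2))
  mask <- array(FALSE, c(30, 5, 2))
  mask[3:28, 2:4, ] <- TRUE                    # 3 px wide: < 8 mm at 1 mm/px
  arr[mask] <- 75
  img <- image_volume(arr, c(1, 1, 5))
  le <- radresp:::new_lesion(mask, "mesentery", c(1, 1, 5))
  r <- ratio_features(le, img, margin_mm = 4)
  expect_true(all(is.na(r[grep("^rim_ratio\\.", names(r))])))
  expect_false(is.na(r["peripheral_ratio.fo.mean"]))
})

test_that("density flags respond to configured thresholds deterministically", {
  arr <- array(40, c(10, 10, 1))
  mask <- array(TRUE, c(10, 10, 1))
  le <- radresp:::new_lesion(mask, "omentum", c(1, 1, 5))
  img <- image_volume(arr, c(1, 1, 5))
  expect_equal(unname(density_flags(le, img)),
               c(FALSE, FALSE))
  arr2 <- arr; arr2[1:5, 1, 1] <- 300          # 5% hyperdense voxels
  f2 <- density_flags(le, image_volume(arr2, c(1, 1, 5)))
  expect_true(f2[["has_hyperdense"]])
  expect_false(f2[["has_hypodense"]])
  # thresholds are configuration: tightening the fraction flips the flag
  f3 <- density_flags(le, image_volume(arr2, c(1, 1, 5)), min_fraction = 0.10)
  expect_false(f3[["has_hyperdense"]])
  f4 <- density_flags(le, img, hypo_hu = 45)
  expect_true(f4[["has_hypodense"]])
})

test_that("patient aggregation means over defined lesion values only", {
  a <- c(f1 = 2, f2 = 2, f3 = NA)
  b <- c(f1 = 4, f2 = NA, f3 = NA)
  ag <- aggregate_patient(list(a, b))
  expect_equal(unname(ag$profile["f1"]), 3)
  expect_equal(unname(ag$profile["f2"]), 2)     # skip-missing, count 1
  expect_true(is.na(ag$profile["f3"]))
  expect_equal(unname(ag$n_lesions), c(2, 1, 0))
  # permutation invariance and single-lesion identity
  expect_equal(aggregate_patient(list(b, a))$profile, ag$profile)
  expect_equal(aggregate_patient(list(a))$profile, a)
  expect_error(aggregate_patient(list()), "at least one lesion")
})

test_that("the per-lesion catalogue is the fixed 120-name set", {
  cat120 <- lesion_feature_catalogue()
  expect_length(cat120, 120)
  expect_equal(sum(grepl("^shape\\.", cat120)), 6)
  expect_equal(sum(grepl("^fo\\.", cat120)), 16)
  expect_equal(sum(grepl("^ivh\\.", cat120)), 4)
  expect_equal(sum(grepl("^glcm\\.", cat120)), 18)
  expect_equal(sum(grepl("^rim_ratio\\.", cat120)), 38)
  expect_equal(sum(grepl("^peripheral_ratio\\.", cat120)), 38)
  hl <- big_lesion()
  fv <- lesion_features(hl$lesion, hl$image)
  expect_named(fv, cat120)
})
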