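test_that("response endpoint identities and complete-response floor", {
  expect_equal(compute_response(100, 100)$response, 0)
  expect_equal(compute_response(100, 50)$response, log(0.5))
  cr <- compute_response(c(60, 40), numeric(0))
  expect_true(cr$complete_response)
  expect_equal(cr$response, log(0.01 / 100))        # ln(1e-4) ~ -9.21
  expect_error(compute_response(numeric(0), 10), "baseline")
  # scale invariance
  set.seed(2)
  pre <- runif(6, 1, 50); post <- runif(4, 1, 30)
  expect_equal(compute_response(pre, post)$response,
               compute_response(7.3 * pre, 7.3 * post)$response)
})

test_that("volumetric criteria apply their thresholds monotonically", {
  r70 <- log(0.30)                                  # 70% reduction
  for (cr in c("recist30", "who50", "sphere65", "ellipsoid30"))
    expect_true(classify_volumetric_response(r70, cr))
  r40 <- log(0.60)                                  # 40% reduction
  expect_true(classify_volumetric_response(r40, "recist30"))
  expect_true(classify_volumetric_response(r40, "ellipsoid30"))
  expect_false(classify_volumetric_response(r40, "who50"))
  expect_false(classify_volumetric_response(r40, "sphere65"))
  expect_error(classify_volumetric_response(r40, "nonsense"))
  # a 30% diameter reduction of a sphere removes 1 - 0.7^3 = 65.7% of volume,
  # just past the 65% spherical-volume threshold
  expect_true(classify_volumetric_response(log(0.7^3), "sphere65"))
  # monotone: more shrinkage never demotes a responder
  rs <- sort(rnorm(50, -0.5, 1))
  cls <- classify_volumetric_response(rs, "recist30")
  expect_true(all(diff(as.integer(cls)) <= 0))
})

test_that("FIGO stages map ordinally from 1A = 1 to 4B = 10", {
  expect_equal(encode_figo("1A"), 1L)
  expect_equal(encode_figo("4B"), 10L)
  expect_equal(encode_figo("IIIC"), 8L)
  expect_equal(encode_figo(c("2b", "iv a", "3c")), c(5L, 9L, 8L))
  expect_error(encode_figo("5A"), "accepted")
})

test_that("schedule classes follow the 6-10 and 18-24 day bands", {
  d0 <- as.Date("2020-01-01")
  expect_equal(schedule_class(d0 + cumsum(c(0, 7, 7, 7))), "weekly")
  expect_equal(schedule_class(d0 + cumsum(c(0, 21, 20, 22))), "3weekly")
  expect_equal(schedule_class(d0 + cumsum(c(0, 14, 14))), "irregular")
  expect_equal(schedule_class(d0), "irregular")      # single dose
  expect_equal(schedule_class(d0 + c(0, 6)), "weekly")    # bounds included
  expect_equal(schedule_class(d0 + c(0, 10)), "weekly")
  expect_equal(schedule_class(d0 + c(0, 18)), "3weekly")
  expect_equal(schedule_class(d0 + c(0, 24)), "3weekly")
  # invariant to dose-date ordering
  expect_equal(schedule_class(rev(d0 + cumsum(c(0, 7, 7, 7)))), "weekly")
})

test_that("regimen encoding emits the 9 treatment features", {
  d0 <- as.Date("2021-03-01")
  course <- list(carboplatin_dates = d0 + seq(0, 63, by = 21),
                 paclitaxel_dates = d0 + seq(0, 63, by = 7),
                 doxorubicin_dates = NULL,
                 sessions_before_second_scan = 3)
  f <- encode_regimen(course)
  expect_named(f, treatment_feature_names())
  expect_equal(unname(f["carboplatin"]), 1)
  expect_equal(unname(f["pac_weekly_carb_3weekly"]), 1)
  expect_equal(unname(f["both_weekly"]), 0)
  expect_equal(unname(f["carboplatin_mono"]), 0)
  expect_equal(unname(f["sessions_before_second_scan"]), 3)

  mono <- encode_regimen(list(carboplatin_dates = d0 + seq(0, 42, 21),
                              sessions_before_second_scan = 2))
  expect_equal(unname(mono["carboplatin_mono"]), 1)
  expect_equal(unname(mono["paclitaxel"]), 0)
})

test_that("nested feature sets assemble to 11/12/176/179 columns", {
  n <- 4
  rec <- data.frame(patient_id = paste0("P", 1:n))
  for (cl in clinical_feature_catalogue()) rec[[cl]] <- rnorm(n)
  rec$ca125 <- runif(n, 10, 800)
  for (im in imaging_feature_catalogue()) rec[[im]] <- rnorm(n)
  for (ct in ctdna_feature_catalogue()) rec[[ct]] <- rnorm(n)
  expect_equal(ncol(assemble_feature_table(rec, "clinical")), 11)
  expect_equal(ncol(assemble_feature_table(rec, "clinical_ca125")), 12)
  expect_equal(ncol(assemble_feature_table(rec, "clinical_ca125_radiomics")), 176)
  full <- assemble_feature_table(rec, "full")
  expect_equal(ncol(full), 179)
  expect_equal(rownames(full), rec$patient_id)
  expect_length(imaging_feature_catalogue(), 164)
  # deterministic column order
  expect_equal(colnames(full), colnames(assemble_feature_table(rec, "full")))
  rec2 <- rbind(rec, rec[1, ])
  expect_error(assemble_feature_table(rec2, "clinical"), "duplicate")
  expect_error(assemble_feature_table(rec[, 1:8], "clinical"), "missing columns")
})
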