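test_that("the worked-example filename decodes exactly", {
  m <- parse_fundus_filename("001_F_GA41_BW2905_PA44_DG2_PF0_RC3_S01_1.jpg")
  expect_equal(m$patient_id, 1L)
  expect_equal(m$sex, "F")
  expect_equal(m$gestational_age_weeks, 41L)
  expect_equal(m$birth_weight_g, 2905L)
  expect_equal(m$postconceptual_age_weeks, 44L)
  expect_equal(m$diagnosis_code, 2L)
  expect_equal(m$plus_form, 0L)
  expect_equal(m$device, 1L)
  expect_equal(m$device_token, "RC3")
  expect_equal(m$series, 1L)
  expect_equal(m$image_index, 1L)
  expect_equal(format_fundus_filename(m),
               "001_F_GA41_BW2905_PA44_DG2_PF0_RC3_S01_1")
})

test_that("device tokens normalize in both dialects", {
  m <- parse_fundus_filename(c(
    "002_M_GA30_BW1500_PA35_DG11_PF0_RE_S02_3.jpg",
    "003_F_GA28_BW900_PA40_DG0_PF0_ICON_S01_2",
    "004_M_GA33_BW2000_PA36_DG0_PF0_2_S01_1.jpg"
  ))
  expect_equal(m$device, c(2L, 3L, 2L))
  expect_equal(m$device_token, c("RE", "ICON", "2"))
})

test_that("malformed names fail with the offending token named", {
  expect_error(parse_fundus_filename("001_F_GA41_BW2905.jpg"), "10")
  expect_error(parse_fundus_filename("001_X_GA41_BW2905_PA44_DG2_PF0_RC3_S01_1"),
               "sex")
  expect_error(parse_fundus_filename("001_F_GAxx_BW2905_PA44_DG2_PF0_RC3_S01_1"),
               "GAxx")
  expect_error(parse_fundus_filename("001_F_GA41_BW2905_PA44_DG2_PF0_XYZ_S01_1"),
               "XYZ")
  expect_error(parse_fundus_filename("001_F_GA41_BW2905_PA44_DG99_PF0_RC3_S01_1"),
               "diagnosis")
})

test_that("format rejects metadata violating the invariants", {
  m <- parse_fundus_filename("001_F_GA41_BW2905_PA44_DG2_PF0_RC3_S01_1")
  bad <- m; bad$plus_form <- 7L
  expect_error(format_fundus_filename(bad), "plus_form")
  bad <- m; bad$postconceptual_age_weeks <- 30L
  expect_error(format_fundus_filename(bad), "postconceptual")
})

test_that("parse/format are mutually inverse on 1000 random cases", {
  tbl <- random_metadata_tbl(1000, seed = 42)
  names_out <- format_fundus_filename(tbl)
  back <- parse_fundus_filename(names_out)
  expect_equal(back[names(tbl)], tbl, ignore_attr = TRUE)
  expect_equal(format_fundus_filename(back), names_out)
})

test_that("diagnosis codes map to the published vocabulary", {
  expect_equal(diagnosis_label(11), "Haemorrhage")
  expect_equal(diagnosis_label(0), "Physiological")
  expect_equal(diagnosis_label(c(1, 8, 13)), c("ROP 0", "A-ROP", "Toxoplasma"))
  expect_error(diagnosis_label(14), "out of range")
})

test_that("scan_fundus_dataset catalogs a tree and reports skips", {
  root <- withr::local_tempdir()
  tbl <- generate_dataset_tree(2, synth_spec(seed = 7, size = c(48, 48)),
                               root, series_per_patient = 2,
                               images_per_series = 3)
  writeLines("not an image", file.path(root, "images", "notes.txt"))
  cat_ <- scan_fundus_dataset(root)
  expect_equal(nrow(cat_), 12)
  expect_true("notes.txt" %in% attr(cat_, "skipped"))
  expect_equal(attr(cat_, "source"), "folder_tree")
  # mirror layouts are deduplicated by basename
  expect_equal(anyDuplicated(cat_$name), 0)
  # workbook route sees the same cohort
  wb <- scan_fundus_dataset(file.path(root, "infant_retinal_database_info.csv"))
  expect_equal(nrow(wb), 12)
  expect_equal(sort(wb$patient_id), sort(cat_$patient_id))
})

test_that("empty roots warn and unparseable-only trees yield empty catalogs", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "images"))
  expect_warning(cat_ <- scan_fundus_dataset(root), "empty catalog")
  expect_equal(nrow(cat_), 0)
})

test_that("cohort summary matches a direct arithmetic oracle", {
  tbl <- random_metadata_tbl(40, seed = 9)
  tbl <- tbl[!duplicated(tbl[c("patient_id", "series", "image_index")]), ]
  sm <- summarize_cohort(tbl)
  pats <- tbl[!duplicated(tbl$patient_id), ]
  ga <- sm$numeric[sm$numeric$variable == "gestational_age", ]
  expect_equal(ga$mean, mean(pats$gestational_age_weeks))
  expect_equal(ga$min, min(pats$gestational_age_weeks))
  expect_equal(ga$max, max(pats$gestational_age_weeks))
  expect_equal(ga$std, sqrt(mean((pats$gestational_age_weeks -
                                    mean(pats$gestational_age_weeks))^2)))
  sers <- tbl[!duplicated(tbl[c("patient_id", "series")]), ]
  pa <- sm$numeric[sm$numeric$variable == "postconceptual_age", ]
  expect_equal(pa$mean, mean(sers$postconceptual_age_weeks))
  # conservation: images by sex sum to total images
  cnt <- sm$counts
  tot_img <- cnt$n[cnt$unit == "image" & cnt$variable == "total"]
  expect_equal(sum(cnt$n[cnt$unit == "image" & cnt$variable == "sex"]), tot_img)
  tot_pat <- cnt$n[cnt$unit == "patient" & cnt$variable == "total"]
  expect_equal(sum(cnt$n[cnt$unit == "patient" & cnt$variable == "device"]),
               tot_pat)
})

test_that("patient-level statistics ignore image multiplicity", {
  tbl <- random_metadata_tbl(10, seed = 3)
  tbl <- tbl[!duplicated(tbl$patient_id), ]
  tbl$series <- 1L; tbl$image_index <- 1L
  rep3 <- dplyr::bind_rows(tbl, dplyr::mutate(tbl, image_index = 2L),
                           dplyr::mutate(tbl, image_index = 3L))
  s1 <- summarize_cohort(tbl); s3 <- summarize_cohort(rep3)
  expect_equal(s1$numeric[c("mean", "std")], s3$numeric[c("mean", "std")])
  n_img1 <- s1$counts$n[s1$counts$unit == "image" & s1$counts$variable == "total"]
  n_img3 <- s3$counts$n[s3$counts$unit == "image" & s3$counts$variable == "total"]
  expect_equal(n_img3, 3 * n_img1)
})

test_that("degenerate single-patient cohort gives zero spread", {
  tbl <- random_metadata_tbl(1, seed = 5)
  tbl$gestational_age_weeks <- 30L
  tbl$postconceptual_age_weeks <- 34L
  sm <- summarize_cohort(tbl)
  ga <- sm$numeric[sm$numeric$variable == "gestational_age", ]
  expect_equal(ga$mean, 30); expect_equal(ga$min, 30)
  expect_equal(ga$max, 30); expect_equal(ga$std, 0)
  expect_error(summarize_cohort(tbl[0, ]), "empty")
})
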