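test_that("mean diameter is the raw average of the two axes", {
  expect_equal(mean_diameter(16, 14), 15)
  expect_equal(mean_diameter(10, 10), 10)
  expect_equal(mean_diameter(35, 35), 35)
  # vectorised, no rounding
  expect_equal(mean_diameter(c(19.95, 20.1), c(19.85, 19.9)),
               c(19.9, 20.0))
})

test_that("mean diameter lies between the axes and rejects bad inputs", {
  for (i in 1:50) {
    long <- runif(1, 5, 40)
    short <- runif(1, 1, long)
    m <- mean_diameter(long, short)
    expect_gte(m, short)
    expect_lte(m, long)
  }
  expect_error(mean_diameter(10, 12), "short_axis_mm")
  expect_error(mean_diameter(-5, -6), "long_axis_mm")
  expect_error(mean_diameter(Inf, 3), "long_axis_mm")
  expect_error(mean_diameter(10, 0), "short_axis_mm")
})

test_that("GVR labels parse case-insensitively from numerals and digits", {
  expect_equal(parse_gvr(c("i", "II", "iii", "IV")), c("I", "II", "III", "IV"))
  expect_equal(parse_gvr(c("1", "2", "3", "4")), c("I", "II", "III", "IV"))
  expect_equal(parse_gvr(c(1L, 4L)), c("I", "IV"))
  expect_true(is.na(parse_gvr(NA)))
  expect_true(is.na(parse_gvr("")))
  expect_error(parse_gvr("V"), "unparseable GVR")
})

test_that("cohort validation enforces the documented invariants", {
  base <- data.frame(nodule_id = c("a", "b"), patient_id = c("p1", "p2"),
                     mean_diameter_mm = c(10, 12), gvr = c("I", "IV"),
                     suspicious_features = FALSE,
                     pathology = "invasive", stringsAsFactors = FALSE)
  expect_s3_class(ggn_cohort(base), "ggn_cohort")

  dup <- base
  dup$nodule_id <- c("a", "a")
  expect_error(ggn_cohort(dup), "duplicate nodule_id")

  bad_axes <- base
  bad_axes$long_axis_mm <- c(10, 12)
  bad_axes$short_axis_mm <- c(11, 12)  # short > long
  expect_error(ggn_cohort(bad_axes), "short_axis_mm")

  inconsistent <- base
  inconsistent$long_axis_mm <- c(12, 14)
  inconsistent$short_axis_mm <- c(10, 12)
  inconsistent$mean_diameter_mm <- c(11, 14)  # second mean wrong
  expect_error(ggn_cohort(inconsistent), "inconsistent")

  neg <- base
  neg$mean_diameter_mm <- c(-1, 12)
  expect_error(ggn_cohort(neg), "mean_diameter_mm")

  badpath <- base
  badpath$pathology <- c("invasive", "metastatic")
  expect_error(ggn_cohort(badpath), "pathology.*row.*2")
})

test_that("missing suspicious flags default to FALSE with a warning", {
  df <- data.frame(nodule_id = "a", patient_id = "p", mean_diameter_mm = 10,
                   gvr = "I", suspicious_features = NA, pathology = "invasive")
  expect_warning(co <- ggn_cohort(df), "suspicious_features")
  expect_false(co$nodules$suspicious_features)
})

test_that("a minimal one-row CSV reads into a one-patient cohort", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,nodule_id,mean_diameter_mm,gvr,suspicious_features,pathology",
               "p1,n1,15.5,iii,false,invasive"), f)
  co <- read_cohort(f)
  expect_equal(nrow(co$patients), 1)
  expect_equal(nrow(co$nodules), 1)
  expect_equal(co$nodules$gvr, "III")
  expect_false(co$nodules$suspicious_features)
  expect_equal(co$nodules$mean_diameter_mm, 15.5)
})

test_that("schema errors name the missing columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,nodule_id,mean_diameter_mm,suspicious_features,pathology",
               "p1,n1,15.5,false,invasive"), f)
  expect_error(read_cohort(f), "gvr")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,nodule_id,gvr",
               "p1,n1,III"), f2)
  err <- tryCatch(read_cohort(f2), error = conditionMessage)
  expect_match(err, "suspicious_features")
  expect_match(err, "pathology")
  expect_match(err, "mean_diameter_mm")
})

test_that("row-level parse errors report the offending row", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,nodule_id,mean_diameter_mm,gvr,suspicious_features,pathology",
               "p1,n1,15.5,III,false,invasive",
               "p2,n2,12.0,VII,false,invasive"), f)
  expect_error(read_cohort(f), "GVR")
})

test_that("write/read round trips are the identity in both formats", {
  co <- generate_cohort(generator_config("training", n_patients = 40), seed = 11)
  for (ext in c(".csv", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_cohort(co, f)
    back <- read_cohort(f, label = co$label)
    expect_equal(back$nodules, co$nodules, tolerance = 1e-12)
    expect_equal(back$patients[order(back$patients$patient_id), ],
                 co$patients[order(co$patients$patient_id), ],
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("an empty cohort writes a header-only CSV and reads back empty", {
  empty <- ggn_cohort(data.frame(nodule_id = character(0),
                                 patient_id = character(0),
                                 mean_diameter_mm = numeric(0),
                                 gvr = character(0),
                                 suspicious_features = logical(0),
                                 pathology = character(0)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(empty, f)
  expect_length(readLines(f), 1)
  back <- read_cohort(f)
  expect_equal(nrow(back$nodules), 0)
})

test_that("category ranks are strictly increasing along the category order", {
  ranks <- category_rank(c("2", "3", "4a", "4b", "4x"))
  expect_equal(ranks, 1:5)
  expect_true(all(diff(ranks) > 0))
  expect_error(category_rank("5"), "unknown category")
})
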