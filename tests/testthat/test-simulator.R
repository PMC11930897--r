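test_that("the generator is bit-identical for a fixed seed and leaves the RNG alone", {
  cfg <- generator_config("training", n_patients = 60)
  set.seed(1)
  before <- .Random.seed
  a <- generate_cohort(cfg, seed = 42)
  expect_identical(.Random.seed, before)  # caller's stream untouched
  b <- generate_cohort(cfg, seed = 42)
  expect_identical(a$nodules, b$nodules)
  expect_identical(a$patients, b$patients)
  c <- generate_cohort(cfg, seed = 43)
  expect_false(identical(a$nodules, c$nodules))
})

test_that("degenerate invasiveness conditionals propagate exactly", {
  cfg <- generator_config("pooled", n_patients = 50,
                          p_invasive_given_gvr_and_flag =
                            matrix(1, 4, 2, dimnames = list(
                              c("I", "II", "III", "IV"),
                              c("unflagged", "flagged"))))
  co <- generate_cohort(cfg, seed = 5)
  expect_true(all(co$nodules$pathology == "invasive"))
})

test_that("invalid configurations are rejected with config errors", {
  expect_error(generator_config("pooled", gvr_probs = c(0.5, 0.5, 0.1, 0.1)),
               "gvr_probs")
  expect_error(generator_config("pooled", multiplicity_probs = c(1, 1, 1)),
               "multiplicity_probs")
  expect_error(generator_config("pooled", p_suspicious_given_gvr = c(2, 0, 0, 0)),
               "p_suspicious_given_gvr")
  expect_error(generator_config("pooled", nonsense = 1), "unknown config field")
})

test_that("generated cohorts recover the configured parameters", {
  cfg <- generator_config("pooled", n_patients = 30000)
  co <- generate_cohort(cfg, seed = 2024)
  nod <- co$nodules
  n <- nrow(nod)
  # GVR frequencies within 3 binomial SEs
  for (g in c("I", "II", "III", "IV")) {
    p <- cfg$gvr_probs[[g]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(nod$gvr == g) - p), 3 * se)
  }
  # diameter moments (lognormal moment-matched to 13.6 +/- 6.1 mm)
  target_mean <- exp(cfg$diameter_logmean + cfg$diameter_logsd^2 / 2)
  target_sd <- target_mean * sqrt(expm1(cfg$diameter_logsd^2))
  expect_lt(abs(mean(nod$mean_diameter_mm) - target_mean),
            3 * target_sd / sqrt(n))
  # invasiveness conditional per (GVR, flag) stratum within 3 SEs
  for (g in c("I", "IV")) {
    sel <- nod$gvr == g & !nod$suspicious_features
    p <- cfg$p_invasive_given_gvr_and_flag[g, "unflagged"]
    se <- sqrt(p * (1 - p) / sum(sel))
    expect_lt(abs(mean(nod$pathology[sel] == "invasive") - p), 3 * se)
  }
  # axis split preserves the mean diameter identically
  expect_equal((nod$long_axis_mm + nod$short_axis_mm) / 2,
               nod$mean_diameter_mm, tolerance = 1e-12)
  # ages live in the truncation interval
  expect_true(all(co$patients$age_years >= 18 & co$patients$age_years <= 90))
})

test_that("calibration solves the stratum conditionals in closed form", {
  cfg <- calibrate_to_cells(
    calibration_target("CLUNGRADS2022", 131, 14, 7, 17),
    generator_config("training"))
  expect_equal(cfg$calibration$p_invasive_positive, 131 / 145)
  expect_equal(cfg$calibration$p_invasive_negative, 7 / 24)
  expect_equal(cfg$calibration$system, "CLUNGRADS2022")
})

test_that("an all-negative target zeroes both conditionals and the positive mass", {
  cfg <- calibrate_to_cells(calibration_target("LUNGRADS10", 0, 0, 0, 100),
                            generator_config("pooled"))
  expect_equal(cfg$calibration$p_invasive_positive, 0)
  expect_equal(cfg$calibration$p_invasive_negative, 0)
  expect_equal(unname(cfg$p_suspicious_given_gvr), rep(0, 4))
  co <- generate_cohort(cfg, seed = 3)
  expect_true(all(co$nodules$pathology == "noninvasive"))
  expect_false(any(stratify_cohort(co, "LUNGRADS10")$positive))
})

test_that("inconsistent or infeasible targets raise calibration errors", {
  expect_error(calibration_target("CLUNGRADS2022", 10, 10, 10, 10, n = 41),
               "sum to 40")
  # baseline positives capped by the mass above the diameter cutoff
  expect_error(
    calibrate_to_cells(calibration_target("LUNGRADS10", 90, 10, 0, 0),
                       generator_config("pooled")),
    "infeasible")
  # cLung positives already exceeded by the GVR III+IV mass
  expect_error(
    calibrate_to_cells(calibration_target("CLUNGRADS2022", 1, 0, 50, 49),
                       generator_config("training")),
    "III")
})

test_that("cohorts from a calibrated config match the target cells in expectation", {
  target <- calibration_target("CLUNGRADS2022", 131, 14, 7, 17)
  cfg <- calibrate_to_cells(target, generator_config("training",
                                                     n_patients = 8000))
  co <- generate_cohort(cfg, seed = 77)
  s <- stratify_cohort(co, "CLUNGRADS2022")
  cm <- confusion_matrix(s$positive, co$nodules$pathology == "invasive")
  n <- nrow(co$nodules)
  got <- c(cm$tp, cm$fp, cm$fn, cm$tn) / n
  want <- c(target$tp, target$fp, target$fn, target$tn) / target$n
  for (i in 1:4) {
    se <- sqrt(want[i] * (1 - want[i]) / n)
    expect_lt(abs(got[i] - want[i]), 4 * se + 1e-6)
  }
})

test_that("exact fixture cohorts reproduce every published cell layout", {
  cells <- reference_cells()
  for (r in seq_len(nrow(cells))) {
    row <- cells[r, ]
    target <- calibration_target(row$system, row$tp, row$fp, row$fn, row$tn)
    co <- fixture_exact_cohort(target, label = row$set)
    s <- stratify_cohort(co, row$system)
    cm <- confusion_matrix(s$positive, co$nodules$pathology == "invasive")
    expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]),
                 c(tp = row$tp, fp = row$fp, fn = row$fn, tn = row$tn),
                 ignore_attr = TRUE)
  }
})

test_that("the baseline fixture uses flagged nodules above the 20-mm cutoff", {
  co <- fixture_exact_cohort(calibration_target("LUNGRADS10", 9, 1, 129, 30))
  expect_equal(nrow(co$nodules), 169)
  flagged <- co$nodules$suspicious_features
  expect_equal(sum(flagged), 10)
  expect_true(all(co$nodules$mean_diameter_mm[flagged] >= 20))
})

test_that("a minimal two-cell fixture builds a two-nodule cohort", {
  co <- fixture_exact_cohort(calibration_target("CLUNGRADS2022", 1, 0, 0, 1))
  expect_equal(nrow(co$nodules), 2)
  expect_equal(nrow(co$patients), 2)
})
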