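test_that("a hand-written two-patient fixture reads into a validated cohort", {
  p <- rbind(patient_row("A", route = "EP", t = 8.5, event = 1),
             patient_row("B", route = "GPTWW", t = 61, event = 0))
  co <- data.frame(patient_id = rep(c("A", "B"), each = 12),
                   month_index = rep(-12:-1, 2),
                   cost_gbp = rep(c(120, 80), each = 12))
  pd <- tempfile(fileext = ".csv"); cd <- tempfile(fileext = ".csv")
  utils::write.csv(p, pd, row.names = FALSE, quote = FALSE)
  utils::write.csv(co, cd, row.names = FALSE, quote = FALSE)
  ch <- read_cohort(pd, cd)
  expect_s3_class(ch, "cohort_table")
  expect_equal(nrow(ch$patients), 2)
  expect_equal(nrow(ch$costs), 24)
  expect_equal(ch$horizon, 60)
})

test_that("write then read is the identity on a synthetic cohort", {
  ch <- simulate_cohort(sim_config(n_patients = 100, seed = 3))
  pd <- tempfile(fileext = ".csv"); cd <- tempfile(fileext = ".csv")
  write_cohort(ch, pd, cd)
  back <- read_cohort(pd, cd)
  expect_equal(back$patients$patient_id, ch$patients$patient_id)
  expect_equal(back$patients$time_to_event, ch$patients$time_to_event,
               tolerance = 1e-10)
  expect_equal(back$patients$event, ch$patients$event)
  expect_equal(as.character(back$patients$route), as.character(ch$patients$route))
  expect_equal(back$costs$month_index, ch$costs$month_index)
  expect_equal(back$costs$cost_gbp, ch$costs$cost_gbp, tolerance = 1e-10)
})

test_that("an empty cohort round-trips as headers-only files", {
  p <- patient_row("A")[0, ]
  co <- data.frame(patient_id = character(0), month_index = integer(0),
                   cost_gbp = numeric(0))
  ch <- cohort_table(p, co, site = "colorectal")
  pd <- tempfile(fileext = ".csv"); cd <- tempfile(fileext = ".csv")
  write_cohort(ch, pd, cd)
  expect_equal(length(readLines(cd)), 1L)
  back <- read_cohort(pd, cd, site = "colorectal")
  expect_equal(nrow(back$patients), 0)
  expect_equal(nrow(back$costs), 0)
})

test_that("validation rejects every mutated fixture", {
  base_p <- rbind(patient_row("A", route = "EP", t = 8.5, event = 1),
                  patient_row("B", route = "GPTWW", t = 61, event = 0))
  base_c <- data.frame(patient_id = "B", month_index = 0, cost_gbp = 50)

  # cost month before the pre-diagnosis window
  expect_error(cohort_table(base_p, transform(base_c, month_index = -13),
                            "colorectal"), "-12")
  # negative cost
  expect_error(cohort_table(base_p, transform(base_c, cost_gbp = -1),
                            "colorectal"), "negative")
  # orphan cost row
  expect_error(cohort_table(base_p, transform(base_c, patient_id = "ZZ"),
                            "colorectal"), "unknown patient_id")
  # duplicate (patient, month)
  expect_error(cohort_table(base_p, rbind(base_c, base_c), "colorectal"),
               "duplicate")
  # cost after observed follow-up
  expect_error(cohort_table(base_p, data.frame(patient_id = "A",
                                               month_index = 9, cost_gbp = 1),
                            "colorectal"), "after observed follow-up")
  # under-age, non-positive follow-up, bad event coding
  expect_error(cohort_table(transform(base_p, age = 17), base_c, "colorectal"),
               "age")
  expect_error(cohort_table(transform(base_p, time_to_event = 0), base_c,
                            "colorectal"), "positive")
  expect_error(cohort_table(transform(base_p, event = 2), base_c, "colorectal"),
               "event")
  # site-sex consistency
  expect_error(cohort_table(transform(base_p, sex = "M"), base_c, "breast"),
               "breast")
  expect_error(cohort_table(transform(base_p, sex = "F"), base_c, "prostate"),
               "prostate")
  # lung horizon is 36 months: cost at month 40 is invalid
  lung_p <- transform(base_p, site = "lung")
  expect_error(cohort_table(lung_p, data.frame(patient_id = "B",
                                               month_index = 40, cost_gbp = 1),
                            "lung"), "36")
  # missing column named in the error
  expect_error(cohort_table(base_p[setdiff(names(base_p), "imd_income")],
                            base_c, "colorectal"), "imd_income")
})
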