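test_that("a well-formed cohort loads identically and round-trips through disk", {
  fx <- make_worked_fixture()
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_cohort(fx, dir1)

  cohort <- read_cohort(file.path(dir1, "persons.csv"),
                        file.path(dir1, "prescriptions.csv"),
                        file.path(dir1, "hospitalizations.csv"))
  expect_equal(nrow(cohort$persons), nrow(fx$persons))
  expect_equal(nrow(cohort$prescriptions), nrow(fx$prescriptions))
  expect_equal(nrow(cohort$hospitalizations), nrow(fx$hospitalizations))
  expect_equal(nrow(cohort$report), 0)

  # field-by-field equality with the generated records
  expect_equal(cohort$prescriptions$atc_code, fx$prescriptions$atc_code)
  expect_equal(cohort$prescriptions$dispense_date, fx$prescriptions$dispense_date)
  expect_equal(cohort$persons$death_date, fx$persons$death_date)

  # canonical files reproduce byte-identically
  write_cohort(cohort, dir2)
  for (f in c("persons.csv", "prescriptions.csv", "hospitalizations.csv")) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
  }
})

test_that("invariant violations are rejected row-wise with reasons", {
  dir <- withr::local_tempdir()
  writeLines(c("person_id,sex,birth_date,index_date,death_date,migration_date",
               "p1,M,1950-01-01,2004-01-01,,",
               "p2,F,1950-01-01,2004-01-01,2003-06-01,",   # died before index
               "p3,X,1950-01-01,2004-01-01,,",             # bad sex
               "p4,M,1970-01-01,2004-01-01,,",             # age 34 < 40
               "p5,M,not-a-date,2004-01-01,,"),            # malformed date
             file.path(dir, "persons.csv"))
  writeLines(c("person_id,atc_code,dispense_date,packages",
               "p1,C01BD01,2003-05-01,1",
               "p1,C01BD01,2003-05-01,0",                  # non-positive packages
               "p2,C01BD01,2003-05-01,1",                  # person rejected above
               "p1,123XYZ,2003-05-01,1"),                  # invalid ATC
             file.path(dir, "prescriptions.csv"))
  writeLines(c("person_id,admission_date,discharge_date,unplanned,diagnoses,in_hospital_death",
               "p1,2003-03-01,2003-03-05,TRUE,410.11,FALSE",
               "p1,2003-03-10,2003-03-01,TRUE,410.11,FALSE",  # discharge < admission
               "nobody,2003-03-01,2003-03-05,TRUE,410.11,FALSE"),
             file.path(dir, "hospitalizations.csv"))

  cohort <- read_cohort(file.path(dir, "persons.csv"),
                        file.path(dir, "prescriptions.csv"),
                        file.path(dir, "hospitalizations.csv"))
  expect_equal(cohort$persons$person_id, "p1")
  expect_equal(nrow(cohort$prescriptions), 1)
  expect_equal(nrow(cohort$hospitalizations), 1)
  rep <- cohort$report
  expect_setequal(
    rep$reason[rep$table == "persons"],
    c("death or migration before index date", "invalid sex code",
      "age below 40 at index date", "malformed date"))
  expect_true("non-positive packages" %in% rep$reason)
  expect_true("unknown person_id" %in% rep$reason)
  expect_true("invalid ATC code" %in% rep$reason)
  expect_true("discharge before admission" %in% rep$reason)
})

test_that("missing files and header mismatches are fatal", {
  dir <- withr::local_tempdir()
  fx <- make_worked_fixture()
  write_cohort(fx, dir)
  expect_error(read_cohort(file.path(dir, "nope.csv"),
                           file.path(dir, "prescriptions.csv"),
                           file.path(dir, "hospitalizations.csv")),
               "not found")
  writeLines(c("id,sex", "p1,M"), file.path(dir, "persons.csv"))
  expect_error(read_cohort(file.path(dir, "persons.csv"),
                           file.path(dir, "prescriptions.csv"),
                           file.path(dir, "hospitalizations.csv")),
               "header mismatch")
})

test_that("derive_survival takes the earliest of death, migration and horizon", {
  index <- as.Date("2004-01-01")
  mk <- function(death_y = NA, mig_y = NA) {
    data.frame(person_id = "x", sex = "M",
               birth_date = index - 20000, index_date = index,
               death_date = if (is.na(death_y)) as.Date(NA) else
                 index + round(death_y * 365.25),
               migration_date = if (is.na(mig_y)) as.Date(NA) else
                 index + round(mig_y * 365.25))
  }
  s <- derive_survival(mk(death_y = 2), 7)
  expect_equal(s$time, 2, tolerance = 0.01)
  expect_true(s$event)

  s <- derive_survival(mk(), 7)
  expect_equal(s$time, 7)
  expect_false(s$event)

  s <- derive_survival(mk(death_y = 3.5, mig_y = 3.1), 7)
  expect_equal(s$time, 3.1, tolerance = 0.01)
  expect_false(s$event)

  expect_error(derive_survival(mk(death_y = -1), 7), "event precedes index")
})

test_that("derive_survival matches a min-of-three oracle over enumerated date triples", {
  index <- as.Date("2004-01-01")
  grid <- expand.grid(death = c(NA, 0.5, 3, 6.9, 7.2, 10),
                      mig = c(NA, 1, 3, 7.5))
  for (k in seq_len(nrow(grid))) {
    d <- grid$death[k]; m <- grid$mig[k]
    p <- data.frame(person_id = "x", sex = "F",
                    birth_date = index - 20000, index_date = index,
                    death_date = if (is.na(d)) as.Date(NA) else index + round(d * 365.25),
                    migration_date = if (is.na(m)) as.Date(NA) else index + round(m * 365.25))
    s <- derive_survival(p, 7)
    dd <- if (is.na(d)) Inf else as.integer(p$death_date - index) / 365.25
    mm <- if (is.na(m)) Inf else as.integer(p$migration_date - index) / 365.25
    expect_equal(s$time, min(dd, mm, 7))
    expect_equal(s$event, dd <= mm && dd <= 7)
    expect_lte(s$time, 7)
  }
})
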