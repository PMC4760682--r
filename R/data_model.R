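# Domain types and I/O for the three claims tables: persons, prescriptions,
# hospitalizations. All tables travel as comma-separated text with a header
# row and ISO-8601 dates; date arithmetic is in days, years = days / 365.25.

PERSON_COLS <- c("person_id", "sex", "birth_date", "index_date",
                 "death_date", "migration_date")
RX_COLS <- c("person_id", "atc_code", "dispense_date", "packages")
HOSP_COLS <- c("person_id", "admission_date", "discharge_date", "unplanned",
               "diagnoses", "in_hospital_death")

# ATC codes are hierarchical: 1 letter (anatomical group), 2 digits, then
# letter / letter / 2 digits down to the 7-character substance level.
# Partial codes at levels 1, 3, 4, 5 and 7 are valid.
ATC_REGEX <- "^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$"

is_valid_atc <- function(x) {
  !is.na(x) & grepl(ATC_REGEX, x)
}

#' Read and validate a claims cohort from delimited text
#'
#' Loads the three cohort tables (persons, prescriptions, hospitalizations)
#' from comma-separated files with mandatory header rows and ISO-8601 dates,
#' applies the type invariants, and returns the validated collections
#' together with a load report. Rows that violate an invariant (malformed
#' date, non-positive package count, unknown person id, age below 40 at the
#' index date, death or migration before the index date, ...) are rejected
#' and counted in the report; a missing file or a header mismatch is a fatal
#' error.
#'
#' @param persons_path Path to `persons.csv` with columns
#'   `person_id, sex, birth_date, index_date, death_date, migration_date`.
#' @param prescriptions_path Path to `prescriptions.csv` with columns
#'   `person_id, atc_code, dispense_date, packages`.
#' @param hospitalizations_path Path to `hospitalizations.csv` with columns
#'   `person_id, admission_date, discharge_date, unplanned, diagnoses,
#'   in_hospital_death`; `diagnoses` holds 1-6 ICD-9-CM codes separated by
#'   semicolons, primary first.
#' @return An object of class `ddci_cohort`: a list with elements `persons`,
#'   `prescriptions`, `hospitalizations` (data frames) and `report` (a data
#'   frame of rejection counts by table and reason).
#' @seealso [write_cohort()], [derive_survival()]
#' @export
read_cohort <- function(persons_path, prescriptions_path, hospitalizations_path) {
  for (p in c(persons_path, prescriptions_path, hospitalizations_path)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  persons_raw <- utils::read.csv(persons_path, colClasses = "character")
  rx_raw <- utils::read.csv(prescriptions_path, colClasses = "character")
  hosp_raw <- utils::read.csv(hospitalizations_path, colClasses = "character")

  check_header(persons_raw, PERSON_COLS, persons_path)
  check_header(rx_raw, RX_COLS, prescriptions_path)
  check_header(hosp_raw, HOSP_COLS, hospitalizations_path)

  rejects <- list()
  note <- function(tab, reason, n) {
    if (n > 0) rejects[[length(rejects) + 1]] <<-
        data.frame(table = tab, reason = reason, n = as.integer(n))
  }

  ## persons
  p <- persons_raw
  p$birth_date <- parse_iso_date(p$birth_date)
  p$index_date <- parse_iso_date(p$index_date)
  p$death_date <- parse_iso_date(p$death_date)
  p$migration_date <- parse_iso_date(p$migration_date)

  bad_date <- is.na(p$birth_date) | is.na(p$index_date) |
    (nzchar(persons_raw$death_date) & !is.na(persons_raw$death_date) & is.na(p$death_date)) |
    (nzchar(persons_raw$migration_date) & !is.na(persons_raw$migration_date) & is.na(p$migration_date))
  note("persons", "malformed date", sum(bad_date))
  p <- p[!bad_date, , drop = FALSE]

  bad_sex <- !p$sex %in% c("M", "F")
  note("persons", "invalid sex code", sum(bad_sex))
  p <- p[!bad_sex, , drop = FALSE]

  bad_order <- p$index_date <= p$birth_date
  note("persons", "index date not after birth date", sum(bad_order))
  p <- p[!bad_order, , drop = FALSE]

  # fixed cohort: alive and resident at index
  pre_index_exit <- (!is.na(p$death_date) & p$death_date < p$index_date) |
    (!is.na(p$migration_date) & p$migration_date < p$index_date)
  note("persons", "death or migration before index date", sum(pre_index_exit))
  p <- p[!pre_index_exit, , drop = FALSE]

  age <- floor(days_between(p$birth_date, p$index_date) / DAYS_PER_YEAR)
  under_40 <- age < 40
  note("persons", "age below 40 at index date", sum(under_40))
  p <- p[!under_40, , drop = FALSE]
  p$age_at_index <- floor(days_between(p$birth_date, p$index_date) / DAYS_PER_YEAR)

  dup <- duplicated(p$person_id)
  note("persons", "duplicate person_id", sum(dup))
  p <- p[!dup, , drop = FALSE]
  known <- p$person_id

  ## prescriptions
  rx <- rx_raw
  rx$dispense_date <- parse_iso_date(rx$dispense_date)
  rx$packages <- suppressWarnings(as.integer(rx$packages))

  bad <- is.na(rx$dispense_date)
  note("prescriptions", "malformed date", sum(bad))
  rx <- rx[!bad, , drop = FALSE]

  bad <- is.na(rx$packages) | rx$packages < 1
  note("prescriptions", "non-positive packages", sum(bad))
  rx <- rx[!bad, , drop = FALSE]

  bad <- !is_valid_atc(rx$atc_code)
  note("prescriptions", "invalid ATC code", sum(bad))
  rx <- rx[!bad, , drop = FALSE]

  bad <- !rx$person_id %in% known
  note("prescriptions", "unknown person_id", sum(bad))
  rx <- rx[!bad, , drop = FALSE]

  ## hospitalizations
  h <- hosp_raw
  h$admission_date <- parse_iso_date(h$admission_date)
  h$discharge_date <- parse_iso_date(h$discharge_date)
  h$unplanned <- h$unplanned %in% c("TRUE", "true", "1")
  h$in_hospital_death <- h$in_hospital_death %in% c("TRUE", "true", "1")

  bad <- is.na(h$admission_date) | is.na(h$discharge_date)
  note("hospitalizations", "malformed date", sum(bad))
  h <- h[!bad, , drop = FALSE]

  bad <- h$discharge_date < h$admission_date
  note("hospitalizations", "discharge before admission", sum(bad))
  h <- h[!bad, , drop = FALSE]

  ndiag <- lengths(strsplit(h$diagnoses, ";", fixed = TRUE))
  bad <- !nzchar(h$diagnoses) | ndiag < 1 | ndiag > 6
  note("hospitalizations", "diagnosis count outside 1-6", sum(bad))
  h <- h[!bad, , drop = FALSE]

  bad <- !h$person_id %in% known
  note("hospitalizations", "unknown person_id", sum(bad))
  h <- h[!bad, , drop = FALSE]

  report <- if (length(rejects)) do.call(rbind, rejects) else
    data.frame(table = character(), reason = character(), n = integer())

  structure(
    list(persons = p, prescriptions = rx, hospitalizations = h, report = report),
    class = "ddci_cohort"
  )
}

check_header <- function(df, expected, path) {
  if (!identical(names(df)[seq_along(expected)], expected)) {
    stop("header mismatch in ", path, ": expected columns ",
         paste(expected, collapse = ", "))
  }
  invisible(TRUE)
}

#' Write a cohort back to delimited text
#'
#' Inverse of [read_cohort()]: writes `persons.csv`, `prescriptions.csv` and
#' `hospitalizations.csv` in the canonical dialect (comma separation, header
#' row, ISO-8601 dates, semicolon-joined diagnoses) so that a canonical file
#' round-trips byte-identically.
#'
#' @param cohort A `ddci_cohort` (or any list with the three data frames).
#' @param dir Output directory; created if absent.
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- cohort$persons[, PERSON_COLS, drop = FALSE]
  for (col in c("birth_date", "index_date", "death_date", "migration_date")) {
    p[[col]] <- ifelse(is.na(p[[col]]), "", format(p[[col]], "%Y-%m-%d"))
  }
  rx <- cohort$prescriptions[, RX_COLS, drop = FALSE]
  rx$dispense_date <- format(rx$dispense_date, "%Y-%m-%d")
  h <- cohort$hospitalizations[, HOSP_COLS, drop = FALSE]
  h$admission_date <- format(h$admission_date, "%Y-%m-%d")
  h$discharge_date <- format(h$discharge_date, "%Y-%m-%d")

  paths <- file.path(dir, c("persons.csv", "prescriptions.csv", "hospitalizations.csv"))
  utils::write.csv(p, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(rx, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(h, paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' @export
print.ddci_cohort <- function(x, ...) {
  cat("claims cohort:",
      nrow(x$persons), "persons,",
      nrow(x$prescriptions), "prescriptions,",
      nrow(x$hospitalizations), "hospitalizations\n")
  if (nrow(x$report)) {
    cat("rejected rows:\n")
    print(x$report, row.names = FALSE)
  }
  invisible(x)
}

#' Derive censored survival records from the civil-registry dates
#'
#' Follow-up runs from the index date to the earliest of death, migration
#' (leaving the region) and the prediction horizon. The event indicator is
#' true only when death is the earliest of the three; migration and the end
#' of the study censor.
#'
#' @param persons Persons data frame (as in a [read_cohort()] result).
#' @param horizon_years Positive prediction horizon in years (default 7).
#' @return Data frame with `person_id`, `time` (years, never exceeding the
#'   horizon) and `event` (logical).
#' @export
#' @examples
#' p <- data.frame(person_id = "a", sex = "M",
#'                 birth_date = as.Date("1950-06-01"),
#'                 index_date = as.Date("2004-01-01"),
#'                 death_date = as.Date("2006-01-01"),
#'                 migration_date = as.Date(NA))
#' derive_survival(p)  # death 2 years after index
derive_survival <- function(persons, horizon_years = 7) {
  stopifnot(horizon_years > 0)
  death_days <- days_between(persons$index_date, persons$death_date)
  mig_days <- days_between(persons$index_date, persons$migration_date)
  if (any(!is.na(death_days) & death_days < 0)) stop("event precedes index")
  death_y <- ifelse(is.na(death_days), Inf, death_days / DAYS_PER_YEAR)
  mig_y <- ifelse(is.na(mig_days) | mig_days < 0, Inf, mig_days / DAYS_PER_YEAR)
  time <- pmin(death_y, mig_y, horizon_years)
  event <- death_y <= mig_y & death_y <= horizon_years
  data.frame(person_id = persons$person_id, time = time, event = event)
}
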