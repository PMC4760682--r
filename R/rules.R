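# Rule engine: converts baseline-window dispensing records into the 19
# drug-class exposure flags. Each rule is executable data: ATC include /
# exclude prefixes, a minimum package count, a look-back window, and (for
# the hypertensive-heart-disease class) a special combination rule.

#' The 19 drug-class names of the published index, in table order
#' @return Character vector of length 19.
#' @export
ddci_classes <- function() {
  c("Antiarrhythmics",
    "Immunosuppressants",
    "Platelet aggregation inhibitors",
    "Parenteral anticoagulants",
    "Oral anticoagulants",
    "Antineoplastic agents",
    "Inhaled bronchodilators",
    "Drugs for arterial hypertension",
    "Antihyperglycemic therapy",
    "Drugs for hypertensive heart disease",
    "Drugs for acid related disorders",
    "Lipid modifying agents",
    "Nonsteroidal anti-inflammatory drugs",
    "Systemic corticosteroids",
    "Opioids",
    "Anti-Parkinson drugs",
    "Antipsychotics",
    "Anti-dementia drugs",
    "Antidepressants")
}

# ATC entries whose co-occurrence within 45 days flags hypertensive heart
# disease; "C09" is a whole therapeutic group, the others are substances.
HHD_COMBINATION_SET <- c("C01AA05", "C03CA01", "C03DA01",
                         "C07AG02", "C07AB07", "C07AB03", "C09")

# Opioid exclusions: codeine and tramadol products. The source names the
# substances; these are their community-dispensing ATC codes (plain and
# combination forms). Configurable per rule.
OPIOID_EXCLUSIONS <- c("N02AA59", "N02AA79", "N02AX02", "N02AX52")

new_rule <- function(name, include, exclude = character(), min_packages = 3L,
                     window_days = 365L, combination = NULL) {
  stopifnot(length(include) >= 1, min_packages >= 1, window_days >= 1)
  structure(list(name = name,
                 include = include,
                 exclude = exclude,
                 min_packages = as.integer(min_packages),
                 window_days = as.integer(window_days),
                 combination = combination),
            class = "ddci_rule")
}

#' Built-in exposure rule table
#'
#' Returns the 19 drug-class rules exactly as printed in the published
#' weight-assignment table: a threshold of 3 packages within 12 months for
#' most classes, 2 packages for antihyperglycemic therapy (A10), a single
#' package for the neurological classes (N04, N05A, and the two N06
#' classes), the C07AB09 exclusion for arterial hypertension, the codeine /
#' tramadol exclusion for opioids, and the 45-day combination rule for
#' hypertensive heart disease.
#'
#' Note on the two N06 classes: the source table assigns "Anti-dementia
#' drugs" to ATC N06A and "Antidepressants" to N06D, which is the reverse of
#' the standard ATC meaning (N06A antidepressants, N06D anti-dementia). The
#' default follows the printed table verbatim; `atc_semantics = "standard"`
#' swaps the two prefixes back to standard ATC usage.
#'
#' @param atc_semantics `"table"` (default, verbatim) or `"standard"`.
#' @return An object of class `ddci_rules`: a named list of 19 rules.
#' @seealso [detect_exposures()], [read_rule_table()]
#' @export
default_rule_table <- function(atc_semantics = c("table", "standard")) {
  atc_semantics <- match.arg(atc_semantics)
  dementia_atc <- if (atc_semantics == "table") "N06A" else "N06D"
  antidep_atc <- if (atc_semantics == "table") "N06D" else "N06A"

  rules <- list(
    new_rule("Antiarrhythmics", "C01B"),
    new_rule("Immunosuppressants", "L04"),
    new_rule("Platelet aggregation inhibitors", "B01AC"),
    new_rule("Parenteral anticoagulants", c("B01AB", "B01AX")),
    new_rule("Oral anticoagulants", "B01AA"),
    new_rule("Antineoplastic agents", "L01"),
    new_rule("Inhaled bronchodilators", c("R03A", "R03BB", "R03DA")),
    new_rule("Drugs for arterial hypertension",
             c("C02A", "C02C", "C02LA", "C02LB", "C03A", "C03BA", "C03EA01",
               "C07AA", "C07AB", "C07AG", "C07BB", "C07C", "C08",
               "C09AA", "C09BA", "C09CA", "C09DA"),
             exclude = "C07AB09"),
    new_rule("Antihyperglycemic therapy", "A10", min_packages = 2L),
    new_rule("Drugs for hypertensive heart disease", HHD_COMBINATION_SET,
             min_packages = 1L,
             combination = list(window_days = 45L,
                                set = HHD_COMBINATION_SET,
                                min_distinct = 2L,
                                repeat_code = "C01AA05",
                                min_repeat = 2L)),
    new_rule("Drugs for acid related disorders", "A02"),
    new_rule("Lipid modifying agents", "C10"),
    new_rule("Nonsteroidal anti-inflammatory drugs", "M01"),
    new_rule("Systemic corticosteroids", "H02AB"),
    new_rule("Opioids", "N02A", exclude = OPIOID_EXCLUSIONS),
    new_rule("Anti-Parkinson drugs", "N04", min_packages = 1L),
    new_rule("Antipsychotics", "N05A", min_packages = 1L),
    new_rule("Anti-dementia drugs", dementia_atc, min_packages = 1L),
    new_rule("Antidepressants", antidep_atc, min_packages = 1L)
  )
  names(rules) <- vapply(rules, `[[`, character(1), "name")
  structure(rules, class = "ddci_rules")
}

#' @export
print.ddci_rules <- function(x, ...) {
  cat("exposure rule table:", length(x), "drug classes\n")
  for (r in x) {
    cat(sprintf("  %-38s >=%d pkg / %dd  ATC %s%s%s\n",
                r$name, r$min_packages, r$window_days,
                paste(r$include, collapse = ","),
                if (length(r$exclude)) paste0(" (excl ", paste(r$exclude, collapse = ","), ")") else "",
                if (!is.null(r$combination)) " [45-day combination rule]" else ""))
  }
  invisible(x)
}

#' Does an ATC code fall under a rule?
#'
#' Prefix semantics: the code must start with at least one include prefix
#' and with no exclude prefix.
#'
#' @param atc_code Character vector of ATC codes.
#' @param rule A single `ddci_rule`.
#' @return Logical vector.
#' @export
#' @examples
#' rules <- default_rule_table()
#' match_atc("C07AB03", rules[["Drugs for arterial hypertension"]])  # TRUE
#' match_atc("C07AB09", rules[["Drugs for arterial hypertension"]])  # FALSE
match_atc <- function(atc_code, rule) {
  matches_any_prefix(atc_code, rule$include) &
    !matches_any_prefix(atc_code, rule$exclude)
}

matches_any_prefix <- function(codes, prefixes) {
  if (!length(prefixes)) return(rep(FALSE, length(codes)))
  out <- rep(FALSE, length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}

#' Detect baseline drug-class exposures
#'
#' Applies the rule table to each person's dispensing history over the
#' baseline look-back window, the half-open interval
#' `[index_date - window_days, index_date)`: a package dispensed exactly
#' `window_days` before the index date counts, one dispensed on the index
#' date does not. For a standard rule the flag is raised when the summed
#' package count of matching prescriptions reaches the rule's threshold.
#'
#' The hypertensive-heart-disease flag instead requires, within any sliding
#' 45-day sub-window of the baseline year, either (a) prescriptions matching
#' at least two distinct entries of the rule's ATC set, or (b) at least two
#' prescriptions (dispensing rows) of digoxin (C01AA05).
#'
#' @param prescriptions Prescription data frame (`person_id`, `atc_code`,
#'   `dispense_date`, `packages`).
#' @param persons Persons data frame carrying `person_id` and `index_date`,
#'   or a `ddci_cohort`.
#' @param rules Rule table; default [default_rule_table()].
#' @return Data frame of class `ddci_exposures`: `person_id` plus one
#'   logical column per drug class (columns carry the class names verbatim),
#'   one row per person in `persons`.
#' @export
detect_exposures <- function(prescriptions, persons, rules = default_rule_table()) {
  if (inherits(persons, "ddci_cohort")) {
    if (missing(prescriptions) || is.null(prescriptions))
      prescriptions <- persons$prescriptions
    persons <- persons$persons
  }
  ids <- persons$person_id
  out <- data.frame(person_id = ids, stringsAsFactors = FALSE)

  rx <- data.table::as.data.table(
    prescriptions[, c("person_id", "atc_code", "dispense_date", "packages")])
  idx <- data.table::data.table(person_id = ids, index_date = persons$index_date)
  rx <- idx[rx, on = "person_id", nomatch = NULL]
  rx[, days_before := as.integer(index_date - dispense_date)]

  for (r in rules) {
    inwin <- rx$days_before >= 1L & rx$days_before <= r$window_days
    hit <- inwin & match_atc(rx$atc_code, r)
    if (is.null(r$combination)) {
      tot <- rx[hit, list(pk = sum(packages)), by = "person_id"]
      flagged <- tot$person_id[tot$pk >= r$min_packages]
    } else {
      flagged <- combination_flag(rx[hit], r$combination)
    }
    out[[r$name]] <- ids %in% flagged
  }
  class(out) <- c("ddci_exposures", "data.frame")
  attr(out, "classes") <- vapply(rules, `[[`, character(1), "name")
  out
}

# Person ids whose matching prescriptions satisfy the 45-day combination
# rule. `rxm`: data.table of matching in-window rows.
combination_flag <- function(rxm, comb) {
  if (!nrow(rxm)) return(character())
  # label each row with the set entry it matches (entries do not overlap)
  entry <- rep(NA_character_, nrow(rxm))
  for (e in comb$set) {
    entry[is.na(entry) & startsWith(rxm$atc_code, e)] <- e
  }
  rxm <- rxm[!is.na(entry)]
  entry <- entry[!is.na(entry)]
  d <- data.table::data.table(person_id = rxm$person_id,
                              day = as.integer(rxm$dispense_date),
                              entry = entry)
  # only persons with >= 2 matching rows can qualify
  d <- d[, if (.N >= 2L) .SD, by = "person_id"]
  if (!nrow(d)) return(character())
  win <- comb$window_days
  qualifies <- function(day, ent) {
    o <- order(day)
    day <- day[o]; ent <- ent[o]
    n <- length(day)
    for (i in seq_len(n - 1L)) {
      j <- i + 1L
      while (j <= n && day[j] - day[i] <= win) {
        if (ent[j] != ent[i]) return(TRUE)                    # two distinct agents
        if (ent[i] == comb$repeat_code) return(TRUE)          # repeated digoxin
        j <- j + 1L
      }
    }
    FALSE
  }
  flags <- d[, list(flag = qualifies(day, entry)), by = "person_id"]
  flags$person_id[flags$flag]
}

#' Write / read a rule table as a YAML configuration file
#'
#' The configuration holds one block per class (`name`, `include`,
#' `exclude`, `min_packages`, `window_days`, optional `combination`), so
#' classes can be re-defined without touching code.
#'
#' @param rules A `ddci_rules` object.
#' @param path File path.
#' @return `read_rule_table()` returns a `ddci_rules` object;
#'   `write_rule_table()` returns the path invisibly.
#' @export
write_rule_table <- function(rules, path) {
  blocks <- lapply(unclass(rules), function(r) {
    b <- list(name = r$name, include = as.list(r$include),
              exclude = as.list(r$exclude),
              min_packages = r$min_packages, window_days = r$window_days)
    if (!is.null(r$combination)) {
      b$combination <- list(window_days = r$combination$window_days,
                            set = as.list(r$combination$set),
                            min_distinct = r$combination$min_distinct,
                            repeat_code = r$combination$repeat_code,
                            min_repeat = r$combination$min_repeat)
    }
    b
  })
  yaml::write_yaml(unname(blocks), path)
  invisible(path)
}

#' @rdname write_rule_table
#' @export
read_rule_table <- function(path) {
  blocks <- yaml::read_yaml(path)
  rules <- lapply(blocks, function(b) {
    comb <- if (!is.null(b$combination)) {
      list(window_days = as.integer(b$combination$window_days),
           set = unlist(b$combination$set),
           min_distinct = as.integer(b$combination$min_distinct),
           repeat_code = b$combination$repeat_code,
           min_repeat = as.integer(b$combination$min_repeat))
    }
    new_rule(b$name, unlist(b$include), unlist(b$exclude) %||% character(),
             b$min_packages, b$window_days, comb)
  })
  names(rules) <- vapply(rules, `[[`, character(1), "name")
  structure(rules, class = "ddci_rules")
}
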