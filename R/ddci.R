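# Score computation: the DDCI raw score from exposure flags and an integer
# weight table, risk-class binning, and the comparator Charlson Comorbidity
# Index from discharge diagnoses.

#' Published index model: coefficients, hazard ratios and weights
#'
#' The 19-row reference model of the published weight-assignment table: per
#' drug class the Cox regression coefficient (log hazard ratio) for overall
#' mortality, the hazard ratio with its 95% confidence interval, and the
#' integer weight obtained by dividing the coefficient by 0.3 and rounding
#' to the nearest integer.
#'
#' @return Data frame with columns `class`, `coefficient`, `hazard_ratio`,
#'   `ci_low`, `ci_high`, `weight`.
#' @export
ddci_reference_model <- function() {
  data.frame(
    class = ddci_classes(),
    coefficient = c(0.418, -0.368, 0.532, 0.435, 0.368, 0.880, 0.739,
                    0.390, 0.530, 0.831, 0.289, -0.560, 0.087, 0.464,
                    1.672, 1.108, 0.841, 1.130, 0.087),
    hazard_ratio = c(1.52, 0.69, 1.70, 1.55, 1.45, 2.41, 2.09, 1.48, 1.70,
                     2.30, 1.34, 0.57, 1.09, 1.59, 5.32, 3.03, 2.32, 3.10, 1.09),
    ci_low = c(1.47, 0.62, 1.67, 1.48, 1.39, 2.33, 2.05, 1.46, 1.67, 2.26,
               1.32, 0.56, 1.08, 1.54, 4.81, 2.93, 2.24, 2.92, 1.06),
    ci_high = c(1.57, 0.78, 1.73, 1.62, 1.50, 2.49, 2.14, 1.50, 1.73, 2.34,
                1.35, 0.58, 1.11, 1.64, 5.88, 3.14, 2.40, 3.29, 1.11),
    weight = c(1L, -1L, 2L, 1L, 1L, 3L, 2L, 1L, 2L, 3L, 1L, -2L, 0L, 2L,
               6L, 4L, 3L, 4L, 0L),
    stringsAsFactors = FALSE
  )
}

#' Default integer weight table
#'
#' @return Named integer vector mapping each of the 19 drug-class names to
#'   its published weight.
#' @export
default_weight_table <- function() {
  ref <- ddci_reference_model()
  stats::setNames(ref$weight, ref$class)
}

#' Compute the DDCI raw score
#'
#' The raw score is the algebraic sum of the weights of the drug classes a
#' person is exposed to. Accepts a single logical flag vector (named by
#' class), a logical matrix (persons x classes), or an exposure table from
#' [detect_exposures()]; the latter two return one score per person.
#'
#' @param flags Named logical vector, logical matrix with class-name
#'   columns, or a `ddci_exposures` data frame.
#' @param weights Named integer weight table; default the published one.
#' @return Integer score(s). For an exposure data frame, a data frame with
#'   `person_id`, `raw_score` and `risk_class`.
#' @export
#' @examples
#' w <- default_weight_table()
#' f <- setNames(rep(FALSE, 19), names(w))
#' f[c("Platelet aggregation inhibitors", "Antihyperglycemic therapy")] <- TRUE
#' compute_ddci(f, w)  # 2 + 2 = 4
compute_ddci <- function(flags, weights = default_weight_table()) {
  if (inherits(flags, "ddci_exposures") ||
      (is.data.frame(flags) && "person_id" %in% names(flags))) {
    classes <- setdiff(names(flags), "person_id")
    check_weighted(classes, weights)
    m <- as.matrix(flags[classes])
    storage.mode(m) <- "double"
    raw <- as.integer(round(m %*% weights[classes]))
    return(data.frame(person_id = flags$person_id,
                      raw_score = raw,
                      risk_class = assign_class(raw)))
  }
  if (is.matrix(flags)) {
    check_weighted(colnames(flags), weights)
    m <- flags
    storage.mode(m) <- "double"
    return(as.integer(round(m %*% weights[colnames(flags)])))
  }
  check_weighted(names(flags), weights)
  as.integer(sum(weights[names(flags)[flags]]))
}

check_weighted <- function(classes, weights) {
  if (is.null(classes)) stop("exposure flags must be named by drug class")
  missing <- setdiff(classes, names(weights))
  if (length(missing)) {
    stop("unweighted class: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Bin a raw score into the 12 risk classes
#'
#' Negative and zero scores fall into the lowest class (0); scores of 11 or
#' greater into the top class (11); scores 1-10 map to themselves. Exactly
#' 12 distinct classes exist.
#'
#' @param raw_score Integer vector of raw scores.
#' @return Integer vector of risk classes in 0..11.
#' @export
#' @examples
#' assign_class(c(-3, 0, 7, 33))  # 0 0 7 11
assign_class <- function(raw_score) {
  pmin(pmax(as.integer(raw_score), 0L), 11L)
}

#' Enumerate the scores of every exposure combination
#'
#' Brute-force enumeration of the raw score over all `2^k` subsets of the
#' weighted drug classes (524,288 combinations for the default 19-class
#' table). Used to establish the attainable score range: with the published
#' weights the minimum is -3 (statin + immunosuppressant exposure).
#'
#' @param weights Named integer weight table.
#' @return Integer vector of length `2^length(weights)` with the score of
#'   every exposure combination.
#' @export
enumerate_scores <- function(weights = default_weight_table()) {
  scores <- 0L
  for (w in as.integer(weights)) scores <- c(scores, scores + w)
  scores
}

## ---- Charlson Comorbidity Index (Deyo ICD-9-CM adaptation) ----

#' Charlson condition mapping (Deyo ICD-9-CM adaptation)
#'
#' Reads the bundled (or a user-supplied) mapping from ICD-9-CM code
#' prefixes to the 17 Charlson conditions with their original weights.
#' Codes are matched dotless by prefix ("410.11" and "41011" both fall
#' under prefix "410"). The `supersedes` column encodes the standard
#' hierarchy: complicated diabetes over diabetes, metastatic tumor over any
#' malignancy, moderate/severe over mild liver disease.
#'
#' @param path CSV file; defaults to the mapping shipped with the package.
#' @return Data frame with `condition`, `weight`, `supersedes` and a
#'   `prefixes` list-column.
#' @export
charlson_map <- function(path = system.file("extdata", "charlson_icd9_deyo.csv",
                                            package = "ddci")) {
  m <- utils::read.csv(path, colClasses = "character")
  m$weight <- as.integer(m$weight)
  m$prefixes <- strsplit(m$prefixes, ";", fixed = TRUE)
  m
}

normalize_icd9 <- function(codes) {
  toupper(gsub(".", "", codes, fixed = TRUE))
}

#' Compute the Charlson Comorbidity Index from baseline hospitalizations
#'
#' Scans all primary and secondary ICD-9-CM discharge diagnoses of
#' hospitalizations falling in the baseline window (admission within the
#' `window_days` before the index date) against the Charlson condition
#' mapping and returns the weighted sum per person, applying the condition
#' hierarchy. Persons without a baseline hospitalization score 0.
#'
#' @param hospitalizations Hospitalization data frame (`person_id`,
#'   `admission_date`, `diagnoses` with semicolon-separated codes).
#' @param persons Persons data frame with `person_id` and `index_date`.
#' @param window_days Baseline look-back in days (default 365, the same
#'   12-month window used for prescriptions).
#' @param map Condition mapping; default [charlson_map()].
#' @return Data frame with `person_id` and `cci`, one row per person.
#' @export
compute_cci <- function(hospitalizations, persons, window_days = 365L,
                        map = charlson_map()) {
  ids <- persons$person_id
  out <- data.frame(person_id = ids, cci = 0L, stringsAsFactors = FALSE)
  if (!nrow(hospitalizations)) return(out)

  h <- merge(hospitalizations[, c("person_id", "admission_date", "diagnoses")],
             persons[, c("person_id", "index_date")], by = "person_id")
  days_before <- days_between(h$admission_date, h$index_date)
  h <- h[days_before >= 1L & days_before <= window_days, , drop = FALSE]
  if (!nrow(h)) return(out)

  diag_list <- strsplit(h$diagnoses, ";", fixed = TRUE)
  long <- data.frame(person_id = rep(h$person_id, lengths(diag_list)),
                     code = normalize_icd9(unlist(diag_list)),
                     stringsAsFactors = FALSE)

  # person x condition incidence
  hit <- matrix(FALSE, nrow = length(ids), ncol = nrow(map),
                dimnames = list(ids, map$condition))
  for (k in seq_len(nrow(map))) {
    rows <- matches_any_prefix(long$code, map$prefixes[[k]])
    if (any(rows)) hit[unique(long$person_id[rows]), k] <- TRUE
  }
  # hierarchy: a superseded condition does not also score
  for (k in which(nzchar(map$supersedes))) {
    hit[hit[, map$condition[k]], map$supersedes[k]] <- FALSE
  }
  out$cci <- as.integer(hit %*% map$weight)
  out
}
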