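# Synthetic claims-cohort generator. Emulates the statistical structure the
# pipeline assumes: drug-exposure prevalences as published for the training
# cohort, mortality following a proportional-hazards model with the
# published class coefficients plus age/sex effects, baseline
# hospitalizations carrying Charlson diagnoses, and post-index unplanned
# admissions whose intensity grows geometrically with the risk class.

#' Simulation configuration with study-condition defaults
#'
#' Defaults encode the published cohort: the 19 drug-class exposure
#' prevalences of the training sample (e.g. 29.45% for arterial
#' hypertension drugs, 0.05% for opioids), the published Cox coefficients
#' as true log hazard ratios, age ~ Normal(60.17, 13.58) truncated at 40,
#' 46.29% male, a 7-year horizon, and a baseline hazard calibrated so the
#' default configuration reproduces the published ~10.7% 7-year cumulative
#' mortality. Exposures are drawn independently across classes unless
#' `exposure_correlation` sets a Gaussian-copula correlation (a stress
#' option emulating real-world comorbidity clustering).
#'
#' @param n_persons Cohort size.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @param exposure_prevalences Named probability per drug class.
#' @param true_coefficients Named true log hazard ratio per drug class.
#' @param baseline_hazard Baseline death hazard per year.
#' @param beta_age Log hazard ratio per year of age (centered at 60).
#' @param beta_sex Log hazard ratio for male sex.
#' @param cci_log_hr Log hazard ratio per Charlson point (gives the
#'   comparator index real signal).
#' @param horizon_years Follow-up horizon in years.
#' @param migration_rate Censoring (out-migration) hazard per year.
#' @param admission_rate_base Unplanned-admission rate (per person-year) in
#'   risk class 0.
#' @param admission_rate_per_class Multiplicative rate step per risk class.
#' @param age_mean,age_sd,age_min Age distribution (truncated normal).
#' @param male_fraction Proportion of men.
#' @param baseline_hosp_prob Probability of at least one baseline-year
#'   hospitalization.
#' @param negative_exposure_rate Probability that an unexposed person still
#'   receives sub-threshold prescriptions of a class (so negatives are not
#'   trivially empty).
#' @param exposure_correlation Equicorrelation of the exposure copula
#'   (0 = independent, the default).
#' @param include_hospitalizations Generate the hospitalization table.
#' @param index_date Common index date.
#' @param atc_semantics Passed to [default_rule_table()].
#' @return List of class `ddci_sim_config`.
#' @export
simulation_config <- function(n_persons = 10000,
                              seed = 1,
                              exposure_prevalences = default_exposure_prevalences(),
                              true_coefficients = default_true_coefficients(),
                              baseline_hazard = 0.0051,
                              beta_age = 0.08,
                              beta_sex = 0.25,
                              cci_log_hr = 0.15,
                              horizon_years = 7,
                              migration_rate = 0.005,
                              admission_rate_base = 0.10,
                              admission_rate_per_class = 1.17,
                              age_mean = 60.17,
                              age_sd = 13.58,
                              age_min = 40,
                              male_fraction = 0.4629,
                              baseline_hosp_prob = 0.125,
                              negative_exposure_rate = 0.15,
                              exposure_correlation = 0,
                              include_hospitalizations = TRUE,
                              index_date = as.Date("2004-01-01"),
                              atc_semantics = "table") {
  cfg <- as.list(environment())
  stopifnot(cfg$n_persons >= 1,
            all(cfg$exposure_prevalences >= 0 & cfg$exposure_prevalences <= 1),
            cfg$baseline_hazard >= 0, cfg$migration_rate >= 0,
            cfg$admission_rate_base >= 0,
            cfg$exposure_correlation >= 0, cfg$exposure_correlation < 1,
            setequal(names(cfg$exposure_prevalences), ddci_classes()),
            setequal(names(cfg$true_coefficients), ddci_classes()))
  class(cfg) <- "ddci_sim_config"
  cfg
}

#' Published training-cohort exposure prevalences
#' @return Named numeric vector (proportions).
#' @export
default_exposure_prevalences <- function() {
  stats::setNames(
    c(0.0103, 0.0019, 0.0825, 0.0065, 0.0104, 0.0122, 0.0373, 0.2945,
      0.0790, 0.0512, 0.2028, 0.0676, 0.1795, 0.0160, 0.0005, 0.0067,
      0.0121, 0.0021, 0.0330),
    ddci_classes())
}

#' Published Cox coefficients as true simulation effects
#' @return Named numeric vector of log hazard ratios.
#' @export
default_true_coefficients <- function() {
  ref <- ddci_reference_model()
  stats::setNames(ref$coefficient, ref$class)
}

# Complete an ATC prefix to a syntactically valid 7-character code using the
# level template (letter, 2 digits, letter, letter, 2 digits).
pad_atc <- function(prefix) {
  template <- "X10AA01"
  paste0(prefix, substr(template, nchar(prefix) + 1, 7))
}

# Representative ICD-9-CM codes per Charlson condition, plus fillers.
CHARLSON_EMIT <- c(
  myocardial_infarction = "410.11", congestive_heart_failure = "428.0",
  peripheral_vascular_disease = "443.9", cerebrovascular_disease = "434.91",
  dementia = "290.0", chronic_pulmonary_disease = "496",
  rheumatologic_disease = "714.0", peptic_ulcer_disease = "531.30",
  mild_liver_disease = "571.5", diabetes = "250.00",
  diabetes_with_complications = "250.40", hemiplegia_paraplegia = "342.90",
  renal_disease = "585", any_malignancy = "153.9",
  moderate_severe_liver_disease = "572.2", metastatic_solid_tumor = "197.0",
  aids = "042")
FILLER_ICD9 <- c("401.9", "486", "780.79", "786.50", "715.90", "574.20")

#' Simulate a synthetic claims cohort
#'
#' Generates persons, prescriptions, hospitalizations and a ground-truth
#' table under the configured study conditions. For each person: age and
#' sex are drawn, exposure indicators are drawn per class, and prescription
#' rows are emitted that satisfy the corresponding rule for positives
#' (matching ATC codes, package counts at threshold, dates uniform in the
#' baseline year) or fail it for a fraction of negatives. Death time is
#' exponential with hazard
#' `baseline_hazard * exp(sum(beta_k flag_k) + beta_age (age - 60) +
#' beta_sex male + cci_log_hr CCI)`, censored at migration or the horizon.
#' Unplanned admissions follow a Poisson process with rate
#' `admission_rate_base * admission_rate_per_class^risk_class`.
#'
#' The per-class emission codes are chosen so that each emitted code
#' matches exactly one rule, making the generated flags recoverable by
#' [detect_exposures()] by construction.
#'
#' @param config A [simulation_config()].
#' @return List of class `c("ddci_sim", "ddci_cohort")` with `persons`,
#'   `prescriptions`, `hospitalizations`, `truth` and an empty `report`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "ddci_sim_config"))
  set.seed(config$seed)
  n <- config$n_persons
  classes <- ddci_classes()
  rules <- default_rule_table(config$atc_semantics)
  index <- config$index_date

  ## persons ----------------------------------------------------------------
  ids <- sprintf("S%07d", seq_len(n))
  male <- stats::rbinom(n, 1, config$male_fraction)
  # truncated normal age via inverse CDF
  u <- stats::runif(n, stats::pnorm(config$age_min, config$age_mean, config$age_sd), 1)
  age <- stats::qnorm(u, config$age_mean, config$age_sd)
  birth_date <- index - round(age * DAYS_PER_YEAR)

  ## exposure flags ---------------------------------------------------------
  prev <- config$exposure_prevalences[classes]
  rho <- config$exposure_correlation
  if (rho > 0) {
    f <- stats::rnorm(n)
    z <- sqrt(rho) * f + sqrt(1 - rho) * matrix(stats::rnorm(n * 19), n, 19)
    flags <- sweep(z, 2, stats::qnorm(prev), "<")
  } else {
    flags <- matrix(stats::runif(n * 19) < rep(prev, each = n), n, 19)
  }
  colnames(flags) <- classes

  ## baseline hospitalizations and true Charlson score ----------------------
  has_hosp <- stats::runif(n) < config$baseline_hosp_prob
  cci_true <- integer(n)
  hosp_rows <- list()
  if (any(has_hosp) && config$include_hospitalizations) {
    map <- charlson_map()
    hi <- which(has_hosp)
    n_cond <- sample(0:2, length(hi), replace = TRUE, prob = c(0.35, 0.45, 0.20))
    cond_pool <- c("congestive_heart_failure", "diabetes",
                   "chronic_pulmonary_disease", "cerebrovascular_disease",
                   "myocardial_infarction", "any_malignancy", "renal_disease",
                   "metastatic_solid_tumor", "mild_liver_disease", "dementia")
    conds <- lapply(n_cond, function(k) sample(cond_pool, k))
    wts <- stats::setNames(map$weight, map$condition)
    sup <- stats::setNames(map$supersedes, map$condition)
    cci_true[hi] <- vapply(conds, function(cs) {
      cs <- setdiff(cs, sup[cs])  # hierarchy: drop superseded conditions
      as.integer(sum(wts[cs]))
    }, integer(1))
    diag_str <- vapply(seq_along(hi), function(j) {
      codes <- c(CHARLSON_EMIT[conds[[j]]],
                 sample(FILLER_ICD9, sample(1:2, 1)))
      paste(codes, collapse = ";")
    }, character(1))
    adm <- index - sample(30:365, length(hi), replace = TRUE)
    hosp_rows$baseline <- data.frame(
      person_id = ids[hi],
      admission_date = adm,
      discharge_date = adm + sample(2:15, length(hi), replace = TRUE),
      unplanned = stats::runif(length(hi)) < 0.7,
      diagnoses = diag_str,
      in_hospital_death = FALSE,
      stringsAsFactors = FALSE)
  }

  ## survival ---------------------------------------------------------------
  beta <- config$true_coefficients[classes]
  lp <- as.vector(flags %*% beta) + config$beta_age * (age - 60) +
    config$beta_sex * male + config$cci_log_hr * cci_true
  t_death <- stats::rexp(n, 1) / (config$baseline_hazard * exp(lp))
  t_mig <- if (config$migration_rate > 0) {
    stats::rexp(n, config$migration_rate)
  } else rep(Inf, n)
  horizon <- config$horizon_years
  time <- pmin(t_death, t_mig, horizon)
  event <- t_death <= t_mig & t_death <= horizon

  death_date <- as.Date(ifelse(t_death <= horizon,
                               index + round(t_death * DAYS_PER_YEAR), NA),
                        origin = "1970-01-01")
  migration_date <- as.Date(ifelse(t_mig <= horizon,
                                   index + round(t_mig * DAYS_PER_YEAR), NA),
                            origin = "1970-01-01")

  persons <- data.frame(
    person_id = ids,
    sex = ifelse(male == 1, "M", "F"),
    birth_date = birth_date,
    index_date = index,
    death_date = death_date,
    migration_date = migration_date,
    age_at_index = floor(days_between(birth_date, index) / DAYS_PER_YEAR),
    stringsAsFactors = FALSE)

  ## prescriptions ----------------------------------------------------------
  rx_parts <- list()
  add_rx <- function(person_id, atc, days_before, packages = 1L) {
    rx_parts[[length(rx_parts) + 1L]] <<- data.frame(
      person_id = person_id, atc_code = atc,
      dispense_date = index - days_before,
      packages = as.integer(packages), stringsAsFactors = FALSE)
  }
  hhd_class <- "Drugs for hypertensive heart disease"
  hhd_safe <- c("C01AA05", "C03CA01", "C03DA01")  # match only the 45-day rule

  for (cl in classes) {
    r <- rules[[cl]]
    pos <- which(flags[, cl])
    neg <- which(!flags[, cl] & stats::runif(n) < config$negative_exposure_rate)
    if (cl == hhd_class) {
      if (length(pos)) {
        branch_b <- stats::runif(length(pos)) < 0.5
        d1 <- sample(46:365, length(pos), replace = TRUE)
        gap <- sample(0:44, length(pos), replace = TRUE)
        code1 <- ifelse(branch_b, "C01AA05",
                        hhd_safe[1 + (seq_along(pos) %% 3)])
        code2 <- ifelse(branch_b, "C01AA05",
                        hhd_safe[1 + ((seq_along(pos) + 1) %% 3)])
        add_rx(ids[pos], code1, d1)
        add_rx(ids[pos], code2, d1 - gap)
      }
      if (length(neg)) {
        add_rx(ids[neg], "C01AA05", sample(365, length(neg), replace = TRUE))
      }
      next
    }
    code <- pad_atc(r$include[1])
    if (cl == "Opioids") code <- "N02AA01"
    if (length(pos)) {
      for (k in seq_len(r$min_packages)) {
        add_rx(ids[pos], code, sample(365, length(pos), replace = TRUE))
      }
    }
    if (length(neg) && r$min_packages > 1L) {
      for (k in seq_len(r$min_packages - 1L)) {
        add_rx(ids[neg], code, sample(365, length(neg), replace = TRUE))
      }
    }
    if (cl == "Opioids" && length(neg)) {
      # tramadol rows: excluded from the opioid rule, must never flag
      add_rx(ids[neg], "N02AX02", sample(365, length(neg), replace = TRUE))
    }
  }
  prescriptions <- if (length(rx_parts)) do.call(rbind, rx_parts) else
    data.frame(person_id = character(), atc_code = character(),
               dispense_date = as.Date(character()), packages = integer())
  prescriptions <- prescriptions[order(prescriptions$person_id,
                                       prescriptions$dispense_date,
                                       prescriptions$atc_code), , drop = FALSE]
  rownames(prescriptions) <- NULL

  ## scores and post-index admissions ---------------------------------------
  raw_score <- as.integer(flags %*% default_weight_table()[classes])
  risk_class <- assign_class(raw_score)

  if (config$include_hospitalizations) {
    rate <- config$admission_rate_base *
      config$admission_rate_per_class^risk_class
    n_adm <- stats::rpois(n, rate * time)
    who <- rep(seq_len(n), n_adm)
    if (length(who)) {
      at_years <- stats::runif(length(who)) * time[who]
      adm_date <- index + floor(at_years * DAYS_PER_YEAR)
      hosp_rows$followup <- data.frame(
        person_id = ids[who],
        admission_date = adm_date,
        discharge_date = adm_date + sample(1:10, length(who), replace = TRUE),
        unplanned = stats::runif(length(who)) < 0.85,
        diagnoses = sample(FILLER_ICD9, length(who), replace = TRUE),
        in_hospital_death = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  hospitalizations <- if (length(hosp_rows)) {
    h <- do.call(rbind, hosp_rows)
    h <- h[order(h$person_id, h$admission_date), , drop = FALSE]
    rownames(h) <- NULL
    h
  } else {
    data.frame(person_id = character(), admission_date = as.Date(character()),
               discharge_date = as.Date(character()), unplanned = logical(),
               diagnoses = character(), in_hospital_death = logical())
  }

  truth <- data.frame(person_id = ids, flags, check.names = FALSE)
  truth$age <- age
  truth$male <- male
  truth$cci_true <- cci_true
  truth$raw_score <- raw_score
  truth$risk_class <- risk_class
  truth$linear_predictor <- lp
  truth$death_time <- t_death
  truth$time <- time
  truth$event <- event

  structure(list(persons = persons,
                 prescriptions = prescriptions,
                 hospitalizations = hospitalizations,
                 truth = truth,
                 report = data.frame(table = character(), reason = character(),
                                     n = integer()),
                 config = config),
            class = c("ddci_sim", "ddci_cohort"))
}

#' Hand-placed worked fixture covering every rule branch
#'
#' A deterministic 15-person cohort exercising each branch of the exposure
#' rules: threshold met and missed for a 3-package class, the 2-package
#' antihyperglycemic rule, the C07AB09 exclusion, a tramadol-only opioid
#' negative, both branches of the 45-day hypertensive-heart rule (and a
#' single-dispensing negative), a negative-score person (statin +
#' immunosuppressant), a maximal-score person landing in the top risk
#' class, baseline hospitalizations with Charlson diagnoses, and
#' window-edge prescriptions (exactly 365 days before the index date
#' counts; on the index date does not).
#'
#' @return A `ddci_cohort` list; attribute `"expected"` carries the
#'   expected raw score, risk class and Charlson index per person.
#' @export
make_worked_fixture <- function() {
  index <- as.Date("2004-01-01")
  ids <- sprintf("W%02d", 1:15)
  persons <- data.frame(
    person_id = ids,
    sex = rep(c("M", "F"), length.out = 15),
    birth_date = as.Date("1949-03-15") + seq(0, 14) * 100,
    index_date = index,
    death_date = as.Date(NA),
    migration_date = as.Date(NA),
    stringsAsFactors = FALSE)
  persons$death_date[persons$person_id == "W12"] <- as.Date("2006-01-01")   # ~2.0 y
  persons$migration_date[persons$person_id == "W03"] <- index + 1132        # 3.1 y
  persons$death_date[persons$person_id == "W03"] <- index + 1278            # 3.5 y
  persons$age_at_index <- floor(days_between(persons$birth_date, index) / DAYS_PER_YEAR)

  rx <- function(id, atc, dates, pk = 1L) {
    data.frame(person_id = id, atc_code = atc, dispense_date = as.Date(dates),
               packages = pk, stringsAsFactors = FALSE)
  }
  prescriptions <- rbind(
    rx("W01", "C01BD01", c("2003-02-01", "2003-06-15", "2003-11-20")),
    rx("W02", "C01BD01", c("2003-03-01", "2003-08-01")),
    rx("W03", "A10BA02", c("2003-03-10", "2003-09-05")),
    rx("W04", "C07AB09", c("2003-02-05", "2003-06-10", "2003-10-15")),
    rx("W05", "C07AB03", c("2003-01-15", "2003-05-20", "2003-10-25")),
    rx("W06", "N02AX02", c("2003-02-20", "2003-05-25", "2003-09-30")),
    rx("W07", "N02AA01", c("2003-01-10", "2003-04-18", "2003-08-22")),
    rx("W08", "C01AA05", "2003-06-01"),
    rx("W08", "C03CA01", "2003-06-25"),
    rx("W09", "C01AA05", c("2003-04-01", "2003-05-10")),
    rx("W10", "C10AA01", c("2003-02-14", "2003-06-21", "2003-11-01")),
    rx("W10", "L04AA01", c("2003-03-03", "2003-07-07", "2003-11-11")),
    rx("W11", "N02AA01", c("2003-02-02", "2003-06-06", "2003-10-10")),
    rx("W11", "N04AA01", "2003-04-04"),
    rx("W11", "N06AA01", "2003-08-08"),
    rx("W13", "C01BD01", rep("2003-01-01", 3)),
    rx("W14", "C01BD01", rep("2004-01-01", 3)),
    rx("W15", "C01AA05", "2003-07-15"))

  hospitalizations <- data.frame(
    person_id = c("W10", "W12"),
    admission_date = as.Date(c("2003-08-15", "2003-05-10")),
    discharge_date = as.Date(c("2003-08-22", "2003-05-18")),
    unplanned = c(TRUE, TRUE),
    diagnoses = c("250.01;428.0", "410.11"),
    in_hospital_death = c(FALSE, FALSE),
    stringsAsFactors = FALSE)

  expected <- data.frame(
    person_id = ids,
    raw_score = c(1L, 0L, 2L, 0L, 1L, 0L, 6L, 3L, 3L, -3L, 14L, 0L, 1L, 0L, 0L),
    cci = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 2L, 0L, 1L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
  expected$risk_class <- assign_class(expected$raw_score)

  out <- structure(list(persons = persons,
                        prescriptions = prescriptions,
                        hospitalizations = hospitalizations,
                        report = data.frame(table = character(),
                                            reason = character(), n = integer())),
                   class = "ddci_cohort")
  attr(out, "expected") <- expected
  out
}
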