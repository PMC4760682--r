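# Orchestration: train/validation splitting and the end-to-end chain
# simulate -> exposures -> score -> derive -> evaluate.

#' Random train/validation split of a cohort
#'
#' Deterministic pseudo-random partition of the person ids into disjoint,
#' exhaustive training and validation sets.
#'
#' @param person_ids Character vector of ids (or a persons data frame).
#' @param fraction Training fraction in (0, 1); default 0.5.
#' @param seed Integer seed.
#' @return List with `training` and `validation` id vectors.
#' @export
split_cohort <- function(person_ids, fraction = 0.5, seed = 1) {
  if (is.data.frame(person_ids)) person_ids <- person_ids$person_id
  stopifnot(fraction > 0, fraction < 1)
  set.seed(seed)
  n <- length(person_ids)
  train <- sort(sample.int(n, round(n * fraction)))
  list(training = person_ids[train],
       validation = person_ids[-train])
}

#' Pipeline configuration
#'
#' @param simulation [simulation_config()] used to generate the cohort, or
#'   `NULL` to read an existing cohort from `input_dir`.
#' @param input_dir Directory with `persons.csv`, `prescriptions.csv`,
#'   `hospitalizations.csv` (used when `simulation` is `NULL`).
#' @param output_dir Run directory for artifacts.
#' @param split_fraction,split_seed Train/validation split.
#' @param horizon_years Evaluation horizon (`NULL` = overall follow-up).
#' @param model Evaluation design: `"A"` (age+sex vs +DDCI), `"B"` (same,
#'   hospitalized subcohort), `"C"` (age+sex vs +CCI, hospitalized), `"D"`
#'   (age+sex+CCI vs +DDCI, hospitalized).
#' @param divisor,alpha Weight-derivation parameters.
#' @param adjust_age_sex Adjust the derivation fit for age and sex.
#' @return List of class `ddci_pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            input_dir = NULL,
                            output_dir = tempfile("ddci_run_"),
                            split_fraction = 0.5,
                            split_seed = 1,
                            horizon_years = 7,
                            model = "A",
                            divisor = 0.3,
                            alpha = 0.05,
                            adjust_age_sex = TRUE) {
  stopifnot(split_fraction > 0, split_fraction < 1,
            model %in% c("A", "B", "C", "D"))
  cfg <- as.list(environment())
  class(cfg) <- "ddci_pipeline_config"
  cfg
}

#' Run the full scoring pipeline
#'
#' Executes the chain: obtain the cohort (simulate or read), split it,
#' detect baseline exposures, derive the integer weights on the training
#' half, score the validation half, and evaluate on the validation half
#' (model comparison, class-wise hazard ratios, and — when
#' hospitalizations are present — the readmission rate model). Artifacts
#' (weights, scores, evaluation report, log) are written to the run
#' directory with the configuration embedded.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage messages.
#' @return List of class `ddci_run` with `weights`, `scores`, `agreement`,
#'   `comparison`, `class_hr`, `readmissions`, `split`, `output_dir`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  t0 <- Sys.time()
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf("[%5.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }

  ## cohort
  if (!is.null(config$simulation)) {
    say("simulate: n=%d seed=%d", config$simulation$n_persons,
        config$simulation$seed)
    cohort <- simulate_cohort(config$simulation)
  } else {
    say("read cohort from %s", config$input_dir)
    cohort <- read_cohort(file.path(config$input_dir, "persons.csv"),
                          file.path(config$input_dir, "prescriptions.csv"),
                          file.path(config$input_dir, "hospitalizations.csv"))
  }
  persons <- cohort$persons
  say("cohort: %d persons, %d prescriptions, %d hospitalizations",
      nrow(persons), nrow(cohort$prescriptions), nrow(cohort$hospitalizations))

  ## split
  split <- split_cohort(persons$person_id, config$split_fraction,
                        config$split_seed)
  say("split: %d training / %d validation",
      length(split$training), length(split$validation))

  ## exposures and survival
  exposures <- detect_exposures(cohort$prescriptions, persons)
  survival <- derive_survival(persons, config$horizon_years %||% 7)
  say("exposures detected: %d flagged person-classes",
      sum(as.matrix(exposures[, -1])))

  in_train <- exposures$person_id %in% split$training
  p_train <- persons[persons$person_id %in% split$training, , drop = FALSE]
  p_valid <- persons[persons$person_id %in% split$validation, , drop = FALSE]

  ## derive weights on the training half
  weights <- derive_ddci_weights(exposures[in_train, , drop = FALSE],
                                 survival[survival$person_id %in% split$training, ],
                                 p_train,
                                 adjust_age_sex = config$adjust_age_sex,
                                 divisor = config$divisor,
                                 alpha = config$alpha)
  agreement <- reproduce_table2(weights)
  say("weights derived on training set: %d/%d match the published table",
      agreement$n_match, agreement$n_total)

  ## score the validation half
  exp_valid <- exposures[!in_train, , drop = FALSE]
  scores <- compute_ddci(exp_valid, as_weight_vector(weights))
  surv_valid <- survival[match(scores$person_id, survival$person_id), ]
  say("validation scored: classes 0..11 occupied: %s",
      paste(sort(unique(scores$risk_class)), collapse = ","))

  ## evaluation on the validation half
  age <- p_valid$age_at_index[match(scores$person_id, p_valid$person_id)]
  male <- as.integer(p_valid$sex[match(scores$person_id, p_valid$person_id)] == "M")
  cci <- compute_cci(cohort$hospitalizations, p_valid)
  cci <- cci$cci[match(scores$person_id, cci$person_id)]

  base_cov <- data.frame(age = age, male = male)
  covs <- switch(config$model,
    A = list(ref = base_cov, aug = cbind(base_cov, ddci = scores$raw_score)),
    B = list(ref = base_cov, aug = cbind(base_cov, ddci = scores$raw_score)),
    C = list(ref = base_cov, aug = cbind(base_cov, cci = cci)),
    D = list(ref = cbind(base_cov, cci = cci),
             aug = cbind(base_cov, cci = cci, ddci = scores$raw_score)))
  keep <- rep(TRUE, nrow(scores))
  if (config$model %in% c("B", "C", "D")) {
    # hospitalized subcohort: at least one hospitalization on record
    keep <- scores$person_id %in% unique(cohort$hospitalizations$person_id)
    say("model %s: hospitalized subcohort n=%d", config$model, sum(keep))
  }
  comparison <- compare_models(covs$ref[keep, , drop = FALSE],
                               covs$aug[keep, , drop = FALSE],
                               surv_valid[keep, , drop = FALSE],
                               horizon = config$horizon_years)
  say("model %s: C %0.3f -> %0.3f, NRI %0.3f", config$model,
      comparison$c_reference$c_index, comparison$c_augmented$c_index,
      comparison$nri$nri)

  class_hr <- tryCatch(
    classwise_hazard_ratios(surv_valid, scores$risk_class, age, male),
    error = function(e) { say("class-wise HRs skipped: %s", conditionMessage(e)); NULL })

  readm <- NULL
  if (nrow(cohort$hospitalizations)) {
    hist <- readmission_history(cohort$hospitalizations, p_valid, surv_valid)
    if (nrow(hist) > 50) {
      i <- match(hist$person_id, scores$person_id)
      readm <- readmission_irr(hist$readmissions, hist$person_years,
                               scores$risk_class[i], age[i], male[i])
      say("readmission model: %d persons, %d classes",
          nrow(hist), nrow(readm$rates))
    }
  }

  ## artifacts
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(weights, file.path(config$output_dir, "weights.csv"),
                   row.names = FALSE)
  utils::write.csv(scores, file.path(config$output_dir, "scores.csv"),
                   row.names = FALSE)
  report <- list(
    model = config$model,
    horizon_years = config$horizon_years,
    split = list(fraction = config$split_fraction, seed = config$split_seed,
                 n_training = length(split$training),
                 n_validation = length(split$validation)),
    weights_agreement = agreement$n_match,
    c_index_reference = comparison$c_reference$c_index,
    c_index_augmented = comparison$c_augmented$c_index,
    nri = comparison$nri[c("nri", "event_component", "nonevent_component",
                           "ci_low", "ci_high")],
    class_hazard_ratios = class_hr,
    readmission_rates = if (!is.null(readm)) readm$rates,
    readmission_irr = if (!is.null(readm)) readm$irr)
  jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  say("artifacts written to %s", config$output_dir)
  writeLines(log_lines, file.path(config$output_dir, "log.txt"))

  structure(list(weights = weights, scores = scores, agreement = agreement,
                 comparison = comparison, class_hr = class_hr,
                 readmissions = readm, split = split,
                 output_dir = config$output_dir, log = log_lines),
            class = "ddci_run")
}
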