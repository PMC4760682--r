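# Validation battery: Kaplan-Meier curves by risk class, class-wise hazard
# ratios, Harrell's survival C-index, continuous Net Reclassification
# Improvement, and the Poisson incidence-rate-ratio model for hospital
# readmissions.

#' Kaplan-Meier estimate per group
#'
#' Product-limit estimator of the survival function, stratified by a group
#' label (typically the risk class).
#'
#' @param survival Data frame with `time` and `event`.
#' @param groups Optional vector of group labels, one per person; a single
#'   group is assumed when omitted.
#' @return Data frame with `group`, `time`, `n_risk`, `n_event`,
#'   `survival`: the step function evaluated at the observed times.
#' @export
km_estimate <- function(survival, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", nrow(survival))
  stopifnot(length(groups) == nrow(survival))
  g <- factor(groups)
  if (any(table(g) == 0)) stop("groups must be non-empty")
  sf <- survival::survfit(
    survival::Surv(survival$time, survival$event) ~ g)
  if (is.null(sf$strata)) {
    grp <- rep(levels(g), length(sf$time))
  } else {
    grp <- rep(sub("^g=", "", names(sf$strata)), sf$strata)
  }
  data.frame(group = grp,
             time = sf$time,
             n_risk = sf$n.risk,
             n_event = sf$n.event,
             survival = sf$surv,
             stringsAsFactors = FALSE)
}

#' Age- and sex-adjusted hazard ratios by risk class
#'
#' Cox model with indicator covariates for classes 1..11 (class 0 is the
#' reference) plus age and sex. Classes absent from the data are omitted
#' with a warning.
#'
#' @param survival Data frame with `time` and `event`.
#' @param classes Integer risk class per person (0..11).
#' @param age,sex Adjustment covariates per person (`sex` coded `"M"`/`"F"`
#'   or 0/1); either may be `NULL` for an unadjusted fit.
#' @return Data frame with `class`, `n`, `hazard_ratio`, `ci_low`,
#'   `ci_high`, `p_value` (reference class has HR 1 by definition and is
#'   included with `p_value = NA`).
#' @export
classwise_hazard_ratios <- function(survival, classes, age = NULL, sex = NULL) {
  classes <- as.integer(classes)
  if (!any(classes == min(classes))) stop("reference class is empty")
  ref <- min(classes)
  present <- sort(unique(classes))
  expected <- seq(ref, max(classes))
  if (length(setdiff(expected, present))) {
    warning("empty risk classes omitted: ",
            paste(setdiff(expected, present), collapse = ", "))
  }
  x <- data.frame(row.names = seq_along(classes))
  for (k in present[present != ref]) {
    x[[paste0("class_", k)]] <- as.integer(classes == k)
  }
  if (!is.null(age) && length(unique(age)) > 1) x$age <- age
  if (!is.null(sex)) {
    male <- if (is.character(sex) || is.factor(sex)) {
      as.integer(as.character(sex) == "M")
    } else as.integer(sex)
    if (length(unique(male)) > 1) x$male <- male
  }
  fit <- fit_cox(x, survival)
  sm <- fit$summary
  keep <- grepl("^class_", sm$name)
  out <- data.frame(class = c(ref, as.integer(sub("class_", "", sm$name[keep]))),
                    n = c(sum(classes == ref),
                          vapply(as.integer(sub("class_", "", sm$name[keep])),
                                 function(k) sum(classes == k), integer(1))),
                    hazard_ratio = c(1, sm$hazard_ratio[keep]),
                    ci_low = c(NA, sm$ci_low[keep]),
                    ci_high = c(NA, sm$ci_high[keep]),
                    p_value = c(NA, sm$p_value[keep]))
  out[order(out$class), , drop = FALSE]
}

#' Harrell's concordance index for a risk score
#'
#' Probability that, of a usable pair (the ordering of whose event times is
#' determinable under censoring), the person with the higher risk score
#' fails first; tied scores receive half credit. The 95% CI uses the
#' asymptotic variance of the concordance statistic; a seeded bootstrap
#' (`ci = "bootstrap"`, 200 resamples) is available for small cohorts.
#'
#' @param score Numeric risk score per person (higher = higher risk).
#' @param survival Data frame with `time` and `event`.
#' @param ci `"asymptotic"` (default) or `"bootstrap"`.
#' @param boot_n,boot_seed Bootstrap resamples and seed.
#' @return List with `c_index`, `se`, `ci_low`, `ci_high`.
#' @export
harrell_c <- function(score, survival, ci = c("asymptotic", "bootstrap"),
                      boot_n = 200, boot_seed = 1) {
  ci <- match.arg(ci)
  stopifnot(length(score) == nrow(survival))
  if (nrow(survival) < 2 || sum(survival$event) < 1) stop("no usable pairs")
  fit <- survival::concordance(
    survival::Surv(survival$time, survival$event) ~ score, reverse = TRUE)
  pairs <- sum(fit$count[1:3])
  if (pairs < 1) stop("no usable pairs")
  cidx <- as.numeric(fit$concordance)
  if (ci == "asymptotic") {
    se <- sqrt(as.numeric(fit$var))
  } else {
    set.seed(boot_seed)
    n <- nrow(survival)
    reps <- vapply(seq_len(boot_n), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      f <- survival::concordance(
        survival::Surv(survival$time[idx], survival$event[idx]) ~ score[idx],
        reverse = TRUE)
      as.numeric(f$concordance)
    }, numeric(1))
    se <- stats::sd(reps)
  }
  list(c_index = cidx, se = se,
       ci_low = max(0, cidx - 1.96 * se),
       ci_high = min(1, cidx + 1.96 * se))
}

#' Continuous (category-free) Net Reclassification Improvement
#'
#' Event component: net proportion of events whose predicted risk rises
#' under the new model, `P(new > ref | event) - P(new < ref | event)`.
#' Non-event component: net proportion of non-events whose risk falls,
#' `P(new < ref | non-event) - P(new > ref | non-event)`. The NRI is their
#' sum; each component lies in [-1, 1]. The CI uses the standard asymptotic
#' variance of the two net proportions.
#'
#' @param reference_risk,new_risk Predicted risks from the reference and
#'   augmented models, aligned per person.
#' @param event Logical outcome status at the horizon.
#' @param weights Optional non-negative per-person weights (used by the
#'   inverse-probability-of-censoring option of [compare_models()]).
#' @return List with `nri`, `event_component`, `nonevent_component`, `se`,
#'   `ci_low`, `ci_high`, `n_events`, `n_nonevents`.
#' @export
nri <- function(reference_risk, new_risk, event, weights = NULL) {
  stopifnot(length(reference_risk) == length(new_risk),
            length(event) == length(new_risk))
  if (is.null(weights)) weights <- rep(1, length(event))
  event <- as.logical(event)
  n_e <- sum(event)
  n_ne <- sum(!event)
  if (n_e == 0) stop("no events")
  if (n_ne == 0) stop("no non-events")
  up <- new_risk > reference_risk
  down <- new_risk < reference_risk
  wmean <- function(z, sel) stats::weighted.mean(z[sel], weights[sel])

  p_up_e <- wmean(up, event); p_down_e <- wmean(down, event)
  p_up_ne <- wmean(up, !event); p_down_ne <- wmean(down, !event)
  ec <- p_up_e - p_down_e
  nec <- p_down_ne - p_up_ne
  # variance of a net proportion difference within each outcome stratum
  var_e <- (p_up_e + p_down_e - ec^2) / n_e
  var_ne <- (p_up_ne + p_down_ne - nec^2) / n_ne
  se <- sqrt(var_e + var_ne)
  total <- ec + nec
  list(nri = total, event_component = ec, nonevent_component = nec,
       se = se, ci_low = total - 1.96 * se, ci_high = total + 1.96 * se,
       n_events = n_e, n_nonevents = n_ne)
}

#' Predicted event risk at a horizon from a fitted Cox model
#'
#' `risk = 1 - S0(t)^exp(lp)` with the Breslow baseline cumulative hazard
#' at the centered linear predictor.
#'
#' @param fit A `ddci_coxfit`.
#' @param horizon Horizon time (same units as the fitted survival times).
#' @return Numeric vector of predicted risks for the fitting data.
#' @export
predict_horizon_risk <- function(fit, horizon) {
  cox <- if (inherits(fit, "ddci_coxfit")) fit$fit else fit
  bh <- survival::basehaz(cox, centered = TRUE)
  at <- bh$hazard[findInterval(horizon, bh$time)]
  if (!length(at) || findInterval(horizon, bh$time) == 0) at <- 0
  lp <- stats::predict(cox, type = "lp")
  1 - exp(-at * exp(lp))
}

#' Follow-up and event counts for the readmission analysis
#'
#' Readmission exposure time starts at the discharge of the first unplanned
#' admission after the index date and ends at death, migration or the end
#' of the study; every subsequent admission counts as a readmission.
#'
#' @param hospitalizations Hospitalization data frame.
#' @param persons Persons data frame (`person_id`, `index_date`).
#' @param survival Survival data frame from [derive_survival()] (defines
#'   the end of follow-up).
#' @return Data frame with `person_id`, `readmissions`, `person_years` for
#'   persons with at least one unplanned admission and positive follow-up.
#' @export
readmission_history <- function(hospitalizations, persons, survival) {
  h <- merge(hospitalizations,
             persons[, c("person_id", "index_date")], by = "person_id")
  h$adm_years <- days_between(h$index_date, h$admission_date) / DAYS_PER_YEAR
  h$dis_years <- days_between(h$index_date, h$discharge_date) / DAYS_PER_YEAR
  h <- h[h$adm_years >= 0, , drop = FALSE]
  if (!nrow(h)) {
    return(data.frame(person_id = character(), readmissions = integer(),
                      person_years = numeric()))
  }
  dt <- data.table::as.data.table(h)
  first <- dt[unplanned == TRUE,
              list(start = min(dis_years[adm_years == min(adm_years)])),
              by = "person_id"]
  counts <- dt[first, on = "person_id"][adm_years > start,
                                        list(readmissions = .N), by = "person_id"]
  out <- merge(as.data.frame(first), as.data.frame(counts),
               by = "person_id", all.x = TRUE)
  out$readmissions[is.na(out$readmissions)] <- 0L
  out <- merge(out, survival[, c("person_id", "time")], by = "person_id")
  out$person_years <- out$time - out$start
  out <- out[out$person_years > 0, , drop = FALSE]
  data.frame(person_id = out$person_id,
             readmissions = as.integer(out$readmissions),
             person_years = out$person_years,
             stringsAsFactors = FALSE)
}

#' Readmission incidence rates and rate ratios by risk class
#'
#' Crude incidence rates (events per person-year) per risk class, and
#' incidence rate ratios versus the lowest class from a Poisson log-linear
#' model with a log person-years offset, optionally adjusted for age and
#' sex. Classes with zero person-years are dropped with a warning. With a
#' single binary class and no covariates the modeled IRR equals the ratio
#' of crude rates exactly.
#'
#' @param events Integer readmission count per person.
#' @param person_years Positive follow-up per person.
#' @param classes Integer risk class per person.
#' @param age,sex Optional adjustment covariates.
#' @return List with `rates` (class, events, person_years, rate), `irr`
#'   (class, irr, ci_low, ci_high, p_value) and the `fit`.
#' @export
readmission_irr <- function(events, person_years, classes,
                            age = NULL, sex = NULL) {
  keep <- person_years > 0
  if (!all(keep)) {
    warning(sum(!keep), " persons with zero person-years dropped")
    events <- events[keep]; person_years <- person_years[keep]
    classes <- classes[keep]
    if (!is.null(age)) age <- age[keep]
    if (!is.null(sex)) sex <- sex[keep]
  }
  classes <- as.integer(classes)
  ref <- min(classes)
  if (sum(person_years[classes == ref]) <= 0) {
    stop("reference class has no person-years")
  }
  agg <- stats::aggregate(
    cbind(events = events, person_years = person_years),
    by = list(class = classes), FUN = sum)
  agg$rate <- agg$events / agg$person_years

  dat <- data.frame(events = events,
                    fclass = factor(classes, levels = sort(unique(classes))),
                    off = log(person_years))
  fml <- "events ~ fclass"
  if (!is.null(age)) { dat$age <- age; fml <- paste(fml, "+ age") }
  if (!is.null(sex)) {
    dat$male <- if (is.character(sex) || is.factor(sex)) {
      as.integer(as.character(sex) == "M")
    } else as.integer(sex)
    fml <- paste(fml, "+ male")
  }
  fit <- stats::glm(stats::as.formula(fml), data = dat,
                    family = stats::poisson(), offset = off)
  co <- summary(fit)$coefficients
  keep_co <- grepl("^fclass", rownames(co))
  irr <- data.frame(
    class = c(ref, as.integer(sub("fclass", "", rownames(co)[keep_co]))),
    irr = c(1, exp(co[keep_co, "Estimate"])),
    ci_low = c(NA, exp(co[keep_co, "Estimate"] - 1.96 * co[keep_co, "Std. Error"])),
    ci_high = c(NA, exp(co[keep_co, "Estimate"] + 1.96 * co[keep_co, "Std. Error"])),
    p_value = c(NA, co[keep_co, "Pr(>|z|)"]))
  list(rates = agg, irr = irr[order(irr$class), , drop = FALSE], fit = fit)
}

#' Compare a reference and an augmented risk model
#'
#' Fits two Cox models on the same cohort (e.g. age + sex versus age + sex
#' + DDCI), computes each person's predicted risk at the horizon, and
#' reports the survival C-index of both models together with the continuous
#' NRI of the augmented over the reference model. Outcome status at the
#' horizon is death on or before it; persons censored alive before the
#' horizon are excluded from the NRI (set `ipcw = TRUE` to instead weight
#' the remaining persons by the inverse probability of being uncensored).
#'
#' @param reference,augmented Covariate data frames (rows aligned with
#'   `survival`; the augmented set typically adds a score column).
#' @param survival Data frame with `time` and `event`.
#' @param horizon Risk horizon in the time unit of `survival`; defaults to
#'   the maximum observed time (overall horizon).
#' @param ipcw Use inverse-probability-of-censoring weights in the NRI.
#' @return Object of class `ddci_model_comparison`: list with `c_reference`
#'   and `c_augmented` ([harrell_c()] results), `delta_c`, `nri` ([nri()]
#'   result), `horizon`, `n`, `n_events`, `n_excluded`.
#' @export
compare_models <- function(reference, augmented, survival, horizon = NULL,
                           ipcw = FALSE) {
  stopifnot(nrow(reference) == nrow(survival),
            nrow(augmented) == nrow(survival))
  if (is.null(horizon)) horizon <- max(survival$time)
  fit_ref <- fit_cox(reference, survival)
  fit_aug <- fit_cox(augmented, survival)
  risk_ref <- predict_horizon_risk(fit_ref, horizon)
  risk_aug <- predict_horizon_risk(fit_aug, horizon)

  c_ref <- harrell_c(risk_ref, survival)
  c_aug <- harrell_c(risk_aug, survival)

  died <- survival$event & survival$time <= horizon
  known <- died | survival$time >= horizon
  w <- NULL
  if (ipcw) {
    # censoring distribution from the reverse Kaplan-Meier
    cens_fit <- survival::survfit(
      survival::Surv(survival$time, !survival$event) ~ 1)
    G <- stats::stepfun(cens_fit$time, c(1, cens_fit$surv))
    w <- ifelse(died, 1 / pmax(G(survival$time), 1e-8),
                1 / pmax(G(horizon), 1e-8))[known]
  }
  reclass <- nri(risk_ref[known], risk_aug[known], died[known], weights = w)

  structure(list(c_reference = c_ref, c_augmented = c_aug,
                 delta_c = c_aug$c_index - c_ref$c_index,
                 nri = reclass,
                 horizon = horizon, n = nrow(survival),
                 n_events = sum(died), n_excluded = sum(!known)),
            class = "ddci_model_comparison")
}

#' @export
print.ddci_model_comparison <- function(x, ...) {
  cat(sprintf("model comparison at horizon %.2f (n=%d, events=%d, excluded=%d)\n",
              x$horizon, x$n, x$n_events, x$n_excluded))
  cat(sprintf("  C-index: reference %.3f (%.3f-%.3f)  augmented %.3f (%.3f-%.3f)  delta %+0.3f\n",
              x$c_reference$c_index, x$c_reference$ci_low, x$c_reference$ci_high,
              x$c_augmented$c_index, x$c_augmented$ci_low, x$c_augmented$ci_high,
              x$delta_c))
  cat(sprintf("  NRI: %.4f (%.4f-%.4f) = events %.4f + non-events %.4f\n",
              x$nri$nri, x$nri$ci_low, x$nri$ci_high,
              x$nri$event_component, x$nri$nonevent_component))
  invisible(x)
}
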