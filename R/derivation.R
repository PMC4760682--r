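# Re-derivation of the integer weights from cohort data: a multivariate Cox
# proportional-hazards fit of overall mortality on the drug-class exposure
# flags, a Wald significance filter, and the divide-by-0.3 rounding rule.

#' Fit a multivariate Cox proportional-hazards model
#'
#' Thin, tidy wrapper around [survival::coxph()] (Efron tie handling,
#' Newton-Raphson maximization of the partial likelihood) returning one
#' record per covariate: coefficient (log hazard ratio), standard error
#' from the observed information, hazard ratio with Wald 95% CI, and the
#' two-sided Wald p-value.
#'
#' @param x Covariate data frame or matrix (one row per person). Logical
#'   columns are treated as 0/1. Column names may contain spaces.
#' @param survival Data frame with `time` and `event` (rows aligned with
#'   `x`, or matched on `person_id` when both carry it).
#' @param ties Tie-handling method, default `"efron"`.
#' @return Object of class `ddci_coxfit`: list with `summary` (the
#'   per-covariate data frame), `converged`, `loglik` (log partial
#'   likelihood at the optimum), `n`, `n_events`, and the underlying `fit`.
#' @export
fit_cox <- function(x, survival, ties = "efron") {
  if (is.data.frame(x) && "person_id" %in% names(x) &&
      "person_id" %in% names(survival)) {
    survival <- survival[match(x$person_id, survival$person_id), , drop = FALSE]
    x <- x[, setdiff(names(x), "person_id"), drop = FALSE]
  }
  x <- as.data.frame(x, check.names = FALSE)
  x[] <- lapply(x, function(col) if (is.logical(col)) as.integer(col) else col)
  if (!nrow(x) || nrow(x) != nrow(survival)) {
    stop("covariates and survival records must align")
  }
  if (sum(survival$event) < 1) stop("at least one event is required")
  constant <- vapply(x, function(col) length(unique(col)) < 2, logical(1))
  if (any(constant)) {
    stop("covariate constant across all persons: ",
         paste(names(x)[constant], collapse = ", "))
  }

  orig <- names(x)
  safe <- make.names(orig, unique = TRUE)
  names(x) <- safe
  dat <- cbind(x, .time = survival$time, .event = as.integer(survival$event))
  fml <- stats::as.formula(
    paste("survival::Surv(.time, .event) ~", paste(safe, collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties,
                         control = survival::coxph.control(iter.max = 100,
                                                           eps = 1e-9))
  sm <- summary(fit)
  co <- sm$coefficients
  separated <- !is.finite(co[, "coef"]) | !is.finite(co[, "se(coef)"]) |
    co[, "se(coef)"] > 10
  res <- data.frame(
    name = orig[match(rownames(co), safe)],
    coefficient = co[, "coef"],
    standard_error = co[, "se(coef)"],
    hazard_ratio = exp(co[, "coef"]),
    ci_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
    ci_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
    p_value = co[, "Pr(>|z|)"],
    separated = separated,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(summary = res,
                 converged = fit$iter < 100 && all(is.finite(stats::coef(fit))),
                 loglik = fit$loglik[2],
                 n = fit$n, n_events = fit$nevent,
                 fit = fit),
            class = "ddci_coxfit")
}

#' @export
print.ddci_coxfit <- function(x, ...) {
  cat(sprintf("Cox PH fit: n=%d, events=%d, log partial likelihood=%.3f%s\n",
              x$n, x$n_events, x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Derive integer score weights from a Cox fit
#'
#' Classes not significantly associated with the outcome (two-sided Wald
#' p >= `alpha`) are excluded from the final model: they keep their key but
#' receive weight 0 and `retained = FALSE`. For retained classes the weight
#' is the coefficient divided by `divisor`, rounded to the nearest integer
#' with halves away from zero; retained classes may legitimately round to
#' weight 0.
#'
#' @param fit A `ddci_coxfit` from [fit_cox()] (must have converged), or a
#'   data frame with `name`, `coefficient`, `p_value` columns.
#' @param divisor Scale divisor, default 0.3.
#' @param alpha Significance level for the Wald filter, default 0.05.
#' @return Object of class `ddci_weights`: data frame with `class`,
#'   `coefficient`, `p_value`, `retained`, `weight`.
#' @seealso [as_weight_vector()], [reproduce_table2()]
#' @export
derive_weights <- function(fit, divisor = 0.3, alpha = 0.05) {
  if (inherits(fit, "ddci_coxfit")) {
    if (!fit$converged) stop("Cox fit did not converge; cannot derive weights")
    sm <- fit$summary
  } else {
    sm <- as.data.frame(fit)
  }
  retained <- sm$p_value < alpha
  weight <- ifelse(retained,
                   weight_from_coefficient(sm$coefficient, divisor), 0L)
  out <- data.frame(class = sm$name,
                    coefficient = sm$coefficient,
                    p_value = sm$p_value,
                    retained = retained,
                    weight = as.integer(weight),
                    stringsAsFactors = FALSE)
  class(out) <- c("ddci_weights", "data.frame")
  out
}

#' Flatten a derived weight table to a named integer vector
#' @param weights A `ddci_weights` data frame or a named vector.
#' @return Named integer vector.
#' @export
as_weight_vector <- function(weights) {
  if (is.data.frame(weights)) {
    stats::setNames(as.integer(weights$weight), weights$class)
  } else {
    stats::setNames(as.integer(weights), names(weights))
  }
}

#' Compare a derived weight table with a reference
#'
#' Per-class agreement report between weights re-derived from data and a
#' reference table (by default the published one). Both tables must cover
#' the same classes.
#'
#' @param derived Derived weights (`ddci_weights` or named vector).
#' @param reference Reference weights (named vector or `ddci_weights`).
#' @return List with `comparison` (class, derived, reference, match),
#'   `n_match`, `n_total` and `mismatches` (class names).
#' @export
reproduce_table2 <- function(derived, reference = default_weight_table()) {
  d <- as_weight_vector(derived)
  r <- as_weight_vector(reference)
  if (!setequal(names(d), names(r))) {
    stop("derived and reference weight tables cover different classes")
  }
  r <- r[names(d)]
  cmp <- data.frame(class = names(d),
                    derived = unname(d),
                    reference = unname(r),
                    match = unname(d == r),
                    stringsAsFactors = FALSE)
  list(comparison = cmp,
       n_match = sum(cmp$match),
       n_total = nrow(cmp),
       mismatches = cmp$class[!cmp$match])
}

#' End-to-end weight derivation from exposures and survival
#'
#' Fits the multivariate Cox model of overall mortality on the drug-class
#' exposure flags and converts the coefficients to integer weights. By
#' default the fit adjusts for age and sex (their coefficients are not
#' weighted and do not appear in the returned table): with a strong age
#' gradient in the cohort, omitting age attenuates the marginal drug-class
#' hazard ratios, so the adjusted fit recovers the intended class effects.
#' Set `adjust_age_sex = FALSE` for the unadjusted, flags-only fit.
#'
#' @param exposures Exposure table from [detect_exposures()].
#' @param survival Survival data frame (`person_id`, `time`, `event`).
#' @param persons Persons data frame (needed when `adjust_age_sex = TRUE`;
#'   supplies `age_at_index` or `birth_date`/`index_date`, and `sex`).
#' @param adjust_age_sex Include age and sex as adjustment covariates.
#' @param divisor,alpha Passed to [derive_weights()].
#' @return A `ddci_weights` table (drug classes only), with the full
#'   `ddci_coxfit` attached as attribute `"fit"`.
#' @export
derive_ddci_weights <- function(exposures, survival, persons = NULL,
                                adjust_age_sex = TRUE,
                                divisor = 0.3, alpha = 0.05) {
  classes <- setdiff(names(exposures), "person_id")
  # classes nobody (or everybody) is exposed to are inestimable: excluded
  # from the fit, reported with weight 0 and retained = FALSE
  constant <- classes[vapply(classes,
                             function(cl) length(unique(exposures[[cl]])) < 2,
                             logical(1))]
  if (length(constant)) {
    warning("classes with constant exposure excluded from the fit: ",
            paste(constant, collapse = ", "))
  }
  estimable <- setdiff(classes, constant)
  x <- exposures[, c("person_id", estimable)]
  if (adjust_age_sex) {
    if (is.null(persons)) stop("persons table required to adjust for age and sex")
    i <- match(x$person_id, persons$person_id)
    age <- persons$age_at_index
    if (is.null(age)) {
      age <- floor(days_between(persons$birth_date, persons$index_date) /
                     DAYS_PER_YEAR)
    }
    x$.age <- age[i]
    x$.male <- as.integer(persons$sex[i] == "M")
  }
  fit <- fit_cox(x, survival)
  sm <- fit$summary[fit$summary$name %in% classes, , drop = FALSE]
  w <- derive_weights(sm, divisor = divisor, alpha = alpha)
  if (length(constant)) {
    w <- rbind(as.data.frame(w),
               data.frame(class = constant, coefficient = NA_real_,
                          p_value = NA_real_, retained = FALSE, weight = 0L))
    w <- w[match(classes, w$class), , drop = FALSE]
    rownames(w) <- NULL
    class(w) <- c("ddci_weights", "data.frame")
  }
  attr(w, "fit") <- fit
  w
}

#' Consistency of printed hazard ratios with printed coefficients
#'
#' Checks, row by row, that a table's hazard-ratio column is consistent
#' with exponentiating its coefficient column, given that both columns are
#' printed rounded (coefficients to `coef_digits`, hazard ratios to
#' `hr_digits`). Consistency means the interval `exp(c +- half-ULP)`
#' overlaps `HR +- half-ULP`.
#'
#' @param model Reference model data frame; default [ddci_reference_model()].
#' @param coef_digits,hr_digits Printed precision of the two columns.
#' @return Data frame with `class`, `coefficient`, `hazard_ratio`,
#'   `exp_coefficient` and logical `consistent`.
#' @export
check_hr_consistency <- function(model = ddci_reference_model(),
                                 coef_digits = 3, hr_digits = 2) {
  half_c <- 0.5 * 10^(-coef_digits)
  half_h <- 0.5 * 10^(-hr_digits)
  lo <- exp(model$coefficient - half_c)
  hi <- exp(model$coefficient + half_c)
  consistent <- (lo <= model$hazard_ratio + half_h) &
    (hi >= model$hazard_ratio - half_h)
  data.frame(class = model$class,
             coefficient = model$coefficient,
             hazard_ratio = model$hazard_ratio,
             exp_coefficient = exp(model$coefficient),
             consistent = consistent,
             stringsAsFactors = FALSE)
}
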