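test_that("Kaplan-Meier matches closed forms and the direct product oracle", {
  # two subjects, events at 1 and 2, no censoring
  km <- km_estimate(data.frame(time = c(1, 2), event = c(TRUE, TRUE)))
  expect_equal(km$survival[km$time == 1], 0.5)
  expect_equal(km$survival[km$time == 2], 0)

  # censoring after the last event leaves the curve unchanged at event times
  km2 <- km_estimate(data.frame(time = c(1, 2, 3), event = c(TRUE, TRUE, FALSE)))
  expect_equal(km2$survival[km2$time == 1], 2 / 3)
  expect_equal(km2$survival[km2$time == 2], 1 / 3)

  # no censoring: equals the empirical survival function
  set.seed(9)
  t3 <- sort(runif(40, 0, 5))
  km3 <- km_estimate(data.frame(time = t3, event = TRUE))
  expect_equal(km3$survival, 1 - seq_along(t3) / 40)

  # 100-person censored fixture vs brute-force product over risk sets
  set.seed(10)
  tt <- round(rexp(100, 0.3), 3)
  ev <- runif(100) < 0.6
  km4 <- km_estimate(data.frame(time = tt, event = ev))
  expect_equal(km4$survival, oracle_km(tt, ev, km4$time), tolerance = 1e-12)

  # probabilities start at 1 and never increase, per group
  g <- rep(1:2, 50)
  km5 <- km_estimate(data.frame(time = tt, event = ev), g)
  for (grp in split(km5, km5$group)) {
    expect_true(all(diff(grp$survival) <= 1e-12))
    expect_lte(grp$survival[1], 1)
  }
})

test_that("harrell_c agrees with exhaustive pair enumeration and is rank-invariant", {
  # perfect ranking, no censoring
  sv <- data.frame(time = c(5, 4, 3, 2, 1), event = TRUE)
  sc <- 1:5
  expect_equal(harrell_c(sc, sv)$c_index, 1)

  # 50-person censored fixture vs O(n^2) oracle, integer scores force ties
  set.seed(12)
  n <- 50
  tt <- round(rexp(n, 0.25), 4)
  ev <- runif(n) < 0.55
  sc <- sample(0:6, n, replace = TRUE)
  sv <- data.frame(time = tt, event = ev)
  got <- harrell_c(sc, sv)
  expect_equal(got$c_index, oracle_concordance(sc, tt, ev), tolerance = 1e-12)
  expect_true(got$ci_low <= got$c_index && got$c_index <= got$ci_high)

  # invariant under strictly monotone transformation of the score
  expect_equal(harrell_c(exp(sc) + 3, sv)$c_index, got$c_index)

  # independent score, large n: near 1/2
  set.seed(13)
  m <- 3000
  sv2 <- data.frame(time = rexp(m, 0.2), event = runif(m) < 0.7)
  expect_equal(harrell_c(rnorm(m), sv2)$c_index, 0.5, tolerance = 0.03)

  expect_error(harrell_c(1, data.frame(time = 1, event = TRUE)), "no usable pairs")
})

test_that("NRI components match direct counting and behave at the extremes", {
  # every event rises, every non-event falls: maximal NRI of 2
  ev <- c(rep(TRUE, 5), rep(FALSE, 5))
  ref <- rep(0.5, 10)
  new <- c(rep(0.9, 5), rep(0.1, 5))
  got <- nri(ref, new, ev)
  expect_equal(got$nri, 2)
  expect_equal(got$event_component, 1)
  expect_equal(got$nonevent_component, 1)

  # identical risks: zero
  expect_equal(nri(ref, ref, ev)$nri, 0)

  # 40-person fixture vs counting oracle
  set.seed(14)
  ev2 <- runif(40) < 0.4
  r1 <- runif(40); r2 <- r1 + rnorm(40, 0, 0.2)
  got2 <- nri(r1, r2, ev2)
  want <- oracle_nri(r1, r2, ev2)
  expect_equal(got2$nri, unname(want["nri"]))
  expect_equal(got2$event_component, unname(want["event"]))
  expect_equal(got2$nonevent_component, unname(want["nonevent"]))

  # bounds and antisymmetry under swapping reference and new
  expect_true(abs(got2$event_component) <= 1 && abs(got2$nonevent_component) <= 1)
  swapped <- nri(r2, r1, ev2)
  expect_equal(swapped$nri, -got2$nri)

  expect_error(nri(r1, r2, rep(FALSE, 40)), "no events")
  expect_error(nri(r1, r2, rep(TRUE, 40)), "no non-events")
})

test_that("class-wise hazard ratios recover simulated effects", {
  set.seed(15)
  n <- 6000
  cls <- sample(0:1, n, replace = TRUE)
  age <- runif(n, 40, 90)
  # true HR of 2 for class 1, plus an age effect
  h <- 0.05 * exp(log(2) * cls + 0.03 * (age - 60))
  tt <- rexp(n, h)
  sv <- data.frame(time = pmin(tt, 10), event = tt <= 10)
  hr <- classwise_hazard_ratios(sv, cls, age, rep(0, n))
  est <- hr[hr$class == 1, ]
  expect_gt(est$ci_high, 2 * 0.99)
  expect_lt(est$ci_low, 2 * 1.01)
  expect_equal(hr$hazard_ratio[hr$class == 0], 1)

  # null: identical hazards give HR near 1
  cls0 <- sample(0:2, n, replace = TRUE)
  sv0 <- data.frame(time = rexp(n, 0.1), event = TRUE)
  hr0 <- classwise_hazard_ratios(sv0, cls0)
  expect_true(all(abs(log(hr0$hazard_ratio[-1])) < 0.15))

  # empty intermediate class warns
  cls_gap <- ifelse(cls == 1, 2, 0)
  expect_warning(classwise_hazard_ratios(sv, cls_gap, age, rep(0, n)),
                 "omitted")
})

test_that("readmission IRR equals the crude rate ratio in the two-class case", {
  set.seed(16)
  n <- 800
  cls <- rep(0:1, each = n / 2)
  py <- runif(n, 0.5, 4)
  events <- rpois(n, py * ifelse(cls == 1, 1.0, 0.5))
  got <- readmission_irr(events, py, cls)
  crude <- with(got, rates$rate[rates$class == 1] / rates$rate[rates$class == 0])
  expect_equal(got$irr$irr[got$irr$class == 1], crude, tolerance = 1e-8)
  expect_equal(got$irr$irr[got$irr$class == 0], 1)

  # identical rates: IRR near 1
  ev2 <- rpois(n, py * 0.7)
  got2 <- readmission_irr(ev2, py, cls)
  expect_equal(got2$irr$irr[got2$irr$class == 1], 1, tolerance = 0.15)

  # simulated multipliers {1, 1.4, 1.9} recovered within their CIs
  cls3 <- sample(0:2, 4000, replace = TRUE)
  py3 <- runif(4000, 0.5, 4)
  mult <- c(1, 1.4, 1.9)[cls3 + 1]
  ev3 <- rpois(4000, 0.6 * py3 * mult)
  got3 <- readmission_irr(ev3, py3, cls3)
  for (k in 1:2) {
    row <- got3$irr[got3$irr$class == k, ]
    truth <- c(1.4, 1.9)[k]
    expect_gt(truth, row$ci_low)
    expect_lt(truth, row$ci_high)
  }

  expect_warning(readmission_irr(c(1, 1, 0), c(1, 1, 0), c(0, 1, 1)), "dropped")
})

test_that("readmission follow-up starts at the first unplanned discharge", {
  index <- as.Date("2004-01-01")
  persons <- data.frame(person_id = c("a", "b"), index_date = index)
  sv <- data.frame(person_id = c("a", "b"), time = c(5, 5), event = FALSE)
  h <- data.frame(
    person_id = c("a", "a", "a", "b"),
    admission_date = index + c(100, 300, 500, 200),
    discharge_date = index + c(110, 305, 505, 210),
    unplanned = c(TRUE, FALSE, TRUE, FALSE),  # b has no unplanned admission
    diagnoses = "486",
    in_hospital_death = FALSE)
  got <- readmission_history(h, persons, sv)
  expect_equal(got$person_id, "a")
  expect_equal(got$readmissions, 2L)  # both later admissions count
  expect_equal(got$person_years, 5 - 110 / 365.25, tolerance = 1e-8)
})

test_that("compare_models is null under a useless covariate and gains under signal", {
  set.seed(17)
  n <- 4000
  age <- runif(n, 40, 90)
  male <- rbinom(n, 1, 0.5)
  score <- rpois(n, 2)
  h <- 0.02 * exp(0.04 * (age - 60) + 0.25 * male + 0.3 * score)
  tt <- rexp(n, h)
  cens <- pmin(rexp(n, 0.02), 7)
  sv <- data.frame(time = pmin(tt, cens), event = tt <= cens)

  base_cov <- data.frame(age = age, male = male)
  # useless augmentation
  null_cmp <- compare_models(base_cov, cbind(base_cov, junk = rnorm(n)), sv,
                             horizon = 7)
  expect_lt(abs(null_cmp$delta_c), 0.01)
  expect_lt(abs(null_cmp$nri$nri), 3 * null_cmp$nri$se + 0.05)

  # augmentation with the true generative score
  true_cmp <- compare_models(base_cov, cbind(base_cov, score = score), sv,
                             horizon = 7)
  expect_gt(true_cmp$delta_c, 0.02)
  expect_gt(true_cmp$nri$nri, 0)
  expect_equal(true_cmp$nri$nri,
               true_cmp$nri$event_component + true_cmp$nri$nonevent_component)

  # predicted risks are probabilities, ordered by the linear predictor
  fit <- fit_cox(cbind(base_cov, score = score), sv)
  risk <- predict_horizon_risk(fit, 7)
  expect_true(all(risk >= 0 & risk <= 1))
  lp <- predict(fit$fit, type = "lp")
  expect_gt(cor(lp, risk, method = "spearman"), 0.999)
})
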