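# Independent brute-force oracles. These deliberately re-derive results by
# direct enumeration, without reusing any package internals, so that each
# fast implementation is checked against a second route.

# exposure flags by a plain triple loop over (person, rule, prescription)
oracle_exposures <- function(prescriptions, persons, rules) {
  out <- data.frame(person_id = persons$person_id, stringsAsFactors = FALSE)
  for (r in rules) {
    flag <- logical(nrow(persons))
    for (i in seq_len(nrow(persons))) {
      idx <- persons$index_date[i]
      rows <- prescriptions[prescriptions$person_id == persons$person_id[i], ]
      if (!nrow(rows)) next
      db <- as.integer(idx - rows$dispense_date)
      inwin <- db >= 1 & db <= r$window_days
      m <- rep(FALSE, nrow(rows))
      for (p in r$include) m <- m | startsWith(rows$atc_code, p)
      for (p in r$exclude) m <- m & !startsWith(rows$atc_code, p)
      rows <- rows[inwin & m, ]
      if (!nrow(rows)) next
      if (is.null(r$combination)) {
        flag[i] <- sum(rows$packages) >= r$min_packages
      } else {
        ent <- rep(NA_character_, nrow(rows))
        for (e in r$combination$set) {
          ent[is.na(ent) & startsWith(rows$atc_code, e)] <- e
        }
        ok <- FALSE
        if (nrow(rows) >= 2) {
          for (a in seq_len(nrow(rows) - 1)) {
            for (b in (a + 1):nrow(rows)) {
              close_enough <- abs(as.integer(rows$dispense_date[a] -
                                             rows$dispense_date[b])) <=
                r$combination$window_days
              if (!close_enough) next
              if (ent[a] != ent[b]) ok <- TRUE
              if (ent[a] == r$combination$repeat_code &&
                  ent[b] == r$combination$repeat_code) ok <- TRUE
            }
          }
        }
        flag[i] <- ok
      }
    }
    out[[r$name]] <- flag
  }
  out
}

# Harrell's C by exhaustive pair enumeration under censoring
oracle_concordance <- function(score, time, event) {
  n <- length(score)
  conc <- disc <- tied <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # usable pair: the earlier time is an event (ties of time with mixed
      # status: event precedes censoring at the same time)
      ti <- time[i]; tj <- time[j]
      if (ti == tj && event[i] && event[j]) next  # tied event times unusable
      if (ti < tj || (ti == tj && event[i] && !event[j])) {
        first <- i; second <- j
      } else if (tj < ti || (ti == tj && event[j] && !event[i])) {
        first <- j; second <- i
      } else next
      if (!event[first]) next
      if (score[first] > score[second]) conc <- conc + 1
      else if (score[first] < score[second]) disc <- disc + 1
      else tied <- tied + 1
    }
  }
  (conc + 0.5 * tied) / (conc + disc + tied)
}

# Kaplan-Meier by the direct product over risk sets
oracle_km <- function(time, event, at) {
  vapply(at, function(t) {
    ev_times <- sort(unique(time[event & time <= t]))
    prod(vapply(ev_times, function(s) {
      d <- sum(event & time == s)
      r <- sum(time >= s)
      1 - d / r
    }, numeric(1)))
  }, numeric(1))
}

# continuous NRI by direct counting
oracle_nri <- function(ref, new, event) {
  e <- which(event); ne <- which(!event)
  ec <- (sum(new[e] > ref[e]) - sum(new[e] < ref[e])) / length(e)
  nec <- (sum(new[ne] < ref[ne]) - sum(new[ne] > ref[ne])) / length(ne)
  c(nri = ec + nec, event = ec, nonevent = nec)
}

# Cox partial log-likelihood for a single covariate, no tied event times
oracle_cox_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# one shared moderate simulation, built once per test run
sim_cache <- new.env(parent = emptyenv())
shared_sim <- function(name, config) {
  if (is.null(sim_cache[[name]])) {
    sim_cache[[name]] <- simulate_cohort(config)
  }
  sim_cache[[name]]
}
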