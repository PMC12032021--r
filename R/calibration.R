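# Calibration: automated, bounded replacement for iterative manual tuning.
# Designated knobs are multiplicative factors (on the odds scale for
# care-seeking intercepts, on the probability scale for risks and
# case-fatality), tuned by coordinate descent against hard-coded coverage
# targets with a weighted relative-squared-error loss.

CALIBRATION_KNOBS <- c("anc", "facility_delivery", "pnc_maternal",
                       "pnc_neonatal", "cfr_scale", "risk_scale")

#' Default calibration targets: population service coverage
#'
#' ANC4+ ~51%, facility delivery ~91%, maternal PNC 42%, newborn PNC 60%.
#' @return data frame (name, target, tolerance, weight).
#' @export
default_calibration_targets <- function() {
  data.frame(name = c("anc4", "facility_delivery", "pnc_maternal",
                      "pnc_neonatal"),
             target = c(0.51, 0.91, 0.42, 0.60),
             tolerance = 0.02, weight = 1)
}

#' Simulated service-coverage statistics
#'
#' Runs the care-seeking layer over a synthetic cohort of women of
#' reproductive age, each carrying one pregnancy to term: plans the ANC
#' schedule (ANC4+ requires initiation by gestational month 6 and at least 4
#' planned contacts), and draws facility delivery and maternal/newborn PNC
#' attendance from the regression models.
#'
#' @param ps parameter set.
#' @param seed integer seed.
#' @param n cohort size.
#' @return named numeric: `anc4`, `facility_delivery`, `pnc_maternal`,
#'   `pnc_neonatal`.
#' @export
coverage_statistics <- function(ps, seed = 1L, n = 4000) {
  w <- make_fixture_population(max(n * 6, 100), seed = seed, ps = ps)
  w <- w[w$sex == "F" & w$age_years >= 15 & w$age_years < 50, ]
  w <- w[seq_len(min(n, nrow(w))), ]
  sched <- plan_anc_schedule(w, ps, seed)
  anc4 <- mean(sched$initiates & !is.na(sched$first_gm) &
                 sched$first_gm <= 6 & sched$planned_visits >= 4)
  draw <- function(service, channel, ids) {
    p <- careseeking_probability(service, w, ps)
    mean(hash_unif(seed, ids, 50L, channel) < p)
  }
  c(anc4 = anc4,
    facility_delivery = draw("facility_delivery", rng_channels$facility, w$id),
    pnc_maternal = draw("pnc_maternal", rng_channels$pnc_maternal, w$id),
    pnc_neonatal = draw("pnc_neonatal", rng_channels$pnc_neonatal, w$id))
}

#' Weighted relative squared-error calibration loss
#'
#' @param simulated_stats named numeric vector of simulated statistics.
#' @param targets data frame (name, target, weight).
#' @return non-negative loss; error if a target's statistic is missing.
#' @export
calibration_loss <- function(simulated_stats, targets) {
  miss <- setdiff(targets$name, names(simulated_stats))
  if (length(miss))
    stop("simulated statistic missing for target(s): ",
         paste(miss, collapse = ", "))
  sim <- simulated_stats[targets$name]
  sum(targets$weight * ((sim - targets$target) / targets$target)^2)
}

apply_knob <- function(ps, knob, factor) {
  shift <- log(factor)
  cs <- ps$careseeking
  if (knob == "anc") {
    cs$intercept[cs$service == "anc"] <- cs$intercept[cs$service == "anc"] + shift
    pt <- ps$scalars$anc_transition_prob
    ps$scalars$anc_transition_prob <- inv_logit(stats::qlogis(pt) + shift)
  } else if (knob %in% c("facility_delivery", "pnc_maternal", "pnc_neonatal")) {
    cs$intercept[cs$service == knob] <- cs$intercept[cs$service == knob] + shift
  } else if (knob == "cfr_scale") {
    ps$conditions$untreated_cfr <- pmin(1, ps$conditions$untreated_cfr * factor)
  } else if (knob == "risk_scale") {
    ps$conditions$baseline_risk <- pmin(1, ps$conditions$baseline_risk * factor)
    ps$conditions$birth_risk <- pmin(1, ps$conditions$birth_risk * factor)
  } else stop("unknown knob: ", knob)
  ps$careseeking <- cs
  ps
}

apply_knobs <- function(ps, factors) {
  for (k in names(factors)) ps <- apply_knob(ps, k, factors[[k]])
  ps
}

#' Tune designated parameters to calibration targets
#'
#' Multiplicative coordinate descent over the declared knob set: each knob's
#' cumulative factor is bounded to \[0.1, 10\] and updated by a step-doubling /
#' step-halving line search, accepting only loss-reducing moves, within an
#' evaluation budget. The simulated statistics come from `simulate_fn(ps,
#' seed)` (by default the coverage simulator) with a fixed seed so the loss
#' surface is deterministic.
#'
#' @param ps base parameter set.
#' @param targets data frame (name, target, tolerance, weight).
#' @param knobs character subset of `CALIBRATION_KNOBS`.
#' @param budget maximum number of loss evaluations (>= 1).
#' @param seed seed passed to the simulator.
#' @param simulate_fn function(ps, seed) -> named statistics.
#' @return list: `parameters` (tuned set), `factors`, `loss`, `trace`
#'   (audit log of evaluations), `evaluations`.
#' @export
tune_parameters <- function(ps, targets = default_calibration_targets(),
                            knobs = c("anc", "facility_delivery",
                                      "pnc_maternal", "pnc_neonatal"),
                            budget = 60, seed = 1L,
                            simulate_fn = coverage_statistics) {
  if (budget < 1) stop("budget must be at least 1")
  bad <- setdiff(knobs, CALIBRATION_KNOBS)
  if (length(bad))
    stop("knob(s) outside the declared tunable set: ",
         paste(bad, collapse = ", "))
  factors <- stats::setNames(rep(1, length(knobs)), knobs)
  evals <- 0L
  trace <- list()
  eval_loss <- function(fac) {
    evals <<- evals + 1L
    l <- calibration_loss(simulate_fn(apply_knobs(ps, fac), seed), targets)
    trace[[length(trace) + 1L]] <<-
      data.frame(evaluation = evals, loss = l,
                 t(as.data.frame(fac)), row.names = NULL)
    l
  }
  best <- eval_loss(factors)
  improved <- TRUE
  while (improved && evals < budget && best > 1e-6) {
    improved <- FALSE
    for (k in knobs) {
      step <- 1.6
      repeat {
        if (evals >= budget) break
        cand_up <- factors; cand_dn <- factors
        cand_up[k] <- min(10, factors[k] * step)
        cand_dn[k] <- max(0.1, factors[k] / step)
        l_up <- eval_loss(cand_up)
        l_dn <- if (evals < budget) eval_loss(cand_dn) else Inf
        if (l_up < best && l_up <= l_dn) {
          factors <- cand_up; best <- l_up; improved <- TRUE
          step <- min(step^2, 4)
        } else if (l_dn < best) {
          factors <- cand_dn; best <- l_dn; improved <- TRUE
          step <- min(step^2, 4)
        } else {
          if (step <= 1.05) break
          step <- sqrt(step)
        }
      }
    }
  }
  list(parameters = apply_knobs(ps, factors), factors = factors, loss = best,
       trace = do.call(rbind, trace), evaluations = evals)
}
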