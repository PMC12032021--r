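# Health system: care-seeking regressions, the ANC contact schedule, the
# quality-of-care model (consumables x competence x EmONC staffing), the
# squeeze factor over healthcare-worker time, and the three-delays logic.

HSI_TYPES <- c("anc_contact", "inpatient_antenatal", "post_abortion_care",
               "delivery_bemonc", "delivery_cemonc", "pnc_maternal",
               "pnc_neonatal", "cemonc_postnatal")

default_overrides <- function() {
  list(quality_max = character(0),      # hsi types with all quality factors pinned to 1
       delivery_prob = c(prophylactic = NA_real_, bemonc = NA_real_,
                         cemonc = NA_real_),
       delay3_disabled = character(0),  # hsi types where delay three is off
       delays12_off = character(0),     # hsi types where delays one/two are off
                                        # ("max." scenarios: care sought at once)
       service_off = character(0),      # hsi types that never occur
       emergency_seek = c(antenatal = NA_real_, postnatal = NA_real_),
       facility_all = FALSE,
       anc_off = FALSE, anc_first_trimester = FALSE,
       anc_transition = NA_real_, anc4_target = NA_real_,
       pnc_target = NA_real_, pnc_max = FALSE, pnc_off = FALSE,
       intercept_shift = c(anc = 0, facility_delivery = 0, pnc_maternal = 0,
                           pnc_neonatal = 0))
}

get_overrides <- function(ps) {
  ov <- ps$overrides
  if (is.null(ov)) default_overrides() else ov
}

inv_logit <- function(x) 1 / (1 + exp(-x))

#' Care-seeking probability from the multivariable regression model
#'
#' Inverse-logit of the linear predictor over centred sociodemographic
#' covariates (wealth quintile, education level, urban residence, parity,
#' age). Any scenario intercept shift for the service is applied.
#'
#' @param service one of `"anc"`, `"facility_delivery"`, `"pnc_maternal"`,
#'   `"pnc_neonatal"`.
#' @param person data frame with columns `wealth`, `edu`, `urban`, `parity`,
#'   `age_years`.
#' @param ps parameter set.
#' @return probability vector in (0,1).
#' @export
careseeking_probability <- function(service, person, ps) {
  cs <- ps$careseeking[ps$careseeking$service == service, ]
  if (!nrow(cs)) stop("unknown care-seeking service: ", service)
  need <- c("wealth", "edu", "urban", "parity", "age_years")
  miss <- setdiff(need, names(person))
  if (length(miss))
    stop("care-seeking covariate(s) missing: ", paste(miss, collapse = ", "))
  shift <- get_overrides(ps)$intercept_shift[[service]]
  lp <- cs$intercept + shift +
    cs$b_wealth * (person$wealth - 3) +
    cs$b_edu * (person$edu - 1) +
    cs$b_urban * as.numeric(person$urban) +
    cs$b_parity * (person$parity - 2) +
    cs$b_age * (person$age_years - 25)
  inv_logit(lp)
}

#' Plan the routine ANC contact schedule for a new pregnancy
#'
#' The first contact's timing is drawn from the configured gestational-month
#' distribution; each subsequent (monthly) contact is attended with the
#' per-transition probability, stopping at the first non-attendance, capped at
#' 8 contacts. The realised schedule is truncated by pregnancy end at
#' simulation time.
#'
#' @param preg rows of the pregnancy table (needs `id` plus the care-seeking
#'   covariates for initiation).
#' @param ps parameter set.
#' @param seed run seed.
#' @return data frame aligned with `preg`: `initiates` (logical),
#'   `first_gm` (gestational month of first contact) and `planned_visits`.
#' @export
plan_anc_schedule <- function(preg, ps, seed) {
  n <- nrow(preg)
  ov <- get_overrides(ps)
  if (ov$anc_off)
    return(data.frame(initiates = rep(FALSE, n), first_gm = rep(NA_real_, n),
                      planned_visits = rep(0L, n)))
  p_init <- careseeking_probability("anc", preg, ps)
  u0 <- hash_unif(seed, preg$id, 0, rng_channels$anc_init)
  initiates <- u0 < p_init
  dist <- ps$anc_first_visit
  if (ov$anc_first_trimester) {
    keep <- dist$gestational_month <= 3
    dist <- data.frame(gestational_month = dist$gestational_month[keep],
                       prob = dist$prob[keep] / sum(dist$prob[keep]))
    initiates <- rep(TRUE, n)
  }
  u1 <- hash_unif(seed, preg$id, 1, rng_channels$anc_first_month)
  first_gm <- dist$gestational_month[1L + findInterval(u1, cumsum(dist$prob))]
  p_trans <- if (!is.na(ov$anc_transition)) ov$anc_transition
             else ps$scalars$anc_transition_prob
  planned <- rep(1L, n)
  cont <- rep(TRUE, n)
  for (k in 1:7) {
    u <- hash_unif(seed, preg$id, k, rng_channels$anc_transition)
    cont <- cont & (u < p_trans)
    planned <- planned + as.integer(cont)
  }
  planned[!initiates] <- 0L
  first_gm[!initiates] <- NA_real_
  data.frame(initiates = initiates, first_gm = first_gm,
             planned_visits = planned)
}

#' Emergency care-seeking decision
#'
#' Bernoulli draw at the configured emergency care-seeking probability;
#' scenario overrides may pin the probability to 0 or 1 per period.
#'
#' @param ids unit ids for the keyed RNG.
#' @param t time index.
#' @param ps parameter set.
#' @param seed run seed.
#' @param period `"antenatal"` or `"postnatal"` (which override pin applies).
#' @return logical vector.
#' @export
emergency_careseeking <- function(ids, t, ps, seed, period = "antenatal") {
  p <- ps$scalars$emergency_careseek_prob
  pin <- get_overrides(ps)$emergency_seek[[period]]
  if (!is.na(pin)) p <- pin
  hash_unif(seed, ids, t, rng_channels$emergency_seek) < p
}

#' Squeeze factor over healthcare-worker time
#'
#' Required HCW time divided by available time for the day, minus one:
#' negative when demand is below availability, 0 at equality, positive under
#' over-demand.
#'
#' @param required_minutes total minutes requested by the event.
#' @param available_minutes minutes remaining in the day's budget (> 0).
#' @return numeric squeeze factor (>= -1).
#' @export
compute_squeeze_factor <- function(required_minutes, available_minutes) {
  if (any(available_minutes <= 0))
    stop("available_minutes must be positive (degenerate budget)")
  required_minutes / available_minutes - 1
}

#' Assess the three delays for a batch of events
#'
#' Delays one and two are fixed-probability Bernoulli draws; delay three
#' occurs iff the squeeze factor strictly exceeds the threshold (boundary
#' equality does not trigger), unless disabled for the event's HSI type by a
#' scenario.
#'
#' @param ids unit ids; `t` time index; `seed` run seed.
#' @param squeeze squeeze factor per event.
#' @param ps parameter set.
#' @param hsi_type HSI type (scalar or vector) for delay-three disabling.
#' @return data frame with logical columns `d1`, `d2`, `d3`.
#' @export
assess_delays <- function(ids, t, squeeze, ps, seed, hsi_type = "delivery_bemonc") {
  sc <- ps$scalars
  ov <- get_overrides(ps)
  d1 <- hash_unif(seed, ids, t, rng_channels$delay1) < sc$delay1_prob
  d2 <- hash_unif(seed, ids, t, rng_channels$delay2) < sc$delay2_prob
  d3 <- squeeze > sc$squeeze_threshold
  d3 <- d3 & !hsi_type %in% ov$delay3_disabled
  off12 <- hsi_type %in% ov$delays12_off
  d1 <- d1 & !off12
  d2 <- d2 & !off12
  data.frame(d1 = d1, d2 = d2, d3 = d3)
}

intervention_row <- function(ps, name) {
  i <- match(name, ps$interventions$name)
  if (is.na(i)) stop("unknown intervention: ", name)
  ps$interventions[i, ]
}

# Scenario-effective probability that one intervention is delivered, before
# the random draw. Returns a list(prob, pinned) where pinned indicates the
# whole quality product was replaced by a scenario value.
delivery_probability <- function(iv, level, ps) {
  ov <- get_overrides(ps)
  if (iv$hsi_type %in% ov$service_off) return(list(prob = 0, pinned = TRUE))
  if (iv$hsi_type %in% ov$quality_max) return(list(prob = 1, pinned = TRUE))
  if (iv$hsi_type %in% c("delivery_bemonc", "delivery_cemonc")) {
    key <- if (iv$class == "preventative") "prophylactic"
           else if (iv$emonc == "CEmONC") "cemonc" else "bemonc"
    p <- ov$delivery_prob[[key]]
    if (!is.na(p)) return(list(prob = p, pinned = TRUE))
  }
  avail <- ps$consumables$availability[ps$consumables$intervention == iv$name]
  p <- prod(avail) * iv$competence_prob
  if (iv$emonc == "BEmONC") p <- p * ps$scalars$bemonc_staffing_prob
  if (iv$emonc == "CEmONC") {
    if (!is.null(level) && length(level) == 1 && level != "hospital")
      return(list(prob = 0, pinned = FALSE))
    p <- p * ps$scalars$cemonc_staffing_prob
  }
  list(prob = p, pinned = FALSE)
}

#' Attempt delivery of an indicated intervention
#'
#' Delivered iff every required consumable's availability draw succeeds, the
#' clinical-competence draw succeeds and - for EmONC-classified interventions -
#' the trained-staffing draw succeeds. Comprehensive EmONC interventions
#' require a hospital. Scenario overrides may pin any service's quality to 1,
#' disable it, or replace the whole product with a fixed delivery probability.
#'
#' @param name intervention name.
#' @param ids unit ids (vectorised over persons).
#' @param t time index.
#' @param ps scenario-effective parameter set.
#' @param seed run seed.
#' @param level facility level (`"health_centre"` or `"hospital"`); `NULL`
#'   skips the level gate.
#' @return logical vector: delivered.
#' @export
attempt_intervention_delivery <- function(name, ids, t, ps, seed,
                                          level = "hospital") {
  iv <- intervention_row(ps, name)
  ividx <- match(name, ps$interventions$name)
  n <- length(ids)
  dp <- delivery_probability(iv, if (length(level) == 1) level else NULL, ps)
  if (dp$pinned) {
    if (dp$prob == 1) return(rep(TRUE, n))
    if (dp$prob == 0) return(rep(FALSE, n))
    return(hash_unif(seed, ids, t, rng_channels$treatment + ividx) < dp$prob)
  }
  ok <- rep(TRUE, n)
  if (length(level) > 1 && iv$emonc == "CEmONC")
    ok <- ok & (level == "hospital")
  else if (length(level) == 1 && iv$emonc == "CEmONC" && level != "hospital")
    return(rep(FALSE, n))
  items <- ps$consumables[ps$consumables$intervention == name, ]
  if (nrow(items)) for (k in seq_len(nrow(items))) {
    u <- hash_unif(seed, ids, t, rng_channels$consumable + ividx * 8L + k)
    ok <- ok & (u < items$availability[k])
  }
  ok <- ok & (hash_unif(seed, ids, t, rng_channels$competence + ividx) <
                iv$competence_prob)
  if (iv$emonc == "BEmONC")
    ok <- ok & (hash_unif(seed, ids, t, rng_channels$staffing + ividx) <
                  ps$scalars$bemonc_staffing_prob)
  if (iv$emonc == "CEmONC")
    ok <- ok & (hash_unif(seed, ids, t, rng_channels$staffing + ividx) <
                  ps$scalars$cemonc_staffing_prob)
  ok
}

# Sequential daily-budget squeeze for a batch of events. Events are processed
# in queue order within each (facility level, day) group against a snapshot
# budget that depletes as earlier events consume minutes; squeeze uses the
# remaining availability at execution time (floored at a small epsilon so an
# exhausted ledger yields a very large squeeze rather than an error).
ledger_squeeze <- function(req, level, day, avail_per_day) {
  n <- length(req)
  squeeze <- numeric(n)
  key <- paste(level, day)
  ord <- order(key)
  cum_prev <- stats::ave(req[ord], key[ord],
                         FUN = function(x) cumsum(x) - x)
  avail0 <- avail_per_day[level[ord]]
  remaining <- pmax(avail0 - cum_prev, 1e-6)
  squeeze[ord] <- req[ord] / remaining - 1
  squeeze
}

#' Execute a batch of health system interaction events
#'
#' Computes each event's squeeze factor against the day's remaining
#' nursing-cadre budget (events deplete the ledger in queue order), assesses
#' the three delays, and attempts every indicated intervention through the
#' quality model. Screening interventions set diagnosis flags; minutes consumed
#' are returned by cadre.
#'
#' @param events data frame with columns `id`, `hsi_type`, `level`, `day`,
#'   and `interventions` (list-column of character vectors of indicated
#'   intervention names).
#' @param ps scenario-effective parameter set.
#' @param seed run seed.
#' @param m month index.
#' @param avail_per_day named vector: available nursing minutes per facility
#'   level per day.
#' @return `events` with added columns `squeeze`, `d1`, `d2`, `d3`,
#'   `nursing_minutes`, `clinician_minutes` and list-column `delivered`.
#' @export
execute_hsi <- function(events, ps, seed, m, avail_per_day) {
  if (!nrow(events)) return(events)
  if (any(!events$hsi_type %in% HSI_TYPES))
    stop("unknown hsi_type: ",
         paste(unique(setdiff(events$hsi_type, HSI_TYPES)), collapse = ", "))
  base_min <- c(anc_contact = ps$scalars$anc_minutes,
                pnc_maternal = ps$scalars$pnc_minutes,
                pnc_neonatal = ps$scalars$pnc_minutes,
                inpatient_antenatal = 30, post_abortion_care = 30,
                delivery_bemonc = 60, delivery_cemonc = 60,
                cemonc_postnatal = 45)
  nursing <- base_min[events$hsi_type]
  clin <- numeric(nrow(events))
  for (i in seq_len(nrow(events))) {
    for (nm in events$interventions[[i]]) {
      iv <- intervention_row(ps, nm)
      if (iv$class == "curative") {
        nursing[i] <- nursing[i] + iv$nursing_minutes
        clin[i] <- clin[i] + iv$clinician_minutes
      }
    }
  }
  events$squeeze <- ledger_squeeze(nursing, events$level, events$day,
                                   avail_per_day)
  dl <- assess_delays(events$id, m, events$squeeze, ps, seed,
                      hsi_type = events$hsi_type)
  events$d1 <- dl$d1; events$d2 <- dl$d2; events$d3 <- dl$d3
  delivered <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    got <- character(0)
    for (nm in events$interventions[[i]]) {
      if (attempt_intervention_delivery(nm, events$id[i], m, ps, seed,
                                        level = events$level[i]))
        got <- c(got, nm)
    }
    delivered[[i]] <- got
  }
  events$delivered <- delivered
  events$nursing_minutes <- unname(nursing)
  events$clinician_minutes <- unname(clin)
  events
}
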